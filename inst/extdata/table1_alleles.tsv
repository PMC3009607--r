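allele	gene	mutation	genetic_interval
L5Jcs1	Tapt1	see ref	see ref
L5Jcs4	Paxip1	see ref	see ref
L5Jcs36	Paxip1	see ref	see ref
L5Jcs5	Tbc1d14	missense in TBC1 domain	M4-J57 (1.6 Mb)
L5Jcs7	Nop14	SA site, exon 3	J36-M268 (600 kb)
L5Jcs14	Nop14	nonsense, exon 3	J36-M268 (600 kb)
L5Jcs11	Tyms	T>A (ASN>LYS)	J63-M176 (1.1 Mb)
L5Jcs37	Rest	C893G (P>R)	NA
Dumbo	Hmx1	see ref	see ref
L5Jcs24	Cad	see ref	M251-M334
L5Jcs27	Cad	see ref	M387-M353
L5Jcs31	Haus3	missense LEU>PRO, exon 4	M388-J88 (1.8 Mb)
L5Jcs32	Fbxl5	missense MET>LYS	M105-J614
L5Jcs8	Ugdh	nonsense	D5Ncnp1-J24 (1.3 Mb)
Ste5Jcs1	Nsun7	see ref	see ref
Deaf5Jcs1	Otof	see ref	see ref
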