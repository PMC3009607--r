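mk_call <- function(pos, sample = "mutant", zygosity = "HET", alt = "T",
                    ref = "A", chrom = "chr5") {
  tibble::tibble(sample = sample, chrom = chrom, pos = pos, ref = ref,
                 alt = alt, zygosity = zygosity)
}

test_that("the four filtering predicates act as documented", {
  region <- interval_from_1based(100, 200)
  ctrl <- mk_call(150, sample = "control_b6")

  kept <- filter_candidates(mk_call(150), list(), region)
  expect_equal(nrow(kept), 1L)

  # same (chrom,pos,alt) in a reference-strain control removes the call
  kept <- filter_candidates(mk_call(150), list(ctrl), region)
  expect_equal(nrow(kept), 0L)
  expect_equal(filter_rejections(kept)$reason, "present_in_control")

  # a HOM_REF control call does not count as presence
  ctrl_ref <- mk_call(150, sample = "control_b6", zygosity = "HOM_REF")
  expect_equal(nrow(filter_candidates(mk_call(150), list(ctrl_ref), region)), 1L)

  # outside the critical region
  kept <- filter_candidates(mk_call(250), list(), region)
  expect_equal(filter_rejections(kept)$reason, "outside_region")

  # homozygous-alt rejected by default, admitted for embryo DNA
  hom <- mk_call(150, zygosity = "HOM_ALT")
  expect_equal(nrow(filter_candidates(hom, list(), region)), 0L)
  expect_equal(nrow(filter_candidates(hom, list(), region, allow_hom_alt = TRUE)), 1L)

  # known catalog
  known <- tibble::tibble(chrom = "chr5", pos = 150, alt = "T")
  kept <- filter_candidates(mk_call(150), list(), region, known)
  expect_equal(filter_rejections(kept)$reason, "known_variant")

  expect_error(filter_candidates(mk_call(150), list(), interval_set()), "non-empty")
  expect_error(
    filter_candidates(mk_call(150), list(mk_call(160, sample = "mutant")), region),
    "distinct"
  )
})

test_that("filtering equals a brute-force four-predicate scan on a planted table", {
  set.seed(606)
  region <- interval_from_1based(1000, 5000)
  n <- 100
  calls <- tibble::tibble(
    sample = "mutant",
    chrom = "chr5",
    pos = sample(1:6000, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    zygosity = sample(c("HET", "HOM_ALT", "HOM_REF"), n, replace = TRUE,
                      prob = c(0.6, 0.2, 0.2))
  )
  calls <- calls[calls$ref != calls$alt, ]
  ctrl <- calls[sample(nrow(calls), 25), ]
  ctrl$sample <- "ctrl"
  known <- calls[sample(nrow(calls), 20), c("chrom", "pos", "alt")]

  kept <- filter_candidates(calls, list(ctrl), region, known)

  # independent scan, predicate by predicate
  in_ctrl <- paste(calls$chrom, calls$pos, calls$alt) %in%
    paste(ctrl$chrom, ctrl$pos, ctrl$alt)
  in_known <- paste(calls$chrom, calls$pos, calls$alt) %in%
    paste(known$chrom, known$pos, known$alt)
  expected <- calls[calls$zygosity == "HET" &
                      calls$pos >= 1000 & calls$pos <= 5000 &
                      !in_ctrl & !in_known, ]
  expected <- expected[order(expected$chrom, expected$pos, expected$ref, expected$alt), ]
  expect_equal(as.data.frame(kept), as.data.frame(expected), ignore_attr = TRUE)

  # idempotence and input-order invariance
  again <- filter_candidates(kept, list(ctrl), region, known)
  expect_equal(as.data.frame(again), as.data.frame(kept), ignore_attr = TRUE)
  shuffled <- calls[sample(nrow(calls)), ]
  expect_equal(as.data.frame(filter_candidates(shuffled, list(ctrl), region, known)),
               as.data.frame(kept), ignore_attr = TRUE)
  # control-list order invariance
  ctrl2 <- ctrl[sample(nrow(ctrl)), ]
  expect_equal(as.data.frame(filter_candidates(calls, list(ctrl2, ctrl), region, known)),
               as.data.frame(filter_candidates(calls, list(ctrl, ctrl2), region, known)),
               ignore_attr = TRUE)
})

test_that("multi-allelic records decompose and malformed records are skipped", {
  region <- interval_from_1based(1, 1000)
  multi <- mk_call(10, alt = "T,G")
  kept <- filter_candidates(multi, list(), region)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$alt, c("T", "G"))

  bad <- dplyr::bind_rows(mk_call(20), mk_call(30, ref = "T", alt = "T"),
                          mk_call(0))
  expect_warning(kept <- filter_candidates(bad, list(), region), "malformed")
  expect_equal(kept$pos, 20)
})

test_that("re-sequenced sites classify as mutation, strain SNP, or artifact", {
  base <- tibble::tibble(chrom = "chr5", pos = 500, alt = "T")
  obs <- function(sample, lineage, present, replicate = 1L) {
    dplyr::bind_cols(tibble::tibble(sample = sample, lineage = lineage,
                                    replicate = replicate, present = present),
                     base)
  }
  # present in a non-mutagenized strain sample
  expect_equal(classify_putative(dplyr::bind_rows(
    obs("mut1", "mutant", TRUE), obs("c3h", "strain", TRUE)
  )), "STRAIN_SNP")
  # unreplicated within the same DNA
  expect_equal(classify_putative(dplyr::bind_rows(
    obs("mut1", "mutant", TRUE, 1L), obs("mut1", "mutant", FALSE, 2L)
  )), "ARTIFACT_SUSPECT")
  # two independent carriers of the pedigree, absent elsewhere
  expect_equal(classify_putative(dplyr::bind_rows(
    obs("carrier1", "mutant", TRUE), obs("carrier2", "mutant", TRUE),
    obs("b6", "strain", FALSE)
  )), "MUTATION")
  # mixed sites are refused
  mixed <- dplyr::bind_rows(obs("mut1", "mutant", TRUE),
                            obs("mut1", "mutant", TRUE))
  mixed$pos[2] <- 501
  expect_error(classify_putative(mixed), "different sites")
})

test_that("planted causative variants survive filtering on simulator output", {
  for (seed in c(21, 22, 23, 24, 25)) {
    cfg <- quick_config(seed = seed)
    vt <- simulate_variant_tables(cfg)
    region <- interval_from_1based(max(1, cfg$true_mutation_pos - 5e5),
                                   cfg$true_mutation_pos + 5e5)
    kept <- filter_candidates(vt$variants$mutant,
                              vt$variants[c("control_reference", "control_carrier")],
                              region, vt$known)
    expect_equal(kept$pos[interval_contains(region, kept$pos)][1],
                 cfg$true_mutation_pos)
    # the causative record itself is always retained
    expect_true(any(kept$pos == cfg$true_mutation_pos & kept$alt == vt$truth$alt))
    # planted confounders never survive: anything kept besides the causative
    # call would have to be a noise variant, which the predicates remove
    others <- kept[kept$pos != cfg$true_mutation_pos, ]
    expect_equal(nrow(others), 0L)
  }
})

test_that("variant calls read identically from the VCF subset and the TSV dialect", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr5>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tmutant\tctrl",
    "chr5\t100\t.\tA\tT\t50\tPASS\t.\tGT\t0/1\t0/0",
    "chr5\t200\t.\tG\tC\t50\tPASS\t.\tGT\t1/1\t0/1",
    "chr5\t300\t.\tT\tA\t50\tPASS\t.\tGT\t./.\t0/1"
  ), vcf)
  v <- read_variant_calls(vcf)
  expect_setequal(unique(v$sample), c("mutant", "ctrl"))
  mut <- v[v$sample == "mutant", ]
  expect_equal(mut$pos, c(100, 200))
  expect_equal(mut$zygosity, c("HET", "HOM_ALT"))
  expect_equal(v$zygosity[v$sample == "ctrl" & v$pos == 100], "HOM_REF")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(v, tsv)
  expect_equal(read_variant_calls(tsv), v)
})
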