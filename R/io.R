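#' Read mapping-panel input tables
#'
#' Tab-separated readers for the small tables the mapping workflow
#' consumes. All genomic positions in these files are 1-based inclusive,
#' the convention of marker maps and genome browsers; conversion to the
#' internal 0-based half-open representation happens inside the interval
#' constructors.
#'
#' * `read_marker_map()`: columns `name`, `pos_bp`; sorted by position on
#'   read.
#' * `read_deletions()`: columns `name`, `complex`, `min_start`,
#'   `min_end`, `max_start`, `max_end`. The minimal extent is DNA known to
#'   be absent; the maximal extent bounds the breakpoint-uncertainty
#'   zones. `complex` (the founding locus of a nested deletion series) is
#'   carried as metadata only.
#' * `read_deletion_tests()`: columns `mutation_id`, `deletion`, `outcome`
#'   (`C` = complements, `F` = fails to complement).
#' * `read_genotypes()`: matrix layout — first column `animal_id`, second
#'   `alive` (1/0), remaining columns one per marker with calls in
#'   `B`/`H`/`C`/`-`.
#' * `read_complementation_results()`: columns `mutation_a`, `mutation_b`,
#'   `outcome` (`C`/`F`/`U`).
#' * `read_known_variants()`: columns `chrom`, `pos`, `alt`, and
#'   optionally `id`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble in the layout described above.
#' @name mapping_io
NULL

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

#' @rdname mapping_io
#' @export
read_marker_map <- function(path) {
  d <- read_tsv_quiet(path, readr::cols(name = "c", pos_bp = "d"))
  d <- dplyr::arrange(d, .data$pos_bp)
  check_markers(d)
  d
}

#' @rdname mapping_io
#' @export
read_deletions <- function(path) {
  d <- read_tsv_quiet(path, readr::cols(
    name = "c", complex = "c", min_start = "d", min_end = "d",
    max_start = "d", max_end = "d"
  ))
  bad <- d$min_start < d$max_start | d$min_end > d$max_end | d$min_start > d$min_end
  if (any(bad)) {
    rlang::abort(paste0("minimal extent must lie within maximal extent for: ",
                        paste(d$name[bad], collapse = ", ")))
  }
  d
}

#' @rdname mapping_io
#' @export
read_deletion_tests <- function(path) {
  d <- read_tsv_quiet(path, readr::cols(mutation_id = "c", deletion = "c",
                                        outcome = "c"))
  d$outcome <- normalize_outcome(d$outcome)
  d
}

#' @rdname mapping_io
#' @export
read_genotypes <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("animal_id", "alive") %in% names(d)[1:2])) {
    rlang::abort("genotype file must start with columns animal_id, alive.")
  }
  d$alive <- d$alive %in% c("1", "TRUE", "true")
  marker_cols <- setdiff(names(d), c("animal_id", "alive"))
  calls <- as.matrix(d[, marker_cols, drop = FALSE])
  bad <- !(calls %in% c("B", "H", "C", "-"))
  if (any(bad)) {
    rlang::abort(sprintf("%d genotype call(s) outside {B,H,C,-}.", sum(bad)))
  }
  d
}

#' @rdname mapping_io
#' @export
read_complementation_results <- function(path) {
  d <- read_tsv_quiet(path, readr::cols(mutation_a = "c", mutation_b = "c",
                                        outcome = "c"))
  normalize_results(d)  # validation only
  d
}

#' @rdname mapping_io
#' @export
read_known_variants <- function(path) {
  read_tsv_quiet(path, readr::cols(chrom = "c", pos = "d", alt = "c",
                                   .default = "c"))
}

#' Read variant calls from a VCF or TSV file
#'
#' For `.vcf` files a minimal VCF 4.x subset is read (CHROM, POS, REF,
#' ALT, and the GT field of each sample) via the vcfR parser; genotypes
#' are collapsed to `HET` / `HOM_ALT` / `HOM_REF`, one output row per
#' sample per record. Any other extension is read as the equivalent TSV
#' dialect with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#' `zygosity`.
#'
#' @param path Path to a `.vcf` (optionally `.vcf.gz`) or TSV file.
#' @return A tibble with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity`.
#' @export
read_variant_calls <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
    gt <- vcfR::extract.gt(v, element = "GT")
    out <- purrr::map_dfr(colnames(gt), function(s) {
      g <- gsub("\\|", "/", gt[, s])
      zyg <- dplyr::case_when(
        is.na(g) ~ NA_character_,
        g %in% c("0/0") ~ "HOM_REF",
        g %in% c("0/1", "1/0") ~ "HET",
        g %in% c("1/1") ~ "HOM_ALT",
        TRUE ~ NA_character_
      )
      tibble::tibble(sample = s, chrom = fix$CHROM, pos = as.numeric(fix$POS),
                     ref = fix$REF, alt = fix$ALT, zygosity = zyg)
    })
    out[!is.na(out$zygosity), , drop = FALSE]
  } else {
    read_tsv_quiet(path, readr::cols(sample = "c", chrom = "c", pos = "d",
                                     ref = "c", alt = "c", zygosity = "c"))
  }
}

#' Write a genotype table in the TSV matrix dialect
#'
#' @param genotypes Genotype tibble (`animal_id`, `alive`, marker
#'   columns).
#' @param path Output path.
#' @return `genotypes`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  out <- genotypes
  out$alive <- as.integer(out$alive)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(genotypes)
}
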