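#' Filter called variants to candidate causative mutations
#'
#' Reduces a mutant sample's variant calls to candidates for the induced
#' lesion by four predicates, mirroring capture-sequencing practice where
#' the mutant library is filtered against reference-strain and unrelated
#' carrier libraries:
#'
#' 1. zygosity — `HET` by default (carrier DNA from an m/+ animal); set
#'    `allow_hom_alt = TRUE` when homozygous mutant embryo DNA was
#'    sequenced;
#' 2. position inside the mutation's critical region;
#' 3. absent (or called homozygous-reference) at the same
#'    `(chrom, pos, alt)` in every control sample;
#' 4. not present in the known-variant catalog (e.g. dbSNP).
#'
#' Multi-allelic records are decomposed into one record per alternate
#' allele before filtering. Malformed records (`ref == alt`, `pos < 1`,
#' missing fields) are skipped with a warning. Every rejected record is
#' logged with its first failing criterion; retrieve the log with
#' [filter_rejections()].
#'
#' @param mutant Tibble of the mutant sample's calls with columns `sample`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `zygosity`
#'   (`HET`/`HOM_ALT`/`HOM_REF`).
#' @param controls A control call tibble or list of them (reference strain,
#'   unrelated carriers).
#' @param critical Non-empty interval set for the mutation's critical
#'   region.
#' @param known Known-variant catalog tibble with columns `chrom`, `pos`,
#'   `alt` (`NULL` for none).
#' @param allow_hom_alt Also retain `HOM_ALT` mutant calls?
#' @return The retained calls, sorted by position, with the rejection log
#'   attached as attribute `"rejections"`.
#' @export
filter_candidates <- function(mutant, controls = list(), critical, known = NULL,
                              allow_hom_alt = FALSE) {
  iv_check(critical, "critical")
  if (nrow(critical) == 0L) rlang::abort("`critical` region must be non-empty.")
  if (is.data.frame(controls)) controls <- list(controls)
  mutant <- validate_calls(mutant, "mutant")
  controls <- lapply(controls, validate_calls, what = "control")
  ctrl_ids <- unlist(lapply(controls, function(x) unique(x$sample)))
  if (any(unique(mutant$sample) %in% ctrl_ids)) {
    rlang::abort("mutant sample id must be distinct from all control sample ids.")
  }

  wanted_zyg <- if (allow_hom_alt) c("HET", "HOM_ALT") else "HET"
  control_keys <- unique(unlist(lapply(controls, function(x) {
    x <- x[x$zygosity != "HOM_REF", , drop = FALSE]
    variant_key(x)
  })))
  known_keys <- if (is.null(known) || nrow(known) == 0L) character() else
    unique(paste(known$chrom, known$pos, known$alt, sep = "\r"))

  keys <- variant_key(mutant)
  reason <- rep(NA_character_, nrow(mutant))
  reason[!(mutant$zygosity %in% wanted_zyg)] <- "zygosity"
  in_region <- interval_contains(critical, mutant$pos) &
    mutant$chrom == iv_chrom(critical)
  reason[is.na(reason) & !in_region] <- "outside_region"
  reason[is.na(reason) & keys %in% control_keys] <- "present_in_control"
  reason[is.na(reason) & keys %in% known_keys] <- "known_variant"

  kept <- mutant[is.na(reason), , drop = FALSE]
  kept <- kept[order(kept$chrom, kept$pos, kept$ref, kept$alt), , drop = FALSE]
  rejections <- mutant[!is.na(reason), , drop = FALSE]
  rejections$reason <- reason[!is.na(reason)]
  attr(kept, "rejections") <- tibble::as_tibble(rejections)
  tibble::new_tibble(kept, rejections = attr(kept, "rejections"),
                     class = "candidate_calls")
}

#' @rdname filter_candidates
#' @param x Output of [filter_candidates()].
#' @export
filter_rejections <- function(x) {
  attr(x, "rejections") %||% tibble::tibble()
}

variant_key <- function(x) paste(x$chrom, x$pos, x$alt, sep = "\r")

validate_calls <- function(calls, what = "variant") {
  need <- c("sample", "chrom", "pos", "ref", "alt", "zygosity")
  if (!is.data.frame(calls) || !all(need %in% names(calls))) {
    rlang::abort(paste0("`", what, "` calls must have columns: ", paste(need, collapse = ", ")))
  }
  calls <- tibble::as_tibble(calls)[, need]
  # decompose multi-allelic records (comma-separated ALT)
  calls <- tidyr::separate_longer_delim(calls, "alt", delim = ",")
  bad <- is.na(calls$pos) | calls$pos < 1 | is.na(calls$alt) | is.na(calls$ref) |
    calls$ref == calls$alt | !(calls$zygosity %in% c("HET", "HOM_ALT", "HOM_REF"))
  if (any(bad)) {
    rlang::warn(sprintf("skipping %d malformed %s record(s).", sum(bad), what))
    calls <- calls[!bad, , drop = FALSE]
  }
  calls
}

#' Classify a re-sequenced site as mutation, strain SNP, or artifact
#'
#' When a candidate nucleotide difference is re-sequenced across samples,
#' three explanations compete: an induced mutation, a pre-existing strain
#' polymorphism, or a sequencing/database artifact. The triage rules are:
#'
#' * present in any non-mutagenized strain sample -> `STRAIN_SNP`;
#' * present in one replicate of a sample but absent in a repeat of the
#'   same DNA -> `ARTIFACT_SUSPECT`;
#' * otherwise, present only in mutant-lineage samples -> `MUTATION`.
#'
#' @param site_calls Tibble of re-sequencing observations at a single site:
#'   columns `sample`, `lineage` (`"mutant"` or `"strain"`), `replicate`
#'   (integer), `present` (logical), plus `chrom`, `pos`, `alt` identifying
#'   the site (must be constant across rows).
#' @return One of `"MUTATION"`, `"STRAIN_SNP"`, `"ARTIFACT_SUSPECT"`.
#' @export
classify_putative <- function(site_calls) {
  need <- c("sample", "lineage", "present")
  if (!is.data.frame(site_calls) || nrow(site_calls) == 0L ||
      !all(need %in% names(site_calls))) {
    rlang::abort("`site_calls` must be a non-empty tibble with sample, lineage, present.")
  }
  site_cols <- intersect(c("chrom", "pos", "alt"), names(site_calls))
  if (length(site_cols)) {
    n_sites <- nrow(unique(site_calls[, site_cols, drop = FALSE]))
    if (n_sites > 1L) rlang::abort("`site_calls` mixes observations from different sites.")
  }
  if (!all(site_calls$lineage %in% c("mutant", "strain"))) {
    rlang::abort('`lineage` must be "mutant" or "strain".')
  }
  if (any(site_calls$present & site_calls$lineage == "strain")) return("STRAIN_SNP")
  per_sample <- tapply(site_calls$present, site_calls$sample,
                       function(p) length(unique(p)) > 1L)
  if (any(per_sample)) return("ARTIFACT_SUSPECT")
  "MUTATION"
}
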