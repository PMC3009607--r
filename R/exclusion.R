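#' Apply one deletion-complementation test to a candidate region
#'
#' A deletion carries two extents: the minimal extent (DNA known to be
#' absent, the solid rectangle in a deletion map) and the maximal extent
#' (the outer bounds within which the uncertain breakpoints reside). The
#' logic is conservative in both directions:
#'
#' * `FAILS` (non-complementation): the mutation must lie in DNA that could
#'   be removed, so the candidate is intersected with the maximal extent.
#' * `COMPLEMENTS`: the mutation cannot lie in DNA known to be absent, so
#'   the minimal extent is subtracted. Breakpoint-uncertainty zones are
#'   retained.
#'
#' @param candidate Non-empty interval set for the mutation's current
#'   candidate region.
#' @param deletion One-row tibble (or list) with fields `name`, `min_start`,
#'   `min_end`, `max_start`, `max_end` (1-based inclusive; see
#'   [read_deletions()]).
#' @param outcome `"FAILS"` or `"COMPLEMENTS"` (also accepts `"F"`/`"C"`).
#' @param chrom Chromosome label for the deletion extents.
#' @return The reduced candidate interval set (always a subset of
#'   `candidate`).
#' @export
apply_deletion_test <- function(candidate, deletion, outcome, chrom = "chr5") {
  iv_check(candidate, "candidate")
  if (nrow(candidate) == 0L) rlang::abort("`candidate` region must be non-empty.")
  outcome <- normalize_outcome(outcome)
  if (!(deletion$min_start >= deletion$max_start && deletion$min_end <= deletion$max_end)) {
    rlang::abort(paste0("deletion ", deletion$name,
                        ": minimal extent must lie within maximal extent."))
  }
  if (outcome == "FAILS") {
    max_iv <- interval_from_1based(deletion$max_start, deletion$max_end, chrom = chrom)
    out <- interval_intersect(candidate, max_iv)
    if (nrow(out) == 0L) {
      rlang::abort(paste0(
        "inconsistent evidence: non-complementation by deletion ", deletion$name,
        " leaves no candidate region."
      ))
    }
    out
  } else {
    min_iv <- interval_from_1based(deletion$min_start, deletion$min_end, chrom = chrom)
    interval_subtract(candidate, min_iv)
  }
}

normalize_outcome <- function(outcome) {
  out <- toupper(as.character(outcome))
  out[out == "F"] <- "FAILS"
  out[out == "C"] <- "COMPLEMENTS"
  bad <- setdiff(out, c("FAILS", "COMPLEMENTS"))
  if (length(bad)) {
    rlang::abort(paste0("deletion-test outcome must be COMPLEMENTS/FAILS (C/F), got: ",
                        paste(bad, collapse = ", ")))
  }
  out
}

#' Spans of homozygous-B6 genotype in one animal
#'
#' In an F2 intercross segregating a recessive lethal on the B6 haplotype,
#' a live animal cannot be B6/B6 at the mutation itself, so every region it
#' is proven B6/B6 over can be excluded. The proof is deliberately
#' conservative: for each maximal run of consecutive `B` calls the excluded
#' span reaches only from the first to the last marker of the run (closed,
#' 1-based), never into flanking intervals where the crossover position is
#' unknown. A single-marker run excludes a 1-bp span at that marker, and
#' `MISSING` calls are uninformative and break runs.
#'
#' @param calls Character vector of genotype calls aligned to `markers`,
#'   coded `"B"` (B6/B6), `"H"` (het), `"C"` (Cast/Cast), `"-"` (missing).
#' @param markers Tibble with columns `name` and `pos_bp` (1-based),
#'   sorted by position.
#' @param chrom Chromosome label.
#' @return An interval set of excluded spans (empty if no `B` call).
#' @export
homozygous_b6_spans <- function(calls, markers, chrom = "chr5") {
  check_markers(markers)
  if (length(calls) != nrow(markers)) {
    rlang::abort(sprintf("calls (%d) and markers (%d) must align one-to-one.",
                         length(calls), nrow(markers)))
  }
  is_b <- calls == "B"
  if (!any(is_b)) return(interval_set(chrom = chrom))
  r <- rle(is_b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  interval_from_1based(markers$pos_bp[starts[keep]],
                       markers$pos_bp[ends[keep]],
                       chrom = chrom)
}

check_markers <- function(markers) {
  if (!is.data.frame(markers) || !all(c("name", "pos_bp") %in% names(markers))) {
    rlang::abort("`markers` must be a tibble with columns name, pos_bp.")
  }
  if (is.unsorted(markers$pos_bp, strictly = TRUE)) {
    rlang::abort("marker positions must be unique and sorted ascending.")
  }
  invisible(markers)
}

#' Pooled recombination exclusions from an F2 genotype table
#'
#' Unions the [homozygous_b6_spans()] of every live animal. Dead or
#' unknown-viability animals contribute nothing: only survival certifies
#' that the animal is not homozygous for the lethal.
#'
#' @param genotypes Tibble with columns `animal_id`, `alive` (logical), and
#'   one column per marker named as in `markers$name`, holding calls in
#'   `B`/`H`/`C`/`-` (see [read_genotypes()]).
#' @param markers Marker map tibble (`name`, `pos_bp`).
#' @param chrom Chromosome label.
#' @return An interval set: the union of all proven-B6/B6 spans.
#' @export
recombination_exclusions <- function(genotypes, markers, chrom = "chr5") {
  check_markers(markers)
  if (nrow(genotypes) == 0L) {
    rlang::warn("empty genotype table: no recombination exclusions derived.")
    return(interval_set(chrom = chrom))
  }
  missing_cols <- setdiff(markers$name, names(genotypes))
  if (length(missing_cols)) {
    rlang::abort(paste0("genotype table lacks marker columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  live <- genotypes[which(genotypes$alive), , drop = FALSE]
  if (nrow(live) == 0L) return(interval_set(chrom = chrom))
  call_mat <- as.matrix(live[, markers$name, drop = FALSE])
  # collect every animal's B6/B6 run spans, then normalize once: the
  # interval_set constructor merges them, which is exactly the union
  all_s <- vector("list", nrow(call_mat))
  all_e <- vector("list", nrow(call_mat))
  for (i in seq_len(nrow(call_mat))) {
    is_b <- call_mat[i, ] == "B"
    if (!any(is_b)) next
    r <- rle(is_b)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    all_s[[i]] <- markers$pos_bp[starts[r$values]]
    all_e[[i]] <- markers$pos_bp[ends[r$values]]
  }
  s <- unlist(all_s)
  if (is.null(s) || !length(s)) return(interval_set(chrom = chrom))
  interval_from_1based(s, unlist(all_e), chrom = chrom)
}

#' Infer a mutation's critical region by interval exclusion
#'
#' Folds deletion-complementation outcomes ([apply_deletion_test()]) and F2
#' recombination exclusions ([recombination_exclusions()]) over an initial
#' search region, recording every step in a replayable evidence log. Both
#' evidence sources only ever remove territory, so the critical region
#' shrinks monotonically and the final result is independent of the order
#' in which evidence is applied.
#'
#' @param initial Interval set for the initial search region (typically the
#'   balancer footprint).
#' @param deletion_tests Tibble with columns `mutation_id`, `deletion`,
#'   `outcome` (`C`/`F`), or `NULL`.
#' @param deletions Deletion catalog tibble (`name`, `min_start`, `min_end`,
#'   `max_start`, `max_end`; 1-based inclusive), or `NULL`.
#' @param genotypes,markers F2 genotype table and marker map, or `NULL`.
#' @param mutation_id Identifier of the mutation being mapped; when
#'   `deletion_tests` covers several mutations, only its rows are used.
#' @return A `critical_region` object: list with `mutation_id`, `region`
#'   (interval set), `initial`, and `evidence` (one row per step with the
#'   source, action, and region width before/after). Supports [tidy()],
#'   [glance()], `print()`, and [ggplot2::autoplot()].
#' @examples
#' region <- interval_from_1based(1, 60.9e6)
#' map_mutation(region, mutation_id = "L5JcsX")  # no evidence: region unchanged
#' @export
map_mutation <- function(initial, deletion_tests = NULL, deletions = NULL,
                         genotypes = NULL, markers = NULL,
                         mutation_id = "mutation") {
  iv_check(initial, "initial")
  if (nrow(initial) == 0L) rlang::abort("`initial` search region must be non-empty.")
  region <- initial
  log <- list()
  note <- function(source, action, before, after) {
    tibble::tibble(
      step = length(log) + 1L, source = source, action = action,
      width_before_bp = interval_width_bp(before),
      width_after_bp = interval_width_bp(after),
      region = list(after)
    )
  }

  if (!is.null(deletion_tests) && nrow(deletion_tests) > 0L) {
    if (is.null(deletions)) rlang::abort("`deletions` catalog required when tests are given.")
    tests <- deletion_tests
    if ("mutation_id" %in% names(tests)) {
      tests <- tests[tests$mutation_id == mutation_id | is.na(tests$mutation_id), , drop = FALSE]
    }
    for (i in seq_len(nrow(tests))) {
      dn <- tests$deletion[i]
      del <- deletions[deletions$name == dn, , drop = FALSE]
      if (nrow(del) != 1L) rlang::abort(paste0("deletion not in catalog: ", dn))
      outcome <- normalize_outcome(tests$outcome[i])
      before <- region
      region <- apply_deletion_test(region, del, outcome, chrom = iv_chrom(initial))
      log[[length(log) + 1L]] <- note(
        paste0("deletion:", dn),
        if (outcome == "FAILS") "intersect_max_extent" else "subtract_min_extent",
        before, region
      )
    }
  }

  if (!is.null(genotypes)) {
    if (is.null(markers)) rlang::abort("`markers` map required with a genotype table.")
    excl <- recombination_exclusions(genotypes, markers, chrom = iv_chrom(initial))
    before <- region
    region <- interval_subtract(region, excl)
    log[[length(log) + 1L]] <- note("recombination", "subtract_b6_spans", before, region)
  }

  evidence <- if (length(log)) dplyr::bind_rows(log) else
    tibble::tibble(step = integer(), source = character(), action = character(),
                   width_before_bp = numeric(), width_after_bp = numeric(),
                   region = list())

  if (nrow(region) == 0L) {
    rlang::abort(c(
      paste0("inconsistent evidence: all of the initial region is excluded for ", mutation_id, "."),
      i = paste0("evidence replay: ",
                 paste(sprintf("%s[%s: %.0f -> %.0f bp]", evidence$source, evidence$action,
                               evidence$width_before_bp, evidence$width_after_bp),
                       collapse = "; "))
    ))
  }

  structure(
    list(mutation_id = mutation_id, region = region,
         initial = initial, evidence = evidence),
    class = "critical_region"
  )
}

#' @export
print.critical_region <- function(x, ...) {
  cat("Critical region for", x$mutation_id, "\n")
  shown <- interval_to_1based(x$region)
  cat(sprintf("  %d interval(s), %.0f bp (%d kb) remaining of %.0f bp initial\n",
              nrow(x$region), interval_width_bp(x$region),
              interval_width_kb(x$region), interval_width_bp(x$initial)))
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("  %s:%s-%s (1-based, %s bp)\n", shown$chrom[i],
                format(shown$start_1based[i], big.mark = ",", scientific = FALSE),
                format(shown$end_1based[i], big.mark = ",", scientific = FALSE),
                format(shown$width_bp[i], big.mark = ",", scientific = FALSE)))
  }
  cat(sprintf("  evidence: %d step(s)\n", nrow(x$evidence)))
  invisible(x)
}

#' Tidy a critical region into per-interval rows
#'
#' @param x A `critical_region` from [map_mutation()].
#' @param ... Unused.
#' @return A tibble with one row per surviving interval: `mutation_id`,
#'   `chrom`, 1-based `start`/`end`, and `width_bp`.
#' @exportS3Method generics::tidy
tidy.critical_region <- function(x, ...) {
  shown <- interval_to_1based(x$region)
  tibble::tibble(
    mutation_id = x$mutation_id,
    chrom = shown$chrom,
    start = shown$start_1based,
    end = shown$end_1based,
    width_bp = shown$width_bp
  )
}

#' One-row summary of a critical region
#'
#' @inheritParams tidy.critical_region
#' @return A one-row tibble: interval count, total width in bp and kb,
#'   number of evidence steps, and fraction of the initial region excluded.
#' @exportS3Method generics::glance
glance.critical_region <- function(x, ...) {
  tibble::tibble(
    mutation_id = x$mutation_id,
    n_intervals = nrow(x$region),
    width_bp = interval_width_bp(x$region),
    width_kb = interval_width_kb(x$region),
    n_evidence_steps = nrow(x$evidence),
    fraction_excluded = 1 - interval_width_bp(x$region) / interval_width_bp(x$initial)
  )
}

#' Export a critical region as BED3 plus a JSON evidence log
#'
#' @param x A `critical_region`.
#' @param bed_path,json_path Output file paths (either may be `NULL` to
#'   skip).
#' @return `x`, invisibly.
#' @export
write_critical_region <- function(x, bed_path = NULL, json_path = NULL) {
  if (!inherits(x, "critical_region")) rlang::abort("`x` must be a critical_region.")
  if (!is.null(bed_path)) write_bed3(x$region, bed_path)
  if (!is.null(json_path)) {
    ev <- x$evidence
    payload <- list(
      mutation_id = x$mutation_id,
      region_1based = interval_to_1based(x$region),
      evidence = lapply(seq_len(nrow(ev)), function(i) list(
        step = ev$step[i], source = ev$source[i], action = ev$action[i],
        width_before_bp = ev$width_before_bp[i],
        width_after_bp = ev$width_after_bp[i],
        region_1based = interval_to_1based(ev$region[[i]])
      ))
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
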