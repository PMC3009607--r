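#' Construct a normalized genomic interval set
#'
#' An interval set is the currency of all mapping logic in rwmapkit: an
#' ordered tibble of pairwise-disjoint, non-adjacent spans on a single
#' chromosome, held internally in 0-based half-open coordinates
#' (`[start, end)`, width = `end - start`). Overlapping or touching input
#' intervals are merged and the result is sorted by start, so equal sets
#' have identical representations.
#'
#' @param start,end Numeric vectors of equal length; 0-based half-open
#'   coordinates with `start < end` and `start >= 0`.
#' @param chrom Chromosome label carried for format fidelity (all loci in the
#'   Rw screen are on chromosome 5); a single string.
#' @return A tibble with columns `chrom`, `start`, `end`, normalized as
#'   described above. Zero rows represent the empty set.
#' @examples
#' interval_set(c(0, 10), c(10, 20))   # adjacent spans merge to [0, 20)
#' interval_set(numeric(), numeric())  # the empty set
#' @export
interval_set <- function(start = numeric(), end = numeric(), chrom = "chr5") {
  if (length(start) != length(end)) {
    rlang::abort("`start` and `end` must have the same length.")
  }
  if (length(start) == 0L) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (anyNA(start) || anyNA(end)) rlang::abort("interval coordinates must not be NA.")
  if (any(start < 0)) rlang::abort("interval `start` must be >= 0.")
  if (any(start >= end)) {
    rlang::abort("every interval must satisfy start < end (empty intervals are represented by absence).")
  }
  if (length(chrom) != 1L) rlang::abort("`chrom` must be a single chromosome label.")
  r <- IRanges::reduce(iv_to_iranges_coords(start, end))
  tibble::tibble(
    chrom = chrom,
    start = as.numeric(IRanges::start(r)) - 1,
    end   = as.numeric(IRanges::end(r))
  )
}

#' Convert 1-based inclusive coordinates to an interval set
#'
#' All positions printed in genome browsers and marker tables are 1-based
#' inclusive; this converts at the boundary (`[s, e]` 1-based becomes
#' `[s - 1, e)` 0-based half-open).
#'
#' @param start,end 1-based inclusive endpoints (`start <= end`, `start >= 1`).
#' @inheritParams interval_set
#' @return An interval set tibble (see [interval_set()]).
#' @export
interval_from_1based <- function(start, end, chrom = "chr5") {
  if (any(start < 1)) rlang::abort("1-based `start` must be >= 1.")
  interval_set(start - 1, end, chrom = chrom)
}

# internal: interval-set tibble <-> IRanges (IRanges is 1-based closed)
iv_to_iranges_coords <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

iv_to_iranges <- function(x) iv_to_iranges_coords(x$start, x$end)

iv_from_iranges <- function(r, chrom) {
  if (length(r) == 0L) return(interval_set())
  tibble::tibble(
    chrom = chrom,
    start = as.numeric(IRanges::start(r)) - 1,
    end   = as.numeric(IRanges::end(r))
  )
}

iv_chrom <- function(...) {
  ch <- unique(unlist(lapply(list(...), function(x) x$chrom)))
  if (length(ch) > 1L) {
    rlang::abort(paste0(
      "interval sets are on different chromosomes: ",
      paste(ch, collapse = ", ")
    ))
  }
  if (length(ch) == 0L) "chr5" else ch
}

iv_check <- function(x, arg = "x") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    rlang::abort(paste0("`", arg, "` must be an interval-set tibble with chrom/start/end columns."))
  }
  invisible(x)
}

#' Interval-set algebra: union, intersection, difference
#'
#' Exact set operations on interval sets sharing one chromosome. A point `p`
#' belongs to `interval_union(a, b)` iff it belongs to `a` or `b`; to
#' `interval_intersect(a, b)` iff it belongs to both; to
#' `interval_subtract(a, b)` iff it belongs to `a` but not `b`. Results are
#' normalized (disjoint, sorted, adjacent spans merged). Subtraction is the
#' workhorse of exclusion mapping: regions shown to harbor B6/B6
#' homozygosity in live offspring, or known to be absent in a complementing
#' deletion, are subtracted from a mutation's candidate region.
#'
#' @param a,b Interval sets (see [interval_set()]) on the same chromosome.
#' @return A normalized interval-set tibble.
#' @examples
#' a <- interval_set(0, 100)
#' interval_subtract(a, interval_set(40, 60))  # splits into [0,40) and [60,100)
#' @export
interval_union <- function(a, b) {
  iv_check(a, "a"); iv_check(b, "b")
  ch <- iv_chrom(a, b)
  iv_from_iranges(IRanges::reduce(c(iv_to_iranges(a), iv_to_iranges(b))), ch)
}

#' @rdname interval_union
#' @export
interval_intersect <- function(a, b) {
  iv_check(a, "a"); iv_check(b, "b")
  ch <- iv_chrom(a, b)
  iv_from_iranges(IRanges::intersect(iv_to_iranges(a), iv_to_iranges(b)), ch)
}

#' @rdname interval_union
#' @export
interval_subtract <- function(a, b) {
  iv_check(a, "a"); iv_check(b, "b")
  ch <- iv_chrom(a, b)
  if (nrow(a) == 0L) return(interval_set(chrom = ch))
  iv_from_iranges(IRanges::setdiff(iv_to_iranges(a), iv_to_iranges(b)), ch)
}

#' Total length of an interval set
#'
#' `interval_width_bp()` returns the summed widths in base pairs;
#' `interval_width_kb()` reports kilobases rounded half away from zero, the
#' convention under which the L5Jcs13 critical region (288,969 bp between
#' rs13478279 and rs13478280) prints as 289 kb.
#'
#' @param x An interval set.
#' @return A single number.
#' @export
interval_width_bp <- function(x) {
  iv_check(x)
  sum(x$end - x$start)
}

#' @rdname interval_width_bp
#' @export
interval_width_kb <- function(x) {
  round_half_up(interval_width_bp(x) / 1000)
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Test whether 1-based positions fall inside an interval set
#'
#' @param x An interval set.
#' @param pos Vector of 1-based base-pair positions.
#' @return Logical vector, one element per position.
#' @export
interval_contains <- function(x, pos) {
  iv_check(x)
  if (nrow(x) == 0L) return(rep(FALSE, length(pos)))
  p0 <- pos - 1
  vapply(p0, function(p) any(x$start <= p & p < x$end), logical(1))
}

#' Read and write interval sets as BED3
#'
#' BED3 is tab-separated `chrom start end` with 0-based half-open
#' coordinates, matching the internal representation exactly.
#'
#' @param path File path.
#' @param x Interval set to write.
#' @return `read_bed3()` returns an interval-set tibble; `write_bed3()`
#'   returns `x` invisibly.
#' @export
read_bed3 <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end"),
                         colClasses = c("character", "numeric", "numeric"))
  if (nrow(d) == 0L) return(interval_set())
  interval_set(d$start, d$end, chrom = unique(d$chrom))
}

#' @rdname read_bed3
#' @export
write_bed3 <- function(x, path) {
  iv_check(x)
  utils::write.table(x[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Display an interval set in 1-based inclusive coordinates
#'
#' Converts the internal 0-based half-open spans to the 1-based inclusive
#' convention used in the mapping literature and marker tables.
#'
#' @param x An interval set.
#' @return A tibble with columns `chrom`, `start_1based`, `end_1based`,
#'   `width_bp`.
#' @export
interval_to_1based <- function(x) {
  iv_check(x)
  tibble::tibble(
    chrom = x$chrom,
    start_1based = x$start + 1,
    end_1based = x$end,
    width_bp = x$end - x$start
  )
}
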