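#' Number of potential pairwise complementation tests
#'
#' For a collection of `n` recessive mutations, every pair is a potential
#' complementation cross. The default counts ordered pairs, `n(n - 1)`,
#' the accounting used when either carrier can serve as sire or dam
#' (37 mutations give 37 x 36 = 1332); `ordered = FALSE` counts each
#' unordered pair once, `n(n - 1) / 2`.
#'
#' @param n Number of mutations (non-negative integer).
#' @param ordered Count ordered pairs? Default `TRUE`.
#' @return A single count.
#' @examples
#' count_potential_tests(37)                  # 1332
#' count_potential_tests(6, ordered = FALSE)  # 15
#' @export
count_potential_tests <- function(n, ordered = TRUE) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    rlang::abort("`n` must be a single non-negative integer.")
  }
  if (ordered) n * (n - 1) else n * (n - 1) / 2
}

#' Triage pairwise complementation tests by map overlap
#'
#' Mutations mapped to non-overlapping intervals cannot be alleles (unless
#' a gene spans adjacent genetic intervals), so breeding tests are only
#' needed for co-localizing pairs. Every unordered pair of mapped mutations
#' is classified as one of:
#'
#' * `DISJOINT_INFERRED_COMPLEMENT` — regions disjoint; allelism excluded
#'   without a cross. A recorded `FAIL` for such a pair contradicts the
#'   mapping and raises an error rather than being silently resolved.
#' * `OVERLAP_FAIL`, `OVERLAP_COMPLEMENT` — overlapping regions with a
#'   recorded test outcome.
#' * `OVERLAP_UNTESTED` — overlapping regions, cross still needed.
#'
#' @param regions Tibble with columns `mutation_id` and `region` (a
#'   list-column of interval sets, e.g. `map_mutation(...)$region`).
#' @param results Optional tibble of recorded outcomes with columns
#'   `mutation_a`, `mutation_b`, `outcome` in
#'   `COMPLEMENT`/`FAIL`/`UNTESTED` (or `C`/`F`/`U`). Pairs are unordered.
#' @return A tibble with one row per unordered pair: `mutation_a`,
#'   `mutation_b` (sorted within pair), `overlap_bp`, `recorded`, and
#'   `category`.
#' @export
plan_tests <- function(regions, results = NULL) {
  if (!is.data.frame(regions) || !all(c("mutation_id", "region") %in% names(regions))) {
    rlang::abort("`regions` must have columns mutation_id and region (list of interval sets).")
  }
  if (anyDuplicated(regions$mutation_id)) {
    rlang::abort("one region per mutation: duplicated mutation_id in `regions`.")
  }
  ids <- as.character(regions$mutation_id)
  if (length(ids) < 2L) {
    return(tibble::tibble(mutation_a = character(), mutation_b = character(),
                          overlap_bp = numeric(), recorded = character(),
                          category = character()))
  }
  lookup <- stats::setNames(regions$region, ids)
  rec <- normalize_results(results)

  pairs <- utils::combn(sort(ids), 2L)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    ov <- interval_width_bp(interval_intersect(lookup[[a]], lookup[[b]]))
    key <- paste(sort(c(a, b)), collapse = "\r")
    recorded <- rec$outcome[match(key, rec$key)]
    if (is.na(recorded)) recorded <- "UNTESTED"
    if (ov == 0) {
      if (recorded == "FAIL") {
        rlang::abort(paste0(
          "contradiction: ", a, " and ", b, " map to disjoint intervals but failed to ",
          "complement; check the mapping or the cross (a gene spanning adjacent ",
          "intervals would also produce this)."
        ))
      }
      category <- "DISJOINT_INFERRED_COMPLEMENT"
    } else {
      category <- switch(recorded,
        FAIL = "OVERLAP_FAIL",
        COMPLEMENT = "OVERLAP_COMPLEMENT",
        UNTESTED = "OVERLAP_UNTESTED"
      )
    }
    tibble::tibble(mutation_a = a, mutation_b = b, overlap_bp = ov,
                   recorded = recorded, category = category)
  })
  out
}

normalize_results <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    return(tibble::tibble(key = character(), outcome = character()))
  }
  need <- c("mutation_a", "mutation_b", "outcome")
  if (!all(need %in% names(results))) {
    rlang::abort("`results` must have columns mutation_a, mutation_b, outcome.")
  }
  out <- toupper(as.character(results$outcome))
  out[out == "C"] <- "COMPLEMENT"
  out[out == "F"] <- "FAIL"
  out[out == "U"] <- "UNTESTED"
  bad <- setdiff(out, c("COMPLEMENT", "FAIL", "UNTESTED"))
  if (length(bad)) {
    rlang::abort(paste0("complementation outcome must be COMPLEMENT/FAIL/UNTESTED (C/F/U), got: ",
                        paste(unique(bad), collapse = ", ")))
  }
  if (any(results$mutation_a == results$mutation_b)) {
    rlang::abort("a mutation cannot be complementation-tested against itself.")
  }
  key <- purrr::map2_chr(as.character(results$mutation_a), as.character(results$mutation_b),
                         ~ paste(sort(c(.x, .y)), collapse = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    contradictory <- tapply(out, key, function(o) length(unique(o)) > 1L)
    if (any(contradictory)) {
      rlang::abort("the same pair is recorded with conflicting outcomes.")
    }
  }
  tibble::tibble(key = key[!dup], outcome = out[!dup])
}

#' Group mutations into allelic classes from failed complementation
#'
#' Failure to complement is evidence of allelism; the allelic classes are
#' the connected components of the graph whose edges are `FAIL` results
#' (transitive closure, computed by union-find). Mutations with no `FAIL`
#' edge are singletons. In the Rw-region screen this identified four
#' two-member classes among the lethal collection.
#'
#' @param results Tibble of complementation outcomes (`mutation_a`,
#'   `mutation_b`, `outcome`); only `FAIL` rows create edges, but every
#'   mutation mentioned appears in the output.
#' @return A tibble with columns `mutation_id`, `group` (integer id,
#'   numbered by each group's smallest member id), and `group_size`.
#'   Multi-member groups come first, ordered by smallest member.
#' @examples
#' res <- tibble::tibble(
#'   mutation_a = c("L5Jcs4", "L5Jcs24", "L5Jcs7", "L5Jcs6"),
#'   mutation_b = c("L5Jcs36", "L5Jcs27", "L5Jcs14", "L5Jcs35"),
#'   outcome = "FAIL"
#' )
#' allelic_groups(res)
#' @export
allelic_groups <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    return(tibble::tibble(mutation_id = character(), group = integer(),
                          group_size = integer()))
  }
  out <- normalize_results(results)  # validates
  ids <- sort(unique(c(as.character(results$mutation_a), as.character(results$mutation_b))))
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  fails <- results[toupper(results$outcome) %in% c("FAIL", "F"), , drop = FALSE]
  for (k in seq_len(nrow(fails))) {
    ra <- find(match(as.character(fails$mutation_a[k]), ids))
    rb <- find(match(as.character(fails$mutation_b[k]), ids))
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(ids), find, integer(1))
  comp <- split(ids, root)
  comp <- comp[order(vapply(comp, min, character(1)))]
  sizes <- vapply(comp, length, integer(1))
  ord <- order(sizes <= 1L, vapply(comp, min, character(1)))
  comp <- comp[ord]
  tibble::tibble(
    mutation_id = unlist(comp, use.names = FALSE),
    group = rep(seq_along(comp), lengths(comp)),
    group_size = rep(lengths(comp), lengths(comp))
  )
}

#' Expected weanling classes under the complementation null
#'
#' In an intercross of two balancer-carrier stocks (m1/Bal x m2/Bal) the
#' balancer homozygote dies in utero, so conceptuses that can wean are
#' 1 trans-heterozygote (m1/m2) : 2 balancer carriers. If the mutations
#' complement, weaned litters follow those thirds: 21 weaned pups give
#' 7 expected non-balancer and 14 balancer animals. Values are exact
#' rationals (no rounding).
#'
#' @param total_weaned Total animals surviving to wean age.
#' @return Named numeric vector `c(non_balancer =, balancer =)`.
#' @export
expected_weaned <- function(total_weaned) {
  if (length(total_weaned) != 1L || is.na(total_weaned) || total_weaned < 0) {
    rlang::abort("`total_weaned` must be a single non-negative count.")
  }
  c(non_balancer = total_weaned / 3, balancer = 2 * total_weaned / 3)
}

#' Chi-square test for failure to complement in a balancer intercross
#'
#' Pearson goodness-of-fit (df = 1, no continuity correction) of the
#' observed weaned class counts against the 1:2 non-balancer:balancer
#' expectation of [expected_weaned()]. A deficit of trans-heterozygotes
#' signals that the two mutations fail to complement: the Tapt1-knockout x
#' L5Jcs1 cross weaned 0 non-balancer and 21 balancer animals, giving
#' chi-square 10.5, P = 0.0012.
#'
#' @param non_balancer,balancer Observed weaned counts; alternatively pass
#'   a one-row tibble with columns `weaned_non_balancer` and
#'   `weaned_balancer` as `non_balancer`.
#' @return A `compl_chisq` object (statistic, df, p.value, observed,
#'   expected) with `print()`, [tidy()] and [glance()] methods.
#' @examples
#' complementation_chisq(0, 21)
#' @export
complementation_chisq <- function(non_balancer, balancer = NULL) {
  if (is.data.frame(non_balancer)) {
    counts <- non_balancer
    balancer <- counts$weaned_balancer
    non_balancer <- counts$weaned_non_balancer
  }
  if (any(is.na(c(non_balancer, balancer))) || non_balancer < 0 || balancer < 0) {
    rlang::abort("observed counts must be non-negative.")
  }
  total <- non_balancer + balancer
  if (total <= 0) rlang::abort("total weaned must be positive (expected counts would be zero).")
  expected <- expected_weaned(total)
  observed <- c(non_balancer = non_balancer, balancer = balancer)
  stat <- sum((observed - expected)^2 / expected)
  structure(
    list(statistic = stat, df = 1L, p.value = chisq_sf(stat, 1L),
         observed = observed, expected = expected,
         method = "Pearson chi-square vs 1:2 weaned classes (no continuity correction)"),
    class = "compl_chisq"
  )
}

#' @export
print.compl_chisq <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  observed: %g non-balancer, %g balancer; expected: %g, %g\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  X-squared = %g, df = %d, p = %.4g\n", x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @rdname complementation_chisq
#' @param x A `compl_chisq` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.compl_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
                 observed_non_balancer = x$observed[["non_balancer"]],
                 observed_balancer = x$observed[["balancer"]],
                 expected_non_balancer = x$expected[["non_balancer"]],
                 expected_balancer = x$expected[["balancer"]])
}

#' @rdname complementation_chisq
#' @exportS3Method generics::glance
glance.compl_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' Upper-tail probability of the chi-squared distribution
#'
#' Survival function `P(X >= x)` for a chi-squared variable, used to turn
#' the complementation statistic into a p-value (for df = 1 this equals
#' the two-sided normal tail of `sqrt(x)`).
#'
#' @param x Statistic value(s), `>= 0`.
#' @param df Degrees of freedom, `>= 1`.
#' @return Upper-tail probability.
#' @export
chisq_sf <- function(x, df = 1) {
  if (any(is.na(x)) || any(x < 0)) rlang::abort("`x` must be >= 0.")
  if (length(df) != 1L || is.na(df) || df < 1) rlang::abort("`df` must be >= 1.")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}
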