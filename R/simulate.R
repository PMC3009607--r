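#' Configuration for a synthetic balancer-screen simulation
#'
#' Bundles every parameter of the generative model: a single chromosome
#' region carrying one recessive lethal mutation on the mutagenized B6
#' haplotype, genotyped in an F2 intercross against a Cast haplotype, plus
#' an optional deletion panel with uncertain breakpoints and capture-style
#' variant tables. All downstream output is a pure function of the
#' configuration, including `seed`.
#'
#' @param region_length Region size in bp (default 60.9 Mb, the proximal
#'   chromosome 5 footprint used as the initial search region).
#' @param markers Marker map tibble (`name`, `pos_bp`) or `NULL` to place
#'   markers every `marker_spacing` bp, SNP-scale density comparable to the
#'   fine-mapping stage of the screen.
#' @param marker_spacing Spacing for the default marker grid (bp).
#' @param true_mutation_pos 1-based position of the planted lethal.
#' @param cM_per_Mb Recombination rate (centimorgans per megabase); 0.5 is
#'   the order of the mouse genome average.
#' @param n_f2 Number of F2 conceptuses drawn (live animals are the subset
#'   not homozygous for the lethal).
#' @param deletions Optional deletion catalog tibble (`name`, `min_start`,
#'   `min_end`, `max_start`, `max_end`, 1-based inclusive).
#' @param geno_error_rate,geno_missing_rate Per-call genotyping error and
#'   missingness probabilities (defaults 0 so exclusion-soundness checks
#'   are deterministic).
#' @param variant_noise Named integer vector
#'   `c(n_strain_snps =, n_shared_background =, n_known_sites =)`:
#'   confounder variants planted alongside the causative lesion.
#' @param seed Integer seed making every simulated output reproducible.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(region_length = 60.9e6,
                       markers = NULL,
                       marker_spacing = 5e5,
                       true_mutation_pos = 30.2e6,
                       cM_per_Mb = 0.5,
                       n_f2 = 100,
                       deletions = NULL,
                       geno_error_rate = 0,
                       geno_missing_rate = 0,
                       variant_noise = c(n_strain_snps = 40,
                                         n_shared_background = 60,
                                         n_known_sites = 25),
                       seed = 1L) {
  if (is.null(markers)) {
    pos <- seq(marker_spacing, region_length, by = marker_spacing)
    markers <- tibble::tibble(name = sprintf("S%04d", seq_along(pos)), pos_bp = pos)
  }
  check_markers(markers)
  stopifnot(
    region_length > 0,
    true_mutation_pos >= 1, true_mutation_pos <= region_length,
    cM_per_Mb > 0, n_f2 > 0,
    geno_error_rate >= 0, geno_error_rate <= 1,
    geno_missing_rate >= 0, geno_missing_rate <= 1
  )
  vn <- c(n_strain_snps = 0, n_shared_background = 0, n_known_sites = 0)
  vn[names(variant_noise)] <- variant_noise
  if (!is.null(deletions)) {
    stopifnot(all(c("name", "min_start", "min_end", "max_start", "max_end")
                  %in% names(deletions)))
  }
  structure(
    list(region_length = region_length, markers = markers,
         true_mutation_pos = true_mutation_pos, cM_per_Mb = cM_per_Mb,
         n_f2 = as.integer(n_f2), deletions = deletions,
         geno_error_rate = geno_error_rate, geno_missing_rate = geno_missing_rate,
         variant_noise = vn, seed = as.integer(seed),
         genetic_length = region_length / 1e6 * cM_per_Mb / 100),
    class = "sim_config"
  )
}

# Phase matrix for n gametes at the given positions under the Haldane model:
# crossover count ~ Poisson(genetic_length), breakpoints uniform on the
# region, no interference; starting phase is a fair coin flip.
# Returns an n x length(pos_bp) integer matrix of 1 (haplotype 1) / 2.
sim_gamete_phases <- function(n, pos_bp, genetic_length, region_length) {
  k <- stats::rpois(n, genetic_length)
  start <- stats::rbinom(n, 1L, 0.5)
  tot <- sum(k)
  L <- length(pos_bp)
  counts <- matrix(0L, nrow = n, ncol = L)
  if (tot > 0L) {
    bp <- stats::runif(tot, 0, region_length)
    g <- rep.int(seq_len(n), k)
    for (j in seq_len(L)) {
      sel <- bp < pos_bp[j]
      if (any(sel)) counts[, j] <- tabulate(g[sel], nbins = n)
    }
  }
  ((start + counts) %% 2L) + 1L
}

#' Simulate one meiotic gamete under the Haldane model
#'
#' Draws a crossover count from Poisson(`genetic_length`), places the
#' breakpoints uniformly on the region (no interference), flips a fair coin
#' for the starting parental phase, and reads off the resulting alleles at
#' the supplied loci. With `genetic_length = 0` the gamete is always one
#' unrecombined parental haplotype; two loci `d` Morgans apart recombine
#' with Haldane's frequency `(1 - exp(-2 d)) / 2`.
#'
#' @param hap1,hap2 Parental allele vectors over the loci.
#' @param pos_bp Locus positions (bp, ascending).
#' @param genetic_length Genetic length of the region in Morgans.
#' @param region_length Physical length in bp (defaults to the last locus).
#' @param n Number of gametes to draw.
#' @return If `n = 1`, an allele vector; otherwise an `n x length(pos_bp)`
#'   matrix with one gamete per row.
#' @export
simulate_gamete <- function(hap1, hap2, pos_bp, genetic_length,
                            region_length = max(pos_bp), n = 1) {
  stopifnot(length(hap1) == length(pos_bp), length(hap2) == length(pos_bp),
            genetic_length >= 0)
  ph <- sim_gamete_phases(n, pos_bp, genetic_length, region_length)
  alleles <- rbind(hap1, hap2)
  out <- matrix(alleles[cbind(as.vector(ph), rep(seq_along(pos_bp), each = n))],
                nrow = n)
  if (n == 1) out[1L, ] else out
}

#' Simulate a live F2 mapping panel under recessive lethality
#'
#' The F1 is (B6 haplotype carrying the lethal) / Cast. Each conceptus
#' draws two independent F1 gametes; conceptuses homozygous for the
#' mutation-bearing haplotype at `true_mutation_pos` die before genotyping
#' and are excluded from the live table. Marker calls are derived from the
#' gamete haplotypes (`B`/`H`/`C`), with optional genotyping error and
#' missingness applied per call.
#'
#' @param config A [sim_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return A list: `genotypes` (live-animal tibble: `animal_id`, `alive`,
#'   one column per marker), `markers`, `n_conceptuses`, `n_dead`, and
#'   `truth` (the mutation position).
#' @export
simulate_f2_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  mpos <- config$markers$pos_bp
  loci <- c(mpos, config$true_mutation_pos)
  mut_i <- length(loci)
  n <- config$n_f2
  ph_a <- sim_gamete_phases(n, loci, config$genetic_length, config$region_length)
  ph_b <- sim_gamete_phases(n, loci, config$genetic_length, config$region_length)
  # haplotype 1 = mutagenized B6 chromosome; homozygotes at the lethal die
  dead <- ph_a[, mut_i] == 1L & ph_b[, mut_i] == 1L
  geno <- matrix("H", nrow = n, ncol = length(mpos))
  geno[ph_a[, -mut_i, drop = FALSE] == 1L & ph_b[, -mut_i, drop = FALSE] == 1L] <- "B"
  geno[ph_a[, -mut_i, drop = FALSE] == 2L & ph_b[, -mut_i, drop = FALSE] == 2L] <- "C"
  live <- geno[!dead, , drop = FALSE]
  if (config$geno_error_rate > 0 && nrow(live) > 0) {
    err <- stats::runif(length(live)) < config$geno_error_rate
    if (any(err)) {
      live[err] <- vapply(live[err], function(g) sample(setdiff(c("B", "H", "C"), g), 1L),
                          character(1))
    }
  }
  if (config$geno_missing_rate > 0 && nrow(live) > 0) {
    live[stats::runif(length(live)) < config$geno_missing_rate] <- "-"
  }
  gt <- tibble::as_tibble(as.data.frame(live, stringsAsFactors = FALSE),
                          .name_repair = "minimal")
  names(gt) <- config$markers$name
  gt <- dplyr::bind_cols(
    tibble::tibble(animal_id = sprintf("F2_%04d", seq_len(nrow(live))),
                   alive = TRUE),
    gt
  )
  list(genotypes = gt, markers = config$markers,
       n_conceptuses = n, n_dead = sum(dead),
       truth = list(mutation_pos = config$true_mutation_pos))
}

#' Simulate deletion-complementation outcomes with uncertain breakpoints
#'
#' For each deletion in the catalog, true breakpoints are drawn uniformly
#' within the uncertainty zones (`[max_start, min_start]` on the left,
#' `[min_end, max_end]` on the right). The cross fails to complement
#' exactly when the planted mutation lies within the sampled true deleted
#' segment.
#'
#' @param config A [sim_config()] whose `deletions` is non-`NULL`.
#' @param seed Seed override (defaults to `config$seed + 1`).
#' @param mutation_id Label used in the output test table.
#' @return A list: `tests` (tibble `mutation_id`, `deletion`, `outcome`)
#'   and `truth` (tibble of sampled breakpoints per deletion).
#' @export
derive_deletion_outcomes <- function(config, seed = config$seed + 1L,
                                     mutation_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  del <- config$deletions
  if (is.null(del) || nrow(del) == 0L) {
    return(list(tests = tibble::tibble(mutation_id = character(),
                                       deletion = character(),
                                       outcome = character()),
                truth = tibble::tibble()))
  }
  withr::local_seed(seed)
  left <- stats::runif(nrow(del), del$max_start, del$min_start)
  right <- stats::runif(nrow(del), del$min_end, del$max_end)
  fails <- left <= config$true_mutation_pos & config$true_mutation_pos <= right
  list(
    tests = tibble::tibble(mutation_id = mutation_id,
                           deletion = del$name,
                           outcome = ifelse(fails, "FAILS", "COMPLEMENTS")),
    truth = tibble::tibble(deletion = del$name,
                           true_left = left, true_right = right,
                           fails = fails)
  )
}

#' Simulate weanling counts from a balancer intercross
#'
#' Models an m1/Bal x m2/Bal intercross: balancer homozygotes die as
#' embryos, so live-born classes are multinomial with 1/3
#' trans-heterozygote and 2/3 balancer carrier. When the two mutations do
#' not complement, the trans-heterozygotes die before wean age and are
#' counted in `died_pre_wean`.
#'
#' @param n_born Number of live-born pups.
#' @param complementing Do the two mutations complement?
#' @param seed Optional seed.
#' @return One-row tibble: `weaned_non_balancer`, `weaned_balancer`,
#'   `born_total`, `died_pre_wean`.
#' @export
simulate_intercross_weaned <- function(n_born, complementing = TRUE, seed = NULL) {
  if (length(n_born) != 1L || is.na(n_born) || n_born < 0) {
    rlang::abort("`n_born` must be a single non-negative count.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  trans_het <- stats::rbinom(1L, n_born, 1 / 3)
  balancer <- n_born - trans_het
  tibble::tibble(
    weaned_non_balancer = if (complementing) trans_het else 0L,
    weaned_balancer = balancer,
    born_total = as.integer(n_born),
    died_pre_wean = if (complementing) 0L else trans_het
  )
}

#' Simulate capture-sequencing variant tables with one planted lesion
#'
#' Emits per-sample variant call tables for a mutant carrier and two
#' control samples (the reference strain and an unrelated carrier), plus a
#' known-variant catalog. Exactly one heterozygous causative variant is
#' planted at `true_mutation_pos` in the mutant sample only. Confounders
#' are planted per `config$variant_noise`: strain SNPs shared between the
#' mutant and the unrelated-carrier control, background variants shared by
#' all samples, and mutant-unique sites present in the known catalog.
#'
#' @param config A [sim_config()].
#' @param seed Seed override (defaults to `config$seed + 2`).
#' @param chrom Chromosome label for emitted records.
#' @return A list: `variants` (named list of call tibbles: `mutant`,
#'   `control_reference`, `control_carrier`), `known` (catalog tibble),
#'   and `truth` (the causative record).
#' @export
simulate_variant_tables <- function(config, seed = config$seed + 2L, chrom = "chr5") {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(seed)
  vn <- config$variant_noise
  n_noise <- sum(vn)
  bases <- c("A", "C", "G", "T")
  noise_pos <- if (n_noise > 0) {
    p <- sample.int(config$region_length, n_noise)
    while (any(hit <- p == config$true_mutation_pos)) {
      p[hit] <- sample.int(config$region_length, sum(hit))
    }
    p
  } else integer()
  mk_alleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    list(ref = ref, alt = alt)
  }
  causal_al <- mk_alleles(1L)
  causal <- tibble::tibble(sample = "mutant", chrom = chrom,
                           pos = config$true_mutation_pos,
                           ref = causal_al$ref, alt = causal_al$alt,
                           zygosity = "HET")
  grp <- rep(c("strain", "background", "known"),
             times = c(vn[["n_strain_snps"]], vn[["n_shared_background"]],
                       vn[["n_known_sites"]]))
  al <- mk_alleles(n_noise)
  noise <- tibble::tibble(chrom = chrom, pos = noise_pos,
                          ref = al$ref, alt = al$alt, group = grp)
  as_calls <- function(sample_id, records, zygosity = "HET") {
    if (nrow(records) == 0L) {
      return(tibble::tibble(sample = character(), chrom = character(),
                            pos = numeric(), ref = character(),
                            alt = character(), zygosity = character()))
    }
    tibble::tibble(sample = sample_id, chrom = records$chrom, pos = records$pos,
                   ref = records$ref, alt = records$alt, zygosity = zygosity)
  }
  strain <- noise[noise$group == "strain", , drop = FALSE]
  backgr <- noise[noise$group == "background", , drop = FALSE]
  knowns <- noise[noise$group == "known", , drop = FALSE]
  mutant <- dplyr::arrange(
    dplyr::bind_rows(causal,
                     as_calls("mutant", strain),
                     as_calls("mutant", backgr),
                     as_calls("mutant", knowns)),
    pos
  )
  control_reference <- dplyr::arrange(as_calls("control_reference", backgr), pos)
  control_carrier <- dplyr::arrange(
    dplyr::bind_rows(as_calls("control_carrier", strain),
                     as_calls("control_carrier", backgr)),
    pos
  )
  list(
    variants = list(mutant = mutant,
                    control_reference = control_reference,
                    control_carrier = control_carrier),
    known = tibble::tibble(chrom = knowns$chrom, pos = knowns$pos,
                           alt = knowns$alt,
                           id = sprintf("known%04d", seq_len(nrow(knowns)))),
    truth = causal
  )
}

#' Simulate a complete balancer screen with ground truth
#'
#' Convenience wrapper running [simulate_f2_cohort()],
#' [derive_deletion_outcomes()] and [simulate_variant_tables()] from one
#' configuration, so every downstream stage (exclusion mapping, test
#' planning, variant filtering) can be validated against the stored truth.
#'
#' @param config A [sim_config()].
#' @return A `simulated_screen` list: `config`, `cohort`, `deletion_tests`,
#'   `variants`, and `truth`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- simulate_f2_cohort(config)
  dels <- derive_deletion_outcomes(config)
  vars <- simulate_variant_tables(config)
  structure(
    list(config = config, cohort = cohort,
         deletion_tests = dels$tests,
         variants = vars,
         truth = list(mutation_pos = config$true_mutation_pos,
                      deletion_breakpoints = dels$truth,
                      causative_variant = vars$truth)),
    class = "simulated_screen"
  )
}
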