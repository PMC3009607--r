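mk_deletion <- function(name = "del", min_start, min_end, max_start, max_end) {
  tibble::tibble(name = name, min_start = min_start, min_end = min_end,
                 max_start = max_start, max_end = max_end)
}

test_that("deletion tests cut the candidate with the correct extent", {
  candidate <- interval_set(0, 50e6)
  # minimal extent [10M, 20M), maximal [9M, 21M) in 0-based terms
  del <- mk_deletion("dfX", 10e6 + 1, 20e6, 9e6 + 1, 21e6)

  comp <- apply_deletion_test(candidate, del, "COMPLEMENTS")
  expect_equal(comp, interval_set(c(0, 20e6), c(10e6, 50e6)))

  fail <- apply_deletion_test(candidate, del, "FAILS")
  expect_equal(fail, interval_set(9e6, 21e6))

  # non-complementation incompatible with the candidate is an error
  far <- interval_set(40e6, 50e6)
  expect_error(apply_deletion_test(far, del, "FAILS"), "inconsistent evidence.*dfX")
  expect_error(apply_deletion_test(candidate, del, "MAYBE"), "COMPLEMENTS/FAILS")
})

test_that("two complementing deletions leave the gap between their minimal extents", {
  # mirrors mutations placed by complementation with flanking deficiencies:
  # minimal extents tile [5M,15M) and [25M,40M), leaving [15M,25M) plus the ends
  candidate <- interval_set(0, 50e6)
  d1 <- mk_deletion("d1", 5e6 + 1, 15e6, 4e6 + 1, 16e6)
  d2 <- mk_deletion("d2", 25e6 + 1, 40e6, 24e6 + 1, 41e6)
  out <- apply_deletion_test(apply_deletion_test(candidate, d1, "C"), d2, "C")
  # bitmap oracle at 10 kb resolution (all coordinates are 10 kb multiples)
  scale <- function(x) interval_set(x$start / 1e4, x$end / 1e4)
  bits <- iv_bitmap(scale(candidate), 5000) &
    !iv_bitmap(scale(interval_set(5e6, 15e6)), 5000) &
    !iv_bitmap(scale(interval_set(25e6, 40e6)), 5000)
  expect_equal(scale(out), iv_from_bitmap(bits))
  expect_true(all(interval_contains(out, c(16e6, 20e6, 24e6, 3e6, 45e6))))
  expect_false(any(interval_contains(out, c(10e6, 30e6))))
})

test_that("homozygous-B6 spans are the closed marker-to-marker run spans", {
  mk <- tibble::tibble(name = paste0("m", 1:4), pos_bp = c(10, 20, 30, 40))
  out <- homozygous_b6_spans(c("H", "B", "B", "H"), mk)
  expect_equal(out, interval_from_1based(20, 30))

  expect_equal(nrow(homozygous_b6_spans(rep("H", 4), mk)), 0L)

  # MISSING breaks runs: two 1-bp point spans, not the bridged span
  mk3 <- tibble::tibble(name = paste0("m", 1:3), pos_bp = c(10, 20, 30))
  out <- homozygous_b6_spans(c("B", "-", "B"), mk3)
  expect_equal(out, interval_from_1based(c(10, 30), c(10, 30)))
  expect_equal(interval_width_bp(out), 2)

  expect_error(homozygous_b6_spans(c("B", "B"), mk3), "align")
})

test_that("recombination exclusions pool live animals only", {
  mk <- tibble::tibble(name = paste0("m", 1:4), pos_bp = c(10, 20, 30, 40) * 1e5)
  gt <- tibble::tibble(
    animal_id = c("a1", "a2", "a3"),
    alive = c(TRUE, TRUE, FALSE),
    m1 = c("B", "H", "B"), m2 = c("B", "H", "B"),
    m3 = c("H", "B", "B"), m4 = c("H", "B", "B")
  )
  out <- recombination_exclusions(gt, mk)
  expect_equal(out, interval_union(interval_from_1based(10e5, 20e5),
                                   interval_from_1based(30e5, 40e5)))

  dead_only <- gt[3, ]
  expect_equal(nrow(recombination_exclusions(dead_only, mk)), 0L)
  expect_warning(out0 <- recombination_exclusions(gt[0, ], mk), "empty")
  expect_equal(nrow(out0), 0L)
})

test_that("map_mutation is the identity without evidence and reproduces the 289 kb interval", {
  init <- rw_initial_region()
  cr <- map_mutation(init, mutation_id = "L5JcsX")
  expect_s3_class(cr, "critical_region")
  expect_equal(cr$region, init)
  expect_equal(nrow(cr$evidence), 0L)

  # two animals whose B6/B6 runs flank the printed SNP coordinates
  mk <- tibble::tibble(
    name = c("m_prox", "rs13478279", "rs13478280", "m_dist"),
    pos_bp = c(1, 60593878, 60882847, 60.9e6)
  )
  gt <- tibble::tibble(
    animal_id = c("a1", "a2"), alive = TRUE,
    m_prox = c("B", "H"), rs13478279 = c("B", "H"),
    rs13478280 = c("H", "B"), m_dist = c("H", "B")
  )
  cr <- map_mutation(init, genotypes = gt, markers = mk, mutation_id = "L5Jcs13")
  expect_equal(nrow(cr$region), 1L)
  expect_equal(interval_width_kb(cr$region), 289)
  shown <- tidy(cr)
  expect_equal(shown$start, 60593879)
  expect_equal(shown$end, 60882846)
  g <- glance(cr)
  expect_equal(g$width_kb, 289)
  expect_equal(g$n_evidence_steps, 1L)
})

test_that("evidence accumulates monotonically and independently of order", {
  set.seed(77)
  cfg <- quick_config(seed = 11, deletions = rw_example_deletions())
  scr <- simulate_screen(cfg)
  init <- rw_initial_region()

  full <- map_mutation(init, scr$deletion_tests, cfg$deletions,
                       scr$cohort$genotypes, cfg$markers, mutation_id = "sim")
  # monotonic: every evidence step leaves width no larger than before
  expect_true(all(full$evidence$width_after_bp <= full$evidence$width_before_bp))
  # subset of evidence (deletions only) never gives a smaller region
  dels_only <- map_mutation(init, scr$deletion_tests, cfg$deletions, mutation_id = "sim")
  expect_true(interval_width_bp(dels_only$region) >= interval_width_bp(full$region))
  # region is a subset of the initial search region
  expect_equal(interval_intersect(full$region, init), full$region)

  # order independence: reverse the deletion tests
  rev_tests <- scr$deletion_tests[rev(seq_len(nrow(scr$deletion_tests))), ]
  full_rev <- map_mutation(init, rev_tests, cfg$deletions,
                           scr$cohort$genotypes, cfg$markers, mutation_id = "sim")
  expect_equal(full$region, full_rev$region)
})

test_that("simulated screens always retain the true mutation position", {
  set.seed(2024)
  for (i in 1:30) {
    cfg <- quick_config(seed = 5000 + i, deletions = rw_example_deletions())
    scr <- simulate_screen(cfg)
    cr <- map_mutation(rw_initial_region(), scr$deletion_tests, cfg$deletions,
                       scr$cohort$genotypes, cfg$markers, mutation_id = "sim")
    expect_true(interval_contains(cr$region, cfg$true_mutation_pos),
                label = paste("containment at seed", cfg$seed))
  }
})

test_that("contradictory evidence that excludes everything raises a replayable error", {
  init <- interval_from_1based(1, 100)
  mk <- tibble::tibble(name = c("mA", "mB"), pos_bp = c(1, 100))
  gt <- tibble::tibble(animal_id = "a1", alive = TRUE, mA = "B", mB = "B")
  expect_error(map_mutation(init, genotypes = gt, markers = mk),
               "inconsistent evidence")
})

test_that("critical regions export to BED3 and a JSON evidence log", {
  mk <- tibble::tibble(name = c("mA", "mB"), pos_bp = c(1, 30e6))
  gt <- tibble::tibble(animal_id = "a1", alive = TRUE, mA = "B", mB = "B")
  cr <- map_mutation(rw_initial_region(), genotypes = gt, markers = mk,
                     mutation_id = "mutX")
  bed <- withr::local_tempfile(fileext = ".bed")
  js <- withr::local_tempfile(fileext = ".json")
  write_critical_region(cr, bed, js)
  expect_equal(read_bed3(bed), cr$region)
  log <- jsonlite::read_json(js)
  expect_equal(log$mutation_id, "mutX")
  expect_equal(length(log$evidence), 1L)
  expect_equal(log$evidence[[1]]$action, "subtract_b6_spans")
})
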