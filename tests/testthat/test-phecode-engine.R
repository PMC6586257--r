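test_that("relatedness pruning drops exactly one member per close pair", {
  kin <- tibble::tibble(id_a = 1L, id_b = 2L, coefficient = 0.25)
  retained <- prune_related(1:4, kin, seed = 3)
  expect_equal(length(retained), 3)
  expect_equal(sum(c(1, 2) %in% retained), 1)
  expect_true(all(c(3, 4) %in% retained))

  kin_far <- tibble::tibble(id_a = c(1L, 3L), id_b = c(2L, 4L),
                            coefficient = c(0.0884, 0.05))
  expect_equal(prune_related(1:4, kin_far), 1:4)

  expect_error(
    prune_related(1:4, tibble::tibble(id_a = 1L, id_b = 9L,
                                      coefficient = 0.2)),
    "unknown id")
  expect_error(
    prune_related(1:4, tibble::tibble(id_a = 1L, id_b = 2L,
                                      coefficient = NaN)),
    "finite")
})

test_that("greedy pruning leaves no retained pair above the threshold", {
  # chains and random graphs, checked by brute force over retained pairs
  chain <- tibble::tibble(id_a = c(1L, 2L), id_b = c(2L, 3L),
                          coefficient = c(0.2, 0.3))
  for (s in 1:20) {
    kept <- prune_related(1:3, chain, seed = s)
    bad <- chain$id_a %in% kept & chain$id_b %in% kept
    expect_false(any(bad))
  }
  withr::with_seed(5, {
    rnd <- tibble::tibble(id_a = sample(30, 25, TRUE),
                          id_b = sample(30, 25, TRUE),
                          coefficient = runif(25, 0, 0.3))
    rnd <- rnd[rnd$id_a != rnd$id_b, ]
  })
  for (s in 1:10) {
    kept <- prune_related(1:30, rnd, seed = s)
    close <- rnd[rnd$coefficient > 0.0884, ]
    expect_false(any(close$id_a %in% kept & close$id_b %in% kept))
  }
})

test_that("pruning disjoint pairs keeps a seed-independent count but varying members", {
  cfg <- scenario_config(n_individuals = 500, n_related_pairs = 40,
                         kinship_range = c(0.1, 0.3), seed = 8)
  kin <- generate_kinship(cfg)
  kept <- lapply(1:8, function(s) prune_related(1:500, kin, seed = s))
  expect_true(all(vapply(kept, length, integer(1)) == 460L))
  expect_gt(length(unique(lapply(kept, sort))), 1)
})

test_that("ICD events map to phecodes idempotently, with unmapped codes logged", {
  map <- toy_phecode_map()
  events <- tibble::tibble(
    person_id = c(1L, 1L, 1L, 2L, 3L),
    icd_version = c(10L, 10L, 10L, 10L, 10L),
    code = c("D50.9", "D509", "D50.9", "I10", "Q999")
  )
  inc <- suppressMessages(map_icd_to_phecodes(events, map))
  # three events for one person and phecode flag once; dots are stripped
  expect_equal(nrow(inc[inc$person_id == 1, ]), 1)
  expect_equal(inc$phecode[inc$person_id == 1], "280.1")
  expect_equal(inc$phecode[inc$person_id == 2], "401.1")
  # unmapped codes counted, not flagged, not fatal
  unmapped <- attr(inc, "unmapped")
  expect_equal(unmapped$code_norm, "Q999")
  expect_equal(unmapped$n_events, 1L)
  expect_false(3L %in% inc$person_id)
  # idempotent: the incidence table is stable under re-derivation
  expect_equal(as.data.frame(suppressMessages(
    map_icd_to_phecodes(events, map))), as.data.frame(inc))
})

test_that("malformed ICD codes are skipped with a warning", {
  map <- toy_phecode_map()
  events <- tibble::tibble(person_id = c(1L, 2L), icd_version = 10L,
                           code = c("D50.9", "??"))
  expect_warning(inc <- map_icd_to_phecodes(events, map), "malformed")
  expect_equal(inc$person_id, 1L)
})

test_that("case/control construction honors the exclusion range", {
  map <- toy_phecode_map()
  incidence <- tibble::tibble(person_id = c(1L, 2L),
                              phecode = c("280.1", "280.2"))
  cc <- build_case_control("280.1", incidence, map, cohort_ids = 1:3)
  expect_equal(cc$case_ids, 1L)
  expect_equal(cc$excluded_ids, 2L)  # related phecode via shared root "280"
  expect_equal(cc$control_ids, 3L)

  # nobody flagged for related codes: no exclusions
  inc2 <- tibble::tibble(person_id = 1L, phecode = "280.1")
  cc2 <- build_case_control("280.1", inc2, map, cohort_ids = 1:3)
  expect_equal(cc2$excluded_ids, integer(0))
  expect_equal(sort(cc2$control_ids), 2:3)

  # everyone a case: empty control pool, later dropped by the case filter
  inc3 <- tibble::tibble(person_id = 1:3, phecode = "280.1")
  cc3 <- build_case_control("280.1", inc3, map, cohort_ids = 1:3)
  expect_equal(length(cc3$control_ids), 0)

  expect_error(build_case_control("280.1", inc2, map, integer(0)),
               "Empty cohort")
  expect_error(build_case_control("123.4", inc2, map, 1:3),
               "not present in the map")
})

test_that("case, control, and excluded sets partition the cohort", {
  cfg <- scenario_config(
    n_individuals = 3000,
    phecode_scenarios = dplyr::bind_rows(
      phecode_scenario("280.1", 0.1),
      phecode_scenario("280.2", 0.1),
      phecode_scenario("401.1", 0.15)),
    seed = 17)
  map <- synthetic_phecode_map(c("280.1", "280.2", "401.1"))
  cohort <- simulate_cohort(cfg, phecode_map = map)
  incidence <- map_icd_to_phecodes(cohort$icd_events, map)
  sets <- build_case_control_sets(incidence, map,
                                  cohort$covariates$person_id)
  for (s in sets) {
    all_ids <- c(s$case_ids, s$control_ids, s$excluded_ids)
    expect_equal(sort(all_ids), 1:3000)   # exhaustive
    expect_equal(anyDuplicated(all_ids), 0L)  # pairwise disjoint
  }
  # 280.1 carriers are excluded from 280.2 controls and vice versa
  expect_true(all(sets[["280.2"]]$excluded_ids %in%
                    setdiff(sets[["280.1"]]$case_ids,
                            sets[["280.2"]]$case_ids)))
})

test_that("the minimum-case filter keeps exactly the phecodes at or above the cutoff", {
  mk <- function(id, n_cases) {
    structure(list(phecode_id = id, case_ids = seq_len(n_cases),
                   control_ids = 1000 + 1:50, excluded_ids = integer(0)),
              class = "case_control_set")
  }
  sets <- list(a = mk("a", 199), b = mk("b", 200), c = mk("c", 512))
  kept <- filter_min_cases(sets, minimum = 200)
  expect_equal(names(kept), c("b", "c"))
  expect_equal(names(filter_min_cases(sets, minimum = 0)),
               c("a", "b", "c"))
  # recount oracle: retained list equals a brute-force count filter
  counts <- vapply(sets, function(s) length(s$case_ids), integer(1))
  expect_equal(names(filter_min_cases(sets, 200)),
               names(counts)[counts >= 200])
})

test_that("case/control counts mirror the sets and join map metadata", {
  map <- toy_phecode_map()
  incidence <- tibble::tibble(person_id = c(1L, 2L),
                              phecode = c("280.1", "280.2"))
  sets <- build_case_control_sets(incidence, map, 1:10,
                                  phecodes = c("280.1", "401.1"))
  counts <- case_control_counts(sets, map)
  expect_equal(counts$n_cases, c(1L, 0L))
  expect_equal(counts$n_controls, c(8L, 10L))
  expect_equal(counts$category[1], "Hematopoietic")
})

test_that("the packaged synthetic phecode map loads and validates", {
  map <- read_phecode_map(system.file("extdata", "phecode_map_synthetic.tsv",
                                      package = "ironmr"))
  expect_true(all(c("icd_version", "icd_code", "phecode", "exclusion_root",
                    "description", "category", "sex") %in% names(map)))
  expect_true("280.1" %in% map$phecode)
  expect_error(validate_phecode_map(map[, -3]), "missing columns")
})
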