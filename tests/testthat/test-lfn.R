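occ <- function(variant, sample, replicate, count, category = "edna") {
  tibble::tibble(run = "run01", marker = "MFZR",
                 variant_id = variant, sample = sample, category = category,
                 replicate = as.integer(replicate), count = as.integer(count))
}

test_that("the three LFN sub-filters evaluate on input-table denominators", {
  # absolute filter
  tab <- occ("v1", "s1", 1, 10)
  out <- lfn_filter(tab, lfn_thresholds(t_abs = 11))
  expect_equal(nrow(out$counts), 0L)
  expect_equal(sum(out$trace$occurrences_removed), 1L)

  # per-variant ratio: counts (95, 5) over two PCRs, 5/100 < 0.10
  tab <- dplyr::bind_rows(occ("v1", "s1", 1, 95), occ("v1", "s2", 1, 5))
  out <- lfn_filter(tab, lfn_thresholds(t_var = 0.10))
  expect_equal(out$counts$sample, "s1")

  # per-replicate ratio: 2/100 of its PCR's reads
  tab <- dplyr::bind_rows(occ("v1", "s1", 1, 98), occ("v2", "s1", 1, 2))
  out <- lfn_filter(tab, lfn_thresholds(t_rep = 0.05))
  expect_equal(out$counts$variant_id, "v1")

  # all thresholds zero leave the table unchanged
  tab <- random_count_table(3)
  expect_equal(lfn_filter(tab, lfn_thresholds())$counts, tab)
})

test_that("lfn_filter is idempotent and monotone in each threshold", {
  for (seed in 1:10) {
    tab <- random_count_table(seed)
    th <- withr::with_seed(seed, lfn_thresholds(
      t_abs = sample(0:10, 1), t_var = stats::runif(1, 0, 0.3),
      t_rep = stats::runif(1, 0, 0.3)))
    once <- lfn_filter(tab, th)$counts
    twice <- lfn_filter(once, th)$counts
    expect_equal(twice, once)

    for (bump in list(c(1, 0, 0), c(0, 0.05, 0), c(0, 0, 0.05))) {
      th2 <- lfn_thresholds(th$t_abs + bump[1], th$t_var + bump[2],
                            th$t_rep + bump[3])
      stricter <- lfn_filter(tab, th2)$counts
      expect_true(nrow(dplyr::anti_join(
        stricter, once,
        by = c("run", "marker", "variant_id", "sample", "replicate"))) == 0)
    }
  }
})

test_that("filter trace conserves occurrences", {
  for (seed in 1:10) {
    tab <- random_count_table(seed)
    out <- lfn_filter(tab, lfn_thresholds(t_abs = 5, t_var = 0.05,
                                          t_rep = 0.02))
    expect_equal(nrow(out$counts) + sum(out$trace$occurrences_removed),
                 nrow(tab))
  }
})

test_that("calibration separates a weak negative from strong mocks", {
  tab <- dplyr::bind_rows(
    occ("v1", "Tpos1", 1:3, c(50, 60, 55), category = "mock"),
    occ("v2", "Tpos1", 1:3, c(80, 90, 85), category = "mock"),
    occ("v3", "neg1", 1, 5, category = "neg_pcr"))
  must_keep <- dplyr::filter(tab, category == "mock")
  cal <- calibrate_lfn(tab, must_keep = must_keep)
  # the 5-read negative is removable by t_abs = 6 without touching mocks
  expect_equal(cal$thresholds$t_abs, 6)
  expect_equal(cal$report$retained_expected, 6L)
  expect_equal(cal$report$eliminated_unexpected, 1L)
  expect_equal(nrow(cal$unremovable), 0L)
  filtered <- lfn_filter(tab, cal)$counts
  expect_true(all(filtered$category == "mock"))
})

test_that("a contaminant stronger than the weakest mock is unremovable", {
  tab <- dplyr::bind_rows(
    occ("v1", "Tpos1", 1:2, c(20, 25), category = "mock"),
    occ("v2", "neg1", 1, 500, category = "neg_pcr"))
  must_keep <- dplyr::filter(tab, category == "mock")
  cal <- calibrate_lfn(tab, must_keep = must_keep)
  expect_equal(nrow(cal$unremovable), 1L)
  expect_equal(cal$unremovable$variant_id, "v2")
  # the hard constraint holds: mocks survive
  filtered <- lfn_filter(tab, cal)$counts
  expect_true(all(c("v1") %in% filtered$variant_id))
})

test_that("expected occurrences with zero reads are reported as dropouts", {
  tab <- occ("v1", "Tpos1", 1:3, c(50, 60, 55), category = "mock")
  mk <- tibble::tibble(variant_id = c("v1", "v_gone"), sample = "Tpos1")
  cal <- calibrate_lfn(tab, must_keep = mk)
  expect_equal(cal$mock_dropouts$variant_id, "v_gone")
})

test_that("calibration matches the exhaustive grid-search oracle", {
  for (seed in 1:40) {
    st <- calibration_instance(seed)
    fit <- olspr:::calibrate_group(st)
    oracle <- brute_force_calibrate(st)
    expect_equal(fit$eliminated_unexpected, oracle$n, info = paste("seed", seed))
    rem_fit <- st$count < fit$t_abs | st$var_ratio < fit$t_var |
      st$rep_ratio < fit$t_rep
    expect_equal(rem_fit, oracle$removed, info = paste("seed", seed))
    expect_equal(fit$t_abs, oracle$t_abs, info = paste("seed", seed))
  }
})

test_that("Renkonen distance and replicate screening follow the formula", {
  expect_equal(renkonen_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(renkonen_distance(c(0.7, 0.3), c(0.5, 0.5)), 0.2)
  expect_equal(renkonen_distance(c(5, 5), c(50, 50)), 0)

  # two identical-profile replicates: none dropped
  tab <- dplyr::bind_rows(occ("v1", "s1", 1:2, c(10, 20)),
                          occ("v2", "s1", 1:2, c(10, 20)))
  out <- renkonen_screen(tab, cutoff = 0.5)
  expect_equal(nrow(out$dropped), 0L)

  # disjoint profiles at distance 1: both replicates dropped (degenerate)
  tab <- dplyr::bind_rows(occ("v1", "s1", 1, 10), occ("v2", "s1", 2, 10))
  out <- renkonen_screen(tab, cutoff = 0.5)
  expect_equal(nrow(out$dropped), 2L)
  expect_equal(nrow(out$counts), 0L)

  # profiles (0.7, 0.3) vs (0.5, 0.5): d = 0.2, kept at cutoff 0.5
  tab <- dplyr::bind_rows(occ("v1", "s1", 1:2, c(70, 50)),
                          occ("v2", "s1", 1:2, c(30, 50)))
  out <- renkonen_screen(tab, cutoff = 0.5)
  expect_equal(nrow(out$dropped), 0L)
})

test_that("empty replicates expected from the design are dropped", {
  d <- tiny_design(n_samples = 1)
  tab <- occ("v1", "s01", 1:2, c(10, 10))
  out <- renkonen_screen(tab, design = d)
  expect_true(all(out$dropped$reason == "empty"))
  # replicate 3 of every marker carries no reads
  expect_equal(sum(out$dropped$replicate == 3), 3L)
})

test_that("the minimum-replicate rule validates and pools correctly", {
  tab <- dplyr::bind_rows(
    occ("v1", "s1", c(1, 3), c(10, 15)),   # two replicates -> validated
    occ("v2", "s1", 2, 40))                # one replicate -> removed
  out <- replicate_consensus(tab)
  expect_equal(out$variant_id, "v1")
  expect_equal(out$count, 25L)
  expect_equal(out$n_replicates, 2L)
  expect_equal(nrow(replicate_consensus(tab, min_replicates = 1L)), 2L)
})

test_that("an empty habitat map makes the second pass a fixed point", {
  tab <- dplyr::bind_rows(
    occ("v1", "Tpos1", 1:3, c(50, 60, 55), category = "mock"),
    occ("v2", "s1", 1:3, c(30, 35, 40)),
    occ("v3", "neg1", 1, 4, category = "neg_aerosol"))
  d <- tiny_design(n_samples = 1)
  must_keep <- dplyr::filter(tab, category == "mock")
  cal1 <- calibrate_lfn(tab, must_keep = must_keep)
  v1 <- replicate_consensus(lfn_filter(tab, cal1)$counts)
  taxa <- tibble::tibble(variant_id = c("v1", "v2"),
                         taxon = c("Taxon A", "Taxon B"))
  sp <- lfn_second_pass(tab, d, v1, taxa,
                        habitat_map = tibble::tibble(taxon = character(),
                                                     habitat = character()),
                        must_keep = must_keep)
  expect_equal(sp$calibration$thresholds, cal1$thresholds)
  expect_equal(nrow(sp$unexpected), 0L)
  # only taxa of validated eDNA detections are habitat-checked
  expect_setequal(sp$unknown_taxa, "Taxon B")
})

test_that("habitat-incompatible detections drive the second pass", {
  # v2 is a freshwater-only taxon detected in a brackish sample
  tab <- dplyr::bind_rows(
    occ("v1", "Tpos1", 1:3, c(50, 60, 55), category = "mock"),
    occ("v2", "s01", 1:3, c(8, 9, 7)),
    occ("v3", "s01", 1:3, c(90, 85, 95)))
  d <- tibble::as_tibble(tiny_design(n_samples = 1)) |>
    dplyr::mutate(habitat = "brackish") |>
    new_design()
  must_keep <- dplyr::filter(tab, category == "mock")
  cal1 <- calibrate_lfn(tab, must_keep = must_keep)
  v1 <- replicate_consensus(lfn_filter(tab, cal1)$counts)
  taxa <- tibble::tibble(variant_id = c("v2", "v3"),
                         taxon = c("Fresh sp", "Brackish sp"))
  hmap <- tibble::tibble(taxon = c("Fresh sp", "Brackish sp"),
                         habitat = c("freshwater", "brackish"))
  sp <- lfn_second_pass(tab, d, v1, taxa, hmap, must_keep = must_keep)
  expect_equal(sp$unexpected$variant_id, "v2")
  expect_false("v2" %in% sp$validated$variant_id)
  expect_true("v3" %in% sp$validated$variant_id)
  expect_true("v1" %in% sp$validated$variant_id)
})
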