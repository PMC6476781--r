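test_that("coverage ratio counts detected taxa against the union", {
  expect_equal(coverage_bc(c("t1", "t2"), c("t1", "t2", "t3")), 2 / 3)
  expect_equal(coverage_bc(c("t1", "t2", "t3"), c("t1", "t2", "t3")), 1)
  expect_true(is.na(coverage_bc(character(0), character(0))))
  expect_error(coverage_bc("t4", c("t1", "t2")), "subset")
})

test_that("complementarity counts taxa detected by exactly one primer set", {
  expect_equal(complementarity_com(list(A = c("t1", "t2"), B = "t2",
                                        C = "t3")), 2 / 3)
  expect_equal(complementarity_com(list(A = c("t1", "t2"),
                                        B = c("t1", "t2"))), 0)
  expect_equal(complementarity_com(list(A = "t1", B = "t2", C = "t3")), 1)
})

test_that("Bray-Curtis follows the formula and matches vegan", {
  expect_equal(bray_curtis(c(2, 1, 0), c(2, 1, 0)), 0)
  expect_equal(bray_curtis(c(2, 1, 0), c(0, 0, 5)), 1)
  expect_equal(bray_curtis(c(2, 1, 0), c(1, 1, 1)), 1 / 3)
  expect_true(is.na(bray_curtis(c(0, 0), c(0, 0))))

  skip_if_not_installed("vegan")
  for (seed in 1:20) {
    xy <- withr::with_seed(seed, matrix(stats::rpois(12, 3), nrow = 2))
    if (all(rowSums(xy) > 0)) {
      expect_equal(bray_curtis(xy[1, ], xy[2, ]),
                   as.numeric(vegan::vegdist(xy, method = "bray")))
    }
  }
})

# a small hand-built detection table: 2 samples, 3 markers, 4 items
fixture_detections <- function() {
  tibble::tibble(
    sample = c("s1", "s1", "s1", "s1", "s2", "s2"),
    marker = c("MFZR", "ZFZR", "ZFZR", "LFCR", "MFZR", "ZFZR"),
    item_id = c("i1", "i1", "i2", "i3", "i4", "i4"))
}

fixture_assignments <- function() {
  tibble::tibble(
    item_id = c("i1", "i2", "i3", "i4"),
    kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
    order = c("Diptera", "Diptera", "Ephemeroptera", "Diptera"),
    family = c("Chironomidae", "Chironomidae", "Baetidae", "Culicidae"),
    genus = NA_character_, species = NA_character_,
    resolution_rank = c("family", "family", "family", "family"))
}

fixture_motus <- function() {
  tibble::tibble(item_id = c("i1", "i2", "i3", "i4"),
                 motu_id = c("m1", "m2", "m3", "m4"),
                 representative = TRUE)
}

test_that("MNI aggregation conserves per-sample item totals", {
  det <- fixture_detections()
  lv <- item_levels(fixture_assignments(), fixture_motus())
  for (L in olspr:::metric_levels()) {
    m <- mni_matrix(det, lv, L)
    totals <- m |> dplyr::group_by(sample) |> dplyr::summarise(n = sum(mni))
    expect_equal(totals$n, c(3L, 1L), info = L)
  }
  # at family level i1 and i2 share a cell in s1
  fam <- mni_matrix(det, lv, "family")
  expect_equal(fam$mni[fam$sample == "s1" & fam$taxon == "Chironomidae"], 2L)
})

test_that("within-sample dissimilarity uses per-primer-set MNI vectors", {
  det <- fixture_detections()
  lv <- item_levels(fixture_assignments(), fixture_motus())
  w <- wsd(det, lv, "variant")
  # s1: MFZR={i1}, ZFZR={i1,i2}, LFCR={i3}
  mfzr_zfzr <- w$value[w$sample == "s1" & w$marker_1 == "MFZR" &
                         w$marker_2 == "ZFZR"]
  expect_equal(mfzr_zfzr, 1 - 2 * 1 / 3)
  mfzr_lfcr <- w$value[w$sample == "s1" &
                         (w$marker_1 == "LFCR" | w$marker_2 == "LFCR")]
  expect_true(all(mfzr_lfcr == 1))
  # s2 has two markers with identical detections: distance 0
  expect_equal(w$value[w$sample == "s2"], 0)
})

test_that("between-sample dissimilarity works on combined MNI", {
  det <- fixture_detections()
  lv <- item_levels(fixture_assignments(), fixture_motus())
  b <- bsd(det, lv, "variant")
  expect_equal(b$value, 1)   # disjoint item sets
  b_dup <- bsd(dplyr::mutate(det, sample = "s1"), lv, "variant")
  expect_equal(nrow(b_dup), 0L)   # single sample: no pairs
})

test_that("the metrics report ties everything together", {
  det <- dplyr::mutate(fixture_detections(), predator_group = "fish")
  met <- compute_metrics(det, fixture_assignments(), fixture_motus(),
                         group = "predator_group")
  expect_s3_class(met, "olsp_metrics")
  # global Bc at variant level: union of 4 items; ZFZR detected i1,i2,i4
  bc <- met$bc_global
  expect_equal(bc$value[bc$marker == "ZFZR" & bc$level == "variant"], 3 / 4)
  # IR: all items family-level -> 4 per sample
  expect_equal(met$ir$ir, c(4, 4))
  # MNI summary: per-sample totals and group mean/sd
  expect_equal(sort(met$mni_summary$per_sample$mni), c(1L, 3L))
  expect_equal(met$mni_summary$per_group$mean_mni, 2)
  expect_equal(met$mni_summary$per_group$sd_mni, sqrt(2))
  # all bounded statistics stay in [0, 1]
  vals <- c(met$bc_sample$value, met$com_sample$value, met$wsd$value,
            met$bsd$value)
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
})

test_that("metrics tolerate detections carried by a single primer set", {
  det <- fixture_detections() |>
    dplyr::filter(marker == "ZFZR") |>
    dplyr::mutate(predator_group = "fish")
  met <- compute_metrics(det, fixture_assignments(), fixture_motus(),
                         group = "predator_group")
  expect_true(all(is.na(met$com_global$value)))
  expect_true(all(met$bc_global$value == 1))
  expect_equal(nrow(met$wsd), 0L)
})

test_that("plot helpers return ggplot objects", {
  det <- dplyr::mutate(fixture_detections(), predator_group = "fish")
  met <- compute_metrics(det, fixture_assignments(), fixture_motus(),
                         group = "predator_group")
  expect_s3_class(autoplot(met, "bc"), "ggplot")
  expect_s3_class(autoplot(met, "wsd"), "ggplot")
  expect_s3_class(plot_mni(met), "ggplot")
})
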