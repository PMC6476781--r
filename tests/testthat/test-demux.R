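mk <- default_markers()

test_that("a constructed read is assigned to its PCR and trimmed exactly", {
  d <- tiny_design(n_samples = 2)
  row <- tibble::as_tibble(d)[5, ]
  insert <- strrep("ACGT", 30)
  read <- make_read(row, mk, insert)
  res <- demultiplex(read, d)
  expect_equal(res$stats$assigned_reads, 1L)
  expect_equal(res$assignments$marker, row$marker)
  expect_equal(res$assignments$sample, row$sample)
  expect_equal(res$assignments$replicate, row$replicate)
  expect_equal(res$assignments$insert, insert)
  expect_equal(nchar(res$assignments$insert), 120L)

  # the reverse-complemented read lands in the same PCR
  res_rc <- demultiplex(olspr:::revcomp(read), d)
  expect_equal(res_rc$assignments$sample, row$sample)
  expect_equal(res_rc$assignments$insert, insert)
})

test_that("a single substitution inside the tag makes the read unassigned", {
  d <- tiny_design(n_samples = 2)
  row <- tibble::as_tibble(d)[1, ]
  read <- make_read(row, mk, strrep("ACGT", 30))
  # corrupt position 3 of the forward tag (tag is AAAAAAAAAAA)
  substr(read, 3, 3) <- "G"
  res <- demultiplex(read, d)
  expect_equal(res$stats$assigned_reads, 0L)
  expect_equal(res$unassigned$reason, "no_construct_match")
})

test_that("primer mismatches are tolerated up to the configured bound", {
  d <- tiny_design(n_samples = 1)
  row <- tibble::as_tibble(d)[1, ]
  read <- make_read(row, mk, strrep("ACGT", 30))
  tag_len <- nchar(row$fwd_tag)
  primer <- first_realization(mk$fwd_primer[mk$marker == row$marker])
  # 3 substitutions in the forward primer region (> default tolerance 2)
  for (i in c(3, 6, 9)) {
    base <- substr(read, tag_len + i, tag_len + i)
    substr(read, tag_len + i, tag_len + i) <-
      setdiff(c("A", "C", "G", "T"), base)[1]
  }
  expect_equal(demultiplex(read, d)$stats$assigned_reads, 0L)
  expect_equal(demultiplex(read, d,
                           max_primer_mismatch = 3)$stats$assigned_reads, 1L)
})

test_that("reads shorter than the construct are unassigned with a reason", {
  d <- tiny_design(n_samples = 1)
  row <- tibble::as_tibble(d)[1, ]
  read <- make_read(row, mk, "")   # no insert at all
  res <- demultiplex(read, d)
  expect_equal(res$stats$assigned_reads, 0L)
  expect_equal(res$unassigned$reason, "too_short")
})

test_that("demultiplexing agrees with simulator provenance at zero noise", {
  cfg <- sim_config(seed = 7, n_edna = 3, reads_per_pcr = 60, n_taxa = 15,
                    substitution_rate = 0, tag_switch_rate = 0,
                    contam_rate = 0, neg_contam_mean = 0)
  run <- simulate_run(cfg)
  res <- demultiplex(run$reads[[1]], run$design)
  expect_equal(res$stats$unassigned_reads, 0L)
  merged <- dplyr::inner_join(
    res$assignments, run$truth$provenance,
    by = "read_id", suffix = c("", ".true"))
  expect_equal(nrow(merged), res$stats$assigned_reads)
  expect_true(all(merged$sample == merged$sample.true))
  expect_true(all(merged$marker == merged$marker.true))
  expect_true(all(merged$replicate == merged$replicate.true))
})

test_that("dereplication pools identical reads and conserves read counts", {
  d <- tiny_design(n_samples = 1)
  rows <- tibble::as_tibble(d)
  s1 <- strrep("ACGT", 30)
  s2 <- strrep("TTCA", 30)
  reads <- c(
    make_read(rows[1, ], mk, s1), make_read(rows[1, ], mk, s1),
    make_read(rows[1, ], mk, s1), make_read(rows[1, ], mk, s2))
  res <- demultiplex(reads, d)
  der <- dereplicate(res)
  expect_equal(nrow(der$variants), 2L)
  expect_equal(sort(der$counts$count), c(1L, 3L))
  expect_equal(sum(der$counts$count), res$stats$assigned_reads)
})

test_that("variant identity is scoped per marker", {
  d <- tiny_design(n_samples = 1)
  rows <- tibble::as_tibble(d)
  ins <- strrep("GATTACA", 20)
  r_mfzr <- rows[rows$marker == "MFZR", ][1, ]
  r_zfzr <- rows[rows$marker == "ZFZR", ][1, ]
  reads <- c(make_read(r_mfzr, mk, ins), make_read(r_zfzr, mk, ins))
  der <- dereplicate(demultiplex(reads, d))
  expect_equal(nrow(der$variants), 2L)
  expect_setequal(der$variants$marker, c("MFZR", "ZFZR"))
  expect_equal(unique(der$variants$seq), ins)
})

test_that("reads with non-ACGT symbols are discarded and counted", {
  d <- tiny_design(n_samples = 1)
  row <- tibble::as_tibble(d)[1, ]
  good <- make_read(row, mk, strrep("ACGT", 30))
  bad <- make_read(row, mk, paste0(strrep("ACGT", 29), "ACGN"))
  res <- demultiplex(c(good, bad), d)
  der <- dereplicate(res)
  expect_equal(der$n_discarded, 1L)
  expect_equal(sum(der$counts$count), 1L)
})

test_that("demultiplexing is order-independent", {
  cfg <- sim_config(seed = 11, n_edna = 2, reads_per_pcr = 40, n_taxa = 14)
  run <- simulate_run(cfg)
  reads <- run$reads[[1]]
  der1 <- dereplicate(demultiplex(reads, run$design))
  perm <- withr::with_seed(1, sample(length(reads)))
  der2 <- dereplicate(demultiplex(reads[perm], run$design))
  expect_equal(der1$variants, der2$variants)
  expect_equal(der1$counts, der2$counts)
})
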