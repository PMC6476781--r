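# Independent oracles used by the property and acceptance tests.

# Exhaustive grid search for the LFN threshold calibration: iterates the full
# candidate grid in ascending lexicographic order and keeps the first triple
# attaining the maximum number of must-drop removals among thresholds that
# keep every must-keep occurrence.
brute_force_calibrate <- function(st) {
  keep <- st$must_keep
  drop <- st$must_drop & !st$must_keep
  a_cands <- sort(unique(c(0, st$count + 1)))
  v_cands <- sort(unique(c(0, st$var_ratio, st$var_ratio + 1e-9)))
  r_cands <- sort(unique(c(0, st$rep_ratio, st$rep_ratio + 1e-9)))
  if (any(keep)) {
    a_cands <- a_cands[a_cands <= min(st$count[keep])]
    v_cands <- v_cands[v_cands <= min(st$var_ratio[keep])]
    r_cands <- r_cands[r_cands <= min(st$rep_ratio[keep])]
  }
  best <- NULL
  for (a in a_cands) {
    A <- st$count < a
    for (v in v_cands) {
      AV <- A | st$var_ratio < v
      for (r in r_cands) {
        rem <- AV | st$rep_ratio < r
        n <- sum(rem & drop)
        if (is.null(best) || n > best$n) {
          best <- list(n = n, t_abs = a, t_var = v, t_rep = r,
                       removed = rem)
        }
      }
    }
  }
  best
}

# Random dereplicated count table with mock / negative / eDNA samples, for
# calibration and filter-law property tests.
random_count_table <- function(seed, n_variants = 6, n_samples = 4,
                               n_reps = 3, lambda = 8) {
  withr::with_seed(seed, {
    cats <- c("mock", "neg_pcr", rep("edna", n_samples - 2))
    samples <- sprintf("s%02d", seq_len(n_samples))
    grid <- tidyr::expand_grid(
      run = "run01", marker = "MFZR",
      variant_id = sprintf("MFZR_%06d", seq_len(n_variants)),
      sample = samples, replicate = seq_len(n_reps))
    grid$category <- cats[match(grid$sample, samples)]
    grid$count <- stats::rpois(nrow(grid), lambda) *
      stats::rbinom(nrow(grid), 1, 0.6)
    dplyr::filter(grid[c("run", "marker", "variant_id", "sample",
                         "category", "replicate", "count")], count > 0)
  })
}

# Annotate a count table with the statistics and control flags that
# calibrate_group / brute_force_calibrate consume.
calibration_instance <- function(seed, max_occurrences = 50, ...) {
  tab <- random_count_table(seed, ...)
  st <- olspr:::occurrence_stats(tab)
  st <- st[seq_len(min(nrow(st), max_occurrences)), ]
  withr::with_seed(seed + 1, {
    mock_rows <- which(st$category == "mock")
    keep_rows <- sample(mock_rows, size = min(length(mock_rows),
                                              stats::rpois(1, 3) + 1))
    st$must_keep <- seq_len(nrow(st)) %in% keep_rows
    st$must_drop <- (st$category == "neg_pcr" |
                       (st$category == "mock" & !st$must_keep))
  })
  st
}

# Naive complete-linkage clustering at a height cut, via stats::hclust --
# an implementation wholly independent of the package's agglomerator.
hclust_partition <- function(d, threshold) {
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  grp <- stats::cutree(hc, h = threshold)
  unname(lapply(split(names(grp), grp), sort))
}

partition_key <- function(part) {
  paste(sort(vapply(part, paste, character(1), collapse = ",")),
        collapse = "|")
}

# A concrete ACGT instance of an IUPAC pattern (first allowed base).
first_realization <- function(pattern) {
  tab <- olspr:::iupac_table()
  paste(vapply(strsplit(toupper(pattern), "")[[1]],
               function(ch) tab[[ch]][1], character(1)), collapse = "")
}

# Construct a merged tagged read for a design row.
make_read <- function(design_row, markers, insert) {
  mk <- markers[markers$marker == design_row$marker, ]
  paste0(design_row$fwd_tag, first_realization(mk$fwd_primer), insert,
         olspr:::revcomp(first_realization(mk$rev_primer)),
         olspr:::revcomp(design_row$rev_tag))
}

# Minimal one-run design for demux tests.
tiny_design <- function(n_samples = 2, n_reps = 3) {
  fwd_tags <- c("AAAAAAAAAAA", "TTTTTTTTTTT", "CCCCCCCCCCC")
  rev_tags <- c("GGGGGGGGGGG", "ACACACACACA", "GTGTGTGTGTG")
  mk <- default_markers()
  rows <- tidyr::expand_grid(marker = mk$marker,
                             sample_i = seq_len(n_samples),
                             replicate = seq_len(n_reps)) |>
    dplyr::mutate(run = "run01",
                  sample = sprintf("s%02d", sample_i),
                  category = "edna",
                  fwd_tag = fwd_tags[sample_i],
                  rev_tag = rev_tags[replicate],
                  predator = "fish", habitat = "freshwater") |>
    dplyr::select(dplyr::all_of(olspr:::design_columns()))
  new_design(rows, markers = mk)
}
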