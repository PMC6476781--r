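#' Low-frequency-noise thresholds
#'
#' The three-filter family used to remove low-frequency noise (tag jumps,
#' cross-contamination, PCR point errors) from a dereplicated read-count
#' table:
#' * `t_abs`: minimum absolute read count of an occurrence;
#' * `t_var`: minimum ratio of the occurrence's reads over that variant's
#'   run-wide total (removes tag-jump leakage of abundant variants);
#' * `t_rep`: minimum ratio of the occurrence's reads over its PCR
#'   replicate's total reads.
#'
#' Setting a component to 0 disables that sub-filter.
#'
#' @param t_abs Non-negative integer (default 0).
#' @param t_var,t_rep Fractions in `[0, 1]` (default 0).
#' @return A list of class `lfn_thresholds`.
#' @export
lfn_thresholds <- function(t_abs = 0L, t_var = 0, t_rep = 0) {
  stopifnot(t_abs >= 0, t_var >= 0, t_var <= 1, t_rep >= 0, t_rep <= 1)
  structure(list(t_abs = as.numeric(t_abs), t_var = t_var, t_rep = t_rep),
            class = "lfn_thresholds")
}

occurrence_stats <- function(counts) {
  counts |>
    dplyr::group_by(.data$run, .data$marker, .data$variant_id) |>
    dplyr::mutate(variant_total = sum(.data$count)) |>
    dplyr::group_by(.data$run, .data$marker, .data$sample, .data$replicate) |>
    dplyr::mutate(replicate_total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      var_ratio = ifelse(.data$variant_total > 0,
                         .data$count / .data$variant_total, 0),
      rep_ratio = ifelse(.data$replicate_total > 0,
                         .data$count / .data$replicate_total, 0))
}

threshold_table <- function(th, counts) {
  if (inherits(th, "lfn_thresholds")) {
    dplyr::distinct(counts, .data$run, .data$marker) |>
      dplyr::mutate(t_abs = th$t_abs, t_var = th$t_var, t_rep = th$t_rep)
  } else if (inherits(th, "olsp_calibration")) {
    th$thresholds
  } else {
    tibble::as_tibble(th)
  }
}

#' Apply low-frequency-noise filters to a read-count table
#'
#' An occurrence (variant i, sample j, replicate k) is kept iff
#' `N_ijk >= t_abs`, `N_ijk / N_i.. >= t_var` and `N_ijk / N_.jk >= t_rep`.
#' Both denominators are computed once on the input table, not recomputed
#' between sub-filters, which makes the filter order-independent and
#' idempotent. Thresholds apply per run and per marker.
#'
#' @param counts Read-count table (tibble with columns
#'   `run, marker, variant_id, sample, category, replicate, count`).
#' @param thresholds An [lfn_thresholds()] object applied everywhere, a
#'   thresholds tibble with columns `run, marker, t_abs, t_var, t_rep`, or an
#'   `olsp_calibration` from [calibrate_lfn()].
#' @return A list with `counts` (the filtered table) and `trace` (tibble of
#'   per-step occurrence removals; steps are attributed sequentially so that
#'   occurrences in = occurrences kept + total removed).
#' @export
lfn_filter <- function(counts, thresholds) {
  if (nrow(counts) == 0) {
    return(list(counts = counts,
                trace = tibble::tibble(filter = c("lfn_abs", "lfn_var",
                                                  "lfn_rep"),
                                       occurrences_removed = c(0L, 0L, 0L))))
  }
  tt <- threshold_table(thresholds, counts)
  st <- occurrence_stats(counts) |>
    dplyr::left_join(tt, by = c("run", "marker")) |>
    dplyr::mutate(
      t_abs = dplyr::coalesce(.data$t_abs, 0),
      t_var = dplyr::coalesce(.data$t_var, 0),
      t_rep = dplyr::coalesce(.data$t_rep, 0),
      rm_abs = .data$count < .data$t_abs,
      rm_var = !.data$rm_abs & .data$var_ratio < .data$t_var,
      rm_rep = !.data$rm_abs & !.data$rm_var & .data$rep_ratio < .data$t_rep)
  trace <- tibble::tibble(
    filter = c("lfn_abs", "lfn_var", "lfn_rep"),
    occurrences_removed = c(sum(st$rm_abs), sum(st$rm_var), sum(st$rm_rep)))
  kept <- st[!(st$rm_abs | st$rm_var | st$rm_rep), names(counts)]
  list(counts = kept, trace = trace)
}

occurrence_keys <- function(x, counts) {
  keys <- intersect(names(x),
                    c("run", "marker", "variant_id", "sample", "replicate"))
  if (length(keys) == 0) stop("occurrence set has no key columns")
  dplyr::semi_join(counts, dplyr::distinct(x[keys]), by = keys)
}

# Per-group calibration: among thresholds keeping every must-keep occurrence,
# maximise removals of must-drop occurrences; among maximisers take the
# lexicographically smallest (t_abs, t_var, t_rep). Separable because the
# removal region is a union over the three statistics.
calibrate_group <- function(st) {
  keep <- st$must_keep
  drop <- st$must_drop & !st$must_keep
  a_bound <- if (any(keep)) min(st$count[keep]) else Inf
  v_bound <- if (any(keep)) min(st$var_ratio[keep]) else Inf
  r_bound <- if (any(keep)) min(st$rep_ratio[keep]) else Inf

  in_A <- st$count < a_bound
  in_V <- st$var_ratio < v_bound
  in_R <- st$rep_ratio < r_bound
  removable <- drop & (in_A | in_V | in_R)

  next_ratio_threshold <- function(values, cover_vals, bound) {
    if (length(cover_vals) == 0) return(0)
    top <- max(cover_vals)
    cand <- sort(unique(values[values > top]))
    cand <- cand[cand <= bound]
    if (length(cand) > 0) cand[1] else top + 1e-9
  }

  cover_a <- removable & !in_V & !in_R
  t_abs <- if (any(cover_a)) max(st$count[cover_a]) + 1 else 0
  rm_a <- st$count < t_abs
  cover_v <- removable & !rm_a & !in_R
  t_var <- next_ratio_threshold(st$var_ratio, st$var_ratio[cover_v], v_bound)
  rm_v <- st$var_ratio < t_var
  cover_r <- removable & !rm_a & !rm_v
  t_rep <- next_ratio_threshold(st$rep_ratio, st$rep_ratio[cover_r], r_bound)

  removed <- st$count < t_abs | st$var_ratio < t_var | st$rep_ratio < t_rep
  list(t_abs = t_abs, t_var = t_var, t_rep = t_rep,
       retained_expected = sum(keep & !removed),
       eliminated_unexpected = sum(drop & removed),
       unremovable = st[drop & !removable, , drop = FALSE])
}

#' Calibrate noise thresholds on mock and negative controls
#'
#' Finds, per run and marker, the threshold triple that keeps every expected
#' mock occurrence (hard constraint) while removing as many unexpected
#' occurrences as possible (occurrences in negative controls, non-expected
#' occurrences in mocks, and any further occurrences supplied in `must_drop`,
#' e.g. habitat-incompatible detections for a second filtering round).
#' Among the removal-maximising thresholds the lexicographically smallest
#' `(t_abs, t_var, t_rep)` is returned. The search runs over the finite grid
#' of observed occurrence statistics; thresholds between observed values are
#' behaviourally identical. Unexpected occurrences that no feasible threshold
#' can remove (stronger than the weakest expected mock occurrence on all
#' three statistics) are reported as `unremovable` rather than sacrificing
#' mock retention. Expected occurrences absent from the table are reported as
#' `mock_dropouts`, not raised as errors.
#'
#' @param counts Read-count table (see [lfn_filter()]).
#' @param must_keep Tibble of occurrence keys (any of
#'   `run, marker, variant_id, sample, replicate`) that filtering must
#'   retain; typically the expected mock-community occurrences.
#' @param must_drop Tibble of occurrence keys that filtering should remove.
#'   Occurrences in negative-control samples are always added to this set.
#' @return An `olsp_calibration`: list with `thresholds` (tibble
#'   `run, marker, t_abs, t_var, t_rep`), `report` (per run x marker retained
#'   and eliminated counts), `unremovable`, and `mock_dropouts`.
#' @export
calibrate_lfn <- function(counts, must_keep = NULL, must_drop = NULL) {
  st <- occurrence_stats(counts)
  keep_tbl <- if (!is.null(must_keep) && nrow(must_keep) > 0) {
    occurrence_keys(must_keep, counts)
  } else counts[0, ]
  drop_tbl <- dplyr::bind_rows(
    if (!is.null(must_drop) && nrow(must_drop) > 0) {
      occurrence_keys(must_drop, counts)
    } else counts[0, ],
    dplyr::filter(counts, .data$category %in% negative_categories())
  ) |> dplyr::distinct()

  key <- c("run", "marker", "variant_id", "sample", "replicate")
  st$must_keep <- vctrs::vec_in(st[key], keep_tbl[key])
  st$must_drop <- vctrs::vec_in(st[key], drop_tbl[key])

  groups <- dplyr::group_split(dplyr::group_by(st, .data$run, .data$marker))
  fits <- purrr::map(groups, calibrate_group)
  heads <- purrr::map(groups, ~ .x[1, c("run", "marker")])

  thresholds <- purrr::map2(heads, fits, function(h, f) {
    dplyr::mutate(h, t_abs = f$t_abs, t_var = f$t_var, t_rep = f$t_rep)
  }) |> dplyr::bind_rows()
  report <- purrr::map2(heads, fits, function(h, f) {
    dplyr::mutate(h, retained_expected = f$retained_expected,
                  eliminated_unexpected = f$eliminated_unexpected,
                  n_unremovable = nrow(f$unremovable))
  }) |> dplyr::bind_rows()
  unremovable <- purrr::map(fits, "unremovable") |>
    dplyr::bind_rows() |>
    dplyr::select(dplyr::all_of(names(counts)))

  dropouts <- if (!is.null(must_keep) && nrow(must_keep) > 0) {
    keys <- intersect(names(must_keep),
                      c("run", "marker", "variant_id", "sample", "replicate"))
    dplyr::anti_join(dplyr::distinct(must_keep[keys]), counts, by = keys)
  } else tibble::tibble()

  structure(list(thresholds = thresholds, report = report,
                 unremovable = unremovable, mock_dropouts = dropouts),
            class = "olsp_calibration")
}

#' @export
print.olsp_calibration <- function(x, ...) {
  cat("<olsp_calibration> thresholds for", nrow(x$thresholds),
      "run x marker group(s)\n")
  print(x$thresholds)
  cat("retained expected:", sum(x$report$retained_expected),
      "| eliminated unexpected:", sum(x$report$eliminated_unexpected),
      "| unremovable:", nrow(x$unremovable),
      "| mock dropouts:", nrow(x$mock_dropouts), "\n")
  invisible(x)
}

#' Renkonen distance between two count or frequency profiles
#'
#' `1 - sum(pmin(p, q))` after normalising each profile to sum 1.
#' @param p,q Non-negative numeric vectors on the same variant axis.
#' @return Distance in `[0, 1]`.
#' @export
renkonen_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (sum(p) == 0 || sum(q) == 0) return(1)
  1 - sum(pmin(p / sum(p), q / sum(q)))
}

#' Screen PCR replicates by Renkonen distance
#'
#' Within each (sample, marker), each replicate's variant profile is
#' normalised to relative frequencies; a replicate whose mean Renkonen
#' distance to the other replicates exceeds `cutoff` is dropped with all its
#' occurrences. Singleton replicates pass untouched. Replicates expected from
#' the design but carrying zero reads are dropped with reason `"empty"`.
#'
#' @param counts Read-count table.
#' @param cutoff Maximum tolerated mean Renkonen distance (default 0.5).
#' @param design Optional `olsp_design` used to enumerate expected replicates
#'   (so empty replicates can be reported).
#' @return A list with `counts` (screened table) and `dropped` (tibble:
#'   `run, marker, sample, replicate, mean_distance, reason`).
#' @export
renkonen_screen <- function(counts, cutoff = 0.5, design = NULL) {
  dropped <- tibble::tibble(run = character(), marker = character(),
                            sample = character(), replicate = integer(),
                            mean_distance = numeric(), reason = character())
  if (!is.null(design)) {
    empties <- tibble::as_tibble(design) |>
      dplyr::anti_join(counts, by = c("run", "marker", "sample", "replicate")) |>
      dplyr::transmute(.data$run, .data$marker, .data$sample, .data$replicate,
                       mean_distance = NA_real_, reason = "empty")
    dropped <- dplyr::bind_rows(dropped, empties)
  }
  if (nrow(counts) == 0) return(list(counts = counts, dropped = dropped))

  grp <- dplyr::group_by(counts, .data$run, .data$marker, .data$sample)
  out <- dplyr::group_map(grp, function(g, key) {
    reps <- sort(unique(g$replicate))
    if (length(reps) < 2) return(list(drop = NULL))
    prof <- g |>
      dplyr::group_by(.data$replicate) |>
      dplyr::mutate(freq = .data$count / sum(.data$count)) |>
      dplyr::ungroup() |>
      tidyr::pivot_wider(id_cols = "variant_id", names_from = "replicate",
                        values_from = "freq", values_fill = 0)
    m <- as.matrix(prof[, as.character(reps), drop = FALSE])
    dmat <- outer(seq_along(reps), seq_along(reps),
                  Vectorize(function(i, j) {
                    if (i == j) 0 else 1 - sum(pmin(m[, i], m[, j]))
                  }))
    mean_d <- rowSums(dmat) / (length(reps) - 1)
    bad <- which(mean_d > cutoff)
    if (length(bad) == 0) return(list(drop = NULL))
    list(drop = dplyr::mutate(key, replicate = list(reps[bad]),
                              mean_distance = list(mean_d[bad])) |>
           tidyr::unnest(c("replicate", "mean_distance")) |>
           dplyr::mutate(reason = "renkonen"))
  })
  drops <- dplyr::bind_rows(purrr::map(out, "drop"))
  dropped <- dplyr::bind_rows(dropped, drops)
  kept <- dplyr::anti_join(counts, dropped,
                           by = c("run", "marker", "sample", "replicate"))
  list(counts = kept, dropped = dropped)
}

#' Validate variants present in a minimum number of PCR replicates
#'
#' A (variant, sample, marker) combination is validated iff the variant is
#' present with positive count in at least `min_replicates` surviving
#' replicates of that sample; its pooled count is the sum over those
#' replicates. Everything else is removed. Replicates dropped by
#' [renkonen_screen()] cannot support validation.
#'
#' @param counts Read-count table after LFN filtering and replicate
#'   screening.
#' @param min_replicates Minimum replicate support (default 2).
#' @return A tibble of validated occurrences:
#'   `run, marker, variant_id, sample, category, n_replicates, count`.
#' @export
replicate_consensus <- function(counts, min_replicates = 2L) {
  counts |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$run, .data$marker, .data$variant_id, .data$sample,
                    .data$category) |>
    dplyr::summarise(n_replicates = dplyr::n_distinct(.data$replicate),
                     count = sum(.data$count), .groups = "drop") |>
    dplyr::filter(.data$n_replicates >= min_replicates)
}

#' Second filtering round driven by habitat-unexpected detections
#'
#' After a first pass of calibration, filtering and taxonomic assignment,
#' detections that are incompatible with their sample's habitat (e.g. a
#' freshwater-only taxon in a brackish-water sample) are evidence of residual
#' noise. Their occurrences are added to the must-drop set, thresholds are
#' recalibrated on the original dereplicated table, and the full filter /
#' replicate-screen / consensus chain is re-run. Taxa absent from
#' `habitat_map` are treated as compatible everywhere (never auto-dropped)
#' and listed in `unknown_taxa`.
#'
#' @param counts The original dereplicated read-count table.
#' @param design The run design (habitats per sample).
#' @param validated First-pass validated occurrences
#'   (from [replicate_consensus()]).
#' @param taxa Tibble `variant_id, taxon` with first-pass assignments.
#' @param habitat_map Tibble `taxon, habitat`; a taxon may list several
#'   compatible habitats on several rows.
#' @param must_keep,must_drop Occurrence sets as in [calibrate_lfn()].
#' @param cutoff Renkonen cutoff (default 0.5).
#' @param min_replicates Minimum replicate support (default 2).
#' @return A list with `calibration` (second-pass `olsp_calibration`),
#'   `validated` (final validated occurrences), `counts` (final filtered
#'   table), `unexpected` (the habitat-incompatible detections), and
#'   `unknown_taxa`.
#' @export
lfn_second_pass <- function(counts, design, validated, taxa, habitat_map,
                            must_keep = NULL, must_drop = NULL,
                            cutoff = 0.5, min_replicates = 2L) {
  sample_habitat <- tibble::as_tibble(design) |>
    dplyr::distinct(.data$sample, .data$habitat)
  assigned <- dplyr::inner_join(validated, taxa, by = "variant_id") |>
    dplyr::filter(.data$category == "edna") |>
    dplyr::left_join(sample_habitat, by = "sample")
  known <- dplyr::filter(assigned, .data$taxon %in% habitat_map$taxon)
  unknown_taxa <- setdiff(unique(assigned$taxon), habitat_map$taxon)
  unexpected <- dplyr::anti_join(known, habitat_map,
                                 by = c("taxon", "habitat")) |>
    dplyr::distinct(.data$run, .data$marker, .data$variant_id, .data$sample)

  drop2 <- dplyr::bind_rows(
    if (!is.null(must_drop)) must_drop else NULL,
    unexpected
  )
  calibration <- calibrate_lfn(counts, must_keep = must_keep,
                               must_drop = drop2)
  filtered <- lfn_filter(counts, calibration)
  screened <- renkonen_screen(filtered$counts, cutoff = cutoff,
                              design = design)
  validated2 <- replicate_consensus(screened$counts,
                                    min_replicates = min_replicates)
  list(calibration = calibration, validated = validated2,
       counts = screened$counts, unexpected = unexpected,
       unknown_taxa = unknown_taxa)
}
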