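metric_levels <- function() {
  c("phylum", "class", "order", "family", "motu", "variant")
}

#' Item labels at every aggregation level
#'
#' Maps each validated item to its label at the six levels used by the
#' coverage/complementarity analyses: Phylum, Class, Order, Family, MOTU and
#' variant. Items with no assignment at a taxonomic rank fall back to their
#' MOTU id, so every item maps to exactly one bin at every level and
#' per-sample item totals are conserved under aggregation.
#'
#' @param assignments Tibble from [assign_taxa()] (must contain `item_id` and
#'   the taxonomy columns).
#' @param motus An `olsp_motus` object from [cluster_motus()] (or its
#'   `membership` tibble).
#' @return A tibble `item_id, phylum, class, order, family, motu, variant`.
#' @export
item_levels <- function(assignments, motus) {
  membership <- if (inherits(motus, "olsp_motus")) motus$membership else motus
  out <- assignments |>
    dplyr::left_join(membership[c("item_id", "motu_id")], by = "item_id") |>
    dplyr::transmute(
      item_id = .data$item_id,
      phylum = dplyr::coalesce(.data$phylum, .data$motu_id),
      class = dplyr::coalesce(.data$class, .data$motu_id),
      order = dplyr::coalesce(.data$order, .data$motu_id),
      family = dplyr::coalesce(.data$family, .data$motu_id),
      motu = .data$motu_id,
      variant = .data$item_id)
  out
}

#' Minimal Number of Individuals matrix at one level
#'
#' The MNI of a taxon in a sample is the number of distinct validated items
#' (variants or contigs) of that taxon detected in the sample, pooled over
#' primer sets (an item detected by several markers counts once).
#'
#' @param detections Tibble of per-sample, per-marker item detections
#'   (columns `sample, marker, item_id`; extra columns are ignored).
#' @param levels Item-level table from [item_levels()].
#' @param level One of `r paste(metric_levels(), collapse = ", ")`.
#' @return Long tibble `sample, taxon, mni`.
#' @export
mni_matrix <- function(detections, levels, level = "variant") {
  level <- match.arg(level, metric_levels())
  detections |>
    dplyr::inner_join(levels[c("item_id", level)], by = "item_id") |>
    dplyr::distinct(.data$sample, taxon = .data[[level]], .data$item_id) |>
    dplyr::count(.data$sample, .data$taxon, name = "mni")
}

#' Coverage ratio of one primer set
#'
#' Fraction of all detected taxa that a given primer set recovered:
#' `|detected_by_p| / |detected_by_all|`.
#' @param detected_by_p Character vector (or set) of taxa detected by the
#'   primer set; must be a subset of `detected_by_all`.
#' @param detected_by_all Taxa detected by all primer sets together.
#' @return Fraction in `[0, 1]`, or `NA` when the union is empty (cell
#'   excluded).
#' @export
coverage_bc <- function(detected_by_p, detected_by_all) {
  p <- unique(detected_by_p); u <- unique(detected_by_all)
  if (length(setdiff(p, u)) > 0) {
    stop("primer-set detections are not a subset of the union")
  }
  if (length(u) == 0) return(NA_real_)
  length(p) / length(u)
}

#' Complementarity of primer sets
#'
#' Fraction of detected taxa recovered by exactly one primer set:
#' `|exactly-one| / |union|`.
#' @param detections_by_set A named list of character vectors, one per primer
#'   set (at least two).
#' @return Fraction in `[0, 1]`, or `NA` when the union is empty.
#' @export
complementarity_com <- function(detections_by_set) {
  stopifnot(length(detections_by_set) >= 2)
  sets <- lapply(detections_by_set, unique)
  u <- unique(unlist(sets))
  if (length(u) == 0) return(NA_real_)
  hits <- vapply(u, function(t) {
    sum(vapply(sets, function(s) t %in% s, logical(1)))
  }, numeric(1))
  sum(hits == 1) / length(u)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))` on aligned taxon axes.
#' @param x,y Non-negative numeric vectors of equal length.
#' @return Dissimilarity in `[0, 1]`; `NA` when both vectors are all zero.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  tot <- sum(x) + sum(y)
  if (tot == 0) return(NA_real_)
  1 - 2 * sum(pmin(x, y)) / tot
}

per_marker_mni <- function(detections, levels, level) {
  detections |>
    dplyr::inner_join(levels[c("item_id", level)], by = "item_id") |>
    dplyr::distinct(.data$sample, .data$marker, taxon = .data[[level]],
                    .data$item_id) |>
    dplyr::count(.data$sample, .data$marker, .data$taxon, name = "mni")
}

#' Within-sample dissimilarity between primer sets
#'
#' For each sample detected by at least two primer sets at the given level,
#' the pairwise Bray-Curtis dissimilarities between the per-primer-set MNI
#' vectors, each computed from that primer set's own detections only. High
#' values mean the primer sets paint different pictures of the same diet.
#'
#' @inheritParams mni_matrix
#' @return Tibble `sample, marker_1, marker_2, level, value`.
#' @export
wsd <- function(detections, levels, level = "variant") {
  level <- match.arg(level, metric_levels())
  pm <- per_marker_mni(detections, levels, level)
  out <- pm |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_map(function(g, key) {
      mk <- sort(unique(g$marker))
      if (length(mk) < 2) return(NULL)
      wide <- tidyr::pivot_wider(g, id_cols = "taxon", names_from = "marker",
                                 values_from = "mni", values_fill = 0)
      pairs <- utils::combn(mk, 2)
      tibble::tibble(
        sample = key$sample,
        marker_1 = pairs[1, ], marker_2 = pairs[2, ],
        value = apply(pairs, 2, function(p) {
          bray_curtis(wide[[p[1]]], wide[[p[2]]])
        }))
    }) |> dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble::tibble(sample = character(), marker_1 = character(),
                          marker_2 = character(), value = numeric())
  }
  dplyr::mutate(out, level = level, .before = "value")
}

#' Between-sample dissimilarity on combined MNI
#'
#' Pairwise Bray-Curtis dissimilarities between samples on their combined
#' (all primer sets pooled) MNI vectors at the given level.
#'
#' @inheritParams mni_matrix
#' @return Tibble `sample_1, sample_2, level, value`.
#' @export
bsd <- function(detections, levels, level = "variant") {
  level <- match.arg(level, metric_levels())
  m <- mni_matrix(detections, levels, level)
  samples <- sort(unique(m$sample))
  if (length(samples) < 2) {
    return(tibble::tibble(sample_1 = character(), sample_2 = character(),
                          level = character(), value = numeric()))
  }
  wide <- tidyr::pivot_wider(m, id_cols = "taxon", names_from = "sample",
                             values_from = "mni", values_fill = 0)
  pairs <- utils::combn(samples, 2)
  tibble::tibble(
    sample_1 = pairs[1, ], sample_2 = pairs[2, ], level = level,
    value = apply(pairs, 2, function(p) bray_curtis(wide[[p[1]]],
                                                    wide[[p[2]]])))
}

#' Per-sample MNI totals and per-group summaries
#'
#' A sample's total MNI is its number of distinct validated items. Group
#' dispersion uses the sample standard deviation (n - 1 denominator).
#'
#' @param detections Tibble with columns `sample, item_id` and optionally a
#'   grouping column.
#' @param group Name of the grouping column (e.g. `"predator_group"`), or
#'   `NULL` for per-sample totals only.
#' @return A list with `per_sample` (tibble `sample, mni`) and `per_group`
#'   (tibble `group, n_samples, mean_mni, sd_mni`; `NULL` when no group).
#' @export
mni_summary <- function(detections, group = NULL) {
  per_sample <- detections |>
    dplyr::distinct(.data$sample, .data$item_id,
                    dplyr::across(dplyr::any_of(group))) |>
    dplyr::count(.data$sample, dplyr::across(dplyr::any_of(group)),
                 name = "mni")
  per_group <- NULL
  if (!is.null(group)) {
    per_group <- per_sample |>
      dplyr::group_by(.data[[group]]) |>
      dplyr::summarise(n_samples = dplyr::n(),
                       mean_mni = mean(.data$mni),
                       sd_mni = stats::sd(.data$mni), .groups = "drop")
  }
  list(per_sample = dplyr::select(per_sample, "sample",
                                  dplyr::any_of(group), "mni"),
       per_group = per_group)
}

#' Coverage, complementarity, dissimilarity and resolution report
#'
#' Computes, at every aggregation level: per-sample and global coverage (Bc)
#' of each primer set, per-sample and global complementarity (Com),
#' within-sample (Wsd) and between-sample (Bsd) Bray-Curtis dissimilarities,
#' per-sample MNI totals, and the per-sample identification-resolution (IR)
#' index.
#'
#' @param detections Tibble of per-sample, per-marker item detections with
#'   columns `sample, marker, item_id` (plus optional grouping columns such
#'   as `predator_group`).
#' @param assignments Tibble from [assign_taxa()].
#' @param motus An `olsp_motus` object.
#' @param group Optional grouping column name in `detections` for MNI
#'   summaries.
#' @return An `olsp_metrics` object: list of tibbles `mni`, `bc_sample`,
#'   `bc_global`, `com_sample`, `com_global`, `wsd`, `bsd`, `ir`,
#'   `mni_summary`.
#' @export
compute_metrics <- function(detections, assignments, motus, group = NULL) {
  lv <- item_levels(assignments, motus)
  levels_used <- metric_levels()

  mni <- purrr::map(levels_used, function(L) {
    dplyr::mutate(mni_matrix(detections, lv, L), level = L, .before = 1)
  }) |> dplyr::bind_rows()

  det_lv <- function(L) {
    detections |>
      dplyr::inner_join(lv[c("item_id", L)], by = "item_id") |>
      dplyr::rename(taxon = dplyr::all_of(L))
  }

  bc_sample <- purrr::map(levels_used, function(L) {
    d <- det_lv(L)
    d |>
      dplyr::group_by(.data$sample) |>
      dplyr::group_map(function(g, key) {
        u <- unique(g$taxon)
        g |>
          dplyr::group_by(.data$marker) |>
          dplyr::summarise(value = coverage_bc(unique(.data$taxon), u),
                           .groups = "drop") |>
          dplyr::mutate(sample = key$sample, level = L)
      }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  bc_global <- purrr::map(levels_used, function(L) {
    d <- det_lv(L)
    u <- unique(d$taxon)
    d |>
      dplyr::group_by(.data$marker) |>
      dplyr::summarise(value = coverage_bc(unique(.data$taxon), u),
                       .groups = "drop") |>
      dplyr::mutate(level = L)
  }) |> dplyr::bind_rows()

  markers_all <- sort(unique(detections$marker))
  com_of <- function(d) {
    if (length(markers_all) < 2) return(NA_real_)
    sets <- purrr::map(markers_all, function(m) unique(d$taxon[d$marker == m]))
    names(sets) <- markers_all
    complementarity_com(sets)
  }
  com_sample <- purrr::map(levels_used, function(L) {
    det_lv(L) |>
      dplyr::group_by(.data$sample) |>
      dplyr::group_map(function(g, key) {
        tibble::tibble(sample = key$sample, level = L, value = com_of(g))
      }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  com_global <- purrr::map(levels_used, function(L) {
    tibble::tibble(level = L, value = com_of(det_lv(L)))
  }) |> dplyr::bind_rows()

  wsd_tbl <- purrr::map(levels_used,
                        function(L) wsd(detections, lv, L)) |>
    dplyr::bind_rows()
  bsd_tbl <- purrr::map(levels_used,
                        function(L) bsd(detections, lv, L)) |>
    dplyr::bind_rows()

  ir_tbl <- detections |>
    dplyr::distinct(.data$sample, .data$item_id) |>
    dplyr::inner_join(assignments[c("item_id", "resolution_rank")],
                      by = "item_id") |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_items = dplyr::n(),
                     ir = sample_ir(.data$resolution_rank),
                     .groups = "drop")

  structure(list(mni = mni, bc_sample = bc_sample, bc_global = bc_global,
                 com_sample = com_sample, com_global = com_global,
                 wsd = wsd_tbl, bsd = bsd_tbl, ir = ir_tbl,
                 mni_summary = mni_summary(detections, group = group)),
            class = "olsp_metrics")
}

#' @export
print.olsp_metrics <- function(x, ...) {
  cat("<olsp_metrics> levels:", paste(unique(x$mni$level), collapse = ", "),
      "\n  samples:", dplyr::n_distinct(x$ir$sample),
      "| mean IR:", round(mean(x$ir$ir, na.rm = TRUE), 2), "\n")
  invisible(x)
}
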