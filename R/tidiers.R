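#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration: one row per run x marker threshold triple
#' @param x An `olsp_calibration`.
#' @param ... Unused.
#' @return Tibble `run, marker, t_abs, t_var, t_rep` joined with the
#'   retention report.
#' @method tidy olsp_calibration
#' @export
tidy.olsp_calibration <- function(x, ...) {
  dplyr::left_join(x$thresholds, x$report, by = c("run", "marker"))
}

#' One-row calibration summary
#' @param x An `olsp_calibration`.
#' @param ... Unused.
#' @return Tibble with totals of retained, eliminated, unremovable and
#'   mock-dropout occurrences.
#' @method glance olsp_calibration
#' @export
glance.olsp_calibration <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$thresholds),
    retained_expected = sum(x$report$retained_expected),
    eliminated_unexpected = sum(x$report$eliminated_unexpected),
    n_unremovable = nrow(x$unremovable),
    n_mock_dropouts = nrow(x$mock_dropouts))
}

#' Tidy MOTU clustering: the membership table
#' @param x An `olsp_motus`.
#' @param ... Unused.
#' @return Tibble `item_id, motu_id, representative`.
#' @method tidy olsp_motus
#' @export
tidy.olsp_motus <- function(x, ...) x$membership

#' One-row MOTU clustering summary
#' @param x An `olsp_motus`.
#' @param ... Unused.
#' @return Tibble with MOTU and item counts and the largest intra-MOTU
#'   distance.
#' @method glance olsp_motus
#' @export
glance.olsp_motus <- function(x, ...) {
  max_intra <- 0
  for (m in unique(x$membership$motu_id)) {
    memb <- x$membership$item_id[x$membership$motu_id == m]
    if (length(memb) > 1) {
      max_intra <- max(max_intra, max(x$distances[memb, memb]))
    }
  }
  tibble::tibble(n_motus = nrow(x$motus), n_items = nrow(x$membership),
                 max_intra_distance = max_intra)
}

#' Tidy a pipeline result: one row per validated item with its MOTU and
#' taxonomic assignment
#' @param x An `olsp_pipeline`.
#' @param ... Unused.
#' @return Tibble of items, assignments and MOTU ids.
#' @method tidy olsp_pipeline
#' @export
tidy.olsp_pipeline <- function(x, ...) {
  x$assignments |>
    dplyr::left_join(x$motus$membership[c("item_id", "motu_id")],
                     by = "item_id")
}

#' One-row pipeline summary
#' @param x An `olsp_pipeline`.
#' @param ... Unused.
#' @return Tibble of headline counts: variants, validated occurrences,
#'   contigs, unmerged variants, items, MOTUs, mean sample IR.
#' @method glance olsp_pipeline
#' @export
glance.olsp_pipeline <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x$variants),
    n_validated_occurrences = nrow(x$validated),
    n_contigs = nrow(x$contigs$contigs),
    n_unmerged_variants = nrow(x$contigs$unmerged),
    n_items = nrow(x$items$items),
    n_motus = nrow(x$motus$motus),
    mean_ir = if (!is.null(x$metrics)) mean(x$metrics$ir$ir, na.rm = TRUE)
      else NA_real_)
}
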