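#' Sample categories recognised in a run design
#'
#' eDNA samples, mock-community positive controls, and the four kinds of
#' negative control (extraction, aerosol, PCR and tag negatives). All negative
#' kinds are kept as distinct labels but are treated identically by threshold
#' calibration, which pools them as "negative controls".
#' @return Character vector of valid `category` values.
#' @export
sample_categories <- function() {
  c("edna", "mock", "neg_extraction", "neg_aerosol", "neg_pcr", "neg_tag")
}

negative_categories <- function() {
  c("neg_extraction", "neg_aerosol", "neg_pcr", "neg_tag")
}

#' Environmental-sample census used by the default synthetic design
#'
#' A transcription of the study design the package emulates: 107 eDNA samples
#' across five predator groups (a freshwater fish, a brackish-water fish from
#' two lagoons, nine bat taxa, an equatorial freshwater fish, and spider webs).
#'
#' @return A tibble with columns `predator`, `predator_group`, `n_samples`,
#'   `material`, `habitat`, `region`.
#' @examples
#' sum(sample_census()$n_samples)  # 107
#' @export
sample_census <- function() {
  path <- system.file("extdata", "sample_census.tsv", package = "olspr",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Mock-community composition used as positive controls
#'
#' Two mock samples (Tpos1, Tpos2), each pooling DNA of seven prey taxa at
#' 0.2 ng/ul plus the predator (*Zingel asper*) at 0.8 ng/ul. Calibration of
#' the low-frequency-noise filters keeps every expected mock member while
#' removing as many unexpected occurrences as possible.
#'
#' @return A tibble with columns `mock`, `species`, `concentration`, `group`,
#'   `role` (`"prey"` or `"predator"`).
#' @export
mock_community <- function() {
  path <- system.file("extdata", "mock_community.tsv", package = "olspr",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

design_columns <- function() {
  c("run", "marker", "sample", "category", "replicate",
    "fwd_tag", "rev_tag", "predator", "habitat")
}

#' Parse a run-design table
#'
#' A run design maps tag pairs x marker to (sample, replicate) PCRs. One row
#' per PCR. Tag pairs must be unique within (run, marker): a duplicated tag
#' pair would make demultiplexing ambiguous.
#'
#' @param path Path to a TSV file with columns
#'   `run, marker, sample, category, replicate, fwd_tag, rev_tag, predator,
#'   habitat`.
#' @param markers Tibble of marker primer definitions (see
#'   [default_markers()]); every `marker` value in the design must appear here.
#' @return An `olsp_design` tibble (one row per PCR) with the marker table
#'   attached as attribute `"markers"`.
#' @export
parse_design <- function(path, markers = default_markers()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    run = readr::col_character(), marker = readr::col_character(),
    sample = readr::col_character(), category = readr::col_character(),
    replicate = readr::col_integer(), fwd_tag = readr::col_character(),
    rev_tag = readr::col_character(), predator = readr::col_character(),
    habitat = readr::col_character()
  ))
  missing_cols <- setdiff(design_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("design file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(raw$run) | is.na(raw$marker) | is.na(raw$sample) |
                 is.na(raw$category) | is.na(raw$replicate) |
                 is.na(raw$fwd_tag) | is.na(raw$rev_tag))
  if (length(bad) > 0) {
    stop("malformed design row(s) at line ", paste(bad[1] + 1L),
         ": required field missing")
  }
  new_design(raw[design_columns()], markers)
}

#' Construct a run design from a tibble
#' @param design Tibble with the design columns (see [parse_design()]).
#' @param markers Marker primer tibble.
#' @return An `olsp_design` tibble.
#' @export
new_design <- function(design, markers = default_markers()) {
  design <- tibble::as_tibble(design)
  validate_markers(markers)
  bad_cat <- setdiff(unique(design$category), sample_categories())
  if (length(bad_cat) > 0) {
    stop("unknown sample category: ", paste(bad_cat, collapse = ", "))
  }
  bad_marker <- setdiff(unique(design$marker), markers$marker)
  if (length(bad_marker) > 0) {
    stop("design references marker(s) not in the marker table: ",
         paste(bad_marker, collapse = ", "))
  }
  dup <- design |>
    dplyr::count(.data$run, .data$marker, .data$fwd_tag, .data$rev_tag) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("design conflict: tag pair ", dup$fwd_tag[1], "/", dup$rev_tag[1],
         " used more than once for marker ", dup$marker[1],
         " in run ", dup$run[1])
  }
  tag_len <- nchar(c(design$fwd_tag, design$rev_tag))
  if (any(tag_len < 11 | tag_len > 13)) {
    stop("tags must be 11-13 nt long")
  }
  dup_pcr <- design |>
    dplyr::count(.data$run, .data$marker, .data$sample, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_pcr) > 0) {
    stop("design conflict: duplicated PCR for sample ", dup_pcr$sample[1],
         " marker ", dup_pcr$marker[1], " replicate ", dup_pcr$replicate[1])
  }
  structure(design, markers = markers,
            class = c("olsp_design", class(tibble::tibble())))
}

#' @export
print.olsp_design <- function(x, ...) {
  cat("<olsp_design> ", dplyr::n_distinct(x$sample), " samples, ",
      dplyr::n_distinct(x$marker), " markers, ", nrow(x), " PCRs\n", sep = "")
  NextMethod()
}

#' Write a run design back to TSV
#'
#' Round-trips bit-identically through [parse_design()].
#' @param design An `olsp_design` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(tibble::as_tibble(design)[design_columns()], path)
  invisible(path)
}

design_markers <- function(design) {
  m <- attr(design, "markers")
  if (is.null(m)) default_markers() else m
}

#' Check the pairwise distinctness of a tag set
#'
#' Tags label the 5' ends of both primers and carry sample identity; a usable
#' tag set keeps every pair of tags at Hamming distance >= 3 so single
#' sequencing errors cannot convert one tag into another. Tags of unequal
#' length are compared over the shorter length from the read-proximal (5')
#' end, where they anchor on the primer construct.
#'
#' @param tags Character vector of at least two nucleotide tags.
#' @param min_mismatches Minimum required pairwise mismatch count (default 3).
#' @return A list with `min_pairwise_mismatches` and `ok`.
#' @examples
#' validate_tagset(c("AAAAAAAAAAA", "TTTTTTTTTTT"))
#' @export
validate_tagset <- function(tags, min_mismatches = 3L) {
  if (length(tags) == 0) stop("empty tag list")
  if (length(tags) < 2) stop("need at least two tags to compare")
  pairs <- utils::combn(length(tags), 2)
  mm <- apply(pairs, 2, function(ij) {
    a <- tags[ij[1]]; b <- tags[ij[2]]
    L <- min(nchar(a), nchar(b))
    sum(strsplit(substr(a, 1, L), "")[[1]] != strsplit(substr(b, 1, L), "")[[1]])
  })
  list(min_pairwise_mismatches = as.integer(min(mm)),
       ok = min(mm) >= min_mismatches)
}
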