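#' Predict amplicon inserts of a reference database (in-silico PCR)
#'
#' Locates each marker's forward primer and the reverse complement of its
#' reverse primer on every reference template (IUPAC-aware, up to
#' `max_mismatch` substitutions) and extracts the insert between them. Used
#' to map observed variants back to the reference taxa whose amplicons they
#' are, e.g. to identify the expected mock-community variants before any
#' taxonomic assignment exists.
#'
#' @param reference Reference list with `seqs` (and optionally precomputed
#'   `amplicons`, returned as-is).
#' @param markers Marker primer tibble.
#' @param max_mismatch Substitutions tolerated per primer (default 2).
#' @return Tibble `ref_id, marker, insert` (rows only where both primers
#'   match).
#' @export
predict_amplicons <- function(reference, markers = default_markers(),
                              max_mismatch = 2L) {
  if (!is.null(reference$amplicons)) {
    return(dplyr::transmute(
      dplyr::filter(reference$amplicons, .data$compatible),
      ref_id = .data$ref_id, marker = .data$marker, insert = .data$insert))
  }
  out <- list()
  for (i in seq_len(nrow(reference$seqs))) {
    subj <- Biostrings::DNAString(reference$seqs$seq[i])
    for (j in seq_len(nrow(markers))) {
      f <- Biostrings::matchPattern(markers$fwd_primer[j], subj,
                                    max.mismatch = max_mismatch,
                                    fixed = "subject")
      r <- Biostrings::matchPattern(revcomp(markers$rev_primer[j]), subj,
                                    max.mismatch = max_mismatch,
                                    fixed = "subject")
      if (length(f) == 0 || length(r) == 0) next
      fe <- BiocGenerics::end(f)[1]
      rs <- BiocGenerics::start(r)[length(r)]
      if (rs <= fe + 1) next
      out[[length(out) + 1]] <- tibble::tibble(
        ref_id = reference$seqs$ref_id[i], marker = markers$marker[j],
        insert = as.character(subj[(fe + 1):(rs - 1)]))
    }
  }
  dplyr::bind_rows(out)
}

mock_occurrence_sets <- function(counts, variants, design, reference,
                                 mock_expect) {
  amp <- predict_amplicons(reference, design_markers(design))
  tax_names <- if (!is.null(reference$amplicons)) {
    dplyr::distinct(reference$amplicons, .data$ref_id, .data$taxon)
  } else {
    dplyr::transmute(reference$taxonomy, ref_id = .data$ref_id,
                     taxon = .data$species)
  }
  amp <- dplyr::inner_join(amp, tax_names, by = "ref_id")
  variant_taxon <- dplyr::inner_join(
    variants, amp, by = c("marker", "seq" = "insert"))
  mock_counts <- dplyr::filter(counts, .data$category == "mock")
  keyed <- dplyr::left_join(mock_counts,
                            variant_taxon[c("variant_id", "taxon")],
                            by = "variant_id")
  expected <- dplyr::semi_join(keyed, mock_expect,
                               by = c("sample", "taxon"))
  unexpected <- dplyr::anti_join(keyed, mock_expect,
                                 by = c("sample", "taxon"))
  list(must_keep = expected[names(counts)],
       must_drop = unexpected[names(counts)],
       variant_taxon = variant_taxon)
}

#' Run the full multi-primer metabarcoding pipeline
#'
#' Orchestrates demultiplexing, dereplication, control-calibrated
#' low-frequency-noise filtering, Renkonen replicate screening, the
#' minimum-replicate rule, first-pass taxonomic assignment, the second
#' recalibrated filtering round driven by habitat-unexpected detections,
#' cross-marker contig building, complete-linkage MOTU clustering, final
#' taxonomic assignment with the Macrometazoan scope filter, and the
#' coverage/complementarity/dissimilarity/resolution metrics.
#'
#' @param reads Named list of read vectors (one per run), or a single
#'   character vector / FASTA/FASTQ path for a single-run design.
#' @param design An `olsp_design`.
#' @param reference Reference database ([read_reference()] or
#'   [generate_reference()]).
#' @param mock_expect Tibble `sample, taxon` of expected mock members;
#'   defaults to the design's attached mock composition, if any.
#' @param habitat_map Tibble `taxon, habitat` of habitat compatibility;
#'   defaults to `reference$habitat`. `NULL` disables the second pass.
#' @param overrides Optional curated assignment overrides (see
#'   [assign_taxa()]).
#' @param max_primer_mismatch Demultiplexing primer tolerance (default 2).
#' @param renkonen_cutoff Replicate screening cutoff (default 0.5).
#' @param min_replicates Minimum replicate support (default 2).
#' @param min_overlap Minimum perfect overlap for contigs (default 100).
#' @param motu_threshold Complete-linkage divergence threshold
#'   (default 0.03).
#' @param exclusion Macrometazoan exclusion list
#'   (default [default_exclusions()]).
#' @param second_pass Run the habitat-driven second filtering round
#'   (default `TRUE`).
#' @return An `olsp_pipeline` object (list) with all stage outputs:
#'   `demux_stats`, `variants`, `counts`, `calibration`, `calibration2`,
#'   `validated`, `contigs`, `items`, `motus`, `assignments`, `detections`,
#'   `metrics`, `mock_retention`, `trace`.
#' @export
run_olsp_pipeline <- function(reads, design, reference,
                              mock_expect = NULL, habitat_map = NULL,
                              overrides = NULL,
                              max_primer_mismatch = 2L,
                              renkonen_cutoff = 0.5, min_replicates = 2L,
                              min_overlap = 100L, motu_threshold = 0.03,
                              exclusion = default_exclusions(),
                              second_pass = TRUE) {
  dtab <- tibble::as_tibble(design)
  runs <- unique(dtab$run)
  if (!is.list(reads)) reads <- stats::setNames(list(reads), runs[1])

  dmx <- purrr::map(runs, function(r) {
    demultiplex(reads[[r]], design, run = r,
                max_primer_mismatch = max_primer_mismatch)
  })
  names(dmx) <- runs
  assignments_all <- dplyr::bind_rows(purrr::map(dmx, "assignments"))
  derep <- dereplicate(assignments_all)
  variants <- derep$variants
  counts <- derep$counts

  if (is.null(mock_expect)) {
    mc <- attr(design, "mock_composition")
    if (!is.null(mc)) mock_expect <- dplyr::distinct(mc, .data$sample,
                                                     .data$taxon, .data$role)
  }
  if (is.null(habitat_map) && !is.null(reference$habitat)) {
    habitat_map <- reference$habitat
  }

  sets <- if (!is.null(mock_expect)) {
    mock_occurrence_sets(counts, variants, design, reference, mock_expect)
  } else list(must_keep = NULL, must_drop = NULL, variant_taxon = NULL)

  calibration <- calibrate_lfn(counts, must_keep = sets$must_keep,
                               must_drop = sets$must_drop)
  pass1 <- lfn_filter(counts, calibration)
  screen1 <- renkonen_screen(pass1$counts, cutoff = renkonen_cutoff,
                             design = design)
  validated1 <- replicate_consensus(screen1$counts,
                                    min_replicates = min_replicates)

  calibration2 <- NULL
  unexpected <- tibble::tibble()
  validated <- validated1
  if (isTRUE(second_pass) && !is.null(habitat_map) &&
      nrow(validated1) > 0) {
    vseqs <- dplyr::semi_join(variants, validated1, by = "variant_id")
    tax1 <- assign_taxa(
      dplyr::transmute(vseqs, item_id = .data$variant_id, seq = .data$seq),
      reference)
    taxa1 <- dplyr::transmute(tax1, variant_id = .data$item_id,
                              taxon = .data$species)
    taxa1 <- dplyr::filter(taxa1, !is.na(.data$taxon))
    sp <- lfn_second_pass(counts, design, validated1, taxa1, habitat_map,
                          must_keep = sets$must_keep,
                          must_drop = sets$must_drop,
                          cutoff = renkonen_cutoff,
                          min_replicates = min_replicates)
    calibration2 <- sp$calibration
    validated <- sp$validated
    unexpected <- sp$unexpected
  }

  vfinal <- dplyr::semi_join(variants, validated, by = "variant_id")
  contigs <- build_contigs(vfinal, min_overlap = min_overlap)
  it <- item_table(contigs)
  motus <- cluster_motus(it$items, threshold = motu_threshold)
  assignments <- assign_taxa(it$items, reference, overrides = overrides)

  sample_meta <- dplyr::distinct(dtab, .data$sample, .data$category,
                                 .data$predator, .data$habitat)
  detections <- validated |>
    dplyr::inner_join(it$item_map, by = c("variant_id", "marker")) |>
    dplyr::distinct(.data$run, .data$sample, .data$category, .data$marker,
                    .data$item_id) |>
    dplyr::left_join(sample_meta,
                     by = c("sample", "category"))

  macro <- filter_macrometazoa(assignments, exclude = exclusion)
  det_macro <- detections |>
    dplyr::filter(.data$category == "edna",
                  .data$item_id %in% macro$item_id) |>
    dplyr::rename(predator_group = "predator")
  metrics <- if (nrow(det_macro) > 0) {
    compute_metrics(det_macro, assignments, motus, group = "predator_group")
  } else NULL

  mock_retention <- NULL
  if (!is.null(mock_expect)) {
    retained <- detections |>
      dplyr::filter(.data$category == "mock") |>
      dplyr::inner_join(assignments[c("item_id", "species")],
                        by = "item_id") |>
      dplyr::distinct(.data$sample, taxon = .data$species)
    mock_retention <- mock_expect |>
      dplyr::mutate(retained = vctrs::vec_in(
        mock_expect[c("sample", "taxon")], retained[c("sample", "taxon")]))
  }

  trace <- list(
    demux = purrr::map(dmx, "stats"),
    occurrences_dereplicated = nrow(counts),
    lfn_trace = pass1$trace,
    replicates_dropped = screen1$dropped,
    occurrences_validated_pass1 = nrow(validated1),
    unexpected_habitat = unexpected,
    occurrences_validated = nrow(validated))

  structure(list(design = design, demux_stats = purrr::map(dmx, "stats"),
                 variants = variants, counts = counts,
                 calibration = calibration, calibration2 = calibration2,
                 validated = validated, contigs = contigs, items = it,
                 motus = motus, assignments = assignments,
                 detections = detections, metrics = metrics,
                 mock_retention = mock_retention, trace = trace),
            class = "olsp_pipeline")
}

#' @export
print.olsp_pipeline <- function(x, ...) {
  cat("<olsp_pipeline>\n",
      " variants dereplicated: ", nrow(x$variants), "\n",
      " validated occurrences: ", nrow(x$validated), "\n",
      " contigs: ", nrow(x$contigs$contigs),
      " | unmerged variants: ", nrow(x$contigs$unmerged), "\n",
      " MOTUs: ", nrow(x$motus$motus), "\n", sep = "")
  if (!is.null(x$mock_retention)) {
    r <- x$mock_retention
    if ("role" %in% names(r)) r <- dplyr::filter(r, .data$role == "prey")
    cat(" mock prey retained: ", sum(r$retained), "/", nrow(r), "\n",
        sep = "")
  }
  invisible(x)
}
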