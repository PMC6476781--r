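#' @importFrom rlang .data
NULL

# Count IUPAC-aware mismatches of `pattern` against a window of each string,
# starting at 1-based position `start` (vectorised over strings; `start` may
# be a vector). Positions past the end of a string count as mismatches.
window_mismatches <- function(strings, pattern, start) {
  tab <- iupac_table()
  p <- strsplit(toupper(pattern), "")[[1]]
  mm <- integer(length(strings))
  for (i in seq_along(p)) {
    pos <- start + i - 1L
    ch <- substr(strings, pos, pos)
    mm <- mm + !(ch %in% tab[[p[i]]])
  }
  mm
}

read_sequences <- function(reads) {
  if (inherits(reads, "DNAStringSet")) {
    out <- as.character(reads)
  } else if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    out <- as.character(Biostrings::readDNAStringSet(reads, format = fmt))
  } else if (is.character(reads)) {
    out <- toupper(reads)
  } else {
    stop("reads must be a character vector, a DNAStringSet, or a file path")
  }
  if (is.null(names(out)) || anyDuplicated(names(out))) {
    names(out) <- sprintf("read_%06d", seq_along(out))
  }
  names(out) <- sub(" .*$", "", names(out))
  out
}

# All (marker, tag-pair) construct hits for one orientation of the reads.
construct_hits <- function(seqs, design_run, markers, max_primer_mismatch) {
  n <- length(seqs)
  widths <- nchar(seqs)
  mk <- markers[match(design_run$marker, markers$marker), ]

  fwd_cons <- dplyr::distinct(
    tibble::tibble(marker = design_run$marker, tag = design_run$fwd_tag,
                   primer = mk$fwd_primer))
  rev_cons <- dplyr::distinct(
    tibble::tibble(marker = design_run$marker, tag = design_run$rev_tag,
                   primer = mk$rev_primer))

  hit_fwd <- purrr::pmap(fwd_cons, function(marker, tag, primer) {
    tl <- nchar(tag)
    idx <- which(substr(seqs, 1L, tl) == tag)
    if (length(idx) == 0) return(NULL)
    mm <- window_mismatches(seqs[idx], primer, tl + 1L)
    idx <- idx[mm <= max_primer_mismatch]
    if (length(idx) == 0) return(NULL)
    tibble::tibble(read = idx, marker = marker, fwd_tag = tag,
                   insert_start = tl + nchar(primer) + 1L)
  }) |> purrr::compact() |> dplyr::bind_rows()

  hit_rev <- purrr::pmap(rev_cons, function(marker, tag, primer) {
    tl <- nchar(tag)
    rc_tag <- revcomp(tag)
    idx <- which(substr(seqs, widths - tl + 1L, widths) == rc_tag)
    if (length(idx) == 0) return(NULL)
    rc_primer <- revcomp(primer)
    pl <- nchar(rc_primer)
    mm <- window_mismatches(seqs[idx], rc_primer, widths[idx] - tl - pl + 1L)
    idx <- idx[mm <= max_primer_mismatch]
    if (length(idx) == 0) return(NULL)
    tibble::tibble(read = idx, marker = marker, rev_tag = tag,
                   insert_end = widths[idx] - tl - pl)
  }) |> purrr::compact() |> dplyr::bind_rows()

  if (nrow(hit_fwd) == 0 || nrow(hit_rev) == 0) {
    return(tibble::tibble(read = integer(), marker = character(),
                          fwd_tag = character(), rev_tag = character(),
                          insert_start = integer(), insert_end = integer()))
  }
  dplyr::inner_join(hit_fwd, hit_rev, by = c("read", "marker"),
                    relationship = "many-to-many")
}

#' Demultiplex merged amplicon reads by tag combination
#'
#' Assigns each merged read to a PCR by requiring, at the 5' end, an exact
#' forward tag followed by the marker's forward primer (IUPAC-aware, up to
#' `max_primer_mismatch` substitutions, no indels) and, at the 3' end, the
#' reverse complement of the reverse primer followed by the reverse tag.
#' Both ends must match: one-sided matches are a known tag-jump vector and are
#' never rescued. Reads are searched in the given orientation and in reverse
#' complement. Reads matching zero constructs, more than one construct, or
#' with no insert left after trimming are routed to the unassigned bin with a
#' reason code, never silently dropped.
#'
#' @param reads Character vector of read sequences, a `DNAStringSet`, or a
#'   path to a FASTA/FASTQ file.
#' @param design An `olsp_design` (see [parse_design()]); must contain a
#'   single run (or pass `run` to select one).
#' @param run Run id to demultiplex against when the design spans several.
#' @param max_primer_mismatch Maximum substitutions tolerated in each primer
#'   (default 2); tags are always matched exactly.
#' @return An object of class `olsp_demux`: a list with `assignments` (tibble:
#'   `read_id, run, marker, sample, category, replicate, insert`),
#'   `unassigned` (tibble: `read_id, reason`), and `stats`.
#' @export
demultiplex <- function(reads, design, run = NULL,
                        max_primer_mismatch = 2L) {
  seqs <- read_sequences(reads)
  markers <- design_markers(design)
  design <- tibble::as_tibble(design)
  if (is.null(run)) {
    run <- unique(design$run)
    if (length(run) > 1) {
      stop("design spans several runs; pass `run` to select the one sequenced")
    }
  }
  design_run <- dplyr::filter(design, .data$run == !!run)
  if (nrow(design_run) == 0) stop("no design rows for run ", run)

  hits_f <- construct_hits(seqs, design_run, markers, max_primer_mismatch)
  hits_r <- construct_hits(revcomp(seqs), design_run, markers,
                           max_primer_mismatch)
  hits <- dplyr::bind_rows(
    dplyr::mutate(hits_f, orientation = "fwd"),
    dplyr::mutate(hits_r, orientation = "rc")
  )
  # a palindromic double-hit of the same construct in both orientations is
  # collapsed; distinct constructs stay distinct and flag ambiguity
  hits <- dplyr::distinct(hits, .data$read, .data$marker, .data$fwd_tag,
                          .data$rev_tag, .keep_all = TRUE)
  hits <- dplyr::inner_join(
    hits,
    design_run[c("marker", "fwd_tag", "rev_tag", "sample", "category",
                 "replicate")],
    by = c("marker", "fwd_tag", "rev_tag"))

  n_hits <- table(factor(hits$read, levels = seq_along(seqs)))
  read_ids <- names(seqs)

  amb_idx <- which(n_hits > 1)
  uni <- hits[hits$read %in% which(n_hits == 1), ]
  too_short <- uni$insert_end < uni$insert_start
  assigned <- uni[!too_short, ]

  oriented <- ifelse(assigned$orientation == "fwd",
                     seqs[assigned$read], revcomp(seqs[assigned$read]))
  assignments <- tibble::tibble(
    read_id = read_ids[assigned$read],
    run = run,
    marker = assigned$marker,
    sample = assigned$sample,
    category = assigned$category,
    replicate = assigned$replicate,
    insert = substr(oriented, assigned$insert_start, assigned$insert_end)
  )
  unassigned <- dplyr::bind_rows(
    tibble::tibble(read_id = read_ids[which(n_hits == 0)],
                   reason = "no_construct_match"),
    tibble::tibble(read_id = read_ids[amb_idx], reason = "ambiguous"),
    tibble::tibble(read_id = read_ids[uni$read[too_short]],
                   reason = "too_short")
  )
  per_pcr <- assignments |>
    dplyr::count(.data$run, .data$marker, .data$sample, .data$replicate,
                 name = "reads")
  stats <- list(total_reads = length(seqs),
                assigned_reads = nrow(assignments),
                unassigned_reads = nrow(unassigned),
                per_pcr_read_counts = per_pcr)
  stopifnot(stats$assigned_reads + stats$unassigned_reads == stats$total_reads)
  structure(list(assignments = assignments, unassigned = unassigned,
                 stats = stats),
            class = "olsp_demux")
}

#' @export
print.olsp_demux <- function(x, ...) {
  cat("<olsp_demux> ", x$stats$assigned_reads, "/", x$stats$total_reads,
      " reads assigned to ", nrow(x$stats$per_pcr_read_counts), " PCRs\n",
      sep = "")
  invisible(x)
}

#' Dereplicate assigned reads into exact sequence variants
#'
#' Pools identical trimmed reads within each marker into variants and counts
#' them per PCR. Variant identity is scoped to the marker: the same sequence
#' observed under two markers yields two distinct variants. Reads containing
#' non-ACGT symbols are discarded and counted.
#'
#' @param demux An `olsp_demux` object from [demultiplex()], or a tibble of
#'   assignments with columns `run, marker, sample, category, replicate,
#'   insert`.
#' @return A list with `variants` (tibble: `variant_id, marker, seq`),
#'   `counts` (the read-count table: one row per occurrence, columns
#'   `run, marker, variant_id, sample, category, replicate, count`) and
#'   `n_discarded` (non-ACGT reads).
#' @export
dereplicate <- function(demux) {
  asg <- if (inherits(demux, "olsp_demux")) demux$assignments else
    tibble::as_tibble(demux)
  ok <- vapply(asg$insert, is_acgt, logical(1), USE.NAMES = FALSE) &
    nchar(asg$insert) > 0
  n_discarded <- sum(!ok)
  asg <- asg[ok, ]

  variants <- asg |>
    dplyr::count(.data$marker, seq = .data$insert, name = "total") |>
    dplyr::arrange(.data$marker, dplyr::desc(.data$total), .data$seq) |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(variant_id = sprintf("%s_%06d", .data$marker,
                                       dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("variant_id", "marker", "seq")

  counts <- asg |>
    dplyr::count(.data$run, .data$marker, seq = .data$insert, .data$sample,
                 .data$category, .data$replicate, name = "count") |>
    dplyr::inner_join(variants, by = c("marker", "seq")) |>
    dplyr::select("run", "marker", "variant_id", "sample", "category",
                  "replicate", "count") |>
    dplyr::arrange(.data$run, .data$marker, .data$variant_id, .data$sample,
                   .data$replicate)

  list(variants = variants, counts = counts, n_discarded = n_discarded)
}
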