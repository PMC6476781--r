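taxonomic_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Read a reference database (FASTA + taxonomy TSV)
#'
#' @param fasta Path to a FASTA of reference barcode sequences; record ids
#'   must match the taxonomy table.
#' @param taxonomy Path to a TSV with columns
#'   `ref_id, kingdom, phylum, class, order, family, genus, species`.
#' @return A list with `seqs` (tibble `ref_id, seq`) and `taxonomy`.
#' @export
read_reference <- function(fasta, taxonomy) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- tibble::tibble(ref_id = sub(" .*$", "", names(ss)),
                         seq = as.character(ss))
  tax <- readr::read_tsv(taxonomy, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(c("ref_id", taxonomic_ranks()), names(tax))
  if (length(missing_cols) > 0) {
    stop("taxonomy file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  list(seqs = seqs, taxonomy = tax)
}

#' Align a query against a reference database
#'
#' Semi-global pairwise alignment of the query against every reference;
#' returns the references matching at or above an identity floor over a
#' minimum fraction of the query length.
#'
#' @param query A single ACGT sequence.
#' @param reference A reference list from [read_reference()] (or a list with
#'   `seqs` and `taxonomy` tibbles).
#' @param min_identity Identity floor in percent (default 80).
#' @param min_coverage Minimum aligned fraction of the query (default 0.8).
#' @return A tibble of hits: `ref_id, identity` plus the taxonomy columns.
#' @export
search_reference <- function(query, reference, min_identity = 80,
                             min_coverage = 0.8) {
  empty <- dplyr::mutate(reference$taxonomy[0, ], identity = numeric(0))
  if (nrow(reference$seqs) == 0) return(empty)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    rep(query, nrow(reference$seqs)),
    Biostrings::DNAStringSet(reference$seqs$seq),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  aligned_q <- gsub("-", "", as.character(Biostrings::pattern(pa)))
  coverage <- nchar(aligned_q) / nchar(query)
  identity <- Biostrings::pid(pa, type = "PID1")
  hit <- coverage >= min_coverage & identity >= min_identity
  out <- tibble::tibble(ref_id = reference$seqs$ref_id[hit],
                        identity = identity[hit])
  dplyr::inner_join(out, reference$taxonomy, by = "ref_id") |>
    dplyr::arrange(dplyr::desc(.data$identity))
}

#' Lowest-taxonomic-group assignment from a hit list
#'
#' Takes the highest identity band of the ladder containing at least one hit
#' and, within that band, returns the lowest (deepest) rank at which a single
#' taxon accounts for at least `inclusion` of the band's hits. Each band caps
#' the depth it can award (by default: >=97% species, >=95% genus, >=90%
#' family, >=85% order, >=80% class), so moderate-identity hits can never
#' yield a species-level call. An empty hit list yields an unassigned result.
#'
#' @param hits Tibble from [search_reference()].
#' @param ladder Identity band floors, descending (default
#'   `c(97, 95, 90, 85, 80)`).
#' @param caps Deepest rank allowed per band (same length as `ladder`).
#' @param inclusion Fraction of band hits a taxon must reach (default 0.9).
#' @return A one-row tibble: taxonomy columns (ranks below the awarded one
#'   are `NA`), `resolution_rank`, `method`, `n_hits`.
#' @export
ltg_assign <- function(hits, ladder = c(97, 95, 90, 85, 80),
                       caps = c("species", "genus", "family", "order",
                                "class"),
                       inclusion = 0.9) {
  stopifnot(length(ladder) == length(caps))
  ranks <- taxonomic_ranks()
  unassigned <- tibble::as_tibble(stats::setNames(
    as.list(rep(NA_character_, length(ranks))), ranks)) |>
    dplyr::mutate(resolution_rank = NA_character_, method = "ltg_auto",
                  n_hits = 0L)
  if (is.null(hits) || nrow(hits) == 0) return(unassigned)

  band <- which(vapply(ladder, function(t) any(hits$identity >= t),
                       logical(1)))[1]
  if (is.na(band)) return(unassigned)
  bh <- hits[hits$identity >= ladder[band], ]
  cap_idx <- match(caps[band], ranks)

  for (ri in seq(cap_idx, 1)) {
    rank <- ranks[ri]
    vals <- bh[[rank]]
    named <- vals[!is.na(vals)]
    if (length(named) == 0) next
    top <- sort(table(named), decreasing = TRUE)
    if (top[1] / nrow(bh) >= inclusion) {
      taxon <- names(top)[1]
      src <- bh[which(!is.na(vals) & vals == taxon)[1], ranks]
      path <- src
      if (ri < length(ranks)) path[ranks[(ri + 1):length(ranks)]] <- NA_character_
      return(dplyr::mutate(tibble::as_tibble(path), resolution_rank = rank,
                           method = "ltg_auto", n_hits = nrow(bh)))
    }
  }
  dplyr::mutate(unassigned, n_hits = nrow(bh))
}

#' Assign taxonomy to a table of items
#'
#' Runs [search_reference()] and [ltg_assign()] for every item. Curated
#' assignments supplied in `overrides` (e.g. from manual database lookups or
#' phylogenetic arbitration) supersede the automatic ones and are tagged
#' `method = "override"`.
#'
#' @param items Tibble with columns `item_id, seq`.
#' @param reference Reference list from [read_reference()].
#' @param overrides Optional tibble with `item_id` plus taxonomy columns and
#'   `resolution_rank`.
#' @param ... Passed to [search_reference()] and [ltg_assign()]
#'   (`min_identity`, `min_coverage`, `ladder`, `caps`, `inclusion`).
#' @return A tibble: `item_id`, taxonomy columns, `resolution_rank`,
#'   `method`, `n_hits`, `ir`.
#' @export
assign_taxa <- function(items, reference, overrides = NULL, ...) {
  dots <- list(...)
  search_args <- dots[intersect(names(dots),
                                c("min_identity", "min_coverage"))]
  ltg_args <- dots[intersect(names(dots),
                             c("ladder", "caps", "inclusion"))]
  out <- purrr::map(seq_len(nrow(items)), function(i) {
    hits <- do.call(search_reference,
                    c(list(items$seq[i], reference), search_args))
    do.call(ltg_assign, c(list(hits), ltg_args)) |>
      dplyr::mutate(item_id = items$item_id[i], .before = 1)
  }) |> dplyr::bind_rows()
  if (!is.null(overrides) && nrow(overrides) > 0) {
    overrides <- dplyr::mutate(overrides, method = "override", n_hits = NA_integer_)
    out <- dplyr::bind_rows(
      overrides[overrides$item_id %in% items$item_id, ],
      dplyr::anti_join(out, overrides, by = "item_id"))
  }
  dplyr::mutate(out, ir = ir_score(.data$resolution_rank))
}

#' Identification-resolution score of an assignment rank
#'
#' Species = 6, Genus = 5, Family = 4, Order = 3, Class = 2, Phylum = 1,
#' Kingdom or unassigned = 0.
#'
#' @param rank Character vector of rank names (may contain `NA`).
#' @return Integer scores, same length as `rank`.
#' @export
ir_score <- function(rank) {
  scale <- c(species = 6L, genus = 5L, family = 4L, order = 3L,
             class = 2L, phylum = 1L, kingdom = 0L)
  out <- unname(scale[as.character(rank)])
  out[is.na(out)] <- 0L
  out
}

#' Mean identification-resolution of one sample
#'
#' Arithmetic mean of [ir_score()] over the sample's validated items.
#' @param ranks Character vector of resolution ranks of the sample's items.
#' @return Mean score, or `NA` for an empty sample (excluded from
#'   summaries).
#' @export
sample_ir <- function(ranks) {
  if (length(ranks) == 0) return(NA_real_)
  mean(ir_score(ranks))
}

#' Default taxon exclusion list for the Macrometazoan target scope
#'
#' Taxa whose detection most likely reflects passive ingestion, secondary
#' predation or parasitism rather than predation on macro-invertebrate or
#' vertebrate prey: microinvertebrates (Amoebozoa, Acari, Tardigrada,
#' Rotifera), diatoms, algae and plants, and potential parasites
#' (Acanthocephala, Nematoda).
#' @return Character vector of taxon names (any rank).
#' @export
default_exclusions <- function() {
  c("Amoebozoa", "Acari", "Tardigrada", "Rotifera",
    "Acanthocephala", "Nematoda",
    "Bacillariophyta", "Chlorophyta", "Rhodophyta", "Streptophyta",
    "Plantae")
}

#' Restrict assignments to the Macrometazoan target scope
#'
#' An item is retained iff no taxon on its assigned path appears in the
#' exclusion list. Unassigned items are retained conservatively and flagged
#' in the `unassigned_kept` column.
#'
#' @param assignments Tibble from [assign_taxa()].
#' @param exclude Character vector of excluded taxon names
#'   (default [default_exclusions()]).
#' @return The retained rows, with a logical `unassigned_kept` column.
#' @export
filter_macrometazoa <- function(assignments, exclude = default_exclusions()) {
  ranks <- taxonomic_ranks()
  path_hit <- apply(as.matrix(assignments[ranks]), 1,
                    function(p) any(p %in% exclude))
  out <- assignments[!path_hit, , drop = FALSE]
  dplyr::mutate(out, unassigned_kept = is.na(.data$resolution_rank))
}
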