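#' Best perfect ungapped overlap between two variants
#'
#' Slides `b` over `a` at every ungapped relative offset and returns the
#' offset maximising the overlap length under 100% identity, provided the
#' overlap spans at least `min_overlap` bases. Ties are broken toward the
#' smaller absolute offset. Cross-marker amplicons of the same template
#' overlap perfectly because all markers amplify the same locus.
#'
#' @param a,b Sequences (ACGT strings).
#' @param min_overlap Minimum overlap length (default 100).
#' @return A list `(offset, length, identical = TRUE)` where `offset` is the
#'   start of `b` relative to the start of `a` (may be negative), or `NULL`
#'   when no perfect overlap of sufficient length exists.
#' @export
pairwise_overlap <- function(a, b, min_overlap = 100L) {
  na <- nchar(a); nb <- nchar(b)
  best <- NULL
  offsets <- seq(-(nb - 1L), na - 1L)
  # visit small |offset| first so ties resolve toward it
  offsets <- offsets[order(abs(offsets), offsets)]
  for (off in offsets) {
    lo <- max(0L, off)                 # 0-based start of overlap on a
    hi <- min(na, off + nb)            # 0-based end (half-open)
    len <- hi - lo
    if (len < min_overlap) next
    if (!is.null(best) && len <= best$length) next
    if (substr(a, lo + 1L, hi) == substr(b, lo - off + 1L, hi - off)) {
      best <- list(offset = off, length = len, identical = TRUE)
    }
  }
  best
}

# minimal union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  parent[uf_find(parent, i)] <- uf_find(parent, j)
  parent
}

#' Combine cross-marker variants into contigs
#'
#' Builds a graph whose edges are perfect overlaps (see [pairwise_overlap()])
#' between variants of different markers. A connected component becomes a
#' contig iff it contains at most one variant per marker and the layout
#' implied by its overlaps is conflict-free at every base; otherwise the
#' whole component is left unmerged and logged as ambiguous. Every input
#' variant therefore ends up in exactly one contig or in the unmerged list.
#' Contig ids are assigned on members sorted by id, so the result is
#' independent of input order.
#'
#' @param variants Tibble with columns `variant_id, marker, seq` (validated
#'   variants across all markers of a run).
#' @param min_overlap Minimum perfect-overlap length (default 100).
#' @return A list with `contigs` (tibble `contig_id, seq, n_members`),
#'   `members` (tibble `contig_id, variant_id, marker, offset`), `unmerged`
#'   (variant rows not merged) and `ambiguous` (tibble of component ids and
#'   reasons).
#' @export
build_contigs <- function(variants, min_overlap = 100L) {
  variants <- dplyr::arrange(tibble::as_tibble(variants), .data$variant_id)
  n <- nrow(variants)
  empty <- list(
    contigs = tibble::tibble(contig_id = character(), seq = character(),
                             n_members = integer()),
    members = tibble::tibble(contig_id = character(), variant_id = character(),
                             marker = character(), offset = integer()),
    unmerged = variants[0, ],
    ambiguous = tibble::tibble(variant_ids = character(), reason = character())
  )
  if (n == 0) return(empty)

  edges <- list()
  parent <- uf_new(n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (variants$marker[i] == variants$marker[j]) next
        ov <- pairwise_overlap(variants$seq[i], variants$seq[j], min_overlap)
        if (!is.null(ov)) {
          edges[[length(edges) + 1]] <- c(i = i, j = j, offset = ov$offset)
          parent <- uf_union(parent, i, j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  edge_tbl <- if (length(edges) > 0) do.call(rbind, edges) else
    matrix(integer(), ncol = 3, dimnames = list(NULL, c("i", "j", "offset")))

  contigs <- list(); members <- list(); unmerged_idx <- integer()
  ambiguous <- list()
  comp_ids <- unique(comp)
  for (cid in comp_ids) {
    idx <- which(comp == cid)
    if (length(idx) == 1) { unmerged_idx <- c(unmerged_idx, idx); next }
    if (anyDuplicated(variants$marker[idx])) {
      unmerged_idx <- c(unmerged_idx, idx)
      ambiguous[[length(ambiguous) + 1]] <- tibble::tibble(
        variant_ids = paste(variants$variant_id[idx], collapse = ","),
        reason = "multiple variants of one marker")
      next
    }
    # layout by BFS over overlap edges
    ce <- edge_tbl[edge_tbl[, "i"] %in% idx & edge_tbl[, "j"] %in% idx, ,
                   drop = FALSE]
    pos <- stats::setNames(rep(NA_integer_, length(idx)), idx)
    pos[as.character(idx[1])] <- 0L
    queue <- idx[1]
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(nrow(ce))) {
        i <- ce[r, "i"]; j <- ce[r, "j"]; off <- ce[r, "offset"]
        if (i == v && is.na(pos[as.character(j)])) {
          pos[as.character(j)] <- pos[as.character(v)] + off
          queue <- c(queue, j)
        } else if (j == v && is.na(pos[as.character(i)])) {
          pos[as.character(i)] <- pos[as.character(v)] - off
          queue <- c(queue, i)
        }
      }
    }
    pos <- pos - min(pos)
    lens <- nchar(variants$seq[idx])
    total <- max(pos + lens)
    # position-wise consistency across all members
    merged <- character(total); merged[] <- ""
    conflict <- FALSE
    for (k in seq_along(idx)) {
      chars <- strsplit(variants$seq[idx[k]], "")[[1]]
      span <- (pos[k] + 1):(pos[k] + lens[k])
      clash <- merged[span] != "" & merged[span] != chars
      if (any(clash)) { conflict <- TRUE; break }
      merged[span] <- chars
    }
    if (conflict || any(merged == "")) {
      unmerged_idx <- c(unmerged_idx, idx)
      ambiguous[[length(ambiguous) + 1]] <- tibble::tibble(
        variant_ids = paste(variants$variant_id[idx], collapse = ","),
        reason = if (conflict) "layout conflict" else "disjoint layout")
      next
    }
    contigs[[length(contigs) + 1]] <- list(
      seq = paste(merged, collapse = ""),
      members = tibble::tibble(variant_id = variants$variant_id[idx],
                               marker = variants$marker[idx],
                               offset = as.integer(pos)))
  }

  if (length(contigs) > 0) {
    ord <- order(vapply(contigs, function(x) x$members$variant_id[1],
                        character(1)))
    contigs <- contigs[ord]
    ids <- sprintf("contig_%04d", seq_along(contigs))
    contig_tbl <- tibble::tibble(
      contig_id = ids,
      seq = vapply(contigs, function(x) x$seq, character(1)),
      n_members = vapply(contigs, function(x) nrow(x$members), integer(1)))
    member_tbl <- purrr::map2(ids, contigs, function(id, x) {
      dplyr::mutate(x$members, contig_id = id, .before = 1)
    }) |> dplyr::bind_rows()
  } else {
    contig_tbl <- empty$contigs
    member_tbl <- empty$members
  }
  list(contigs = contig_tbl, members = member_tbl,
       unmerged = variants[sort(unmerged_idx), ],
       ambiguous = if (length(ambiguous) > 0) dplyr::bind_rows(ambiguous) else
         empty$ambiguous)
}

#' Item table: contigs and leftover variants treated uniformly
#'
#' Downstream stages (taxonomy, MOTU clustering, metrics) operate on
#' "validated items": each contig is one item and each unmerged variant is
#' one item. The mapping from variant to item makes per-marker detection
#' recoverable: a contig counts as detected by a marker in a sample only when
#' that marker's member variant itself was validated there.
#'
#' @param contig_result Result of [build_contigs()].
#' @return A list with `items` (tibble `item_id, seq`) and `item_map` (tibble
#'   `item_id, variant_id, marker`).
#' @export
item_table <- function(contig_result) {
  items <- dplyr::bind_rows(
    dplyr::transmute(contig_result$contigs, item_id = .data$contig_id,
                     seq = .data$seq),
    dplyr::transmute(contig_result$unmerged, item_id = .data$variant_id,
                     seq = .data$seq))
  item_map <- dplyr::bind_rows(
    dplyr::transmute(contig_result$members, item_id = .data$contig_id,
                     variant_id = .data$variant_id, marker = .data$marker),
    dplyr::transmute(contig_result$unmerged, item_id = .data$variant_id,
                     variant_id = .data$variant_id, marker = .data$marker))
  list(items = items, item_map = item_map)
}
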