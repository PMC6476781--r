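#' Pairwise divergence between two amplicon sequences
#'
#' A p-distance with gaps counted, computed on a semi-global (end-gap free)
#' pairwise alignment: `(mismatches + internal gap bases) / aligned overlap
#' length`. End gaps are free because items span different, overlapping
#' amplicon windows of the same locus; terminal overhangs reflect primer
#' geometry, not divergence. If the alignable overlap is shorter than
#' `min_overlap` the sequences are considered non-comparable and the distance
#' is the defined ceiling 1.
#'
#' @param a,b Non-empty ACGT sequences.
#' @param min_overlap Minimum alignment overlap for a meaningful distance
#'   (default 50).
#' @return Distance in `[0, 1]`; symmetric; `seq_distance(x, x) == 0`.
#' @export
seq_distance <- function(a, b, min_overlap = 50L) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  if (a == b) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                      substitutionMatrix = mat,
                                      gapOpening = 4, gapExtension = 1)
  aligned <- nchar(as.character(Biostrings::pattern(pa)))
  if (aligned < min_overlap) return(1)
  mism <- Biostrings::nmismatch(pa)
  gaps <- Biostrings::nindel(pa)
  gap_bases <- sum(gaps@insertion[, "WidthSum"]) +
    sum(gaps@deletion[, "WidthSum"])
  min(1, (mism + gap_bases) / aligned)
}

#' Distance matrix over a set of items
#'
#' @param items Tibble with columns `item_id, seq`.
#' @param min_overlap Passed to [seq_distance()].
#' @return A symmetric numeric matrix with item ids as dimnames.
#' @export
motu_distances <- function(items, min_overlap = 50L) {
  n <- nrow(items)
  d <- matrix(0, n, n, dimnames = list(items$item_id, items$item_id))
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- seq_distance(items$seq[i], items$seq[j],
                                           min_overlap = min_overlap)
      }
    }
  }
  d
}

# Agglomerative complete linkage on a distance matrix, cutting so that no
# merge happens at linkage distance > threshold. Ties are broken by merging
# the lexicographically smallest pair of cluster ids (a cluster's id is its
# smallest member label), making the partition order-independent.
complete_linkage_partition <- function(d, threshold) {
  labels <- rownames(d)
  n <- length(labels)
  if (n == 0) return(list())
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k < 2) break
    ids <- vapply(clusters, function(m) min(labels[m]), character(1))
    best <- NULL
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        link <- max(d[clusters[[i]], clusters[[j]]])
        if (link > threshold) next
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        cand <- list(link = link, i = i, j = j, a = a, b = b)
        if (is.null(best) || link < best$link ||
            (link == best$link &&
             (cand$a < best$a || (cand$a == best$a && cand$b < best$b)))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  lapply(clusters, function(m) sort(labels[m]))
}

#' Cluster validated items into MOTUs by complete linkage
#'
#' Agglomerative complete-linkage clustering of items at a divergence
#' threshold (default 3%): no merge is performed that would put two items at
#' distance greater than the threshold into one cluster, so every intra-MOTU
#' pairwise distance is guaranteed to be at most the threshold. Each MOTU's
#' representative is its longest member sequence (ties broken by
#' lexicographic item id).
#'
#' @param items Tibble with columns `item_id, seq`.
#' @param threshold Maximum intra-cluster divergence (default 0.03).
#' @param distances Optional precomputed matrix from [motu_distances()].
#' @param min_overlap Passed to [seq_distance()] when distances are computed.
#' @return An `olsp_motus` object: list with `membership` (tibble
#'   `item_id, motu_id, representative`), `motus` (tibble
#'   `motu_id, n_members, representative`) and `distances`.
#' @export
cluster_motus <- function(items, threshold = 0.03, distances = NULL,
                          min_overlap = 50L) {
  items <- tibble::as_tibble(items)
  if (nrow(items) == 0) {
    return(structure(list(
      membership = tibble::tibble(item_id = character(),
                                  motu_id = character(),
                                  representative = logical()),
      motus = tibble::tibble(motu_id = character(), n_members = integer(),
                             representative = character()),
      distances = matrix(0, 0, 0)), class = "olsp_motus"))
  }
  if (is.null(distances)) distances <- motu_distances(items, min_overlap)
  part <- complete_linkage_partition(distances, threshold)
  part <- part[order(vapply(part, min, character(1)))]
  motu_ids <- sprintf("motu_%04d", seq_along(part))
  membership <- purrr::map2(motu_ids, part, function(id, memb) {
    seqs <- items$seq[match(memb, items$item_id)]
    rep_id <- memb[order(-nchar(seqs), memb)][1]
    tibble::tibble(item_id = memb, motu_id = id,
                   representative = memb == rep_id)
  }) |> dplyr::bind_rows()
  motus <- membership |>
    dplyr::group_by(.data$motu_id) |>
    dplyr::summarise(n_members = dplyr::n(),
                     representative = .data$item_id[.data$representative],
                     .groups = "drop")
  structure(list(membership = membership, motus = motus,
                 distances = distances),
            class = "olsp_motus")
}

#' @export
print.olsp_motus <- function(x, ...) {
  cat("<olsp_motus> ", nrow(x$motus), " MOTUs over ", nrow(x$membership),
      " items\n", sep = "")
  invisible(x)
}
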