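# Greedy centroid clustering for the two redundancy-reduction steps:
# exact dedup at identity 1.0 and 50%-identity centroid selection before
# motif discovery.

#' Pairwise identity between two proteins
#'
#' Identity of the optimal global alignment with free end gaps: identical
#' aligned columns divided by alignment columns (internal gaps count in the
#' denominator, end gaps do not).
#'
#' @param a,b protein sequences (character scalars).
#' @param substitution,gap_open,gap_extend alignment parameters.
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b, substitution = blosum62(),
                              gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (toupper(a) == toupper(b)) return(1.0)
  al <- align_pair(a, b, mode = "overlap", substitution, gap_open, gap_extend)
  if (al$columns == 0) return(0.0)
  al$identity
}

#' Greedy centroid clustering
#'
#' Sequences are processed longest-first (ties broken by id); each sequence
#' joins the first existing cluster whose centroid identity is at least
#' `threshold`, otherwise it founds a new cluster. Output order is founding
#' order. At `threshold = 1` the identity test reduces exactly to a substring
#' test (under free end gaps, identity 1 iff the shorter sequence is a
#' contiguous substring of the longer), which is used as a fast path.
#'
#' @param seqs a protein [seq_set].
#' @param threshold identity threshold in (0, 1].
#' @return list of clusters, each `list(centroid_id, member_ids, identities)`.
#' @export
greedy_cluster <- function(seqs, threshold) {
  stopifnot(inherits(seqs, "seq_set"), threshold > 0, threshold <= 1)
  n <- length(seqs)
  if (n == 0) return(list())
  ord <- order(-nchar(seqs$seqs), seqs$ids)
  clusters <- list()
  cent_seq <- character(0)
  for (k in ord) {
    s <- seqs$seqs[k]; id <- seqs$ids[k]
    joined <- FALSE
    for (ci in seq_along(clusters)) {
      ident <- if (threshold >= 1) {
        if (grepl(toupper(s), toupper(cent_seq[ci]), fixed = TRUE)) 1.0 else 0.0
      } else {
        pairwise_identity(cent_seq[ci], s)
      }
      if (ident >= threshold) {
        clusters[[ci]]$member_ids <- c(clusters[[ci]]$member_ids, id)
        clusters[[ci]]$identities <- c(clusters[[ci]]$identities, ident)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      clusters[[length(clusters) + 1]] <-
        list(centroid_id = id, member_ids = id, identities = 1.0)
      cent_seq <- c(cent_seq, s)
    }
  }
  clusters
}

#' Extract centroid sequences of a clustering
#' @param seqs the clustered [seq_set].
#' @param clusters result of [greedy_cluster].
#' @return a [seq_set] of centroids, in founding order.
#' @export
cluster_centroids <- function(seqs, clusters) {
  ids <- vapply(clusters, function(cl) cl$centroid_id, "")
  seqs[match(ids, seqs$ids)]
}

#' Write clusters as TSV
#' @param clusters result of [greedy_cluster].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  df <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, centroid_id = cl$centroid_id,
               member_id = cl$member_ids,
               identity_to_centroid = round(cl$identities, 4),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
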