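# Distance-based neighbor-joining with bootstrap supports, condensed-tree
# collapse, and the two-clade partition of the family tree. Trees are ape
# "phylo" objects; the NJ algorithm itself is implemented here (ape::nj is
# used only as an independent oracle in the test suite).

#' Length filter before tree building
#' @param seqs a [seq_set].
#' @param min_len strict lower bound; sequences longer than `min_len`
#'   residues are kept (default 300).
#' @return filtered [seq_set].
#' @export
filter_by_length <- function(seqs, min_len = 300) {
  seqs[nchar(seqs$seqs) > min_len]
}

#' Center-star progressive multiple alignment
#'
#' The center sequence maximizes the total pairwise global-alignment score;
#' every other sequence is aligned to the center and the pairwise alignments
#' are merged on center coordinates ("once a gap, always a gap").
#'
#' @param seqs a protein [seq_set] (>= 2 sequences).
#' @param substitution,gap_open,gap_extend alignment parameters.
#' @return an [msa] in input order.
#' @export
build_msa <- function(seqs, substitution = blosum62(), gap_open = 11,
                      gap_extend = 1) {
  n <- length(seqs)
  stopifnot(n >= 2)
  enc <- lapply(seqs$seqs, encode_protein)
  total <- numeric(n)
  pair_score <- function(i, j)
    align_pair_cpp(enc[[i]], enc[[j]], substitution, gap_open, gap_extend,
                   1L)$score
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- pair_score(i, j)
    total[i] <- total[i] + s; total[j] <- total[j] + s
  }
  center <- which.max(total)
  clen <- length(enc[[center]])
  others <- setdiff(seq_len(n), center)
  # per alignment: insertions after each center position (index 0..clen)
  ins <- matrix(0L, length(others) + 1, clen + 1)
  alns <- vector("list", n)
  for (oi in seq_along(others)) {
    o <- others[oi]
    al <- align_pair_cpp(enc[[center]], enc[[o]], substitution, gap_open,
                         gap_extend, 1L)
    alns[[o]] <- al
    cpos <- 0L
    run <- integer(clen + 1)
    for (k in seq_along(al$ai)) {
      if (al$ai[k] >= 0) cpos <- al$ai[k] + 1L
      else run[cpos + 1L] <- run[cpos + 1L] + 1L
    }
    ins[oi + 1, ] <- run
  }
  master_ins <- apply(ins, 2, max)
  width <- clen + sum(master_ins)
  pad_row <- function(chars_by_slot) {
    # chars_by_slot: list of length clen+1; slot k = residues between center
    # positions k-1 and k (slot 1 = before first), plus center residue rows
    unlist(chars_by_slot)
  }
  rows <- character(n)
  cc <- strsplit(toupper(seqs$seqs[center]), "")[[1]]
  slots <- vector("list", clen + 1)
  for (k in 0:clen) {
    gapfill <- rep("-", master_ins[k + 1])
    slots[[k + 1]] <- if (k == 0) gapfill else c(cc[k], gapfill)
  }
  rows[center] <- paste(pad_row(slots), collapse = "")
  for (oi in seq_along(others)) {
    o <- others[oi]
    al <- alns[[o]]
    och <- strsplit(toupper(seqs$seqs[o]), "")[[1]]
    slot_chars <- vector("list", clen + 1)
    for (k in 0:clen) slot_chars[[k + 1]] <- character(0)
    center_char <- rep("-", clen)
    cpos <- 0L
    for (k in seq_along(al$ai)) {
      if (al$ai[k] >= 0) {
        cpos <- al$ai[k] + 1L
        center_char[cpos] <- if (al$bi[k] >= 0) och[al$bi[k] + 1L] else "-"
      } else {
        slot_chars[[cpos + 1L]] <- c(slot_chars[[cpos + 1L]],
                                     och[al$bi[k] + 1L])
      }
    }
    out <- vector("list", clen + 1)
    for (k in 0:clen) {
      insk <- slot_chars[[k + 1]]
      pad <- rep("-", master_ins[k + 1] - length(insk))
      body <- c(insk, pad)
      out[[k + 1]] <- if (k == 0) body else c(center_char[k], body)
    }
    rows[o] <- paste(pad_row(out), collapse = "")
  }
  stopifnot(all(nchar(rows) == width))
  msa(rows, ids = seqs$ids)
}

#' Pairwise distances from an alignment
#'
#' `model = "p"`: mismatches / compared columns with pairwise deletion of gap
#' columns. `model = "poisson"`: `-ln(1 - p)`.
#'
#' @param aln an [msa] with >= 3 rows.
#' @param model `"poisson"` (default) or `"p"`.
#' @return symmetric distance matrix with leaf ids as dimnames.
#' @export
distances <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "msa"), length(aln$rows) >= 3)
  M <- do.call(rbind, strsplit(toupper(aln$rows), ""))
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- M[i, ] != "-" & M[j, ] != "-"
    if (!any(ok)) stop("gap-only overlap between rows '", aln$ids[i],
                       "' and '", aln$ids[j], "'")
    p <- mean(M[i, ok] != M[j, ok])
    d <- if (model == "p") p else {
      if (p >= 1) stop("saturated distance (p = 1) between '", aln$ids[i],
                       "' and '", aln$ids[j], "' under poisson model")
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei Q-criterion agglomeration with deterministic tie-breaking
#' (smallest current (i, j) index pair) and negative branch lengths clamped
#' to zero. Returns an unrooted `phylo` with a trifurcating root.
#'
#' @param d symmetric distance matrix with dimnames (n >= 3).
#' @return an `ape::phylo` object.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(d)
  stopifnot(n >= 3)
  labels <- rownames(d)
  # node ids: 1..n leaves; internal nodes created as n+2, n+3, ... with the
  # root taking n+1 at the end (ape convention: root = n+1)
  active_id <- seq_len(n)
  D <- d
  next_internal <- n + 2L
  edges <- matrix(0L, 0, 2)
  elens <- numeric(0)
  while (length(active_id) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    best <- NULL
    for (i in seq_len(r - 1)) for (j in (i + 1):r) {
      q <- (r - 2) * D[i, j] - R[i] - R[j]
      if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, i = i, j = j)
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    u <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, active_id[i]), c(u, active_id[j]))
    elens <- c(elens, max(0, li), max(0, lj))
    duk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    D <- D2
    active_id <- c(active_id[keep], u)
  }
  # join final three at the root
  root <- n + 1L
  i <- 1; j <- 2; k <- 3
  l1 <- (D[i, j] + D[i, k] - D[j, k]) / 2
  l2 <- (D[i, j] + D[j, k] - D[i, k]) / 2
  l3 <- (D[i, k] + D[j, k] - D[i, j]) / 2
  edges <- rbind(edges, c(root, active_id[1]), c(root, active_id[2]),
                 c(root, active_id[3]))
  elens <- c(elens, max(0, l1), max(0, l2), max(0, l3))
  n_internal <- next_internal - n - 1L
  tr <- structure(list(edge = edges, edge.length = elens,
                       tip.label = labels, Nnode = n_internal),
                  class = "phylo", order = NULL)
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

# leaf-label sets below each internal node (bipartitions), canonical keys
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  internal <- setdiff(unique(tree$edge[, 1]), root)
  sets <- lapply(internal, below)
  names(sets) <- internal
  sets
}

bipartition_key <- function(leafset, all_leaves) {
  other <- setdiff(all_leaves, leafset)
  a <- paste(sort(leafset), collapse = "|")
  b <- paste(sort(other), collapse = "|")
  if (a < b) paste(a, b, sep = "||") else paste(b, a, sep = "||")
}

#' Bootstrap supports for an alignment's NJ tree
#'
#' Columns are resampled with replacement, the tree is rebuilt per replicate,
#' and the support of each internal branch of the point-estimate tree is the
#' percentage of replicates containing its bipartition.
#'
#' @param aln an [msa].
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param model distance model (see [distances]).
#' @return the point-estimate `phylo` with `node.label` supports (root `NA`)
#'   and a `support` attribute keyed by internal node id.
#' @export
bootstrap_supports <- function(aln, n_reps = 1000, seed = 1,
                               model = "poisson") {
  stopifnot(n_reps >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tree <- neighbor_joining(distances(aln, model))
  sets <- tree_bipartitions(tree)
  all_leaves <- tree$tip.label
  keys <- vapply(sets, bipartition_key, "", all_leaves = all_leaves)
  counts <- setNames(numeric(length(keys)), keys)
  L <- nchar(aln$rows[1])
  rows_chars <- do.call(rbind, strsplit(toupper(aln$rows), ""))
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    rep_aln <- msa(apply(rows_chars[, idx, drop = FALSE], 1, paste,
                         collapse = ""), ids = aln$ids)
    rep_tree <- neighbor_joining(distances(rep_aln, model))
    rep_keys <- vapply(tree_bipartitions(rep_tree), bipartition_key, "",
                       all_leaves = all_leaves)
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  supports <- round(100 * counts / n_reps, 1)
  node_ids <- as.integer(names(sets))
  sup_by_node <- setNames(supports, node_ids)
  nlab <- rep(NA_character_, tree$Nnode)
  nlab[node_ids - length(all_leaves)] <- as.character(sup_by_node)
  tree$node.label <- nlab
  attr(tree, "support") <- sup_by_node
  tree
}

node_supports <- function(tree) {
  sup <- attr(tree, "support")
  if (is.null(sup)) {
    n <- length(tree$tip.label)
    ids <- (n + 1):(n + tree$Nnode)
    sup <- suppressWarnings(as.numeric(tree$node.label))
    names(sup) <- ids
    sup <- sup[!is.na(sup)]
  }
  sup
}

#' Condense a tree by collapsing weakly supported branches
#'
#' Internal branches whose support falls below `min_support` get length 0;
#' topology is retained (a zero-length internal branch renders as a
#' polytomy).
#'
#' @param tree a `phylo` with supports (see [bootstrap_supports]).
#' @param min_support percent threshold (default 50).
#' @return modified `phylo`.
#' @export
condense <- function(tree, min_support = 50) {
  sup <- node_supports(tree)
  if (length(sup) == 0) stop("tree carries no supports")
  low <- as.integer(names(sup)[sup < min_support])
  hit <- tree$edge[, 2] %in% low
  tree$edge.length[hit] <- 0
  tree
}

#' Two-clade partition of a tree
#'
#' The partition is defined by the internal branch maximizing the product of
#' bootstrap support and branch length; ties prefer the branch with the
#' larger smaller-side size, then the lexicographically smallest side. The
#' clade containing `ref` (default: the first tip) is labelled clade 1.
#'
#' @param tree a `phylo` with supports on internal branches.
#' @param ref leaf id anchored to clade 1.
#' @return data.frame (leaf, clade) with clade in {1, 2}.
#' @export
split_two_clades <- function(tree, ref = tree$tip.label[1]) {
  n <- length(tree$tip.label)
  if (n == 2) {
    return(data.frame(leaf = tree$tip.label, clade = c(1L, 2L),
                      stringsAsFactors = FALSE))
  }
  sets <- tree_bipartitions(tree)
  if (length(sets) <= 1) {   # only the root (star) -> no internal branch
    nontrivial <- Filter(function(s) length(s) > 1 && length(s) < n, sets)
    if (length(nontrivial) == 0) stop("star tree: no internal branch to cut")
  }
  sup <- node_supports(tree)
  cand <- names(sets)[names(sets) %in% names(sup)]
  if (length(cand) == 0) stop("no supported internal branch")
  elen <- setNames(tree$edge.length, tree$edge[, 2])
  score <- vapply(cand, function(nd) sup[nd] * elen[nd], 1.0)
  small <- vapply(cand, function(nd)
    min(length(sets[[nd]]), n - length(sets[[nd]])), 1L)
  keystr <- vapply(cand, function(nd) paste(sort(sets[[nd]]), collapse = "|"),
                   "")
  ord <- order(-score, -small, keystr)
  bestnode <- cand[ord[1]]
  side <- sets[[bestnode]]
  clade1 <- if (ref %in% side) side else setdiff(tree$tip.label, side)
  data.frame(leaf = tree$tip.label,
             clade = ifelse(tree$tip.label %in% clade1, 1L, 2L),
             stringsAsFactors = FALSE)
}

#' Write a tree in Newick format (supports as internal-node labels)
#' @param tree `phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
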