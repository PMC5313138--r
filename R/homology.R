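# Iterative PSSM homology search: a desk-scale analog of profile-based
# (psi-blast style) collection of family members, with empirically calibrated
# Gumbel (Karlin-Altschul form) E-values.

#' Build a position-specific score matrix from aligned member segments
#'
#' Column scores are half-bit log-odds, `2 * log2(freq / background)`, where
#' the column frequencies mix observed counts with substitution-matrix
#' conditioned pseudocounts: the pseudocount distribution of a column is
#' `g(a) = sum_b f(b) q(a|b)` with `q(a|b) ~ p(a) 2^(s_ab/2)` derived from
#' BLOSUM62. With a single row and large `pseudocount_weight` the scores
#' therefore approach the substitution-matrix rows themselves.
#'
#' @param sites an [msa] of equal-length member segments (gaps allowed; a
#'   gapped position contributes nothing to its column).
#' @param background 20-vector of residue frequencies (default
#'   Robinson-Robinson).
#' @param pseudocount_weight positive pseudocount mass added per column.
#' @return a `pssm` object: `scores` (width x 21 half-bit matrix, column `X`
#'   fixed at -1), `background`, `pseudocount_weight`, `width`.
#' @export
build_pssm <- function(sites, background = aa_background(),
                       pseudocount_weight = 1) {
  stopifnot(inherits(sites, "msa"), pseudocount_weight > 0)
  rows <- toupper(sites$rows)
  w <- nchar(rows[1])
  mat <- do.call(rbind, strsplit(rows, ""))
  bg <- background / sum(background)
  # q(a|b) from BLOSUM62 half-bit scores
  B <- blosum62()[AA_ALPHABET, AA_ALPHABET]
  Q <- outer(bg, rep(1, 20)) * 2^(B / 2)   # rows a, cols b
  Q <- sweep(Q, 2, colSums(Q), "/")
  scores <- matrix(0, w, 21, dimnames = list(NULL, c(AA_ALPHABET, "X")))
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0) {
      stop("all-gap column at position ", j)
    }
    col <- col[col %in% AA_ALPHABET]   # X/unknown drop out of the counts
    cnt <- table(factor(col, levels = AA_ALPHABET))
    f <- as.numeric(cnt)
    n <- sum(f)
    fobs <- if (n > 0) f / n else bg
    g <- as.numeric(Q %*% fobs)
    freq <- (n * fobs + pseudocount_weight * g) / (n + pseudocount_weight)
    scores[j, 1:20] <- 2 * log2(freq / bg)
  }
  scores[, 21] <- -1
  structure(list(width = w, scores = scores, background = bg,
                 pseudocount_weight = pseudocount_weight), class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("pssm: width", x$width, "(half-bit log-odds)\n")
  invisible(x)
}

#' Calibrate Gumbel E-value parameters against shuffled decoys
#'
#' Fits the Karlin-Altschul form `E(S) = K * m * n * exp(-lambda * S)` by the
#' method of moments on maximal local scores of the PSSM against
#' residue-shuffled database sequences.
#'
#' @param pssm a [build_pssm] object.
#' @param db a protein [seq_set] supplying decoy material.
#' @param n_decoys number of shuffled decoys (>= 100).
#' @param seed RNG seed.
#' @param gap_open,gap_extend affine gap parameters.
#' @return list with `lambda`, `K`, `mean_len` (decoy length used in the fit).
#' @export
calibrate_evalues <- function(pssm, db, n_decoys = 200, seed = 1,
                              gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(pssm, "pssm"), n_decoys >= 100)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(length(db), n_decoys, replace = TRUE)
  decoys <- lapply(idx, function(i) {
    e <- encode_protein(db$seqs[i])
    sample(e)                      # residue shuffle
  })
  sc <- pssm_best_scores_cpp(pssm$scores, decoys, gap_open, gap_extend)
  if (stats::sd(sc) < 1e-9) stop("degenerate decoy score distribution")
  lambda <- pi / (stats::sd(sc) * sqrt(6))
  mu <- mean(sc) - 0.5772156649 / lambda
  mean_len <- mean(vapply(decoys, length, 1L))
  K <- exp(lambda * mu) / (pssm$width * mean_len)
  list(lambda = lambda, K = K, mean_len = mean_len, scores = sc)
}

#' E-value of a score under calibrated Gumbel parameters
#' @param calib result of [calibrate_evalues].
#' @param score alignment score (same units as the calibration).
#' @param m query (PSSM) width.
#' @param n total database residue count.
#' @return E-value(s).
#' @export
evalue_of_score <- function(calib, score, m, n) {
  calib$K * m * n * exp(-calib$lambda * score)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Iterative profile search for family members
#'
#' Round 1 scores the database with a PSSM built from the seed alone (which,
#' by construction of the pseudocounts, is substitution-matrix search); each
#' later round rebuilds the PSSM from the accepted hit segments stacked by
#' their alignment to the query (the seed row is always included, so every
#' query column is covered; query positions unaligned in a hit contribute
#' background). Membership is monotone: once accepted, never dropped. The
#' search stops when a round adds no new member, or after `max_rounds`.
#'
#' @param seed_seq the query protein (character scalar).
#' @param db a protein [seq_set].
#' @param evalue_threshold inclusion threshold (default 1e-15).
#' @param max_rounds maximal number of rounds (default 10).
#' @param n_decoys decoys per round for E-value calibration.
#' @param seed RNG seed (calibration shuffles).
#' @param gap_open,gap_extend affine gap parameters.
#' @return list with `rounds` (data.frame: round, n_members, new_members,
#'   converged), `members` (character ids), `hits` (data.frame: target_id,
#'   evalue, bitscore, identity, query/target spans, round of first
#'   acceptance), and `final_round`.
#' @export
psi_search <- function(seed_seq, db, evalue_threshold = 1e-15,
                       max_rounds = 10, n_decoys = 100, seed = 1,
                       gap_open = 11, gap_extend = 1) {
  stopifnot(length(db) > 0, nchar(seed_seq) > 0)
  seed_seq <- toupper(seed_seq)
  enc_db <- lapply(db$seqs, encode_protein)
  Ntot <- sum(nchar(db$seqs))
  members <- character(0)
  hit_info <- list()
  rounds <- list()
  seg_rows <- c(seed = seed_seq)     # aligned-segment stack, seed always in
  converged <- FALSE
  r <- 0L
  while (r < max_rounds && !converged) {
    r <- r + 1L
    pssm <- build_pssm(msa(seg_rows, ids = paste0("s", seq_along(seg_rows))),
                       pseudocount_weight = if (r == 1L) 1e6 else 1)
    calib <- calibrate_evalues(pssm, db, n_decoys = max(100, n_decoys),
                               seed = seed * 131L + r,
                               gap_open = gap_open, gap_extend = gap_extend)
    sc <- pssm_best_scores_cpp(pssm$scores, enc_db, gap_open, gap_extend)
    ev <- evalue_of_score(calib, sc, pssm$width, Ntot)
    accept <- which(ev <= evalue_threshold)
    new_ids <- setdiff(db$ids[accept], members)
    members <- union(members, db$ids[accept])
    # stack accepted hit segments for the next profile
    seg_rows <- c(seed = seed_seq)
    for (id in members) {
      i <- match(id, db$ids)
      al <- pssm_align(pssm$scores, db$seqs[i], gap_open, gap_extend)
      row <- rep("-", pssm$width)
      tchars <- strsplit(toupper(db$seqs[i]), "")[[1]]
      keep <- al$ai >= 0 & al$bi >= 0
      row[al$ai[keep] + 1L] <- tchars[al$bi[keep] + 1L]
      seg_rows <- c(seg_rows, setNames(paste(row, collapse = ""), id))
      if (!(id %in% names(hit_info))) {
        schars <- strsplit(seed_seq, "")[[1]]
        qpos <- al$ai[keep] + 1L
        ident <- mean(schars[qpos] == tchars[al$bi[keep] + 1L])
        hit_info[[id]] <- data.frame(
          target_id = id, evalue = ev[i], bitscore = sc[i] / 2,
          identity = ident,
          query_start = al$a_start + 1L, query_end = al$a_end,
          target_start = al$b_start + 1L, target_end = al$b_end,
          round = r, stringsAsFactors = FALSE)
      }
    }
    converged <- length(new_ids) == 0L
    rounds[[r]] <- data.frame(round = r, n_members = length(members),
                              new_members = length(new_ids),
                              converged = converged)
  }
  # internal consistency: a db copy of the seed must hit itself
  self <- db$ids[toupper(db$seqs) == seed_seq]
  if (length(self) && !all(self %in% members)) {
    stop("internal consistency error: seed sequence present in db but not accepted")
  }
  hits <- if (length(hit_info)) do.call(rbind, unname(hit_info)) else
    data.frame(target_id = character(), evalue = numeric(),
               bitscore = numeric(), identity = numeric(),
               query_start = integer(), query_end = integer(),
               target_start = integer(), target_end = integer(),
               round = integer(), stringsAsFactors = FALSE)
  list(rounds = do.call(rbind, rounds), members = members, hits = hits,
       final_round = r)
}

#' Write a member search report as TSV
#' @param res a [psi_search] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_search_report <- function(res, path) {
  utils::write.table(res$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
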