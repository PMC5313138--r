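# Independent oracles and small fixture builders shared across the suite.

# exhaustive local-alignment enumerator (affine gaps, gap of length k costs
# go + k*ge); feasible for sequences of length <= 5. Recursion explores all
# monotone paths; the best prefix score seen anywhere is the local optimum.
brute_local_score <- function(a, b, S, go = 11, ge = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  best <- 0
  rec <- function(i, j, state, score) {
    if (score > best) best <<- score
    if (i <= n && j <= m)
      rec(i + 1, j + 1, "M", score + S[ac[i], bc[j]])
    if (i <= n)
      rec(i + 1, j, "X", score - ge - if (state != "X") go else 0)
    if (j <= m)
      rec(i, j + 1, "Y", score - ge - if (state != "Y") go else 0)
  }
  for (i in seq_len(n)) for (j in seq_len(m)) rec(i, j, "start", 0)
  best
}

# Biostrings reference for local alignment scores (independent implementation)
biostrings_local_score <- function(a, b, go = 11, ge = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = go, gapExtension = ge,
    type = "local", scoreOnly = TRUE)
}

# brute-force repeat finder: enumerate all windows on every (anti)diagonal,
# keep those whose arm edges match, whose mismatch count is within bounds,
# and which cannot be extended without adding a mismatch.
brute_repeats <- function(seq, min_arm = 4, max_loop = 20, max_mismatch = 1) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  add <- function(kind, a1, a2, arm, loop, mm)
    rows[[length(rows) + 1]] <<- data.frame(
      kind = kind, arm1_start = a1, arm2_start = a2, arm_len = arm,
      loop_len = loop, mismatches = mm, stringsAsFactors = FALSE)
  emit_windows <- function(match_vec, handler) {
    len <- length(match_vec)
    for (lo in seq_len(len)) {
      if (!match_vec[lo]) next
      for (hi in lo:len) {
        if (!match_vec[hi]) next
        mm <- sum(!match_vec[lo:hi])
        if (mm > max_mismatch) next
        left_ok <- lo == 1 || !match_vec[lo - 1]
        right_ok <- hi == len || !match_vec[hi + 1]
        if (left_ok && right_ok) handler(lo, hi, mm)
      }
    }
  }
  # direct repeats, offset d
  for (d in seq_len(n - 1)) {
    len <- n - d
    if (len < 1) break
    mv <- ch[seq_len(len)] == ch[seq_len(len) + d]
    emit_windows(mv, function(lo, hi, mm) {
      arm <- hi - lo + 1
      if (arm >= min_arm && d >= arm)
        add("direct", lo, lo + d, arm, d - arm, mm)
    })
  }
  # inverted repeats / palindromes, anti-diagonal C = p + q (0-based)
  for (C in 1:(2 * n - 3)) {
    pmax_ <- (C - 1) %/% 2
    pmin_ <- max(0, C - (n - 1))
    if (pmax_ < pmin_) next
    ps <- pmin_:pmax_
    mv <- comp[ch[ps + 1]] == ch[C - ps + 1]
    mv[is.na(mv)] <- FALSE
    emit_windows(mv, function(lo, hi, mm) {
      arm <- hi - lo + 1
      p_in <- pmin_ + hi - 1
      loop <- C - 2 * p_in - 1
      if (arm >= min_arm && loop >= 0 && loop <= max_loop) {
        p_out <- pmin_ + lo - 1
        add(if (loop == 0) "palindrome" else "inverted",
            p_out + 1, C - p_in + 1, arm, loop, mm)
      }
    })
  }
  if (length(rows) == 0) {
    return(data.frame(kind = character(), arm1_start = integer(),
                      arm2_start = integer(), arm_len = integer(),
                      loop_len = integer(), mismatches = integer()))
  }
  df <- do.call(rbind, rows)
  df[order(df$kind, df$arm1_start, df$arm2_start), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein_str <- function(n)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")

# planted-literal family for motif tests
planted_family <- function(n = 40, len = 60, literal = "HIHEKHTH",
                           seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      s <- random_protein_str(len)
      p <- sample.int(len - nchar(literal) + 1, 1)
      substr(s, p, p + nchar(literal) - 1) <- literal
      s
    }, "")
    seq_set(seqs, sprintf("p%03d", seq_len(n)), "protein")
  })
}

norm_repeat_df <- function(df) {
  rownames(df) <- NULL
  df[order(df$kind, df$arm1_start, df$arm2_start, df$arm_len), ]
}
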