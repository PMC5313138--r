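# Signature (motif) discovery and cross-family scanning. A "signature" is a
# fixed-width position-weight matrix discovered within one relaxase family by
# a zero-or-one-occurrence-per-sequence (ZOOPS) EM mixture, retained when its
# Monte-Carlo-calibrated E-value passes the discovery threshold.

#' Discover signatures by ZOOPS expectation-maximization
#'
#' Sequential discovery: for each candidate width, EM is seeded from sampled
#' data subsequences (short runs on all starts, long runs on the best few);
#' the best-scoring motif across widths is kept if its E-value passes
#' `max_evalue`, its sites are erased (replaced by background-sampled
#' residues), and discovery repeats up to `max_motifs`. Retained motifs are
#' trimmed of uninformative edge columns (< 0.5 bits).
#'
#' The motif E-value is the upper-tail probability of the site alignment's
#' log-likelihood ratio under a Monte-Carlo null in which the same EM
#' optimization is re-run on within-sequence residue-shuffled copies of the
#' data (`n_em_null` replicates), using a Gaussian tail fit to the null
#' optima, Bonferroni-scaled by the number of widths tried. Re-optimizing on
#' shuffled data is what accounts for EM's selection effect: a null of
#' merely random site sets is far too optimistic and would call signatures
#' in pure noise. A pure empirical p-value would also be floored at
#' 1/n_em_null and could never reach thresholds such as 1e-15; the fitted
#' tail is what makes the threshold meaningful.
#'
#' @param seqs a protein [seq_set]; redundancy-reduced input (50% centroids)
#'   is expected for specific motifs.
#' @param max_motifs maximal number of signatures (default 10).
#' @param max_evalue retention threshold (default 1e-15).
#' @param width_range integer 2-vector, candidate motif widths.
#' @param seed RNG seed (EM starts, null shuffles, erasure).
#' @param n_starts EM starting points (distinct data subsequences) sampled
#'   per width (default 200).
#' @param n_em_null EM-refit null replicates per width (default 6).
#' @return list of `signature` objects (`name`, `width`, `pwm` width x 20
#'   probability matrix, `evalue`, `sites` data.frame, `nsites`, `llr`).
#' @export
discover_signatures <- function(seqs, max_motifs = 10, max_evalue = 1e-15,
                                width_range = c(6, 50), seed = 1,
                                n_starts = 200, n_em_null = 6) {
  stopifnot(inherits(seqs, "seq_set"), length(seqs) >= 2)
  if (attr(seqs, "alphabet") != "protein") stop("protein alphabet required")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bg <- aa_background()
  enc <- lapply(seqs$seqs, function(s) {
    e <- encode_protein(s)
    x <- e >= 20L
    if (any(x)) e[x] <- sample(0:19, sum(x), replace = TRUE, prob = bg)
    e
  })
  widths <- candidate_widths(width_range[1], width_range[2],
                             max(nchar(seqs$seqs)))
  occupied <- lapply(seq_along(enc), function(i) integer(0)) # erased positions
  sigs <- list()
  # the EM-refit null per width is computed once, on shuffles of the intact
  # data, and reused across motif iterations (erasure replaces a few percent
  # of residues by background, which leaves the null essentially unchanged)
  null_cache <- list()
  shuffles <- lapply(seq_len(n_em_null), function(k) lapply(enc, sample))
  for (motif_i in seq_len(max_motifs)) {
    best <- NULL
    for (w in widths) {
      fit <- zoops_fit_width(enc, w, bg, n_starts)
      if (is.null(fit)) next
      st <- site_llr(enc, fit, w, bg)
      if (st$nsites < 2) next
      key <- as.character(w)
      if (is.null(null_cache[[key]])) {
        # the null gets the same optimization effort as the observed fit,
        # otherwise null optima are both biased low and unstable
        null_llr <- vapply(shuffles, function(sh) {
          nf <- zoops_fit_width(sh, w, bg, n_starts)
          if (is.null(nf)) return(0)
          site_llr(sh, nf, w, bg)$llr
        }, 1.0)
        null_cache[[key]] <- c(mean(null_llr), stats::sd(null_llr))
      }
      mu0 <- null_cache[[key]][1]
      sd0 <- max(null_cache[[key]][2], 0.02 * abs(mu0), 1e-9)
      z <- (st$llr - mu0) / sd0
      pval <- stats::pnorm(z, lower.tail = FALSE)
      ev <- min(1, pval * length(widths))
      # among widths passing the threshold prefer the largest LLR in excess
      # of that width's own null mean: p-values of strong motifs underflow
      # and cannot rank widths, raw LLR favors widths that classify more
      # spurious sites, but the excess is null-comparable across widths
      # (the edge trim then removes uninformative flanking columns)
      cand <- list(width = w, fit = fit, evalue = ev, llr = st$llr,
                   excess = st$llr - mu0, sites = st$sites,
                   nsites = st$nsites)
      better <- if (is.null(best)) TRUE
        else if ((ev <= max_evalue) != (best$evalue <= max_evalue))
          ev <= max_evalue
        else if (ev <= max_evalue) cand$excess > best$excess
        else ev < best$evalue
      if (better) best <- cand
    }
    if (is.null(best) || best$evalue > max_evalue) break
    best <- trim_motif(best, enc, bg, min_ic = 0.5)
    if (is.null(best)) break
    # sites that fall on previously erased ground are background noise
    keep <- vapply(seq_len(nrow(best$sites)), function(r) {
      i <- best$sites$idx[r]; s <- best$sites$start[r]
      !any((s:(s + best$width - 1L)) %in% occupied[[i]])
    }, TRUE)
    best$sites <- best$sites[keep, , drop = FALSE]
    if (nrow(best$sites) < 2) break
    pwm <- pwm_from_sites(enc, best$sites$idx, best$sites$start, best$width,
                          bg, pseudo = 0.25)
    sig <- structure(list(name = paste0("sig", length(sigs) + 1L),
                          width = best$width, pwm = pwm,
                          evalue = best$evalue, llr = best$llr,
                          nsites = nrow(best$sites),
                          sites = data.frame(seq_id = seqs$ids[best$sites$idx],
                                             start = best$sites$start,
                                             stringsAsFactors = FALSE)),
                     class = "signature")
    sigs[[length(sigs) + 1L]] <- sig
    # erase
    for (r in seq_len(nrow(best$sites))) {
      i <- best$sites$idx[r]; s <- best$sites$start[r]
      pos <- s:(s + best$width - 1L)
      enc[[i]][pos] <- sample(0:19, best$width, replace = TRUE, prob = bg)
      occupied[[i]] <- c(occupied[[i]], pos)
    }
  }
  sigs
}

candidate_widths <- function(min_w, max_w, max_len) {
  max_w <- min(max_w, max_len)
  if (max_w < min_w) stop("sequences shorter than minimal motif width")
  w <- min_w
  out <- integer(0)
  while (w <= max_w) { out <- c(out, round(w)); w <- w * 1.4 }
  unique(pmin(c(out, max_w), max_w))
}

# EM at one width: short runs on all starts, full run on the best few.
zoops_fit_width <- function(enc, w, bg, n_starts, n_long = 3L) {
  usable <- which(vapply(enc, length, 1L) >= w)
  if (length(usable) < 2) return(NULL)
  starts <- list()
  for (k in seq_len(n_starts)) {
    i <- sample(usable, 1L)
    s <- sample.int(length(enc[[i]]) - w + 1L, 1L)
    starts[[k]] <- enc[[i]][s:(s + w - 1L)]
  }
  pwm0s <- lapply(starts, function(sub) {
    p <- matrix(rep(bg * 0.3, each = w), w, 20)
    for (k in seq_len(w)) p[k, sub[k] + 1L] <- p[k, sub[k] + 1L] + 0.7
    p / rowSums(p)
  })
  short <- lapply(pwm0s, function(p0)
    zoops_em_cpp(enc, p0, bg, 0.5, 4L, 1e-4, 0.25))
  ll <- vapply(short, function(f) f$loglik, 1.0)
  top <- order(ll, decreasing = TRUE)[seq_len(min(n_long, length(ll)))]
  fits <- lapply(top, function(t)
    zoops_em_cpp(enc, short[[t]]$pwm, bg, short[[t]]$gamma, 60L, 1e-6, 0.25))
  fits[[which.max(vapply(fits, function(f) f$loglik, 1.0))]]
}

# trim uninformative edge columns from an accepted motif; site starts shift
# with the left trim. The cutoff tracks the sampling noise of apparent IC:
# a background column of n sites has mean IC ~ 19/(2 ln2 n) bits with sd
# ~ sqrt(2*19)/(2 ln2 n); edges below mean + 3 sd (floored at min_ic) go.
trim_motif <- function(best, enc, bg, min_ic = 0.5) {
  w <- best$width
  pwm <- pwm_from_sites(enc, best$sites$idx, best$sites$start, w, bg,
                        pseudo = 0.25)
  ic <- info_content(pwm)
  n <- best$nsites
  # EM is free to slide all sites coherently, so flank columns are selected
  # (max over offsets) rather than i.i.d.; a relative cutoff at a quarter of
  # the median column IC catches what the noise rule alone would miss
  min_ic <- max(min_ic, (19 + 3 * sqrt(38)) / (2 * log(2) * n),
                0.25 * stats::median(ic))
  lo <- 1; hi <- w
  while (lo <= hi && ic[lo] < min_ic) lo <- lo + 1
  while (hi >= lo && ic[hi] < min_ic) hi <- hi - 1
  if (hi - lo + 1 < 4) return(NULL)
  best$sites$start <- best$sites$start + lo - 1L
  best$width <- hi - lo + 1L
  best$llr <- alignment_llr(enc, best$sites$idx, best$sites$start,
                            best$width, bg)
  best
}

# classify ZOOPS sites (posterior > 0.5) and compute the alignment LLR
site_llr <- function(enc, fit, w, bg) {
  has <- which(fit$site_post > 0.5 & fit$best_pos >= 0)
  idx <- has
  starts <- fit$best_pos[has] + 1L
  list(llr = alignment_llr(enc, idx, starts, w, bg),
       nsites = length(idx),
       sites = data.frame(idx = idx, start = starts))
}

# LLR (bits) of the ungapped alignment of nsites width-w sites
alignment_llr <- function(enc, idx, starts, w, bg) {
  if (length(idx) == 0) return(0)
  cnt <- matrix(0, w, 20)
  for (r in seq_along(idx)) {
    site <- enc[[idx[r]]][starts[r]:(starts[r] + w - 1L)]
    for (k in seq_len(w)) cnt[k, site[k] + 1L] <- cnt[k, site[k] + 1L] + 1
  }
  n <- length(idx)
  f <- cnt / n
  lr <- log2(sweep(f, 2, bg, "/"))
  lr[!is.finite(lr)] <- 0
  sum(cnt * lr)
}

pwm_from_sites <- function(enc, idx, starts, w, bg, pseudo = 0.25) {
  cnt <- matrix(0, w, 20, dimnames = list(NULL, AA_ALPHABET))
  for (r in seq_along(idx)) {
    site <- enc[[idx[r]]][starts[r]:(starts[r] + w - 1L)]
    for (k in seq_len(w)) cnt[k, site[k] + 1L] <- cnt[k, site[k] + 1L] + 1
  }
  p <- sweep(cnt + pseudo * matrix(rep(bg, each = w), w, 20), 1,
             rowSums(cnt) + pseudo, "/")
  p
}

#' @export
print.signature <- function(x, ...) {
  cat("signature", x$name, ": width", x$width, ", E =",
      format(x$evalue, digits = 3), ",", x$nsites, "sites\n")
  cat("consensus:", consensus_of(x$pwm), "\n")
  invisible(x)
}

#' Consensus string of a probability matrix
#' @param pwm width x 20 probability matrix (columns in residue order).
#' @return character scalar.
#' @export
consensus_of <- function(pwm) {
  paste(AA_ALPHABET[apply(pwm, 1, which.max)], collapse = "")
}

#' Scan sequences for a signature
#'
#' Per sequence, the best window log-odds score is converted to a p-value by
#' exact convolution of the per-column score distributions under the
#' background (independent columns), then to a sequence E-value
#' `p * scannable positions * number of sequences`. A sequence "contains" the
#' signature if its E-value passes `evalue_threshold`.
#'
#' @param signature a `signature` (or a width x 20 probability matrix).
#' @param seqs a protein [seq_set].
#' @param evalue_threshold default 1e-6.
#' @return data.frame: seq_id, best_score (bits), best_pos (1-based or NA),
#'   pvalue, evalue, contains.
#' @export
scan_signature <- function(signature, seqs, evalue_threshold = 1e-6) {
  pwm <- if (inherits(signature, "signature")) signature$pwm else signature
  bg <- aa_background()
  lo <- log2(sweep(pmax(pwm, 1e-9), 2, bg, "/"))
  enc <- lapply(seqs$seqs, function(s) {
    e <- encode_protein(s); e[e >= 20L] <- 0L; e
  })
  hits <- pwm_best_hit_cpp(lo, enc)
  pv <- score_pvalue_fun(lo, bg)
  m <- pmax(0L, nchar(seqs$seqs) - nrow(lo) + 1L)
  p <- ifelse(is.na(hits[, 1]), NA_real_, pv(hits[, 1]))
  ev <- ifelse(is.na(p), Inf, pmin(1, p * pmax(m, 1)) * length(seqs))
  data.frame(seq_id = seqs$ids,
             best_score = hits[, 1], best_pos = hits[, 2] + 1L,
             pvalue = p, evalue = ev,
             contains = !is.na(ev) & ev <= evalue_threshold,
             stringsAsFactors = FALSE)
}

# exact single-position score distribution by integer-grid convolution;
# returns a function p(s) = P(score >= s) under background
score_pvalue_fun <- function(logodds, bg, grid = 100) {
  w <- nrow(logodds)
  si <- round(logodds * grid)
  lo_min <- sum(apply(si, 1, min)); lo_max <- sum(apply(si, 1, max))
  dist <- c(1)  # prob vector, offset = current minimum
  off <- 0
  for (k in seq_len(w)) {
    vals <- si[k, ]
    newmin <- off + min(vals); newmax <- off + length(dist) - 1 + max(vals)
    nd <- numeric(newmax - newmin + 1)
    for (a in seq_len(20)) {
      sh <- (off + vals[a]) - newmin
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * bg[a]
    }
    dist <- nd; off <- newmin
  }
  tail_p <- rev(cumsum(rev(dist)))
  function(s) {
    i <- ceiling(s * grid) - off + 1
    i <- pmax(1, pmin(length(tail_p) + 1, i))
    ifelse(i > length(tail_p), 0, tail_p[i])
  }
}

#' Cross-family occurrence table
#'
#' Rows are the signatures of each source family, columns the member sets of
#' each target family; a cell is the percentage (1 decimal) of the target
#' family's members containing the signature at the scan threshold.
#'
#' @param signatures named list (by family) of signature lists.
#' @param members named list (by family) of protein [seq_set]s.
#' @param evalue_threshold scan threshold (default 1e-6).
#' @return numeric matrix, rownames `family.signame`, colnames families.
#' @export
occurrence_table <- function(signatures, members, evalue_threshold = 1e-6) {
  stopifnot(length(signatures) > 0, length(members) > 0)
  for (fam in names(members)) {
    if (length(members[[fam]]) == 0) stop("empty member set for family ", fam)
  }
  rows <- list()
  for (fam_a in names(signatures)) {
    for (sig in signatures[[fam_a]]) {
      cell <- vapply(names(members), function(fam_b) {
        sc <- scan_signature(sig, members[[fam_b]], evalue_threshold)
        round(100 * sum(sc$contains) / nrow(sc), 1)
      }, 1.0)
      rows[[paste0(fam_a, ".", sig$name)]] <- cell
    }
  }
  do.call(rbind, rows)
}

#' Per-column information content of a probability matrix
#' @param pwm width x 20 probability matrix.
#' @return numeric vector of bits per column (`log2(20) - entropy`).
#' @export
info_content <- function(pwm) {
  apply(pwm, 1, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
}

#' Conservation shading counts
#'
#' For a region aligned against several family consensus strings, counts per
#' position how many consensuses match the region's residue, by identity or
#' by conservative similarity group ({ILMV}, {KR}, {DE}, {FYW}, {ST}).
#'
#' @param region aligned residue string of the reference protein segment.
#' @param consensuses character vector of consensus strings aligned to
#'   `region` (equal length).
#' @return integer vector of counts in 0..length(consensuses).
#' @export
conservation_shading <- function(region, consensuses) {
  rc <- strsplit(toupper(region), "")[[1]]
  cons <- lapply(toupper(consensuses), function(s) strsplit(s, "")[[1]])
  if (any(vapply(cons, length, 1L) != length(rc)))
    stop("consensus length differs from region length")
  groups <- list(c("I", "L", "M", "V"), c("K", "R"), c("D", "E"),
                 c("F", "Y", "W"), c("S", "T"))
  same <- function(x, y) {
    if (x == y) return(TRUE)
    any(vapply(groups, function(g) x %in% g && y %in% g, TRUE))
  }
  vapply(seq_along(rc), function(i)
    sum(vapply(cons, function(cc) same(rc[i], cc[i]), TRUE)), 1L)
}

#' Write signatures in MEME minimal motif text format
#' @param signatures list of `signature` objects.
#' @param path output file.
#' @param background residue background written to the header.
#' @return `path`, invisibly.
#' @export
write_meme_minimal <- function(signatures, path, background = aa_background()) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", ""),
             con)
  writeLines("Background letter frequencies", con)
  writeLines(paste(paste(AA_ALPHABET, sprintf("%.5f", background)),
                   collapse = " "), con)
  writeLines("", con)
  for (sig in signatures) {
    writeLines(sprintf("MOTIF %s", sig$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d E= %.2e",
      sig$width, sig$nsites, sig$evalue), con)
    for (k in seq_len(sig$width))
      writeLines(paste(sprintf("%.6f", sig$pwm[k, ]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
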