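# Wedge-model intrinsic curvature and oriT feature annotation: repeats,
# palindromes, GC windows and nic-site localization.

DINUCS <- as.vector(outer(DNA_ALPHABET, DNA_ALPHABET, paste0))

#' Dinucleotide wedge parameter sets
#'
#' Two named tables in the tradition of wedge-model curvature programs:
#' `"AAWedge"` carries a nonzero wedge only on AA (and its complement-strand
#' reading TT), after the classic A-tract wedge (~8.7 degrees magnitude,
#' helical repeat 10.5 bp/turn); `"CDS"` is a full 16-dinucleotide roll/tilt
#' set in the spirit of conformational-energy calculations. The exact source
#' tables are not printed in the literature this package follows and are not
#' redistributable here, so both sets are synthetic stand-ins of the
#' respective lineages: curve *positions* (phasing), not absolute
#' magnitudes, are the supported contract. User-supplied tables with the
#' same structure are accepted anywhere a `WedgeParams` is.
#'
#' @param name `"AAWedge"` or `"CDS"`.
#' @return list (`name`, `twist`, `roll`, `tilt`): named 16-vectors, degrees.
#' @export
wedge_params <- function(name = c("AAWedge", "CDS")) {
  name <- match.arg(name)
  if (name == "AAWedge") {
    twist <- setNames(rep(360 / 10.5, 16), DINUCS)
    roll <- setNames(rep(0, 16), DINUCS)
    tilt <- setNames(rep(0, 16), DINUCS)
    roll["AA"] <- -7.4; tilt["AA"] <- 2.4   # wedge magnitude ~7.8 deg
    roll["TT"] <- -7.4; tilt["TT"] <- -2.4  # complement-strand reading
  } else {
    twist <- setNames(c(35.6, 34.4, 27.7, 31.5, 34.5, 33.7, 29.8, 27.7,
                        36.9, 40.0, 33.7, 34.4, 36.0, 36.9, 34.5, 35.6),
                      DINUCS)
    roll <- setNames(c(-5.4, -2.5, 1.0, -7.3, 6.7, 1.3, 4.6, 1.0,
                       2.0, 1.3, 1.3, -2.5, 8.0, 2.0, 6.7, -5.4), DINUCS)
    tilt <- setNames(c(-0.5, -2.7, -1.7, 0.0, 0.4, -0.1, 0.0, 1.7,
                       -1.5, 0.0, 0.1, 2.7, 0.0, 1.5, -0.4, 0.5), DINUCS)
  }
  list(name = name, twist = twist, roll = roll, tilt = tilt)
}

check_wedge_params <- function(params) {
  stopifnot(is.list(params),
            all(c("twist", "roll", "tilt") %in% names(params)),
            all(DINUCS %in% names(params$twist)),
            all(DINUCS %in% names(params$roll)),
            all(DINUCS %in% names(params$tilt)))
  invisible(params)
}

#' Helical axis path under the wedge model
#'
#' Composes, per dinucleotide step, a twist rotation about the local helix
#' axis followed by roll and tilt wedge deflections, advancing one unit
#' along the local axis. All-zero wedge angles give collinear points. Steps
#' containing `N` contribute zero wedge (their count is reported in the
#' `n_unknown` attribute).
#'
#' @param seq nucleotide character scalar (length >= 2).
#' @param params a [wedge_params] table.
#' @return (length-1) x 3 matrix of axis points, unit spacing.
#' @export
helical_path <- function(seq, params = wedge_params("AAWedge")) {
  check_wedge_params(params)
  e <- encode_dna(seq)
  helical_path_cpp(e, unname(params$twist[DINUCS]),
                   unname(params$roll[DINUCS]), unname(params$tilt[DINUCS]))
}

#' Wedge-model curvature profile
#'
#' Curvature at position i is the angle between the chord vectors of the
#' helical path over `[i - w, i]` and `[i, i + w]` divided by `w` (per-step
#' degrees, `w = window_curv`); the curvature-angle is the undivided chord
#' angle at the wider window (`window_angle`). Circular sequences wrap; on
#' linear sequences the first/last `w` positions are `NA`.
#'
#' @param seq nucleotide character scalar.
#' @param params a [wedge_params] table.
#' @param window_curv,window_angle window sizes in bp (defaults 10 and 15).
#' @param circular logical.
#' @return `curvature_profile`: list with `curvature`, `angle` (per-position
#'   vectors), `windows`, `circular`, `length`.
#' @export
curvature_profile <- function(seq, params = wedge_params("AAWedge"),
                              window_curv = 10, window_angle = 15,
                              circular = TRUE) {
  s <- toupper(seq)
  L <- nchar(s)
  wmax <- max(window_curv, window_angle)
  if (L <= wmax) stop("sequence shorter than the curvature window")
  if (circular) {
    ext <- paste0(substring(s, L - wmax, L), s, substring(s, 1, wmax + 1))
    off <- wmax + 1   # base i of s sits at ext position i + off
  } else {
    ext <- s; off <- 0
  }
  path <- helical_path(ext, params)
  # axis point of base k (1-based in ext): P[k], with P[1] = origin
  P <- rbind(c(0, 0, 0), path)
  chord_angle <- function(i, w) {
    a <- P[i, ] - P[i - w, ]
    b <- P[i + w, ] - P[i, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) return(0)
    cosv <- max(-1, min(1, sum(a * b) / (na * nb)))
    acos(cosv) * 180 / pi
  }
  curv <- rep(NA_real_, L); ang <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    k <- i + off
    if (circular || (i > window_curv && i + window_curv <= L))
      curv[i] <- chord_angle(k, window_curv) / window_curv
    if (circular || (i > window_angle && i + window_angle <= L))
      ang[i] <- chord_angle(k, window_angle)
  }
  structure(list(curvature = curv, angle = ang,
                 windows = c(curv = window_curv, angle = window_angle),
                 circular = circular, length = L),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat("curvature_profile over", x$length, "bp",
      if (x$circular) "(circular)" else "(linear)", "\n")
  invisible(x)
}

#' Smooth and z-normalize a curvature profile
#'
#' Centered moving average over `window` bp (circular wrap for circular
#' profiles, truncated renormalized windows at linear edges), followed by a
#' z-transform to mean 0 and standard deviation 1.
#'
#' @param profile a [curvature_profile] (or numeric vector with a `circular`
#'   attribute).
#' @param window smoothing window in bp (default 600).
#' @param which `"curvature"` or `"angle"`.
#' @return numeric z-profile (attributes `circular`, `window`).
#' @export
smooth_normalize <- function(profile, window = 600, which = "curvature") {
  if (inherits(profile, "curvature_profile")) {
    x <- profile[[which]]
    circular <- profile$circular
  } else {
    x <- as.numeric(profile)
    circular <- isTRUE(attr(profile, "circular"))
  }
  n <- length(x)
  if (n < window) stop("profile shorter than smoothing window")
  # exactly `window` positions per window; for even windows the extra
  # position sits on the right of the center
  half_l <- (window - 1) %/% 2
  half_r <- window - 1 - half_l
  sm <- numeric(n)
  if (circular) {
    xx <- c(tail(x, half_l), x, head(x, half_r))
    cs <- cumsum(c(0, xx))
    sm <- (cs[(1:n) + window] - cs[1:n]) / window
  } else {
    for (i in seq_len(n)) {
      lo <- max(1, i - half_l); hi <- min(n, i + half_r)
      v <- x[lo:hi]
      sm[i] <- mean(v, na.rm = TRUE)
    }
  }
  if (stats::sd(sm, na.rm = TRUE) < 1e-12)
    stop("degenerate constant profile after smoothing")
  z <- (sm - mean(sm, na.rm = TRUE)) / stats::sd(sm, na.rm = TRUE)
  attr(z, "circular") <- circular
  attr(z, "window") <- window
  z
}

#' Peak calling on a z-normalized profile
#'
#' Local maxima above `min_z`, greedily thinned so that no two peaks are
#' closer than `min_separation` (circular distance when applicable),
#' returned sorted by position (1-based).
#'
#' @param z z-profile from [smooth_normalize].
#' @param min_z threshold (default 2).
#' @param min_separation bp (default 1200).
#' @return integer positions (possibly empty), attribute `z` with heights.
#' @export
call_peaks <- function(z, min_z = 2.0, min_separation = 1200) {
  n <- length(z)
  circular <- isTRUE(attr(z, "circular"))
  nb <- function(i, d) if (circular) ((i - 1 + d) %% n) + 1 else i + d
  is_peak <- vapply(seq_len(n), function(i) {
    if (is.na(z[i]) || z[i] < min_z) return(FALSE)
    l <- nb(i, -1); r <- nb(i, 1)
    lv <- if (l >= 1 && l <= n) z[l] else -Inf
    rv <- if (r >= 1 && r <= n) z[r] else -Inf
    z[i] >= lv && z[i] > rv
  }, TRUE)
  cand <- which(is_peak)
  cand <- cand[order(-z[cand])]
  keep <- integer(0)
  for (p in cand) {
    dist <- if (circular) pmin(abs(keep - p), n - abs(keep - p)) else
      abs(keep - p)
    if (all(dist >= min_separation)) keep <- c(keep, p)
  }
  keep <- sort(keep)
  attr(keep, "z") <- z[keep]
  keep
}

#' Exhaustive repeat / palindrome scan
#'
#' Finds direct repeats (same-strand duplicated words at any separation,
#' non-overlapping arms), inverted repeats (arm 2 the reverse complement of
#' arm 1 within the loop bound) and palindromes (loop 0). Hits are
#' maximal-arm at their own mismatch count, with arm edges required to
#' match. Intended for oriT-scale regions (quadratic in length).
#'
#' @param seq nucleotide character scalar.
#' @param min_arm minimal arm length (default 4).
#' @param max_loop maximal loop for inverted repeats (default 20).
#' @param max_mismatch maximal mismatches per arm pairing (default 1).
#' @return data.frame: kind, arm1_start, arm2_start (1-based), arm_len,
#'   loop_len, mismatches.
#' @export
find_repeats <- function(seq, min_arm = 4, max_loop = 20, max_mismatch = 1) {
  e <- encode_dna(seq)
  r <- find_repeats_cpp(e, as.integer(min_arm), as.integer(max_loop),
                        as.integer(max_mismatch))
  df <- as.data.frame(r, stringsAsFactors = FALSE)
  df[order(df$kind, df$arm1_start, df$arm2_start), , drop = FALSE]
}

#' Sliding-window GC content
#'
#' GC percentage per 1-bp-stepped window; `N` is excluded from both
#' numerator and denominator. Circular sequences wrap.
#'
#' @param seq nucleotide character scalar.
#' @param window window size in bp (default 30).
#' @param circular logical.
#' @return numeric vector of GC percentages, element i = window starting at
#'   position i (length `L` when circular, `L - window + 1` otherwise).
#' @export
gc_windows <- function(seq, window = 30, circular = FALSE) {
  s <- toupper(seq)
  L <- nchar(s)
  stopifnot(window <= L)
  ch <- strsplit(s, "")[[1]]
  if (circular) ch <- c(ch, ch[seq_len(window - 1)])
  gc <- as.numeric(ch %in% c("G", "C"))
  valid <- as.numeric(ch != "N")
  csg <- cumsum(c(0, gc)); csv <- cumsum(c(0, valid))
  n_out <- if (circular) L else L - window + 1
  i <- seq_len(n_out)
  num <- csg[i + window] - csg[i]
  den <- csv[i + window] - csv[i]
  ifelse(den == 0, NA_real_, round(100 * num / den, 1))
}

NICK_MOTIF <- "GAATCGGGGGCCGG"

#' Locate the nic-site recognition 14-mer
#'
#' Searches both strands for the recognition string; the nick position is
#' the first base 3' of the match on the matched strand (on the minus
#' strand, that is one position before the match in plus-strand
#' coordinates). Circular sequences wrap across the origin. Multiple
#' occurrences are all returned and flagged ambiguous.
#'
#' @param seq nucleotide character scalar.
#' @param motif recognition string (default the nic 14-mer).
#' @param circular logical.
#' @return data.frame (position, strand, match_start, ambiguous); zero rows
#'   when the motif is absent.
#' @export
locate_nick <- function(seq, motif = NICK_MOTIF, circular = TRUE) {
  s <- toupper(seq)
  L <- nchar(s)
  k <- nchar(motif)
  hay <- if (circular) paste0(s, substring(s, 1, k - 1)) else s
  wrap1 <- function(p) ((p - 1) %% L) + 1
  find_all <- function(pat) {
    m <- gregexpr(pat, hay, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m[m <= L])
  }
  plus <- find_all(motif)
  minus <- find_all(reverse_complement(motif))
  rows <- list()
  for (p in plus) {
    rows[[length(rows) + 1]] <- data.frame(
      position = if (circular) wrap1(p + k) else p + k,
      strand = "+", match_start = p, stringsAsFactors = FALSE)
  }
  for (p in minus) {
    rows[[length(rows) + 1]] <- data.frame(
      position = if (circular) wrap1(p - 1) else p - 1,
      strand = "-", match_start = p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(position = integer(), strand = character(),
                      match_start = integer(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df$ambiguous <- nrow(df) > 1
  df[order(df$match_start), , drop = FALSE]
}

# ---- plain-text writers -----------------------------------------------------

#' Write a profile as wiggle (fixedStep) / peaks as BED / features as GFF3
#' @param z numeric per-position values.
#' @param chrom sequence name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wig <- function(z, chrom, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
  writeLines(sprintf("%.6g", as.numeric(z)), con)
  invisible(path)
}

#' @rdname write_wig
#' @param peaks 1-based peak positions ([call_peaks]).
#' @export
write_bed <- function(peaks, chrom, path) {
  df <- data.frame(chrom = chrom, start = as.integer(peaks) - 1L,
                   end = as.integer(peaks),
                   name = paste0("peak", seq_along(peaks)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_wig
#' @param repeats data.frame from [find_repeats].
#' @param nicks data.frame from [locate_nick].
#' @export
write_gff3 <- function(repeats, nicks, chrom, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(repeats) && nrow(repeats)) {
    for (i in seq_len(nrow(repeats))) {
      r <- repeats[i, ]
      writeLines(sprintf(
        "%s\tmoblkit\t%s\t%d\t%d\t.\t+\t.\tID=rep%d;arm_len=%d;loop=%d;mismatches=%d;arm2_start=%d",
        chrom, r$kind, r$arm1_start, r$arm2_start + r$arm_len - 1L,
        i, r$arm_len, r$loop_len, r$mismatches, r$arm2_start), con)
    }
  }
  if (!is.null(nicks) && nrow(nicks)) {
    for (i in seq_len(nrow(nicks))) {
      nk <- nicks[i, ]
      writeLines(sprintf(
        "%s\tmoblkit\tnick_site\t%d\t%d\t.\t%s\t.\tID=nick%d;ambiguous=%s",
        chrom, nk$position, nk$position, nk$strand, i,
        tolower(as.character(nk$ambiguous))), con)
    }
  }
  invisible(path)
}
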