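test_that("helical path geometry: spacing, straight limits", {
  aw <- wedge_params("AAWedge")
  s <- strrep("G", 50)
  path <- helical_path(s, aw)
  expect_equal(nrow(path), 49)
  # unit spacing between consecutive points
  P <- rbind(c(0, 0, 0), path)
  steps <- sqrt(rowSums(diff(P)^2))
  expect_equal(steps, rep(1, 49), tolerance = 1e-9)
  # poly-G has no AA/TT step: maximal deviation from the end-to-end chord
  chord <- P[50, ] / sqrt(sum(P[50, ]^2))
  dev <- apply(P, 1, function(p) sqrt(sum((p - sum(p * chord) * chord)^2)))
  expect_lt(max(dev), 1e-6)
  # zero-wedge parameter table is collinear for any sequence
  zero <- aw; zero$roll[] <- 0; zero$tilt[] <- 0
  withr::with_seed(91, s2 <- random_dna(40))
  prof <- curvature_profile(s2, zero, circular = TRUE)
  expect_equal(max(abs(prof$curvature)), 0, tolerance = 1e-9)
})

test_that("phased A-tracts curve macroscopically; shuffles do not", {
  tract <- function() {
    gaps <- rep(c(10, 11), length.out = 9)
    starts <- cumsum(c(1, gaps))
    span <- max(starts) + 5
    ch <- rep("C", span + 10)
    for (st in starts) ch[st:(st + 5)] <- "A"
    paste(ch, collapse = "")
  }
  aw <- wedge_params("AAWedge")
  s <- tract()
  end_dist <- function(x) {
    p <- helical_path(x, aw)
    sqrt(sum(p[nrow(p), ]^2))
  }
  d0 <- end_dist(s)
  withr::with_seed(92, {
    wins <- vapply(1:20, function(k) {
      sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      end_dist(sh) > d0
    }, TRUE)
  })
  expect_gte(sum(wins), 19)      # bent tract is shorter end-to-end
  expect_lt(d0, 0.8 * nchar(s))
})

test_that("curvature profiles rotate with circular rotation, and the
           normalization is exact", {
  pl <- gen_plasmid(plasmid_spec(length = 3000, bend = list(
    center = 800, tract_len = 6, copies = 10), orit = NULL), seed = 93)
  prof <- curvature_profile(pl$seq, circular = TRUE)
  k <- 700
  rot <- paste0(substring(pl$seq, k + 1), substring(pl$seq, 1, k))
  prof_rot <- curvature_profile(rot, circular = TRUE)
  # equivariance is exact in exact arithmetic; 3000 composed rotations
  # leave ~1e-7 of floating-point frame drift
  expect_lt(max(abs(prof_rot$curvature -
                      c(prof$curvature[-(1:k)], prof$curvature[1:k]))), 1e-6)
  z <- smooth_normalize(prof, window = 600)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  # linear profiles lose the first/last window positions
  lin <- curvature_profile(substring(pl$seq, 1, 500), circular = FALSE)
  expect_true(all(is.na(lin$curvature[1:10])))
  expect_true(all(!is.na(lin$curvature[16:485])))
})

test_that("smoothing arithmetic: impulse height and degenerate input", {
  # a 600-impulse smoothed over a 600-bp window becomes a plateau of 600
  # positions at exactly 1/600 of the impulse (closed-form z oracle)
  n <- 6000; imp <- 600
  x <- numeric(n); x[3000] <- imp
  attr(x, "circular") <- TRUE
  z <- smooth_normalize(x, window = 600)
  plateau <- which(abs(z - max(z)) < 1e-12)
  expect_length(plateau, 600)
  expect_true(3000 %in% plateau)
  sm_val <- imp / 600                      # = 1
  mu <- sm_val * 600 / n
  sdv <- sqrt((600 * (sm_val - mu)^2 + (n - 600) * mu^2) / (n - 1))
  expect_equal(max(z), (sm_val - mu) / sdv, tolerance = 1e-9)
  const <- rep(2.5, 1000); attr(const, "circular") <- TRUE
  expect_error(smooth_normalize(const, 600), "degenerate")
})

test_that("peak calling separates planted bends and stays quiet on noise", {
  two <- gen_plasmid(plasmid_spec(length = 8000,
                                  bend = list(center = 1500, tract_len = 6,
                                              copies = 10),
                                  orit = NULL), seed = 94)
  # plant a second bend manually 5 kb away
  gaps <- rep(c(10, 11), length.out = 9)
  starts <- cumsum(c(1, gaps))
  ch <- strsplit(two$seq, "")[[1]]
  for (st in starts) ch[(6500 + st):(6500 + st + 5)] <- "A"
  s2 <- paste(ch, collapse = "")
  z <- smooth_normalize(curvature_profile(s2, circular = TRUE), 600)
  pk <- call_peaks(z, min_z = 2, min_separation = 1200)
  expect_equal(length(pk), 2)
  expect_lt(min(abs(pk - 1500)), 300)
  expect_lt(min(abs(pk - 6550)), 300)
  # a planted bend is the global maximum and localizes within 300 bp;
  # matched bend-free noise never reaches its height (the z-profile of pure
  # noise still exceeds 2 routinely, since normalization forces sd 1, so
  # absolute peak count in noise is not a meaningful null - see vignette)
  for (k in 1:5) {
    pl <- gen_plasmid(plasmid_spec(length = 5000,
                                   bend = list(center = 2000, tract_len = 6,
                                               copies = 10), orit = NULL),
                      seed = 300 + k)
    zb <- smooth_normalize(curvature_profile(pl$seq, circular = TRUE), 600)
    expect_lt(abs(which.max(zb) - 2000), 300)
    noise <- gen_plasmid(plasmid_spec(length = 5000, bend = NULL,
                                      orit = NULL), seed = 300 + k)
    zn <- smooth_normalize(curvature_profile(noise$seq, circular = TRUE), 600)
    expect_gt(max(zb), max(zn))
  }
})

test_that("repeat finder reproduces the canonical oriT features", {
  ir <- find_repeats("GGCTTTTTGCTGCCGCAAAAAGCC", max_mismatch = 0)
  hit <- ir[ir$arm_len == 10, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$kind, "inverted")
  expect_equal(hit$loop_len, 4)
  expect_equal(hit$mismatches, 0)
  pal <- find_repeats("TGGTACCA", max_mismatch = 0)
  expect_equal(pal$kind, "palindrome")
  expect_equal(pal$arm_len, 4)
  expect_equal(pal$loop_len, 0)
  # a word inserted three times gives all three direct-repeat pairings
  withr::with_seed(95, {
    bgs <- random_dna(150)
    s <- paste0(substr(bgs, 1, 40), "TGTGCATA", substr(bgs, 41, 90),
                "TGTGCATA", substr(bgs, 91, 130), "TGTGCATA")
  })
  dr <- find_repeats(s, min_arm = 8, max_mismatch = 0)
  word_hits <- dr[dr$kind == "direct" & dr$arm_len >= 8, ]
  expect_gte(nrow(word_hits), 3)
})

test_that("repeat finder equals the brute-force oracle on random strings", {
  withr::with_seed(96, {
    for (k in 1:6) {
      s <- random_dna(sample(40:90, 1))
      got <- norm_repeat_df(find_repeats(s, min_arm = 4, max_loop = 10,
                                         max_mismatch = 1))
      want <- norm_repeat_df(brute_repeats(s, min_arm = 4, max_loop = 10,
                                           max_mismatch = 1))
      expect_equal(got, want, ignore_attr = TRUE, info = s)
    }
  })
})

test_that("GC windows: closed forms, N handling, wrap", {
  expect_equal(gc_windows(strrep("G", 30), 30), 100)
  expect_equal(gc_windows(strrep("AT", 15), 30), 0)
  w <- paste0(strrep("G", 22), strrep("A", 8))
  expect_equal(gc_windows(w, 30), 73.3)
  expect_equal(gc_windows("GGNN", 4), 100)   # N out of both numerator/denominator
  circ <- gc_windows("GGGAAA", 3, circular = TRUE)
  expect_length(circ, 6)
  expect_equal(circ[5], 33.3)                # wraps A A G
})

test_that("nic-site localization: strands, wrap, multiplicity", {
  m <- "GAATCGGGGGCCGG"
  s <- paste0(strrep("T", 39), m, strrep("C", 46))
  hit <- locate_nick(s, circular = FALSE)
  expect_equal(hit$position, 54)
  expect_equal(hit$strand, "+")
  expect_false(hit$ambiguous)
  # reverse-complement occurrence reports the minus strand
  s2 <- paste0(strrep("T", 10), reverse_complement(m), strrep("A", 20))
  hit2 <- locate_nick(s2, circular = FALSE)
  expect_equal(hit2$strand, "-")
  expect_equal(hit2$position, 10)      # first base 3' of the match on minus
  # circular wrap across the origin
  s3 <- paste0(substring(m, 8), strrep("A", 30), substring(m, 1, 7))
  hit3 <- locate_nick(s3, circular = TRUE)
  expect_equal(hit3$strand, "+")
  expect_equal(hit3$position, 8)
  # absent -> empty; duplicated -> ambiguous
  expect_equal(nrow(locate_nick(strrep("A", 50))), 0)
  s4 <- paste0(m, strrep("A", 20), m)
  hits4 <- locate_nick(s4, circular = FALSE)
  expect_equal(nrow(hits4), 2)
  expect_true(all(hits4$ambiguous))
})

test_that("plain-text writers emit parseable wiggle/BED/GFF3", {
  z <- c(0.5, -1, 2)
  f1 <- withr::local_tempfile(fileext = ".wig")
  write_wig(z, "chr", f1)
  expect_equal(readLines(f1)[1], "fixedStep chrom=chr start=1 step=1")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(c(10L, 20L), "chr", f2)
  expect_equal(read.table(f2)$V2, c(9, 19))
  f3 <- withr::local_tempfile(fileext = ".gff3")
  reps <- find_repeats("TGGTACCA")
  nk <- locate_nick(paste0("AA", moblkit:::NICK_MOTIF, "TT"), circular = FALSE)
  write_gff3(reps, nk, "chr", f3)
  txt <- readLines(f3)
  expect_equal(txt[1], "##gff-version 3")
  expect_true(any(grepl("nick_site", txt)))
})
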