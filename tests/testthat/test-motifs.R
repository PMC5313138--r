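test_that("a planted literal is recovered as the first signature", {
  fam <- planted_family(n = 40, len = 60, literal = "HIHEKHTH", seed = 61)
  sigs <- discover_signatures(fam, max_motifs = 2, width_range = c(6, 12),
                              seed = 5, n_starts = 60)
  expect_gte(length(sigs), 1)
  expect_equal(consensus_of(sigs[[1]]$pwm), "HIHEKHTH")
  expect_lte(sigs[[1]]$evalue, 1e-15)
  # site list matches the planting coordinates on most members
  sc <- scan_signature(sigs[[1]], fam)
  expect_gte(mean(sc$contains), 0.9)
})

test_that("two planted motifs: the full-presence one ranks first and site
           lists never overlap", {
  withr::with_seed(62, {
    seqs <- vapply(1:40, function(i) {
      s <- random_protein_str(70)
      substr(s, 5, 12) <- "HIHEKHTH"                 # all members
      if (i <= 20) substr(s, 40, 49) <- "WQDNPLRTYG" # half of them
      s
    }, "")
  })
  ss <- seq_set(seqs, sprintf("m%02d", 1:40), "protein")
  sigs <- discover_signatures(ss, max_motifs = 3, width_range = c(6, 12),
                              seed = 9)
  expect_gte(length(sigs), 2)
  expect_equal(consensus_of(sigs[[1]]$pwm), "HIHEKHTH")
  # the half-presence motif may be recovered at a neighboring grid width;
  # its 8-column core must be present (full-width recovery is exercised by
  # the KL criterion in the acceptance suite)
  cons2 <- vapply(sigs[-1], function(s) consensus_of(s$pwm), "")
  expect_true(any(grepl("WQDNPLRT", cons2, fixed = TRUE)))
  # no overlapping sites within a sequence across signatures
  allsites <- do.call(rbind, lapply(sigs, function(s)
    cbind(s$sites, width = s$width)))
  for (id in unique(allsites$seq_id)) {
    x <- allsites[allsites$seq_id == id, ]
    iv <- unlist(lapply(seq_len(nrow(x)), function(r)
      x$start[r]:(x$start[r] + x$width[r] - 1)))
    expect_equal(anyDuplicated(iv), 0)
  }
})

test_that("uniform-background sequences yield no signature at 1e-15", {
  dec <- gen_decoys(30, c(60, 80), seed = 63)
  sigs <- discover_signatures(dec, max_motifs = 2, width_range = c(6, 10),
                              seed = 3, n_starts = 40)
  expect_length(sigs, 0)
})

test_that("scanning: consensus hits, decoys do not, thresholds nest", {
  fam <- planted_family(n = 30, len = 60, seed = 64)
  sigs <- discover_signatures(fam, max_motifs = 1, width_range = c(8, 8),
                              seed = 2, n_starts = 40)
  sig <- sigs[[1]]
  cons <- seq_set(consensus_of(sig$pwm), "cons", "protein")
  expect_true(scan_signature(sig, cons)$contains)
  dec <- gen_decoys(200, c(60, 100), seed = 65)
  hits <- scan_signature(sig, dec)
  expect_lte(mean(hits$contains), 0.01)
  # monotonicity: flagged at 1e-8 is a subset of flagged at 1e-6
  both <- seq_set(c(fam$seqs, dec$seqs), c(fam$ids, dec$ids), "protein")
  f6 <- scan_signature(sig, both, 1e-6)
  f8 <- scan_signature(sig, both, 1e-8)
  expect_true(all(f8$seq_id[f8$contains] %in% f6$seq_id[f6$contains]))
  # sequence shorter than the motif is simply not flagged
  short <- seq_set("MK", "tiny", "protein")
  expect_false(scan_signature(sig, short)$contains)
})

test_that("occurrence tables report percentages over the scanned family", {
  fam <- planted_family(n = 20, len = 60, seed = 66)
  sigs <- discover_signatures(fam, max_motifs = 1, width_range = c(8, 8),
                              seed = 2, n_starts = 40)
  one <- seq_set(consensus_of(sigs[[1]]$pwm), "only", "protein")
  dec <- gen_decoys(20, c(60, 80), seed = 67)
  occ <- occurrence_table(list(L = sigs),
                          list(L = fam, one = one, null = dec))
  expect_equal(unname(occ["L.sig1", "one"]), 100.0)
  expect_gte(occ["L.sig1", "L"], 90)
  expect_lte(occ["L.sig1", "null"], 5)
  # member order does not change cells
  perm <- fam[rev(seq_len(length(fam)))]
  occ2 <- occurrence_table(list(L = sigs), list(L = perm))
  expect_equal(unname(occ2["L.sig1", "L"]), unname(occ["L.sig1", "L"]))
  expect_error(occurrence_table(list(L = sigs),
                                list(bad = gen_decoys(0, seed = 1))),
               "bad")
})

test_that("information content follows the closed forms", {
  unif <- matrix(1 / 20, 1, 20)
  expect_equal(info_content(unif), 0)
  single <- matrix(0, 1, 20); single[1, 7] <- 1
  expect_equal(info_content(single), log2(20))
  half <- matrix(0, 1, 20); half[1, c(3, 9)] <- 0.5
  expect_equal(info_content(half), log2(20) - 1)
})

test_that("conservation shading counts identity and similarity groups", {
  expect_equal(conservation_shading("H", c("H", "H", "H")), 3)
  expect_equal(conservation_shading("G", c("H", "W", "P")), 0)
  # planted alignment: per-column expected counts, including {ILMV} and {KR}
  region <- "HIK"
  cons <- c("HLR", "HVK", "WIK")
  expect_equal(conservation_shading(region, cons), c(2L, 3L, 3L))
  expect_error(conservation_shading("HI", c("H")), "length")
})

test_that("MEME minimal output is well-formed", {
  fam <- planted_family(n = 20, len = 50, seed = 68)
  sigs <- discover_signatures(fam, max_motifs = 1, width_range = c(8, 8),
                              seed = 2, n_starts = 30)
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme_minimal(sigs, f)
  txt <- readLines(f)
  expect_true(any(grepl("^MEME version", txt)))
  expect_true(any(grepl("^MOTIF sig1", txt)))
  mat <- grep("letter-probability matrix", txt)
  expect_length(mat, length(sigs))
  first_row <- as.numeric(strsplit(txt[mat[1] + 1], " ")[[1]])
  expect_equal(sum(first_row), 1, tolerance = 1e-4)
})
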