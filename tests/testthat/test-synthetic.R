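test_that("family generation is deterministic and honors the manifest", {
  sp <- family_spec(n_clade1 = 6, n_clade2 = 6, length_mean = 150,
                    length_sd = 10)
  f1 <- gen_family(sp, seed = 111)
  f2 <- gen_family(sp, seed = 111)
  expect_identical(f1$seqs$seqs, f2$seqs$seqs)
  expect_identical(f1$truth$sites, f2$truth$sites)
  f3 <- gen_family(sp, seed = 112)
  expect_false(identical(f1$seqs$seqs, f3$seqs$seqs))
  # sig1 has presence 1: a site in every member, at the recorded position
  sites1 <- f1$truth$sites[f1$truth$sites$signature == "sig1", ]
  expect_setequal(sites1$seq_id, f1$seqs$ids)
  cons <- "HIHEKHTH"
  n_exact <- 0
  for (r in seq_len(nrow(sites1))) {
    s <- f1$seqs$seqs[match(sites1$seq_id[r], f1$seqs$ids)]
    frag <- substr(s, sites1$start[r], sites1$start[r] + sites1$width[r] - 1)
    n_exact <- n_exact + (frag == cons)
  }
  expect_gte(n_exact / nrow(sites1), 0.5)   # 0.95 per-residue fidelity
  # spec validation
  expect_error(family_spec(signatures = list(
    list(name = "s", consensus = "AAA", presence = c(0.5, 0.5)))),
    "present in all")
})

test_that("clades are closer within than between", {
  f <- gen_family(family_spec(n_clade1 = 6, n_clade2 = 6,
                              length_mean = 150, length_sd = 5), seed = 113)
  tr <- f$truth$members
  ids <- f$seqs$ids
  pick <- function(cl) sample(ids[tr$clade == cl], 3)
  withr::with_seed(114, { a <- pick(1); b <- pick(2) })
  idfun <- function(x, y) pairwise_identity(
    f$seqs$seqs[match(x, ids)], f$seqs$seqs[match(y, ids)])
  intra <- mean(c(idfun(a[1], a[2]), idfun(a[1], a[3]),
                  idfun(b[1], b[2]), idfun(b[1], b[3])))
  inter <- mean(c(idfun(a[1], b[1]), idfun(a[2], b[2]), idfun(a[3], b[3])))
  expect_gt(intra, inter)
})

test_that("decoy generation obeys n, composition and determinism", {
  expect_equal(length(gen_decoys(0, seed = 1)), 0)
  comp <- setNames(rep(0, 20), moblkit:::AA_ALPHABET); comp["A"] <- 1
  homo <- gen_decoys(3, c(10, 20), comp, seed = 2)
  expect_true(all(grepl("^A+$", homo$seqs)))
  d1 <- gen_decoys(5, seed = 3); d2 <- gen_decoys(5, seed = 3)
  expect_identical(d1$seqs, d2$seqs)
})

test_that("plasmid features round-trip through the annotation stages", {
  pl <- gen_plasmid(plasmid_spec(length = 6000), seed = 115)
  tf <- pl$truth$features
  # nick 14-mer is found exactly at the manifest position
  nick <- locate_nick(pl$seq)
  expect_equal(nrow(nick), 1)
  expect_equal(nick$position, tf$start[tf$feature == "nick_site"])
  expect_equal(nick$strand, "+")
  # planted inverted repeat (arms 10, loop 4) is reported exactly
  ir <- tf[tf$feature == "inverted_repeat", ]
  cassette <- substring(pl$seq, ir$start, ir$end)
  hits <- find_repeats(cassette, max_mismatch = 0)
  expect_true(any(hits$kind == "inverted" & hits$arm_len == 10 &
                    hits$loop_len == 4))
  # GC-rich 30-mer scores 73.3
  gc <- tf[tf$feature == "gc30", ]
  expect_equal(gc_windows(substring(pl$seq, gc$start, gc$end), 30), 73.3)
  # bend recovered by curvature
  bend <- tf[tf$feature == "bend", ]
  z <- smooth_normalize(curvature_profile(pl$seq, circular = TRUE), 600)
  pk <- call_peaks(z, min_z = 2, min_separation = 1200)
  expect_gte(length(pk), 1)
  dist_circ <- pmin(abs(pk - bend$center), 6000 - abs(pk - bend$center))
  expect_lte(min(dist_circ), 300)
  # determinism
  pl2 <- gen_plasmid(plasmid_spec(length = 6000), seed = 115)
  expect_identical(pl$seq, pl2$seq)
})

test_that("overlapping feature placement errors out", {
  expect_error(
    gen_plasmid(plasmid_spec(length = 800,
                             bend = list(center = 400, tract_len = 6,
                                         copies = 10),
                             orit = list(start = 380)), seed = 116),
    "overlap")
})

test_that("manifest JSON is writable and re-readable", {
  f <- gen_family(family_spec(n_clade1 = 3, n_clade2 = 3,
                              length_mean = 100, length_sd = 5), seed = 117)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(f$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(back$members), 6)
  expect_equal(back$seed, 117)
})
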