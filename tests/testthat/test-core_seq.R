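test_that("FASTA round-trip is lossless for ids and residues", {
  withr::with_seed(11, {
    seqs <- vapply(sample(8:30, 20, replace = TRUE), random_protein_str, "")
  })
  ss <- seq_set(seqs, sprintf("m%02d", 1:20), "protein")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ss, f)
  back <- read_fasta(f, "protein")
  expect_identical(back$ids, ss$ids)
  expect_identical(back$seqs, ss$seqs)
  # empty file -> empty set
  f0 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f0)
  expect_equal(length(read_fasta(f0, "protein")), 0)
  # two records with given lengths
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc", strrep("M", 10), ">b", strrep("K", 20)), f2)
  two <- read_fasta(f2, "protein")
  expect_equal(length(two), 2)
  expect_equal(seq_widths(two), c(10, 20))
  expect_equal(seq_ids(two), c("a", "b"))
})

test_that("seq_set enforces unique non-empty ids and the alphabet", {
  expect_error(seq_set(c("MK", "ML"), c("a", "a"), "protein"), "duplicate")
  expect_error(seq_set("MK", "", "protein"), "empty")
  expect_error(seq_set("MJ", "a", "protein"), "illegal character")
  expect_error(seq_set("ACGU", "a", "nucleotide"), "illegal character")
  expect_silent(seq_set("ACGTN", "a", "nucleotide"))
  expect_silent(seq_set("MKX", "a", "protein"))
})

test_that("reverse_complement: hand-computed values and involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("GAATCGGGGGCCGG"), "CCGGCCCCCGATTC")
  expect_equal(reverse_complement("N"), "N")
  expect_error(reverse_complement("ACGU"), "illegal")
  withr::with_seed(3, {
    for (k in 1:10) {
      x <- random_dna(sample(1:60, 1))
      expect_equal(reverse_complement(reverse_complement(x)), x)
    }
  })
})

test_that("translation follows table 11, drops partial codons, marks stops", {
  expect_equal(translate_seq("ATGAAA"), "MK")
  expect_equal(translate_seq("ATGTAA"), "M*")
  expect_equal(translate_seq("ATGAAAG"), "MK")   # trailing partial dropped
  expect_equal(translate_seq("TTTCAT", strand = "-"), "MK")
  withr::with_seed(4, {
    s <- random_dna(300)
    fr <- six_frame(s)
    expect_equal(unname(nchar(fr)), rep(c(100, 99, 99), 2))
  })
  # strand/frame consistency: translating the revcomp on + equals - frames
  withr::with_seed(5, {
    s <- random_dna(90)
    expect_equal(translate_seq(reverse_complement(s), 1, "+"),
                 translate_seq(s, 1, "-"))
  })
})

test_that("coordinate conversion round-trips", {
  expect_equal(to_reported(0, 10), c(1, 10))
  expect_equal(to_internal(1, 10), c(0, 10))
  withr::with_seed(6, {
    for (k in 1:10) {
      s <- sample.int(1000, 1); e <- s + sample.int(100, 1)
      expect_equal(to_reported(to_internal(s, e)[1], to_internal(s, e)[2]),
                   c(s, e))
    }
  })
})

test_that("msa validates rows and ungap reproduces inputs", {
  expect_error(msa(c("AB-", "ABCD")), "differ in length")
  al <- msa(c(x = "MK-L", y = "M-AL"))
  expect_identical(al$ids, c("x", "y"))
  expect_equal(ungap(al$rows[1]), "MKL")
  expect_equal(ungap(al$rows[2]), "MAL")
})

test_that("minimal GenBank reader extracts id, topology, sequence and CDS", {
  gb <- c(
    "LOCUS       pTEST                 60 bp    DNA     circular BCT 01-JAN-2020",
    "DEFINITION  synthetic test plasmid.",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..22",
    "                     /locus_tag=\"orf1\"",
    "     CDS             complement(30..50)",
    "                     /locus_tag=\"orf2\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//")
  f <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, f)
  rec <- read_genbank(f)
  expect_equal(rec$id, "pTEST")
  expect_true(rec$circular)
  expect_equal(nchar(rec$seq), 60)
  expect_equal(rec$cds$locus_tag, c("orf1", "orf2"))
  expect_equal(rec$cds$strand, c("+", "-"))
  expect_equal(rec$cds$start, c(5, 30))
})
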