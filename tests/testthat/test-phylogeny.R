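test_that("length filter is strict ('longer than')", {
  ss <- seq_set(vapply(c(299, 300, 301), function(n) strrep("M", n), ""),
                c("a", "b", "c"), "protein")
  kept <- filter_by_length(ss, 300)
  expect_equal(seq_ids(kept), "c")
  expect_equal(length(filter_by_length(seq_set(character(), character(),
                                               "protein"))), 0)
  all400 <- seq_set(rep(strrep("K", 400), 3), c("x", "y", "z"), "protein")
  expect_equal(length(filter_by_length(all400)), 3)
})

test_that("center-star MSA ungaps back to its inputs", {
  fam <- gen_family(family_spec(n_clade1 = 4, n_clade2 = 4,
                                length_mean = 120, length_sd = 10), seed = 71)
  al <- build_msa(fam$seqs)
  expect_equal(length(unique(nchar(al$rows))), 1)
  for (i in seq_along(al$rows)) {
    expect_equal(ungap(al$rows[i]),
                 toupper(fam$seqs$seqs[match(al$ids[i], fam$seqs$ids)]))
  }
})

test_that("distances: closed forms and degenerate input", {
  al <- msa(c(a = "MMMM", b = "MMMM", c = "MMKK"))
  D <- distances(al, "p")
  expect_equal(unname(D["a", "b"]), 0)
  expect_equal(unname(D["a", "c"]), 0.5)
  Dp <- distances(al, "poisson")
  expect_equal(unname(Dp["a", "c"]), -log(0.5), tolerance = 1e-9)
  gappy <- msa(c(a = "MM--", b = "--KK", c = "MMKK"))
  expect_error(distances(gappy), "gap-only overlap.*'a'.*'b'")
  sat <- msa(c(a = "MMMM", b = "KKKK", c = "MMKK"))
  expect_error(distances(sat, "poisson"), "saturated")
})

test_that("neighbor joining: 3-taxon closed form and additive recovery", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # closed form: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # additive matrices from random trees are recovered exactly
  withr::with_seed(72, {
    for (n in c(5, 6, 8)) {
      gt <- ape::rtree(n)
      gt$edge.length <- runif(nrow(gt$edge), 0.3, 1.5)
      D <- ape::cophenetic.phylo(gt)
      ord <- sort(rownames(D))
      mine <- neighbor_joining(D[ord, ord])
      expect_equal(ape::dist.topo(ape::unroot(gt), mine), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("equidistant taxa resolve deterministically by the tie-break", {
  D <- matrix(1, 4, 4) - diag(4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # smallest index pair is joined first
  first_join <- t1$edge[t1$edge[, 1] == length(t1$tip.label) + 2L, 2]
  expect_equal(sort(t1$tip.label[first_join]), c("a", "b"))
})

test_that("bootstrap: perfectly separating columns give 100% support,
           and the same seed reproduces supports", {
  rows <- c(a1 = strrep("AK", 20), a2 = paste0(strrep("AK", 19), "AR"),
            b1 = strrep("EK", 20), b2 = paste0(strrep("EK", 19), "ER"),
            c1 = paste0(strrep("AK", 10), strrep("AT", 10)))
  al <- msa(rows)
  tr <- bootstrap_supports(al, n_reps = 100, seed = 4)
  sup <- attr(tr, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  # the a|b split is supported by every column
  sets <- moblkit:::tree_bipartitions(tr)
  ab <- vapply(sets, function(s) setequal(s, c("b1", "b2")) ||
                 setequal(s, c("a1", "a2", "c1")), TRUE)
  expect_true(any(ab))
  expect_equal(unname(sup[names(sets)[which(ab)[1]]]), 100)
  tr2 <- bootstrap_supports(al, n_reps = 100, seed = 4)
  expect_identical(attr(tr, "support"), attr(tr2, "support"))
  expect_error(bootstrap_supports(al, n_reps = 0), "n_reps")
})

test_that("condense zeroes exactly the weak internal branches", {
  rows <- c(a1 = strrep("AK", 20), a2 = paste0(strrep("AK", 19), "AR"),
            b1 = strrep("EK", 20), b2 = paste0(strrep("EK", 19), "ER"),
            c1 = paste0(strrep("AK", 10), strrep("AT", 10)))
  tr <- bootstrap_supports(msa(rows), n_reps = 50, seed = 4)
  sup <- attr(tr, "support")
  ct <- condense(tr, min_support = 100)
  low_nodes <- as.integer(names(sup)[sup < 100])
  zeroed <- ct$edge[, 2] %in% low_nodes
  expect_true(all(ct$edge.length[zeroed] == 0))
  expect_equal(ct$edge.length[!zeroed], tr$edge.length[!zeroed])
  all_keep <- condense(tr, min_support = 0)
  expect_equal(all_keep$edge.length, tr$edge.length)
})

test_that("two-clade partition recovers the planted clades and is
           equivariant under relabeling", {
  fam <- gen_family(family_spec(n_clade1 = 8, n_clade2 = 8,
                                length_mean = 150, length_sd = 10), seed = 73)
  al <- build_msa(fam$seqs)
  tr <- bootstrap_supports(al, n_reps = 50, seed = 2)
  part <- split_two_clades(tr, ref = fam$seqs$ids[1])
  truth <- fam$truth$members
  m <- merge(part, truth, by.x = "leaf", by.y = "id")
  agree <- mean(m$clade.x == m$clade.y)
  expect_gte(max(agree, 1 - agree), 0.95)
  # 2-leaf tree: each leaf its own clade
  two <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                        edge.length = c(1, 1), tip.label = c("x", "y"),
                        Nnode = 1L), class = "phylo")
  p2 <- split_two_clades(two)
  expect_setequal(p2$clade, c(1L, 2L))
  # relabeling permutes the partition identically
  tr_rel <- tr
  map <- setNames(paste0("L", seq_along(tr$tip.label)), tr$tip.label)
  tr_rel$tip.label <- unname(map[tr$tip.label])
  part_rel <- split_two_clades(tr_rel, ref = unname(map[fam$seqs$ids[1]]))
  expect_equal(part_rel$clade[match(map[part$leaf], part_rel$leaf)],
               part$clade)
})
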