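# Ground-truth generators: protein families with two clades and planted
# PWM signatures, unrelated decoys, and circular plasmids carrying member
# CDSs, a phased-A-tract bent region and an oriT cassette. Every generator
# returns a manifest sufficient for recovery tests.

#' Family specification
#'
#' The stated world of the family generator: two clades descended from a
#' common ancestor, with clade-specific signature presence. Members within a
#' clade diverge from a clade ancestor; the clade ancestors diverge from the
#' root. With the defaults, intra-clade identity is well above inter-clade
#' identity and members sit in the 40-60% identity band relative to the
#' seed.
#'
#' @param n_clade1,n_clade2 members per clade (defaults 30/30).
#' @param length_mean,length_sd ancestor-core length distribution (400/40).
#' @param inter_divergence substitution probability root -> clade ancestor
#'   (default 0.13 per clade).
#' @param intra_divergence substitution probability clade ancestor -> member
#'   (default 0.30). With the defaults, within-clade pairs sit near 55%
#'   identity and cross-clade pairs near 43%, i.e. the 40-60% band the
#'   family emulates, with clades still separable.
#' @param signatures list of planted signatures: each
#'   `list(name, consensus, presence = c(p_clade1, p_clade2))`. The default
#'   set plants one universal signature (the "signature 1" analog, present
#'   in every member) and two clade-biased ones.
#' @param tail_max maximal random tail appended per member end (default 20).
#' @return a `family_spec` list.
#' @export
family_spec <- function(n_clade1 = 30, n_clade2 = 30,
                        length_mean = 400, length_sd = 40,
                        inter_divergence = 0.13, intra_divergence = 0.30,
                        signatures = default_signatures(), tail_max = 20) {
  stopifnot(n_clade1 >= 1, n_clade2 >= 1)
  for (sg in signatures) {
    stopifnot(all(sg$presence >= 0 & sg$presence <= 1))
  }
  if (!any(vapply(signatures, function(sg) all(sg$presence >= 1), TRUE)))
    stop("at least one signature must be present in all members")
  structure(list(n_clade1 = n_clade1, n_clade2 = n_clade2,
                 length_mean = length_mean, length_sd = length_sd,
                 inter_divergence = inter_divergence,
                 intra_divergence = intra_divergence,
                 signatures = signatures, tail_max = tail_max),
            class = "family_spec")
}

#' @rdname family_spec
#' @export
default_signatures <- function() {
  list(list(name = "sig1", consensus = "HIHEKHTH", presence = c(1, 1)),
       list(name = "sig2", consensus = "WQDNPLRTYG", presence = c(0.9, 0.1)),
       list(name = "sig3", consensus = "CKEMFYDAWP", presence = c(0.1, 0.9)))
}

random_protein <- function(n, bg = aa_background()) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = bg), collapse = "")
}

mutate_protein <- function(seq, rate, bg = aa_background()) {
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE, prob = bg)
  paste(ch, collapse = "")
}

sample_site <- function(consensus, fidelity = 0.95, bg = aa_background()) {
  ch <- strsplit(consensus, "")[[1]]
  flip <- runif(length(ch)) >= fidelity
  ch[flip] <- sample(AA_ALPHABET, sum(flip), replace = TRUE, prob = bg)
  paste(ch, collapse = "")
}

#' Generate a two-clade protein family with planted signatures
#'
#' @param spec a [family_spec].
#' @param seed RNG seed (same seed, same output).
#' @return list: `seqs` (a protein [seq_set]), `truth` (list with `members`
#'   data.frame (id, clade, length), `sites` data.frame (seq_id, signature,
#'   start, width), the ancestor, and the spec).
#' @export
gen_family <- function(spec = family_spec(), seed = 1) {
  stopifnot(inherits(spec, "family_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  bg <- aa_background()
  L0 <- max(60, round(rnorm(1, spec$length_mean, spec$length_sd)))
  maxw <- max(vapply(spec$signatures, function(sg) nchar(sg$consensus), 1L))
  if (maxw > L0) stop("signature wider than member length")
  ancestor <- random_protein(L0, bg)
  clade_anc <- c(mutate_protein(ancestor, spec$inter_divergence, bg),
                 mutate_protein(ancestor, spec$inter_divergence, bg))
  ids <- character(0); seqs <- character(0)
  members <- list(); sites <- list()
  k <- 0
  for (clade in 1:2) {
    n <- if (clade == 1) spec$n_clade1 else spec$n_clade2
    for (i in seq_len(n)) {
      k <- k + 1
      id <- sprintf("fam_c%d_%03d", clade, i)
      s <- mutate_protein(clade_anc[clade], spec$intra_divergence, bg)
      # plant signatures at non-overlapping offsets
      occupied <- integer(0)
      for (sg in spec$signatures) {
        if (runif(1) > sg$presence[clade]) next
        w <- nchar(sg$consensus)
        for (try in 1:200) {
          st <- sample.int(nchar(s) - w + 1L, 1L)
          if (!any((st:(st + w - 1L)) %in% occupied)) break
          st <- NA_integer_
        }
        if (is.na(st)) next
        site <- sample_site(sg$consensus, 0.95, bg)
        substr(s, st, st + w - 1L) <- site
        occupied <- c(occupied, st:(st + w - 1L))
        sites[[length(sites) + 1]] <- data.frame(
          seq_id = id, signature = sg$name, start = st, width = w,
          stringsAsFactors = FALSE)
      }
      tails <- sample.int(spec$tail_max + 1L, 2L, replace = TRUE) - 1L
      s <- paste0(random_protein(tails[1], bg), s, random_protein(tails[2], bg))
      # planted site coordinates shift with the leading tail
      if (tails[1] > 0 && length(sites)) {
        for (r in seq_along(sites)) {
          if (sites[[r]]$seq_id == id)
            sites[[r]]$start <- sites[[r]]$start + tails[1]
        }
      }
      ids <- c(ids, id); seqs <- c(seqs, s)
      members[[k]] <- data.frame(id = id, clade = clade, length = nchar(s),
                                 stringsAsFactors = FALSE)
    }
  }
  truth <- list(members = do.call(rbind, members),
                sites = if (length(sites)) do.call(rbind, sites) else
                  data.frame(seq_id = character(), signature = character(),
                             start = integer(), width = integer()),
                ancestor = ancestor, spec = spec, seed = seed)
  list(seqs = seq_set(seqs, ids, "protein", source = "gen_family"),
       truth = truth)
}

#' Generate unrelated decoy proteins
#'
#' @param n number of decoys.
#' @param length_range integer 2-vector, uniform length distribution.
#' @param composition residue frequencies (default background).
#' @param seed RNG seed.
#' @return a protein [seq_set].
#' @export
gen_decoys <- function(n, length_range = c(250, 450),
                       composition = aa_background(), seed = 1) {
  stopifnot(n >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (n == 0) {
    return(seq_set(character(0), character(0), "protein",
                   source = "gen_decoys"))
  }
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = composition),
          collapse = ""), "")
  seq_set(seqs, sprintf("decoy_%04d", seq_len(n)), "protein",
          source = "gen_decoys")
}

#' Plasmid specification
#'
#' @param length plasmid length in bp (default 10000).
#' @param cds list of CDS embeddings: each `list(protein, id, strand,
#'   origin_spanning)`.
#' @param bend `list(center, tract_len = 6, copies = 10)` phased-A-tract
#'   bent region (tracts phased at alternating 10/11 bp, the classic
#'   curvature-maximizing 10.5 bp period), or `NULL`.
#' @param orit `list(start)` for the oriT cassette (direct repeats, GC-rich
#'   30-mer, nic 14-mer, inverted repeat, palindrome), or `NULL`.
#' @param gc background GC fraction (default 0.4, Firmicutes-like).
#' @return a `plasmid_spec` list.
#' @export
plasmid_spec <- function(length = 10000, cds = list(),
                         bend = list(center = 2500, tract_len = 6,
                                     copies = 10),
                         orit = list(start = 6000), gc = 0.4) {
  structure(list(length = length, cds = cds, bend = bend, orit = orit,
                 gc = gc), class = "plasmid_spec")
}

back_translate <- function(protein, code = "11") {
  gc <- Biostrings::getGeneticCode(as.character(code))
  by_aa <- split(names(gc), unname(gc))
  ch <- strsplit(toupper(protein), "")[[1]]
  codons <- vapply(ch, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot back-translate residue ", a)
    opts[sample.int(length(opts), 1)]
  }, "")
  paste(c(codons, sample(by_aa[["*"]], 1)), collapse = "")  # add a stop
}

orit_cassette <- function() {
  dr <- "TGTGCAT"
  spacer <- function(n) paste(sample(DNA_ALPHABET, n, replace = TRUE,
                                     prob = c(0.3, 0.2, 0.2, 0.3)),
                              collapse = "")
  gc30 <- paste(sample(c(rep(c("G", "C"), 11), rep(c("A", "T"), 4))),
                collapse = "")                      # 22/30 = 73.3% GC
  ir <- "GGCTTTTTGCTGCCGCAAAAAGCC"
  pal <- "TGGTACCA"
  parts <- list(dr1 = dr, s1 = spacer(9), dr2 = dr, s2 = spacer(12),
                dr3 = dr, s3 = spacer(7), gc30 = gc30, nick14 = NICK_MOTIF,
                ir = ir, s4 = spacer(10), pal = pal)
  seqc <- paste(unlist(parts), collapse = "")
  # coordinates of the named features within the cassette (1-based)
  offs <- cumsum(c(1, nchar(unlist(parts))))
  names(offs) <- c(names(parts), "end")
  list(seq = seqc, offsets = offs)
}

#' Generate a circular plasmid with planted features
#'
#' Background sequence at the specified GC; features (CDS embeddings,
#' phased-A-tract bent region, oriT cassette) are written at recorded,
#' non-overlapping coordinates (overlap is an error). CDS embedding
#' back-translates the protein with uniform codon choice; minus-strand and
#' origin-spanning placements are supported.
#'
#' @param spec a [plasmid_spec].
#' @param seed RNG seed.
#' @return list: `seq` (character), `circular = TRUE`, `truth` (feature
#'   coordinate tables; positions 1-based).
#' @export
gen_plasmid <- function(spec = plasmid_spec(), seed = 1) {
  stopifnot(inherits(spec, "plasmid_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  L <- spec$length
  pgc <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  base <- sample(DNA_ALPHABET, L, replace = TRUE, prob = pgc)
  occupied <- logical(L)
  feats <- list()
  write_feature <- function(seqchars, start, label) {
    n <- length(seqchars)
    pos <- ((start - 1 + 0:(n - 1)) %% L) + 1
    if (any(occupied[pos])) stop("feature overlap at '", label, "'")
    occupied[pos] <<- TRUE
    base[pos] <<- seqchars
    feats[[length(feats) + 1]] <<- data.frame(
      feature = label, start = start, end = ((start - 1 + n - 1) %% L) + 1,
      length = n, stringsAsFactors = FALSE)
    invisible(NULL)
  }
  # bent region(s): A6 tracts phased at alternating 10/11 bp; `bend` may be
  # a single spec or a list of them
  if (!is.null(spec$bend)) {
    bends <- if (!is.null(spec$bend$center)) list(spec$bend) else spec$bend
    for (b in bends) {
      gaps <- rep(c(10, 11), length.out = b$copies - 1)
      starts <- cumsum(c(1, gaps))
      span <- max(starts) + b$tract_len - 1
      region <- sample(DNA_ALPHABET, span, replace = TRUE, prob = pgc)
      for (st in starts) region[st:(st + b$tract_len - 1)] <- "A"
      reg_start <- ((b$center - span %/% 2 - 1) %% L) + 1
      write_feature(region, reg_start, "bend")
      feats[[length(feats)]]$center <- b$center
    }
  }
  # oriT cassette
  if (!is.null(spec$orit)) {
    cas <- orit_cassette()
    write_feature(strsplit(cas$seq, "")[[1]], spec$orit$start, "orit")
    off <- cas$offsets
    add <- function(lbl, from, len) {
      st <- ((spec$orit$start - 1 + off[[from]] - 1) %% L) + 1
      feats[[length(feats) + 1]] <<- data.frame(
        feature = lbl, start = st, end = ((st - 1 + len - 1) %% L) + 1,
        length = len, stringsAsFactors = FALSE)
    }
    add("direct_repeat", "dr1", 7); add("direct_repeat", "dr2", 7)
    add("direct_repeat", "dr3", 7)
    add("gc30", "gc30", 30)
    add("nick14", "nick14", 14)
    add("inverted_repeat", "ir", 24)
    add("palindrome", "pal", 8)
    nick_pos <- ((spec$orit$start - 1 + off[["nick14"]] - 1 + 14) %% L) + 1
    feats[[length(feats) + 1]] <- data.frame(
      feature = "nick_site", start = nick_pos, end = nick_pos, length = 1,
      stringsAsFactors = FALSE)
  }
  # CDS embeddings
  for (ci in seq_along(spec$cds)) {
    cd <- spec$cds[[ci]]
    nt <- back_translate(cd$protein)
    if (identical(cd$strand, "-")) nt <- reverse_complement(nt)
    n <- nchar(nt)
    if (isTRUE(cd$origin_spanning)) {
      st <- L - n %/% 2
    } else {
      for (try in 1:500) {
        st <- sample.int(L - n, 1)
        pos <- st:(st + n - 1)
        if (!any(occupied[pos])) break
        st <- NA_integer_
      }
      if (is.na(st)) stop("could not place CDS ", ci, " without overlap")
    }
    write_feature(strsplit(nt, "")[[1]], st,
                  paste0("cds_", if (!is.null(cd$id)) cd$id else ci))
    feats[[length(feats)]]$strand <-
      if (identical(cd$strand, "-")) "-" else "+"
  }
  truth <- list(
    features = do.call(rbind, lapply(feats, function(f) {
      f$center <- if ("center" %in% names(f)) f$center else NA
      f$strand <- if ("strand" %in% names(f)) f$strand else NA
      f
    })),
    spec = spec, seed = seed)
  list(id = sprintf("synplasmid_%d", seed),
       seq = paste(base, collapse = ""), circular = TRUE, truth = truth)
}

#' Write a ground-truth manifest as JSON
#' @param truth a generator `truth` list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(truth, path) {
  truth$spec <- unclass(truth$spec)
  truth$spec$signatures <- NULL
  truth$spec$cds <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
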