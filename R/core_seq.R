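#' @useDynLib moblkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd rnorm runif setNames quantile
#' @importFrom utils head tail write.table read.table
NULL

# canonical residue orders used throughout the package
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA_ALPHABET <- c("A", "C", "G", "T")

.pkg_cache <- new.env(parent = emptyenv())

#' Construct a sequence set
#'
#' The shared container of the toolkit: an ordered, uniquely named collection
#' of protein or nucleotide sequences. Nucleotide sequences carry a per-record
#' circularity flag (plasmids are circular and all window arithmetic on them
#' wraps modulo length).
#'
#' @param seqs character vector of sequences (case preserved; comparisons are
#'   case-insensitive, so validation and all algorithms use the uppercased
#'   form).
#' @param ids character vector of unique, non-empty identifiers.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param circular logical, recycled to `length(seqs)`; only meaningful for
#'   nucleotide sets.
#' @param source optional label describing provenance.
#' @return A `seq_set` object.
#' @export
seq_set <- function(seqs, ids = names(seqs), alphabet = c("protein", "nucleotide"),
                    circular = FALSE, source = NA_character_) {
  alphabet <- match.arg(alphabet)
  seqs <- as.character(seqs)
  if (is.null(ids)) stop("ids are required")
  ids <- as.character(ids)
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (any(!nzchar(ids))) stop("empty sequence id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  validate_alphabet(seqs, ids, alphabet)
  structure(list(ids = ids, seqs = unname(seqs),
                 circular = rep_len(as.logical(circular), length(seqs))),
            alphabet = alphabet, source = source, class = "seq_set")
}

validate_alphabet <- function(seqs, ids, alphabet) {
  allowed <- if (alphabet == "protein") c(AA_ALPHABET, "X", "*") else
    c(DNA_ALPHABET, "N")
  pat <- paste0("[^", paste(allowed, collapse = ""), "]")
  bad <- grepl(pat, toupper(seqs))
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(toupper(seqs[i]), regexpr(pat, toupper(seqs[i])))
    stop("illegal character '", ch, "' in record '", ids[i], "' (", alphabet,
         " alphabet)")
  }
  invisible(TRUE)
}

#' @export
length.seq_set <- function(x) length(x$ids)

#' @export
`[.seq_set` <- function(x, i) {
  structure(list(ids = x$ids[i], seqs = x$seqs[i], circular = x$circular[i]),
            alphabet = attr(x, "alphabet"), source = attr(x, "source"),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), attr(x, "alphabet"), "sequence(s)")
  if (!is.na(attr(x, "source"))) cat(" [", attr(x, "source"), "]", sep = "")
  cat("\n")
  n <- min(length(x), 6L)
  if (n > 0) {
    w <- nchar(x$seqs[seq_len(n)])
    cat(paste0("  ", x$ids[seq_len(n)], " (", w, ")"), sep = "\n")
    if (length(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Sequence ids and widths
#' @param x a `seq_set`
#' @return character / integer vector
#' @export
seq_ids <- function(x) x$ids

#' @rdname seq_ids
#' @export
seq_widths <- function(x) nchar(x$seqs)

#' Read a FASTA file
#'
#' One record per header; the id is the header token before the first
#' whitespace. Duplicate ids and characters outside the declared alphabet are
#' errors.
#'
#' @param path file path.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param circular circularity flag applied to all records (nucleotide only).
#' @return A [seq_set].
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       circular = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  seq_set(as.character(x), ids, alphabet, circular = circular,
          source = basename(path))
}

#' Write a FASTA file (60-column wrap)
#' @param x a [seq_set]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "seq_set"))
  b <- Biostrings::BStringSet(setNames(x$seqs, x$ids))
  Biostrings::writeXStringSet(b, path, width = 60L)
  invisible(path)
}

#' Read an annotated plasmid from a GenBank flat file (read-only, minimal)
#'
#' Parses the LOCUS line (length, circular/linear), CDS features with their
#' `/locus_tag`, and the ORIGIN sequence block. Only what the plasmid
#' localization stage needs; everything else is ignored.
#'
#' @param path GenBank flat file.
#' @return list with `id`, `seq` (uppercase), `circular`, and a data.frame
#'   `cds` (locus_tag, start, end, strand; 1-based inclusive).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))
  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("no ORIGIN block in ", path)
  seq_lines <- lines[(ori[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  # CDS features
  feat <- grep("^\\s{5}CDS\\s", lines)
  cds <- list()
  for (f in feat) {
    locstr <- trimws(sub("^\\s{5}CDS\\s+", "", lines[f]))
    strand <- if (grepl("complement", locstr)) "-" else "+"
    nums <- as.integer(regmatches(locstr, gregexpr("[0-9]+", locstr))[[1]])
    if (length(nums) < 2) next
    tag <- NA_character_
    j <- f + 1
    while (j <= length(lines) && grepl("^\\s{6,}", lines[j]) &&
           !grepl("^\\s{5}\\S", lines[j])) {
      m <- regmatches(lines[j], regexpr('/locus_tag="[^"]+"', lines[j]))
      if (length(m)) tag <- sub('/locus_tag="([^"]+)"', "\\1", m)
      j <- j + 1
    }
    cds[[length(cds) + 1]] <- data.frame(locus_tag = tag, start = nums[1],
                                         end = nums[2], strand = strand,
                                         stringsAsFactors = FALSE)
  }
  cds <- if (length(cds)) do.call(rbind, cds) else
    data.frame(locus_tag = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  list(id = id, seq = seq, circular = circular, cds = cds)
}

#' Reverse complement of a nucleotide sequence
#'
#' Standard Watson-Crick complement, reversed; `N` maps to `N`. Case is
#' normalized to upper case. Works on a plain character scalar.
#'
#' @param seq character scalar over A,C,G,T,N.
#' @return character scalar.
#' @export
reverse_complement <- function(seq) {
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) stop("illegal base in sequence")
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

#' Translate a nucleotide sequence
#'
#' Trailing partial codons are dropped; stop codons render as `*`. The default
#' genetic code is the bacterial/plastid table 11.
#'
#' @param seq character scalar over A,C,G,T,N.
#' @param frame 0, 1 or 2 (offset into the strand being read).
#' @param strand `"+"` or `"-"` (minus reads the reverse complement).
#' @param code NCBI translation table id (character or integer).
#' @return character scalar of amino acids (`X` for ambiguous codons).
#' @export
translate_seq <- function(seq, frame = 0, strand = c("+", "-"), code = "11") {
  strand <- match.arg(strand)
  stopifnot(frame %in% 0:2)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) stop("illegal base in sequence")
  if (strand == "-") s <- reverse_complement(s)
  s <- substring(s, frame + 1)
  n_codon <- nchar(s) %/% 3
  if (n_codon == 0) return("")
  gc <- Biostrings::getGeneticCode(as.character(code))
  codons <- substring(s, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"   # codons containing N
  paste(aa, collapse = "")
}

#' Six-frame translation
#' @param seq nucleotide character scalar.
#' @param code translation table id.
#' @return named character vector of 6 proteins (`F0,F1,F2,R0,R1,R2`).
#' @export
six_frame <- function(seq, code = "11") {
  fr <- expand.grid(frame = 0:2, strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  out <- mapply(function(f, st) translate_seq(seq, f, st, code),
                fr$frame, fr$strand)
  names(out) <- paste0(ifelse(fr$strand == "+", "F", "R"), fr$frame)
  out
}

#' Multiple sequence alignment container
#'
#' Rows are equal-length aligned strings with `-` as the gap symbol; ungapping
#' a row reproduces the input sequence exactly.
#'
#' @param rows character vector of aligned strings.
#' @param ids row identifiers.
#' @return an `msa` object.
#' @export
msa <- function(rows, ids = names(rows)) {
  force(ids)
  rows <- as.character(rows)
  if (length(rows) == 0) stop("empty alignment")
  if (length(unique(nchar(rows))) != 1) stop("msa rows differ in length")
  if (is.null(ids)) ids <- paste0("row", seq_along(rows))
  if (anyDuplicated(ids)) stop("duplicate msa row ids")
  structure(list(rows = unname(rows), ids = as.character(ids)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$rows), "rows x", nchar(x$rows[1]), "columns\n")
  invisible(x)
}

#' Remove gaps from an aligned row
#' @param row aligned string with `-` gaps.
#' @return ungapped string.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

# ---- coordinate conventions -------------------------------------------------
# internal: 0-based half-open [start, end); reported: 1-based inclusive

#' Convert between internal (0-based half-open) and reported (1-based
#' inclusive) coordinates
#' @param start,end interval bounds.
#' @return two-element integer vector.
#' @export
to_reported <- function(start, end) c(start + 1L, end)

#' @rdname to_reported
#' @export
to_internal <- function(start, end) c(start - 1L, end)

# ---- integer encodings for the C++ kernels ---------------------------------

encode_protein <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  m <- match(s, c(AA_ALPHABET, "X", "*")) - 1L
  if (anyNA(m)) stop("illegal residue in protein sequence")
  m[m > 20L] <- 20L   # '*' scored like X
  m
}

encode_dna <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  m <- match(s, DNA_ALPHABET) - 1L
  m[is.na(m)] <- -1L   # N / unknown
  m
}

decode_protein <- function(code) paste(c(AA_ALPHABET, "X")[code + 1L],
                                       collapse = "")

# Robinson-Robinson amino-acid background frequencies, reordered to
# AA_ALPHABET and renormalized.
aa_background <- function() {
  if (!is.null(.pkg_cache$bg)) return(.pkg_cache$bg)
  rr <- c(A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640,
          C = 0.019246, Q = 0.042644, E = 0.062949, G = 0.073772,
          H = 0.021992, I = 0.051420, L = 0.090191, K = 0.057438,
          M = 0.022425, F = 0.038556, P = 0.052028, S = 0.071198,
          T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409)
  bg <- rr[AA_ALPHABET]
  bg <- bg / sum(bg)
  .pkg_cache$bg <- bg
  bg
}

# BLOSUM62 over AA_ALPHABET + X (21 x 21), taken from Biostrings' bundled
# table; gap penalties are carried separately.
blosum62 <- function() {
  if (!is.null(.pkg_cache$blosum)) return(.pkg_cache$blosum)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  letters21 <- c(AA_ALPHABET, "X")
  M <- B[letters21, letters21]
  .pkg_cache$blosum <- M
  M
}
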