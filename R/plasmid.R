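# Plasmid localization of family members: six-frame translated matching of
# each protein against circular plasmid sequences (a desk-scale tblastn
# analog), and the clade-by-location crosstab.

#' Match a protein against a circular plasmid by six-frame translation
#'
#' The plasmid sequence is doubled minus one codon so that genes spanning the
#' circular origin stay intact in some frame; the protein is locally aligned
#' against all six frame translations. A member is called plasmid-located
#' when identity exceeds `min_identity` over more than `min_coverage` of the
#' entire protein length. `mode = "similarity"` counts positive-scoring
#' substitutions instead of identities.
#'
#' @param protein character scalar (the family member).
#' @param plasmid list with `id`, `seq`, `circular` (or a nucleotide
#'   character scalar, assumed circular).
#' @param min_identity identity threshold (strict, default 0.95).
#' @param min_coverage coverage threshold (strict, default 0.80), denominator
#'   the full protein length.
#' @param mode `"identity"` (default) or `"similarity"`.
#' @param substitution,gap_open,gap_extend alignment parameters.
#' @return list: `plasmid_id`, `identity`, `coverage`, `frame`, `positive`
#'   (the call).
#' @export
translated_match <- function(protein, plasmid, min_identity = 0.95,
                             min_coverage = 0.80,
                             mode = c("identity", "similarity"),
                             substitution = blosum62(), gap_open = 11,
                             gap_extend = 1, prescreen = TRUE) {
  mode <- match.arg(mode)
  if (is.character(plasmid)) plasmid <- list(id = "plasmid", seq = plasmid,
                                             circular = TRUE)
  stopifnot(nchar(plasmid$seq) >= 3)
  s <- toupper(plasmid$seq)
  scan_seq <- if (isTRUE(plasmid$circular)) {
    paste0(s, substring(s, 1, nchar(s) - 3))   # doubled minus one codon
  } else s
  frames <- six_frame(scan_seq)
  best <- list(identity = 0, coverage = 0, frame = NA_character_)
  # word prescreen: a >95%-identity match over >80% of the protein shares
  # an exact 10-mer with some frame with near certainty; without one the
  # expensive DP cannot produce a positive call and is skipped.
  if (isTRUE(prescreen) && nchar(protein) >= 10) {
    haystack <- paste(frames, collapse = "#")
    starts <- seq(1, nchar(protein) - 9, by = 4)
    words <- substring(toupper(protein), starts, starts + 9)
    if (!any(vapply(words, function(wd) grepl(wd, haystack, fixed = TRUE),
                    TRUE))) {
      return(list(plasmid_id = plasmid$id, identity = 0, coverage = 0,
                  frame = NA_character_, positive = FALSE))
    }
  }
  ep <- encode_protein(protein)
  for (fn in names(frames)) {
    ft <- frames[[fn]]
    if (nchar(ft) == 0) next
    ef <- encode_protein(ft)
    al <- align_pair_cpp(ep, ef, substitution, gap_open, gap_extend, 0L)
    if (al$columns == 0) next
    keep <- al$ai >= 0 & al$bi >= 0
    if (mode == "identity") {
      ok <- ep[al$ai[keep] + 1L] == ef[al$bi[keep] + 1L]
    } else {
      ok <- substitution[cbind(ep[al$ai[keep] + 1L] + 1L,
                               ef[al$bi[keep] + 1L] + 1L)] > 0
    }
    ident <- sum(ok) / al$columns
    cov <- (al$a_end - al$a_start) / nchar(protein)
    if (ident * cov > best$identity * best$coverage ||
        (is.na(best$frame))) {
      best <- list(identity = ident, coverage = min(1, cov), frame = fn)
    }
  }
  positive <- best$identity > min_identity && best$coverage > min_coverage
  list(plasmid_id = plasmid$id, identity = best$identity,
       coverage = best$coverage, frame = best$frame, positive = positive)
}

#' Localization calls for a protein set against a plasmid database
#'
#' @param proteins a protein [seq_set].
#' @param plasmids list of plasmid records (`id`, `seq`, `circular`) or a
#'   nucleotide [seq_set] (circular flags honored).
#' @param ... passed to [translated_match].
#' @return data.frame: protein_id, plasmid_id (NA when no positive call),
#'   identity, coverage, call.
#' @export
localize_members <- function(proteins, plasmids, ...) {
  if (inherits(plasmids, "seq_set")) {
    plasmids <- lapply(seq_len(length(plasmids)), function(i)
      list(id = plasmids$ids[i], seq = plasmids$seqs[i],
           circular = plasmids$circular[i]))
  }
  out <- lapply(seq_len(length(proteins)), function(i) {
    best <- NULL
    for (pl in plasmids) {
      m <- translated_match(proteins$seqs[i], pl, ...)
      if (is.null(best) || (m$identity * m$coverage >
                            best$identity * best$coverage)) best <- m
      if (isTRUE(best$positive)) break   # first positive suffices
    }
    data.frame(protein_id = proteins$ids[i],
               plasmid_id = if (isTRUE(best$positive)) best$plasmid_id
                            else NA_character_,
               identity = best$identity, coverage = best$coverage,
               call = isTRUE(best$positive), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Clade-by-plasmid-location crosstab
#'
#' @param calls data.frame from [localize_members].
#' @param partition data.frame (leaf, clade) from [split_two_clades].
#' @return list: `counts` (2x2 clade x on-plasmid), `row_totals`,
#'   `col_totals`, `pct_plasmid_by_clade` (percentage of plasmid-located
#'   members falling in each clade), `zero_denominator` flag.
#' @export
clade_plasmid_crosstab <- function(calls, partition) {
  missing <- setdiff(partition$leaf, calls$protein_id)
  if (length(missing)) {
    stop("no localization call for: ", paste(head(missing, 5), collapse = ", "))
  }
  m <- merge(partition, calls, by.x = "leaf", by.y = "protein_id")
  counts <- table(factor(paste0("clade", m$clade),
                         levels = c("clade1", "clade2")),
                  factor(ifelse(m$call, "plasmid", "not_plasmid"),
                         levels = c("plasmid", "not_plasmid")))
  counts <- unclass(as.matrix(counts))
  npos <- sum(counts[, "plasmid"])
  pct <- if (npos == 0) c(clade1 = 0, clade2 = 0) else
    round(100 * counts[, "plasmid"] / npos, 1)
  list(counts = counts,
       row_totals = rowSums(counts), col_totals = colSums(counts),
       pct_plasmid_by_clade = pct,
       zero_denominator = npos == 0)
}

#' Write localization calls / crosstab as TSV
#' @param calls data.frame from [localize_members].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_localization <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_localization
#' @param crosstab result of [clade_plasmid_crosstab].
#' @export
write_crosstab <- function(crosstab, path) {
  df <- as.data.frame(crosstab$counts)
  df <- cbind(clade = rownames(crosstab$counts), df,
              pct_of_plasmid_located = crosstab$pct_plasmid_by_clade)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
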