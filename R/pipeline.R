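# End-to-end orchestration: seed protein -> family members -> redundancy
# reduction -> signatures -> occurrence -> tree and clades -> plasmid
# localization crosstab -> oriT / curvature report, with a reproducible
# report bundle.

#' Run configuration with the pipeline's stated defaults
#'
#' All thresholds default to the values the workflow is defined with:
#' search E-value 1e-15 with up to 10 profile rounds, dedup at identity
#' 1.0 and centroid clustering at 0.50, motif discovery E-value 1e-15 (up
#' to 10 signatures), scan threshold 1e-6, plasmid localization identity
#' 0.95 over coverage 0.80, tree length filter 300, 1000 bootstraps,
#' 600-bp curvature smoothing.
#'
#' @param seed_protein path to the seed protein FASTA (single record).
#' @param protein_db path to the protein database FASTA.
#' @param plasmid_db optional path to a plasmid multi-FASTA (circular).
#' @param out_dir output directory for the report bundle.
#' @param seed RNG seed for the whole run.
#' @param search_evalue,max_rounds,dedup_identity,cluster_identity
#'   search/clustering thresholds.
#' @param motif_evalue,max_motifs,motif_width_range,scan_evalue motif
#'   thresholds.
#' @param min_identity,min_coverage localization thresholds.
#' @param min_len,n_bootstrap,condense_support tree parameters.
#' @param smooth_window,peak_z curvature parameters.
#' @return a `run_config` list.
#' @export
run_config <- function(seed_protein, protein_db, plasmid_db = NULL,
                       out_dir = "moblkit_run", seed = 1,
                       search_evalue = 1e-15, max_rounds = 10,
                       dedup_identity = 1.0, cluster_identity = 0.50,
                       motif_evalue = 1e-15, max_motifs = 10,
                       motif_width_range = c(6, 50),
                       scan_evalue = 1e-6,
                       min_identity = 0.95, min_coverage = 0.80,
                       min_len = 300, n_bootstrap = 1000,
                       condense_support = 50,
                       smooth_window = 600, peak_z = 2.0) {
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(seed, stage) {
  # per-stage substream, independent of stage order
  (seed * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
}

#' Run the full pipeline
#'
#' Stages run in order (search, dedup, cluster, motifs, scan, tree,
#' localization, curvature); a stage failure aborts with a stage-named
#' error and partial outputs retained next to a FAILED marker. A missing
#' plasmid database skips the localization stage with a warning.
#'
#' @param config a [run_config].
#' @return invisible list of stage results (the report bundle is written to
#'   `config$out_dir`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  res <- list()
  current_stage <- "init"
  on.exit({
    if (!identical(current_stage, "done")) {
      writeLines(current_stage, file.path(config$out_dir, "FAILED"))
    }
  })
  run <- function(stage, expr) {
    current_stage <<- stage
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  seedset <- read_fasta(config$seed_protein, "protein")
  db <- read_fasta(config$protein_db, "protein")

  search <- run("search", psi_search(
    seedset$seqs[1], db, evalue_threshold = config$search_evalue,
    max_rounds = config$max_rounds, seed = stage_seed(config$seed, "search")))
  log_stage("search", length(search$members), " members in ",
            search$final_round, " rounds")
  write_search_report(search, file.path(config$out_dir, "members.tsv"))
  members <- db[match(search$members, db$ids)]
  write_fasta(members, file.path(config$out_dir, "members.fasta"))
  res$search <- search

  dedup <- run("dedup", greedy_cluster(members, config$dedup_identity))
  unique_members <- cluster_centroids(members, dedup)
  log_stage("dedup", length(members), " -> ", length(unique_members),
            " unique members")
  clusters <- run("cluster", greedy_cluster(unique_members,
                                            config$cluster_identity))
  centroids <- cluster_centroids(unique_members, clusters)
  log_stage("cluster", length(centroids), " centroids at ",
            config$cluster_identity)
  write_clusters(clusters, file.path(config$out_dir, "clusters.tsv"))
  res$clusters <- clusters

  motif_in <- if (length(centroids) >= 5) centroids else unique_members
  sigs <- run("motifs", discover_signatures(
    motif_in, max_motifs = config$max_motifs,
    max_evalue = config$motif_evalue,
    width_range = config$motif_width_range,
    seed = stage_seed(config$seed, "motifs")))
  log_stage("motifs", length(sigs), " signatures")
  write_meme_minimal(sigs, file.path(config$out_dir, "signatures.meme"))
  res$signatures <- sigs

  occ <- if (length(sigs)) {
    run("scan", occurrence_table(list(family = sigs),
                                 list(family = unique_members),
                                 config$scan_evalue))
  } else matrix(numeric(0), 0, 1, dimnames = list(NULL, "family"))
  utils::write.table(occ, file.path(config$out_dir, "occurrence.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  res$occurrence <- occ

  tree_in <- filter_by_length(unique_members, config$min_len)
  res$tree <- NULL
  if (length(tree_in) >= 4) {
    aln <- run("tree", build_msa(tree_in))
    tree <- run("tree", bootstrap_supports(
      aln, n_reps = config$n_bootstrap,
      seed = stage_seed(config$seed, "tree")))
    tree <- condense(tree, config$condense_support)
    write_tree_newick(tree, file.path(config$out_dir, "tree.nwk"))
    seed_id <- seedset$ids[1]
    ref <- if (seed_id %in% tree$tip.label) seed_id else {
      self <- tree_in$ids[toupper(tree_in$seqs) == toupper(seedset$seqs[1])]
      if (length(self)) self[1] else tree$tip.label[1]
    }
    clades <- run("tree", split_two_clades(tree, ref = ref))
    utils::write.table(clades, file.path(config$out_dir, "clades.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("tree", nrow(clades), " leaves; clade1 = ",
              sum(clades$clade == 1))
    res$tree <- tree; res$clades <- clades
  }

  if (!is.null(config$plasmid_db) && file.exists(config$plasmid_db)) {
    plasmids <- read_fasta(config$plasmid_db, "nucleotide", circular = TRUE)
    calls <- run("localize", localize_members(
      unique_members, plasmids, min_identity = config$min_identity,
      min_coverage = config$min_coverage))
    write_localization(calls, file.path(config$out_dir, "localization.tsv"))
    log_stage("localize", sum(calls$call), " plasmid-located members")
    res$localization <- calls
    if (!is.null(res$clades)) {
      part <- res$clades[res$clades$leaf %in% calls$protein_id, ]
      ct <- run("crosstab",
                clade_plasmid_crosstab(calls[calls$protein_id %in% part$leaf, ],
                                       part))
      write_crosstab(ct, file.path(config$out_dir, "crosstab.tsv"))
      res$crosstab <- ct
    }
    # curvature / oriT report on the first plasmid
    pl <- plasmids[1]
    prof <- run("curvature", curvature_profile(pl$seqs[1], circular = TRUE))
    z <- smooth_normalize(prof, window = min(config$smooth_window,
                                             nchar(pl$seqs[1]) %/% 2))
    peaks <- call_peaks(z, min_z = config$peak_z)
    write_wig(z, pl$ids[1], file.path(config$out_dir, "curvature.wig"))
    write_bed(peaks, pl$ids[1], file.path(config$out_dir, "peaks.bed"))
    nicks <- locate_nick(pl$seqs[1], circular = TRUE)
    window <- 1500
    reg_start <- if (nrow(nicks)) max(1, nicks$position[1] - window %/% 2)
                 else 1
    region <- substring(pl$seqs[1], reg_start,
                        min(nchar(pl$seqs[1]), reg_start + window))
    reps <- run("curvature", find_repeats(region))
    if (nrow(reps)) {
      reps$arm1_start <- reps$arm1_start + reg_start - 1L
      reps$arm2_start <- reps$arm2_start + reg_start - 1L
    }
    write_gff3(reps, nicks, pl$ids[1],
               file.path(config$out_dir, "features.gff3"))
    log_stage("curvature", length(peaks), " peaks; ", nrow(nicks),
              " nick site(s)")
    res$peaks <- peaks; res$nicks <- nicks
  } else if (!is.null(config$plasmid_db)) {
    warning("plasmid database not found; localization stage skipped")
  }

  runinfo <- unclass(config)
  runinfo$package_version <- as.character(utils::packageVersion("moblkit"))
  jsonlite::write_json(runinfo, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  current_stage <- "done"
  invisible(res)
}
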