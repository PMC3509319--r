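#' Pipeline orchestration
#'
#' `run_pipeline()` drives the full analysis on a simulated family with one
#' configuration object: simulate, screen, curate, cluster, reconcile,
#' hydropathicity tracks and the phosphosite screen. Every stage is a pure
#' function of (inputs, config, seed); outputs are TSV/FASTA/Newick files
#' plus a JSON run manifest echoing the full configuration, record counts
#' and seeds, which suffices to re-run the analysis bit-identically.
#'
#' @name pipeline
NULL

#' Pipeline configuration with validated defaults
#'
#' Houses the pipeline's named constants: the screening E-value cut-off
#' (1e-3, implementing the "at least one motif with score > 0.001"
#' inclusion rule as an E-value criterion), the curation identity cut-offs
#' (< 20 and > 97), the 25% alignment gap mask, the phosphosite criteria
#' (> 90% conservation, maximum score > 0.6, mean score > 0.2) and the
#' Kyte-Doolittle window.
#'
#' @param ... Overrides of the default keys; unknown keys are rejected.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    preset = "slac", seed = 1L, n_species = 10L, n_decoys = 5L,
    evalue_max = 1e-3, calib_n_random = 1000L, calib_len_random = 400L,
    curation_low = 20, curation_high = 97,
    gap_mask = 0.25, kd_window = 19L,
    tm_score_min = 1.0, tm_min_len = 10L,
    phospho_cons_min = 0.90, phospho_max_min = 0.6, phospho_mean_min = 0.2,
    phospho_mean_over = "carriers",
    bootstrap_reps = 0L,
    stages = c("simulate", "screen", "curate", "cluster", "reconcile",
               "tracks", "phospho"))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations, all of them (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(config$preset %in% c("slac", "almt"), "preset must be 'slac' or 'almt'")
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  chk(config$gap_mask >= 0 && config$gap_mask <= 1,
      "gap_mask must lie in [0, 1]")
  chk(config$phospho_cons_min >= 0 && config$phospho_cons_min <= 1,
      "phospho_cons_min must lie in [0, 1]")
  chk(config$phospho_max_min >= 0 && config$phospho_max_min <= 1,
      "phospho_max_min must lie in [0, 1]")
  chk(config$phospho_mean_min >= 0 && config$phospho_mean_min <= 1,
      "phospho_mean_min must lie in [0, 1]")
  chk(config$curation_low >= 0 && config$curation_low <= 100,
      "curation_low must lie in [0, 100]")
  chk(config$curation_high >= 0 && config$curation_high <= 100,
      "curation_high must lie in [0, 100]")
  chk(config$curation_low <= config$curation_high,
      "curation_low must not exceed curation_high")
  chk(config$kd_window >= 1 && config$kd_window %% 2 == 1,
      "kd_window must be odd and >= 1")
  chk(config$evalue_max > 0, "evalue_max must be positive")
  chk(config$calib_n_random >= 100, "calib_n_random must be >= 100")
  chk(config$bootstrap_reps >= 0, "bootstrap_reps must be >= 0")
  v
}

#' Cut an ultrametric clustering tree into k groups
#'
#' Removes the k-1 deepest merges of an ultrametric tree (as produced by
#' [upgma()]), yielding the k clusters below them.
#'
#' @param phy Ultrametric `phylo`.
#' @param k Number of groups (>= 1, <= number of leaves).
#' @return Named character vector: cluster label (`"cluster1"`, ...) per
#'   leaf, numbered in leaf order of first appearance.
#' @export
cut_upgma <- function(phy, k) {
  nt <- length(phy$tip.label)
  stopifnot(k >= 1, k <= nt)
  depth_e <- ape::node.depth.edgelength(phy)
  height <- max(depth_e[seq_len(nt)]) - depth_e  # 0 at leaves
  internal <- order(height[(nt + 1):(nt + phy$Nnode)],
                    decreasing = TRUE) + nt
  cut_nodes <- internal[seq_len(k - 1)]
  par <- tree_parent(phy)
  lab <- integer(nt)
  for (i in seq_len(nt)) {
    v <- i
    while (!is.na(par[v]) && !(par[v] %in% cut_nodes)) v <- par[v]
    lab[i] <- v
  }
  setNames(paste0("cluster", match(lab, unique(lab))), phy$tip.label)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Partition labels over the same elements (named vectors are
#'   matched by name).
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Run the full pipeline on a simulated family
#'
#' @param config A [pipeline_config()]; must validate.
#' @param dir Output directory for stage outputs and the run manifest.
#' @return List of stage results: `bundle`, `screen`, `curation`, `tree`,
#'   `cluster_assignment`, `ari`, `group_stats`, `reconciliation`,
#'   `tm_segments`, `sites`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), dir = tempfile("run_")) {
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- list()
  res <- list()

  fam_cfg <- family_config(preset = config$preset,
                           n_species = config$n_species,
                           n_decoys = config$n_decoys, seed = config$seed)
  bundle <- simulate_family(fam_cfg)
  res$bundle <- bundle
  counts$simulated_members <- length(bundle$sequences)
  counts$simulated_decoys <- length(bundle$decoys)

  if ("screen" %in% config$stages) {
    seeds <- motif_seeds(bundle)
    models <- lapply(names(seeds), function(nm)
      calibrate_evalue(build_profile(seeds[[nm]], motif_id = nm),
                       n_random = config$calib_n_random,
                       len_random = config$calib_len_random,
                       seed = config$seed))
    proteome <- c(bundle$sequences, bundle$decoys)
    scr <- screen_proteome(models, proteome, evalue_max = config$evalue_max)
    res$screen <- scr
    counts$screen_kept <- length(scr$kept_ids)
    write_hits_tsv(scr, file.path(dir, "screen_hits.tsv"))
  }

  kept <- if (!is.null(res$screen)) res$screen$kept else bundle$sequences
  kept <- kept[names(kept) %in% names(bundle$sequences) |
                 !startsWith(names(kept), "decoy")]

  if ("curate" %in% config$stages) {
    refs <- bundle$sequences[paste0("sp1_", fam_cfg$groups)]
    cur <- curate(kept, refs, low = config$curation_low,
                  high = config$curation_high)
    res$curation <- cur
    counts$curation_groups <- length(cur$groups)
    counts$curation_duplicates_removed <- length(cur$removed_as_duplicate)
    write_group_report(cur, file.path(dir, "curation_groups.tsv"))
  }

  if ("cluster" %in% config$stages) {
    aln <- bundle$alignment
    D <- identity_distance_matrix(aln)
    tree <- if (config$bootstrap_reps > 0)
      bootstrap_support(aln, n_reps = config$bootstrap_reps,
                        seed = config$seed) else upgma(D)
    res$tree <- tree
    res$cluster_assignment <- cut_upgma(tree, length(unique(bundle$groups)))
    res$ari <- adjusted_rand_index(bundle$groups, res$cluster_assignment)
    counts$recovered_groups <- length(unique(res$cluster_assignment))
    res$group_stats <- group_identity_stats(aln, bundle$groups)
    writeLines(write_newick(tree), file.path(dir, "upgma.nwk"))
    write.table(res$group_stats, file.path(dir, "group_identity_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("reconcile" %in% config$stages) {
    rec <- lca_reconcile(bundle$gene_tree, bundle$species_tree,
                         bundle$species_map)
    res$reconciliation <- rec
    counts$duplications_inferred <- rec$n_duplications
    counts$losses_inferred <- rec$loss_count
    write_reconciliation_tsv(rec, file.path(dir, "reconciliation.tsv"))
  }

  if ("tracks" %in% config$stages) {
    tracks <- lapply(names(bundle$sequences), function(id)
      kd_hydropathicity(bundle$sequences[id], window = config$kd_window))
    names(tracks) <- names(bundle$sequences)
    ct <- project_tracks(tracks, bundle$alignment)
    prof <- clade_average(ct, bundle$alignment, bundle$groups,
                          max_gap_frac = config$gap_mask)
    res$tm_segments <- call_tm_segments(prof$all,
                                        score_min = config$tm_score_min,
                                        min_len = config$tm_min_len)
    counts$tm_segments_called <- nrow(res$tm_segments)
    write.table(res$tm_segments, file.path(dir, "tm_segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("phospho" %in% config$stages) {
    ptracks <- lapply(names(bundle$sequences), function(id)
      phospho_scores(bundle$sequences[id]))
    names(ptracks) <- names(bundle$sequences)
    pt <- project_tracks(ptracks, bundle$alignment)
    res$sites <- conserved_site_screen(
      bundle$alignment, bundle$groups, pt,
      cons_min = config$phospho_cons_min,
      max_min = config$phospho_max_min,
      mean_min = config$phospho_mean_min,
      mean_over = config$phospho_mean_over)
    counts$sites_reported <- nrow(res$sites)
    write.table(res$sites, file.path(dir, "conserved_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(tool = "phyloscreen",
                   version = as.character(packageVersion("phyloscreen")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   config = unclass(config),
                   counts = counts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  res$dir <- dir
  invisible(res)
}
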