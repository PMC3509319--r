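#' Protein-family simulator with known ground truth
#'
#' The simulator produces families whose true structure is known at every
#' level: a Yule species tree; a gene family evolving on it by duplication
#' and loss; and leaf sequences with a fixed domain architecture (cytosolic
#' linkers, hydrophobic transmembrane segments, conserved anchor motifs and
#' group-specifically conserved phosphosites). Version 1 is indel-free, so
#' the true alignment is the trivial column map. Presets emulate the
#' SLAC-like (10 TM) and ALMT-like (6 TM + 2 extra C-half segments)
#' architectures, with three divergence tiers calibrated to realized
#' within-group identities near 78/69/58% and between-group identities in
#' the 35-52% band.
#'
#' @name synthetic_data
NULL

# hydrophobic-biased composition for TM segments (KD mean ~ +3.5)
tm_composition <- function() {
  c(I = 0.18, V = 0.18, L = 0.18, F = 0.12, A = 0.12, M = 0.08, C = 0.04,
    G = 0.05, W = 0.03, T = 0.02)
}

# hydrophilic-leaning composition for linkers/loops (KD mean ~ -1.7)
linker_composition <- function() {
  c(D = 0.08, E = 0.08, K = 0.08, R = 0.07, N = 0.07, Q = 0.07, S = 0.10,
    T = 0.08, G = 0.09, P = 0.07, H = 0.04, A = 0.07, Y = 0.03, V = 0.03,
    L = 0.02, I = 0.02)
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Starting from the root split, lineages speciate at rate `birth_rate`
#' each; growth stops when `n_species` lineages exist and tips are extended
#' by one further exponential waiting time, giving an ultrametric tree.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed; the tree is deterministic given it.
#' @param birth_rate Per-lineage speciation rate.
#' @return Ultrametric `phylo` with tips `sp1..spN`.
#' @export
simulate_species_tree <- function(n_species, seed, birth_rate = 1) {
  stopifnot(n_species >= 2, birth_rate > 0)
  set.seed(seed)
  sim <- yule_forward(Inf, birth_rate, n_max = n_species)
  phy <- read_newick(sim$newick)
  phy$tip.label <- paste0("sp", seq_len(n_species))
  phy
}

# forward Yule simulation (RNG must be seeded by the caller);
# stops at time t_max or when n_max lineages exist, then extends tips
yule_forward <- function(t_max, birth_rate, n_max = Inf) {
  # active lineages as (newick-so-far is built at the end) parent pointers
  parent <- c(NA_integer_, 1L, 1L)
  birth <- c(0, 0, 0)
  death <- rep(NA_real_, 3)
  active <- c(2L, 3L)
  t <- 0
  repeat {
    k <- length(active)
    if (k >= n_max) break
    dt <- stats::rexp(1, rate = k * birth_rate)
    if (t + dt > t_max) { t <- t_max; break }
    t <- t + dt
    splitter <- active[sample.int(k, 1)]
    death[splitter] <- t
    id <- length(parent)
    parent <- c(parent, splitter, splitter)
    birth <- c(birth, t, t)
    death <- c(death, NA_real_, NA_real_)
    active <- c(setdiff(active, splitter), id + 1L, id + 2L)
  }
  # extend tips beyond the last split so leaf branches are positive
  t_end <- t + if (is.finite(t_max)) 0 else stats::rexp(1, length(active) * birth_rate)
  death[active] <- t_end
  kids <- lapply(seq_along(parent), function(i) which(parent == i))
  leaf_i <- 0L
  build <- function(v) {
    blen <- death[v] - birth[v]
    if (!length(kids[[v]])) {
      leaf_i <<- leaf_i + 1L
      return(paste0("t", leaf_i, ":", format(blen, digits = 12)))
    }
    inner <- paste(vapply(kids[[v]], build, character(1)), collapse = ",")
    paste0("(", inner, ")",
           if (is.na(parent[v])) "" else paste0(":", format(blen, digits = 12)))
  }
  list(newick = paste0(build(1L), ";"), n_leaves = length(active),
       height = t_end)
}

#' Simulate a gene family by duplication and loss along a species tree
#'
#' A single gene lineage enters at the species root; along every
#' species-tree branch it duplicates at rate `dup_rate` and is lost at rate
#' `loss_rate` (per unit branch length); at speciations every surviving
#' lineage is copied into both daughter branches. Every event is recorded
#' with its species-tree location.
#'
#' @param species_tree Rooted `phylo` with branch lengths.
#' @param dup_rate,loss_rate Non-negative event rates.
#' @param seed Integer seed.
#' @return List: `gene_tree` (`phylo`, or `NULL` when the family died out),
#'   `events` (data.frame `type`, `species_node`, `time_remaining`),
#'   `n_duplications` (all duplication events), `n_duplications_visible`
#'   (duplication nodes with surviving descendants on both sides),
#'   `species_map` (named vector), `empty` flag.
#' @export
simulate_gene_family <- function(species_tree, dup_rate, loss_rate, seed) {
  stopifnot(inherits(species_tree, "phylo"), dup_rate >= 0, loss_rate >= 0,
            !is.null(species_tree$edge.length))
  set.seed(seed)
  kids <- tree_children(species_tree)
  nt <- length(species_tree$tip.label)
  elen <- setNames(rep(NA_real_, nt + species_tree$Nnode), NULL)
  elen[species_tree$edge[, 2]] <- species_tree$edge.length
  events <- list()
  counter <- new.env(); counter$n <- setNames(rep(0L, nt), species_tree$tip.label)
  total_rate <- dup_rate + loss_rate
  n_visible <- 0L

  evolve <- function(snode, t_remaining) {
    # returns list(nwk, blen_accumulated, n_leaves) or NULL when lost
    wait <- if (total_rate > 0) stats::rexp(1, total_rate) else Inf
    if (wait >= t_remaining) {
      if (!length(kids[[snode]])) {
        sp <- species_tree$tip.label[snode]
        counter$n[sp] <- counter$n[sp] + 1L
        return(list(nwk = paste0(sp, "_g", counter$n[sp]),
                    blen = t_remaining, n = 1L))
      }
      parts <- lapply(kids[[snode]], function(ch) evolve(ch, elen[ch]))
      parts <- parts[!vapply(parts, is.null, logical(1))]
      if (!length(parts)) return(NULL)
      if (length(parts) == 1L) {
        p <- parts[[1]]
        return(list(nwk = p$nwk, blen = p$blen + t_remaining, n = p$n))
      }
      inner <- paste(vapply(parts, function(p)
        paste0(p$nwk, ":", format(p$blen, digits = 12)), character(1)),
        collapse = ",")
      return(list(nwk = paste0("(", inner, ")"), blen = t_remaining,
                  n = sum(vapply(parts, `[[`, integer(1), "n"))))
    }
    # an event occurs after `wait`
    t_left <- t_remaining - wait
    if (stats::runif(1) < dup_rate / total_rate) {
      events[[length(events) + 1L]] <<- data.frame(
        type = "duplication", species_node = snode, time_remaining = t_left)
      a <- evolve(snode, t_left)
      b <- evolve(snode, t_left)
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a) || is.null(b)) {
        p <- if (is.null(a)) b else a
        return(list(nwk = p$nwk, blen = p$blen + wait, n = p$n))
      }
      n_visible <<- n_visible + 1L
      return(list(nwk = paste0("(", a$nwk, ":", format(a$blen, digits = 12),
                               ",", b$nwk, ":", format(b$blen, digits = 12),
                               ")"),
                  blen = wait, n = a$n + b$n))
    }
    events[[length(events) + 1L]] <<- data.frame(
      type = "loss", species_node = snode, time_remaining = t_left)
    NULL
  }

  root_kids <- kids[[nt + 1L]]
  parts <- lapply(root_kids, function(ch) evolve(ch, elen[ch]))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), species_node = integer(0),
               time_remaining = numeric(0))
  n_dup <- sum(ev$type == "duplication")
  if (length(parts) == 0 || sum(vapply(parts, `[[`, integer(1), "n")) < 2) {
    return(list(gene_tree = NULL, events = ev, n_duplications = n_dup,
                n_duplications_visible = n_visible,
                species_map = character(0), empty = TRUE))
  }
  nwk <- if (length(parts) == 1L) {
    # root lies along one surviving side; keep it as the tree root
    p <- parts[[1]]
    if (!startsWith(p$nwk, "(")) NULL else paste0(p$nwk, ";")
  } else {
    paste0("(", paste(vapply(parts, function(p)
      paste0(p$nwk, ":", format(p$blen, digits = 12)), character(1)),
      collapse = ","), ");")
  }
  if (is.null(nwk))
    return(list(gene_tree = NULL, events = ev, n_duplications = n_dup,
                n_duplications_visible = n_visible,
                species_map = character(0), empty = TRUE))
  gt <- read_newick(nwk)
  smap <- setNames(sub("_g[0-9]+$", "", gt$tip.label), gt$tip.label)
  list(gene_tree = gt, events = ev, n_duplications = n_dup,
       n_duplications_visible = n_visible, species_map = smap,
       empty = FALSE)
}

#' Configure a synthetic protein family
#'
#' Presets: `"slac"` -- N-terminal cytosolic region, 10 transmembrane
#' segments and a C-terminus, with four group-specifically conserved
#' phosphosites planted in the cytosolic regions; `"almt"` -- 6
#' transmembrane segments, then a C-terminal half carrying a WEP anchor
#' triplet and two further hydrophobic segments. Both presets produce three
#' divergence-tier groups (one gene per species per group) plus unrelated
#' decoy sequences drawn from the uniform screening background.
#'
#' @param preset `"slac"` or `"almt"`.
#' @param n_species Species per group (default 10).
#' @param n_decoys Number of decoy sequences (default 5).
#' @param seed Integer seed fixing all randomness.
#' @param tier_divergence Target mean pairwise path length within each of
#'   the three group subtrees (divergence tiers, most to least conserved
#'   last); each group's copy of the species tree is rescaled so that its
#'   mean leaf-to-leaf distance equals this value.
#' @param join_margins Path-length margins `c(inner, outer)`: the
#'   group1/group2 ancestor joins `inner` units above twice the deepest
#'   within-group coalescence and group3 joins `outer` units above that, so
#'   the three groups always separate cleanly before any within-group
#'   structure.
#' @return A `family_config` object.
#' @export
family_config <- function(preset = c("slac", "almt"), n_species = 10L,
                          n_decoys = 5L, seed = 1L,
                          tier_divergence = c(0.46, 0.70, 0.92),
                          join_margins = c(0.45, 0.15)) {
  preset <- match.arg(preset)
  lnk <- "linker"; tm <- "tm"
  if (preset == "slac") {
    reg <- data.frame(
      name = c("nterm",
               as.vector(rbind(paste0("tm", 1:10), paste0("loop", 1:10)))[-20],
               "cterm"),
      length = c(60, rep(c(21L, 15L), 10)[-20], 40L),
      kind = c(lnk, rep(c(tm, lnk), 10)[-20], lnk),
      stringsAsFactors = FALSE)
    rate <- c(linker = 1, tm = 0.45, anchor = 0.02)
    motif_regions <- paste0("tm", c(1, 3, 5, 7, 9))
    planted_sites <- list(
      list(name = "site_nterm_g1", region = "nterm", offset = 20L,
           carriers = "group1"),
      list(name = "site_nterm_g12", region = "nterm", offset = 45L,
           carriers = c("group1", "group2")),
      list(name = "site_loop4_g2", region = "loop4", offset = 8L,
           carriers = "group2"),
      list(name = "site_cterm_g12", region = "cterm", offset = 15L,
           carriers = c("group1", "group2")))
  } else {
    reg <- data.frame(
      name = c("nterm",
               as.vector(rbind(paste0("tm", 1:6), paste0("loop", 1:6)))[-12],
               "chalf1", "wep", "chalf2", "cseg1", "cloop", "cseg2", "cterm"),
      length = c(30L, rep(c(21L, 15L), 6)[-12], 30L, 3L, 30L, 21L, 20L, 21L,
                 40L),
      kind = c(lnk, rep(c(tm, lnk), 6)[-12], lnk, "anchor", lnk, tm, lnk, tm,
               lnk),
      stringsAsFactors = FALSE)
    rate <- c(linker = 1, tm = 0.45, anchor = 0.02)
    motif_regions <- c("tm1", "tm3", "wep", "cseg1")
    planted_sites <- list(
      list(name = "site_chalf_g3", region = "chalf1", offset = 12L,
           carriers = "group3"))
  }
  reg$start <- cumsum(c(1L, reg$length[-nrow(reg)]))
  reg$end <- reg$start + reg$length - 1L
  reg$rate_mult <- unname(rate[reg$kind])
  structure(list(preset = preset, n_species = as.integer(n_species),
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 architecture = reg, motif_regions = motif_regions,
                 planted_sites = planted_sites,
                 tier_divergence = tier_divergence,
                 join_margins = join_margins,
                 groups = paste0("group", 1:3),
                 anchor_seq = "WEP"),
            class = "family_config")
}

# per-site rate multipliers and composition index from an architecture table
site_layout <- function(arch) {
  L <- sum(arch$length)
  rate <- numeric(L); kind <- character(L)
  for (r in seq_len(nrow(arch))) {
    idx <- arch$start[r]:arch$end[r]
    rate[idx] <- arch$rate_mult[r]
    kind[idx] <- arch$kind[r]
  }
  list(L = L, rate = rate, kind = kind)
}

draw_from <- function(comp, n) sample(names(comp), n, replace = TRUE,
                                      prob = comp)

# root sequence under the architecture (RNG must be seeded by caller)
root_sequence <- function(config) {
  lay <- site_layout(config$architecture)
  ch <- character(lay$L)
  ch[lay$kind == "linker"] <- draw_from(linker_composition(),
                                        sum(lay$kind == "linker"))
  ch[lay$kind == "tm"] <- draw_from(tm_composition(), sum(lay$kind == "tm"))
  if (any(lay$kind == "anchor")) {
    anchor_pos <- which(lay$kind == "anchor")
    ch[anchor_pos] <- strsplit(config$anchor_seq, "")[[1]][
      seq_along(anchor_pos)]
  }
  ch
}

# evolve a character vector along one branch
mutate_branch <- function(ch, t, lay) {
  p <- -expm1(-lay$rate * t)
  hit <- stats::runif(length(ch)) < p
  if (any(hit & lay$kind == "linker"))
    ch[hit & lay$kind == "linker"] <- draw_from(linker_composition(),
                                                sum(hit & lay$kind == "linker"))
  if (any(hit & lay$kind == "tm"))
    ch[hit & lay$kind == "tm"] <- draw_from(tm_composition(),
                                            sum(hit & lay$kind == "tm"))
  if (any(hit & lay$kind == "anchor"))
    ch[hit & lay$kind == "anchor"] <- draw_from(linker_composition(),
                                                sum(hit & lay$kind == "anchor"))
  ch
}

#' Evolve sequences down a gene tree under a family configuration
#'
#' The root sequence is drawn region-wise from the architecture's
#' composition biases; along every branch each site substitutes with
#' probability `1 - exp(-rate_mult * branch_length)`, the replacement drawn
#' from the region composition. Indel-free, so the true alignment is the
#' identity column map.
#'
#' @param gene_tree Rooted `phylo` with branch lengths.
#' @param config A [family_config()].
#' @param root Optional root sequence (character vector) to evolve from.
#' @return Named character vector of leaf sequences (all of equal length).
#' @export
evolve_sequences <- function(gene_tree, config, root = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(config, "family_config"),
            !is.null(gene_tree$edge.length))
  lay <- site_layout(config$architecture)
  if (is.null(root)) root <- root_sequence(config)
  stopifnot(length(root) == lay$L)
  nt <- length(gene_tree$tip.label)
  seqs <- vector("list", nt + gene_tree$Nnode)
  seqs[[nt + 1L]] <- root
  par <- tree_parent(gene_tree)
  emap <- integer(nt + gene_tree$Nnode)
  emap[gene_tree$edge[, 2]] <- seq_len(nrow(gene_tree$edge))
  for (v in node_preorder(gene_tree)) {
    if (v == nt + 1L) next
    seqs[[v]] <- mutate_branch(seqs[[par[v]]],
                               gene_tree$edge.length[emap[v]], lay)
  }
  setNames(vapply(seq_len(nt), function(i) paste(seqs[[i]], collapse = ""),
                  character(1)),
           gene_tree$tip.label)
}

# absolute residue position of a planted site
site_position <- function(config, site) {
  r <- config$architecture[config$architecture$name == site$region, ]
  stopifnot(nrow(r) == 1, site$offset >= 5, site$offset <= r$length - 4)
  r$start + site$offset - 1L
}

#' Simulate a complete three-group family with decoys and truth tables
#'
#' Builds the preset gene tree (three species-tree-congruent group copies
#' joined by two ancient duplications), evolves sequences, plants the
#' group-specific phosphosite contexts (held invariant in carrier groups,
#' S/T/Y removed in non-carriers), and appends decoy sequences drawn from
#' the uniform screening background.
#'
#' @param config A [family_config()].
#' @return A `truth_bundle`: `species_tree`, `gene_tree`, `sequences`
#'   (members), `decoys`, `alignment` (members; indel-free),
#'   `groups`, `species_map`, `tm_intervals`, `planted_sites`,
#'   `n_duplications_true`, `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "family_config"))
  set.seed(config$seed)
  sp_sim <- yule_forward(Inf, 1, n_max = config$n_species)
  species <- read_newick(sp_sim$newick)
  species$tip.label <- paste0("sp", seq_len(config$n_species))
  # rescale each group copy so its mean pairwise leaf distance hits the
  # tier's divergence target (stabler across tree shapes than height scaling)
  coph <- ape::cophenetic.phylo(species)
  P <- mean(coph[upper.tri(coph)])
  H <- max(ape::node.depth.edgelength(species))
  sub_nwk <- function(d, tag) {
    g <- species
    g$edge.length <- g$edge.length * (d / P)
    g$tip.label <- paste0(g$tip.label, "_", tag)
    sub(";$", "", write_newick(g))
  }
  th <- config$tier_divergence
  # ultrametric joins: the group1/group2 ancestor sits a fixed path margin
  # above the deepest within-group coalescence, the root a further margin
  # above that, so groups always separate before any within-group structure
  h_real <- H * th / P                      # realized subtree heights
  h12 <- max(h_real) + config$join_margins[1] / 2
  h123 <- h12 + config$join_margins[2]
  st <- c(h12 - h_real[1], h12 - h_real[2],  # a1, a2
          h123 - h12, h123 - h_real[3])      # b, a3
  gene_nwk <- paste0("((", sub_nwk(th[1], "group1"), ":", st[1], ",",
                     sub_nwk(th[2], "group2"), ":", st[2], "):", st[3], ",",
                     sub_nwk(th[3], "group3"), ":", st[4], ");")
  gene <- read_newick(gene_nwk)
  seqs <- evolve_sequences(gene, config)
  groups <- setNames(sub("^.*_(group[0-9])$", "\\1", names(seqs)),
                     names(seqs))
  species_map <- setNames(sub("_group[0-9]$", "", names(seqs)), names(seqs))
  # plant the phosphosite contexts
  ctx <- strsplit(phospho_consensus_context(), "")[[1]]
  site_rows <- list()
  for (site in config$planted_sites) {
    p <- site_position(config, site)
    for (id in names(seqs)) {
      ch <- strsplit(seqs[[id]], "")[[1]]
      if (groups[[id]] %in% site$carriers) {
        ch[(p - 4):(p + 4)] <- ctx
      } else if (ch[p] %in% c("S", "T", "Y")) {
        ch[p] <- "A"
      }
      seqs[[id]] <- paste(ch, collapse = "")
    }
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      name = site$name, column = p,
      carriers = paste(site$carriers, collapse = ","),
      stringsAsFactors = FALSE)
  }
  arch <- config$architecture
  tm_intervals <- arch[arch$kind == "tm", c("name", "start", "end")]
  names(tm_intervals) <- c("name", "start_col", "end_col")
  rownames(tm_intervals) <- NULL
  decoys <- setNames(vapply(seq_len(config$n_decoys), function(i)
    paste(sample(AA20, sum(arch$length), replace = TRUE), collapse = ""),
    character(1)), paste0("decoy", seq_len(config$n_decoys)))
  structure(list(species_tree = species, gene_tree = gene,
                 sequences = seqs, decoys = decoys,
                 alignment = protein_msa(seqs),
                 groups = groups, species_map = species_map,
                 tm_intervals = tm_intervals,
                 planted_sites = if (length(site_rows))
                   do.call(rbind, site_rows) else
                     data.frame(name = character(0), column = integer(0),
                                carriers = character(0)),
                 n_duplications_true = 2L,
                 config = config),
            class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("truth_bundle (", x$config$preset, "): ", length(x$sequences),
      " members in ", length(unique(x$groups)), " groups + ",
      length(x$decoys), " decoys; ", nrow(x$tm_intervals),
      " TM segments; ", nrow(x$planted_sites), " planted site(s)\n", sep = "")
  invisible(x)
}

#' Build motif seed alignments from a truth bundle
#'
#' Extracts the true alignment columns of the configured motif regions,
#' giving gapped seed alignments for [build_profile()].
#'
#' @param bundle A [simulate_family()] result.
#' @return Named list of [protein_msa()] seeds, one per motif region.
#' @export
motif_seeds <- function(bundle) {
  stopifnot(inherits(bundle, "truth_bundle"))
  arch <- bundle$config$architecture
  m <- unclass(bundle$alignment)
  out <- lapply(bundle$config$motif_regions, function(rn) {
    r <- arch[arch$name == rn, ]
    protein_msa(m[, r$start:r$end, drop = FALSE])
  })
  names(out) <- bundle$config$motif_regions
  out
}

#' Write a truth bundle to a directory
#'
#' Emits the member and decoy FASTA, the true (gapped) alignment, both
#' Newick trees, TSV truth tables and a JSON manifest carrying the seed and
#' a hash of the configuration. Files are staged in a temporary directory
#' and moved into place only on success, so interrupted runs leave no
#' partial bundle. Output is byte-identical for identical configurations.
#'
#' @param config A [family_config()].
#' @param dir Output directory (created; must not already contain a bundle).
#' @return The `truth_bundle`, invisibly; `dir` holds the files.
#' @export
make_benchmark <- function(config, dir) {
  bundle <- simulate_family(config)
  stage <- tempfile("bundle_stage_")
  dir.create(stage)
  write_fasta(bundle$sequences, file.path(stage, "sequences.fasta"))
  write_fasta(bundle$decoys, file.path(stage, "decoys.fasta"))
  write_fasta(msa_rows(bundle$alignment), file.path(stage, "alignment.fasta"))
  writeLines(write_newick(bundle$species_tree),
             file.path(stage, "species_tree.nwk"))
  writeLines(write_newick(bundle$gene_tree),
             file.path(stage, "gene_tree.nwk"))
  write.table(data.frame(gene_id = names(bundle$species_map),
                         species_id = unname(bundle$species_map)),
              file.path(stage, "species_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(seq_id = names(bundle$groups),
                         group = unname(bundle$groups)),
              file.path(stage, "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$tm_intervals, file.path(stage, "tm_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$planted_sites, file.path(stage, "sites_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_dump <- file.path(stage, "config_dump.txt")
  writeLines(deparse(config[setdiff(names(config), "")]), cfg_dump)
  manifest <- list(tool = "phyloscreen",
                   version = as.character(packageVersion("phyloscreen")),
                   preset = config$preset, seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_dump)),
                   n_members = length(bundle$sequences),
                   n_decoys = length(bundle$decoys))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- file.copy(list.files(stage, full.names = TRUE), dir,
                  overwrite = TRUE)
  unlink(stage, recursive = TRUE)
  if (!all(ok)) stop("failed to write bundle to ", dir)
  invisible(bundle)
}
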