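test_that("species-tree simulation is deterministic and well-formed", {
  tr <- simulate_species_tree(2, seed = 5)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$Nnode, 1)
  expect_identical(write_newick(simulate_species_tree(8, seed = 9)),
                   write_newick(simulate_species_tree(8, seed = 9)))
  expect_true(ape::is.ultrametric(simulate_species_tree(12, seed = 3),
                                  tol = 1e-8))
})

test_that("the unconstrained birth process matches the Yule expectation", {
  # starting from the root split (2 lineages), E[N(T)] = 2 * exp(b * T)
  set.seed(101)
  Tmax <- 1; b <- 1
  n <- vapply(1:200, function(i)
    phyloscreen:::yule_forward(Tmax, b)$n_leaves, numeric(1))
  expected <- 2 * exp(b * Tmax)
  se <- stats::sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 4 * se)
})

test_that("gene-family simulation reduces to congruence at zero rates", {
  sp <- simulate_species_tree(6, seed = 2)
  fam <- simulate_gene_family(sp, 0, 0, seed = 1)
  expect_false(fam$empty)
  expect_equal(nrow(fam$events), 0)
  rec <- lca_reconcile(fam$gene_tree, sp, fam$species_map)
  expect_equal(rec$n_duplications, 0)
  expect_equal(rec$loss_count, 0)
  relabeled <- fam$gene_tree
  relabeled$tip.label <- unname(fam$species_map[relabeled$tip.label])
  expect_equal(ape::dist.topo(ape::unroot(relabeled), ape::unroot(sp)), 0,
               ignore_attr = TRUE)
})

test_that("duplication events occur at the Poisson-expected rate", {
  sp <- simulate_species_tree(5, seed = 4)
  dup_rate <- 0.1
  tot_len <- sum(sp$edge.length)
  dups <- vapply(1:500, function(s)
    simulate_gene_family(sp, dup_rate, 0, seed = s)$n_duplications, numeric(1))
  expected <- dup_rate * tot_len
  se <- stats::sd(dups) / sqrt(length(dups))
  # small upward bias from copies duplicating in turn; allow for it
  expect_lt(abs(mean(dups) - expected), 4 * se + 0.1 * expected)
})

test_that("loss-free reconciliation recovers the true duplication count", {
  sp <- simulate_species_tree(6, seed = 7)
  hits <- 0
  for (s in 1:25) {
    fam <- simulate_gene_family(sp, 0.3, 0, seed = s)
    if (fam$empty) next
    hits <- hits + 1
    rec <- lca_reconcile(fam$gene_tree, sp, fam$species_map)
    expect_equal(rec$n_duplications, fam$n_duplications)
  }
  expect_gt(hits, 10)
  # with losses the inferred count never exceeds the truth
  for (s in 1:25) {
    fam <- simulate_gene_family(sp, 0.3, 0.25, seed = s)
    if (fam$empty || length(fam$gene_tree$tip.label) < 2) next
    rec <- lca_reconcile(fam$gene_tree, sp, fam$species_map)
    expect_lte(rec$n_duplications, fam$n_duplications)
  }
})

test_that("sequence evolution is faithful to branch lengths", {
  cfg <- family_config("slac", seed = 11)
  sp <- simulate_species_tree(4, seed = 11)
  frozen <- sp; frozen$edge.length[] <- 0
  frozen$tip.label <- paste0(frozen$tip.label, "_group1")
  set.seed(11)
  seqs <- evolve_sequences(frozen, cfg)
  expect_equal(length(unique(unname(seqs))), 1)
})

test_that("the preset bundle realizes the published identity tiers", {
  w1 <- vapply(1:20, function(s) {
    b <- simulate_family(family_config("slac", seed = s))
    gs <- group_identity_stats(b$alignment, b$groups)
    gs$mean[gs$group_a == "group1" & gs$type == "within"]
  }, numeric(1))
  expect_true(all(w1 >= 73 & w1 <= 83))
  b <- simulate_family(family_config("slac", seed = 21))
  gs <- group_identity_stats(b$alignment, b$groups)
  between <- gs$mean[gs$type == "between"]
  within <- gs$mean[gs$type == "within"]
  expect_true(all(between < min(within)))
})

test_that("the anchor motif stays present in nearly all leaves", {
  n_wep <- vapply(1:10, function(s) {
    b <- simulate_family(family_config("almt", seed = s))
    arch <- b$config$architecture
    wep <- arch[arch$name == "wep", ]
    mean(substr(b$sequences, wep$start, wep$end) == "WEP")
  }, numeric(1))
  expect_gte(mean(n_wep), 0.95)
})

test_that("truth bundles are internally consistent and preset-sized", {
  b <- simulate_family(family_config("slac", seed = 6))
  expect_equal(length(b$sequences), 30)   # 3 groups x 10 members
  expect_equal(length(b$decoys), 5)
  expect_equal(sort(unique(unname(b$groups))), paste0("group", 1:3))
  # alignment ungaps to the emitted sequences (indel-free truth)
  expect_equal(ungap(b$alignment), b$sequences)
  # every gene leaf maps to a species leaf
  expect_true(all(b$species_map %in% b$species_tree$tip.label))
  # true TM intervals have hydrophobic composition
  for (i in seq_len(nrow(b$tm_intervals))) {
    seg <- substr(b$sequences[[1]], b$tm_intervals$start_col[i],
                  b$tm_intervals$end_col[i])
    kd <- mean(kd_scale[strsplit(seg, "")[[1]]])
    expect_gt(kd, 1)
  }
  # planted sites are S/T in all carrier leaves
  for (r in seq_len(nrow(b$planted_sites))) {
    carriers <- strsplit(b$planted_sites$carriers[r], ",")[[1]]
    ids <- names(b$groups)[b$groups %in% carriers]
    res <- substr(b$sequences[ids], b$planted_sites$column[r],
                  b$planted_sites$column[r])
    expect_true(all(res %in% c("S", "T")))
  }
})

test_that("benchmark directories are reproducible and reload cleanly", {
  cfg <- family_config("slac", seed = 12, n_species = 4, n_decoys = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- make_benchmark(cfg, d1)
  make_benchmark(cfg, d2)
  for (f in c("sequences.fasta", "alignment.fasta", "species_tree.nwk",
              "gene_tree.nwk", "species_map.tsv", "groups.tsv",
              "tm_truth.tsv", "sites_truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$config_hash, m2$config_hash)

  # the bundle round-trips through the core readers with invariants intact
  seqs <- read_fasta(file.path(d1, "sequences.fasta"))
  expect_identical(seqs, b1$sequences)
  aln <- read_alignment(file.path(d1, "alignment.fasta"))
  expect_equal(ungap(aln), seqs)
  sp <- read_newick(file.path(d1, "species_tree.nwk"))
  gt <- read_newick(file.path(d1, "gene_tree.nwk"))
  smap <- read_species_map(file.path(d1, "species_map.tsv"))
  rec <- lca_reconcile(gt, sp, smap)
  expect_equal(rec$n_duplications, b1$n_duplications_true)
})
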