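test_that("identity distances are symmetric with zero diagonal", {
  aln <- protein_msa(c(a = "MKVL", b = "MKVL", c = "MAAL"))
  D <- identity_distance_matrix(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(diag(D), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(D, t(D))
  # hand count: a vs c share M,L of 4 columns -> 50% identity, distance 50
  expect_equal(D["a", "c"], 50)
})

test_that("double-gap columns are excluded from aligned identity", {
  aln <- protein_msa(c(a = "MK-L", b = "MA-L"))
  # 3 shared columns, 2 identical
  D <- identity_distance_matrix(aln)
  expect_equal(D["a", "b"], 100 - 100 * 2 / 3)
})

test_that("UPGMA reproduces the hand-executed recurrence", {
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- upgma(D2)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_equal(unname(tr2$edge.length), c(2, 2))

  ids <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 6,
                6, 6, 6, 0), 4, dimnames = list(ids, ids))
  tr <- upgma(D)
  expect_equal(attr(tr, "merge_heights"), c(1, 2, 3))
  expect_identical(phyloscreen:::topo_string(tr), "(((a,b),c),d);")
  expect_true(ape::is.ultrametric(tr))
})

test_that("UPGMA recovers the generating tree from ultrametric distances", {
  set.seed(61)
  for (rep in 1:8) {
    src <- ape::rcoal(sample(5:12, 1))
    D <- ape::cophenetic.phylo(src)
    D <- D[order(rownames(D)), order(colnames(D))]
    tr <- upgma(D)
    expect_true(ape::is.ultrametric(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(src)), 0,
                 ignore_attr = TRUE)
    # heights non-decreasing along the merge sequence
    expect_true(all(diff(attr(tr, "merge_heights")) > -1e-12))
  }
})

test_that("UPGMA topology agrees with average-linkage hclust", {
  set.seed(62)
  for (rep in 1:8) {
    n <- sample(5:10, 1)
    M <- matrix(runif(n * n, 1, 10), n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- upgma(D)
    hc <- ape::as.phylo(stats::hclust(stats::as.dist(D), method = "average"))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(hc)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("conserved blocks follow the two-rule surrogate", {
  full <- protein_msa(c(a = "MKVLAY", b = "MKVLAY", c = "MKVLAY"))
  expect_equal(conserved_blocks(full, min_block_len = 2),
               data.frame(start_col = 1L, end_col = 6L))
  # one non-conserved middle column splits the run
  split <- protein_msa(c(a = "MKVLAY", b = "MKWLAY", c = "MKHLAY"))
  b2 <- conserved_blocks(split, min_ident_frac = 0.9, min_block_len = 2)
  expect_equal(b2, data.frame(start_col = c(1L, 4L), end_col = c(2L, 6L)))
  # all-gap column can never sit inside a block
  gappy <- protein_msa(c(a = "MK-LAY", b = "MK-LAY", c = "MK-LAY"))
  b3 <- conserved_blocks(gappy, min_block_len = 2)
  expect_true(all(b3$start_col > 3 | b3$end_col < 3))
})

test_that("tightening the conservation rule never enlarges blocks", {
  set.seed(63)
  rows <- replicate(6, random_protein(80))
  rows <- vapply(rows, function(r) { substr(r, 10, 30) <- substr(rows[1], 10, 30); r },
                 character(1))
  aln <- protein_msa(setNames(rows, paste0("s", 1:6)))
  covered <- function(bs) sum(bs$end_col - bs$start_col + 1)
  loose <- conserved_blocks(aln, min_ident_frac = 0.4)
  tight <- conserved_blocks(aln, min_ident_frac = 0.8)
  expect_lte(covered(tight), covered(loose))
})

test_that("group identity statistics use population SD over the right pairs", {
  seqs <- c(g1a = "MKVLAY", g1b = "MKVLAY", g1c = "MKVLAY",
            g2a = "MKVVCW", g2b = "MAVVCW", g2c = "MAVVCY")
  grp <- setNames(rep(c("G1", "G2"), each = 3), names(seqs))
  st <- group_identity_stats(protein_msa(seqs), grp)
  w1 <- st[st$group_a == "G1" & st$type == "within", ]
  expect_equal(w1$mean, 100); expect_equal(w1$sd, 0); expect_equal(w1$n_pairs, 3)
  # hand-computed: g2a-g2b 5/6, g2a-g2c 4/6, g2b-g2c 5/6
  w2 <- st[st$group_a == "G2" & st$type == "within", ]
  vals <- 100 * c(5, 4, 5) / 6
  expect_equal(w2$mean, mean(vals))
  expect_equal(w2$sd, sqrt(mean((vals - mean(vals))^2)))
  expect_equal(w2$min, min(vals)); expect_equal(w2$max, max(vals))
  bt <- st[st$type == "between", ]
  expect_equal(bt$n_pairs, 9)
  # invariant under member reordering
  st2 <- group_identity_stats(protein_msa(seqs[c(4, 2, 6, 1, 3, 5)]), grp)
  expect_equal(st[order(st$group_a, st$group_b), -c(1:3)],
               st2[order(st2$group_a, st2$group_b), -c(1:3)],
               ignore_attr = TRUE)
})

test_that("singleton groups are flagged with undefined within stats", {
  seqs <- c(a = "MKVL", b = "MKVL", solo = "WWWW")
  st <- group_identity_stats(protein_msa(seqs),
                             c(a = "G", b = "G", solo = "S"))
  solo <- st[st$group_a == "S" & st$type == "within", ]
  expect_equal(solo$n_pairs, 0)
  expect_true(is.na(solo$mean))
})

test_that("bootstrap support is 1.0 on a homoplasy-free split", {
  rows <- c(a1 = paste(rep("AW", 20), collapse = ""),
            a2 = paste(rep("AW", 20), collapse = ""),
            b1 = paste(rep("CY", 20), collapse = ""),
            b2 = paste(rep("CY", 20), collapse = ""))
  rows[c("a2", "b2")] <- sub("^..", "MK", rows[c("a2", "b2")])
  aln <- protein_msa(rows)
  tr <- bootstrap_support(aln, n_reps = 20, seed = 5)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 1))
  # the a|b bipartition must be supported in every replicate
  sets <- phyloscreen:::node_leafsets(tr)
  nt <- length(tr$tip.label)
  ab_nodes <- which(vapply(sets, function(s)
    identical(s, c("a1", "a2")) || identical(s, c("b1", "b2")), logical(1)))
  expect_true(all(tr$node.label[ab_nodes - nt] == 1))
})

test_that("a single bootstrap replicate yields supports in {0, 1}", {
  set.seed(8)
  aln <- protein_msa(setNames(replicate(5, random_protein(30)), paste0("s", 1:5)))
  tr <- bootstrap_support(aln, n_reps = 1, seed = 2)
  expect_true(all(tr$node.label %in% c(0, 1)))
})

test_that("conservation zones tile the region with alternating labels", {
  uniform <- protein_msa(c(a = "MKVLAYMKVL", b = "MKVLAYMKVL"))
  z <- conservation_zones(uniform, window = 3, threshold = 0.5)
  expect_equal(nrow(z), 1)
  expect_equal(z$label, "high")
  expect_equal(c(z$start_col, z$end_col), c(1, 10))

  # planted alternating conservation: 3 high zones, 2 low zones
  con <- "MKVLAYWEPC"
  set.seed(66)
  mk_row <- function() paste0(con, random_protein(10), con, random_protein(10), con)
  aln <- protein_msa(c(a = mk_row(), b = mk_row(), c = mk_row(), d = mk_row()))
  z2 <- conservation_zones(aln, window = 5, threshold = 0.6)
  expect_equal(z2$label, c("high", "low", "high", "low", "high"))
  # boundaries within half a window of the planted 10-column tiles
  expect_true(all(abs(z2$start_col - c(1, 11, 21, 31, 41)) <= 3))
  # zones tile the alignment
  expect_equal(z2$start_col[-1], z2$end_col[-nrow(z2)] + 1)
  expect_true(all(z2$label == c("high", "low")[1 + (seq_len(nrow(z2)) + 1) %% 2]))
})
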