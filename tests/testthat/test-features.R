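test_that("Kyte-Doolittle windows average the published scale constants", {
  polyI <- c(p = paste(rep("I", 15), collapse = ""))
  tr <- kd_hydropathicity(polyI, window = 5)
  expect_true(all(tr[3:13] == 4.5))
  expect_true(all(is.na(tr[c(1, 2, 14, 15)])))

  tr2 <- kd_hydropathicity(c(p = "IRI"), window = 3)
  expect_equal(unname(tr2[2]), (4.5 - 4.5 + 4.5) / 3)
  expect_true(is.na(tr2[1]) && is.na(tr2[3]))

  tr3 <- kd_hydropathicity(c(p = "IWKR"), window = 1)
  expect_equal(as.numeric(tr3), unname(kd_scale[c("I", "W", "K", "R")]))

  expect_true(all(is.na(kd_hydropathicity(c(p = "MKV"), window = 5))))
  expect_error(kd_hydropathicity(c(p = "MKV"), window = 4), "window")
})

test_that("track projection places values at residue-bearing columns", {
  aln <- protein_msa(c(x = "A-CD", y = "AACD"))
  tr <- structure(c(1, 2, 3), seq_id = "x")
  proj <- project_track(tr, aln)
  expect_equal(proj, c(1, NA, 2, 3))
  # round trip: ungapping the projection recovers the track
  expect_equal(proj[!is.na(proj)], c(1, 2, 3))
  # gap-free row keeps the ordering untouched
  tr_y <- structure(c(9, 8, 7, 6), seq_id = "y")
  expect_equal(project_track(tr_y, aln), c(9, 8, 7, 6))
  expect_error(project_track(structure(1:2, seq_id = "x"), aln),
               "does not match")
  expect_error(project_track(structure(1:3, seq_id = "zz"), aln), "not found")
})

test_that("clade averaging applies the gap-fraction mask uniformly", {
  rows <- c(sprintf("s%02d", 1:10))
  mk <- function(i) if (i <= 3) "-IIII" else "IIIII"
  aln <- protein_msa(setNames(vapply(1:10, mk, character(1)), rows))
  tracks <- lapply(rows, function(id)
    structure(rep(1.0, nchar(ungap(aln)[[id]])), seq_id = id))
  names(tracks) <- rows
  ct <- project_tracks(tracks, aln)
  prof <- clade_average(ct, aln, setNames(rep("g", 10), rows))
  # column 1: 3/10 gaps (30% >= 25%) -> masked
  expect_true(prof$g$masked[1])
  expect_true(is.na(prof$g$mean[1]))
  expect_equal(prof$g$mean[2:5], rep(1, 4))

  # 2/10 gaps stays unmasked
  mk2 <- function(i) if (i <= 2) "-IIII" else "IIIII"
  aln2 <- protein_msa(setNames(vapply(1:10, mk2, character(1)), rows))
  ct2 <- project_tracks(lapply(setNames(rows, rows), function(id)
    structure(rep(1.0, nchar(ungap(aln2)[[id]])), seq_id = id)), aln2)
  prof2 <- clade_average(ct2, aln2, setNames(rep("g", 10), rows))
  expect_false(prof2$g$masked[1])
  expect_equal(prof2$g$mean[1], 1)

  expect_error(clade_average(ct, aln, setNames(rep("g", 10), paste0("z", 1:10))),
               "empty group")
})

test_that("constant tracks give constant profiles under any grouping", {
  set.seed(44)
  rows <- setNames(replicate(8, random_protein(30)), paste0("s", 1:8))
  aln <- protein_msa(rows)
  ct <- project_tracks(lapply(setNames(names(rows), names(rows)), function(id)
    structure(rep(2.5, 30), seq_id = id)), aln)
  for (k in 1:3) {
    grp <- setNames(sample(c("a", "b"), 8, replace = TRUE), names(rows))
    prof <- clade_average(ct, aln, grp)
    for (p in prof) expect_true(all(p$mean[!p$masked] == 2.5))
  }
})

test_that("TM segment calling respects threshold and length rules", {
  neg <- data.frame(column = 1:50, mean = rep(-2, 50), masked = FALSE)
  expect_equal(nrow(call_tm_segments(neg)), 0)

  prof <- data.frame(column = 1:60,
                     mean = c(rep(-1, 10), rep(2, 15), rep(0, 5),
                              rep(2, 8), rep(-1, 22)),
                     masked = FALSE)
  seg <- call_tm_segments(prof, score_min = 1, min_len = 10)
  expect_equal(seg$start_col, 11); expect_equal(seg$end_col, 25)
  # the 8-column run fails min_len
  expect_equal(nrow(seg), 1)
  # masked columns break runs
  prof$masked[18] <- TRUE
  expect_equal(nrow(call_tm_segments(prof, score_min = 1, min_len = 10)), 0)
  # raising the threshold never adds segments or covered columns
  covered <- function(s) sum(s$end_col - s$start_col + 1)
  prof$masked[18] <- FALSE
  lo <- call_tm_segments(prof, score_min = 0.5, min_len = 5)
  hi <- call_tm_segments(prof, score_min = 1.8, min_len = 5)
  expect_lte(nrow(hi), nrow(lo))
  expect_lte(covered(hi), covered(lo))
})

test_that("phospho scorer contract: S/T/Y only, scores in [0, 1]", {
  no_sty <- c(p = "MKVLAGIF")
  expect_true(all(is.na(phospho_scores(no_sty))))
  bad <- function(seq) structure(rep(2, nchar(seq)), seq_id = names(seq))
  expect_error(phospho_scores(c(p = "MS"), bad), "non-S/T/Y|outside")
  bad2 <- function(seq) { out <- rep(NA_real_, nchar(seq)); out[2] <- 1.5; out }
  expect_error(phospho_scores(c(p = "MS"), bad2), "outside")
})

test_that("the surrogate scorer ranks its consensus context highest", {
  ctx <- phospho_consensus_context()
  planted <- c(p = paste0("MMMM", ctx, "MMMM"))
  tr <- phospho_scores(planted)
  s_pos <- 4 + 5
  expect_gt(tr[s_pos], 0.6)
  set.seed(15)
  for (i in 1:20) {
    scram <- strsplit(ctx, "")[[1]]
    scram[-5] <- sample(scram[-5])
    if (paste(scram, collapse = "") == ctx) next
    tr2 <- phospho_scores(c(p = paste0("MMMM", paste(scram, collapse = ""), "MMMM")))
    expect_lte(tr2[s_pos], tr[s_pos])
  }
  # background S/T contexts stay far below the max-score criterion
  set.seed(16)
  lc <- phyloscreen:::linker_composition()
  prob <- setNames(rep(0, 20), AA); prob[names(lc)] <- lc
  bg <- vapply(1:50, function(i) {
    sc <- phospho_scores(c(p = random_protein(40, prob = prob)))
    if (all(is.na(sc))) 0 else max(sc, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(bg > 0.6), 0.1)
})

test_that("the score-table adapter passes values through exactly", {
  tab <- data.frame(seq_id = "p", position = c(2, 5), residue = c("S", "T"),
                    score = c(0.42, 0.9))
  tr <- phospho_scores(c(p = "MSKVT"), phospho_table_adapter(tab))
  expect_equal(unname(tr[c(2, 5)]), c(0.42, 0.9))
  expect_true(all(is.na(tr[c(1, 3, 4)])))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tr2 <- phospho_scores(c(p = "MSKVT"), phospho_table_adapter(tf))
  expect_equal(tr, tr2)
  bad <- data.frame(seq_id = "p", position = 3, residue = "S", score = 0.5)
  expect_error(phospho_scores(c(p = "MSKVT"), phospho_table_adapter(bad)),
               "mismatch")
})

test_that("the three-criterion site screen evaluates each rule strictly", {
  ids <- sprintf("m%02d", 1:10)
  aln <- protein_msa(setNames(rep("MSK", 10), ids))
  grp <- setNames(rep("g", 10), ids)
  mk_tracks <- function(scores) {
    tab <- data.frame(seq_id = rep(ids, each = 1), position = 2,
                      residue = "S", score = scores)
    project_tracks(lapply(setNames(ids, ids), function(id)
      phospho_scores(setNames("MSK", id), phospho_table_adapter(tab))), aln)
  }
  # 10/10 S with scores {0.9, 0.3 x 9}: all three criteria pass
  ct <- mk_tracks(c(0.9, rep(0.3, 9)))
  rep1 <- conserved_site_screen(aln, grp, ct)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$conservation, 1.0)
  expect_equal(rep1$max_score, 0.9)
  expect_equal(rep1$mean_score, (0.9 + 9 * 0.3) / 10)
  expect_equal(rep1$column, 2)
  expect_equal(rep1$residue_class, "ST")

  # 8/10 carriers fails criterion (i) regardless of scores
  rows8 <- setNames(c(rep("MSK", 8), rep("MAK", 2)), ids)
  aln8 <- protein_msa(rows8)
  tab8 <- data.frame(seq_id = ids[1:8], position = 2, residue = "S",
                     score = 0.95)
  ct8 <- project_tracks(lapply(setNames(ids, ids), function(id)
    phospho_scores(setNames(rows8[[id]], id), phospho_table_adapter(tab8))),
    aln8)
  expect_equal(nrow(conserved_site_screen(aln8, grp, ct8)), 0)

  # all-Y column with max score 0.5 fails criterion (ii)
  alnY <- protein_msa(setNames(rep("MYK", 10), ids))
  tabY <- data.frame(seq_id = ids, position = 2, residue = "Y", score = 0.5)
  ctY <- project_tracks(lapply(setNames(ids, ids), function(id)
    phospho_scores(setNames("MYK", id), phospho_table_adapter(tabY))), alnY)
  expect_equal(nrow(conserved_site_screen(alnY, grp, ctY)), 0)

  # mean just above the threshold is reported with its exact value ...
  ct_lo <- mk_tracks(c(0.8, rep(0.16, 9)))
  expect_equal(conserved_site_screen(aln, grp, ct_lo)$mean_score,
               (0.8 + 9 * 0.16) / 10)
  # ... but criterion (iii) is strict: mean exactly 0.2 is rejected
  ct_eq <- mk_tracks(c(0.65, rep(0.15, 9)))
  expect_equal(nrow(conserved_site_screen(aln, grp, ct_eq)), 0)
})

test_that("S and T are interchangeable for conservation; Y is separate", {
  ids <- sprintf("m%02d", 1:10)
  rows <- setNames(c(rep("MSK", 5), rep("MTK", 5)), ids)
  aln <- protein_msa(rows)
  tab <- data.frame(seq_id = ids, position = 2,
                    residue = c(rep("S", 5), rep("T", 5)), score = 0.8)
  ct <- project_tracks(lapply(setNames(ids, ids), function(id)
    phospho_scores(setNames(rows[[id]], id), phospho_table_adapter(tab))), aln)
  rep_st <- conserved_site_screen(aln, setNames(rep("g", 10), ids), ct)
  expect_equal(nrow(rep_st), 1)
  expect_equal(rep_st$residue_class, "ST")
})

test_that("tightening any site-screen threshold never adds sites", {
  set.seed(91)
  b <- simulate_family(family_config("slac", seed = 14, n_species = 4))
  pt <- project_tracks(lapply(setNames(names(b$sequences), names(b$sequences)),
                              function(id) phospho_scores(b$sequences[id])),
                       b$alignment)
  base <- conserved_site_screen(b$alignment, b$groups, pt,
                                cons_min = 0.8, max_min = 0.5, mean_min = 0.1)
  for (tight in list(c(0.95, 0.5, 0.1), c(0.8, 0.7, 0.1), c(0.8, 0.5, 0.3))) {
    sub <- conserved_site_screen(b$alignment, b$groups, pt,
                                 cons_min = tight[1], max_min = tight[2],
                                 mean_min = tight[3])
    key <- function(df) paste(df$column, df$group, df$residue_class)
    expect_true(all(key(sub) %in% key(base)))
  }
})

test_that("position frequency matrices count residues and gaps to sum 1", {
  ids <- paste0("s", 1:4)
  aln <- protein_msa(setNames(c("MSKAV", "MSKAV", "MTK-V", "MSRAV"), ids))
  pfm <- pfm_window(aln, column = 3, halfwidth = 1)
  expect_equal(dim(pfm), c(21, 3))
  expect_equal(unname(colSums(pfm)), rep(1, 3))
  expect_equal(pfm["S", "2"], 0.75)
  expect_equal(pfm["T", "2"], 0.25)
  expect_equal(pfm["K", "3"], 0.75)
  expect_equal(pfm["R", "3"], 0.25)
  expect_equal(pfm["-", "4"], 0.25)
  # identical rows give single frequency-1 entries
  same <- protein_msa(setNames(rep("MSKAV", 3), paste0("t", 1:3)))
  pfm2 <- pfm_window(same, 3, 1)
  expect_true(all(apply(pfm2, 2, max) == 1))
  expect_error(pfm_window(aln, 1, 2), "bounds")
})
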