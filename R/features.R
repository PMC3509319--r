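#' Per-residue feature tracks, clade profiles and the conserved
#' phosphosite screen
#'
#' Per-residue scores (hydropathicity, phosphorylation propensity) are
#' computed on each ungapped sequence, projected onto the columns of a
#' master alignment, and averaged per clade with columns masked when too
#' many sequences are gapped there. Sustained hydrophobic stretches of the
#' clade profile are called as transmembrane segments; serine/threonine
#' (and tyrosine) columns passing a three-criterion conservation/score
#' screen are reported as group-specifically conserved phosphosites.
#'
#' @name feature_tracks
NULL

#' Kyte-Doolittle hydropathicity scale
#'
#' Named numeric vector of the 20 residue hydropathicity constants
#' (I = 4.5 down to R = -4.5).
#' @export
kd_scale <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
              G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
              H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
              R = -4.5)

#' Sliding-window Kyte-Doolittle hydropathicity of one sequence
#'
#' Score at position i is the mean scale value over the full window of
#' `window` residues centered at i; positions whose window would run off
#' either end are `NA`. `X` residues carry no scale value and are dropped
#' from the window mean.
#'
#' @param seq Single residue string (optionally named; the name is kept as
#'   the track's `seq_id` attribute).
#' @param window Odd window width >= 1 (default 19, the transmembrane-scan
#'   convention).
#' @return Numeric vector of length `nchar(seq)` with attributes `seq_id`
#'   and `feature = "kd_hydropathicity"`.
#' @examples
#' kd_hydropathicity(c(p = "IRI"), window = 3)
#' @export
kd_hydropathicity <- function(seq, window = 19L) {
  stopifnot(length(seq) == 1, window >= 1, window %% 2 == 1)
  ch <- strsplit(unname(seq), "", fixed = TRUE)[[1]]
  vals <- kd_scale[ch]          # X and unknowns -> NA
  L <- length(ch); half <- window %/% 2
  out <- rep(NA_real_, L)
  if (L >= window) {
    for (i in (half + 1):(L - half))
      out[i] <- mean(vals[(i - half):(i + half)], na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
  }
  structure(out, seq_id = names(seq), feature = "kd_hydropathicity")
}

#' Project a per-residue track onto alignment columns
#'
#' Each defined residue value is placed at the alignment column carrying
#' that residue; gap columns are `NA`. Projection is a bijection on the
#' defined values, so ungapping the projected track recovers the input.
#'
#' @param track Numeric vector, one value (or `NA`) per ungapped residue.
#' @param aln A [protein_msa()].
#' @param seq_id Row of `aln` to project onto; defaults to the track's
#'   `seq_id` attribute.
#' @return Numeric vector of length `ncol(aln)`.
#' @export
project_track <- function(track, aln, seq_id = attr(track, "seq_id")) {
  stopifnot(inherits(aln, "protein_msa"))
  if (is.null(seq_id) || !seq_id %in% rownames(aln))
    stop("seq_id not found in alignment: ", seq_id)
  row <- unclass(aln)[seq_id, ]
  res <- which(row != GAP)
  if (length(res) != length(track))
    stop("track length ", length(track), " does not match ungapped row of '",
         seq_id, "' (", length(res), " residues)")
  out <- rep(NA_real_, ncol(aln))
  out[res] <- as.numeric(track)
  out
}

#' @rdname project_track
#' @param tracks Named list of per-residue tracks (names = sequence ids).
#' @return `project_tracks`: numeric matrix sequences x columns.
#' @export
project_tracks <- function(tracks, aln) {
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  out <- matrix(NA_real_, length(tracks), ncol(aln),
                dimnames = list(names(tracks), NULL))
  for (id in names(tracks))
    out[id, ] <- project_track(tracks[[id]], aln, seq_id = id)
  out
}

#' Clade-averaged column profiles with a gap mask
#'
#' For each group (and for all sequences pooled), a column is masked when
#' the fraction of group members gapped there is `>= max_gap_frac`
#' (default 0.25: averages are only computed where fewer than 25% of the
#' sequences show gaps); elsewhere the profile is the mean of the defined
#' member values.
#'
#' @param coltracks Matrix from [project_tracks()] (sequences x columns).
#' @param aln The alignment the tracks were projected on.
#' @param groups Named character vector: group label per sequence id; ids
#'   absent from `groups` enter only the pooled profile.
#' @param max_gap_frac Masking threshold on the column gap fraction.
#' @return A `clade_profiles` object: named list (one per group plus
#'   `"all"`) of data.frames `column`, `mean`, `masked`, `gap_frac`.
#' @export
clade_average <- function(coltracks, aln, groups, max_gap_frac = 0.25) {
  stopifnot(inherits(aln, "protein_msa"),
            all(rownames(coltracks) %in% rownames(aln)))
  gm <- unclass(aln) == GAP
  profile_for <- function(ids) {
    if (!length(ids)) stop("empty group")
    gapf <- colMeans(gm[ids, , drop = FALSE])
    masked <- gapf >= max_gap_frac
    mu <- colMeans(coltracks[ids, , drop = FALSE], na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    mu[masked] <- NA_real_
    data.frame(column = seq_len(ncol(coltracks)), mean = mu,
               masked = masked, gap_frac = gapf)
  }
  labs <- unique(unname(groups))
  out <- lapply(labs, function(g) {
    ids <- intersect(rownames(coltracks), names(groups)[groups == g])
    if (!length(ids)) stop("empty group: ", g)
    profile_for(ids)
  })
  names(out) <- labs
  out$all <- profile_for(rownames(coltracks))
  structure(out, max_gap_frac = max_gap_frac, class = "clade_profiles")
}

#' Call transmembrane segments from a clade hydropathicity profile
#'
#' Maximal runs of unmasked columns whose mean hydropathicity is at least
#' `score_min`, of length at least `min_len`; masked columns break runs.
#'
#' @param profile One element of a [clade_average()] result (data.frame
#'   with `column`, `mean`, `masked`).
#' @param score_min Minimum mean hydropathicity (default 1.0).
#' @param min_len Minimum run length in columns (default 10).
#' @return data.frame `start_col`, `end_col`, `mean_hydropathicity`.
#' @export
call_tm_segments <- function(profile, score_min = 1.0, min_len = 10L) {
  good <- !profile$masked & !is.na(profile$mean) & profile$mean >= score_min
  r <- rle(good)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start_col = profile$column[starts[keep]],
                    end_col = profile$column[ends[keep]])
  out$mean_hydropathicity <- vapply(seq_len(nrow(out)), function(k)
    mean(profile$mean[starts[keep][k]:ends[keep][k]]), numeric(1))
  out
}

#' Position-weight context scorer for phosphorylation propensity
#'
#' A transparent surrogate for an external kinase-target predictor: the
#' score of an S/T/Y residue is a logistic transform of a position-weight
#' sum over the +-4 residue context. The shipped default weights reward an
#' R-x-R..S..L-E-like context (R at -3 and -2, L at +1, E at +2), chosen so
#' that a full consensus context scores near 0.8 while background contexts
#' stay far below the screen's 0.6 maximum-score criterion.
#'
#' @param weights 20 x 8 matrix (rows [kd_scale()] residue order is not
#'   required; rows named by residue, columns by offsets -4..-1, 1..4).
#' @param intercept Logistic intercept (default -4).
#' @return A scorer function `seq -> numeric track` usable with
#'   [phospho_scores()].
#' @export
surrogate_phospho_scorer <- function(weights = phospho_pwm_default(),
                                     intercept = -4) {
  offsets <- as.integer(colnames(weights))
  function(seq) {
    ch <- strsplit(unname(seq), "", fixed = TRUE)[[1]]
    L <- length(ch)
    out <- rep(NA_real_, L)
    for (i in which(ch %in% c("S", "T", "Y"))) {
      s <- intercept
      for (k in seq_along(offsets)) {
        j <- i + offsets[k]
        if (j >= 1 && j <= L && ch[j] %in% rownames(weights))
          s <- s + weights[ch[j], k]
      }
      out[i] <- stats::plogis(s)
    }
    structure(out, seq_id = names(seq), feature = "phospho")
  }
}

#' @rdname surrogate_phospho_scorer
#' @export
phospho_pwm_default <- function() {
  w <- matrix(0, 20, 8, dimnames = list(AA20, c(-4:-1, 1:4)))
  w["R", "-3"] <- 1.3
  w["R", "-2"] <- 1.3
  w["L", "1"] <- 1.3
  w["E", "2"] <- 1.3
  w
}

#' @rdname surrogate_phospho_scorer
#' @return `phospho_consensus_context`: the 9-residue context (positions
#'   -4..+4 around a central serine) that maximizes the default surrogate
#'   score.
#' @export
phospho_consensus_context <- function() "ARRASLEAA"

#' Adapter for precomputed per-residue phosphosite score tables
#'
#' @param table Path to a TSV, or a data.frame, with columns `seq_id`,
#'   `position` (1-based), `residue`, `score`.
#' @return A scorer function `seq -> numeric track`; sequences are looked
#'   up by name and table scores are passed through unchanged.
#' @export
phospho_table_adapter <- function(table) {
  if (is.character(table)) table <- read.delim(table, stringsAsFactors = FALSE)
  stopifnot(all(c("seq_id", "position", "residue", "score") %in% names(table)))
  function(seq) {
    id <- names(seq)
    if (is.null(id)) stop("adapter requires a named sequence")
    rows <- table[table$seq_id == id, , drop = FALSE]
    ch <- strsplit(unname(seq), "", fixed = TRUE)[[1]]
    out <- rep(NA_real_, length(ch))
    if (nrow(rows)) {
      if (any(rows$position < 1 | rows$position > length(ch)))
        stop("score table position out of range for ", id)
      mismatch <- ch[rows$position] != rows$residue
      if (any(mismatch))
        stop("score table residue mismatch for ", id, " at position(s) ",
             paste(rows$position[mismatch], collapse = ", "))
      out[rows$position] <- rows$score
    }
    structure(out, seq_id = id, feature = "phospho")
  }
}

#' Score the S/T/Y residues of a sequence with a pluggable scorer
#'
#' @param seq Named residue string.
#' @param scorer Scorer function (see [surrogate_phospho_scorer()] and
#'   [phospho_table_adapter()]). Scores must lie in `[0, 1]` and only
#'   S/T/Y positions may carry values.
#' @return Numeric track of length `nchar(seq)`.
#' @export
phospho_scores <- function(seq, scorer = surrogate_phospho_scorer()) {
  out <- scorer(seq)
  ch <- strsplit(unname(seq), "", fixed = TRUE)[[1]]
  if (length(out) != length(ch))
    stop("scorer returned a track of wrong length")
  defined <- !is.na(out)
  if (any(defined & !ch %in% c("S", "T", "Y")))
    stop("scorer assigned scores to non-S/T/Y positions")
  if (any(out[defined] < 0 | out[defined] > 1))
    stop("scores outside [0, 1]")
  out
}

# residue class at a column: S/T interchangeable, Y separate
site_class <- function(res) ifelse(res %in% c("S", "T"), "ST",
                                   ifelse(res == "Y", "Y", NA))

#' Screen alignment columns for group-specifically conserved phosphosites
#'
#' A column is reported for a group when (i) more than `cons_min` of the
#' group's members carry the residue class there (S and T are
#' interchangeable, Y is its own class), (ii) the maximum member score
#' exceeds `max_min`, and (iii) the mean score exceeds `mean_min`.
#'
#' @param aln A [protein_msa()].
#' @param groups Named character vector: group label per sequence id.
#' @param coltracks Projected phosphosite score matrix
#'   ([project_tracks()] of [phospho_scores()] tracks).
#' @param cons_min Conservation criterion (default 0.90, strict `>`).
#' @param max_min Maximum-score criterion (default 0.6, strict `>`).
#' @param mean_min Mean-score criterion (default 0.2, strict `>`).
#' @param mean_over `"carriers"` (default): the mean runs over the group
#'   members carrying the residue class; `"all"`: members lacking the class
#'   contribute a zero score.
#' @return data.frame `column`, `group`, `residue_class`, `conservation`,
#'   `mean_score`, `sd_score` (population SD), `max_score`,
#'   `representative` (first carrier as `id:position`).
#' @export
conserved_site_screen <- function(aln, groups, coltracks, cons_min = 0.90,
                                  max_min = 0.6, mean_min = 0.2,
                                  mean_over = c("carriers", "all")) {
  mean_over <- match.arg(mean_over)
  stopifnot(inherits(aln, "protein_msa"),
            all(rownames(coltracks) %in% rownames(aln)))
  m <- unclass(aln)
  respos <- t(apply(m != GAP, 1, cumsum))  # ungapped position per column
  out <- list()
  for (g in unique(unname(groups[rownames(coltracks)]))) {
    if (is.na(g)) next
    ids <- intersect(rownames(coltracks), names(groups)[groups == g])
    for (col in seq_len(ncol(m))) {
      res <- m[ids, col]
      for (cls in c("ST", "Y")) {
        carriers <- ids[!is.na(site_class(res)) & site_class(res) == cls]
        conservation <- length(carriers) / length(ids)
        if (conservation <= cons_min) next
        sc <- coltracks[carriers, col]
        sc <- sc[!is.na(sc)]
        if (!length(sc)) next
        mean_sc <- if (mean_over == "carriers") mean(sc) else
          sum(sc) / length(ids)
        if (max(sc) <= max_min || mean_sc <= mean_min) next
        rep_id <- carriers[1]
        out[[length(out) + 1]] <- data.frame(
          column = col, group = g, residue_class = cls,
          conservation = conservation,
          mean_score = mean_sc,
          sd_score = sqrt(mean((sc - mean(sc))^2)),
          max_score = max(sc),
          representative = paste0(rep_id, ":", respos[rep_id, col]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(column = integer(0), group = character(0),
                      residue_class = character(0), conservation = numeric(0),
                      mean_score = numeric(0), sd_score = numeric(0),
                      max_score = numeric(0), representative = character(0)))
  do.call(rbind, out)
}

#' Position frequency matrix of an alignment window
#'
#' @param aln A [protein_msa()].
#' @param column Central alignment column (1-based).
#' @param halfwidth Window half-width; the window must fit the alignment.
#' @param group Optional ids (or named `groups` vector plus `label`) of the
#'   rows to count; defaults to all rows.
#' @return 21 x (2*halfwidth+1) matrix (residues + gap by window columns);
#'   every column sums to 1. Column names give the alignment columns.
#' @export
pfm_window <- function(aln, column, halfwidth, group = NULL) {
  stopifnot(inherits(aln, "protein_msa"))
  cols <- (column - halfwidth):(column + halfwidth)
  if (cols[1] < 1 || cols[length(cols)] > ncol(aln))
    stop("window out of alignment bounds")
  m <- unclass(aln)
  if (!is.null(group)) m <- m[group, , drop = FALSE]
  syms <- c(AA20, GAP)
  out <- vapply(cols, function(j)
    as.numeric(table(factor(m[, j], levels = syms))) / nrow(m),
    numeric(21))
  dimnames(out) <- list(syms, cols)
  out
}

#' @rdname pfm_window
#' @param pfm A position frequency matrix.
#' @param path Output TSV path.
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(symbol = rownames(pfm), pfm, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
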