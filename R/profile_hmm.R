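#' Profile HMMs for motif screening
#'
#' A light profile HMM in the Plan7 spirit: match/insert/delete states per
#' motif position, built from a gapped seed alignment. Scoring is local in
#' the target sequence (free flanks contribute zero log-odds) and global in
#' the model: a scoring path enters before position 1 and leaves after
#' position K, optionally through flanking insert states I0/IK. Insert
#' states emit from the background, so only match emissions and transition
#' probabilities contribute to the log2-odds score. There is no multi-hit
#' mode and no biased-composition correction.
#'
#' @name profile_hmm
NULL

#' Build a profile HMM from a motif seed alignment
#'
#' Columns whose gap fraction is below `match_gap_frac` become match states;
#' the remaining columns feed the insert states between them. Match
#' emissions are background-proportional pseudocounted:
#' `(count + w * background) / (n_eff + w)` with `n_eff` the number of
#' residues observed in the column. Transition probabilities are estimated
#' from the seed rows' state paths with add-one pseudocounts over the
#' allowed moves (M->M/I/D, I->M/I, D->M/D).
#'
#' @param seed A [protein_msa()] with at least two rows.
#' @param motif_id Identifier stored in the model and reported with hits.
#' @param pseudocount_weight Total pseudocount mass added per emission row.
#' @param background Length-20 background amino-acid distribution
#'   (default uniform 1/20; `X` residues are ignored when counting and score
#'   zero when matched).
#' @param match_gap_frac Columns with gap fraction below this become match
#'   states.
#' @return A `profile_hmm` object with `K` match states, emission and
#'   transition tables, and (after [calibrate_evalue()]) Gumbel calibration.
#' @examples
#' seed <- protein_msa(c(a = "WEP", b = "WEP", c = "WDP"))
#' m <- build_profile(seed, "wep")
#' m$K
#' @export
build_profile <- function(seed, motif_id = "motif", pseudocount_weight = 1.0,
                          background = rep(1 / 20, 20), match_gap_frac = 0.5) {
  stopifnot(inherits(seed, "protein_msa"))
  if (nrow(seed) < 2) stop("seed alignment needs >= 2 rows")
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9)
  names(background) <- AA20
  mat <- unclass(seed)
  gapfrac <- colMeans(mat == GAP)
  is_match <- gapfrac < match_gap_frac
  K <- sum(is_match)
  if (K == 0) stop("seed has zero match columns (all columns too gappy)")

  # match emissions
  match_cols <- which(is_match)
  em <- matrix(0, K, 20, dimnames = list(NULL, AA20))
  for (k in seq_len(K)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% AA20]
    cnt <- table(factor(col, levels = AA20))
    n_eff <- sum(cnt)
    em[k, ] <- (as.numeric(cnt) + pseudocount_weight * background) /
      (n_eff + pseudocount_weight)
  }

  # transition counts from the seed rows' state paths
  # position index k runs 0..K; M0 is the begin state, "E" position K+1
  cMM <- cMI <- cMD <- rep(1, K + 1)  # add-one pseudocounts
  cIM <- cII <- rep(1, K + 1)
  cDM <- cDD <- rep(1, K + 1)
  colpos <- cumsum(is_match)          # match index at/before each column
  for (r in seq_len(nrow(mat))) {
    state <- "M"; k <- 0L
    for (j in seq_len(ncol(mat))) {
      resid <- mat[r, j] != GAP
      if (is_match[j]) {
        to <- if (resid) "M" else "D"
        if (state == "M") { if (to == "M") cMM[k + 1] <- cMM[k + 1] + 1 else cMD[k + 1] <- cMD[k + 1] + 1 }
        else if (state == "I") { cIM[k + 1] <- cIM[k + 1] + 1 }  # I->D disallowed; fold into I->M
        else { if (to == "M") cDM[k + 1] <- cDM[k + 1] + 1 else cDD[k + 1] <- cDD[k + 1] + 1 }
        state <- to; k <- colpos[j]
      } else if (resid) {
        if (state == "M") cMI[k + 1] <- cMI[k + 1] + 1
        else if (state == "I") cII[k + 1] <- cII[k + 1] + 1
        # from D an emitted insert is folded into D->M ... M->I bookkeeping;
        # rare in seeds, counted as I self-visit
        else cII[k + 1] <- cII[k + 1] + 1
        state <- "I"
      }
    }
    # exit to E
    if (state == "M") cMM[K + 1] <- cMM[K + 1] + 1
    else if (state == "I") cIM[K + 1] <- cIM[K + 1] + 1
    else cDM[K + 1] <- cDM[K + 1] + 1
  }
  normalize3 <- function(a, b, d) { s <- a + b + d; cbind(a / s, b / s, d / s) }
  tM <- normalize3(cMM, cMI, cMD)                 # rows k=0..K: M_k -> M/I/D
  tI <- cbind(cIM, cII) / (cIM + cII)             # I_k -> M/I
  tD <- normalize3(cDM, 0, cDD)[, c(1, 3)]        # D_k -> M/D
  # boundary: no D0 / no D_{K+1}; from position K, "M" means exit to E
  tM[K + 1, 3] <- 0; tM[K + 1, ] <- tM[K + 1, ] / sum(tM[K + 1, ])
  tD[K + 1, 2] <- 0; tD[K + 1, 1] <- 1
  colnames(tM) <- c("M", "I", "D"); colnames(tI) <- c("M", "I")
  colnames(tD) <- c("M", "D")

  structure(list(motif_id = motif_id, K = K,
                 match_emissions = em,
                 insert_emissions = background,
                 background = background,
                 tM = tM, tI = tI, tD = tD,
                 match_cols = match_cols,
                 pseudocount_config = list(scheme = "background-proportional",
                                           weight = pseudocount_weight),
                 calibration = NULL),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$motif_id, "': ", x$K, " match states",
      if (!is.null(x$calibration)) sprintf(
        "; Gumbel calibrated (mu=%.2f, lambda=%.3f, n=%d)",
        x$calibration$mu, x$calibration$lambda, x$calibration$n_random) else
        "; not calibrated", "\n", sep = "")
  invisible(x)
}

# log2 transition tables, emission log-odds; shared by viterbi/forward
hmm_log_tables <- function(model) {
  lod <- log2(sweep(model$match_emissions, 2, model$background, "/"))
  list(lod = cbind(lod, X = 0),  # X residues score as background
       lMM = log2(model$tM[, "M"]), lMI = log2(model$tM[, "I"]),
       lMD = log2(model$tM[, "D"]),
       lIM = log2(model$tI[, "M"]), lII = log2(model$tI[, "I"]),
       lDM = log2(model$tD[, "M"]), lDD = log2(model$tD[, "D"]))
}

#' Score a sequence against a profile HMM
#'
#' `viterbi_local` returns the log2-odds score of the single best local
#' match (free flanks, model traversed in full) together with the matched
#' span in 1-based target coordinates; `forward_local` returns the log2 sum
#' over all such paths and is always `>=` the Viterbi score.
#'
#' @param model A calibrated or uncalibrated `profile_hmm`.
#' @param seq A single residue string.
#' @return `viterbi_local`: list with `bit_score`, `start`, `end`.
#'   `forward_local`: a numeric bit score.
#' @export
viterbi_local <- function(model, seq) {
  lt <- hmm_log_tables(model)
  x <- strsplit(unname(seq), "", fixed = TRUE)[[1]]
  x[!x %in% AA20] <- "X"
  L <- length(x); K <- model$K
  NEG <- -Inf
  # delete-chain entry: score of reaching D_k having consumed nothing
  # (D_1 from B, then D_{k-1} -> D_k)
  d_entry <- lt$lMD[1] +
    cumsum(c(0, if (K > 1) lt$lDD[2:K] else NULL))  # D_1..D_K

  VM <- matrix(NEG, L + 1, K)  # VM[i+1, k]: best path ending in M_k at residue i
  VI <- matrix(NEG, L + 1, K + 1)  # I_0..I_K
  VD <- matrix(NEG, L + 1, K)
  SM <- matrix(NA_integer_, L + 1, K)
  SI <- matrix(NA_integer_, L + 1, K + 1)
  SD <- matrix(NA_integer_, L + 1, K)
  # i = 0 row: nothing consumed; D chain reachable
  VD[1, ] <- d_entry
  VI[1, 1] <- NEG  # I_0 requires an emission
  best <- NEG; best_start <- NA_integer_; best_end <- NA_integer_
  ex_end <- function(i) {
    # exit scores at residue i (row i+1)
    c(VM[i + 1, K] + lt$lMM[K + 1],
      VI[i + 1, K + 1] + lt$lIM[K + 1],
      if (K >= 1) VD[i + 1, K] + lt$lDM[K + 1] else NEG)
  }
  e0 <- ex_end(0)
  if (max(e0) > best) { best <- max(e0); best_start <- 0L; best_end <- 0L }
  for (i in seq_len(L)) {
    ei <- lt$lod[, x[i]]
    # I_0: from B (fresh start at this residue) or self
    cand <- c(lt$lMI[1], VI[i, 1] + lt$lII[1])
    w <- which.max(cand)
    VI[i + 1, 1] <- cand[w]
    SI[i + 1, 1] <- if (w == 1) i else SI[i, 1]
    # M_k
    for (k in seq_len(K)) {
      prevM <- if (k > 1) VM[i, k - 1] + lt$lMM[k] else lt$lMM[1]  # k=1: from B
      prevI <- VI[i, k] + lt$lIM[k]
      prevD <- if (k > 1) VD[i, k - 1] + lt$lDM[k] else NEG
      cand <- c(prevM, prevI, prevD)
      w <- which.max(cand)
      VM[i + 1, k] <- cand[w] + ei[k]
      SM[i + 1, k] <- if (k == 1 && w == 1) i else
        switch(w, SM[i, k - 1], SI[i, k], SD[i, k - 1])
      if (is.na(SM[i + 1, k])) SM[i + 1, k] <- i  # predecessor consumed nothing
    }
    # I_k, k>=1
    for (k in seq_len(K)) {
      cand <- c(VM[i, k] + lt$lMI[k + 1], VI[i, k + 1] + lt$lII[k + 1])
      w <- which.max(cand)
      VI[i + 1, k + 1] <- cand[w]
      SI[i + 1, k + 1] <- if (w == 1) SM[i, k] else SI[i, k + 1]
      if (is.na(SI[i + 1, k + 1]) && is.finite(VI[i + 1, k + 1]))
        SI[i + 1, k + 1] <- i
    }
    # D_k at this i (consume nothing): from M_{k-1}/D_{k-1} at same i, or entry chain
    VD[i + 1, 1] <- lt$lMD[1]  # from B after i flank residues
    SD[i + 1, 1] <- NA_integer_
    for (k in seq_len(K)[-1]) {
      cand <- c(VM[i + 1, k - 1] + lt$lMD[k], VD[i + 1, k - 1] + lt$lDD[k])
      w <- which.max(cand)
      VD[i + 1, k] <- cand[w]
      SD[i + 1, k] <- if (w == 1) SM[i + 1, k - 1] else SD[i + 1, k - 1]
    }
    e <- ex_end(i)
    w <- which.max(e)
    if (e[w] > best) {
      best <- e[w]
      best_start <- switch(w, SM[i + 1, K], SI[i + 1, K + 1], SD[i + 1, K])
      best_end <- i
    }
  }
  if (is.na(best_start)) { best_start <- 0L; best_end <- 0L }
  list(bit_score = best, start = as.integer(best_start),
       end = as.integer(best_end))
}

# score-only Viterbi (no span traceback), vectorized over match states;
# the delete-chain maximum is folded in with a cummax over entry points
viterbi_score <- function(model, seq, lt = hmm_log_tables(model)) {
  x <- strsplit(unname(seq), "", fixed = TRUE)[[1]]
  x[!x %in% AA20] <- "X"
  L <- length(x); K <- model$K
  S <- cumsum(c(0, if (K > 1) lt$lDD[2:K] else NULL))  # S[k] = sum lDD[2..k]
  VM <- rep(-Inf, K)
  VI <- rep(-Inf, K + 1)
  VD <- S + cummax(c(lt$lMD[1], if (K > 1)
    rep(-Inf, K - 1) else NULL) - c(0, S[seq_len(K - 1)]))
  exit <- function() max(VM[K] + lt$lMM[K + 1], VI[K + 1] + lt$lIM[K + 1],
                         VD[K] + lt$lDM[K + 1])
  best <- exit()
  idx <- seq_len(K - 1)
  for (i in seq_len(L)) {
    ei <- lt$lod[, x[i]]
    nVI0 <- max(lt$lMI[1], VI[1] + lt$lII[1])
    prevM <- c(lt$lMM[1], VM[idx] + lt$lMM[idx + 1])
    prevI <- VI[seq_len(K)] + lt$lIM[seq_len(K)]
    prevD <- c(-Inf, VD[idx] + lt$lDM[idx + 1])
    nVM <- pmax(prevM, prevI, prevD) + ei
    nVIk <- pmax(VM + lt$lMI[2:(K + 1)], VI[2:(K + 1)] + lt$lII[2:(K + 1)])
    G <- c(lt$lMD[1], nVM[idx] + lt$lMD[idx + 1] - S[idx + 1])
    VD <- S + cummax(G)
    VM <- nVM
    VI <- c(nVI0, nVIk)
    best <- max(best, exit())
  }
  best
}

log2sumexp <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) return(-Inf)
  m <- max(v)
  m + log2(sum(2^(v - m)))
}

#' @rdname viterbi_local
#' @export
forward_local <- function(model, seq) {
  lt <- hmm_log_tables(model)
  x <- strsplit(unname(seq), "", fixed = TRUE)[[1]]
  x[!x %in% AA20] <- "X"
  L <- length(x); K <- model$K
  NEG <- -Inf
  FM <- matrix(NEG, L + 1, K)
  FI <- matrix(NEG, L + 1, K + 1)
  FD <- matrix(NEG, L + 1, K)
  FD[1, 1] <- lt$lMD[1]
  if (K > 1) for (k in 2:K) FD[1, k] <- FD[1, k - 1] + lt$lDD[k]
  ends <- rep(NEG, L + 1)
  exit_at <- function(row) log2sumexp(c(FM[row, K] + lt$lMM[K + 1],
                                        FI[row, K + 1] + lt$lIM[K + 1],
                                        FD[row, K] + lt$lDM[K + 1]))
  ends[1] <- exit_at(1)
  for (i in seq_len(L)) {
    ei <- lt$lod[, x[i]]
    FI[i + 1, 1] <- log2sumexp(c(lt$lMI[1], FI[i, 1] + lt$lII[1]))
    for (k in seq_len(K)) {
      prevM <- if (k > 1) FM[i, k - 1] + lt$lMM[k] else lt$lMM[1]
      prevI <- FI[i, k] + lt$lIM[k]
      prevD <- if (k > 1) FD[i, k - 1] + lt$lDM[k] else NEG
      FM[i + 1, k] <- log2sumexp(c(prevM, prevI, prevD)) + ei[k]
    }
    for (k in seq_len(K))
      FI[i + 1, k + 1] <- log2sumexp(c(FM[i, k] + lt$lMI[k + 1],
                                       FI[i, k + 1] + lt$lII[k + 1]))
    FD[i + 1, 1] <- lt$lMD[1]
    for (k in seq_len(K)[-1])
      FD[i + 1, k] <- log2sumexp(c(FM[i + 1, k - 1] + lt$lMD[k],
                                   FD[i + 1, k - 1] + lt$lDD[k]))
    ends[i + 1] <- exit_at(i + 1)
  }
  log2sumexp(ends)
}

#' Fit a Gumbel (type-I extreme value) law by maximum likelihood
#'
#' @param x Numeric scores, length >= 2, non-degenerate.
#' @return List with `mu` (location) and `lambda` (inverse scale).
#' @export
fit_gumbel <- function(x) {
  if (length(x) < 2 || stats::sd(x) < 1e-12)
    stop("degenerate score distribution: cannot fit Gumbel")
  xbar <- mean(x)
  f <- function(lam) {
    w <- exp(-lam * (x - xbar))  # shift for numeric stability
    xbar - sum(x * w) / sum(w) - 1 / lam
  }
  lam0 <- pi / (stats::sd(x) * sqrt(6))  # moment start
  lo <- lam0 / 50; hi <- lam0 * 50
  lambda <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  mu <- -log(mean(exp(-lambda * (x - xbar)))) / lambda + xbar
  list(mu = mu, lambda = lambda)
}

#' Calibrate a profile HMM's E-values by random-sequence simulation
#'
#' Scores `n_random` i.i.d. background sequences of length `len_random`
#' with [viterbi_local()] and fits a Gumbel law to the scores. The E-value
#' of a score `s` against a database of `N` sequences is then
#' `N * P(S >= s)` under the fitted null.
#'
#' @param model A `profile_hmm`.
#' @param n_random Number of random sequences (>= 100).
#' @param len_random Length of each random sequence.
#' @param seed Integer seed fixing the simulation.
#' @return The model with a `calibration` element
#'   (`mu`, `lambda`, `n_random`, `len_random`, `seed`).
#' @export
calibrate_evalue <- function(model, n_random = 1000L, len_random = 400L,
                             seed = 1L) {
  stopifnot(inherits(model, "profile_hmm"))
  if (n_random < 100) stop("n_random must be >= 100")
  rng <- local({ set.seed(seed)
    matrix(sample(AA20, n_random * len_random, replace = TRUE,
                  prob = model$background), n_random) })
  lt <- hmm_log_tables(model)
  scores <- apply(rng, 1, function(ch)
    viterbi_score(model, paste(ch, collapse = ""), lt = lt))
  fit <- fit_gumbel(scores)
  model$calibration <- list(mu = fit$mu, lambda = fit$lambda,
                            n_random = as.integer(n_random),
                            len_random = as.integer(len_random),
                            seed = as.integer(seed))
  model
}

#' @rdname calibrate_evalue
#' @param bit_score Viterbi bit score(s).
#' @param db_size Number of sequences in the searched database.
#' @export
hit_evalue <- function(model, bit_score, db_size) {
  cal <- model$calibration
  if (is.null(cal)) stop("model '", model$motif_id, "' is not calibrated")
  p <- -expm1(-exp(-cal$lambda * (bit_score - cal$mu)))  # P(S >= s)
  db_size * p
}

#' Screen a proteome with a set of motif HMMs
#'
#' A protein is kept when at least one motif matches it with E-value at or
#' below `evalue_max` (the at-least-one-motif inclusion rule); kept entries
#' carry the full protein sequence, never the matched fragment.
#'
#' @param models List of calibrated `profile_hmm` objects.
#' @param proteome Named character vector of protein sequences.
#' @param evalue_max E-value cut-off (default `1e-3`).
#' @return A `screen_result`: `hits` (data.frame of best hit per
#'   sequence/motif: seq_id, motif_id, bit_score, evalue, start, end),
#'   `flags` (logical matrix sequence x motif of per-motif passes),
#'   `kept_ids`, `kept` (full sequences), `evalue_max`.
#' @export
screen_proteome <- function(models, proteome, evalue_max = 1e-3) {
  if (length(models) == 0) stop("empty model list")
  if (inherits(models, "profile_hmm")) models <- list(models)
  motif_ids <- vapply(models, `[[`, character(1), "motif_id")
  if (length(proteome) == 0) {
    return(structure(list(
      hits = data.frame(seq_id = character(0), motif_id = character(0),
                        bit_score = numeric(0), evalue = numeric(0),
                        start = integer(0), end = integer(0)),
      flags = matrix(logical(0), 0, length(models),
                     dimnames = list(NULL, motif_ids)),
      kept_ids = character(0), kept = setNames(character(0), character(0)),
      evalue_max = evalue_max), class = "screen_result"))
  }
  validate_protein_seqs(proteome)
  N <- length(proteome)
  rows <- vector("list", N * length(models)); ri <- 0L
  flags <- matrix(FALSE, N, length(models),
                  dimnames = list(names(proteome), motif_ids))
  for (m in seq_along(models)) {
    for (s in seq_len(N)) {
      v <- viterbi_local(models[[m]], proteome[[s]])
      ev <- hit_evalue(models[[m]], v$bit_score, N)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(seq_id = names(proteome)[s],
                               motif_id = motif_ids[m],
                               bit_score = v$bit_score, evalue = ev,
                               start = v$start, end = v$end,
                               stringsAsFactors = FALSE)
      flags[s, m] <- ev <= evalue_max
    }
  }
  hits <- do.call(rbind, rows)
  keep <- rowSums(flags) > 0
  structure(list(hits = hits[order(hits$seq_id, hits$evalue), ],
                 flags = flags,
                 kept_ids = names(proteome)[keep],
                 kept = proteome[keep],
                 evalue_max = evalue_max),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", length(x$kept_ids), "of", nrow(x$flags),
      "proteins kept at E <=", format(x$evalue_max), "\n")
  invisible(x)
}

#' @rdname screen_proteome
#' @param result A `screen_result`.
#' @param path Output TSV path.
#' @export
write_hits_tsv <- function(result, path) {
  write.table(result$hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
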