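# Independent oracles used to cross-check the package implementations.
# Each one recomputes the quantity from first principles (enumeration or
# textbook dynamic programming) without touching the implementation path.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# --- exhaustive enumeration of all legal local HMM paths ---------------
# A path enters the model at position 0 (after any number of free flank
# residues), walks match/insert/delete states, exits after position K, and
# consumes a contiguous window of the target. Viterbi = max path score,
# forward = log2 sum over paths.
brute_hmm_paths <- function(model, seq) {
  lt <- phyloscreen:::hmm_log_tables(model)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  x[!x %in% AA] <- "X"
  L <- length(x); K <- model$K
  scores <- c()
  rec <- function(state, k, pos, acc, t_end) {
    row <- k + 1
    if (k == K) {
      exit_cost <- switch(state, M = lt$lMM[row], I = lt$lIM[row],
                          D = lt$lDM[row])
      if (pos > t_end && is.finite(exit_cost))
        scores <<- c(scores, acc + exit_cost)
    }
    if (k < K && pos <= t_end) {
      cost <- switch(state, M = lt$lMM[row], I = lt$lIM[row],
                     D = lt$lDM[row])
      if (is.finite(cost))
        rec("M", k + 1, pos + 1, acc + cost + lt$lod[k + 1, x[pos]], t_end)
    }
    if (pos <= t_end) {
      cost <- switch(state, M = lt$lMI[row], I = lt$lII[row], D = -Inf)
      if (is.finite(cost)) rec("I", k, pos + 1, acc + cost, t_end)
    }
    if (k < K && state != "I") {
      cost <- switch(state, M = lt$lMD[row], D = lt$lDD[row])
      if (is.finite(cost)) rec("D", k + 1, pos, acc + cost, t_end)
    }
  }
  for (s in 0:L) for (t in s:L) rec("M", 0, s + 1, 0, t)
  list(viterbi = max(scores), forward = phyloscreen:::log2sumexp(scores))
}

# --- independent affine-gap Needleman-Wunsch with percent identity -----
# Gotoh three-matrix recursion written directly from the textbook; returns
# identity over all alignment columns (X never identical).
nw_identity_oracle <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  subst <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) Y[1, j + 1] <- -gap_open - gap_extend * (j - 1)
  for (i in seq_len(n)) X[i + 1, 1] <- -gap_open - gap_extend * (i - 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- subst[x[i], y[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open,
                           X[i, j + 1] - gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open,
                           Y[i + 1, j] - gap_extend)
  }
  # traceback for identity
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  ident <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (state == 1) {
      if (x[i] == y[j] && x[i] != "X") ident <- ident + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2) {
      from_open <- abs(X[i + 1, j + 1] - (M[i, j + 1] - gap_open)) < 1e-9
      i <- i - 1
      state <- if (from_open) 1 else 2
      if (i == 0 && j == 0) break
    } else {
      from_open <- abs(Y[i + 1, j + 1] - (M[i + 1, j] - gap_open)) < 1e-9
      j <- j - 1
      state <- if (from_open) 1 else 3
      if (i == 0 && j == 0) break
    }
    if (i == 0 && j == 0) break
    if (i == 0 && state == 1) state <- 3
    if (j == 0 && state == 1) state <- 2
  }
  list(score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]),
       identity = 100 * ident / cols)
}

# --- exhaustive duplication-loss reconciliation cost -------------------
# Enumerates every valid gene-node -> species-node map (each internal gene
# node mapped to an ancestor of its children's images) and scores it under
# the standard duplication-loss event rules; returns the minimum cost and
# the (D, L) achieving it.
reconcile_oracle <- function(gene, species, map) {
  nt_g <- length(gene$tip.label)
  nt_s <- length(species$tip.label)
  gkids <- phyloscreen:::tree_children(gene)
  skids <- phyloscreen:::tree_children(species)
  spar <- phyloscreen:::tree_parent(species)
  sdepth <- phyloscreen:::node_depths(species)
  ancestors <- function(v) {
    out <- v
    while (!is.na(spar[v])) { v <- spar[v]; out <- c(out, v) }
    out
  }
  is_anc <- function(a, d) a %in% ancestors(d)  # a ancestor-or-equal of d
  n_nodes_g <- nt_g + gene$Nnode
  leaf_map <- integer(n_nodes_g)
  for (v in seq_len(nt_g)) leaf_map[v] <- match(map[[gene$tip.label[v]]],
                                                species$tip.label)
  internal <- (nt_g + 1):n_nodes_g
  best <- list(cost = Inf, D = NA, L = NA)
  assign_next <- function(idx, M) {
    if (idx > length(internal)) {
      D <- 0L; L <- 0L
      for (v in internal) {
        ch <- gkids[[v]]
        sides <- skids[[M[v]]]
        on_distinct <- length(ch) == 2 && M[v] != M[ch[1]] &&
          M[v] != M[ch[2]] && length(sides) == 2 &&
          is_anc(sides[1], M[ch[1]]) != is_anc(sides[1], M[ch[2]])
        dup <- !on_distinct
        if (dup) D <- D + 1L
        for (c1 in ch)
          L <- L + (sdepth[M[c1]] - sdepth[M[v]] - 1L + as.integer(dup))
      }
      cost <- D + L
      if (cost < best$cost) best <<- list(cost = cost, D = D, L = L)
      return(invisible())
    }
    v <- internal[idx]
    ch_imgs <- sapply(gkids[[v]], function(c1) M[c1])
    lca <- ch_imgs[1]
    for (c2 in ch_imgs[-1])
      lca <- { a <- lca; b <- c2
        while (a != b) if (sdepth[a] < sdepth[b]) b <- spar[b] else a <- spar[a]
        a }
    for (cand in ancestors(lca)) {
      M[v] <- cand
      assign_next(idx + 1, M)
    }
  }
  # process internal nodes leaves-up so children are mapped first
  internal <- rev(phyloscreen:::node_preorder(gene))
  internal <- internal[internal > nt_g]
  M0 <- leaf_map
  assign_next(1, M0)
  best
}

# Jaccard overlap of a called interval set against a truth interval
best_jaccard <- function(truth_start, truth_end, calls) {
  if (!nrow(calls)) return(0)
  best <- 0
  for (j in seq_len(nrow(calls))) {
    a <- max(truth_start, calls$start_col[j])
    z <- min(truth_end, calls$end_col[j])
    inter <- max(0, z - a + 1)
    uni <- (truth_end - truth_start + 1) +
      (calls$end_col[j] - calls$start_col[j] + 1) - inter
    best <- max(best, inter / uni)
  }
  best
}

# deterministic random protein string
random_protein <- function(L, prob = NULL) {
  paste(sample(AA, L, replace = TRUE, prob = prob), collapse = "")
}
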