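#' Identity-based grouping and alignment diagnostics
#'
#' The family structure is recovered by UPGMA clustering on pairwise
#' identity distances (distance = 100 - percent identity). Helper
#' operations select robust alignment blocks, summarize within- and
#' between-group identities, attach bootstrap support to the clustering and
#' segment an alignment into alternating conservation zones.
#'
#' @name grouping
NULL

# column-wise percent identity for two gapped rows (character vectors)
aligned_identity <- function(ra, rb) {
  shared <- !(ra == GAP & rb == GAP)
  if (!any(shared)) return(NA_real_)
  ra <- ra[shared]; rb <- rb[shared]
  100 * sum(ra == rb & ra != GAP & ra != "X") / length(ra)
}

#' Pairwise identity distance matrix
#'
#' Distance is `100 - percent identity`. For a [protein_msa()] the identity
#' is computed column-wise over columns not gapped in both rows; for
#' unaligned sequences each pair is globally aligned ([global_identity()]).
#'
#' @param x A `protein_msa` or a named character vector of sequences.
#' @inheritParams global_identity
#' @return Symmetric numeric matrix with zero diagonal and id dimnames.
#' @export
identity_distance_matrix <- function(x, scoring = default_scoring()) {
  if (inherits(x, "protein_msa")) {
    m <- unclass(x); ids <- rownames(m); n <- nrow(m)
    stopifnot(n >= 2)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- 100 - aligned_identity(m[i, ], m[j, ])
  } else {
    stopifnot(length(x) >= 2)
    ids <- names(x); n <- length(x)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- 100 - global_identity(x[[i]], x[[j]], scoring)
  }
  D
}

#' UPGMA clustering of a distance matrix
#'
#' Standard size-weighted average-linkage agglomeration; the pair with the
#' smallest distance is merged at height `d/2`, ties broken deterministically
#' by the lowest cluster-index pair. The result is ultrametric by
#' construction.
#'
#' @param D Symmetric distance matrix with id dimnames (see
#'   [identity_distance_matrix()]).
#' @return A rooted ultrametric `phylo`; `attr(, "merge_heights")` records
#'   the successive merge heights.
#' @examples
#' D <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' upgma(D)
#' @export
upgma <- function(D) {
  D <- as.matrix(D)
  ids <- rownames(D)
  n <- nrow(D)
  stopifnot(n >= 2, !is.null(ids),
            max(abs(D - t(D))) < 1e-12, all(diag(D) == 0))
  # clusters indexed by creation order; active set shrinks as we merge
  nwk <- ids; height <- rep(0, n); size <- rep(1, n)
  M <- matrix(NA_real_, 2 * n - 1, 2 * n - 1)
  M[1:n, 1:n] <- D
  active <- seq_len(n)
  merge_heights <- numeric(0)
  nxt <- n
  while (length(active) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(active)[-length(active)])
      for (b in (a + 1):length(active)) {
        i <- active[a]; j <- active[b]
        if (M[i, j] < bd) { bd <- M[i, j]; best <- c(i, j) }  # strict: lowest index wins ties
      }
    i <- best[1]; j <- best[2]
    h <- bd / 2
    nxt <- nxt + 1
    nwk[nxt] <- paste0("(", nwk[i], ":", format(h - height[i], digits = 12),
                       ",", nwk[j], ":", format(h - height[j], digits = 12), ")")
    height[nxt] <- h; size[nxt] <- size[i] + size[j]
    merge_heights <- c(merge_heights, h)
    others <- setdiff(active, c(i, j))
    for (k in others)
      M[nxt, k] <- M[k, nxt] <- (size[i] * M[i, k] + size[j] * M[j, k]) /
        (size[i] + size[j])
    active <- c(others, nxt)
  }
  phy <- ape::read.tree(text = paste0(nwk[nxt], ";"))
  attr(phy, "merge_heights") <- merge_heights
  phy
}

# per-column conservation: modal residue fraction (gaps never the mode)
column_conservation <- function(aln) {
  m <- unclass(aln)
  apply(m, 2, function(col) {
    col <- col[col != GAP]
    if (!length(col)) return(0)
    max(table(col)) / nrow(m)
  })
}

#' Select robust alignment blocks
#'
#' A transparent two-rule surrogate for robust-region selection: a column is
#' good when its modal-residue fraction is at least `min_ident_frac` and its
#' gap fraction is at most `max_gap_frac`; blocks are maximal runs of good
#' columns of length at least `min_block_len`.
#'
#' @param aln A [protein_msa()].
#' @param min_ident_frac Minimum modal-residue fraction (default 0.5).
#' @param min_block_len Minimum block length in columns (default 5).
#' @param max_gap_frac Maximum column gap fraction (default 0.5).
#' @return data.frame `start_col`, `end_col` (1-based inclusive, sorted,
#'   non-overlapping).
#' @export
conserved_blocks <- function(aln, min_ident_frac = 0.5, min_block_len = 5L,
                             max_gap_frac = 0.5) {
  stopifnot(inherits(aln, "protein_msa"))
  cons <- column_conservation(aln)
  gapf <- colMeans(unclass(aln) == GAP)
  good <- cons >= min_ident_frac & gapf <= max_gap_frac
  r <- rle(good)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_block_len
  data.frame(start_col = starts[keep], end_col = ends[keep])
}

#' Within- and between-group pairwise identity statistics
#'
#' Mean, population SD, min and max of pairwise identities within each group
#' (all unordered member pairs) and between each group pair (all cross
#' pairs).
#'
#' @param x A `protein_msa` or named character vector of sequences.
#' @param groups Named character vector: group label per sequence id.
#' @inheritParams global_identity
#' @return data.frame `group_a`, `group_b`, `type` (within/between),
#'   `n_pairs`, `mean`, `sd`, `min`, `max`; singleton groups get `NA`
#'   within-group stats with `n_pairs = 0`.
#' @export
group_identity_stats <- function(x, groups, scoring = default_scoring()) {
  D <- identity_distance_matrix(x, scoring)
  idm <- 100 - D
  ids <- rownames(idm)
  stopifnot(all(ids %in% names(groups)))
  g <- groups[ids]
  labs <- unique(unname(g))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- list()
  for (a in seq_along(labs)) {
    ia <- which(g == labs[a])
    vals <- if (length(ia) >= 2) idm[ia, ia][upper.tri(idm[ia, ia])] else numeric(0)
    out[[length(out) + 1]] <- data.frame(
      group_a = labs[a], group_b = labs[a], type = "within",
      n_pairs = length(vals),
      mean = if (length(vals)) mean(vals) else NA_real_,
      sd = if (length(vals)) pop_sd(vals) else NA_real_,
      min = if (length(vals)) min(vals) else NA_real_,
      max = if (length(vals)) max(vals) else NA_real_)
    if (a < length(labs)) for (b in (a + 1):length(labs)) {
      ib <- which(g == labs[b])
      vals <- as.vector(idm[ia, ib, drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        group_a = labs[a], group_b = labs[b], type = "between",
        n_pairs = length(vals), mean = mean(vals), sd = pop_sd(vals),
        min = min(vals), max = max(vals))
    }
  }
  do.call(rbind, out)
}

#' Column-bootstrap support for the UPGMA grouping
#'
#' Alignment columns are resampled with replacement `n_reps` times, the tree
#' builder is re-run on each replicate, and every internal node of the
#' reference tree is annotated with the fraction of replicates containing
#' its clade.
#'
#' @param aln A [protein_msa()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param builder Function `protein_msa -> phylo`; defaults to UPGMA on the
#'   column-wise identity distance.
#' @return The reference tree with `node.label` set to supports in `[0, 1]`.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, seed = 1L,
                              builder = function(a) upgma(identity_distance_matrix(a))) {
  stopifnot(inherits(aln, "protein_msa"), n_reps >= 1)
  ref <- builder(aln)
  m <- unclass(aln)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[r]] <- builder(protein_msa(m[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(ref, reps, rooted = TRUE)
  counts[is.na(counts)] <- 0
  ref$node.label <- counts / n_reps
  ref
}

#' Segment an alignment into alternating conservation zones
#'
#' Per-column conservation (modal-residue fraction) is smoothed with a
#' centered moving average of width `window` (shrunk at the edges); zones
#' are maximal runs at or above (`high`) versus below (`low`) `threshold`.
#'
#' @param aln A [protein_msa()].
#' @param window Odd smoothing width in columns (default 11).
#' @param threshold Conservation level separating high from low zones.
#' @param columns Optional 1-based column interval `c(from, to)` restricting
#'   the analysis (e.g. a C-terminal region).
#' @return data.frame `zone`, `start_col`, `end_col`, `label`
#'   (high/low, strictly alternating), `mean_identity` (mean raw
#'   conservation within the zone, percent).
#' @export
conservation_zones <- function(aln, window = 11L, threshold = 0.3,
                               columns = NULL) {
  stopifnot(inherits(aln, "protein_msa"), window >= 1)
  cons <- column_conservation(aln)
  if (!is.null(columns)) cons <- cons[columns[1]:columns[2]]
  nc <- length(cons)
  half <- window %/% 2
  sm <- vapply(seq_len(nc), function(i)
    mean(cons[max(1, i - half):min(nc, i + half)]), numeric(1))
  lab <- ifelse(sm >= threshold, "high", "low")
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  off <- if (is.null(columns)) 0L else columns[1] - 1L
  data.frame(zone = seq_along(r$values),
             start_col = starts + off, end_col = ends + off,
             label = r$values,
             mean_identity = vapply(seq_along(starts), function(k)
               100 * mean(cons[starts[k]:ends[k]]), numeric(1)))
}
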