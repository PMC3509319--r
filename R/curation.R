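#' Semi-automatic curation of screened candidates
#'
#' Screened candidates are curated by exhaustive pairwise comparison: all
#' n(n-1)/2 candidate pairs are globally aligned and scored as percent
#' identity; pairs above the high cut-off (default 97, effectively identical
#' sequences) collapse to a single representative, pairs below the low
#' cut-off (default 20) contribute no edge, and the remaining pairs fragment
#' the candidates into connected-component groups. The group most similar
#' to a set of reference channels is selected for downstream analysis.
#'
#' @name curation
NULL

default_scoring <- function() {
  list(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5)
}

#' Percent identity of the global alignment of two proteins
#'
#' Needleman-Wunsch global alignment under a substitution matrix with affine
#' gap penalties; identity is `100 * identical residue pairs / alignment
#' columns` (no column of a pairwise alignment is gapped in both rows).
#' `X` never counts as identical.
#'
#' @param a,b Residue strings.
#' @param scoring List with `matrix` (substitution matrix name), `gap_open`,
#'   `gap_extend`; defaults BLOSUM62 / 10 / 0.5.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' global_identity("MKVLA", "MKVLA")
#' @export
global_identity <- function(a, b, scoring = default_scoring()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(unname(a)), Biostrings::AAString(unname(b)),
    type = "global",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ident <- pa == pb & pa != "-" & pa != "X"
  100 * sum(ident) / length(pa)
}

#' All-pairs identity table for a candidate set
#'
#' @param seqs Named character vector (>= 2 sequences).
#' @inheritParams global_identity
#' @return data.frame `id_a`, `id_b`, `identity` over all unordered pairs in
#'   input order (`n(n-1)/2` rows).
#' @export
pair_identities <- function(seqs, scoring = default_scoring()) {
  n <- length(seqs)
  stopifnot(n >= 2)
  ids <- names(seqs)
  out <- vector("list", n * (n - 1) / 2); k <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + 1L
    out[[k]] <- data.frame(id_a = ids[i], id_b = ids[j],
                           identity = global_identity(seqs[[i]], seqs[[j]],
                                                      scoring),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# connected components by union-find; returns integer component id per vertex
components_of <- function(vertices, edge_a, edge_b) {
  parent <- seq_along(vertices)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ia <- match(edge_a, vertices); ib <- match(edge_b, vertices)
  for (e in seq_along(ia)) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(vertices), find, integer(1))
  match(roots, unique(roots))
}

#' Curate screened candidates into similarity groups and pick the
#' reference-anchored group
#'
#' @param candidates Named character vector of candidate proteins.
#' @param refs Named character vector of reference proteins (e.g. the five
#'   A. thaliana channels of the family under study).
#' @param low,high Identity cut-offs: pairs `< low` contribute no edge,
#'   pairs `> high` collapse the later candidate as a duplicate of the
#'   earlier (first-by-input-order representative kept).
#' @inheritParams global_identity
#' @return A `curation_result`: `selected` (the chosen group), `groups`
#'   (list of member-id vectors), `group_scores` (aggregate reference
#'   similarity per group: mean over refs of the best member identity),
#'   `removed_as_duplicate`, `pair_table`, `edges`.
#' @export
curate <- function(candidates, refs, low = 20, high = 97,
                   scoring = default_scoring()) {
  stopifnot(length(candidates) >= 1, length(refs) >= 1)
  validate_protein_seqs(candidates); validate_protein_seqs(refs)
  ids <- names(candidates)
  if (length(candidates) == 1) {
    pairs <- data.frame(id_a = character(0), id_b = character(0),
                        identity = numeric(0))
  } else {
    pairs <- pair_identities(candidates, scoring)
  }
  # duplicate collapse, deterministic by input order
  removed <- setNames(rep(FALSE, length(ids)), ids)
  for (r in seq_len(nrow(pairs))) {
    if (pairs$identity[r] > high &&
        !removed[pairs$id_a[r]] && !removed[pairs$id_b[r]])
      removed[pairs$id_b[r]] <- TRUE
  }
  alive <- ids[!removed]
  if (length(alive) == 0) stop("all candidates collapsed away as duplicates")
  keep_edge <- !removed[pairs$id_a] & !removed[pairs$id_b] &
    pairs$identity >= low & pairs$identity <= high
  edges <- pairs[keep_edge, , drop = FALSE]
  comp <- components_of(alive, edges$id_a, edges$id_b)
  groups <- split(alive, comp)
  names(groups) <- paste0("group", seq_along(groups))
  # aggregate reference similarity: mean over refs of best member identity
  ref_scores <- lapply(groups, function(members) {
    vapply(refs, function(rf)
      max(vapply(members, function(m)
        global_identity(candidates[[m]], rf, scoring), numeric(1))),
      numeric(1))
  })
  agg <- vapply(ref_scores, mean, numeric(1))
  sel <- which.max(agg)
  structure(list(selected = groups[[sel]],
                 selected_group = names(groups)[sel],
                 groups = groups,
                 group_scores = agg,
                 per_ref_scores = ref_scores,
                 removed_as_duplicate = ids[removed],
                 pair_table = pairs,
                 edges = edges,
                 low = low, high = high),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("curation_result:", length(x$groups), "group(s);",
      length(x$removed_as_duplicate), "duplicate(s) removed; selected ",
      x$selected_group, " (", length(x$selected), " members, ref score ",
      round(x$group_scores[x$selected_group], 1), ")\n", sep = "")
  invisible(x)
}

#' @rdname curate
#' @param result A `curation_result`.
#' @param path Output TSV path (`group_id`, `member_id`, `selected_flag`).
#' @export
write_group_report <- function(result, path) {
  df <- do.call(rbind, lapply(names(result$groups), function(g)
    data.frame(group_id = g, member_id = result$groups[[g]],
               selected_flag = g == result$selected_group)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check a candidate for completeness against gold-standard references
#'
#' The candidate is aligned to the analysis region of its best-matching
#' reference (global in the region, local in the candidate); it is flagged
#' incomplete when more than `max_missing_frac` of the reference region
#' aligns to gaps — the signature of an internal deletion or truncation such
#' as those produced by wrongly predicted splice sites.
#'
#' @param candidate Single residue string (named).
#' @param reference_set Named character vector of reference proteins.
#' @param region_specs Optional named list of [region_spec()] keyed by
#'   reference id; defaults to the full reference sequence.
#' @param max_missing_frac Tolerated uncovered fraction of the reference
#'   region (default 0.1).
#' @inheritParams global_identity
#' @return List: `complete` (logical), `reference`, `missing_frac`,
#'   `region_length`.
#' @export
completeness_check <- function(candidate, reference_set, region_specs = NULL,
                               max_missing_frac = 0.1,
                               scoring = default_scoring()) {
  stopifnot(length(candidate) == 1, length(reference_set) >= 1)
  idents <- vapply(reference_set, function(rf)
    global_identity(candidate, rf, scoring), numeric(1))
  best <- names(reference_set)[which.max(idents)]
  refseq <- reference_set[[best]]
  if (!is.null(region_specs) && best %in% names(region_specs))
    refseq <- unname(extract_region(setNames(refseq, best),
                                    region_specs[[best]]))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(refseq), Biostrings::AAString(unname(candidate)),
    type = "global-local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pr <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pc <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  uncovered <- sum(pr != "-" & pc == "-")
  missing_frac <- uncovered / nchar(refseq)
  list(complete = missing_frac <= max_missing_frac,
       reference = best,
       missing_frac = missing_frac,
       region_length = nchar(refseq))
}
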