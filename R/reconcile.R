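#' Gene-tree/species-tree reconciliation
#'
#' LCA (lowest-common-ancestor) reconciliation: every gene-tree node is
#' mapped to the species-tree node spanning the species of its descendant
#' leaves. An internal gene node is a duplication when it maps to the same
#' species node as one of its children; gene losses are implied on edges
#' that skip species-tree levels. Unrooted gene trees are rooted by
#' minimizing duplications + losses over all edge rootings.
#'
#' @name reconcile
NULL

species_label <- function(species, node, leafsets) {
  nt <- length(species$tip.label)
  if (node <= nt) return(species$tip.label[node])
  if (!is.null(species$node.label) && nzchar(species$node.label[node - nt]))
    return(species$node.label[node - nt])
  paste(leafsets[[node]], collapse = "|")
}

#' Reconcile a rooted gene tree with a binary rooted species tree
#'
#' @param gene Rooted `phylo` gene tree.
#' @param species Rooted binary `phylo` species tree.
#' @param map Named character vector: species leaf label per gene leaf label.
#' @return A `reconciliation`: `node_map` (species node per gene node),
#'   `duplication_nodes` (internal gene node ids), `n_duplications`,
#'   `loss_count`, `edge_losses` (data.frame with per-edge loss counts),
#'   plus the input trees and map.
#' @examples
#' g <- read_newick("((A_1,B_1),(A_2,B_2));")
#' s <- read_newick("(A,B);")
#' lca_reconcile(g, s, c(A_1 = "A", B_1 = "B", A_2 = "A", B_2 = "B"))
#' @export
lca_reconcile <- function(gene, species, map) {
  stopifnot(inherits(gene, "phylo"), inherits(species, "phylo"))
  skids <- tree_children(species)
  nt_s <- length(species$tip.label)
  if (any(lengths(skids[(nt_s + 1):(nt_s + species$Nnode)]) != 2))
    stop("species tree must be binary")
  missing <- setdiff(gene$tip.label, names(map))
  if (length(missing))
    stop("unmapped gene leaf/leaves: ", paste(missing, collapse = ", "))
  bad <- setdiff(unname(map[gene$tip.label]), species$tip.label)
  if (length(bad))
    stop("species not in species tree: ", paste(bad, collapse = ", "))

  sdepth <- node_depths(species)
  spar <- tree_parent(species)
  s_lca <- function(a, b) {
    while (a != b) {
      if (sdepth[a] < sdepth[b]) b <- spar[b] else a <- spar[a]
    }
    a
  }
  nt_g <- length(gene$tip.label)
  gkids <- tree_children(gene)
  if (any(lengths(gkids[(nt_g + 1):(nt_g + gene$Nnode)]) > 2))
    stop("gene tree contains a polytomy; resolve it before reconciling")
  M <- integer(nt_g + gene$Nnode)
  for (v in rev(node_preorder(gene))) {
    if (v <= nt_g) {
      M[v] <- match(map[[gene$tip.label[v]]], species$tip.label)
    } else {
      ch <- gkids[[v]]
      m <- M[ch[1]]
      for (c2 in ch[-1]) m <- s_lca(m, M[c2])
      M[v] <- m
    }
  }
  dup <- integer(0)
  for (v in (nt_g + 1):(nt_g + gene$Nnode))
    if (any(M[gkids[[v]]] == M[v])) dup <- c(dup, v)

  is_dup <- rep(FALSE, nt_g + gene$Nnode)
  is_dup[dup] <- TRUE
  el <- data.frame(gene_parent = gene$edge[, 1], gene_child = gene$edge[, 2],
                   losses = 0L)
  for (e in seq_len(nrow(el))) {
    v <- el$gene_parent[e]; c1 <- el$gene_child[e]
    el$losses[e] <- sdepth[M[c1]] - sdepth[M[v]] - 1L + as.integer(is_dup[v])
  }
  structure(list(node_map = M,
                 duplication_nodes = dup,
                 n_duplications = length(dup),
                 loss_count = sum(el$losses),
                 edge_losses = el,
                 gene = gene, species = species, map = map),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("reconciliation:", x$n_duplications, "duplication(s),",
      x$loss_count, "loss(es)\n")
  invisible(x)
}

# topology-only canonical string (branch lengths stripped)
topo_string <- function(phy) {
  phy$edge.length <- NULL
  phy$node.label <- NULL
  write_newick(phy)
}

#' Root an unrooted gene tree by duplication-loss minimization
#'
#' Every edge of the unrooted gene tree is evaluated as a root position and
#' the rooting(s) with the smallest duplication + loss cost are returned
#' (all co-optima, ordered by their canonical Newick string).
#'
#' @param gene_unrooted Unrooted `phylo` with >= 3 leaves.
#' @inheritParams lca_reconcile
#' @return List: `rooted` (list of co-optimal rooted `phylo`),
#'   `reconciliation` (for the first co-optimum), `cost` (D + L),
#'   `edge_costs` (cost per evaluated rooting).
#' @export
root_min_dl <- function(gene_unrooted, species, map) {
  phy <- gene_unrooted
  stopifnot(inherits(phy, "phylo"), length(phy$tip.label) >= 3)
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  had_lengths <- !is.null(phy$edge.length)
  if (!had_lengths) phy$edge.length <- rep(1, nrow(phy$edge))
  cand <- list(); costs <- numeric(0)
  for (e in seq_len(nrow(phy$edge))) {
    rooted <- phytools::reroot(phy, phy$edge[e, 2],
                               position = phy$edge.length[e] / 2)
    rec <- lca_reconcile(rooted, species, map)
    cand[[e]] <- rooted
    costs[e] <- rec$n_duplications + rec$loss_count
  }
  best <- which(costs == min(costs))
  opts <- cand[best]
  if (!had_lengths) opts <- lapply(opts, function(p) { p$edge.length <- NULL; p })
  keys <- vapply(opts, topo_string, character(1))
  keep <- !duplicated(keys)
  opts <- opts[keep][order(keys[keep])]
  list(rooted = opts,
       reconciliation = lca_reconcile(opts[[1]], species, map),
       cost = min(costs),
       edge_costs = costs)
}

#' Tabulate the duplication history of a reconciliation
#'
#' Each duplication node is reported with the species-tree node where it
#' occurred and the two descendant leaf groups it separates; rows are
#' independent of the gene tree's child ordering.
#'
#' @param rec A [lca_reconcile()] result.
#' @return data.frame `gene_node`, `species_node`, `species_label`,
#'   `side_a`, `side_b` (comma-joined descendant gene leaves, the
#'   lexicographically smaller side first); zero rows when there are no
#'   duplications.
#' @export
annotate_duplication_history <- function(rec) {
  stopifnot(inherits(rec, "reconciliation"))
  gene <- rec$gene
  leafsets_g <- node_leafsets(gene)
  leafsets_s <- node_leafsets(rec$species)
  kids <- tree_children(gene)
  rows <- lapply(rec$duplication_nodes, function(v) {
    sides <- vapply(kids[[v]], function(c1)
      paste(leafsets_g[[c1]], collapse = ","), character(1))
    sides <- sort(sides)
    data.frame(gene_node = v,
               species_node = rec$node_map[v],
               species_label = species_label(rec$species, rec$node_map[v],
                                             leafsets_s),
               side_a = sides[1],
               side_b = paste(sides[-1], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene_node = integer(0), species_node = integer(0),
                      species_label = character(0), side_a = character(0),
                      side_b = character(0)))
  do.call(rbind, rows)
}

#' @rdname lca_reconcile
#' @param rec A `reconciliation`.
#' @param path Output TSV path (`node_id`, `mapped_species_node`,
#'   `is_duplication`, `losses_on_parent_edge`).
#' @export
write_reconciliation_tsv <- function(rec, path) {
  n <- length(rec$node_map)
  par_losses <- setNames(rep(0L, n), seq_len(n))
  par_losses[as.character(rec$edge_losses$gene_child)] <- rec$edge_losses$losses
  df <- data.frame(node_id = seq_len(n),
                   mapped_species_node = rec$node_map,
                   is_duplication = seq_len(n) %in% rec$duplication_nodes,
                   losses_on_parent_edge = unname(par_losses))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
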