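#' Newick tree input/output and rooted-tree helpers
#'
#' Trees are `ape` `phylo` objects throughout. `read_newick` accepts a
#' Newick string or a file path; `write_newick` emits a canonical form in
#' which the children of every node are ordered lexicographically by the
#' smallest leaf label below them, so equal topologies serialize to equal
#' strings.
#'
#' @name trees
NULL

#' @rdname trees
#' @param text A Newick string (terminal semicolon required) or the path of
#'   a file containing one.
#' @return `read_newick`: a `phylo`. `write_newick`: a Newick string.
#' @examples
#' tr <- read_newick("((a:1,b:2):0.5,c:1);")
#' write_newick(tr)
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl(";", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at offset ", i, ": unbalanced ')'")
    }
  }
  if (depth != 0L)
    stop("newick parse error at offset ", length(chars),
         ": ", depth, " unclosed '('")
  if (!grepl(";\\s*$", text))
    stop("newick parse error at offset ", nchar(text),
         ": missing terminal ';'")
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("newick parse error: unparseable string")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy
}

#' @rdname trees
#' @param phy A `phylo`.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(phy, digits = 10L) {
  stopifnot(inherits(phy, "phylo"))
  nt <- length(phy$tip.label)
  kids <- tree_children(phy)
  minlab <- character(nt + phy$Nnode)
  # smallest leaf label below each node, computed leaves-up
  ord <- rev(node_preorder(phy))
  for (v in ord) {
    minlab[v] <- if (v <= nt) phy$tip.label[v] else min(minlab[kids[[v]]])
  }
  elen <- phy$edge.length
  emap <- integer(nt + phy$Nnode)
  emap[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  fmt <- function(v) {
    lab <- if (v <= nt) {
      phy$tip.label[v]
    } else {
      ch <- kids[[v]]
      ch <- ch[order(minlab[ch])]
      inner <- paste(vapply(ch, fmt, character(1)), collapse = ",")
      nl <- if (!is.null(phy$node.label)) phy$node.label[v - nt] else ""
      if (is.na(nl)) nl <- ""
      paste0("(", inner, ")", nl)
    }
    if (!is.null(elen) && emap[v] > 0L)
      lab <- paste0(lab, ":", format(elen[emap[v]], digits = digits))
    lab
  }
  paste0(fmt(nt + 1L), ";")
}

# children of every node (index: node id; leaves have integer(0))
tree_children <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(n)) kids[[i]] <- integer(0)
  for (e in seq_len(nrow(phy$edge)))
    kids[[phy$edge[e, 1]]] <- c(kids[[phy$edge[e, 1]]], phy$edge[e, 2])
  kids
}

# parent of every node (root gets NA)
tree_parent <- function(phy) {
  n <- length(phy$tip.label) + phy$Nnode
  par <- rep(NA_integer_, n)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  par
}

# nodes in root-first (pre)order
node_preorder <- function(phy) {
  nt <- length(phy$tip.label)
  kids <- tree_children(phy)
  out <- integer(0)
  stack <- nt + 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, rev(kids[[v]]))
  }
  out
}

# depth of every node: root 0, increasing toward leaves
node_depths <- function(phy) {
  par <- tree_parent(phy)
  nt <- length(phy$tip.label)
  d <- rep(NA_real_, length(par))
  d[nt + 1L] <- 0
  for (v in node_preorder(phy)) if (v != nt + 1L) d[v] <- d[par[v]] + 1
  d
}

# set of tip labels below each node
node_leafsets <- function(phy) {
  nt <- length(phy$tip.label)
  kids <- tree_children(phy)
  sets <- vector("list", nt + phy$Nnode)
  for (v in rev(node_preorder(phy)))
    sets[[v]] <- if (v <= nt) phy$tip.label[v] else
      sort(unlist(sets[kids[[v]]], use.names = FALSE))
  sets
}
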