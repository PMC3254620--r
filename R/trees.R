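# Conversions between the engine's edge-matrix topologies and ape phylo
# objects, canonical newick serialization, and consensus trees.

# Canonical newick of an unrooted binary edge-matrix tree: rooted on the
# outgroup's pendant edge, outgroup emitted as the first child of the
# root, all other sibling subtrees sorted lexicographically by their
# serialized form. Identical topologies always serialize identically.
canonical_newick <- function(edges, labels, outgroup = labels[1]) {
  n <- length(labels)
  og <- match(outgroup, labels)
  if (is.na(og)) stop("outgroup '", outgroup, "' not among taxa")
  if (n == 1) return(paste0("(", labels[1], ");"))
  nn <- max(edges)
  adj <- vector("list", nn)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  quote_name <- function(x)
    if (grepl("[\\s(),;:]", x, perl = TRUE))
      paste0("'", gsub("'", "''", x), "'") else x
  sub <- function(v, parent) {
    if (v <= n) return(quote_name(labels[v]))
    kids <- setdiff(adj[[v]], parent)
    paste0("(", paste(sort(vapply(kids, sub, "", parent = v)),
                      collapse = ","), ")")
  }
  paste0("(", quote_name(labels[og]), ",", sub(adj[[og]][1], og), ");")
}

#' Extract the most-parsimonious trees as ape phylo objects
#'
#' Trees are rooted on the matrix outgroup for display (the search itself
#' is unrooted) and returned in canonical sort order.
#'
#' @param x a \code{"parsimony_result"}.
#' @return a \code{multiPhylo} list of \code{phylo} trees.
#' @export
mp_trees <- function(x) {
  stopifnot(inherits(x, "parsimony_result"))
  out <- lapply(x$trees, function(tr)
    ape::read.tree(text = canonical_newick(tr, x$cm$taxa, x$cm$outgroup)))
  class(out) <- "multiPhylo"
  out
}

#' Serialize a tree as newick text
#'
#' @param tree a \code{phylo} object.
#' @param file optional path.
#' @return the newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

# ape phylo -> engine edge matrix with tips numbered by `taxa` order.
phylo_to_edges <- function(phy, taxa) {
  stopifnot(inherits(phy, "phylo"))
  if (!setequal(phy$tip.label, taxa))
    stop("tree tips do not match matrix taxa")
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  n <- length(taxa)
  if (phy$Nnode != n - 2) stop("tree must be binary (unrooted)")
  e <- phy$edge
  map <- integer(n + phy$Nnode)
  map[seq_len(n)] <- match(phy$tip.label, taxa)
  map[(n + 1):(n + phy$Nnode)] <- n + seq_len(phy$Nnode)
  cbind(map[e[, 1]], map[e[, 2]])
}

#' Consensus of a set of trees
#'
#' Bipartition-counting consensus: the strict rule keeps clades present in
#' every tree, the majority rule keeps clades whose frequency exceeds the
#' threshold (default 0.5). Trees are rooted on a common outgroup before
#' counting so clade frequencies are well defined.
#'
#' @param trees a \code{multiPhylo}/list of \code{phylo} objects on one
#'   taxon set (e.g. from \code{\link{mp_trees}}).
#' @param rule \code{"strict"} or \code{"majority"}.
#' @param threshold clade frequency that must be exceeded under the
#'   majority rule.
#' @return list with \code{tree} (a \code{phylo}, possibly multifurcating)
#'   and \code{support}, the per-clade frequency (proportion of input
#'   trees) for each internal node of the consensus.
#' @export
consensus_trees <- function(trees, rule = c("strict", "majority"),
                            threshold = 0.5) {
  rule <- match.arg(rule)
  if (inherits(trees, "phylo")) trees <- list(trees)
  class(trees) <- "multiPhylo"
  tips <- trees[[1]]$tip.label
  for (t in trees)
    if (!setequal(t$tip.label, tips))
      stop("trees must share an identical taxon set")
  if (length(trees) == 1) {
    phy <- trees[[1]]
    return(list(tree = phy,
                support = rep(1, phy$Nnode), rule = rule))
  }
  p <- if (rule == "strict") 1 else threshold
  cons <- ape::consensus(trees, p = p, check.labels = TRUE, rooted = TRUE)
  # force a common tip ordering before counting bipartitions
  trees <- ape::.compressTipLabel(trees)
  trees <- ape::.uncompressTipLabel(trees)
  pp <- ape::prop.part(trees)
  freq <- attr(pp, "number") / length(trees)
  clade_key <- function(tipset) paste(sort(tipset), collapse = "|")
  counted <- stats::setNames(freq, vapply(pp, function(ix)
    clade_key(trees[[1]]$tip.label[ix]), ""))
  support <- vapply(seq_len(cons$Nnode), function(k) {
    node <- length(cons$tip.label) + k
    tipset <- cons$tip.label[unlist(descendant_tips(cons, node))]
    s <- counted[clade_key(tipset)]
    if (is.na(s)) 1 else unname(s)
  }, numeric(1))
  list(tree = cons, support = support, rule = rule)
}

# tip indices descending from `node` (plain DFS)
descendant_tips <- function(phy, node) {
  n <- length(phy$tip.label)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k)
    if (k <= n) k else descendant_tips(phy, k)))
}
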