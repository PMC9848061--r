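#' @importFrom ape read.tree write.tree unroot collapse.singles Ntip drop.tip
#'   dist.nodes is.rooted
NULL

#' Parse a newick string into a normalized unrooted tree
#'
#' Trees are stored as [ape::read.tree()] `"phylo"` objects, unrooted and with
#' degree-2 nodes collapsed, so that every internal node has degree >= 3.
#' Numeric internal-node labels (the IQTREE/RAxML convention) are interpreted
#' as branch support values and kept in `$node.label`; bracketed newick
#' comments are ignored.
#'
#' @param text A single newick string (terminating `;` optional).
#' @return An unrooted `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1)95:0.5,C:1,D:1);")
#' bipartitions(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- sub("\\s+$", "", text)
  if (!nzchar(text)) stop("empty newick string")
  # strip bracketed comments before structural validation
  text <- gsub("\\[[^]]*\\]", "", text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed newick: unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed newick: %d unclosed '(' at end of string", depth))
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed newick: could not be parsed at or before position ",
         nchar(text))
  normalize_tree(tr)
}

#' Normalize a tree to canonical unrooted form
#'
#' Unroots rooted input (collapsing the root), removes degree-2 nodes, and
#' validates leaf labels. Trees with fewer than 3 leaves are rejected: they
#' cannot form an unrooted tree.
#'
#' @param tree A `"phylo"` object.
#' @return An unrooted `"phylo"` object.
#' @export
normalize_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 3L)
    stop("an unrooted tree needs at least 3 leaves, got ", ape::Ntip(tree))
  labs <- tree$tip.label
  if (anyNA(labs) || any(!nzchar(labs)))
    stop("leaf labels must be nonempty")
  if (anyDuplicated(labs))
    stop("duplicate leaf label: ", labs[duplicated(labs)][1])
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE))
    stop("negative branch length")
  tree <- ape::collapse.singles(tree)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree
}

#' Write a tree as a newick string
#'
#' @param tree A `"phylo"` object.
#' @param digits Precision for branch lengths.
#' @return A newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Read a multi-tree newick file (one tree per line)
#'
#' @param path File with one newick string per line (blank lines skipped).
#' @param burnin Number of leading trees to discard.
#' @param thin Keep every `thin`-th tree after the burn-in.
#' @return A list of normalized unrooted `"phylo"` objects.
#' @export
read_tree_list <- function(path, burnin = 0L, thin = 1L) {
  stopifnot(burnin >= 0L, thin >= 1L)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (burnin >= length(lines))
    stop("burn-in (", burnin, ") removes all ", length(lines), " trees")
  lines <- lines[seq(burnin + 1L, length(lines), by = thin)]
  lapply(lines, parse_newick)
}

## --- bipartitions ---------------------------------------------------------

# Leaf set below each edge (edges indexed as rows of tree$edge), as a list of
# character vectors of tip labels. Includes pendant edges.
edge_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  # postorder over edges: children before parents
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; chi <- po$edge[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  lapply(seq_len(nrow(tree$edge)),
         function(k) desc[[tree$edge[k, 2]]])
}

#' Canonical string key for a bipartition
#'
#' The side containing the alphabetically smallest leaf, sorted and
#' comma-joined; two splits are equal iff their keys are equal, regardless
#' of which side is given.
#'
#' @param side Taxa on one side of the split.
#' @param leaves All leaves of the tree.
#' @return A character key.
#' @export
split_key <- function(side, leaves) {
  other <- setdiff(leaves, side)
  anchor <- min(leaves)
  keep <- if (anchor %in% side) side else other
  paste(sort(keep), collapse = ",")
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree splits the leaves into two sets; a
#' split is nontrivial when both sides have at least two leaves. A fully
#' resolved unrooted tree of N leaves has exactly N - 3 nontrivial splits.
#'
#' @param tree A `"phylo"` object (normalized with [normalize_tree()] if
#'   rooted).
#' @param keys If `TRUE` return canonical string keys; otherwise a list of
#'   two-element lists of taxon vectors (`side_a`, `side_b`).
#' @return Character vector of split keys, or list of splits.
#' @export
bipartitions <- function(tree, keys = TRUE) {
  tree <- if (ape::is.rooted(tree)) normalize_tree(tree) else tree
  leaves <- tree$tip.label
  sets <- edge_tip_sets(tree)
  nt <- vapply(sets, function(s)
    length(s) >= 2L && length(s) <= length(leaves) - 2L, logical(1))
  sets <- sets[nt]
  ks <- vapply(sets, split_key, character(1), leaves = leaves)
  dup <- duplicated(ks)
  if (keys) return(unique(ks))
  sets <- sets[!dup]
  lapply(sets, function(s)
    list(side_a = sort(s), side_b = sort(setdiff(leaves, s))))
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' The symmetric-difference count of nontrivial bipartitions, with a
#' normalized value `rf / (2 * (N - 3))`. The denominator is kept at
#' `2 * (N - 3)` for multifurcating trees too, so normalized distances stay
#' comparable along a chain trace.
#'
#' @param t1,t2 `"phylo"` objects on the same leaf set.
#' @return A list with integer `rf` and `normalized` in `[0, 1]`.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2))
    stop("leaf-set mismatch: trees must share identical leaves")
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(l1)
  denom <- 2L * (n - 3L)
  list(rf = rf, normalized = if (denom > 0) rf / denom else 0)
}

#' Bipartition-frequency discrepancy between two MCMC chains
#'
#' Summarizes topological agreement of two tree samples the way PhyloBayes'
#' `bpcomp` does: per-bipartition posterior frequencies are compared between
#' chains over the union of nontrivial bipartitions observed in either chain
#' (a split absent from a chain has frequency 0), giving the maximum
#' (`maxdiff`) and mean (`meandiff`) absolute difference. `maxdiff < 0.3` is
#' the conventional threshold for topological convergence.
#'
#' @param chain1,chain2 Lists of `"phylo"` objects on a common leaf set.
#' @param burnin Trees to discard from the start of each chain.
#' @param thin Keep every `thin`-th tree after burn-in.
#' @return An object of class `"chain_comparison"`: list with `maxdiff`,
#'   `meandiff`, and `per_bipartition` (data frame of split key and the two
#'   chain frequencies).
#' @export
chain_discrepancy <- function(chain1, chain2, burnin = 0L, thin = 1L) {
  retain <- function(chain) {
    if (burnin >= length(chain))
      stop("empty chain after burn-in of ", burnin)
    chain[seq(burnin + 1L, length(chain), by = thin)]
  }
  c1 <- retain(chain1); c2 <- retain(chain2)
  l1 <- sort(c1[[1]]$tip.label)
  for (tr in c(c1, c2))
    if (!identical(sort(tr$tip.label), l1))
      stop("all trees in both chains must share a common leaf set")
  freq <- function(chain) {
    ks <- unlist(lapply(chain, bipartitions))
    table(ks) / length(chain)
  }
  f1 <- freq(c1); f2 <- freq(c2)
  keys <- union(names(f1), names(f2))
  v1 <- as.numeric(f1[keys]); v1[is.na(v1)] <- 0
  v2 <- as.numeric(f2[keys]); v2[is.na(v2)] <- 0
  d <- abs(v1 - v2)
  structure(list(
    maxdiff = if (length(d)) max(d) else 0,
    meandiff = if (length(d)) mean(d) else 0,
    per_bipartition = data.frame(bipartition = keys, freq_chain1 = v1,
                                 freq_chain2 = v2, row.names = NULL)),
    class = "chain_comparison")
}

#' @export
print.chain_comparison <- function(x, ...) {
  cat(sprintf("chain comparison over %d bipartitions: maxdiff %.4g, meandiff %.4g\n",
              nrow(x$per_bipartition), x$maxdiff, x$meandiff))
  invisible(x)
}
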