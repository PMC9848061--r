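# Independent brute-force oracles, deliberately implemented from first
# principles (edge-removal graph traversal), not via the package's own
# bipartition machinery.

# all splits of a phylo by removing each edge in turn and flooding the
# child-side component over the remaining edges
oracle_splits <- function(tree, nontrivial_only = TRUE) {
  edges <- tree$edge
  ntip <- length(tree$tip.label)
  out <- list()
  for (k in seq_len(nrow(edges))) {
    rem <- edges[-k, , drop = FALSE]
    comp <- edges[k, 2]
    repeat {
      grow <- unique(c(rem[rem[, 1] %in% comp, 2], rem[rem[, 2] %in% comp, 1]))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    side <- sort(tree$tip.label[comp[comp <= ntip]])
    if (nontrivial_only &&
        (length(side) < 2 || length(side) > ntip - 2)) next
    out[[length(out) + 1]] <- side
  }
  unique(out)
}

oracle_split_keys <- function(tree) {
  leaves <- tree$tip.label
  anchor <- min(leaves)
  vapply(oracle_splits(tree), function(s) {
    side <- if (anchor %in% s) s else sort(setdiff(leaves, s))
    paste(side, collapse = ",")
  }, character(1))
}

oracle_clan_status <- function(tree, clan) {
  p <- sort(intersect(tree$tip.label, clan))
  if (length(p) < 2) return("INSUFFICIENT")
  q <- setdiff(tree$tip.label, p)
  if (length(q) <= 1) return("RECOVERED")
  sides <- oracle_splits(tree, nontrivial_only = FALSE)
  for (s in sides) {
    if (identical(s, p) || identical(sort(setdiff(tree$tip.label, s)), p))
      return("RECOVERED")
  }
  "VIOLATED"
}

oracle_rf <- function(t1, t2) {
  k1 <- oracle_split_keys(t1); k2 <- oracle_split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# patristic distance by explicit path search (BFS parent tracking)
oracle_patristic <- function(tree, a, b) {
  edges <- tree$edge
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  adj <- rbind(cbind(edges, tree$edge.length),
               cbind(edges[, 2:1], tree$edge.length))
  dist <- c(); dist[as.character(ia)] <- 0
  queue <- ia
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[adj[, 1] == v, , drop = FALSE]
    for (r in seq_len(nrow(nb))) {
      w <- as.character(nb[r, 2])
      if (is.null(dist[w]) || is.na(dist[w])) {
        dist[w] <- dist[as.character(v)] + nb[r, 3]
        queue <- c(queue, nb[r, 2])
      }
    }
  }
  unname(dist[as.character(ib)])
}

random_unrooted_tree <- function(n, labels = LETTERS[seq_len(n)]) {
  ape::unroot(ape::rtree(n, tip.label = sample(labels)))
}

# small random amino-acid alignment
random_alignment <- function(ntaxa, nsites, gap_rate = 0,
                             alphabet = c("A", "C", "D", "E", "F")) {
  m <- matrix(sample(alphabet, ntaxa * nsites, replace = TRUE),
              nrow = ntaxa,
              dimnames = list(sprintf("t%02d", seq_len(ntaxa)), NULL))
  if (gap_rate > 0) m[runif(length(m)) < gap_rate] <- "-"
  aa_alignment(m)
}
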