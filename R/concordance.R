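#' Gene concordance factors
#'
#' For each nontrivial branch x of the species tree `T`, a gene tree is
#' *decisive* when the branch restricted to that tree's taxa still has at
#' least two taxa on each side, and *concordant* when, in addition, the
#' restricted bipartition is among the gene tree's bipartitions. The gCF is
#' `100 * concordant / decisive` (missing when no gene tree is decisive).
#'
#' @param T A `"phylo"` species tree.
#' @param S List of `"phylo"` gene trees with leaves contained in `T`'s.
#' @return Data frame with one row per species-tree branch: `branch`
#'   (canonical split key), `gcf`, `gcf_concordant`, `gcf_n`.
#' @export
gene_concordance <- function(T, S) {
  stopifnot(length(S) >= 1L)
  leaves <- T$tip.label
  for (g in S)
    if (!all(g$tip.label %in% leaves))
      stop("gene tree contains taxa outside the species tree: ",
           paste(setdiff(g$tip.label, leaves), collapse = ", "))
  branches <- bipartitions(T, keys = FALSE)
  gsplits <- lapply(S, bipartitions)
  gleaves <- lapply(S, function(g) g$tip.label)
  rows <- lapply(branches, function(br) {
    conc <- 0L; dec <- 0L
    for (k in seq_along(S)) {
      a <- intersect(br$side_a, gleaves[[k]])
      b <- intersect(br$side_b, gleaves[[k]])
      if (length(a) >= 2L && length(b) >= 2L) {
        dec <- dec + 1L
        if (split_key(a, gleaves[[k]]) %in% gsplits[[k]]) conc <- conc + 1L
      }
    }
    data.frame(branch = split_key(br$side_a, leaves),
               gcf = if (dec > 0) 100 * conc / dec else NA_real_,
               gcf_concordant = conc, gcf_n = dec)
  })
  do.call(rbind, rows)
}

# For each internal edge of an unrooted tree, the four (or more, at
# polytomies) leaf groups hanging off its two endpoints: a list per edge
# with `left` (list of groups on the parent side) and `right` (child side).
edge_quartet_groups <- function(tree) {
  sets <- edge_tip_sets(tree)
  leaves <- tree$tip.label
  ntip <- ape::Ntip(tree)
  internal <- which(tree$edge[, 2] > ntip)
  lapply(internal, function(k) {
    par <- tree$edge[k, 1]; chi <- tree$edge[k, 2]
    right <- lapply(which(tree$edge[, 1] == chi), function(e) sets[[e]])
    sibs <- setdiff(which(tree$edge[, 1] == par), k)
    left <- lapply(sibs, function(e) sets[[e]])
    up <- which(tree$edge[, 2] == par)
    if (length(up) == 1L)
      left <- c(left, list(setdiff(leaves, sets[[up]])))
    list(key = split_key(sets[[k]], leaves), left = left, right = right)
  })
}

#' Site concordance factors
#'
#' For each internal branch x of the species tree, quartets are sampled
#' (one taxon from each of two distinct subtree groups on each side of x).
#' A site is *decisive* for a quartet when all four residues are non-gap,
#' non-`X` and the site is parsimony-informative for the quartet (two
#' states, two-and-two); it is *concordant* when the matched pairs straddle
#' the branch as in the species tree. The sCF of x is the mean over
#' quartets (with at least one decisive site) of
#' `100 * concordant / decisive`; `sdf1` and `sdf2` summarize the two
#' discordant pairings the same way.
#'
#' @param T A `"phylo"` species tree.
#' @param matrix A `"supermatrix"` (or `"aa_alignment"`) whose taxa cover
#'   `T`'s leaves.
#' @param n_quartets Quartets sampled per branch.
#' @param seed Integer seed (mandatory: sampling must be reproducible).
#' @return Data frame with one row per branch: `branch`, `scf`, `sdf1`,
#'   `sdf2`, `scf_n` (quartets with decisive sites).
#' @export
site_concordance <- function(T, matrix, n_quartets = 100L, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_quartets >= 1L)
  aln <- if (inherits(matrix, "supermatrix")) matrix$alignment else matrix
  m <- unclass(aln)
  if (!all(T$tip.label %in% rownames(m)))
    stop("matrix must contain all species-tree taxa")
  set.seed(seed)
  groups <- edge_quartet_groups(T)
  ok <- res_mask(m)
  rows <- lapply(groups, function(gr) {
    if (!length(gr$left) || !length(gr$right))
      return(data.frame(branch = gr$key, scf = NA_real_, sdf1 = NA_real_,
                        sdf2 = NA_real_, scf_n = 0L))
    qs <- base::matrix(NA_real_, n_quartets, 3L)
    used <- 0L
    for (q in seq_len(n_quartets)) {
      gl <- if (length(gr$left) >= 2L) sample(length(gr$left), 2L)
            else c(1L, 1L)
      gr2 <- if (length(gr$right) >= 2L) sample(length(gr$right), 2L)
             else c(1L, 1L)
      pick <- function(g, two) {
        if (two[1] == two[2]) {
          if (length(g[[two[1]]]) < 2L) return(NULL)
          sample(g[[two[1]]], 2L)
        } else {
          c(g[[two[1]]][sample.int(length(g[[two[1]]]), 1L)],
            g[[two[2]]][sample.int(length(g[[two[2]]]), 1L)])
        }
      }
      a <- pick(gr$left, gl); b <- pick(gr$right, gr2)
      if (is.null(a) || is.null(b)) next
      idx <- match(c(a, b), rownames(m))
      cols <- which(ok[idx[1], ] & ok[idx[2], ] & ok[idx[3], ] & ok[idx[4], ])
      if (!length(cols)) next
      s <- m[idx, cols, drop = FALSE]
      conc <- s[1, ] == s[2, ] & s[3, ] == s[4, ] & s[1, ] != s[3, ]
      d1 <- s[1, ] == s[3, ] & s[2, ] == s[4, ] & s[1, ] != s[2, ]
      d2 <- s[1, ] == s[4, ] & s[2, ] == s[3, ] & s[1, ] != s[2, ]
      dec <- sum(conc) + sum(d1) + sum(d2)
      if (dec == 0L) next
      used <- used + 1L
      qs[used, ] <- 100 * c(sum(conc), sum(d1), sum(d2)) / dec
    }
    if (used == 0L)
      return(data.frame(branch = gr$key, scf = NA_real_, sdf1 = NA_real_,
                        sdf2 = NA_real_, scf_n = 0L))
    v <- colMeans(qs[seq_len(used), , drop = FALSE])
    data.frame(branch = gr$key, scf = v[1], sdf1 = v[2], sdf2 = v[3],
               scf_n = used)
  })
  do.call(rbind, rows)
}

#' Combined branch concordance table
#'
#' Joins gene and site concordance factors per species-tree branch into a
#' single table ready for TSV export.
#'
#' @param T Species tree.
#' @param S Gene trees (for gCF).
#' @param matrix Supermatrix (for sCF), or `NULL` to skip.
#' @param n_quartets,seed Passed to [site_concordance()].
#' @return Data frame keyed by `branch`.
#' @export
branch_concordance <- function(T, S, matrix = NULL, n_quartets = 100L,
                               seed = 1L) {
  g <- gene_concordance(T, S)
  if (is.null(matrix)) return(g)
  s <- site_concordance(T, matrix, n_quartets = n_quartets, seed = seed)
  merge(g, s, by = "branch", all = TRUE, sort = FALSE)
}
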