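res_mask <- function(m) m != "-" & m != "X"

#' Variable and parsimony-informative site counts
#'
#' A site is variable when it shows at least two distinct residues (gaps
#' and `X` excluded from state counts, the PhyKIT convention), and
#' parsimony-informative when at least two residues each occur in at least
#' two sequences.
#'
#' @param aln An `"aa_alignment"`.
#' @return List with `variable_sites`, `parsimony_informative_sites`,
#'   `length`.
#' @export
site_counts <- function(aln) {
  m <- unclass(aln)
  variable <- 0L; informative <- 0L
  for (j in seq_len(ncol(m))) {
    res <- m[, j][res_mask(m[, j, drop = FALSE])]
    tab <- table(res)
    if (length(tab) >= 2L) {
      variable <- variable + 1L
      if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  list(variable_sites = variable, parsimony_informative_sites = informative,
       length = ncol(m))
}

# per-taxon residue frequency matrix over non-gap, non-X sites
taxon_freqs <- function(aln, warn = TRUE) {
  m <- unclass(aln)
  f <- t(apply(m, 1, function(row) {
    res <- row[row %in% AA_LETTERS]
    if (!length(res)) return(rep(NA_real_, 20L))
    tabulate(match(res, AA_LETTERS), 20L) / length(res)
  }))
  colnames(f) <- AA_LETTERS
  empty <- apply(f, 1, anyNA)
  if (any(empty)) {
    if (warn) warning("taxa with no non-gap sites excluded: ",
                      paste(rownames(m)[empty], collapse = ", "))
    f <- f[!empty, , drop = FALSE]
  }
  f
}

#' Treeness, RCV, and their ratio
#'
#' Treeness is the fraction of total tree length on internal branches;
#' relative composition variability (RCV) is the mean absolute deviation of
#' per-taxon residue *counts* from the across-taxon mean count, scaled by
#' taxon number and alignment length. Their ratio is a composition-aware
#' signal metric: higher values indicate less susceptibility to composition
#' bias. Undefined quantities (zero tree length, zero RCV) are returned as
#' `NA`.
#'
#' @param tree A `"phylo"` with branch lengths, leaves in `aln`.
#' @param aln An `"aa_alignment"` covering the tree's leaves.
#' @return List with `treeness`, `rcv`, `ratio`.
#' @export
treeness_rcv <- function(tree, aln) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  total <- sum(tree$edge.length)
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  treeness <- if (total > 0) sum(tree$edge.length[internal]) / total
              else NA_real_
  m <- unclass(aln)
  counts <- t(apply(m, 1, function(row)
    tabulate(match(row[row %in% AA_LETTERS], AA_LETTERS), 20L)))
  mean_counts <- colMeans(counts)
  rcv <- sum(abs(sweep(counts, 2, mean_counts))) / (nrow(m) * ncol(m))
  list(treeness = treeness, rcv = rcv,
       ratio = if (!is.na(treeness) && rcv > 0) treeness / rcv else NA_real_)
}

#' Long-branch scores
#'
#' For each taxon i, `LB_i = 100 * (mean patristic distance from i to all
#' other taxa / grand mean pairwise patristic distance - 1)`. Positive
#' scores mark taxa sitting on disproportionately long paths (long-branch
#' attraction candidates). Because the per-taxon means average back to the
#' grand mean, the plain mean of LB scores is identically ~0; the mean of
#' the upper decile is therefore also reported as a tail summary.
#'
#' @param tree A `"phylo"` with branch lengths and >= 2 leaves.
#' @return List with `per_taxon` (named vector), `mean_abs` (mean of
#'   per-taxon scores), and `mean_upper_decile`.
#' @export
long_branch_scores <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- ape::Ntip(tree)
  if (n < 2L) stop("need >= 2 taxa")
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  rownames(d) <- colnames(d) <- tree$tip.label
  grand <- mean(d[upper.tri(d)])
  if (grand == 0) stop("all patristic distances are zero")
  per <- 100 * (rowSums(d) / (n - 1) / grand - 1)
  dec <- sort(per, decreasing = TRUE)
  k <- max(1L, ceiling(n / 10))
  list(per_taxon = per, mean_abs = mean(per),
       mean_upper_decile = mean(dec[seq_len(k)]))
}

# uncorrected pairwise p-distances, ignoring columns with a gap/X in either
# sequence; NA when no comparable site
p_distances <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  ok <- res_mask(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- ok[i, ] & ok[j, ]
    if (any(both)) {
      d[i, j] <- d[j, i] <- mean(m[i, both] != m[j, both])
    }
  }
  diag(d) <- 0
  d
}

#' Sequence saturation
#'
#' The slope of the through-origin regression of uncorrected pairwise
#' p-distances on patristic distances. A slope of 1 means substitutions
#' accumulate linearly with tree distance (no saturation); lower slopes
#' mean multiple hits are hiding divergence.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param aln An `"aa_alignment"` covering the tree's leaves.
#' @return Slope (numeric), or `NA` when all patristic distances are zero.
#' @export
saturation <- function(tree, aln) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- ape::Ntip(tree)
  patr <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  rownames(patr) <- colnames(patr) <- tree$tip.label
  taxa <- intersect(rownames(unclass(aln)), tree$tip.label)
  pd <- p_distances(aln)[taxa, taxa]
  pa <- patr[taxa, taxa]
  ut <- upper.tri(pa)
  x <- pa[ut]; y <- pd[ut]
  keep <- !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x) || sum(x^2) == 0) return(NA_real_)
  sum(x * y) / sum(x^2)
}

#' Mean bipartition support
#'
#' Arithmetic mean of the numeric support values attached to internal
#' edges (stored in `$node.label` by the parser). `NA` when no supports are
#' present.
#'
#' @param tree A `"phylo"`.
#' @return Numeric mean support, or `NA`.
#' @export
mean_bipartition_support <- function(tree) {
  if (is.null(tree$node.label)) return(NA_real_)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup <- sup[!is.na(sup)]
  if (!length(sup)) return(NA_real_)
  mean(sup)
}

#' Relative composition frequency variability (RCFV)
#'
#' `RCFV = sum_j sum_i |f_ij - fbar_j| / n` where `f_ij` is the frequency
#' of amino acid j in taxon i over its non-gap sites and `fbar_j` the mean
#' over the n taxa. Zero iff all per-taxon compositions are identical;
#' larger values flag lineage-specific compositional bias.
#'
#' @param aln An `"aa_alignment"` with >= 2 taxa.
#' @return Numeric RCFV >= 0.
#' @export
rcfv <- function(aln) {
  f <- taxon_freqs(aln)
  if (nrow(f) < 2L) stop("need >= 2 taxa with non-gap sites")
  sum(abs(sweep(f, 2, colMeans(f)))) / nrow(f)
}

#' Chi-square test of compositional homogeneity
#'
#' Standard contingency chi-square of per-taxon residue counts against the
#' pooled expectation, df = (n_taxa - 1) x (n_observed_states - 1).
#' Returns `NA`s for degenerate tables (a single observed state).
#'
#' @param aln An `"aa_alignment"` with >= 2 taxa.
#' @return List with `stat`, `df`, `p`.
#' @export
chi2_homogeneity <- function(aln) {
  m <- unclass(aln)
  counts <- t(apply(m, 1, function(row)
    tabulate(match(row[row %in% AA_LETTERS], AA_LETTERS), 20L)))
  colnames(counts) <- AA_LETTERS
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2L || nrow(counts) < 2L)
    return(list(stat = NA_real_, df = NA_integer_, p = NA_real_))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(stat = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' All per-orthogroup metrics as one row
#'
#' Convenience wrapper computing the seven information criteria plus RCFV
#' and the chi-square homogeneity test for one orthogroup.
#'
#' @param aln An `"aa_alignment"`.
#' @param tree The orthogroup's gene tree (branch lengths required for the
#'   tree-based metrics; pass `NULL` to skip them).
#' @return A one-row `data.frame`.
#' @export
orthogroup_metrics <- function(aln, tree = NULL) {
  sc <- site_counts(aln)
  ch <- chi2_homogeneity(aln)
  out <- data.frame(
    alignment_length = sc$length,
    variable_sites = sc$variable_sites,
    parsimony_informative_sites = sc$parsimony_informative_sites,
    mean_bipartition_support = NA_real_,
    mean_long_branch_score = NA_real_,
    long_branch_upper_decile = NA_real_,
    saturation = NA_real_,
    treeness = NA_real_,
    rcv = NA_real_,
    treeness_over_rcv = NA_real_,
    rcfv = rcfv(aln),
    chi2_stat = ch$stat, chi2_df = ch$df, chi2_p = ch$p)
  if (!is.null(tree)) {
    out$mean_bipartition_support <- mean_bipartition_support(tree)
    if (!is.null(tree$edge.length)) {
      lb <- long_branch_scores(tree)
      tr <- treeness_rcv(tree, aln)
      out$mean_long_branch_score <- lb$mean_abs
      out$long_branch_upper_decile <- lb$mean_upper_decile
      out$saturation <- saturation(tree, aln)
      out$treeness <- tr$treeness
      out$rcv <- tr$rcv
      out$treeness_over_rcv <- tr$ratio
    }
  }
  out
}

significance_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 1e-2, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Compare metric distributions between passing and failing orthogroups
#'
#' Per-metric two-sided Wilcoxon rank-sum tests between the group of
#' orthogroups that passed a clan filter and the group that failed it, with
#' group medians and significance stars at 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param pass,fail Data frames of metric rows (as from
#'   [orthogroup_metrics()]).
#' @param metrics Columns to compare (default: all shared numeric columns).
#' @return Data frame with metric, medians, W statistic, p, stars.
#' @export
compare_groups <- function(pass, fail, metrics = NULL) {
  stopifnot(nrow(pass) > 0, nrow(fail) > 0)
  if (is.null(metrics)) {
    shared <- intersect(names(pass), names(fail))
    metrics <- shared[vapply(pass[shared], is.numeric, logical(1))]
  }
  rows <- lapply(metrics, function(mt) {
    x <- pass[[mt]]; y <- fail[[mt]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y))
      return(data.frame(metric = mt, median_pass = NA, median_fail = NA,
                        W = NA, p = NA, stars = NA))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(metric = mt, median_pass = stats::median(x),
               median_fail = stats::median(y),
               W = unname(wt$statistic), p = wt$p.value,
               stars = significance_stars(wt$p.value))
  })
  do.call(rbind, rows)
}
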