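#' Define a set of clans
#'
#' A clan is the unrooted-tree analogue of a clade: a taxon set separable
#' from all remaining leaves by removing a single edge. Clan definitions are
#' dataset-wide taxon memberships; a clan is *countable* (participates in
#' per-orthogroup recovered-clan counts) only when it has at least two
#' members dataset-wide. In the animal datasets this is why a
#' singleton-represented phylum (Placozoa) is reported but never counted.
#'
#' @param ... Named character vectors, one per clan.
#' @return An object of class `"clan_set"`: named list of taxon vectors.
#' @examples
#' clan_set(Porifera = c("Sp1", "Sp2"), Outgroup = c("Og1", "Og2"))
#' @export
clan_set <- function(...) {
  clans <- list(...)
  if (length(clans) == 1L && is.list(clans[[1]]) && is.null(names(clans)[1]))
    clans <- clans[[1]]
  if (is.null(names(clans)) || any(!nzchar(names(clans))))
    stop("every clan must be named")
  if (anyDuplicated(names(clans)))
    stop("duplicate clan name: ", names(clans)[duplicated(names(clans))][1])
  clans <- lapply(clans, function(x) {
    x <- as.character(x)
    if (!length(x)) stop("clan taxa must be nonempty")
    unique(x)
  })
  all_taxa <- unlist(clans, use.names = FALSE)
  if (anyDuplicated(all_taxa))
    stop("taxon assigned to more than one clan: ",
         all_taxa[duplicated(all_taxa)][1])
  structure(clans, class = "clan_set")
}

#' Countable clans of a clan set
#'
#' @param clans A `"clan_set"`.
#' @return Names of clans with >= 2 dataset-wide members.
#' @export
countable_clans <- function(clans) {
  names(clans)[vapply(clans, length, integer(1)) >= 2L]
}

#' Read clan definitions from a two-column TSV
#'
#' @param path TSV with columns `clan_name`, `taxon` (no header required;
#'   a header line matching those names is skipped).
#' @return A `"clan_set"`.
#' @export
read_clans <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("clan_name", "taxon"),
                          colClasses = "character", quote = "")
  if (nrow(df) && df$clan_name[1] == "clan_name") df <- df[-1, , drop = FALSE]
  clan_set(split(df$taxon, factor(df$clan_name, levels = unique(df$clan_name))))
}

#' Write clan definitions to a two-column TSV
#' @param clans A `"clan_set"`.
#' @param path Output path.
#' @export
write_clans <- function(clans, path) {
  df <- data.frame(clan_name = rep(names(clans), lengths(clans)),
                   taxon = unlist(clans, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Test one clan in one unrooted gene tree
#'
#' Let P be the clan taxa present in the tree and Q the remaining leaves.
#' The status is `"INSUFFICIENT"` when fewer than two clan taxa are present;
#' otherwise `"RECOVERED"` when some single edge separates exactly P from Q,
#' and `"VIOLATED"` when no such edge exists. When at most one non-clan
#' taxon is present the exclusion condition is trivially satisfiable (any
#' single leaf hangs off its own pendant edge), so the status is
#' `"RECOVERED"`; this edge case is flagged with attribute
#' `"trivial_exclusion"`.
#'
#' With `polytomy = "strict"` (default) a polytomy mixing clan and non-clan
#' children violates the clan: recovery requires an actual edge realizing
#' the split. With `polytomy = "soft"`, polytomies are allowed to be
#' refined in the clan's favor: the clan is recovered if some node's
#' surrounding subtrees can be grouped to separate P from Q.
#'
#' @param tree A `"phylo"` gene tree.
#' @param clan Character vector of dataset-wide clan taxa.
#' @param polytomy `"strict"` or `"soft"`.
#' @return One of `"RECOVERED"`, `"VIOLATED"`, `"INSUFFICIENT"`.
#' @export
clan_status <- function(tree, clan, polytomy = c("strict", "soft")) {
  polytomy <- match.arg(polytomy)
  leaves <- tree$tip.label
  p <- intersect(leaves, clan)
  if (length(p) < 2L) return("INSUFFICIENT")
  q <- setdiff(leaves, p)
  if (length(q) <= 1L)
    return(structure("RECOVERED", trivial_exclusion = TRUE))
  key <- split_key(p, leaves)
  if (polytomy == "strict") {
    if (key %in% bipartitions(tree)) "RECOVERED" else "VIOLATED"
  } else {
    if (clan_realizable(tree, p)) "RECOVERED" else "VIOLATED"
  }
}

# Soft-polytomy test: P is realizable as a clan in some refinement of the
# tree iff around some node every incident subtree is pure (entirely inside
# or entirely outside P).
clan_realizable <- function(tree, p) {
  if (split_key(p, tree$tip.label) %in% bipartitions(tree)) return(TRUE)
  ntip <- ape::Ntip(tree)
  sets <- edge_tip_sets(tree)
  leaves <- tree$tip.label
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    comps <- list()
    kids <- which(tree$edge[, 1] == v)
    for (k in kids) comps <- c(comps, list(sets[[k]]))
    up <- which(tree$edge[, 2] == v)
    if (length(up) == 1L) comps <- c(comps, list(setdiff(leaves, sets[[up]])))
    pure <- vapply(comps, function(s) {
      inside <- sum(s %in% p)
      inside == 0L || inside == length(s)
    }, logical(1))
    if (all(pure)) return(TRUE)
  }
  FALSE
}

#' Test all clans across a set of orthogroup gene trees
#'
#' Runs [clan_status()] for every (orthogroup, clan) pair and counts, per
#' orthogroup, how many *countable* clans are recovered. Clans with fewer
#' than two dataset-wide members are still tested and reported but excluded
#' from the count. Taxa in trees that belong to no clan definition are
#' treated as non-clan taxa for every clan.
#'
#' @param trees Named list of `"phylo"` gene trees (names = orthogroup ids).
#' @param clans A `"clan_set"` (or named list of taxon vectors).
#' @param polytomy Passed to [clan_status()].
#' @return Object of class `"clan_report"`: list with `statuses` (long data
#'   frame orthogroup/clan/status), `n_recovered` (named integer vector over
#'   orthogroups), and `countable` (character vector of countable clans).
#' @export
check_clans <- function(trees, clans, polytomy = "strict") {
  stopifnot(length(trees) >= 1L, length(clans) >= 1L)
  if (is.null(names(trees)))
    names(trees) <- sprintf("OG%04d", seq_along(trees))
  countable <- countable_clans(clans)
  ids <- names(trees)
  rows <- vector("list", length(trees))
  n_rec <- integer(length(trees)); names(n_rec) <- ids
  for (i in seq_along(trees)) {
    st <- vapply(clans, function(cl)
      as.character(clan_status(trees[[i]], cl, polytomy)), character(1))
    rows[[i]] <- data.frame(orthogroup = ids[i], clan = names(clans),
                            status = unname(st), row.names = NULL)
    n_rec[i] <- sum(st[countable] == "RECOVERED")
  }
  structure(list(statuses = do.call(rbind, rows),
                 n_recovered = n_rec, countable = countable),
            class = "clan_report")
}

#' @export
print.clan_report <- function(x, ...) {
  cat(sprintf("clan report: %d orthogroups x %d clans (%d countable)\n",
              length(x$n_recovered),
              length(unique(x$statuses$clan)), length(x$countable)))
  print(clan_histogram(x))
  invisible(x)
}

#' Histogram of recovered-clan counts
#'
#' Counts orthogroups by the number n of countable clans they recover, the
#' per-dataset accounting used to decide how aggressive a clan filter is.
#'
#' @param report A `"clan_report"`.
#' @return Named integer vector over n = number of countable clans .. 0
#'   (descending, matching the conventional presentation).
#' @export
clan_histogram <- function(report) {
  k <- length(report$countable)
  tab <- table(factor(report$n_recovered, levels = k:0))
  stats::setNames(as.integer(tab), names(tab))
}

#' Filter orthogroups by recovered-clan count
#'
#' Retains orthogroups whose gene tree recovers at least `min_clans`
#' countable clans (inclusive threshold; an INSUFFICIENT clan counts as not
#' recovered). The default of 3 reflects the expectation that an orthogroup
#' of sufficient sampling and quality should recapitulate most major
#' internal relationships of the species tree.
#'
#' @param report A `"clan_report"`.
#' @param min_clans Minimum number of recovered countable clans.
#' @return Character vector of retained orthogroup ids, in input order.
#' @export
filter_orthogroups <- function(report, min_clans = 3L) {
  stopifnot(min_clans >= 0L)
  names(report$n_recovered)[report$n_recovered >= min_clans]
}

#' Write a clan report as TSVs
#'
#' @param report A `"clan_report"`.
#' @param path Output TSV (orthogroup, clan, status).
#' @param histogram_path Optional TSV with the per-n histogram.
#' @export
write_clan_report <- function(report, path, histogram_path = NULL) {
  utils::write.table(report$statuses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(histogram_path)) {
    h <- clan_histogram(report)
    utils::write.table(data.frame(n = names(h), orthogroups = h),
                       histogram_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
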