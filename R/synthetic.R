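#' Specification for synthetic phylogenomic datasets
#'
#' Bundles every knob of the synthetic generators. The defaults emulate the
#' structure of published animal-root datasets: five major-phylum clans of
#' realistic relative sizes plus an outgroup clan and a singleton clan
#' (~70 taxa, the size of a typical published matrix), ~200 orthogroups,
#' moderate per-taxon dropout, a majority of orthogroups carrying at least
#' one clan-violating rearrangement (published datasets show ~3/4 of
#' orthogroups failing to recover more than two major clans), orthogroup
#' alignment lengths of 100-500 sites (matrix totals of ~50k sites over
#' ~200 orthogroups), gamma rate heterogeneity, and a stretched stem for a
#' fast-evolving comb-jelly-like clan.
#'
#' @param clan_sizes Named integer vector: taxa per clan.
#' @param n_orthogroups Number of orthogroups to simulate.
#' @param dropout Per-clan probability that each taxon is missing from an
#'   orthogroup; a single number recycles over clans.
#' @param violation_rate Probability that an orthogroup tree receives
#'   clan-breaking rearrangements.
#' @param n_violating_moves Tip relocations applied per violating tree.
#' @param aln_length Length-2 vector: min/max alignment length (sites).
#' @param gamma_shape Shape of the gamma distribution of among-site rates.
#' @param comp_shift Strength in `[0, 1]` of the stationary-frequency bias
#'   applied to the designated fast lineage.
#' @param comp_shift_clan Clan receiving the compositional shift.
#' @param stem_stretch Multiplier (>= 1) applied to the designated clan's
#'   stem branch.
#' @param stem_stretch_clan Clan receiving the stem stretch.
#' @param mean_branch_length Mean of the exponential branch lengths.
#' @param seed Integer master seed; every generator derives its stream
#'   from it.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(clan_sizes = c(Bilateria = 30, Cnidaria = 10,
                                          Ctenophora = 8, Porifera = 10,
                                          Placozoa = 1, Outgroup = 11),
                           n_orthogroups = 200L,
                           dropout = 0.2,
                           violation_rate = 0.6,
                           n_violating_moves = 1L,
                           aln_length = c(100L, 500L),
                           gamma_shape = 0.8,
                           comp_shift = 0,
                           comp_shift_clan = "Ctenophora",
                           stem_stretch = 3,
                           stem_stretch_clan = "Ctenophora",
                           mean_branch_length = 0.1,
                           seed = 1L) {
  stopifnot(sum(clan_sizes) >= 4, all(clan_sizes >= 1),
            !is.null(names(clan_sizes)),
            violation_rate >= 0, violation_rate <= 1,
            gamma_shape > 0, comp_shift >= 0, comp_shift <= 1,
            stem_stretch >= 1, length(aln_length) == 2L,
            aln_length[1] >= 1, aln_length[2] >= aln_length[1])
  if (length(dropout) == 1L)
    dropout <- stats::setNames(rep(dropout, length(clan_sizes)),
                               names(clan_sizes))
  stopifnot(all(dropout >= 0), all(dropout <= 1),
            setequal(names(dropout), names(clan_sizes)))
  structure(list(clan_sizes = clan_sizes, n_orthogroups = n_orthogroups,
                 dropout = dropout, violation_rate = violation_rate,
                 n_violating_moves = n_violating_moves,
                 aln_length = aln_length, gamma_shape = gamma_shape,
                 comp_shift = comp_shift, comp_shift_clan = comp_shift_clan,
                 stem_stretch = stem_stretch,
                 stem_stretch_clan = stem_stretch_clan,
                 mean_branch_length = mean_branch_length,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Clan definitions implied by a synthetic spec
#'
#' Taxa are named `<Clan>_<index>`.
#'
#' @param spec A `"synthetic_spec"`.
#' @return A `"clan_set"`.
#' @export
default_clans <- function(spec) {
  clan_set(stats::setNames(lapply(names(spec$clan_sizes), function(cl)
    sprintf("%s_%02d", cl, seq_len(spec$clan_sizes[[cl]]))),
    names(spec$clan_sizes)))
}

# comb newick over block strings: (((b1,b2),b3),b4); optional per-block
# stem lengths and per-join internal (spine) lengths
comb_newick <- function(blocks, lengths = NULL, internal_lengths = NULL) {
  if (!is.null(lengths)) blocks <- sprintf("%s:%g", blocks, lengths)
  s <- blocks[1]
  for (i in seq_along(blocks)[-1]) {
    s <- sprintf("(%s,%s)", s, blocks[i])
    if (!is.null(internal_lengths))
      s <- sprintf("%s:%g", s, internal_lengths[i - 1])
  }
  s
}

#' Simulate a species tree with clan structure
#'
#' Each clan is generated as a random subtree and the clan subtrees are
#' joined on a comb backbone, so every clan is monophyletic (as a clan) by
#' construction. Branch lengths are exponential with mean
#' `spec$mean_branch_length`; the designated clan's stem is multiplied by
#' `spec$stem_stretch`, emulating a long-stemmed fast-evolving lineage.
#'
#' @param spec A `"synthetic_spec"`.
#' @return An unrooted `"phylo"` with branch lengths.
#' @export
simulate_species_tree <- function(spec) {
  set.seed(spec$seed)
  rate <- 1 / spec$mean_branch_length
  clans <- default_clans(spec)
  sub <- vapply(names(clans), function(cl) {
    taxa <- clans[[cl]]
    if (length(taxa) == 1L) return(taxa)
    tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
    tr$edge.length <- stats::rexp(nrow(tr$edge), rate)
    sub(";$", "", ape::write.tree(tr))
  }, character(1))
  stems <- stats::rexp(length(sub), rate)
  stems[names(clans) == spec$stem_stretch_clan] <-
    stems[names(clans) == spec$stem_stretch_clan] * spec$stem_stretch
  spine <- stats::rexp(length(sub) - 1L, rate)
  parse_newick(paste0(comb_newick(sub, stems, spine), ";"))
}

#' Relocate a tip next to another leaf
#'
#' Prunes `tip` and re-grafts it as the sister of leaf `sister` (a single
#' subtree-prune-regraft move on a tip). Used to mimic hidden paralogy:
#' relocating a clan member outside its clan guarantees the clan can no
#' longer be separated by one edge.
#'
#' @param tree A `"phylo"` (branch lengths optional).
#' @param tip Leaf to move.
#' @param sister Leaf to attach it next to.
#' @return A `"phylo"` with the same leaf set.
#' @export
relocate_tip <- function(tree, tip, sister) {
  stopifnot(tip %in% tree$tip.label, sister %in% tree$tip.label,
            tip != sister)
  has_len <- !is.null(tree$edge.length)
  pend <- if (has_len)
    tree$edge.length[tree$edge[, 2] == match(tip, tree$tip.label)]
  else 0.1
  tr <- ape::drop.tip(tree, tip)
  where <- match(sister, tr$tip.label)
  if (!has_len) tr$edge.length <- rep(1, nrow(tr$edge))
  sis_len <- tr$edge.length[tr$edge[, 2] == where]
  out <- phytools::bind.tip(tr, tip, edge.length = pend, where = where,
                            position = sis_len / 2)
  if (!has_len) out$edge.length <- NULL
  normalize_tree(out)
}

#' Simulate gene trees with dropout and clan violations
#'
#' Per orthogroup, each taxon is dropped with its clan's dropout
#' probability (orthogroups reduced below 4 leaves are resampled and
#' counted); with probability `violation_rate` the tree then receives
#' `n_violating_moves` relocations of a clan member next to a leaf outside
#' its clan. The returned truth table records exactly what was done, so
#' every downstream expectation (violated clans, dropout) can be recomputed
#' independently.
#'
#' @param species The species tree from [simulate_species_tree()].
#' @param spec A `"synthetic_spec"`.
#' @param clans Clan definitions (default [default_clans()]).
#' @return List with `trees` (named list of `"phylo"`) and `truth` (data
#'   frame: orthogroup, dropped, n_present, violating, moves, resamples).
#' @export
simulate_gene_trees <- function(species, spec, clans = default_clans(spec)) {
  set.seed(spec$seed + 1L)
  countable <- countable_clans(clans)
  taxa <- species$tip.label
  clan_of <- stats::setNames(rep(names(clans), lengths(clans)),
                             unlist(clans, use.names = FALSE))
  ids <- sprintf("OG%04d", seq_len(spec$n_orthogroups))
  trees <- vector("list", spec$n_orthogroups)
  truth <- vector("list", spec$n_orthogroups)
  for (i in seq_len(spec$n_orthogroups)) {
    resamples <- 0L
    repeat {
      drop_p <- spec$dropout[clan_of[taxa]]
      dropped <- taxa[stats::runif(length(taxa)) < drop_p]
      if (length(taxa) - length(dropped) >= 4L) break
      resamples <- resamples + 1L
    }
    tr <- if (length(dropped)) ape::drop.tip(species, dropped) else species
    moves <- character(0)
    if (stats::runif(1) < spec$violation_rate) {
      for (mv in seq_len(spec$n_violating_moves)) {
        present <- tr$tip.label
        eligible <- countable[vapply(countable, function(cl)
          sum(present %in% clans[[cl]]) >= 2L &&
            sum(!present %in% clans[[cl]]) >= 1L, logical(1))]
        if (!length(eligible)) break
        cl <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        members <- intersect(present, clans[[cl]])
        tip <- if (length(members) == 1L) members else sample(members, 1L)
        outside <- setdiff(present, clans[[cl]])
        sis <- if (length(outside) == 1L) outside else sample(outside, 1L)
        tr <- relocate_tip(tr, tip, sis)
        moves <- c(moves, sprintf("%s->%s", tip, sis))
      }
    }
    trees[[i]] <- tr
    truth[[i]] <- data.frame(
      orthogroup = ids[i],
      dropped = paste(dropped, collapse = ","),
      n_present = length(tr$tip.label),
      violating = length(moves) > 0L,
      moves = paste(moves, collapse = ";"),
      resamples = resamples)
  }
  names(trees) <- ids
  list(trees = trees, truth = do.call(rbind, truth))
}

# stationary frequencies biased toward a fixed residue subset
shifted_freqs <- function(base, comp_shift) {
  target <- stats::setNames(rep(0, 20L), AA_LETTERS)
  target[c("A", "V", "L", "S", "G")] <- 1 / 5
  (1 - comp_shift) * base + comp_shift * target
}

#' Simulate an amino-acid alignment along a gene tree
#'
#' Residues evolve under an equal-exchangeability (Poisson-style)
#' substitution process: on a branch of length t, each site is resampled
#' from the branch's stationary frequencies with probability
#' `1 - exp(-r t)` where r is the site's gamma-distributed rate (shape
#' `spec$gamma_shape`). Branches lying entirely within the designated
#' fast lineage use frequencies linearly biased by `spec$comp_shift`;
#' all other branches use the uniform base frequencies. A zero-length
#' tree therefore yields identical sequences, and doubling branch lengths
#' increases multiple hits (lowering the saturation slope).
#'
#' @param gene_tree A `"phylo"` with branch lengths.
#' @param spec A `"synthetic_spec"`.
#' @param length Number of sites; default drawn uniformly from
#'   `spec$aln_length`.
#' @param seed Seed; default derives from `spec$seed`.
#' @param shifted_taxa Taxa whose within-group branches get the biased
#'   frequencies; default the members of `spec$comp_shift_clan`.
#' @return An `"aa_alignment"` (no gaps).
#' @export
simulate_alignment <- function(gene_tree, spec, length = NULL, seed = NULL,
                               shifted_taxa = NULL) {
  if (is.null(gene_tree$edge.length)) stop("gene tree needs branch lengths")
  if (is.null(seed)) seed <- spec$seed + 2L
  set.seed(seed)
  if (is.null(length))
    length <- sample(spec$aln_length[1]:spec$aln_length[2], 1L)
  if (is.null(shifted_taxa))
    shifted_taxa <- default_clans(spec)[[spec$comp_shift_clan]]
  base <- stats::setNames(rep(1 / 20, 20L), AA_LETTERS)
  shifted <- shifted_freqs(base, spec$comp_shift)
  rates <- stats::rgamma(length, shape = spec$gamma_shape,
                         rate = spec$gamma_shape)
  ntip <- ape::Ntip(gene_tree)
  tr <- ape::reorder.phylo(gene_tree, "cladewise")
  sets <- edge_tip_sets(tr)
  seqs <- vector("list", ntip + tr$Nnode)
  root <- tr$edge[1, 1]
  seqs[[root]] <- sample(AA_LETTERS, length, replace = TRUE, prob = base)
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    f <- if (spec$comp_shift > 0 && all(sets[[k]] %in% shifted_taxa))
      shifted else base
    p <- 1 - exp(-rates * tr$edge.length[k])
    s <- seqs[[par]]
    hit <- stats::runif(length) < p
    if (any(hit))
      s[hit] <- sample(AA_LETTERS, sum(hit), replace = TRUE, prob = f)
    seqs[[chi]] <- s
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tr$tip.label
  structure(m, class = c("aa_alignment", class(m)))
}

#' Inject gaps uniformly at random (occupancy testing helper)
#'
#' @param aln An `"aa_alignment"`.
#' @param rate Per-cell gap probability.
#' @param seed Integer seed.
#' @return An `"aa_alignment"` with gaps.
#' @export
inject_gaps <- function(aln, rate, seed) {
  set.seed(seed)
  m <- unclass(aln)
  m[stats::runif(base::length(m)) < rate] <- "-"
  structure(m, class = c("aa_alignment", class(m)))
}

#' Construct gene trees with an exact recovered-clan profile
#'
#' Deterministically builds, for each requested n, trees that recover
#' exactly n countable clans: n clans are kept as intact pendant subtrees
#' on a comb backbone while the members of the remaining countable clans
#' are scattered along the spine (round-robin interleaved, so no violated
#' clan can be separated by a single edge). Non-countable (singleton)
#' clans are appended as single leaves. Every emitted tree is re-checked
#' with [clan_status()] before being returned; a mismatch is an error.
#'
#' @param counts_per_n Named integer vector: `counts_per_n[["3"]] = 25`
#'   requests 25 trees recovering exactly 3 clans.
#' @param clans A `"clan_set"` (all clan taxa appear in every tree).
#' @param seed Integer seed (controls which clans are recovered in each
#'   tree).
#' @return Named list of `"phylo"` gene trees, with attribute `"n_target"`
#'   (integer vector of the requested n per tree).
#' @export
construct_profile_dataset <- function(counts_per_n, clans, seed = 1L) {
  set.seed(seed)
  countable <- countable_clans(clans)
  k <- length(countable)
  singletons <- setdiff(names(clans), countable)
  ns <- as.integer(names(counts_per_n))
  if (anyNA(ns) || any(ns < 0) || any(ns > k))
    stop("infeasible n: requested counts for n outside 0..", k)
  trees <- list(); n_target <- integer(0)
  total <- 0L
  for (j in seq_along(counts_per_n)) {
    n <- ns[j]
    for (rep in seq_len(counts_per_n[[j]])) {
      total <- total + 1L
      rec <- if (n == 0L) character(0)
             else countable[sort(sample.int(k, n))]
      vio <- setdiff(countable, rec)
      if (length(vio) == 1L && length(rec) == 0L && !length(singletons))
        stop("infeasible: cannot violate a single clan with no other taxa")
      rec_blocks <- vapply(rec, function(cl) comb_newick(clans[[cl]]),
                           character(1))
      sing_blocks <- unlist(lapply(singletons, function(cl) clans[[cl]]))
      if (length(vio) >= 2L) {
        sizes <- lengths(clans[vio])
        blocks <- character(0)
        for (r in seq_len(max(sizes)))
          for (cl in vio)
            if (length(clans[[cl]]) >= r) blocks <- c(blocks, clans[[cl]][r])
        blocks <- c(blocks, rec_blocks, sing_blocks)
      } else if (length(vio) == 1L) {
        vt <- clans[[vio]]
        blocks <- c(vt[1], rec_blocks, sing_blocks, vt[-1])
      } else {
        blocks <- c(rec_blocks, sing_blocks)
      }
      tr <- parse_newick(paste0(comb_newick(blocks), ";"))
      st <- vapply(countable, function(cl)
        as.character(clan_status(tr, clans[[cl]])), character(1))
      if (sum(st == "RECOVERED") != n)
        stop("internal error: constructed tree recovers ",
             sum(st == "RECOVERED"), " clans, wanted ", n)
      trees[[sprintf("OG%04d", total)]] <- tr
      n_target <- c(n_target, n)
    }
  }
  attr(trees, "n_target") <- n_target
  trees
}
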