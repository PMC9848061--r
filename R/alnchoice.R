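# homology statements of an alignment: for every unordered sequence pair
# and column, either a residue-residue pairing (by ungapped residue index)
# or a residue-gap statement tagged with the gap's column index
homology_statements <- function(aln) {
  m <- unclass(aln)
  taxa <- rownames(m)
  gap <- m == "-"
  ridx <- t(apply(!gap, 1, cumsum))  # residue index per column (valid where !gap)
  out <- character(0)
  n <- nrow(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- !gap[i, ] & !gap[j, ]
    ij <- both
    rr <- sprintf("%s|%s|%d:%d", taxa[i], taxa[j], ridx[i, ij], ridx[j, ij])
    gi <- !gap[i, ] & gap[j, ]   # residue in i aligned to gap in j
    gj <- gap[i, ] & !gap[j, ]
    rg <- sprintf("%s|%s|%d:g%d", taxa[i], taxa[j],
                  ridx[i, gi], which(gi))
    gr <- sprintf("%s|%s|g%d:%d", taxa[i], taxa[j],
                  which(gj), ridx[j, gj])
    out <- c(out, rr, rg, gr)
  }
  out
}

#' Distance between two alignments of the same sequences
#'
#' A pair-homology distance in the spirit of MetAl's positional `d_pos`
#' metric: each alignment is decomposed into homology statements (aligned
#' residue-residue index pairs per sequence pair, plus residue-gap
#' statements tagged with the gap's column index), and the distance is
#' `1 - |H_a intersect H_b| / max(|H_a|, |H_b|)`. Zero iff the alignments
#' assert identical homologies; bounded in `[0, 1]`. The exact published
#' d_pos normalization differs in detail, so the metric is pluggable in
#' [select_alignment()].
#'
#' @param a,b `"aa_alignment"` objects of the same sequences (identical
#'   taxa and ungapped residues).
#' @return Numeric distance in `[0, 1]`.
#' @export
alignment_distance <- function(a, b) {
  ta <- sort(rownames(unclass(a))); tb <- sort(rownames(unclass(b)))
  if (!identical(ta, tb)) stop("alignments have different sequence sets")
  sa <- gsub("-", "", as_strings(a))[ta]
  sb <- gsub("-", "", as_strings(b))[ta]
  if (!identical(sa, sb))
    stop("underlying (ungapped) sequences differ between alignments")
  ha <- homology_statements(a); hb <- homology_statements(b)
  denom <- max(length(ha), length(hb))
  if (denom == 0) return(0)
  1 - length(intersect(ha, hb)) / denom
}

# BLOSUM62 over the 20 standard residues, normalized pair scores to [0,1]
blosum62_norm <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      b <- e$BLOSUM62[AA_LETTERS, AA_LETTERS]
      tab <<- (b - min(b)) / (max(b) - min(b))
    }
    tab
  }
})

#' Column-based mean amino-acid similarity score
#'
#' Mean over columns of the normalized sum-of-pairs similarity: each
#' residue pair is scored with BLOSUM62 rescaled to `[0, 1]` by the
#' table's min/max; pairs involving a gap or `X` score 0, and the column
#' score is the mean over all sequence pairs. This is a norMD-style
#' surrogate (normalized mean sum-of-pairs), labelled as such in outputs.
#'
#' @param aln An `"aa_alignment"` with >= 2 sequences.
#' @return Numeric score in `[0, 1]`.
#' @export
column_similarity_score <- function(aln) {
  m <- unclass(aln)
  stopifnot(nrow(m) >= 2L)
  b <- blosum62_norm()
  n <- nrow(m)
  npair <- n * (n - 1) / 2
  colscore <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    tot <- 0
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      if (col[i] %in% AA_LETTERS && col[k] %in% AA_LETTERS)
        tot <- tot + b[col[i], col[k]]
    }
    tot / npair
  }, numeric(1))
  mean(colscore)
}

#' Alignment-selection configuration
#'
#' @param distance_threshold Agreement threshold: a pair of alignments
#'   with distance strictly below it is judged mutually concordant.
#' @param seed Integer seed for the random pick on full agreement.
#' @param distance Function of two alignments returning a distance
#'   (default [alignment_distance()]).
#' @param column_score Function of one alignment returning a similarity
#'   score (default [column_similarity_score()]).
#' @return List of class `"alignment_choice_config"`.
#' @export
alignment_choice_config <- function(distance_threshold = 0.15, seed = 1L,
                                    distance = alignment_distance,
                                    column_score = column_similarity_score) {
  stopifnot(distance_threshold > 0, distance_threshold < 1)
  structure(list(distance_threshold = distance_threshold, seed = seed,
                 distance = distance, column_score = column_score),
            class = "alignment_choice_config")
}

#' Select the best of three candidate alignments
#'
#' The three pairwise alignment distances are computed. If every pair is
#' in mutual agreement (distance strictly below the threshold; a distance
#' exactly at the threshold counts as discordant), the choice among the
#' interchangeable candidates is a seeded uniform pick. Otherwise the
#' candidate with the highest column similarity score is selected (ties
#' broken by input order).
#'
#' @param candidates List of exactly 3 `"aa_alignment"`s of the same
#'   sequences.
#' @param cfg An [alignment_choice_config()].
#' @return List with `index` (chosen candidate), and `rationale` (list
#'   with `rule` = `"agreement"` or `"discordant"`, the `distances`, and
#'   `scores` when computed).
#' @export
select_alignment <- function(candidates, cfg = alignment_choice_config()) {
  if (length(candidates) != 3L)
    stop("exactly 3 candidate alignments are expected")
  d <- c(`1-2` = cfg$distance(candidates[[1]], candidates[[2]]),
         `1-3` = cfg$distance(candidates[[1]], candidates[[3]]),
         `2-3` = cfg$distance(candidates[[2]], candidates[[3]]))
  if (all(d < cfg$distance_threshold)) {
    set.seed(cfg$seed)
    idx <- sample.int(3L, 1L)
    return(list(index = idx,
                rationale = list(rule = "agreement", distances = d,
                                 scores = NULL)))
  }
  scores <- vapply(candidates, cfg$column_score, numeric(1))
  list(index = which.max(scores),
       rationale = list(rule = "discordant", distances = d, scores = scores))
}
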