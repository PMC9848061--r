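AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
ALN_ALPHABET <- c(AA_LETTERS, "-", "X")

#' Construct an amino-acid alignment
#'
#' Alignments are stored as character matrices (rows = taxa, columns =
#' sites) over the 20 amino-acid letters plus gap `-` and ambiguity `X`.
#'
#' @param sequences Named character vector of equal-length strings, or a
#'   character matrix with taxon rownames.
#' @param strict If `TRUE` (default) illegal characters are an error;
#'   otherwise they are replaced by `X` with a warning.
#' @return An object of class `"aa_alignment"` (a character matrix).
#' @export
aa_alignment <- function(sequences, strict = TRUE) {
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    stopifnot(is.character(sequences))
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named by taxon")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: taxon '",
           names(sequences)[which(lens != lens[1])[1]],
           "' has length ", lens[lens != lens[1]][1],
           " but expected ", lens[1])
    if (lens[1] < 1L) stop("alignment length must be >= 1")
    m <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
    rownames(m) <- names(sequences)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named by taxon")
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon: ", rownames(m)[duplicated(rownames(m))][1])
  bad <- !(m %in% ALN_ALPHABET)
  dim(bad) <- dim(m)
  if (any(bad)) {
    if (strict) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      stop("illegal character '", m[bad][1], "' for taxon '",
           rownames(m)[ij[1]], "' at site ", ij[2])
    }
    warning(sum(bad), " illegal characters replaced by 'X'")
    m[bad] <- "X"
  }
  structure(m, class = c("aa_alignment", class(m)))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("amino-acid alignment: %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

as_strings <- function(aln) {
  apply(unclass(aln), 1, paste, collapse = "")
}

#' Read an amino-acid alignment (FASTA or relaxed PHYLIP)
#'
#' FASTA is read through [Biostrings::readAAStringSet()]. PHYLIP is the
#' relaxed sequential dialect: a header line `ntaxa nsites`, then one record
#' per taxon consisting of a whitespace-delimited name followed by the
#' sequence (which may wrap across lines).
#'
#' @param path Input file.
#' @param format `"auto"` (sniff: `>` means FASTA), `"fasta"`, or
#'   `"phylip"`.
#' @param strict Passed to [aa_alignment()].
#' @return An `"aa_alignment"`.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip"),
                           strict = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    seqs <- stats::setNames(as.character(ss),
                            sub("\\s.*$", "", names(ss)))
    return(aa_alignment(seqs, strict = strict))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("malformed PHYLIP header: ", lines[1])
  ntax <- as.integer(hdr[1]); nsite <- as.integer(hdr[2])
  toks <- unlist(strsplit(trimws(lines[-1]), "\\s+"))
  seqs <- character(0)
  i <- 1L
  for (t in seq_len(ntax)) {
    if (i > length(toks)) stop("PHYLIP file truncated at taxon ", t)
    name <- toks[i]; i <- i + 1L
    s <- ""
    while (nchar(s) < nsite) {
      if (i > length(toks))
        stop("PHYLIP sequence for taxon '", name, "' shorter than ", nsite)
      s <- paste0(s, toks[i]); i <- i + 1L
    }
    if (nchar(s) != nsite)
      stop("PHYLIP sequence for taxon '", name, "' has ", nchar(s),
           " sites, expected ", nsite)
    seqs[name] <- s
  }
  aa_alignment(seqs, strict = strict)
}

#' Write an amino-acid alignment
#'
#' @param aln An `"aa_alignment"`.
#' @param path Output file.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @param width Line-wrap width for FASTA.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip"),
                            width = 70L) {
  format <- match.arg(format)
  seqs <- as_strings(aln)
  if (format == "fasta") {
    con <- file(path, "w"); on.exit(close(con))
    for (tx in names(seqs)) {
      writeLines(paste0(">", tx), con)
      s <- seqs[[tx]]
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  } else {
    writeLines(c(sprintf("%d %d", nrow(aln), ncol(aln)),
                 sprintf("%s  %s", names(seqs), seqs)), path)
  }
  invisible(path)
}

## --- supermatrix ----------------------------------------------------------

#' Concatenate orthogroup alignments into a supermatrix
#'
#' Builds a single alignment over the union of taxa; a taxon absent from an
#' orthogroup is filled with gaps across that partition. Partition
#' coordinates are recorded 1-based inclusive (the RAxML convention), and
#' per-taxon occupancy is the fraction of non-gap sites.
#'
#' @param orthogroups Named list of `"aa_alignment"` objects, in the order
#'   partitions should appear.
#' @return Object of class `"supermatrix"`: list with `alignment`,
#'   `partitions` (data frame name/start/end), and `occupancy`.
#' @export
concatenate <- function(orthogroups) {
  if (!length(orthogroups)) stop("no orthogroups to concatenate")
  if (is.null(names(orthogroups)))
    names(orthogroups) <- sprintf("OG%04d", seq_along(orthogroups))
  taxa <- sort(unique(unlist(lapply(orthogroups, rownames))))
  lens <- vapply(orthogroups, ncol, integer(1))
  total <- sum(lens)
  m <- matrix("-", nrow = length(taxa), ncol = total, dimnames = list(taxa, NULL))
  end <- cumsum(lens); start <- end - lens + 1L
  for (i in seq_along(orthogroups)) {
    og <- orthogroups[[i]]
    m[rownames(og), start[i]:end[i]] <- unclass(og)
  }
  aln <- structure(m, class = c("aa_alignment", class(m)))
  structure(list(
    alignment = aln,
    partitions = data.frame(name = names(orthogroups), start = start,
                            end = end, row.names = NULL),
    occupancy = rowMeans(m != "-")),
    class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d sites in %d partitions (mean occupancy %.2f)\n",
              nrow(x$alignment), ncol(x$alignment), nrow(x$partitions),
              mean(x$occupancy)))
  invisible(x)
}

# columns whose non-gap, non-X residues are all identical (all-gap/X counts
# as constant too)
constant_columns <- function(m) {
  apply(m, 2, function(col) {
    res <- col[col != "-" & col != "X"]
    length(unique(res)) <= 1L
  })
}

#' Remove constant sites from a supermatrix
#'
#' A column is constant when all its non-gap residues are identical,
#' ignoring gaps and treating `X` as non-informative (a column of one
#' residue plus X's is constant; an all-gap column is dropped too).
#' Partition coordinates are re-mapped; the old-to-new site map is attached
#' as attribute `"site_map"` (NA for removed sites). Partitions left empty
#' are dropped.
#'
#' @param matrix A `"supermatrix"`.
#' @return A `"supermatrix"` without constant sites.
#' @export
remove_constant_sites <- function(matrix) {
  m <- unclass(matrix$alignment)
  keep <- !constant_columns(m)
  site_map <- rep(NA_integer_, ncol(m))
  site_map[keep] <- seq_len(sum(keep))
  newm <- m[, keep, drop = FALSE]
  parts <- matrix$partitions
  out <- list()
  for (i in seq_len(nrow(parts))) {
    kept <- site_map[parts$start[i]:parts$end[i]]
    kept <- kept[!is.na(kept)]
    if (length(kept))
      out[[length(out) + 1L]] <- data.frame(name = parts$name[i],
                                            start = min(kept), end = max(kept))
  }
  res <- structure(list(
    alignment = structure(newm, class = c("aa_alignment", class(newm))),
    partitions = if (length(out)) do.call(rbind, out)
                 else parts[0, , drop = FALSE],
    occupancy = rowMeans(newm != "-")),
    class = "supermatrix")
  attr(res, "site_map") <- site_map
  res
}

#' Restrict a supermatrix or orthogroup list to a taxon subset
#'
#' Rows outside `keep` are removed; columns are untouched. For orthogroup
#' lists, orthogroups left with fewer than 4 taxa are flagged in attribute
#' `"flagged"` (their trees are undefined as unrooted topologies).
#'
#' @param x A `"supermatrix"` or a (named) list of `"aa_alignment"`s.
#' @param keep Character vector of taxa to retain.
#' @return Same type as `x`.
#' @export
subset_taxa <- function(x, keep) {
  stopifnot(length(keep) >= 1L)
  if (inherits(x, "supermatrix")) {
    taxa <- intersect(rownames(x$alignment), keep)
    if (!length(taxa)) stop("keep set is disjoint from matrix taxa")
    m <- unclass(x$alignment)[taxa, , drop = FALSE]
    return(structure(list(
      alignment = structure(m, class = c("aa_alignment", class(m))),
      partitions = x$partitions,
      occupancy = rowMeans(m != "-")),
      class = "supermatrix"))
  }
  stopifnot(is.list(x))
  if (!length(intersect(unlist(lapply(x, rownames)), keep)))
    stop("keep set is disjoint from orthogroup taxa")
  out <- lapply(x, function(og) {
    taxa <- intersect(rownames(og), keep)
    m <- unclass(og)[taxa, , drop = FALSE]
    structure(m, class = c("aa_alignment", class(m)))
  })
  flagged <- names(out)[vapply(out, nrow, integer(1)) < 4L]
  attr(out, "flagged") <- flagged
  out
}

#' Write a RAxML-style partition file
#'
#' One line per partition: `MODEL, name = start-end` with 1-based inclusive
#' coordinates.
#'
#' @param matrix A `"supermatrix"`.
#' @param path Output path.
#' @param model Model string to prefix each line with.
#' @export
write_partitions <- function(matrix, path, model = "AUTO") {
  p <- matrix$partitions
  writeLines(sprintf("%s, %s = %d-%d", model, p$name, p$start, p$end), path)
  invisible(path)
}

#' Write per-taxon occupancy as TSV
#' @param matrix A `"supermatrix"`.
#' @param path Output path.
#' @export
write_occupancy <- function(matrix, path) {
  utils::write.table(
    data.frame(taxon = names(matrix$occupancy),
               occupancy = unname(matrix$occupancy)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
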