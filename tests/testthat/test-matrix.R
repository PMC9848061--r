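test_that("alignment construction validates shape and alphabet", {
  aln <- aa_alignment(c(t1 = "ACDEF", t2 = "AC-EF", t3 = "ACDEX"))
  expect_equal(ncol(aln), 5)
  expect_error(aa_alignment(c(t1 = "ACDE", t2 = "AC")), "ragged.*t2")
  expect_error(aa_alignment(c(t1 = "ACDE", t1 = "ACDE")), "duplicate")
  expect_error(aa_alignment(c(t1 = "AC1E")), "illegal")
  expect_warning(lax <- aa_alignment(c(t1 = "AC?E"), strict = FALSE),
                 "replaced")
  expect_equal(unname(unclass(lax)[1, 3]), "X")
})

test_that("FASTA and relaxed PHYLIP round-trip losslessly", {
  aln <- aa_alignment(c(taxon_one = "ACDEFGHIKL", tx2 = "ACDEF-HIKX",
                        a_rather_long_name = "MNPQRSTVWY"))
  fa <- tempfile(fileext = ".fasta"); ph <- tempfile(fileext = ".phy")
  write_alignment(aln, fa, "fasta")
  write_alignment(aln, ph, "phylip")
  expect_equal(unclass(read_alignment(fa)), unclass(aln))
  expect_equal(unclass(read_alignment(ph)), unclass(aln))
  # format sniffing
  expect_equal(unclass(read_alignment(fa, "auto")), unclass(aln))
  expect_equal(unclass(read_alignment(ph, "auto")), unclass(aln))
})

test_that("concatenation records partitions, gaps absentees, sums occupancy", {
  og1 <- aa_alignment(c(A = "AAAAAAAAAA", B = "CCCCCCCCCC", C = "DDDDDDDDDD"))
  og2 <- aa_alignment(c(B = strrep("E", 20), C = strrep("F", 20),
                        D = strrep("G", 20)))
  sm <- concatenate(list(og1 = og1, og2 = og2))
  expect_equal(ncol(sm$alignment), 30)
  expect_equal(sm$partitions$start, c(1L, 11L))
  expect_equal(sm$partitions$end, c(10L, 30L))
  expect_equal(unname(sm$occupancy["A"]), 10 / 30)
  expect_true(all(unclass(sm$alignment)["A", 11:30] == "-"))
  # single orthogroup is the identity
  one <- concatenate(list(og1 = og1))
  expect_equal(unclass(one$alignment), unclass(og1))
  expect_equal(nrow(one$partitions), 1)
  expect_error(concatenate(list()), "no orthogroups")
})

test_that("per-taxon residue counts are preserved by concatenation", {
  set.seed(3)
  ogs <- lapply(1:5, function(i)
    random_alignment(sample(3:6, 1), sample(5:20, 1), gap_rate = 0.2))
  names(ogs) <- paste0("og", 1:5)
  sm <- concatenate(ogs)
  for (tx in rownames(sm$alignment)) {
    direct <- sum(unclass(sm$alignment)[tx, ] != "-")
    parts <- sum(vapply(ogs, function(og)
      if (tx %in% rownames(og)) sum(unclass(og)[tx, ] != "-") else 0L,
      numeric(1)))
    expect_equal(direct, parts)
  }
  # total length invariant to order, partition names follow order
  sm_rev <- concatenate(rev(ogs))
  expect_equal(ncol(sm_rev$alignment), ncol(sm$alignment))
  expect_equal(sm_rev$partitions$name, rev(sm$partitions$name))
})

test_that("constant-site removal is gap-insensitive and idempotent", {
  aln <- aa_alignment(c(t1 = "AACAA", t2 = "AACA-", t3 = "AGC-A"))
  # col1 constant, col2 variable, col3 constant, col4 constant w/ gap,
  # col5 constant w/ gap
  sm <- concatenate(list(og = aln))
  out <- remove_constant_sites(sm)
  expect_equal(ncol(out$alignment), 1)
  expect_equal(attr(out, "site_map"), c(NA, 1L, NA, NA, NA))
  again <- remove_constant_sites(out)
  expect_equal(unclass(again$alignment), unclass(out$alignment))
  # X is non-informative: one residue plus X's is constant
  alnx <- aa_alignment(c(t1 = "AX", t2 = "AA", t3 = "XA"))
  expect_equal(ncol(remove_constant_sites(concatenate(list(a = alnx)))$alignment),
               0)
})

test_that("constant-site counts match a per-column recount on random data", {
  set.seed(17)
  aln <- random_alignment(6, 200, gap_rate = 0.15, alphabet = c("A", "C"))
  sm <- concatenate(list(og = aln))
  out <- remove_constant_sites(sm)
  m <- unclass(aln)
  brute <- sum(vapply(seq_len(ncol(m)), function(j) {
    r <- m[, j][m[, j] != "-"]
    length(unique(r)) <= 1
  }, logical(1)))
  expect_equal(ncol(out$alignment), ncol(m) - brute)
})

test_that("partition re-mapping survives constant-site removal", {
  og1 <- aa_alignment(c(t1 = "AAC", t2 = "AAG"))   # cols 1,2 constant
  og2 <- aa_alignment(c(t1 = "TTAC", t2 = "TAAG")) # col2 variable, col4 variable
  sm <- remove_constant_sites(concatenate(list(og1 = og1, og2 = og2)))
  expect_equal(sm$partitions$name, c("og1", "og2"))
  expect_equal(sm$partitions$start, c(1L, 2L))
  expect_equal(sm$partitions$end, c(1L, 3L))
})

test_that("splitting a supermatrix at partition boundaries recovers inputs", {
  set.seed(23)
  ogs <- list(a = random_alignment(4, 12), b = random_alignment(4, 7))
  rownames_b <- rownames(unclass(ogs$b))
  sm <- concatenate(ogs)
  for (i in seq_len(nrow(sm$partitions))) {
    p <- sm$partitions[i, ]
    block <- unclass(sm$alignment)[, p$start:p$end, drop = FALSE]
    orig <- unclass(ogs[[p$name]])
    expect_equal(block[rownames(orig), ], orig, ignore_attr = TRUE)
    absent <- setdiff(rownames(block), rownames(orig))
    if (length(absent)) expect_true(all(block[absent, ] == "-"))
  }
})

test_that("taxon subsetting keeps columns, flags tiny orthogroups", {
  og <- random_alignment(6, 10)
  taxa <- rownames(unclass(og))
  sm <- concatenate(list(og = og))
  sub <- subset_taxa(sm, taxa[1:4])
  expect_equal(nrow(sub$alignment), 4)
  expect_equal(ncol(sub$alignment), 10)
  # identity
  idem <- subset_taxa(sm, taxa)
  expect_equal(unclass(idem$alignment), unclass(sm$alignment))
  expect_error(subset_taxa(sm, c("nope")), "disjoint")
  ogs <- list(big = og, small = og)
  out <- subset_taxa(ogs, taxa[1:3])
  expect_equal(attr(out, "flagged"), c("big", "small"))
})

test_that("partition and occupancy files are written in standard formats", {
  sm <- concatenate(list(og1 = random_alignment(3, 5),
                         og2 = random_alignment(3, 8)))
  pf <- tempfile(); of <- tempfile()
  write_partitions(sm, pf, model = "LG")
  expect_equal(readLines(pf), c("LG, og1 = 1-5", "LG, og2 = 6-13"))
  write_occupancy(sm, of)
  occ <- read.delim(of)
  expect_equal(nrow(occ), nrow(sm$alignment))
})
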