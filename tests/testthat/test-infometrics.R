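test_that("variable and parsimony-informative sites follow their definitions", {
  # columns over 4 taxa: AAAA (constant), AAAG (variable), AAGG (informative)
  aln <- aa_alignment(c(t1 = "AAA", t2 = "AAA", t3 = "AAG", t4 = "AGG"))
  sc <- site_counts(aln)
  expect_equal(sc$variable_sites, 2)
  expect_equal(sc$parsimony_informative_sites, 1)
  expect_equal(sc$length, 3)
  const <- aa_alignment(c(t1 = "AAAA", t2 = "AAAA"))
  expect_equal(site_counts(const),
               list(variable_sites = 0L, parsimony_informative_sites = 0L,
                    length = 4L))
})

test_that("site counts equal a per-column brute-force tally on random data", {
  set.seed(31)
  aln <- random_alignment(10, 100, gap_rate = 0.1, alphabet = c("A", "C", "D"))
  sc <- site_counts(aln)
  m <- unclass(aln)
  v <- 0L; pis <- 0L
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j][!(m[, j] %in% c("-", "X"))])
    if (length(tab) >= 2) {
      v <- v + 1L
      if (sum(tab >= 2) >= 2) pis <- pis + 1L
    }
  }
  expect_equal(sc$variable_sites, v)
  expect_equal(sc$parsimony_informative_sites, pis)
  # invariances: taxon order and column order
  sc2 <- site_counts(aa_alignment(m[sample(nrow(m)), sample(ncol(m))]))
  expect_equal(sc2$variable_sites, v)
  expect_equal(sc2$parsimony_informative_sites, pis)
})

test_that("treeness and RCV match hand-computed sums", {
  # unrooted ((A:1,B:2):9,C:4,D:5): internal 9 of total 21
  tr <- parse_newick("((A:1,B:2):9,C:4,D:5);")
  aln <- aa_alignment(c(A = "AA", B = "AC", C = "CC", D = "AC"))
  res <- treeness_rcv(tr, aln)
  expect_equal(res$treeness, 9 / 21)
  # counts: A has (A:2), B (A:1,C:1), C (C:2), D (A:1,C:1); means A=1, C=1
  # sum |dev| = 2 + 0 + 2 + 0 = 4; rcv = 4 / (4 taxa * 2 sites)
  expect_equal(res$rcv, 0.5)
  expect_equal(res$ratio, (9 / 21) / 0.5)
  # star tree: treeness 0
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(treeness_rcv(star, aln)$treeness, 0)
  # identical rows: rcv 0, ratio undefined
  same <- aa_alignment(c(A = "AC", B = "AC", C = "AC", D = "AC"))
  res2 <- treeness_rcv(tr, same)
  expect_equal(res2$rcv, 0)
  expect_true(is.na(res2$ratio))
})

test_that("long-branch scores center at zero and match the patristic oracle", {
  bal <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  lb <- long_branch_scores(bal)
  expect_equal(unname(lb$per_taxon), rep(0, 4), tolerance = 1e-12)
  # doubling one pendant edge raises that taxon above the rest
  skew <- parse_newick("((A:2,B:1):1,(C:1,D:1):1);")
  lb2 <- long_branch_scores(skew)
  expect_gt(lb2$per_taxon[["A"]], 0)
  expect_true(all(lb2$per_taxon[c("B", "C", "D")] < lb2$per_taxon[["A"]]))
  expect_equal(lb2$mean_abs, 0, tolerance = 1e-12)  # means average out
  # random tree vs explicit path-length oracle
  set.seed(19)
  tr <- random_unrooted_tree(7)
  lb3 <- long_branch_scores(tr)
  taxa <- tr$tip.label
  pm <- outer(taxa, taxa, Vectorize(function(a, b)
    if (a == b) 0 else oracle_patristic(tr, a, b)))
  grand <- mean(pm[upper.tri(pm)])
  expected <- 100 * (rowSums(pm) / (length(taxa) - 1) / grand - 1)
  expect_equal(unname(lb3$per_taxon), expected, tolerance = 1e-8)
})

test_that("saturation is the through-origin slope of p vs patristic distance", {
  # star tree, pendant edges 0.05: patristic 0.1 for every pair; disjoint
  # 5-site difference blocks give every pair p-distance 10/100
  base <- strrep("A", 100)
  mutate <- function(s, at) {
    v <- strsplit(s, "")[[1]]; v[at] <- "C"; paste(v, collapse = "")
  }
  aln <- aa_alignment(c(t1 = mutate(base, 1:5), t2 = mutate(base, 6:10),
                        t3 = mutate(base, 11:15), t4 = mutate(base, 16:20)))
  tr <- parse_newick("(t1:0.05,t2:0.05,t3:0.05,t4:0.05);")
  expect_equal(saturation(tr, aln), 1.0)
  # doubling the tree halves the slope
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  expect_equal(saturation(tr2, aln), 0.5)
})

test_that("mean bipartition support averages internal supports", {
  tr <- parse_newick("(((A,B)95,(C,D)80)62,E,F);")
  expect_equal(mean_bipartition_support(tr), 79)
  expect_equal(mean_bipartition_support(parse_newick("((A,B)0,C,D);")), 0)
  expect_true(is.na(mean_bipartition_support(parse_newick("((A,B),C,D);"))))
})

test_that("RCFV matches hand computation and frequency-based invariances", {
  expect_equal(rcfv(aa_alignment(c(t1 = "ACDA", t2 = "ACDA", t3 = "ACDA"))), 0)
  # one all-A taxon vs one all-C taxon: sum |f - fbar| = 1 per taxon
  expect_equal(rcfv(aa_alignment(c(t1 = "AAAA", t2 = "CCCC"))), 1.0)
  set.seed(41)
  aln <- random_alignment(5, 60, gap_rate = 0.1)
  perm <- aa_alignment(unclass(aln)[, sample(60)])
  expect_equal(rcfv(perm), rcfv(aln))
})

test_that("chi-square homogeneity matches the textbook statistic", {
  same <- aa_alignment(c(t1 = "AACC", t2 = "CACA", t3 = "CCAA"))
  res <- chi2_homogeneity(same)
  expect_equal(res$stat, 0)
  expect_equal(res$p, 1)
  # 2x2 counts (A:90,C:10) vs (A:10,C:90): sum (o-e)^2/e = 4 * 40^2/50
  big <- aa_alignment(c(t1 = paste0(strrep("A", 90), strrep("C", 10)),
                        t2 = paste0(strrep("A", 10), strrep("C", 90))))
  res2 <- chi2_homogeneity(big)
  expect_equal(res2$stat, 128)
  expect_equal(res2$df, 1)
  # invariant to taxon order
  flip <- aa_alignment(c(t2 = paste0(strrep("A", 10), strrep("C", 90)),
                         t1 = paste0(strrep("A", 90), strrep("C", 10))))
  expect_equal(chi2_homogeneity(flip)$stat, res2$stat)
  # degenerate: one observed state
  expect_true(is.na(chi2_homogeneity(aa_alignment(c(t1 = "AA", t2 = "AA")))$stat))
})

test_that("group comparison flags shifted metrics and matches a permutation null", {
  set.seed(53)
  base <- data.frame(rcfv = rnorm(50, 1), treeness = rnorm(50, 0.5))
  cmp_same <- compare_groups(base, base)
  expect_true(all(cmp_same$stars == "ns"))
  shifted <- base; shifted$rcfv <- shifted$rcfv + 10
  cmp <- compare_groups(shifted, base)
  expect_equal(cmp$stars[cmp$metric == "rcfv"], "****")
  expect_equal(cmp$stars[cmp$metric == "treeness"], "ns")
  # permutation oracle on small groups, no ties
  x <- c(1.2, 3.4, 0.7, 5.1, 2.2, 4.4, 0.1, 6.3, 2.9, 3.7)
  y <- c(2.1, 4.8, 1.9, 7.2, 3.3, 5.5, 1.1, 8.0, 4.1, 6.1)
  p_pkg <- compare_groups(data.frame(m = x), data.frame(m = y))$p
  pooled <- c(x, y)
  stat_obs <- sum(rank(pooled)[1:10])
  set.seed(99)
  null <- replicate(10000, sum(sample(rank(pooled), 10)))
  p_perm <- mean(abs(null - mean(null)) >= abs(stat_obs - mean(null)) - 1e-9)
  expect_lt(abs(p_pkg - p_perm), 0.05)
})

test_that("the combined metric row carries every criterion", {
  set.seed(61)
  tr <- random_unrooted_tree(6)
  tr$node.label <- c("", "90", "80", "70")[seq_len(tr$Nnode)]
  aln <- random_alignment(6, 50)
  rownames(aln) <- tr$tip.label
  row <- orthogroup_metrics(aa_alignment(unclass(aln)), tr)
  expect_equal(row$alignment_length, 50)
  expect_false(is.na(row$treeness))
  expect_false(is.na(row$saturation))
  expect_false(is.na(row$rcfv))
  expect_equal(row$mean_bipartition_support, 80)
})
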