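small_spec <- function(...) {
  synthetic_spec(clan_sizes = c(P = 4, Q = 4, R = 3, S = 1),
                 n_orthogroups = 30, aln_length = c(60, 120), seed = 5, ...)
}

test_that("generators are pure functions of spec and seed", {
  spec <- small_spec()
  expect_identical(write_newick(simulate_species_tree(spec)),
                   write_newick(simulate_species_tree(spec)))
  sp <- simulate_species_tree(spec)
  g1 <- simulate_gene_trees(sp, spec)
  g2 <- simulate_gene_trees(sp, spec)
  expect_identical(vapply(g1$trees, write_newick, character(1)),
                   vapply(g2$trees, write_newick, character(1)))
  expect_identical(g1$truth, g2$truth)
  a1 <- simulate_alignment(sp, spec, length = 80)
  a2 <- simulate_alignment(sp, spec, length = 80)
  expect_identical(unclass(a1), unclass(a2))
  spec2 <- small_spec(); spec2$seed <- 6L
  expect_false(identical(write_newick(simulate_species_tree(spec)),
                         write_newick(simulate_species_tree(spec2))))
})

test_that("the species tree realizes every clan with the requested taxa", {
  spec <- small_spec()
  sp <- simulate_species_tree(spec)
  expect_equal(length(sp$tip.label), sum(spec$clan_sizes))
  clans <- default_clans(spec)
  for (cl in countable_clans(clans))
    expect_equal(as.character(clan_status(sp, clans[[cl]])), "RECOVERED")
  expect_equal(as.character(clan_status(sp, clans$S)), "INSUFFICIENT")
})

test_that("the stem stretch lengthens the designated clan's stem branch", {
  spec <- small_spec(stem_stretch = 1, stem_stretch_clan = "Q")
  long <- small_spec(stem_stretch = 25, stem_stretch_clan = "Q")
  expect_gt(sum(simulate_species_tree(long)$edge.length),
            sum(simulate_species_tree(spec)$edge.length))
})

test_that("zero violation rate leaves all sufficiently sampled clans intact", {
  spec <- small_spec(violation_rate = 0, dropout = 0.3)
  sp <- simulate_species_tree(spec)
  gt <- simulate_gene_trees(sp, spec)
  expect_true(all(!gt$truth$violating))
  rep <- check_clans(gt$trees, default_clans(spec))
  expect_true(all(rep$statuses$status %in% c("RECOVERED", "INSUFFICIENT")))
})

test_that("total dropout makes a clan insufficient everywhere", {
  spec <- small_spec(dropout = c(P = 1, Q = 0, R = 0, S = 0),
                     violation_rate = 0)
  sp <- simulate_species_tree(spec)
  gt <- simulate_gene_trees(sp, spec)
  rep <- check_clans(gt$trees, default_clans(spec))
  stP <- rep$statuses[rep$statuses$clan == "P", "status"]
  expect_true(all(stP == "INSUFFICIENT"))
})

test_that("recorded moves predict which trees violate a clan", {
  spec <- small_spec(violation_rate = 0.5, dropout = 0)
  sp <- simulate_species_tree(spec)
  gt <- simulate_gene_trees(sp, spec)
  rep <- check_clans(gt$trees, default_clans(spec))
  # every tree with a recorded move violates >=1 countable clan; every
  # clean tree violates none
  violated <- tapply(rep$statuses$status == "VIOLATED",
                     rep$statuses$orthogroup, any)[gt$truth$orthogroup]
  expect_equal(as.vector(violated), gt$truth$violating)
})

test_that("the observed violating fraction sits inside the binomial envelope", {
  spec <- small_spec(violation_rate = 0.4)
  spec$n_orthogroups <- 150L
  sp <- simulate_species_tree(spec)
  gt <- simulate_gene_trees(sp, spec)
  phat <- mean(gt$truth$violating)
  se <- sqrt(0.4 * 0.6 / 150)
  expect_lt(abs(phat - 0.4), 3 * se)
})

test_that("a zero-length tree yields identical sequences", {
  spec <- small_spec()
  sp <- simulate_species_tree(spec)
  sp$edge.length[] <- 0
  aln <- simulate_alignment(sp, spec, length = 50)
  expect_equal(length(unique(as.character(
    apply(unclass(aln), 1, paste, collapse = "")))), 1)
})

test_that("doubling branch lengths lowers the saturation slope", {
  spec <- small_spec(gamma_shape = 1)
  sp <- simulate_species_tree(spec)
  fast <- sp; fast$edge.length <- sp$edge.length * 6
  a_slow <- simulate_alignment(sp, spec, length = 400, seed = 31)
  a_fast <- simulate_alignment(fast, spec, length = 400, seed = 31)
  expect_gt(saturation(sp, a_slow), saturation(fast, a_fast))
})

test_that("the compositional shift raises RCFV in paired simulations", {
  spec0 <- small_spec(comp_shift = 0, comp_shift_clan = "P",
                      stem_stretch_clan = "P")
  spec1 <- small_spec(comp_shift = 0.5, comp_shift_clan = "P",
                      stem_stretch_clan = "P")
  sp <- simulate_species_tree(spec0)
  r0 <- rcfv(simulate_alignment(sp, spec0, length = 800, seed = 37))
  r1 <- rcfv(simulate_alignment(sp, spec1, length = 800, seed = 37))
  expect_gt(r1, r0)
})

test_that("gap injection hits roughly the requested occupancy", {
  aln <- random_alignment(10, 200)
  gapped <- inject_gaps(aln, 0.25, seed = 41)
  frac <- mean(unclass(gapped) == "-")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
  expect_identical(unclass(inject_gaps(aln, 0.25, seed = 41)),
                   unclass(gapped))
})

test_that("profile construction hits each requested recovered-clan count", {
  clans <- clan_set(a = c("a1", "a2"), b = c("b1", "b2"), c = c("c1", "c2"),
                    d = c("d1", "d2"), e = c("e1", "e2"), z = "z1")
  counts <- c(`5` = 2, `4` = 3, `3` = 4, `2` = 5, `1` = 6, `0` = 2)
  trees <- construct_profile_dataset(counts, clans, seed = 43)
  expect_length(trees, sum(counts))
  rep <- check_clans(trees, clans)
  expect_equal(unname(clan_histogram(rep)), unname(counts))
  expect_equal(attr(trees, "n_target"),
               rep(as.integer(names(counts)), counts))
  expect_error(construct_profile_dataset(c(`7` = 1), clans, seed = 1),
               "infeasible")
})

test_that("single-tree profiles recover exactly the requested clans", {
  clans <- clan_set(a = c("a1", "a2"), b = c("b1", "b2"), c = c("c1", "c2"),
                    d = c("d1", "d2"), e = c("e1", "e2"))
  trees <- construct_profile_dataset(c(`3` = 1), clans, seed = 47)
  rep <- check_clans(trees, clans)
  expect_equal(unname(rep$n_recovered), 3L)
})
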