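# Long-term evolution: reference projection, Fitch parsimony, site
# rates and the two gene-level rate features.

toy_tree <- function(newick = "((s1:1,s2:1):1,(s3:1,s4:1):1);") {
  ape::read.tree(text = newick)
}

test_that("projection keeps exactly the reference's residue columns", {
  msa <- rbind(ref = c("M", "-", "K", "T"),
               sp2 = c("M", "A", "K", "S"),
               sp3 = c("M", "A", "R", "T"))
  proj <- project_to_reference(msa, "ref")
  expect_equal(ncol(proj), 3)
  expect_equal(attr(proj, "positions"), 1:3)
  expect_equal(unname(proj["ref", ]), c("M", "K", "T"))

  # no gaps -> identity projection
  msa2 <- msa[, c(1, 3, 4)]
  proj2 <- project_to_reference(msa2, "ref")
  expect_equal(unname(proj2), unname(msa2), ignore_attr = TRUE)

  all_gap <- rbind(ref = c("-", "-"), sp2 = c("A", "A"))
  expect_error(project_to_reference(all_gap, "ref"), "all gaps")
  expect_error(project_to_reference(msa, "nope"), "nope")
})

test_that("Fitch counts match hand-checkable columns", {
  tree <- toy_tree()
  expect_equal(fitch_site_substitutions(
    c(s1 = "A", s2 = "A", s3 = "A", s4 = "A"), tree), 0L)
  # A,A,G,G on ((s1,s2),(s3,s4)): one change on the internal edge
  expect_equal(fitch_site_substitutions(
    c(s1 = "A", s2 = "A", s3 = "G", s4 = "G"), tree), 1L)
  # A,G,A,G: no single internal labeling explains it with < 2 changes
  expect_equal(fitch_site_substitutions(
    c(s1 = "A", s2 = "G", s3 = "A", s4 = "G"), tree), 2L)
  # gaps are missing data and never force a substitution
  expect_equal(fitch_site_substitutions(
    c(s1 = "A", s2 = "-", s3 = "A", s4 = "-"), tree), 0L)
  expect_error(fitch_site_substitutions(
    c(s1 = "A", s9 = "G"), tree), "s9")
})

test_that("Fitch equals the exhaustive-labeling minimum on random columns", {
  set.seed(101)
  alphabet <- c("A", "C", "G", "T")
  for (i in 1:120) {
    n_leaves <- sample(3:6, 1)
    tree <- ape::rtree(n_leaves, tip.label = paste0("s", 1:n_leaves))
    res <- sample(c(alphabet, "-"), n_leaves, replace = TRUE,
                  prob = c(rep(0.22, 4), 0.12))
    column <- stats::setNames(res, tree$tip.label)
    expect_equal(fitch_site_substitutions(column, tree),
                 oracle_fitch(column, tree),
                 info = sprintf("case %d", i))
  }
})

test_that("Fitch count respects parsimony bounds and ignores rooting", {
  set.seed(202)
  for (i in 1:60) {
    n_leaves <- sample(4:6, 1)
    tree <- ape::rtree(n_leaves, tip.label = paste0("s", 1:n_leaves))
    column <- stats::setNames(
      sample(c("A", "C", "G", "T"), n_leaves, replace = TRUE),
      tree$tip.label)
    cnt <- fitch_site_substitutions(column, tree)
    k <- length(unique(column))
    expect_gte(cnt, k - 1)
    expect_lte(cnt, (k - 1) * (n_leaves - 1))
    rerooted <- ape::root(ape::unroot(tree),
                          outgroup = sample(tree$tip.label, 1),
                          resolve.root = TRUE)
    expect_equal(fitch_site_substitutions(column, rerooted), cnt)
  }
})

test_that("site rates are substitutions per total branch length", {
  tree <- toy_tree()   # total branch length 6
  expect_equal(site_rate(3L, tree), 0.5)
  expect_equal(site_rate(0L, tree), 0)
  doubled <- tree
  doubled$edge.length <- tree$edge.length * 2
  expect_equal(site_rate(3L, doubled), site_rate(3L, tree) / 2)
  no_lengths <- ape::read.tree(text = "((s1,s2),(s3,s4));")
  expect_error(site_rate(1L, no_lengths), "branch length")
})

test_that("gene rate features follow their definitions", {
  rates <- data.frame(position = c(1, 5), rate = c(0.2, 0.8))
  mut <- make_records(c(1, 1, 1, 5),
                      rep("missense", 4))
  e <- gene_rate_features(rates, mut)
  expect_equal(e[["E_gene"]], 0.5)     # mean over distinct positions
  expect_equal(e[["E_summit"]], 0.2)   # position 1 has 3 of 4 mutations

  # single mutated position: both features agree
  single <- gene_rate_features(rates, make_records(5, "missense"))
  expect_equal(single[["E_gene"]], single[["E_summit"]])

  # tie at positions 2 and 7 -> summit is the lower position
  rates2 <- data.frame(position = c(2, 7), rate = c(0.3, 0.9))
  tied <- gene_rate_features(rates2,
                             make_records(c(2, 2, 7, 7),
                                          rep("missense", 4)))
  expect_equal(tied[["E_summit"]], 0.3)

  # E_gene bounded by the site rates at mutated positions
  set.seed(5)
  for (i in 1:20) {
    r <- data.frame(position = 1:30, rate = stats::rexp(30))
    pos <- sample(1:30, 10, replace = TRUE)
    e_i <- gene_rate_features(r, make_records(pos, rep("missense", 10)))
    expect_gte(e_i[["E_gene"]], min(r$rate[unique(pos)]))
    expect_lte(e_i[["E_gene"]], max(r$rate[unique(pos)]))
  }

  # no coverage -> imputation with a warning
  expect_warning(
    out <- gene_rate_features(rates, make_records(9, "missense"),
                              impute = 0.7),
    "imputing")
  expect_equal(unname(out), c(0.7, 0.7))
})

test_that("simulated alignments give rate-monotone Fitch counts", {
  sim <- gen_toy_phylo(n_species = 8, depth_bys = 0.5,
                       rate_profile = rep(c(0, 2, 10), each = 40),
                       seed = 99)
  rts <- site_rates(sim$alignment, sim$tree, "sp1")
  expect_equal(nrow(rts), 120)
  by_rate <- split(rts$substitutions, rep(c("zero", "mid", "high"),
                                          each = 40))
  expect_equal(mean(by_rate$zero), 0)
  expect_lt(mean(by_rate$mid), mean(by_rate$high))
  # identical under the same seed
  sim2 <- gen_toy_phylo(8, 0.5, rep(c(0, 2, 10), each = 40), seed = 99)
  expect_identical(sim$alignment, sim2$alignment)
})

test_that("Fitch counts agree with an independent parsimony engine", {
  skip_if_not_installed("phangorn")
  set.seed(505)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    tree <- ape::rtree(n, tip.label = paste0("s", 1:n))
    col <- stats::setNames(sample(c("a", "c", "g", "t"), n, TRUE),
                           tree$tip.label)
    dat <- phangorn::phyDat(matrix(col, ncol = 1,
                                   dimnames = list(names(col), NULL)),
                            type = "DNA")
    expect_equal(fitch_site_substitutions(toupper(col), tree),
                 phangorn::parsimony(tree, dat),
                 ignore_attr = TRUE)
  }
})
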