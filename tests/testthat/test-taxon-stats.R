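test_that("clade taxon assignment requires unanimity at the rank", {
  md <- data.frame(
    tip_id = c("t1", "t2", "t3"),
    host_taxon_id = "H", host_genus = "G", site_id = "S",
    phylum = c("Bacteroidota", "Bacteroidota", "Firmicutes"),
    genus = c("g1", "g2", "g3"), stringsAsFactors = FALSE
  )
  expect_equal(assign_clade_taxon(c("t1", "t2"), md, "phylum"), "Bacteroidota")
  expect_true(is.na(assign_clade_taxon(c("t1", "t3"), md, "phylum")))
  expect_true(is.na(assign_clade_taxon(c("t1", "t2"), md, "genus")))
})

test_that("weighted centroids reduce to means and honor weights", {
  res <- data.frame(r_phylo = c(0.2, 0.8), r_geo = c(0.1, 0.3),
                    delta = c(0.1, 0.5))
  # equal weights = arithmetic mean
  out <- weighted_centroids(res, c(1, 1), c("A", "A"))
  expect_equal(out$weighted_mean_r_phylo, 0.5)
  # hand-computed weighted mean: (0.2*1 + 0.8*3) / 4 = 0.65
  out2 <- weighted_centroids(res, c(1, 3), c("A", "A"))
  expect_equal(out2$weighted_mean_r_phylo, 0.65)
  # single-node group passes through
  out3 <- weighted_centroids(res, c(1, 3), c("A", "B"))
  expect_equal(out3$weighted_mean_r_phylo[out3$taxon == "B"], 0.8)
  # centroid lies in the convex hull of the group's points
  expect_true(all(out2$weighted_mean_r_phylo >= min(res$r_phylo) &
                    out2$weighted_mean_r_phylo <= max(res$r_phylo)))
})

test_that("sign test reproduces exact binomial tails", {
  expect_equal(round(sign_test(12, 15), 4), 0.0176)
  expect_equal(sign_test(15, 15), 0.5^15)
  expect_equal(sign_test(0, 15), 1.0)
  expect_error(sign_test(16, 15), "successes")
  # complementarity: P(X >= k) + P(X <= k-1) = 1
  for (k in 1:10) {
    expect_equal(sign_test(k, 10) + pbinom(k - 1, 10, 0.5), 1)
  }
  # two-sided option agrees with binom.test
  expect_equal(sign_test(99, 156, alternative = "two.sided"),
               binom.test(99, 156)$p.value)
})

test_that("weighted t-test reduces to Welch and is weight-scale invariant", {
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(9, mean = 0.5)
    res <- weighted_t_test(a, rep(1, 7), b, rep(1, 9))
    ref <- t.test(a, b)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    # doubling all weights changes nothing
    w1 <- runif(7, 0.5, 2); w2 <- runif(9, 0.5, 2)
    r1 <- weighted_t_test(a, w1, b, w2)
    r2 <- weighted_t_test(a, 2 * w1, b, 2 * w2)
    expect_equal(r1$t, r2$t, tolerance = 1e-12)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
  }
  # identical groups: t = 0, p = 1
  x <- c(1, 2, 3)
  res0 <- weighted_t_test(x, c(1, 2, 1), x, c(1, 2, 1))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_error(weighted_t_test(1, 1, c(1, 2), c(1, 1)), "2 entries")
})

test_that("unique branch length equals the spanning subtree", {
  tr <- tree_from_text("((A:1,B:2):3,(C:4,D:5):6);")
  expect_equal(unique_branch_length(tr, c("A", "B")), 3)
  expect_equal(unique_branch_length(tr, c("A", "C")), 1 + 3 + 6 + 4)
  expect_equal(unique_branch_length(tr, c("A", "B", "C", "D")), 21)
  expect_equal(unique_branch_length(tr, "A"), 0)
})

test_that("phylogenetic ANOVA handles degenerate input and is deterministic", {
  tr <- ape::stree(8, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("x", 1:8)
  grp <- setNames(rep(c("a", "b"), each = 4), tr$tip.label)
  const <- setNames(rep(2, 8), tr$tip.label)
  res <- phylogenetic_anova(tr, const, grp, n_simulations = 50, seed = 1)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  set.seed(2)
  trait <- setNames(rnorm(8), tr$tip.label)
  r1 <- phylogenetic_anova(tr, trait, grp, n_simulations = 200, seed = 9)
  r2 <- phylogenetic_anova(tr, trait, grp, n_simulations = 200, seed = 9)
  expect_identical(r1, r2)
  expect_error(phylogenetic_anova(tr, trait, setNames(rep("a", 8),
                                                      tr$tip.label), 10),
               "groups")
})

test_that("star-tree phylogenetic ANOVA converges to ordinary ANOVA", {
  # BM on a star with unit branches = i.i.d. normals, so the simulation p
  # must approach the parametric F-test p
  tr <- ape::stree(20, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("x", 1:20)
  set.seed(5)
  grp <- setNames(rep(c("a", "b"), each = 10), tr$tip.label)
  trait <- setNames(rnorm(20) + (grp == "b") * 1.2, tr$tip.label)
  res <- phylogenetic_anova(tr, trait, grp, n_simulations = 4000, seed = 31)
  p_ref <- anova(lm(trait ~ grp))$`Pr(>F)`[1]
  se <- sqrt(p_ref * (1 - p_ref) / 4000)
  expect_lt(abs(res$p - p_ref), 2 * se + 2 / 4000)
})

test_that("phylogenetic ANOVA agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(8)
  tr <- ape::rtree(16)
  tr$tip.label <- paste0("x", 1:16)
  grp <- setNames(rep(c("a", "b"), 8), tr$tip.label)
  trait <- setNames(rnorm(16) + (grp == "b") * 0.8, tr$tip.label)
  mine <- phylogenetic_anova(tr, trait, grp, n_simulations = 2000, seed = 3)
  ref <- phytools::phylANOVA(tr, grp, trait, nsim = 2000, posthoc = FALSE)
  expect_equal(mine$F, ref$F, tolerance = 1e-8)
  expect_lt(abs(mine$p - ref$Pf), 0.05)
})

test_that("taxon summaries and pairwise phylum tests run on synthetic data", {
  cfg <- synthetic_config(n_codiv_clades = 6, n_geo_clades = 6,
                          n_random_clades = 0, seed = 55)
  ds <- assemble_dataset(cfg)
  ctl <- scan_control(n_permutations = 99, seed = 55)
  sc <- codiv_scan(ds$tree, ds$metadata, ds$sites, ds$host_tree, ctl)

  phy <- taxon_summaries(sc, ds$metadata, rank = "phylum")
  expect_true(all(phy$summaries$weight > 0))
  expect_true(all(abs(phy$summaries$weighted_mean_r_phylo) <= 1, na.rm = TRUE))
  expect_true(phy$n_phylo_greater <= phy$n_taxa)
  expect_equal(phy$sign_test_p,
               sign_test(phy$n_phylo_greater, phy$n_taxa))

  gen <- taxon_summaries(sc, ds$metadata, rank = "genus")
  # every synthetic clade has its own genus: genus summaries >= phylum ones
  expect_gte(nrow(gen$summaries), nrow(phy$summaries))

  pw <- phylum_pairwise_tests(sc, ds$tree, ds$metadata, min_genera = 2)
  if (nrow(pw) > 0) {
    expect_true(all(pw$p_holm >= pw$p - 1e-12))
    expect_equal(pw$p_holm, oracle_holm(pw$p), tolerance = 1e-12)
  }
})
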