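test_that("clade simulators are deterministic and sized correctly", {
  cfg <- synthetic_config(seed = 1)
  a <- simulate_codiv_clade(cfg, 123, "c1")
  b <- simulate_codiv_clade(cfg, 123, "c1")
  expect_equal(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$metadata, b$metadata)
  expect_equal(length(a$tree$tip.label), 18)
  expect_equal(nrow(a$metadata), 18)

  g <- simulate_geo_clade(cfg, 99, "g1")
  g2 <- simulate_geo_clade(cfg, 99, "g1")
  expect_equal(ape::write.tree(g$tree), ape::write.tree(g2$tree))
  expect_equal(nrow(g$metadata), 18)

  r <- simulate_random_clade(cfg, 77, "r1")
  r2 <- simulate_random_clade(cfg, 77, "r1")
  expect_equal(ape::write.tree(r$tree), ape::write.tree(r2$tree))
  # bookkeeping: n tips = strains_per_host_taxon x n host taxa
  expect_equal(length(r$tree$tip.label),
               cfg$strains_per_host_taxon * length(cfg$host_tree$tip.label))
  # sites always within the assigned taxon's range
  ranges <- cfg$host_ranges
  ok <- mapply(function(tax, s) s %in% ranges[[tax]],
               r$metadata$host_taxon_id, r$metadata$site_id)
  expect_true(all(ok))
})

test_that("zero-noise codiv clades mirror the host tree exactly", {
  cfg <- synthetic_config(strains_per_host_taxon = 1,
                          within_taxon_noise_sd = 0, seed = 2)
  sim <- simulate_codiv_clade(cfg, 11, "c1")
  D <- patristic_distances(sim$tree)
  hD <- host_taxon_distances(cfg$host_tree)
  taxa <- sim$metadata$host_taxon_id[match(rownames(D), sim$metadata$tip_id)]
  expanded <- hD[taxa, taxa]
  # proportional: correlation exactly 1
  expect_equal(cor(D[upper.tri(D)], expanded[upper.tri(expanded)]), 1,
               tolerance = 1e-12)
})

test_that("noise lowers the codiv clades' r_phylo on average", {
  r_at_noise <- function(noise_sd) {
    vals <- numeric(10)
    for (s in 1:10) {
      cfg <- synthetic_config(within_taxon_noise_sd = noise_sd, seed = s)
      sim <- simulate_codiv_clade(cfg, 1000 + s, "c")
      D <- patristic_distances(sim$tree)
      hD <- host_taxon_distances(cfg$host_tree)
      taxa <- sim$metadata$host_taxon_id[match(rownames(D),
                                               sim$metadata$tip_id)]
      ref <- hD[taxa, taxa]
      dimnames(ref) <- dimnames(D)
      vals[s] <- mantel_r(D, ref)
    }
    mean(vals)
  }
  r0 <- r_at_noise(0)
  r1 <- r_at_noise(1.0)
  expect_equal(r0, 1, tolerance = 1e-10)
  expect_lt(r1, r0)
})

test_that("geo clades track site distances; strains cluster by site", {
  cfg <- synthetic_config(geo_tree_noise_sd = 0, within_taxon_noise_sd = 0,
                          seed = 3)
  sim <- simulate_geo_clade(cfg, 21, "g")
  D <- patristic_distances(sim$tree)
  site_D <- geo_site_distances(cfg$sites)
  s <- sim$metadata$site_id[match(rownames(D), sim$metadata$tip_id)]
  ref <- site_D[s, s]
  dimnames(ref) <- dimnames(D)
  expect_gt(mantel_r(D, ref), 0.7)
  # same-site strains coincide at zero noise
  same_site <- outer(s, s, "==") & upper.tri(D)
  if (any(same_site)) expect_equal(max(D[same_site]), 0, tolerance = 1e-9)
})

test_that("assembled datasets validate, separate scales, and reproduce", {
  cfg <- synthetic_config(n_codiv_clades = 3, n_geo_clades = 3,
                          n_random_clades = 3, seed = 8)
  ds <- assemble_dataset(cfg)
  expect_true(validate_dataset(ds$tree, ds$metadata, ds$sites,
                               ds$host_tree)$valid)
  expect_equal(nrow(ds$truth), 9)

  # enumeration finds exactly the simulated clades' nodes: every truth root
  # present, nothing spanning the backbone
  ctl <- scan_control(seed = 8)
  clades <- enumerate_testable_nodes(ds$tree, ctl)
  ids <- vapply(clades, `[[`, "", "node_id")
  expect_true(all(ds$truth$node_id %in% ids))
  clade_prefixes <- paste0(ds$truth$clade_id, "_")
  for (cl in clades) {
    from_one <- vapply(clade_prefixes,
                       function(p) all(startsWith(cl$tips, p)), logical(1))
    expect_true(any(from_one))
  }

  # byte-identical re-assembly and file round trip
  ds2 <- assemble_dataset(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  write_dataset(ds2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- read_dataset(d1)
  expect_true(validate_dataset(back$tree, back$metadata, back$sites,
                               back$host_tree)$valid)
  expect_setequal(back$tree$tip.label, ds$tree$tip.label)
})

test_that("insufficient backbone separation raises a named error", {
  cfg <- synthetic_config(n_codiv_clades = 2, n_geo_clades = 0,
                          n_random_clades = 0, backbone_scale = 0.1, seed = 4)
  expect_error(assemble_dataset(cfg), "backbone_scale too small.*codiv00")
})

test_that("zero clades yields an empty dataset and truth table", {
  cfg <- synthetic_config(n_codiv_clades = 0, n_geo_clades = 0,
                          n_random_clades = 0, seed = 5)
  ds <- assemble_dataset(cfg)
  expect_equal(nrow(ds$truth), 0)
  expect_equal(nrow(ds$metadata), 0)
})

test_that("random-clade scan p-values are roughly uniform", {
  # null calibration on a small batch; the full-size check lives in the
  # acceptance suite
  cfg <- synthetic_config(n_codiv_clades = 0, n_geo_clades = 0,
                          n_random_clades = 30, seed = 12)
  ds <- assemble_dataset(cfg)
  ctl <- scan_control(n_permutations = 199, seed = 12)
  sc <- codiv_scan(ds$tree, ds$metadata, ds$sites, ds$host_tree, ctl)
  roots <- sc$results[sc$results$node_id %in% ds$truth$node_id, ]
  p <- roots$p_phylo[!roots$untestable_phylo]
  expect_gt(length(p), 20)
  # Kolmogorov-Smirnov against uniform should not reject wildly
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})
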