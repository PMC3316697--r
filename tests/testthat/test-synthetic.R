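test_that("the Yule generator produces valid seeded ultrametric trees", {
  tr <- generate_surface_tree(2, 0.5, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_identical(length(tr$tip.label), 2L)
  expect_equal(tr$edge.length[1], tr$edge.length[2])

  tr1 <- generate_surface_tree(40, 0.5, seed = 42)
  tr2 <- generate_surface_tree(40, 0.5, seed = 42)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_true(ape::is.ultrametric(tr1, tol = 1e-8))
  diag <- capture.output(ape::checkValidPhylo(tr1))
  expect_false(any(grepl("FATAL|MODERATE", diag)))

  expect_error(generate_surface_tree(1, 0.5), "n_tips")
  expect_error(generate_surface_tree(10, -1), "birth_rate")
})

test_that("Yule depths match the pure-birth expectation", {
  lambda <- 0.5
  n <- 12
  depths <- vapply(1:400, function(i) {
    tr <- generate_surface_tree(n, lambda, seed = 1000 + i)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expected <- sum(1 / ((2:n) * lambda))
  se <- sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 3 * se)
})

test_that("generator -> detector -> tally round trip is exact", {
  cen <- aquifer_census(4, 4, 3)
  scenarios <- list(
    colonization_scenario("single", 0.8, diversification_prob = 1),
    colonization_scenario("single", 0.5, diversification_prob = 0.7),
    colonization_scenario("repeated", c(0.5, 1), pool_size = 4),
    colonization_scenario("repeated", c(0.4, 0.4, 1), pool_size = 5)
  )
  for (scen in scenarios) {
    for (seed in c(1, 2, 3)) {
      ds <- generate_colonization_dataset(cen, scen, n_surface_tips = 120,
                                          birth_rate = 0.2, seed = seed)
      det <- detect_report(ds$tree, ds$census)
      expect_identical(det$tally$pair_aquifers, ds$tally$pair_aquifers)
      expect_identical(det$tally$triplet_aquifers, ds$tally$triplet_aquifers)
      # metadata covers the tree exactly and the tree stays ultrametric
      expect_setequal(ds$metadata$tip_id, ds$tree$phylo$tip.label)
      expect_true(ape::is.ultrametric(ds$tree$phylo, tol = 1e-8))
    }
  }
})

test_that("degenerate scenarios plant no sisters", {
  cen <- aquifer_census(2, 2, 2)
  ds <- generate_colonization_dataset(cen,
    colonization_scenario("repeated", c(1, 1), pool_size = 5),
    n_surface_tips = 150, birth_rate = 0.2, seed = 5)
  expect_identical(ds$tally$pair_aquifers + ds$tally$triplet_aquifers, 0L)
  expect_identical(nrow(find_sympatric_sister_clades(ds$tree)), 0L)
})

test_that("datasets round-trip through plain-text files", {
  cen <- aquifer_census(2, 2, 1)
  ds <- generate_colonization_dataset(cen,
    colonization_scenario("single", 0.8, diversification_prob = 1),
    n_surface_tips = 60, birth_rate = 0.2, seed = 9)
  dir <- tempfile("synthds")
  paths <- write_synthetic_dataset(ds, dir)
  on.exit(unlink(dir, recursive = TRUE))
  reread <- read_annotated_tree(paths[1], paths[2])
  det <- detect_report(reread, cen)
  expect_identical(det$tally$pair_aquifers, ds$tally$pair_aquifers)
  expect_identical(det$tally$triplet_aquifers, ds$tally$triplet_aquifers)
  truth <- jsonlite::read_json(paths[3])
  expect_identical(truth$tally$pair_aquifers, ds$tally$pair_aquifers)
})

test_that("parameter recovery closes the loop", {
  cen <- aquifer_census(18, 16, 11)
  ds <- generate_colonization_dataset(cen,
    colonization_scenario("single", 0.784, diversification_prob = 1),
    seed = 21)
  rec <- recover_parameters(ds)
  expect_identical(rec$tally$sister_fraction,
                   ds$tally$sister_fraction)
  if (length(rec$roots)) {
    expect_true(all(rec$roots >= 0 & rec$roots <= 1))
    pred <- expected_sister_fractions(cen,
      colonization_scenario("single", rec$estimate, diversification_prob = 1))
    expect_equal(pred$expected_sister_fraction, rec$tally$sister_fraction,
                 tolerance = 1e-6)
  }
  # an all-surface dataset recovers the boundary roots
  ds0 <- generate_colonization_dataset(aquifer_census(4, 4, 3),
    colonization_scenario("repeated", c(1, 1), pool_size = 5),
    n_surface_tips = 150, birth_rate = 0.2, seed = 4)
  rec0 <- recover_parameters(ds0, model = "single")
  expect_equal(rec0$roots, c(0, 1))
})
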