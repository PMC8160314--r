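# The synthetic-community generator: trees, traits, pools, regimes.

test_that("simulated trees have the requested labelled tips, reproducibly", {
  tr <- simulate_tree(5, seed = 1)
  expect_equal(sort(tr$tip.label), sprintf("T%04d", 1:5))
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(simulate_tree(12, seed = 9)),
                   ape::write.tree(simulate_tree(12, seed = 9)))
  expect_false(identical(ape::write.tree(simulate_tree(12, seed = 9)),
                         ape::write.tree(simulate_tree(12, seed = 10))))
  expect_error(simulate_tree(2), class = "validation_error")
})

test_that("expected tip depth grows with the number of tips (Yule)", {
  depth_of <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      tr <- simulate_tree(n, seed = s)
      max(ape::node.depth.edgelength(tr)[seq_len(n)])
    }, numeric(1)))
  }
  # E[height] ~ sum_{k=2}^{n} 1/k for a unit-rate Yule tree
  d8 <- depth_of(8, 1:100)
  d64 <- depth_of(64, 1:100)
  expect_gt(d64, d8)
  expect_equal(d8, sum(1 / (2:8)), tolerance = 0.25)
  expect_equal(d64, sum(1 / (2:64)), tolerance = 0.25)
})

test_that("Brownian traits have the closed-form covariance structure", {
  # fixed 4-tip tree: cov(trait_i, trait_j) = sigma^2 * shared root path
  tr <- tree_from_text("((A:1,B:1):2,(C:2,D:2):1);")
  tt <- t(vapply(1:2000, function(s) evolve_trait(tr, sigma = 1, seed = s),
                 stats::setNames(numeric(4), tr$tip.label)))
  cv <- stats::cov(tt)
  expect_equal(cv["A", "A"], 3, tolerance = 0.3)
  expect_equal(cv["A", "B"], 2, tolerance = 0.3)
  expect_equal(cv["A", "C"], 0, tolerance = 0.3)
  expect_equal(cv["C", "D"], 1, tolerance = 0.3)
  # degenerate sigma: variance shrinks towards zero
  small <- evolve_trait(tr, sigma = 1e-6, seed = 3)
  expect_true(all(abs(small) < 1e-4))
  expect_error(evolve_trait(tr, sigma = 0), class = "validation_error")
  expect_identical(evolve_trait(tr, 1, seed = 4), evolve_trait(tr, 1, seed = 4))
})

test_that("conserved niche traits are constant within their niche lineages", {
  tr <- simulate_tree(64, seed = 21)
  trait <- conserved_trait(tr, sigma = 1, seed = 22, n_lineages = 12)
  cl <- attr(trait, "clades")
  expect_equal(length(unique(cl)), 12)
  for (f in unique(cl)) {
    vals <- trait[names(cl)[cl == f]]
    expect_lt(max(vals) - min(vals), 1e-12)
  }
  expect_gt(stats::sd(trait), 0)
  expect_identical(as.numeric(conserved_trait(tr, 1, seed = 5)),
                   as.numeric(conserved_trait(tr, 1, seed = 5)))
})

test_that("regional pools are normalised, positive and heavy-tailed", {
  tr <- simulate_tree(30, seed = 31)
  pool <- make_pool(tr, seed = 32)
  expect_equal(sum(pool), 1)
  expect_true(all(pool > 0))
  expect_gt(max(pool), mean(pool))
  expect_identical(make_pool(tr, seed = 32), make_pool(tr, seed = 32))
})

test_that("every regime conserves depth and is seed-reproducible", {
  tr <- simulate_tree(32, seed = 41)
  pool <- make_pool(tr, seed = 41)
  trait <- conserved_trait(tr, 1, seed = 41)
  for (reg in c("homogeneous_selection", "variable_selection",
                "dispersal_limitation", "homogenizing_dispersal",
                "pure_drift", "nst_null")) {
    scen <- scenario(reg, n_taxa_pool = 32, n_samples = 4, depth = 400,
                     seed = 42)
    tab <- simulate_community(pool, trait, scen)
    expect_true(all(sample_totals(tab) == 400L), info = reg)
    expect_equal(attr(tab, "truth")$regime, reg)
    tab2 <- simulate_community(pool, trait, scen)
    expect_identical(counts(tab), counts(tab2), info = reg)
  }
  expect_error(scenario("no_such_regime"))
})

test_that("dispersal limitation yields near-disjoint cross-subpool pairs", {
  tr <- simulate_tree(64, seed = 51)
  pool <- make_pool(tr, seed = 51)
  trait <- conserved_trait(tr, 1, seed = 51)
  scen <- scenario("dispersal_limitation", n_taxa_pool = 64, n_samples = 6,
                   depth = 1000, seed = 52)
  tab <- simulate_community(pool, trait, scen)
  blk <- attr(tab, "truth")$block
  m <- counts(tab)
  for (i in 1:5) for (j in (i + 1):6) {
    bc <- bray_curtis(m[, i], m[, j])
    if (blk[i] != blk[j]) expect_gt(bc, 0.9)
  }
})

test_that("the paper-shaped preset writes a consistent, readable dataset", {
  dir <- tempfile("simdata")
  ds <- simulate_dataset(n_taxa_pool = 64, depth = 400, seed = 61,
                         out_dir = dir)
  expect_equal(length(sample_ids(ds$table)), 24)
  expect_equal(nrow(ds$metadata), 24)
  expect_equal(sort(unique(ds$metadata$position)), c("floating", "settled"))
  expect_equal(sort(unique(ds$metadata$reactor)), c("R1", "R2", "R3"))

  back_tab <- read_abundance_table(ds$paths$table)
  back_tree <- read_newick(ds$paths$tree)
  back_tax <- read_taxonomy(ds$paths$taxonomy)
  back_md <- read_metadata(ds$paths$metadata)
  expect_identical(counts(back_tab), counts(ds$table))
  expect_silent(validate_crossrefs(back_tab, tree = back_tree,
                                   taxonomy = back_tax, metadata = back_md))
  truth <- jsonlite::read_json(ds$paths$truth)
  expect_equal(truth$positions$settled$regime, "homogeneous_selection")
  expect_equal(truth$positions$floating$regime, "pure_drift")

  ds2 <- simulate_dataset(n_taxa_pool = 64, depth = 400, seed = 62)
  expect_false(identical(counts(ds2$table), counts(ds$table)))
  expect_equal(dim(counts(ds2$table)), dim(counts(ds$table)))
})
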