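# MNTD/NTI and betaMNTD/betaNTI against hand values, brute-force oracles
# and (where the conventions coincide) picante.

test_that("cophenetic distances match hand path sums", {
  tree <- tree_from_text("(A:1,(B:0.5,C:0.5):0.5);")
  d <- cophenetic_distances(tree)
  expect_equal(d["B", "C"], 1.0)
  expect_equal(d["A", "B"], 2.0)
  expect_equal(d["A", "C"], 2.0)

  star <- tree_from_text("(A:1,B:1,C:1,D:1);")
  ds <- cophenetic_distances(star)
  expect_true(all(ds[upper.tri(ds)] == 2))

  # ultrametric three-point condition: the max pairwise distance is attained
  # at least twice in every triple
  tr <- ape::rcoal(6)
  du <- cophenetic_distances(tr)
  combs <- combn(6, 3)
  for (k in seq_len(ncol(combs))) {
    v <- sort(c(du[combs[1, k], combs[2, k]], du[combs[1, k], combs[3, k]],
                du[combs[2, k], combs[3, k]]))
    expect_lt(v[3] - v[2], 1e-9)
  }
})

test_that("cophenetic distances agree with path enumeration on small trees", {
  set.seed(5)
  for (n in 3:6) {
    for (rep in 1:5) {
      tr <- ape::rtree(n)
      d <- cophenetic_distances(tr)
      b <- brute_cophenetic(tr)
      expect_equal(d[rownames(b), colnames(b)], b, tolerance = 1e-12)
    }
  }
})

test_that("MNTD matches hand nearest-neighbour minima and the brute force", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  comm <- c(A = 1, B = 1, C = 1)
  expect_equal(mntd(comm, d), (2 + 2 + 4) / 3)

  two <- c(A = 1, B = 1, C = 0)
  expect_equal(mntd(two, d), 2)
  expect_equal(mntd(c(A = 7, B = 1, C = 0), d, abundance_weighted = TRUE), 2)

  expect_error(mntd(c(A = 1, B = 0, C = 0), d), class = "validation_error")

  set.seed(9)
  for (rep in 1:10) {
    tr <- ape::rtree(6)
    dd <- cophenetic_distances(tr)
    comm <- stats::setNames(rpois(6, 2), tr$tip.label)
    if (sum(comm > 0) < 2) comm[1:2] <- 1
    expect_equal(mntd(comm, dd), brute_mntd(comm, dd), tolerance = 1e-12)
    expect_equal(mntd(comm, dd, abundance_weighted = TRUE),
                 brute_mntd(comm, dd, weighted = TRUE), tolerance = 1e-12)
  }
})

test_that("MNTD agrees with picante", {
  skip_if_not_installed("picante")
  set.seed(13)
  tr <- ape::rtree(10)
  d <- cophenetic_distances(tr)
  comm <- matrix(rpois(30, 2), 3, 10,
                 dimnames = list(c("S1", "S2", "S3"), tr$tip.label))
  comm[comm == 0 & col(comm) <= 2] <- 1 # keep >=2 taxa everywhere
  ours <- vapply(1:3, function(i)
    mntd(comm[i, ], d, abundance_weighted = TRUE), numeric(1))
  theirs <- picante::mntd(comm, d, abundance.weighted = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("betaMNTD matches hand values, symmetry, and the brute force", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(beta_mntd(c(A = 1, B = 0), c(A = 0, B = 1), d), 2)
  expect_equal(beta_mntd(c(A = 3, B = 1), c(A = 1, B = 5), d), 0)

  set.seed(17)
  for (rep in 1:10) {
    tr <- ape::rtree(6)
    dd <- cophenetic_distances(tr)
    x <- stats::setNames(rpois(6, 2), tr$tip.label)
    y <- stats::setNames(rpois(6, 2), tr$tip.label)
    x[1] <- x[1] + 1
    y[2] <- y[2] + 1
    expect_equal(beta_mntd(x, y, dd), beta_mntd(y, x, dd))
    expect_gte(beta_mntd(x, y, dd), 0)
    expect_equal(beta_mntd(x, y, dd), brute_beta_mntd(x, y, dd),
                 tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with picante comdistnt on equal-total samples", {
  skip_if_not_installed("picante")
  set.seed(19)
  tr <- ape::rtree(8)
  d <- cophenetic_distances(tr)
  # equal totals make picante's pooled weighted mean identical to the
  # half-sum of per-sample weighted means
  m <- matrix(0L, 3, 8, dimnames = list(c("S1", "S2", "S3"), tr$tip.label))
  for (i in 1:3) m[i, sample(8, 5)] <- as.integer(c(4, 3, 1, 1, 1))
  theirs <- as.matrix(picante::comdistnt(m, d, abundance.weighted = TRUE))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(beta_mntd(m[i, ], m[j, ], d), theirs[i, j],
                 tolerance = 1e-10)
})

test_that("NTI is deterministic under seed and detects clade restriction", {
  tree <- simulate_tree(64, seed = 31)
  sub <- ape::subtrees(tree)
  sizes <- vapply(sub, ape::Ntip, integer(1))
  clade <- sub[[which.min(abs(sizes - 10))]]$tip.label
  m <- matrix(0L, 64, 4, dimnames = list(tree$tip.label,
                                         c("C1", "C2", "R1", "R2")))
  set.seed(32)
  m[sample(clade, 8), "C1"] <- 1L        # clade-restricted samples
  m[sample(clade, 8), "C2"] <- 1L
  m[sample(64, 20), "R1"] <- 1L          # diffuse samples set the taxa pool
  m[sample(64, 20), "R2"] <- 1L
  tab <- asv_table(m)
  res <- nti(tab, tree, reps = 299, seed = 7)
  expect_gt(res$nti[res$sample_id == "C1"], 2)
  expect_gt(res$nti[res$sample_id == "C2"], 2)

  res2 <- nti(tab, tree, reps = 299, seed = 7)
  expect_identical(res, res2)
  res3 <- nti(tab, tree, reps = 299, seed = 8)
  expect_false(identical(res$null_mean, res3$null_mean))
})

test_that("NTI null agrees statistically with picante ses.mntd richness null", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(32, seed = 41)
  set.seed(42)
  m <- matrix(rbinom(32 * 4, 1, 0.4), 4, 32,
              dimnames = list(paste0("S", 1:4), tree$tip.label))
  m[, 1:2] <- 1 # ensure richness >= 2
  tab <- asv_table(t(m))
  ours <- nti(tab, tree, reps = 499, seed = 43)
  theirs <- picante::ses.mntd(m, cophenetic_distances(tree),
                              null.model = "richness", runs = 499,
                              abundance.weighted = FALSE)
  expect_equal(ours$mntd_obs, theirs$mntd.obs, tolerance = 1e-10)
  # z-scores estimated from independent 499-run nulls; allow Monte Carlo slack
  expect_equal(ours$nti, -theirs$mntd.obs.z, tolerance = 0.5)
})

test_that("betaNTI matches an independent per-pair brute force", {
  tree <- simulate_tree(6, seed = 51)
  set.seed(52)
  m <- matrix(rpois(18, 3), 6, 3,
              dimnames = list(tree$tip.label, c("S1", "S2", "S3")))
  m[1:2, ] <- m[1:2, ] + 1L
  tab <- asv_table(m)
  res <- beta_nti(tab, tree, reps = 999, seed = 53)
  oracle <- brute_beta_nti(tab, tree, reps = 999, seed = 53)
  key <- paste(res$sample_a, res$sample_b)
  expect_equal(res$bnti[match(names(oracle), key)], unname(oracle),
               tolerance = 1e-12)
})

test_that("betaNTI flags identical-membership pairs as undefined", {
  tree <- simulate_tree(8, seed = 61)
  m <- matrix(0L, 8, 3, dimnames = list(tree$tip.label, c("S1", "S2", "S3")))
  m[1:4, 1] <- c(5L, 3L, 2L, 1L)
  m[1:4, 2] <- c(1L, 2L, 3L, 5L)  # same membership as S1
  m[5:8, 3] <- 2L
  tab <- asv_table(m)
  res <- beta_nti(tab, tree, reps = 99, seed = 62)
  row12 <- res[res$sample_a == "S1" & res$sample_b == "S2", ]
  expect_true(row12$undefined)
  expect_true(is.na(row12$bnti))
  expect_equal(row12$bmntd_obs, 0)
})
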