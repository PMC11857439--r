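test_that("t-maps match the per-voxel lm oracle to 1e-10", {
  d <- tiny_design(8)
  Y <- withr::with_seed(2, matrix(rnorm(8 * 2, mean = 1, sd = 0.2), 8, 2))
  dims <- c(2L, 1L, 1L)
  mask <- array(TRUE, dims)
  sm <- fit_glm(vols_from_matrix(Y, dims), d$design, mask)
  expect_equal(sm$df, 8L - 4L)
  expect_equal(sm$t[mask], tmap_lm_oracle(Y, d$design), tolerance = 1e-10)
})

test_that("a noiseless age effect gives the exact coefficient and diverging t", {
  d <- tiny_design(10)
  Y <- matrix(rep(2 * d$cohort$age, 2), ncol = 2)
  dims <- c(2L, 1L, 1L)
  sm <- fit_glm(vols_from_matrix(Y, dims), d$design, array(TRUE, dims))
  expect_equal(sm$beta[array(TRUE, dims)], c(2, 2), tolerance = 1e-8)
  # residuals are zero up to round-off, so |t| explodes
  expect_true(all(abs(sm$t[array(TRUE, dims)]) > 1e6))
})

test_that("jointly permuting subjects leaves the map unchanged", {
  d <- tiny_design(12)
  dims <- c(3L, 2L, 1L)
  Y <- withr::with_seed(3, matrix(rnorm(12 * 6), 12, 6))
  mask <- array(TRUE, dims)
  sm1 <- fit_glm(vols_from_matrix(Y, dims), d$design, mask)
  perm <- withr::with_seed(4, sample(12))
  sm2 <- fit_glm(vols_from_matrix(Y[perm, ], dims),
                 d$design[perm, ], mask)
  expect_equal(sm1$t, sm2$t, tolerance = 1e-12)
})

test_that("rank-deficient or undersized designs are rejected", {
  d <- tiny_design(8)
  bad <- d$design
  bad[, "global_mean"] <- 2 * bad[, "age"]
  dims <- c(2L, 1L, 1L)
  Y <- matrix(rnorm(16), 8, 2)
  expect_error(fit_glm(vols_from_matrix(Y, dims), bad, array(TRUE, dims)),
               "rank deficient")
  d4 <- tiny_design(4)
  expect_error(
    fit_glm(vols_from_matrix(matrix(rnorm(8), 4, 2), dims), d4$design,
            array(TRUE, dims)),
    "fewer subjects"
  )
  expect_error(fit_glm(vols_from_matrix(Y, dims), d$design,
                       array(FALSE, dims)), "empty")
})

test_that("exhaustive enumeration reproduces the permutation threshold", {
  d <- tiny_design(5, seed = 7)
  dims <- c(2L, 1L, 1L)
  Y <- withr::with_seed(8, matrix(rnorm(10), 5, 2))
  mask <- array(TRUE, dims)
  perms <- all_permutations(5L)

  thr <- permutation_fwe(vols_from_matrix(Y, dims), d$design, mask,
                         alpha = 0.05, permutations = perms)

  # independent Freedman-Lane oracle: reduced-model fit via lm, per-voxel
  # lm t-statistics on each re-assembled dataset
  X <- d$design
  Z <- X[, colnames(X) != "age"]
  red <- lm(Y ~ Z - 1)
  Fit <- fitted(red); Res <- residuals(red)
  maxs <- apply(perms, 1, function(pp) {
    max(abs(tmap_lm_oracle(Fit + Res[pp, ], X)))
  })
  k <- ceiling(0.95 * nrow(perms))
  expect_equal(as.numeric(thr), sort(maxs)[k], tolerance = 1e-10)

  # alpha = 1 degenerates to the minimum of the null maxima
  thr1 <- permutation_fwe(vols_from_matrix(Y, dims), d$design, mask,
                          alpha = 1, permutations = perms)
  expect_equal(as.numeric(thr1), min(maxs), tolerance = 1e-10)
})

test_that("permutation options are validated", {
  d <- tiny_design(6)
  dims <- c(2L, 1L, 1L)
  Y <- matrix(rnorm(12), 6, 2)
  vols <- vols_from_matrix(Y, dims)
  mask <- array(TRUE, dims)
  expect_error(permutation_fwe(vols, d$design, mask, alpha = 0), "must lie in")
  expect_error(permutation_fwe(vols, d$design, mask, alpha = 1.2), "must lie in")
  expect_error(permutation_fwe(vols, d$design, mask, n_perm = 50),
               "at least 100")
})

blob_map <- function(dims, blobs) {
  tarr <- array(0, dim = dims)
  for (b in blobs) tarr[b$x, b$y, b$z] <- b$t
  mask <- array(TRUE, dims)
  structure(list(t = tarr, df = 100L, mask = mask, effect = "age"),
            class = "stat_map")
}

test_that("clusters below the extent threshold are dropped", {
  # positive blobs of 60 (4x5x3) and 40 (4x5x2) voxels
  sm <- blob_map(c(20, 20, 10), list(
    list(x = 1:4, y = 1:5, z = 1:3, t = 5),
    list(x = 10:13, y = 10:14, z = 8:9, t = 7)
  ))
  ct <- cluster_table(sm, threshold = 3, extent = 50)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$size, 60L)
  expect_equal(ct$peak_t, 5)
  # with extent 1 both survive, sorted by size descending
  ct2 <- cluster_table(sm, threshold = 3, extent = 1)
  expect_equal(ct2$size, c(60L, 40L))
})

test_that("an empty suprathreshold set yields an empty table", {
  sm <- blob_map(c(10, 10, 5), list())
  ct <- cluster_table(sm, threshold = 3, extent = 1)
  expect_equal(nrow(ct), 0L)
})

test_that("touching blobs of opposite sign are two clusters", {
  sm <- blob_map(c(20, 10, 5), list(
    list(x = 1:5, y = 1:4, z = 1:3, t = 6),
    list(x = 6:10, y = 1:4, z = 1:3, t = -6)   # shares a face at x=5/6
  ))
  ct <- cluster_table(sm, threshold = 3, extent = 1)
  expect_equal(nrow(ct), 2L)
  expect_setequal(ct$sign, c("positive", "negative"))
})

test_that("26-connectivity merges diagonal neighbors", {
  tarr <- array(0, dim = c(6, 6, 6))
  tarr[2, 2, 2] <- 5; tarr[3, 3, 3] <- 5   # corner contact only
  sm <- structure(list(t = tarr, df = 10L, mask = array(TRUE, dim(tarr)),
                       effect = "age"), class = "stat_map")
  ct <- cluster_table(sm, threshold = 3, extent = 1)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$size, 2L)
})

test_that("peak coordinates are 0-based and map through the affine", {
  sm <- blob_map(c(10, 10, 5), list(list(x = 4, y = 5, z = 2, t = 9)))
  aff <- diag(c(2, 2, 2, 1))
  ct <- cluster_table(sm, threshold = 3, extent = 1, affine = aff)
  expect_equal(c(ct$peak_i, ct$peak_j, ct$peak_k), c(3L, 4L, 1L))
  expect_equal(c(ct$peak_x, ct$peak_y, ct$peak_z), c(6, 8, 2))
})
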