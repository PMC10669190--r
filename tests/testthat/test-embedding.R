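random_binary_vectors <- function(n, d, seed) {
  set.seed(seed)
  matrix(rbinom(n * d, 1, 0.4), n, d)
}

test_that("PCA agrees with brute-force covariance eigendecomposition", {
  x <- random_binary_vectors(15, 10, seed = 11)
  fit <- pca_embed(x, k = 3)
  ref <- bf_pca_scores(x, 3)
  for (j in 1:3) {
    a <- fit$scores[[paste0("PC", j)]]
    b <- ref$scores[, j]
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-9)
    expect_equal(sort(abs(a)), sort(abs(b)), tolerance = 1e-9)
  }
  expect_equal(fit$sdev^2, ref$values[seq_along(fit$sdev)], tolerance = 1e-9)
})

test_that("variance is conserved and components are orthonormal", {
  x <- random_binary_vectors(40, 20, seed = 12)
  fit <- pca_embed(x, k = 20)
  xc <- sweep(x, 2, colMeans(x))
  total <- sum(xc^2) / (nrow(x) - 1)
  expect_equal(fit$total_var, total, tolerance = 1e-6 * total)
  expect_false(is.unsorted(rev(fit$sdev)))
  gram <- t(fit$loadings) %*% fit$loadings
  expect_equal(gram, diag(ncol(fit$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # completeness: all components reconstruct the centred data
  recon <- as.matrix(fit$scores[, -1]) %*% t(fit$loadings)
  expect_equal(recon, xc, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("identical vectors give zero variance and zero projections", {
  x <- matrix(1, 10, 6)
  fit <- pca_embed(x, k = 2)
  expect_equal(fit$total_var, 0, tolerance = 1e-12)
  expect_true(all(abs(as.matrix(fit$scores[, -1])) < 1e-12))
})

test_that("component signs follow the largest-loading-positive convention", {
  x <- random_binary_vectors(30, 8, seed = 13)
  fit <- pca_embed(x, k = 4)
  for (j in seq_len(4)) {
    lo <- fit$loadings[, j]
    expect_gt(lo[which.max(abs(lo))], 0)
  }
})

test_that("helix- and coil-dominated ensembles separate in 1-D PCA", {
  spec <- spec406()
  eh <- sample_helix_coil(spec, helix_coil_model(0.95, n_frames = 200,
                                                 seed = 21))
  ec <- sample_helix_coil(spec, helix_coil_model(0.05, n_frames = 200,
                                                 seed = 22))
  fit <- pca_embed(rbind(contact_vectors(eh), contact_vectors(ec)), k = 1)
  expect_lt(midpoint_overlap(fit$scores$PC1, 200), 0.05)
})

test_that("nonlinear embedding is seeded-deterministic and recovers clusters", {
  set.seed(5)
  a <- matrix(rbinom(60 * 20, 1, 0.15), 60, 20)
  b <- matrix(rbinom(60 * 20, 1, 0.85), 60, 20)
  x <- rbind(a, b)
  e1 <- nonlinear_embed(x, k = 2, params = list(seed = 7))
  e2 <- nonlinear_embed(x, k = 2, params = list(seed = 7))
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$method, "nmds")
  expect_identical(e1$params$seed, 7)
  # 1-nearest-neighbour label recovery in embedded space
  co <- as.matrix(e1$coords[, -1])
  lab <- rep(c(1, 2), each = 60)
  d <- as.matrix(dist(co))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  expect_gte(mean(lab[nn] == lab), 0.9)
})

test_that("degenerate identical input surfaces a documented warning", {
  x <- matrix(1, 10, 5)
  expect_warning(e <- nonlinear_embed(x, k = 2), "degenerate")
  expect_true(all(as.matrix(e$coords[, -1]) == 0))
})

test_that("embedding input is validated", {
  expect_error(pca_embed(matrix(1, 1, 5)), "at least 2")
  expect_error(pca_embed(matrix(1, 5, 5), k = 9), "k must be")
  expect_error(pca_embed(list(c(1, 2), c(1, 2, 3))), "inconsistent")
  expect_error(nonlinear_embed(matrix(1, 2, 5)), "at least 4")
})

test_that("joint embedding shares one coordinate system across ensembles", {
  spec <- spec406()
  ens <- sample_helix_coil(spec, helix_coil_model(0.7, n_frames = 60,
                                                  seed = 33))
  # an ensemble pooled with itself projects both copies identically
  emb <- joint_embed(list(a = ens, b = ens), method = "pca", k = 2)
  a <- emb[emb$ensemble == "a", c("dim1", "dim2")]
  b <- emb[emb$ensemble == "b", c("dim1", "dim2")]
  expect_equal(as.matrix(a), as.matrix(b), ignore_attr = TRUE)
  # pooled eigenvalue sum equals pooled centred variance
  fit <- attr(emb, "fit")
  pooled <- rbind(contact_vectors(ens), contact_vectors(ens))
  xc <- sweep(pooled, 2, colMeans(pooled))
  expect_equal(fit$total_var, sum(xc^2) / (nrow(pooled) - 1),
               tolerance = 1e-9)
  # projections depend on the pool: adding data changes the coordinates
  blocks <- split_blocks(ens, 2)
  solo <- joint_embed(list(b1 = blocks[[1]]), method = "pca", k = 2)
  both <- joint_embed(list(b1 = blocks[[1]], b2 = blocks[[2]]),
                      method = "pca", k = 2)
  expect_false(isTRUE(all.equal(
    as.matrix(solo[, c("dim1", "dim2")]),
    as.matrix(both[both$ensemble == "b1", c("dim1", "dim2")]))))
  # dimensionality mismatch across ensembles is an error
  short <- sample_helix_coil(segment_spec(406, flank = 5,
                                          sequence = "AAAAACAAAAA"),
                             helix_coil_model(0.7, n_frames = 10, seed = 1))
  expect_error(joint_embed(list(a = ens, s = short)), "mismatch")
})
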