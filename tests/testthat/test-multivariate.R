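test_that("autoscaling centres, scales by sample sd, and drops constants", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(0, 10, 20))
  expect_warning(s <- autoscale(x), "constant")
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_equal(colnames(s), c("a", "c"))
  expect_lt(max(abs(colMeans(s))), 1e-12)
  expect_lt(max(abs(apply(s, 2, stats::sd) - 1)), 1e-12)
  # idempotent on already-scaled input
  s2 <- autoscale(s)
  expect_equal(as.vector(s2), as.vector(s), tolerance = 1e-12)
  expect_error(autoscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("SVD-based PCA matches the eigendecomposition oracle", {
  set.seed(41)
  x <- matrix(stats::rnorm(15), 5, 3)
  colnames(x) <- c("f1", "f2", "f3")
  p <- flux_pca(x, n_components = 3)
  xs <- autoscale(x)
  ev <- eigen(stats::cov(xs))$values
  expect_equal(p$sdev^2, ev, tolerance = 1e-9)
  expect_equal(p$explained, ev / sum(ev), tolerance = 1e-9)
  # cross-check against prcomp (the reference implementation)
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(abs(p$loadings), abs(pr$rotation[, 1:3]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # loadings orthonormal, full reconstruction exact
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(p$scores %*% t(p$loadings) - xs)), 1e-9)
  # deterministic sign: the largest-magnitude loading per component is positive
  for (k in 1:3) expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
})

test_that("rank-1 data load entirely on the first component", {
  x <- outer(c(1, 2, 3, 4), c(1, -2, 0.5))
  x <- x + matrix(1e-12, 4, 3)
  p <- flux_pca(x, n_components = 1)
  expect_equal(p$explained[1], 1, tolerance = 1e-6)
  expect_error(flux_pca(x, n_components = 3), "rank")
})

test_that("PLS-DA ranks the separating flux first and VIP is normalized", {
  set.seed(43)
  n <- 60
  x <- cbind(sep = c(stats::rnorm(n, 0), stats::rnorm(n, 3)),
             n1 = stats::rnorm(2 * n), n2 = stats::rnorm(2 * n),
             n3 = stats::rnorm(2 * n))
  cls <- factor(rep(c("ctrl", "stress"), each = n))
  pl <- flux_plsda(x, cls, n_components = 2, n_permutations = 50)
  expect_equal(names(which.max(pl$vip)), "sep")
  expect_gt(pl$vip[["sep"]], 1)
  expect_equal(mean(pl$vip^2), 1, tolerance = 1e-9)  # VIP mean-square is 1
  expect_gt(pl$accuracy, 0.9)
  expect_lt(pl$permutation_p, 0.05)
})

test_that("permuted labels give chance-level accuracy and null separation", {
  set.seed(47)
  x <- matrix(stats::rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  cls <- factor(sample(rep(c("a", "b"), each = 100)))
  pl <- flux_plsda(x, cls, n_components = 2, n_permutations = 100)
  expect_gt(pl$accuracy, 0.3)
  expect_lt(pl$accuracy, 0.7)
  expect_gt(pl$permutation_p, 0.05)
  expect_error(flux_plsda(x, factor(rep("a", 200))), "2 classes")
})

test_that("NIPALS PLS-DA agrees with the reference PLS implementation", {
  set.seed(53)
  n <- 40
  x <- cbind(sep = c(stats::rnorm(n, 0), stats::rnorm(n, 2)),
             n1 = stats::rnorm(2 * n), n2 = stats::rnorm(2 * n))
  cls <- factor(rep(c("a", "b"), each = n))
  pl <- flux_plsda(x, cls, n_components = 2, cv_folds = 0, n_permutations = 0)
  mo <- mixOmics::plsda(x, cls, ncomp = 2, scale = TRUE)
  r <- abs(stats::cor(pl$scores[, 1], mo$variates$X[, 1]))
  expect_gt(r, 0.99)
})
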