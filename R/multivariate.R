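#' Autoscale a flux matrix (mean 0, unit variance per column)
#'
#' Columns are centred and scaled by the sample standard deviation (n - 1),
#' the convention of `prcomp(..., scale. = TRUE)`. Zero-variance columns
#' are dropped with a warning.
#'
#' @param x numeric matrix (rows = samples, columns = fluxes).
#' @return scaled matrix with attributes `center`, `scale`, `dropped`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty matrix", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  drop_cols <- which(sds == 0 | !is.finite(sds))
  if (length(drop_cols)) {
    warning(sprintf("dropping %d constant column(s): %s", length(drop_cols),
                    paste(colnames(x)[drop_cols], collapse = ", ")), call. = FALSE)
    x <- x[, -drop_cols, drop = FALSE]
    sds <- sds[-drop_cols]
  }
  mns <- colMeans(x)
  out <- sweep(sweep(x, 2, mns), 2, sds, "/")
  attr(out, "center") <- mns
  attr(out, "scale") <- sds
  attr(out, "dropped") <- drop_cols
  out
}

#' Stack Monte Carlo ensembles into a net-flux matrix for ordination
#'
#' Builds the rows-by-fluxes matrix analysed by [flux_pca()] and
#' [flux_plsda()]: Monte Carlo net-flux samples of both conditions stacked,
#' restricted to genuine net fluxes — pool sizes, exchange fluxes, mixing
#' parameters and pseudo (mixing/dilution) reactions are excluded, and
#' constant columns (e.g. the fixed uptake) are dropped by [autoscale()]
#' downstream.
#'
#' @param a,b `mfa_ensemble` objects.
#' @return list: `x` (matrix), `class` (factor of condition labels).
#' @export
flux_ensemble_matrix <- function(a, b) {
  model <- a$fit$problem$model
  pseudo <- vapply(model$reactions, function(r) isTRUE(r$pseudo), TRUE)
  keep <- paste0("net.", reaction_ids(model)[!pseudo])
  keep <- intersect(keep, intersect(colnames(a$net), colnames(b$net)))
  x <- rbind(a$net[, keep, drop = FALSE], b$net[, keep, drop = FALSE])
  cls <- factor(c(rep(a$condition, nrow(a$net)), rep(b$condition, nrow(b$net))))
  list(x = x, class = cls)
}

#' Principal component analysis by singular value decomposition
#'
#' PCA of an autoscaled matrix via `svd()`: loadings are the right
#' singular vectors (orthonormal), scores are `x %*% loadings`, explained
#' variance fractions are the squared singular values over their total.
#' For a deterministic sign convention, each component is flipped so its
#' largest-magnitude loading is positive.
#'
#' @param x matrix of samples x variables (autoscaled with [autoscale()]
#'   unless `scale = FALSE`).
#' @param n_components number of components kept.
#' @param scale autoscale the input first (default TRUE).
#' @return object of class `flux_pca`: `scores`, `loadings`,
#'   `explained` (fractions), `sdev`.
#' @export
flux_pca <- function(x, n_components = 2, scale = TRUE) {
  xs <- if (scale) autoscale(x) else as.matrix(x)
  if (nrow(xs) < 2) stop("need at least 2 rows", call. = FALSE)
  sv <- svd(xs)
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_components > rank) {
    stop(sprintf("n_components = %d exceeds rank %d", n_components, rank), call. = FALSE)
  }
  expl <- sv$d^2 / sum(sv$d^2)
  L <- sv$v[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  }
  rownames(L) <- colnames(xs)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- xs %*% L
  structure(list(scores = scores, loadings = L,
                 explained = expl[seq_len(n_components)],
                 sdev = sv$d / sqrt(nrow(xs) - 1), rank = rank,
                 all_explained = expl),
            class = "flux_pca")
}

#' @export
print.flux_pca <- function(x, ...) {
  cat(sprintf("<flux_pca> %d components; explained: %s\n", ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @rdname tidy.mfa_fit
#' @method tidy flux_pca
#' @export
tidy.flux_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "flux") |>
    tidyr::pivot_longer(-"flux", names_to = "component", values_to = "loading")
}

#' @rdname tidy.mfa_fit
#' @method glance flux_pca
#' @export
glance.flux_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$explained)),
                 explained = x$explained)
}

# ---- PLS-DA ----------------------------------------------------------------

# NIPALS PLS2 on an autoscaled X and a centred class-indicator Y
nipals_pls2 <- function(X, Y, n_components, tol = 1e-10, max_it = 500) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, n_components); P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components); Q <- matrix(0, ncol(Y), n_components)
  ssy <- numeric(n_components)
  Xd <- X; Yd <- Y
  for (a in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_it)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt) / sum(tt^2)
      u <- Yd %*% q / sum(q^2)
      if (sum((tt - t_old)^2) < tol * sum(tt^2)) break
      t_old <- tt
    }
    pp <- crossprod(Xd, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; Q[, a] <- q
    ssy[a] <- sum(tt^2) * sum(q^2)  # Y variance explained by component a
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(q)
  }
  list(W = W, P = P, T = Tm, Q = Q, ssy = ssy)
}

# variable importance in projection over A components
vip_scores <- function(pls) {
  W <- pls$W; ssy <- pls$ssy
  p <- nrow(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(p * as.numeric(wn^2 %*% ssy) / sum(ssy))
  stats::setNames(v, rownames(W))
}

#' Partial least squares discriminant analysis of flux ensembles
#'
#' NIPALS PLS2 regression of an autoscaled flux matrix on a centred
#' two-class indicator response, with variable-importance-in-projection
#' (VIP) scores, k-fold cross-validated classification accuracy, and a
#' label-permutation test of the class separation along component 1.
#'
#' @param x samples-by-fluxes matrix.
#' @param class factor (exactly 2 levels) of condition labels per row.
#' @param n_components number of PLS components (default 2).
#' @param cv_folds folds for cross-validated accuracy (0 skips CV).
#' @param n_permutations label permutations for the separation test
#'   (0 skips the test).
#' @param seed seed for fold assignment and permutations.
#' @return object of class `flux_plsda`: `scores`, `loadings` (X
#'   loadings), `weights`, `vip`, `accuracy` (CV), `permutation_p`,
#'   `explained_y`.
#' @export
flux_plsda <- function(x, class, n_components = 2, cv_folds = 5,
                       n_permutations = 100, seed = 1) {
  class <- as.factor(class)
  if (nlevels(class) != 2) stop("exactly 2 classes required", call. = FALSE)
  xs <- autoscale(x)
  Y <- stats::model.matrix(~ class - 1)
  Y <- sweep(Y, 2, colMeans(Y))
  n_components <- min(n_components, ncol(xs), nrow(xs) - 1)
  pls <- nipals_pls2(xs, Y, n_components)
  rownames(pls$W) <- colnames(xs)
  vip <- vip_scores(pls)

  sep_stat <- function(scores, cls) {
    m <- tapply(scores, cls, mean)
    v <- tapply(scores, cls, stats::var)
    abs(diff(m)) / sqrt(mean(v))
  }
  t1 <- pls$T[, 1]
  perm_p <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    obs <- sep_stat(t1, class)
    cnt <- 0
    for (b in seq_len(n_permutations)) {
      cp <- sample(class)
      Yp <- stats::model.matrix(~ cp - 1); Yp <- sweep(Yp, 2, colMeans(Yp))
      pb <- nipals_pls2(xs, Yp, 1)
      if (sep_stat(pb$T[, 1], cp) >= obs) cnt <- cnt + 1
    }
    perm_p <- (cnt + 1) / (n_permutations + 1)
  }

  acc <- NA_real_
  if (cv_folds > 1) {
    xk <- as.matrix(x)
    xk <- xk[, apply(xk, 2, stats::sd) > 0, drop = FALSE]
    set.seed(seed + 1)
    fold <- sample(rep_len(seq_len(cv_folds), nrow(xk)))
    hits <- 0
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      ctr <- colMeans(xk[tr, , drop = FALSE])
      sct <- apply(xk[tr, , drop = FALSE], 2, stats::sd)
      sct[sct == 0] <- 1
      xtr <- sweep(sweep(xk[tr, , drop = FALSE], 2, ctr), 2, sct, "/")
      ytr <- stats::model.matrix(~ class[tr] - 1)
      ytr <- sweep(ytr, 2, colMeans(ytr))
      pf <- nipals_pls2(xtr, ytr, n_components)
      xte <- sweep(sweep(xk[!tr, , drop = FALSE], 2, ctr), 2, sct, "/")
      # regression coefficients B = W (P'W)^-1 Q'
      B <- pf$W %*% solve(crossprod(pf$P, pf$W)) %*% t(pf$Q)
      pred <- xte %*% B
      pred_class <- levels(class)[apply(pred, 1, which.max)]
      hits <- hits + sum(pred_class == as.character(class[!tr]))
    }
    acc <- hits / nrow(xk)
  }

  structure(list(scores = pls$T, loadings = pls$P, weights = pls$W,
                 q = pls$Q, vip = vip, explained_y = pls$ssy / sum(pls$ssy),
                 class = class, accuracy = acc, permutation_p = perm_p,
                 n_components = n_components),
            class = "flux_plsda")
}

#' @export
print.flux_plsda <- function(x, ...) {
  cat(sprintf("<flux_plsda> %d components; CV accuracy %.2f; permutation p = %.3g\n",
              x$n_components, x$accuracy, x$permutation_p))
  top <- utils::head(sort(x$vip, decreasing = TRUE), 5)
  cat("  top VIP:", paste(sprintf("%s=%.2f", names(top), top), collapse = " "), "\n")
  invisible(x)
}

#' @rdname tidy.mfa_fit
#' @method tidy flux_plsda
#' @export
tidy.flux_plsda <- function(x, ...) {
  tibble::tibble(flux = names(x$vip), vip = unname(x$vip),
                 w1 = x$weights[, 1],
                 w2 = if (ncol(x$weights) > 1) x$weights[, 2] else NA_real_) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}
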