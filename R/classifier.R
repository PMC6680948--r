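# Regularized linear discriminant classifier on per-fold sufficient
# statistics.  The feature cap (<= 16 selected features) keeps a linear
# discriminative model well-posed; shrinkage of the pooled covariance toward
# its diagonal guards against near-singular fits during selection.  Storing
# per-fold class counts, sums and cross-products lets any feature subset be
# fitted and cross-validated without revisiting the rows.

fold_stats <- function(x, y, fold_id) {
  k <- max(fold_id)
  d <- ncol(x)
  st <- list(k = k, d = d,
             n0 = integer(k), n1 = integer(k),
             s0 = matrix(0, k, d), s1 = matrix(0, k, d),
             cp0 = vector("list", k), cp1 = vector("list", k))
  for (f in seq_len(k)) {
    rows <- fold_id == f
    x0 <- x[rows & y == 0L, , drop = FALSE]
    x1 <- x[rows & y == 1L, , drop = FALSE]
    st$n0[f] <- nrow(x0); st$n1[f] <- nrow(x1)
    st$s0[f, ] <- colSums(x0); st$s1[f, ] <- colSums(x1)
    st$cp0[[f]] <- crossprod(x0); st$cp1[[f]] <- crossprod(x1)
  }
  st$tn0 <- sum(st$n0); st$tn1 <- sum(st$n1)
  st$ts0 <- colSums(st$s0); st$ts1 <- colSums(st$s1)
  st$tcp0 <- Reduce(`+`, st$cp0); st$tcp1 <- Reduce(`+`, st$cp1)
  st
}

# fit the discriminant on the given class statistics, restricted to columns S
lda_from_stats <- function(n0, n1, s0, s1, cp0, cp1, S, lambda) {
  mu0 <- s0[S] / n0
  mu1 <- s1[S] / n1
  sw <- (cp0[S, S, drop = FALSE] - n0 * tcrossprod(mu0) +
         cp1[S, S, drop = FALSE] - n1 * tcrossprod(mu1)) /
    max(1, n0 + n1 - 2)
  dg <- diag(sw)
  sigma <- (1 - lambda) * sw + lambda * diag(dg, nrow = length(S))
  floor_applied <- FALSE
  ridge <- 1e-8 * max(mean(dg), 1e-300)
  repeat {
    w <- tryCatch(solve(sigma + diag(ridge, length(S)), mu1 - mu0),
                  error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    floor_applied <- TRUE
    ridge <- max(ridge * 100, 1e-6 * max(mean(dg), 1e-12))
  }
  list(w = w, b = -sum(w * (mu0 + mu1) / 2), floor_applied = floor_applied)
}

# Mean cross-validated balanced accuracy for each candidate subset.
# `subsets` is a list of integer column-index vectors; folds whose test block
# misses a class are skipped (with a one-time warning).
cv_balanced_accuracy <- function(x, y, fold_id, st, subsets, lambda) {
  k <- st$k
  cols <- sort(unique(unlist(subsets)))
  nsub <- length(subsets)
  acc <- matrix(NA_real_, k, nsub)
  skipped <- 0L
  for (f in seq_len(k)) {
    rows <- which(fold_id == f)
    yt <- y[rows]
    if (!any(yt == 0L) || !any(yt == 1L)) { skipped <- skipped + 1L; next }
    n0 <- st$tn0 - st$n0[f]; n1 <- st$tn1 - st$n1[f]
    if (n0 == 0 || n1 == 0) { skipped <- skipped + 1L; next }
    s0 <- st$ts0 - st$s0[f, ]; s1 <- st$ts1 - st$s1[f, ]
    cp0 <- st$tcp0 - st$cp0[[f]]; cp1 <- st$tcp1 - st$cp1[[f]]
    W <- matrix(0, length(cols), nsub)
    b <- numeric(nsub)
    for (j in seq_len(nsub)) {
      S <- subsets[[j]]
      fit <- lda_from_stats(n0, n1, s0, s1, cp0, cp1, S, lambda)
      W[match(S, cols), j] <- fit$w
      b[j] <- fit$b
    }
    P <- x[rows, cols, drop = FALSE] %*% W
    P <- sweep(P, 2, b, `+`)
    pos <- P > 0
    tpr <- colMeans(pos[yt == 1L, , drop = FALSE])
    tnr <- colMeans(!pos[yt == 0L, , drop = FALSE])
    acc[f, ] <- (tpr + tnr) / 2
  }
  if (skipped > 0L)
    warning(sprintf("%d fold(s) with a missing class skipped during cross-validation",
                    skipped), call. = FALSE)
  if (all(is.na(acc)))
    stop("every fold misses one class; cannot cross-validate", call. = FALSE)
  colMeans(acc, na.rm = TRUE)
}
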