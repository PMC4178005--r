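## Two-class linear discriminant with diagonal shrinkage.
##
## The discriminant is the workhorse behind the LDA-performance
## similarity feature: its held-out accuracy at telling two knockdown
## cell populations apart is read as phenotype dissimilarity. Cell
## feature matrices are high-dimensional and frequently collinear, so
## the pooled within-class covariance is shrunk toward its diagonal
## just enough to be well conditioned; a singular covariance therefore
## degrades gracefully instead of failing.

fitShrinkageLda <- function(x, y) {
  y <- as.factor(y)
  lev <- levels(y)
  if (length(lev) != 2L) stop("exactly two classes required")
  x <- as.matrix(x)
  mu0 <- colMeans(x[y == lev[1L], , drop = FALSE])
  mu1 <- colMeans(x[y == lev[2L], , drop = FALSE])
  n0 <- sum(y == lev[1L])
  n1 <- sum(y == lev[2L])
  c0 <- stats::cov(x[y == lev[1L], , drop = FALSE])
  c1 <- stats::cov(x[y == lev[2L], , drop = FALSE])
  s <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  dg <- diag(s)
  dg[dg <= 0] <- mean(dg[dg > 0], na.rm = TRUE)
  if (!is.finite(mean(dg))) dg[] <- 1
  target <- diag(dg, nrow = nrow(s))
  w <- NULL
  for (lambda in c(0, 0.01, 0.05, 0.1, 0.25, 0.5, 0.9, 0.99, 1)) {
    st <- (1 - lambda) * s + lambda * target
    ok <- tryCatch(rcond(st) > 1e-10, error = function(e) FALSE)
    if (ok) {
      w <- solve(st, mu1 - mu0)
      break
    }
  }
  if (is.null(w)) {
    ## fully diagonal target still singular: fall back to a ridge
    st <- target + mean(dg) * 1e-6 * diag(nrow(s))
    w <- solve(st, mu1 - mu0)
  }
  list(
    w = w,
    cut = sum(w * (mu0 + mu1)) / 2,
    levels = lev
  )
}

predictShrinkageLda <- function(fit, x) {
  score <- as.matrix(x) %*% fit$w
  factor(
    ifelse(drop(score) > fit$cut, fit$levels[2L], fit$levels[1L]),
    levels = fit$levels
  )
}
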