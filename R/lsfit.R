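## Internal dense least-squares engine shared by the screening and
## response-surface fits.  QR-based; also returns hat diagonals (needed
## for the closed-form leave-one-out PRESS) and the coefficient
## covariance.

ls_engine <- function(X, y) {
  stopifnot(nrow(X) == length(y), !anyNA(y), !anyNA(X))
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop(sprintf("rank-deficient model matrix (rank %d < %d columns)",
                 qrx$rank, ncol(X)))
  b <- qr.coef(qrx, y)
  fitted <- drop(X %*% b)
  r <- y - fitted
  df <- nrow(X) - ncol(X)
  rss <- sum(r^2)
  s2 <- if (df > 0) rss / df else NA_real_
  XtXinv <- chol2inv(qr.R(qrx))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  h <- rowSums(qr.Q(qrx)^2)
  sst <- sum((y - mean(y))^2)
  press <- if (all(h < 1 - 1e-12)) sum((r / (1 - h))^2) else NA_real_
  list(coefficients = stats::setNames(b, colnames(X)),
       fitted = fitted, residuals = r, df_residual = df,
       rss = rss, s2 = s2, XtXinv = XtXinv, hat = h, sst = sst,
       press = press,
       r_squared = 1 - rss / sst,
       q_squared = 1 - press / sst)
}

## two-sided t-test p-values for the coefficients of an ls_engine fit
ls_coef_tests <- function(fit) {
  se <- sqrt(diag(fit$XtXinv) * fit$s2)
  tval <- fit$coefficients / se
  p <- 2 * stats::pt(abs(tval), fit$df_residual, lower.tail = FALSE)
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients), se = unname(se),
             t = unname(tval), p = unname(p), row.names = NULL)
}
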