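## Independent oracles used to cross-check the package's least-squares
## and Monte Carlo machinery.  Deliberately naive: explicit normal
## equations, explicit leave-one-out refits, explicit coefficient-vector
## sampling.

## explicit normal-equations least squares: (X'X)^-1 X'y
oracle_ls <- function(X, y) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  b <- drop(XtXinv %*% t(X) %*% y)
  r <- y - drop(X %*% b)
  df <- nrow(X) - ncol(X)
  s2 <- sum(r^2) / df
  list(b = b, cov = XtXinv * s2, s2 = s2, df = df,
       r_squared = 1 - sum(r^2) / sum((y - mean(y))^2))
}

## Q2 by explicitly refitting with each run left out
oracle_loo_q2 <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    b <- solve(t(X[-i, ]) %*% X[-i, ], t(X[-i, ]) %*% y[-i])
    press <- press + (y[i] - drop(X[i, , drop = FALSE] %*% b))^2
  }
  1 - press / sum((y - mean(y))^2)
}

## joint pass probability by sampling full coefficient vectors with
## MASS::mvrnorm (the package collapses the draw to its exact scalar law)
oracle_joint_pass <- function(models, specs, point, n_sims, seed) {
  set.seed(seed)
  pass <- rep(TRUE, n_sims)
  for (nm in names(specs)) {
    m <- models[[nm]]
    M <- aqbd::quadratic_model_matrix(
      matrix(point, nrow = 1,
             dimnames = list(NULL, colnames(m$design$coded))))
    M <- M[, m$terms$term, drop = FALSE]
    B <- MASS::mvrnorm(n_sims, m$coefficients, m$covariance)
    dr <- drop(B %*% t(M)) + rnorm(n_sims, 0, m$residual_sd)
    thr <- if (m$transform == "log10") log10(specs[[nm]]$threshold)
           else specs[[nm]]$threshold
    pass <- pass & (if (specs[[nm]]$direction == "ge") dr >= thr
                    else dr <= thr)
  }
  100 * mean(pass)
}

## shared fixtures (loaded once per test file)
ccd_study <- trimecaine_ccd_study()
screening_study <- trimecaine_screening_study()
rsm_factors <- trimecaine_factors("rsm")
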