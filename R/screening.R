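#' Free-Wilson model matrix for a three-level screening design
#'
#' Encodes each three-level factor as two sum-to-zero indicator contrasts:
#' a run at level 1 contributes (1, 0), level 2 contributes (0, 1) and
#' level 3 contributes (-1, -1), so the three level coefficients of every
#' factor sum to zero and the third is implied by the first two.  The
#' model has one intercept column plus two columns per factor.
#'
#' @param design An `"aqbd_design"` whose coded entries are level indices
#'   1/2/3.
#' @return Numeric model matrix (runs x (1 + 2 k)).
#' @export
free_wilson_matrix <- function(design) {
  stopifnot(inherits(design, "aqbd_design"))
  lv <- design$coded
  if (!all(lv %in% 1:3))
    stop("Free-Wilson encoding expects level indices 1/2/3")
  for (j in seq_len(ncol(lv)))
    if (length(unique(lv[, j])) != 3L)
      stop("factor ", colnames(lv)[j], " does not show all 3 levels")
  X <- matrix(1, nrow(lv), 1 + 2 * ncol(lv))
  cn <- "(Intercept)"
  for (j in seq_len(ncol(lv))) {
    X[, 2 * j]     <- ifelse(lv[, j] == 1, 1, ifelse(lv[, j] == 3, -1, 0))
    X[, 2 * j + 1] <- ifelse(lv[, j] == 2, 1, ifelse(lv[, j] == 3, -1, 0))
    cn <- c(cn, paste0(colnames(lv)[j], "_l", 1:2))
  }
  colnames(X) <- cn
  X
}

#' Fit a Free-Wilson screening model
#'
#' Additive model assigning one effect per factor level, fitted by least
#' squares under the sum-to-zero constraint, with an overall ANOVA F-test
#' of the model against the intercept-only fit.  The residual error of
#' the saturated-but-one fit is exposed alongside a pure-error estimate
#' pooled from duplicated design rows (for the embedded screening array
#' the two coincide, both carrying a single degree of freedom).
#'
#' @param design A three-level `"aqbd_design"`.
#' @param y Numeric response vector, one value per run, no missing values.
#' @param error Which error mean square drives the coefficient and
#'   contrast tests: `"residual"` (default) or `"pure"` (replicate-based).
#' @return An object of class `"free_wilson"` with per-factor level
#'   coefficient matrices (`level_coefficients`, rows = factors,
#'   columns = levels 1..3), their standard errors, the residual standard
#'   deviation and the model ANOVA.
#' @export
fit_free_wilson <- function(design, y, error = c("residual", "pure")) {
  error <- match.arg(error)
  stopifnot(length(y) == nrow(design$coded))
  if (anyNA(y)) stop("missing response values are not allowed in screening")
  X <- free_wilson_matrix(design)
  k <- ncol(design$coded)

  if (stats::var(y) == 0) {
    ## degenerate constant response: no variation to model
    lc <- matrix(0, k, 3, dimnames = list(colnames(design$coded),
                                          paste0("level", 1:3)))
    out <- list(intercept = y[1], level_coefficients = lc,
                coefficient_se = lc * NA, residual_sd = 0,
                anova = list(F = NA_real_, df_model = 2 * k,
                             df_residual = nrow(X) - ncol(X), p = NA_real_,
                             computable = FALSE),
                design = design, X = X, y = y, fit = NULL, error = error)
    class(out) <- "free_wilson"
    return(out)
  }

  fit <- ls_engine(X, y)

  ## pure error from duplicated rows
  key <- apply(design$coded, 1, paste, collapse = "/")
  groups <- split(y, key)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_pe <- sum(vapply(groups, length, 0L) - 1L)
  if (error == "pure") {
    if (df_pe == 0)
      stop("no replicated runs: replicate-based error unavailable")
    s2 <- ss_pe / df_pe; df_err <- df_pe
  } else {
    if (fit$df_residual == 0)
      stop("saturated design leaves no residual degrees of freedom")
    s2 <- fit$s2; df_err <- fit$df_residual
  }

  F <- ((fit$sst - fit$rss) / (2 * k)) / s2
  p <- stats::pf(F, 2 * k, df_err, lower.tail = FALSE)

  b <- fit$coefficients
  lc <- matrix(NA_real_, k, 3, dimnames = list(colnames(design$coded),
                                               paste0("level", 1:3)))
  se <- lc
  V <- fit$XtXinv * s2
  for (j in seq_len(k)) {
    i1 <- 2 * j; i2 <- 2 * j + 1
    lc[j, ] <- c(b[i1], b[i2], -b[i1] - b[i2])
    se[j, ] <- sqrt(c(V[i1, i1], V[i2, i2],
                      V[i1, i1] + V[i2, i2] + 2 * V[i1, i2]))
  }
  out <- list(intercept = unname(b[1]), level_coefficients = lc,
              coefficient_se = se, residual_sd = sqrt(s2),
              anova = list(F = F, df_model = 2 * k, df_residual = df_err,
                           p = p, computable = TRUE),
              pure_error = list(s2 = if (df_pe > 0) ss_pe / df_pe else NA,
                                df = df_pe),
              design = design, X = X, y = y, fit = fit, error = error,
              error_s2 = s2, error_df = df_err)
  class(out) <- "free_wilson"
  out
}

#' @export
print.free_wilson <- function(x, ...) {
  cat("Free-Wilson screening model\n")
  cat(sprintf("  intercept %.4g, residual sd %.4g\n", x$intercept,
              x$residual_sd))
  if (isTRUE(x$anova$computable))
    cat(sprintf("  ANOVA: F(%d,%d) = %.3f, p = %.4f\n", x$anova$df_model,
                x$anova$df_residual, x$anova$F, x$anova$p))
  else cat("  ANOVA: not computable (constant response)\n")
  invisible(x)
}

#' Per-level effects for the graphic analysis of effects
#'
#' For every factor, the predicted response at each of its three levels
#' with all other factors averaged out: intercept + level coefficient.
#' These are the bar heights of the classic screening effect plot -- a
#' longer bar marks the level that maximises the attribute.
#'
#' @param model A fitted [fit_free_wilson()] model.
#' @return Data frame with columns `factor`, `level`, `effect`,
#'   `coefficient`.
#' @export
level_effects <- function(model) {
  stopifnot(inherits(model, "free_wilson"))
  lc <- model$level_coefficients
  data.frame(factor = rep(rownames(lc), each = 3),
             level = rep(1:3, nrow(lc)),
             coefficient = as.vector(t(lc)),
             effect = model$intercept + as.vector(t(lc)),
             row.names = NULL)
}

#' Significance of level changes
#'
#' t-tests of the pairwise level transitions (2 to 1, 3 to 2, 3 to 1) of
#' each factor against the model's error term, mirroring the orange/blue
#' significance bars of screening software.  The contrast variance is
#' `c' (X'X)^-1 c * s^2` on the free (first-two-level) parameterisation.
#'
#' @param model A fitted [fit_free_wilson()] model.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame of class `"effect_contrasts"`: one row per factor
#'   and transition with `estimate`, `se`, `p_value`, `significant`.
#' @export
level_change_significance <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "free_wilson"))
  if (is.null(model$fit))
    stop("contrasts unavailable for a constant response")
  if (model$error_df <= 0)
    stop("no residual degrees of freedom for contrast tests")
  k <- nrow(model$level_coefficients)
  V <- model$fit$XtXinv * model$error_s2
  ## contrast weights on (b1, b2): effect(to) - effect(from), b3 = -b1-b2
  trans <- list(`2->1` = c(from = 2, to = 1, w1 = 1, w2 = -1),
                `3->2` = c(from = 3, to = 2, w1 = 1, w2 = 2),
                `3->1` = c(from = 3, to = 1, w1 = 2, w2 = 1))
  rows <- list()
  for (j in seq_len(k)) {
    i1 <- 2 * j; i2 <- 2 * j + 1
    for (nm in names(trans)) {
      tr <- trans[[nm]]
      cvec <- rep(0, ncol(model$X))
      cvec[c(i1, i2)] <- c(tr[["w1"]], tr[["w2"]])
      est <- sum(cvec * model$fit$coefficients)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      p <- if (se == 0) {
        if (abs(est) < 1e-12) 1 else 0
      } else 2 * stats::pt(abs(est / se), model$error_df,
                           lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(factor = rownames(model$level_coefficients)[j],
                   from_level = unname(tr[["from"]]),
                   to_level = unname(tr[["to"]]),
                   estimate = est, se = se, p_value = p,
                   significant = is.finite(p) && p < alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_contrasts", "data.frame")
  out
}

#' Predictions from a Free-Wilson model
#'
#' @param object A `"free_wilson"` model.
#' @param newdesign Optional design to predict at; defaults to the
#'   training design.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.free_wilson <- function(object, newdesign = NULL, ...) {
  if (is.null(object$fit)) {
    n <- if (is.null(newdesign)) length(object$y) else nrow(newdesign$coded)
    return(rep(object$intercept, n))
  }
  X <- if (is.null(newdesign)) object$X else free_wilson_matrix(newdesign)
  drop(X %*% object$fit$coefficients)
}
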