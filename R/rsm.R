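## Quadratic term bookkeeping: every term is a pair (i, j) of factor
## indices with the conventions (0,0) intercept, (i,0) linear, (i,i)
## quadratic, (i,j) i<j interaction.  Canonical order: intercept, all
## linear, all quadratic, all interactions.

quadratic_term_set <- function(nm) {
  k <- length(nm)
  ti <- c(0L, seq_len(k), seq_len(k))
  tj <- c(0L, rep(0L, k), seq_len(k))
  lab <- c("(Intercept)", nm, paste0(nm, "^2"))
  if (k >= 2) {
    pr <- utils::combn(k, 2)
    ti <- c(ti, pr[1, ]); tj <- c(tj, pr[2, ])
    lab <- c(lab, paste0(nm[pr[1, ]], ":", nm[pr[2, ]]))
  }
  data.frame(term = lab, i = ti, j = tj, stringsAsFactors = FALSE)
}

eval_terms <- function(terms, X) {
  X1 <- cbind(1, X)      # column 1 is the constant, factor i at column i+1
  M <- X1[, terms$i + 1L, drop = FALSE] * X1[, terms$j + 1L, drop = FALSE]
  colnames(M) <- terms$term
  M
}

#' Full quadratic model matrix
#'
#' Builds the 1 + 2k + k(k-1)/2 column matrix of the full second-order
#' model in canonical order: intercept, linear terms, pure quadratics,
#' then two-factor interactions (21 columns for five factors).
#'
#' @param design An `"aqbd_design"` with continuous coded factors, or a
#'   coded numeric matrix with column names.
#' @return Numeric model matrix.
#' @export
quadratic_model_matrix <- function(design) {
  X <- if (inherits(design, "aqbd_design")) design$coded else as.matrix(design)
  eval_terms(quadratic_term_set(colnames(X)), X)
}

#' Fit a quadratic response-surface model
#'
#' Least-squares fit of the full second-order model to a CCD (or any
#' coded design), optionally after a log10 transformation of the
#' response.  Runs with a missing response are excluded before fitting --
#' in the embedded CCD study the plate count is missing at the three
#' co-migration runs, leaving 26 usable runs for that response.  Model
#' quality is summarised by R-squared and by the leave-one-out
#' goodness-of-prediction Q-squared (see [q2()]), both computed on the
#' fitting scale.
#'
#' @param design An `"aqbd_design"` with continuous coded factors.
#' @param y Response vector aligned to the design runs; `NA`s allowed.
#' @param transform `"none"` or `"log10"`.
#' @param terms Optional term subset (data frame from an earlier model's
#'   `terms`); defaults to the full quadratic set.
#' @return An object of class `"rsm_model"`.
#' @export
fit_rsm <- function(design, y, transform = c("none", "log10"),
                    terms = NULL) {
  transform <- match.arg(transform)
  stopifnot(inherits(design, "aqbd_design"),
            length(y) == nrow(design$coded))
  used <- !is.na(y)
  yy <- y[used]
  if (transform == "log10") {
    if (any(yy <= 0))
      stop("log10 transform requires strictly positive responses")
    yy <- log10(yy)
  }
  if (is.null(terms)) terms <- quadratic_term_set(colnames(design$coded))
  X <- eval_terms(terms, design$coded[used, , drop = FALSE])
  if (nrow(X) <= ncol(X))
    stop("more retained terms than usable runs")
  fit <- ls_engine(X, yy)
  out <- list(terms = terms, coefficients = fit$coefficients,
              covariance = fit$XtXinv * fit$s2,
              residual_sd = sqrt(fit$s2), transform = transform,
              n_used = nrow(X), used = used,
              quality = c(R2 = fit$r_squared, Q2 = fit$q_squared),
              fit = fit, design = design, y = y,
              alpha = attr(design, "alpha") %||% max(abs(design$coded)))
  class(out) <- "rsm_model"
  out
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf(
    "quadratic response-surface model (%s scale): %d terms, n = %d\n",
    if (x$transform == "log10") "log10" else "original",
    nrow(x$terms), x$n_used))
  cat(sprintf("  R2 = %.4f, Q2 = %.4f, residual sd = %.4g\n",
              x$quality["R2"], x$quality["Q2"], x$residual_sd))
  invisible(x)
}

#' Coefficient table with t-tests
#'
#' @param model An `"rsm_model"`.
#' @return Data frame of term estimates, standard errors and p-values
#'   (residual degrees of freedom of this model).
#' @export
coef_table <- function(model) {
  stopifnot(inherits(model, "rsm_model"))
  ls_coef_tests(model$fit)
}

#' Goodness of prediction (Q-squared)
#'
#' `Q2 = 1 - PRESS / SS_total(corrected)` where PRESS is the
#' leave-one-out prediction error sum of squares, computed without
#' refitting through the identity `e_(i) = e_i / (1 - h_ii)`.  Q2 is
#' never larger than R2; values well below it flag overfitting.  The raw
#' value is returned; some RSM software floors it at zero, so
#' `q2(model, floor = TRUE)` is also available.
#'
#' @param model An `"rsm_model"`.
#' @param floor If `TRUE`, return `max(Q2, 0)`.
#' @return Numeric Q-squared on the fitting scale.
#' @export
q2 <- function(model, floor = FALSE) {
  stopifnot(inherits(model, "rsm_model"))
  if (any(model$fit$hat >= 1 - 1e-12))
    stop("a run is exactly self-predicting (hat diagonal >= 1); ",
         "leave-one-out prediction undefined")
  val <- model$fit$q_squared
  if (floor) max(val, 0) else val
}

#' PRESS statistic
#' @param model An `"rsm_model"`.
#' @return Leave-one-out prediction error sum of squares.
#' @export
press <- function(model) {
  stopifnot(inherits(model, "rsm_model"))
  model$fit$press
}

#' Backward refinement maximising Q-squared
#'
#' Iteratively removes one non-intercept term at a time: among the terms
#' that are not significant at `alpha` (t-test, residual degrees of
#' freedom of the current model), the removal giving the largest increase
#' in Q-squared is applied; the process stops when no such removal
#' increases Q-squared.  Ties in Q-squared gain (within 1e-12) are broken
#' towards the larger p-value, then towards the later term in canonical
#' order.  The intercept is never removed and term heredity is not
#' enforced.
#'
#' @param model A fitted full `"rsm_model"`.
#' @param alpha Significance level guarding removals.
#' @return The refined `"rsm_model"` (the input model if no removal
#'   helps).
#' @export
refine_backward <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "rsm_model"))
  design <- model$design; y <- model$y
  terms <- model$terms
  current <- model
  repeat {
    tests <- ls_coef_tests(current$fit)
    cand <- which(tests$p > alpha & tests$term != "(Intercept)")
    if (!length(cand)) return(current)
    q2_now <- current$quality["Q2"]
    q2_try <- vapply(cand, function(i)
      fit_rsm(design, y, transform = model$transform,
              terms = current$terms[-i, , drop = FALSE])$quality["Q2"],
      numeric(1))
    best_gain <- max(q2_try) - q2_now
    if (best_gain <= 0) return(current)
    tied <- which(q2_try >= max(q2_try) - 1e-12)
    if (length(tied) > 1L) {
      pv <- tests$p[cand[tied]]
      tied <- tied[pv >= max(pv) - 1e-15]
      pick <- tied[length(tied)]          # later term in canonical order
    } else pick <- tied
    current <- fit_rsm(design, y, transform = model$transform,
                       terms = current$terms[-cand[pick], , drop = FALSE])
  }
}

#' Predict from a response-surface model
#'
#' Mean predictions on the original response scale (point back-transform
#' `10^` for log10 models) together with the prediction standard
#' deviation on the fitting scale, combining coefficient covariance and
#' residual variance: `sqrt(x' V x + s^2)`.
#'
#' @param object An `"rsm_model"`.
#' @param newdata Coded coordinates: a numeric vector (one point), a
#'   matrix or a data frame, columns in design-factor order.
#' @param guard Extrapolation guard in coded units; points with any
#'   |coordinate| beyond it raise a warning.  Defaults to the design's
#'   axial distance + 0.1.
#' @param ... Unused.
#' @return Data frame with columns `mean` (original scale), `se_fit`
#'   (fitting scale, coefficient part only) and `se_pred` (fitting scale,
#'   including residual noise).
#' @export
predict.rsm_model <- function(object, newdata, guard = NULL, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  X <- as.matrix(newdata)
  colnames(X) <- colnames(object$design$coded)
  if (is.null(guard)) guard <- object$alpha + 0.1
  if (any(abs(X) > guard + 1e-9))
    warning(sprintf("prediction beyond the extrapolation guard (|coded| > %.3g)",
                    guard))
  M <- eval_terms(object$terms, X)
  mu <- drop(M %*% object$coefficients)
  v_coef <- rowSums((M %*% object$covariance) * M)
  se_fit <- sqrt(pmax(v_coef, 0))
  se_pred <- sqrt(pmax(v_coef, 0) + object$residual_sd^2)
  mean_orig <- if (object$transform == "log10") 10^mu else mu
  data.frame(mean = mean_orig, fit = mu, se_fit = se_fit,
             se_pred = se_pred)
}

#' Sweet-spot grid: how many attribute criteria the mean predictions meet
#'
#' Evaluates the mean prediction of every model over a two-factor grid
#' (the remaining factors held at fixed values) and counts, node by node,
#' how many specifications are satisfied.  With the trimecaine models the
#' classic layout is CyD concentration against pH in a 3 x 3 trellis of
#' voltage and buffer concentration panels with n-butanol fixed at 1.00%.
#'
#' @param models Named list of `"rsm_model"`s, one per specification.
#' @param specs Named list of [cma_spec()]s (names match `models`).
#' @param grid A [panel_grid()] describing the slice layout.
#' @return Object of class `"sweet_spot"`: list with the grid and a list
#'   of integer count matrices, one per panel.
#' @export
sweet_spot <- function(models, specs, grid) {
  stopifnot(all(names(specs) %in% names(models)))
  counts <- lapply(grid$panels, function(panel) {
    cnt <- matrix(0L, length(grid$x_values), length(grid$y_values))
    for (nm in names(specs)) {
      mu <- predict(models[[nm]], panel$coded)$mean
      ok <- spec_satisfied(specs[[nm]], mu)
      cnt <- cnt + matrix(as.integer(ok), length(grid$x_values))
    }
    cnt
  })
  out <- list(grid = grid, counts = counts, n_specs = length(specs))
  class(out) <- "sweet_spot"
  out
}

#' @export
print.sweet_spot <- function(x, ...) {
  areas <- vapply(x$counts, function(m) sum(m == x$n_specs), 0L)
  cat(sprintf("sweet-spot grid: %d panels of %d x %d nodes\n",
              length(x$counts), length(x$grid$x_values),
              length(x$grid$y_values)))
  for (i in seq_along(x$counts))
    cat(sprintf("  %-28s all-%d nodes: %d\n", x$grid$panel_labels[i],
                x$n_specs, areas[i]))
  invisible(x)
}

#' Plot a sweet-spot trellis
#'
#' @param x A `"sweet_spot"` object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sweet_spot <- function(x, ...) {
  np <- length(x$counts)
  nrow_p <- floor(sqrt(np)); ncol_p <- ceiling(np / nrow_p)
  op <- graphics::par(mfrow = c(nrow_p, ncol_p), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(x$n_specs + 1, "RdYlGn")
  for (i in seq_along(x$counts)) {
    graphics::image(x$grid$x_values, x$grid$y_values, x$counts[[i]],
                    zlim = c(0, x$n_specs), col = cols,
                    xlab = x$grid$x, ylab = x$grid$y,
                    main = x$grid$panel_labels[i], ...)
  }
  invisible(x)
}
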