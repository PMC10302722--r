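#' Fit a main-effects model to Plackett-Burman robustness data
#'
#' Each factor's effect is the difference between the response means at
#' its high and low settings (equal to twice the regression coefficient
#' on the -1/+1 column).  Significance is judged against the error mean
#' square carried by the unassigned (dummy) columns: regressing on the
#' assigned columns only, the residual collects exactly the dummy-column
#' contrasts, giving an error estimate with one degree of freedom per
#' dummy column.
#'
#' @param design A `"plackett_burman"` design from [pb_design()]; columns
#'   named `dummy*` are treated as error carriers.
#' @param y Response vector, one value per run.
#' @param alpha Significance level.
#' @return Object of class `"pb_fit"` with an `effects` data frame
#'   (factor, effect, coefficient, se, p, significant).
#' @export
fit_pb_linear <- function(design, y, alpha = 0.05) {
  stopifnot(inherits(design, "aqbd_design"),
            design$kind == "plackett_burman",
            length(y) == nrow(design$coded))
  X <- design$coded
  if (any(colSums(X) != 0)) stop("unbalanced Plackett-Burman columns")
  nms <- colnames(X)
  real <- !grepl("^dummy", nms)
  if (!any(real)) stop("no assigned factor columns")
  Xa <- cbind(`(Intercept)` = 1, X[, real, drop = FALSE])
  fit <- ls_engine(Xa, y)
  tests <- ls_coef_tests(fit)[-1, ]      # drop intercept row
  eff <- data.frame(factor = tests$term,
                    effect = 2 * tests$estimate,
                    coefficient = tests$estimate,
                    se = tests$se, t = tests$t, p = tests$p,
                    significant = is.finite(tests$p) & tests$p < alpha,
                    row.names = NULL)
  ## dummy-column effects: pure noise contrasts (diagnostic)
  dummies <- if (any(!real)) {
    drop(crossprod(X[, !real, drop = FALSE], y)) / (nrow(X) / 2)
  } else numeric(0)
  structure(list(effects = eff, dummy_effects = dummies,
                 df_error = fit$df_residual, s2 = fit$s2, fit = fit,
                 design = design, y = y, alpha = alpha),
            class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Plackett-Burman main-effects fit (%d runs, %d error df)\n",
              nrow(x$design$coded), x$df_error))
  print(x$effects, digits = 4)
  invisible(x)
}

#' Significance summary of a robustness study
#'
#' One line per response naming the parameters whose variation, over the
#' narrow robustness ranges, still moves the attribute significantly.
#'
#' @param fits Named list of [fit_pb_linear()] results, one per response.
#' @return Named character vector of summaries.
#' @export
robustness_summary <- function(fits) {
  vapply(names(fits), function(nm) {
    sig <- fits[[nm]]$effects$factor[fits[[nm]]$effects$significant]
    if (!length(sig)) sprintf("no parameter significant on %s", nm)
    else sprintf("%s significant on %s", paste(sig, collapse = " and "),
                 nm)
  }, "")
}

#' System-suitability acceptance ranges
#'
#' The acceptance interval of each attribute runs from the lowest to the
#' highest value observed during robustness testing.  When model
#' predictions (for instance the fitted plate-count model evaluated over
#' the robustness conditions) exceed the observed maximum, the upper
#' limit is widened to cover them and the range is flagged.
#'
#' @param responses A [response_table()] (or plain data frame with a
#'   `run_id` column) of robustness measurements.
#' @param predictions Optional named list of numeric model predictions
#'   per response.
#' @param widen_low Also allow widening of the lower limit below the
#'   observed minimum (off by default).
#' @return Data frame of class `"suitability_ranges"`: `response`, `low`,
#'   `high`, `widened`, `reason`.
#' @export
suitability_ranges <- function(responses, predictions = NULL,
                               widen_low = FALSE) {
  resp <- setdiff(names(responses), "run_id")
  rows <- lapply(resp, function(nm) {
    v <- responses[[nm]]
    v <- v[!is.na(v)]
    if (length(v) < 2)
      stop("fewer than 2 observed values for response ", nm)
    low <- min(v); high <- max(v)
    widened <- FALSE; reason <- ""
    pr <- predictions[[nm]]
    if (!is.null(pr)) {
      pr <- pr[!is.na(pr)]
      if (length(pr) && max(pr) > high) {
        high <- max(pr); widened <- TRUE
        reason <- "upper limit widened to include model predictions"
      }
      if (widen_low && length(pr) && min(pr) < low) {
        low <- min(pr); widened <- TRUE
        reason <- trimws(paste(reason,
                               "lower limit widened to include model predictions"))
      }
    }
    data.frame(response = nm, low = low, high = high, widened = widened,
               reason = reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("suitability_ranges", "data.frame")
  out
}

#' Robustness conditions around a working point
#'
#' Maps the -1/+1 levels of a Plackett-Burman robustness design onto
#' response-surface coded coordinates: low/high of each assigned factor
#' become working point -/+ the chosen half-width.  Factors of the
#' response-surface model that are not exercised (or are dummy columns)
#' stay at the working point.
#'
#' @param pb A [pb_design()].
#' @param working_point Coded working point over `factors`.
#' @param half_widths Named perturbation half-widths in coded units for
#'   the assigned PB factors.
#' @param factors The response-surface factor list.
#' @return Coded matrix (runs x factors) suitable for
#'   [predict.rsm_model()] or [simulate_study()].
#' @export
robustness_conditions <- function(pb, working_point, half_widths,
                                  factors) {
  stopifnot(inherits(pb, "aqbd_design"), pb$kind == "plackett_burman")
  nms <- factor_names(factors)
  wp <- working_point[nms]
  out <- matrix(rep(as.numeric(wp), each = nrow(pb$coded)),
                nrow(pb$coded), length(nms), dimnames = list(NULL, nms))
  for (f in intersect(colnames(pb$coded), names(half_widths))) {
    if (!f %in% nms) next
    out[, f] <- wp[[f]] + pb$coded[, f] * half_widths[[f]]
  }
  out
}
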