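#' Ground-truth generator for synthetic method-development studies
#'
#' Defines, for each response, a true quadratic surface on the coded
#' factor basis, a noise standard deviation (on the fitting scale) and an
#' optional log10 transform tag.  A co-migration rule mirrors the failure
#' mode of the embedded study: wherever the simulated signed resolution
#' is closer to zero than `comigration_tol`, the companion efficiency
#' response is set missing, because overlapping peaks carry no readable
#' plate count.
#'
#' @param coefficients Named list: per response, a named numeric vector
#'   of coefficients over quadratic-basis term labels (as produced by
#'   [quadratic_model_matrix()]; absent terms are zero).
#' @param sd Named numeric vector of noise standard deviations (fitting
#'   scale; must be >= 0).
#' @param transform Named character vector, `"none"` or `"log10"` per
#'   response.
#' @param comigration Optional list `list(resolution=, efficiency=)`
#'   naming the signed resolution that drives missingness and the
#'   efficiency response it blanks.
#' @param comigration_tol Absolute resolution below which peaks are
#'   considered co-migrating.
#' @return Object of class `"truth_model"`.
#' @export
truth_model <- function(coefficients, sd, transform = NULL,
                        comigration = NULL, comigration_tol = 0.05) {
  stopifnot(is.list(coefficients), all(names(sd) %in% names(coefficients)),
            all(sd >= 0))
  if (is.null(transform))
    transform <- stats::setNames(rep("none", length(coefficients)),
                                 names(coefficients))
  structure(list(coefficients = coefficients, sd = sd,
                 transform = transform, comigration = comigration,
                 comigration_tol = comigration_tol),
            class = "truth_model")
}

## evaluate one response's noiseless truth (fitting scale) on a coded design
truth_surface <- function(truth, response, coded) {
  beta <- truth$coefficients[[response]]
  M <- quadratic_model_matrix(coded)
  missing_terms <- setdiff(names(beta), colnames(M))
  if (length(missing_terms))
    stop("truth coefficients refer to unknown terms: ",
         paste(missing_terms, collapse = ", "))
  full <- stats::setNames(numeric(ncol(M)), colnames(M))
  full[names(beta)] <- beta
  drop(M %*% full)
}

#' Simulate a method-development study from known truth
#'
#' Draws `y = truth + N(0, sd)` per response on the fitting scale;
#' log10-scale responses are generated on the log scale and then
#' exponentiated, so they are strictly positive and noise is
#' multiplicative on the original scale.  The co-migration rule is
#' applied after simulation.  Deterministic for a fixed seed.
#'
#' @param truth A [truth_model()].
#' @param design An `"aqbd_design"` over the same factors.
#' @param seed RNG seed.
#' @return A [response_table()] aligned to the design runs.
#' @export
simulate_study <- function(truth, design, seed = 1) {
  stopifnot(inherits(truth, "truth_model"),
            inherits(design, "aqbd_design"))
  coded <- design$coded
  out <- data.frame(run_id = design$run_ids)
  with_seed(seed, {
    for (nm in names(truth$coefficients)) {
      mu <- truth_surface(truth, nm, coded)
      yy <- mu + stats::rnorm(nrow(coded), 0, truth$sd[[nm]])
      out[[nm]] <- if (identical(truth$transform[[nm]], "log10"))
        10^yy else yy
    }
  })
  cm <- truth$comigration
  if (!is.null(cm)) {
    hide <- abs(out[[cm$resolution]]) < truth$comigration_tol
    out[[cm$efficiency]][hide] <- NA_real_
  }
  response_table(out)
}

#' Realistic truth calibrated to the embedded CCD study
#'
#' Fits and refines the five response-surface models on the embedded
#' trimecaine CCD study and packages the refined coefficients and
#' residual standard deviations as a [truth_model()].  Studies simulated
#' from it carry the statistical structure the analysis assumes --
#' quadratic surfaces, a signed resolution that changes sign across the
#' domain, co-migration-induced missing plate counts, and a log-scale
#' efficiency -- and re-analysing them end to end should recover a
#' working point inside the design space.
#'
#' @param alpha Significance level used by the refinement.
#' @return A [truth_model()] over the five response-surface factors.
#' @export
trimecaine_truth_models <- function(alpha = 0.05) {
  models <- trimecaine_rsm_models(alpha = alpha)
  truth_model(
    coefficients = lapply(models, `[[`, "coefficients"),
    sd = vapply(models, `[[`, 0, "residual_sd"),
    transform = vapply(models, `[[`, "", "transform"),
    comigration = list(resolution = "R3", efficiency = "N_I2"),
    comigration_tol = 0.05)
}

#' Fitted and refined response-surface models of the embedded study
#'
#' Convenience wrapper running [fit_rsm()] (log10 for the plate count)
#' and [refine_backward()] on all five responses of the embedded CCD
#' study.
#'
#' @param alpha Significance level for the refinement.
#' @param refine Refine by backward elimination (default) or return the
#'   full 21-term fits.
#' @return Named list of `"rsm_model"`s (`R2`, `R3`, `R5`, `N_I2`, `t`).
#' @export
trimecaine_rsm_models <- function(alpha = 0.05, refine = TRUE) {
  study <- trimecaine_ccd_study()
  out <- lapply(stats::setNames(nm = c("R2", "R3", "R5", "N_I2", "t")),
                function(nm) {
    m <- fit_rsm(study$design, study$responses[[nm]],
                 transform = if (nm == "N_I2") "log10" else "none")
    if (refine) refine_backward(m, alpha = alpha) else m
  })
  out
}
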