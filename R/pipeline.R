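#' Configuration of a method-development analysis
#'
#' Collects everything the end-to-end pipeline needs: factor
#' declarations, attribute specifications, the working point, fixed
#' settings excluded from the response-surface domain, Monte Carlo
#' settings and the seed.  Defaults reproduce the embedded trimecaine
#' study.
#'
#' @param factors List of continuous [factor_spec()]s (response-surface
#'   domain).
#' @param specs Named list of [cma_spec()]s.
#' @param working_point Physical working point (named vector over the
#'   factors).
#' @param fixed_settings Named physical constants carried but never
#'   modelled.
#' @param transforms Named character vector of response transforms.
#' @param mc A [modr_config()].
#' @param map_grid_n Nodes per axis of the probability-map panels.
#' @param map_n_sims Draws per probability-map node (maps are usually run
#'   at a lighter setting than the single-point checks).
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(factors = trimecaine_factors("rsm"),
                         specs = trimecaine_specs(),
                         working_point = trimecaine_working_point(coded = FALSE),
                         fixed_settings = trimecaine_fixed_settings(),
                         transforms = c(N_I2 = "log10"),
                         mc = modr_config(),
                         map_grid_n = 15, map_n_sims = 2000,
                         seed = 20230613) {
  nms <- factor_names(factors)
  if (!all(names(working_point) %in% nms))
    stop("working point names must match declared factors")
  if (any(names(fixed_settings) %in% nms))
    stop("fixed settings must not appear among the modelled factors")
  structure(list(factors = factors, specs = specs,
                 working_point = working_point,
                 fixed_settings = fixed_settings,
                 transforms = transforms, mc = mc,
                 map_grid_n = map_grid_n, map_n_sims = map_n_sims,
                 seed = seed),
            class = "study_config")
}

#' Run the full method-development analysis
#'
#' Orchestrates the workflow on a screening study and/or a
#' response-surface study: Free-Wilson screening models, quadratic model
#' fits with backward Q-squared refinement, working-point pass
#' probability, probability maps, MODR box extraction with vertex
#' verification, and (optionally) robustness suitability ranges.  Every
#' stage is wrapped so that a failure is reported with its stage name and
#' the downstream stages are skipped.  The machine-readable summary and
#' all written tables are byte-reproducible for a fixed config.
#'
#' @param config A [study_config()].
#' @param ccd_study List with `design` and `responses` (default: the
#'   embedded trimecaine CCD study).
#' @param screening_study Optional list with `design` and `responses`.
#' @param robustness Optional list with `design` (Plackett-Burman) and
#'   `responses`.
#' @param outdir Optional directory; when given, per-stage CSV tables and
#'   a plain-text summary are written there.
#' @return A list bundle with one element per completed stage plus
#'   `summary` (character vector) and `errors` (named list of per-stage
#'   failures).
#' @export
run_pipeline <- function(config = study_config(),
                         ccd_study = trimecaine_ccd_study(),
                         screening_study = NULL,
                         robustness = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  bundle <- list(config = config, errors = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      bundle$errors[[name]] <<- conditionMessage(e)
      message(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
    res
  }

  if (!is.null(screening_study)) {
    bundle$screening <- stage("screening", {
      resp <- setdiff(names(screening_study$responses), "run_id")
      fits <- lapply(stats::setNames(nm = resp), function(nm)
        fit_free_wilson(screening_study$design,
                        screening_study$responses[[nm]]))
      list(models = fits,
           effects = lapply(fits, level_effects),
           contrasts = lapply(fits, level_change_significance))
    })
  }

  bundle$rsm <- stage("rsm", {
    resp <- setdiff(names(ccd_study$responses), "run_id")
    lapply(stats::setNames(nm = resp), function(nm) {
      tr <- if (nm %in% names(config$transforms))
        config$transforms[[nm]] else "none"
      refine_backward(fit_rsm(ccd_study$design,
                              ccd_study$responses[[nm]], transform = tr))
    })
  })

  if (!is.null(bundle$rsm)) {
    models <- bundle$rsm[names(config$specs)]
    wp_coded <- mapply(function(v, f) code_values(v, f),
                       config$working_point[factor_names(config$factors)],
                       config$factors)
    names(wp_coded) <- factor_names(config$factors)

    bundle$working_point <- stage("working_point", {
      p <- joint_pass_probability(models, config$specs, wp_coded,
                                  n_sims = config$mc$n_sims,
                                  seed = config$mc$seed)
      list(coded = wp_coded, physical = config$working_point,
           pass_probability = p, dpmo = 1e6 * (1 - p / 100))
    })

    bundle$map <- stage("probability_map", {
      nms <- factor_names(config$factors)
      panel_nms <- intersect(c("V", "Buffer_conc"), nms)
      grid_nms <- intersect(c("CyD_conc", "pH"), nms)
      if (length(panel_nms) == 2 && length(grid_nms) == 2) {
        panels <- expand.grid(V = c(20, 25, 30),
                              Buffer_conc = c(20, 25, 30))
        fixed <- list(BuOH_conc = 1.00)
        g <- panel_grid(config$factors, x = grid_nms[1], y = grid_nms[2],
                        panels = panels, fixed = fixed,
                        n = config$map_grid_n)
        probability_map(models, config$specs, g,
                        modr_config(n_sims = config$map_n_sims,
                                    dpmo_target = config$mc$dpmo_target,
                                    seed = config$seed))
      } else NULL
    })

    bundle$modr <- stage("modr_box", {
      box <- extract_modr_box(models, config$specs, wp_coded,
                              config = config$mc)
      list(box = box, edges = verify_edges(models, config$specs, box))
    })
  }

  if (!is.null(robustness)) {
    bundle$robustness <- stage("robustness", {
      resp <- setdiff(names(robustness$responses), "run_id")
      fits <- lapply(stats::setNames(nm = resp), function(nm)
        fit_pb_linear(robustness$design, robustness$responses[[nm]]))
      preds <- if (!is.null(bundle$rsm) && !is.null(robustness$conditions)) {
        ## model predictions over the robustness conditions, for widening
        lapply(stats::setNames(nm = intersect(resp, names(bundle$rsm))),
               function(nm)
                 predict(bundle$rsm[[nm]], robustness$conditions)$mean)
      } else NULL
      list(fits = fits, summary = robustness_summary(fits),
           ranges = suitability_ranges(robustness$responses, preds))
    })
  }

  bundle$summary <- pipeline_summary(bundle)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  class(bundle) <- "aqbd_pipeline"
  bundle
}

pipeline_summary <- function(bundle) {
  out <- c("aqbd pipeline summary",
           sprintf("seed: %d", bundle$config$seed))
  if (!is.null(bundle$rsm)) {
    for (nm in names(bundle$rsm)) {
      m <- bundle$rsm[[nm]]
      out <- c(out, sprintf(
        "model %s: transform=%s terms=%d n=%d R2=%.4f Q2=%.4f",
        nm, m$transform, nrow(m$terms), m$n_used,
        m$quality["R2"], m$quality["Q2"]))
    }
  }
  if (!is.null(bundle$working_point))
    out <- c(out, sprintf("working point pass probability: %.3f%%",
                          bundle$working_point$pass_probability),
             sprintf("working point DPMO: %.0f",
                     bundle$working_point$dpmo))
  if (!is.null(bundle$modr)) {
    iv <- bundle$modr$box$intervals
    out <- c(out, vapply(seq_len(nrow(iv)), function(i)
      sprintf("MODR %s: %s-%s %s", iv$factor[i], format(iv$low[i]),
              format(iv$high[i]), iv$units[i]), ""))
  }
  if (!is.null(bundle$robustness)) {
    rg <- bundle$robustness$ranges
    out <- c(out, vapply(seq_len(nrow(rg)), function(i)
      sprintf("suitability %s: %s-%s%s", rg$response[i],
              format(rg$low[i]), format(rg$high[i]),
              if (rg$widened[i]) " (widened)" else ""), ""))
  }
  if (length(bundle$errors))
    out <- c(out, sprintf("FAILED stage %s: %s", names(bundle$errors),
                          unlist(bundle$errors)))
  out
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeLines(bundle$summary, file.path(outdir, "summary.txt"))
  if (!is.null(bundle$rsm)) {
    for (nm in names(bundle$rsm))
      utils::write.csv(coef_table(bundle$rsm[[nm]]),
                       file.path(outdir, paste0("rsm_", nm, "_coef.csv")),
                       row.names = FALSE)
  }
  if (!is.null(bundle$modr)) {
    utils::write.csv(bundle$modr$box$intervals,
                     file.path(outdir, "modr_box.csv"), row.names = FALSE)
    utils::write.csv(bundle$modr$edges,
                     file.path(outdir, "modr_edges.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$robustness))
    utils::write.csv(bundle$robustness$ranges,
                     file.path(outdir, "suitability_ranges.csv"),
                     row.names = FALSE)
  invisible(outdir)
}

#' @export
print.aqbd_pipeline <- function(x, ...) {
  writeLines(x$summary)
  invisible(x)
}
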