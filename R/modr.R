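#' Critical method attribute specification
#'
#' A one-sided acceptance threshold on a measured response, e.g.
#' resolution at least 1.5 or analysis time at most 10 min.  Thresholds
#' are stated on the original response scale by default; for a
#' log10-modelled response the comparison is applied after per-draw
#' back-transformation, so "N_I2 >= 10,000" constrains simulated plate
#' counts, not their mean.
#'
#' @param response Response name.
#' @param direction `"ge"` (at least) or `"le"` (at most).
#' @param threshold Numeric threshold, finite.
#' @param scale `"original"` (default) or `"fitting"` if the threshold is
#'   already expressed on the model's fitting scale.
#' @return An object of class `"cma_spec"`.
#' @export
cma_spec <- function(response, direction = c("ge", "le"), threshold,
                     scale = c("original", "fitting")) {
  direction <- match.arg(direction)
  scale <- match.arg(scale)
  stopifnot(is.finite(threshold))
  structure(list(response = response, direction = direction,
                 threshold = threshold, scale = scale),
            class = "cma_spec")
}

#' @export
print.cma_spec <- function(x, ...) {
  cat(sprintf("%s %s %s (%s scale)\n", x$response,
              if (x$direction == "ge") ">=" else "<=",
              format(x$threshold), x$scale))
  invisible(x)
}

spec_satisfied <- function(spec, values) {
  if (spec$direction == "ge") values >= spec$threshold
  else values <= spec$threshold
}

## threshold of `spec` expressed on the fitting scale of `model`
fitting_threshold <- function(spec, model) {
  if (spec$scale == "fitting" || model$transform == "none")
    return(spec$threshold)
  if (spec$threshold <= 0)
    stop("cannot place a non-positive threshold on a log10 scale")
  log10(spec$threshold)
}

## Evaluate the RNG action `expr` under a fixed seed without disturbing
## the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## Monte Carlo draws of a model's fitting-scale prediction at one coded
## point.  Under the least-squares sampling model the prediction
## x'beta + eps with beta ~ MVN(b, V) and eps ~ N(0, s^2) is exactly
## N(x'b, x'Vx) + N(0, s^2); draws are taken from that law (two normal
## streams), which is distributionally identical to sampling full
## coefficient vectors and much cheaper.
draw_predictions <- function(model, point, n_sims) {
  if (is.null(model$covariance)) stop("model lacks a coefficient covariance")
  M <- eval_terms(model$terms,
                  matrix(point, nrow = 1,
                         dimnames = list(NULL,
                                         colnames(model$design$coded))))
  mu <- drop(M %*% model$coefficients)
  sd_coef <- sqrt(max(drop(M %*% model$covariance %*% t(M)), 0))
  stats::rnorm(n_sims, mu, sd_coef) +
    stats::rnorm(n_sims, 0, model$residual_sd)
}

#' Joint probability of meeting every specification at a point
#'
#' Propagates model uncertainty by Monte Carlo: per draw, each model's
#' prediction is sampled from its coefficient distribution plus residual
#' noise on the fitting scale, back-transformed where the model is
#' log10-scaled, and checked against all specifications simultaneously.
#' The responses are fitted independently, so draws are independent
#' across models.
#'
#' @param models Named list of `"rsm_model"`s.
#' @param specs Named list of [cma_spec()]s; every name must appear in
#'   `models`.
#' @param point Coded coordinates (named or design-factor order).
#' @param n_sims Number of Monte Carlo draws.
#' @param seed RNG seed; the result is reproducible for a fixed seed.
#' @return Percentage (0-100) of draws meeting all specifications.
#' @export
joint_pass_probability <- function(models, specs, point, n_sims = 20000,
                                   seed = 20230613) {
  stopifnot(all(names(specs) %in% names(models)), n_sims >= 1)
  point <- order_point(models[[1]], point)
  with_seed(seed, {
    pass <- rep(TRUE, n_sims)
    for (nm in names(specs)) {
      dr <- draw_predictions(models[[nm]], point, n_sims)
      thr <- fitting_threshold(specs[[nm]], models[[nm]])
      ok <- if (specs[[nm]]$direction == "ge") dr >= thr else dr <= thr
      pass <- pass & ok
    }
    100 * mean(pass)
  })
}

order_point <- function(model, point) {
  nms <- colnames(model$design$coded)
  if (!is.null(names(point))) {
    if (!all(nms %in% names(point)))
      stop("point is missing coordinates: ",
           paste(setdiff(nms, names(point)), collapse = ", "))
    point <- point[nms]
  }
  stopifnot(length(point) == length(nms))
  as.numeric(point)
}

#' Monte Carlo settings for design-space mapping
#'
#' @param n_sims Draws per grid node (at least 1,000; default 20,000
#'   gives a binomial standard error of about 0.2 percentage points near
#'   10\% risk).
#' @param dpmo_target Defects-per-million target defining the MODR;
#'   100,000 corresponds to a 10\% risk of failure.
#' @param seed Base RNG seed; node `i` of a map uses `seed + i`.
#' @return An object of class `"modr_config"`.
#' @export
modr_config <- function(n_sims = 20000, dpmo_target = 1e5,
                        seed = 20230613) {
  stopifnot(n_sims >= 1000, dpmo_target > 0, dpmo_target < 1e6)
  structure(list(n_sims = n_sims, dpmo_target = dpmo_target, seed = seed),
            class = "modr_config")
}

#' Two-factor slice grid through the factor domain
#'
#' Describes the trellis used by sweet-spot and probability maps: a grid
#' over two factors, a set of panels fixing one or more further factors
#' at given physical values, and constant physical settings for the rest.
#'
#' @param factors List of [factor_spec()]s (the model factors).
#' @param x,y Names of the grid factors.
#' @param panels Data frame of physical values, one row per panel, one
#'   column per panel factor (e.g. `expand.grid(V = c(20,25,30),
#'   Buffer_conc = c(20,25,30))`).
#' @param fixed Named physical values for the remaining factors.
#' @param n Nodes per grid axis (`n x n` per panel).
#' @param domain Optional named list overriding per-factor physical grid
#'   ranges; defaults to each factor's declared domain.
#' @return Object of class `"panel_grid"` with coded node matrices per
#'   panel.
#' @export
panel_grid <- function(factors, x, y, panels = NULL, fixed = NULL,
                       n = 61, domain = NULL) {
  nms <- factor_names(factors)
  names(factors) <- nms
  stopifnot(x %in% nms, y %in% nms)
  rng <- function(f) {
    d <- domain[[f$name]] %||% f$domain
    if (is.null(d)) stop("no domain declared for factor ", f$name)
    d
  }
  x_phys <- seq(rng(factors[[x]])[1], rng(factors[[x]])[2], length.out = n)
  y_phys <- seq(rng(factors[[y]])[1], rng(factors[[y]])[2], length.out = n)
  if (is.null(panels)) panels <- data.frame(row.names = 1)
  panel_factors <- names(panels)
  other <- setdiff(nms, c(x, y, panel_factors, names(fixed)))
  if (length(other))
    stop("factors neither gridded, panelled nor fixed: ",
         paste(other, collapse = ", "))
  nodes <- expand.grid(xv = x_phys, yv = y_phys)
  plist <- lapply(seq_len(max(nrow(panels), 1L)), function(ip) {
    point <- stats::setNames(numeric(length(nms)), nms)
    point[x] <- 0; point[y] <- 0
    coded <- matrix(0, nrow(nodes), length(nms),
                    dimnames = list(NULL, nms))
    coded[, x] <- code_values(nodes$xv, factors[[x]])
    coded[, y] <- code_values(nodes$yv, factors[[y]])
    for (f in panel_factors)
      coded[, f] <- code_values(panels[ip, f], factors[[f]])
    for (f in names(fixed))
      coded[, f] <- code_values(fixed[[f]], factors[[f]])
    list(coded = coded, values = panels[ip, , drop = FALSE])
  })
  labels <- if (ncol(panels)) {
    vapply(seq_len(nrow(panels)), function(ip)
      paste(sprintf("%s=%s", names(panels), format(unlist(panels[ip, ]))),
            collapse = ", "), "")
  } else "slice"
  structure(list(x = x, y = y, x_values = x_phys, y_values = y_phys,
                 panels = plist, panel_labels = labels,
                 factors = factors, fixed = fixed),
            class = "panel_grid")
}

#' Gridded risk-of-failure (probability) map
#'
#' Runs [joint_pass_probability()] at every node of a [panel_grid()],
#' converting the pass probability to a percentage risk of failure and a
#' defects-per-million count.  Nodes with DPMO at or below the target
#' (risk at or below 10\% for the default 100,000) are flagged as inside
#' the MODR.  Node `i` uses seed `config$seed + i`, so the whole map is
#' reproducible and each node's value equals a direct
#' [joint_pass_probability()] call with that seed.
#'
#' @param models Named list of `"rsm_model"`s.
#' @param specs Named list of [cma_spec()]s.
#' @param grid A [panel_grid()].
#' @param config A [modr_config()].
#' @return Object of class `"probability_map"` with per-panel matrices
#'   `risk`, `dpmo` and logical `in_modr`.
#' @export
probability_map <- function(models, specs, grid, config = modr_config()) {
  node_counter <- 0L
  risk <- lapply(grid$panels, function(panel) {
    m <- matrix(NA_real_, length(grid$x_values), length(grid$y_values))
    for (i in seq_len(nrow(panel$coded))) {
      node_counter <<- node_counter + 1L
      p <- joint_pass_probability(models, specs, panel$coded[i, ],
                                  n_sims = config$n_sims,
                                  seed = config$seed + node_counter)
      m[i] <- 100 - p
    }
    m
  })
  dpmo <- lapply(risk, function(m) m * 1e4)
  in_modr <- lapply(dpmo, function(m) m <= config$dpmo_target)
  structure(list(grid = grid, risk = risk, dpmo = dpmo,
                 in_modr = in_modr, config = config),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("probability map: %d panels of %d x %d nodes, %d draws/node\n",
              length(x$risk), length(x$grid$x_values),
              length(x$grid$y_values), x$config$n_sims))
  for (i in seq_along(x$risk))
    cat(sprintf("  %-28s in-MODR nodes: %d\n", x$grid$panel_labels[i],
                sum(x$in_modr[[i]])))
  invisible(x)
}

#' Plot a probability map with the 10\% isoprobability contour
#'
#' @param x A `"probability_map"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.probability_map <- function(x, ...) {
  np <- length(x$risk)
  nrow_p <- floor(sqrt(np)); ncol_p <- ceiling(np / nrow_p)
  op <- graphics::par(mfrow = c(nrow_p, ncol_p), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  risk_target <- x$config$dpmo_target / 1e4
  for (i in seq_along(x$risk)) {
    graphics::image(x$grid$x_values, x$grid$y_values, x$risk[[i]],
                    zlim = c(0, 100),
                    col = grDevices::hcl.colors(24, "RdYlGn", rev = TRUE),
                    xlab = x$grid$x, ylab = x$grid$y,
                    main = x$grid$panel_labels[i], ...)
    graphics::contour(x$grid$x_values, x$grid$y_values, x$risk[[i]],
                      levels = risk_target, add = TRUE, lwd = 2)
  }
  invisible(x)
}

#' Extract an axis-aligned MODR box around a working point
#'
#' Expands each factor's interval around the working point by bisection
#' until the joint pass probability at the axis extreme (all other
#' factors held at the working point) drops below the target, then
#' validates the full box at its 2^k vertices and shrinks it
#' proportionally towards the working point until every vertex passes.
#' The true design space is generally non-convex; the probability map is
#' the primary artifact and the box a convenient per-factor summary.
#'
#' @param models Named list of `"rsm_model"`s.
#' @param specs Named list of [cma_spec()]s.
#' @param working_point Coded coordinates of the routine operating point.
#' @param config A [modr_config()].
#' @param tol Bisection tolerance in coded units.
#' @return Object of class `"modr_box"`: per-factor physical intervals
#'   (rounded per factor) of the vertex-validated box, the wider
#'   axis-wise intervals before vertex shrinking (`axis_intervals`), the
#'   working point, and the minimum vertex pass probability.
#' @export
extract_modr_box <- function(models, specs, working_point,
                             config = modr_config(), tol = 0.02) {
  wp <- order_point(models[[1]], working_point)
  factors <- models[[1]]$design$factors
  nms <- factor_names(factors)
  p_target <- 100 - config$dpmo_target / 1e4
  pp <- function(pt, seed_off) joint_pass_probability(
    models, specs, pt, n_sims = config$n_sims,
    seed = config$seed + seed_off)
  if (pp(wp, 0L) < p_target)
    stop("working point outside MODR: pass probability below target")
  k <- length(wp)
  lo <- hi <- wp
  seed_off <- 0L
  for (j in seq_len(k)) {
    dom <- coded_domain(factors[[j]])
    for (side in c("lo", "hi")) {
      inner <- wp[j]
      outer <- if (side == "lo") dom[1] else dom[2]
      probe <- function(v) {
        pt <- wp; pt[j] <- v
        seed_off <<- seed_off + 1L
        pp(pt, seed_off)
      }
      if (probe(outer) >= p_target) {
        inner <- outer
      } else {
        while (abs(outer - inner) > tol) {
          mid <- (inner + outer) / 2
          if (probe(mid) >= p_target) inner <- mid else outer <- mid
        }
      }
      if (side == "lo") lo[j] <- inner else hi[j] <- inner
    }
  }
  ## vertex validation: shrink the half-widths proportionally until all
  ## 2^k vertices pass
  vertices <- function(lo, hi) {
    V <- as.matrix(expand.grid(lapply(seq_len(k),
                                      function(j) c(lo[j], hi[j]))))
    colnames(V) <- nms
    V
  }
  scale <- 1
  repeat {
    lo_s <- wp + scale * (lo - wp)
    hi_s <- wp + scale * (hi - wp)
    V <- vertices(lo_s, hi_s)
    pv <- vapply(seq_len(nrow(V)), function(i) {
      seed_off <<- seed_off + 1L
      pp(V[i, ], seed_off)
    }, numeric(1))
    if (all(pv >= p_target) || scale < 0.05) break
    scale <- scale - 0.05
  }
  interval <- data.frame(
    factor = nms,
    low = vapply(seq_len(k), function(j)
      decode_values(lo_s[j], factors[[j]]), 0),
    high = vapply(seq_len(k), function(j)
      decode_values(hi_s[j], factors[[j]]), 0),
    units = vapply(factors, `[[`, "", "units"))
  axis_interval <- data.frame(
    factor = nms,
    low = vapply(seq_len(k), function(j)
      decode_values(lo[j], factors[[j]]), 0),
    high = vapply(seq_len(k), function(j)
      decode_values(hi[j], factors[[j]]), 0))
  structure(list(intervals = interval, axis_intervals = axis_interval,
                 coded_low = lo_s,
                 coded_high = hi_s, working_point = wp,
                 min_vertex_pass = min(pv), scale = scale,
                 config = config, factors = factors),
            class = "modr_box")
}

#' @export
print.modr_box <- function(x, ...) {
  cat("MODR box (axis-aligned, vertex-validated):\n")
  for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  %-12s %s - %s %s\n", x$intervals$factor[i],
                format(x$intervals$low[i]), format(x$intervals$high[i]),
                x$intervals$units[i]))
  cat(sprintf("  minimum vertex pass probability: %.1f%%\n",
              x$min_vertex_pass))
  invisible(x)
}

#' Mean predictions and pass flags at the MODR box vertices
#'
#' Companion table for wet-lab verification experiments at the edges of
#' the region: every vertex of the box with each model's mean prediction
#' and its specification flag.
#'
#' @param models Named list of `"rsm_model"`s.
#' @param specs Named list of [cma_spec()]s.
#' @param box A `"modr_box"`.
#' @return Data frame: vertex coordinates (physical), one prediction and
#'   one pass flag column per response, and an `all_pass` column.
#' @export
verify_edges <- function(models, specs, box) {
  stopifnot(inherits(box, "modr_box"))
  k <- length(box$coded_low)
  nms <- factor_names(box$factors)
  V <- as.matrix(expand.grid(lapply(seq_len(k), function(j)
    unique(c(box$coded_low[j], box$coded_high[j])))))
  colnames(V) <- nms
  out <- as.data.frame(lapply(seq_len(k), function(j)
    decode_values(V[, j], box$factors[[j]])))
  names(out) <- nms
  all_ok <- rep(TRUE, nrow(V))
  for (nm in names(specs)) {
    mu <- predict(models[[nm]], V)$mean
    ok <- spec_satisfied(specs[[nm]], mu)
    out[[paste0("pred_", nm)]] <- mu
    out[[paste0("pass_", nm)]] <- ok
    all_ok <- all_ok & ok
  }
  out$all_pass <- all_ok
  out
}
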