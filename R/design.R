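#' Experimental design container
#'
#' Bundles a matrix of coded run settings with the factor declarations
#' that give them physical meaning.  Coded levels follow the usual DoE
#' conventions: two-level designs use -1/+1, central composite designs use
#' \{-alpha, -1, 0, +1, +alpha\}, and three-level screening arrays store
#' level indices 1/2/3.
#'
#' @param coded Numeric matrix, one row per run, one column per factor.
#' @param factors List of [factor_spec()] objects, one per column.
#' @param kind One of `"screening"`, `"ccd"`, `"plackett_burman"`,
#'   `"custom"`.
#' @param run_ids Integer run identifiers as printed in the source table;
#'   defaults to `1:nrow(coded)`.
#' @return An object of class `"aqbd_design"`.
#' @export
design_matrix <- function(coded, factors,
                          kind = c("custom", "screening", "ccd",
                                   "plackett_burman"),
                          run_ids = NULL) {
  kind <- match.arg(kind)
  coded <- as.matrix(coded)
  if (length(factors) != ncol(coded))
    stop("number of factors must match number of design columns")
  colnames(coded) <- factor_names(factors)
  if (is.null(run_ids)) run_ids <- seq_len(nrow(coded))
  if (length(run_ids) != nrow(coded)) stop("one run_id per run required")
  if (kind == "plackett_burman" && !all(coded %in% c(-1, 1)))
    stop("Plackett-Burman levels must be -1/+1")
  out <- list(coded = coded, factors = factors, kind = kind,
              run_ids = as.integer(run_ids))
  class(out) <- "aqbd_design"
  out
}

#' @export
print.aqbd_design <- function(x, ...) {
  cat(sprintf("%s design: %d runs x %d factors (%s)\n", x$kind,
              nrow(x$coded), ncol(x$coded),
              paste(colnames(x$coded), collapse = ", ")))
  invisible(x)
}

#' Axial distance making a central composite design orthogonal
#'
#' For a CCD with `F` factorial runs, `n_axial` axial runs and `n_center`
#' centre runs (total `N`), the axial distance
#' \deqn{\alpha = \sqrt{(\sqrt{N F} - F)/2}}
#' makes the centred quadratic columns of the moment matrix mutually
#' orthogonal (and orthogonal to the intercept), so quadratic coefficient
#' estimates are uncorrelated with the intercept.
#'
#' @param n_factorial Number of factorial (cube) runs.
#' @param n_axial Number of axial (star) runs; must be even.
#' @param n_center Number of centre runs.
#' @return The orthogonal axial distance (coded units).
#' @examples
#' orthogonal_alpha(16, 10, 3)  # 1.66 to two decimals
#' orthogonal_alpha(4, 4, 1)    # exactly 1
#' @export
orthogonal_alpha <- function(n_factorial, n_axial, n_center) {
  stopifnot(n_factorial >= 1, n_axial >= 1, n_center >= 1)
  if (n_axial %% 2 != 0) stop("'n_axial' must be even (a low/high pair per factor)")
  F <- n_factorial
  N <- n_factorial + n_axial + n_center
  a2 <- (sqrt(N * F) - F) / 2
  if (a2 <= 0) stop("no real orthogonal axial distance: sqrt(N*F) <= F")
  sqrt(a2)
}

#' Generate a central composite design
#'
#' Runs are laid out factorial block first (standard order), then one
#' low/high axial pair per factor, then the centre runs.  For the
#' half-fraction the last factor is aliased with the product of all the
#' others (defining relation `I = ABCDE` for five factors), which has
#' resolution V and therefore supports a full quadratic model only for
#' five or more factors.
#'
#' @param factors List of continuous [factor_spec()] objects.
#' @param fraction `"full"` or `"half"` factorial cube.
#' @param n_center Number of centre runs.
#' @param alpha `"orthogonal"` (computed with [orthogonal_alpha()]),
#'   `"rotatable"` (`F^(1/4)`), or a positive number.
#' @return An `"aqbd_design"` of kind `"ccd"` with attribute `"alpha"`.
#' @examples
#' facs <- trimecaine_factors("rsm")
#' d <- ccd_design(facs, fraction = "half", n_center = 3)
#' attr(d, "alpha")  # 1.66...
#' @export
ccd_design <- function(factors, fraction = c("full", "half"), n_center = 3,
                       alpha = "orthogonal") {
  fraction <- match.arg(fraction)
  k <- length(factors)
  stopifnot(k >= 2)
  if (fraction == "half" && k < 5)
    stop("half-fraction resolution below V for fewer than 5 factors; ",
         "a full quadratic model would be aliased")
  if (fraction == "half") {
    cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k - 1)))
    cube <- cbind(cube, apply(cube, 1, prod))
  } else {
    cube <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  }
  dimnames(cube) <- NULL
  n_fac <- nrow(cube)
  n_axial <- 2L * k
  if (identical(alpha, "orthogonal")) {
    a <- orthogonal_alpha(n_fac, n_axial, n_center)
  } else if (identical(alpha, "rotatable")) {
    a <- n_fac^0.25
  } else {
    a <- as.numeric(alpha)
    if (!is.finite(a) || a <= 0) stop("'alpha' must be positive")
  }
  star <- matrix(0, n_axial, k)
  for (i in seq_len(k)) {
    star[2 * i - 1, i] <- -a
    star[2 * i, i] <- a
  }
  coded <- rbind(cube, star, matrix(0, n_center, k))
  d <- design_matrix(coded, factors, kind = "ccd")
  attr(d, "alpha") <- a
  attr(d, "blocks") <- rep(c("factorial", "axial", "center"),
                           c(n_fac, n_axial, n_center))
  d
}

## Plackett-Burman cyclic generator rows (standard first rows).
pb_generators <- list(
  `8`  = c(1, 1, 1, -1, 1, -1, -1),
  `12` = c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1),
  `16` = c(1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1),
  `20` = c(1, 1, -1, -1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1),
  `24` = c(1, 1, 1, 1, 1, -1, 1, -1, 1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
           1, -1, -1, -1, -1))

#' Generate a Plackett-Burman design
#'
#' Two-level saturated orthogonal design built from the standard cyclic
#' first rows, with a final all-minus run.  Every column is balanced and
#' every pair of columns is orthogonal (`X'X = n I`).
#'
#' @param n_runs One of 8, 12, 16, 20, 24.
#' @param factors Optional list of [factor_spec()]s for the first columns;
#'   remaining columns are named `dummy1`, `dummy2`, ... and serve as an
#'   error estimate.
#' @return An `"aqbd_design"` of kind `"plackett_burman"`.
#' @export
pb_design <- function(n_runs, factors = NULL) {
  key <- as.character(n_runs)
  if (!key %in% names(pb_generators))
    stop("unsupported Plackett-Burman size; choose one of 8, 12, 16, 20, 24")
  g <- pb_generators[[key]]
  p <- length(g)                      # n_runs - 1 columns
  M <- matrix(0, n_runs, p)
  row <- g
  for (i in seq_len(n_runs - 1)) {
    M[i, ] <- row
    row <- c(row[p], row[-p])         # cyclic right shift
  }
  M[n_runs, ] <- -1
  if (is.null(factors)) {
    factors <- lapply(seq_len(p), function(i)
      factor_spec(paste0("X", i), center = 0, step = 1, rounding = 6))
  } else {
    if (length(factors) > p)
      stop(sprintf("at most %d factors fit in a %d-run Plackett-Burman design",
                   p, n_runs))
    nd <- p - length(factors)
    if (nd > 0)
      factors <- c(factors, lapply(seq_len(nd), function(i)
        factor_spec(paste0("dummy", i), center = 0, step = 1, rounding = 6)))
  }
  d <- design_matrix(M, factors, kind = "plackett_burman")
  attr(d, "n_assigned") <- sum(!grepl("^dummy", factor_names(factors)))
  d
}

#' Smallest supported Plackett-Burman size for k factors
#'
#' Chooses the smallest supported run count with at least `k + 5` columns,
#' leaving four or more dummy columns for error estimation.
#'
#' @param k Number of real factors.
#' @return A supported run count.
#' @export
pb_default_runs <- function(k) {
  sizes <- as.integer(names(pb_generators))
  ok <- sizes[sizes - 1L >= k + 4L]
  if (!length(ok)) stop("too many factors for the supported Plackett-Burman sizes")
  min(ok)
}

#' The 3^7//16 symmetric screening array
#'
#' The 16-run orthogonal array in which seven three-level factors are each
#' exercised four times at the low level, eight times at the middle level
#' and four times at the high level.  This array is shipped as a fixture
#' (it is the screening plan of the trimecaine study); a generic
#' three-level array supplied by the user can be wrapped with
#' [design_matrix()] instead.
#'
#' @return An `"aqbd_design"` of kind `"screening"` whose coded entries
#'   are level indices 1/2/3, bound to the trimecaine screening factors.
#' @seealso [trimecaine_screening_study()] for the array together with its
#'   measured responses.
#' @export
screening_matrix_3_7_16 <- function() {
  study <- trimecaine_screening_study()
  study$design
}

#' Decode a design to physical settings
#'
#' @param design An `"aqbd_design"`.
#' @param round Apply per-factor rounding (default `TRUE`).
#' @return A data frame of physical settings with a `run_id` column.
#' @export
physical_design <- function(design, round = TRUE) {
  stopifnot(inherits(design, "aqbd_design"))
  out <- as.data.frame(design$coded)
  for (j in seq_along(design$factors)) {
    f <- design$factors[[j]]
    out[[j]] <- if (f$kind == "continuous") {
      decode_values(design$coded[, j], f, round = round)
    } else {
      f$levels[design$coded[, j]]
    }
  }
  cbind(run_id = design$run_ids, out)
}

## Moment-matrix cross-products of the centred quadratic columns with the
## intercept and with each other; all must vanish for an orthogonal CCD.
quadratic_cross_moments <- function(design) {
  X <- design$coded
  Q <- X^2
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(cbind(1, Qc))
  k <- ncol(Q)
  idx <- which(upper.tri(M), arr.ind = TRUE)
  M[upper.tri(M)]
}
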