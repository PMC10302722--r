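## Embedded trimecaine CyD-MEKC development study: factor declarations and
## loaders for the printed screening and CCD tables shipped in extdata.

#' Factors of the trimecaine CyD-MEKC development study
#'
#' Factor declarations for the two experimental phases of the embedded
#' study.  The screening phase exercised seven method parameters at three
#' levels each; the response-surface phase varied five of them
#' continuously (SDS concentration and temperature having been fixed at
#' 65.0 mM and 22 degC after screening).  The response-surface coding puts
#' the factorial points at coded -1/+1 and the axial points at the
#' orthogonal axial distance; physical settings are reported at each
#' factor's instrument resolution (`rounding`).
#'
#' @param stage `"rsm"` (five continuous factors) or `"screening"` (seven
#'   three-level factors).
#' @return A list of [factor_spec()] objects.
#' @export
trimecaine_factors <- function(stage = c("rsm", "screening")) {
  stage <- match.arg(stage)
  if (stage == "rsm") {
    list(
      factor_spec("pH",          center = 9.5,  step = 0.3,  units = "",
                  rounding = 2, domain = c(9.00, 10.00)),
      factor_spec("Buffer_conc", center = 25,   step = 3,    units = "mM",
                  rounding = 0, domain = c(20, 30)),
      factor_spec("CyD_conc",    center = 17.5, step = 4.5,  units = "mM",
                  rounding = 1, domain = c(10, 25)),
      factor_spec("V",           center = 25,   step = 3,    units = "kV",
                  rounding = 0, domain = c(20, 30)),
      factor_spec("BuOH_conc",   center = 1.0,  step = 0.48, units = "%v/v",
                  rounding = 2, domain = c(0.20, 1.80)))
  } else {
    list(
      factor_spec("Buffer_conc", levels = c(15, 25, 35),       units = "mM"),
      factor_spec("pH",          levels = c(8.20, 9.20, 10.20)),
      factor_spec("SDS_conc",    levels = c(50.0, 62.5, 75.0), units = "mM"),
      factor_spec("CyD_conc",    levels = c(10, 20, 30),       units = "mM"),
      factor_spec("BuOH_conc",   levels = c(0.00, 1.00, 2.00), units = "%v/v"),
      factor_spec("V",           levels = c(20, 25, 30),       units = "kV"),
      factor_spec("T",           levels = c(19, 22, 25),       units = "degC"))
  }
}

#' Method settings held fixed after screening
#'
#' SDS concentration and capillary temperature were fixed after the
#' screening phase and are carried as constants, never simulated.
#'
#' @return Named numeric vector.
#' @export
trimecaine_fixed_settings <- function() {
  c(SDS_conc = 65.0, T = 22)
}

#' Critical method attribute specifications of the trimecaine study
#'
#' The acceptance thresholds the separation must meet: the three critical
#' resolutions at least 1.5, the impurity-2 plate count at least 10,000
#' and the analysis time at most 10 minutes.
#'
#' @return A list of [cma_spec()] objects named by response.
#' @export
trimecaine_specs <- function() {
  list(R2   = cma_spec("R2",   "ge", 1.5),
       R3   = cma_spec("R3",   "ge", 1.5),
       R5   = cma_spec("R5",   "ge", 1.5),
       N_I2 = cma_spec("N_I2", "ge", 10000),
       t    = cma_spec("t",    "le", 10))
}

#' Routine working point of the trimecaine method
#'
#' @param coded Return coded coordinates (default) or physical settings.
#' @return Named numeric vector over the five response-surface factors.
#' @export
trimecaine_working_point <- function(coded = TRUE) {
  phys <- c(pH = 9.70, Buffer_conc = 23, CyD_conc = 20, V = 25,
            BuOH_conc = 1.00)
  if (!coded) return(phys)
  facs <- trimecaine_factors("rsm")
  out <- mapply(function(x, f) code_values(x, f), phys, facs)
  names(out) <- names(phys)
  out
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "aqbd")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install
  if (!file.exists(p)) stop("fixture not found: ", file)
  p
}

#' Embedded screening study of the trimecaine method
#'
#' The 16-run 3^7//16 symmetric screening array together with the five
#' measured critical method attributes (R2, signed R3, R5, N_I2, t).
#' Values are embedded verbatim from the study table; runs 8 and 16 are a
#' duplicated centre-of-array condition.
#'
#' @return A list with components `design` (an `"aqbd_design"` holding
#'   level indices 1/2/3) and `responses` (a [response_table()]).
#' @export
trimecaine_screening_study <- function() {
  tab <- read_table(fixture_path("trimecaine_screening.csv"))
  factors <- trimecaine_factors("screening")
  lv <- matrix(NA_real_, nrow(tab), length(factors))
  cols <- c("Buffer_conc", "pH", "SDS_conc", "CyD_conc", "BuOH_conc",
            "V", "T")
  for (j in seq_along(factors)) {
    lv[, j] <- match(tab[[cols[j]]], factors[[j]]$levels)
    if (anyNA(lv[, j]))
      stop("screening fixture has a setting outside the declared levels: ",
           cols[j])
  }
  design <- design_matrix(lv, factors, kind = "screening",
                          run_ids = tab$run_id)
  responses <- response_table(tab[c("run_id", "R2", "R3", "R5", "N_I2",
                                    "t")])
  list(design = design, responses = responses)
}

#' Embedded central composite study of the trimecaine method
#'
#' The 29-run orthogonal CCD (16-run half-fraction, 10 axial runs at the
#' orthogonal axial distance, 3 centre runs) with the five measured
#' responses.  R3 is signed: negative values mark runs where the two
#' impurities swapped migration order.  In the three runs where R3 is
#' exactly zero the impurity peaks co-migrated and the plate count N_I2
#' could not be determined (missing).
#'
#' The design component is regenerated from [ccd_design()] and the factor
#' declarations; its decoded settings reproduce the embedded physical
#' table after per-factor rounding, while the coded axial levels stay at
#' the exact orthogonal distance.
#'
#' @return A list with components `design` and `responses`.
#' @export
trimecaine_ccd_study <- function() {
  tab <- read_table(fixture_path("trimecaine_ccd.csv"))
  factors <- trimecaine_factors("rsm")
  design <- ccd_design(factors, fraction = "half", n_center = 3,
                       alpha = "orthogonal")
  design$run_ids <- tab$run_id
  phys <- physical_design(design)
  for (f in factor_names(factors)) {
    if (max(abs(phys[[f]] - tab[[f]])) > 10^(-6))
      stop("embedded CCD table does not match the generated design: ", f)
  }
  responses <- response_table(tab[c("run_id", "R2", "R3", "R5", "N_I2",
                                    "t")])
  list(design = design, responses = responses)
}
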