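## synthetic three-level design + known additive truth, for recovery tests
make_screening_truth <- function(design, effects, intercept = 5) {
  lv <- design$coded
  y <- rep(intercept, nrow(lv))
  for (j in seq_len(ncol(lv)))
    y <- y + effects[[j]][lv[, j]]
  y
}

test_that("Free-Wilson encoding follows the sum-to-zero convention", {
  d <- screening_study$design
  X <- free_wilson_matrix(d)
  expect_identical(dim(X), c(16L, 15L))
  ## run 11 is at level 1 of Buffer_conc, run 9 at level 3
  expect_equal(unname(X[11, c("Buffer_conc_l1", "Buffer_conc_l2")]),
               c(1, 0))
  expect_equal(unname(X[9, c("Buffer_conc_l1", "Buffer_conc_l2")]),
               c(-1, -1))
  ## full column rank by an independent decomposition
  expect_equal(sum(svd(X)$d > 1e-8), 15)
})

test_that("Free-Wilson estimates match the normal-equations oracle", {
  d <- screening_study$design
  y <- screening_study$responses$R5
  fw <- fit_free_wilson(d, y)
  o <- oracle_ls(free_wilson_matrix(d), y)
  expect_equal(fw$intercept, unname(o$b[1]), tolerance = 1e-8)
  for (j in 1:7) {
    expect_equal(unname(fw$level_coefficients[j, 1:2]),
                 unname(o$b[c(2 * j, 2 * j + 1)]), tolerance = 1e-8)
    ## the three level coefficients of every factor sum to zero
    expect_lt(abs(sum(fw$level_coefficients[j, ])), 1e-9)
  }
})

test_that("screening models of the embedded study behave as printed", {
  d <- screening_study$design
  ## R2, R3, N_I2 and t models are significant by ANOVA; the residual
  ## error and the duplicate-based pure error coincide here (1 df each)
  for (nm in c("R2", "R3", "N_I2", "t")) {
    fw <- fit_free_wilson(d, screening_study$responses[[nm]])
    expect_lt(fw$anova$p, 0.05)
    fw_pe <- fit_free_wilson(d, screening_study$responses[[nm]],
                             error = "pure")
    expect_equal(fw$anova$p, fw_pe$anova$p, tolerance = 1e-12)
  }
  ## no SDS-concentration level change is significant for R2 or R3
  for (nm in c("R2", "R3")) {
    fw <- fit_free_wilson(d, screening_study$responses[[nm]])
    ct <- level_change_significance(fw)
    expect_false(any(ct$significant[ct$factor == "SDS_conc"]))
  }
  ## favourable directions for R5: higher buffer, pH and SDS levels
  fw5 <- fit_free_wilson(d, screening_study$responses$R5)
  eff <- level_effects(fw5)
  for (f in c("Buffer_conc", "pH", "SDS_conc")) {
    e <- eff$effect[eff$factor == f]
    expect_gt(e[3], e[1])
  }
})

test_that("duplicated runs predict identically and run order does not matter", {
  d <- screening_study$design
  y <- screening_study$responses$R2
  fw <- fit_free_wilson(d, y)
  pred <- predict(fw)
  expect_identical(pred[8], pred[16])

  set.seed(3)
  perm <- sample(16)
  d_p <- design_matrix(d$coded[perm, ], d$factors, kind = "screening",
                       run_ids = d$run_ids[perm])
  fw_p <- fit_free_wilson(d_p, y[perm])
  expect_equal(fw_p$level_coefficients, fw$level_coefficients,
               tolerance = 1e-10)
  expect_equal(fw_p$intercept, fw$intercept, tolerance = 1e-10)
})

test_that("known level effects are recovered exactly without noise", {
  d <- screening_study$design
  effects <- lapply(1:7, function(j) {
    e <- c(-1, 0.4, 0.6) * j / 7
    e - mean(e)                      # centred truth, identifiable
  })
  y <- make_screening_truth(d, effects)
  fw <- fit_free_wilson(d, y)
  for (j in 1:7)
    expect_lt(max(abs(fw$level_coefficients[j, ] - effects[[j]])), 1e-6)
  expect_lt(fw$residual_sd, 1e-8)
})

test_that("contrast standard errors match the covariance oracle", {
  d <- screening_study$design
  y <- screening_study$responses$t
  fw <- fit_free_wilson(d, y)
  ct <- level_change_significance(fw)
  X <- free_wilson_matrix(d)
  o <- oracle_ls(X, y)
  ## transition 2 -> 1 of factor 1: c = e_2 - e_3 on the free parameters
  cvec <- rep(0, 15); cvec[2] <- 1; cvec[3] <- -1
  se_o <- sqrt(drop(t(cvec) %*% o$cov %*% cvec))
  row <- ct[ct$factor == "Buffer_conc" & ct$from_level == 2, ]
  expect_equal(row$se, se_o, tolerance = 1e-10)
  expect_equal(row$estimate, sum(cvec * o$b), tolerance = 1e-10)
  ## path additivity (equivalent to antisymmetry of reversed contrasts):
  ## est(3 -> 2) + est(2 -> 1) = est(3 -> 1), factor by factor
  for (f in unique(ct$factor)) {
    cf <- ct[ct$factor == f, ]
    expect_equal(cf$estimate[cf$from_level == 3 & cf$to_level == 2] +
                   cf$estimate[cf$from_level == 2 & cf$to_level == 1],
                 cf$estimate[cf$from_level == 3 & cf$to_level == 1],
                 tolerance = 1e-10)
  }
})

test_that("degenerate screening inputs are handled explicitly", {
  d <- screening_study$design
  fw <- fit_free_wilson(d, rep(4.2, 16))
  expect_false(fw$anova$computable)
  expect_true(all(fw$level_coefficients == 0))
  expect_equal(fw$residual_sd, 0)
  expect_equal(predict(fw), rep(4.2, 16))
  expect_error(fit_free_wilson(d, c(NA, rnorm(15))), "missing")
  ## constant-coefficient contrast: estimate 0, p = 1 on a factor whose
  ## three levels act identically
  y <- make_screening_truth(d, c(list(c(0, 0, 0)),
                                 lapply(2:7, function(j) c(-1, 0, 1))))
  ct <- level_change_significance(fit_free_wilson(d, y))
  first <- ct[ct$factor == "Buffer_conc", ]
  expect_true(all(abs(first$estimate) < 1e-12))
  ## a zero contrast against a (numerically) zero error is reported as
  ## clearly non-significant
  expect_true(all(first$p_value > 0.5))
  expect_false(any(first$significant))
})
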