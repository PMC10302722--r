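test_that("quadratic model matrices have the canonical term inventory", {
  X5 <- quadratic_model_matrix(ccd_study$design)
  expect_equal(ncol(X5), 21)
  expect_equal(colnames(X5)[1:2], c("(Intercept)", "pH"))
  ## centre run: (1, 0, 0, ..., 0)
  centre <- which(rowSums(abs(ccd_study$design$coded)) == 0)[1]
  expect_equal(unname(X5[centre, ]), c(1, rep(0, 20)))
  ## one factor: intercept, linear, quadratic
  X1 <- quadratic_model_matrix(matrix(c(-1, 0, 2), 3, 1,
                                      dimnames = list(NULL, "x")))
  expect_equal(colnames(X1), c("(Intercept)", "x", "x^2"))
  expect_equal(unname(X1[3, ]), c(1, 2, 4))
})

test_that("noise-free quadratic truth is interpolated exactly", {
  set.seed(42)
  beta <- rnorm(21)
  names(beta) <- colnames(quadratic_model_matrix(ccd_study$design))
  truth <- truth_model(list(y = beta), sd = c(y = 0))
  sim <- simulate_study(truth, ccd_study$design, seed = 5)
  m <- fit_rsm(ccd_study$design, sim$y)
  expect_lt(max(abs(m$coefficients - beta)), 1e-8)
  expect_gt(m$quality["Q2"], 1 - 1e-9)
})

test_that("missing responses are excluded only from their own fit", {
  m_n <- fit_rsm(ccd_study$design, ccd_study$responses$N_I2,
                 transform = "log10")
  expect_equal(m_n$n_used, 26)
  expect_identical(ccd_study$design$run_ids[!m_n$used], c(7L, 13L, 15L))
  m_t <- fit_rsm(ccd_study$design, ccd_study$responses$t)
  expect_equal(m_t$n_used, 29)
  expect_error(fit_rsm(ccd_study$design, ccd_study$responses$R3,
                       transform = "log10"), "positive")
})

test_that("fit quality matches the explicit projection oracle", {
  y <- ccd_study$responses$t
  X <- quadratic_model_matrix(ccd_study$design)
  o <- oracle_ls(X, y)        # frozen oracle route: explicit normal equations
  m <- fit_rsm(ccd_study$design, y)
  expect_equal(unname(m$quality["R2"]), o$r_squared, tolerance = 1e-10)
  expect_equal(unname(m$coefficients), unname(o$b), tolerance = 1e-8)
  expect_equal(unname(m$covariance), unname(o$cov), tolerance = 1e-8)
})

test_that("closed-form Q2 equals explicit leave-one-out refits", {
  for (nm in c("t", "R2")) {
    y <- ccd_study$responses[[nm]]
    m <- fit_rsm(ccd_study$design, y)
    expect_equal(q2(m), oracle_loo_q2(quadratic_model_matrix(ccd_study$design), y),
                 tolerance = 1e-10)
  }
})

test_that("Q2 never exceeds R2 and refinement never lowers Q2", {
  for (nm in c("R2", "R3", "R5", "N_I2", "t")) {
    full <- fit_rsm(ccd_study$design, ccd_study$responses[[nm]],
                    transform = if (nm == "N_I2") "log10" else "none")
    expect_lte(q2(full), full$quality[["R2"]])
    ref <- refine_backward(full)
    expect_gte(q2(ref), q2(full))
    expect_lte(q2(ref), ref$quality[["R2"]])
    ## removing any surviving term never increases R2
    for (i in seq_len(nrow(ref$terms))[-1]) {
      sub <- fit_rsm(ccd_study$design, ccd_study$responses[[nm]],
                     transform = ref$transform,
                     terms = ref$terms[-i, , drop = FALSE])
      expect_lte(sub$quality[["R2"]], ref$quality[["R2"]] + 1e-12)
    }
  }
})

test_that("refinement leaves an all-significant model unchanged", {
  ## build a model whose every term is strongly significant
  facs <- lapply(c("a", "b"), function(nm)
    factor_spec(nm, center = 0, step = 1, rounding = 6))
  d <- ccd_design(facs, fraction = "full", n_center = 4)
  beta <- c(`(Intercept)` = 10, a = 5, b = -4, `a^2` = 3, `b^2` = -3,
            `a:b` = 4)
  truth <- truth_model(list(y = beta), sd = c(y = 0.05))
  sim <- simulate_study(truth, d, seed = 9)
  m <- fit_rsm(d, sim$y)
  ref <- refine_backward(m)
  expect_identical(ref$terms$term, m$terms$term)
})

test_that("fitting is invariant to run order and run_id relabeling", {
  y <- ccd_study$responses$R3
  m <- fit_rsm(ccd_study$design, y)
  set.seed(11)
  perm <- sample(29)
  d_p <- design_matrix(ccd_study$design$coded[perm, ],
                       ccd_study$design$factors, kind = "ccd",
                       run_ids = 100 + seq_len(29))
  attr(d_p, "alpha") <- attr(ccd_study$design, "alpha")
  m_p <- fit_rsm(d_p, y[perm])
  expect_equal(m_p$coefficients, m$coefficients, tolerance = 1e-9)
  expect_equal(m_p$quality, m$quality, tolerance = 1e-10)
})

test_that("predictions back-transform and propagate variance correctly", {
  m_n <- fit_rsm(ccd_study$design, ccd_study$responses$N_I2,
                 transform = "log10")
  ## a fitting-scale prediction of 4.0 is 10,000 on the original scale
  pr <- predict(m_n, rep(0, 5))
  expect_equal(pr$mean, 10^pr$fit)
  m_t <- fit_rsm(ccd_study$design, ccd_study$responses$t)
  x <- c(0.5, -0.5, 0.25, 0, 1)
  M <- quadratic_model_matrix(matrix(x, 1, 5, dimnames = list(NULL,
        colnames(ccd_study$design$coded))))
  o <- oracle_ls(quadratic_model_matrix(ccd_study$design),
                 ccd_study$responses$t)
  v_o <- drop(M %*% o$cov %*% t(M)) + o$s2
  pr_t <- predict(m_t, x)
  expect_equal(pr_t$se_pred^2, v_o, tolerance = 1e-10)
  ## centre prediction close to the centre-run mean
  ctr <- predict(m_t, rep(0, 5))
  expect_lt(abs(ctr$mean - mean(ccd_study$responses$t[27:29])),
            2 * ctr$se_pred)
  expect_warning(predict(m_t, c(3, 0, 0, 0, 0)), "guard")
})

test_that("sweet-spot counts agree with a brute-force spec check", {
  models <- trimecaine_rsm_models()
  specs <- trimecaine_specs()
  g <- panel_grid(rsm_factors, x = "CyD_conc", y = "pH",
                  panels = data.frame(V = c(20, 30)),
                  fixed = list(Buffer_conc = 25, BuOH_conc = 1.00),
                  n = 11)
  ss <- sweet_spot(models, specs, g)
  for (ip in seq_along(g$panels)) {
    brute <- rep(0L, nrow(g$panels[[ip]]$coded))
    for (nm in names(specs)) {
      mu <- predict(models[[nm]], g$panels[[ip]]$coded)$mean
      ok <- if (specs[[nm]]$direction == "ge") mu >= specs[[nm]]$threshold
            else mu <= specs[[nm]]$threshold
      brute <- brute + as.integer(ok)
    }
    expect_identical(as.vector(ss$counts[[ip]]), brute)
  }
  expect_true(all(unlist(ss$counts) >= 0) && all(unlist(ss$counts) <= 5))
})
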