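## small single-factor model with controllable uncertainty, built by
## fitting simulated data from known truth
make_toy_model <- function(sd = 0.2, seed = 4, n_center = 6) {
  f <- list(factor_spec("x", center = 0, step = 1, rounding = 6,
                        domain = c(-2, 2)))
  d <- design_matrix(matrix(c(-1, -0.5, 0, 0.5, 1,
                              rep(0, n_center)), ncol = 1),
                     f, kind = "custom")
  truth <- truth_model(list(y = c(`(Intercept)` = 5, x = 1, `x^2` = -0.5)),
                       sd = c(y = sd))
  sim <- simulate_study(truth, d, seed = seed)
  fit_rsm(d, sim$y)
}

test_that("degenerate (noise-free) models give certainty", {
  m <- make_toy_model(sd = 0)
  expect_lt(m$residual_sd, 1e-8)
  models <- list(y = m)
  specs <- list(y = cma_spec("y", "ge", 4))   # mean is ~5 at the centre
  expect_equal(joint_pass_probability(models, specs, 0, 2000, seed = 1),
               100)
  specs_fail <- list(y = cma_spec("y", "ge", 6))
  expect_equal(joint_pass_probability(models, specs_fail, 0, 2000,
                                      seed = 1), 0)
})

test_that("a mean exactly at the threshold passes about half the time", {
  m <- make_toy_model(sd = 0.3)
  thr <- predict(m, 0.4)$fit
  specs <- list(y = cma_spec("y", "ge", thr, scale = "fitting"))
  n <- 20000
  p <- joint_pass_probability(list(y = m), specs, 0.4, n, seed = 2)
  se <- 100 * sqrt(0.25 / n)
  expect_lt(abs(p - 50), 3 * se)
})

test_that("the scalar draw law matches full coefficient-vector sampling", {
  skip_if_not_installed("MASS")
  models <- trimecaine_rsm_models()
  specs <- trimecaine_specs()
  wp <- trimecaine_working_point()
  n <- 20000
  p_impl <- joint_pass_probability(models, specs, wp, n, seed = 31)
  p_oracle <- oracle_joint_pass(models, specs, wp, n, seed = 77)
  se <- 100 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(p_impl - p_oracle), 4 * sqrt(2) * se)
})

## two-factor companion used for gridded maps
make_toy_model2 <- function(sd = 0.2, seed = 4) {
  facs <- lapply(c("x1", "x2"), function(nm)
    factor_spec(nm, center = 0, step = 1, rounding = 6,
                domain = c(-1.5, 1.5)))
  d <- ccd_design(facs, fraction = "full", n_center = 4)
  truth <- truth_model(list(y = c(`(Intercept)` = 5, x1 = 1, x2 = -0.6,
                                  `x1^2` = -0.5)),
                       sd = c(y = sd))
  sim <- simulate_study(truth, d, seed = seed)
  fit_rsm(d, sim$y)
}

test_that("fixed seeds make probabilities, maps and boxes reproducible", {
  m1 <- make_toy_model()
  p1 <- joint_pass_probability(list(y = m1),
                               list(y = cma_spec("y", "ge", 4.5)),
                               0.3, 5000, seed = 10)
  p2 <- joint_pass_probability(list(y = m1),
                               list(y = cma_spec("y", "ge", 4.5)),
                               0.3, 5000, seed = 10)
  expect_identical(p1, p2)
  m <- make_toy_model2()
  models <- list(y = m); specs <- list(y = cma_spec("y", "ge", 4.5))
  g <- panel_grid(m$design$factors, x = "x1", y = "x2", n = 5)
  ## maps: node-by-node equality with direct calls at the node seeds
  cfg <- modr_config(n_sims = 1000, seed = 123)
  map1 <- probability_map(models, specs, g, cfg)
  map2 <- probability_map(models, specs, g, cfg)
  expect_identical(map1$risk, map2$risk)
  node <- 0L
  for (i in seq_len(nrow(g$panels[[1]]$coded))) {
    node <- node + 1L
    expect_identical(map1$risk[[1]][i],
                     100 - joint_pass_probability(models, specs,
                                                  g$panels[[1]]$coded[i, ],
                                                  1000, seed = 123 + node))
  }
  expect_true(all((map1$risk[[1]] <= 10) == map1$in_modr[[1]]))
  expect_equal(map1$dpmo[[1]], map1$risk[[1]] * 1e4)
})

test_that("inflating residual noise never raises the pass probability", {
  m <- make_toy_model(sd = 0.25)
  specs <- list(y = cma_spec("y", "ge", 4.6))
  ## points where the mean prediction clears the threshold, so widening
  ## the predictive distribution can only push draws across it
  set.seed(8)
  pts <- runif(20, 0, 1)
  for (x in pts) {
    m_wide <- m
    m_wide$residual_sd <- m$residual_sd * 2.5
    p_narrow <- joint_pass_probability(list(y = m), specs, x, 4000,
                                       seed = 55)
    p_wide <- joint_pass_probability(list(y = m_wide), specs, x, 4000,
                                     seed = 55)
    expect_lte(p_wide, p_narrow)
  }
})

test_that("moving a threshold toward the mean raises the pass probability", {
  m <- make_toy_model(sd = 0.25)
  mu <- predict(m, 0.2)$fit
  thresholds <- mu + c(0.6, 0.4, 0.2, 0)
  probs <- vapply(thresholds, function(thr)
    joint_pass_probability(list(y = m),
                           list(y = cma_spec("y", "ge", thr,
                                             scale = "fitting")),
                           0.2, 4000, seed = 66), 0)
  expect_true(all(diff(probs) >= 0))
})

test_that("independent seeds scatter within binomial bounds", {
  m <- make_toy_model(sd = 0.25)
  specs <- list(y = cma_spec("y", "ge", 4.6))
  n <- 2000
  ps <- vapply(1:20, function(s)
    joint_pass_probability(list(y = m), specs, 0.1, n, seed = 1000 + s),
    0)
  p_hat <- mean(ps) / 100
  se <- 100 * sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(sd(ps), 3 * se)
})

test_that("the MODR box around the working point is vertex-valid", {
  models <- trimecaine_rsm_models()
  specs <- trimecaine_specs()
  wp <- trimecaine_working_point()
  cfg <- modr_config(n_sims = 3000, seed = 2024)
  box <- extract_modr_box(models, specs, wp, config = cfg, tol = 0.05)
  ## working point inside the box, box inside the factor domains
  for (j in seq_along(wp)) {
    expect_lte(box$coded_low[j], wp[j])
    expect_gte(box$coded_high[j], wp[j])
    dom <- c(box$factors[[j]]$domain)
    expect_gte(box$intervals$low[j], dom[1] - 1e-9)
    expect_lte(box$intervals$high[j], dom[2] + 1e-9)
  }
  ## dense re-check of every vertex with an independent seed; the MC
  ## endpoint carries about one percentage point of sampling noise
  V <- as.matrix(expand.grid(lapply(seq_along(wp), function(j)
    c(box$coded_low[j], box$coded_high[j]))))
  colnames(V) <- names(wp)
  for (i in seq_len(nrow(V))) {
    p <- joint_pass_probability(models, specs, V[i, ], 20000,
                                seed = 999000 + i)
    expect_gte(p, 90 - 1)
  }
  ## edge-verification table re-evaluates the means
  ed <- verify_edges(models, specs, box)
  expect_true(all(ed$all_pass))
  pr <- predict(models$t, V)$mean
  expect_equal(ed$pred_t, pr, tolerance = 1e-10)
  ## extracted intervals overlap the study's reported operable region
  ivl <- box$intervals
  ph <- ivl[ivl$factor == "pH", ]
  expect_gte(ph$low, 9.4);  expect_lte(ph$high, 9.9)
  expect_lt(ph$low, 9.77);  expect_gt(ph$high, 9.50)
  vv <- ivl[ivl$factor == "V", ]
  expect_gte(vv$low, 22);   expect_lte(vv$high, 30)
  ## a box collapsed onto the working point verifies as a single row
  box0 <- box
  box0$coded_low <- box0$coded_high <- wp
  ed0 <- verify_edges(models, specs, box0)
  expect_equal(nrow(ed0), 1)
  expect_equal(ed0$pred_t, predict(models$t, wp)$mean, tolerance = 1e-10)
})

test_that("a working point outside the region is refused", {
  models <- trimecaine_rsm_models()
  specs <- trimecaine_specs()
  bad <- c(pH = -1.5, Buffer_conc = 1.5, CyD_conc = 1.5, V = -1.5,
           BuOH_conc = 1.5)
  expect_error(extract_modr_box(models, specs, bad,
                                config = modr_config(n_sims = 2000,
                                                     seed = 3)),
               "outside MODR")
})
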