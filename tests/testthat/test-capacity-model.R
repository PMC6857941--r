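test_that("beta is the total-to-wild-oriented pose ratio", {
  expect_equal(compute_beta(100, 40), 2.5)
  expect_equal(compute_beta(100, 100), 1.0)
  expect_error(compute_beta(100, 0), "no oriented poses")
})

test_that("the logistic term behaves at its midpoint and limits", {
  expect_equal(sigmoid_term(0.4, gamma = 8, mu = 0.4), 0.5)
  expect_equal(sigmoid_term(0, gamma = 3, mu = 0), 0.5)
  expect_equal(sigmoid_term(0.6, gamma = 1e4, mu = 0.4), 1, tolerance = 1e-12)
  expect_equal(sigmoid_term(0.2, gamma = 1e4, mu = 0.4), 0, tolerance = 1e-12)
  # strictly increasing in f
  f <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sigmoid_term(f, gamma = 5, mu = 0.5)) > 0))
})

test_that("substrate contribution is the logistic raised to beta", {
  params <- model_params(sigma = 1, gamma = 8, mu = 0.4, beta = 2)
  s <- docking_summary("v", "aap", S_DT = 100, S_DH = 40,
                       udpga_correct_count = 90)
  expect_equal(substrate_contribution(s, params), 0.25)

  params1 <- model_params(sigma = 1, gamma = 8, mu = 0.4, beta = 1)
  expect_equal(substrate_contribution(s, params1),
               sigmoid_term(0.4, 8, 0.4))

  # zero oriented poses: (1/(1+e^5))^2, frozen from direct evaluation
  params2 <- model_params(sigma = 1, gamma = 10, mu = 0.5, beta = 2)
  s0 <- docking_summary("v", "aap", S_DT = 100, S_DH = 0,
                        udpga_correct_count = 90)
  expect_equal(substrate_contribution(s0, params2), 4.4794253e-05,
               tolerance = 1e-7)
})

test_that("kappa follows the promoter-genotype Vmax ratios", {
  expect_equal(kappa("wild/wild"), 1.0)
  expect_equal(kappa("wild/*28"), 0.74)
  expect_equal(kappa("*28/*28"), 0.21)
  expect_equal(kappa("wild/*28", mode = "exact"), 12.0 / 16.2)
  expect_equal(kappa("*28/*28", mode = "exact"), 3.4 / 16.2)
  expect_error(kappa("wild/*6"), "unknown genotype")
})

test_that("absolute prediction multiplies scale, genotype and S term", {
  # sigma=100, kappa=1, S=0.25 -> 25
  params <- model_params(sigma = 100, gamma = 8, mu = 0.4, beta = 2)
  s <- docking_summary("v", "aap", 100, 40, 90)
  expect_equal(as.numeric(predict_absolute(s, "wild/wild", params)), 25)

  hom <- predict_absolute(s, "*28/*28", params)
  expect_equal(as.numeric(hom), 0.21 * 25)

  s_none <- docking_summary("v", "aap", 100, 40, 0)
  flagged <- predict_absolute(s_none, "wild/wild", params)
  expect_equal(as.numeric(flagged), 0)
  expect_true(attr(flagged, "no_udpga_binding"))
})

test_that("relative prediction returns percent of wild-type", {
  params <- model_params(sigma = 100, gamma = 8, mu = 0.4, beta = 2.5)
  wild <- docking_summary("wild", "aap", 100, 40, 95)
  expect_equal(as.numeric(predict_relative(wild, "wild/wild", params, wild)), 100)
  expect_equal(as.numeric(predict_relative(wild, "*28/*28", params, wild)), 21,
               tolerance = 1e-12)
  none <- docking_summary("v", "aap", 100, 40, 0)
  expect_equal(as.numeric(predict_relative(none, "wild/wild", params, wild)), 0)
})

test_that("with zero offset the two relative formulas agree to 1e-12", {
  params <- model_params(sigma = 73, gamma = 6.5, mu = 0.35, epsilon = 0,
                         beta = 2.2)
  wild <- docking_summary("wild", "aap", 100, 45, 95)
  for (sdh in c(5, 20, 45, 80)) {
    m <- docking_summary("v", "aap", 100, sdh, 90)
    rel_reduced <- as.numeric(predict_relative(m, "wild/*28", params, wild))
    # full ratio form evaluated directly
    s_m <- substrate_contribution(m, params)
    s_w <- substrate_contribution(wild, params)
    rel_full <- 100 * (params$sigma * 0.74 * s_m + 0) /
      (params$sigma * s_w + 0)
    expect_equal(rel_reduced, rel_full, tolerance = 1e-12)
  }
})

test_that("predictions scale exactly by kappa across genotypes", {
  params <- model_params(sigma = 50, gamma = 8, mu = 0.4, beta = 2.5)
  wild <- docking_summary("wild", "aap", 100, 40, 95)
  m <- docking_summary("v", "aap", 100, 55, 88)
  p_ww <- as.numeric(predict_relative(m, "wild/wild", params, wild))
  expect_equal(as.numeric(predict_relative(m, "wild/*28", params, wild)),
               0.74 * p_ww, tolerance = 1e-12)
  expect_equal(as.numeric(predict_relative(m, "*28/*28", params, wild)),
               0.21 * p_ww, tolerance = 1e-12)
})

test_that("predicted capacity increases strictly with the oriented count", {
  params <- model_params(sigma = 50, gamma = 8, mu = 0.4, beta = 2.5)
  preds <- vapply(0:100, function(sdh) {
    as.numeric(predict_absolute(docking_summary("v", "aap", 100, sdh, 90),
                                "wild/wild", params))
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
  # range: S in (0,1) so P_c in (0, sigma * kappa)
  expect_true(all(preds > 0 & preds < 50))
})

test_that("the fit recovers noise-free generating constants within 1%", {
  gen <- generate_variant_panel(panel_spec(n_variants = 20, noise_sd = 0,
                                           seed = 7))
  fit <- fit_parameters(gen$panel, fit_control(seed = 17))
  truth <- gen$truth$params
  expect_lt(abs(fit$params$sigma - truth$sigma) / truth$sigma, 0.01)
  expect_lt(abs(fit$params$gamma - truth$gamma) / truth$gamma, 0.01)
  expect_lt(abs(fit$params$mu - truth$mu) / truth$mu, 0.01)
  expect_lt(fit$sse, 1e-6)
  expect_equal(fit$params$beta, gen$truth$beta_realized)
})

test_that("rescaling capacities rescales sigma and leaves the shape alone", {
  gen <- generate_variant_panel(panel_spec(n_variants = 20, noise_sd = 0,
                                           seed = 8))
  fit1 <- fit_parameters(gen$panel, fit_control(seed = 17))
  scaled <- gen$panel
  scaled$members$V_c <- scaled$members$V_c * 3
  fit3 <- fit_parameters(scaled, fit_control(seed = 17))
  expect_equal(fit3$params$sigma, 3 * fit1$params$sigma, tolerance = 1e-4)
  expect_equal(fit3$params$gamma, fit1$params$gamma, tolerance = 1e-3)
  expect_equal(fit3$params$mu, fit1$params$mu, tolerance = 1e-4)
})

test_that("under-determined or degenerate panels refuse to fit", {
  gen <- generate_variant_panel(panel_spec(n_variants = 2, noise_sd = 0,
                                           seed = 9))
  expect_error(fit_parameters(gen$panel,
                              fit_control(seed = 17, free_epsilon = TRUE)),
               "free constants")

  flat <- generate_variant_panel(panel_spec(n_variants = 8, noise_sd = 0,
                                            seed = 10))$panel
  flat$members$V_c <- 42
  expect_error(fit_parameters(flat, fit_control(seed = 17)), "unidentifiable")
})

test_that("identical panel and seed give bit-identical fits", {
  gen <- generate_variant_panel(panel_spec(n_variants = 15, seed = 21))
  f1 <- fit_parameters(gen$panel, fit_control(seed = 17))
  f2 <- fit_parameters(gen$panel, fit_control(seed = 17))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse, f2$sse)
})

test_that("fitting does not disturb the caller's RNG stream", {
  gen <- generate_variant_panel(panel_spec(n_variants = 12, seed = 3))
  set.seed(101)
  before <- runif(1)
  set.seed(101)
  invisible(fit_parameters(gen$panel, fit_control(seed = 17)))
  expect_identical(runif(1), before)
})

test_that("the profiled fit matches an independent nonlinear least-squares run", {
  gen <- generate_variant_panel(panel_spec(n_variants = 20, seed = 31))
  fit <- fit_parameters(gen$panel, fit_control(seed = 17))
  m <- fit_set(gen$panel)
  df <- data.frame(f = m$S_DH / m$S_DT, v = m$V_c)
  beta <- compute_beta(gen$panel$wild_summary$S_DT, gen$panel$wild_summary$S_DH)
  nls_fit <- minpack.lm::nlsLM(
    v ~ sigma * (1 / (1 + exp(-gamma * (f - mu))))^beta,
    data = df, start = list(sigma = 40, gamma = 5, mu = 0.5),
    lower = c(1e-6, 1e-3, 0), upper = c(Inf, 100, 1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  sse_nls <- sum(residuals(nls_fit)^2)
  expect_lte(fit$sse, sse_nls * (1 + 1e-6))
  expect_equal(fit$params$gamma, coef(nls_fit)[["gamma"]], tolerance = 1e-2)
  expect_equal(fit$params$mu, coef(nls_fit)[["mu"]], tolerance = 1e-2)
})

test_that("noisy panels recover constants within the stated band", {
  gen <- generate_variant_panel(panel_spec(n_variants = 20, seed = 55))
  # default noise: sd = 5% of wild-type capacity
  fit <- fit_parameters(gen$panel, fit_control(seed = 17))
  truth <- gen$truth$params
  expect_lt(abs(fit$params$sigma - truth$sigma) / truth$sigma, 0.15)
  expect_lt(abs(fit$params$gamma - truth$gamma) / truth$gamma, 0.15)
  expect_lt(abs(fit$params$mu - truth$mu) / truth$mu, 0.15)
})
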