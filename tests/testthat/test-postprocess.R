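# a fitted posterior is expensive; most operations are exercised against
# fabricated ("mock") posteriors whose draws are fully under our control

test_that("predict_correlation pushes draws through the inverse link", {
  sim <- simulate_intraindividual(tiny_cfg(1))
  model <- crn_build(spec_nonrep_sim(), sim$data)
  params <- sim$truth$params
  post <- covrn:::mock_posterior(model, params)
  curve <- predict_correlation(post, sim$data$contexts["climate"])
  # self-consistency: point-mass posterior reproduces the exact truth
  expect_equal(curve$median, sim$truth$r_true, tolerance = 1e-12)
  expect_equal(curve$mean, curve$median, tolerance = 1e-12)
  # bands are nested and ordered at every grid point
  expect_true(all(curve$l89 <= curve$l50 & curve$l50 <= curve$median &
                    curve$median <= curve$u50 & curve$u50 <= curve$u89))
  expect_true(all(abs(attr(curve, "draws")) < 1))
  expect_error(predict_correlation(post, data.frame(x = 1)), "climate")
})

test_that("an all-positive slope posterior gives monotone curves draw by draw", {
  sim <- simulate_intraindividual(tiny_cfg(2))
  model <- crn_build(spec_nonrep_sim(), sim$data)
  set.seed(2)
  post <- covrn:::mock_posterior(model, sim$truth$params, jitter = 0.01)
  stopifnot(all(coef_draws(post)[, "br_climate"] > 0))
  grid <- data.frame(climate = seq(-2, 2, length.out = 9))
  dr <- attr(predict_correlation(post, grid), "draws")
  expect_true(all(apply(dr, 2, function(col) all(diff(col) > 0))))
})

test_that("curves are invariant to affine recoding when fits standardize internally", {
  sim <- simulate_intraindividual(tiny_cfg(3))
  m1 <- crn_build(spec_nonrep_sim(standardize = TRUE), sim$data)
  rec <- sim$data
  for (tb in c("trait1", "trait2", "contexts")) {
    rec[[tb]]$climate <- 10 + 5 * rec[[tb]]$climate
  }
  m2 <- crn_build(spec_nonrep_sim(standardize = TRUE), rec)
  params <- c("br_(Intercept)" = -0.2, "br_climate" = 0.5)
  p1 <- covrn:::mock_posterior(m1, params)
  p2 <- covrn:::mock_posterior(m2, params)
  g1 <- data.frame(climate = c(-1, 0, 1.5))
  g2 <- data.frame(climate = 10 + 5 * g1$climate)
  expect_equal(predict_correlation(p1, g1)$median,
               predict_correlation(p2, g2)$median, tolerance = 1e-12)
})

test_that("recovery report flags coverage correctly for mock posteriors", {
  sim <- simulate_intraindividual(tiny_cfg(4))
  model <- crn_build(spec_nonrep_sim(), sim$data)
  exact <- covrn:::mock_posterior(model, sim$truth$params)
  rec <- recovery_report(sim$truth, exact)
  expect_true(all(rec$covered50) && all(rec$covered89))
  expect_equal(rec$u89 - rec$l89, rep(0, nrow(rec)))  # point mass
  shifted <- sim$truth$params + 1
  post2 <- covrn:::mock_posterior(model, shifted)
  rec2 <- recovery_report(sim$truth, post2)
  expect_false(any(rec2$covered89))
  bad <- sim$truth
  bad$params <- c(bad$params, nonexistent = 1)
  expect_error(recovery_report(bad, exact), "nonexistent")
})

test_that("posterior predictive replication counts and errors are enforced", {
  sim <- simulate_intraindividual(tiny_cfg(5))
  model <- crn_build(spec_nonrep_sim(), sim$data)
  post <- covrn:::mock_posterior(model, sim$truth$params, n = 40)
  set.seed(5)
  ppc <- posterior_predictive(post)          # one replicate per draw
  expect_equal(ppc$n_reps, 80)
  expect_error(posterior_predictive(post, n_reps = 1000), "subsample")
  expect_named(ppc$stats, c("trait", "statistic", "observed", "rep_mean",
                            "rep_sd", "p_lower", "p_upper", "p_two_sided"))
  expect_false(is.null(ppc$histogram))       # fecundity is discrete
  expect_true(all(ppc$stats$p_lower >= 0 & ppc$stats$p_upper <= 1))
})

test_that("a correct generating posterior yields calibrated tail probabilities", {
  set.seed(6)
  p_mean <- matrix(NA_real_, 20, 2)
  for (k in seq_len(20)) {
    sim <- simulate_intraindividual(tiny_cfg(seed = 300 + k), seed = 300 + k)
    model <- crn_build(spec_nonrep_sim(), sim$data)
    post <- covrn:::mock_posterior(model, sim$truth$params, n = 100)
    ppc <- posterior_predictive(post, n_reps = 100)
    p_mean[k, ] <- ppc$stats$p_two_sided[ppc$stats$statistic == "mean"]
  }
  # smoke test of uniformity: extreme tails should be rare and not one-sided
  expect_gte(mean(p_mean > 0.05), 0.8)
  expect_gt(mean(p_mean), 0.25)
  expect_lt(mean(p_mean), 1.01)
})

test_that("injected overdispersion beyond the count family is detected", {
  sim <- simulate_intraindividual(sim_config(n_years = 12,
                                             recruits_per_year = 15,
                                             seed = 7))
  contaminated <- sim$data
  idx <- seq(1, nrow(contaminated$trait2), by = 12)
  contaminated$trait2$value[idx] <- contaminated$trait2$value[idx] + 25
  model <- crn_build(spec_nonrep_sim(), contaminated)
  post <- covrn:::mock_posterior(model, sim$truth$params, n = 100)
  set.seed(7)
  ppc <- posterior_predictive(post, n_reps = 100)
  p_sd <- ppc$stats$p_two_sided[ppc$stats$statistic == "sd" &
                                  ppc$stats$trait == "fecundity"]
  expect_lt(p_sd, 0.01)
})
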