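test_that("analytic gradients match numerical differentiation in every variant", {
  skip_if_not_installed("numDeriv")
  set.seed(42)
  models <- list(
    hybrid = crn_build(spec_hybrid_sim(),
                       simulate_intergenerational(tiny_cfg(3))$data),
    marmot = local({
      s <- simulate_marmot_like(tiny_cfg(3))
      crn_build(marmot_preset(s$data), s$data)
    }),
    nonrep_gp = crn_build(spec_nonrep_sim(),
                          simulate_intraindividual(tiny_cfg(3))$data),
    sheep = local({
      s <- simulate_sheep_like(tiny_cfg(3))
      crn_build(sheep_preset(s$data), s$data)
    }),
    nonrep_gg = crn_build(spec_nonrep_gg(year_effects = c(TRUE, TRUE)),
                          make_gg_sim(tiny_cfg(3))$data),
    full = crn_build(spec_full_sim(), make_full_sim(seed = 3)$data))
  for (nm in names(models)) {
    q <- rnorm(models[[nm]]$layout$npar, 0, 0.4)
    expect_lt(grad_discrepancy(models[[nm]], q), 1e-5)
    expect_lt(grad_discrepancy(models[[nm]], q, prior_only = TRUE), 1e-6)
  }
})

test_that("joint density differences agree with an independent R oracle (Gaussian pair)", {
  skip_if_not_installed("mvtnorm")
  sim <- make_gg_sim(tiny_cfg(5))
  model <- crn_build(spec_nonrep_gg(), sim$data)
  cd <- model$cdata
  oracle <- function(q) {
    P1 <- ncol(cd$X1); P2 <- ncol(cd$X2); P3 <- ncol(cd$X3)
    b1 <- q[1:P1]; b2 <- q[P1 + 1:P2]; br <- q[P1 + P2 + 1:P3]
    t1 <- q[P1 + P2 + P3 + 1]; t2 <- q[P1 + P2 + P3 + 2]
    s1 <- exp(t1); s2 <- exp(t2)
    r <- tanh(as.vector(cd$X3 %*% br))[cd$ctx + 1]
    mu1 <- as.vector(cd$X1 %*% b1); mu2 <- as.vector(cd$X2 %*% b2)
    lik <- sum(vapply(seq_along(cd$y1), function(i) {
      S <- matrix(c(s1^2, r[i] * s1 * s2, r[i] * s1 * s2, s2^2), 2)
      mvtnorm::dmvnorm(c(cd$y1[i], cd$y2[i]), c(mu1[i], mu2[i]), S,
                       log = TRUE)
    }, numeric(1)))
    lik + sum(dnorm(c(b1, b2, br), 0, 1, log = TRUE)) +
      sum(dexp(c(s1, s2), 2, log = TRUE)) + t1 + t2
  }
  set.seed(6)
  q1 <- rnorm(model$layout$npar, 0, 0.3)
  q2 <- rnorm(model$layout$npar, 0, 0.3)
  expect_equal(crn_lp(model, q1)$lp - crn_lp(model, q2)$lp,
               oracle(q1) - oracle(q2), tolerance = 1e-8)
})

test_that("joint density differences agree with an independent R oracle (ordinal pair)", {
  sim <- simulate_sheep_like(tiny_cfg(6))
  spec <- crn_model_spec("non_repeated", c("ordinal_logit", "gaussian"),
                         covariates1 = "age", covariates2 = "age",
                         covariates_corr = "nao", standardize = FALSE)
  model <- crn_build(spec, sim$data)
  cd <- model$cdata
  lay <- model$layout
  oracle <- function(q) {
    P1 <- ncol(cd$X1); P2 <- ncol(cd$X2); P3 <- ncol(cd$X3)
    b1 <- q[1:P1]; b2 <- q[P1 + 1:P2]; br <- q[P1 + P2 + 1:P3]
    ts <- q[lay$sd0 + 1:2]; s1 <- exp(ts[1]); s2 <- exp(ts[2])
    c1 <- q[lay$cut + 1]; g <- q[lay$cut + 2]
    th <- c(c1, c1 + exp(g))
    u1 <- q[lay$u1 + seq_len(lay$nu1)]
    r <- tanh(as.vector(cd$X3 %*% br))[cd$ctx + 1]
    mu2 <- as.vector(cd$X2 %*% b2)
    v <- (cd$y2 - mu2) / s2
    o1 <- s1 * (r * v + sqrt(1 - r^2) * u1)
    eta1 <- as.vector(cd$X1 %*% b1) + o1
    pcat <- cbind(plogis(th[1] - eta1),
                  plogis(th[2] - eta1) - plogis(th[1] - eta1),
                  1 - plogis(th[2] - eta1))
    lik <- sum(log(pcat[cbind(seq_along(eta1), cd$y1 + 1)])) +
      sum(dnorm(cd$y2, mu2, s2, log = TRUE))
    lik + sum(dnorm(c(b1, b2, br), 0, 1, log = TRUE)) +
      sum(dexp(c(s1, s2), 2, log = TRUE)) + sum(ts) +
      sum(dnorm(th, 0, 2, log = TRUE)) + g + sum(dnorm(u1, log = TRUE))
  }
  set.seed(7)
  q1 <- rnorm(lay$npar, 0, 0.3)
  q2 <- rnorm(lay$npar, 0, 0.3)
  expect_equal(crn_lp(model, q1)$lp - crn_lp(model, q2)$lp,
               oracle(q1) - oracle(q2), tolerance = 1e-8)
})

test_that("same seed and data give identical fits; seeds differ otherwise", {
  sim <- make_gg_sim(tiny_cfg(7))
  model <- crn_build(spec_nonrep_gg(), sim$data)
  cfg <- mcmc_config(chains = 2, warmup = 200, samples = 200, seed = 3)
  f1 <- suppressWarnings(crn_fit(model, cfg))
  f2 <- suppressWarnings(crn_fit(model, cfg))
  expect_identical(summarize(f1), summarize(f2))
  f3 <- suppressWarnings(crn_fit(model, mcmc_config(chains = 2, warmup = 200,
                                                    samples = 200, seed = 4)))
  expect_false(identical(summarize(f1)$mean, summarize(f3)$mean))
})

test_that("R-hat behaves as a convergence detector", {
  set.seed(8)
  good <- matrix(rnorm(3 * 3000), ncol = 3)
  expect_lt(rhat(good), 1.01)
  bad <- sweep(matrix(rnorm(3 * 500), ncol = 3), 2, c(5, 0, -5), `+`)
  expect_gt(rhat(bad), 1.1)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "at least 2 chains")
})

test_that("interval summaries are equal-tailed quantiles at 50% and 89%", {
  set.seed(9)
  z <- matrix(rnorm(1e6), ncol = 1, dimnames = list(NULL, "z"))
  s <- summarize(z)
  expect_equal(s$l89, -1.598, tolerance = 0.01)
  expect_equal(s$u89, 1.598, tolerance = 0.01)
  expect_equal(s$mean, mean(z), tolerance = 1e-12)
  # nesting: 50% interval inside the 89% interval
  expect_true(s$l89 < s$l50 && s$u50 < s$u89)
})

test_that("a non-finite starting density raises an initialization error", {
  sim <- make_gg_sim(tiny_cfg(10))
  model <- crn_build(spec_nonrep_gg(), sim$data)
  cd <- model$cdata
  expect_error(
    covrn:::cpp_nuts(cd, rep(1e4, model$layout$npar), 10, 10, 0.8, 5, 0L),
    "not finite")
})

test_that("intercept-only reaction norm recovers a constant correlation", {
  cfg <- sim_config(n_years = 15, recruits_per_year = 25, seed = 11,
                    beta_r = c(0.4, 0))
  sim <- make_gg_sim(cfg)
  spec <- crn_model_spec("non_repeated", c("gaussian", "gaussian"),
                         covariates1 = "climate", covariates2 = "climate",
                         covariates_corr = character(), standardize = FALSE)
  model <- crn_build(spec, sim$data)
  expect_equal(colnames(model$cdata$X3), "(Intercept)")
  post <- suppressWarnings(crn_fit(model, mcmc_config(chains = 2,
                                                      warmup = 300,
                                                      samples = 400,
                                                      seed = 2)))
  s <- summarize(post, pars = "br_(Intercept)")
  expect_gt(s$u89, 0.4)
  expect_lt(s$l89, 0.4 + 0.35)  # posterior concentrated near atanh-scale truth
  expect_lt(abs(s$mean - 0.4), 0.2)
})

test_that("prior-only sampling reproduces the prior specification", {
  sim <- make_gg_sim(tiny_cfg(12))
  model <- crn_build(spec_nonrep_gg(), sim$data)
  post <- suppressWarnings(
    crn_fit(model, mcmc_config(chains = 2, warmup = 400, samples = 1500,
                               seed = 5, prior_only = TRUE)))
  d <- coef_draws(post)
  bcols <- grep("^(b1|b2|br)_", colnames(d), value = TRUE)
  for (cc in bcols) {
    expect_equal(sd(d[, cc]), 1, tolerance = 0.1)
    expect_equal(mean(d[, cc]), 0, tolerance = 0.12)
  }
  for (sc in c("sigma_o1", "sigma_o2")) {
    expect_equal(mean(d[, sc]), 0.5, tolerance = 0.06)
    expect_equal(sd(d[, sc]), 0.5, tolerance = 0.08)  # Exp(2): mean = sd
  }
})

test_that("89% intervals are approximately calibrated for the reaction-norm slope", {
  covered <- logical(20)
  for (k in seq_len(20)) {
    sim <- make_gg_sim(tiny_cfg(seed = 100 + k), seed = 100 + k)
    model <- crn_build(spec_nonrep_gg(), sim$data)
    post <- suppressWarnings(
      crn_fit(model, mcmc_config(chains = 2, warmup = 250, samples = 250,
                                 seed = k)))
    rec <- recovery_report(sim$truth, post)
    covered[k] <- rec$covered89[rec$param == "br_climate"]
  }
  # binomial(20, 0.89): >= 14 successes covers all but ~0.4% of outcomes
  expect_gte(sum(covered), 14)
})
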