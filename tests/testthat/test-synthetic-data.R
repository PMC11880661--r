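test_that("identical seed and config give byte-identical datasets", {
  a <- simulate_intergenerational(tiny_cfg(seed = 4))
  b <- simulate_intergenerational(tiny_cfg(seed = 4))
  expect_identical(a$data, b$data)
  expect_identical(a$truth$mother_year, b$truth$mother_year)
  c1 <- simulate_intraindividual(tiny_cfg(seed = 4))
  c2 <- simulate_intraindividual(tiny_cfg(seed = 4))
  expect_identical(c1$data, c2$data)
})

test_that("demographic bookkeeping: roster size and contiguous lifespans", {
  cfg <- sim_config(n_years = 12, recruits_per_year = 10, seed = 2)
  sim <- simulate_intraindividual(cfg)
  expect_equal(sim$truth$n_individuals, 12 * 10)
  # every individual's recorded years form a contiguous run
  yrs <- split(sim$truth$mother_year$year, sim$truth$mother_year$individual)
  expect_true(all(vapply(yrs, function(y) all(diff(sort(y)) == 1), logical(1))))
  # survival = 0 means exactly one year each
  s0 <- simulate_intraindividual(tiny_cfg(seed = 3, annual_survival = 0))
  expect_true(all(table(s0$truth$mother_year$individual) == 1))
  expect_equal(nrow(s0$truth$mother_year), s0$truth$n_individuals)
})

test_that("no injected correlation leaves latents uncorrelated", {
  sim <- simulate_intergenerational(
    sim_config(n_years = 20, recruits_per_year = 60, beta_r = c(0, 0),
               seed = 8))
  my <- sim$truth$mother_year
  expect_lt(abs(cor(my$o1, my$o2)), 3 / sqrt(nrow(my)))
})

test_that("fixed climates +/-1 reproduce tanh(+/-1) latent correlations", {
  for (cl in c(-1, 1)) {
    sim <- simulate_intergenerational(
      sim_config(n_years = 2, recruits_per_year = 5000, beta_r = c(0, 1),
                 climate_dist = "constant", climate_value = cl, seed = 5))
    my <- sim$truth$mother_year
    expect_equal(cor(my$o1, my$o2), tanh(cl), tolerance = 3 / sqrt(nrow(my)))
  }
})

test_that("per-context latent correlations track the reaction norm at scale", {
  cfg <- sim_config(n_years = 30, recruits_per_year = 5000, seed = 6)
  sim <- simulate_intraindividual(cfg)
  my <- sim$truth$mother_year
  r_hat <- vapply(split(my, my$context),
                  function(d) cor(d$o1, d$o2), numeric(1))
  clim <- sim$truth$contexts$climate[match(names(r_hat),
                                           sim$truth$contexts$context)]
  fit <- lm(atanh(r_hat) ~ clim)
  est <- summary(fit)$coefficients
  expect_lt(abs(est["clim", "Estimate"] - cfg$beta_r[2]),
            3 * est["clim", "Std. Error"])
  expect_lt(abs(est["(Intercept)", "Estimate"] - cfg$beta_r[1]),
            3 * est["(Intercept)", "Std. Error"])
  # realized annual survival near its generating probability
  my29 <- my[!is.na(my$survived), ]
  expect_equal(mean(my29$survived), cfg$annual_survival,
               tolerance = 3 * sqrt(0.6 * 0.4 / nrow(my29)))
})

test_that("ground truth r(C) is exact and family supports are respected", {
  sim <- simulate_intergenerational(tiny_cfg(seed = 9))
  cfg <- sim$truth$config
  expect_equal(sim$truth$r_true,
               tanh(cfg$beta_r[1] + cfg$beta_r[2] * sim$truth$contexts$climate))
  y2 <- sim$data$trait2$value
  expect_true(all(y2 >= 1 & y2 == floor(y2)))  # zero-truncated litter sizes
  intra <- simulate_intraindividual(tiny_cfg(seed = 9))
  yf <- intra$data$trait2$value
  expect_true(all(yf >= 0 & yf == floor(yf)))  # fecundity counts keep zeros
  expect_true(any(yf == 0))
})

test_that("hybrid dataset structure: repeated masses, single litter rows", {
  sim <- simulate_intergenerational(tiny_cfg(seed = 10))
  d <- sim$data
  expect_s3_class(d, "trait_dataset")
  expect_equal(d$design, "hybrid")
  k2 <- paste(d$trait2$individual, d$trait2$context)
  expect_equal(anyDuplicated(k2), 0L)
  # number of mass rows equals total recorded litter size
  expect_equal(nrow(d$trait1), sum(d$trait2$value))
  # every mass row has its litter row
  k1 <- paste(d$trait1$individual, d$trait1$context)
  expect_true(all(k1 %in% k2))
})

test_that("sheep-like data are ordinal in {0,1,2} with saturating thresholds", {
  sim <- simulate_sheep_like(tiny_cfg(seed = 11))
  expect_true(all(sim$data$trait1$value %in% 0:2))
  expect_setequal(unique(sim$data$trait1$value), 0:2)
  hi <- simulate_sheep_like(tiny_cfg(seed = 11, thresholds = c(1e6, 2e6)))
  expect_true(all(hi$data$trait1$value == 0))
  lo <- simulate_sheep_like(tiny_cfg(seed = 11, thresholds = c(-2e6, -1e6)))
  expect_true(all(lo$data$trait1$value == 2))
  expect_error(simulate_sheep_like(tiny_cfg(thresholds = c(1, 1))),
               "strictly increasing")
})

test_that("marmot-like data with zero covariate effects partition variance like a random-intercept model", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_years = 25, recruits_per_year = 40, seed = 12,
                    beta1 = c(snow = 0, june_temperature = 0, age = 0,
                              age2 = 0, mother_mass = 0),
                    beta2 = c(snow = 0, age = 0, age2 = 0, mother_mass = 0),
                    beta_r3 = c(0, 0, 0), sd_delta = 0.4)
  sim <- simulate_marmot_like(cfg)
  t1 <- sim$data$trait1
  t1$my <- paste(t1$individual, t1$context)
  fit <- lme4::lmer(value ~ 1 + (1 | context) + (1 | my), data = t1)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_year <- vc$sdcor[vc$grp == "context"]
  sd_mother <- vc$sdcor[vc$grp == "my"]
  sd_res <- vc$sdcor[vc$grp == "Residual"]
  expect_equal(sd_year, 0.4, tolerance = 0.5)
  expect_equal(sd_mother, cfg$sd_o1, tolerance = 0.2)
  expect_equal(sd_res, cfg$sd_within, tolerance = 0.1)
})

test_that("ground truth serializes to YAML", {
  sim <- simulate_intraindividual(tiny_cfg(seed = 13))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(sim$truth, path)
  y <- yaml::read_yaml(path)
  expect_equal(y$design, "intraindividual")
  expect_equal(y$n_individuals, sim$truth$n_individuals)
  expect_equal(unlist(y$params), sim$truth$params, tolerance = 1e-8)
})
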