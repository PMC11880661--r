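test_that("variant/family combinations are policed", {
  expect_s3_class(spec_hybrid_sim(), "crn_model_spec")
  expect_error(crn_model_spec("hybrid", c("poisson_log", "gaussian")),
               "unsupported")
  expect_error(crn_model_spec("full", c("gaussian", "poisson_log")),
               "unsupported")
  expect_error(crn_model_spec("hybrid", c("gaussian", "ordinal_logit")),
               "unsupported")
})

test_that("free parameter count matches the closed-form audit", {
  # expected count: P1 + P2 + P3 (+P3 full) + SDs (+deltas) + cutpoints +
  # year effects + latent pairs
  audit <- function(model) {
    cd <- model$cdata
    P <- ncol(cd$X1) + ncol(cd$X2) + ncol(cd$X3)
    n_sd <- switch(cd$variant, 3, 2, 2, 2, 4)
    extra <- 0
    if (cd$variant == 5) extra <- extra + ncol(cd$X3)
    if (cd$variant != 5) {
      n_sd <- n_sd + cd$has_d1 + cd$has_d2
      extra <- extra + (cd$has_d1 + cd$has_d2) * cd$n_year
    }
    if (cd$variant == 3) extra <- extra + cd$K - 1
    n_u <- switch(cd$variant, 2 * cd$M, cd$M, cd$M, 0, 2 * cd$M)
    P + n_sd + extra + n_u
  }
  sims <- list(
    crn_build(spec_hybrid_sim(), simulate_intergenerational(tiny_cfg(1))$data),
    crn_build(spec_nonrep_sim(), simulate_intraindividual(tiny_cfg(2))$data),
    crn_build(spec_nonrep_gg(year_effects = c(TRUE, TRUE)),
              make_gg_sim(tiny_cfg(3))$data),
    crn_build(spec_full_sim(), make_full_sim(seed = 4)$data))
  sheep <- simulate_sheep_like(tiny_cfg(5))
  sims <- c(sims, list(crn_build(sheep_preset(sheep$data), sheep$data)))
  for (m in sims) expect_equal(m$layout$npar, audit(m))
})

test_that("specs are pure data: rebuilding yields structurally identical models", {
  sim <- simulate_intraindividual(tiny_cfg(6))
  m1 <- crn_build(spec_nonrep_sim(), sim$data)
  m2 <- crn_build(spec_nonrep_sim(), sim$data)
  expect_identical(m1$cdata, m2$cdata)
  expect_identical(m1$par_names, m2$par_names)
})

test_that("structural invariants are enforced at build time", {
  inter <- simulate_intergenerational(tiny_cfg(7))$data
  intra <- simulate_intraindividual(tiny_cfg(7))$data
  expect_error(crn_build(spec_nonrep_sim(), inter), "non_repeated")
  # hybrid on single-measure data builds (trait1 repetition is allowed, not
  # required structurally) but duplicate trait-2 rows are rejected
  bad <- inter
  bad$trait2 <- rbind(bad$trait2, bad$trait2[1, ])
  expect_error(trait_dataset(bad$trait1, bad$trait2, bad$contexts,
                             design = "hybrid",
                             families = bad$families),
               "duplicate")
  expect_error(crn_build(spec_full_sim(), intra), "full variant")
})

test_that("degenerate and malformed responses are refused", {
  sim <- simulate_intraindividual(tiny_cfg(8))
  flat <- sim$data
  flat$trait1$value <- 1.5
  expect_error(crn_build(spec_nonrep_sim(), flat), "degenerate")
  neg <- sim$data
  neg$trait2$value[1] <- -2
  expect_error(crn_build(spec_nonrep_sim(), neg), "nonnegative")
  frac <- sim$data
  frac$trait2$value[1] <- 2.5
  expect_error(crn_build(spec_nonrep_sim(), frac), "nonnegative")
})

test_that("rank-deficient designs are reported with the collinear column", {
  sim <- simulate_intraindividual(tiny_cfg(9))
  d <- sim$data
  d$trait1$climate2 <- 2 * d$trait1$climate
  spec <- crn_model_spec("non_repeated", c("gaussian", "poisson_log"),
                         covariates1 = c("climate", "climate2"),
                         covariates2 = "climate",
                         covariates_corr = "climate", standardize = FALSE)
  expect_error(crn_build(spec, d), "collinear.*climate2")
})

test_that("marmot preset matches its published structure", {
  sim <- simulate_marmot_like(tiny_cfg(10))
  spec <- marmot_preset(sim$data)
  expect_equal(spec$variant, "hybrid")
  expect_setequal(spec$covariates_corr, c("snow", "june_temperature"))
  expect_false("june_temperature" %in% spec$covariates2)
  expect_true("june_temperature" %in% spec$covariates1)
  expect_true(all(spec$year_effects))
  m <- crn_build(spec, sim$data)
  expect_setequal(colnames(m$cdata$X3),
                  c("(Intercept)", "snow", "june_temperature"))
  bad <- sim$data
  bad$trait1$snow <- NULL
  expect_error(marmot_preset(bad), "missing covariate.*snow")
})

test_that("sheep preset matches its published structure", {
  sim <- simulate_sheep_like(tiny_cfg(11))
  spec <- sheep_preset(sim$data)
  expect_equal(spec$families, c("ordinal_logit", "gaussian"))
  expect_equal(spec$n_categories, 3L)
  expect_setequal(spec$covariates1,
                  c("log_mass_prev", "age", "age2", "density"))
  expect_true("nao" %in% spec$covariates2)
  expect_setequal(spec$covariates_corr, c("nao", "density"))
  m <- crn_build(spec, sim$data)
  # ordinal identifiability: trait-1 intercept absorbed by the thresholds
  expect_false("(Intercept)" %in% colnames(m$cdata$X1))
  expect_true("theta_2" %in% m$par_names)
})

test_that("model specs round-trip through YAML", {
  sim <- simulate_sheep_like(tiny_cfg(12))
  spec <- sheep_preset(sim$data)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back, spec)
})

test_that("internal standardization is invariant to affine covariate recoding", {
  sim <- simulate_intraindividual(tiny_cfg(13))
  m1 <- crn_build(spec_nonrep_sim(standardize = TRUE), sim$data)
  rec <- sim$data
  rec$trait1$climate <- 3 + 2 * rec$trait1$climate
  rec$trait2$climate <- 3 + 2 * rec$trait2$climate
  rec$contexts$climate <- 3 + 2 * rec$contexts$climate
  m2 <- crn_build(spec_nonrep_sim(standardize = TRUE), rec)
  expect_equal(m1$cdata$X1, m2$cdata$X1)
  expect_equal(m1$cdata$X3, m2$cdata$X3)
})
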