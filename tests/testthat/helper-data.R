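# Shared fixtures: all data are generated in code, never stored on disk.

tiny_cfg <- function(seed = 1, ...) {
  sim_config(n_years = 8, recruits_per_year = 6, seed = seed, ...)
}

spec_hybrid_sim <- function(standardize = FALSE) {
  crn_model_spec("hybrid", c("gaussian", "poisson_log_trunc"),
                 covariates1 = "climate", covariates2 = "climate",
                 covariates_corr = "climate", standardize = standardize)
}

spec_nonrep_sim <- function(standardize = FALSE) {
  crn_model_spec("non_repeated", c("gaussian", "poisson_log"),
                 covariates1 = "climate", covariates2 = "climate",
                 covariates_corr = "climate", standardize = standardize)
}

spec_nonrep_gg <- function(standardize = FALSE, year_effects = c(FALSE, FALSE)) {
  crn_model_spec("non_repeated", c("gaussian", "gaussian"),
                 covariates1 = "climate", covariates2 = "climate",
                 covariates_corr = "climate", year_effects = year_effects,
                 standardize = standardize)
}

# bivariate-Gaussian non-repeated dataset built from the engine's latents
make_gg_sim <- function(cfg = tiny_cfg(), seed = 1) {
  sim <- simulate_intraindividual(cfg, seed)
  my <- sim$truth$mother_year
  t2 <- sim$data$trait2
  t2$value <- 0.1 + cfg$beta_mu2 * my$climate + my$o2
  data <- trait_dataset(sim$data$trait1, t2, sim$data$contexts,
                        design = "non_repeated",
                        families = c("gaussian", "gaussian"),
                        trait_names = c("growth", "condition"))
  truth <- sim$truth
  truth$params <- c("b1_(Intercept)" = cfg$intercept_mu1,
                    "b1_climate" = cfg$beta_mu1,
                    "b2_(Intercept)" = 0.1, "b2_climate" = cfg$beta_mu2,
                    "br_(Intercept)" = cfg$beta_r[1],
                    "br_climate" = cfg$beta_r[2],
                    "sigma_o1" = cfg$sd_o1, "sigma_o2" = cfg$sd_o2)
  list(data = data, truth = truth)
}

# paired repeated-measures Gaussian dataset with separate among- and
# within-individual correlation reaction norms (full-variant fixture)
make_full_sim <- function(n_years = 8, n_ind = 15, n_rep = 4,
                          beta_ra = c(0.2, 0.6), beta_re = c(-0.3, -0.4),
                          sds = c(sa1 = 0.6, sa2 = 0.5, se1 = 0.4, se2 = 0.5),
                          seed = 1) {
  set.seed(seed)
  clim <- rnorm(n_years)
  rows <- vector("list", n_years * n_ind)
  k <- 0
  for (y in seq_len(n_years)) {
    ra <- tanh(beta_ra[1] + beta_ra[2] * clim[y])
    re <- tanh(beta_re[1] + beta_re[2] * clim[y])
    for (i in seq_len(n_ind)) {
      u <- rnorm(2)
      a1 <- sds["sa1"] * u[1]
      a2 <- sds["sa2"] * (ra * u[1] + sqrt(1 - ra^2) * u[2])
      e1 <- rnorm(n_rep)
      e2 <- re * e1 + sqrt(1 - re^2) * rnorm(n_rep)
      k <- k + 1
      rows[[k]] <- data.frame(
        individual = sprintf("i%03d", i), context = sprintf("y%03d", y),
        climate = clim[y],
        v1 = 0.2 * clim[y] + a1 + sds["se1"] * e1,
        v2 = -0.1 + 0.1 * clim[y] + a2 + sds["se2"] * e2)
    }
  }
  df <- do.call(rbind, rows)
  ctx <- data.frame(context = sprintf("y%03d", seq_len(n_years)),
                    climate = clim)
  data <- trait_dataset(
    data.frame(individual = df$individual, context = df$context,
               value = df$v1, climate = df$climate),
    data.frame(individual = df$individual, context = df$context,
               value = df$v2, climate = df$climate),
    ctx, design = "full", families = c("gaussian", "gaussian"))
  params <- c("b1_(Intercept)" = 0, "b1_climate" = 0.2,
              "b2_(Intercept)" = -0.1, "b2_climate" = 0.1,
              "br_(Intercept)" = beta_ra[1], "br_climate" = beta_ra[2],
              "br_eps_(Intercept)" = beta_re[1], "br_eps_climate" = beta_re[2],
              "sigma_alpha1" = unname(sds["sa1"]),
              "sigma_alpha2" = unname(sds["sa2"]),
              "sigma_eps1" = unname(sds["se1"]),
              "sigma_eps2" = unname(sds["se2"]))
  list(data = data, params = params)
}

spec_full_sim <- function(standardize = FALSE) {
  crn_model_spec("full", c("gaussian", "gaussian"),
                 covariates1 = "climate", covariates2 = "climate",
                 covariates_corr = "climate", standardize = standardize)
}

# relative gradient discrepancy against numerical differentiation
grad_discrepancy <- function(model, q, prior_only = FALSE) {
  res <- crn_lp(model, q, prior_only)
  ng <- numDeriv::grad(function(z) crn_lp(model, z, prior_only)$lp, q)
  max(abs(res$grad - ng) / pmax(1, abs(ng)))
}
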