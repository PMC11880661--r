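#' Configuration for the individual-based simulator
#'
#' Defaults reproduce the validation world: 30 years of data, 25 new
#' individuals entering per year (750 individuals in total), a mean
#' fecundity of 2.5 offspring per individual-year, and annual survival 0.6.
#' The among-individual correlation between the two traits is a linear
#' function of a yearly climate covariate on the atanh scale:
#' `r(C) = tanh(beta_r[1] + beta_r[2] * climate(C))`.
#'
#' The fecundity intercept is set to `log(mean_fecundity) - sd_o2^2 / 2`, so
#' that `mean_fecundity` is the marginal mean offspring count per
#' individual-year at baseline climate, marginal over the lognormal latent.
#'
#' @param n_years number of sampling years (contexts).
#' @param recruits_per_year new individuals entering each year.
#' @param mean_fecundity marginal mean offspring count at baseline climate.
#' @param annual_survival yearly survival probability.
#' @param beta_mu1,beta_mu2 climate effects on the trait-1 / trait-2 linear
#'   predictors.
#' @param beta_r length-2 (intercept, slope) of the correlation reaction
#'   norm on the atanh scale.
#' @param sd_o1,sd_o2 latent-effect standard deviations (trait 1, trait 2).
#' @param sd_within within-litter residual SD (hybrid design only).
#' @param intercept_mu1 trait-1 intercept (traits are on a standardized
#'   scale, so 0 by default).
#' @param climate_dist `"normal"` (standard normal per year, the
#'   standardized-predictor convention) or `"constant"`.
#' @param climate_value the fixed value used when `climate_dist="constant"`.
#' @param seed integer RNG seed.
#' @param ... additional fields stored verbatim (used by the marmot/sheep
#'   lookalike generators, e.g. `thresholds`, `sd_delta`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_years = 30, recruits_per_year = 25,
                       mean_fecundity = 2.5, annual_survival = 0.6,
                       beta_mu1 = 0.3, beta_mu2 = 0.2,
                       beta_r = c(-0.3, 0.7),
                       sd_o1 = 0.5, sd_o2 = 0.5, sd_within = 0.5,
                       intercept_mu1 = 0,
                       climate_dist = c("normal", "constant"),
                       climate_value = 0, seed = 1L, ...) {
  climate_dist <- match.arg(climate_dist)
  cfg <- c(list(n_years = as.integer(n_years),
                recruits_per_year = as.integer(recruits_per_year),
                mean_fecundity = mean_fecundity,
                annual_survival = annual_survival,
                beta_mu1 = beta_mu1, beta_mu2 = beta_mu2, beta_r = beta_r,
                sd_o1 = sd_o1, sd_o2 = sd_o2, sd_within = sd_within,
                intercept_mu1 = intercept_mu1,
                climate_dist = climate_dist, climate_value = climate_value,
                seed = as.integer(seed)),
           list(...))
  stopifnot(cfg$n_years >= 1, cfg$recruits_per_year >= 1,
            cfg$mean_fecundity > 0,
            cfg$annual_survival >= 0, cfg$annual_survival <= 1,
            cfg$sd_o1 > 0, cfg$sd_o2 > 0, cfg$sd_within > 0,
            length(cfg$beta_r) == 2)
  class(cfg) <- "sim_config"
  cfg
}

# One RNG substream per year: reseeding with a fixed per-year offset keeps
# early years byte-identical under config edits that only affect later years.
year_seed <- function(seed, year, salt = 0L) {
  as.integer((as.double(seed) + 7919 * year + 104729 * salt) %% 2147483629)
}

ctx_id <- function(year) sprintf("y%03d", year)
ind_id <- function(i) sprintf("i%05d", i)

draw_climate <- function(cfg) {
  if (cfg$climate_dist == "constant") cfg$climate_value else rnorm(1)
}

# correlated latent pair, exact construction from independent N(0,1)
draw_latents <- function(n, r, sd1, sd2) {
  u1 <- rnorm(n); u2 <- rnorm(n)
  list(o1 = sd1 * u1, o2 = sd2 * (r * u1 + sqrt(1 - r^2) * u2))
}

new_ground_truth <- function(config, design, contexts, r_true, params,
                             mother_year, roster) {
  structure(list(config = config, design = design, contexts = contexts,
                 r_true = r_true, params = params,
                 mother_year = mother_year, roster = roster,
                 n_individuals = nrow(roster)),
            class = "crn_ground_truth")
}

#' @export
print.crn_ground_truth <- function(x, ...) {
  cat(sprintf("<crn_ground_truth> %s design, %d individuals, %d contexts\n",
              x$design, x$n_individuals, nrow(x$contexts)))
  print(round(x$params, 3))
  invisible(x)
}

#' Simulate an intergenerational (offspring quantity-quality) dataset
#'
#' Individual-based simulation of a hybrid sampling design.  Each year,
#' `recruits_per_year` new mothers enter; every living mother draws a
#' bivariate latent pair `(o1, o2)` whose correlation is
#' `tanh(beta_r[1] + beta_r[2] * climate)`; her litter size is Poisson on the
#' log scale with the climate effect and `o2` in the predictor; each
#' offspring's mass is Gaussian around the climate effect plus `o1`; mothers
#' then survive with probability `annual_survival`.  A litter of zero is
#' recorded as no reproductive event that year, so recorded litter sizes are
#' zero-truncated (the dataset's trait-2 family is `poisson_log_trunc`).
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list with elements `data` (a hybrid-design [trait_dataset()]:
#'   trait 1 = offspring mass, repeated within mother-year; trait 2 = litter
#'   size, one per mother-year) and `truth` (ground-truth parameters, per
#'   mother-year latent effects, and the full demographic roster).
#' @export
simulate_intergenerational <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- seed %||% cfg$seed
  eng <- simulate_engine(cfg, seed)
  my <- eng$mother_year
  rec <- my[my$litter >= 1, , drop = FALSE]

  n_off <- sum(rec$litter)
  t1 <- tibble::tibble(
    individual = rep(rec$individual, rec$litter),
    context = rep(rec$context, rec$litter),
    value = NA_real_,
    climate = rep(rec$climate, rec$litter))
  mass_mu <- cfg$intercept_mu1 + cfg$beta_mu1 * t1$climate +
    rep(rec$o1, rec$litter)
  # per-year substream for offspring masses
  masses <- numeric(n_off)
  yr_of <- rep(rec$year, rec$litter)
  for (y in unique(yr_of)) {
    set.seed(year_seed(seed, y, salt = 5L))
    idx <- which(yr_of == y)
    masses[idx] <- rnorm(length(idx), mass_mu[idx], cfg$sd_within)
  }
  t1$value <- masses

  t2 <- tibble::tibble(individual = rec$individual, context = rec$context,
                       value = as.numeric(rec$litter), climate = rec$climate)
  data <- trait_dataset(t1, t2, eng$contexts, design = "hybrid",
                        families = c("gaussian", "poisson_log_trunc"),
                        trait_names = c("offspring_mass", "litter_size"))
  params <- c("b1_(Intercept)" = cfg$intercept_mu1,
              "b1_climate" = cfg$beta_mu1,
              "b2_(Intercept)" = log(cfg$mean_fecundity) - cfg$sd_o2^2 / 2,
              "b2_climate" = cfg$beta_mu2,
              "br_(Intercept)" = cfg$beta_r[1],
              "br_climate" = cfg$beta_r[2],
              "sigma_alpha1" = cfg$sd_o1, "sigma_o2" = cfg$sd_o2,
              "sigma_eps1" = cfg$sd_within)
  truth <- new_ground_truth(cfg, "intergenerational", eng$contexts,
                            eng$r_true, params, my, eng$roster)
  list(data = data, truth = truth)
}

#' Simulate an intraindividual (fecundity-growth) dataset
#'
#' Same demographic engine as [simulate_intergenerational()], but each
#' individual-year yields exactly one Gaussian growth measurement
#' (`intercept + beta_mu1 * climate + o1`) and one Poisson fecundity count,
#' with the correlation between the latent pair `(o1, o2)` injected at the
#' observation level.  All individual-years are recorded (fecundity may be
#' zero), matching a non-repeated-measures sampling design.
#'
#' @inheritParams simulate_intergenerational
#' @return list with `data` (non-repeated [trait_dataset()]: trait 1 =
#'   growth, trait 2 = fecundity) and `truth`.
#' @export
simulate_intraindividual <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- seed %||% cfg$seed
  eng <- simulate_engine(cfg, seed)
  my <- eng$mother_year
  t1 <- tibble::tibble(individual = my$individual, context = my$context,
                       value = cfg$intercept_mu1 + cfg$beta_mu1 * my$climate +
                         my$o1,
                       climate = my$climate)
  t2 <- tibble::tibble(individual = my$individual, context = my$context,
                       value = as.numeric(my$fecundity), climate = my$climate)
  data <- trait_dataset(t1, t2, eng$contexts, design = "non_repeated",
                        families = c("gaussian", "poisson_log"),
                        trait_names = c("growth", "fecundity"))
  params <- c("b1_(Intercept)" = cfg$intercept_mu1,
              "b1_climate" = cfg$beta_mu1,
              "b2_(Intercept)" = log(cfg$mean_fecundity) - cfg$sd_o2^2 / 2,
              "b2_climate" = cfg$beta_mu2,
              "br_(Intercept)" = cfg$beta_r[1],
              "br_climate" = cfg$beta_r[2],
              "sigma_o1" = cfg$sd_o1, "sigma_o2" = cfg$sd_o2)
  truth <- new_ground_truth(cfg, "intraindividual", eng$contexts,
                            eng$r_true, params, my, eng$roster)
  list(data = data, truth = truth)
}

# Shared demographic engine: tracks the population year by year and draws
# the latent pairs, fecundity counts and survival for every individual-year.
simulate_engine <- function(cfg, seed) {
  Y <- cfg$n_years
  fec_icpt <- log(cfg$mean_fecundity) - cfg$sd_o2^2 / 2
  alive <- integer(0)
  entry <- integer(0)     # entry year, indexed by individual
  exit <- integer(0)
  next_id <- 1L
  climate <- numeric(Y)
  rows <- vector("list", Y)
  for (y in seq_len(Y)) {
    set.seed(year_seed(seed, y))
    newc <- seq.int(next_id, next_id + cfg$recruits_per_year - 1L)
    next_id <- next_id + cfg$recruits_per_year
    entry[newc] <- y
    exit[newc] <- y
    alive <- c(alive, newc)
    climate[y] <- draw_climate(cfg)
    r_y <- tanh(cfg$beta_r[1] + cfg$beta_r[2] * climate[y])
    n <- length(alive)
    lat <- draw_latents(n, r_y, cfg$sd_o1, cfg$sd_o2)
    lambda <- exp(fec_icpt + cfg$beta_mu2 * climate[y] + lat$o2)
    fec <- rpois(n, lambda)
    surv <- if (y < Y) rbinom(n, 1, cfg$annual_survival) else rep(NA_integer_, n)
    rows[[y]] <- data.frame(
      individual = ind_id(alive), year = y, context = ctx_id(y),
      climate = climate[y], o1 = lat$o1, o2 = lat$o2,
      fecundity = fec, litter = fec, survived = surv)
    if (y < Y) {
      exit[alive] <- y
      alive <- alive[surv == 1L]
      exit[alive] <- y + 1L
    } else {
      exit[alive] <- y
    }
  }
  mother_year <- do.call(rbind, rows)
  contexts <- tibble::tibble(context = ctx_id(seq_len(Y)), climate = climate)
  roster <- tibble::tibble(individual = ind_id(seq_len(next_id - 1L)),
                           entry = entry, exit = exit)
  r_true <- tanh(cfg$beta_r[1] + cfg$beta_r[2] * climate)
  list(mother_year = tibble::as_tibble(mother_year), contexts = contexts,
       roster = roster, r_true = r_true)
}

#' Simulate a marmot-like intergenerational dataset
#'
#' Synthetic lookalike of a high-altitude rodent system: a hybrid design
#' with repeated offspring-mass measurements per mother-year and a single
#' litter-size count, two context covariates (winter `snow` and
#' `june_temperature`) driving the correlation reaction norm, mother-level
#' covariates (`age`, `age2`, `mother_mass`) on both trait means, and year
#' random effects on both traits.  `june_temperature` is excluded from the
#' fecundity predictor (pregnancies predate it).
#'
#' @inheritParams simulate_intergenerational
#' @details Effect sizes can be overridden through `sim_config(...)` extras
#'   `beta1` (mass: snow, june_temperature, age, age2, mother_mass),
#'   `beta2` (litter size: snow, age, age2, mother_mass), `beta_r3`
#'   (correlation: intercept, snow, june_temperature) and `sd_delta`.
#' @return list with `data` (hybrid [trait_dataset()]) and `truth`.
#' @export
simulate_marmot_like <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- seed %||% cfg$seed
  beta1 <- cfg$beta1 %||% c(snow = 0.2, june_temperature = -0.2, age = 0.1,
                            age2 = -0.1, mother_mass = 0.3)
  beta2 <- cfg$beta2 %||% c(snow = 0.15, age = 0.1, age2 = -0.1,
                            mother_mass = 0.2)
  beta_r3 <- cfg$beta_r3 %||% c(-0.3, 0.4, -0.4)
  sd_delta <- cfg$sd_delta %||% 0.2
  Y <- cfg$n_years
  fec_icpt <- log(cfg$mean_fecundity) - cfg$sd_o2^2 / 2

  alive <- integer(0); entry <- integer(0); next_id <- 1L
  snow <- numeric(Y); june <- numeric(Y)
  set.seed(year_seed(seed, 0L, salt = 9L))
  d1 <- rnorm(Y, 0, sd_delta); d2 <- rnorm(Y, 0, sd_delta)
  t1_rows <- list(); t2_rows <- list(); r_true <- numeric(Y)
  for (y in seq_len(Y)) {
    set.seed(year_seed(seed, y, salt = 1L))
    newc <- seq.int(next_id, next_id + cfg$recruits_per_year - 1L)
    next_id <- next_id + cfg$recruits_per_year
    entry[newc] <- y
    alive <- c(alive, newc)
    snow[y] <- rnorm(1); june[y] <- rnorm(1)
    r_y <- tanh(beta_r3[1] + beta_r3[2] * snow[y] + beta_r3[3] * june[y])
    r_true[y] <- r_y
    n <- length(alive)
    age <- y - entry[alive] + 1
    age_s <- (age - 2.5) / 1.5          # roughly centred/scaled
    mmass <- rnorm(n)
    lat <- draw_latents(n, r_y, cfg$sd_o1, cfg$sd_o2)
    eta2 <- fec_icpt + d2[y] + beta2["snow"] * snow[y] + beta2["age"] * age_s +
      beta2["age2"] * age_s^2 + beta2["mother_mass"] * mmass + lat$o2
    litter <- rpois(n, exp(eta2))
    keep <- which(litter >= 1)
    if (length(keep)) {
      mu1 <- cfg$intercept_mu1 + d1[y] + beta1["snow"] * snow[y] +
        beta1["june_temperature"] * june[y] + beta1["age"] * age_s +
        beta1["age2"] * age_s^2 + beta1["mother_mass"] * mmass
      t2_rows[[y]] <- tibble::tibble(
        individual = ind_id(alive[keep]), context = ctx_id(y),
        value = as.numeric(litter[keep]), snow = snow[y],
        june_temperature = june[y], age = age_s[keep],
        age2 = age_s[keep]^2, mother_mass = mmass[keep])
      reps <- litter[keep]
      t1_rows[[y]] <- tibble::tibble(
        individual = rep(ind_id(alive[keep]), reps), context = ctx_id(y),
        value = rnorm(sum(reps), rep(mu1[keep] + lat$o1[keep], reps),
                      cfg$sd_within),
        snow = snow[y], june_temperature = june[y],
        age = rep(age_s[keep], reps), age2 = rep(age_s[keep]^2, reps),
        mother_mass = rep(mmass[keep], reps))
    }
    if (y < Y) {
      surv <- rbinom(n, 1, cfg$annual_survival)
      alive <- alive[surv == 1L]
    }
  }
  contexts <- tibble::tibble(context = ctx_id(seq_len(Y)), snow = snow,
                             june_temperature = june)
  data <- trait_dataset(do.call(rbind, t1_rows), do.call(rbind, t2_rows),
                        contexts, design = "hybrid",
                        families = c("gaussian", "poisson_log_trunc"),
                        trait_names = c("offspring_mass", "litter_size"))
  roster <- tibble::tibble(individual = ind_id(seq_len(next_id - 1L)),
                           entry = entry, exit = NA_integer_)
  params <- c("br_(Intercept)" = beta_r3[1], "br_snow" = beta_r3[2],
              "br_june_temperature" = beta_r3[3],
              "sigma_alpha1" = cfg$sd_o1, "sigma_o2" = cfg$sd_o2,
              "sigma_eps1" = cfg$sd_within, "sigma_delta1" = sd_delta,
              "sigma_delta2" = sd_delta)
  truth <- new_ground_truth(cfg, "marmot_like", contexts, r_true, params,
                            NULL, roster)
  truth$delta1 <- d1; truth$delta2 <- d2
  list(data = data, truth = truth)
}

#' Simulate a Soay-sheep-like intraindividual dataset
#'
#' Synthetic lookalike of an island ungulate system: a non-repeated design
#' where trait 1 is an ordinal fecundity (0, 1 or 2 lambs) generated from a
#' cumulative-logit latent, trait 2 is Gaussian log mass, context covariates
#' `nao` (winter North Atlantic Oscillation) and `density` drive the
#' correlation reaction norm, and both traits carry year random effects.
#'
#' @inheritParams simulate_intergenerational
#' @details Overridable `sim_config(...)` extras: `thresholds` (strictly
#'   increasing cumulative-logit cutpoints, default `c(-1, 2)`), `beta1`
#'   (fecundity: log_mass_prev, age, age2, density), `beta2` (mass: same +
#'   nao), `beta_r3` (correlation: intercept, nao, density), `sd_delta`.
#' @return list with `data` (non-repeated [trait_dataset()], trait-1 family
#'   `ordinal_logit`) and `truth`.
#' @export
simulate_sheep_like <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  seed <- seed %||% cfg$seed
  thr <- cfg$thresholds %||% c(-1, 2)
  if (length(thr) < 2 || any(diff(thr) <= 0)) {
    stop("ordinal thresholds must be strictly increasing", call. = FALSE)
  }
  beta1 <- cfg$beta1 %||% c(log_mass_prev = 0.4, age = 0.2, age2 = -0.15,
                            density = -0.2)
  beta2 <- cfg$beta2 %||% c(log_mass_prev = 0.5, age = 0.2, age2 = -0.15,
                            density = -0.1, nao = -0.1)
  beta_r3 <- cfg$beta_r3 %||% c(-0.3, 0.3, 0.3)
  sd_delta <- cfg$sd_delta %||% 0.2
  Y <- cfg$n_years

  alive <- integer(0); entry <- integer(0); next_id <- 1L
  nao <- numeric(Y); dens <- numeric(Y)
  set.seed(year_seed(seed, 0L, salt = 13L))
  d1 <- rnorm(Y, 0, sd_delta); d2 <- rnorm(Y, 0, sd_delta)
  t1_rows <- list(); t2_rows <- list(); r_true <- numeric(Y)
  for (y in seq_len(Y)) {
    set.seed(year_seed(seed, y, salt = 2L))
    newc <- seq.int(next_id, next_id + cfg$recruits_per_year - 1L)
    next_id <- next_id + cfg$recruits_per_year
    entry[newc] <- y
    alive <- c(alive, newc)
    nao[y] <- rnorm(1); dens[y] <- rnorm(1)
    r_y <- tanh(beta_r3[1] + beta_r3[2] * nao[y] + beta_r3[3] * dens[y])
    r_true[y] <- r_y
    n <- length(alive)
    age <- y - entry[alive] + 1
    age_s <- (age - 2.5) / 1.5
    lmp <- rnorm(n, 0, 0.5)
    lat <- draw_latents(n, r_y, cfg$sd_o1, cfg$sd_o2)
    eta1 <- d1[y] + beta1["log_mass_prev"] * lmp + beta1["age"] * age_s +
      beta1["age2"] * age_s^2 + beta1["density"] * dens[y] + lat$o1
    # cumulative logit: P(y <= i) = plogis(theta_i - eta)
    pl <- vapply(thr, function(th) plogis(th - eta1), numeric(n))
    uu <- runif(n)
    fec <- rowSums(uu > pl)          # category in 0..K-1
    mu2 <- cfg$intercept_mu1 + d2[y] + beta2["log_mass_prev"] * lmp +
      beta2["age"] * age_s + beta2["age2"] * age_s^2 +
      beta2["density"] * dens[y] + beta2["nao"] * nao[y]
    t1_rows[[y]] <- tibble::tibble(
      individual = ind_id(alive), context = ctx_id(y),
      value = as.numeric(fec), log_mass_prev = lmp, age = age_s,
      age2 = age_s^2, density = dens[y], nao = nao[y])
    t2_rows[[y]] <- tibble::tibble(
      individual = ind_id(alive), context = ctx_id(y),
      value = mu2 + lat$o2, log_mass_prev = lmp, age = age_s,
      age2 = age_s^2, density = dens[y], nao = nao[y])
    if (y < Y) {
      surv <- rbinom(n, 1, cfg$annual_survival)
      alive <- alive[surv == 1L]
    }
  }
  contexts <- tibble::tibble(context = ctx_id(seq_len(Y)), nao = nao,
                             density = dens)
  data <- trait_dataset(do.call(rbind, t1_rows), do.call(rbind, t2_rows),
                        contexts, design = "non_repeated",
                        families = c("ordinal_logit", "gaussian"),
                        trait_names = c("fecundity", "log_mass"))
  roster <- tibble::tibble(individual = ind_id(seq_len(next_id - 1L)),
                           entry = entry, exit = NA_integer_)
  params <- c("br_(Intercept)" = beta_r3[1], "br_nao" = beta_r3[2],
              "br_density" = beta_r3[3],
              "sigma_o1" = cfg$sd_o1, "sigma_o2" = cfg$sd_o2,
              "theta_1" = thr[1], "theta_2" = thr[2])
  truth <- new_ground_truth(cfg, "sheep_like", contexts, r_true, params,
                            NULL, roster)
  truth$delta1 <- d1; truth$delta2 <- d2
  list(data = data, truth = truth)
}

#' Write simulator ground truth to YAML
#'
#' Records the generating configuration, parameter values and per-context
#' realized correlations, so a simulation run is fully reproducible and
#' recovery experiments can be re-read from disk.
#'
#' @param truth the `truth` element returned by a simulator.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "crn_ground_truth"))
  cfg <- unclass(truth$config)
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  yaml::write_yaml(list(
    design = truth$design,
    config = cfg,
    params = as.list(truth$params),
    contexts = as.list(truth$contexts),
    r_true = truth$r_true,
    n_individuals = truth$n_individuals), path, precision = 12)
  invisible(path)
}
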