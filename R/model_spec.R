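#' Prior specification for covariance reaction norm models
#'
#' Regularising defaults: Normal(0, 1) on intercepts and slopes (including
#' the correlation reaction norm coefficients), Exponential(rate 2) on all
#' standard deviations, and Normal(0, 2) on ordered cumulative-logit
#' thresholds.
#'
#' @param coef_location,coef_scale normal prior on regression coefficients.
#' @param sd_rate exponential prior rate on SD parameters.
#' @param threshold_scale normal prior SD on ordinal thresholds.
#' @return list of class `crn_priors`.
#' @export
crn_priors <- function(coef_location = 0, coef_scale = 1, sd_rate = 2,
                       threshold_scale = 2) {
  stopifnot(coef_scale > 0, sd_rate > 0, threshold_scale > 0)
  structure(list(coef_location = coef_location, coef_scale = coef_scale,
                 sd_rate = sd_rate, threshold_scale = threshold_scale),
            class = "crn_priors")
}

supported_families <- c("gaussian", "poisson_log", "poisson_log_trunc",
                        "ordinal_logit")

#' Declare a covariance reaction norm model
#'
#' A pure-data description of one model: the sampling-design variant, the
#' per-trait response families, which covariate columns enter each trait's
#' mean predictor and which context-level columns drive the correlation
#' reaction norm, optional year random effects, and priors.  Combine with a
#' dataset via [crn_build()].
#'
#' @param variant `"full"` (both traits repeated and paired within
#'   individual-context, with separate among- and within-individual
#'   correlation reaction norms), `"non_repeated"` (single measurement of
#'   each trait per individual-context; a single observation-level
#'   correlation), or `"hybrid"` (trait 1 repeated, trait 2 single).
#' @param families length-2 character; supported combinations:
#'   hybrid = gaussian + poisson_log(`_trunc`); non_repeated = gaussian +
#'   poisson_log(`_trunc`), ordinal_logit + gaussian, or gaussian +
#'   gaussian; full = gaussian + gaussian.  `poisson_log_trunc` is a
#'   zero-truncated Poisson for fecundity records that exist only when at
#'   least one offspring was produced.
#' @param covariates1,covariates2 character vectors of measurement-level
#'   covariate columns for each trait's mean (intercept added automatically,
#'   except for an ordinal trait whose intercept is absorbed by the
#'   thresholds).
#' @param covariates_corr character vector of context-table columns
#'   predicting the correlation on the atanh scale (intercept added).
#' @param year_effects length-2 logical: include a year (context) random
#'   effect in each trait's predictor.
#' @param n_categories number of ordinal categories (ordinal family only).
#' @param variance_model `"intercept_only"` (default; latent SDs constant
#'   across contexts, as no predictions are made on this variation) —
#'   placeholder for future covariate-dependent variance models.
#' @param standardize standardize continuous covariates internally (sample
#'   mean/SD of the supplied data); coefficient summaries can be mapped back
#'   with [coef_draws()].
#' @param priors a [crn_priors()].
#' @return list of class `crn_model_spec`.
#' @export
crn_model_spec <- function(variant = c("non_repeated", "hybrid", "full"),
                           families = c("gaussian", "poisson_log"),
                           covariates1 = character(),
                           covariates2 = character(),
                           covariates_corr = character(),
                           year_effects = c(FALSE, FALSE),
                           n_categories = 3L,
                           variance_model = "intercept_only",
                           standardize = TRUE,
                           priors = crn_priors()) {
  variant <- match.arg(variant)
  stopifnot(length(families) == 2, all(families %in% supported_families),
            length(year_effects) == 2, is.logical(year_effects),
            n_categories >= 2)
  if (variance_model != "intercept_only") {
    stop("only the intercept-only variance model is implemented",
         call. = FALSE)
  }
  if (is.na(variant_id(variant, families))) {
    stop(sprintf("unsupported variant/family combination: %s with %s + %s",
                 variant, families[1], families[2]), call. = FALSE)
  }
  structure(list(variant = variant, families = families,
                 covariates1 = covariates1, covariates2 = covariates2,
                 covariates_corr = covariates_corr,
                 year_effects = year_effects,
                 n_categories = as.integer(n_categories),
                 variance_model = variance_model,
                 standardize = standardize, priors = priors),
            class = "crn_model_spec")
}

variant_id <- function(variant, families) {
  pois <- c("poisson_log", "poisson_log_trunc")
  if (variant == "hybrid" && families[1] == "gaussian" &&
      families[2] %in% pois) return(1L)
  if (variant == "non_repeated") {
    if (families[1] == "gaussian" && families[2] %in% pois) return(2L)
    if (families[1] == "ordinal_logit" && families[2] == "gaussian") return(3L)
    if (families[1] == "gaussian" && families[2] == "gaussian") return(4L)
  }
  if (variant == "full" && all(families == "gaussian")) return(5L)
  NA_integer_
}

std_cols <- function(X, skip_intercept = TRUE) {
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (skip_intercept && colnames(X)[j] == "(Intercept)") next
    s <- sd(X[, j])
    if (s > 0) {
      ctr[j] <- mean(X[, j]); scl[j] <- s
      X[, j] <- (X[, j] - ctr[j]) / scl[j]
    }
  }
  list(X = X, center = ctr, scale = scl)
}

design_matrix <- function(df, covariates, intercept, what) {
  missing <- setdiff(covariates, names(df))
  if (length(missing)) {
    stop(sprintf("missing covariate column(s) for %s: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = if (intercept) 1 else NULL,
             as.matrix(df[covariates]))
  if (!intercept && !length(covariates)) {
    X <- matrix(0, nrow(df), 0)
  }
  storage.mode(X) <- "double"
  X
}

check_rank <- function(X, what) {
  if (!ncol(X)) return(invisible())
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design for %s; collinear column(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible()
}

#' Compile a model specification against a dataset
#'
#' Validates the variant's repeated-measures invariants, assembles the
#' design matrices (`X1`, `X2` at the measurement level, `X3` with one row
#' per context), builds the measurement-to-subject incidence structure, and
#' returns a fit-ready model object for [crn_fit()].  Latent effect pairs
#' are parameterised non-centred (raw standard-normal pairs scaled by the
#' SDs and rotated by the context correlation), which is essential for
#' Hamiltonian Monte Carlo geometry.
#'
#' @param spec a [crn_model_spec()].
#' @param data a [trait_dataset()].
#' @return list of class `crn_model`.
#' @export
crn_build <- function(spec, data) {
  stopifnot(inherits(spec, "crn_model_spec"), inherits(data, "trait_dataset"))
  vid <- variant_id(spec$variant, spec$families)
  t1 <- data$trait1; t2 <- data$trait2
  key1 <- paste(t1$individual, t1$context, sep = "\r")
  key2 <- paste(t2$individual, t2$context, sep = "\r")

  # structural invariants
  if (spec$variant %in% c("non_repeated")) {
    for (nm in c("trait1", "trait2")) {
      k <- if (nm == "trait1") key1 else key2
      if (anyDuplicated(k)) {
        stop(sprintf("non_repeated variant forbids repeated measures, but %s has duplicated (individual, context) rows",
                     nm), call. = FALSE)
      }
    }
    if (!setequal(key1, key2) || length(key1) != length(key2)) {
      stop("non_repeated variant requires the same (individual, context) set in both trait tables",
           call. = FALSE)
    }
    t2 <- t2[match(key1, key2), , drop = FALSE]
    key2 <- key1
  } else if (spec$variant == "hybrid") {
    if (anyDuplicated(key2)) {
      stop("hybrid variant requires at most one trait-2 measurement per (individual, context)",
           call. = FALSE)
    }
    if (anyNA(match(key1, key2))) {
      stop("hybrid variant: trait-1 measurements exist for (individual, context) pairs missing from trait2",
           call. = FALSE)
    }
  } else if (spec$variant == "full") {
    if (nrow(t1) != nrow(t2) || !all(key1 == key2)) {
      stop("full variant requires trait tables of equal length with pairwise-aligned (individual, context) rows",
           call. = FALSE)
    }
    if (!anyDuplicated(key1)) {
      stop("full variant requires repeated measures within (individual, context)",
           call. = FALSE)
    }
  }

  # response checks
  for (i in 1:2) {
    y <- if (i == 1) t1$value else t2$value
    fam <- spec$families[i]
    if (fam == "gaussian") {
      if (var(y) == 0) {
        stop(sprintf("trait %d is degenerate (zero variance); refusing to build",
                     i), call. = FALSE)
      }
    } else if (fam %in% c("poisson_log", "poisson_log_trunc")) {
      if (any(y < 0) || any(y != floor(y))) {
        stop(sprintf("trait %d: Poisson responses must be nonnegative integers",
                     i), call. = FALSE)
      }
      if (fam == "poisson_log_trunc" && any(y < 1)) {
        stop(sprintf("trait %d: zero-truncated Poisson responses must be >= 1",
                     i), call. = FALSE)
      }
    } else if (fam == "ordinal_logit") {
      if (any(!y %in% 0:(spec$n_categories - 1))) {
        stop(sprintf("trait %d: ordinal responses must lie in 0..%d",
                     i, spec$n_categories - 1), call. = FALSE)
      }
    }
  }

  ctx_levels <- as.character(data$contexts$context)
  X3 <- design_matrix(data$contexts, spec$covariates_corr, TRUE, "X3")
  ord1 <- spec$families[1] == "ordinal_logit"
  X1 <- design_matrix(t1, spec$covariates1, !ord1, "X1")
  X2 <- design_matrix(t2, spec$covariates2, TRUE, "X2")

  scal <- list(X1 = NULL, X2 = NULL, X3 = NULL)
  if (spec$standardize) {
    s1 <- std_cols(X1); s2 <- std_cols(X2); s3 <- std_cols(X3)
    X1 <- s1$X; X2 <- s2$X; X3 <- s3$X
    scal <- list(X1 = s1[-1], X2 = s2[-1], X3 = s3[-1])
  }
  check_rank(X1, "X1"); check_rank(X2, "X2"); check_rank(X3, "X3")

  cmatch <- function(ctx) match(as.character(ctx), ctx_levels) - 1L
  if (vid %in% c(1L, 5L)) {
    if (vid == 1L) {
      pair_key <- key2
      pair_ctx <- cmatch(t2$context)
      pair1 <- match(key1, key2) - 1L
    } else {
      pair_key <- unique(key1)
      pair1 <- match(key1, pair_key) - 1L
      pair_ctx <- cmatch(t1$context[match(pair_key, key1)])
    }
    M <- length(pair_key)
    yr1 <- cmatch(t1$context)
    yr2 <- if (vid == 1L) pair_ctx else cmatch(t2$context)
  } else {
    M <- nrow(t1)
    pair_key <- key1
    pair_ctx <- cmatch(t1$context)
    pair1 <- integer(nrow(t1))
    yr1 <- pair_ctx
    yr2 <- pair_ctx
  }

  has_d1 <- isTRUE(spec$year_effects[1])
  has_d2 <- isTRUE(spec$year_effects[2])
  if (vid == 5L && (has_d1 || has_d2)) {
    stop("year random effects are not implemented for the full variant",
         call. = FALSE)
  }
  pr <- spec$priors
  cdata <- list(
    variant = vid, prior_only = FALSE,
    trunc2 = spec$families[2] == "poisson_log_trunc",
    X1 = X1, X2 = X2, X3 = X3,
    y1 = as.numeric(t1$value), y2 = as.numeric(t2$value),
    pair1 = pair1, ctx = pair_ctx, yr1 = yr1, yr2 = yr2,
    K = spec$n_categories, n_year = length(ctx_levels),
    has_d1 = has_d1, has_d2 = has_d2, M = as.integer(M),
    coef_location = pr$coef_location, coef_scale = pr$coef_scale,
    sd_rate = pr$sd_rate, thr_scale = pr$threshold_scale)
  if (cdata$trunc2) {
    # record-selection integrals are shared by identical trait-2
    # predictor rows (e.g. all mothers of a year in the validation design)
    key <- do.call(paste, c(as.data.frame(cbind(X2, yr2)), sep = "\r"))
    ukey <- unique(key)
    cdata$trunc_grp <- match(key, ukey) - 1L
    cdata$n_trunc_grp <- length(ukey)
  } else {
    cdata$trunc_grp <- integer(0)
    cdata$n_trunc_grp <- 0L
  }
  lay <- cpp_layout(cdata)

  sd_names <- switch(vid,
    c("sigma_alpha1", "sigma_o2", "sigma_eps1"),
    c("sigma_o1", "sigma_o2"),
    c("sigma_o1", "sigma_o2"),
    c("sigma_o1", "sigma_o2"),
    c("sigma_alpha1", "sigma_alpha2", "sigma_eps1", "sigma_eps2"))
  if (vid != 5L) {
    if (has_d1) sd_names <- c(sd_names, "sigma_delta1")
    if (has_d2) sd_names <- c(sd_names, "sigma_delta2")
  }
  nm <- c(paste0("b1_", colnames(X1)),
          paste0("b2_", colnames(X2)),
          paste0("br_", colnames(X3)))
  if (vid == 5L) nm <- c(nm, paste0("br_eps_", colnames(X3)))
  nm <- c(nm, sd_names)
  if (vid == 3L) nm <- c(nm, paste0("theta_", seq_len(spec$n_categories - 1)))
  if (has_d1) nm <- c(nm, paste0("delta1_", ctx_levels))
  if (has_d2) nm <- c(nm, paste0("delta2_", ctx_levels))
  if (lay$nu1 > 0) nm <- c(nm, paste0("u1_", seq_len(lay$nu1)))
  if (lay$nu2 > 0) nm <- c(nm, paste0("u2_", seq_len(lay$nu2)))
  stopifnot(length(nm) == lay$npar)

  structure(list(spec = spec, data = data, cdata = cdata, layout = lay,
                 par_names = nm, sd_names = sd_names,
                 context_levels = ctx_levels, pair_key = pair_key,
                 scaling = scal),
            class = "crn_model")
}

#' @export
print.crn_model <- function(x, ...) {
  cat(sprintf("<crn_model> %s (%s + %s): %d + %d measurements, %d contexts, %d free parameters\n",
              x$spec$variant, x$spec$families[1], x$spec$families[2],
              length(x$cdata$y1), length(x$cdata$y2),
              nrow(x$cdata$X3), x$layout$npar))
  invisible(x)
}

#' Log posterior density and gradient of a compiled model
#'
#' Mainly for testing and diagnostics: evaluates the joint (unnormalised)
#' log posterior and its exact gradient at an unconstrained parameter
#' vector.
#'
#' @param model a `crn_model` from [crn_build()].
#' @param q unconstrained parameter vector of length `model$layout$npar`.
#' @param prior_only drop all likelihood terms.
#' @return list with `lp` and `grad`.
#' @export
crn_lp <- function(model, q, prior_only = FALSE) {
  cd <- model$cdata
  cd$prior_only <- prior_only
  cpp_lp_grad(cd, q)
}

#' Marmot-style hybrid model preset
#'
#' Fully configured hybrid specification for an intergenerational
#' quantity-quality analysis: Gaussian offspring mass with covariates
#' `snow`, `june_temperature`, `age`, `age2`, `mother_mass`; (truncated)
#' Poisson litter size with the same covariates except `june_temperature`
#' (pregnancies predate it); correlation reaction norm on `snow` and
#' `june_temperature`; year random effects on both traits.
#'
#' @param data a hybrid-design [trait_dataset()] providing the named
#'   covariate columns (e.g. from [simulate_marmot_like()]).
#' @return a [crn_model_spec()].
#' @export
marmot_preset <- function(data) {
  stopifnot(inherits(data, "trait_dataset"))
  need1 <- c("snow", "june_temperature", "age", "age2", "mother_mass")
  need2 <- setdiff(need1, "june_temperature")
  miss <- c(setdiff(need1, names(data$trait1)),
            setdiff(need2, names(data$trait2)),
            setdiff(c("snow", "june_temperature"), names(data$contexts)))
  if (length(miss)) {
    stop("marmot preset: missing covariate column(s): ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  fam2 <- if (data$families[2] == "poisson_log_trunc") "poisson_log_trunc"
          else "poisson_log"
  crn_model_spec(variant = "hybrid", families = c("gaussian", fam2),
                 covariates1 = need1, covariates2 = need2,
                 covariates_corr = c("snow", "june_temperature"),
                 year_effects = c(TRUE, TRUE))
}

#' Soay-sheep-style non-repeated model preset
#'
#' Non-repeated specification for an intraindividual fecundity-growth
#' analysis: cumulative-logit ordinal fecundity (3 categories) with
#' covariates `log_mass_prev`, `age`, `age2`, `density`; Gaussian mass with
#' the same covariates plus `nao`; correlation reaction norm on `nao` and
#' `density`; year random effects on both traits.
#'
#' @param data a non-repeated [trait_dataset()] providing the named
#'   covariate columns (e.g. from [simulate_sheep_like()]).
#' @return a [crn_model_spec()].
#' @export
sheep_preset <- function(data) {
  stopifnot(inherits(data, "trait_dataset"))
  need1 <- c("log_mass_prev", "age", "age2", "density")
  need2 <- c(need1, "nao")
  miss <- c(setdiff(need1, names(data$trait1)),
            setdiff(need2, names(data$trait2)),
            setdiff(c("nao", "density"), names(data$contexts)))
  if (length(miss)) {
    stop("sheep preset: missing covariate column(s): ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  crn_model_spec(variant = "non_repeated",
                 families = c("ordinal_logit", "gaussian"),
                 covariates1 = need1, covariates2 = need2,
                 covariates_corr = c("nao", "density"),
                 year_effects = c(TRUE, TRUE), n_categories = 3L)
}

#' Serialize a model specification to YAML
#'
#' @param spec a [crn_model_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "crn_model_spec"))
  yaml::write_yaml(list(
    variant = spec$variant, families = as.list(spec$families),
    covariates1 = as.list(spec$covariates1),
    covariates2 = as.list(spec$covariates2),
    covariates_corr = as.list(spec$covariates_corr),
    year_effects = as.list(spec$year_effects),
    n_categories = spec$n_categories,
    variance_model = spec$variance_model,
    standardize = spec$standardize,
    priors = unclass(spec$priors)), path)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' @param path file written by [write_model_spec()].
#' @return a [crn_model_spec()].
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  crn_model_spec(
    variant = y$variant, families = unlist(y$families),
    covariates1 = as.character(unlist(y$covariates1)),
    covariates2 = as.character(unlist(y$covariates2)),
    covariates_corr = as.character(unlist(y$covariates_corr)),
    year_effects = as.logical(unlist(y$year_effects)),
    n_categories = y$n_categories %||% 3L,
    variance_model = y$variance_model %||% "intercept_only",
    standardize = y$standardize %||% TRUE,
    priors = do.call(crn_priors, y$priors %||% list()))
}
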