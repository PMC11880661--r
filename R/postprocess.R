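#' Predict the correlation reaction norm over new contexts
#'
#' Pushes every posterior draw of the correlation coefficients through the
#' inverse link: `tanh(X3_new %*% beta_r)`.  Covariates in `newdata`
#' are given on the original (unstandardized) scale; the standardization
#' stored at build time is applied internally, so columns must match the
#' fitted correlation predictors by name.
#'
#' For non-repeated and hybrid designs the returned curve is the
#' observation-level correlation, not the among-individual correlation: it
#' blends among- and within-individual correlations weighted by
#' repeatability, and can differ in sign from the among-individual
#' correlation when repeatabilities are low (see
#' [observation_level_correlation()] and [hybrid_correlation()]).  The
#' print method restates this caveat.
#'
#' @param post a `crn_posterior`.
#' @param newdata data frame with one row per prediction point and one
#'   column per fitted correlation predictor.
#' @return data frame of class `correlation_curve`: `newdata` columns plus
#'   posterior `mean`, `median` and 50%/89% interval bounds of `r`; the full
#'   draw matrix is attached as attribute `"draws"`.
#' @export
predict_correlation <- function(post, newdata) {
  stopifnot(inherits(post, "crn_posterior"))
  model <- post$model
  cols <- colnames(model$cdata$X3)
  vars <- setdiff(cols, "(Intercept)")
  missing <- setdiff(vars, names(newdata))
  if (length(missing)) {
    stop("newdata lacks fitted correlation predictor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(newdata[vars]))[, cols, drop = FALSE]
  sc <- model$scaling$X3
  if (!is.null(sc)) {
    for (j in seq_along(cols)) X[, j] <- (X[, j] - sc$center[j]) / sc$scale[j]
  }
  br <- coef_draws(post)[, paste0("br_", cols), drop = FALSE]
  r_draws <- tanh(X %*% t(br))            # points x draws
  qs <- apply(r_draws, 1, quantile,
              probs = c(0.055, 0.25, 0.5, 0.75, 0.945), names = FALSE)
  out <- cbind(as.data.frame(newdata),
               data.frame(mean = rowMeans(r_draws), median = qs[3, ],
                          l89 = qs[1, ], l50 = qs[2, ], u50 = qs[4, ],
                          u89 = qs[5, ]))
  attr(out, "draws") <- r_draws
  attr(out, "level") <- if (model$spec$variant == "full") "among-individual"
                        else "observation-level"
  class(out) <- c("correlation_curve", class(out))
  out
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> (%s correlation)\n", attr(x, "level")))
  if (attr(x, "level") != "among-individual") {
    cat("note: under non-repeated/hybrid sampling this is the observation-level\n",
        "correlation; it equals the among-individual correlation only under\n",
        "high repeatability and may even differ in sign (sign-bias risk when\n",
        "sign(r_alpha) != sign(r_eps) and repeatabilities are low).\n", sep = "")
  }
  print(as.data.frame(x), ...)
  invisible(x)
}

# draw from a zero-truncated Poisson by inverse-CDF conditioning
rpois_trunc <- function(n, lambda) {
  u <- runif(n, exp(-lambda), 1)
  qpois(pmin(u, 1 - 1e-16), lambda)
}

# joint draw of (latent pair, count) conditional on the record existing
# (count >= 1): rejection on the plain model, so the replicated latents are
# correctly selection-tilted, matching the fitted record likelihood
draw_selected_pair <- function(M, r, s, sd1, sd2, mu2, max_iter = 200) {
  u1 <- rnorm(M); u2 <- rnorm(M)
  o1 <- sd1 * u1
  o2 <- sd2 * (r * u1 + s * u2)
  y <- rpois(M, exp(mu2 + o2))
  pending <- which(y == 0)
  it <- 0
  while (length(pending) && it < max_iter) {
    it <- it + 1
    n <- length(pending)
    v1 <- rnorm(n); v2 <- rnorm(n)
    no1 <- sd1 * v1
    no2 <- sd2 * (r[pending] * v1 + s[pending] * v2)
    ny <- rpois(n, exp(mu2[pending] + no2))
    ok <- ny >= 1
    acc <- pending[ok]
    o1[acc] <- no1[ok]; o2[acc] <- no2[ok]; y[acc] <- ny[ok]
    pending <- pending[!ok]
  }
  if (length(pending)) {  # pathological rates: fall back to truncated draws
    y[pending] <- rpois_trunc(length(pending), exp(mu2[pending] + o2[pending]))
  }
  list(o1 = o1, o2 = o2, y = y)
}

# simulate one replicate dataset from one posterior draw, redrawing latents
simulate_replicate <- function(model, par) {
  cd <- model$cdata
  vid <- cd$variant
  r <- tanh(as.vector(cd$X3 %*% par[paste0("br_", colnames(cd$X3))]))
  s <- sqrt(1 - r^2)
  d1 <- if (cd$has_d1) par[paste0("delta1_", model$context_levels)] else
    rep(0, cd$n_year)
  d2 <- if (cd$has_d2) par[paste0("delta2_", model$context_levels)] else
    rep(0, cd$n_year)
  xb1 <- if (ncol(cd$X1)) as.vector(cd$X1 %*% par[paste0("b1_", colnames(cd$X1))]) else
    rep(0, length(cd$y1))
  xb2 <- as.vector(cd$X2 %*% par[paste0("b2_", colnames(cd$X2))])
  ctx1 <- cd$ctx + 1L
  if (vid == 1L) {
    M <- cd$M
    mu2 <- xb2 + d2[cd$yr2 + 1L]
    if (cd$trunc2) {
      dr <- draw_selected_pair(M, r[ctx1], s[ctx1], par["sigma_alpha1"],
                               par["sigma_o2"], mu2)
      alpha <- dr$o1
      y2 <- dr$y
    } else {
      u1 <- rnorm(M); u2 <- rnorm(M)
      alpha <- par["sigma_alpha1"] * u1
      o2 <- par["sigma_o2"] * (r[ctx1] * u1 + s[ctx1] * u2)
      y2 <- rpois(M, exp(mu2 + o2))
    }
    # replicate trait-1 rows follow the *replicated* litter sizes: row
    # counts are outcomes, correlated with the latents, not fixed design.
    # Trait-1 covariates are constant within a pair in hybrid schemas, so
    # the pair's first observed row supplies the fixed effects.
    idx1 <- match(seq_len(M) - 1L, cd$pair1)
    base1 <- xb1[idx1] + d1[cd$ctx + 1L] + alpha
    reps <- ifelse(is.na(idx1), 0L, y2)
    mu1 <- rep(base1, reps)
    y1 <- rnorm(length(mu1), mu1, par["sigma_eps1"])
  } else if (vid == 2L) {
    n <- cd$M
    mu2 <- xb2 + d2[cd$yr2 + 1L]
    if (cd$trunc2) {
      dr <- draw_selected_pair(n, r[ctx1], s[ctx1], par["sigma_o1"],
                               par["sigma_o2"], mu2)
      o1 <- dr$o1
      y2 <- dr$y
    } else {
      u1 <- rnorm(n); u2 <- rnorm(n)
      o1 <- par["sigma_o1"] * u1
      o2 <- par["sigma_o2"] * (r[ctx1] * u1 + s[ctx1] * u2)
      y2 <- rpois(n, exp(mu2 + o2))
    }
    y1 <- xb1 + d1[cd$yr1 + 1L] + o1
  } else if (vid == 3L) {
    n <- cd$M
    u1 <- rnorm(n); u2 <- rnorm(n)
    o1 <- par["sigma_o1"] * u1
    o2 <- par["sigma_o2"] * (r[ctx1] * u1 + s[ctx1] * u2)
    eta1 <- xb1 + d1[cd$yr1 + 1L] + o1
    th <- par[grep("^theta_", names(par))]
    pl <- vapply(th, function(t) plogis(t - eta1), numeric(n))
    y1 <- rowSums(runif(n) > pl)
    y2 <- xb2 + d2[cd$yr2 + 1L] + o2
  } else if (vid == 4L) {
    n <- cd$M
    u1 <- rnorm(n); u2 <- rnorm(n)
    y1 <- xb1 + d1[cd$yr1 + 1L] + par["sigma_o1"] * u1
    y2 <- xb2 + d2[cd$yr2 + 1L] +
      par["sigma_o2"] * (r[ctx1] * u1 + s[ctx1] * u2)
  } else {
    M <- cd$M
    u1 <- rnorm(M); u2 <- rnorm(M)
    a1 <- par["sigma_alpha1"] * u1
    a2 <- par["sigma_alpha2"] * (r[ctx1] * u1 + s[ctx1] * u2)
    bre <- par[paste0("br_eps_", colnames(cd$X3))]
    re <- tanh(as.vector(cd$X3 %*% bre))
    se <- sqrt(1 - re^2)
    cobs <- ctx1[cd$pair1 + 1L]
    n <- length(cd$y1)
    e1 <- rnorm(n); e2 <- rnorm(n)
    y1 <- xb1 + a1[cd$pair1 + 1L] + par["sigma_eps1"] * e1
    y2 <- xb2 + a2[cd$pair1 + 1L] +
      par["sigma_eps2"] * (re[cobs] * e1 + se[cobs] * e2)
  }
  list(y1 = y1, y2 = y2)
}

#' Posterior predictive checks
#'
#' Replicates the dataset under the fitted model — one replicate per
#' retained draw (or an evenly spaced subsample), redrawing the latent
#' effects each time — and compares summary statistics (mean and SD per
#' trait, plus a count histogram for discrete families) between observed
#' and replicated data.  Two-sided tail probabilities near 0 or 1 flag
#' aspects of the data the model fails to reproduce.
#'
#' @param post a `crn_posterior`.
#' @param n_reps number of replicates; defaults to the number of retained
#'   draws and must not exceed it.
#' @return list of class `crn_ppc`: `stats` (per trait x statistic:
#'   observed value, replicated mean/SD, tail probabilities) and `histogram`
#'   (for discrete traits: observed vs replicated counts per value).
#' @export
posterior_predictive <- function(post, n_reps = NULL) {
  stopifnot(inherits(post, "crn_posterior"))
  model <- post$model
  d <- coef_draws(post, "fitted")
  total <- nrow(d)
  n_reps <- n_reps %||% total
  if (n_reps > total) {
    stop(sprintf("n_reps (%d) exceeds available draws (%d); subsample instead",
                 n_reps, total), call. = FALSE)
  }
  take <- unique(round(seq(1, total, length.out = n_reps)))
  obs <- list(y1 = model$cdata$y1, y2 = model$cdata$y2)
  stat_mat <- matrix(NA_real_, length(take), 4)
  discrete <- model$spec$families %in%
    c("poisson_log", "poisson_log_trunc", "ordinal_logit")
  hist_acc <- list()
  for (i in 1:2) {
    if (discrete[i]) {
      hist_acc[[i]] <- matrix(0, length(take), max(obs[[i]]) + 2)
    }
  }
  for (k in seq_along(take)) {
    rep_k <- simulate_replicate(model, d[take[k], ])
    stat_mat[k, ] <- c(mean(rep_k$y1), sd(rep_k$y1),
                       mean(rep_k$y2), sd(rep_k$y2))
    for (i in 1:2) {
      if (discrete[i]) {
        y <- pmin(rep_k[[i]], max(obs[[i]]) + 1)
        tb <- tabulate(y + 1, nbins = max(obs[[i]]) + 2)
        hist_acc[[i]][k, ] <- tb
      }
    }
  }
  obs_stats <- c(mean(obs$y1), sd(obs$y1), mean(obs$y2), sd(obs$y2))
  tail_p <- function(col, o) {
    c(p_lower = mean(col <= o), p_upper = mean(col >= o))
  }
  stats <- data.frame(
    trait = rep(model$data$trait_names, each = 2),
    statistic = rep(c("mean", "sd"), 2),
    observed = obs_stats,
    rep_mean = colMeans(stat_mat),
    rep_sd = apply(stat_mat, 2, sd))
  tp <- t(vapply(1:4, function(j) tail_p(stat_mat[, j], obs_stats[j]),
                 numeric(2)))
  stats$p_lower <- tp[, 1]; stats$p_upper <- tp[, 2]
  stats$p_two_sided <- 2 * pmin(stats$p_lower, stats$p_upper)
  hist_df <- NULL
  for (i in 1:2) {
    if (discrete[i]) {
      vals <- 0:(ncol(hist_acc[[i]]) - 1)
      oc <- tabulate(pmin(obs[[i]], max(obs[[i]]) + 1) + 1,
                     nbins = ncol(hist_acc[[i]]))
      hist_df <- rbind(hist_df, data.frame(
        trait = model$data$trait_names[i], value = vals, observed = oc,
        rep_mean = colMeans(hist_acc[[i]]),
        rep_l89 = apply(hist_acc[[i]], 2, quantile, 0.055),
        rep_u89 = apply(hist_acc[[i]], 2, quantile, 0.945)))
    }
  }
  structure(list(stats = stats, histogram = hist_df, n_reps = length(take)),
            class = "crn_ppc")
}

#' @export
print.crn_ppc <- function(x, ...) {
  cat(sprintf("<crn_ppc> %d replicates\n", x$n_reps))
  print(x$stats, digits = 3)
  invisible(x)
}

#' Compare a posterior against simulator ground truth
#'
#' One row per generating parameter: the true value, the posterior mean and
#' 50%/89% equal-tailed intervals, and whether each interval covers the
#' truth.  Coefficients are compared on the natural (unstandardized)
#' covariate scale, matching how the data were generated.
#'
#' @param truth a `crn_ground_truth` (or any object with a named `params`
#'   vector).
#' @param post a `crn_posterior`.
#' @return data frame of class `crn_recovery`.
#' @export
recovery_report <- function(truth, post) {
  params <- if (inherits(truth, "crn_ground_truth")) truth$params else
    truth
  d <- coef_draws(post, "natural")
  missing <- setdiff(names(params), colnames(d))
  if (length(missing)) {
    stop("ground-truth parameter(s) not found in the posterior: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(names(params), function(p) {
    x <- d[, p]
    qs <- quantile(x, c(0.055, 0.25, 0.75, 0.945), names = FALSE)
    data.frame(param = p, truth = unname(params[p]), mean = mean(x),
               median = median(x), l89 = qs[1], l50 = qs[2], u50 = qs[3],
               u89 = qs[4],
               covered50 = params[p] >= qs[2] & params[p] <= qs[3],
               covered89 = params[p] >= qs[1] & params[p] <= qs[4])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("crn_recovery", class(out))
  out
}

# internal: fabricate a degenerate posterior at given parameter values
# (used for testing postprocessing operations without an MCMC run)
mock_posterior <- function(model, params, n = 100, jitter = 0) {
  keep <- keep_indices(model, FALSE)
  nm <- model$par_names[keep + 1L]
  base <- setNames(rep(0, length(nm)), nm)
  base[names(params)] <- params
  arr <- array(rep(base, each = n * 2), dim = c(n, 2, length(nm)),
               dimnames = list(NULL, NULL, nm))
  if (jitter > 0) arr <- arr + rnorm(length(arr), 0, jitter)
  structure(list(draws = arr, par_names = nm,
                 rhat = setNames(rep(1, length(nm)), nm),
                 diagnostics = list(), mcmc = NULL, model = model),
            class = "crn_posterior")
}
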