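#' MCMC sampler configuration
#'
#' The default mirrors the fitting protocol used for the empirical analyses:
#' 3 chains, 1000 warmup iterations, 3000 sampling iterations, no thinning.
#' [mcmc_test_profile()] gives a cheap 2-chain, 500/500 profile for tests
#' and quick checks.
#'
#' @param chains number of chains (run serially; >= 2 needed for R-hat).
#' @param warmup warmup (adaptation) iterations per chain, discarded.
#' @param samples retained sampling iterations per chain.
#' @param seed integer seed; chain c uses a deterministic function of
#'   `seed` and `c`, so a fit is exactly reproducible.
#' @param adapt_delta target acceptance statistic of the step-size
#'   adaptation (raise towards 1 to shrink the step size if divergences
#'   occur).
#' @param max_treedepth cap on trajectory doublings per iteration.
#' @param thin keep every `thin`-th draw (default 1: keep all).
#' @param keep_latent store draws of the per-pair latent effects (memory
#'   heavy; off by default).
#' @param prior_only detach the likelihood and sample from the prior.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, warmup = 1000, samples = 3000, seed = 1L,
                        adapt_delta = 0.9, max_treedepth = 10, thin = 1,
                        keep_latent = FALSE, prior_only = FALSE) {
  stopifnot(chains >= 1, warmup >= 0, samples >= 1, thin >= 1,
            adapt_delta > 0, adapt_delta < 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 samples = as.integer(samples), seed = as.integer(seed),
                 adapt_delta = adapt_delta,
                 max_treedepth = as.integer(max_treedepth),
                 thin = as.integer(thin),
                 keep_latent = keep_latent, prior_only = prior_only),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... passed on to [mcmc_config()].
#' @export
mcmc_test_profile <- function(seed = 1L, ...) {
  mcmc_config(chains = 2, warmup = 500, samples = 500, seed = seed, ...)
}

chain_seed <- function(seed, chain) {
  as.integer((as.double(seed) + 7177 * chain) %% 2147483629)
}

init_chain <- function(model) {
  lay <- model$layout
  q <- numeric(lay$npar)
  nb <- ncol(model$cdata$X1) + ncol(model$cdata$X2)
  q[seq_len(nb)] <- 0.1 * rnorm(nb)
  # correlation-scale coefficients start at 0 (r = 0): avoids boundary starts
  sd_idx <- lay$sd0 + seq_len(lay$n_sd)
  q[sd_idx] <- log(0.5) + 0.1 * rnorm(lay$n_sd)
  if (lay$cut >= 0) {
    K1 <- model$spec$n_categories - 1
    q[lay$cut + 1] <- -0.5 + 0.1 * rnorm(1)
    if (K1 > 1) q[lay$cut + 1 + seq_len(K1 - 1)] <- 0.1 * rnorm(K1 - 1)
  }
  for (off in c(lay$d1, lay$d2)) {
    if (off >= 0) {
      q[off + seq_len(model$cdata$n_year)] <-
        0.1 * rnorm(model$cdata$n_year)
    }
  }
  if (lay$nu1 > 0) q[lay$u1 + seq_len(lay$nu1)] <- 0.1 * rnorm(lay$nu1)
  if (lay$nu2 > 0) q[lay$u2 + seq_len(lay$nu2)] <- 0.1 * rnorm(lay$nu2)
  q
}

keep_indices <- function(model, keep_latent) {
  lay <- model$layout
  if (keep_latent) return(seq_len(lay$npar) - 1L)
  first_u <- Inf
  if (lay$nu1 > 0) first_u <- min(first_u, lay$u1)
  if (lay$nu2 > 0) first_u <- min(first_u, lay$u2)
  if (!is.finite(first_u)) return(seq_len(lay$npar) - 1L)
  seq_len(first_u) - 1L
}

# map unconstrained kept draws to the natural scale, by parameter name
natural_draws <- function(model, draws, names) {
  colnames(draws) <- names
  sd_cols <- intersect(model$sd_names, names)
  draws[, sd_cols] <- exp(draws[, sd_cols, drop = FALSE])
  th_cols <- grep("^theta_", names, value = TRUE)
  if (length(th_cols) > 1) {
    for (k in 2:length(th_cols)) {
      draws[, th_cols[k]] <- draws[, th_cols[k - 1]] + exp(draws[, th_cols[k]])
    }
  }
  for (i in 1:2) {
    dcol <- grep(sprintf("^delta%d_", i), names, value = TRUE)
    if (length(dcol)) {
      draws[, dcol] <- draws[, dcol, drop = FALSE] *
        draws[, sprintf("sigma_delta%d", i)]
    }
  }
  draws
}

#' Fit a covariance reaction norm model by NUTS
#'
#' Samples the joint posterior with the package's No-U-Turn Hamiltonian
#' Monte Carlo sampler (exact analytic gradients, diagonal metric adapted
#' during warmup, dual-averaging step size).  Chains run serially and are
#' fully deterministic given `mcmc$seed`.
#'
#' A warning (never silent) is raised when any parameter's split-chain
#' Gelman-Rubin statistic exceeds 1.01 or when post-warmup divergences
#' occurred.
#'
#' @param model a `crn_model` from [crn_build()].
#' @param mcmc an [mcmc_config()].
#' @return An object of class `crn_posterior`: element `draws` is an
#'   `iterations x chains x parameters` array on the natural scale (SDs
#'   exponentiated, ordinal thresholds accumulated, year effects scaled by
#'   their SD), plus R-hat values, sampler diagnostics and the model.
#' @export
crn_fit <- function(model, mcmc = mcmc_config()) {
  stopifnot(inherits(model, "crn_model"), inherits(mcmc, "mcmc_config"))
  cd <- model$cdata
  cd$prior_only <- isTRUE(mcmc$prior_only)
  keep <- keep_indices(model, mcmc$keep_latent)
  names <- model$par_names[keep + 1L]
  n_iter <- mcmc$samples
  arr <- array(NA_real_, dim = c(n_iter, mcmc$chains, length(keep)),
               dimnames = list(NULL, NULL, names))
  diag_list <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(chain_seed(mcmc$seed, ch))
    q0 <- init_chain(model)
    res <- cpp_nuts(cd, q0, mcmc$warmup, n_iter * mcmc$thin,
                    mcmc$adapt_delta, mcmc$max_treedepth, as.integer(keep))
    idx <- seq(mcmc$thin, n_iter * mcmc$thin, by = mcmc$thin)
    arr[, ch, ] <- natural_draws(model, res$draws[idx, , drop = FALSE], names)
    diag_list[[ch]] <- list(n_divergent = res$n_divergent,
                            step_size = res$step_size,
                            accept_stat = res$accept_stat,
                            max_treedepth_hits =
                              sum(res$treedepth >= mcmc$max_treedepth))
  }
  rh <- if (mcmc$chains >= 2) {
    apply(arr, 3, function(m) split_rhat(m))
  } else {
    setNames(rep(NA_real_, length(names)), names)
  }
  out <- structure(list(draws = arr, par_names = names, rhat = rh,
                        diagnostics = diag_list, mcmc = mcmc, model = model),
                   class = "crn_posterior")
  bad <- names(rh)[!is.na(rh) & rh > 1.01]
  if (length(bad)) {
    warning(sprintf("R-hat > 1.01 for %d parameter(s): %s",
                    length(bad), paste(head(bad, 5), collapse = ", ")),
            call. = FALSE)
  }
  ndiv <- sum(vapply(diag_list, function(d) d$n_divergent, numeric(1)))
  if (ndiv > 0) {
    warning(sprintf("%d post-warmup divergent transition(s); consider raising adapt_delta",
                    ndiv), call. = FALSE)
  }
  out
}

#' @export
print.crn_posterior <- function(x, ...) {
  cat(sprintf("<crn_posterior> %d chains x %d draws, %d parameters stored\n",
              dim(x$draws)[2], dim(x$draws)[1], dim(x$draws)[3]))
  print(summarize(x, pars = grep("^(b|sigma|theta)", x$par_names,
                                 value = TRUE)))
  invisible(x)
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Each chain is split in half, and the classic potential-scale-reduction
#' statistic is computed over the resulting sequences.  Values near 1
#' indicate between-chain agreement; the package warns above 1.01.
#'
#' @param x an `iterations x chains` matrix of draws for one parameter, or
#'   a `crn_posterior` (then a named vector over parameters is returned).
#' @return numeric R-hat value(s).
#' @export
rhat <- function(x) {
  if (inherits(x, "crn_posterior")) return(x$rhat)
  split_rhat(as.matrix(x))
}

split_rhat <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) {
    stop("R-hat requires at least 2 chains", call. = FALSE)
  }
  n <- nrow(m)
  h <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(h), j], m[(n - h + 1):n, j])
  }))
  if (all(abs(halves - halves[1]) < 1e-300)) return(1)
  W <- mean(apply(halves, 2, var))
  B <- h * var(colMeans(halves))
  if (W == 0) return(Inf)
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Posterior summaries with 50% and 89% credible intervals
#'
#' Reports, per parameter, the posterior mean, median, SD, equal-tailed
#' credible intervals at the requested levels, and R-hat.
#'
#' @param x a `crn_posterior`, or a plain vector/matrix of draws.
#' @param levels credible-interval levels (default 0.50 and 0.89).
#' @param pars optional character vector restricting the parameters.
#' @return A data frame, one row per parameter.
#' @export
summarize <- function(x, levels = c(0.50, 0.89), pars = NULL) {
  if (inherits(x, "crn_posterior")) {
    nm <- pars %||% x$par_names
    nm <- intersect(nm, x$par_names)
    draws <- sapply(nm, function(p) as.vector(x$draws[, , p]))
    rh <- x$rhat[nm]
  } else {
    draws <- as.matrix(x)
    nm <- colnames(draws) %||% paste0("par", seq_len(ncol(draws)))
    rh <- rep(NA_real_, length(nm))
  }
  draws <- as.matrix(draws)
  out <- data.frame(param = nm, mean = colMeans(draws),
                    median = apply(draws, 2, median),
                    sd = apply(draws, 2, sd))
  for (lv in sort(levels)) {
    a <- (1 - lv) / 2
    qs <- apply(draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)
    out[[sprintf("l%g", 100 * lv)]] <- qs[1, ]
    out[[sprintf("u%g", 100 * lv)]] <- qs[2, ]
  }
  out$rhat <- unname(rh)
  rownames(out) <- NULL
  out
}

#' Extract posterior coefficient draws, optionally on the unstandardized scale
#'
#' When the model was built with `standardize = TRUE`, regression
#' coefficients refer to internally standardized covariates.  With
#' `scale = "natural"` the draws are mapped back to the units of the
#' supplied data (slopes divided by the covariate SD; intercepts shifted
#' accordingly).
#'
#' @param post a `crn_posterior`.
#' @param scale `"fitted"` (as sampled) or `"natural"`.
#' @return matrix of draws (rows = draws across all chains, columns =
#'   parameters).
#' @export
coef_draws <- function(post, scale = c("fitted", "natural")) {
  scale <- match.arg(scale)
  nm <- post$par_names
  d <- do.call(rbind, lapply(seq_len(dim(post$draws)[2]),
                             function(ch) post$draws[, ch, ]))
  colnames(d) <- nm
  if (scale == "fitted" || is.null(post$model$scaling$X1)) return(d)
  for (blk in c("X1", "X2", "X3")) {
    sc <- post$model$scaling[[blk]]
    if (is.null(sc)) next
    pre <- c(X1 = "b1_", X2 = "b2_", X3 = "br_")[blk]
    cols <- paste0(pre, colnames(post$model$cdata[[blk]]))
    cols <- intersect(cols, nm)
    if (!length(cols)) next
    icpt <- paste0(pre, "(Intercept)")
    shift <- 0
    for (j in seq_along(cols)) {
      if (cols[j] == icpt) next
      jj <- match(sub(pre, "", cols[j], fixed = TRUE),
                  colnames(post$model$cdata[[blk]]))
      shift <- shift + d[, cols[j]] * sc$center[jj] / sc$scale[jj]
      d[, cols[j]] <- d[, cols[j]] / sc$scale[jj]
    }
    if (icpt %in% nm) d[, icpt] <- d[, icpt] - shift
  }
  d
}

#' Export posterior draws to a tidy data frame
#'
#' One row per (chain, iteration), one column per stored parameter.
#'
#' @param post a `crn_posterior`.
#' @return data frame with leading `chain` and `iteration` columns.
#' @export
draws_df <- function(post) {
  nch <- dim(post$draws)[2]; nit <- dim(post$draws)[1]
  d <- do.call(rbind, lapply(seq_len(nch), function(ch) post$draws[, ch, ]))
  out <- data.frame(chain = rep(seq_len(nch), each = nit),
                    iteration = rep(seq_len(nit), nch))
  cbind(out, as.data.frame(d))
}
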