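#' Correlation link function (inverse hyperbolic tangent)
#'
#' Maps a correlation coefficient in (-1, 1) to the real line, where it can
#' be modelled as a linear function of environmental covariates.  The link is
#' `atanh(r)`, identical to `logit((r + 1) / 2) / 2`: a logistic regression
#' rescaled from \[0, 1\] to \[-1, 1\].
#'
#' The link deliberately performs no clamping.  Callers that may produce
#' `|r| = 1` (e.g. summaries of degenerate posteriors) must clamp to
#' `+/-(1 - 1e-9)` themselves.
#'
#' @param r numeric vector of correlations, all strictly inside (-1, 1).
#' @return `atanh(r)`, same shape as `r`.
#' @seealso [corr_unlink()]
#' @export
#' @examples
#' corr_link(0.5)
#' corr_unlink(corr_link(0.5))
corr_link <- function(r) {
  if (!is.numeric(r) || anyNA(r)) {
    stop("`r` must be numeric with no missing values", call. = FALSE)
  }
  bad <- abs(r) >= 1
  if (any(bad)) {
    stop(sprintf("correlation out of (-1, 1): %s",
                 paste(format(r[bad]), collapse = ", ")), call. = FALSE)
  }
  atanh(r)
}

#' Inverse correlation link (hyperbolic tangent)
#'
#' For `|eta| > atanh(1 - 1e-12)` (about 14.2) the double-precision value of
#' `tanh(eta)` would round to exactly +/-1; the result is therefore clamped
#' to +/-(1 - 1e-12) so the output stays strictly inside (-1, 1).
#'
#' @param eta numeric vector on the link (real) scale; must be finite.
#' @return `tanh(eta)`, strictly inside (-1, 1).
#' @seealso [corr_link()]
#' @export
corr_unlink <- function(eta) {
  if (!is.numeric(eta) || anyNA(eta) || any(!is.finite(eta))) {
    stop("`eta` must be finite numeric", call. = FALSE)
  }
  pmin(pmax(tanh(eta), -1 + 1e-12), 1 - 1e-12)
}

check_range <- function(x, name, lo, hi) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric with no missing values", name),
         call. = FALSE)
  }
  if (any(x < lo | x > hi)) {
    stop(sprintf("`%s` out of [%g, %g]: %s", name, lo, hi,
                 paste(format(x[x < lo | x > hi]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Observation-level correlation implied by among- and within-individual parts
#'
#' When only single measurements per individual are available in a context,
#' the observable correlation between two traits blends the among-individual
#' correlation `r_alpha` and the within-individual correlation `r_eps`,
#' weighted by the geometric mean of the traits' repeatabilities:
#'
#' \deqn{r_{obs} = r_\alpha \sqrt{R_1 R_2} + r_\epsilon \sqrt{(1-R_1)(1-R_2)}}
#'
#' Repeatabilities are understood as proportions of phenotypic variance
#' (after adjusting for mean effects) attributable to among-individual
#' differences; they must be supplied already adjusted.
#'
#' @param r_alpha among-individual correlation(s) in \[-1, 1\].
#' @param r_eps within-individual correlation(s) in \[-1, 1\].
#' @param R1,R2 repeatabilities of traits 1 and 2 in \[0, 1\].
#' @return A data frame of class `bias_point` with columns `r_alpha`,
#'   `r_eps`, `R1`, `R2`, `r_obs`, `bias` (`r_obs - r_alpha`) and
#'   `sign_flipped` (`TRUE` iff `r_obs` and `r_alpha` have strictly opposite
#'   signs; zero on either side is classified as not flipped).
#' @export
#' @examples
#' observation_level_correlation(0.5, 0.5, 1, 1)    # full repeatability
#' observation_level_correlation(0.6, -0.6, 0.5, 0.5)
observation_level_correlation <- function(r_alpha, r_eps, R1, R2) {
  check_range(r_alpha, "r_alpha", -1, 1)
  check_range(r_eps, "r_eps", -1, 1)
  check_range(R1, "R1", 0, 1)
  check_range(R2, "R2", 0, 1)
  n <- max(length(r_alpha), length(r_eps), length(R1), length(R2))
  r_alpha <- rep_len(r_alpha, n); r_eps <- rep_len(r_eps, n)
  R1 <- rep_len(R1, n); R2 <- rep_len(R2, n)
  r_obs <- r_alpha * sqrt(R1 * R2) + r_eps * sqrt((1 - R1) * (1 - R2))
  out <- data.frame(
    r_alpha = r_alpha, r_eps = r_eps, R1 = R1, R2 = R2,
    r_obs = r_obs, bias = r_obs - r_alpha,
    sign_flipped = sign(r_alpha) != 0 & sign(r_obs) != 0 &
      sign(r_alpha) != sign(r_obs)
  )
  class(out) <- c("bias_point", class(out))
  out
}

#' Observation-level correlation under a hybrid sampling design
#'
#' In a hybrid design (repeated measures of trait 1 per individual-context,
#' a single measure of trait 2) the latent correlation between the trait-1
#' individual effect and the trait-2 observation-level effect is the
#' among-individual correlation attenuated by the square root of trait 2's
#' repeatability: `r_alpha * sqrt(R2)`.  Equivalent to
#' [observation_level_correlation()] with `r_eps = 0`, `R1 = 1`.
#'
#' @inheritParams observation_level_correlation
#' @return numeric vector of attenuated correlations.
#' @export
hybrid_correlation <- function(r_alpha, R2) {
  check_range(r_alpha, "r_alpha", -1, 1)
  check_range(R2, "R2", 0, 1)
  r_alpha * sqrt(R2)
}

#' Sweep the observation-level correlation over a two-parameter grid
#'
#' Builds the surface used to map regions of "sign bias": parameter
#' combinations where the observation-level correlation carries the opposite
#' sign of the among-individual correlation, so that a non-repeated-measures
#' analysis would invert the apparent direction of a trade-off.
#'
#' @param fixed named list fixing two of `r_alpha`, `r_eps`, `R1`, `R2`.
#' @param sweep named list of exactly two `c(from, to)` ranges for the
#'   remaining parameters.
#' @param n integer step counts (length 1 or 2) per axis; endpoints are
#'   included, so `n` points span each closed interval.
#' @return A data frame of class `bias_grid` (one row per cell, tidy) with
#'   an `axes` attribute describing the sweep.
#' @export
#' @examples
#' g <- bias_grid(fixed = list(r_alpha = 0.5, r_eps = -0.5),
#'                sweep = list(R1 = c(0, 1), R2 = c(0, 1)), n = 21)
#' subset(g, sign_flipped)
bias_grid <- function(fixed, sweep, n = 101) {
  pars <- c("r_alpha", "r_eps", "R1", "R2")
  if (length(sweep) != 2 || is.null(names(sweep)) ||
      anyDuplicated(names(sweep)) || !all(names(sweep) %in% pars)) {
    stop("`sweep` must name two distinct parameters among ",
         paste(pars, collapse = ", "), call. = FALSE)
  }
  if (!all(setdiff(pars, names(sweep)) %in% names(fixed))) {
    stop("`fixed` must supply the two parameters not swept", call. = FALSE)
  }
  n <- rep_len(as.integer(n), 2)
  if (any(n < 1)) stop("step counts must be >= 1 (got zero cells)", call. = FALSE)
  axes <- lapply(seq_along(sweep), function(i) {
    rng <- sweep[[i]]
    if (length(rng) != 2 || rng[1] > rng[2]) {
      stop(sprintf("range for `%s` must be c(from, to) with from <= to",
                   names(sweep)[i]), call. = FALSE)
    }
    if (n[i] == 1) mean(rng) else seq(rng[1], rng[2], length.out = n[i])
  })
  names(axes) <- names(sweep)
  cells <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  args <- as.list(cells)
  for (p in setdiff(pars, names(sweep))) args[[p]] <- fixed[[p]]
  out <- observation_level_correlation(args$r_alpha, args$r_eps,
                                       args$R1, args$R2)
  attr(out, "axes") <- axes
  class(out) <- c("bias_grid", class(out))
  out
}

#' Export a bias grid to a tidy CSV
#'
#' One row per cell: parameter values, `r_obs`, `bias`, `sign_flipped`.
#'
#' @param grid a [bias_grid()] result.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_bias_grid <- function(grid, path) {
  stopifnot(inherits(grid, "bias_point"))
  readr::write_csv(as.data.frame(unclass(grid)), path)
  invisible(path)
}
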