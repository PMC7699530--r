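#' Fit an uncertainty distribution to a mean and interval
#'
#' Fits the sampling distribution used in probabilistic sensitivity analysis
#' from a parameter's mean and its low/high sensitivity bounds, interpreted
#' as a central 95% interval. The implied standard deviation is
#' `(high - low) / (2 * 1.96)`.
#'
#' * `beta`: method of moments on (mean, sd). If the implied variance is
#'   incompatible with the beta family (`sd^2 >= mean * (1 - mean)`), the
#'   fit falls back to `uniform(low, high)` with a warning.
#' * `gamma`: method of moments, `shape = mean^2/sd^2`, `rate = mean/sd^2`.
#' * `lognormal`: fitted on the log scale; `sdlog = log(high/low)/(2*1.96)`
#'   (the bounds read as a geometric interval) and `meanlog` chosen so the
#'   arithmetic mean equals `mean` exactly.
#' * `fixed`: degenerate point mass at `mean`.
#'
#' The fitted sampler's analytic mean equals `mean` (exactly for all
#' families except the uniform fallback, whose mean is `(low + high)/2`).
#'
#' @param mean,low,high Parameter mean and 95% bounds (`low < high` unless
#'   the family is `fixed`).
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param name Optional identifier used in messages.
#' @return An object of class `param_sampler`: a list with the resolved
#'   `family`, its parameters, the analytic `mean`, and a `sample(n)`
#'   function drawing `n` values.
#' @examples
#' s <- fit_sampler(0.5, 0.402, 0.598, "beta")
#' s$mean            # 0.5
#' sd_implied <- (0.598 - 0.402) / (2 * 1.96) # 0.05
#' @export
fit_sampler <- function(mean, low, high, family, name = NULL) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "fixed"))
  tag <- if (is.null(name)) "" else paste0(" for `", name, "`")
  if (family == "fixed") {
    out <- list(
      family = "fixed", mean = mean,
      sample = function(n) rep(mean, n),
      quantile = function(p) rep(mean, length(p))
    )
    class(out) <- "param_sampler"
    return(out)
  }
  if (!(low < high)) {
    if (low == high) {
      # a zero-width interval is a point mass, whatever the family
      out <- list(
        family = "fixed", mean = mean,
        sample = function(n) rep(mean, n),
        quantile = function(p) rep(mean, length(p))
      )
      class(out) <- "param_sampler"
      return(out)
    }
    abort(paste0("`low` must be strictly below `high`", tag, "."))
  }
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  v <- sd^2
  out <- switch(family,
    beta = {
      if (mean <= 0 || mean >= 1 || v >= mean * (1 - mean)) {
        warn(paste0(
          "Implied variance incompatible with a beta distribution", tag,
          "; falling back to uniform(low, high)."
        ))
        list(
          family = "uniform", mean = (low + high) / 2, min = low, max = high,
          sample = function(n) runif(n, low, high),
          quantile = function(p) stats::qunif(p, low, high)
        )
      } else {
        nu <- mean * (1 - mean) / v - 1
        shape1 <- mean * nu
        shape2 <- (1 - mean) * nu
        list(
          family = "beta", mean = mean, shape1 = shape1, shape2 = shape2,
          sample = function(n) rbeta(n, shape1, shape2),
          quantile = function(p) stats::qbeta(p, shape1, shape2)
        )
      }
    },
    gamma = {
      if (mean <= 0) {
        warn(paste0(
          "Non-positive mean incompatible with a gamma distribution", tag,
          "; falling back to uniform(low, high)."
        ))
        list(
          family = "uniform", mean = (low + high) / 2, min = low, max = high,
          sample = function(n) runif(n, low, high),
          quantile = function(p) stats::qunif(p, low, high)
        )
      } else {
        shape <- mean^2 / v
        rate <- mean / v
        list(
          family = "gamma", mean = mean, shape = shape, rate = rate,
          sample = function(n) rgamma(n, shape = shape, rate = rate),
          quantile = function(p) stats::qgamma(p, shape = shape, rate = rate)
        )
      }
    },
    lognormal = {
      if (mean <= 0 || low <= 0) {
        abort(paste0("Lognormal requires positive mean and bounds", tag, "."))
      }
      sdlog <- log(high / low) / (2 * stats::qnorm(0.975))
      meanlog <- log(mean) - sdlog^2 / 2
      list(
        family = "lognormal", mean = mean, meanlog = meanlog, sdlog = sdlog,
        sample = function(n) rlnorm(n, meanlog, sdlog),
        quantile = function(p) stats::qlnorm(p, meanlog, sdlog)
      )
    }
  )
  class(out) <- "param_sampler"
  out
}

#' @export
print.param_sampler <- function(x, ...) {
  cat("<param_sampler> family:", x$family, " mean:", format(x$mean), "\n")
  invisible(x)
}

#' Draw a matrix of parameter values for probabilistic analysis
#'
#' Draws `n` joint parameter vectors, one column per parameter in the order
#' of the table, each sampled from its fitted distribution
#' ([fit_sampler()]) by inverse-CDF on uniform variates. Distinct
#' quantities are mutually independent. For the trial-based arm pairs
#' (`*_exercise` / `*_usual`, covering non-breast-cancer mortality,
#' breast-cancer mortality, recurrence and the first-year utility
#' increment) the default `arm_correlation = "comonotonic"` feeds both
#' members of a pair the *same* uniform, so each draw moves the pair up or
#' down together while every marginal distribution (and hence every
#' sampled mean) is unchanged. This preserves the trial's relative effect
#' under uncertainty about its level; `"independent"` severs the pairing.
#'
#' @param parameters Parameter tibble (see [default_parameters()]).
#' @param n Number of draws.
#' @param arm_correlation `"comonotonic"` (default) or `"independent"`.
#' @return An `n` x `nrow(parameters)` numeric matrix with parameter names
#'   as column names.
#' @export
sample_parameters <- function(parameters, n,
                              arm_correlation = c("comonotonic", "independent")) {
  arm_correlation <- match.arg(arm_correlation)
  validate_parameters(parameters)
  samplers <- purrr::pmap(
    parameters[c("mean", "low", "high", "family", "name")],
    function(mean, low, high, family, name) fit_sampler(mean, low, high, family, name)
  )
  stems <- if (arm_correlation == "comonotonic") {
    arm_pair_stems(parameters$name)
  } else {
    parameters$name
  }
  u <- matrix(runif(n * length(unique(stems))), nrow = n)
  colnames(u) <- unique(stems)
  draws <- vapply(seq_along(samplers), function(j) {
    samplers[[j]]$quantile(u[, stems[j]])
  }, numeric(n))
  if (n == 1) draws <- matrix(draws, nrow = 1)
  colnames(draws) <- parameters$name
  draws
}

# Pair key for arm-specific parameters: "p_brc_death_exercise" and
# "p_brc_death_usual" share the stem "p_brc_death"; unpaired parameters
# keep their own name.
arm_pair_stems <- function(names) {
  sub("_(exercise|usual)$", "", names)
}
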