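#' Preservation model
#'
#' Time-variable Poisson fossilization process with among-lineage rate
#' heterogeneity: per-bin baseline rates \code{q} are multiplied by a
#' species-specific factor drawn from a mean-one gamma distribution
#' (shape = rate = \code{alpha}), marginalized over \code{n_categories}
#' equal-weight discrete quantile categories.
#'
#' @param q Per-time-bin baseline preservation rates
#'   (occurrences / lineage / Myr); recycled to the bin count downstream.
#' @param alpha Gamma shape of the multipliers (larger = more homogeneous).
#' @param n_categories Number of discretization categories.
#' @return Object of class \code{preservation_model}.
#' @export
preservation_model <- function(q, alpha = 1, n_categories = 4L) {
  if (any(q <= 0)) stop("preservation rates q must be positive")
  if (alpha <= 0) stop("alpha must be positive")
  structure(list(q = q, alpha = alpha,
                 n_categories = as.integer(n_categories)),
            class = "preservation_model")
}

# Equal-weight discrete gamma multipliers (quantile medians of
# Gamma(alpha, alpha)); collapses to 1 for a single category or huge alpha.
gamma_categories <- function(alpha, n_categories) {
  if (n_categories == 1L || !is.finite(alpha)) return(1)
  p <- (seq_len(n_categories) - 0.5) / n_categories
  stats::qgamma(p, shape = alpha, rate = alpha)
}

#' Birth-death log-likelihood of one lineage
#'
#' Probability density of the origination/extinction times of a lineage
#' under the sampled birth-death process with piecewise-constant
#' lineage-time rates: \code{log lambda(s) + log mu(e) - int_e^s
#' (lambda + mu) dt} for extinct lineages, dropping the \code{log mu} term
#' and integrating to the present for extant ones (\code{e = 0}). The
#' integral is exact as a sum over bin overlaps.
#'
#' @param s,e Origination and extinction times (Ma); \code{s > e >= 0}.
#' @param lambda,mu Per-bin rates (vectors over the bin grid).
#' @param time_bins Strictly decreasing bin boundary ages.
#' @param extant Is the lineage extant (forces \code{e = 0})?
#' @return Log-likelihood (scalar).
#' @export
bd_lineage_loglik <- function(s, e, lambda, mu, time_bins, extant = (e == 0)) {
  if (s <= e) stop("origination time s must exceed extinction time e")
  if (any(lambda <= 0) || any(mu <= 0)) stop("rates must be strictly positive")
  B <- length(time_bins) - 1
  lam <- matrix(rep_len(lambda, B), 1, B)
  mum <- matrix(rep_len(mu, B), 1, B)
  as.numeric(.cpp_bd_loglik(s, e, extant, lam, mum, time_bins))
}

#' Total birth-death log-likelihood of a dataset
#'
#' Sums the lineage-level birth-death log-likelihood over all taxa using
#' the lineage-time-specific rate matrices emitted by the networks.
#'
#' @param params A \code{\link{bdnn_params}} state carrying \code{s},
#'   \code{e}, and \code{extant}.
#' @param predictors A \code{\link{predictor_tensor}}.
#' @param rates Optional precomputed output of
#'   \code{\link{lineage_time_rates}}.
#' @return Total log-likelihood (scalar).
#' @export
bd_total_loglik <- function(params, predictors, rates = NULL) {
  if (is.null(rates)) rates <- lineage_time_rates(params, predictors)
  sum(.cpp_bd_loglik(params$s, params$e, params$extant,
                     rates$lambda, rates$mu, predictors$time_bins))
}

#' Preservation log-likelihood of a lineage
#'
#' Poisson likelihood of the observed occurrences over the lifespan
#' \code{[e, s]}: per bin, \code{K_b} occurrences contribute
#' \code{K_b log(q_b m) - q_b m Delta_b} where \code{Delta_b} is the
#' bin-lifespan overlap, marginalized over the discrete-gamma multiplier
#' \code{m} and conditioned on observing at least one occurrence.
#'
#' @param ages Occurrence ages of the lineage (Ma), all within
#'   \code{[e, s]}.
#' @param s,e Origination and extinction times.
#' @param model A \code{\link{preservation_model}}.
#' @param time_bins Strictly decreasing bin boundary ages.
#' @return Log-likelihood (scalar).
#' @export
preservation_loglik <- function(ages, s, e, model, time_bins) {
  if (length(ages) < 1) stop("lineage must have >= 1 occurrence")
  if (any(ages < e - 1e-9) || any(ages > s + 1e-9))
    stop("occurrence ages must lie within [e, s]")
  B <- length(time_bins) - 1
  bins <- .cpp_bin_of(ages, time_bins)
  counts <- matrix(tabulate(bins, B), 1, B)
  q <- rep_len(model$q, B)
  m <- gamma_categories(model$alpha, model$n_categories)
  as.numeric(.cpp_preservation_loglik(counts, s, e, q, m, time_bins))
}
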