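#' Median absolute relative error
#'
#' Accuracy of inferred rates against the simulated truth:
#' \code{median(|r - r_hat| / r)}, with the even-length midpoint rule.
#' An error of 0.2 means the inferred rates deviate from the truth by 20\%
#' at the median. Entries with a true rate of zero are excluded with a
#' warning (their relative error is undefined).
#'
#' @param true_rates Vector of true rates.
#' @param inferred_rates Vector of inferred rates (same length).
#' @return Scalar MARE.
#' @export
mare <- function(true_rates, inferred_rates) {
  if (length(true_rates) != length(inferred_rates))
    stop("true and inferred rate vectors must have equal length")
  keep <- true_rates != 0
  if (any(!keep))
    warning(sum(!keep), " entries with zero true rate excluded from MARE")
  stats::median(abs(true_rates[keep] - inferred_rates[keep]) /
                  true_rates[keep])
}

# Per-species rate draws evaluated at each posterior sample's own times:
# lambda at the sampled origination bin, mu at the sampled extinction bin.
species_rate_samples <- function(trace) {
  edges <- trace$time_bins
  M <- n_samples(trace)
  S <- length(trace$species)
  lam <- mu <- matrix(NA_real_, S, M)
  for (m in seq_len(M)) {
    z <- trace$samples[[m]]
    bs <- .cpp_bin_of(z$s, edges)
    be <- .cpp_bin_of(z$e, edges)
    lam[, m] <- z$lambda[cbind(seq_len(S), bs)]
    mu[, m] <- z$mu[cbind(seq_len(S), be)]
  }
  rownames(lam) <- rownames(mu) <- trace$species
  list(lambda = lam, mu = mu)
}

#' Credible-interval coverage
#'
#' Fraction of lineages whose equal-tailed credible interval contains the
#' true simulated rate.
#'
#' @param true_rates Vector of true per-lineage rates.
#' @param posterior_rate_samples Matrix (lineages x posterior draws).
#' @param level Credible level (default 95\%).
#' @return Proportion in [0, 1].
#' @export
rate_coverage <- function(true_rates, posterior_rate_samples, level = 0.95) {
  a <- (1 - level) / 2
  qs <- t(apply(posterior_rate_samples, 1, stats::quantile,
                probs = c(a, 1 - a)))
  mean(true_rates >= qs[, 1] & true_rates <= qs[, 2])
}

#' Coefficient-of-variation test for rate variation
#'
#' Computes the coefficient of variation (SD / mean) of the posterior-mean
#' lineage-time-specific rates and rejects rate constancy when the CV
#' exceeds a threshold calibrated on constant-rate simulations (see
#' \code{\link{calibrate_threshold}}). The default pools the
#' posterior-mean rate matrix over all cells within each lineage's
#' (posterior-mean) lifespan; \code{cells = "events"} instead uses each
#' lineage's rate at its own origination/extinction — a sharper but less
#' robust statistic, since the at-event cells are the ones most exposed
#' to overfitting.
#'
#' @param trace A \code{bdnn_trace}.
#' @param thresholds Named vector \code{c(lambda = , mu = )}, or NULL to
#'   return the CVs only.
#' @param cells \code{"lifespan"} (pooled cells, default) or
#'   \code{"events"}.
#' @return List with \code{cv} (named vector) and, when thresholds are
#'   given, logical \code{reject} verdicts per rate type.
#' @export
cv_rate_variation_test <- function(trace, thresholds = NULL,
                                   cells = c("lifespan", "events")) {
  cells <- match.arg(cells)
  cv1 <- function(x) {
    m <- mean(x)
    if (!is.finite(m) || m <= 0) stop("undefined CV: mean rate is not positive")
    stats::sd(x) / m
  }
  if (cells == "events") {
    sr <- species_rate_samples(trace)
    cv <- c(lambda = cv1(rowMeans(sr$lambda)), mu = cv1(rowMeans(sr$mu)))
  } else {
    M <- n_samples(trace)
    lam <- Reduce(`+`, trace_field(trace, "lambda")) / M
    mu <- Reduce(`+`, trace_field(trace, "mu")) / M
    s_bar <- Reduce(`+`, trace_field(trace, "s")) / M
    e_bar <- Reduce(`+`, trace_field(trace, "e")) / M
    edges <- trace$time_bins
    B <- length(edges) - 1
    keep <- matrix(FALSE, nrow(lam), B)
    for (b in seq_len(B))
      keep[, b] <- s_bar > edges[b + 1] & e_bar < edges[b]
    cv <- c(lambda = cv1(lam[keep]), mu = cv1(mu[keep]))
  }
  out <- list(cv = cv)
  if (!is.null(thresholds))
    out$reject <- c(lambda = unname(cv["lambda"] > thresholds["lambda"]),
                    mu = unname(cv["mu"] > thresholds["mu"]))
  out
}

#' Calibrate CV rejection thresholds
#'
#' Given fits of constant-rate (scenario 1) simulations, returns the
#' specificity-quantile of their CVs per rate type: rejecting constancy
#' above these thresholds erroneously rejects a true constant-rate model
#' in a fraction \code{1 - specificity} of cases. The quantile is the
#' order statistic at index \code{ceiling(specificity * n)}.
#'
#' @param constant_rate_traces List of \code{bdnn_trace} objects (>= 20),
#'   or a data frame with columns \code{lambda}, \code{mu} of precomputed
#'   CVs.
#' @param specificity Target specificity (default 0.95).
#' @return Named vector \code{c(lambda = , mu = )}.
#' @export
calibrate_threshold <- function(constant_rate_traces, specificity = 0.95) {
  if (is.data.frame(constant_rate_traces)) {
    cvs <- constant_rate_traces
  } else {
    if (length(constant_rate_traces) < 20)
      stop("threshold calibration needs >= 20 constant-rate fits")
    cvs <- as.data.frame(do.call(rbind, lapply(constant_rate_traces,
      function(tr) cv_rate_variation_test(tr)$cv)))
  }
  n <- nrow(cvs)
  k <- min(n, max(1L, ceiling(specificity * n)))
  c(lambda = sort(cvs$lambda)[k], mu = sort(cvs$mu)[k])
}

#' Rate trajectories through time
#'
#' Summarizes the lineage-time-specific rates into overall trajectories:
#' for each posterior sample and time bin, the mean rate over lineages
#' whose sampled lifespan overlaps the bin; then the posterior mean and
#' equal-tailed credible interval per bin. Bins without living lineages
#' are flagged missing.
#'
#' @param trace A \code{bdnn_trace}.
#' @param level Credible level.
#' @return Data frame with one row per bin: \code{bin_top}, \code{bin_mid},
#'   posterior mean and CI of \code{lambda} and \code{mu}, and the flag
#'   \code{empty}.
#' @export
rates_through_time <- function(trace, level = 0.95) {
  edges <- trace$time_bins
  B <- length(edges) - 1
  M <- n_samples(trace)
  lam <- mu <- matrix(NA_real_, M, B)
  for (m in seq_len(M)) {
    z <- trace$samples[[m]]
    for (b in seq_len(B)) {
      alive <- which(z$s > edges[b + 1] & z$e < edges[b])
      if (length(alive)) {
        lam[m, b] <- mean(z$lambda[alive, b])
        mu[m, b] <- mean(z$mu[alive, b])
      }
    }
  }
  a <- (1 - level) / 2
  qs <- function(x) if (all(is.na(x))) c(NA, NA) else
    stats::quantile(x, c(a, 1 - a), na.rm = TRUE)
  data.frame(
    bin_top = edges[-(B + 1)],
    bin_mid = (edges[-(B + 1)] + edges[-1]) / 2,
    lambda = colMeans(lam, na.rm = TRUE),
    lambda_lo = apply(lam, 2, function(x) qs(x)[1]),
    lambda_hi = apply(lam, 2, function(x) qs(x)[2]),
    mu = colMeans(mu, na.rm = TRUE),
    mu_lo = apply(mu, 2, function(x) qs(x)[1]),
    mu_hi = apply(mu, 2, function(x) qs(x)[2]),
    empty = apply(lam, 2, function(x) all(is.na(x))))
}

#' Evaluate a fit against simulated truth
#'
#' Computes the accuracy and calibration summary of a BDNN fit on a
#' simulated dataset: MARE of speciation and extinction (inferred
#' species-specific rates at the inferred times versus the true rate of
#' the ancestral lineage at origination and the lineage's own rate at
#' extinction), 95\% CI coverage, and the rate CVs.
#'
#' @param trace A \code{bdnn_trace}.
#' @param truth The \code{truth} element of \code{\link{simulate_dataset}}.
#' @return List with \code{mare}, \code{coverage}, and \code{cv}, each a
#'   named (lambda, mu) vector.
#' @export
evaluate_fit <- function(trace, truth) {
  ord <- match(trace$species, truth$species)
  sr <- species_rate_samples(trace)
  lam_true <- truth$lambda_birth[ord]
  mu_true <- truth$mu_death[ord]
  keepl <- which(lam_true > 0); keepm <- which(mu_true > 0)
  list(
    mare = c(lambda = mare(lam_true[keepl], rowMeans(sr$lambda)[keepl]),
             mu = mare(mu_true[keepm], rowMeans(sr$mu)[keepm])),
    coverage = c(
      lambda = rate_coverage(lam_true[keepl],
                             sr$lambda[keepl, , drop = FALSE]),
      mu = rate_coverage(mu_true[keepm], sr$mu[keepm, , drop = FALSE])),
    cv = cv_rate_variation_test(trace)$cv)
}
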