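#' Hyperbolic tangent activation
#'
#' The activation used in the hidden layers of the rate networks, computed
#' through the identity \code{tanh(z) = 1 - 2 / (exp(2 z) + 1)}. Small
#' networks with tanh hidden units are well behaved under the standard-normal
#' weight priors used here.
#'
#' @param z Numeric vector of pre-activations.
#' @return Numeric vector in (-1, 1).
#' @export
#' @examples
#' activation_tanh(c(-1, 0, 1))
activation_tanh <- function(z) {
  1 - 2 / (exp(2 * z) + 1)
}

#' Softplus activation
#'
#' Output activation \code{log(exp(z) + 1)} mapping the last layer to a
#' strictly positive rate. Numerically stable for large \code{|z|}.
#'
#' @param z Numeric vector of pre-activations.
#' @return Strictly positive numeric vector.
#' @export
#' @examples
#' activation_softplus(0)  # log(2)
activation_softplus <- function(z) {
  ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
}

#' Network architecture description
#'
#' @param n_predictors Number of input predictors J (including time).
#' @param hidden Sizes of the two hidden layers; the default of 16 and 8
#'   nodes works well for clades of a few hundred species and up to ~10
#'   predictors.
#' @param bias Include a bias (intercept) node in the last hidden layer.
#' @return An object of class \code{bdnn_architecture}.
#' @export
bdnn_architecture <- function(n_predictors, hidden = c(16L, 8L), bias = TRUE) {
  stopifnot(n_predictors >= 1, length(hidden) == 2, all(hidden >= 1))
  structure(list(n_predictors = as.integer(n_predictors),
                 hidden = as.integer(hidden), bias = isTRUE(bias)),
            class = "bdnn_architecture")
}

#' Network weights container
#'
#' Bundles the three weight matrices of one rate network. \code{w3} carries
#' a trailing bias entry when the architecture includes a bias node in the
#' last hidden layer.
#'
#' @param W1 J x L1 matrix.
#' @param W2 L1 x L2 matrix.
#' @param w3 Numeric vector of length L2 (+ 1 if \code{bias}).
#' @param bias Whether \code{w3} includes a bias entry.
#' @return An object of class \code{network_weights}.
#' @export
network_weights <- function(W1, W2, w3, bias = TRUE) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2); w3 <- as.numeric(w3)
  if (ncol(W1) != nrow(W2))
    stop("W1/W2 shapes inconsistent: ", ncol(W1), " vs ", nrow(W2))
  if (length(w3) != ncol(W2) + as.integer(isTRUE(bias)))
    stop("w3 length inconsistent with L2 = ", ncol(W2),
         if (isTRUE(bias)) " (+ bias)")
  if (!all(is.finite(W1)) || !all(is.finite(W2)) || !all(is.finite(w3)))
    stop("network weights must be finite")
  structure(list(W1 = W1, W2 = W2, w3 = w3, bias = isTRUE(bias)),
            class = "network_weights")
}

#' Draw network weights
#'
#' Draws all weights independently from N(0, sd). With \code{sd = 1} this is
#' the regularizing prior used by the sampler.
#'
#' @param architecture A \code{\link{bdnn_architecture}}.
#' @param sd Standard deviation of the normal draw.
#' @return A \code{\link{network_weights}} object.
#' @export
draw_weights <- function(architecture, sd = 1) {
  J <- architecture$n_predictors
  L1 <- architecture$hidden[1]; L2 <- architecture$hidden[2]
  nb <- as.integer(architecture$bias)
  network_weights(
    W1 = matrix(stats::rnorm(J * L1, 0, sd), J, L1),
    W2 = matrix(stats::rnorm(L1 * L2, 0, sd), L1, L2),
    w3 = stats::rnorm(L2 + nb, 0, sd),
    bias = architecture$bias
  )
}

n_weights <- function(weights) {
  length(weights$W1) + length(weights$W2) + length(weights$w3)
}

#' Baseline rate from a predictor row
#'
#' Deterministic forward pass producing the species-time-specific baseline
#' rate: two tanh hidden layers followed by a softplus output.
#'
#' @param weights A \code{\link{network_weights}} object.
#' @param x Numeric predictor row of length J, or an n x J matrix of rows.
#' @return Strictly positive baseline rate(s), one per row of \code{x}.
#' @export
forward_baseline <- function(weights, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(weights$W1))
    stop("predictor row length ", ncol(x), " does not match W1 rows ",
         nrow(weights$W1))
  out <- .cpp_forward_baseline(x, weights$W1, weights$W2, weights$w3,
                               weights$bias)
  as.numeric(out)
}

#' Mean-preserving rate regularization
#'
#' Shrinks positive baseline rates toward their grand mean:
#' \code{phi(x) = x^t_reg * E(x) / E(x^t_reg)}, where \code{E} averages over
#' all species and time bins. The transform preserves the mean exactly,
#' collapses all rates onto the mean at \code{t_reg = 0}, and is the
#' identity at \code{t_reg = 1}.
#'
#' @param baseline Positive numeric matrix (species x time bins) or vector.
#' @param t_reg Regularization parameter in [0, 1].
#' @return Object of the same shape as \code{baseline}.
#' @export
regularize_rates <- function(baseline, t_reg) {
  if (length(t_reg) != 1 || !is.finite(t_reg) || t_reg < 0 || t_reg > 1)
    stop("t_reg must be a single value in [0, 1]")
  if (any(baseline <= 0)) stop("baseline rates must be strictly positive")
  d <- dim(baseline)
  out <- as.numeric(.cpp_regularize(as.numeric(baseline), t_reg))
  if (!is.null(d)) dim(out) <- d
  dimnames(out) <- dimnames(baseline)
  out
}

#' Model state of the birth-death neural network
#'
#' Collects everything the sampler updates: the weights of the independent
#' speciation and extinction networks, the shared regularizer \code{t_reg},
#' the latent origination/extinction times, and the preservation parameters.
#'
#' @param weights_lambda,weights_mu \code{\link{network_weights}} for the
#'   speciation and extinction networks.
#' @param t_reg Shared regularization parameter in [0, 1].
#' @param s,e Origination and extinction times (Ma before present);
#'   \code{e} must be 0 for extant taxa and \code{s > e} throughout.
#' @param extant Logical vector flagging extant taxa.
#' @param q Per-time-bin baseline preservation rates, or NULL if the state
#'   carries no preservation component.
#' @param alpha Gamma shape of the among-lineage preservation multipliers.
#' @return An object of class \code{bdnn_params}.
#' @export
bdnn_params <- function(weights_lambda, weights_mu, t_reg, s = NULL, e = NULL,
                        extant = NULL, q = NULL, alpha = NULL) {
  if (t_reg < 0 || t_reg > 1) stop("t_reg must be in [0, 1]")
  if (!is.null(s)) {
    if (any(s <= e)) stop("origination times must exceed extinction times")
    if (any(e < 0)) stop("extinction times must be >= 0")
    if (!is.null(extant) && any(e[extant] != 0))
      stop("extant taxa must have extinction time 0")
  }
  structure(list(weights_lambda = weights_lambda, weights_mu = weights_mu,
                 t_reg = t_reg, s = s, e = e, extant = extant,
                 q = q, alpha = alpha),
            class = "bdnn_params")
}

#' Lineage-time-specific rates
#'
#' Applies the forward pass of both networks to every (species, time-bin)
#' predictor row and regularizes each rate type with the shared
#' \code{t_reg}, yielding the speciation and extinction rate matrices that
#' enter the birth-death likelihood.
#'
#' @param params A \code{\link{bdnn_params}} state.
#' @param predictors A \code{\link{predictor_tensor}}.
#' @return List with matrices \code{lambda} and \code{mu}
#'   (species x time bins), in events / lineage / Myr.
#' @export
lineage_time_rates <- function(params, predictors) {
  X <- tensor_matrix(predictors)
  S <- length(predictors$species); B <- length(predictors$bin_mid)
  bl_l <- forward_baseline(params$weights_lambda, X)
  bl_m <- forward_baseline(params$weights_mu, X)
  lam <- matrix(regularize_rates(bl_l, params$t_reg), S, B)
  mu <- matrix(regularize_rates(bl_m, params$t_reg), S, B)
  rownames(lam) <- rownames(mu) <- predictors$species
  list(lambda = lam, mu = mu)
}
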