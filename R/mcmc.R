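#' MCMC configuration
#'
#' Settings for the Metropolis-Hastings sampler over origination and
#' extinction times, preservation parameters, network weights, and the
#' shared regularizer.
#'
#' @param n_iterations Total iterations.
#' @param sampling_freq Record one sample every this many iterations.
#' @param burnin Burn-in fraction in [0, 1).
#' @param seed Integer seed; chains are bit-reproducible given the seed.
#' @param hidden Hidden-layer sizes of both rate networks.
#' @param bias Bias node in the last hidden layer.
#' @param n_categories Discrete-gamma categories of the preservation model.
#' @param update_mix Named probabilities of the four update blocks
#'   (\code{times}, \code{weights}, \code{preservation}, \code{treg}).
#' @param scale_weights SD of the normal jitter on weights.
#' @param weight_frac Fraction of one layer's weights updated per move.
#' @param scale_times Sliding-window half-width (Myr) for s/e moves.
#' @param times_frac Fraction of taxa whose times are updated per move.
#' @param scale_q Log-window of the multiplier proposals on q and alpha.
#' @param scale_treg Sliding-window SD for t_reg (reflected into [0, 1]).
#' @param likelihood \code{"full"} for the posterior, \code{"none"} to
#'   sample from the prior alone (diagnostics).
#' @param init_weight_sd SD of the initial weight draw.
#' @param out_prefix Optional path prefix; when set, a TSV trace log is
#'   written incrementally and the sampled weights are stored alongside.
#' @return Object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(n_iterations = 1e6, sampling_freq = 1000,
                        burnin = 0.25, seed = 1, hidden = c(16L, 8L),
                        bias = TRUE, n_categories = 4L,
                        update_mix = c(times = 0.4, weights = 0.4,
                                       preservation = 0.15, treg = 0.05),
                        scale_weights = 0.2, weight_frac = 0.2,
                        scale_times = 1.0, times_frac = 0.1,
                        scale_q = 1.0, scale_treg = 0.2,
                        likelihood = c("full", "none"),
                        init_weight_sd = 0.1, out_prefix = NULL) {
  stopifnot(n_iterations > 0, burnin >= 0, burnin < 1)
  likelihood <- match.arg(likelihood)
  update_mix <- update_mix / sum(update_mix)
  structure(list(n_iterations = as.integer(n_iterations),
                 sampling_freq = as.integer(sampling_freq), burnin = burnin,
                 seed = as.integer(seed), hidden = as.integer(hidden),
                 bias = bias, n_categories = as.integer(n_categories),
                 update_mix = update_mix, scale_weights = scale_weights,
                 weight_frac = weight_frac, scale_times = scale_times,
                 times_frac = times_frac, scale_q = scale_q,
                 scale_treg = scale_treg, likelihood = likelihood,
                 init_weight_sd = init_weight_sd, out_prefix = out_prefix),
            class = "mcmc_config")
}

# Reflect a value into [lo, hi].
reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

weights_prior <- function(W) {
  sum(stats::dnorm(c(W$W1, W$W2, W$w3), 0, 1, log = TRUE))
}

treg_prior <- function(t_reg) {
  if (t_reg < 0 || t_reg > 1) return(-Inf)
  stats::dexp(t_reg, 1, log = TRUE) - log(1 - exp(-1))
}

q_prior <- function(q) sum(stats::dgamma(q, shape = 1.5, rate = 1.1,
                                         log = TRUE))
alpha_prior <- function(alpha) stats::dexp(alpha, 1, log = TRUE)

#' Log-prior of a model state
#'
#' Standard-normal regularizing priors on all network weights, a truncated
#' Exp(1) prior on \code{t_reg} over [0, 1] (placing the highest prior
#' probability on \code{t_reg = 0}, the constant-rate null), a
#' Gamma(1.5, 1.1) prior on each per-bin preservation rate, and an Exp(1)
#' prior on the gamma heterogeneity shape. Preservation terms are included
#' only when the state carries them.
#'
#' @param params A \code{\link{bdnn_params}} state.
#' @return Log prior density (scalar; \code{-Inf} outside the support).
#' @export
log_prior <- function(params) {
  lp <- weights_prior(params$weights_lambda) +
    weights_prior(params$weights_mu) + treg_prior(params$t_reg)
  if (!is.null(params$q)) lp <- lp + q_prior(params$q)
  if (!is.null(params$alpha)) lp <- lp + alpha_prior(params$alpha)
  lp
}

#' Propose a Metropolis-Hastings move
#'
#' Draws one update block at random — normal jitter on a random subset of
#' one network's weights, reflected sliding windows on a random subset of
#' origination/extinction times (respecting each taxon's occurrence
#' range), a log-multiplier on a preservation parameter, or a reflected
#' sliding window on \code{t_reg} — and returns the proposed state with
#' its log-Hastings ratio (0 for the symmetric moves, \code{log m} for
#' multipliers).
#'
#' @param params A \code{\link{bdnn_params}} state.
#' @param config An \code{\link{mcmc_config}}.
#' @param bounds Optional list with \code{min_occ}, \code{max_occ},
#'   \code{t_max} constraining time moves; required when the state carries
#'   times.
#' @return List with \code{params}, \code{log_hastings}, and \code{block}.
#' @export
propose_move <- function(params, config, bounds = NULL) {
  blocks <- names(config$update_mix)
  avail <- blocks
  if (is.null(params$s)) avail <- setdiff(avail, "times")
  if (is.null(params$q)) avail <- setdiff(avail, "preservation")
  p <- config$update_mix[avail]
  block <- sample(avail, 1, prob = p)
  lh <- 0
  if (block == "weights") {
    net <- sample(c("weights_lambda", "weights_mu"), 1)
    W <- params[[net]]
    layer <- sample(c("W1", "W2", "w3"), 1)
    v <- W[[layer]]
    k <- max(1L, round(config$weight_frac * length(v)))
    idx <- sample(length(v), k)
    v[idx] <- v[idx] + stats::rnorm(k, 0, config$scale_weights)
    W[[layer]] <- v
    params[[net]] <- W
  } else if (block == "treg") {
    params$t_reg <- reflect(params$t_reg +
                              stats::rnorm(1, 0, config$scale_treg), 0, 1)
  } else if (block == "times") {
    if (is.null(bounds)) stop("time moves require occurrence bounds")
    S <- length(params$s)
    k <- max(1L, round(config$times_frac * S))
    ids <- sample(S, k)
    for (i in ids) {
      if (params$extant[i] || stats::runif(1) < 0.5) {
        params$s[i] <- reflect(params$s[i] +
                                 stats::rnorm(1, 0, config$scale_times),
                               bounds$max_occ[i], bounds$t_max)
      } else {
        params$e[i] <- reflect(params$e[i] +
                                 stats::rnorm(1, 0, config$scale_times),
                               0, bounds$min_occ[i])
      }
    }
  } else if (block == "preservation") {
    m <- exp(stats::runif(1, -config$scale_q, config$scale_q))
    if (stats::runif(1) < 0.8) {
      b <- sample(length(params$q), 1)
      params$q[b] <- params$q[b] * m
    } else {
      params$alpha <- params$alpha * m
    }
    lh <- log(m)
  }
  list(params = params, log_hastings = lh, block = block)
}

#' Run the BDNN Metropolis-Hastings sampler
#'
#' Samples origination/extinction times, preservation parameters, the
#' weights of the speciation and extinction networks, and the shared
#' regularizer \code{t_reg} from their joint posterior under the
#' birth-death likelihood of the (point-aged) occurrence data and the
#' preservation likelihood. Occurrence age uncertainty is handled by
#' analysing replicates produced with \code{\link{resample_ages}};
#' interval-aged occurrences are collapsed to their midpoints here.
#'
#' @param dataset An \code{\link{occurrence_dataset}}.
#' @param predictors A \code{\link{predictor_tensor}} over the same
#'   species.
#' @param config An \code{\link{mcmc_config}}.
#' @return Object of class \code{bdnn_trace}: thinned posterior samples
#'   (weights, \code{t_reg}, times, preservation parameters, and the
#'   derived lineage-time rate matrices), plus acceptance statistics and
#'   everything needed to re-evaluate the likelihood in post-processing.
#' @export
run_mcmc <- function(dataset, predictors, config = mcmc_config()) {
  set.seed(config$seed)
  species <- predictors$species
  if (!setequal(species, dataset$taxa))
    stop("dataset and predictor tensor cover different species")
  S <- length(species); B <- length(predictors$bin_mid)
  edges <- predictors$time_bins
  t_max <- edges[1]
  X <- tensor_matrix(predictors)
  J <- ncol(X)
  use_lik <- as.numeric(config$likelihood == "full")

  occ <- dataset$occurrences
  ages <- (occ$min_age + occ$max_age) / 2
  if (any(ages > t_max))
    stop("occurrences older than the oldest time bin boundary")
  ti <- match(occ$taxon, species)
  bins <- .cpp_bin_of(ages, edges)
  counts <- matrix(0, S, B)
  for (r in seq_along(ages)) counts[ti[r], bins[r]] <- counts[ti[r], bins[r]] + 1
  min_occ <- rep(Inf, S); max_occ <- rep(-Inf, S)
  for (r in seq_along(ages)) {
    min_occ[ti[r]] <- min(min_occ[ti[r]], ages[r])
    max_occ[ti[r]] <- max(max_occ[ti[r]], ages[r])
  }
  extant <- dataset$extant[match(species, dataset$taxa)]
  bounds <- list(min_occ = min_occ, max_occ = max_occ, t_max = t_max)

  arch <- bdnn_architecture(J, config$hidden, config$bias)
  s <- pmin(max_occ + 0.01, t_max)
  s <- pmax(s, max_occ)  # guard grids that end at an occurrence age
  e <- ifelse(extant, 0, pmax(min_occ - 0.01, 0))
  bad <- which(s <= e)
  if (length(bad)) s[bad] <- e[bad] + 0.01

  init_sd <- config$init_weight_sd
  for (attempt in 1:6) {
    Wl <- draw_weights(arch, init_sd)
    Wm <- draw_weights(arch, init_sd)
    # start at the constant-rate null (prior mode); heterogeneity must be
    # earned by the likelihood, which mixes far better than a mid-range
    # start whose early weight adaptation can lock t_reg high
    treg <- 0.05
    q <- rep(1, B); alpha <- 1
    m_cats <- gamma_categories(alpha, config$n_categories)
    H1l <- .cpp_layer_tanh(X, Wl$W1); H2l <- .cpp_layer_tanh(H1l, Wl$W2)
    H1m <- .cpp_layer_tanh(X, Wm$W1); H2m <- .cpp_layer_tanh(H1m, Wm$W2)
    bl_l <- as.numeric(.cpp_output_softplus(H2l, Wl$w3, Wl$bias))
    bl_m <- as.numeric(.cpp_output_softplus(H2m, Wm$w3, Wm$bias))
    lam <- matrix(.cpp_regularize(bl_l, treg), S, B)
    mu <- matrix(.cpp_regularize(bl_m, treg), S, B)
    bd <- as.numeric(.cpp_bd_loglik(s, e, extant, lam, mu, edges))
    pres <- as.numeric(.cpp_preservation_loglik(counts, s, e, q, m_cats,
                                                edges))
    if (all(is.finite(bd)) && all(is.finite(pres))) break
    init_sd <- init_sd / 2
    if (attempt == 6) stop("could not initialize a finite posterior")
  }
  pr_wl <- weights_prior(Wl); pr_wm <- weights_prior(Wm)
  pr_treg <- treg_prior(treg); pr_q <- q_prior(q); pr_alpha <- alpha_prior(alpha)

  n_iter <- config$n_iterations
  freq <- config$sampling_freq
  burn_iter <- n_iter - floor((1 - config$burnin) * n_iter)
  n_samp <- floor((n_iter - burn_iter) / freq)
  samples <- vector("list", n_samp)
  acc <- att <- c(times = 0, weights = 0, preservation = 0, treg = 0)
  blocks <- names(config$update_mix)
  mixp <- as.numeric(config$update_mix)

  log_file <- NULL
  if (!is.null(config$out_prefix)) {
    log_file <- paste0(config$out_prefix, ".trace.tsv")
    cat("iteration\tposterior\tloglik\tprior\tt_reg\talpha\tmean_q",
        "\tmean_lambda\tmean_mu\n", sep = "", file = log_file)
  }

  si <- 0L
  for (it in seq_len(n_iter)) {
    block <- sample(blocks, 1, prob = mixp)
    att[block] <- att[block] + 1
    if (block == "weights") {
      is_l <- stats::runif(1) < 0.5
      W <- if (is_l) Wl else Wm
      if (stats::runif(1) < 0.5) {
        # joint jitter of one input row of W1: explores the overall
        # leverage of a single predictor much faster than scattered moves
        layer <- "W1"
        v <- W$W1
        j <- sample.int(nrow(v), 1)
        v[j, ] <- v[j, ] + stats::rnorm(ncol(v), 0,
                                        config$scale_weights / 2)
        W$W1 <- v
      } else {
        layer <- sample(c("W1", "W2", "w3"), 1)
        v <- W[[layer]]
        k <- max(1L, round(config$weight_frac * length(v)))
        idx <- sample.int(length(v), k)
        v[idx] <- v[idx] + stats::rnorm(k, 0, config$scale_weights)
        W[[layer]] <- v
      }
      # recompute only the layers downstream of the change
      H1_new <- if (layer == "W1") .cpp_layer_tanh(X, W$W1) else
        if (is_l) H1l else H1m
      H2_new <- if (layer %in% c("W1", "W2")) .cpp_layer_tanh(H1_new, W$W2)
        else if (is_l) H2l else H2m
      bl_new <- as.numeric(.cpp_output_softplus(H2_new, W$w3, W$bias))
      if (is_l) {
        lam_new <- matrix(.cpp_regularize(bl_new, treg), S, B)
        bd_new <- as.numeric(.cpp_bd_loglik(s, e, extant, lam_new, mu, edges))
      } else {
        mu_new <- matrix(.cpp_regularize(bl_new, treg), S, B)
        bd_new <- as.numeric(.cpp_bd_loglik(s, e, extant, lam, mu_new, edges))
      }
      pr_new <- weights_prior(W)
      d <- use_lik * (sum(bd_new) - sum(bd)) +
        pr_new - (if (is_l) pr_wl else pr_wm)
      if (is.finite(d) && log(stats::runif(1)) < d) {
        acc[block] <- acc[block] + 1
        bd <- bd_new
        if (is_l) {
          Wl <- W; bl_l <- bl_new; lam <- lam_new; pr_wl <- pr_new
          H1l <- H1_new; H2l <- H2_new
        } else {
          Wm <- W; bl_m <- bl_new; mu <- mu_new; pr_wm <- pr_new
          H1m <- H1_new; H2m <- H2_new
        }
      }
    } else if (block == "treg") {
      treg_new <- reflect(treg + stats::rnorm(1, 0, config$scale_treg), 0, 1)
      lam_new <- matrix(.cpp_regularize(bl_l, treg_new), S, B)
      mu_new <- matrix(.cpp_regularize(bl_m, treg_new), S, B)
      bd_new <- as.numeric(.cpp_bd_loglik(s, e, extant, lam_new, mu_new,
                                          edges))
      pr_new <- treg_prior(treg_new)
      d <- use_lik * (sum(bd_new) - sum(bd)) + pr_new - pr_treg
      if (is.finite(d) && log(stats::runif(1)) < d) {
        acc[block] <- acc[block] + 1
        treg <- treg_new; lam <- lam_new; mu <- mu_new; bd <- bd_new
        pr_treg <- pr_new
      }
    } else if (block == "times") {
      # sequential single-taxon updates over a random subset
      k <- max(1L, round(config$times_frac * S))
      ids <- sample.int(S, k)
      n_acc <- 0L
      for (i in ids) {
        si_new <- s[i]; ei_new <- e[i]
        if (extant[i] || stats::runif(1) < 0.5) {
          si_new <- reflect(s[i] + stats::rnorm(1, 0, config$scale_times),
                            max_occ[i], t_max)
        } else {
          ei_new <- reflect(e[i] + stats::rnorm(1, 0, config$scale_times),
                            0, min_occ[i])
        }
        if (si_new <= ei_new) next
        bd_i <- as.numeric(.cpp_bd_loglik(si_new, ei_new, extant[i],
                                          lam[i, , drop = FALSE],
                                          mu[i, , drop = FALSE], edges))
        pres_i <- as.numeric(.cpp_preservation_loglik(
          counts[i, , drop = FALSE], si_new, ei_new, q, m_cats, edges))
        d <- use_lik * (bd_i - bd[i] + pres_i - pres[i])
        if (is.finite(d) && log(stats::runif(1)) < d) {
          n_acc <- n_acc + 1L
          s[i] <- si_new; e[i] <- ei_new
          bd[i] <- bd_i; pres[i] <- pres_i
        }
      }
      if (n_acc > 0) acc[block] <- acc[block] + 1
    } else { # preservation
      m <- exp(stats::runif(1, -config$scale_q, config$scale_q))
      if (stats::runif(1) < 0.8) {
        q_new <- q; b <- sample.int(B, 1); q_new[b] <- q_new[b] * m
        pres_new <- as.numeric(.cpp_preservation_loglik(counts, s, e, q_new,
                                                        m_cats, edges))
        pr_new <- q_prior(q_new)
        d <- use_lik * (sum(pres_new) - sum(pres)) + pr_new - pr_q + log(m)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          acc[block] <- acc[block] + 1
          q <- q_new; pres <- pres_new; pr_q <- pr_new
        }
      } else {
        alpha_new <- alpha * m
        m_new <- gamma_categories(alpha_new, config$n_categories)
        pres_new <- as.numeric(.cpp_preservation_loglik(counts, s, e, q,
                                                        m_new, edges))
        pr_new <- alpha_prior(alpha_new)
        d <- use_lik * (sum(pres_new) - sum(pres)) + pr_new - pr_alpha +
          log(m)
        if (is.finite(d) && log(stats::runif(1)) < d) {
          acc[block] <- acc[block] + 1
          alpha <- alpha_new; m_cats <- m_new; pres <- pres_new
          pr_alpha <- pr_new
        }
      }
    }

    if (it > burn_iter && (it - burn_iter) %% freq == 0 && si < n_samp) {
      si <- si + 1L
      loglik <- sum(bd) + sum(pres)
      prior <- pr_wl + pr_wm + pr_treg + pr_q + pr_alpha
      samples[[si]] <- list(
        iteration = it, loglik = loglik, prior = prior,
        posterior = use_lik * loglik + prior,
        t_reg = treg, q = q, alpha = alpha, s = s, e = e,
        lambda = lam, mu = mu,
        weights_lambda = Wl, weights_mu = Wm,
        mean_bl_lambda = mean(bl_l), mean_bl_mu = mean(bl_m))
      if (!is.null(log_file))
        cat(sprintf("%d\t%.4f\t%.4f\t%.4f\t%.5f\t%.4f\t%.4f\t%.5f\t%.5f\n",
                    it, use_lik * loglik + prior, loglik, prior, treg,
                    alpha, mean(q), mean(lam), mean(mu)),
            file = log_file, append = TRUE)
    }
  }

  trace <- structure(list(
    samples = samples, species = species, time_bins = edges,
    extant = extant, counts = counts, bounds = bounds,
    predictors = predictors, config = config,
    acceptance = rbind(accepted = acc, attempted = att)),
    class = "bdnn_trace")
  if (!is.null(config$out_prefix)) {
    saveRDS(trace, paste0(config$out_prefix, ".trace.rds"))
    utils::write.table(
      data.frame(species = species,
                 lambda = rowMeans(sapply(samples, function(z)
                   rowMeans(z$lambda))),
                 mu = rowMeans(sapply(samples, function(z) rowMeans(z$mu)))),
      paste0(config$out_prefix, ".rates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  trace
}

#' @export
print.bdnn_trace <- function(x, ...) {
  cat("BDNN posterior trace:", length(x$samples), "samples,",
      length(x$species), "species,", length(x$time_bins) - 1, "time bins\n")
  ar <- x$acceptance["accepted", ] / pmax(x$acceptance["attempted", ], 1)
  cat("Acceptance rates:",
      paste(names(ar), sprintf("%.2f", ar), collapse = ", "), "\n")
  invisible(x)
}

#' Number of posterior samples in a trace
#' @param trace A \code{bdnn_trace}.
#' @return Integer sample count.
#' @export
n_samples <- function(trace) length(trace$samples)

# Per-sample scalar or array extraction helpers.
trace_field <- function(trace, field) {
  lapply(trace$samples, `[[`, field)
}

#' Posterior mean lineage-time rate matrices
#' @param trace A \code{bdnn_trace}.
#' @return List with matrices \code{lambda} and \code{mu}.
#' @export
posterior_mean_rates <- function(trace) {
  lam <- Reduce(`+`, trace_field(trace, "lambda")) / n_samples(trace)
  mu <- Reduce(`+`, trace_field(trace, "mu")) / n_samples(trace)
  list(lambda = lam, mu = mu)
}
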