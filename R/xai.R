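# Post-hoc predictor-effect estimation from a posterior trace: partial
# dependence, permutation importance, PD posterior rate differences,
# kappa-additive SHAP values, and consensus ranking.

# Evenly thinned sample indices.
thin_idx <- function(trace, n_samples) {
  M <- n_samples(trace)
  if (is.null(n_samples) || n_samples >= M) return(seq_len(M))
  unique(round(seq(1, M, length.out = n_samples)))
}

# Resolve a predictor name to its tensor column(s); one-hot groups map to
# their member columns.
predictor_columns <- function(predictors, name) {
  kinds <- predictors$predictor_kinds
  nms <- predictors$predictor_names
  if (name %in% nms && !startsWith(kinds[match(name, nms)], "one-hot"))
    return(list(cols = name, kind = kinds[match(name, nms)]))
  grp <- paste0("one-hot:", name)
  members <- nms[kinds == grp]
  if (!length(members)) stop("unknown predictor: ", name)
  list(cols = members, kind = "one-hot",
       states = sub(paste0("^", name, "_"), "", members))
}

# Base predictor names: one-hot groups collapsed to the group name.
base_predictors <- function(predictors) {
  kinds <- predictors$predictor_kinds
  nms <- predictors$predictor_names
  out <- character()
  for (j in seq_along(nms)) {
    if (startsWith(kinds[j], "one-hot")) {
      out <- c(out, sub("^one-hot:", "", kinds[j]))
    } else out <- c(out, nms[j])
  }
  unique(out)
}

# Default evaluation grid of a predictor.
default_grid <- function(predictors, name, n_grid = 100) {
  pc <- predictor_columns(predictors, name)
  if (pc$kind == "one-hot") return(pc$states)
  X <- tensor_matrix(predictors)
  v <- X[, pc$cols]
  if (pc$kind == "binary") return(sort(unique(v)))
  if (name == "time") return(unique(v))  # bin midpoints (z-scaled)
  seq(min(v), max(v), length.out = n_grid)
}

# Rates for a modified flat predictor matrix under one posterior sample.
sample_rates_for <- function(z, X, target) {
  W <- if (target == "lambda") z$weights_lambda else z$weights_mu
  bl <- as.numeric(.cpp_forward_baseline(X, W$W1, W$W2, W$w3, W$bias))
  as.numeric(.cpp_regularize(bl, z$t_reg))
}

#' Partial dependence of a rate on one or two predictors
#'
#' Marginal effect of a predictor on the speciation or extinction rate:
#' for each grid value and posterior sample, the predictor is set to that
#' value in every (species, time-bin) row, the rates are recomputed
#' through the networks, and averaged over rows. One-hot encoded
#' predictors are evaluated at their states (group columns toggled
#' jointly); pairs of predictors are evaluated on the grid product.
#'
#' @param trace A \code{bdnn_trace}.
#' @param target \code{"lambda"} or \code{"mu"}.
#' @param predictor Predictor name (or a one-hot group name).
#' @param predictor2 Optional second predictor for a two-way effect.
#' @param grid,grid2 Evaluation grid(s); default 100 equally spaced points
#'   over the observed range (continuous), the states (categorical), or
#'   the bin midpoints (time).
#' @param n_grid Grid resolution when \code{grid} is NULL.
#' @param n_samples Number of (evenly thinned) posterior samples to use.
#' @param level Credible level of the returned interval.
#' @return Object of class \code{pd_curve}: grid data frame, per-sample
#'   marginal rates (samples x grid), posterior mean and CI.
#' @export
partial_dependence <- function(trace, target = c("lambda", "mu"), predictor,
                               predictor2 = NULL, grid = NULL, grid2 = NULL,
                               n_grid = 100, n_samples = NULL,
                               level = 0.95) {
  target <- match.arg(target)
  pt <- trace$predictors
  if (is.null(grid)) grid <- default_grid(pt, predictor, n_grid)
  gdf <- data.frame(v1 = grid)
  names(gdf) <- predictor
  if (!is.null(predictor2)) {
    if (is.null(grid2)) grid2 <- default_grid(pt, predictor2, n_grid)
    gdf <- expand.grid(v1 = grid, v2 = grid2, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
    names(gdf) <- c(predictor, predictor2)
  }
  X0 <- tensor_matrix(pt)
  idx <- thin_idx(trace, n_samples)
  out <- matrix(NA_real_, length(idx), nrow(gdf))
  for (mi in seq_along(idx)) {
    z <- trace$samples[[idx[mi]]]
    for (g in seq_len(nrow(gdf))) {
      X <- set_predictor(X0, pt, predictor, gdf[[1]][g])
      if (!is.null(predictor2))
        X <- set_predictor(X, pt, predictor2, gdf[[2]][g])
      out[mi, g] <- mean(sample_rates_for(z, X, target))
    }
  }
  a <- (1 - level) / 2
  structure(list(predictor = c(predictor, predictor2), grid = gdf,
                 samples = out, mean = colMeans(out),
                 lo = apply(out, 2, stats::quantile, a),
                 hi = apply(out, 2, stats::quantile, 1 - a),
                 target = target),
            class = "pd_curve")
}

#' @export
print.pd_curve <- function(x, ...) {
  cat("Partial dependence of", x$target, "on",
      paste(x$predictor, collapse = " x "), "(",
      nrow(x$samples), "posterior samples x", nrow(x$grid),
      "grid points )\n")
  df <- cbind(x$grid, mean = x$mean, lo = x$lo, hi = x$hi)
  print(utils::head(df, 12))
  invisible(x)
}

#' PD-based posterior rate difference
#'
#' Importance of a predictor as the consistency of its effect direction:
#' locates the maximum and minimum of the posterior-mean partial
#' dependence curve and returns the fraction of posterior samples in
#' which the rate at the maximum exceeds the rate at the minimum (ties
#' count one half; a flat curve gives 0.5, "no effect").
#'
#' @param pd A \code{pd_curve}.
#' @return Probability in [0, 1].
#' @export
pd_posterior_difference <- function(pd) {
  if (nrow(pd$grid) < 2) stop("PD posterior difference needs >= 2 grid points")
  amax <- which.max(pd$mean)
  amin <- which.min(pd$mean)
  if (amax == amin) return(0.5)
  mean(pd$samples[, amax] > pd$samples[, amin]) +
    0.5 * mean(pd$samples[, amax] == pd$samples[, amin])
}

# Permute one predictor in the flat matrix. Species-level predictors are
# permuted across species (jointly over a one-hot group, constant within a
# species' time rows); bin-level predictors (time, environmental series)
# are permuted across time bins, so each predictor is shuffled along the
# axis on which it actually varies.
permute_predictor <- function(X, predictors, name, perm_s, perm_b) {
  pc <- predictor_columns(predictors, name)
  S <- length(predictors$species); B <- length(predictors$bin_mid)
  # a predictor is bin-level iff its values are constant across species
  col1 <- pc$cols[1]
  M1 <- matrix(X[, col1], S, B)
  bin_level <- all(abs(M1 - rep(M1[1, ], each = S)) < 1e-12)
  for (cn in pc$cols) {
    M <- matrix(X[, cn], S, B)
    M <- if (bin_level) M[, perm_b, drop = FALSE]
         else M[perm_s, , drop = FALSE]
    X[, cn] <- as.numeric(M)
  }
  X
}

#' Permutation importance of predictors
#'
#' Decrease in the birth-death log-likelihood after permuting a
#' predictor's values, averaged over posterior samples and permutations.
#' Species-level predictors are permuted across species (one-hot groups
#' as a block); predictors varying only through time are permuted across
#' time bins. The interaction score of a pair is the drop after jointly
#' permuting both minus the sum of the two single drops.
#'
#' @param trace A \code{bdnn_trace}.
#' @param predictor Predictor name.
#' @param predictor2 Optional second predictor (interaction score).
#' @param n_perm Permutations per posterior sample.
#' @param n_samples Posterior samples to use (evenly thinned).
#' @param seed Seed for the permutations.
#' @return Scalar importance score (expected log-likelihood drop).
#' @export
permutation_importance <- function(trace, predictor, predictor2 = NULL,
                                   n_perm = 10, n_samples = NULL,
                                   seed = 1) {
  set.seed(seed)
  pt <- trace$predictors
  S <- length(pt$species); B <- length(pt$bin_mid)
  if (S < 2) stop("permutation importance needs >= 2 species")
  edges <- trace$time_bins
  X0 <- tensor_matrix(pt)
  idx <- thin_idx(trace, n_samples)
  bd_of <- function(z, X) {
    lam <- matrix(sample_rates_for(z, X, "lambda"), S, B)
    mu <- matrix(sample_rates_for(z, X, "mu"), S, B)
    sum(.cpp_bd_loglik(z$s, z$e, trace$extant, lam, mu, edges))
  }
  drops <- matrix(NA_real_, length(idx), n_perm)
  drops2 <- dropsJ <- drops
  for (mi in seq_along(idx)) {
    z <- trace$samples[[idx[mi]]]
    ll0 <- sum(.cpp_bd_loglik(z$s, z$e, trace$extant, z$lambda, z$mu, edges))
    for (p in seq_len(n_perm)) {
      ps <- sample(S); pb <- sample(B)
      Xp <- permute_predictor(X0, pt, predictor, ps, pb)
      drops[mi, p] <- ll0 - bd_of(z, Xp)
      if (!is.null(predictor2)) {
        ps2 <- sample(S); pb2 <- sample(B)
        Xq <- permute_predictor(X0, pt, predictor2, ps2, pb2)
        drops2[mi, p] <- ll0 - bd_of(z, Xq)
        Xj <- permute_predictor(Xp, pt, predictor2, ps2, pb2)
        dropsJ[mi, p] <- ll0 - bd_of(z, Xj)
      }
    }
  }
  if (is.null(predictor2)) return(mean(drops))
  mean(dropsJ) - mean(drops) - mean(drops2)
}

# --- SHAP -------------------------------------------------------------

# Coalition value function: v(S) for each row of `rows`, computed as the
# marginal expectation over a background matrix Z of the per-row model
# (forward pass + frozen regularization constant).
coalition_values <- function(rows, Z, mask, W, t_reg, reg_const) {
  n <- nrow(rows); nbg <- nrow(Z)
  M <- Z[rep(seq_len(nbg), n), , drop = FALSE]
  for (j in which(mask))
    M[, j] <- rep(rows[, j], each = nbg)
  bl <- as.numeric(.cpp_forward_baseline(M, W$W1, W$W2, W$w3, W$bias))
  f <- bl^t_reg * reg_const
  colMeans(matrix(f, nbg, n))
}

# All subset masks of 1:J as a logical matrix (2^J rows).
all_masks <- function(J) {
  m <- matrix(FALSE, 2^J, J)
  for (j in seq_len(J)) m[, j] <- rep(c(FALSE, TRUE), each = 2^(j - 1),
                                      length.out = 2^J)
  m
}

#' SHAP values of the rate networks
#'
#' Additive per-predictor attributions of the speciation or extinction
#' rate for each (species, time-bin) row: \code{base + sum_j phi_j =
#' rate}, with absent predictors imputed by averaging the model over a
#' background sample of rows (marginal expectations). The default
#' \code{kernel} method fits a kappa-additive (kappa = 2) game by
#' constrained weighted least squares with the Shapley kernel, yielding
#' both the per-predictor attributions and pairwise interaction terms;
#' \code{exact} enumerates all \code{2^J} coalitions (J <= 12) and serves
#' as the reference estimator. The regularization layer is applied with
#' the normalizing constant of each posterior sample's full rate matrix
#' held fixed, making the attributed model a per-row function.
#'
#' @param trace A \code{bdnn_trace}.
#' @param target \code{"lambda"} or \code{"mu"}.
#' @param method \code{"kernel"} (kappa-additive) or \code{"exact"}.
#' @param rows Indices of (species, time-bin) cells to explain (default:
#'   up to 100 random cells).
#' @param n_samples Posterior samples to average over (default 10).
#' @param n_background Background rows for the marginal expectation.
#' @param seed Seed for row/background subsampling.
#' @return Object of class \code{shap_values}: \code{phi} (rows x J
#'   matrix, averaged over posterior samples), \code{base} (per-row base
#'   values), \code{rate} (per-row model output), \code{interactions}
#'   (J x J mean absolute pairwise terms; kernel method only), and the
#'   row/predictor bookkeeping.
#' @export
shap_values <- function(trace, target = c("lambda", "mu"),
                        method = c("kernel", "exact"), rows = NULL,
                        n_samples = 10, n_background = 100, seed = 1) {
  target <- match.arg(target)
  method <- match.arg(method)
  set.seed(seed)
  pt <- trace$predictors
  X0 <- tensor_matrix(pt)
  J <- ncol(X0)
  if (J < 2) stop("SHAP attribution needs >= 2 predictors")
  if (method == "exact" && J > 12)
    stop("exact SHAP enumeration is limited to J <= 12 predictors")
  if (is.null(rows)) rows <- sample(nrow(X0), min(100, nrow(X0)))
  bg <- X0[sample(nrow(X0), min(n_background, nrow(X0))), , drop = FALSE]
  R <- X0[rows, , drop = FALSE]
  idx <- thin_idx(trace, n_samples)

  masks <- all_masks(J)
  sizes <- rowSums(masks)
  if (method == "kernel") {
    use <- which(sizes > 0 & sizes < J)
    # Shapley kernel weights
    wts <- (J - 1) / (choose(J, sizes[use]) * sizes[use] * (J - sizes[use]))
    # design over (a_i, a_ij)
    pairs <- t(utils::combn(J, 2))
    Zd <- cbind(masks[use, , drop = FALSE] * 1,
                (masks[use, pairs[, 1], drop = FALSE] &
                   masks[use, pairs[, 2], drop = FALSE]) * 1)
    cvec <- rep(1, ncol(Zd))
    ZtWZ <- t(Zd) %*% (Zd * wts)
    K <- rbind(cbind(ZtWZ + diag(1e-10, ncol(Zd)), cvec), c(cvec, 0))
  }

  phi_sum <- matrix(0, length(rows), J)
  inter_sum <- matrix(0, J, J)
  base_sum <- rate_sum <- numeric(length(rows))
  for (mi in seq_along(idx)) {
    z <- trace$samples[[idx[mi]]]
    W <- if (target == "lambda") z$weights_lambda else z$weights_mu
    # frozen normalizer E(bl) / E(bl^t) of the sample's full matrix
    bl_all <- as.numeric(.cpp_forward_baseline(X0, W$W1, W$W2, W$w3, W$bias))
    reg_const <- mean(bl_all) / mean(bl_all^z$t_reg)
    v <- matrix(NA_real_, nrow(masks), length(rows))
    which_eval <- if (method == "exact") seq_len(nrow(masks)) else
      c(which(sizes == 0), which(sizes > 0 & sizes < J), which(sizes == J))
    for (k in which_eval)
      v[k, ] <- coalition_values(R, bg, masks[k, ], W, z$t_reg, reg_const)
    v0 <- v[which(sizes == 0), ]
    vN <- v[which(sizes == J), ]
    base_sum <- base_sum + v0
    rate_sum <- rate_sum + vN
    if (method == "exact") {
      for (j in seq_len(J)) {
        without <- which(!masks[, j])
        with_j <- without + 2^(j - 1)
        ssz <- sizes[without]
        wgt <- factorial(ssz) * factorial(J - ssz - 1) / factorial(J)
        phi_sum[, j] <- phi_sum[, j] +
          colSums((v[with_j, , drop = FALSE] -
                     v[without, , drop = FALSE]) * wgt)
      }
    } else {
      g <- v[use, , drop = FALSE] - matrix(v0, length(use), length(rows),
                                           byrow = TRUE)
      rhs <- rbind(t(Zd) %*% (g * wts), vN - v0)
      sol <- solve(K, rhs)
      a_i <- sol[seq_len(J), , drop = FALSE]
      a_ij <- sol[J + seq_len(nrow(pairs)), , drop = FALSE]
      phim <- t(a_i)
      for (p in seq_len(nrow(pairs))) {
        phim[, pairs[p, 1]] <- phim[, pairs[p, 1]] + a_ij[p, ] / 2
        phim[, pairs[p, 2]] <- phim[, pairs[p, 2]] + a_ij[p, ] / 2
        inter_sum[pairs[p, 1], pairs[p, 2]] <-
          inter_sum[pairs[p, 1], pairs[p, 2]] + mean(abs(a_ij[p, ]))
      }
      phi_sum <- phi_sum + phim
    }
  }
  M <- length(idx)
  inter <- (inter_sum + t(inter_sum)) / M
  dimnames(inter) <- list(pt$predictor_names, pt$predictor_names)
  structure(list(phi = phi_sum / M, base = base_sum / M,
                 rate = rate_sum / M, interactions = inter,
                 rows = rows, predictors = pt$predictor_names,
                 target = target, method = method),
            class = "shap_values")
}

#' @export
print.shap_values <- function(x, ...) {
  cat("SHAP values (", x$method, ") for", x$target, ":",
      nrow(x$phi), "rows x", ncol(x$phi), "predictors\n")
  cat("mean |phi|:\n")
  print(sort(colMeans(abs(x$phi)), decreasing = TRUE))
  invisible(x)
}

#' Consensus ranking of predictors
#'
#' Aggregates several metric-wise rankings into one consensus ordering:
#' the Kemeny-optimal ranking (minimum total Kendall distance to the
#' input rankings, found by exhaustive search) for up to 8 items, and the
#' mean-rank (Borda) ordering for larger sets. Ties are broken by mean
#' rank and then by name.
#'
#' @param ranks Matrix of ranks (metrics x predictors, 1 = most
#'   important), with predictor names as column names.
#' @return Character vector of predictor names, most important first.
#' @export
consensus_rank <- function(ranks) {
  ranks <- as.matrix(ranks)
  n <- ncol(ranks)
  nms <- colnames(ranks)
  if (is.null(nms)) nms <- paste0("p", seq_len(n))
  mean_rank <- colMeans(ranks)
  borda <- nms[order(mean_rank, nms)]
  if (n > 8 || n < 2) return(borda)
  # pairwise preference counts: P[i, j] = #metrics ranking i before j
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    P[i, j] <- sum(ranks[, i] < ranks[, j])
  perms <- all_perms(n)
  cost <- apply(perms, 1, function(p) {
    cst <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      cst <- cst + P[p[b], p[a]]
    cst
  })
  best <- which(cost == min(cost))
  if (length(best) > 1) {
    # among Kemeny optima prefer agreement with mean rank, then name
    dev <- sapply(best, function(k)
      sum(abs(match(seq_len(n), perms[k, ]) - rank(mean_rank))))
    best <- best[order(dev, apply(perms[best, , drop = FALSE], 1,
                                  function(p) paste(nms[p],
                                                    collapse = "")))]
  }
  nms[perms[best[1], ]]
}

# All permutations of 1:n as rows (n <= 8).
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(nrow(sub))) for (pos in seq_len(n)) {
    r <- r + 1L
    out[r, ] <- append(sub[i, ] + 1L, 1L, after = pos - 1L)
  }
  out
}

#' Rank predictors by importance
#'
#' Builds the importance table of individual predictors for one rate
#' type: permutation score (log-likelihood drop), PD posterior-difference
#' probability, and mean absolute SHAP value, each ranked separately,
#' plus their consensus ranking. One-hot groups are treated as single
#' predictors (permuted as blocks, SHAP summed over member columns, PD
#' over the states).
#'
#' @param trace A \code{bdnn_trace}.
#' @param target \code{"lambda"} or \code{"mu"}.
#' @param predictors Base predictor names to rank (default: all).
#' @param n_perm,n_samples,n_grid,n_background Effort knobs passed to the
#'   underlying metrics.
#' @param seed Seed for the stochastic components.
#' @return Object of class \code{importance_table}: data frame with one
#'   row per predictor, the three metric scores, their ranks, and the
#'   consensus rank.
#' @export
rank_predictors <- function(trace, target = c("lambda", "mu"),
                            predictors = NULL, n_perm = 5, n_samples = 10,
                            n_grid = 12, n_background = 50, seed = 1) {
  target <- match.arg(target)
  pt <- trace$predictors
  if (is.null(predictors)) predictors <- base_predictors(pt)
  perm <- pd <- numeric(length(predictors))
  for (k in seq_along(predictors)) {
    perm[k] <- permutation_importance(trace, predictors[k], n_perm = n_perm,
                                      n_samples = n_samples, seed = seed)
    pdc <- partial_dependence(trace, target, predictors[k], n_grid = n_grid,
                              n_samples = n_samples)
    pd[k] <- pd_posterior_difference(pdc)
  }
  sh <- shap_values(trace, target, method = "kernel",
                    n_samples = min(n_samples, 5),
                    n_background = n_background, seed = seed)
  shap_score <- vapply(predictors, function(nm) {
    cols <- predictor_columns(pt, nm)$cols
    ci <- match(cols, pt$predictor_names)
    mean(abs(rowSums(sh$phi[, ci, drop = FALSE])))
  }, numeric(1))
  rk <- function(x) rank(-x, ties.method = "average")
  ranks <- rbind(perm = rk(perm), pd = rk(pd), shap = rk(shap_score))
  colnames(ranks) <- predictors
  cons <- consensus_rank(ranks)
  df <- data.frame(predictor = predictors, permutation = perm,
                   pd_probability = pd, mean_abs_shap = shap_score,
                   rank_permutation = ranks["perm", ],
                   rank_pd = ranks["pd", ], rank_shap = ranks["shap", ],
                   consensus_rank = match(predictors, cons))
  df <- df[order(df$consensus_rank), ]
  rownames(df) <- NULL
  structure(df, class = c("importance_table", "data.frame"),
            target = target)
}
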