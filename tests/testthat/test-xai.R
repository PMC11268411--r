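test_that("partial dependence is flat for a predictor with zero weights", {
  ds <- toy_dataset(S = 6, seed = 4)
  pt <- toy_tensor(ds, seed = 4)
  tr <- toy_trace(ds, pt, n_samp = 4, seed = 4,
                  modify_weights = zero_predictor_weights("cont_trait", pt))
  pd <- partial_dependence(tr, "lambda", "cont_trait", n_grid = 8)
  expect_lt(diff(range(pd$mean)), 1e-12)
  expect_true(all(pd$samples > 0))
  expect_error(partial_dependence(tr, "lambda", "no_such"), "unknown")
})

test_that("single-sample PD equals a brute-force recomputation (oracle)", {
  ds <- toy_dataset(S = 5, seed = 6)
  pt <- toy_tensor(ds, seed = 6)
  tr <- toy_trace(ds, pt, n_samp = 1, seed = 6, t_reg = 0.8)
  v <- 0.37
  pd <- partial_dependence(tr, "mu", "cont_trait", grid = c(v, 1))
  # oracle: rebuild every row explicitly and push it through the model
  z <- tr$samples[[1]]
  X <- bdnn:::tensor_matrix(pt)
  X[, "cont_trait"] <- v
  bl <- forward_baseline(z$weights_mu, X)
  oracle <- mean(regularize_rates(bl, z$t_reg))
  expect_equal(pd$samples[1, 1], oracle, tolerance = 1e-12)

  # one-hot group evaluated at its states toggles the block jointly
  ds3 <- occurrence_dataset(
    data.frame(taxon = c("A", "B", "C"), min_age = 1:3, max_age = 1:3),
    extant = character(), time_bins = c(5, 2.5, 0))
  tr3 <- data.frame(row.names = c("A", "B", "C"),
                    region = c("af", "eu", "am"), x = rnorm(3))
  pt3 <- build_predictor_tensor(ds3, traits = tr3, time_bins = c(5, 2.5, 0))
  trace3 <- toy_trace(ds3, pt3, n_samp = 2, seed = 3)
  pd3 <- partial_dependence(trace3, "lambda", "region")
  expect_equal(nrow(pd3$grid), 3)
  expect_true(all(is.finite(pd3$mean)))
})

test_that("PD posterior difference counts sample-wise exceedances", {
  # hand-built 3-sample curve object
  pd <- structure(list(
    predictor = "x", grid = data.frame(x = c(0, 1, 2)),
    samples = rbind(c(1.0, 1.4, 1.2),
                    c(1.1, 1.0, 1.05),
                    c(0.9, 1.3, 1.0)),
    mean = colMeans(rbind(c(1.0, 1.4, 1.2), c(1.1, 1.0, 1.05),
                          c(0.9, 1.3, 1.0))),
    target = "lambda"), class = "pd_curve")
  # mean curve peaks at grid 2, dips at grid 1; samples 1 and 3 exceed
  expect_equal(pd_posterior_difference(pd), 2 / 3)

  # monotone-increasing in every sample: probability 1
  inc <- structure(list(grid = data.frame(x = 1:3),
                        samples = rbind(1:3, 2:4) * 1.0,
                        mean = c(1.5, 2.5, 3.5)), class = "pd_curve")
  expect_equal(pd_posterior_difference(inc), 1)

  # identical rates everywhere: "no effect", 0.5 by tie-breaking
  flat <- structure(list(grid = data.frame(x = 1:3),
                         samples = matrix(1, 2, 3),
                         mean = rep(1, 3)), class = "pd_curve")
  expect_equal(pd_posterior_difference(flat), 0.5)
})

test_that("permutation importance is exactly zero for constant predictors", {
  ds <- occurrence_dataset(
    data.frame(taxon = c("A", "B", "C", "D"), min_age = 1:4, max_age = 1:4),
    extant = character(), time_bins = seq(6, 0, -2))
  trt <- data.frame(row.names = c("A", "B", "C", "D"),
                    const = rep(1, 4), x = c(0.1, -0.4, 2, 1))
  pt <- build_predictor_tensor(ds, traits = trt, time_bins = seq(6, 0, -2))
  tr <- toy_trace(ds, pt, n_samp = 3, seed = 9)
  expect_equal(permutation_importance(tr, "const", n_perm = 4), 0)
  # a varying predictor under unfitted weights still yields a finite score
  expect_true(is.finite(permutation_importance(tr, "x", n_perm = 8,
                                               seed = 2)))
})

test_that("redundant predictor copies dilute single permutation scores", {
  # fit a small clade whose rates depend on one continuous trait, but feed
  # the analysis two identical copies of it: the posterior can lean on
  # either copy, so each single permutation score is diluted relative to
  # the total drop when both are permuted jointly
  sim <- simulate_dataset(6, seed = 91, richness = c(40, 120))
  traits <- data.frame(
    row.names = sim$truth$species,
    a = sim$tensor$values[, 1, match("cont_trait",
                                     sim$tensor$predictor_names)],
    b = sim$tensor$values[, 1, match("cont_trait",
                                     sim$tensor$predictor_names)])
  pt <- build_predictor_tensor(sim$dataset, traits = traits,
                               time_bins = sim$tensor$time_bins)
  cfg <- mcmc_config(n_iterations = 8000, sampling_freq = 100,
                     burnin = 0.25, seed = 91)
  tr <- run_mcmc(sim$dataset, pt, cfg)
  sa <- permutation_importance(tr, "a", n_perm = 5, n_samples = 10, seed = 5)
  sb <- permutation_importance(tr, "b", n_perm = 5, n_samples = 10, seed = 5)
  inter <- permutation_importance(tr, "a", "b", n_perm = 5, n_samples = 10,
                                  seed = 5)
  # redundancy shows up as a sub-additive joint drop: the interaction score
  # (joint minus the sum of singles) is negative for collinear copies
  expect_lt(inter, 0)
  expect_gt(sa + sb, 0)  # the duplicated causal trait matters overall
})

test_that("SHAP attributions satisfy local accuracy and the dummy axiom", {
  ds <- toy_dataset(S = 6, seed = 15)
  pt <- toy_tensor(ds, seed = 15, extra_cont = 1)
  tr <- toy_trace(ds, pt, n_samp = 2, seed = 15,
                  modify_weights = zero_predictor_weights("noise1", pt))
  for (method in c("kernel", "exact")) {
    sh <- shap_values(tr, "lambda", method = method, rows = 1:12,
                      n_samples = 2, n_background = 30, seed = 2)
    # local accuracy: base + sum(phi) = model output per row
    expect_lt(max(abs(sh$base + rowSums(sh$phi) - sh$rate)), 1e-6)
    # dummy: the zero-weight predictor gets zero attribution
    j <- match("noise1", pt$predictor_names)
    expect_lt(max(abs(sh$phi[, j])), 1e-10)
  }
})

test_that("SHAP symmetry: identical predictors receive equal attributions", {
  ds <- toy_dataset(S = 6, seed = 18)
  set.seed(18)
  x <- rnorm(6)
  trt <- data.frame(row.names = ds$taxa, a = x, b = x)
  pt <- build_predictor_tensor(ds, traits = trt, time_bins = ds$time_bins)
  same_rows <- function(W) {
    ja <- match("a", pt$predictor_names); jb <- match("b", pt$predictor_names)
    W$W1[jb, ] <- W$W1[ja, ]
    W
  }
  tr <- toy_trace(ds, pt, n_samp = 2, seed = 18, modify_weights = same_rows)
  ja <- match("a", pt$predictor_names); jb <- match("b", pt$predictor_names)
  for (method in c("kernel", "exact")) {
    sh <- shap_values(tr, "mu", method = method, rows = 1:10,
                      n_samples = 2, n_background = 25, seed = 3)
    expect_equal(sh$phi[, ja], sh$phi[, jb], tolerance = 1e-8)
  }
})

test_that("kernel SHAP tracks the exact enumeration at J = 5 (oracle)", {
  ds <- toy_dataset(S = 7, seed = 20)
  pt <- toy_tensor(ds, seed = 20, extra_cont = 2)  # time + 4 traits = 5+
  expect_gte(length(pt$predictor_names), 5)
  tr <- toy_trace(ds, pt, n_samp = 1, seed = 20, weight_sd = 0.8)
  rows <- 1:15
  ke <- shap_values(tr, "lambda", method = "kernel", rows = rows,
                    n_samples = 1, n_background = 40, seed = 4)
  ex <- shap_values(tr, "lambda", method = "exact", rows = rows,
                    n_samples = 1, n_background = 40, seed = 4)
  rc <- cor(as.numeric(ke$phi), as.numeric(ex$phi), method = "spearman")
  expect_gt(rc, 0.95)
  # both satisfy local accuracy on the same rows
  expect_lt(max(abs(ke$base + rowSums(ke$phi) - ke$rate)), 1e-6)
  expect_lt(max(abs(ex$base + rowSums(ex$phi) - ex$rate)), 1e-6)
})

test_that("consensus ranking aggregates metric rankings correctly", {
  # unanimity: all metrics agree
  r <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  colnames(r) <- c("A", "B", "C")
  expect_equal(consensus_rank(r), c("A", "B", "C"))
  # majority: A first on all, B/C split 2-1
  r2 <- rbind(c(1, 2, 3), c(1, 3, 2), c(1, 2, 3))
  colnames(r2) <- c("A", "B", "C")
  expect_equal(consensus_rank(r2), c("A", "B", "C"))

  # Kemeny brute-force oracle on near-consistent 5-predictor tables
  kendall <- function(ord, ranks) {
    n <- length(ord)
    d <- 0
    for (m in seq_len(nrow(ranks)))
      for (a in seq_len(n - 1)) for (b in (a + 1):n)
        d <- d + (ranks[m, ord[a]] > ranks[m, ord[b]])
    unname(d)
  }
  perm5 <- bdnn:::all_perms(5)
  set.seed(7)
  for (rep in 1:10) {
    base <- sample(5)
    ranks <- do.call(rbind, lapply(1:3, function(m) {
      r <- base
      if (runif(1) < 0.7) {  # swap one adjacent pair per metric
        i <- sample(4, 1)
        o <- order(r); r[o[c(i, i + 1)]] <- r[o[c(i + 1, i)]]
      }
      r
    }))
    colnames(ranks) <- letters[1:5]
    got <- consensus_rank(ranks)
    costs <- apply(perm5, 1, kendall, ranks = ranks)
    best <- min(costs)
    got_cost <- kendall(match(got, letters[1:5]), ranks)
    expect_equal(got_cost, best)
  }
})

test_that("the importance table ranks an informative trait consistently", {
  ds <- toy_dataset(S = 7, seed = 25)
  pt <- toy_tensor(ds, seed = 25)
  tr <- toy_trace(ds, pt, n_samp = 3, seed = 25,
                  modify_weights = zero_predictor_weights("cont_trait", pt))
  it <- rank_predictors(tr, "lambda", n_perm = 3, n_samples = 3,
                        n_grid = 6, n_background = 25, seed = 1)
  expect_s3_class(it, "importance_table")
  expect_setequal(it$predictor, bdnn:::base_predictors(pt))
  # ranks are a permutation of 1..n
  expect_setequal(it$consensus_rank, seq_len(nrow(it)))
  # a zero-weight predictor cannot out-rank every live one
  expect_gt(it$consensus_rank[it$predictor == "cont_trait"], 1)
})
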