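test_that("birth-death likelihood matches the constant-rate closed form", {
  bins <- seq(35, 0, by = -1)
  # extinct: log(lambda) + log(mu) - (lambda + mu) * (s - e)
  expect_equal(bd_lineage_loglik(10, 5, 0.2, 0.1, bins),
               log(0.2) + log(0.1) - 0.3 * 5, tolerance = 1e-12)
  # extant: no extinction term, integral to the present
  expect_equal(bd_lineage_loglik(10, 0, 0.2, 0.1, bins, extant = TRUE),
               log(0.2) - 0.3 * 10, tolerance = 1e-12)
  expect_error(bd_lineage_loglik(3, 5, 0.2, 0.1, bins), "exceed")
  expect_error(bd_lineage_loglik(10, 5, -0.2, 0.1, bins), "positive")

  set.seed(21)
  for (i in 1:200) {
    lam <- runif(1, 0.01, 1); mu <- runif(1, 0.01, 1)
    e <- runif(1, 0, 20); s <- e + runif(1, 0.1, 14)
    ext <- runif(1) < 0.5
    if (ext) e <- 0
    closed <- log(lam) - (lam + mu) * (s - e) + if (ext) 0 else log(mu)
    expect_equal(bd_lineage_loglik(s, e, lam, mu, bins, extant = ext),
                 closed, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under refinement of the time grid", {
  coarse <- c(12, 8, 4, 0)
  lam <- c(0.3, 0.15, 0.6); mu <- c(0.1, 0.25, 0.05)
  fine <- c(12, 10, 8, 6, 4, 2, 0)
  lam_f <- rep(lam, each = 2); mu_f <- rep(mu, each = 2)
  for (se in list(c(11.5, 3.2), c(9, 0), c(7.7, 6.1))) {
    expect_equal(
      bd_lineage_loglik(se[1], se[2], lam, mu, coarse),
      bd_lineage_loglik(se[1], se[2], lam_f, mu_f, fine),
      tolerance = 1e-12)
  }
})

test_that("total likelihood is additive and reduces to the constant model", {
  ds <- occurrence_dataset(
    data.frame(taxon = c("A", "A", "B", "B"),
               min_age = c(6, 3, 6, 3), max_age = c(6, 3, 6, 3)),
    extant = character(), time_bins = c(10, 5, 0))
  tr <- data.frame(row.names = c("A", "B"), x = c(1, 1))
  pt <- build_predictor_tensor(ds, traits = tr, time_bins = c(10, 5, 0))
  arch <- bdnn_architecture(2)
  set.seed(2)
  W <- draw_weights(arch)
  par <- bdnn_params(W, draw_weights(arch), t_reg = 0.7,
                     s = c(7, 7), e = c(1, 1), extant = c(FALSE, FALSE))
  # identical lineages: total = 2 x the single-lineage value at the same rates
  r <- lineage_time_rates(par, pt)
  expect_equal(r$lambda["A", ], r$lambda["B", ])
  single <- bd_lineage_loglik(7, 1, r$lambda["A", ], r$mu["A", ],
                              c(10, 5, 0))
  expect_equal(bd_total_loglik(par, pt), 2 * single, tolerance = 1e-9)

  # t_reg = 0: equals the constant-rate closed form at the grid means
  par0 <- bdnn_params(par$weights_lambda, par$weights_mu, 0,
                      s = c(7, 9), e = c(1, 0), extant = c(FALSE, TRUE))
  r0 <- lineage_time_rates(par0, pt)
  lam0 <- unname(r0$lambda[1, 1]); mu0 <- unname(r0$mu[1, 1])
  closed <- (log(lam0) + log(mu0) - (lam0 + mu0) * 6) +
    (log(lam0) - (lam0 + mu0) * 9)
  expect_equal(bd_total_loglik(par0, pt), closed, tolerance = 1e-10)
})

test_that("raising extinction lowers the likelihood of a long-lived extant lineage", {
  bins <- seq(20, 0, by = -1)
  base <- bd_lineage_loglik(18, 0, 0.3, 0.1, bins, extant = TRUE)
  worse <- bd_lineage_loglik(18, 0, 0.3, 0.2, bins, extant = TRUE)
  expect_lt(worse, base)
})

test_that("preservation likelihood matches the homogeneous Poisson closed form", {
  bins <- seq(35, 0, by = -1)
  pm <- preservation_model(q = 0.5, alpha = Inf, n_categories = 1)
  # K = 3 occurrences, lifespan 10, q = 0.5, conditioned on K >= 1
  expect_equal(preservation_loglik(c(2, 5, 9), 10, 0, pm, bins),
               3 * log(0.5) - 5 - log(1 - exp(-5)), tolerance = 1e-10)
  expect_error(preservation_loglik(c(2, 11), 10, 0, pm, bins), "within")
  expect_error(preservation_loglik(numeric(0), 10, 0, pm, bins), ">= 1")
})

test_that("doubling q with no occurrences in a bin lowers the likelihood", {
  bins <- c(10, 5, 0)
  # occurrences only in the younger bin; raise q of the empty older bin
  ll1 <- preservation_loglik(c(1, 3), 8, 0,
                             preservation_model(q = c(1, 1), alpha = Inf,
                                                n_categories = 1), bins)
  ll2 <- preservation_loglik(c(1, 3), 8, 0,
                             preservation_model(q = c(2, 1), alpha = Inf,
                                                n_categories = 1), bins)
  expect_lt(ll2, ll1)
})

test_that("discrete-gamma marginal converges to the quadrature integral", {
  bins <- seq(12, 0, by = -1)
  ages <- c(1.5, 4.2, 7.7, 9.1)
  s <- 10; e <- 1; alpha <- 1.3; q <- 0.8
  # quadrature oracle: integrate the conditional likelihood against the
  # Gamma(alpha, alpha) density
  lifespan_overlap <- function(b) {
    top <- pmin(s, bins[b]); bot <- pmax(e, bins[b + 1])
    pmax(0, top - bot)
  }
  B <- length(bins) - 1
  K <- tabulate(bdnn:::.cpp_bin_of(ages, bins), B)
  delta <- vapply(seq_len(B), lifespan_overlap, numeric(1))
  lik_given_m <- function(m)
    vapply(m, function(mm)
      exp(sum(K * log(q * mm * pmax(delta, 1e-300))[K > 0]) -
            mm * q * sum(delta)), numeric(1))
  num <- stats::integrate(function(m)
    lik_given_m(m) * stats::dgamma(m, alpha, alpha), 0, Inf,
    rel.tol = 1e-10)$value
  den <- stats::integrate(function(m)
    (1 - exp(-m * q * sum(delta))) * stats::dgamma(m, alpha, alpha), 0, Inf,
    rel.tol = 1e-10)$value
  oracle <- log(num) - log(den)
  got <- preservation_loglik(ages, s, e,
                             preservation_model(q, alpha,
                                                n_categories = 10000), bins)
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("conditioned preservation likelihood is normalized over K >= 1", {
  # small q * lifespan: enumerate occurrence-count outcomes per bin and
  # check the conditional probabilities sum to 1
  bins <- c(2, 1, 0)
  q <- c(0.3, 0.5); s <- 2; e <- 0
  pm <- preservation_model(q, alpha = Inf, n_categories = 1)
  lam <- q * 1  # expected counts per bin (overlap 1 each)
  p0 <- exp(-sum(lam))
  tot <- 0
  for (k1 in 0:12) for (k2 in 0:12) {
    if (k1 + k2 == 0) next
    # probability of (k1, k2) occurrences under the Poisson model
    p <- dpois(k1, lam[1]) * dpois(k2, lam[2])
    tot <- tot + p / (1 - p0)
  }
  expect_equal(tot, 1, tolerance = 1e-8)
  # and the implemented density agrees with the Poisson factorization up to
  # the uniform age density within bins
  ages <- c(1.5, 0.5, 0.25)
  ll <- preservation_loglik(ages, s, e, pm, bins)
  manual <- (1 * log(q[1]) - q[1]) + (2 * log(q[2]) - q[2]) - log(1 - p0)
  expect_equal(ll, manual, tolerance = 1e-10)
})
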