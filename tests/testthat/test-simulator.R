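test_that("scenario rate rules match their stated parameters", {
  s1 <- scenario_spec(1)
  r <- scenario_rates(s1, t = 17, cont_trait = 2, cat_state = 2, temp = 3)
  expect_equal(r$lambda, 0.2)
  expect_equal(r$mu, 0.1)

  # scenario 2: logistic midpoints at 20 (speciation) and 15 Ma (extinction)
  s2 <- scenario_spec(2)
  expect_equal(scenario_rates(s2, t = 20)$lambda, (0.4 + 0.1) / 2)
  expect_equal(scenario_rates(s2, t = 15)$mu, (0.05 + 0.4) / 2)
  expect_equal(scenario_rates(s2, t = 35)$lambda, 0.4, tolerance = 1e-3)
  expect_equal(scenario_rates(s2, t = 0)$mu, 0.4, tolerance = 1e-3)

  # scenario 3: piecewise shifts
  s3 <- scenario_spec(3)
  expect_equal(scenario_rates(s3, t = 25)$lambda, 0.4)
  expect_equal(scenario_rates(s3, t = 15)$lambda, 0.1)
  expect_equal(scenario_rates(s3, t = 5)$lambda, 0.01)
  expect_equal(scenario_rates(s3, t = 12)$mu, 0.3)

  # scenario 5: state 2 has 5-fold higher rates; extinction linear in time
  s5 <- scenario_spec(5)
  r1 <- scenario_rates(s5, t = 35, cat_state = 1)
  expect_equal(r1$lambda, 0.1)
  expect_equal(r1$mu, 0.01)
  r0 <- scenario_rates(s5, t = 0, cat_state = c(1, 2))
  expect_equal(r0$mu[1], 0.1)          # reaches speciation at the present
  expect_equal(r0$lambda[2] / r0$lambda[1], 5)
  expect_equal(r0$mu[2] / r0$mu[1], 5)

  # scenario 6: baselines at trait 0; 30% of baseline at 1 SD
  s6 <- scenario_spec(6)
  expect_equal(scenario_rates(s6, cont_trait = 0)$lambda, 0.5)
  expect_equal(scenario_rates(s6, cont_trait = 0)$mu, 0.4)
  expect_equal(scenario_rates(s6, cont_trait = 1)$lambda, 0.5 * 0.3,
               tolerance = 1e-10)
  expect_equal(scenario_rates(s6, cont_trait = -1)$mu, 0.4 * 0.3,
               tolerance = 1e-10)

  # scenario 7: state 2 inverts the bell
  s7 <- scenario_spec(7)
  expect_equal(scenario_rates(s7, cont_trait = 0, cat_state = 2)$lambda, 0)
  expect_equal(scenario_rates(s7, cont_trait = 5, cat_state = 2)$lambda,
               0.5, tolerance = 1e-5)

  # scenario 8: inversion switches at 15 Ma
  s8 <- scenario_spec(8)
  expect_equal(scenario_rates(s8, t = 20, cont_trait = 0)$lambda, 0.5)
  expect_equal(scenario_rates(s8, t = 10, cont_trait = 0)$lambda, 0)

  # scenario 4: Gaussian in the temperature anomaly, inverted for state 2
  s4 <- scenario_spec(4)
  expect_equal(scenario_rates(s4, temp = 0, cat_state = 1)$lambda, 0.5)
  expect_equal(scenario_rates(s4, temp = 0, cat_state = 2)$lambda, 0)
  expect_equal(scenario_rates(s4, temp = 1.2, cat_state = 1)$lambda,
               0.5 * exp(-0.5), tolerance = 1e-10)
  expect_error(scenario_spec(12), "unknown scenario")
})

test_that("pure birth matches the Yule expectation (oracle)", {
  # E[N(T)] = exp(lambda T) under a pure-birth process
  spec <- scenario_spec(1, root_age = 10, richness = c(1, 1e6),
                        custom_rates = function(t, x, st, temp)
                          list(lambda = 0.2, mu = 0))
  n <- replicate(400, {
    cl <- simulate_clade(spec, seed = sample.int(1e6, 1))
    nrow(cl$lineages)
  })
  expected <- exp(0.2 * 10)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3.5 * se + 0.05 * expected)

  # no events at all: exactly the root lineage survives
  dead <- scenario_spec(1, root_age = 5, richness = c(1, 10),
                        custom_rates = function(t, x, st, temp)
                          list(lambda = 0, mu = 0))
  cl <- simulate_clade(dead, seed = 3)
  expect_equal(nrow(cl$lineages), 1)
  expect_true(cl$lineages$extant)
  expect_equal(cl$lineages$s, 5)
})

test_that("accepted clades fall in the richness window and rates are reproducible", {
  spec <- scenario_spec(5, richness = c(60, 140))
  for (seed in c(51, 52)) {
    cl <- simulate_clade(spec, seed = seed)
    n <- nrow(cl$lineages)
    expect_gte(n, 60); expect_lte(n, 140)
    # stored true rates reproduce the scenario rules at the recorded traits
    for (b in c(5, 20, 30)) {
      alive <- which(!is.na(cl$lambda_bin[, b]))
      r <- scenario_rates(spec, cl$bin_mid[b], cl$trait_bin[alive, b],
                          cl$lineages$state[alive], cl$temp_bin[b])
      expect_equal(cl$lambda_bin[alive, b], r$lambda, tolerance = 1e-12)
      expect_equal(cl$mu_bin[alive, b], r$mu, tolerance = 1e-12)
    }
    # scenario-5 construction: state-2 rates exactly 5x state-1 rates
    for (b in c(10, 25)) {
      alive <- which(!is.na(cl$lambda_bin[, b]))
      st <- cl$lineages$state[alive]
      if (length(unique(st)) == 2) {
        expect_equal(unique(cl$lambda_bin[alive[st == 2], b]) /
                       unique(cl$lambda_bin[alive[st == 1], b]), 5)
      }
    }
  }
  tiny <- scenario_spec(1, richness = c(5000, 5001), retry_cap = 3L)
  expect_error(simulate_clade(tiny, seed = 1), "richness window")
})

test_that("preservation sampling follows the Poisson model", {
  # fixed q = 1, no heterogeneity: a 10-Myr lineage yields ~10 occurrences
  spec <- scenario_spec(1, root_age = 10, richness = c(1, 2),
                        custom_rates = function(t, x, st, temp)
                          list(lambda = 0, mu = 0))
  cl <- simulate_clade(spec, seed = 1)
  ks <- replicate(800, {
    pres <- simulate_preservation(cl, seed = sample.int(1e6, 1), q = 1,
                                  alpha = Inf)
    nrow(pres$dataset$occurrences)
  })
  expect_lt(abs(mean(ks) - 10), 3.5 * sd(ks) / sqrt(length(ks)))

  # occurrence ages always inside the lineage's lifespan
  spec5 <- scenario_spec(5, richness = c(40, 120))
  cl5 <- simulate_clade(spec5, seed = 9)
  pres <- simulate_preservation(cl5, seed = 10)
  lin <- cl5$lineages
  for (i in seq_len(nrow(pres$dataset$occurrences))) {
    tx <- pres$dataset$occurrences$taxon[i]
    a <- pres$dataset$occurrences$min_age[i]
    j <- match(tx, lin$name)
    expect_gte(a, lin$e[j]); expect_lte(a, lin$s[j])
  }
  # dropped species are exactly those without occurrences
  expect_setequal(lin$name[pres$sampled],
                  unique(pres$dataset$occurrences$taxon))
})

test_that("synthetic temperature is standardized, smooth, and reproducible", {
  tp1 <- synthetic_temperature(seed = 5)
  tp2 <- synthetic_temperature(seed = 5)
  expect_equal(tp1, tp2)
  expect_equal(sd(tp1$value), 1, tolerance = 1e-9)
  expect_equal(mean(tp1$value), 0, tolerance = 1e-9)
  # autocorrelation at one 1-Myr bin lag (10 rows at 0.1-Myr resolution)
  v <- tp1$value
  lag <- 10
  expect_gt(cor(v[-seq_len(lag)], v[seq_len(length(v) - lag)]), 0.9)
})

test_that("the simulated clade converts to a consistent phylogeny", {
  # hand-built clade: root (35 -> 0), daughter at 20, granddaughter at 10
  clade <- list(lineages = data.frame(
    name = c("sp1", "sp2", "sp3"), parent = c(0L, 1L, 1L),
    s = c(35, 20, 10), e = c(0, 0, 0), extant = TRUE, state = 1L))
  tr <- clade_to_phylo(clade)
  D <- stats::cophenetic(tr)
  expect_equal(D["sp1", "sp3"], 20)   # diverged at 10 Ma
  expect_equal(D["sp1", "sp2"], 40)   # diverged at 20 Ma
  expect_equal(D["sp2", "sp3"], 40)

  spec <- scenario_spec(1, richness = c(40, 120))
  cl <- simulate_clade(spec, seed = 13)
  tr <- clade_to_phylo(cl)
  expect_equal(sort(tr$tip.label), sort(cl$lineages$name))
  # tip depths (plus the stem edge) reach the present for extant tips
  stem <- if (is.null(tr$root.edge)) 0 else tr$root.edge
  depth <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)] + stem
  ext <- cl$lineages$extant[match(tr$tip.label, cl$lineages$name)]
  expect_equal(max(depth), 35, tolerance = 1e-4)
  expect_true(all(abs(depth[ext] - 35) < 1e-4))
})

test_that("simulate_dataset assembles an analysis-ready replicate", {
  sim <- simulate_dataset(4, seed = 77, richness = c(40, 120))
  expect_s3_class(sim$dataset, "occurrence_dataset")
  expect_true("paleotemperature" %in% sim$tensor$predictor_names)
  expect_true(all(c("phylo_ev1", "phylo_ev2") %in%
                    sim$tensor$predictor_names))
  expect_equal(length(sim$truth$species), length(sim$dataset$taxa))
  # under scenario 9 the causal trait is withheld (replaced by noise)
  sim6 <- simulate_dataset(6, seed = 78, richness = c(40, 120))
  sim9 <- simulate_dataset(9, seed = 78, richness = c(40, 120))
  expect_equal(length(sim9$tensor$predictor_names),
               length(sim6$tensor$predictor_names))
})
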