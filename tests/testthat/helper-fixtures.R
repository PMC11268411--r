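# Shared fixtures: tiny datasets, tensors, and hand-built posterior traces
# assembled in code (no stored data files).

toy_dataset <- function(S = 6, seed = 1, extant_frac = 0.3, t_max = 10) {
  set.seed(seed)
  taxa <- paste0("sp", seq_len(S))
  occ <- do.call(rbind, lapply(seq_len(S), function(i) {
    k <- sample(2:5, 1)
    a <- sort(stats::runif(k, 0.5, t_max - 0.5), decreasing = TRUE)
    data.frame(taxon = taxa[i], min_age = a, max_age = a)
  }))
  extant <- taxa[stats::runif(S) < extant_frac]
  occurrence_dataset(occ, extant = extant, time_bins = seq(t_max, 0, by = -1))
}

toy_tensor <- function(dataset, seed = 1, extra_cont = 0) {
  set.seed(seed)
  S <- length(dataset$taxa)
  tr <- data.frame(row.names = dataset$taxa,
                   cont_trait = stats::rnorm(S),
                   cat_trait = sample(c("state1", "state2"), S,
                                      replace = TRUE))
  if (extra_cont > 0)
    for (j in seq_len(extra_cont))
      tr[[paste0("noise", j)]] <- stats::rnorm(S)
  build_predictor_tensor(dataset, traits = tr,
                         time_bins = dataset$time_bins)
}

# A synthetic posterior trace built directly from drawn weights (no MCMC):
# the xai and evaluation modules only need samples with consistent fields.
toy_trace <- function(dataset = toy_dataset(), tensor = NULL, n_samp = 5,
                      seed = 1, t_reg = 1, weight_sd = 0.5,
                      modify_weights = NULL) {
  set.seed(seed)
  if (is.null(tensor)) tensor <- toy_tensor(dataset, seed = seed)
  S <- length(tensor$species); B <- length(tensor$bin_mid)
  J <- length(tensor$predictor_names)
  arch <- bdnn_architecture(J, hidden = c(6L, 4L))
  occ <- dataset$occurrences
  idx <- match(occ$taxon, tensor$species)
  max_occ <- tapply(occ$max_age, idx, max)[as.character(seq_len(S))]
  min_occ <- tapply(occ$min_age, idx, min)[as.character(seq_len(S))]
  extant <- dataset$extant[match(tensor$species, dataset$taxa)]
  s <- pmin(as.numeric(max_occ) + 0.3, tensor$time_bins[1])
  e <- ifelse(extant, 0, pmax(as.numeric(min_occ) - 0.3, 0))
  edges <- tensor$time_bins
  counts <- matrix(0, S, B)
  ages <- (occ$min_age + occ$max_age) / 2
  bn <- bdnn:::.cpp_bin_of(ages, edges)
  for (r in seq_along(ages)) counts[idx[r], bn[r]] <- counts[idx[r], bn[r]] + 1
  samples <- lapply(seq_len(n_samp), function(m) {
    Wl <- draw_weights(arch, weight_sd)
    Wm <- draw_weights(arch, weight_sd)
    if (!is.null(modify_weights)) {
      Wl <- modify_weights(Wl); Wm <- modify_weights(Wm)
    }
    par <- bdnn_params(Wl, Wm, t_reg = t_reg)
    rates <- lineage_time_rates(par, tensor)
    X <- bdnn:::tensor_matrix(tensor)
    bl_l <- forward_baseline(Wl, X); bl_m <- forward_baseline(Wm, X)
    list(iteration = m, t_reg = t_reg, s = s, e = e,
         q = rep(1, B), alpha = 1,
         lambda = rates$lambda, mu = rates$mu,
         weights_lambda = Wl, weights_mu = Wm,
         mean_bl_lambda = mean(bl_l), mean_bl_mu = mean(bl_m))
  })
  structure(list(samples = samples, species = tensor$species,
                 time_bins = edges, extant = extant, counts = counts,
                 bounds = list(min_occ = as.numeric(min_occ),
                               max_occ = as.numeric(max_occ),
                               t_max = edges[1]),
                 predictors = tensor, config = NULL,
                 acceptance = rbind(accepted = rep(0, 4),
                                    attempted = rep(0, 4))),
            class = "bdnn_trace")
}

# Zero out the first-layer weights feeding one predictor in both networks.
zero_predictor_weights <- function(name, tensor) {
  j <- match(name, tensor$predictor_names)
  function(W) { W$W1[j, ] <- 0; W }
}
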