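#' Benchmark scenario specification
#'
#' Generating rules for the nine benchmark diversification scenarios. All
#' scenarios run forward in time from a root age of 35 Ma in discrete steps
#' of 0.01 Ma and target a total richness window of 200-300 extant or
#' extinct species via rejection sampling of whole clades. Species carry
#' one continuous trait (unbiased random walk, rate sigma^2 = 0.02, plus a
#' cladogenetic jump with SD 0.2) and one two-state categorical trait
#' (state switch probability 0.1 at speciation, no anagenetic change).
#'
#' Scenario rate rules: (1) constant lambda = 0.2, mu = 0.1; (2) logistic
#' decline of speciation 0.4 -> 0.1 (midpoint 20 Ma) and rise of extinction
#' 0.05 -> 0.4 (midpoint 15 Ma), steepness 0.5; (3) speciation shifts
#' 0.4 -> 0.1 at 20 Ma and -> 0.01 at 10 Ma, extinction 0.05 before 15 Ma,
#' 0.3 in 15-10 Ma, 0.01 after; (4) Gaussian link (SD 1.2) between a
#' temperature anomaly and rates, baselines 0.5/0.4, inverted bell for the
#' second categorical state; (5) state 1: lambda = 0.1 and extinction rising
#' linearly 0.01 -> 0.1 over 35 Myr, state 2: 5-fold higher rates;
#' (6) Gaussian link between the continuous trait and rates, baselines
#' 0.5/0.4, rate at 1 SD = 30\% of baseline; (7) as 6 for state 1, inverted
#' bell for state 2; (8) bell before 15 Ma, inverted bell after;
#' (9) the rules of scenario 6 (the causal trait is withheld at analysis).
#'
#' @param scenario Integer 1-9.
#' @param root_age Clade origin (Ma).
#' @param dt Simulation step (Myr).
#' @param richness Accepted window for the total number of species.
#' @param temperature Optional binned temperature anomaly series
#'   (\code{bin_top_age}, \code{value}); required by scenario 4 and
#'   generated by \code{\link{synthetic_temperature}} when absent.
#' @param sigma2 Random-walk rate of the continuous trait.
#' @param jump_sd Cladogenetic jump SD of the continuous trait.
#' @param switch_prob State-switch probability at speciation.
#' @param trait_sd_unit Width of one "SD" of trait effect in trait units.
#' @param bell_reduction_1sd Fraction of the baseline remaining at 1 SD for
#'   the trait-dependent Gaussian scenarios (6-9).
#' @param gauss_sd_temp Gaussian SD of the temperature-rate link
#'   (scenario 4), in units of the (SD-1-scaled) anomaly.
#' @param retry_cap Rejection-sampling cap on simulated clades.
#' @param custom_rates Optional function \code{(t, cont_trait, cat_state,
#'   temp) -> list(lambda, mu)} overriding the scenario's rate rules
#'   (e.g. for pure-birth checks).
#' @return Object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(scenario, root_age = 35, dt = 0.01,
                          richness = c(200, 300), temperature = NULL,
                          sigma2 = 0.02, jump_sd = 0.2, switch_prob = 0.1,
                          trait_sd_unit = 1, bell_reduction_1sd = 0.3,
                          gauss_sd_temp = 1.2, retry_cap = 1000L,
                          custom_rates = NULL) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:9) stop("unknown scenario: ", scenario)
  if (dt <= 0) stop("dt must be positive")
  structure(list(scenario = scenario, root_age = root_age, dt = dt,
                 custom_rates = custom_rates,
                 richness = richness, temperature = temperature,
                 sigma2 = sigma2, jump_sd = jump_sd,
                 switch_prob = switch_prob,
                 trait_sd_unit = trait_sd_unit,
                 bell_reduction_1sd = bell_reduction_1sd,
                 gauss_sd_temp = gauss_sd_temp,
                 retry_cap = as.integer(retry_cap)),
            class = "scenario_spec")
}

# Gaussian bell in x with sigma chosen so bell(1 SD) = bell_reduction_1sd.
bell_sigma <- function(spec) {
  spec$trait_sd_unit * sqrt(1 / (2 * log(1 / spec$bell_reduction_1sd)))
}

#' True scenario rates
#'
#' Evaluates the generating speciation and extinction rates of a benchmark
#' scenario for given time, trait values, and temperature anomaly.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param t Time (Ma before present).
#' @param cont_trait Continuous trait value(s).
#' @param cat_state Categorical state(s), coded 1 or 2.
#' @param temp Temperature anomaly at \code{t} (scenario 4 only).
#' @return List with vectors \code{lambda} and \code{mu}.
#' @export
scenario_rates <- function(spec, t, cont_trait = 0, cat_state = 1, temp = 0) {
  n <- max(length(cont_trait), length(cat_state))
  x <- rep_len(cont_trait, n); st <- rep_len(cat_state, n)
  if (!is.null(spec$custom_rates)) {
    r <- spec$custom_rates(t, x, st, temp)
    return(list(lambda = rep_len(r$lambda, n), mu = rep_len(r$mu, n)))
  }
  bell <- function(v, sigma) exp(-v^2 / (2 * sigma^2))
  sc <- spec$scenario
  if (sc == 1) {
    lam <- rep(0.2, n); mu <- rep(0.1, n)
  } else if (sc == 2) {
    lam <- rep(0.1 + 0.3 / (1 + exp(-0.5 * (t - 20))), n)
    mu <- rep(0.05 + 0.35 / (1 + exp(0.5 * (t - 15))), n)
  } else if (sc == 3) {
    lam <- rep(if (t > 20) 0.4 else if (t > 10) 0.1 else 0.01, n)
    mu <- rep(if (t > 15) 0.05 else if (t > 10) 0.3 else 0.01, n)
  } else if (sc == 4) {
    b <- bell(temp, spec$gauss_sd_temp)
    lam <- ifelse(st == 1, 0.5 * b, 0.5 * (1 - b))
    mu <- ifelse(st == 1, 0.4 * b, 0.4 * (1 - b))
  } else if (sc == 5) {
    mult <- ifelse(st == 1, 1, 5)
    lam <- 0.1 * mult
    mu <- (0.01 + 0.09 * (spec$root_age - t) / spec$root_age) * mult
  } else if (sc %in% c(6, 9)) {
    b <- bell(x, bell_sigma(spec))
    lam <- 0.5 * b; mu <- 0.4 * b
  } else if (sc == 7) {
    b <- bell(x, bell_sigma(spec))
    lam <- ifelse(st == 1, 0.5 * b, 0.5 * (1 - b))
    mu <- ifelse(st == 1, 0.4 * b, 0.4 * (1 - b))
  } else if (sc == 8) {
    b <- bell(x, bell_sigma(spec))
    if (t >= 15) {
      lam <- 0.5 * b; mu <- 0.4 * b
    } else {
      lam <- 0.5 * (1 - b); mu <- 0.4 * (1 - b)
    }
  }
  list(lambda = lam, mu = mu)
}

#' Synthetic temperature anomaly curve
#'
#' Smooth autocorrelated stand-in for an isotope-derived paleotemperature
#' trajectory: a Gaussian-smoothed random walk over [0, root_age] Ma,
#' centered and scaled to a target SD. Real curves can be supplied as a
#' binned TSV instead (see \code{\link{read_time_series}}).
#'
#' @param seed Integer seed.
#' @param sd_target SD of the returned anomaly.
#' @param root_age Oldest age covered (Ma).
#' @param resolution Bin width of the returned series (Myr).
#' @param bandwidth Gaussian smoothing bandwidth (Myr).
#' @return Data frame with columns \code{bin_top_age}, \code{value}
#'   (anomaly, mean 0, SD \code{sd_target}).
#' @export
synthetic_temperature <- function(seed, sd_target = 1, root_age = 35,
                                  resolution = 0.1, bandwidth = 3) {
  set.seed(seed)
  ages <- seq(root_age, resolution, by = -resolution)
  n <- length(ages)
  rw <- cumsum(stats::rnorm(n))
  h <- bandwidth / resolution
  k <- stats::dnorm(seq(-ceiling(3 * h), ceiling(3 * h)) / h)
  k <- k / sum(k)
  pad <- (length(k) - 1) / 2
  xp <- c(rep(rw[1], pad), rw, rep(rw[n], pad))
  sm <- stats::filter(xp, k, sides = 2)[(pad + 1):(pad + n)]
  v <- (sm - mean(sm)) / stats::sd(sm) * sd_target
  data.frame(bin_top_age = ages, value = as.numeric(v))
}

#' Simulate a clade under a benchmark scenario
#'
#' Forward-time birth-death simulation at discrete steps of \code{dt}:
#' each living lineage speciates with probability \code{lambda dt} and goes
#' extinct with probability \code{mu dt} per step; the continuous trait
#' follows an unbiased random walk with cladogenetic jumps, and the
#' categorical state can switch at speciation. Whole clades are
#' rejection-sampled until the total species count falls in the target
#' richness window. True rates, trait values, and the temperature anomaly
#' are recorded at the midpoints of 1-Myr bins, and the true speciation
#' rate of each species is the rate of its ancestral lineage at the moment
#' of branching.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param seed Integer seed.
#' @return Object of class \code{simulated_clade}: lineage table
#'   (\code{name}, \code{parent}, \code{s}, \code{e}, \code{extant},
#'   \code{state}), per-bin true rates and traits, trait trajectories, the
#'   birth/death rates at each lineage's own events, the time-bin grid, and
#'   the temperature series used.
#' @export
simulate_clade <- function(spec, seed) {
  set.seed(seed)
  temp_series <- spec$temperature
  if (spec$scenario == 4 && is.null(temp_series))
    temp_series <- synthetic_temperature(seed)

  root_age <- spec$root_age; dt <- spec$dt
  nsteps <- round(root_age / dt)
  t_steps <- root_age - (seq_len(nsteps) - 1) * dt
  temp_step <- if (is.null(temp_series)) numeric(nsteps) else
    series_at(temp_series, pmax(t_steps, min(temp_series$bin_top_age)))
  edges <- seq(root_age, 0, by = -1)
  B <- length(edges) - 1
  mids <- (edges[-1] + edges[-(B + 1)]) / 2
  # step index closest to each bin midpoint
  mid_step <- vapply(mids, function(m) which.min(abs(t_steps - m)), integer(1))
  step_is_mid <- integer(nsteps); step_is_mid[mid_step] <- seq_len(B)
  rec_every <- max(1L, round(0.1 / dt))  # trait trajectory resolution
  rec_steps <- seq(1L, nsteps, by = rec_every)
  step_rec <- integer(nsteps); step_rec[rec_steps] <- seq_along(rec_steps)

  cap <- max(2L, spec$richness[2])  # reject as soon as the window is blown
  sim_once <- function() {
    Nmax <- min(256L, cap)
    parent <- integer(Nmax); s <- numeric(Nmax); e <- rep(NA_real_, Nmax)
    state <- integer(Nmax); trait <- numeric(Nmax)
    lam_birth <- numeric(Nmax); mu_death <- rep(NA_real_, Nmax)
    traj <- matrix(NA_real_, Nmax, length(rec_steps))
    trait_bin <- matrix(NA_real_, Nmax, B)
    lam_bin <- matrix(NA_real_, Nmax, B)
    mu_bin <- matrix(NA_real_, Nmax, B)
    temp_bin <- numeric(B)
    grow <- function() {
      add <- Nmax
      Nmax <<- Nmax + add
      parent <<- c(parent, integer(add)); s <<- c(s, numeric(add))
      e <<- c(e, rep(NA_real_, add)); state <<- c(state, integer(add))
      trait <<- c(trait, numeric(add))
      lam_birth <<- c(lam_birth, numeric(add))
      mu_death <<- c(mu_death, rep(NA_real_, add))
      pad <- function(m) rbind(m, matrix(NA_real_, add, ncol(m)))
      traj <<- pad(traj); trait_bin <<- pad(trait_bin)
      lam_bin <<- pad(lam_bin); mu_bin <<- pad(mu_bin)
    }
    n <- 1L; parent[1] <- 0L; s[1] <- root_age; state[1] <- 1L; trait[1] <- 0
    lam_birth[1] <- scenario_rates(spec, root_age, 0, 1,
                                   temp_step[1])$lambda[1]
    alive <- 1L
    step_sd <- sqrt(spec$sigma2 * dt)
    for (k in seq_len(nsteps)) {
      if (!length(alive)) break
      tk <- t_steps[k]
      r <- scenario_rates(spec, tk, trait[alive], state[alive], temp_step[k])
      b <- step_is_mid[k]
      if (b > 0) {
        trait_bin[alive, b] <- trait[alive]
        lam_bin[alive, b] <- r$lambda
        mu_bin[alive, b] <- r$mu
        temp_bin[b] <- temp_step[k]
      }
      rc <- step_rec[k]
      if (rc > 0) traj[alive, rc] <- trait[alive]
      u <- stats::runif(length(alive))
      sp <- alive[u < r$lambda * dt]
      ud <- stats::runif(length(alive))
      dd <- which(ud < r$mu * dt)
      if (length(sp)) {
        m <- length(sp)
        if (n + m > cap) return(NULL)  # exceeds the richness window: reject
        while (n + m > Nmax) grow()
        idx <- n + seq_len(m)
        parent[idx] <- sp
        s[idx] <- tk
        trait[idx] <- trait[sp] + stats::rnorm(m, 0, spec$jump_sd)
        sw <- stats::runif(m) < spec$switch_prob
        state[idx] <- ifelse(sw, 3L - state[sp], state[sp])
        lam_birth[idx] <- r$lambda[match(sp, alive)]
        n <- n + m
        alive <- c(alive, idx)
      }
      if (length(dd)) {
        dead <- alive[dd]
        e[dead] <- tk
        mu_death[dead] <- r$mu[dd]
        alive <- setdiff(alive, dead)
      }
      trait[alive] <- trait[alive] + stats::rnorm(length(alive), 0, step_sd)
    }
    extant <- is.na(e[seq_len(n)])
    if (length(alive)) {
      # closing records for extant lineages at the present
      r0 <- scenario_rates(spec, 0, trait[alive], state[alive],
                           temp_step[nsteps])
      mu_death[alive] <- r0$mu
    }
    e[extant] <- 0
    list(n = n, parent = parent[seq_len(n)], s = s[seq_len(n)],
         e = e[seq_len(n)], extant = extant, state = state[seq_len(n)],
         trait_final = trait[seq_len(n)],
         lam_birth = lam_birth[seq_len(n)], mu_death = mu_death[seq_len(n)],
         traj = traj[seq_len(n), , drop = FALSE],
         trait_bin = trait_bin[seq_len(n), , drop = FALSE],
         lam_bin = lam_bin[seq_len(n), , drop = FALSE],
         mu_bin = mu_bin[seq_len(n), , drop = FALSE],
         temp_bin = temp_bin)
  }

  res <- NULL
  for (try in seq_len(spec$retry_cap)) {
    cand <- sim_once()
    if (!is.null(cand) && cand$n >= spec$richness[1] &&
        cand$n <= spec$richness[2]) { res <- cand; break }
  }
  if (is.null(res))
    stop("richness window [", spec$richness[1], ", ", spec$richness[2],
         "] not reached within ", spec$retry_cap, " simulated clades")

  lineages <- data.frame(name = paste0("sp", seq_len(res$n)),
                         parent = res$parent, s = res$s, e = res$e,
                         extant = res$extant, state = res$state)
  structure(list(lineages = lineages, traj = res$traj,
                 trait_final = res$trait_final,
                 rec_times = t_steps[rec_steps],
                 trait_bin = res$trait_bin, lambda_bin = res$lam_bin,
                 mu_bin = res$mu_bin, temp_bin = res$temp_bin,
                 lambda_birth = res$lam_birth, mu_death = res$mu_death,
                 time_bins = edges, bin_mid = mids, spec = spec,
                 temperature = temp_series),
            class = "simulated_clade")
}

#' @export
print.simulated_clade <- function(x, ...) {
  cat("Simulated clade (scenario", x$spec$scenario, "):",
      nrow(x$lineages), "species,", sum(x$lineages$extant), "extant\n")
  invisible(x)
}

#' Simulate fossil preservation of a clade
#'
#' Samples fossil occurrences under a time-variable Poisson process:
#' per-stage baseline rates drawn log-uniformly from [0.5, 5]
#' occurrences/lineage/Myr, among-species mean-one gamma multipliers with a
#' shape parameter itself drawn log-uniformly from [0.5, 5]. Occurrence
#' ages are uniform within each lineage-stage overlap; species with no
#' occurrences are dropped. The observed continuous trait of a species is
#' the average of its true trait trajectory at the sampled occurrence
#' times, mirroring what is observable in real fossil data.
#'
#' @param clade A \code{\link{simulated_clade}}.
#' @param seed Integer seed.
#' @param q,alpha Optional fixed preservation parameters; drawn from the
#'   stated distributions when NULL. \code{alpha = Inf} disables
#'   among-lineage heterogeneity (all multipliers 1).
#' @return List with the \code{\link{occurrence_dataset}}, the per-species
#'   observed trait table (\code{cont_trait}, \code{cat_trait}), the
#'   sampled lineage indices, and the drawn preservation parameters
#'   \code{q} and \code{alpha}.
#' @export
simulate_preservation <- function(clade, seed, q = NULL, alpha = NULL) {
  set.seed(seed)
  lin <- clade$lineages
  edges <- clade$time_bins
  B <- length(edges) - 1
  if (is.null(q)) q <- exp(stats::runif(B, log(0.5), log(5)))
  q <- rep_len(q, B)
  if (is.null(alpha)) alpha <- exp(stats::runif(1, log(0.5), log(5)))
  mult <- if (is.finite(alpha))
    stats::rgamma(nrow(lin), shape = alpha, rate = alpha)
  else rep(1, nrow(lin))
  occ_taxon <- character(0); occ_age <- numeric(0)
  for (i in seq_len(nrow(lin))) {
    for (b in seq_len(B)) {
      top <- min(lin$s[i], edges[b]); bot <- max(lin$e[i], edges[b + 1])
      if (top <= bot) next
      K <- stats::rpois(1, q[b] * mult[i] * (top - bot))
      if (K > 0) {
        occ_taxon <- c(occ_taxon, rep(lin$name[i], K))
        occ_age <- c(occ_age, stats::runif(K, bot, top))
      }
    }
  }
  sampled <- which(lin$name %in% unique(occ_taxon))
  traits <- data.frame(row.names = lin$name[sampled],
                       cont_trait = NA_real_,
                       cat_trait = paste0("state", lin$state[sampled]),
                       stringsAsFactors = FALSE)
  for (j in seq_along(sampled)) {
    i <- sampled[j]
    ages <- occ_age[occ_taxon == lin$name[i]]
    ri <- vapply(ages, function(a) which.min(abs(clade$rec_times - a)),
                 integer(1))
    vals <- clade$traj[i, ri]
    # occurrences can fall a fraction of a step outside the recorded grid
    if (anyNA(vals)) vals <- vals[!is.na(vals)]
    traits$cont_trait[j] <- if (length(vals)) mean(vals) else
      clade$trait_final[i]
  }
  ds <- occurrence_dataset(
    data.frame(taxon = occ_taxon, min_age = occ_age, max_age = occ_age),
    extant = lin$name[lin$extant & lin$name %in% occ_taxon],
    time_bins = edges)
  list(dataset = ds, traits = traits, sampled = sampled, q = q,
       alpha = alpha)
}

#' Convert a simulated clade to a phylogenetic tree
#'
#' Builds the (non-ultrametric) tree implied by the lineage table under
#' budding speciation — every lineage is a tip; each branching event
#' attaches the daughter to its ancestor at the recorded origination time —
#' optionally pruned to a subset of tips.
#'
#' @param clade A \code{\link{simulated_clade}}.
#' @param tips Optional character vector of tip names to keep.
#' @return An \code{ape::phylo} tree with branch lengths in Myr.
#' @export
clade_to_phylo <- function(clade, tips = NULL) {
  lin <- clade$lineages
  n <- nrow(lin)
  kids <- split(seq_len(n), factor(lin$parent, levels = 0:n))
  node_str <- function(i, t0, ds) {
    if (!length(ds))
      return(sprintf("%s:%.6f", lin$name[i], t0 - lin$e[i]))
    t1 <- lin$s[ds[1]]
    left <- node_str(i, t1, ds[-1])
    d1 <- ds[1]
    right <- node_str(d1, t1, kids[[as.character(d1)]]
                      [order(-lin$s[kids[[as.character(d1)]]])])
    sprintf("(%s,%s):%.6f", left, right, t0 - t1)
  }
  ds1 <- kids[["1"]][order(-lin$s[kids[["1"]]])]
  nwk <- paste0(node_str(1L, lin$s[1], ds1), ";")
  tr <- ape::read.tree(text = nwk)
  if (!is.null(tips) && length(tips) < length(tr$tip.label))
    tr <- ape::keep.tip(tr, tips)
  tr
}

#' Simulate a complete benchmark dataset
#'
#' End-to-end generation of one analysis-ready replicate: clade simulation,
#' preservation sampling, pruning of the tree to sampled species,
#' phylogenetic eigenvectors, and assembly of the predictor tensor (time,
#' observed traits, two eigenvectors, and — in scenario 4 — the temperature
#' series). Under scenario 9 the causal continuous trait is withheld and
#' replaced by an uninformative standard-normal draw, keeping the predictor
#' count unchanged.
#'
#' @param scenario Integer 1-9, or a \code{\link{scenario_spec}}.
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{scenario_spec}} when \code{scenario}
#'   is an integer.
#' @return List with \code{dataset} (occurrences), \code{tensor}
#'   (predictors), \code{tree}, \code{clade}, and \code{truth} (per
#'   sampled species: true \code{s}, \code{e}, the true speciation rate at
#'   origination taken from the ancestral lineage, the true extinction
#'   rate at extinction, and the per-bin true rate matrices).
#' @export
simulate_dataset <- function(scenario, seed, ...) {
  spec <- if (inherits(scenario, "scenario_spec")) scenario
          else scenario_spec(scenario, ...)
  clade <- simulate_clade(spec, seed)
  pres <- simulate_preservation(clade, seed + 1L)
  lin <- clade$lineages
  sampled <- pres$sampled
  tree <- clade_to_phylo(clade, tips = lin$name[sampled])
  ev <- phylo_eigenvectors(tree, k = 2)
  traits <- pres$traits
  if (spec$scenario == 9) {
    set.seed(seed + 2L)
    traits$cont_trait <- stats::rnorm(nrow(traits))
  }
  series <- list()
  if (spec$scenario == 4)
    series <- list(paleotemperature = clade$temperature)
  tensor <- build_predictor_tensor(pres$dataset, traits = traits,
                                   time_series = series, eigenvectors = ev,
                                   time_bins = clade$time_bins)
  truth <- list(species = lin$name[sampled], s = lin$s[sampled],
                e = lin$e[sampled], extant = lin$extant[sampled],
                lambda_birth = clade$lambda_birth[sampled],
                mu_death = clade$mu_death[sampled],
                lambda_bin = clade$lambda_bin[sampled, , drop = FALSE],
                mu_bin = clade$mu_bin[sampled, , drop = FALSE],
                q = pres$q, alpha = pres$alpha)
  list(dataset = pres$dataset, tensor = tensor, tree = tree, clade = clade,
       truth = truth, spec = spec)
}
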