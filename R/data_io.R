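#' Fossil occurrence dataset
#'
#' Validated container for dated fossil occurrences. Ages are in Ma before
#' present (larger = older); each occurrence carries an age-uncertainty
#' interval \code{[min_age, max_age]}.
#'
#' @param occurrences Data frame with columns \code{taxon}, \code{min_age},
#'   \code{max_age}.
#' @param extant Named logical vector (one entry per taxon) flagging extant
#'   taxa, or a character vector of extant taxon names.
#' @param time_bins Optional strictly decreasing vector of bin boundary ages
#'   (Ma) used downstream as the analysis grid.
#' @return Object of class \code{occurrence_dataset}.
#' @export
occurrence_dataset <- function(occurrences, extant = character(), time_bins = NULL) {
  occurrences <- as.data.frame(occurrences)
  need <- c("taxon", "min_age", "max_age")
  if (!all(need %in% names(occurrences)))
    stop("occurrences must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(occurrences$min_age)) || any(!is.finite(occurrences$max_age)))
    stop("occurrence ages must be finite")
  if (any(occurrences$min_age < 0))
    stop("occurrence ages must be non-negative")
  bad <- which(occurrences$min_age > occurrences$max_age)
  if (length(bad))
    stop("min_age > max_age for occurrence row(s): ",
         paste(bad, collapse = ", "))
  taxa <- unique(occurrences$taxon)
  if (is.logical(extant)) {
    if (is.null(names(extant))) stop("logical 'extant' must be named")
    extant <- names(extant)[extant]
  }
  if (!all(extant %in% taxa))
    stop("extant taxa absent from occurrences: ",
         paste(setdiff(extant, taxa), collapse = ", "))
  if (!is.null(time_bins)) {
    if (any(diff(time_bins) >= 0)) stop("time_bins must be strictly decreasing")
  }
  structure(list(occurrences = occurrences[, need],
                 taxa = taxa,
                 extant = taxa %in% extant,
                 time_bins = time_bins),
            class = "occurrence_dataset")
}

#' @export
print.occurrence_dataset <- function(x, ...) {
  cat("Occurrence dataset:", length(x$taxa), "taxa,",
      nrow(x$occurrences), "occurrences (", sum(x$extant), "extant )\n")
  rng <- range(c(x$occurrences$min_age, x$occurrences$max_age))
  cat("Age range:", round(rng[2], 3), "-", round(rng[1], 3), "Ma\n")
  invisible(x)
}

#' Read a fossil occurrence table
#'
#' Tab-separated file with a header row and columns \code{taxon},
#' \code{min_age}, \code{max_age}, \code{status} (\code{extinct} or
#' \code{extant}); ages in Ma before present.
#'
#' @param path File path.
#' @return An \code{\link{occurrence_dataset}}; row order per taxon is
#'   preserved.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("taxon", "min_age", "max_age", "status")
  if (!all(need %in% names(raw)))
    stop("occurrence file must have columns: ", paste(need, collapse = ", "))
  for (col in c("min_age", "max_age")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed ", col, " at data line ", bad[1], " of ", path)
    raw[[col]] <- v
  }
  bad <- which(raw$min_age > raw$max_age)
  if (length(bad))
    stop("min_age > max_age at data line ", bad[1], " of ", path)
  if (any(raw$min_age < 0))
    stop("negative age at data line ", which(raw$min_age < 0)[1], " of ", path)
  if (!all(raw$status %in% c("extinct", "extant")))
    stop("status must be 'extinct' or 'extant' (line ",
         which(!raw$status %in% c("extinct", "extant"))[1], ")")
  extant <- unique(raw$taxon[raw$status == "extant"])
  occurrence_dataset(raw[, c("taxon", "min_age", "max_age")], extant = extant)
}

#' Write a fossil occurrence table
#'
#' @param dataset An \code{\link{occurrence_dataset}}.
#' @param path Output file path (TSV).
#' @return \code{path}, invisibly.
#' @export
write_occurrences <- function(dataset, path) {
  df <- dataset$occurrences
  status <- ifelse(dataset$extant[match(df$taxon, dataset$taxa)],
                   "extant", "extinct")
  out <- data.frame(taxon = df$taxon, min_age = df$min_age,
                    max_age = df$max_age, status = status)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resample occurrence ages within their uncertainty intervals
#'
#' Draws every occurrence age uniformly from its \code{[min_age, max_age]}
#' range, the standard treatment of fossil age uncertainty when generating
#' replicate datasets.
#'
#' @param dataset An \code{\link{occurrence_dataset}}.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A new \code{occurrence_dataset} with point ages
#'   (\code{min_age == max_age}).
#' @export
resample_ages <- function(dataset, seed) {
  set.seed(seed)
  occ <- dataset$occurrences
  a <- stats::runif(nrow(occ), occ$min_age, occ$max_age)
  occ$min_age <- occ$max_age <- a
  occurrence_dataset(occ, extant = dataset$taxa[dataset$extant],
                     time_bins = dataset$time_bins)
}

#' Read a species trait table
#'
#' TSV with a \code{species} column and one column per trait; character or
#' factor columns are treated as categorical.
#'
#' @param path File path.
#' @return Data frame with species as row names.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  rownames(df) <- df$species
  df$species <- NULL
  df
}

#' Read a binned time series
#'
#' TSV with columns \code{bin_top_age} (Ma, the older boundary of each bin)
#' and \code{value}.
#'
#' @param path File path.
#' @return Data frame with columns \code{bin_top_age}, \code{value}.
#' @export
read_time_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("bin_top_age", "value") %in% names(df)))
    stop("time series needs columns bin_top_age, value")
  df[order(-df$bin_top_age), c("bin_top_age", "value")]
}

# Value of a binned series at each query age: the series bin containing the
# age (bins run from each bin_top_age down to the next one, the last bin
# extends to 0).
series_at <- function(series, ages) {
  tops <- series$bin_top_age
  idx <- vapply(ages, function(a) {
    w <- which(tops >= a)
    if (!length(w)) 1L else max(w)
  }, integer(1))
  series$value[idx]
}

#' Phylogenetic eigenvectors
#'
#' Principal-coordinate decomposition of the pairwise patristic distance
#' matrix among tips: the distances are squared, Gower-centered, and
#' eigen-decomposed; tip coordinates on the leading axes summarize both
#' topology and branching times and serve as predictors proxying
#' phylogenetic relatedness. The sign of each axis is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param tree A rooted \code{ape::phylo} tree with branch lengths, or a
#'   patristic distance matrix.
#' @param k Number of leading eigenvectors to return.
#' @return Object of class \code{phylo_eigenvectors}: list with
#'   \code{vectors} (tips x k coordinate matrix) and \code{values}
#'   (all positive eigenvalues, decreasing).
#' @export
phylo_eigenvectors <- function(tree, k = 2) {
  if (inherits(tree, "phylo")) {
    if (length(tree$tip.label) < 3) stop("tree must have >= 3 tips")
    if (is.null(tree$edge.length) || any(tree$edge.length < 0))
      stop("tree must have non-negative branch lengths")
    D <- stats::cophenetic(tree)
  } else {
    D <- as.matrix(tree)
  }
  n <- nrow(D)
  A <- -0.5 * D^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  G <- ctr %*% A %*% ctr
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values) * 1e-10)
  if (k > length(pos))
    stop("k = ", k, " exceeds the ", length(pos),
         " positive eigenvalues of the decomposition")
  V <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eg$values[pos]), length(pos))
  # sign convention: largest-|loading| positive per axis
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(D)
  colnames(V) <- paste0("phylo_ev", seq_len(ncol(V)))
  structure(list(vectors = V[, seq_len(k), drop = FALSE],
                 values = eg$values[pos]),
            class = "phylo_eigenvectors")
}

#' Predictor tensor for the rate networks
#'
#' Assembles the per-(species, time-bin) predictor rows feeding the
#' networks: time (bin midpoints), species traits, phylogenetic
#' eigenvectors, and binned environmental series. Continuous predictors
#' (including time, eigenvectors, and environmental series) are
#' z-transformed to mean 0 and SD 1 over all cells; categorical traits with
#' two states become a single binary column and those with more states are
#' one-hot encoded with the full indicator set. Zero-variance columns are
#' kept as all-zero so the predictor set stays fixed.
#'
#' @param dataset An \code{\link{occurrence_dataset}} (defines the species
#'   set), or a character vector of species names.
#' @param traits Data frame of per-species traits (row names = species);
#'   may be NULL.
#' @param time_series Named list of binned series (each as returned by
#'   \code{\link{read_time_series}}).
#' @param eigenvectors Optional \code{\link{phylo_eigenvectors}}.
#' @param time_bins Strictly decreasing bin boundary ages (Ma).
#' @return Object of class \code{predictor_tensor} with fields
#'   \code{values} (species x bin x predictor array),
#'   \code{predictor_names}, \code{predictor_kinds},
#'   \code{standardization}, \code{species}, \code{time_bins},
#'   \code{bin_mid}.
#' @export
build_predictor_tensor <- function(dataset, traits = NULL,
                                   time_series = list(),
                                   eigenvectors = NULL, time_bins) {
  species <- if (inherits(dataset, "occurrence_dataset")) dataset$taxa
             else as.character(dataset)
  if (any(diff(time_bins) >= 0)) stop("time_bins must be strictly decreasing")
  S <- length(species)
  B <- length(time_bins) - 1
  mids <- (time_bins[-length(time_bins)] + time_bins[-1]) / 2

  cols <- list(); kinds <- character()
  add_col <- function(mat, name, kind) {
    cols[[name]] <<- mat
    kinds[name] <<- kind
  }
  add_col(matrix(mids, S, B, byrow = TRUE), "time", "time")

  if (!is.null(traits)) {
    missing <- setdiff(species, rownames(traits))
    if (length(missing))
      stop("species missing from trait table: ",
           paste(missing, collapse = ", "))
    traits <- traits[species, , drop = FALSE]
    for (nm in names(traits)) {
      v <- traits[[nm]]
      if (is.numeric(v)) {
        add_col(matrix(v, S, B), nm, "continuous")
      } else {
        states <- sort(unique(as.character(v)))
        if (length(states) == 2) {
          add_col(matrix(as.numeric(v == states[2]), S, B), nm, "binary")
        } else {
          for (st in states)
            add_col(matrix(as.numeric(v == st), S, B),
                    paste0(nm, "_", st), paste0("one-hot:", nm))
        }
      }
    }
  }
  if (!is.null(eigenvectors)) {
    EV <- eigenvectors$vectors
    missing <- setdiff(species, rownames(EV))
    if (length(missing))
      stop("species missing from eigenvectors: ",
           paste(missing, collapse = ", "))
    for (j in seq_len(ncol(EV)))
      add_col(matrix(EV[species, j], S, B), colnames(EV)[j], "eigenvector")
  }
  for (nm in names(time_series)) {
    ser <- time_series[[nm]]
    if (max(ser$bin_top_age) < time_bins[1] - 1e-9)
      stop("time series '", nm, "' does not cover the oldest analysis bin")
    add_col(matrix(series_at(ser, mids), S, B, byrow = TRUE), nm, "continuous")
  }

  J <- length(cols)
  values <- array(NA_real_, dim = c(S, B, J),
                  dimnames = list(species, NULL, names(cols)))
  standardization <- data.frame(predictor = names(cols), mean = 0, sd = 1)
  for (j in seq_len(J)) {
    m <- cols[[j]]
    if (!startsWith(kinds[j], "one-hot") && kinds[j] != "binary") {
      mu <- mean(m); sdv <- stats::sd(as.numeric(m))
      if (sdv == 0) {
        m <- m * 0  # zero-variance column kept, all-zero
        standardization$mean[j] <- mu; standardization$sd[j] <- 0
      } else {
        m <- (m - mu) / sdv
        standardization$mean[j] <- mu; standardization$sd[j] <- sdv
      }
    }
    values[, , j] <- m
  }
  structure(list(values = values, predictor_names = names(cols),
                 predictor_kinds = unname(kinds),
                 standardization = standardization, species = species,
                 time_bins = time_bins, bin_mid = mids),
            class = "predictor_tensor")
}

#' @export
print.predictor_tensor <- function(x, ...) {
  cat("Predictor tensor:", length(x$species), "species x",
      length(x$bin_mid), "bins x", length(x$predictor_names), "predictors\n")
  cat("Predictors:", paste(x$predictor_names, collapse = ", "), "\n")
  invisible(x)
}

# Flatten the tensor to an (S*B) x J matrix whose row for cell (i, b) is
# i + (b - 1) * S, matching matrix(v, S, B) on the kernel side.
tensor_matrix <- function(predictors) {
  d <- dim(predictors$values)
  matrix(predictors$values, d[1] * d[2], d[3],
         dimnames = list(NULL, predictors$predictor_names))
}

# Replace the values of one predictor (or a one-hot group) in the flattened
# matrix; `value` is either a scalar/vector for one column, or a state name
# for a one-hot group.
set_predictor <- function(X, predictors, name, value) {
  kinds <- predictors$predictor_kinds
  names(kinds) <- predictors$predictor_names
  if (name %in% predictors$predictor_names &&
      !startsWith(kinds[name], "one-hot")) {
    X[, name] <- value
    return(X)
  }
  grp <- paste0("one-hot:", name)
  members <- predictors$predictor_names[kinds == grp]
  if (!length(members)) stop("unknown predictor: ", name)
  target <- paste0(name, "_", value)
  if (!target %in% members)
    stop("unknown state '", value, "' for one-hot predictor ", name)
  for (m in members) X[, m] <- as.numeric(m == target)
  X
}
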