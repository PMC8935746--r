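#' Configuration of the synthetic-data generators
#'
#' One configuration object defines a "latent world": a base log2-expression
#' profile (the embryonic stem cell state) plus a planted set of stemness
#' genes whose means move monotonically with differentiation time. All
#' generators in this module are pure functions of a config and a seed; the
#' latent world itself is derived deterministically from `seed`, so a
#' differentiation course, an ESC reference pool and a tumor mixture built
#' from the same config share one latent gene ordering — exactly the
#' situation the scoring machinery assumes.
#'
#' Defaults are desk-scale: 300 genes of which 40 are planted (half rising,
#' half falling with time at 1 log2 unit per time unit), 60 cells over 6
#' time points (time 0..5), Gaussian log-scale noise sd 0.5, and an
#' expression-dependent dropout budget of 0.2 for single-cell-like data.
#'
#' @param seed integer world seed (mandatory; keep below 2^31).
#' @param n_genes total number of genes.
#' @param n_stemness_genes number of planted time-monotone genes
#'   (`<= n_genes`; half get a positive slope, half a negative one).
#' @param n_samples number of samples/cells per generated dataset.
#' @param n_timepoints number of equally spaced time points `0 .. T-1`.
#' @param effect_size absolute slope of planted trends, log2 units per unit
#'   time.
#' @param noise_sd per-entry Gaussian noise sd on the log2 scale.
#' @param dropout_rate maximal per-entry dropout probability for
#'   single-cell-like data in \[0, 1\]; the realized probability decays
#'   logistically with latent log2 expression, mimicking the
#'   expression-dependent detection of real single-cell protocols.
#' @param base_mean,base_sd Gaussian parameters of the latent log2 base
#'   means.
#' @param count_mode if `TRUE`, emit Poisson counts around the latent
#'   (linear-scale) means instead of log-normal values.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed, n_genes = 300L, n_stemness_genes = 40L,
                             n_samples = 60L, n_timepoints = 6L,
                             effect_size = 1.0, noise_sd = 0.5,
                             dropout_rate = 0.2, base_mean = 5, base_sd = 2,
                             count_mode = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(n_genes >= 2, n_stemness_genes >= 0, n_stemness_genes <= n_genes,
            n_samples >= 1, n_timepoints >= 2, effect_size >= 0,
            noise_sd >= 0, dropout_rate >= 0, dropout_rate <= 1, base_sd >= 0)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_stemness_genes = as.integer(n_stemness_genes),
                 n_samples = as.integer(n_samples),
                 n_timepoints = as.integer(n_timepoints),
                 effect_size = effect_size, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, base_mean = base_mean,
                 base_sd = base_sd, count_mode = isTRUE(count_mode)),
            class = "SyntheticConfig")
}

# The latent world: base means, planted roles and slopes. Deterministic in
# config$seed only.
latent_world <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  with_seed(derive_seed(config$seed, 0L), {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    mu <- stats::rnorm(config$n_genes, config$base_mean, config$base_sd)
    roles <- rep("null", config$n_genes)
    planted <- sample.int(config$n_genes, config$n_stemness_genes)
    n_up <- config$n_stemness_genes %/% 2L
    roles[planted[seq_len(n_up)]] <- "time-up"
    roles[planted[-seq_len(n_up)]] <- "time-down"
    slope <- ifelse(roles == "time-up", config$effect_size,
                    ifelse(roles == "time-down", -config$effect_size, 0))
    list(genes = genes, mu = mu, roles = roles, slope = slope)
  })
}

# Expression-dependent dropout: probability decays logistically with latent
# log2 expression, so strongly expressed genes are essentially never lost.
dropout_prob <- function(log2_expr, rate, midpoint, steepness = 2) {
  rate * stats::plogis((midpoint - log2_expr) * steepness)
}

# Build a synthetic ExpressionDataset from latent log2 means + noise.
synth_dataset <- function(world, config, times, dataset_id, seed,
                          scale = 1, dropout = 0, extra_meta = NULL) {
  n <- length(times)
  with_seed(seed, {
    log2e <- matrix(world$mu, config$n_genes, n) +
      outer(world$slope, times) +
      matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
             config$n_genes, n)
    X <- if (config$count_mode) {
      matrix(stats::rpois(length(log2e), lambda = scale * 2^log2e),
             config$n_genes, n)
    } else scale * 2^log2e
    if (dropout > 0) {
      p <- dropout_prob(log2e, dropout, config$base_mean)
      drop <- matrix(stats::runif(length(X)), nrow(X)) < p
      X[drop & X > 0] <- 0
    }
    dimnames(X) <- list(world$genes,
                        sprintf("%s_c%03d", dataset_id, seq_len(n)))
    meta <- data.frame(sample = colnames(X), time = times,
                       stringsAsFactors = FALSE)
    if (!is.null(extra_meta)) meta <- cbind(meta, extra_meta)
    ds <- expression_dataset(X, dataset_id = dataset_id, sample_meta = meta)
    ds$truth <- list(roles = stats::setNames(world$roles, world$genes),
                     time = stats::setNames(times, colnames(X)))
    class(ds) <- c("SyntheticDataset", class(ds))
    ds
  })
}

#' Generate a synthetic differentiation time course
#'
#' Cells are spread evenly over `n_timepoints` equally spaced times
#' `0 .. T-1`. Planted genes follow monotone log2-mean trends of slope
#' `±effect_size`; null genes stay flat. Values are log-normal (or Poisson
#' in count mode), hence nonnegative. Time-course data emulate sorted
#' bulk-like protocols, so no dropout is applied unless requested.
#'
#' @param config a [synthetic_config()].
#' @param dataset_id dataset label.
#' @param seed noise seed; defaults to the config seed. Datasets generated
#'   with different seeds from the same config are independent replicates of
#'   the same latent world.
#' @param dropout_rate optional dropout budget for single-cell-like courses
#'   (default 0).
#' @return a `SyntheticDataset`: an `ExpressionDataset` whose `sample_meta`
#'   carries `time` and `state` (one label per time point) and whose `truth`
#'   element records planted gene roles, true times and the origin state.
#' @export
generate_differentiation_course <- function(config, dataset_id = "course",
                                            seed = config$seed,
                                            dropout_rate = 0) {
  stopifnot(inherits(config, "SyntheticConfig"))
  world <- latent_world(config)
  times <- sort(rep_len(seq_len(config$n_timepoints) - 1, config$n_samples))
  ds <- synth_dataset(world, config, times, dataset_id,
                      seed = derive_seed(seed, 1L),
                      dropout = dropout_rate,
                      extra_meta = data.frame(state = sprintf("S%d", times + 1)))
  ds$truth$origin_state <- "S1"
  ds
}

#' Generate bulk-like and single-cell-like ESC reference pools
#'
#' Every dataset is drawn around the same latent time-0 (ESC) profile as
#' [generate_differentiation_course()] for the same config, with an
#' independent per-dataset library scale factor and per-entry noise.
#' Single-cell-like datasets additionally receive expression-dependent
#' dropout at the config's `dropout_rate` budget. Default pool sizes (3 x 30
#' cells single-cell, 2 x 24 samples bulk) mirror the order of magnitude of
#' typical public ESC compendia.
#'
#' @param config a [synthetic_config()].
#' @param n_datasets_sc,n_datasets_bulk number of datasets per pool.
#' @param n_cells_sc,n_cells_bulk samples per dataset.
#' @param seed pool seed; defaults to the config seed.
#' @return list with elements `sc` and `bulk`, each a list of
#'   `SyntheticDataset`s.
#' @export
generate_esc_pool <- function(config, n_datasets_sc = 3L, n_datasets_bulk = 2L,
                              n_cells_sc = 30L, n_cells_bulk = 24L,
                              seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"),
            n_datasets_sc >= 1, n_datasets_bulk >= 1)
  world <- latent_world(config)
  make <- function(i, id, n_cells, dropout) {
    s <- derive_seed(seed, 100L + i)
    scale <- with_seed(derive_seed(seed, 200L + i), 2^stats::rnorm(1, 0, 1))
    synth_dataset(world, config, times = rep(0, n_cells), dataset_id = id,
                  seed = s, scale = scale, dropout = dropout)
  }
  sc <- lapply(seq_len(n_datasets_sc), function(i)
    make(i, sprintf("sc%02d", i), n_cells_sc, config$dropout_rate))
  bulk <- lapply(seq_len(n_datasets_bulk), function(i)
    make(1000L + i, sprintf("bulk%02d", i), n_cells_bulk, 0))
  list(sc = sc, bulk = bulk)
}

#' Apply a random per-sample monotone batch distortion
#'
#' Each sample is transformed by an independent random strictly increasing
#' map `y = a * x^b` with log-normal scale `a > 0` and power
#' `b ~ Uniform(0.5, 2)`; zeros stay zero. Within-sample ranks — and hence
#' every REO-based quantity — are unchanged, while absolute values and
#' cross-sample comparability are destroyed, emulating severe batch effects.
#'
#' @param dataset an `ExpressionDataset`.
#' @param seed integer seed.
#' @return a distorted `ExpressionDataset` with the same metadata.
#' @export
apply_batch_distortion <- function(dataset, seed) {
  dataset <- as_expression_dataset(dataset)
  X <- dataset$values
  with_seed(seed, {
    a <- exp(stats::rnorm(ncol(X), 0, 1))
    b <- stats::runif(ncol(X), 0.5, 2)
    Y <- sweep(sweep(X, 2, b, `^`), 2, a, `*`)
  })
  out <- dataset
  out$values <- Y
  out
}

#' Apply uniform dropout to positive entries
#'
#' Each positive entry is independently set to zero with probability `rate`.
#' (The ESC-pool and tumor generators use an expression-dependent variant
#' internally; this uniform operation is the building block exposed for
#' stress testing.)
#'
#' @param dataset an `ExpressionDataset`.
#' @param rate dropout probability in \[0, 1\].
#' @param seed integer seed.
#' @return an `ExpressionDataset` with zeros injected.
#' @export
apply_dropout <- function(dataset, rate, seed) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1)
    stop("`rate` must be a single probability in [0, 1]")
  dataset <- as_expression_dataset(dataset)
  X <- dataset$values
  with_seed(seed, {
    drop <- matrix(stats::runif(length(X)), nrow(X)) < rate
  })
  X[drop & X > 0] <- 0
  out <- dataset
  out$values <- X
  out
}

#' Generate a synthetic tumor mixture with validated CSCs
#'
#' A single-cell dataset in which a `csc_fraction` of the cells sit at the
#' latent stem (time 0) state and the remaining differentiated cells sit at
#' latent time `separation`. True CSC flags are recorded in `sample_meta$csc`
#' and in `truth$csc`. Expression-dependent dropout at the config budget is
#' applied (tumor mixtures are single-cell data).
#'
#' @param config a [synthetic_config()].
#' @param csc_fraction fraction of CSC cells, strictly between 0 and 1; the
#'   planted CSC count is `round(csc_fraction * n_samples)` and must leave
#'   both classes nonempty.
#' @param separation latent time offset of the differentiated cells, in the
#'   same units as the course time axis (default 3 of a 0..5 axis).
#' @param dataset_id dataset label.
#' @param seed noise seed; defaults to the config seed.
#' @return a `SyntheticDataset` with CSC flags.
#' @export
generate_tumor_mixture <- function(config, csc_fraction = 0.2, separation = 3,
                                   dataset_id = "tumor", seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (!is.numeric(csc_fraction) || csc_fraction <= 0 || csc_fraction >= 1)
    stop("`csc_fraction` must lie strictly between 0 and 1")
  n <- config$n_samples
  n_csc <- round(csc_fraction * n)
  if (n_csc < 1L || n_csc >= n)
    stop("`csc_fraction` leaves an empty class at n_samples = ", n)
  world <- latent_world(config)
  times <- c(rep(0, n_csc), rep(separation, n - n_csc))
  csc <- times == 0
  ds <- synth_dataset(world, config, times, dataset_id,
                      seed = derive_seed(seed, 3L),
                      dropout = config$dropout_rate,
                      extra_meta = data.frame(csc = csc))
  ds$truth$csc <- stats::setNames(csc, dataset_samples(ds))
  ds
}
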