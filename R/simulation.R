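#' Null-design simulation configuration
#'
#' The default null design: 10,000 samples by 100 genes of independent
#' Poisson(lambda = 5) counts, library-size normalized, scored for a
#' single gene set containing the first 20 genes, with the per-gene mean
#' as reference and neutral tissue weights (the simulation has no tissue
#' structure, so weighting must be a no-op).
#'
#' @param n_samples Number of simulated samples (default 10000).
#' @param n_genes Number of simulated genes (default 100).
#' @param lambda Poisson mean (default 5).
#' @param set_size Size of the single scored gene set, taken as the first
#'   `set_size` genes (default 20).
#' @param alpha Nominal significance level for rejection-rate estimation
#'   (default 0.05).
#' @param seed Integer RNG seed.
#' @return A `null_sim_config` list.
#' @export
null_sim_config <- function(n_samples = 10000L, n_genes = 100L, lambda = 5,
                            set_size = 20L, alpha = 0.05, seed = 1L) {
  stopifnot(set_size <= n_genes, lambda > 0, alpha >= 0, alpha <= 1,
            n_samples >= 2)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes), lambda = lambda,
                 set_size = as.integer(set_size), alpha = alpha,
                 seed = as.integer(seed)),
            class = "null_sim_config")
}

#' Power-design simulation configuration
#'
#' Extends the null design with a planted signal: a constant offset of
#' `lambda * delta` added to the counts of the first `n_affected_samples`
#' samples for the first `set_size` genes, before normalization, for each
#' effect size delta on the grid.
#'
#' @inheritParams null_sim_config
#' @param delta_grid Effect sizes (default `seq(0.1, 2, by = 0.1)`).
#' @param n_affected_samples Number of samples receiving the offset
#'   (default 1000).
#' @return A `power_sim_config` list.
#' @export
power_sim_config <- function(n_samples = 10000L, n_genes = 100L, lambda = 5,
                             set_size = 20L, alpha = 0.05, seed = 1L,
                             delta_grid = seq(0.1, 2, by = 0.1),
                             n_affected_samples = 1000L) {
  base <- null_sim_config(n_samples, n_genes, lambda, set_size, alpha, seed)
  stopifnot(n_affected_samples <= n_samples, all(delta_grid > 0))
  base$delta_grid <- as.numeric(delta_grid)
  base$n_affected_samples <- as.integer(n_affected_samples)
  class(base) <- c("power_sim_config", "null_sim_config")
  base
}

#' Simulate a null Poisson count matrix
#'
#' @param config A `null_sim_config`.
#' @return Integer-valued n_samples x n_genes matrix of i.i.d.
#'   Poisson(lambda) counts with sample/gene dimnames; deterministic given
#'   `config$seed`.
#' @export
simulate_null_counts <- function(config = null_sim_config()) {
  set.seed(config$seed)
  counts <- matrix(stats::rpois(config$n_samples * config$n_genes,
                                lambda = config$lambda),
                   nrow = config$n_samples, ncol = config$n_genes)
  dimnames(counts) <- list(paste0("sample_", seq_len(config$n_samples)),
                           paste0("gene_", seq_len(config$n_genes)))
  # double storage so offset/normalization steps never reallocate types
  storage.mode(counts) <- "double"
  counts
}

#' Plant a constant offset in a count matrix
#'
#' Adds `lambda * delta` to the counts of the first `n_affected_samples`
#' rows and first `set_size` columns. Applied to raw counts, before
#' library-size normalization.
#'
#' @param counts Count matrix.
#' @param delta Effect size (> 0; 0 is tolerated internally and is the
#'   identity).
#' @param n_affected_samples,set_size Extent of the affected block.
#' @param lambda Poisson mean used to scale the offset.
#' @return The modified matrix.
#' @export
add_offset <- function(counts, delta, n_affected_samples, set_size, lambda) {
  if (delta < 0) stop("delta must be nonnegative")
  stopifnot(n_affected_samples <= nrow(counts), set_size <= ncol(counts))
  if (delta == 0 || n_affected_samples == 0L) return(counts)
  rows <- seq_len(n_affected_samples)
  cols <- seq_len(set_size)
  counts[rows, cols] <- counts[rows, cols] + lambda * delta
  counts
}

#' Library-size normalization by depth matching
#'
#' Rescales each sample so its total equals the mean total across samples
#' (equivalent to counts-per-million up to one global constant). Relative
#' within-sample proportions are preserved.
#'
#' @param counts Nonnegative matrix, samples in rows; no all-zero sample.
#' @return Normalized matrix of the same shape.
#' @export
normalize_library_size <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("Sample(s) with zero total count cannot be normalized: ",
         paste(utils::head(which(totals == 0), 3), collapse = ", "))
  }
  sweep(counts, 1L, mean(totals) / totals, "*")
}

# Shared scoring path for both simulation designs: per-gene mean reference,
# neutral tissue weights, one set = first set_size genes.
simulate_and_score <- function(counts, config, tpac_seed) {
  X <- normalize_library_size(counts)
  t_ref <- colMeans(X)
  sets <- list(set1 = colnames(X)[seq_len(config$set_size)])
  fit <- tpac(X, t = t_ref, t_bar = NULL, collection = sets,
              min_set_size = min(5L, config$set_size),
              n_permutations = 1L, seed = tpac_seed)
  fit
}

#' Empirical type I error of sample-level p-values under the null design
#'
#' Simulates the null design, runs the full scoring pipeline and reports
#' the fraction of the n_samples sample-level p-values (from the combined
#' score matrix S) falling below `config$alpha`.
#'
#' @param config A `null_sim_config`.
#' @return A `sim_result` list: `rejection_rate` (single-row data.frame
#'   with columns condition, delta, rate, n), `seed`, `config`.
#' @export
estimate_type1_error <- function(config = null_sim_config()) {
  counts <- simulate_null_counts(config)
  fit <- simulate_and_score(counts, config, tpac_seed = config$seed + 1L)
  p <- fit$P[, 1L]
  rate <- mean(p < config$alpha)
  structure(list(
    rejection_rate = data.frame(condition = "null", delta = 0, rate = rate,
                                n = length(p)),
    seed = config$seed, config = config), class = "sim_result")
}

#' Empirical power across a grid of effect sizes
#'
#' For each delta on the grid: simulates Poisson counts, adds the planted
#' offset to the affected block, normalizes, scores, and reports the
#' fraction of affected samples with combined-score p-value below
#' `config$alpha` (raw p, matching the type I error convention). The
#' rejection rate among unaffected samples is reported alongside as a
#' specificity check.
#'
#' @param config A `power_sim_config`.
#' @return A `sim_result`; `rejection_rate` has one row per delta with
#'   columns condition, delta, rate, n, null_rate.
#' @export
estimate_power <- function(config = power_sim_config()) {
  rows <- lapply(seq_along(config$delta_grid), function(i) {
    delta <- config$delta_grid[[i]]
    cfg_i <- config
    # Independent count draw per delta, deterministic in (seed, i).
    cfg_i$seed <- config$seed + i
    counts <- simulate_null_counts(cfg_i)
    counts <- add_offset(counts, delta, config$n_affected_samples,
                         config$set_size, config$lambda)
    fit <- simulate_and_score(counts, config, tpac_seed = cfg_i$seed + 1L)
    p <- fit$P[, 1L]
    affected <- seq_len(config$n_affected_samples)
    data.frame(condition = "power", delta = delta,
               rate = mean(p[affected] < config$alpha),
               n = config$n_affected_samples,
               null_rate = mean(p[-affected] < config$alpha))
  })
  structure(list(rejection_rate = do.call(rbind, rows),
                 seed = config$seed, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation result (seed ", x$seed, ")\n", sep = "")
  print(x$rejection_rate, row.names = FALSE)
  invisible(x)
}
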