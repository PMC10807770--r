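#' Prepare an expression matrix for scoring
#'
#' Validates a samples-by-genes matrix of normalized, linear-scale
#' expression values and removes genes with zero variance across samples
#' (their deviations carry no calibratable signal and their sample variance
#' cannot be used as a Mahalanobis denominator).
#'
#' Orientation is samples in rows, genes in columns throughout the package.
#' Values must be linear-scale (TPM-like): the tissue-specificity weight is
#' a linear fold-change, so log-scale input silently changes its meaning.
#'
#' @param values Numeric matrix, n samples x p genes, finite and
#'   nonnegative.
#' @param sample_ids Optional character vector of unique sample
#'   identifiers; defaults to existing rownames.
#' @param gene_ids Optional character vector of unique gene identifiers;
#'   defaults to existing colnames.
#' @return The matrix with dimnames set and zero-variance columns removed;
#'   attribute `dropped_genes` lists the removed identifiers.
#' @export
prepare_expression <- function(values, sample_ids = rownames(values),
                               gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("Expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("Expression values must be finite; missing values are not supported")
  }
  if (any(values < 0)) {
    stop("Expression values must be nonnegative (linear-scale normalized)")
  }
  if (nrow(values) < 2L) {
    stop("At least 2 samples are required (sample variance is undefined)")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(gene_ids)) stop("gene_ids are required (or set colnames)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (length(sample_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("sample_ids/gene_ids lengths must match matrix dimensions")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  v <- matrixStats_colVars(values)
  zero <- v == 0
  if (all(zero)) stop("All genes have zero variance")
  dropped <- gene_ids[zero]
  out <- values[, !zero, drop = FALSE]
  attr(out, "dropped_genes") <- dropped
  out
}

# Unbiased (n-1) column variances, two-pass for numerical stability;
# exactly-constant columns are forced to exactly 0 so zero-variance
# detection never depends on floating-point cancellation.
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  centered <- sweep(x, 2L, colMeans(x), "-")
  v <- colSums(centered * centered) / (n - 1)
  constant <- colSums(sweep(x, 2L, x[1L, ], "-") != 0) == 0L
  v[constant] <- 0
  v
}

#' Tissue-specificity weights from reference profiles
#'
#' Computes per-gene tissue-specificity t* as the linear fold-change
#' t / t_bar between the mean expression in the cancer's matched normal
#' tissue (t) and the average of mean expression across all normal tissues
#' (t_bar). A gene with t* > 1 is enriched in the matched tissue; t* < 1
#' means it is relatively suppressed there.
#'
#' Genes with t_bar = 0 carry no cross-tissue information: their weight is
#' set to 1 (weighting becomes a no-op for them) and they are flagged in
#' the `no_tissue_info` attribute. Ratios are clamped to
#' `[clamp_lo, clamp_hi]` so that a single extreme ratio cannot dominate a
#' set's distance.
#'
#' @param t Numeric vector, per-gene mean expression in the matched normal
#'   tissue (length p, nonnegative).
#' @param t_bar Numeric vector, per-gene mean expression averaged across
#'   all reference tissues (length p, nonnegative).
#' @param clamp_lo,clamp_hi Bounds on t*; defaults 1e-4 and 1e4.
#' @return Numeric vector t* of length p (names carried over from `t`),
#'   with attribute `no_tissue_info` (logical, TRUE where t_bar = 0).
#' @export
tissue_specificity <- function(t, t_bar, clamp_lo = 1e-4, clamp_hi = 1e4) {
  if (length(t) != length(t_bar)) {
    stop("t and t_bar must have the same length")
  }
  if (any(t < 0) || any(t_bar < 0)) stop("t and t_bar must be nonnegative")
  if (clamp_lo <= 0 || clamp_hi < clamp_lo) {
    stop("Require 0 < clamp_lo <= clamp_hi")
  }
  no_info <- t_bar == 0
  t_star <- ifelse(no_info, 1, t / t_bar)
  t_star <- pmin(pmax(t_star, clamp_lo), clamp_hi)
  names(t_star) <- names(t)
  attr(t_star, "no_tissue_info") <- no_info
  t_star
}

#' Split tumor-minus-reference deviations by sign
#'
#' Subtracts the reference profile `t` from each sample row of `X` and
#' splits the result into its nonnegative part (up-regulation relative to
#' normal tissue) and nonpositive part (down-regulation). The two parts
#' reconstruct X - t exactly and are never simultaneously nonzero.
#'
#' @param X Numeric matrix, n samples x p genes.
#' @param t Numeric reference vector of length p, aligned to the columns
#'   of `X`.
#' @return List with `delta_plus` (>= 0) and `delta_minus` (<= 0), both
#'   n x p.
#' @export
split_deviations <- function(X, t) {
  if (length(t) != ncol(X)) {
    stop("Reference t must have one value per gene column of X")
  }
  delta <- sweep(X, 2L, t, "-")
  list(delta_plus = pmax(delta, 0), delta_minus = pmin(delta, 0))
}

#' Direction-specific tissue-weighted gene variances
#'
#' The per-gene unbiased sample variance (computed on `X` itself, not on
#' the deviations) is inflated by t* for the positive direction and
#' deflated by t* for the negative direction:
#' `var_plus = var * t_star`, `var_minus = var / t_star`.
#'
#' These are the diagonals of the two weighted covariance matrices. The
#' directionality means up-regulation of a gene that is already enriched
#' in the matched tissue (t* > 1) is down-weighted, while down-regulation
#' of such a gene is amplified — and vice versa for tissue-suppressed
#' genes.
#'
#' @param X Prepared expression matrix (no zero-variance genes).
#' @param t_star Tissue-specificity weights, length ncol(X), strictly
#'   positive.
#' @return List with `var_plus`, `var_minus` and the unweighted `var`,
#'   each length p.
#' @export
weighted_variances <- function(X, t_star) {
  if (length(t_star) != ncol(X)) {
    stop("t_star must have one value per gene column of X")
  }
  if (any(t_star <= 0)) stop("t_star must be strictly positive")
  v <- matrixStats_colVars(X)
  if (any(v <= 0)) {
    stop("Zero-variance gene present; run prepare_expression() first")
  }
  list(var_plus = v * t_star, var_minus = v / t_star, var = v)
}

#' Per-set squared Mahalanobis distances with diagonal covariance
#'
#' For each gene set k, computes the squared modified Mahalanobis distance
#' of each sample's deviation sub-vector against the diagonal covariance
#' restricted to the set:
#' \deqn{M[i,k] = \sum_{j \in k} dev[i,j]^2 / variances[j]}
#' which is the closed form of diag(D_k Sigma_k^{-1} D_k^T) when all
#' off-diagonal covariances are zero.
#'
#' @param dev Numeric n x p matrix of (signed) deviations.
#' @param variances Strictly positive length-p vector of per-gene
#'   variances.
#' @param index A `set_index` from [build_set_index()].
#' @return Numeric n x m matrix of nonnegative squared distances, columns
#'   named by set.
#' @export
set_distances <- function(dev, variances, index) {
  if (length(variances) != ncol(dev)) {
    stop("variances must have one value per gene column")
  }
  used <- unique(unlist(index, use.names = FALSE))
  if (any(variances[used] <= 0)) {
    stop("variances must be strictly positive on all indexed genes")
  }
  scaled <- sweep(dev * dev, 2L, variances, "/")
  M <- vapply(index, function(cols) {
    rowSums(scaled[, cols, drop = FALSE])
  }, numeric(nrow(dev)))
  M <- matrix(M, nrow = nrow(dev),
              dimnames = list(rownames(dev), names(index)))
  M
}

#' Combine positive and negative distance matrices
#'
#' Total dysregulation distance is the elementwise sum of the positive and
#' negative components.
#'
#' @param M_plus,M_minus Numeric n x m matrices of the same shape.
#' @return Their elementwise sum.
#' @export
total_distances <- function(M_plus, M_minus) {
  if (!identical(dim(M_plus), dim(M_minus))) {
    stop("M_plus and M_minus must have identical dimensions")
  }
  M_plus + M_minus
}

#' Column-permuted copies of an expression matrix
#'
#' Generates the permutation null: each gene column is independently
#' shuffled across samples, destroying inter-gene correlation and any
#' sample-level mean shift while preserving each gene's marginal value
#' multiset (and hence its sample variance).
#'
#' @param X Numeric n x p matrix, n >= 2.
#' @param n_permutations Number of independent permuted copies (default 1,
#'   matching the reference procedure; more copies pool null distances for
#'   small-n stability).
#' @param rng_seed Optional integer seed; if `NULL` the current RNG state
#'   is used.
#' @return List of `n_permutations` matrices with the shape and dimnames
#'   of `X`.
#' @export
permute_columns <- function(X, n_permutations = 1L, rng_seed = NULL) {
  if (nrow(X) < 2L) stop("Need at least 2 samples to permute")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  n <- nrow(X)
  lapply(seq_len(n_permutations), function(b) {
    Xp <- apply(X, 2L, function(col) col[sample.int(n)])
    dimnames(Xp) <- dimnames(X)
    Xp
  })
}

#' Gamma maximum-likelihood fit
#'
#' Fits shape/rate gamma parameters to strictly positive values by maximum
#' likelihood. The shape MLE solves `log(a) - digamma(a) = log(mean(x)) -
#' mean(log(x))` (a strictly decreasing equation in a), found by Newton
#' iteration from the method-of-moments start; the rate is then
#' `shape / mean(x)`.
#'
#' @param values Strictly positive numeric vector. Values must already be
#'   filtered: zeros are a contract violation, not silently dropped,
#'   because the caller decides what "nonzero" means for its null.
#' @param min_fit_n Minimum number of values required for a fit
#'   (default 10).
#' @return List with `shape`, `rate`, `n` (values used), `fit_ok` and, when
#'   `fit_ok` is FALSE, a `reason` string. No error is thrown for
#'   degenerate inputs of valid type: the caller records the failure and
#'   emits missing scores.
#' @export
fit_gamma_mle <- function(values, min_fit_n = 10L) {
  if (anyNA(values)) stop("values must not contain NA")
  if (any(values <= 0)) {
    stop("fit_gamma_mle requires strictly positive values; ",
         "filter zeros before calling")
  }
  n <- length(values)
  failed <- function(reason) {
    list(shape = NA_real_, rate = NA_real_, n = n, fit_ok = FALSE,
         reason = reason)
  }
  if (n < min_fit_n) {
    return(failed(sprintf("too few values (%d < %d)", n, min_fit_n)))
  }
  m <- mean(values)
  s <- log(m) - mean(log(values))
  if (!is.finite(s) || s <= 0) {
    # s == 0 iff all values equal: the gamma MLE degenerates (shape -> Inf)
    return(failed("degenerate input (zero variance of log-values)"))
  }
  # Method-of-moments start, then Newton on f(a) = log(a) - digamma(a) - s.
  a <- m * m / stats::var(values)
  if (!is.finite(a) || a <= 0) a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  tol <- 1e-10
  converged <- FALSE
  for (iter in seq_len(100L)) {
    f <- log(a) - digamma(a) - s
    fp <- 1 / a - trigamma(a)
    step <- f / fp
    a_new <- a - step
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < tol * (a + tol)) {
      a <- a_new
      converged <- TRUE
      break
    }
    a <- a_new
  }
  if (!converged || !is.finite(a) || a <= 0) {
    return(failed("Newton iteration did not converge"))
  }
  list(shape = a, rate = a / m, n = n, fit_ok = TRUE, reason = NULL)
}

#' Fit per-set gamma nulls on permuted distance matrices
#'
#' For each set column of each permuted distance matrix, pools the strictly
#' positive distances across permuted copies and fits a gamma by maximum
#' likelihood. Zeros are excluded from fitting (a zero distance means no
#' deviation in any set gene and is not informative about the null tail).
#'
#' @param M_perm_list List of n x m permuted-null distance matrices (one
#'   per permuted copy).
#' @param min_fit_n Passed to [fit_gamma_mle()].
#' @return A data.frame with one row per set: `set`, `shape`, `rate`,
#'   `n_nonzero`, `fit_ok`, `reason`.
#' @export
fit_gamma_null <- function(M_perm_list, min_fit_n = 10L) {
  stopifnot(length(M_perm_list) >= 1L)
  m <- ncol(M_perm_list[[1L]])
  set_names <- colnames(M_perm_list[[1L]])
  rows <- lapply(seq_len(m), function(k) {
    vals <- unlist(lapply(M_perm_list, function(M) M[, k]), use.names = FALSE)
    vals <- vals[vals > 0]
    fit <- if (length(vals) == 0L) {
      list(shape = NA_real_, rate = NA_real_, n = 0L, fit_ok = FALSE,
           reason = "no nonzero null distances")
    } else {
      fit_gamma_mle(vals, min_fit_n = min_fit_n)
    }
    data.frame(set = set_names[[k]], shape = fit$shape, rate = fit$rate,
               n_nonzero = fit$n, fit_ok = fit$fit_ok,
               reason = if (is.null(fit$reason)) NA_character_ else fit$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gamma-CDF scores and p-values from distances
#'
#' Converts a distance matrix to scores via the per-set fitted gamma CDF:
#' `S[i,k] = F_gamma(shape_k, rate_k)(M[i,k])`, and p-values `P = 1 - S`.
#' A distance of 0 maps to score 0 and p-value 1. Sets whose gamma fit
#' failed yield `NA` scores and p-values, never fabricated values.
#'
#' @param M Numeric n x m distance matrix.
#' @param null_fit Data.frame from [fit_gamma_null()] for the matching
#'   direction, rows aligned to the columns of `M`.
#' @return List with matrices `S` and `P` (both n x m).
#' @export
score_with_null <- function(M, null_fit) {
  if (nrow(null_fit) != ncol(M)) {
    stop("null_fit must have one row per set column of M")
  }
  S <- M
  for (k in seq_len(ncol(M))) {
    if (isTRUE(null_fit$fit_ok[[k]])) {
      S[, k] <- stats::pgamma(M[, k], shape = null_fit$shape[[k]],
                              rate = null_fit$rate[[k]])
    } else {
      S[, k] <- NA_real_
    }
  }
  list(S = S, P = 1 - S)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up BH adjustment over one family of p-values. `NA`
#' entries are excluded from the family and returned as `NA`.
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Vector of adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- q
  out
}

#' Tissue-adjusted single-sample gene set scores
#'
#' End-to-end scoring of a tumor expression matrix against a normal-tissue
#' reference. The pipeline: drop zero-variance genes; compute
#' tissue-specificity weights t* = t / t_bar; split per-sample deviations
#' from `t` into positive and negative parts; weight per-gene sample
#' variances by t* per direction; compute per-set diagonal Mahalanobis
#' distances M+, M- and M = M+ + M-; recompute all three on
#' column-permuted copies of the matrix; fit a gamma to the nonzero null
#' distances of every set and direction; score via the gamma CDF and
#' derive p-values and BH FDR values.
#'
#' @param X Numeric samples x genes matrix of linear-scale normalized
#'   expression with unique row/column names (or supply ids via
#'   [prepare_expression()] semantics).
#' @param t Named numeric vector: per-gene mean expression in the matched
#'   normal tissue. Aligned to `X` by name when named, by position
#'   otherwise.
#' @param t_bar Named numeric vector: per-gene cross-tissue average mean
#'   expression. Same alignment rules. If `NULL`, tissue weighting is
#'   neutral (t* = 1 for every gene).
#' @param collection Gene sets: a `gene_set_collection`, a named list of
#'   character vectors, or a GMT file path.
#' @param min_set_size Minimum surviving set size (default 5).
#' @param n_permutations Number of permuted null copies (default 1; the
#'   null distances of additional copies are pooled before gamma fitting).
#' @param clamp_lo,clamp_hi Clamp bounds for t* (defaults 1e-4, 1e4).
#' @param seed Integer seed for the permutation RNG; `NULL` leaves the RNG
#'   state untouched.
#' @return A `tpac_scores` object: list with score matrices `S`, `S_plus`,
#'   `S_minus`; p-value matrices `P`, `P_plus`, `P_minus`; FDR matrices
#'   `fdr`, `fdr_plus`, `fdr_minus` (per-run family); `gamma_null` (list of
#'   three fit tables); `set_index`; and `provenance` (dropped genes/sets,
#'   flagged genes, config, seed).
#' @export
tpac <- function(X, t, t_bar = NULL, collection,
                 min_set_size = 5L, n_permutations = 1L,
                 clamp_lo = 1e-4, clamp_hi = 1e4, seed = NULL) {
  X <- prepare_expression(X)
  dropped_genes <- attr(X, "dropped_genes")
  genes <- colnames(X)

  t <- align_reference(t, genes, "t")
  if (is.null(t_bar)) {
    t_star <- stats::setNames(rep(1, length(genes)), genes)
    attr(t_star, "no_tissue_info") <- rep(FALSE, length(genes))
  } else {
    t_bar <- align_reference(t_bar, genes, "t_bar")
    t_star <- tissue_specificity(t, t_bar, clamp_lo, clamp_hi)
  }

  if (is.character(collection) && length(collection) == 1L &&
      file.exists(collection)) {
    collection <- read_gmt(collection)
  }
  index <- build_set_index(collection, genes, min_set_size = min_set_size)

  dev <- split_deviations(X, t)
  vars <- weighted_variances(X, t_star)

  M_plus <- set_distances(dev$delta_plus, vars$var_plus, index)
  M_minus <- set_distances(dev$delta_minus, vars$var_minus, index)
  M <- total_distances(M_plus, M_minus)

  # Null: permuting each gene column preserves its marginal values, so the
  # per-gene variances (weighted or not) are unchanged on the permuted data.
  X_perm <- permute_columns(X, n_permutations = n_permutations,
                            rng_seed = seed)
  Mp_plus <- list()
  Mp_minus <- list()
  Mp_total <- list()
  for (b in seq_along(X_perm)) {
    dev_p <- split_deviations(X_perm[[b]], t)
    Mp_plus[[b]] <- set_distances(dev_p$delta_plus, vars$var_plus, index)
    Mp_minus[[b]] <- set_distances(dev_p$delta_minus, vars$var_minus, index)
    Mp_total[[b]] <- total_distances(Mp_plus[[b]], Mp_minus[[b]])
  }

  null_total <- fit_gamma_null(Mp_total)
  null_plus <- fit_gamma_null(Mp_plus)
  null_minus <- fit_gamma_null(Mp_minus)

  sc <- score_with_null(M, null_total)
  sc_plus <- score_with_null(M_plus, null_plus)
  sc_minus <- score_with_null(M_minus, null_minus)

  res <- structure(list(
    S = sc$S, S_plus = sc_plus$S, S_minus = sc_minus$S,
    P = sc$P, P_plus = sc_plus$P, P_minus = sc_minus$P,
    fdr = matrix_bh(sc$P), fdr_plus = matrix_bh(sc_plus$P),
    fdr_minus = matrix_bh(sc_minus$P),
    M = M, M_plus = M_plus, M_minus = M_minus,
    gamma_null = list(total = null_total, plus = null_plus,
                      minus = null_minus),
    set_index = index,
    provenance = list(
      n_samples = nrow(X), n_genes = length(genes),
      dropped_genes = dropped_genes,
      dropped_sets = attr(index, "dropped_sets"),
      no_tissue_info = names(t_star)[attr(t_star, "no_tissue_info")],
      config = list(min_set_size = as.integer(min_set_size),
                    n_permutations = as.integer(n_permutations),
                    clamp_lo = clamp_lo, clamp_hi = clamp_hi,
                    seed = if (is.null(seed)) NA_integer_ else
                      as.integer(seed)),
      fit_failures = sum(!null_total$fit_ok, !null_plus$fit_ok,
                         !null_minus$fit_ok)
    )
  ), class = "tpac_scores")
  res
}

# BH over the per-run family: all samples x all sets of one matrix.
matrix_bh <- function(P) {
  q <- bh_fdr(as.vector(P))
  matrix(q, nrow = nrow(P), dimnames = dimnames(P))
}

align_reference <- function(v, genes, what) {
  if (!is.null(names(v))) {
    missing <- setdiff(genes, names(v))
    if (length(missing)) {
      stop("Reference ", what, " lacks values for ", length(missing),
           " gene(s), e.g. ", paste(utils::head(missing, 3), collapse = ", "))
    }
    v <- v[genes]
  } else if (length(v) != length(genes)) {
    stop("Unnamed reference ", what, " must match the gene axis length (",
         length(genes), " after zero-variance removal); name it by gene ",
         "identifier to allow alignment")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("Reference ", what, " must be finite and nonnegative")
  }
  stats::setNames(as.numeric(v), genes)
}

#' @export
print.tpac_scores <- function(x, ...) {
  cat("Tissue-adjusted gene set scores\n")
  cat("  samples:", nrow(x$S), " sets:", ncol(x$S), "\n")
  cat("  permutations:", x$provenance$config$n_permutations,
      " seed:", x$provenance$config$seed, "\n")
  cat("  dropped genes:", length(x$provenance$dropped_genes),
      " dropped sets:", length(x$provenance$dropped_sets),
      " gamma fit failures:", x$provenance$fit_failures, "\n")
  invisible(x)
}
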