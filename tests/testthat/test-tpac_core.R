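test_that("prepare_expression removes exactly the zero-variance genes", {
  X <- rand_expression(50L, 200L, seed = 11L)
  set.seed(12)
  constant_cols <- sort(sample(200L, 17L))
  X[, constant_cols] <- rep(runif(17, 0, 5), each = 50L)

  # oracle: per-column variance computed directly
  zero_by_oracle <- colnames(X)[apply(X, 2L, var) == 0]
  out <- prepare_expression(X)
  expect_identical(attr(out, "dropped_genes"), zero_by_oracle)
  expect_identical(colnames(out), setdiff(colnames(X), zero_by_oracle))
  expect_length(zero_by_oracle, 17L)

  # identity on a matrix with no constant columns
  clean <- rand_expression(10L, 20L, seed = 13L)
  expect_equal(prepare_expression(clean), clean, ignore_attr = TRUE)
})

test_that("prepare_expression enforces its contract", {
  X <- rand_expression(5L, 4L)
  expect_error(prepare_expression(X[1L, , drop = FALSE]), "2 samples")
  expect_error(prepare_expression(matrix(1, 3, 3,
                                         dimnames = list(1:3, 1:3))),
               "zero variance")
  Xna <- X; Xna[2, 2] <- NA
  expect_error(prepare_expression(Xna), "finite")
  Xneg <- X; Xneg[1, 1] <- -1
  expect_error(prepare_expression(Xneg), "nonnegative")
})

test_that("tissue_specificity computes clamped fold-changes", {
  expect_equal(as.vector(tissue_specificity(c(2, 4), c(2, 2))), c(1, 2))

  # identity case: t == t_bar makes weighting a no-op
  t <- c(a = 1.5, b = 0.2, c = 7)
  ts <- tissue_specificity(t, t)
  expect_equal(unname(ts), rep(1, 3), ignore_attr = TRUE)
  expect_named(ts, names(t))

  # clamp boundaries
  ts <- tissue_specificity(c(5, 0.001), c(0.0005, 1), clamp_hi = 1e4)
  expect_equal(as.vector(ts), c(1e4, 0.001))

  # t_bar = 0 -> neutral weight, flagged
  ts <- tissue_specificity(c(3, 3), c(0, 1))
  expect_equal(as.vector(ts), c(1, 3))
  expect_identical(attr(ts, "no_tissue_info"), c(TRUE, FALSE))

  expect_error(tissue_specificity(1:3, 1:2), "length")
})

test_that("split_deviations decomposes exactly by sign", {
  X <- rand_expression(20L, 30L, seed = 21L)
  t <- colMeans(X) * runif(30L, 0.5, 1.5)
  dev <- split_deviations(X, t)

  expect_true(all(dev$delta_plus >= 0))
  expect_true(all(dev$delta_minus <= 0))
  # exact reconstruction and disjoint support
  expect_identical(dev$delta_plus + dev$delta_minus, sweep(X, 2L, t, "-"))
  expect_true(all(dev$delta_plus * dev$delta_minus == 0))

  # a row equal to t deviates nowhere
  Xeq <- rbind(X, t)
  dev2 <- split_deviations(Xeq, t)
  expect_equal(unname(dev2$delta_plus[nrow(Xeq), ]), rep(0, 30L))
  expect_equal(unname(dev2$delta_minus[nrow(Xeq), ]), rep(0, 30L))
})

test_that("weighted_variances follows the directionality table", {
  X <- rand_expression(15L, 10L, seed = 31L)
  v <- apply(X, 2L, var)

  # definition on a synthetic case: variance 4, t* = 2 -> (8, 2)
  ts <- rep(1, 10L); ts[3] <- 2
  wv <- weighted_variances(X, ts)
  expect_equal(wv$var_plus[3], v[3] * 2)
  expect_equal(wv$var_minus[3], v[3] / 2)

  # t* = 1 is the identity
  wv1 <- weighted_variances(X, rep(1, 10L))
  expect_equal(wv1$var_plus, v)
  expect_equal(wv1$var_minus, v)

  # product identity var_plus * var_minus = var^2 for random weights
  set.seed(32)
  tsr <- exp(rnorm(10L))
  wvr <- weighted_variances(X, tsr)
  expect_equal(wvr$var_plus * wvr$var_minus, v * v)

  expect_error(weighted_variances(X, c(tsr[-1], -1)), "positive")
})

test_that("set_distances matches the explicit Mahalanobis quadratic form", {
  # trivial case: one-gene set, deviation 2, variance 4 -> 1.0
  dev <- matrix(2, 1, 1, dimnames = list("s1", "g1"))
  idx <- structure(list(one = 1L), class = c("set_index", "list"))
  expect_equal(as.vector(set_distances(dev, 4, idx)), 1.0)

  # zero deviations -> zero distances
  devz <- matrix(0, 4, 6, dimnames = list(paste0("s", 1:4),
                                          paste0("g", 1:6)))
  idx2 <- structure(list(a = 1:3, b = c(2L, 5L)),
                    class = c("set_index", "list"))
  expect_true(all(set_distances(devz, rep(2, 6), idx2) == 0))

  # oracle: diag(D_k solve(Sigma_k) t(D_k)) with explicit inversion,
  # >= 100 random instances with g <= 10
  set.seed(41)
  for (rep_i in 1:100) {
    n <- sample(2:10, 1L)
    p <- sample(5:12, 1L)
    g <- sample(1:min(10L, p), 1L)
    dev <- matrix(rnorm(n * p), n, p)
    vars <- rgamma(p, 3, 1) + 0.1
    cols <- sample(p, g)
    idx <- structure(list(k = cols), class = c("set_index", "list"))
    M <- set_distances(dev, vars, idx)
    Dk <- dev[, cols, drop = FALSE]
    Sigma_k <- diag(vars[cols], nrow = g)
    oracle <- diag(Dk %*% solve(Sigma_k) %*% t(Dk))
    expect_equal(as.vector(M[, 1L]), oracle, tolerance = 1e-10)
  }
})

test_that("total_distances sums components and checks shapes", {
  A <- matrix(runif(12), 3, 4)
  B <- matrix(runif(12), 3, 4)
  expect_equal(total_distances(A, B), A + B)
  expect_equal(total_distances(A, B), total_distances(B, A))
  expect_equal(total_distances(A, 0 * B), A)
  expect_error(total_distances(A, t(B)), "dimensions")
})

test_that("permute_columns preserves marginals, is seeded, and shuffles columns independently", {
  X <- rand_expression(30L, 5L, seed = 51L)
  perms <- permute_columns(X, n_permutations = 3L, rng_seed = 7L)
  expect_length(perms, 3L)
  for (Xp in perms) {
    expect_identical(dim(Xp), dim(X))
    for (j in seq_len(ncol(X))) {
      expect_identical(sort(unname(Xp[, j])), sort(unname(X[, j])))
    }
  }
  # determinism
  again <- permute_columns(X, n_permutations = 3L, rng_seed = 7L)
  expect_identical(perms, again)

  # independence of the per-column permutations: 3 samples x 2 columns,
  # classify each column's permutation among the 6 possibilities and
  # chi-square test the 6x6 contingency table
  X2 <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 3,
               dimnames = list(paste0("s", 1:3), c("a", "b")))
  draws <- permute_columns(X2, n_permutations = 3000L, rng_seed = 99L)
  perm_id <- function(col, vals) {
    paste(match(col, vals), collapse = "")
  }
  ids <- t(vapply(draws, function(Xp) {
    c(perm_id(Xp[, 1], X2[, 1]), perm_id(Xp[, 2], X2[, 2]))
  }, character(2)))
  tab <- table(ids[, 1], ids[, 2])
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("fit_gamma_mle recovers parameters and honors its contract", {
  set.seed(61)
  x <- rgamma(1e5, shape = 2, rate = 3)
  fit <- fit_gamma_mle(x)
  expect_true(fit$fit_ok)
  expect_gt(fit$shape, 1.95); expect_lt(fit$shape, 2.05)
  expect_gt(fit$rate, 2.9); expect_lt(fit$rate, 3.1)

  # bias shrinks with sample size
  set.seed(62)
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    f <- fit_gamma_mle(rgamma(n, shape = 2, rate = 3))
    abs(f$shape - 2) + abs(f$rate - 3)
  }, numeric(1))
  expect_lt(errs[3], errs[1])

  # degenerate constant input -> fit_ok = FALSE, not an error
  const <- fit_gamma_mle(rep(2.5, 50))
  expect_false(const$fit_ok)
  expect_match(const$reason, "degenerate")

  # too few values
  few <- fit_gamma_mle(c(1, 2, 3))
  expect_false(few$fit_ok)

  # zeros are a contract violation: the caller must filter
  expect_error(fit_gamma_mle(c(0, 1, 2)), "strictly positive")
})

test_that("score_with_null applies the gamma CDF and propagates failures", {
  null_fit <- data.frame(set = c("k1", "k2"), shape = c(2, NA),
                         rate = c(3, NA), n_nonzero = c(100L, 0L),
                         fit_ok = c(TRUE, FALSE), reason = NA_character_)
  med <- qgamma(0.5, shape = 2, rate = 3)
  M <- matrix(c(0, med, 1, 1), nrow = 2,
              dimnames = list(c("s1", "s2"), c("k1", "k2")))
  sc <- score_with_null(M, null_fit)
  expect_equal(sc$S["s1", "k1"], 0)      # CDF at 0
  expect_equal(sc$P["s1", "k1"], 1)
  expect_equal(sc$S["s2", "k1"], 0.5)    # median -> 0.5
  expect_true(all(is.na(sc$S[, "k2"])))  # failed fit -> missing, not 0/1
  expect_true(all(is.na(sc$P[, "k2"])))

  # probability integral transform: draws from the fitted gamma give
  # uniform p-values
  set.seed(71)
  draws <- rgamma(5000, shape = 2, rate = 3)
  Mk <- matrix(draws, ncol = 1, dimnames = list(NULL, "k1"))
  sck <- score_with_null(Mk, null_fit[1, ])
  ks <- suppressWarnings(ks.test(sck$P[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_fdr reproduces the step-up procedure", {
  # textbook example
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # all equal p -> all FDR equal p; single p -> itself
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)

  # oracle: stats::p.adjust on random families, with NA passthrough
  set.seed(81)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1L))^sample(1:3, 1L)
    p[sample(length(p), size = floor(length(p) / 5))] <- NA
    got <- bh_fdr(p)
    want <- p.adjust(p, method = "BH")
    expect_equal(got, unname(want))
    ok <- !is.na(p)
    expect_true(all(got[ok] >= p[ok] & got[ok] <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
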