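#' Call per-sample gene set significance at an FDR threshold
#'
#' Recomputes BH FDR values over a declared family of the p-values in a
#' scoring result and calls an entry significant when its FDR is strictly
#' below `q`. Family policies: `"per-run"` adjusts all samples x sets
#' jointly (the default used for cohort-level displays); `"per-set"`
#' adjusts each set column across samples; `"per-sample"` adjusts each
#' sample row across sets.
#'
#' @param score_result A `tpac_scores` object.
#' @param q FDR threshold in (0, 1].
#' @param family One of "per-run", "per-set", "per-sample".
#' @param direction Which score to use: "total", "plus" or "minus".
#' @return A `significance_calls` list: logical `calls` matrix (`NA` where
#'   the score is missing), the recomputed `fdr` matrix, `q`, `family`,
#'   and per-set / per-sample significant counts.
#' @export
call_significant <- function(score_result, q = 0.25,
                             family = c("per-run", "per-set", "per-sample"),
                             direction = c("total", "plus", "minus")) {
  family <- match.arg(family)
  direction <- match.arg(direction)
  if (!(q > 0 && q <= 1)) stop("q must lie in (0, 1]")
  P <- switch(direction, total = score_result$P, plus = score_result$P_plus,
              minus = score_result$P_minus)
  fdr <- switch(family,
    "per-run" = matrix_bh(P),
    "per-set" = apply(P, 2L, bh_fdr),
    "per-sample" = t(apply(P, 1L, bh_fdr)))
  dimnames(fdr) <- dimnames(P)
  calls <- fdr < q
  structure(list(calls = calls, fdr = fdr, q = q, family = family,
                 direction = direction,
                 n_significant_per_set = colSums(calls, na.rm = TRUE),
                 n_significant_per_sample = rowSums(calls, na.rm = TRUE),
                 fraction_significant = mean(calls, na.rm = TRUE)),
            class = "significance_calls")
}

#' @export
print.significance_calls <- function(x, ...) {
  cat("Significance calls at FDR <", x$q, "(", x$family, "family,",
      x$direction, "scores )\n")
  cat("  significant:", sum(x$calls, na.rm = TRUE), "of",
      sum(!is.na(x$calls)),
      sprintf("(%.1f%%)\n", 100 * x$fraction_significant))
  invisible(x)
}

#' Zero out non-significant scores for display
#'
#' Returns the score matrix with every entry whose FDR value is >= `q`
#' replaced by 0, the masking used for significance-filtered heatmaps.
#' Missing scores stay missing.
#'
#' @inheritParams call_significant
#' @return Masked numeric score matrix.
#' @export
threshold_scores_for_display <- function(score_result, q = 0.3,
                                         family = c("per-run", "per-set",
                                                    "per-sample"),
                                         direction = c("total", "plus",
                                                       "minus")) {
  family <- match.arg(family)
  direction <- match.arg(direction)
  calls <- call_significant(score_result, q = q, family = family,
                            direction = direction)
  S <- switch(direction, total = score_result$S, plus = score_result$S_plus,
              minus = score_result$S_minus)
  masked <- S
  masked[!is.na(calls$calls) & !calls$calls] <- 0
  masked
}

#' Export scores in tidy long format
#'
#' One row per (sample, set, direction) with score, p-value, FDR and the
#' significance call at `q` — the shape survival or stage models expect
#' as input.
#'
#' @param score_result A `tpac_scores` object.
#' @param q FDR threshold used for the `significant` column.
#' @param family FDR family policy, see [call_significant()].
#' @return A data.frame with columns sample_id, set_name, direction,
#'   score, p, fdr, significant.
#' @export
scores_long <- function(score_result, q = 0.25, family = "per-run") {
  one <- function(direction) {
    calls <- call_significant(score_result, q = q, family = family,
                              direction = direction)
    S <- switch(direction, total = score_result$S,
                plus = score_result$S_plus, minus = score_result$S_minus)
    P <- switch(direction, total = score_result$P,
                plus = score_result$P_plus, minus = score_result$P_minus)
    data.frame(
      sample_id = rep(rownames(S), times = ncol(S)),
      set_name = rep(colnames(S), each = nrow(S)),
      direction = direction,
      score = as.vector(S), p = as.vector(P), fdr = as.vector(calls$fdr),
      significant = as.vector(calls$calls),
      stringsAsFactors = FALSE)
  }
  out <- rbind(one("total"), one("plus"), one("minus"))
  rownames(out) <- NULL
  out
}
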