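#' Benjamini-Hochberg step-up correction
#'
#' Standard step-up control of the false discovery rate: with the
#' p-values sorted ascending, the largest rank `k` with
#' `p(k) <= (k/m) * fdr` is found and hypotheses `1..k` are rejected.
#' The returned q-values are the usual monotone BH-adjusted p-values
#' (computed with [stats::p.adjust()]), and rejecting `{q <= fdr}`
#' coincides with the step-up rejection set; identical p-values always
#' receive identical decisions.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param fdr Target false discovery rate in (0, 1); default 0.01.
#' @return A list with `reject` (logical, aligned with the input order)
#'   and `q_values`.
#' @examples
#' benjamini_hochberg(c(0.001, 0.008, 0.039, 0.041), fdr = 0.05)$reject
#' @export
benjamini_hochberg <- function(p_values, fdr = 0.01) {
  check_pvalues(p_values)
  stopifnot(fdr > 0, fdr < 1)
  q <- stats::p.adjust(p_values, method = "BH")
  list(reject = q <= fdr, q_values = q)
}

#' Bonferroni correction
#'
#' Rejects a hypothesis iff `p < alpha / m`, with `m` the number of
#' tests. The inequality is strict (a p-value exactly at the threshold
#' is not rejected); the BH comparison in [benjamini_hochberg()] uses
#' `<=`. Bonferroni rejections are always a subset of the BH rejections
#' at `fdr = alpha`.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param alpha Family-wise error level in (0, 1); default 0.01.
#' @return A list with `reject` (logical) and `p_adjusted`
#'   (`min(p * m, 1)`).
#' @export
bonferroni <- function(p_values, alpha = 0.01) {
  check_pvalues(p_values)
  stopifnot(alpha > 0, alpha < 1)
  m <- length(p_values)
  list(reject = p_values < alpha / m,
       p_adjusted = pmin(p_values * m, 1))
}

check_pvalues <- function(p) {
  if (length(p) == 0L) return(invisible(TRUE))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  invisible(TRUE)
}

#' Correct an exome's tests and partition the significant genes
#'
#' Applies the chosen multiple-testing correction over the tested genes
#' of a result table — the family is the whole exome in one list, never
#' split by direction first — and fills the `q_value` and `significant`
#' columns. Untested genes do not count towards the family size `m` and
#' are never significant; neither are genes whose direction is `none`
#' (observed exactly equal to expected). Significant genes partition
#' into the enriched and depleted lists by the sign of `O - E`.
#'
#' @param results Result tibble from [test_exome()].
#' @param method `"bh"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @param fdr False discovery rate for BH (default 0.01).
#' @param alpha Family-wise error level for Bonferroni (default 0.01).
#' @return The result tibble with `q_value` and `significant` filled
#'   (for Bonferroni, `q_value` holds the Bonferroni-adjusted p-value),
#'   and the correction settings in `attr(, "correction")`.
#' @seealso [enriched_genes()], [depleted_genes()]
#' @export
partition_significant <- function(results, method = c("bh", "bonferroni"),
                                  fdr = 0.01, alpha = 0.01) {
  method <- match.arg(method)
  tested <- results$tested
  p <- results$p_value[tested]
  adj <- if (method == "bh") {
    b <- benjamini_hochberg(p, fdr = fdr)
    list(q = b$q_values, reject = b$reject)
  } else {
    b <- bonferroni(p, alpha = alpha)
    list(q = b$p_adjusted, reject = b$reject)
  }
  results$q_value <- NA_real_
  results$q_value[tested] <- adj$q
  results$significant <- FALSE
  results$significant[tested] <- adj$reject
  results$significant[results$direction == "none"] <- FALSE
  attr(results, "correction") <- list(
    method = method,
    level = if (method == "bh") fdr else alpha,
    m = sum(tested))
  results
}

#' Significant gene lists
#'
#' Extract the genes called significantly enriched (or depleted) for the
#' target codons from a corrected result table, ordered by ascending
#' p-value (ties broken by gene id).
#'
#' @param results A tibble from [partition_significant()].
#' @return A tibble of the matching result rows.
#' @export
enriched_genes <- function(results) significant_slice(results, "enriched")

#' @rdname enriched_genes
#' @export
depleted_genes <- function(results) significant_slice(results, "depleted")

significant_slice <- function(results, dir) {
  if (all(is.na(results$significant))) {
    abort("results are uncorrected; run partition_significant() first")
  }
  results %>%
    dplyr::filter(.data$significant, .data$direction == dir) %>%
    dplyr::arrange(.data$p_value, .data$gene_id)
}
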