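#' Chi-square comparison of observed versus expected target-codon counts
#'
#' The per-gene test fills a 2x2 table whose rows are the protein length
#' and the target-codon count and whose columns are Observed and
#' Expected:
#'
#' \preformatted{
#'                     Observed   Expected
#'   protein length       L          L
#'   target codons        O          E
#' }
#'
#' and applies the Pearson chi-square test of homogeneity between the two
#' columns (df = 1), with expected cells taken from the row and column
#' marginals. `E` enters as a real number; rounding it to an integer
#' would discard information and the formula does not require integer
#' cells. No continuity correction is applied by default; set
#' `yates = TRUE` for the Yates-corrected statistic, which is never
#' larger than the uncorrected one. When `O = E` the statistic is 0 and
#' the p-value 1.
#'
#' Genes with `E = 0` (no amino acid covered by the codon set, hence
#' `O = 0` as well) have an undefined test and are flagged untested
#' rather than dropped.
#'
#' @param length_codons Protein length(s) `L` in sense codons (>= 1).
#' @param observed Observed target-codon count(s) `O`.
#' @param expected Expected count(s) `E` from [expected_count()].
#' @param yates Apply the Yates continuity correction? Default `FALSE`.
#' @return A tibble with columns `statistic`, `p_value` and `tested`;
#'   untested rows carry `NA` statistics.
#' @examples
#' chi_square_test(100, 30, 20)  # statistic 1.60256, p 0.2056
#' @export
chi_square_test <- function(length_codons, observed, expected, yates = FALSE) {
  L <- as.numeric(length_codons)
  O <- as.numeric(observed)
  E <- as.numeric(expected)
  n <- max(length(L), length(O), length(E))
  L <- rep_len(L, n); O <- rep_len(O, n); E <- rep_len(E, n)
  if (any(L < 1)) abort("length_codons must be >= 1")
  if (any(O < 0) || any(E < 0)) abort("counts must be non-negative")

  tested <- E > 0 & (O + E) > 0
  stat <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  if (any(tested)) {
    Lt <- L[tested]; Ot <- O[tested]; Et <- E[tested]
    grand <- 2 * Lt + Ot + Et
    r1 <- 2 * Lt; r2 <- Ot + Et
    c1 <- Lt + Ot; c2 <- Lt + Et
    obs <- cbind(Lt, Lt, Ot, Et)
    exp_cells <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / grand
    dev <- abs(obs - exp_cells)
    if (yates) dev <- pmax(dev - 0.5, 0)
    stat[tested] <- rowSums(dev^2 / exp_cells)
    p[tested] <- stats::pchisq(stat[tested], df = 1L, lower.tail = FALSE)
  }
  tibble::tibble(statistic = stat, p_value = p, tested = tested)
}

#' Test every gene of an exome for target-codon enrichment or depletion
#'
#' Computes each gene's expected target-codon count under the background
#' model and compares it with the observed count via
#' [chi_square_test()]. One result row is produced per gene; genes whose
#' test is undefined (`E = 0`) are flagged `tested = FALSE`, never
#' silently dropped. The `direction` is `enriched` when `O > E`,
#' `depleted` when `O < E`, and `none` when `O = E` or the gene is
#' untested. `frequency` is the gene's target-codon frequency `O / L`
#' over all sense codons.
#'
#' The background model must have been built from the same gene set
#' (enforced through the exome digest); mixing provenances is an error.
#' Multiple-testing correction is applied afterwards with
#' [partition_significant()], which fills `q_value` and `significant`.
#'
#' @param counts An `exome_counts` object from [count_exome()].
#' @param background A `background_model` built on `counts` by
#'   [build_background()].
#' @inheritParams chi_square_test
#' @return A tibble with one row per gene: `gene_id`, `length_codons`,
#'   `observed`, `expected`, `frequency`, `chi2`, `p_value`, `q_value`
#'   (`NA` until corrected), `direction`, `significant` (`NA` until
#'   corrected), `tested`.
#' @export
test_exome <- function(counts, background, yates = FALSE) {
  stopifnot(inherits(counts, "exome_counts"),
            inherits(background, "background_model"))
  if (!identical(attr(background, "exome_hash"), counts$hash)) {
    abort("background model was built from a different gene set than `counts`")
  }
  genes <- counts$genes
  if (any(genes$length_codons < 1L)) {
    abort(paste0("gene with no sense codons: ",
                 paste(genes$gene_id[genes$length_codons < 1L], collapse = ", ")))
  }
  E <- expected_count(counts, background)$expected
  ct <- chi_square_test(genes$length_codons, genes$observed, E, yates = yates)
  direction <- dplyr::case_when(
    !ct$tested ~ "none",
    genes$observed > E ~ "enriched",
    genes$observed < E ~ "depleted",
    TRUE ~ "none"
  )
  tibble::tibble(
    gene_id = genes$gene_id,
    length_codons = genes$length_codons,
    observed = genes$observed,
    expected = E,
    frequency = genes$observed / genes$length_codons,
    chi2 = ct$statistic,
    p_value = ct$p_value,
    q_value = NA_real_,
    direction = direction,
    significant = NA,
    tested = ct$tested
  )
}
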