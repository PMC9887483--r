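#' Build the exome-wide background model of target-codon usage
#'
#' For every amino acid `a` encoded by at least one codon in the codon
#' set, the model records how often that amino acid is encoded by a
#' target codon anywhere in the exome: `N_aa` codons encode `a` in total,
#' `T_aa` of them are target codons, and the background frequency is
#' `f_aa = T_aa / N_aa`. Frequencies are kept at full precision. The
#' model carries the digest of the gene set it was built from, so that
#' [test_exome()] refuses to mix a model with a different gene set.
#'
#' The model should be built on exactly the post-QC, deduplicated gene
#' set that will be tested; self-consistency then guarantees that the
#' expected counts over the exome sum to the observed counts.
#'
#' @param counts An `exome_counts` object from [count_exome()].
#' @return A tibble of class `background_model` with columns
#'   `amino_acid`, `exome_total_codons` (`N_aa`), `exome_target_codons`
#'   (`T_aa`) and `background_frequency` (`f_aa`), plus attributes
#'   `codon_set_name`, `exome_hash` and `n_genes`.
#' @examples
#' exome <- tibble::tibble(
#'   gene_id = c("a", "b"),
#'   sequence = c("ATGATCATC", "ATGATT"))
#' counts <- count_exome(exome, codon_set("ATC", name = "ile-only"))
#' build_background(counts)  # f_I = 2/3
#' @export
build_background <- function(counts) {
  stopifnot(inherits(counts, "exome_counts"))
  relevant <- colnames(counts$aa_targets)
  n_aa <- colSums(counts$aa_totals)[relevant]
  t_aa <- colSums(counts$aa_targets)
  if (any(n_aa == 0)) {
    abort(paste0("background frequency undefined: amino acid(s) absent from exome: ",
                 paste(relevant[n_aa == 0], collapse = ", ")))
  }
  out <- tibble::tibble(
    amino_acid = relevant,
    exome_total_codons = as.integer(n_aa),
    exome_target_codons = as.integer(t_aa),
    background_frequency = unname(t_aa / n_aa)
  )
  structure(out,
            codon_set_name = attr(counts$codon_set, "name"),
            exome_hash = counts$hash,
            n_genes = nrow(counts$genes),
            class = c("background_model", class(out)))
}

#' Expected target-codon count under the background model
#'
#' A gene's expectation is determined by its amino-acid composition: each
#' relevant amino-acid count `n_aa` is multiplied by the exome-wide
#' background frequency `f_aa` and the products are summed,
#' `E = sum_a n_aa * f_aa`. `E` is zero exactly when the gene contains no
#' amino acid covered by the codon set.
#'
#' @param counts An `exome_counts` object ([count_exome()]) or a single
#'   `gene_codon_counts` ([count_codons()]).
#' @param background A `background_model` from [build_background()].
#' @return For an exome: a tibble `gene_id`, `expected`. For a single
#'   gene: the scalar expectation.
#' @export
expected_count <- function(counts, background) {
  UseMethod("expected_count")
}

#' @export
expected_count.exome_counts <- function(counts, background) {
  f <- background_vector(background, colnames(counts$aa_targets))
  n_mat <- counts$aa_totals[, names(f), drop = FALSE]
  tibble::tibble(gene_id = counts$genes$gene_id,
                 expected = as.vector(n_mat %*% f))
}

#' @export
expected_count.gene_codon_counts <- function(counts, background) {
  relevant <- names(counts$target_by_aa)
  f <- background_vector(background, relevant)
  n_aa <- counts$total_by_aa[relevant]
  n_aa[is.na(n_aa)] <- 0
  sum(n_aa * f)
}

background_vector <- function(background, relevant) {
  stopifnot(inherits(background, "background_model"))
  missing <- setdiff(relevant, background$amino_acid)
  if (length(missing) > 0L) {
    abort(paste0("background model does not cover amino acid(s): ",
                 paste(missing, collapse = ", ")))
  }
  stats::setNames(background$background_frequency, background$amino_acid)[relevant]
}
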