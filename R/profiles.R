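#' Gene-body (metagene) profile of target-codon frequency
#'
#' Maps every gene onto `bins` equal-width relative-position bins — the
#' sense codon at 0-based index `i` of a gene with `L` codons falls in
#' bin `floor(i * bins / L)` — and averages, within each significance
#' category, the per-gene per-bin target-codon frequency. Per-bin
#' frequencies use all sense codons in the bin as denominator,
#' consistent with the per-gene frequency `O / L`; category means are
#' unweighted across genes, so long genes do not dominate. Genes are
#' grouped as `enriched`, `depleted` or `nonsignificant` (untested genes
#' fall in `nonsignificant`).
#'
#' @param exome Data frame with `gene_id` and `sequence` columns — the
#'   same gene set the results were computed from.
#' @param results Corrected result tibble from [partition_significant()].
#' @param codon_set The [codon_set()] that was tested.
#' @param bins Number of relative-position bins, >= 2; default 20.
#' @param code Genetic code, as returned by [genetic_code()].
#' @return A tibble of class `profile_table` with columns `category`,
#'   `bin_index` (0-based), `mean_frequency` (`NA` when no gene
#'   contributes) and `n_genes`.
#' @seealso [autoplot.profile_table()]
#' @export
gene_body_profile <- function(exome, results, codon_set, bins = 20L,
                              code = genetic_code()) {
  stopifnot(bins >= 2L)
  if (all(is.na(results$significant))) {
    abort("results are uncorrected; run partition_significant() first")
  }
  bins <- as.integer(bins)

  categories <- tibble::tibble(
    gene_id = results$gene_id,
    category = dplyr::case_when(
      results$significant & results$direction == "enriched" ~ "enriched",
      results$significant & results$direction == "depleted" ~ "depleted",
      TRUE ~ "nonsignificant"
    )
  )

  exome <- dplyr::semi_join(exome, categories, by = "gene_id")
  seqs <- strip_trailing_stop(frame_triplets(exome$sequence), code)
  sense <- names(code)[code != "*"]

  codon_list <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 3L) return(character())
    starts <- seq.int(1L, n - 2L, by = 3L)
    cods <- substring(s, starts, starts + 2L)
    cods[cods %in% sense]
  })
  lens <- lengths(codon_list)
  keep <- lens >= 1L
  codon_list <- codon_list[keep]
  lens <- lens[keep]
  ids <- exome$gene_id[keep]

  per_codon <- tibble::tibble(
    gene_id = rep(ids, lens),
    target = unlist(codon_list, use.names = FALSE) %in% codon_set$codon,
    bin_index = ((sequence(lens) - 1L) * bins) %/% rep(lens, lens)
  )

  per_gene_bin <- per_codon %>%
    dplyr::group_by(.data$gene_id, .data$bin_index) %>%
    dplyr::summarise(freq = mean(.data$target), .groups = "drop") %>%
    dplyr::left_join(categories, by = "gene_id")

  out <- per_gene_bin %>%
    dplyr::group_by(.data$category, .data$bin_index) %>%
    dplyr::summarise(mean_frequency = mean(.data$freq),
                     n_genes = dplyr::n_distinct(.data$gene_id),
                     .groups = "drop") %>%
    tidyr::complete(
      category = c("enriched", "depleted", "nonsignificant"),
      bin_index = seq_len(bins) - 1L,
      fill = list(mean_frequency = NA_real_, n_genes = 0L)) %>%
    dplyr::arrange(.data$category, .data$bin_index)

  structure(out, bins = bins, class = c("profile_table", class(out)))
}

#' Plot a gene-body profile
#'
#' Line plot of mean target-codon frequency across relative gene-body
#' position, one line per significance category.
#'
#' @param object A `profile_table` from [gene_body_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_table <- function(object, ...) {
  bins <- attr(object, "bins")
  df <- dplyr::filter(object, !is.na(.data$mean_frequency))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$bin_index + 0.5) / bins,
    y = .data$mean_frequency,
    colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "relative position in gene body",
                  y = "mean target-codon frequency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of per-gene target-codon frequencies
#'
#' Histogram of the per-gene frequency `O / L` across the exome.
#'
#' @param results Result tibble from [test_exome()] or
#'   [partition_significant()].
#' @param binwidth Histogram bin width; default 0.005.
#' @return A ggplot object.
#' @export
plot_codon_frequencies <- function(results, binwidth = 0.005) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "target-codon frequency (O / L)", y = "genes") +
    ggplot2::theme_minimal()
}
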