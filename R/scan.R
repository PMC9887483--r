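#' Scan an exome for codon-set enrichment and depletion
#'
#' The full pipeline: tally codons per gene, build the exome-wide
#' per-amino-acid background model, test every gene's observed
#' target-codon count against its expectation with the 2x2 chi-square
#' construction, correct across the exome, and compute the gene-body
#' profile. All downstream tables are available through [tidy()],
#' [glance()] and the object's elements.
#'
#' @param exome A tibble with `gene_id` and `sequence` columns (from
#'   [read_exome()] or [generate_exome()]), or a path to a CDS FASTA
#'   file.
#' @param codon_set A [codon_set()], a preset name (`"human-adat"`,
#'   `"yeast-adat"`), a codon-set file path, or a comma-separated codon
#'   string.
#' @param dialect FASTA header dialect, used only when `exome` is a
#'   path; see [read_exome()].
#' @param correction,fdr,alpha Multiple-testing settings; see
#'   [partition_significant()].
#' @param bins Gene-body profile bins; see [gene_body_profile()].
#' @param yates Continuity correction; see [chi_square_test()].
#' @param top_n Number of smallest-p enriched genes exported for GO
#'   analysis by [write_scan_results()]; default 500.
#' @return An object of class `codon_scan`: a list with elements
#'   `results` (corrected per-gene tibble), `background`
#'   (`background_model`), `profile` (`profile_table`), `qc`
#'   (per-record QC report, empty unless read from a file), `codon_set`
#'   and `config`.
#' @examples
#' sim <- generate_exome(synthetic_spec(n_genes = 40, gene_length = 120, seed = 7))
#' scan <- scan_exome(sim$exome, "human-adat", fdr = 0.05)
#' glance(scan)
#' @export
scan_exome <- function(exome, codon_set,
                       dialect = "generic",
                       correction = c("bh", "bonferroni"),
                       fdr = 0.01, alpha = 0.01,
                       bins = 20L, yates = FALSE, top_n = 500L) {
  correction <- match.arg(correction)
  codon_set <- resolve_codon_set(codon_set)
  source_path <- NULL
  if (is.character(exome)) {
    source_path <- exome
    exome <- read_exome(exome, dialect = dialect)
  }
  qc <- qc_report(exome)

  counts <- count_exome(exome, codon_set)
  background <- build_background(counts)
  results <- test_exome(counts, background, yates = yates)
  results <- partition_significant(results, method = correction,
                                   fdr = fdr, alpha = alpha)
  profile <- gene_body_profile(exome, results, codon_set, bins = bins)

  config <- list(
    fasta = source_path, dialect = dialect,
    codon_set = attr(codon_set, "name"), codons = codon_set$codon,
    correction = correction, fdr = fdr, alpha = alpha,
    bins = as.integer(bins), yates = yates, top_n = as.integer(top_n)
  )
  structure(list(results = results, background = background,
                 profile = profile, qc = qc,
                 codon_set = codon_set, config = config),
            class = "codon_scan")
}

#' @export
print.codon_scan <- function(x, ...) {
  g <- glance(x)
  level <- if (x$config$correction == "bh") x$config$fdr else x$config$alpha
  cat("<codon_scan> codon set:", x$config$codon_set,
      "| correction:", x$config$correction, "at", level, "\n")
  cat("  genes:", g$n_genes, "(", g$n_tested, "tested )",
      "| enriched:", g$n_enriched, "| depleted:", g$n_depleted, "\n")
  invisible(x)
}

#' @describeIn scan_exome `tidy()` returns the per-gene result tibble.
#' @param x A `codon_scan` object.
#' @param ... Unused.
#' @export
tidy.codon_scan <- function(x, ...) x$results

#' @describeIn scan_exome `glance()` returns a one-row summary.
#' @export
glance.codon_scan <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_genes = nrow(r),
    n_tested = sum(r$tested),
    n_enriched = sum(r$significant & r$direction == "enriched"),
    n_depleted = sum(r$significant & r$direction == "depleted"),
    correction = x$config$correction,
    level = if (x$config$correction == "bh") x$config$fdr else x$config$alpha,
    codon_set = x$config$codon_set
  )
}

# -- output writing ----------------------------------------------------------

fmt_g <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
}
fmt_e <- function(x, underflow = rep(FALSE, length(x))) {
  out <- ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "e"))
  out[!is.na(x) & underflow] <- "0.0"
  out
}

#' Write the full output file set of a scan
#'
#' Writes, under `out_dir`: `background_model.tsv`, `results.tsv`
#' (sorted by gene id), `enriched_genes.txt` / `depleted_genes.txt`
#' (one id per line), `go_export_top500.txt` (the `top_n` enriched
#' genes with the smallest p-values, for GO-term analysis; the file
#' name tracks `top_n`), `profile.tsv`, `qc_report.tsv` and
#' `run_config.json`. All tables are TSV with one header line; floats
#' carry 6 significant digits and p-values are in scientific notation.
#' A p-value that underflowed to zero is written as `0.0` with the
#' `p_underflow` flag set rather than clipped silently. Output is
#' deterministic given the scan object.
#'
#' @param scan A `codon_scan` from [scan_exome()].
#' @param out_dir Output directory, created if needed; must be
#'   writable (checked before any file is written).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_scan_results <- function(scan, out_dir) {
  stopifnot(inherits(scan, "codon_scan"))
  if (nrow(scan$results) == 0L) abort("no results to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2L) != 0L) {
    abort(paste0("output directory not writable: ", out_dir))
  }

  r <- dplyr::arrange(scan$results, .data$gene_id)
  p_under <- !is.na(r$p_value) & r$p_value == 0
  q_under <- !is.na(r$q_value) & r$q_value == 0
  results_tbl <- tibble::tibble(
    gene_id = r$gene_id,
    length_codons = r$length_codons,
    observed = r$observed,
    expected = fmt_g(r$expected),
    frequency = fmt_g(r$frequency),
    chi2 = fmt_g(r$chi2),
    p_value = fmt_e(r$p_value, p_under),
    q_value = fmt_e(r$q_value, q_under),
    direction = r$direction,
    significant = as.integer(r$significant),
    tested = as.integer(r$tested),
    p_underflow = as.integer(p_under | q_under)
  )

  bg <- scan$background
  bg_tbl <- tibble::tibble(
    amino_acid = bg$amino_acid,
    exome_total_codons = bg$exome_total_codons,
    exome_target_codons = bg$exome_target_codons,
    background_frequency = fmt_g(bg$background_frequency)
  )

  prof <- scan$profile
  prof_tbl <- tibble::tibble(
    category = prof$category,
    bin_index = prof$bin_index,
    mean_frequency = fmt_g(prof$mean_frequency),
    n_genes = prof$n_genes
  )

  enr <- enriched_genes(r)
  dep <- depleted_genes(r)
  top_n <- scan$config$top_n
  go_ids <- utils::head(enr$gene_id, top_n)

  paths <- c(
    background_model = file.path(out_dir, "background_model.tsv"),
    results = file.path(out_dir, "results.tsv"),
    profile = file.path(out_dir, "profile.tsv"),
    qc_report = file.path(out_dir, "qc_report.tsv"),
    enriched = file.path(out_dir, "enriched_genes.txt"),
    depleted = file.path(out_dir, "depleted_genes.txt"),
    go_export = file.path(out_dir, sprintf("go_export_top%d.txt", top_n)),
    run_config = file.path(out_dir, "run_config.json")
  )
  readr::write_tsv(bg_tbl, paths[["background_model"]])
  readr::write_tsv(results_tbl, paths[["results"]])
  readr::write_tsv(prof_tbl, paths[["profile"]])
  readr::write_tsv(scan$qc, paths[["qc_report"]], na = "")
  writeLines(sort(enr$gene_id), paths[["enriched"]])
  writeLines(sort(dep$gene_id), paths[["depleted"]])
  writeLines(go_ids, paths[["go_export"]])
  jsonlite::write_json(scan$config, paths[["run_config"]],
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(paths)
}

#' Run a scan from a configuration and write every output
#'
#' Thin wrapper used by the command-line entry point: reads the FASTA,
#' resolves the codon set, runs [scan_exome()] and writes the output
#' file set plus the serialized configuration with
#' [write_scan_results()]. Identical inputs produce identical outputs.
#'
#' @inheritParams scan_exome
#' @param fasta Path to the CDS FASTA file.
#' @param out_dir Output directory.
#' @return The `codon_scan` object, invisibly.
#' @export
run_scan <- function(fasta, codon_set, out_dir,
                     dialect = "generic",
                     correction = c("bh", "bonferroni"),
                     fdr = 0.01, alpha = 0.01,
                     bins = 20L, yates = FALSE, top_n = 500L) {
  scan <- scan_exome(fasta, codon_set, dialect = dialect,
                     correction = correction, fdr = fdr, alpha = alpha,
                     bins = bins, yates = yates, top_n = top_n)
  write_scan_results(scan, out_dir)
  invisible(scan)
}
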