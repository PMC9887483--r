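# Synthetic exomes with known ground truth. Genes are drawn codon by
# codon: an amino acid from the composition, then — for amino acids the
# codon set covers — a target vs non-target synonymous codon with the
# null probability g_aa (uniform within each group). "Spiked" genes have
# the target odds g/(1-g) multiplied by a single effect parameter, so
# effect > 1 simulates enrichment and effect < 1 depletion. Stop codons
# are never drawn; each gene gets an ATG start and a TAA trailing stop,
# so generator output always passes read_exome() QC.

#' Specify a synthetic exome
#'
#' Collects and validates the parameters of the synthetic-exome
#' generator. Defaults describe a featureless null exome: uniform
#' amino-acid composition over the 20 standard residues, target
#' frequency 0.5 for every amino acid the codon set covers, 1000 genes
#' of 300 codons, no spiked genes.
#'
#' @param n_genes Number of genes.
#' @param gene_length Codons per gene (excluding start and stop): a
#'   single length or a `c(min, max)` range sampled uniformly.
#' @param codon_set The [codon_set()] targets are drawn from; default
#'   the human ADAT-dependent set.
#' @param amino_acid_composition Named probability vector over amino
#'   acids; default uniform over the 20 standard residues. Need not be
#'   normalised.
#' @param target_frequency Null probability `g_aa` that a relevant amino
#'   acid is encoded by a target codon: a single value or a named vector
#'   over the codon set's amino acids. Must leave room for non-target
#'   synonymous codons (`g < 1`).
#' @param spike_fraction Fraction of genes whose target odds are
#'   perturbed; default 0.
#' @param spike_effect Multiplier applied to the target odds
#'   `g/(1-g)` in spiked genes; 1 leaves them null.
#' @param seed Mandatory integer seed; generation is fully reproducible
#'   and leaves the global RNG untouched.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1000L,
                           gene_length = 300L,
                           codon_set = codon_set_preset("human-adat"),
                           amino_acid_composition = NULL,
                           target_frequency = 0.5,
                           spike_fraction = 0,
                           spike_effect = 1,
                           seed) {
  if (missing(seed)) abort("`seed` is mandatory for a synthetic_spec")
  stopifnot(n_genes >= 1L, length(gene_length) %in% c(1L, 2L),
            all(gene_length >= 1L),
            spike_fraction >= 0, spike_fraction <= 1, spike_effect > 0)
  code <- genetic_code()
  aa_all <- sort(unique(code[code != "*"]))
  if (is.null(amino_acid_composition)) {
    amino_acid_composition <- stats::setNames(rep(1, length(aa_all)), aa_all)
  }
  comp <- amino_acid_composition
  if (is.null(names(comp)) || !all(names(comp) %in% aa_all) || any(comp < 0) ||
      sum(comp) <= 0) {
    abort("amino_acid_composition must be a non-negative named vector over amino acids")
  }
  comp <- comp / sum(comp)

  relevant <- sort(unique(codon_set$amino_acid))
  g <- target_frequency
  if (length(g) == 1L && is.null(names(g))) {
    g <- stats::setNames(rep(g, length(relevant)), relevant)
  }
  extra <- setdiff(names(g), relevant)
  if (length(extra) > 0L) {
    abort(paste0("target_frequency names amino acid(s) with no target codon in the set: ",
                 paste(extra, collapse = ", ")))
  }
  if (!setequal(names(g), relevant)) {
    abort("target_frequency must cover every amino acid of the codon set")
  }
  if (any(g <= 0) || any(g >= 1)) {
    abort("target_frequency must lie strictly in (0, 1)")
  }
  for (a in relevant) {
    syn <- names(code)[code == a]
    if (length(setdiff(syn, codon_set$codon)) == 0L) {
      abort(paste0("amino acid ", a, " has no non-target synonymous codon"))
    }
  }

  structure(list(
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    codon_set = codon_set,
    amino_acid_composition = comp,
    target_frequency = g[relevant],
    spike_fraction = spike_fraction,
    spike_effect = spike_effect,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic exome with known ground truth
#'
#' Draws an in-frame CDS exome according to a [synthetic_spec()] and
#' returns both the exome table and a truth table recording which genes
#' were spiked. The same spec (same seed) always yields byte-identical
#' sequences.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_exome` with elements `exome`
#'   (tibble `gene_id`, `raw_header`, `sequence`), `truth` (tibble
#'   `gene_id`, `spiked`, `spike_effect`) and `spec`.
#' @examples
#' sim <- generate_exome(synthetic_spec(n_genes = 5, gene_length = 30, seed = 1))
#' sim$truth
#' @export
generate_exome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code()
  cs <- spec$codon_set
  relevant <- names(spec$target_frequency)

  withr::with_seed(spec$seed, {
    n <- spec$n_genes
    lens <- if (length(spec$gene_length) == 1L) {
      rep(spec$gene_length, n)
    } else {
      sample(spec$gene_length[1L]:spec$gene_length[2L], n, replace = TRUE)
    }
    spiked <- rep(FALSE, n)
    n_spiked <- round(spec$spike_fraction * n)
    if (n_spiked > 0L) spiked[sample.int(n, n_spiked)] <- TRUE

    total <- sum(lens)
    aa_names <- names(spec$amino_acid_composition)
    aa_vec <- sample(aa_names, total, replace = TRUE,
                     prob = spec$amino_acid_composition)
    gene_of <- rep(seq_len(n), lens)
    spiked_row <- spiked[gene_of]

    codon <- character(total)
    for (a in unique(aa_vec)) {
      syn <- sort(names(code)[code == a])
      tgt <- intersect(syn, cs$codon)
      nt <- setdiff(syn, tgt)
      for (sp in c(FALSE, TRUE)) {
        sel <- aa_vec == a & spiked_row == sp
        if (!any(sel)) next
        if (length(tgt) == 0L) {
          probs <- rep(1 / length(syn), length(syn))
          pool <- syn
        } else {
          g <- spec$target_frequency[[a]]
          if (sp) {
            odds <- g / (1 - g) * spec$spike_effect
            g <- odds / (1 + odds)
          }
          pool <- c(tgt, nt)
          probs <- c(rep(g / length(tgt), length(tgt)),
                     rep((1 - g) / length(nt), length(nt)))
        }
        codon[sel] <- sample(pool, sum(sel), replace = TRUE, prob = probs)
      }
    }

    body <- vapply(split(codon, factor(gene_of, levels = seq_len(n))),
                   paste, character(1L), collapse = "")
    ids <- sprintf("gene%05d", seq_len(n))
    exome <- tibble::tibble(
      gene_id = ids,
      raw_header = ids,
      sequence = paste0("ATG", unname(body), "TAA")
    )
    truth <- tibble::tibble(gene_id = ids, spiked = spiked,
                            spike_effect = ifelse(spiked, spec$spike_effect, 1))
    structure(list(exome = exome, truth = truth, spec = spec),
              class = "synthetic_exome")
  })
}

#' @export
print.synthetic_exome <- function(x, ...) {
  cat("<synthetic_exome>", nrow(x$exome), "genes;",
      sum(x$truth$spiked), "spiked (effect", x$spec$spike_effect, ")\n")
  invisible(x)
}

#' False-positive and power calibration on synthetic exomes
#'
#' Runs the full pipeline (count, background, test, correct) on
#' `n_replicates` independently seeded synthetic exomes and reports, per
#' replicate, the fraction of null genes called significant (the
#' empirical false-positive fraction) and the fraction of spiked genes
#' recovered in the direction their spike implies (the empirical power).
#' Replicate `r` uses seed `spec$seed + r`.
#'
#' @param spec A [synthetic_spec()].
#' @param method,fdr,alpha Correction settings as in
#'   [partition_significant()].
#' @param n_replicates Number of replicates; default 20.
#' @param yates Continuity correction, as in [chi_square_test()].
#' @return A tibble with one row per replicate: `replicate`, `seed`,
#'   `n_null`, `n_spiked`, `false_positive_fraction`, `power` (`NA`
#'   when no gene is spiked).
#' @export
run_calibration <- function(spec, method = c("bh", "bonferroni"),
                            fdr = 0.01, alpha = 0.01,
                            n_replicates = 20L, yates = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"), n_replicates >= 1L)
  method <- match.arg(method)
  expect_dir <- if (spec$spike_effect >= 1) "enriched" else "depleted"

  purrr::map_dfr(seq_len(n_replicates) - 1L, function(r) {
    sp <- spec
    sp$seed <- spec$seed + r
    sim <- generate_exome(sp)
    counts <- count_exome(sim$exome, sp$codon_set)
    res <- test_exome(counts, build_background(counts), yates = yates)
    res <- partition_significant(res, method = method, fdr = fdr, alpha = alpha)
    res <- dplyr::left_join(res, sim$truth, by = "gene_id")
    null_res <- dplyr::filter(res, !.data$spiked)
    spike_res <- dplyr::filter(res, .data$spiked)
    tibble::tibble(
      replicate = r + 1L,
      seed = sp$seed,
      n_null = nrow(null_res),
      n_spiked = nrow(spike_res),
      false_positive_fraction = mean(null_res$significant),
      power = if (nrow(spike_res) == 0L) NA_real_ else {
        mean(spike_res$significant & spike_res$direction == expect_dir)
      }
    )
  })
}
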