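# Codon tallying. All counting runs through one matrix primitive:
# Biostrings::trinucleotideFrequency(step = 3) over the in-frame triplets,
# which silently drops triplets containing non-ACGT letters — those are the
# "skipped" codons. A trailing stop codon, if present, is removed first, so
# protein length L counts sense codons only.

# Drop one trailing stop codon (vectorised over sequences already uppercased
# and truncated to complete triplets).
strip_trailing_stop <- function(seqs, code = genetic_code()) {
  n <- nchar(seqs)
  has_stop <- n >= 3L
  last <- substr(seqs, n - 2L, n)
  is_stop <- has_stop & !is.na(code[last]) & code[last] == "*"
  seqs[is_stop] <- substr(seqs[is_stop], 1L, n[is_stop] - 3L)
  seqs
}

# Truncate to complete triplets, uppercase.
frame_triplets <- function(seqs) {
  seqs <- toupper(seqs)
  substr(seqs, 1L, 3L * (nchar(seqs) %/% 3L))
}

# genes x 64 in-frame codon count matrix
codon_count_matrix <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::trinucleotideFrequency(dss, step = 3L)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(m)))
  m
}

# Sum matrix columns by a grouping of codons; returns genes x groups matrix.
sum_by_group <- function(m, codons_by_group) {
  out <- vapply(codons_by_group,
                function(cods) rowSums(m[, cods, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) {
    out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(codons_by_group)))
  }
  out
}

#' Tally codons across an exome
#'
#' Counts, for every gene, the sense codons (protein length `L`), the
#' per-amino-acid codon totals, and the target codons of `codon_set`
#' (observed count `O`). A single trailing stop codon is excluded from
#' `L`; triplets containing non-ACGT letters are skipped and reported in
#' `skipped_codons`. Counting is case-insensitive.
#'
#' @param exome Data frame with columns `gene_id` and `sequence`
#'   (in-frame CDS), e.g. from [read_exome()] or [generate_exome()].
#' @param codon_set A [codon_set()].
#' @param code Genetic code, as returned by [genetic_code()].
#' @return An object of class `exome_counts`: a list with
#'   \describe{
#'     \item{genes}{tibble `gene_id`, `length_codons`, `observed`,
#'       `skipped_codons`, one row per gene;}
#'     \item{by_aa}{long tibble `gene_id`, `amino_acid`, `total`,
#'       `target` (`NA` for amino acids outside the codon set), rows with
#'       `total > 0` only;}
#'     \item{codon_set}{the codon set used;}
#'     \item{hash}{a digest of gene ids and counts, used to guarantee a
#'       background model is only applied to the gene set it was built
#'       from.}
#'   }
#' @examples
#' exome <- tibble::tibble(gene_id = c("a", "b"),
#'                         sequence = c("ATGATCATTTAA", "ATGAAA"))
#' counts <- count_exome(exome, codon_set_preset("human-adat"))
#' counts$genes
#' @export
count_exome <- function(exome, codon_set, code = genetic_code()) {
  stopifnot(is.data.frame(exome), all(c("gene_id", "sequence") %in% names(exome)))
  if (nrow(exome) == 0L) abort("exome has no genes")
  if (anyDuplicated(exome$gene_id)) abort("duplicate gene_id in exome")

  seqs <- strip_trailing_stop(frame_triplets(exome$sequence), code)
  m <- codon_count_matrix(seqs)

  sense <- names(code)[code != "*"]
  aa_of_sense <- code[sense]
  aa_levels <- sort(unique(aa_of_sense))

  totals <- sum_by_group(m, split(sense, aa_of_sense)[aa_levels])
  relevant <- sort(unique(codon_set$amino_acid))
  targets <- sum_by_group(
    m, lapply(stats::setNames(relevant, relevant),
              function(a) codon_set$codon[codon_set$amino_acid == a]))

  L <- rowSums(m[, sense, drop = FALSE])
  n_triplets <- nchar(seqs) %/% 3L
  skipped <- n_triplets - rowSums(m)
  observed <- rowSums(targets)

  genes <- tibble::tibble(
    gene_id = exome$gene_id,
    length_codons = as.integer(L),
    observed = as.integer(observed),
    skipped_codons = as.integer(skipped)
  )

  by_aa <- tibble::tibble(
    gene_id = rep(exome$gene_id, times = length(aa_levels)),
    amino_acid = rep(aa_levels, each = nrow(m)),
    total = as.integer(as.vector(totals))
  )
  tgt_long <- tibble::tibble(
    gene_id = rep(exome$gene_id, times = length(relevant)),
    amino_acid = rep(relevant, each = nrow(m)),
    target = as.integer(as.vector(targets))
  )
  by_aa <- dplyr::left_join(by_aa, tgt_long, by = c("gene_id", "amino_acid"))
  by_aa <- dplyr::filter(by_aa, .data$total > 0L)

  structure(
    list(genes = genes, by_aa = by_aa, codon_set = codon_set,
         aa_totals = totals, aa_targets = targets,
         hash = rlang::hash(list(exome$gene_id, m))),
    class = "exome_counts")
}

#' Count codons in a single coding sequence
#'
#' Single-sequence counterpart of [count_exome()], convenient for
#' inspecting one gene. The sequence is read in frame from its first
#' base; an incomplete trailing triplet is ignored and one trailing stop
#' codon is excluded from the length.
#'
#' @param sequence A nucleotide string (at least one complete codon).
#' @inheritParams count_exome
#' @return A list of class `gene_codon_counts` with elements
#'   `length_codons` (sense codons, `L`), `observed` (target codons,
#'   `O`), `skipped_codons`, `total_by_aa` (named counts, amino acids
#'   present only) and `target_by_aa` (named counts over the codon set's
#'   amino acids).
#' @examples
#' count_codons("ATGATCATTTAA", codon_set_preset("human-adat"))
#' @export
count_codons <- function(sequence, codon_set, code = genetic_code()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 3L) abort("sequence shorter than one codon")
  counts <- count_exome(
    tibble::tibble(gene_id = "gene", sequence = sequence), codon_set, code)
  by_aa <- counts$by_aa
  structure(
    list(length_codons = counts$genes$length_codons,
         observed = counts$genes$observed,
         skipped_codons = counts$genes$skipped_codons,
         total_by_aa = stats::setNames(by_aa$total, by_aa$amino_acid),
         target_by_aa = stats::setNames(
           as.integer(counts$aa_targets[1L, ]), colnames(counts$aa_targets))),
    class = "gene_codon_counts")
}

#' @export
print.gene_codon_counts <- function(x, ...) {
  cat("<gene_codon_counts> L =", x$length_codons,
      " O =", x$observed,
      " skipped =", x$skipped_codons, "\n")
  aa <- tibble::tibble(amino_acid = names(x$total_by_aa),
                       total = unname(x$total_by_aa))
  aa$target <- unname(x$target_by_aa[aa$amino_acid])
  print(aa, ...)
  invisible(x)
}

#' @export
print.exome_counts <- function(x, ...) {
  cat("<exome_counts>", nrow(x$genes), "genes;",
      "codon set:", attr(x$codon_set, "name"), "\n")
  print(x$genes, ...)
  invisible(x)
}

#' @describeIn count_exome `tidy()` returns the per-gene summary tibble.
#' @param x An `exome_counts` object.
#' @param ... Unused.
#' @export
tidy.exome_counts <- function(x, ...) x$genes
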