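#' Read a CDS FASTA file as an exome
#'
#' Parses a coding-sequence FASTA file into a tibble of nonredundant gene
#' records, applying the quality-control rules under which the enrichment
#' test is defined: records are deduplicated by gene id (first occurrence
#' kept), and a gene is excluded when its sequence is empty, its length is
#' not a multiple of three (the reading frame would be unknowable), it
#' contains an internal stop codon (a malformed CDS entry), or more than
#' `1 - min_valid` of its triplets contain non-ACGT characters. Every
#' exclusion is recorded in a QC report attached to the result.
#'
#' Header dialects determine how the gene id is extracted:
#' \describe{
#'   \item{`ccds`}{first `|`-delimited token (e.g. `>CCDS2.2|Hs110|chr1`
#'     gives `CCDS2.2`);}
#'   \item{`generic`, `wormbase`, `flybase`, `sgd`}{first
#'     whitespace-delimited token; remaining annotation fields are kept in
#'     `raw_header` but otherwise ignored.}
#' }
#'
#' @param path Path to a FASTA file of spliced, in-frame coding sequences,
#'   one record per gene.
#' @param dialect Header dialect, one of `"generic"`, `"ccds"`,
#'   `"wormbase"`, `"flybase"`, `"sgd"`.
#' @param min_valid Minimum fraction of triplets that must be plain ACGT
#'   for a gene to be retained (default 0.9); sparser ambiguity is
#'   tolerated, with the affected triplets skipped during counting.
#' @param code Genetic code, as returned by [genetic_code()].
#' @return A tibble with columns `gene_id`, `raw_header`, `sequence`
#'   (retained genes, in input order), carrying the QC report in
#'   `attr(, "qc")`; retrieve it with [qc_report()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">geneA first", "ATGATCGTCTAA", ">geneB other", "ATGAAATAG"), fa)
#' exome <- read_exome(fa, dialect = "generic")
#' qc_report(exome)
#' @export
read_exome <- function(path,
                       dialect = c("generic", "ccds", "wormbase", "flybase", "sgd"),
                       min_valid = 0.9,
                       code = genetic_code()) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) abort(paste0("no FASTA records in ", path))

  headers <- names(seqs)
  ids <- if (dialect == "ccds") {
    vapply(strsplit(headers, "|", fixed = TRUE), `[`, "", 1L)
  } else {
    vapply(strsplit(headers, "[[:space:]]+"), `[`, "", 1L)
  }
  ids <- trimws(ids)
  sequence <- unname(toupper(as.character(seqs)))

  qc <- tibble::tibble(
    record = seq_along(ids),
    gene_id = ids,
    status = "retained",
    reason = NA_character_
  )

  mark <- function(qc, idx, status, reason) {
    idx <- idx & qc$status == "retained"
    qc$status[idx] <- status
    qc$reason[idx] <- reason
    qc
  }

  qc <- mark(qc, !nzchar(ids), "excluded", "empty gene id")
  qc <- mark(qc, duplicated(ids) & nzchar(ids), "duplicate", "duplicate gene_id")
  qc <- mark(qc, nchar(sequence) == 0L, "excluded", "empty sequence")
  qc <- mark(qc, nchar(sequence) %% 3L != 0L & nchar(sequence) > 0L,
             "excluded", "length not a multiple of 3")

  # internal stop: a stop codon before the final triplet
  live <- qc$status == "retained"
  internal_stop <- rep(FALSE, length(ids))
  if (any(live)) {
    internal_stop[live] <- vapply(sequence[live], function(s) {
      n <- nchar(s)
      starts <- seq.int(1L, n - 2L, by = 3L)
      cods <- substring(s, starts, starts + 2L)
      any(code[cods[-length(cods)]] == "*", na.rm = TRUE)
    }, logical(1L), USE.NAMES = FALSE)
  }
  qc <- mark(qc, internal_stop, "excluded", "internal stop codon")

  live <- qc$status == "retained"
  too_ambiguous <- rep(FALSE, length(ids))
  if (any(live)) {
    m <- codon_count_matrix(strip_trailing_stop(sequence[live], code))
    n_trip <- nchar(strip_trailing_stop(sequence[live], code)) %/% 3L
    frac_valid <- ifelse(n_trip == 0L, 0, rowSums(m) / n_trip)
    too_ambiguous[live] <- frac_valid < min_valid
  }
  qc <- mark(qc, too_ambiguous, "excluded", "too many ambiguous codons")

  keep <- qc$status == "retained"
  out <- tibble::tibble(
    gene_id = ids[keep],
    raw_header = headers[keep],
    sequence = sequence[keep]
  )
  attr(out, "qc") <- qc
  out
}

#' Per-record quality-control report of a parsed exome
#'
#' One row per FASTA record read, with `status` in `retained` /
#' `excluded` / `duplicate` and the exclusion `reason`. The statuses
#' always account for every record read.
#'
#' @param exome A tibble from [read_exome()].
#' @return A tibble with columns `record`, `gene_id`, `status`, `reason`.
#' @export
qc_report <- function(exome) {
  qc <- attr(exome, "qc")
  if (is.null(qc)) {
    tibble::tibble(record = integer(), gene_id = character(),
                   status = character(), reason = character())
  } else {
    qc
  }
}

#' Write an exome as FASTA
#'
#' Minimal deterministic FASTA writer (one sequence line per record),
#' used by the synthetic-exome generator so that identical inputs give
#' byte-identical files.
#'
#' @param exome Data frame with columns `gene_id` and `sequence`; a
#'   `raw_header` column, if present, is used as the header line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exome_fasta <- function(exome, path) {
  headers <- if ("raw_header" %in% names(exome)) exome$raw_header else exome$gene_id
  lines <- as.vector(rbind(paste0(">", headers), exome$sequence))
  writeLines(lines, path)
  invisible(path)
}
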