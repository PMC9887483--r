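#' The standard genetic code
#'
#' Returns the standard genetic code (NCBI translation table 1) as a named
#' character vector mapping the 64 DNA triplets (uppercase `A`/`C`/`G`/`T`)
#' to single-letter amino acids, with `"*"` marking the three stop codons.
#' This is the only code built in; every counting and translation step in
#' the package takes a `code` argument so an alternative table could be
#' supplied, but none is shipped.
#'
#' @return A named character vector of length 64.
#' @examples
#' code <- genetic_code()
#' code["ATG"]
#' sum(code == "*")
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(code), names(code))
}

#' Define and validate a codon set
#'
#' A codon set is the collection of codons whose per-gene usage is tested
#' against the exome-wide background — for example the wobble-inosine
#' (ADAT-dependent) codons of a species. The constructor validates the
#' codons against the genetic code and derives the amino-acid grouping
#' that the background model is stratified by.
#'
#' Input may be a character vector of triplets or a single comma-separated
#' string (as passed on a command line). Case is ignored. Stop codons,
#' duplicates and non-ACGT characters are rejected with an error naming
#' the offending codon.
#'
#' @param codons Character vector of DNA triplets, or one comma-separated
#'   string such as `"ACC,GCC,CCC"`.
#' @param name Label carried through outputs (default `"custom"`).
#' @param code Genetic code, as returned by [genetic_code()].
#' @return A tibble of class `codon_set` with columns `codon` and
#'   `amino_acid`, sorted by amino acid then codon, with the label in
#'   `attr(, "name")`.
#' @examples
#' codon_set(c("ACC", "GCC", "CCC", "TCC", "CTC", "ATC", "GTC", "CGC"),
#'           name = "human-adat")
#' @seealso [codon_set_preset()], [read_codon_set()]
#' @export
codon_set <- function(codons, name = "custom", code = genetic_code()) {
  if (length(codons) == 1L && grepl(",", codons)) {
    codons <- strsplit(codons, ",")[[1]]
  }
  codons <- toupper(trimws(codons))
  codons <- codons[nzchar(codons)]
  if (length(codons) == 0L) {
    abort("codon set is empty")
  }
  bad <- codons[!grepl("^[ACGT]{3}$", codons)]
  if (length(bad) > 0L) {
    abort(paste0("not a valid DNA triplet: ", paste(unique(bad), collapse = ", ")))
  }
  dup <- unique(codons[duplicated(codons)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate codon in set: ", paste(dup, collapse = ", ")))
  }
  aa <- unname(code[codons])
  if (any(aa == "*")) {
    abort(paste0("stop codon not allowed in a codon set: ",
                 paste(codons[aa == "*"], collapse = ", ")))
  }
  out <- tibble::tibble(codon = codons, amino_acid = aa)
  out <- dplyr::arrange(out, .data$amino_acid, .data$codon)
  structure(out, name = name, class = c("codon_set", class(out)))
}

#' Built-in codon-set presets
#'
#' Two sets of wobble-inosine (ADAT-dependent) codons ship with the
#' package: `"human-adat"` (ACC, GCC, CCC, TCC, CTC, ATC, GTC, CGC; the
#' set shared by human, mouse, nematode and fruit fly) and `"yeast-adat"`
#' (TCC, CCC, CGC, CGA, ATC, ACC, GTC, GCC). These are C- or A-ending
#' codons lacking a cognate tRNA, decodable only through wobble-inosine
#' modified tRNAs; any other set is supplied by the user via
#' [codon_set()] or [read_codon_set()].
#'
#' @param name `"human-adat"` or `"yeast-adat"`.
#' @return A [codon_set()].
#' @examples
#' codon_set_preset("yeast-adat")
#' @export
codon_set_preset <- function(name = c("human-adat", "yeast-adat")) {
  name <- match.arg(name)
  codons <- switch(name,
    "human-adat" = c("ACC", "GCC", "CCC", "TCC", "CTC", "ATC", "GTC", "CGC"),
    "yeast-adat" = c("TCC", "CCC", "CGC", "CGA", "ATC", "ACC", "GTC", "GCC")
  )
  codon_set(codons, name = name)
}

#' Read a codon set from a text file
#'
#' One codon per line; `#` starts a comment; blank lines and commas within
#' a line are tolerated.
#'
#' @param path Path to the file.
#' @param name Label for the set; defaults to the file name.
#' @inheritParams codon_set
#' @return A [codon_set()].
#' @export
read_codon_set <- function(path, name = NULL, code = genetic_code()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tokens <- unlist(strsplit(lines, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  codon_set(tokens, name = name, code = code)
}

# Resolve a user-facing codon-set argument: an existing codon_set, a preset
# name, a file path, a comma-separated string, or a character vector.
resolve_codon_set <- function(x, code = genetic_code()) {
  if (inherits(x, "codon_set")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("human-adat", "yeast-adat")) return(codon_set_preset(x))
    if (file.exists(x) && !grepl("^[ACGTacgt]{3}$", x)) {
      return(read_codon_set(x, code = code))
    }
  }
  codon_set(x, code = code)
}
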