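# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain string loops and literal textbook formulas.

# hard-coded standard genetic code (translation table 1)
ORACLE_CODE <- local({
  map <- c(
    TTT="F", TTC="F", TTA="L", TTG="L", CTT="L", CTC="L", CTA="L", CTG="L",
    ATT="I", ATC="I", ATA="I", ATG="M", GTT="V", GTC="V", GTA="V", GTG="V",
    TCT="S", TCC="S", TCA="S", TCG="S", CCT="P", CCC="P", CCA="P", CCG="P",
    ACT="T", ACC="T", ACA="T", ACG="T", GCT="A", GCC="A", GCA="A", GCG="A",
    TAT="Y", TAC="Y", TAA="*", TAG="*", CAT="H", CAC="H", CAA="Q", CAG="Q",
    AAT="N", AAC="N", AAA="K", AAG="K", GAT="D", GAC="D", GAA="E", GAG="E",
    TGT="C", TGC="C", TGA="*", TGG="W", CGT="R", CGC="R", CGA="R", CGG="R",
    AGT="S", AGC="S", AGA="R", AGG="R", GGT="G", GGC="G", GGA="G", GGG="G")
  map
})

# literal triplet-iteration counter
naive_gene_counts <- function(sequence, target_codons) {
  s <- toupper(sequence)
  n_trip <- nchar(s) %/% 3L
  cods <- character(0)
  if (n_trip > 0) {
    cods <- vapply(seq_len(n_trip) - 1L,
                   function(i) substr(s, 3L * i + 1L, 3L * i + 3L), "")
  }
  # one trailing stop excluded
  if (length(cods) > 0) {
    last_aa <- ORACLE_CODE[cods[length(cods)]]
    if (!is.na(last_aa) && last_aa == "*") cods <- cods[-length(cods)]
  }
  L <- 0L; skipped <- 0L; O <- 0L
  total_by_aa <- integer(0); target_by_aa <- integer(0)
  target_aa <- unique(unname(ORACLE_CODE[target_codons]))
  for (cod in cods) {
    if (!grepl("^[ACGT]{3}$", cod)) { skipped <- skipped + 1L; next }
    aa <- unname(ORACLE_CODE[cod])
    if (aa == "*") next
    L <- L + 1L
    total_by_aa[aa] <- sum(total_by_aa[aa], 1L, na.rm = TRUE)
    if (aa %in% target_aa) {
      hit <- as.integer(cod %in% target_codons)
      target_by_aa[aa] <- sum(target_by_aa[aa], hit, na.rm = TRUE)
      O <- O + hit
    }
  }
  list(L = L, O = O, skipped = skipped,
       total_by_aa = total_by_aa, target_by_aa = target_by_aa)
}

# literal Pearson chi-square on the 2x2 table [[L, L], [O, E]]
pearson_2x2_oracle <- function(L, O, E, yates = FALSE) {
  obs <- matrix(c(L, O, L, E), nrow = 2)
  stat <- 0
  for (i in 1:2) for (j in 1:2) {
    exp_ij <- sum(obs[i, ]) * sum(obs[, j]) / sum(obs)
    d <- abs(obs[i, j] - exp_ij)
    if (yates) d <- max(d - 0.5, 0)
    stat <- stat + d^2 / exp_ij
  }
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# literal step-up BH rejection
bh_stepup_oracle <- function(p, fdr) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) / m * fdr)
  k <- if (length(ok) == 0) 0L else max(ok)
  reject <- logical(m)
  if (k > 0) reject[ord[seq_len(k)]] <- TRUE
  reject
}

# random in-frame CDS built from sense codons, with optional trailing stop
random_cds <- function(n_codons, trailing_stop = TRUE) {
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  body <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  if (trailing_stop) paste0(body, sample(c("TAA", "TAG", "TGA"), 1)) else body
}

# random sequence over an alphabet that can include ambiguity and stops
random_messy_seq <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N"), n_bases,
               replace = TRUE, prob = c(rep(0.115, 8), 0.08)),
        collapse = "")
}

scan_of_sim <- function(sim, ...) scan_exome(sim$exome, "human-adat", ...)
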