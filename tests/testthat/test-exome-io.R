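write_fa <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", names(records)), unname(records))), path)
  path
}

test_that("header dialects extract the documented gene id", {
  fa <- write_fa(c("CCDS2.2|Hs110|chr1" = "ATGGTCTAA",
                   "geneA some description" = "ATGAAATAA"))
  expect_equal(read_exome(fa, dialect = "ccds")$gene_id[1], "CCDS2.2")
  expect_equal(read_exome(fa, dialect = "generic")$gene_id[2], "geneA")
  for (d in c("wormbase", "flybase", "sgd")) {
    expect_equal(read_exome(fa, dialect = d)$gene_id[2], "geneA")
  }
})

test_that("duplicates are dropped first-wins and reported", {
  fa <- write_fa(c("g1 first copy" = "ATGGTCTAA",
                   "g2" = "ATGAAATAA",
                   "g1 second copy" = "ATGATCTAA"))
  exome <- read_exome(fa)
  expect_equal(exome$gene_id, c("g1", "g2"))
  expect_equal(exome$sequence[1], "ATGGTCTAA")  # first occurrence kept
  qc <- qc_report(exome)
  expect_equal(sum(qc$status == "duplicate"), 1L)
})

test_that("QC excludes frame violations, internal stops, empty and ambiguous records", {
  fa <- write_fa(c(
    ok = "ATGGTCATCTAA",
    frame = "ATGGTCA",               # length not multiple of 3
    internal_stop = "ATGTAAGTCTAA",  # TAA before the final codon
    empty = "",
    ambiguous = paste0("ATG", strrep("NNN", 5), "TAA")  # 5/7 triplets invalid
  ))
  exome <- read_exome(fa)
  expect_equal(exome$gene_id, "ok")
  qc <- qc_report(exome)
  expect_equal(qc$status[qc$gene_id == "ok"], "retained")
  expect_match(qc$reason[qc$gene_id == "frame"], "multiple of 3")
  expect_match(qc$reason[qc$gene_id == "internal_stop"], "internal stop")
  expect_match(qc$reason[qc$gene_id == "empty"], "empty sequence")
  expect_match(qc$reason[qc$gene_id == "ambiguous"], "ambiguous")
})

test_that("sparse ambiguity is tolerated below the threshold", {
  # 1 ambiguous triplet out of 21 -> retained; codons with N are skipped
  seq <- paste0("ATG", strrep("GTC", 19), "GNC", "TAA")
  fa <- write_fa(c(g = seq))
  exome <- read_exome(fa)
  expect_equal(exome$gene_id, "g")
  x <- count_codons(exome$sequence, codon_set_preset("human-adat"))
  expect_equal(x$skipped_codons, 1L)
  expect_equal(x$length_codons, 20L)
})

test_that("QC accounting identity holds: retained + excluded + duplicates = records read", {
  fa <- write_fa(c(a = "ATGGTCTAA", b = "ATGGT", a = "ATGGTCTAA",
                   c = "ATGTAACCCTAA", d = "ATGCCCTAA"))
  exome <- read_exome(fa)
  qc <- qc_report(exome)
  expect_equal(nrow(qc), 5L)
  expect_equal(sum(qc$status == "retained"), nrow(exome))
  expect_equal(sum(qc$status %in% c("retained", "excluded", "duplicate")), nrow(qc))
})

test_that("an empty FASTA file is an error", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), path)
  expect_error(read_exome(path), "no FASTA records")
})

test_that("written result tables round-trip their numeric fields at printed precision", {
  sim <- generate_exome(synthetic_spec(n_genes = 30, gene_length = 100, seed = 11))
  scan <- scan_of_sim(sim, fdr = 0.05)
  dir <- withr::local_tempdir()
  paths <- write_scan_results(scan, dir)
  back <- readr::read_tsv(paths[["results"]], show_col_types = FALSE)
  orig <- dplyr::arrange(scan$results, gene_id)
  expect_equal(back$gene_id, orig$gene_id)
  expect_equal(back$observed, orig$observed)
  expect_equal(back$expected, as.numeric(formatC(orig$expected, digits = 6, format = "g")))
  expect_equal(back$p_value, as.numeric(formatC(orig$p_value, digits = 6, format = "e")))
  bg <- readr::read_tsv(paths[["background_model"]], show_col_types = FALSE)
  expect_equal(bg$amino_acid, scan$background$amino_acid)
})

test_that("output files are deterministic and ordered by gene id", {
  sim <- generate_exome(synthetic_spec(n_genes = 25, gene_length = 90, seed = 5))
  scan <- scan_of_sim(sim)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_scan_results(scan, d1)
  p2 <- write_scan_results(scan, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  res <- readr::read_tsv(p1[["results"]], show_col_types = FALSE)
  expect_equal(res$gene_id, sort(res$gene_id))
})

test_that("the GO export holds exactly top_n ids when more genes are enriched", {
  sim <- generate_exome(synthetic_spec(n_genes = 40, gene_length = 80, seed = 2))
  scan <- scan_of_sim(sim)
  # fabricate a corrected result table with 30 enriched genes, top_n = 20
  scan$results$p_value <- seq(1e-10, 1e-3, length.out = 40)
  scan$results$q_value <- scan$results$p_value
  scan$results$tested <- TRUE
  scan$results$direction <- rep(c("enriched", "depleted"), c(30, 10))
  scan$results$significant <- TRUE
  scan$config$top_n <- 20L
  dir <- withr::local_tempdir()
  paths <- write_scan_results(scan, dir)
  expect_match(basename(paths[["go_export"]]), "top20")
  expect_length(readLines(paths[["go_export"]]), 20L)
  # and the exported ids are the smallest-p enriched genes
  enr <- enriched_genes(scan$results)
  expect_equal(readLines(paths[["go_export"]]), head(enr$gene_id, 20))
})

test_that("empty significant lists still produce files with zero data lines", {
  sim <- generate_exome(synthetic_spec(n_genes = 20, gene_length = 60, seed = 9))
  scan <- scan_of_sim(sim)
  dir <- withr::local_tempdir()
  paths <- write_scan_results(scan, dir)
  expect_true(file.exists(paths[["enriched"]]))
  expect_length(readLines(paths[["enriched"]]), length(enriched_genes(scan$results)$gene_id))
})
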