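test_that("expected counts follow E = sum(n_aa * f_aa)", {
  exome <- tibble::tibble(
    gene_id = c("a", "b"),
    sequence = c(paste0(strrep("ATC", 2), strrep("ATT", 2)),  # 4 Ile, 2 targets
                 strrep("AAA", 5)))                           # no relevant aa
  counts <- count_exome(exome, codon_set("ATC"))
  bg <- build_background(counts)  # f_I = 2/4 = 0.5
  E <- expected_count(counts, bg)
  expect_equal(E$expected[E$gene_id == "a"], 4 * 0.5)
  expect_equal(E$expected[E$gene_id == "b"], 0)

  # single-gene method agrees
  x <- count_codons(exome$sequence[1], codon_set("ATC"))
  expect_equal(expected_count(x, bg), 2)
})

test_that("expected counts match a literal per-amino-acid sum on random genes", {
  human <- codon_set_preset("human-adat")
  sim <- generate_exome(synthetic_spec(n_genes = 40, gene_length = 150, seed = 21))
  counts <- count_exome(sim$exome, human)
  bg <- build_background(counts)
  E <- expected_count(counts, bg)
  f <- setNames(bg$background_frequency, bg$amino_acid)
  for (g in sample(sim$exome$gene_id, 10)) {
    one <- count_codons(sim$exome$sequence[sim$exome$gene_id == g], human)
    manual <- 0
    for (a in names(f)) {
      n_aa <- one$total_by_aa[a]
      if (!is.na(n_aa)) manual <- manual + n_aa * f[[a]]
    }
    expect_equal(E$expected[E$gene_id == g], unname(manual))
  }
})

test_that("the worked 2x2 example reproduces the hand-computed statistic", {
  res <- chi_square_test(100, 30, 20)
  expect_equal(res$statistic, 16 / 104 + 16 / 96 + 16 / 26 + 16 / 24)
  expect_equal(res$statistic, 1.60256, tolerance = 1e-5)
  expect_equal(res$p_value, 0.2056, tolerance = 1e-3)
  expect_true(res$tested)
})

test_that("identical observed and expected columns give statistic 0 and p 1", {
  res <- chi_square_test(100, 20, 20)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the statistic matches the literal Pearson oracle and chisq.test on random tables", {
  withr::with_seed(31, {
    for (i in 1:300) {
      L <- sample(1:2000, 1)
      O <- sample(0:L, 1)
      E <- runif(1, 0.01, L)
      for (yates in c(FALSE, TRUE)) {
        got <- chi_square_test(L, O, E, yates = yates)
        want <- pearson_2x2_oracle(L, O, E, yates = yates)
        expect_equal(got$statistic, want$statistic)
        expect_equal(got$p_value, want$p_value)
      }
    }
    # cross-check the uncorrected form against stats::chisq.test on integer tables
    for (i in 1:20) {
      L <- sample(50:500, 1); O <- sample(1:L, 1); E <- sample(1:L, 1)
      got <- chi_square_test(L, O, E)
      ref <- suppressWarnings(
        stats::chisq.test(matrix(c(L, O, L, E), nrow = 2), correct = FALSE))
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, unname(ref$p.value))
    }
  })
})

test_that("the Yates-corrected statistic never exceeds the uncorrected one", {
  withr::with_seed(8, {
    L <- sample(1:1000, 200, replace = TRUE)
    O <- floor(runif(200) * (L + 1))
    E <- runif(200, 0.01, L)
    plain <- chi_square_test(L, O, E, yates = FALSE)
    corr <- chi_square_test(L, O, E, yates = TRUE)
    expect_true(all(corr$statistic <= plain$statistic + 1e-12))
  })
})

test_that("p-values are valid and monotone in |O - E| at fixed L and E", {
  L <- 500; E <- 60
  O <- seq(60, 180, by = 5)
  res <- chi_square_test(rep(L, length(O)), O, rep(E, length(O)))
  expect_true(all(res$statistic >= 0))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(diff(res$p_value) <= 1e-12))
  # and symmetrically below E
  res_dn <- chi_square_test(rep(L, 5), seq(60, 20, by = -10), rep(E, 5))
  expect_true(all(diff(res_dn$p_value) <= 1e-12))
})

test_that("genes with E = 0 are flagged untested, never dropped", {
  exome <- tibble::tibble(gene_id = c("with", "without"),
                          sequence = c("ATGATCTAA", "ATGAAATAA"))
  counts <- count_exome(exome, codon_set("ATC"))
  res <- test_exome(counts, build_background(counts))
  expect_equal(nrow(res), 2L)
  expect_false(res$tested[res$gene_id == "without"])
  expect_true(is.na(res$p_value[res$gene_id == "without"]))
  expect_equal(res$direction[res$gene_id == "without"], "none")
})

test_that("expected counts are conserved over the exome the model was built on", {
  sim <- generate_exome(synthetic_spec(n_genes = 200, gene_length = 200, seed = 17))
  counts <- count_exome(sim$exome, codon_set_preset("human-adat"))
  res <- test_exome(counts, build_background(counts))
  expect_equal(sum(res$expected), sum(res$observed), tolerance = 1e-9)
})

test_that("a single-gene exome is its own background: E = O and p = 1", {
  exome <- tibble::tibble(gene_id = "only", sequence = random_cds(80))
  counts <- count_exome(exome, codon_set_preset("human-adat"))
  res <- test_exome(counts, build_background(counts))
  expect_equal(res$expected, res$observed, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
})

test_that("identical genes receive identical p-values and direction follows sign(O - E)", {
  seq <- paste0("ATG", strrep("ATCATT", 20), "TAA")
  exome <- tibble::tibble(gene_id = c("g1", "g2", "g3"), sequence = rep(seq, 3))
  counts <- count_exome(exome, codon_set("ATC"))
  res <- test_exome(counts, build_background(counts))
  expect_length(unique(res$p_value), 1L)

  sim <- generate_exome(synthetic_spec(n_genes = 100, gene_length = 150, seed = 23))
  counts <- count_exome(sim$exome, codon_set_preset("human-adat"))
  res <- test_exome(counts, build_background(counts))
  expect_true(all(res$direction[res$observed > res$expected] == "enriched"))
  expect_true(all(res$direction[res$observed < res$expected] == "depleted"))
})

test_that("a background model from a different gene set is refused", {
  s1 <- generate_exome(synthetic_spec(n_genes = 10, gene_length = 50, seed = 1))
  s2 <- generate_exome(synthetic_spec(n_genes = 10, gene_length = 50, seed = 2))
  c1 <- count_exome(s1$exome, codon_set_preset("human-adat"))
  c2 <- count_exome(s2$exome, codon_set_preset("human-adat"))
  expect_error(test_exome(c1, build_background(c2)), "different gene set")
})
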