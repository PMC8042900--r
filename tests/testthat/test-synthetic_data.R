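test_that("simulation specs validate their invariants", {
  expect_error(simulation_spec(target_r2 = 0.5, noise_sd = 1),
               "mutually exclusive")
  expect_error(simulation_spec(target_r2 = 1.2), "target_r2")
  w <- setNames(rep(0, 64), sort(Biostrings::mkAllStrings(c("A","C","G","T"), 3)))
  expect_error(simulation_spec(codon_weights = w), "positive sum")
  w2 <- w; w2[c("AAG", "AAA")] <- c(0.95, 0.05)
  expect_error(simulation_spec(codon_weights = w2,
                               aag_boost = c(fraction = 0.1, add = 0.3)),
               "infeasible")
  expect_error(simulation_spec(protein_missing_rate = 1), "missing_rate")
})

test_that("CDS structure: ATG start, stop end, interior from the weight vector", {
  w <- setNames(rep(0, 64), sort(Biostrings::mkAllStrings(c("A","C","G","T"), 3)))
  w[c("GCT", "CCC", "TTT")] <- 1  # no AAG mass at all
  spec <- simulation_spec(n_genes = 30, codon_weights = w,
                          aag_boost = c(fraction = 0, add = 0), seed = 5)
  sim <- simulate_catalog(spec)
  cds <- as.character(sim$catalog$cds)
  expect_true(all(startsWith(cds, "ATG")))
  expect_true(all(substring(cds, nchar(cds) - 2) %in% c("TAA", "TAG", "TGA")))
  interior <- substring(cds, 4, nchar(cds) - 3)
  allowed <- unique(unlist(lapply(interior, function(s)
    oracle_codons_of(s))))
  expect_true(all(allowed %in% c("GCT", "CCC", "TTT")))
  ## zero AAG weight and no boost: AAG frequency identically 0 in interiors
  expect_false(any(grepl("AAG", vapply(interior, function(s)
    paste(oracle_codons_of(s), collapse = " "), ""))))
})

test_that("uniform weights give mean interior AAG frequency near 1/61", {
  spec <- simulation_spec(n_genes = 500, aag_boost = c(fraction = 0, add = 0),
                          seed = 6)
  sim <- simulate_catalog(spec)
  interior <- substring(as.character(sim$catalog$cds), 4,
                        nchar(as.character(sim$catalog$cds)) - 3)
  freqs <- vapply(interior, function(s) {
    cod <- oracle_codons_of(s)
    mean(cod == "AAG")
  }, numeric(1))
  ## ~300 codons per gene, 500 genes: SE of the mean ~ 3e-4
  expect_lt(abs(mean(freqs) - 1 / 61), 0.0015)
})

test_that("identical spec and seed reproduce identical files bit for bit", {
  spec <- simulation_spec(n_genes = 40, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(spec, dir = d1)
  simulate_dataset(spec, dir = d2)
  for (f in c("genome.fa", "annot.gff3", "transcripts.tsv", "proteins.tsv",
              "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("substreams are independent: protein missingness does not perturb sequences", {
  s1 <- simulation_spec(n_genes = 30, seed = 9, protein_missing_rate = 0)
  s2 <- simulation_spec(n_genes = 30, seed = 9, protein_missing_rate = 0.1)
  c1 <- simulate_catalog(s1); c2 <- simulate_catalog(s2)
  expect_identical(as.character(c1$catalog$cds), as.character(c2$catalog$cds))
  e1 <- simulate_expression(c1$catalog, s1)
  e2 <- simulate_expression(c2$catalog, s2)
  expect_identical(e1$truth$l2_protein_fc, e2$truth$l2_protein_fc)
})

test_that("zero missingness makes imputation a no-op", {
  spec <- simulation_spec(n_genes = 60, protein_missing_rate = 0, seed = 8)
  sim <- simulate_dataset(spec)
  out <- filter_and_impute_protein(sim$proteins, normalize = FALSE)
  expect_equal(out$values, sim$proteins$values)
})

test_that("the generator hits its target R^2 and records matching ground truth", {
  spec <- simulation_spec(seed = 101)  # n = 3000, target 0.6
  sim <- simulate_dataset(spec)
  expect_true(all(abs(sim$truth$realized_r2 - 0.6) < 0.05))
  ## the recorded protein log2 fold change is baseline-consistent with the
  ## protein table: per-gene replicate means reproduce 2^l2pfc
  pr <- sim$proteins
  m20 <- rowMeans(pr$values[, pr$samples$condition == "20C"], na.rm = TRUE)
  m30 <- rowMeans(pr$values[, pr$samples$condition == "30C"], na.rm = TRUE)
  est <- log2(m30 / m20)
  expect_gt(cor(est, sim$truth$l2_protein_fc[, "30C"]), 0.98)
})

test_that("recovery_report passes on faithful output and fails on corrupted ranking", {
  spec <- simulation_spec(n_genes = 1200, seed = 33)
  sim <- simulate_dataset(spec)
  fc <- build_fc_table(sim$transcripts,
                       filter_and_impute_protein(sim$proteins), "20C", "30C")
  fm <- build_feature_matrix(sim$catalog,
                             setNames(fc$transcript_fc, fc$gene_id))
  res <- associate(fm, fc, seed = 33)
  rec <- recovery_report(sim$truth, res$contribution, res$correlation, "30C")
  expect_true(rec$overall)
  ## negative control: invert the contribution ranking
  corrupt <- res$contribution
  corrupt$features$contribution_pct <- rev(corrupt$features$contribution_pct)
  rec2 <- recovery_report(sim$truth, corrupt, res$correlation, "30C")
  expect_false(rec2$checks$pass[rec2$checks$check == "top_contributors"])
})

test_that("a zero-effect spec reports near-zero explained variance", {
  spec <- simulation_spec(effects = numeric(0), noise_sd = 0.8,
                          target_r2 = NULL, seed = 44)  # n = 3000
  sim <- simulate_dataset(spec)
  fc <- build_fc_table(sim$transcripts,
                       filter_and_impute_protein(sim$proteins), "20C", "30C")
  fm <- build_feature_matrix(sim$catalog,
                             setNames(fc$transcript_fc, fc$gene_id))
  res <- associate(fm, fc, seed = 44)
  expect_lt(res$contribution$total_explained_pct, 5)
  rec <- recovery_report(sim$truth, res$contribution, res$correlation, "30C")
  expect_true(is.na(rec$checks$pass[rec$checks$check == "top_contributors"]))
  expect_true(all(rec$checks$pass[-1]))
})
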