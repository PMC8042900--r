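protein_fixture <- function(values) {
  toy_expression(values, conds = rep(c("20C", "30C"), each = 4))
}

test_that("single missing replicate is filled with the mean of the other three", {
  v <- rbind(gA = c(2, NA, 4, 6, 1, 1, 1, 1),
             gB = c(2, NA, NA, 6, 1, 1, 1, 1),
             gC = c(5, 5, 5, 5, 2, 2, 2, 2))
  out <- filter_and_impute_protein(protein_fixture(v), normalize = FALSE)
  expect_equal(unname(out$values["gA", 2]), 4)       # mean(2, 4, 6)
  expect_false("gB" %in% rownames(out$values))       # < 3 observed
  expect_equal(attr(out, "dropped_genes"), "gB")
  ## observed entries are untouched
  expect_equal(unname(out$values["gA", c(1, 3, 4)]), c(2, 4, 6))
  expect_equal(unname(out$values["gC", ]), v["gC", ])
})

test_that("imputation clears all missingness and median normalization matches the hand formula", {
  spec <- simulation_spec(n_genes = 300, protein_missing_rate = 0.1, seed = 21)
  sim <- simulate_dataset(spec)
  raw <- sim$proteins
  expect_gt(sum(is.na(raw$values)), 0)
  out <- filter_and_impute_protein(raw)
  expect_false(anyNA(out$values))
  ## recompute the normalization independently: impute, then scale each
  ## sample so its median equals the grand median of the imputed table
  nonorm <- filter_and_impute_protein(raw, normalize = FALSE)
  fac <- median(nonorm$values) / apply(nonorm$values, 2, median)
  expect_equal(unname(attr(out, "norm_factors")), unname(fac))
  expect_equal(out$values, sweep(nonorm$values, 2, fac, `*`),
               ignore_attr = TRUE)
})

test_that("replicate-count mismatches are rejected unless overridden", {
  v <- matrix(1, 2, 6, dimnames = list(c("a", "b"), NULL))
  tab <- toy_expression(v, conds = rep(c("20C", "30C"), each = 3))
  expect_error(filter_and_impute_protein(tab), "3 replicates, expected 4")
  expect_silent(filter_and_impute_protein(tab, replicates = 3L,
                                          min_observed = 3L,
                                          normalize = FALSE))
})

test_that("fold change is the ratio of replicate means, with epsilon guard", {
  v <- rbind(flat = c(3, 3, 3, 2, 4, 3),
             up = c(2, 2, 2, 4, 4, 4),
             zeroed = c(0, 0, 0, 1, 1, 1),
             allzero = c(0, 0, 0, 0, 0, 0))
  tab <- toy_expression(v, conds = rep(c("20C", "30C"), each = 3))
  fc <- fold_changes(tab, "20C", "30C", test = "none")
  expect_equal(fc$fc[fc$gene_id == "flat"], 1)
  expect_equal(fc$fc[fc$gene_id == "up"], 2)
  ## all-zero genes are excluded; zero-control genes flagged, finite
  expect_false("allzero" %in% fc$gene_id)
  zr <- fc[fc$gene_id == "zeroed", ]
  expect_true(zr$eps_flag)
  expect_true(is.finite(zr$fc) && zr$fc > 1)
})

test_that("a planted log2 fold change of 1.5 is recovered within its CI", {
  spec <- simulation_spec(n_genes = 200, seed = 31)
  sim <- simulate_dataset(spec)
  truth <- sim$truth$l2_transcript_fc[, "30C"]
  fc <- fold_changes(sim$transcripts, "20C", "30C", test = "none")
  est <- log2(fc$fc[match(names(truth), fc$gene_id)])
  ## replicate noise sdlog 0.2 at 3 reps -> per-gene log2 fc sd ~ 0.24
  expect_gt(cor(est, truth), 0.95)
  expect_lt(mean(abs(est - truth)), 0.35)
  ## specifically, near-1.5 planted genes should estimate near 1.5
  sel <- which(abs(truth - 1.5) < 0.25)
  expect_gt(length(sel), 2)
  expect_lt(abs(mean(est[sel] - truth[sel])), 0.3)
})

test_that("DET and DEP threshold logic follows the stated gates", {
  expect_true(call_dets(3, 0.01))
  expect_false(call_dets(3, 0.2))
  expect_false(call_dets(1.5, 0.001))   # fold-change gate
  expect_true(call_dets(0.4, 0.01))     # down-regulation side
  expect_true(call_deps(0.005))
  expect_false(call_deps(0.05))
})

test_that("the protein t-test degenerates to p = 1 on identical groups and separates clear shifts", {
  v <- rbind(same = c(10, 10, 10, 10, 10, 10, 10, 10),
             shift = c(10, 10.1, 9.9, 10, 20, 20.1, 19.9, 20))
  tab <- protein_fixture(v)
  fc <- fold_changes(tab, "20C", "30C", test = "t_raw")
  expect_equal(fc$p[fc$gene_id == "same"], 1)
  expect_lt(fc$p[fc$gene_id == "shift"], 1e-6)
  expect_true(call_deps(fc$p[fc$gene_id == "shift"]))
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.007), 0.007)
  set.seed(8)
  p <- runif(200)^2
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p))
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("expression tables round-trip through the two-line-header TSV", {
  spec <- simulation_spec(n_genes = 40, seed = 3)
  sim <- simulate_dataset(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(sim$proteins, path)
  back <- read_expression(path)
  expect_equal(back$values, sim$proteins$values)
  expect_equal(back$samples, sim$proteins$samples)
})

test_that("build_fc_table combines transcript and protein calls consistently", {
  spec <- simulation_spec(n_genes = 250, seed = 17)
  sim <- simulate_dataset(spec)
  fc <- build_fc_table(sim$transcripts,
                       filter_and_impute_protein(sim$proteins),
                       "20C", "30C")
  expect_true(all(fc$transcript_q >= fc$transcript_p, na.rm = TRUE))
  expect_identical(fc$det,
                   call_dets(fc$transcript_fc, fc$transcript_q))
  expect_identical(fc$dep, call_deps(fc$protein_p))
  expect_true(all(fc$transcript_fc > 0) && all(fc$protein_fc > 0))
})
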