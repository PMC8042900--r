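test_that("correlation screen: perfect, null and constant features behave", {
  set.seed(12)
  n <- 2000
  x <- cbind(self = rnorm(n), noise = rnorm(n), flat = rep(1, n))
  y <- x[, "self"]
  tab <- correlation_screen(x, y)
  expect_equal(tab$r[tab$feature == "self"], 1, tolerance = 1e-12)
  expect_lt(tab$p[tab$feature == "self"], 1e-100)
  expect_equal(tab$star[tab$feature == "self"], "**")
  ## independent standard normals at n = 2000
  expect_lt(abs(tab$r[tab$feature == "noise"]), 0.08)
  expect_equal(tab$r[tab$feature == "flat"], 0)
  expect_equal(tab$p[tab$feature == "flat"], 1)
  expect_true(tab$constant[tab$feature == "flat"])
  expect_error(correlation_screen(x[1:2, ], y[1:2]), "at least 3")
})

test_that("a planted correlation of 0.48 is estimated within 0.05 at n = 3000", {
  set.seed(13)
  n <- 3000
  r_target <- 0.48
  x <- cbind(aag = rnorm(n))
  y <- r_target * x[, 1] + sqrt(1 - r_target^2) * rnorm(n)
  tab <- correlation_screen(x, y)
  expect_lt(abs(tab$r[1] - r_target), 0.05)
  expect_equal(tab$star[1], "**")
})

test_that("misaligned gene sets are a hard error", {
  x <- matrix(rnorm(30), 10, dimnames = list(paste0("g", 1:10), c("a", "b", "c")))
  y <- setNames(rnorm(10), paste0("h", 1:10))
  expect_error(correlation_screen(x, y), "does not match")
})

test_that("OLS matches closed forms and the normal-equation oracle", {
  x <- matrix(seq(0.1, 2, length.out = 20), dimnames = list(NULL, "x"))
  fit <- fit_ols(x, 2 * x[, 1])
  expect_equal(fit$estimate[fit$term == "x"], 2, tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "(Intercept)"], 0, tolerance = 1e-10)

  ## orthonormal design: slopes equal X'y
  q <- qr.Q(qr(matrix(rnorm(100 * 3), 100)))
  colnames(q) <- c("u1", "u2", "u3")
  y <- rnorm(100)
  fit2 <- fit_ols(q, y)
  ## with an intercept, centered-orthonormal columns still give X'y up to
  ## the projection on 1; use exact normal equations as the oracle instead
  X <- cbind(1, q)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit2$estimate, as.numeric(beta), tolerance = 1e-8)

  set.seed(14)
  Xr <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  yr <- rnorm(50)
  fit3 <- fit_ols(Xr, yr)
  Xi <- cbind(1, Xr)
  expect_equal(fit3$estimate,
               as.numeric(solve(t(Xi) %*% Xi, t(Xi) %*% yr)),
               tolerance = 1e-8)
  ## and the p-values are two-tailed t
  sigma2 <- sum((yr - Xi %*% fit3$estimate)^2) / (50 - 5)
  se <- sqrt(diag(solve(t(Xi) %*% Xi)) * sigma2)
  expect_equal(fit3$se, as.numeric(se), tolerance = 1e-8)
})

test_that("rank-deficient OLS designs are rejected naming the collinear column", {
  x <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(x, rnorm(10)), "collinear.*b")
})

test_that("elastic net: no-penalty limit matches OLS, heavy penalty shrinks to zero", {
  set.seed(15)
  n <- 300
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + x[, 1] - 0.5 * x[, 2] + rnorm(n, 0, 0.3)
  en0 <- fit_elastic_net(x, y, alpha = 0.5, seed = 1,
                         lambda = c(1, 0.1, 0.001, 1e-5, 0))
  ols <- fit_ols(x, y)
  cf <- en0$coefficients
  fit_at_0 <- coef(en0$cv$glmnet.fit, s = 0, exact = FALSE)
  expect_equal(as.numeric(fit_at_0),
               ols$estimate[match(rownames(fit_at_0), ols$term)],
               tolerance = 1e-4)
  big <- fit_elastic_net(x, y, alpha = 0.5, seed = 1, lambda = c(1e4, 5e3))
  expect_true(all(big$coefficients$estimate[-1] == 0))
})

test_that("single-predictor lasso equals the soft-threshold closed form", {
  set.seed(16)
  n <- 400
  x <- matrix(scale(rnorm(n)) * sqrt(n / (n - 1)), dimnames = list(NULL, "x"))
  ## x now has mean 0 and 1/n * sum(x^2) = 1, glmnet's internal scaling
  y <- 0.7 * x[, 1] + rnorm(n, 0, 0.5)
  lam <- 0.25
  fit <- glmnet::glmnet(cbind(x, 0), y, alpha = 1, lambda = lam,
                        standardize = FALSE, intercept = TRUE)
  rho <- mean(x[, 1] * (y - mean(y)))
  soft <- sign(rho) * max(abs(rho) - lam, 0)
  expect_equal(as.numeric(coef(fit)[2]), soft, tolerance = 1e-3)
})

test_that("verification report covers the union of selections and flags sign conflicts", {
  set.seed(17)
  n <- 400
  x <- cbind(up = rnorm(n), down = rnorm(n), junk = rnorm(n))
  y <- x[, 1] - x[, 2] + rnorm(n, 0, 0.4)
  m <- mars(x, y, max_terms = 11)
  sel <- m$feature_names[m$selected_features]
  ols <- fit_ols(x, y, features = sel)
  en <- fit_elastic_net(x, y, seed = 2)
  vr <- verification_report(m, ols, en, x, y)
  expect_true(all(c("up", "down") %in% vr$feature))
  expect_true(all(vr$agree[vr$feature %in% c("up", "down")]))
  expect_equal(vr$mars_sign[vr$feature == "up"], 1L)
  expect_equal(vr$mars_sign[vr$feature == "down"], -1L)
})

test_that("associate() produces a coherent stage result on simulated data", {
  spec <- simulation_spec(n_genes = 500, seed = 23)
  sim <- simulate_dataset(spec)
  fc <- build_fc_table(sim$transcripts,
                       filter_and_impute_protein(sim$proteins), "20C", "30C")
  fm <- build_feature_matrix(sim$catalog,
                             setNames(fc$transcript_fc, fc$gene_id))
  res <- associate(fm, fc, max_terms = 13, seed = 23)
  expect_s3_class(res$model, "mars_model")
  expect_equal(res$contribution$total_explained_pct +
                 res$contribution$unexplained_pct, 100)
  expect_true(all(c("transcript_fc", "codon:AAG") %in%
                    res$correlation$feature))
  expect_true(is.finite(res$enet$lambda_min))
  ## planted positive effects surface with positive correlation
  expect_gt(res$correlation$r[res$correlation$feature == "codon:AAG"], 0)
})
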