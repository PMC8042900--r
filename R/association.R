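## association: correlation screen, OLS and elastic-net verification, and the
## high-level stage combining them with the MARS contribution decomposition.

#' Pearson correlation screen of features against protein fold change
#'
#' Two-tailed t-based p-value per feature; significance stars at 0.05 (`*`)
#' and 0.01 (`**`).  Constant features are reported with `r = 0`, `p = 1`
#' and a flag rather than `NA`.
#'
#' @param features A `feature_matrix` (or plain numeric matrix).
#' @param response Per-gene protein fold change, aligned with the feature
#'   rows (names checked when present).
#' @param log2_fc Correlate on `log2` of the fold-change variables (the
#'   response and `transcript_fc`) instead of the raw ratios.
#' @return data.frame(feature, category, r, p, star, constant).
#' @export
correlation_screen <- function(features, response, log2_fc = FALSE) {
  values <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  registry <- if (inherits(features, "feature_matrix")) features$registry
              else data.frame(name = colnames(values), category = "feature")
  if (nrow(values) < 3L) stopf("need at least 3 genes for the screen")
  if (!is.null(names(response)) && !is.null(rownames(values))) {
    if (!setequal(names(response), rownames(values)))
      stopf("response gene set does not match feature rows")
    response <- response[rownames(values)]
  } else if (length(response) != nrow(values))
    stopf("response length does not match feature rows")
  y <- if (log2_fc) log2(response) else response
  res <- lapply(seq_len(ncol(values)), function(j) {
    xj <- values[, j]
    if (log2_fc && colnames(values)[j] == "transcript_fc") xj <- log2(xj)
    if (sd(xj) == 0 || sd(y) == 0)
      return(data.frame(r = 0, p = 1, constant = TRUE))
    ct <- cor.test(xj, y, method = "pearson", alternative = "two.sided")
    data.frame(r = unname(ct$estimate), p = ct$p.value, constant = FALSE)
  })
  res <- do.call(rbind, res)
  data.frame(feature = colnames(values),
             category = registry$category[match(colnames(values), registry$name)],
             r = res$r, p = res$p,
             star = ifelse(res$p < 0.01, "**", ifelse(res$p < 0.05, "*", "")),
             constant = res$constant,
             stringsAsFactors = FALSE)
}

#' Ordinary least squares with standard errors and p-values
#'
#' @param x Numeric predictor matrix.
#' @param y Response.
#' @param features Optional subset of column names to fit on.
#' @return data.frame(term, estimate, se, t, p) including the intercept.
#' @export
fit_ols <- function(x, y, features = NULL) {
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  if (nrow(x) <= ncol(x))
    stopf("need n > p for OLS (n = %d, p = %d); pass a feature subset",
          nrow(x), ncol(x))
  X <- cbind(`(Intercept)` = 1, x)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stopf("rank-deficient design; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  dfres <- nrow(X) - ncol(X)
  XtXinv <- chol2inv(qr.R(q))
  se <- sqrt(diag(XtXinv) * rss / dfres)[order(q$pivot)]
  est <- coef(fit)
  tval <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t = unname(tval), p = unname(2 * pt(-abs(tval), dfres)),
             stringsAsFactors = FALSE)
}

#' Elastic net with cross-validated lambda
#'
#' Thin, seeded wrapper around [glmnet::cv.glmnet()]: predictors are
#' standardized internally and coefficients returned on the original scale;
#' lambda is chosen by k-fold CV minimizing mean squared error.
#'
#' @param x Predictor matrix.
#' @param y Response.
#' @param alpha L1 mixing parameter in \[0, 1\] (default 0.5).
#' @param nfolds CV folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @param lambda Optional lambda path.
#' @return List with `coefficients` (data.frame term/estimate at
#'   `lambda_min`), `lambda_min`, `cv` (the `cv.glmnet` object) and
#'   `foldid`.
#' @export
fit_elastic_net <- function(x, y, alpha = 0.5, nfolds = 10L, seed = 1L,
                            lambda = NULL) {
  x <- as.matrix(x)
  set.seed(substream_seed(seed, "enet_folds"))
  foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                          lambda = lambda, standardize = TRUE)
  cf <- as.matrix(coef(cv, s = "lambda.min"))
  list(coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                                 row.names = NULL, stringsAsFactors = FALSE),
       lambda_min = cv$lambda.min, cv = cv, foldid = foldid)
}

#' Sign/selection agreement of MARS, OLS and elastic net
#'
#' For every feature selected by any of the three methods, compares the
#' direction of its association: MARS direction is the sign of the
#' correlation between the feature and the model's fitted values, OLS and
#' elastic net use their coefficient signs (zero coefficients count as not
#' selected).
#'
#' @param model Pruned `mars_model`.
#' @param ols [fit_ols()] table fitted on the MARS-selected features.
#' @param enet [fit_elastic_net()] result.
#' @param x,y The data both were fitted on.
#' @return data.frame(feature, mars_selected, mars_sign, ols_sign,
#'   enet_sign, agree).
#' @export
verification_report <- function(model, ols, enet, x, y) {
  x <- as.matrix(x)
  sel_mars <- model$feature_names[model$selected_features]
  ols_cf <- ols[ols$term != "(Intercept)", ]
  enet_cf <- enet$coefficients[enet$coefficients$term != "(Intercept)", ]
  enet_sel <- enet_cf$term[enet_cf$estimate != 0]
  union_feats <- sort(unique(c(sel_mars, ols_cf$term, enet_sel)))
  fitted <- predict(model, x)
  sgn <- function(v) ifelse(is.na(v) | v == 0, 0L, ifelse(v > 0, 1L, -1L))
  mars_sign <- vapply(union_feats, function(f) {
    if (!f %in% sel_mars) return(0L)
    sgn(suppressWarnings(cor(x[, f], fitted)))
  }, 0L)
  ols_sign <- sgn(ols_cf$estimate[match(union_feats, ols_cf$term)])
  enet_sign <- sgn(enet_cf$estimate[match(union_feats, enet_cf$term)])
  nonzero <- cbind(mars_sign, ols_sign, enet_sign)
  agree <- apply(nonzero, 1, function(r) {
    r <- r[r != 0]
    length(r) == 0 || all(r == r[1])
  })
  data.frame(feature = union_feats,
             mars_selected = union_feats %in% sel_mars,
             mars_sign = unname(mars_sign), ols_sign = unname(ols_sign),
             enet_sign = unname(enet_sign), agree = unname(agree),
             stringsAsFactors = FALSE)
}

#' Full association stage for one contrast
#'
#' Correlation screen on raw fold changes, MARS fit with contribution
#' decomposition, and OLS + elastic-net verification.  The regression is run
#' on log2 fold changes (response and `transcript_fc` feature) so up- and
#' down-regulation are treated symmetrically.
#'
#' @param features A `feature_matrix` whose rows align with `fc_table`.
#' @param fc_table Output of [build_fc_table()] for the contrast.
#' @param max_terms,degree,thresh,max_knots Passed to [mars()].
#' @param seed Seed for the elastic-net fold assignment.
#' @param log2_regression Regress on log2 fold changes (default `TRUE`).
#' @return List with `correlation`, `model`, `importance`, `contribution`,
#'   `ols`, `enet`, `verification`.
#' @export
associate <- function(features, fc_table, max_terms = 21L, degree = 1L,
                      thresh = 0.001, max_knots = 50L, seed = 1L,
                      log2_regression = TRUE) {
  stopifnot(inherits(features, "feature_matrix"))
  common <- intersect(rownames(features$values), fc_table$gene_id)
  if (!length(common)) stopf("no genes shared between features and fold changes")
  vals <- features$values[common, , drop = FALSE]
  fc <- fc_table[match(common, fc_table$gene_id), ]
  response <- setNames(fc$protein_fc, common)

  correlation <- correlation_screen(
    structure(list(values = vals, registry = features$registry),
              class = "feature_matrix"),
    response, log2_fc = FALSE)

  X <- vals
  y <- response
  if (log2_regression) {
    y <- log2(response)
    if ("transcript_fc" %in% colnames(X))
      X[, "transcript_fc"] <- log2(X[, "transcript_fc"])
  }
  keep <- apply(X, 2, sd) > 0
  Xr <- X[, keep, drop = FALSE]
  model <- mars(Xr, y, max_terms = max_terms, degree = degree,
                thresh = thresh, max_knots = max_knots)
  importance <- variable_importance(model)
  contribution <- contribution_report(model, importance, features$registry)
  sel <- model$feature_names[model$selected_features]
  ols <- if (length(sel)) fit_ols(Xr, y, features = sel)
         else data.frame(term = character(0), estimate = numeric(0),
                         se = numeric(0), t = numeric(0), p = numeric(0))
  enet <- fit_elastic_net(Xr, y, seed = seed)
  verification <- verification_report(model, ols, enet, Xr, y)
  list(correlation = correlation, model = model, importance = importance,
       contribution = contribution, ols = ols, enet = enet,
       verification = verification)
}
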