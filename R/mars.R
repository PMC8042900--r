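## Multivariate adaptive regression splines: greedy forward selection of
## reflected hinge pairs max(0, x - t) / max(0, t - x), backward elimination,
## and GCV-based model-size selection, with the pruning trace retained for
## variance-decomposition importance.
##
## The forward step exploits that, with the intercept (or the parent basis
## function) in the model, adding the reflected pair {h+, h-} spans the same
## space as adding {parent * x, h+}; each candidate is then a two-predictor
## least-squares problem in the residual space, solved in closed form for
## every knot of a feature at once.

term_features <- function(term) unique(term$factors$feature)

term_label <- function(term, feature_names) {
  if (nrow(term$factors) == 0L) return("(Intercept)")
  lab <- vapply(seq_len(nrow(term$factors)), function(i) {
    f <- term$factors[i, ]
    nm <- feature_names[f$feature]
    if (f$dir == 0L) nm
    else if (f$dir > 0L) sprintf("h(%s-%g)", nm, f$knot)
    else sprintf("h(%g-%s)", f$knot, nm)
  }, "")
  paste(lab, collapse = "*")
}

term_column <- function(term, x) {
  col <- rep(1, nrow(x))
  for (i in seq_len(nrow(term$factors))) {
    f <- term$factors[i, ]
    xi <- x[, f$feature]
    col <- col * if (f$dir == 0L) xi
                 else if (f$dir > 0L) pmax(0, xi - f$knot)
                 else pmax(0, f$knot - xi)
  }
  col
}

gcv_value <- function(rss, n, k, penalty) {
  C <- k + penalty * (k - 1) / 2
  d <- 1 - C / n
  if (d <= 0) return(Inf)
  (rss / n) / d^2
}

rss_of <- function(B, y) sum(lm.fit(B, y)$residuals^2)

#' MARS forward pass
#'
#' Greedily adds the reflected hinge pair (parent basis times
#' `max(0, x - t)` and `max(0, t - x)`) that most reduces the residual sum
#' of squares, until `max_terms` basis functions are reached or the relative
#' RSS improvement falls below `thresh`.  Knots are observed data values;
#' when a feature has more than `max_knots` distinct values the candidate
#' set is thinned to evenly spaced order statistics.  Ties are broken toward
#' the lowest feature index, then the smallest knot.
#'
#' @param x Numeric matrix of predictors (no missing values).
#' @param y Numeric response.
#' @param max_terms Maximum number of basis functions including the
#'   intercept (default 21).
#' @param degree Maximum interaction order; 1 (default) fits an additive
#'   model, which keeps the contribution decomposition well defined.
#' @param thresh Stop when the step's RSS reduction is below `thresh` times
#'   the total sum of squares (default 0.001).
#' @param max_knots Knot-candidate budget per feature (default 50; use `Inf`
#'   to consider every distinct value).
#' @param linear_only Replace hinge candidates by plain linear terms, making
#'   the forward pass a greedy linear regression (used for verification).
#' @param penalty GCV penalty per knot recorded on the model (default 2 for
#'   additive fits, 3 otherwise).
#' @return An unpruned `mars_model`.
#' @export
mars_forward <- function(x, y, max_terms = 21L, degree = 1L, thresh = 0.001,
                         max_knots = 50L, linear_only = FALSE, penalty = NULL) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  stopifnot(n == length(y), n > 2, !anyNA(x), !anyNA(y))
  if (n <= max_terms)
    stopf("need more observations (%d) than max_terms (%d)", n, max_terms)
  penalty <- penalty %||% if (degree == 1L) 2 else 3

  knots_list <- lapply(seq_len(p), function(j) {
    v <- sort(unique(x[, j]))
    if (length(v) > max_knots)
      v <- v[unique(round(seq(1, length(v), length.out = max_knots)))]
    v
  })

  terms <- list(list(factors = data.frame(feature = integer(0), knot = numeric(0),
                                          dir = integer(0))))
  B <- matrix(1, n, 1)
  tss <- sum((y - mean(y))^2)
  skipped <- 0L
  forward_rss <- numeric(0)

  repeat {
    k <- ncol(B)
    if (k + (if (linear_only) 1L else 2L) > max_terms) break
    Q <- qr.Q(qr(B))
    yr <- y - Q %*% crossprod(Q, y)
    rss <- sum(yr^2)
    if (tss <= 0 || rss < 1e-12 * max(tss, 1)) break

    best <- list(red = 0, parent = NA, feature = NA, knot = NA)
    parent_idx <- if (degree == 1L) 1L
      else which(vapply(terms, function(t) nrow(t$factors), 0L) < degree)
    for (pi in parent_idx) {
      bp <- B[, pi]
      used <- term_features(terms[[pi]])
      for (j in seq_len(p)) {
        if (j %in% used) next
        xj <- x[, j]
        xp <- bp * xj
        xpr <- xp - Q %*% crossprod(Q, xp)
        a <- sum(xpr^2); u <- sum(xpr * yr)
        tolA <- 1e-10 * max(sum(xp^2), 1e-300)
        if (linear_only) {
          red <- if (a > tolA) u^2 / a else 0
          if (red > best$red)
            best <- list(red = red, parent = pi, feature = j, knot = NA)
          next
        }
        kn <- knots_list[[j]]
        if (pi != 1L) {
          sup <- xj[bp > 0]
          if (!length(sup)) next
          kn <- kn[kn >= min(sup) & kn <= max(sup)]
          if (!length(kn)) next
        }
        H <- pmax(outer(xj, kn, "-"), 0)  # matrix first: pmax keeps its dim
        if (pi != 1L) H <- H * bp
        Hr <- H - Q %*% crossprod(Q, H)
        bv <- colSums(Hr * as.vector(xpr))
        cv <- colSums(Hr * Hr)
        vv <- colSums(Hr * as.vector(yr))
        tolC <- 1e-10 * pmax(colSums(H * H), 1e-300)
        det <- a * cv - bv^2
        red_x <- if (a > tolA) u^2 / a else 0
        red_h <- ifelse(cv > tolC, vv^2 / cv, 0)
        red <- pmax(red_x, red_h)
        full <- a > tolA & cv > tolC & det > 1e-10 * a * cv
        red[full] <- ((cv * u^2 - 2 * bv * u * vv + a * vv^2)[full]) / det[full]
        m <- which.max(red)
        if (length(m) && red[m] > best$red)
          best <- list(red = red[m], parent = pi, feature = j, knot = kn[m])
      }
    }
    if (!is.finite(best$red) || best$red <= thresh * tss) break

    pf <- terms[[best$parent]]$factors
    mk_term <- function(dir) {
      list(factors = rbind(pf, data.frame(feature = best$feature,
                                          knot = if (linear_only) NA_real_ else best$knot,
                                          dir = dir)))
    }
    new_terms <- if (linear_only) list(mk_term(0L))
                 else list(mk_term(1L), mk_term(-1L))
    for (tm in new_terms) {
      col <- term_column(tm, x)
      Btry <- cbind(B, col)
      if (qr(Btry)$rank > qr(B)$rank) {
        B <- Btry; terms <- c(terms, list(tm))
      } else skipped <- skipped + 1L
    }
    forward_rss <- c(forward_rss, sum(lm.fit(B, y)$residuals^2))
  }

  fit <- lm.fit(B, y)
  rss <- sum(fit$residuals^2)
  model <- structure(list(
    terms = terms, B = B, coefficients = unname(coef(fit)),
    rss = rss, r_squared = if (tss > 0) 1 - rss / tss else 0,
    gcv = gcv_value(rss, n, ncol(B), penalty),
    n = n, penalty = penalty, degree = degree, forward_rss = forward_rss,
    feature_names = colnames(x), x = x, y = y,
    pruned = FALSE, skipped_collinear = skipped,
    selected_features = sort(unique(unlist(lapply(terms, term_features))))),
    class = "mars_model")
  model
}

#' MARS backward pass with GCV model selection
#'
#' Starting from the unpruned basis, repeatedly removes the term (never the
#' intercept) whose removal least increases the residual sum of squares,
#' then keeps the subset minimizing the generalized cross-validation score
#' `GCV = (RSS/n) / (1 - C/n)^2` with effective parameters
#' `C = k + penalty * (k - 1) / 2`.  Sizes with `1 - C/n <= 0` are
#' inadmissible and skipped with a warning.  The full pruning trace is kept
#' on the model for [variable_importance()].
#'
#' @param model Unpruned `mars_model` from [mars_forward()].
#' @param penalty GCV penalty (default: the model's, i.e. 2 for additive).
#' @return The pruned `mars_model` with a `trace` element.
#' @export
mars_prune <- function(model, penalty = NULL) {
  stopifnot(inherits(model, "mars_model"))
  penalty <- penalty %||% model$penalty
  B <- model$B; y <- model$y; n <- model$n
  k0 <- ncol(B)
  subset <- seq_len(k0)
  trace <- list(list(size = k0, terms = subset, rss = model$rss))
  while (length(subset) > 1L) {
    cands <- subset[subset != 1L]
    rss_c <- vapply(cands, function(d)
      rss_of(B[, setdiff(subset, d), drop = FALSE], y), numeric(1))
    drop <- cands[which.min(rss_c)]
    subset <- setdiff(subset, drop)
    trace <- c(trace, list(list(size = length(subset), terms = subset,
                                rss = min(rss_c))))
  }
  gcvs <- vapply(trace, function(tr) gcv_value(tr$rss, n, tr$size, penalty),
                 numeric(1))
  if (any(is.infinite(gcvs)))
    warnf("%d candidate sizes inadmissible for GCV (1 - C/n <= 0), skipped",
          sum(is.infinite(gcvs)))
  for (i in seq_along(trace)) trace[[i]]$gcv <- gcvs[i]
  ## trace runs from largest to smallest; prefer the smaller model on ties
  sel <- length(gcvs) - which.min(rev(gcvs)) + 1L
  keep <- trace[[sel]]$terms
  fit <- lm.fit(B[, keep, drop = FALSE], y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  out <- model
  out$terms <- model$terms[keep]
  out$B <- B[, keep, drop = FALSE]
  out$coefficients <- unname(coef(fit))
  out$rss <- rss
  out$r_squared <- if (tss > 0) 1 - rss / tss else 0
  out$gcv <- gcvs[sel]
  out$penalty <- penalty
  out$pruned <- TRUE
  out$trace <- trace
  out$unpruned_terms <- model$terms
  out$selected_features <- sort(unique(unlist(lapply(out$terms, term_features))))
  out
}

#' Fit a MARS model (forward pass then GCV pruning)
#'
#' @inheritParams mars_forward
#' @param ... Passed to [mars_forward()].
#' @return A pruned `mars_model`.
#' @export
mars <- function(x, y, max_terms = 21L, degree = 1L, ...) {
  mars_prune(mars_forward(x, y, max_terms = max_terms, degree = degree, ...))
}

#' @export
print.mars_model <- function(x, ...) {
  cat(sprintf("MARS model (%s): %d terms, R^2 = %.3f, GCV = %.4g\n",
              if (x$pruned) "pruned" else "unpruned",
              length(x$terms), x$r_squared, x$gcv))
  labs <- vapply(x$terms, term_label, "", feature_names = x$feature_names)
  for (i in seq_along(labs))
    cat(sprintf("  %+.4g * %s\n", x$coefficients[i], labs[i]))
  invisible(x)
}

#' @export
predict.mars_model <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  nd <- nd[, object$feature_names, drop = FALSE]
  B <- vapply(object$terms, term_column, numeric(nrow(nd)), x = nd)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1L)
  as.numeric(B %*% object$coefficients)
}

#' Per-feature importance from the pruning trace
#'
#' For every feature: `nsubsets` counts the pruning-path subsets (of size up
#' to the selected model) whose terms use the feature; `rss_importance`
#' sums, over consecutive subset sizes, the RSS decrease contributed by the
#' term that re-enters between the two subsets, attributed to that term's
#' feature(s); `gcv_importance` does the same with GCV decreases (clamped at
#' zero).  Both are scaled so the top feature scores 100.
#'
#' @param model Pruned `mars_model` (the trace must be present).
#' @return data.frame(feature, nsubsets, rss_importance, gcv_importance,
#'   normalized_importance), one row per input feature.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "mars_model"))
  if (is.null(model$trace)) stopf("model has no pruning trace; run mars_prune()")
  fn <- model$feature_names
  p <- length(fn)
  nsub <- numeric(p); rssi <- numeric(p); gcvi <- numeric(p)
  sel_size <- length(model$terms)
  path <- Filter(function(tr) tr$size <= sel_size, model$trace)
  path <- path[order(vapply(path, `[[`, 0, "size"))]
  all_terms <- model$unpruned_terms
  feats_of_subset <- function(tr)
    unique(unlist(lapply(all_terms[tr$terms], term_features)))
  for (tr in path) {
    f <- feats_of_subset(tr)
    nsub[f] <- nsub[f] + 1
  }
  if (length(path) > 1L) {
    for (i in 2:length(path)) {
      added <- setdiff(path[[i]]$terms, path[[i - 1L]]$terms)
      f <- unique(unlist(lapply(all_terms[added], term_features)))
      if (!length(f)) next
      d_rss <- max(path[[i - 1L]]$rss - path[[i]]$rss, 0)
      d_gcv <- max(path[[i - 1L]]$gcv - path[[i]]$gcv, 0)
      rssi[f] <- rssi[f] + d_rss
      gcvi[f] <- gcvi[f] + d_gcv
    }
  }
  ## divide first so the top feature is exactly 100 (no ulp overshoot)
  norm100 <- function(v) if (max(v) > 0) v / max(v) * 100 else v
  data.frame(feature = fn, nsubsets = as.integer(nsub),
             rss_importance = norm100(rssi), gcv_importance = norm100(gcvi),
             normalized_importance = norm100(rssi),
             stringsAsFactors = FALSE)
}

#' Contribution decomposition of explained variance
#'
#' Each feature's contribution is its share of RSS-based importance times
#' the model's training R-squared, in percent; category contributions sum
#' member features; the remainder to 100 is the unexplained part.
#'
#' @param model Pruned `mars_model`.
#' @param importance Output of [variable_importance()] (computed if `NULL`).
#' @param category_map Named character vector feature -> category, or a
#'   registry data.frame with `name` and `category` columns.
#' @return A `contribution_report`: list with `features` and `categories`
#'   data.frames, `total_explained_pct`, `unexplained_pct`, `r_squared`.
#' @export
contribution_report <- function(model, importance = NULL, category_map = NULL) {
  importance <- importance %||% variable_importance(model)
  if (is.data.frame(category_map))
    category_map <- setNames(category_map$category, category_map$name)
  if (is.null(category_map))
    category_map <- setNames(rep("feature", nrow(importance)), importance$feature)
  miss <- setdiff(model$selected_features, seq_along(model$feature_names))
  stopifnot(length(miss) == 0)
  sel_names <- model$feature_names[model$selected_features]
  if (!all(sel_names %in% names(category_map)))
    stopf("selected features without a category: %s",
          paste(setdiff(sel_names, names(category_map)), collapse = ", "))
  tot_imp <- sum(importance$rss_importance)
  share <- if (tot_imp > 0) importance$rss_importance / tot_imp
           else rep(0, nrow(importance))
  expl <- model$r_squared * 100
  feats <- data.frame(feature = importance$feature,
                      category = unname(category_map[importance$feature]),
                      contribution_pct = share * expl,
                      stringsAsFactors = FALSE)
  cats <- aggregate(contribution_pct ~ category, feats, sum)
  structure(list(features = feats[order(-feats$contribution_pct), ],
                 categories = cats[order(-cats$contribution_pct), ],
                 total_explained_pct = expl,
                 unexplained_pct = 100 - expl,
                 r_squared = model$r_squared),
            class = "contribution_report")
}

#' @export
print.contribution_report <- function(x, ...) {
  cat(sprintf("contribution_report: %.1f%% explained, %.1f%% unexplained\n",
              x$total_explained_pct, x$unexplained_pct))
  top <- head(x$features[x$features$contribution_pct > 0, ], 10)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-18s %-12s %6.2f%%\n", top$feature[i], top$category[i],
                top$contribution_pct[i]))
  invisible(x)
}

#' Serialize a MARS model to JSON
#'
#' @param model A `mars_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mars_json <- function(model, path) {
  terms <- lapply(model$terms, function(tm) {
    f <- tm$factors
    list(label = term_label(tm, model$feature_names),
         features = model$feature_names[f$feature],
         knots = f$knot, dirs = f$dir)
  })
  jsonlite::write_json(
    list(terms = terms, coefficients = model$coefficients,
         gcv = model$gcv, r_squared = model$r_squared, n_obs = model$n,
         penalty = model$penalty, degree = model$degree,
         selected_features = model$feature_names[model$selected_features]),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
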