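## group_stats: AAG-frequency (or any feature) distributions across gene
## groups — whole genome, detected proteome, up- and down-regulated — with
## tie-corrected Kruskal-Wallis omnibus tests.

#' Assign genes to regulation groups
#'
#' Mirrors the boxplot groupings used for codon-frequency comparisons:
#' `up` = protein fold change above `up_fc` and significant, `down` = below
#' `down_fc` and significant, `identified` = every gene in the fold-change
#' table, `whole_genome` = every gene in the catalog (when supplied).
#'
#' @param fc_table Output of [build_fc_table()].
#' @param up_fc,down_fc Fold-change cutoffs (defaults 1.2 and 0.83).
#' @param sig_rule `"q"` (BH-adjusted protein p, default) or `"p"`.
#' @param sig_cut Significance cutoff (default 0.05).
#' @param whole_genome Optional character vector of all catalog gene ids.
#' @return A `gene_group_set`: list of gene-id vectors plus the thresholds
#'   used.
#' @export
assign_groups <- function(fc_table, up_fc = 1.2, down_fc = 0.83,
                          sig_rule = c("q", "p"), sig_cut = 0.05,
                          whole_genome = NULL) {
  sig_rule <- match.arg(sig_rule)
  if (up_fc <= down_fc) stopf("up_fc must exceed down_fc")
  sig <- if (sig_rule == "q") fc_table$protein_q else fc_table$protein_p
  sig <- !is.na(sig) & sig < sig_cut
  up <- fc_table$gene_id[sig & fc_table$protein_fc > up_fc]
  down <- fc_table$gene_id[sig & fc_table$protein_fc < down_fc]
  groups <- list(identified = fc_table$gene_id, up = up, down = down)
  if (!is.null(whole_genome))
    groups <- c(list(whole_genome = whole_genome), groups)
  structure(list(groups = groups,
                 thresholds = list(up_fc = up_fc, down_fc = down_fc,
                                   sig_rule = sig_rule, sig_cut = sig_cut)),
            class = "gene_group_set")
}

#' @export
print.gene_group_set <- function(x, ...) {
  cat("gene_group_set:",
      paste(sprintf("%s=%d", names(x$groups), lengths(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

## Tie-corrected H statistic from pooled values and a grouping factor.
kw_statistic <- function(values, g) {
  N <- length(values)
  r <- rank(values)
  sums <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(c(H = 0, C = 1))
  c(H = H / C, C = C)
}

#' Kruskal-Wallis test across groups of values
#'
#' Mid-ranks for ties, the tie correction `1 - sum(t^3 - t) / (N^3 - N)`,
#' and a chi-square p-value on k-1 degrees of freedom.  When any group has
#' fewer than 5 values (and `permutation = "auto"`), a seeded permutation
#' p-value is added, since the chi-square approximation is then unreliable.
#'
#' @param groups List of numeric vectors, one per group (at least 2 groups,
#'   no group empty, total N at least 3).
#' @param permutation `"auto"` (default), `"never"` or `"always"`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation draw.
#' @return A `kw_test` list: `H`, `df`, `p`, `tie_correction`, `method`,
#'   and `p_perm` when computed.
#' @export
kruskal_wallis <- function(groups, permutation = c("auto", "never", "always"),
                           n_perm = 10000L, seed = 1L) {
  permutation <- match.arg(permutation)
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stopf("empty group")
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3L) stopf("need at least 3 values in total")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  st <- kw_statistic(values, g)
  H <- unname(st["H"])
  ## cross-check against the reference implementation
  ref <- suppressWarnings(kruskal.test(values, g))
  if (is.finite(ref$statistic) && abs(ref$statistic - H) > 1e-8 * max(1, H))
    warnf("rank-formula H (%.6f) differs from kruskal.test (%.6f)",
          H, ref$statistic)
  p <- pchisq(H, df = k - 1, lower.tail = FALSE)
  out <- list(H = H, df = k - 1L, p = p,
              tie_correction = unname(st["C"]),
              method = "chi-square")
  if (permutation == "always" ||
      (permutation == "auto" && any(lengths(groups) < 5L))) {
    out$p_perm <- kw_permutation_p(values, g, n_perm, seed)
    out$method <- "chi-square + permutation"
  }
  structure(out, class = "kw_test")
}

## Permutation p-value for H; ranks are fixed, group labels are shuffled.
kw_permutation_p <- function(values, g, n_perm, seed) {
  set.seed(substream_seed(seed, "kw_perm"))
  N <- length(values)
  r <- rank(values)
  ns <- tabulate(g)
  obs <- kw_h_from_ranks(r, g, ns, N)
  ge <- 0L
  for (i in seq_len(n_perm)) {
    perm <- kw_h_from_ranks(r[sample.int(N)], g, ns, N)
    if (perm >= obs - 1e-12) ge <- ge + 1L
  }
  (ge + 1) / (n_perm + 1)
}

## Uncorrected H from ranks (the tie correction is a constant under
## permutation, so it cancels in the comparison).
kw_h_from_ranks <- function(r, g, ns, N) {
  sums <- rowsum(r, g)
  12 / (N * (N + 1)) * sum(sums^2 / ns) - 3 * (N + 1)
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (tie correction %.4f)%s\n",
              x$H, x$df, x$p, x$tie_correction,
              if (!is.null(x$p_perm)) sprintf("; permutation p = %.4g", x$p_perm)
              else ""))
  invisible(x)
}

#' Per-group distribution summary and omnibus test for one feature
#'
#' @param groups A `gene_group_set` from [assign_groups()].
#' @param features A `feature_matrix` containing the feature.
#' @param feature_name Feature column, default `"codon:AAG"`.
#' @param ... Passed to [kruskal_wallis()].
#' @return A `group_comparison`: `summary` data.frame (group, n, min, q1,
#'   median, q3, max), `test` (a `kw_test`, `NULL` for a single group),
#'   `values` (long per-gene data.frame for external plotting), and the
#'   thresholds.
#' @export
group_summary <- function(groups, features, feature_name = "codon:AAG", ...) {
  stopifnot(inherits(groups, "gene_group_set"))
  values <- if (inherits(features, "feature_matrix")) features$values else features
  if (!feature_name %in% colnames(values))
    stopf("feature '%s' not present in the matrix", feature_name)
  feat <- values[, feature_name]
  per_group <- lapply(groups$groups, function(ids) {
    feat[intersect(ids, rownames(values))]
  })
  empty <- lengths(per_group) == 0L
  if (any(empty)) {
    warnf("groups with no genes in the feature matrix skipped: %s",
          paste(names(per_group)[empty], collapse = ", "))
    per_group <- per_group[!empty]
  }
  if (!length(per_group)) stopf("no group has genes in the feature matrix")
  qs <- t(vapply(per_group, quantile, numeric(5), probs = c(0, .25, .5, .75, 1)))
  summ <- data.frame(group = names(per_group), n = lengths(per_group),
                     min = qs[, 1], q1 = qs[, 2], median = qs[, 3],
                     q3 = qs[, 4], max = qs[, 5], row.names = NULL,
                     stringsAsFactors = FALSE)
  test <- if (length(per_group) >= 2L) kruskal_wallis(per_group, ...) else NULL
  long <- data.frame(group = rep(names(per_group), lengths(per_group)),
                     gene_id = unlist(lapply(per_group, names), use.names = FALSE),
                     value = unlist(per_group, use.names = FALSE),
                     stringsAsFactors = FALSE)
  structure(list(summary = summ, test = test, values = long,
                 feature = feature_name, thresholds = groups$thresholds),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison of %s\n", x$feature))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$test)) print(x$test)
  invisible(x)
}
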