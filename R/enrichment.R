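## enrichment: flat hypergeometric term enrichment with BH FDR and the
## count / q-value filter, plus selection of the AAG-rich gene set.

#' Read a gene -> term annotation map
#'
#' TSV with columns `gene_id`, `term_id` and optionally `term_label`
#' (GO/KEGG-agnostic).  Terms annotating no gene are dropped.
#'
#' @param path Annotation TSV.
#' @return An `annotation_map`: list with `terms` (term_id -> character
#'   vector of gene ids) and `labels` (named character vector).
#' @export
read_annotation_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stopf("annotation file needs gene_id and term_id columns")
  annotation_map(split(as.character(df$gene_id), df$term_id),
                 labels = if ("term_label" %in% names(df))
                   setNames(df$term_label, df$term_id) else NULL)
}

#' @rdname read_annotation_map
#' @param terms Named list term_id -> gene ids.
#' @param labels Optional named character vector of term labels.
#' @export
annotation_map <- function(terms, labels = NULL) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  terms <- terms[lengths(terms) > 0L]
  labels <- if (is.null(labels)) setNames(names(terms), names(terms))
            else labels[names(terms)]
  labels[is.na(labels)] <- names(terms)[is.na(labels)]
  names(labels) <- names(terms)
  structure(list(terms = terms, labels = labels), class = "annotation_map")
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of seeing at
#' least `k` annotated genes in a study set of size `n` drawn from a
#' universe of `N` genes of which `K` carry the term.  Delegates to
#' `phyper`, which computes the tail stably (in log space internally).
#'
#' @param k Observed annotated genes in the study set.
#' @param K Annotated genes in the universe.
#' @param n Study-set size.
#' @param N Universe size.
#' @return The upper-tail probability (vectorized).
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    stopf("invalid hypergeometric bounds: need 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric term enrichment with BH FDR
#'
#' One upper-tail test per term intersecting the universe; BH adjustment
#' over the terms with at least one study-set hit (terms with `k = 0` are
#' reported with `q = NA` and never pass); `passes_filter` requires
#' `k >= min_count` and `q < q_max`.
#'
#' @param study_set Character vector of study gene ids (subset of the
#'   universe; genes outside it are dropped with a message).
#' @param universe Character vector of universe gene ids.
#' @param annot An `annotation_map`.
#' @param min_count Minimum study-set hits to pass (default 7).
#' @param q_max BH q cutoff to pass (default 0.05).
#' @return data.frame(term_id, label, k, K, n, N, p, q, passes_filter),
#'   sorted by q then p.
#' @export
enrich <- function(study_set, universe, annot, min_count = 7L, q_max = 0.05) {
  stopifnot(inherits(annot, "annotation_map"))
  universe <- unique(as.character(universe))
  study_set <- unique(as.character(study_set))
  if (!length(study_set)) stopf("empty study set")
  outside <- setdiff(study_set, universe)
  if (length(outside)) {
    message(sprintf("dropping %d study genes absent from the universe",
                    length(outside)))
    study_set <- setdiff(study_set, outside)
    if (!length(study_set)) stopf("no study genes left inside the universe")
  }
  N <- length(universe); n <- length(study_set)
  rows <- lapply(names(annot$terms), function(tm) {
    genes <- intersect(annot$terms[[tm]], universe)
    if (!length(genes)) return(NULL)
    K <- length(genes)
    k <- length(intersect(genes, study_set))
    data.frame(term_id = tm, label = unname(annot$labels[tm]),
               k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stopf("no annotation term intersects the universe")
  res$q <- NA_real_
  tested <- res$k >= 1L
  res$q[tested] <- bh_adjust(res$p[tested])
  res$passes_filter <- tested & res$k >= min_count & !is.na(res$q) &
    res$q < q_max
  res[order(res$q, res$p), , drop = FALSE]
}

#' Genes with high AAG codon usage
#'
#' Selects genes whose AAG frequency in the coding sequence strictly exceeds
#' the threshold (default 0.08), the criterion used to define the AAG-rich
#' gene class.
#'
#' @param features A `feature_matrix` containing `codon:AAG`.
#' @param threshold Strict lower bound on the frequency (default 0.08).
#' @param feature_name Feature column (default `"codon:AAG"`).
#' @return Character vector of gene ids.
#' @export
aag_rich_set <- function(features, threshold = 0.08,
                         feature_name = "codon:AAG") {
  values <- if (inherits(features, "feature_matrix")) features$values else features
  if (!feature_name %in% colnames(values))
    stopf("feature '%s' not present", feature_name)
  rownames(values)[values[, feature_name] > threshold]
}
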