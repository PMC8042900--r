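## expression: replicate abundance tables -> fold-change tables with
## DET/DEP calls, including TMT-style reliability filtering and imputation.

#' Construct an expression table
#'
#' @param values Non-negative numeric matrix, genes x samples (rownames =
#'   gene ids).  `NA` marks a missing protein quantification; transcript
#'   tables must be complete.
#' @param condition Character vector of condition labels per sample (e.g.
#'   `"20C"`, `"30C"`, `"40C"`).
#' @param replicate Integer replicate index per sample.
#' @param sample_ids Optional sample names (default `condition:replicate`).
#' @return An `expression_table`.
#' @export
expression_table <- function(values, condition, replicate,
                             sample_ids = paste0(condition, ":", replicate)) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(condition),
            length(condition) == length(replicate))
  if (is.null(rownames(values))) stopf("values must have gene ids as rownames")
  if (any(values < 0, na.rm = TRUE)) stopf("abundances must be non-negative")
  if (any(table(condition) < 2L))
    stopf("every condition needs at least 2 replicates")
  colnames(values) <- sample_ids
  structure(list(values = values,
                 samples = data.frame(sample_id = sample_ids,
                                      condition = condition,
                                      replicate = as.integer(replicate),
                                      stringsAsFactors = FALSE)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s); %d missing values\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", "),
              sum(is.na(x$values))))
  invisible(x)
}

cond_cols <- function(tab, condition) which(tab$samples$condition == condition)

#' Write / read an expression table
#'
#' TSV with a two-line header: the sample ids, then a `#design` line giving
#' `condition:replicate` per sample.
#'
#' @param tab An `expression_table`.
#' @param path File path.
#' @return `path` (write) or an `expression_table` (read).
#' @export
write_expression <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", tab$samples$sample_id), collapse = "\t"), con)
  writeLines(paste(c("#design", paste0(tab$samples$condition, ":",
                                       tab$samples$replicate)), collapse = "\t"), con)
  write.table(data.frame(rownames(tab$values), tab$values, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  hdr <- readLines(path, n = 2L)
  ids <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
  design <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-1]
  if (!startsWith(hdr[2], "#design"))
    stopf("'%s' lacks the #design header line", path)
  parts <- strsplit(design, ":", fixed = TRUE)
  df <- read.delim(path, skip = 2L, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  expression_table(values,
                   condition = vapply(parts, `[`, "", 1L),
                   replicate = as.integer(vapply(parts, `[`, "", 2L)),
                   sample_ids = ids)
}

#' Reliability filter and imputation for protein reporter intensities
#'
#' A gene is quantitatively reliable when at least `min_observed` of the
#' replicates in a condition are observed; genes failing the rule in any
#' condition are dropped.  A single missing replicate is filled with the mean
#' of the observed replicates of that condition, after which every sample is
#' median-scaled so its median matches the grand median.
#'
#' @param tab Protein `expression_table` (4 replicates per condition unless
#'   `replicates` overrides).
#' @param min_observed Minimum observed replicates per condition (default 3).
#' @param replicates Expected replicate count per condition (default 4).
#' @param normalize Apply per-sample median scaling (default `TRUE`).
#' @return Imputed `expression_table`; attributes `dropped_genes` and
#'   `norm_factors` record the filter and normalization.
#' @export
filter_and_impute_protein <- function(tab, min_observed = 3L, replicates = 4L,
                                      normalize = TRUE) {
  conds <- unique(tab$samples$condition)
  nrep <- table(tab$samples$condition)
  if (any(nrep != replicates))
    stopf("condition '%s' has %d replicates, expected %d (override with `replicates`)",
          names(nrep)[nrep != replicates][1], nrep[nrep != replicates][1],
          replicates)
  values <- tab$values
  ok <- rep(TRUE, nrow(values))
  for (cc in conds) {
    cols <- cond_cols(tab, cc)
    ok <- ok & rowSums(!is.na(values[, cols, drop = FALSE])) >= min_observed
  }
  dropped <- rownames(values)[!ok]
  values <- values[ok, , drop = FALSE]
  for (cc in conds) {
    cols <- cond_cols(tab, cc)
    block <- values[, cols, drop = FALSE]
    miss <- which(is.na(block), arr.ind = TRUE)
    if (nrow(miss)) {
      fill <- rowMeans(block, na.rm = TRUE)
      block[miss] <- fill[miss[, "row"]]
      values[, cols] <- block
    }
  }
  factors <- rep(1, ncol(values))
  if (normalize && nrow(values)) {
    med <- apply(values, 2, median)
    factors <- median(values) / med
    values <- sweep(values, 2, factors, `*`)
  }
  out <- expression_table(values, tab$samples$condition, tab$samples$replicate,
                          tab$samples$sample_id)
  attr(out, "dropped_genes") <- dropped
  attr(out, "norm_factors") <- setNames(factors, tab$samples$sample_id)
  out
}

## Differential tests per gene between two replicate groups.
row_test <- function(a, b, test) {
  if (test == "none") return(rep(NA_real_, nrow(a)))
  ## +1 offset keeps zero abundances finite; negligible for reporter
  ## intensities, conventional for FPKM
  ta <- if (test == "t_raw") a else log2(a + 1)
  tb <- if (test == "t_raw") b else log2(b + 1)
  vapply(seq_len(nrow(a)), function(i) {
    x <- ta[i, ]; y <- tb[i, ]
    if (sd(x) == 0 && sd(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
      return(0)
    }
    tryCatch(t.test(y, x, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Fold changes (treatment / control) with per-gene tests
#'
#' `fc = mean(treatment replicates) / mean(control replicates)`.  A zero
#' control mean is handled by adding half the smallest nonzero abundance of
#' the table to both means (the gene is flagged); genes at zero in both
#' conditions are excluded and flagged.
#'
#' @param tab An `expression_table` (proteins already imputed).
#' @param control,treatment Condition labels.
#' @param test Per-gene test: `"welch_log2"` (Welch t on `log2(x+1)`, the
#'   transcript default), `"t_log2"` (t on `log2(x)`, the protein default),
#'   `"t_raw"`, or `"none"`.
#' @return data.frame(gene_id, fc, log2_fc, p, eps_flag).
#' @export
fold_changes <- function(tab, control, treatment,
                         test = c("welch_log2", "t_log2", "t_raw", "none")) {
  test <- match.arg(test)
  for (cc in c(control, treatment))
    if (!cc %in% tab$samples$condition) stopf("condition '%s' not present", cc)
  a <- tab$values[, cond_cols(tab, control), drop = FALSE]
  b <- tab$values[, cond_cols(tab, treatment), drop = FALSE]
  if (anyNA(a) || anyNA(b))
    stopf("expression table contains missing values; impute first")
  ma <- rowMeans(a); mb <- rowMeans(b)
  both_zero <- ma == 0 & mb == 0
  eps_flag <- ma == 0 & !both_zero
  nz <- tab$values[tab$values > 0]
  eps <- if (length(nz)) min(nz) / 2 else 1
  fc <- ifelse(eps_flag, (mb + eps) / (ma + eps), mb / ma)
  p <- row_test(a, b, test)
  out <- data.frame(gene_id = rownames(tab$values), fc = fc,
                    log2_fc = log2(fc), p = p, eps_flag = eps_flag,
                    stringsAsFactors = FALSE)
  out[!both_zero, , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment with monotonicity enforcement (wraps
#' `p.adjust(method = "BH")`).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "BH")
}

#' DET / DEP threshold calls
#'
#' Differentially expressed transcripts: `fc > fc_cut` or `fc < 1/fc_cut`
#' with BH q below `q_cut` (defaults 2 and 0.05).  Differentially expressed
#' proteins: two-sided t-test p below `p_cut` (default 0.01, no FDR).
#'
#' @param fc,q,p Numeric vectors.
#' @param fc_cut,q_cut,p_cut Thresholds.
#' @return Logical vector.
#' @export
call_dets <- function(fc, q, fc_cut = 2, q_cut = 0.05) {
  (fc > fc_cut | fc < 1 / fc_cut) & !is.na(q) & q < q_cut
}

#' @rdname call_dets
#' @export
call_deps <- function(p, p_cut = 0.01) !is.na(p) & p < p_cut

#' Combined transcript + protein fold-change table for one contrast
#'
#' Runs [fold_changes()] on both tables, BH-adjusts the transcript (and,
#' for group assignment, protein) p-values, and applies the DET/DEP calls.
#'
#' @param transcripts,proteins `expression_table`s (proteins imputed).
#' @param control,treatment Condition labels.
#' @param det_fc,det_q,dep_p Call thresholds.
#' @param protein_test Test for protein p-values (default `"t_log2"`).
#' @return data.frame(gene_id, contrast, transcript_fc, transcript_p,
#'   transcript_q, det, protein_fc, protein_p, protein_q, dep) over genes
#'   present in both tables.
#' @export
build_fc_table <- function(transcripts, proteins, control, treatment,
                           det_fc = 2, det_q = 0.05, dep_p = 0.01,
                           protein_test = "t_log2") {
  tfc <- fold_changes(transcripts, control, treatment, test = "welch_log2")
  tfc$q <- bh_adjust(tfc$p)
  pfc <- fold_changes(proteins, control, treatment, test = protein_test)
  pfc$q <- bh_adjust(pfc$p)
  common <- intersect(tfc$gene_id, pfc$gene_id)
  if (!length(common)) stopf("no genes shared between transcript and protein tables")
  ti <- tfc[match(common, tfc$gene_id), ]
  pr <- pfc[match(common, pfc$gene_id), ]
  data.frame(gene_id = common, contrast = paste0(treatment, "_vs_", control),
             transcript_fc = ti$fc, transcript_p = ti$p, transcript_q = ti$q,
             det = call_dets(ti$fc, ti$q, det_fc, det_q),
             protein_fc = pr$fc, protein_p = pr$p, protein_q = pr$q,
             dep = call_deps(pr$p, dep_p),
             stringsAsFactors = FALSE)
}
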