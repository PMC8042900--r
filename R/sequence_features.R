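## sequence_features: codon usage, amino-acid frequency, base/GC composition
## and lengths per region, assembled into the regression feature matrix.

CODONS <- sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3))
AA20   <- sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))

#' Default feature registry
#'
#' 64 codon frequencies + 20 amino-acid frequencies + base frequencies
#' (A/C/G/T) and GC fraction and length for each of CDS, 5'UTR and 3'UTR,
#' plus the transcript fold change: 103 named features in 6 categories.
#' The registry is an ordinary data.frame and can be subset or extended.
#'
#' @return data.frame with columns `name` and `category`.
#' @export
default_registry <- function() {
  rbind(
    data.frame(name = "transcript_fc", category = "transcript"),
    data.frame(name = paste0("codon:", CODONS), category = "codon"),
    data.frame(name = paste0("aa:", AA20), category = "amino_acid"),
    data.frame(name = paste0("base:", rep(c("A", "C", "G", "T"), 3), ":",
                             rep(c("cds", "utr5", "utr3"), each = 4)),
               category = "base"),
    data.frame(name = paste0("gc:", c("cds", "utr5", "utr3")), category = "gc"),
    data.frame(name = paste0("len:", c("cds", "utr5", "utr3")), category = "length")
  )
}

check_cds_frame <- function(cds, drop_incomplete) {
  n <- nchar(cds)
  if (any(n < 3L)) stopf("CDS shorter than one codon")
  if (any(n %% 3L != 0L)) {
    if (!drop_incomplete)
      stopf("CDS length not divisible by 3; set drop_incomplete = TRUE to drop the trailing partial codon")
    cds <- substr(cds, 1L, n - n %% 3L)
  }
  cds
}

#' Codon usage frequencies of a CDS
#'
#' Counts in-frame codons (frame starting at position 1).  Codons containing
#' `N` are excluded from both numerator and denominator; all 64 codons are
#' reported, zero-filled.
#'
#' @param cds Nucleotide string (alphabet `A/C/G/T/N`).
#' @param drop_incomplete Drop a trailing partial codon instead of erroring.
#' @return Named numeric vector of length 64 summing to 1 (all-`N` CDS gives
#'   all zero).
#' @export
codon_frequencies <- function(cds, drop_incomplete = FALSE) {
  cds <- check_cds_frame(cds, drop_incomplete)
  counts <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(cds), step = 3)
  tot <- sum(counts)
  if (tot == 0) return(setNames(numeric(64), CODONS))
  (counts / tot)[CODONS]
}

## 64 x 20 indicator matrix mapping codons to the amino acid they encode
## (stop codons map to nothing).
codon_aa_matrix <- function() {
  gc <- Biostrings::GENETIC_CODE
  m <- matrix(0, length(CODONS), length(AA20), dimnames = list(CODONS, AA20))
  coding <- names(gc)[gc != "*"]
  m[cbind(coding, gc[coding])] <- 1
  m
}

#' Amino-acid frequencies of a CDS
#'
#' Translates with the standard genetic code; stop codons (and codons
#' containing `N`) are excluded from the denominator, so frequencies over the
#' 20 coding amino acids sum to 1.
#'
#' @inheritParams codon_frequencies
#' @return Named numeric vector of length 20.
#' @export
amino_acid_frequencies <- function(cds, drop_incomplete = FALSE) {
  cds <- check_cds_frame(cds, drop_incomplete)
  counts <- Biostrings::trinucleotideFrequency(Biostrings::DNAString(cds), step = 3)
  aa <- as.numeric(counts[CODONS] %*% codon_aa_matrix())
  tot <- sum(aa)
  if (tot == 0) return(setNames(numeric(length(AA20)), AA20))
  setNames(aa / tot, AA20)
}

#' Base composition, GC fraction and length of a region
#'
#' Base frequencies are over non-`N` bases; `gc = (G+C)/(A+C+G+T)`; length is
#' the raw length including `N`.  An empty (absent) region reports `NA`
#' frequencies and GC with length 0 — the feature-matrix assembly replaces
#' these by the genome-wide mean of the feature.
#'
#' @param seq Nucleotide string, possibly empty.
#' @return List with `base_freq` (named A/C/G/T), `gc_fraction`, `length`.
#' @export
region_composition <- function(seq) {
  len <- nchar(seq)
  if (len == 0L)
    return(list(base_freq = setNames(rep(NA_real_, 4), c("A", "C", "G", "T")),
                gc_fraction = NA_real_, length = 0L))
  cnt <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq), baseOnly = TRUE)
  acgt <- cnt[c("A", "C", "G", "T")]
  tot <- sum(acgt)
  if (tot == 0)
    return(list(base_freq = setNames(rep(NA_real_, 4), c("A", "C", "G", "T")),
                gc_fraction = NA_real_, length = len))
  list(base_freq = acgt / tot,
       gc_fraction = unname((acgt["G"] + acgt["C"]) / tot),
       length = len)
}

## Vectorized per-region composition block for a DNAStringSet.
region_block <- function(seqs, region) {
  cnt <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- cnt[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(acgt)
  freq <- acgt / ifelse(tot == 0, NA_real_, tot)
  gc <- (acgt[, "G"] + acgt[, "C"]) / ifelse(tot == 0, NA_real_, tot)
  out <- cbind(freq, gc = gc, len = Biostrings::width(seqs))
  colnames(out) <- c(paste0("base:", c("A", "C", "G", "T"), ":", region),
                     paste0("gc:", region), paste0("len:", region))
  out
}

#' Assemble the genes-by-features regression matrix
#'
#' One row per gene having both a usable (in-frame) CDS in the catalog and a
#' transcript fold change; columns follow the registry order.  Genes lacking
#' a UTR get that region's base/GC features imputed with the column mean
#' (length stays 0) and are flagged in the assembly report.
#'
#' @param catalog A [new_transcript_catalog()] object.
#' @param transcript_fc Named numeric vector of per-gene transcript fold
#'   changes.
#' @param registry Feature registry data.frame, default [default_registry()].
#' @param drop_incomplete Passed to the codon counters for flagged CDS;
#'   flagged transcripts are dropped (never codon-counted) unless this is
#'   `TRUE`.
#' @return A `feature_matrix`: list with `values` (numeric matrix, rownames =
#'   gene ids), `registry`, and `report` (dropped genes with reasons, imputed
#'   region flags).
#' @export
build_feature_matrix <- function(catalog, transcript_fc,
                                 registry = default_registry(),
                                 drop_incomplete = FALSE) {
  stopifnot(is.data.frame(registry), nrow(registry) > 0,
            !anyDuplicated(registry$name))
  info <- catalog$info
  dropped <- list()
  usable <- !info$incomplete_cds | drop_incomplete
  if (any(!usable))
    dropped$incomplete_cds <- info$gene_id[!usable]
  have_fc <- info$gene_id %in% names(transcript_fc)
  if (any(!have_fc))
    dropped$no_fold_change <- info$gene_id[!have_fc]
  keep <- usable & have_fc
  if (!any(keep)) stopf("no genes with both sequence and fold-change data")
  info <- info[keep, , drop = FALSE]
  gene_ids <- info$gene_id
  tid <- info$transcript_id

  cds <- catalog$cds[tid]
  if (drop_incomplete) {
    w <- Biostrings::width(cds)
    cds <- Biostrings::subseq(cds, 1L, w - w %% 3L)
  }
  cod_cnt <- Biostrings::trinucleotideFrequency(cds, step = 3)[, CODONS, drop = FALSE]
  cod_tot <- rowSums(cod_cnt)
  cod_freq <- cod_cnt / ifelse(cod_tot == 0, NA_real_, cod_tot)
  colnames(cod_freq) <- paste0("codon:", CODONS)
  aa_cnt <- cod_cnt %*% codon_aa_matrix()
  aa_tot <- rowSums(aa_cnt)
  aa_freq <- aa_cnt / ifelse(aa_tot == 0, NA_real_, aa_tot)
  colnames(aa_freq) <- paste0("aa:", AA20)

  blocks <- cbind(
    transcript_fc = unname(transcript_fc[gene_ids]),
    cod_freq, aa_freq,
    region_block(catalog$cds[tid], "cds"),
    region_block(catalog$utr5[tid], "utr5"),
    region_block(catalog$utr3[tid], "utr3"))
  rownames(blocks) <- gene_ids

  missing_feats <- setdiff(registry$name, colnames(blocks))
  if (length(missing_feats))
    stopf("registry features not computable: %s",
          paste(missing_feats, collapse = ", "))
  values <- blocks[, registry$name, drop = FALSE]

  imputed <- which(is.na(values), arr.ind = TRUE)
  if (nrow(imputed)) {
    cm <- colMeans(values, na.rm = TRUE)
    cm[is.nan(cm)] <- 0
    values[imputed] <- cm[imputed[, "col"]]
  }
  report <- list(
    dropped = dropped,
    imputed_regions = if (nrow(imputed))
      data.frame(gene_id = gene_ids[imputed[, "row"]],
                 feature = registry$name[imputed[, "col"]])
      else data.frame(gene_id = character(0), feature = character(0)),
    n_genes = length(gene_ids))
  structure(list(values = values, registry = registry, report = report),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d genes x %d features (%d imputed region values)\n",
              nrow(x$values), ncol(x$values), nrow(x$report$imputed_regions)))
  invisible(x)
}

#' Write a feature matrix and its registry manifest
#'
#' @param fm A `feature_matrix`.
#' @param path Output TSV (gene_id + one column per feature).
#' @param registry_path Optional TSV manifest of feature names and categories.
#' @return `path`, invisibly.
#' @export
write_features <- function(fm, path, registry_path = NULL) {
  df <- data.frame(gene_id = rownames(fm$values), fm$values,
                   check.names = FALSE)
  write_tsv(df, path)
  if (!is.null(registry_path)) write_tsv(fm$registry, registry_path)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path Features TSV.
#' @param registry_path Optional registry manifest TSV; when absent,
#'   categories are reconstructed from the feature-name prefixes.
#' @return A `feature_matrix`.
#' @export
read_features <- function(path, registry_path = NULL) {
  df <- tryCatch(read_tsv(path), error = function(e)
    stopf("failed to read features table '%s': %s", path, conditionMessage(e)))
  if (!"gene_id" %in% names(df) || ncol(df) < 2L)
    stopf("'%s' is not a valid features table", path)
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values) || anyNA(values))
    stopf("'%s' is not a valid features table (non-numeric or missing values)",
          path)
  rownames(values) <- df$gene_id
  registry <- if (!is.null(registry_path)) read_tsv(registry_path)
    else {
      cat_of <- function(n) {
        if (n == "transcript_fc") return("transcript")
        switch(sub(":.*$", "", n), codon = "codon", aa = "amino_acid",
               base = "base", gc = "gc", len = "length", "other")
      }
      data.frame(name = colnames(values),
                 category = vapply(colnames(values), cat_of, ""))
    }
  structure(list(values = values, registry = registry,
                 report = list(dropped = list(),
                               imputed_regions = data.frame(),
                               n_genes = nrow(values))),
            class = "feature_matrix")
}
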