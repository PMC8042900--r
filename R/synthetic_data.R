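## synthetic_data: transcript catalogs and expression tables with planted,
## recoverable structure.  Emulates the statistical shape of the study
## inputs — FPKM-like transcript tables (3 replicates), TMT-like protein
## reporter tables (4 replicates, sporadic missingness), and coding
## sequences with a planted AAG-enriched subset — plus ground truth for
## recovery tests.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation specification
#'
#' Defaults define the package's reference study conditions: 3000 genes,
#' interior CDS length ~ Normal(300, 80) codons (minimum 60), uniform sense
#' codon usage with a 10% gene subset whose interior AAG probability is
#' raised by 0.08, standardized planted effects of 0.5 (log2 transcript fold
#' change) and 0.4 (AAG frequency) on the protein log2 fold change with
#' noise solved so the planted linear predictor explains 60% of its
#' variance, 3 transcript and 4 protein replicates per condition, and a 5%
#' missing-completely-at-random protein rate (at most one missing replicate
#' per gene and condition).
#'
#' @param n_genes Number of genes.
#' @param cds_len_mean,cds_len_sd,cds_len_min Interior CDS length
#'   distribution, in codons (start and stop are added).
#' @param codon_weights Named non-negative weights over the 64 codons for
#'   interior draws (stop codons are zeroed); default uniform over the 61
#'   sense codons.
#' @param aag_boost `c(fraction, add)`: fraction of genes whose interior AAG
#'   probability is raised by `add`.
#' @param utr5_len,utr3_len `c(mean, sd)` UTR length distributions (bases).
#' @param utr_missing_rate Probability a gene lacks each UTR entirely.
#' @param effects Named numeric vector of standardized planted effects on
#'   the protein log2 fold change; `transcript_fc` refers to the gene's
#'   log2 transcript fold change, other names to registry features.
#' @param target_r2 Fraction of protein log2-fold-change variance explained
#'   by the planted linear predictor (exclusive with `noise_sd`).
#' @param noise_sd Residual SD on the protein log2 fold change (exclusive
#'   with `target_r2`).
#' @param control,treatments Condition labels.
#' @param transcript_replicates,protein_replicates Replicates per condition.
#' @param transcript_rep_sdlog,protein_rep_sdlog Log-normal replicate noise.
#' @param protein_missing_rate MCAR missingness per protein measurement.
#' @param max_missing_per_condition Cap on missing replicates per gene and
#'   condition (default 1, so the mean-of-three imputation rule applies).
#' @param max_exons Transcripts get 1..`max_exons` exons.
#' @param seed Integer master seed; named substreams derive from it.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_genes = 3000L,
                            cds_len_mean = 300, cds_len_sd = 80,
                            cds_len_min = 60,
                            codon_weights = NULL,
                            aag_boost = c(fraction = 0.1, add = 0.08),
                            utr5_len = c(150, 70), utr3_len = c(250, 110),
                            utr_missing_rate = 0.05,
                            effects = c(transcript_fc = 0.5, `codon:AAG` = 0.4),
                            target_r2 = 0.6, noise_sd = NULL,
                            control = "20C", treatments = c("30C", "40C"),
                            transcript_replicates = 3L,
                            protein_replicates = 4L,
                            transcript_rep_sdlog = 0.2,
                            protein_rep_sdlog = 0.15,
                            protein_missing_rate = 0.05,
                            max_missing_per_condition = 1L,
                            max_exons = 3L,
                            seed = 1L) {
  if (is.null(codon_weights)) {
    codon_weights <- setNames(rep(1, 64), CODONS)
  }
  stopifnot(length(codon_weights) == 64L, all(codon_weights >= 0))
  if (is.null(names(codon_weights))) names(codon_weights) <- CODONS
  codon_weights <- codon_weights[CODONS]
  codon_weights[STOP_CODONS] <- 0
  if (sum(codon_weights) <= 0) stopf("codon weights must have positive sum")
  if (!is.null(target_r2) && !is.null(noise_sd))
    stopf("target_r2 and noise_sd are mutually exclusive")
  if (!is.null(target_r2) && (target_r2 <= 0 || target_r2 >= 1))
    stopf("target_r2 must be in (0, 1)")
  q <- codon_weights / sum(codon_weights)
  if (unname(q["AAG"] + aag_boost[["add"]]) >= 1)
    stopf("infeasible AAG boost: probability would reach %.3f",
          q["AAG"] + aag_boost[["add"]])
  if (protein_missing_rate < 0 || protein_missing_rate >= 1)
    stopf("protein_missing_rate must be in [0, 1)")
  structure(list(
    n_genes = as.integer(n_genes), cds_len_mean = cds_len_mean,
    cds_len_sd = cds_len_sd, cds_len_min = cds_len_min,
    codon_weights = codon_weights, aag_boost = aag_boost,
    utr5_len = utr5_len, utr3_len = utr3_len,
    utr_missing_rate = utr_missing_rate,
    effects = effects, target_r2 = target_r2, noise_sd = noise_sd,
    control = control, treatments = treatments,
    transcript_replicates = as.integer(transcript_replicates),
    protein_replicates = as.integer(protein_replicates),
    transcript_rep_sdlog = transcript_rep_sdlog,
    protein_rep_sdlog = protein_rep_sdlog,
    protein_missing_rate = protein_missing_rate,
    max_missing_per_condition = as.integer(max_missing_per_condition),
    max_exons = as.integer(max_exons), seed = as.integer(seed)),
    class = "simulation_spec")
}

## Sample `total` codons from probability vector q and split them into
## per-gene CDS strings of `len` codons each.
sample_cds <- function(len, q) {
  total <- sum(len)
  draws <- sample(CODONS, total, replace = TRUE, prob = q)
  big <- paste0(draws, collapse = "")
  ends <- cumsum(3 * len)
  starts <- ends - 3 * len + 1
  substring(big, starts, ends)
}

sample_bases <- function(len) {
  total <- sum(len)
  if (total == 0) return(rep("", length(len)))
  big <- paste0(sample(c("A", "C", "G", "T"), total, replace = TRUE),
                collapse = "")
  ends <- cumsum(len)
  starts <- ends - len + 1
  out <- substring(big, starts, ends)
  out[len == 0] <- ""
  out
}

#' Simulate a transcript catalog (and optionally genome FASTA + GFF3)
#'
#' Every CDS starts with ATG and ends with a stop codon; interior codons are
#' drawn from the spec's codon weights, with the boosted subset's AAG
#' probability raised by the planted margin.  When `dir` is given, each gene
#' is placed on its own contig (random strand, 1-3 exons with introns) and
#' `genome.fa` + `annot.gff3` are written so the files round-trip through
#' [load_catalog()].
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional output directory for `genome.fa` and `annot.gff3`.
#' @return List with `catalog` (a `transcript_catalog`), `boosted_genes`,
#'   and `paths` (when written).
#' @export
simulate_catalog <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(substream_seed(spec$seed, "sequences"))
  n <- spec$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  tids <- paste0(gene_ids, ".t1")

  len <- pmax(spec$cds_len_min,
              round(rnorm(n, spec$cds_len_mean, spec$cds_len_sd)))
  n_boost <- round(spec$aag_boost[["fraction"]] * n)
  boosted <- sort(sample.int(n, n_boost))
  q <- spec$codon_weights / sum(spec$codon_weights)
  q2 <- q * (1 - (q[["AAG"]] + spec$aag_boost[["add"]])) / (1 - q[["AAG"]])
  q2[["AAG"]] <- q[["AAG"]] + spec$aag_boost[["add"]]

  interior <- character(n)
  is_b <- seq_len(n) %in% boosted
  interior[!is_b] <- sample_cds(len[!is_b], q)
  if (any(is_b)) interior[is_b] <- sample_cds(len[is_b], q2)
  stops <- sample(STOP_CODONS, n, replace = TRUE)
  cds <- paste0("ATG", interior, stops)

  u5len <- pmax(0L, round(rnorm(n, spec$utr5_len[1], spec$utr5_len[2])))
  u3len <- pmax(0L, round(rnorm(n, spec$utr3_len[1], spec$utr3_len[2])))
  u5len[runif(n) < spec$utr_missing_rate] <- 0L
  u3len[runif(n) < spec$utr_missing_rate] <- 0L
  utr5 <- sample_bases(u5len)
  utr3 <- sample_bases(u3len)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  info <- data.frame(transcript_id = tids, gene_id = gene_ids,
                     chrom = sprintf("ctg%05d", seq_len(n)),
                     strand = strand, incomplete_cds = FALSE,
                     stringsAsFactors = FALSE)
  mk <- function(x) { s <- Biostrings::DNAStringSet(x); names(s) <- tids; s }
  catalog <- new_transcript_catalog(info, mk(cds), mk(utr5), mk(utr3),
    provenance = list(source = "simulate_catalog", seed = spec$seed,
                      n_transcripts = n))
  out <- list(catalog = catalog, boosted_genes = gene_ids[boosted])
  if (!is.null(dir))
    out$paths <- write_simulated_annotation(spec, info, cds, utr5, utr3, dir)
  out
}

## Lay each transcript out on its own contig with random exon structure and
## emit genome FASTA + GFF3 (explicit UTR and exon features, CDS phase set).
write_simulated_annotation <- function(spec, info, cds, utr5, utr3, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(info)
  genome <- character(n)
  gff <- vector("list", n)
  flank_len <- 10L
  for (i in seq_len(n)) {
    tx <- paste0(utr5[i], cds[i], utr3[i])
    L <- nchar(tx)
    n_ex <- sample.int(spec$max_exons, 1L)
    cuts <- if (n_ex > 1L && L > n_ex)
      sort(sample(seq_len(L - 1L), n_ex - 1L)) else integer(0)
    ex_tx <- cbind(start = c(1L, cuts + 1L), end = c(cuts, L))
    introns <- if (n_ex > 1L) 30L + rpois(n_ex - 1L, 90) else integer(0)
    flank1 <- sample_bases(flank_len); flank2 <- sample_bases(flank_len)
    ## genomic layout in plus orientation
    ex_g <- ex_tx
    off <- flank_len
    pieces <- character(0)
    for (e in seq_len(nrow(ex_tx))) {
      w <- ex_tx[e, "end"] - ex_tx[e, "start"] + 1L
      ex_g[e, "start"] <- off + 1L
      ex_g[e, "end"] <- off + w
      pieces <- c(pieces, substring(tx, ex_tx[e, "start"], ex_tx[e, "end"]))
      off <- off + w
      if (e < nrow(ex_tx)) {
        pieces <- c(pieces, sample_bases(introns[e]))
        off <- off + introns[e]
      }
    }
    gplus <- paste0(flank1, paste0(pieces, collapse = ""), flank2)
    G <- nchar(gplus)

    ## map a transcript-space interval to genomic pieces (plus orientation)
    map_region <- function(s, e) {
      if (e < s) return(NULL)
      res <- NULL
      for (x in seq_len(nrow(ex_tx))) {
        ss <- max(s, ex_tx[x, "start"]); ee <- min(e, ex_tx[x, "end"])
        if (ss <= ee)
          res <- rbind(res, c(ex_g[x, "start"] + ss - ex_tx[x, "start"],
                              ex_g[x, "start"] + ee - ex_tx[x, "start"]))
      }
      res
    }
    u5 <- nchar(utr5[i]); lc <- nchar(cds[i])
    cds_pieces <- map_region(u5 + 1L, u5 + lc)
    u5_pieces <- map_region(1L, u5)
    u3_pieces <- map_region(u5 + lc + 1L, L)
    ## CDS phase in transcript order
    plens <- cds_pieces[, 2] - cds_pieces[, 1] + 1L
    phase <- (3L - cumsum(c(0L, plens[-length(plens)])) %% 3L) %% 3L

    minus <- info$strand[i] == "-"
    flip <- function(m) {
      if (is.null(m)) return(NULL)
      m2 <- cbind(G - m[, 2] + 1L, G - m[, 1] + 1L)
      m2[order(m2[, 1]), , drop = FALSE]
    }
    if (minus) {
      genome[i] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gplus)))
      ## mirroring reverses piece order, so genomic-ascending rows on the
      ## minus strand carry the phases in reverse transcript order
      phase <- rev(phase)
      ex_gg <- flip(ex_g); cds_gg <- flip(cds_pieces)
      u5_gg <- flip(u5_pieces); u3_gg <- flip(u3_pieces)
    } else {
      genome[i] <- gplus
      ex_gg <- ex_g; cds_gg <- cds_pieces
      u5_gg <- u5_pieces; u3_gg <- u3_pieces
    }
    chrom <- info$chrom[i]; str <- info$strand[i]
    gid <- info$gene_id[i]; tid <- info$transcript_id[i]
    row9 <- function(type, m, attrs, phases = ".") {
      if (is.null(m) || nrow(m) == 0L) return(NULL)
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              chrom, type, m[, 1], m[, 2], str, phases, attrs)
    }
    span <- cbind(min(ex_gg[, 1]), max(ex_gg[, 2]))
    gff[[i]] <- c(
      row9("gene", span, sprintf("ID=%s", gid)),
      row9("mRNA", span, sprintf("ID=%s;Parent=%s", tid, gid)),
      row9("exon", ex_gg, sprintf("ID=%s.e%d;Parent=%s", tid,
                                  seq_len(nrow(ex_gg)), tid)),
      row9("five_prime_UTR", u5_gg, sprintf("Parent=%s", tid)),
      row9("CDS", cds_gg, sprintf("ID=%s.c%d;Parent=%s", tid,
                                  seq_len(nrow(cds_gg)), tid),
           phases = as.character(phase)),
      row9("three_prime_UTR", u3_gg, sprintf("Parent=%s", tid)))
  }
  fasta <- file.path(dir, "genome.fa")
  gff3 <- file.path(dir, "annot.gff3")
  gset <- Biostrings::DNAStringSet(genome)
  names(gset) <- info$chrom
  Biostrings::writeXStringSet(gset, fasta)
  writeLines(c("##gff-version 3", unlist(gff)), gff3)
  list(fasta = fasta, gff3 = gff3)
}

## Feature values needed for planting effects, by registry name.
feature_values <- function(catalog, name) {
  tid <- catalog$info$transcript_id
  if (startsWith(name, "codon:")) {
    cnt <- Biostrings::trinucleotideFrequency(catalog$cds, step = 3)
    v <- cnt[, sub("^codon:", "", name)] / rowSums(cnt)
  } else if (startsWith(name, "aa:")) {
    cnt <- Biostrings::trinucleotideFrequency(catalog$cds, step = 3)[, CODONS]
    aa <- cnt %*% codon_aa_matrix()
    v <- aa[, sub("^aa:", "", name)] / rowSums(aa)
  } else if (startsWith(name, "gc:") || startsWith(name, "base:") ||
             startsWith(name, "len:")) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    region <- parts[length(parts)]
    blk <- region_block(catalog[[region]], region)
    v <- blk[, name]
  } else stopf("cannot compute feature '%s' for effect planting", name)
  setNames(as.numeric(v), catalog$info$gene_id)
}

#' Simulate expression tables with planted protein effects
#'
#' Transcript log2 fold changes are standard normal per gene and treatment;
#' the protein log2 fold change is the planted linear combination of
#' standardized features plus Gaussian noise (solved from `target_r2` when
#' given).  Replicate abundances are log-normal around
#' `baseline * 2^(condition effect)`; protein entries are masked missing at
#' random.
#'
#' @param catalog A `transcript_catalog` (typically from
#'   [simulate_catalog()]).
#' @param spec The same [simulation_spec()].
#' @return List with `transcripts` and `proteins` (`expression_table`s) and
#'   `truth` (planted betas, per-treatment log2 fold changes, realized R2,
#'   noise SD, seed).
#' @export
simulate_expression <- function(catalog, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  genes <- catalog$info$gene_id
  n <- length(genes)
  trts <- spec$treatments
  set.seed(substream_seed(spec$seed, "transcript_fc"))
  l2tfc <- matrix(rnorm(n * length(trts)), n,
                  dimnames = list(genes, trts))

  feat_static <- lapply(setdiff(names(spec$effects), "transcript_fc"),
                        function(nm) feature_values(catalog, nm))
  names(feat_static) <- setdiff(names(spec$effects), "transcript_fc")

  zscore <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  linpred <- sapply(trts, function(tt) {
    lp <- rep(0, n)
    for (nm in names(spec$effects)) {
      v <- if (nm == "transcript_fc") l2tfc[, tt] else feat_static[[nm]]
      lp <- lp + spec$effects[[nm]] * zscore(v)
    }
    lp
  })
  linpred <- matrix(linpred, n, dimnames = list(genes, trts))
  noise_sd <- sapply(trts, function(tt) {
    if (!is.null(spec$noise_sd)) spec$noise_sd
    else {
      s <- sd(linpred[, tt])
      if (s == 0) 1 else s * sqrt((1 - spec$target_r2) / spec$target_r2)
    }
  })
  set.seed(substream_seed(spec$seed, "protein_noise"))
  l2pfc <- linpred + sapply(trts, function(tt) rnorm(n, 0, noise_sd[[tt]]))
  realized_r2 <- sapply(trts, function(tt)
    var(linpred[, tt]) / var(l2pfc[, tt]))

  set.seed(substream_seed(spec$seed, "baselines"))
  base_t <- rlnorm(n, meanlog = 3, sdlog = 1.2)    # FPKM-like skew
  base_p <- rlnorm(n, meanlog = 11, sdlog = 1)     # reporter-intensity-like

  conds <- c(spec$control, trts)
  make_table <- function(base, l2fc_mat, reps, sdlog, stream) {
    set.seed(substream_seed(spec$seed, stream))
    cond <- rep(conds, each = reps)
    repl <- rep(seq_len(reps), times = length(conds))
    mu <- cbind(base, sweep(2^l2fc_mat, 1, base, `*`))
    colnames(mu) <- conds
    vals <- matrix(0, n, length(cond), dimnames = list(genes, NULL))
    for (s in seq_along(cond))
      vals[, s] <- mu[, cond[s]] * rlnorm(n, 0, sdlog)
    expression_table(vals, cond, repl)
  }
  transcripts <- make_table(base_t, l2tfc, spec$transcript_replicates,
                            spec$transcript_rep_sdlog, "transcript_reps")
  proteins <- make_table(base_p, l2pfc, spec$protein_replicates,
                         spec$protein_rep_sdlog, "protein_reps")

  if (spec$protein_missing_rate > 0) {
    set.seed(substream_seed(spec$seed, "missingness"))
    vals <- proteins$values
    for (cc in conds) {
      cols <- cond_cols(proteins, cc)
      mask <- matrix(runif(n * length(cols)) < spec$protein_missing_rate,
                     n, length(cols))
      if (spec$max_missing_per_condition < length(cols)) {
        excess <- rowSums(mask) > spec$max_missing_per_condition
        if (any(excess)) {
          for (i in which(excess)) {
            on <- which(mask[i, ])
            mask[i, on[-seq_len(spec$max_missing_per_condition)]] <- FALSE
          }
        }
      }
      vals[, cols][mask] <- NA
    }
    proteins$values <- vals
  }
  truth <- list(betas = spec$effects,
                l2_transcript_fc = l2tfc, l2_protein_fc = l2pfc,
                noise_sd = noise_sd, realized_r2 = realized_r2,
                target_r2 = spec$target_r2, seed = spec$seed)
  list(transcripts = transcripts, proteins = proteins, truth = truth)
}

#' Simulate a complete dataset, optionally writing all files
#'
#' @param spec A [simulation_spec()].
#' @param dir Optional directory; writes `genome.fa`, `annot.gff3`,
#'   `transcripts.tsv`, `proteins.tsv` and `truth.json`.
#' @return List with `catalog`, `boosted_genes`, `transcripts`, `proteins`,
#'   `truth` (including `boosted_genes`) and `paths` when written.
#' @export
simulate_dataset <- function(spec, dir = NULL) {
  cat_out <- simulate_catalog(spec, dir = dir)
  expr <- simulate_expression(cat_out$catalog, spec)
  expr$truth$boosted_genes <- cat_out$boosted_genes
  out <- c(list(catalog = cat_out$catalog,
                boosted_genes = cat_out$boosted_genes), expr)
  if (!is.null(dir)) {
    out$paths <- cat_out$paths
    out$paths$transcripts <- file.path(dir, "transcripts.tsv")
    out$paths$proteins <- file.path(dir, "proteins.tsv")
    out$paths$truth <- file.path(dir, "truth.json")
    write_expression(expr$transcripts, out$paths$transcripts)
    write_expression(expr$proteins, out$paths$proteins)
    tr <- expr$truth
    jsonlite::write_json(
      list(betas = as.list(tr$betas), noise_sd = as.list(tr$noise_sd),
           realized_r2 = as.list(tr$realized_r2), target_r2 = tr$target_r2,
           seed = tr$seed, boosted_genes = tr$boosted_genes,
           l2_transcript_fc = as.data.frame(tr$l2_transcript_fc),
           l2_protein_fc = as.data.frame(tr$l2_protein_fc)),
      out$paths$truth, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Check that the pipeline recovered the planted structure
#'
#' Three machine-readable verdicts: (a) the planted features rank as the top
#' contributors, (b) every planted feature's correlation sign matches its
#' planted beta, (c) the estimated total explained variance is within 10
#' percentage points of the realized planted R-squared.
#'
#' @param truth `truth` element from [simulate_expression()].
#' @param contribution A `contribution_report` for one treatment.
#' @param correlation A [correlation_screen()] table for the same treatment.
#' @param treatment Which treatment the reports belong to (default: first).
#' @param tolerance_pp Allowed gap for check (c), percentage points.
#' @return List with `checks` data.frame(check, pass, detail) and `overall`.
#' @export
recovery_report <- function(truth, contribution, correlation,
                            treatment = NULL, tolerance_pp = 10) {
  trts <- colnames(truth$l2_protein_fc)
  treatment <- treatment %||% trts[1]
  planted <- names(truth$betas)
  feats <- contribution$features
  topk <- head(feats$feature[order(-feats$contribution_pct)], length(planted))
  a_pass <- if (!length(planted)) NA else setequal(topk, planted)
  signs <- sign(correlation$r[match(planted, correlation$feature)])
  b_pass <- all(signs == sign(truth$betas), na.rm = TRUE)
  realized <- 100 * truth$realized_r2[[treatment]]
  gap <- abs(contribution$total_explained_pct - realized)
  c_pass <- gap <= tolerance_pp
  checks <- data.frame(
    check = c("top_contributors", "correlation_signs", "explained_variance"),
    pass = c(a_pass, b_pass, c_pass),
    detail = c(paste(topk, collapse = ","),
               paste(signs, collapse = ","),
               sprintf("estimated %.1f vs realized %.1f",
                       contribution$total_explained_pct, realized)),
    stringsAsFactors = FALSE)
  list(checks = checks, overall = all(checks$pass, na.rm = TRUE))
}
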