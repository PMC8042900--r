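## annotation_io: read FASTA + GFF3, assemble transcript models, extract
## strand-correct CDS / 5'UTR / 3'UTR sequences.
##
## Coordinates are GFF3 1-based inclusive throughout.  Sequences handed out
## by the catalog are in transcript orientation: on the minus strand the
## spliced genomic sequence is reverse-complemented so position 1 is the
## 5' end.

#' Transcript catalog
#'
#' A `transcript_catalog` holds, for one representative transcript per gene,
#' the spliced CDS, 5'UTR and 3'UTR sequences in transcript orientation plus
#' a per-transcript info table.  Transcripts whose CDS length is not a
#' multiple of 3 are retained but flagged (`incomplete_cds`); downstream
#' codon-level feature extraction refuses them.
#'
#' @param info data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `incomplete_cds`.
#' @param cds,utr5,utr3 [Biostrings::DNAStringSet] objects named by
#'   transcript id (UTR entries may be empty strings).
#' @param provenance list recording source files and counts.
#' @return A `transcript_catalog` object.
#' @export
new_transcript_catalog <- function(info, cds, utr5, utr3, provenance = list()) {
  stopifnot(is.data.frame(info),
            all(c("transcript_id", "gene_id", "chrom", "strand",
                  "incomplete_cds") %in% names(info)))
  if (anyDuplicated(info$transcript_id))
    stopf("duplicate transcript ids in catalog")
  if (!all(info$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  ids <- info$transcript_id
  for (s in list(cds, utr5, utr3))
    stopifnot(identical(names(s), ids))
  info$cds_len  <- Biostrings::width(cds)
  info$utr5_len <- Biostrings::width(utr5)
  info$utr3_len <- Biostrings::width(utr3)
  if (any(info$cds_len == 0L)) stopf("catalog contains a zero-length CDS")
  structure(list(info = info, cds = cds, utr5 = utr5, utr3 = utr3,
                 provenance = provenance),
            class = "transcript_catalog")
}

#' @export
print.transcript_catalog <- function(x, ...) {
  cat(sprintf("transcript_catalog: %d transcripts (%d genes), %d flagged incomplete CDS\n",
              nrow(x$info), length(unique(x$info$gene_id)),
              sum(x$info$incomplete_cds)))
  invisible(x)
}

#' @export
length.transcript_catalog <- function(x) nrow(x$info)

#' Gene ids represented in a catalog
#' @param catalog A `transcript_catalog`.
#' @param exclude_flagged Drop genes whose CDS length is not a multiple of 3.
#' @return Character vector of gene ids.
#' @export
catalog_genes <- function(catalog, exclude_flagged = FALSE) {
  info <- catalog$info
  if (exclude_flagged) info <- info[!info$incomplete_cds, , drop = FALSE]
  info$gene_id
}

## ---- interval helpers (1-based inclusive, matrices with columns start,end) ----

as_intervals <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  if (is.null(x) || NROW(x) == 0L)
    return(cbind(start = numeric(0), end = numeric(0)))
  m <- cbind(start = as.numeric(x[, 1]), end = as.numeric(x[, 2]))
  if (any(m[, "end"] < m[, "start"])) stopf("interval end precedes start")
  m[order(m[, "start"]), , drop = FALSE]
}

merge_intervals <- function(m) {
  if (nrow(m) <= 1L) return(m)
  out <- m[1, , drop = FALSE]
  for (i in 2:nrow(m)) {
    if (m[i, "start"] <= out[nrow(out), "end"] + 1)
      out[nrow(out), "end"] <- max(out[nrow(out), "end"], m[i, "end"])
    else out <- rbind(out, m[i, , drop = FALSE])
  }
  out
}

## Intersection of an interval set with [lo, hi].
clip_intervals <- function(m, lo, hi) {
  s <- pmax(m[, "start"], lo); e <- pmin(m[, "end"], hi)
  keep <- s <= e
  cbind(start = s[keep], end = e[keep])
}

interval_len <- function(m) if (nrow(m) == 0L) 0 else sum(m[, "end"] - m[, "start"] + 1)

#' Infer UTR intervals from exon and CDS structure
#'
#' Many GFF3 dialects omit explicit UTR features; the UTRs are then the
#' exonic regions 5' and 3' of the CDS in transcript orientation.
#'
#' @param model List with elements `cds_intervals` (matrix of 1-based
#'   inclusive start/end rows) and `strand` (`"+"` or `"-"`).
#' @param exon_intervals Matrix (or list of pairs) of exon intervals that
#'   must cover the CDS.
#' @return The model with `utr5_intervals` and `utr3_intervals` filled in.
#' @export
infer_utrs <- function(model, exon_intervals) {
  cds <- as_intervals(model$cds_intervals)
  ex  <- as_intervals(exon_intervals)
  mex <- merge_intervals(ex)
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, "start"] >= mex[, "start"] & cds[i, "end"] <= mex[, "end"])
    if (!inside) stopf("CDS interval %d..%d not contained in exons",
                       cds[i, "start"], cds[i, "end"])
  }
  left  <- clip_intervals(ex, -Inf, min(cds[, "start"]) - 1)
  right <- clip_intervals(ex, max(cds[, "end"]) + 1, Inf)
  if (identical(model$strand, "-")) {
    model$utr5_intervals <- right; model$utr3_intervals <- left
  } else {
    model$utr5_intervals <- left;  model$utr3_intervals <- right
  }
  model
}

## Extract and splice a sequence from the genome; reverse-complement on "-".
splice_sequence <- function(genome, chrom, intervals, strand) {
  if (nrow(intervals) == 0L) return(Biostrings::DNAString(""))
  if (!chrom %in% names(genome))
    stopf("chromosome '%s' present in GFF3 but missing from FASTA", chrom)
  chrlen <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(intervals[, "start"] < 1) || any(intervals[, "end"] > chrlen))
    stopf("interval outside sequence '%s' (length %d)", chrom, chrlen)
  pieces <- Biostrings::DNAStringSet(genome[[chrom]],
                                     start = intervals[, "start"],
                                     end = intervals[, "end"])
  seq <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  seq
}

## Cheap structural validation so a malformed GFF3 line is reported with its
## line number before the real parser runs.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (identical(ln, "##FASTA")) break
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nf != 9L)
      stopf("unparseable GFF3 line %d in '%s': expected 9 tab-separated fields, found %d",
            i, path, nf)
  }
  invisible(TRUE)
}

#' Load a transcript catalog from FASTA + GFF3
#'
#' Assembles one transcript model per mRNA from CDS (and, where present,
#' explicit `five_prime_UTR`/`three_prime_UTR`) features, inferring UTRs
#' from `exon` minus CDS when explicit UTR lines are absent.  Sequences are
#' spliced in transcript order and reverse-complemented on the minus strand.
#' When a gene has several isoforms the longest-CDS transcript represents
#' the gene by default.
#'
#' @param fasta_path Genome (or contig) FASTA; record names must match the
#'   GFF3 seqid column up to the first whitespace.
#' @param gff3_path GFF3 annotation containing CDS features.
#' @param id_attribute Attribute naming features (default `"ID"`); `Parent`
#'   links CDS/exon/UTR features to their mRNA.
#' @param collapse `"longest_cds"` (default) keeps one transcript per gene;
#'   `"none"` keeps every transcript.
#' @return A [new_transcript_catalog()] object.
#' @export
load_catalog <- function(fasta_path, gff3_path, id_attribute = "ID",
                         collapse = c("longest_cds", "none")) {
  collapse <- match.arg(collapse)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_gff3_lines(gff3_path)
  gff <- tryCatch(
    suppressWarnings(rtracklayer::import(gff3_path, format = "gff3")),
    error = function(e) stopf("failed to parse GFF3 '%s': %s",
                              gff3_path, conditionMessage(e)))
  mc <- S4Vectors::mcols(gff)
  ids <- if (id_attribute %in% names(mc)) as.character(mc[[id_attribute]])
         else rep(NA_character_, length(gff))
  plist <- if ("Parent" %in% names(mc)) mc$Parent
           else replicate(length(gff), character(0), simplify = FALSE)
  np <- lengths(plist)
  idx <- rep(seq_along(gff), pmax(np, 1L))
  parent <- rep(NA_character_, length(idx))
  parent[rep(np, pmax(np, 1L)) > 0L] <- as.character(unlist(plist))
  feat <- data.frame(
    seqid  = as.character(GenomicRanges::seqnames(gff))[idx],
    type   = as.character(mc$type)[idx],
    start  = GenomicRanges::start(gff)[idx],
    end    = GenomicRanges::end(gff)[idx],
    strand = as.character(GenomicRanges::strand(gff))[idx],
    id     = ids[idx],
    parent = parent,
    stringsAsFactors = FALSE)

  mrna <- feat[feat$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tid2gene <- setNames(ifelse(is.na(mrna$parent), mrna$id, mrna$parent), mrna$id)

  cds_rows <- feat[feat$type == "CDS", , drop = FALSE]
  if (nrow(cds_rows) == 0L) stopf("GFF3 '%s' contains no CDS features", gff3_path)
  ## CDS may attach directly to a gene in minimal annotations.
  cds_rows$tid <- ifelse(is.na(cds_rows$parent), cds_rows$id, cds_rows$parent)
  if (anyNA(cds_rows$tid)) stopf("CDS feature without ID or Parent attribute")

  part <- function(type) {
    r <- feat[feat$type == type, , drop = FALSE]
    r$tid <- ifelse(is.na(r$parent), r$id, r$parent)
    split(r, r$tid)
  }
  exon_by  <- part("exon")
  utr5_by  <- part("five_prime_UTR")
  utr3_by  <- part("three_prime_UTR")
  cds_by   <- split(cds_rows, cds_rows$tid)

  tids <- names(cds_by)
  recs <- vector("list", length(tids))
  for (k in seq_along(tids)) {
    tid <- tids[k]
    cr <- cds_by[[tid]]
    chrom <- unique(cr$seqid); strand <- unique(cr$strand)
    if (length(chrom) != 1L) stopf("transcript '%s' spans multiple seqids", tid)
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stopf("transcript '%s' has inconsistent or missing strand", tid)
    model <- list(transcript_id = tid,
                  gene_id = unname(tid2gene[tid]) %||% NA_character_,
                  chrom = chrom, strand = strand,
                  cds_intervals = as_intervals(cr[, c("start", "end")]))
    if (is.na(model$gene_id)) model$gene_id <- tid
    have_explicit <- !is.null(utr5_by[[tid]]) || !is.null(utr3_by[[tid]])
    if (have_explicit) {
      model$utr5_intervals <- if (is.null(utr5_by[[tid]]))
        cbind(start = numeric(0), end = numeric(0))
        else as_intervals(utr5_by[[tid]][, c("start", "end")])
      model$utr3_intervals <- if (is.null(utr3_by[[tid]]))
        cbind(start = numeric(0), end = numeric(0))
        else as_intervals(utr3_by[[tid]][, c("start", "end")])
    } else if (!is.null(exon_by[[tid]])) {
      model <- infer_utrs(model, as_intervals(exon_by[[tid]][, c("start", "end")]))
    } else {
      model$utr5_intervals <- cbind(start = numeric(0), end = numeric(0))
      model$utr3_intervals <- cbind(start = numeric(0), end = numeric(0))
    }
    recs[[k]] <- model
  }

  cds_seq  <- character(length(recs))
  utr5_seq <- character(length(recs))
  utr3_seq <- character(length(recs))
  for (k in seq_along(recs)) {
    m <- recs[[k]]
    cds_seq[k]  <- as.character(splice_sequence(genome, m$chrom, m$cds_intervals, m$strand))
    utr5_seq[k] <- as.character(splice_sequence(genome, m$chrom, m$utr5_intervals, m$strand))
    utr3_seq[k] <- as.character(splice_sequence(genome, m$chrom, m$utr3_intervals, m$strand))
  }
  info <- data.frame(
    transcript_id = vapply(recs, `[[`, "", "transcript_id"),
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    incomplete_cds = nchar(cds_seq) %% 3L != 0L,
    stringsAsFactors = FALSE)

  if (collapse == "longest_cds") {
    ord <- order(info$gene_id, -nchar(cds_seq), info$transcript_id)
    keep <- ord[!duplicated(info$gene_id[ord])]
    keep <- sort(keep)
    info <- info[keep, , drop = FALSE]
    cds_seq <- cds_seq[keep]; utr5_seq <- utr5_seq[keep]; utr3_seq <- utr3_seq[keep]
  }
  if (nrow(info) == 0L) stopf("no transcripts with CDS features found")
  rownames(info) <- NULL
  mk <- function(x) {
    s <- Biostrings::DNAStringSet(x); names(s) <- info$transcript_id; s
  }
  new_transcript_catalog(info, mk(cds_seq), mk(utr5_seq), mk(utr3_seq),
    provenance = list(fasta = fasta_path, gff3 = gff3_path,
                      n_transcripts = nrow(info),
                      n_genes = length(unique(info$gene_id)),
                      n_flagged = sum(info$incomplete_cds)))
}

#' Write extracted sequences and a manifest
#'
#' Emits one FASTA per region (`cds.fa`, `utr5.fa`, `utr3.fa`; empty UTRs are
#' omitted from their file) and `manifest.tsv` with per-transcript lengths
#' and the incomplete-CDS flag.
#'
#' @param catalog A `transcript_catalog`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(catalog$cds, file.path(dir, "cds.fa"))
  for (r in c("utr5", "utr3")) {
    s <- catalog[[r]]
    s <- s[Biostrings::width(s) > 0]
    Biostrings::writeXStringSet(s, file.path(dir, paste0(r, ".fa")))
  }
  info <- catalog$info
  write_tsv(info[, c("transcript_id", "gene_id", "cds_len", "utr5_len",
                     "utr3_len", "incomplete_cds")],
            file.path(dir, "manifest.tsv"))
  invisible(dir)
}
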