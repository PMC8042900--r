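## Tiny hand-built FASTA/GFF3 fixtures written to tempfiles at test time.

## genes: list of lists with fields id, seq (contig sequence), strand,
## cds = c(start, end) or matrix, and either utr5/utr3 intervals or exons.
write_toy_annotation <- function(genes,
                                 dir = withr::local_tempdir(
                                   .local_envir = parent.frame())) {
  fa <- file.path(dir, "toy.fa")
  gff <- file.path(dir, "toy.gff3")
  fasta_lines <- character(0)
  gff_lines <- "##gff-version 3"
  for (g in genes) {
    chrom <- paste0("chr_", g$id)
    fasta_lines <- c(fasta_lines, paste0(">", chrom), g$seq)
    ivl <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 2, byrow = TRUE)
    row <- function(type, m, attrs, phase = ".")
      sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              chrom, type, m[, 1], m[, 2], g$strand, phase, attrs)
    cds <- ivl(g$cds)
    span <- c(1, nchar(g$seq))
    tid <- paste0(g$id, ".t1")
    gff_lines <- c(gff_lines,
      row("gene", matrix(span, 1), sprintf("ID=%s", g$id)),
      row("mRNA", matrix(span, 1), sprintf("ID=%s;Parent=%s", tid, g$id)))
    if (!is.null(g$exons))
      gff_lines <- c(gff_lines, row("exon", ivl(g$exons),
                                    sprintf("Parent=%s", tid)))
    if (!is.null(g$utr5))
      gff_lines <- c(gff_lines, row("five_prime_UTR", ivl(g$utr5),
                                    sprintf("Parent=%s", tid)))
    gff_lines <- c(gff_lines, row("CDS", cds,
                                  sprintf("ID=%s.c;Parent=%s", tid, tid)))
    if (!is.null(g$utr3))
      gff_lines <- c(gff_lines, row("three_prime_UTR", ivl(g$utr3),
                                    sprintf("Parent=%s", tid)))
  }
  writeLines(fasta_lines, fa)
  writeLines(gff_lines, gff)
  list(fasta = fa, gff3 = gff, dir = dir)
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## small expression table fixture
toy_expression <- function(values, conds, reps = NULL) {
  reps <- reps %||% stats::ave(seq_along(conds), conds, FUN = seq_along)
  codoncontrib::expression_table(values, conds, reps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
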