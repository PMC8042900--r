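test_that("single-exon gene extracts strand-correct CDS and explicit UTRs", {
  g <- "CCATGAAGAAATGACC"
  fx <- write_toy_annotation(list(
    list(id = "gplus", seq = g, strand = "+", cds = c(3, 14),
         utr5 = c(1, 2), utr3 = c(15, 16)),
    list(id = "gminus", seq = g, strand = "-", cds = c(3, 14),
         utr5 = c(15, 16), utr3 = c(1, 2))))
  cat <- load_catalog(fx$fasta, fx$gff3)
  seqs <- setNames(as.character(cat$cds), cat$info$transcript_id)
  expect_identical(seqs[["gplus.t1"]], "ATGAAGAAATGA")
  expect_identical(as.character(cat$utr5[["gplus.t1"]]), "CC")
  expect_identical(as.character(cat$utr3[["gplus.t1"]]), "CC")
  ## minus strand: reverse complement, 5' end first
  expect_identical(seqs[["gminus.t1"]], "TCATTTCTTCAT")
  expect_false(any(cat$info$incomplete_cds))
})

test_that("UTRs are inferred from exon minus CDS in transcript orientation", {
  m <- infer_utrs(list(cds_intervals = matrix(c(3, 14), 1), strand = "+"),
                  matrix(c(1, 16), 1))
  expect_equal(unname(m$utr5_intervals), matrix(c(1, 2), 1))
  expect_equal(unname(m$utr3_intervals), matrix(c(15, 16), 1))

  m2 <- infer_utrs(list(cds_intervals = matrix(c(1, 16), 1), strand = "+"),
                   matrix(c(1, 16), 1))
  expect_equal(nrow(m2$utr5_intervals), 0)
  expect_equal(nrow(m2$utr3_intervals), 0)

  expect_error(infer_utrs(list(cds_intervals = matrix(c(3, 20), 1),
                               strand = "+"), matrix(c(1, 16), 1)),
               "not contained in exons")
})

test_that("multi-exon minus-strand splice matches a manual oracle", {
  set.seed(42)
  contig <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
  exons <- matrix(c(5, 20, 31, 50), 2, byrow = TRUE)
  cds <- matrix(c(10, 20, 31, 44), 2, byrow = TRUE)
  fx <- write_toy_annotation(list(
    list(id = "mx", seq = contig, strand = "-", cds = cds, exons = exons)))
  cat <- load_catalog(fx$fasta, fx$gff3)
  ## manual splice: concatenate genomic pieces ascending, then revcomp
  piece <- function(m) paste(vapply(seq_len(nrow(m)), function(i)
    substr(contig, m[i, 1], m[i, 2]), ""), collapse = "")
  expect_identical(as.character(cat$cds[[1]]), revcomp_chr(piece(cds)))
  ## minus strand: 5'UTR comes from the genomic right of the CDS
  expect_identical(as.character(cat$utr5[[1]]),
                   revcomp_chr(piece(matrix(c(45, 50), 1))))
  expect_identical(as.character(cat$utr3[[1]]),
                   revcomp_chr(piece(matrix(c(5, 9), 1))))
  ## inferred regions partition the spliced exons
  expect_equal(length(cat$utr5[[1]]) + length(cat$cds[[1]]) +
                 length(cat$utr3[[1]]),
               sum(exons[, 2] - exons[, 1] + 1))
})

test_that("loader errors are specific: missing seqid, bad line, empty catalog", {
  fx <- write_toy_annotation(list(
    list(id = "g1", seq = "CCATGAAGAAATGACC", strand = "+", cds = c(3, 14))))
  ## seqid present in GFF3 but absent from FASTA
  fa2 <- file.path(fx$dir, "wrong.fa")
  writeLines(c(">other", "ACGT"), fa2)
  expect_error(load_catalog(fa2, fx$gff3), "chr_g1")

  bad <- file.path(fx$dir, "bad.gff3")
  writeLines(c("##gff-version 3", "chr_g1\ttoy\tgene\t1\t16"), bad)
  expect_error(load_catalog(fx$fasta, bad), "line 2")

  empty <- file.path(fx$dir, "empty.gff3")
  writeLines(c("##gff-version 3",
               "chr_g1\ttoy\tgene\t1\t16\t.\t+\t.\tID=g1"), empty)
  expect_error(load_catalog(fx$fasta, empty), "no CDS")
})

test_that("longest-CDS transcript represents a multi-isoform gene; flagging works", {
  seq <- "CCATGAAGAAATGACCAA"
  dir <- withr::local_tempdir()
  writeLines(c(">c1", seq), file.path(dir, "g.fa"))
  writeLines(c("##gff-version 3",
    "c1\ttoy\tgene\t1\t18\t.\t+\t.\tID=g1",
    "c1\ttoy\tmRNA\t1\t18\t.\t+\t.\tID=t_short;Parent=g1",
    "c1\ttoy\tCDS\t3\t11\t.\t+\t0\tID=c1a;Parent=t_short",
    "c1\ttoy\tmRNA\t1\t18\t.\t+\t.\tID=t_long;Parent=g1",
    "c1\ttoy\tCDS\t3\t14\t.\t+\t0\tID=c1b;Parent=t_long",
    "c1\ttoy\tmRNA\t1\t18\t.\t+\t.\tID=t_flag;Parent=g1",
    "c1\ttoy\tCDS\t3\t15\t.\t+\t0\tID=c1c;Parent=t_flag"),
    file.path(dir, "g.gff3"))
  cat1 <- load_catalog(file.path(dir, "g.fa"), file.path(dir, "g.gff3"))
  expect_equal(nrow(cat1$info), 1L)
  expect_equal(cat1$info$transcript_id, "t_flag")  # 13 bases, longest
  expect_true(cat1$info$incomplete_cds)

  cat2 <- load_catalog(file.path(dir, "g.fa"), file.path(dir, "g.gff3"),
                       collapse = "none")
  expect_equal(sort(cat2$info$transcript_id),
               c("t_flag", "t_long", "t_short"))
  expect_equal(sum(cat2$info$incomplete_cds), 1L)
})

test_that("a 50-gene simulated annotation round-trips byte-for-byte", {
  spec <- simulation_spec(n_genes = 50, cds_len_mean = 60, cds_len_sd = 15,
                          cds_len_min = 20, seed = 99)
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(spec, dir = dir)
  reloaded <- load_catalog(file.path(dir, "genome.fa"),
                           file.path(dir, "annot.gff3"))
  ids <- sim$catalog$info$transcript_id
  expect_setequal(reloaded$info$transcript_id, ids)
  for (r in c("cds", "utr5", "utr3"))
    expect_identical(as.character(reloaded[[r]][ids]),
                     as.character(sim$catalog[[r]][ids]))
})

test_that("strand-flip + coordinate-mirror of the genome leaves sequences invariant", {
  spec <- simulation_spec(n_genes = 12, cds_len_mean = 50, cds_len_sd = 10,
                          cds_len_min = 20, seed = 5)
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(spec, dir = dir)
  fa <- file.path(dir, "genome.fa"); gff <- file.path(dir, "annot.gff3")
  genome <- Biostrings::readDNAStringSet(fa)
  lens <- setNames(Biostrings::width(genome), sub("\\s.*", "", names(genome)))
  mirrored <- Biostrings::reverseComplement(genome)
  fa2 <- file.path(dir, "mirror.fa"); gff2 <- file.path(dir, "mirror.gff3")
  Biostrings::writeXStringSet(mirrored, fa2)
  lines <- readLines(gff)
  body <- lines[!startsWith(lines, "#")]
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  G <- lens[f[, 1]]
  s <- as.integer(f[, 4]); e <- as.integer(f[, 5])
  f[, 4] <- as.character(G - e + 1L); f[, 5] <- as.character(G - s + 1L)
  f[, 7] <- ifelse(f[, 7] == "+", "-", "+")
  writeLines(c("##gff-version 3", apply(f, 1, paste, collapse = "\t")), gff2)
  cat1 <- load_catalog(fa, gff)
  cat2 <- load_catalog(fa2, gff2)
  ids <- cat1$info$transcript_id
  for (r in c("cds", "utr5", "utr3"))
    expect_identical(as.character(cat2[[r]][ids]),
                     as.character(cat1[[r]][ids]))
})
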