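## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic 32-bit sub-stream seed so that, e.g., resampling replicate
## noise never perturbs the sequence draw.  Names hash to small offsets.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x >= 0

## Write a data.frame as TSV without quoting or row names (the package's
## uniform tabular output format).
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
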