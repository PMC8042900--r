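## Independent brute-force oracles, deliberately written with none of the
## package's machinery (plain substring loops, rank formulas, combinatorial
## enumeration, lm-based exhaustive searches).

ORACLE_BASES <- c("A", "C", "G", "T")
ORACLE_CODONS <- sort(as.vector(outer(outer(ORACLE_BASES, ORACLE_BASES,
                                            paste0), ORACLE_BASES, paste0)))

## sliding-window in-frame codon counting
oracle_codons_of <- function(cds) {
  n <- nchar(cds)
  stopifnot(n %% 3 == 0)
  substring(cds, seq(1, n - 2, by = 3), seq(3, n, by = 3))
}

oracle_codon_freq <- function(cds) {
  cod <- oracle_codons_of(cds)
  cod <- cod[!grepl("N", cod, fixed = TRUE)]
  tab <- table(factor(cod, levels = ORACLE_CODONS))
  out <- as.numeric(tab) / max(sum(tab), 1)
  setNames(out, ORACLE_CODONS)
}

## translate-then-count amino-acid frequencies (standard genetic code)
oracle_aa_freq <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  cod <- oracle_codons_of(cds)
  cod <- cod[!grepl("N", cod, fixed = TRUE)]
  aa <- gc[cod]
  aa <- aa[aa != "*"]
  lv <- sort(setdiff(unique(gc), "*"))
  tab <- table(factor(aa, levels = lv))
  setNames(as.numeric(tab) / max(sum(tab), 1), lv)
}

oracle_base_freq <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch <- ch[ch %in% ORACLE_BASES]
  tab <- table(factor(ch, levels = ORACLE_BASES))
  setNames(as.numeric(tab) / sum(tab), ORACLE_BASES)
}

## random test sequence of n_codons whole codons (optionally with N noise)
random_cds <- function(n_codons, with_n = FALSE) {
  ch <- sample(ORACLE_BASES, 3 * n_codons, replace = TRUE)
  if (with_n) ch[sample(length(ch), max(1, length(ch) %/% 50))] <- "N"
  paste(ch, collapse = "")
}

## hand rank-formula Kruskal-Wallis H with tie correction
oracle_kw_h <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- rank(v)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(v)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

## exact upper-tail hypergeometric by pmf enumeration (choose products)
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Benjamini-Hochberg step-up by the direct formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

## Exhaustive MARS forward step: best reflected hinge pair over every
## (feature, knot) by direct least squares.  Returns per-step RSS.
oracle_mars_forward_rss <- function(x, y, max_terms, thresh = 0.001) {
  n <- nrow(x)
  B <- matrix(1, n, 1)
  tss <- sum((y - mean(y))^2)
  rss_steps <- numeric(0)
  rss_fit <- function(B) sum(lm.fit(B, y)$residuals^2)
  ## rank-degenerate hinge twins are not retained as basis functions
  add_col <- function(B, col)
    if (qr(cbind(B, col))$rank > qr(B)$rank) cbind(B, col) else B
  rss_prev <- rss_fit(B)
  repeat {
    if (ncol(B) + 2 > max_terms) break
    best <- list(rss = Inf)
    for (j in seq_len(ncol(x))) {
      for (t in sort(unique(x[, j]))) {
        h1 <- pmax(x[, j] - t, 0); h2 <- pmax(t - x[, j], 0)
        r <- rss_fit(cbind(B, h1, h2))
        if (r < best$rss - 1e-12) best <- list(rss = r, h1 = h1, h2 = h2)
      }
    }
    if (!is.finite(best$rss) || rss_prev - best$rss <= thresh * tss) break
    B <- add_col(add_col(B, best$h1), best$h2)
    rss_prev <- best$rss
    rss_steps <- c(rss_steps, best$rss)
  }
  rss_steps
}

## Exhaustive GCV-ranked subset search over all term subsets containing the
## intercept.
oracle_best_gcv_subset <- function(B, y, penalty) {
  n <- nrow(B)
  k0 <- ncol(B)
  gcv_of <- function(cols) {
    k <- length(cols)
    C <- k + penalty * (k - 1) / 2
    if (1 - C / n <= 0) return(Inf)
    rss <- sum(lm.fit(B[, cols, drop = FALSE], y)$residuals^2)
    (rss / n) / (1 - C / n)^2
  }
  best <- list(gcv = Inf, cols = 1L)
  others <- setdiff(seq_len(k0), 1L)
  for (size in 0:length(others)) {
    sets <- if (size == 0) list(integer(0))
            else asplit(utils::combn(others, size), 2)
    for (s in sets) {
      cols <- c(1L, as.integer(s))
      g <- gcv_of(cols)
      if (g < best$gcv - 1e-12 ||
          (abs(g - best$gcv) <= 1e-12 && length(cols) < length(best$cols)))
        best <- list(gcv = g, cols = cols)
    }
  }
  best
}

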