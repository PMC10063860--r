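# First-principles oracles, kept independent of the package implementation:
# sums of squares and closed-form test statistics only, no calls into
# saltpanel and no stats::var/t.test/cor.test.

oracle_var <- function(x) sum((x - mean(x))^2) / (length(x) - 1)

oracle_f <- function(a, b) {
  va <- oracle_var(a); vb <- oracle_var(b)
  if (va >= vb) {
    f <- va / vb; d1 <- length(a) - 1; d2 <- length(b) - 1
  } else {
    f <- vb / va; d1 <- length(b) - 1; d2 <- length(a) - 1
  }
  list(f = f, p = min(1, 2 * pf(f, d1, d2, lower.tail = FALSE)))
}

oracle_t <- function(a, b, pooled) {
  na <- length(a); nb <- length(b)
  if (pooled) {
    sp2 <- ((na - 1) * oracle_var(a) + (nb - 1) * oracle_var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- oracle_var(a) / na; vb <- oracle_var(b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  tt <- (mean(a) - mean(b)) / se
  list(t = tt, df = df, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  cx <- x - mean(x); cy <- y - mean(y)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
}

# Pairwise LSD significance matrix by brute force; `values` is a list of
# per-group numeric vectors.
oracle_lsd_sig <- function(values, alpha = 0.05) {
  k <- length(values)
  ns <- vapply(values, length, 0L)
  means <- vapply(values, mean, 0)
  sse <- sum(vapply(values, function(v) sum((v - mean(v))^2), 0))
  df_err <- sum(ns) - k
  mse <- sse / df_err
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    tt <- (means[i] - means[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    sig[i, j] <- 2 * pt(abs(tt), df_err, lower.tail = FALSE) < alpha
  }
  sig
}

letters_share <- function(l1, l2) {
  length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])) > 0
}

# minimal genotype-call table from a named list of allele tuples
calls_from_tuples <- function(tuples, gene = "G1", positions = NULL) {
  n_loci <- length(tuples[[1]])
  if (is.null(positions)) positions <- seq_len(n_loci) * 100L
  do.call(rbind, lapply(names(tuples), function(acc) {
    data.frame(accession_id = acc, gene = gene, position_bp = positions,
               allele = as.character(tuples[[acc]]), stringsAsFactors = FALSE)
  }))
}

# a small fast panel configuration for Monte-Carlo loops; default row 3 is
# Fm, a continuous index with no rounding/clamping
small_panel_config <- function(seed, n_accessions = 12L, null_effects = FALSE,
                               rows = 3L) {
  idx <- default_index_defs()[rows, , drop = FALSE]
  idx$sd_stress <- idx$sd
  if (null_effects) {
    idx$effect_sensitive <- 0
    idx$effect_tolerant <- 0
  }
  panel_config(n_accessions = n_accessions, frac_tolerant = 0.5,
               index_defs = idx, timepoints = 6, n_replicates = 3L,
               locus_defs = list(), ct_targets = NULL, seed = seed)
}
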