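#' Descriptive and inferential statistics for salt-tolerance indices
#'
#' The control-versus-stress statistical layer: distribution range and
#' coefficient of variation per group, the classical variance-ratio F test,
#' the independent-samples t test (pooled, with a Welch fallback when the
#' F test finds unequal variances), significance stars, and the Pearson
#' correlation matrix across indices.
#'
#' @name group_stats
NULL

#' Significance stars for a p value
#'
#' @param p p value(s).
#' @param levels significance thresholds, largest star first.
#' @param symbols symbols matching `levels`.
#' @return character vector: the symbol of the smallest threshold exceeded,
#'   `""` if none (or `p` is `NA`).
#' @export
significance_stars <- function(p, levels = c(0.001, 0.01, 0.05),
                               symbols = c("***", "**", "*")) {
  stopifnot(length(levels) == length(symbols), !is.unsorted(levels))
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    hit <- which(pi < levels)
    if (length(hit)) symbols[hit[1]] else ""
  }, character(1))
}

#' Range and coefficient of variation
#'
#' @param values numeric vector of at least two measurements.
#' @return list with `range_min`, `range_max`, `cv_percent`
#'   (100 x sample SD / mean, n-1 denominator).
#' @examples
#' summarize_values(c(2, 4, 6))  # CV 50
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("summarize_values: need >= 2 non-missing values")
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0 && s > 0) stop("summarize_values: CV undefined for zero mean")
  cv <- if (s == 0) 0 else 100 * s / m
  list(range_min = min(values), range_max = max(values), cv_percent = cv)
}

#' Variance-ratio F test
#'
#' Classical two-sample F test of equal variances, reported SPSS-style:
#' F is the larger sample variance over the smaller (so F >= 1), with the
#' two-sided p value from the F distribution using the matching degrees of
#' freedom. When one sample is constant the test is not applicable and
#' `f_value`/`p_value` are `NA` with `applicable = FALSE` (the printed
#' tables show a dash there); both samples constant is an error.
#'
#' @param sample_a,sample_b numeric vectors, each with >= 2 values.
#' @return list with `f_value`, `df1`, `df2`, `p_value`, `applicable`.
#' @export
variance_ratio_f <- function(sample_a, sample_b) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b)) {
    stop("variance_ratio_f: each sample needs >= 2 non-missing values")
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("variance_ratio_f: both samples have zero variance")
  if (va == 0 || vb == 0) {
    return(list(f_value = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                p_value = NA_real_, applicable = FALSE))
  }
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  list(f_value = f, df1 = df1, df2 = df2, p_value = p, applicable = TRUE)
}

#' Independent-samples t test with F-test-guided pooling
#'
#' Pooled-variance t test when the variance-ratio F test does not reject
#' equality at `alpha_f` (or is not applicable because one sample is
#' constant), otherwise the Welch unequal-variance t test — mirroring the
#' equal-variances-assumed convention of classical statistical software.
#'
#' @param sample_a,sample_b numeric vectors, each with >= 2 values.
#' @param equal_var_rule `"ftest"` (default), or force `"pooled"`/`"welch"`.
#' @param alpha_f significance level of the variance pre-test.
#' @return list with `t_value`, `df`, `p_value`, `method` ("pooled" or
#'   "welch"), `star` (`**` p < 0.01, `*` p < 0.05).
#' @export
independent_t <- function(sample_a, sample_b,
                          equal_var_rule = c("ftest", "pooled", "welch"),
                          alpha_f = 0.05) {
  equal_var_rule <- match.arg(equal_var_rule)
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 2L || length(b) < 2L || anyNA(a) || anyNA(b)) {
    stop("independent_t: each sample needs >= 2 non-missing values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    return(list(t_value = 0, df = length(a) + length(b) - 2L, p_value = 1,
                method = "pooled", star = ""))
  }
  pooled <- switch(equal_var_rule,
    pooled = TRUE,
    welch = FALSE,
    ftest = {
      ft <- variance_ratio_f(a, b)
      !ft$applicable || ft$p_value >= alpha_f
    })
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(t_value = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, method = if (pooled) "pooled" else "welch",
       star = significance_stars(tt$p.value, c(0.01, 0.05), c("**", "*")))
}

#' Per-index group summaries with control-versus-stress tests
#'
#' Builds the descriptive/inferential table for one group of accessions:
#' for each index and timepoint, the distribution range and CV% under each
#' treatment, and the F and t statistics comparing control with stress.
#' Accession replicate means are the statistical units.
#'
#' @param observations long trait table (see [build_index_matrix()]).
#' @param group_label label stored in the output (e.g. "salt-tolerant").
#' @param accession_ids accessions belonging to the group.
#' @param control,stress treatment labels.
#' @return data frame, one row per (index, timepoint, treatment), with
#'   columns `group`, `index`, `timepoint_d`, `treatment`, `n`, `range_min`,
#'   `range_max`, `cv_percent`, and (on the control rows) `f_value`,
#'   `t_value`, `p_f`, `p_t`, `star`.
#' @export
group_summary_table <- function(observations, group_label, accession_ids,
                                control = "CK", stress = "SST") {
  obs <- observations[observations$accession_id %in% accession_ids, , drop = FALSE]
  if (nrow(obs) == 0L) stop("group_summary_table: no observations for the group")
  combos <- unique(obs[, c("index", "timepoint_d")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    idx <- combos$index[i]; tp <- combos$timepoint_d[i]
    vals <- function(trt) {
      sl <- obs[obs$index == idx & obs$timepoint_d == tp & obs$treatment == trt, ]
      # accession replicate means are the units, as in the field's tables
      as.numeric(tapply(sl$value, sl$accession_id, mean))
    }
    ck <- vals(control); sst <- vals(stress)
    if (!length(ck) || !length(sst)) next
    f <- tryCatch(variance_ratio_f(ck, sst), error = function(e) NULL)
    t <- independent_t(ck, sst)
    for (trt in c(control, stress)) {
      v <- if (trt == control) ck else sst
      s <- summarize_values(v)
      rows[[length(rows) + 1L]] <- data.frame(
        group = group_label, index = idx, timepoint_d = tp, treatment = trt,
        n = length(v), range_min = s$range_min, range_max = s$range_max,
        cv_percent = s$cv_percent,
        f_value = if (trt == control && !is.null(f)) f$f_value else NA_real_,
        p_f = if (trt == control && !is.null(f)) f$p_value else NA_real_,
        t_value = if (trt == control) t$t_value else NA_real_,
        p_t = if (trt == control) t$p_value else NA_real_,
        star = if (trt == control) t$star else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pearson correlation matrix across indices
#'
#' Pairwise Pearson correlations over accessions with p values from the
#' t transform on n-2 degrees of freedom and stars at the 0.001/0.01/0.05
#' levels. Zero-variance columns yield `NA` correlations for their pairs,
#' with a warning.
#'
#' @param m accessions x indices matrix (see [build_index_matrix()]).
#' @return list of matrices `r`, `p`, `star` plus `indices`.
#' @export
correlation_matrix <- function(m) {
  if (nrow(m) < 3L) stop("correlation_matrix: need >= 3 accessions")
  p_ind <- ncol(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("correlation_matrix: zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; their correlations are reported as NA")
  }
  r <- p <- matrix(NA_real_, p_ind, p_ind, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p_ind)) {
    for (j in seq_len(p_ind)) {
      if (i == j) {
        if (sds[i] > 0) { r[i, j] <- 1; p[i, j] <- 0 }
        next
      }
      if (sds[i] == 0 || sds[j] == 0) next
      ct <- stats::cor.test(m[, i], m[, j], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  star <- matrix(significance_stars(p), p_ind, p_ind,
                 dimnames = dimnames(r))
  list(indices = colnames(m), r = r, p = p, star = star)
}
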