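#' Comparative-Ct relative expression
#'
#' Relative expression of target genes against a constant reference gene
#' (e.g. OsActin) by the comparative-Ct method, with each accession's own
#' 0 h sample as calibrator per (gene, tissue), and per-timepoint
#' two-accession comparisons.
#'
#' @name qpcr_expression
NULL

#' Fold change by the comparative-Ct method
#'
#' `dCt = ct_target - ct_ref`, `ddCt = dCt - calib_dct`,
#' `fold = efficiency^(-ddCt)` (efficiency 2 assumes perfect doubling per
#' cycle).
#'
#' @param ct_target target-gene Ct.
#' @param ct_ref reference-gene Ct in the same stratum.
#' @param calib_dct calibrator dCt (target minus reference at the
#'   calibrator sample).
#' @param efficiency amplification efficiency (default 2).
#' @return fold change (> 0).
#' @examples
#' ddct(25, 20, 5)      # 1: at the calibrator
#' ddct(24, 20, 5)      # 2: one cycle earlier
#' @export
ddct <- function(ct_target, ct_ref, calib_dct, efficiency = 2) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref)) ||
      any(!is.finite(calib_dct))) {
    stop("ddct: Ct inputs must be finite")
  }
  if (efficiency <= 1) stop("ddct: efficiency must exceed 1")
  efficiency^(-((ct_target - ct_ref) - calib_dct))
}

#' Relative expression table from a long Ct table
#'
#' For every (accession, target gene, tissue, treatment) series, reference
#' and target Cts are paired by replicate index, dCt computed per
#' replicate, and the calibrator dCt taken as the mean replicate dCt of the
#' same series at `calib_timepoint`. The stratum-level fold is
#' `efficiency^-(mean ddCt)` (the geometric-mean fold, exactly 1 at the
#' calibrator stratum); replicate-level folds are retained for the
#' t tests.
#'
#' @param ct data frame with columns `accession_id`, `gene`, `tissue`,
#'   `timepoint_h`, `treatment`, `replicate`, `ct`.
#' @param reference_gene reference gene name (default `"OsActin"`).
#' @param calib_timepoint calibrator timepoint in hours (default 0).
#' @param efficiency amplification efficiency.
#' @return list with `strata` (one row per stratum: `rel_expr`, `sd_fold`,
#'   `n`) and `replicates` (per-replicate folds).
#' @export
relative_expression <- function(ct, reference_gene = "OsActin",
                                calib_timepoint = 0, efficiency = 2) {
  needed <- c("accession_id", "gene", "tissue", "timepoint_h", "treatment",
              "replicate", "ct")
  missing_cols <- setdiff(needed, names(ct))
  if (length(missing_cols)) {
    stop("relative_expression: Ct table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!any(ct$gene == reference_gene)) {
    stop("relative_expression: reference gene '", reference_gene,
         "' absent from the Ct table")
  }
  ref <- ct[ct$gene == reference_gene, ]
  tgt <- ct[ct$gene != reference_gene, ]
  key <- function(d) paste(d$accession_id, d$tissue, d$timepoint_h,
                           d$treatment, d$replicate, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref))
  tgt$ct_ref <- ref_ct[key(tgt)]
  if (anyNA(tgt$ct_ref)) {
    bad <- tgt[is.na(tgt$ct_ref), c("accession_id", "gene", "tissue",
                                    "timepoint_h", "treatment", "replicate")]
    stop("relative_expression: missing reference-gene Ct for ",
         nrow(bad), " stratum/replicate combination(s), e.g. ",
         paste(unlist(bad[1, ]), collapse = " / "))
  }
  tgt$dct <- tgt$ct - tgt$ct_ref
  series <- paste(tgt$accession_id, tgt$gene, tgt$tissue, tgt$treatment, sep = "\r")
  calib <- tgt$timepoint_h == calib_timepoint
  if (!any(calib)) stop("relative_expression: no calibrator samples at ",
                        calib_timepoint, " h")
  calib_dct <- tapply(tgt$dct[calib], series[calib], mean)
  tgt$calib_dct <- calib_dct[series]
  if (anyNA(tgt$calib_dct)) {
    stop("relative_expression: series without a calibrator sample at ",
         calib_timepoint, " h")
  }
  tgt$ddct <- tgt$dct - tgt$calib_dct
  tgt$fold <- efficiency^(-tgt$ddct)

  stratum <- interaction(tgt$accession_id, tgt$gene, tgt$tissue,
                         tgt$timepoint_h, tgt$treatment, drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(tgt, stratum), function(d) {
    data.frame(accession_id = d$accession_id[1], gene = d$gene[1],
               tissue = d$tissue[1], timepoint_h = d$timepoint_h[1],
               treatment = d$treatment[1], n = nrow(d),
               rel_expr = efficiency^(-mean(d$ddct)),
               sd_fold = stats::sd(d$fold), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg <- agg[order(agg$gene, agg$tissue, agg$accession_id, agg$timepoint_h), ]
  reps <- tgt[, c("accession_id", "gene", "tissue", "timepoint_h",
                  "treatment", "replicate", "dct", "ddct", "fold")]
  list(strata = agg, replicates = reps)
}

#' Per-timepoint comparison of two accessions
#'
#' Independent t test on replicate-level folds (or ddCt values) for every
#' (gene, tissue, timepoint) stratum shared by the two accessions, with
#' stars at the 0.01/0.05 levels. Strata missing on either side are skipped
#' with a warning.
#'
#' @param expr result of [relative_expression()].
#' @param accession_a,accession_b the two accessions to compare.
#' @param scale `"fold"` (default) or `"ddct"`.
#' @return data frame with per-stratum means, `t_value`, `p_value`, `star`.
#' @export
compare_timepoints <- function(expr, accession_a, accession_b,
                               scale = c("fold", "ddct")) {
  scale <- match.arg(scale)
  reps <- expr$replicates
  col <- if (scale == "fold") "fold" else "ddct"
  a <- reps[reps$accession_id == accession_a, ]
  b <- reps[reps$accession_id == accession_b, ]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("compare_timepoints: accession absent from the expression table")
  }
  strata <- unique(rbind(a, b)[, c("gene", "tissue", "timepoint_h", "treatment")])
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    pick <- function(d) d[d$gene == st$gene & d$tissue == st$tissue &
                            d$timepoint_h == st$timepoint_h &
                            d$treatment == st$treatment, col]
    va <- pick(a); vb <- pick(b)
    if (length(va) < 2L || length(vb) < 2L) { skipped <- skipped + 1L; next }
    tt <- independent_t(va, vb)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = st$gene, tissue = st$tissue, timepoint_h = st$timepoint_h,
      treatment = st$treatment, mean_a = mean(va), mean_b = mean(vb),
      t_value = tt$t_value, p_value = tt$p_value, star = tt$star,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    warning("compare_timepoints: skipped ", skipped,
            " stratum/strata with < 2 replicates on one side")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
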