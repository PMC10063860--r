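#' Bundled reference worked example
#'
#' A transcribed reference evaluation of a 12-accession japonica rice
#' panel screened at 125 mmol/L NaCl: accession metadata with prior
#' composite scores, the PCA loading table with eigenvalues and
#' contribution rates, and the membership-function table with composite
#' D values and ranking. It is bundled so the composite-scoring arithmetic
#' (weights, D values, ranking, loading/eigenvalue consistency) can be
#' validated end to end without raw field data.
#'
#' @return list with data frames `accessions`, `loadings`, `pca_summary`,
#'   `membership`.
#' @export
reference_panel <- function() {
  path <- function(f) system.file("extdata", f, package = "saltpanel",
                                  mustWork = TRUE)
  list(accessions = read_tsv(path("ref_accessions.tsv")),
       loadings = read_tsv(path("ref_loadings.tsv")),
       pca_summary = read_tsv(path("ref_pca_summary.tsv")),
       membership = read_tsv(path("ref_membership.tsv")))
}

#' Validate the composite-scoring arithmetic on the bundled reference
#'
#' Recomputes, from the bundled reference tables: the contribution-rate
#' weights from the printed proportions, every composite D value from the
#' printed membership values, the ranking, the cumulative contribution of
#' the retained components, and the per-component sum of squared loadings
#' against the printed eigenvalues — and compares each with the printed
#' value at the stated tolerance.
#'
#' @param d_tolerance allowed absolute deviation for recomputed D values
#'   (default 0.001, the print precision).
#' @param eigen_tolerance allowed deviation of the sum of squared loadings
#'   from the printed eigenvalue.
#' @return data frame of checks (`check`, `expected`, `got`, `pass`) with
#'   attribute `pass` (overall logical); of class
#'   `"saltpanel_fixture_report"`.
#' @export
validate_reference_fixture <- function(d_tolerance = 0.001,
                                       eigen_tolerance = 0.01) {
  ref <- reference_panel()
  w <- pc_weights(ref$pca_summary$proportion)
  checks <- data.frame(check = character(0), expected = numeric(0),
                       got = numeric(0), pass = logical(0),
                       stringsAsFactors = FALSE)
  add <- function(check, expected, got, tol) {
    rbind(checks, data.frame(check = check, expected = expected, got = got,
                             pass = abs(got - expected) <= tol,
                             stringsAsFactors = FALSE))
  }
  printed_w <- c(0.648, 0.216, 0.136)
  for (j in 1:3) {
    checks <- add(paste0("weight_PC", j), printed_w[j], round(w[j], 3), 0)
  }
  u <- as.matrix(ref$membership[, c("u_PC1", "u_PC2", "u_PC3")])
  d <- apply(u, 1, d_value, weights = w)
  for (i in seq_len(nrow(u))) {
    checks <- add(paste0("D_", ref$membership$name[i]),
                  ref$membership$D[i], d[i], d_tolerance)
  }
  rk <- rank_and_select(stats::setNames(d, ref$membership$name))
  checks <- add("rank_agreement",
                expected = 1,
                got = as.numeric(all(rk$rank[ref$membership$name] ==
                                       ref$membership$rank)),
                tol = 0)
  checks <- add("cumulative_contribution",
                ref$pca_summary$cumulative[3],
                100 * sum(ref$pca_summary$eigenvalue) / nrow(ref$loadings),
                0.01)
  for (j in 1:3) {
    ss <- sum(ref$loadings[[paste0("PC", j)]]^2)
    checks <- add(paste0("sum_sq_loadings_PC", j),
                  ref$pca_summary$eigenvalue[j], ss, eigen_tolerance)
  }
  structure(checks, pass = all(checks$pass),
            class = c("saltpanel_fixture_report", "data.frame"))
}

#' @export
print.saltpanel_fixture_report <- function(x, ...) {
  cat("Reference-fixture validation:",
      if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  print.data.frame(transform(x, expected = signif(expected, 6),
                             got = signif(got, 6)), row.names = FALSE)
  invisible(x)
}
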