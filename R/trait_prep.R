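#' Derived salt-tolerance indices and the accession-by-index matrix
#'
#' Raw seedling measurements (visual salt-tolerance scores, SPAD readings,
#' chlorophyll-fluorescence parameters, shoot/root Na+ and K+ contents,
#' conductivities) are turned into the 13-index table that feeds the
#' downstream statistics and the composite D-value evaluation.
#'
#' @name trait_prep
NULL

#' Ratio-to-control index as a percentage
#'
#' Expresses a measurement under salt stress relative to the same
#' accession's control measurement, e.g. relative SPAD chlorophyll content
#' (RSPAD), so that control material reads 100.
#'
#' @param sst_value measurement under salt stress.
#' @param ck_value matching control measurement; must be positive.
#' @return `100 * sst_value / ck_value` (percent).
#' @examples
#' relative_index(45, 50)  # 90
#' @export
relative_index <- function(sst_value, ck_value) {
  stopifnot(is.numeric(sst_value), is.numeric(ck_value))
  if (any(!is.finite(ck_value)) || any(ck_value <= 0)) {
    stop("relative_index: 'ck_value' must be finite and > 0")
  }
  100 * sst_value / ck_value
}

#' Electrolyte leakage from paired conductivity readings
#'
#' Cell-membrane permeability assay: `l1` is the conductivity of the bathing
#' solution after vacuum infiltration of fresh leaf pieces, `l2` the
#' conductivity of the same sample after boiling (total electrolytes).
#' Leakage is `l1 / l2` expressed as a percentage; the boiled reading bounds
#' the fresh one, so `l1 > l2` is rejected as a measurement error.
#'
#' @param l1 conductivity before boiling (>= 0).
#' @param l2 conductivity after boiling (> 0).
#' @return leakage percentage in `[0, 100]`.
#' @examples
#' electrolyte_leakage(10, 40)  # 25
#' @export
electrolyte_leakage <- function(l1, l2) {
  stopifnot(is.numeric(l1), is.numeric(l2))
  if (any(!is.finite(l2)) || any(l2 <= 0)) {
    stop("electrolyte_leakage: 'l2' (boiled-extract conductivity) must be > 0")
  }
  if (any(!is.finite(l1)) || any(l1 < 0)) {
    stop("electrolyte_leakage: 'l1' must be finite and >= 0")
  }
  if (any(l1 > l2)) {
    stop("electrolyte_leakage: 'l1' exceeds 'l2'; boiled-extract conductivity must bound the fresh reading")
  }
  100 * l1 / l2
}

#' Na+/K+ ratio
#'
#' Ion-homeostasis index: sodium content divided by potassium content
#' (both mg per g dry weight) for a given tissue.
#'
#' @param na Na+ content (>= 0).
#' @param k K+ content (> 0).
#' @return the ratio `na / k`.
#' @examples
#' na_k_ratio(6, 3)  # 2
#' @export
na_k_ratio <- function(na, k) {
  stopifnot(is.numeric(na), is.numeric(k))
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("na_k_ratio: 'k' must be finite and > 0")
  }
  na / k
}

#' Assemble the accession-by-index mean matrix
#'
#' Slices a long trait-observation table to one treatment and timepoint and
#' averages replicates into an accessions x indices matrix. Assembly is
#' complete-case: any missing (accession, index) cell aborts with a message
#' listing the gaps, because silent imputation would corrupt the composite
#' ranking downstream.
#'
#' @param observations data frame with columns `accession_id`, `index`,
#'   `treatment`, `timepoint_d`, `replicate`, `value` (the trait TSV layout;
#'   a `tissue` column may be present and is ignored for assembly).
#' @param treatment treatment label to slice, e.g. `"SST"`.
#' @param timepoint_d timepoint (days) to slice.
#' @param accessions,indices optional orderings; default is order of first
#'   appearance in `observations`.
#' @return numeric matrix (accessions in rows, indices in columns) of
#'   replicate means, with `treatment` and `timepoint_d` attributes.
#' @export
build_index_matrix <- function(observations, treatment, timepoint_d,
                               accessions = NULL, indices = NULL) {
  required <- c("accession_id", "index", "treatment", "timepoint_d", "value")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols)) {
    stop("build_index_matrix: observations lack column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  slice <- observations[observations$treatment == treatment &
                          observations$timepoint_d == timepoint_d, , drop = FALSE]
  if (nrow(slice) == 0L) {
    stop("build_index_matrix: no observations for treatment '", treatment,
         "' at timepoint ", timepoint_d, " d")
  }
  if (is.null(accessions)) accessions <- unique(observations$accession_id)
  if (is.null(indices)) indices <- unique(observations$index)

  m <- matrix(NA_real_, length(accessions), length(indices),
              dimnames = list(accessions, indices))
  agg <- stats::aggregate(value ~ accession_id + index, data = slice, FUN = mean)
  keep <- agg$accession_id %in% accessions & agg$index %in% indices
  agg <- agg[keep, , drop = FALSE]
  m[cbind(match(agg$accession_id, accessions), match(agg$index, indices))] <- agg$value

  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    gap_txt <- paste0("(", rownames(m)[gaps[, 1]], ", ", colnames(m)[gaps[, 2]], ")")
    stop("build_index_matrix: missing cells: ", paste(gap_txt, collapse = ", "))
  }
  structure(m, treatment = treatment, timepoint_d = timepoint_d)
}

#' Write an index matrix as TSV
#'
#' @param m matrix from [build_index_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_index_matrix <- function(m, path) {
  df <- data.frame(accession_id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
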