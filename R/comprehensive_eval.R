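#' Membership-function / index-weight composite evaluation
#'
#' The scoring procedure at the heart of the package: principal component
#' analysis of the correlation matrix of the accession-by-index table,
#' retention of components with eigenvalue > 1 (Kaiser rule), min-max
#' membership functions u(X_PCj) on the retained component scores,
#' contribution-rate weights, and the weighted composite D value used to
#' rank accessions and pick the extreme tolerant/sensitive entries.
#'
#' @name comprehensive_eval
NULL

#' Correlation-matrix PCA
#'
#' Columns are z-scored (n-1 SD) and the correlation matrix is
#' eigen-decomposed. Loadings are eigenvectors scaled by sqrt(eigenvalue)
#' (component loadings, i.e. index-component correlations); scores are the
#' z-scored data projected on the unit eigenvectors. Each component is
#' sign-oriented so that its largest-magnitude loading is positive, since
#' eigenvector sign is solver-arbitrary.
#'
#' @param m accessions x indices numeric matrix; >= 3 rows, >= 2 columns,
#'   every column with positive variance.
#' @return object of class `"saltpanel_pca"`: list with `eigenvalues`,
#'   `proportion` (percent), `cumulative` (percent), `loadings`
#'   (indices x components), `scores` (accessions x components),
#'   `n_retained` (Kaiser rule, see [retain_components()]).
#' @export
run_pca <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop("run_pca: need >= 3 accessions")
  if (ncol(m) < 2L) stop("run_pca: need >= 2 indices")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("run_pca: zero-variance index column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  if (ncol(m) > nrow(m)) {
    warning("run_pca: more indices than accessions; trailing eigenvalues are zero")
  }
  z <- scale(m)
  ev <- eigen(stats::cor(m), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  vec <- ev$vectors
  # orient: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(vec))) {
    k <- which.max(abs(vec[, j]))
    if (vec[k, j] < 0) vec[, j] <- -vec[, j]
  }
  comp_names <- paste0("PC", seq_along(lambda))
  loadings <- sweep(vec, 2, sqrt(lambda), `*`)
  dimnames(loadings) <- list(colnames(m), comp_names)
  scores <- z %*% vec
  dimnames(scores) <- list(rownames(m), comp_names)
  proportion <- 100 * lambda / ncol(m)
  structure(list(
    eigenvalues = stats::setNames(lambda, comp_names),
    proportion = stats::setNames(proportion, comp_names),
    cumulative = stats::setNames(cumsum(proportion), comp_names),
    loadings = loadings, scores = scores,
    n_retained = retain_components(lambda)
  ), class = "saltpanel_pca")
}

#' Kaiser-rule component retention
#'
#' Number of eigenvalues strictly greater than `threshold`; at least one
#' component is always retained so the composite score is defined.
#'
#' @param eigenvalues numeric vector, descending.
#' @param threshold retention threshold (default 1, correlation-matrix PCA).
#' @return integer count of retained components.
#' @export
retain_components <- function(eigenvalues, threshold = 1.0) {
  if (length(eigenvalues) == 0L) stop("retain_components: empty eigenvalue list")
  if (is.unsorted(rev(eigenvalues))) stop("retain_components: eigenvalues must be descending")
  max(1L, sum(eigenvalues > threshold))
}

#' Min-max membership function
#'
#' Maps one component's accession scores to `[0, 1]`:
#' `u_i = (x_i - min) / (max - min)`. The best accession on the component
#' gets 1, the worst 0.
#'
#' @param scores_column numeric vector of component scores (>= 2 values).
#' @return membership values in `[0, 1]`.
#' @export
membership <- function(scores_column) {
  x <- as.numeric(scores_column)
  if (length(x) < 2L || anyNA(x)) stop("membership: need >= 2 non-missing scores")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    stop("membership: degenerate (constant) score column; membership undefined")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Contribution-rate index weights
#'
#' Weight of each retained component is its variance-contribution
#' proportion divided by the summed proportions of the retained set.
#'
#' @param proportions percent of variance explained per retained component.
#' @return weights summing to 1.
#' @examples
#' pc_weights(c(58.471, 19.509, 12.273))  # 0.648 0.216 0.136 (3 dp)
#' @export
pc_weights <- function(proportions) {
  p <- as.numeric(proportions)
  if (length(p) == 0L || anyNA(p) || any(p <= 0)) {
    stop("pc_weights: proportions must be positive")
  }
  p / sum(p)
}

#' Composite D value
#'
#' Weighted sum of an accession's membership values over the retained
#' components: `D = sum(u_j * w_j)`.
#'
#' @param u_row membership values in `[0, 1]`.
#' @param weights component weights summing to 1.
#' @return composite score in `[0, 1]`.
#' @export
d_value <- function(u_row, weights) {
  u <- as.numeric(u_row); w <- as.numeric(weights)
  if (length(u) != length(w)) stop("d_value: 'u_row' and 'weights' differ in length")
  if (anyNA(u) || anyNA(w)) stop("d_value: missing values")
  if (any(u < -1e-9) || any(u > 1 + 1e-9)) stop("d_value: memberships must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-6) stop("d_value: weights must sum to 1")
  sum(u * w)
}

#' Rank accessions by composite D value
#'
#' Descending D order; ties broken lexicographically by accession name.
#'
#' @param d_values named numeric vector of composite D values (>= 2).
#' @return list with `rank` (named integer vector, 1 = largest D),
#'   `order` (accession names best to worst), `top`, `bottom`, and
#'   `ties` (TRUE if any D values coincide).
#' @export
rank_and_select <- function(d_values) {
  d <- d_values
  if (length(d) < 2L) stop("rank_and_select: need >= 2 accessions")
  if (is.null(names(d))) names(d) <- paste0("acc", seq_along(d))
  ord <- order(-d, names(d), method = "radix")
  rk <- integer(length(d)); rk[ord] <- seq_along(d)
  names(rk) <- names(d)
  list(rank = rk, order = names(d)[ord],
       top = names(d)[ord[1]], bottom = names(d)[ord[length(d)]],
       ties = anyDuplicated(d) > 0L)
}

#' Full comprehensive evaluation of an index matrix
#'
#' Convenience pipeline: [run_pca()], [retain_components()],
#' [membership()] per retained component, [pc_weights()], [d_value()] per
#' accession, [rank_and_select()].
#'
#' @param m accessions x indices matrix (see [build_index_matrix()]).
#' @param threshold eigenvalue retention threshold.
#' @return list with the `"saltpanel_pca"` object (`pca`) and a
#'   `membership` data frame (u columns, `D`, `rank`) plus `weights`,
#'   `top`, `bottom`.
#' @export
evaluate_panel <- function(m, threshold = 1.0) {
  pca <- run_pca(m)
  k <- retain_components(pca$eigenvalues, threshold)
  u <- sapply(seq_len(k), function(j) membership(pca$scores[, j]))
  u <- matrix(u, nrow = nrow(m),
              dimnames = list(rownames(m), paste0("u_PC", seq_len(k))))
  w <- pc_weights(pca$proportion[seq_len(k)])
  d <- apply(u, 1, d_value, weights = w)
  rs <- rank_and_select(d)
  tab <- data.frame(accession_id = rownames(m), u, D = d, rank = rs$rank[rownames(m)],
                    row.names = NULL, check.names = FALSE)
  list(pca = pca, membership = tab, weights = stats::setNames(w, paste0("PC", seq_len(k))),
       top = rs$top, bottom = rs$bottom)
}

#' @export
print.saltpanel_pca <- function(x, ...) {
  k <- x$n_retained
  cat("Correlation-matrix PCA:", length(x$eigenvalues), "indices,",
      nrow(x$scores), "accessions\n")
  tab <- rbind(Eigenvalue = x$eigenvalues,
               `Proportion (%)` = x$proportion,
               `Cumulative (%)` = x$cumulative)
  print(round(tab[, seq_len(min(ncol(tab), max(k, 3L)))], 3))
  cat("Retained (eigenvalue > 1):", k, "component(s)\n")
  invisible(x)
}
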