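#' Run configuration and high-level commands
#'
#' A declarative YAML run configuration drives the three high-level
#' entry points: [cmd_simulate()] (write a synthetic panel to TSV),
#' [cmd_evaluate()] (full analysis of a panel's TSV inputs) and
#' [cmd_validate_fixture()] (check the bundled reference arithmetic).
#' `inst/scripts/saltpanel-cli.R` wraps them for shell use.
#'
#' @name run
NULL

default_run_config <- function() {
  list(
    inputs = list(traits = "traits.tsv", genotypes = "genotypes.tsv",
                  ct = "ct.tsv"),
    slice = list(treatment = "SST", timepoint_d = 6),
    thresholds = list(eigenvalue = 1.0, alpha = 0.05, min_group_size = 2),
    rounding = 3,
    reference_gene = "OsActin",
    seed = 1,
    output_dir = "saltpanel-out")
}

#' Read a run configuration
#'
#' Reads a YAML key/value configuration and fills unset entries with the
#' defaults (stress slice at day 6, eigenvalue threshold 1, alpha 0.05,
#' minimum haplotype group size 2, 3-decimal reporting).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("run_config: no such file: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  alpha <- cfg$thresholds$alpha
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("run_config: thresholds$alpha must lie in (0, 1)")
  }
  cfg
}

run_log <- function(cfg, out_dir, extra = list()) {
  log <- c(list(package = "saltpanel",
                version = as.character(utils::packageVersion("saltpanel")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = cfg), extra)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a panel and write its tables
#'
#' @param cfg run configuration (see [run_config()]); `cfg$seed` seeds the
#'   generator.
#' @param panel_cfg optional [panel_config()] overriding the default panel
#'   design (its seed is replaced by `cfg$seed`).
#' @return file paths written, invisibly.
#' @export
cmd_simulate <- function(cfg = run_config(), panel_cfg = NULL) {
  if (is.null(panel_cfg)) panel_cfg <- panel_config(seed = cfg$seed)
  else panel_cfg$seed <- as.integer(cfg$seed)
  panel <- generate_panel(panel_cfg)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- panel_to_tables(panel, out)
  run_log(cfg, out, list(command = "simulate",
                         n_accessions = nrow(panel$accessions)))
  invisible(paths)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Evaluate a panel from its TSV inputs
#'
#' Full pipeline: read the trait (and optionally genotype and Ct) tables,
#' assemble the accession-by-index matrix for the configured slice, compute
#' the correlation matrix, run the comprehensive membership-function /
#' index-weight evaluation, per-gene and combined haplotype association
#' against the stress STS means, SSR dose trends, and relative expression.
#' Writes TSV reports plus a JSON summary and run log into
#' `cfg$output_dir`.
#'
#' @param cfg run configuration (see [run_config()]). Input paths are taken
#'   from `cfg$inputs`; missing genotype/Ct files skip those stages, but a
#'   missing trait file is an error.
#' @return list with the in-memory results (`index_matrix`, `correlation`,
#'   `evaluation`, `haplotypes`, `expression`), invisibly.
#' @export
cmd_evaluate <- function(cfg = run_config()) {
  if (!file.exists(cfg$inputs$traits)) {
    stop("cmd_evaluate: trait table not found: ", cfg$inputs$traits)
  }
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  digits <- cfg$rounding

  obs <- read_tsv(cfg$inputs$traits)
  m <- build_index_matrix(obs, cfg$slice$treatment, cfg$slice$timepoint_d)
  write_index_matrix(m, file.path(out, "index_matrix.tsv"))

  cm <- correlation_matrix(m)
  write_tsv_exact(data.frame(index = rownames(cm$r),
                             round(as.data.frame(cm$r), digits),
                             check.names = FALSE),
                  file.path(out, "correlation_r.tsv"))
  utils::write.table(data.frame(index = rownames(cm$star),
                                as.data.frame(cm$star), check.names = FALSE),
                     file.path(out, "correlation_stars.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ev <- evaluate_panel(m, threshold = cfg$thresholds$eigenvalue)
  k <- ev$pca$n_retained
  load_tab <- data.frame(index = rownames(ev$pca$loadings),
                         round(as.data.frame(ev$pca$loadings[, seq_len(k),
                                                             drop = FALSE]), digits),
                         check.names = FALSE)
  summ <- data.frame(component = paste0("PC", seq_len(k)),
                     eigenvalue = round(ev$pca$eigenvalues[seq_len(k)], digits),
                     proportion = round(ev$pca$proportion[seq_len(k)], digits),
                     cumulative = round(ev$pca$cumulative[seq_len(k)], digits),
                     weight = round(ev$weights, digits))
  utils::write.table(load_tab, file.path(out, "pca_loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ, file.path(out, "pca_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  memb <- round_df(ev$membership, digits)
  utils::write.table(memb, file.path(out, "membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  hap_results <- NULL
  if (!is.null(cfg$inputs$genotypes) && file.exists(cfg$inputs$genotypes)) {
    gen <- read_tsv(cfg$inputs$genotypes)
    gen$allele <- as.character(gen$allele)
    sts_obs <- obs[obs$index == "STS" & obs$treatment == cfg$slice$treatment &
                     obs$timepoint_d == cfg$slice$timepoint_d, ]
    sts <- tapply(sts_obs$value, sts_obs$accession_id, mean)
    hap_results <- list()
    for (gene in unique(gen$gene)) {
      groups <- group_haplotypes(gen, gene)
      assoc <- anova_lsd(groups, sts, alpha = cfg$thresholds$alpha,
                         min_group_size = cfg$thresholds$min_group_size)
      tab <- merge(haplotypes_as_data_frame(groups), assoc$table,
                   by = c("label", "n"), sort = FALSE)
      utils::write.table(round_df(tab, digits),
                         file.path(out, paste0("haplotypes_",
                                               gsub("[^A-Za-z0-9]+", "_", gene),
                                               ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hap_results[[gene]] <- list(groups = groups, assoc = assoc)
    }
    all_loci <- unique(gen[, c("gene", "position_bp")])
    combined <- combine_loci(gen, all_loci)
    comb_assoc <- anova_lsd(combined, sts, alpha = cfg$thresholds$alpha,
                            min_group_size = cfg$thresholds$min_group_size)
    comb_tab <- merge(haplotypes_as_data_frame(combined), comb_assoc$table,
                      by = c("label", "n"), sort = FALSE)
    utils::write.table(round_df(comb_tab, digits),
                       file.path(out, "haplotypes_combined.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hap_results$combined <- list(groups = combined, assoc = comb_assoc)
  } else if (!is.null(cfg$inputs$genotypes) && !file.exists(cfg$inputs$genotypes)) {
    message("cmd_evaluate: genotype table not found (",
            cfg$inputs$genotypes, "); haplotype stage skipped")
  }

  expr <- NULL
  if (!is.null(cfg$inputs$ct) && file.exists(cfg$inputs$ct)) {
    ct <- read_tsv(cfg$inputs$ct)
    expr <- relative_expression(ct, reference_gene = cfg$reference_gene)
    utils::write.table(round_df(expr$strata, digits),
                       file.path(out, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary_json <- list(
    n_accessions = nrow(m), n_indices = ncol(m),
    slice = cfg$slice,
    retained_components = k,
    eigenvalues = round(unname(ev$pca$eigenvalues[seq_len(k)]), digits),
    weights = round(unname(ev$weights), digits),
    cumulative_contribution = round(unname(ev$pca$cumulative[k]), digits),
    top_accession = ev$top, bottom_accession = ev$bottom,
    d_values = as.list(round(stats::setNames(ev$membership$D,
                                             ev$membership$accession_id), digits)))
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_log(cfg, out, list(command = "evaluate"))

  invisible(list(index_matrix = m, correlation = cm, evaluation = ev,
                 haplotypes = hap_results, expression = expr))
}

#' Validate the bundled reference fixture
#'
#' Thin command wrapper around [validate_reference_fixture()]; see there.
#'
#' @param ... passed to [validate_reference_fixture()].
#' @return the fixture report (invisibly); signals an error if any check
#'   fails, so shell wrappers exit non-zero.
#' @export
cmd_validate_fixture <- function(...) {
  report <- validate_reference_fixture(...)
  print(report)
  if (!attr(report, "pass")) {
    stop("cmd_validate_fixture: reference-fixture validation failed")
  }
  invisible(report)
}
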