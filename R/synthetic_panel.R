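#' Synthetic germplasm-panel generator
#'
#' Generates a complete synthetic rice germplasm panel — trait
#' observations, genotype calls and qPCR Ct records — with the statistical
#' structure the downstream analysis assumes: a two-class
#' (tolerant/sensitive) panel measured for 13 indices under control (CK)
#' and 125 mmol/L NaCl stress (SST), genotyped at SNP/indel/SSR loci whose
#' alleles shift the salt-tolerance score, and assayed by qPCR against a
#' constant reference gene. Latent per-accession tolerance and true locus
#' effects are retained so recovery tests can compare estimates to truth.
#'
#' @name synthetic_panel
NULL

#' Default definitions of the 13 salt-tolerance indices
#'
#' Control-condition baseline mean, per-treatment replicate SDs, and the
#' additive stress effect for a fully sensitive and a fully tolerant
#' accession, for each of the 13 indices (visual salt-tolerance score STS
#' on the 1-9 scale; relative SPAD; five chlorophyll-fluorescence
#' parameters; shoot/root Na+ and K+ contents and their ratios). Two SDs
#' are carried because in screened panels the spread of the ionic indices
#' under stress is an order of magnitude larger than under control while
#' their control means sit near zero; a single additive SD cannot emulate
#' both. Effects are scaled so that under stress the tolerant and
#' sensitive class means of the seven positively directed indices are
#' separated by at least three within-index (stress) SDs, while the ionic
#' indices separate by only ~1 SD, with ranges comparable to field panels
#' screened at 125 mmol/L NaCl.
#'
#' @return data frame with columns `index`, `tissue`, `baseline`, `sd`
#'   (control replicate SD), `sd_stress` (stress replicate SD),
#'   `effect_sensitive`, `effect_tolerant`, `direction` (+1 higher under
#'   tolerance, -1 lower).
#' @export
default_index_defs <- function() {
  data.frame(
    index = c("STS", "RSPAD", "Fm", "Fv/Fm", "Y", "NPQ", "ETR",
              "SNa+", "RNa+", "SK+", "RK+", "SNa+/K+", "RNa+/K+"),
    tissue = c("whole", "shoot", "shoot", "shoot", "shoot", "shoot", "shoot",
               "shoot", "root", "shoot", "root", "shoot", "root"),
    baseline = c(9, 100, 3500, 0.82, 0.05, 2.8, 2.2,
                 4, 13, 33, 20, 0.12, 0.8),
    sd = c(0.15, 0.01, 250, 0.012, 0.012, 0.5, 0.6,
           1.2, 2.5, 4, 3, 0.035, 0.2),
    sd_stress = c(0.8, 2.5, 400, 0.06, 0.01, 0.4, 0.4,
                  8, 12, 5, 3.5, 0.9, 2),
    effect_sensitive = c(-7, -36, -2300, -0.35, -0.045, -1.9, -1.7,
                         72, 75, -15, -9, 4.3, 9),
    effect_tolerant = c(-2.5, -13, -400, -0.04, 0.01, 0.1, 0.3,
                        58, 55, -8, -5, 2.3, 4),
    direction = c(1, 1, 1, 1, 1, 1, 1, -1, -1, 1, 1, -1, -1),
    stringsAsFactors = FALSE)
}

#' Default locus definitions
#'
#' Five polymorphic loci emulating the kinds of variation found in
#' salt-tolerance candidate genes: a trinucleotide (AGA) promoter SSR with
#' a per-repeat dose effect on STS, a promoter indel, two promoter/exon
#' SNPs with additive STS effects, and one neutral SNP. Allele frequencies
#' differ between classes so tolerant-favoured alleles co-occur with high
#' latent tolerance.
#'
#' @param ssr_effect_per_repeat additive STS shift per extra SSR repeat
#'   (negative = more repeats, less tolerant).
#' @return list of locus definitions (gene, position_bp, region, var_type,
#'   motif, alleles, effects, freq_tolerant, freq_sensitive).
#' @export
default_locus_defs <- function(ssr_effect_per_repeat = -0.5) {
  list(
    list(gene = "OsHKT1;5", position_bp = -240L, region = "promoter",
         var_type = "SNP", motif = NA_character_,
         alleles = c("C", "T"), effects = c(0, 0),
         freq_tolerant = c(0.5, 0.5), freq_sensitive = c(0.5, 0.5)),
    list(gene = "OsHAK21", position_bp = -1231L, region = "promoter",
         var_type = "SSR", motif = "AGA",
         alleles = c("3", "4", "5", "6"),
         effect_per_repeat = ssr_effect_per_repeat,
         freq_tolerant = c(0.55, 0.35, 0.08, 0.02),
         freq_sensitive = c(0.02, 0.08, 0.35, 0.55)),
    list(gene = "OsNHX1", position_bp = -822L, region = "promoter",
         var_type = "indel", motif = NA_character_,
         alleles = c("A", "-", "AA"), effects = c(0.6, 0, 0),
         freq_tolerant = c(0.7, 0.2, 0.1), freq_sensitive = c(0.15, 0.6, 0.25)),
    list(gene = "OsAKT2", position_bp = -1866L, region = "promoter",
         var_type = "SNP", motif = NA_character_,
         alleles = c("G", "A"), effects = c(0.5, 0),
         freq_tolerant = c(0.75, 0.25), freq_sensitive = c(0.2, 0.8)),
    list(gene = "OsABCI7", position_bp = 1605L, region = "exon",
         var_type = "SNP", motif = NA_character_,
         alleles = c("T", "C"), effects = c(0.5, 0),
         freq_tolerant = c(0.75, 0.25), freq_sensitive = c(0.2, 0.8)))
}

#' Default qPCR target-gene definitions
#'
#' Each target gene has a baseline dCt against the reference gene, a
#' stress-induction amplitude (log2, applied at post-0 h timepoints under
#' stress) and a class effect (log2 expression shift for a fully tolerant
#' accession, so 1 means tolerant material expresses 2-fold more).
#'
#' @return data frame with columns `gene`, `dct_baseline`, `stress_log2`,
#'   `class_log2`.
#' @export
default_ct_targets <- function() {
  data.frame(gene = c("OsHKT1;5", "OsHAK21"),
             dct_baseline = c(6, 7),
             stress_log2 = c(1.5, 2),
             class_log2 = c(1, 1),
             stringsAsFactors = FALSE)
}

#' Panel configuration
#'
#' Validates and assembles the configuration driving
#' [generate_panel()]. Defaults emulate a 12-accession half-tolerant panel
#' with 3 replicates, trait timepoints at 3 and 6 days, and qPCR at
#' 0-48 h.
#'
#' @param n_accessions number of accessions (>= 4).
#' @param frac_tolerant proportion of tolerant accessions, strictly in
#'   (0, 1).
#' @param index_defs see [default_index_defs()].
#' @param timepoints trait timepoints in days.
#' @param n_replicates replicates per trait observation cell.
#' @param locus_defs see [default_locus_defs()].
#' @param ct_targets see [default_ct_targets()].
#' @param ct_baseline reference-gene Ct mean and replicate SD (cycles).
#' @param ct_timepoints qPCR timepoints in hours.
#' @param ct_tissues tissues assayed by qPCR.
#' @param latent_mean_tolerant,latent_mean_sensitive,latent_sd mean latent
#'   tolerance of each class and its within-class SD (latent is truncated
#'   to (0, 1); 1 = fully tolerant).
#' @param seed integer seed; one global seed drives independent substreams
#'   for latents, traits, genotypes and Ct records.
#' @return object of class `"saltpanel_config"`.
#' @export
panel_config <- function(n_accessions = 12L, frac_tolerant = 0.5,
                         index_defs = default_index_defs(),
                         timepoints = c(3, 6), n_replicates = 3L,
                         locus_defs = default_locus_defs(),
                         ct_targets = default_ct_targets(),
                         ct_baseline = c(mean = 20, sd = 0.15),
                         ct_timepoints = c(0, 3, 6, 12, 24, 48),
                         ct_tissues = c("shoot", "root"),
                         latent_mean_tolerant = 0.8,
                         latent_mean_sensitive = 0.2,
                         latent_sd = 0.1,
                         seed = 1L) {
  if (!is.numeric(n_accessions) || n_accessions < 4) {
    stop("panel_config: 'n_accessions' must be >= 4")
  }
  if (!is.numeric(frac_tolerant) || frac_tolerant <= 0 || frac_tolerant >= 1) {
    stop("panel_config: 'frac_tolerant' must lie strictly between 0 and 1")
  }
  needed <- c("index", "tissue", "baseline", "sd", "effect_sensitive",
              "effect_tolerant", "direction")
  if (!all(needed %in% names(index_defs))) {
    stop("panel_config: 'index_defs' lacks column(s): ",
         paste(setdiff(needed, names(index_defs)), collapse = ", "))
  }
  if (is.null(index_defs$sd_stress)) index_defs$sd_stress <- index_defs$sd
  if (any(index_defs$sd <= 0) || any(index_defs$sd_stress <= 0)) {
    stop("panel_config: all 'index_defs' SDs must be > 0")
  }
  if (anyDuplicated(index_defs$index)) stop("panel_config: duplicate index names in 'index_defs'")
  if (length(timepoints) < 1L) stop("panel_config: 'timepoints' must be non-empty")
  if (n_replicates < 1L) stop("panel_config: 'n_replicates' must be >= 1")
  if (!is.numeric(ct_baseline) || ct_baseline[["sd"]] <= 0) {
    stop("panel_config: 'ct_baseline' sd must be > 0")
  }
  if (latent_sd <= 0) stop("panel_config: 'latent_sd' must be > 0")
  for (ld in locus_defs) {
    ft <- ld$freq_tolerant; fs <- ld$freq_sensitive
    if (length(ft) != length(ld$alleles) || length(fs) != length(ld$alleles)) {
      stop("panel_config: allele frequencies of locus ", ld$gene, ":",
           ld$position_bp, " do not match its alleles")
    }
    if (abs(sum(ft) - 1) > 1e-8 || abs(sum(fs) - 1) > 1e-8) {
      stop("panel_config: allele frequencies of locus ", ld$gene, ":",
           ld$position_bp, " must sum to 1")
    }
    if (identical(ld$var_type, "SSR") && is.null(ld$motif)) {
      stop("panel_config: SSR locus ", ld$gene, ":", ld$position_bp,
           " lacks a motif")
    }
  }
  structure(list(
    n_accessions = as.integer(n_accessions), frac_tolerant = frac_tolerant,
    index_defs = index_defs, timepoints = timepoints,
    n_replicates = as.integer(n_replicates), locus_defs = locus_defs,
    ct_targets = ct_targets, ct_baseline = ct_baseline,
    ct_timepoints = ct_timepoints, ct_tissues = ct_tissues,
    latent_mean_tolerant = latent_mean_tolerant,
    latent_mean_sensitive = latent_mean_sensitive,
    latent_sd = latent_sd, seed = as.integer(seed)
  ), class = "saltpanel_config")
}

with_stream_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

ssr_reference_count <- function(ld) min(as.integer(ld$alleles))

locus_allele_effect <- function(ld, allele) {
  if (identical(ld$var_type, "SSR")) {
    ld$effect_per_repeat * (as.integer(allele) - ssr_reference_count(ld))
  } else {
    ld$effects[match(allele, ld$alleles)]
  }
}

#' Generate a synthetic germplasm panel
#'
#' Deterministic given the config seed. Trait values follow
#' `value = baseline + treatment-by-tolerance effect + N(0, sd)` per
#' replicate, where the effect under stress interpolates between the
#' sensitive-class and tolerant-class effects by the accession's latent
#' tolerance; under control the classes share one distribution. STS values
#' additionally receive the additive genetic shift implied by the
#' accession's alleles (SSR dose effect per repeat) under stress, and are
#' rounded and clamped to the 1-9 integer scale. Reference-gene Cts are
#' drawn around the configured baseline; target-gene dCt is shifted by
#' stress induction and the class effect.
#'
#' Four independent RNG substreams (latents, traits, genotypes, Ct) are
#' derived from the global seed, so e.g. adding qPCR timepoints does not
#' perturb the trait stream.
#'
#' @param config a [panel_config()] object.
#' @return object of class `"saltpanel_panel"`: list with `accessions`,
#'   `observations`, `genotypes`, `ct_records`, `truth`, `config`.
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "saltpanel_config")) {
    stop("generate_panel: 'config' must come from panel_config()")
  }
  n <- config$n_accessions
  n_tol <- max(1L, min(n - 1L, round(n * config$frac_tolerant)))
  ids <- sprintf("ACC%03d", seq_len(n))
  cls <- rep(c("tolerant", "sensitive"), c(n_tol, n - n_tol))

  seeds <- with_stream_seed(config$seed, sample.int(.Machine$integer.max - 1L, 4L))

  latent <- with_stream_seed(seeds[1], {
    mu <- ifelse(cls == "tolerant", config$latent_mean_tolerant,
                 config$latent_mean_sensitive)
    pmin(0.99, pmax(0.01, stats::rnorm(n, mu, config$latent_sd)))
  })

  empty_genotypes <- data.frame(accession_id = character(0), gene = character(0),
                                position_bp = integer(0), allele = character(0),
                                stringsAsFactors = FALSE)
  genotypes <- with_stream_seed(seeds[2], {
    do.call(rbind, lapply(config$locus_defs, function(ld) {
      pr <- rbind(tolerant = ld$freq_tolerant, sensitive = ld$freq_sensitive)
      allele <- vapply(seq_len(n), function(i) {
        sample(ld$alleles, 1L, prob = pr[cls[i], ])
      }, character(1))
      data.frame(accession_id = ids, gene = ld$gene,
                 position_bp = ld$position_bp, allele = allele,
                 stringsAsFactors = FALSE)
    }))
  })
  if (is.null(genotypes)) genotypes <- empty_genotypes
  genetic_shift <- stats::setNames(numeric(n), ids)
  for (ld in config$locus_defs) {
    g <- genotypes[genotypes$gene == ld$gene &
                     genotypes$position_bp == ld$position_bp, ]
    genetic_shift[g$accession_id] <- genetic_shift[g$accession_id] +
      locus_allele_effect(ld, g$allele)
  }

  idx <- config$index_defs
  observations <- with_stream_seed(seeds[3], {
    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        accession = seq_len(n),
                        index = seq_len(nrow(idx)),
                        treatment = c("CK", "SST"),
                        timepoint_d = config$timepoints,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ai <- grid$accession; ii <- grid$index
    stress <- grid$treatment == "SST"
    eff <- ifelse(stress,
                  (1 - latent[ai]) * idx$effect_sensitive[ii] +
                    latent[ai] * idx$effect_tolerant[ii],
                  0)
    gshift <- ifelse(stress & idx$index[ii] == "STS", genetic_shift[ai], 0)
    noise_sd <- ifelse(stress, idx$sd_stress[ii], idx$sd[ii])
    value <- idx$baseline[ii] + eff + gshift +
      stats::rnorm(nrow(grid), 0, noise_sd)
    is_sts <- idx$index[ii] == "STS"
    value[is_sts] <- pmin(9, pmax(1, round(value[is_sts])))
    data.frame(accession_id = ids[ai], index = idx$index[ii],
               treatment = grid$treatment, timepoint_d = grid$timepoint_d,
               tissue = idx$tissue[ii], replicate = grid$replicate,
               value = value, stringsAsFactors = FALSE)
  })

  ct_records <- with_stream_seed(seeds[4], {
    tg <- config$ct_targets
    if (is.null(tg) || nrow(tg) == 0L) {
      NULL
    } else {
      grid <- expand.grid(replicate = seq_len(config$n_replicates),
                          accession = seq_len(n),
                          tissue = config$ct_tissues,
                          timepoint_h = config$ct_timepoints,
                          gene = c("OsActin", tg$gene),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      mu <- config$ct_baseline[["mean"]]; sdv <- config$ct_baseline[["sd"]]
      gi <- match(grid$gene, tg$gene)  # NA for the reference gene
      induced <- grid$timepoint_h > 0
      dct <- ifelse(is.na(gi), 0,
                    tg$dct_baseline[gi] -
                      ifelse(induced, tg$stress_log2[gi] +
                               tg$class_log2[gi] * latent[grid$accession], 0))
      ct <- mu + dct + stats::rnorm(nrow(grid), 0, sdv)
      data.frame(accession_id = ids[grid$accession], gene = grid$gene,
                 tissue = grid$tissue, timepoint_h = grid$timepoint_h,
                 treatment = "SST", replicate = grid$replicate, ct = ct,
                 stringsAsFactors = FALSE)
    }
  })

  sts6 <- observations[observations$index == "STS" &
                         observations$treatment == "SST" &
                         observations$timepoint_d == max(config$timepoints), ]
  sts_score <- if (nrow(sts6)) tapply(sts6$value, sts6$accession_id, mean)[ids]
               else rep(NA_real_, n)

  structure(list(
    accessions = data.frame(accession_id = ids, class = cls,
                            sts = as.numeric(sts_score), stringsAsFactors = FALSE),
    observations = observations,
    genotypes = genotypes,
    ct_records = ct_records,
    truth = data.frame(accession_id = ids, class = cls, latent = latent,
                       genetic_sts_shift = as.numeric(genetic_shift),
                       stringsAsFactors = FALSE),
    config = config
  ), class = "saltpanel_panel")
}

#' @export
print.saltpanel_panel <- function(x, ...) {
  cat("Synthetic germplasm panel:", nrow(x$accessions), "accessions (",
      sum(x$accessions$class == "tolerant"), "tolerant /",
      sum(x$accessions$class == "sensitive"), "sensitive )\n")
  cat(" ", nrow(x$observations), "trait observations,",
      nrow(x$genotypes), "genotype calls,",
      if (is.null(x$ct_records)) 0 else nrow(x$ct_records), "Ct records\n")
  invisible(x)
}

write_tsv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a panel to TSV files
#'
#' Writes `traits.tsv`, `genotypes.tsv`, `ct.tsv` and `truth.tsv` (readers
#' ignore the truth file) in the package's external tab-delimited formats.
#' Numeric values are written with full precision so the files round-trip
#' losslessly through [read_panel_tables()].
#'
#' @param panel a [generate_panel()] result.
#' @param directory output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
panel_to_tables <- function(panel, directory) {
  if (!inherits(panel, "saltpanel_panel")) stop("panel_to_tables: not a panel object")
  if (nrow(panel$observations) == 0L) {
    stop("panel_to_tables: refusing to write an empty panel")
  }
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("panel_to_tables: cannot create directory '", directory, "'")
  }
  paths <- c(traits = file.path(directory, "traits.tsv"),
             genotypes = file.path(directory, "genotypes.tsv"),
             ct = file.path(directory, "ct.tsv"),
             truth = file.path(directory, "truth.tsv"))
  write_tsv_exact(panel$observations, paths["traits"])
  if (nrow(panel$genotypes)) write_tsv_exact(panel$genotypes, paths["genotypes"])
  if (!is.null(panel$ct_records)) write_tsv_exact(panel$ct_records, paths["ct"])
  write_tsv_exact(panel$truth, paths["truth"])
  invisible(paths)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = NA)
}

#' Read panel tables back from a directory
#'
#' @param directory directory holding `traits.tsv`, `genotypes.tsv` and
#'   (optionally) `ct.tsv` as written by [panel_to_tables()].
#' @return list with `observations`, `genotypes`, `ct_records` data frames.
#' @export
read_panel_tables <- function(directory) {
  obs <- read_tsv(file.path(directory, "traits.tsv"))
  obs$timepoint_d <- as.numeric(obs$timepoint_d)
  obs$replicate <- as.integer(obs$replicate)
  obs$value <- as.numeric(obs$value)
  gen <- read_tsv(file.path(directory, "genotypes.tsv"))
  gen$allele <- as.character(gen$allele)
  gen$position_bp <- as.integer(gen$position_bp)
  ct_path <- file.path(directory, "ct.tsv")
  ct <- NULL
  if (file.exists(ct_path)) {
    ct <- read_tsv(ct_path)
    ct$timepoint_h <- as.numeric(ct$timepoint_h)
    ct$replicate <- as.integer(ct$replicate)
    ct$ct <- as.numeric(ct$ct)
  }
  list(observations = obs, genotypes = gen, ct_records = ct)
}
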