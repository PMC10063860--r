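#' Haplotype-phenotype association
#'
#' Groups accessions into haplotypes over a gene's (or a selected
#' multi-gene set's) polymorphic loci, tests haplotype effects on the
#' salt-tolerance score with one-way ANOVA followed by protected LSD
#' pairwise comparisons and a compact letter display, and tests the
#' repeat-dose trend of SSR alleles.
#'
#' @name haplotype_assoc
NULL

hap_tuples <- function(calls, loci_keys) {
  # loci_keys: character "gene:position_bp" defining the tuple order
  calls$key <- paste0(calls$gene, ":", calls$position_bp)
  calls <- calls[calls$key %in% loci_keys, , drop = FALSE]
  if (anyDuplicated(calls[, c("accession_id", "key")])) {
    stop("haplotypes: duplicate genotype call for an (accession, locus) pair")
  }
  acc <- unique(calls$accession_id)
  tup <- matrix(NA_character_, length(acc), length(loci_keys),
                dimnames = list(acc, loci_keys))
  tup[cbind(match(calls$accession_id, acc), match(calls$key, loci_keys))] <- calls$allele
  complete <- !apply(tup, 1, anyNA)
  if (any(!complete)) {
    warning("haplotypes: excluded accession(s) with missing locus call(s): ",
            paste(acc[!complete], collapse = ", "))
  }
  tup[complete, , drop = FALSE]
}

hap_partition <- function(tup) {
  tuple_str <- apply(tup, 1, paste, collapse = "/")
  # label by decreasing group size, ties by first occurrence
  first_seen <- match(unique(tuple_str), tuple_str)
  sizes <- table(tuple_str)[unique(tuple_str)]
  ord <- order(-as.integer(sizes), first_seen)
  lev <- unique(tuple_str)[ord]
  groups <- lapply(seq_along(lev), function(i) {
    members <- rownames(tup)[tuple_str == lev[i]]
    list(label = paste0("Hap", i),
         allele_tuple = strsplit(lev[i], "/", fixed = TRUE)[[1]],
         loci = colnames(tup), members = members, n = length(members))
  })
  names(groups) <- vapply(groups, `[[`, "", "label")
  groups
}

#' Group accessions into haplotypes of one gene
#'
#' One haplotype per distinct ordered allele tuple over the gene's loci.
#' Labels `Hap1..HapK` are assigned by decreasing group size, ties by first
#' occurrence in the input; accessions missing any locus call are excluded
#' with a warning.
#'
#' @param calls genotype-call data frame with columns `accession_id`,
#'   `gene`, `position_bp`, `allele`.
#' @param gene gene name to group on.
#' @return list of haplotype groups (`label`, `allele_tuple`, `loci`,
#'   `members`, `n`).
#' @export
group_haplotypes <- function(calls, gene) {
  g <- calls[calls$gene == gene, , drop = FALSE]
  if (nrow(g) == 0L) stop("group_haplotypes: no calls for gene '", gene, "'")
  loci_keys <- paste0(gene, ":", sort(unique(g$position_bp)))
  hap_partition(hap_tuples(g, loci_keys))
}

#' Multigene combinatorial haplotypes
#'
#' Same partition semantics as [group_haplotypes()] but over an ordered
#' cross-gene selection of loci.
#'
#' @param calls genotype-call data frame (see [group_haplotypes()]).
#' @param selected_loci data frame with columns `gene`, `position_bp`
#'   giving the loci (in order) forming the combined tuple.
#' @return list of haplotype groups.
#' @export
combine_loci <- function(calls, selected_loci) {
  if (nrow(selected_loci) == 0L) stop("combine_loci: no loci selected")
  loci_keys <- paste0(selected_loci$gene, ":", selected_loci$position_bp)
  hap_partition(hap_tuples(calls, loci_keys))
}

#' Loci at which two haplotypes differ
#'
#' @param group_a,group_b haplotype groups over the same loci.
#' @return character vector of `"gene:position"` keys where the allele
#'   tuples differ.
#' @export
haplotype_difference <- function(group_a, group_b) {
  if (!identical(group_a$loci, group_b$loci)) {
    stop("haplotype_difference: groups are defined over different loci")
  }
  group_a$loci[group_a$allele_tuple != group_b$allele_tuple]
}

lsd_pairwise <- function(means, ns, mse, df_err, alpha) {
  k <- length(means)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  pmat <- matrix(NA_real_, k, k, dimnames = dimnames(sig))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { pmat[i, j] <- 1; next }
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    tij <- (means[i] - means[j]) / se
    pij <- 2 * stats::pt(abs(tij), df_err, lower.tail = FALSE)
    pmat[i, j] <- pij
    sig[i, j] <- pij < alpha
  }
  list(p = pmat, significant = sig)
}

#' Insert-and-absorb compact letter display
#'
#' Assigns letters to groups from a logical pairwise significance matrix so
#' that two groups share a letter if and only if they are not significantly
#' different.
#'
#' @param sig logical symmetric matrix; `TRUE` means significantly
#'   different. Row/column names are the group labels.
#' @param letters_pool letters used, in order.
#' @return named character vector of letter strings, groups in input order.
#' @export
compact_letters <- function(sig, letters_pool = letters) {
  k <- nrow(sig)
  labels <- rownames(sig)
  # letter classes as logical membership k-vectors; start with one class
  # holding everyone, then split on each significant pair (insert) and drop
  # classes contained in another (absorb)
  cols <- list(rep(TRUE, k))
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (!sig[i, j]) next
    newcols <- list()
    for (cl in cols) {
      if (cl[i] && cl[j]) {
        a <- cl; a[j] <- FALSE
        b <- cl; b[i] <- FALSE
        newcols <- c(newcols, list(a), list(b))
      } else {
        newcols <- c(newcols, list(cl))
      }
    }
    newcols <- Filter(any, newcols)
    drop <- rep(FALSE, length(newcols))
    for (x in seq_along(newcols)) for (y in seq_along(newcols)) {
      if (x == y || drop[x] || drop[y]) next
      if (all(!newcols[[x]] | newcols[[y]])) {
        # x is a subset of y; for duplicates drop the later one only
        if (!identical(newcols[[x]], newcols[[y]]) || x > y) drop[x] <- TRUE
      }
    }
    cols <- newcols[!drop]
  }
  # stable letter ordering: by first member index
  ord <- order(vapply(cols, function(cl) which(cl)[1], integer(1)))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(g) {
    paste(letters_pool[which(vapply(cols, `[[`, logical(1), g))], collapse = "")
  }, character(1))
  stats::setNames(out, labels)
}

#' Haplotype association: ANOVA with protected LSD letters
#'
#' One-way ANOVA of the phenotype (e.g. salt-tolerance score) across
#' haplotype groups, followed — only if the ANOVA is significant at
#' `alpha` (protected LSD) — by Fisher's least-significant-difference
#' pairwise comparisons using the ANOVA mean-square error, summarised as a
#' compact letter display. Groups smaller than `min_group_size` are
#' excluded from testing and reported unlettered.
#'
#' @param groups haplotype groups from [group_haplotypes()]/[combine_loci()].
#' @param sts named numeric vector of per-accession phenotype values.
#' @param alpha significance level (default 0.05).
#' @param min_group_size smallest group entering the ANOVA (default 2).
#' @param protected if `FALSE`, LSD comparisons are made regardless of the
#'   ANOVA result.
#' @return list with `table` (label, n, mean, letter), `anova_f`,
#'   `anova_p`, `df_error`, `mse`, `lsd_p` (pairwise p matrix), `testable`.
#' @export
anova_lsd <- function(groups, sts, alpha = 0.05, min_group_size = 2L,
                      protected = TRUE) {
  tab <- data.frame(
    label = vapply(groups, `[[`, "", "label"),
    n = vapply(groups, `[[`, 0L, "n"),
    mean_sts = vapply(groups, function(g) mean(sts[g$members]), 0),
    letter = "", stringsAsFactors = FALSE, row.names = NULL)
  eligible <- tab$n >= min_group_size
  if (sum(eligible) < 2L) {
    return(list(table = tab, anova_f = NA_real_, anova_p = NA_real_,
                df_error = NA_integer_, mse = NA_real_, lsd_p = NULL,
                testable = FALSE))
  }
  el <- which(eligible)
  df <- do.call(rbind, lapply(el, function(i) {
    data.frame(hap = tab$label[i], y = unname(sts[groups[[i]]$members]))
  }))
  df$hap <- factor(df$hap, levels = tab$label[el])
  fit <- stats::aov(y ~ hap, data = df)
  an <- stats::anova(fit)
  f <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]; df_err <- an[["Df"]][2]
  means <- tapply(df$y, df$hap, mean)
  ns <- tapply(df$y, df$hap, length)
  if (!protected || (is.finite(p) && p < alpha)) {
    pw <- lsd_pairwise(means, ns, mse, df_err, alpha)
    letts <- compact_letters(pw$significant)
  } else {
    pw <- NULL
    letts <- stats::setNames(rep("a", length(el)), tab$label[el])
  }
  tab$letter[el] <- letts[tab$label[el]]
  list(table = tab, anova_f = f, anova_p = p, df_error = df_err, mse = mse,
       lsd_p = if (is.null(pw)) NULL else pw$p, testable = TRUE)
}

#' SSR repeat-dose trend
#'
#' Spearman rank correlation between SSR repeat counts and the phenotype,
#' testing whether salt tolerance changes monotonically with repeat number
#' (e.g. the AGA promoter repeat).
#'
#' @param repeat_counts integer repeat counts per accession.
#' @param sts phenotype values, same order/length.
#' @return list with `rho`, `p_value`, `n`, `testable`.
#' @export
ssr_dose_trend <- function(repeat_counts, sts) {
  r <- as.numeric(repeat_counts); s <- as.numeric(sts)
  if (length(r) != length(s)) stop("ssr_dose_trend: length mismatch")
  ok <- is.finite(r) & is.finite(s)
  r <- r[ok]; s <- s[ok]
  if (length(r) < 4L) stop("ssr_dose_trend: need >= 4 accessions")
  if (length(unique(r)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(r), testable = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(r, s, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(r),
       testable = TRUE)
}

#' Haplotype groups as a data frame
#'
#' @param groups haplotype group list.
#' @return data frame with label, allele tuple, members, n.
#' @export
haplotypes_as_data_frame <- function(groups) {
  data.frame(
    label = vapply(groups, `[[`, "", "label"),
    alleles = vapply(groups, function(g) paste(g$allele_tuple, collapse = "/"), ""),
    loci = vapply(groups, function(g) paste(g$loci, collapse = ";"), ""),
    n = vapply(groups, `[[`, 0L, "n"),
    members = vapply(groups, function(g) paste(g$members, collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}
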