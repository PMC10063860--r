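test_that("haplotype grouping partitions accessions by allele tuple", {
  tuples <- list(a1 = c("A", "T"), a2 = c("A", "T"),
                 a3 = c("A", "C"), a4 = c("G", "C"))
  groups <- group_haplotypes(calls_from_tuples(tuples), "G1")
  expect_length(groups, 3)
  expect_equal(vapply(groups, `[[`, 0L, "n"), c(Hap1 = 2L, Hap2 = 1L, Hap3 = 1L))
  expect_setequal(groups$Hap1$members, c("a1", "a2"))
  # partition property
  expect_setequal(unlist(lapply(groups, `[[`, "members")), names(tuples))

  mono <- group_haplotypes(calls_from_tuples(list(x = "A", y = "A", z = "A")), "G1")
  expect_length(mono, 1)
  expect_equal(mono$Hap1$n, 3L)
})

test_that("a seeded 29-accession panel with 5 planted tuples is recovered exactly", {
  set.seed(77)
  planted <- list(c("3", "A"), c("4", "A"), c("3", "G"), c("5", "G"), c("6", "A"))
  assignment <- sample(rep(1:5, c(9, 8, 6, 4, 2)))
  tuples <- setNames(lapply(assignment, function(k) planted[[k]]),
                     sprintf("acc%02d", 1:29))
  groups <- group_haplotypes(calls_from_tuples(tuples, gene = "OsHAK21",
                                               positions = c(-1231L, 940L)),
                             "OsHAK21")
  expect_length(groups, 5)
  got <- lapply(groups, function(g) sort(g$members))
  want <- lapply(1:5, function(k) sort(names(tuples)[assignment == k]))
  # same partition, labels ordered by group size
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  expect_equal(vapply(groups, `[[`, 0L, "n"), sort(c(9L, 8L, 6L, 4L, 2L),
                                                   decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("partition is stable under accession permutation", {
  set.seed(5)
  tuples <- setNames(lapply(1:12, function(i) sample(c("A", "G"), 2, TRUE)),
                     sprintf("a%02d", 1:12))
  calls <- calls_from_tuples(tuples)
  g1 <- group_haplotypes(calls, "G1")
  g2 <- group_haplotypes(calls[sample(nrow(calls)), ], "G1")
  # labels may permute on size ties; the partition itself must not change
  part <- function(g) unname(sort(vapply(g, function(x) paste(sort(x$members), collapse = ","), "")))
  expect_equal(part(g1), part(g2))
})

test_that("combining loci matches single-gene grouping and names differing loci", {
  tuples <- list(a = c("A", "T"), b = c("A", "C"), c = c("G", "T"), d = c("G", "C"))
  calls <- calls_from_tuples(tuples, gene = "G1", positions = c(10L, 20L))
  sel <- data.frame(gene = "G1", position_bp = c(10L, 20L))
  comb <- combine_loci(calls, sel)
  expect_length(comb, 4)  # full Cartesian support
  single <- combine_loci(calls, sel[1, , drop = FALSE])
  expect_equal(lapply(single, `[[`, "members"),
               lapply(group_haplotypes(calls[calls$position_bp == 10, ], "G1"),
                      `[[`, "members"))
  two <- comb[vapply(comb, function(g) any(c("a", "b") %in% g$members), TRUE)]
  d <- haplotype_difference(two[[1]], two[[2]])
  expect_equal(d, "G1:20")
})

test_that("missing locus calls exclude the accession with a warning", {
  calls <- calls_from_tuples(list(a = c("A", "T"), b = c("A", "C")))
  calls <- calls[-4, ]  # drop b's second locus
  expect_warning(groups <- group_haplotypes(calls, "G1"), "b")
  expect_equal(unlist(lapply(groups, `[[`, "members")), c(Hap1 = "a"),
               ignore_attr = TRUE)
})

test_that("identical groups share a letter; widely separated means get distinct letters", {
  sts <- c(g1 = 5, g2 = 5.02, g3 = 4.98, g4 = 5.01, h1 = 5.01, h2 = 4.99,
           h3 = 5, h4 = 5.02)
  groups <- list(list(label = "Hap1", members = paste0("g", 1:4), n = 4L),
                 list(label = "Hap2", members = paste0("h", 1:4), n = 4L))
  res <- anova_lsd(groups, sts)
  expect_equal(res$table$letter, c("a", "a"))

  set.seed(9)
  sts2 <- c(rnorm(5, 2, 0.1), rnorm(5, 5, 0.1), rnorm(5, 8, 0.1))
  names(sts2) <- sprintf("x%02d", 1:15)
  groups2 <- lapply(1:3, function(k) {
    list(label = paste0("Hap", k), members = names(sts2)[(k - 1) * 5 + 1:5], n = 5L)
  })
  res2 <- anova_lsd(groups2, sts2)
  expect_true(res2$anova_p < 0.05)
  expect_equal(sort(res2$table$letter), c("a", "b", "c"))
  # brute-force: all pairs significant
  sig <- oracle_lsd_sig(split(unname(sts2), rep(1:3, each = 5)))
  expect_true(all(sig[upper.tri(sig)]))
})

test_that("letter sharing matches the brute-force pairwise LSD matrix", {
  set.seed(303)
  for (rep in 1:300) {
    k <- sample(3:5, 1)
    ns <- sample(3:6, k, replace = TRUE)
    mus <- rnorm(k, 0, sample(c(0.3, 1, 3), 1))
    values <- lapply(1:k, function(i) rnorm(ns[i], mus[i], 1))
    sts <- unlist(values)
    names(sts) <- sprintf("m%03d", seq_along(sts))
    stops <- cumsum(ns)
    groups <- lapply(1:k, function(i) {
      members <- names(sts)[(c(0, stops)[i] + 1):stops[i]]
      list(label = paste0("Hap", i), members = members, n = ns[i])
    })
    res <- anova_lsd(groups, sts, protected = FALSE)
    sig <- oracle_lsd_sig(values)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      expect_identical(letters_share(res$table$letter[i], res$table$letter[j]),
                       !sig[i, j])
    }
  }
})

test_that("protected LSD suppresses pairwise letters when the ANOVA is flat", {
  set.seed(12)
  sts <- rnorm(12, 5, 1)
  names(sts) <- sprintf("p%02d", 1:12)
  groups <- lapply(1:3, function(k) {
    list(label = paste0("Hap", k), members = names(sts)[(k - 1) * 4 + 1:4], n = 4L)
  })
  res <- anova_lsd(groups, sts)
  if (res$anova_p >= 0.05) expect_equal(res$table$letter, rep("a", 3))
  # singleton groups are reported unlettered
  groups2 <- c(groups, list(list(label = "Hap4", members = "p01", n = 1L)))
  res2 <- anova_lsd(groups2, sts)
  expect_equal(res2$table$letter[4], "")
  # fewer than two eligible groups: not testable, no error
  res3 <- anova_lsd(groups2[3:4], sts, min_group_size = 5L)
  expect_false(res3$testable)
})

test_that("SSR dose trend recovers monotone relations and flags constants", {
  expect_equal(ssr_dose_trend(1:4, c(9, 7, 5, 3))$rho, -1)
  expect_equal(ssr_dose_trend(1:4, c(3, 5, 7, 9))$rho, 1)
  expect_false(ssr_dose_trend(rep(3, 5), rnorm(5))$testable)
  expect_error(ssr_dose_trend(1:3, 1:3), ">= 4")
})

test_that("a planted negative repeat-dose effect is detected in a synthetic panel", {
  cfg <- panel_config(n_accessions = 50, seed = 424,
                      locus_defs = default_locus_defs(ssr_effect_per_repeat = -1),
                      ct_targets = NULL)
  p <- generate_panel(cfg)
  reps <- as.integer(p$genotypes$allele[p$genotypes$gene == "OsHAK21"])
  names(reps) <- p$genotypes$accession_id[p$genotypes$gene == "OsHAK21"]
  trend <- ssr_dose_trend(reps[p$accessions$accession_id],
                          p$accessions$sts)
  expect_lt(trend$rho, 0)
  expect_lt(trend$p_value, 0.05)
})
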