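test_that("dominant-taxon labelling recovers planted cluster identities", {
  hits <- vapply(1:50, function(s) {
    sim <- simulate_paired_cohort(cohort_spec(n_subjects = 40, seed = s))
    oral <- to_relative(sim$oral)
    d <- jsd_distance_matrix(oral)
    sol <- dominant_taxon_labels(oral, pam_cluster(d, 2))
    # each cluster must be named after its majority planted genus
    all(vapply(1:2, function(c) {
      maj <- names(which.max(table(sim$truth$ko_label[sol$labels == c])))
      substr(sol$dominant_taxon[c], 1, 1) == maj
    }, logical(1))) && !anyDuplicated(sol$dominant_taxon)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("dominant-taxon rules: k = 1 reduces to the global mean, ties go alphabetical", {
  tab <- rel_table(matrix(c(0.7, 0.3, 0.6, 0.4), 2, byrow = TRUE),
                   taxa = c("Zeta", "Alpha"))
  d <- jsd_distance_matrix(tab)
  s1 <- dominant_taxon_labels(tab, pam_cluster(d, 1))
  expect_identical(s1$dominant_taxon, "Zeta")

  tie <- rel_table(matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE),
                   taxa = c("Beta", "Alpha"))
  st <- dominant_taxon_labels(tie, pam_cluster(jsd_distance_matrix(tie), 1))
  expect_identical(st$dominant_taxon, "Alpha")
})

test_that("oral typing recovers planted labels at high boost and not at boost 1", {
  sim <- simulate_paired_cohort(cohort_spec(seed = 17))
  oral <- prevalence_filter(to_relative(sim$oral))
  ko <- assign_ko_types(oral, sim$meta)
  expect_identical(ko$k_report$chosen_k, 2L)
  expect_gte(ari(ko$assignments$ko_label, sim$truth$ko_label), 0.9)

  null_sim <- simulate_paired_cohort(cohort_spec(dominance_boost = 1, seed = 18,
                                                 depth = 2000))
  null_oral <- prevalence_filter(to_relative(null_sim$oral))
  ko0 <- assign_ko_types(null_oral, null_sim$meta, force_k = 2)
  expect_lt(abs(ari(ko0$assignments$ko_label, null_sim$truth$ko_label)), 0.1)
})

test_that("a minimal four-subject cohort runs end to end with k forced to 2", {
  sim <- simulate_paired_cohort(cohort_spec(n_subjects = 4, depth = 2000, seed = 2))
  oral <- to_relative(sim$oral)
  ko <- assign_ko_types(oral, sim$meta, k_max = 3, force_k = 2)
  expect_identical(sort(unique(ko$assignments$ko_label)), sort(unique(
    substr(ko$solution$dominant_taxon, 1, 1))))
  expect_identical(nrow(ko$assignments), 4L)
})

test_that("nested gut typing yields four composite types matching the coupling", {
  sim <- simulate_paired_cohort(cohort_spec(seed = 23))
  res <- run_typing_pipeline(sim$oral, sim$gut, sim$meta)
  expect_setequal(res$assignments$koga_label, c("SB", "SP", "HB", "HP"))
  expect_gte(ari(res$assignments$koga_label, sim$truth$koga_label), 0.85)
  # recovered per-type counts sit within sampling error of the coupling expectation
  p <- c(SB = 0.554 * 0.694, SP = 0.554 * 0.306,
         HB = 0.446 * 0.720, HP = 0.446 * 0.280)
  n <- nrow(res$assignments)
  counts <- table(factor(res$assignments$koga_label, names(p)))
  expect_true(all(abs(counts - n * p) < 4 * sqrt(n * p * (1 - p))))
})

test_that("independent coupling leaves gut labels independent of oral labels", {
  tabs <- lapply(1:25, function(s) {
    sim <- simulate_paired_cohort(cohort_spec(
      n_subjects = 60, seed = s, depth = 5000,
      coupling = matrix(0.5, 2, 2)))
    res <- run_typing_pipeline(sim$oral, sim$gut, sim$meta)
    table(res$assignments$ko_label, res$assignments$gut_label)
  })
  agg <- Reduce(`+`, tabs)
  expect_gt(suppressWarnings(chisq.test(agg)$p.value), 0.01)
})

test_that("undersized oral-type subgroups are refused", {
  sim <- simulate_paired_cohort(cohort_spec(n_subjects = 12, depth = 2000, seed = 4))
  gut <- to_relative(sim$gut)
  ko <- data.frame(subject_id = sim$truth$subject_id,
                   ko_label = c("X", rep(c("S", "H"), c(8, 3))),
                   stringsAsFactors = FALSE)
  expect_error(assign_koga_types(gut, sim$meta, ko), "need >= 4")
})

test_that("type frequencies use half-up one-decimal percentages", {
  labs <- rep(c("SB", "SP", "HB", "HP"), c(43, 19, 36, 14))
  freq <- type_frequencies(labs)
  expect_equal(freq$percent[match(c("SB", "SP", "HB", "HP"), freq$label)],
               c(38.4, 17.0, 32.1, 12.5))
  ko <- type_frequencies(rep(c("S", "H"), c(62, 50)))
  expect_equal(ko$percent[match(c("S", "H"), ko$label)], c(55.4, 44.6))
  expect_equal(type_frequencies("SB")$percent, 100.0)
  expect_error(type_frequencies(character(0)), "no labels")
})
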