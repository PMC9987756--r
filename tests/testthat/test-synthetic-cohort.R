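test_that("cohort simulation is deterministic and respects depth", {
  spec <- cohort_spec(n_subjects = 10, depth = 500, seed = 99)
  a <- simulate_paired_cohort(spec)
  b <- simulate_paired_cohort(spec)
  expect_identical(a$oral$values, b$oral$values)
  expect_identical(a$gut$values, b$gut$values)
  expect_identical(a$truth, b$truth)
  expect_true(all(rowSums(a$oral$values) == 500))
  expect_true(all(rowSums(a$gut$values) == 500))
  expect_s3_class(a$meta, "sample_metadata")
  expect_identical(nrow(a$meta), 20L)
})

test_that("cohort tables round-trip through the TSV layer unchanged", {
  sim <- simulate_paired_cohort(cohort_spec(n_subjects = 6, depth = 300, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(sim$oral, path)
  back <- read_abundance(path, "counts", body_site = "oral")
  expect_equal(back$values, sim$oral$values)
})

test_that("dominance_boost = 1 plants no signal", {
  sim <- simulate_paired_cohort(cohort_spec(n_subjects = 120, depth = 5000,
                                            dominance_boost = 1, seed = 5))
  rel <- to_relative(sim$oral)
  s_mean <- tapply(rel$values[, "Streptococcus"], sim$truth$ko_label, mean)
  # planted labels carry no abundance signal: cluster means agree within MC error
  expect_lt(abs(s_mean["S"] - s_mean["H"]), 3 * sd(rel$values[, "Streptococcus"]) /
              sqrt(min(table(sim$truth$ko_label))))
})

test_that("default study conditions reproduce the expected type proportions", {
  # aggregate over seeds so the binomial error on the realised split is small
  labs <- unlist(lapply(1:10, function(s)
    simulate_paired_cohort(cohort_spec(seed = s, depth = 200))$truth$koga_label))
  freq <- type_frequencies(labs)
  expected <- c(SB = 0.554 * 0.694, SP = 0.554 * 0.306,
                HB = 0.446 * 0.720, HP = 0.446 * 0.280)
  got <- freq$percent[match(names(expected), freq$label)] / 100
  se <- sqrt(expected * (1 - expected) / length(labs))
  expect_true(all(abs(got - expected) < 4 * se))
})

test_that("planted dominant taxon leads its cluster at boost >= 20", {
  ok <- vapply(1:100, function(s) {
    sim <- simulate_paired_cohort(cohort_spec(n_subjects = 40, depth = 5000,
                                              dominance_boost = 20, seed = s))
    rel <- to_relative(sim$oral)
    all(vapply(c(S = "Streptococcus", H = "Haemophilus"), function(g) {
      rows <- sim$truth$ko_label == substr(g, 1, 1)
      mu <- colMeans(rel$values[rows, c("Streptococcus", "Haemophilus"), drop = FALSE])
      names(which.max(mu)) == g
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("correlated count simulation matches its basis-log oracle", {
  D <- 10
  S <- diag(D); S[1, 2] <- S[2, 1] <- 0.8
  spec <- correlated_count_spec(400, D, basis_log_covariance = S,
                                depth = 10000, seed = 21)
  tab <- simulate_correlated_counts(spec)
  expect_true(all(rowSums(tab$values) == 10000))
  logs <- attr(tab, "basis_log")
  expect_equal(cor(logs[, 1], logs[, 2]), 0.8, tolerance = 0.1)
  # independence case: basis correlations centred on zero
  tab0 <- simulate_correlated_counts(correlated_count_spec(400, D, depth = 1000,
                                                           seed = 22))
  logs0 <- attr(tab0, "basis_log")
  off <- cor(logs0)[upper.tri(diag(D))]
  expect_lt(max(abs(off)), 0.2)
  # degenerate depth accepted
  one <- simulate_correlated_counts(correlated_count_spec(5, 4, depth = 1, seed = 1))
  expect_true(all(rowSums(one$values) == 1))
})

test_that("invalid simulation specs are rejected", {
  expect_error(cohort_spec(mixture_weights = c(0.7, 0.7)), "summing to 1")
  expect_error(cohort_spec(dominance_boost = 0.5), "dominance_boost")
  expect_error(cohort_spec(coupling = matrix(1, 2, 2)), "row-stochastic")
  S <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(correlated_count_spec(10, 2, basis_log_covariance = S), "n_taxa")
  S3 <- diag(3); S3[1, 2] <- S3[2, 1] <- 2
  expect_error(correlated_count_spec(10, 3, basis_log_covariance = S3),
               "positive semidefinite")
})

test_that("the published scoring panel has standardised beneficial rows", {
  fix <- scoring_panel_fixture()
  expect_identical(dim(fix$z), c(29L, 4L))
  expect_identical(sum(fix$panel$body_site == "oral"), 14L)
  expect_identical(sum(fix$panel$body_site == "gut"), 15L)
  expect_equal(unname(fix$z["Streptococcus sanguinis", ]),
               c(1.109359234, 0.581684099, -0.821522451, -0.869520881))
  expect_equal(unname(fix$z["Fusobacterium nucleatum", ]), c(0.5, 0.5, -1.5, 0.5))
  # z-standardisation property (n-1 sd) holds for every beneficial row;
  # harmful rows are stored sign-reversed, which preserves mean 0 / sd 1 too
  expect_true(all(abs(rowMeans(fix$z)) < 2e-3))
  expect_true(all(abs(apply(fix$z, 1, sd) - 1) < 2e-3))
})
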