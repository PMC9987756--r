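test_that("type means average per type, zero-fill absent species, and reject empty types", {
  tab <- rel_table(matrix(c(0.2, 0.8,
                            0.4, 0.6,
                            0.5, 0.5,
                            0.9, 0.1), 4, byrow = TRUE),
                   taxa = c("sp1", "sp2"))
  assign <- data.frame(sample_id = paste0("s", 1:4),
                       type = c("A", "A", "B", "B"))
  panel <- species_panel(c("sp1", "sp2", "ghost"),
                         rep("beneficial", 3), rep("oral", 3))
  expect_warning(mu <- type_means(tab, assign, panel), "ghost")
  expect_equal(mu["sp1", ], c(A = 0.3, B = 0.7))
  expect_equal(unname(mu["ghost", ]), c(0, 0))

  one_each <- data.frame(sample_id = paste0("s", 1:4), type = c("A", "B", "C", "D"))
  mu1 <- suppressWarnings(type_means(tab, one_each, panel))
  expect_equal(unname(mu1["sp2", ]), tab$values[, "sp2"], ignore_attr = TRUE)

  partial <- data.frame(sample_id = paste0("s", 1:2), type = c("A", "B"))
  expect_error(suppressWarnings(type_means(tab, partial, panel)), "missing")
})

test_that("z-standardisation uses the sample sd and the degenerate convention", {
  m <- matrix(c(0, 0, 3, 0), 1, dimnames = list("sp", c("SB", "SP", "HB", "HP")))
  expect_equal(unname(z_across_types(m)[1, ]), c(-0.5, -0.5, 1.5, -0.5))

  fix <- scoring_panel_fixture("oral")
  row <- fix$z["Streptococcus sanguinis", , drop = FALSE]
  expect_equal(mean(row), 0, tolerance = 1e-6)
  expect_equal(sd(row), 1, tolerance = 1e-6)

  const <- matrix(2, 1, 4, dimnames = list("sp", c("a", "b", "c", "d")))
  expect_warning(zc <- z_across_types(const), "identical means")
  expect_equal(unname(zc[1, ]), rep(0, 4))
  expect_error(z_across_types(matrix(1, 2, 1)), ">= 2 types")
})

test_that("harmful-row reversal is a sign flip and an involution", {
  panel <- species_panel(c("good", "bad"), c("beneficial", "harmful"),
                         c("gut", "gut"))
  z <- matrix(c(-0.5, -0.5, 1.5, -0.5,
                -0.5, -0.5, 1.5, -0.5), 2, byrow = TRUE,
              dimnames = list(c("good", "bad"), c("SB", "SP", "HB", "HP")))
  out <- reverse_harmful(z, panel)
  expect_equal(unname(out["bad", ]), c(0.5, 0.5, -1.5, 0.5))
  expect_equal(unname(out["good", ]), unname(z["good", ]))
  expect_equal(reverse_harmful(out, panel), z)
})

test_that("percentiles round half-up and bins are lower-closed", {
  expect_identical(percentile_from_z(0), 50L)
  expect_identical(percentile_from_z(-0.690221094), 25L)  # 24.506 -> 25
  expect_identical(percentile_from_z(1.109359234), 87L)   # 86.65 -> 87
  expect_error(percentile_from_z(Inf), "finite")

  expect_identical(quartile_score(c(0L, 24L, 25L, 49L, 50L, 74L, 75L, 100L)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(quartile_score(101L), "out of")
})

test_that("the published panel reproduces every printed site and grand total", {
  oral <- scoring_panel_fixture("oral")
  gut <- scoring_panel_fixture("gut")
  co <- score_panel(oral$z, oral$panel)
  cg <- score_panel(gut$z, gut$panel)
  expect_equal(co$site_totals["oral", ], c(SB = 35, SP = 42, HB = 34, HP = 30))
  expect_equal(cg$site_totals["gut", ], c(SB = 49, SP = 27, HB = 43, HP = 28))
  expect_equal(grand_totals(co, cg), c(SB = 84, SP = 69, HB = 77, HP = 58))

  # totals are bounded by panel size x bin range
  expect_true(all(co$site_totals >= 14 & co$site_totals <= 56))
  expect_true(all(cg$site_totals >= 15 & cg$site_totals <= 60))

  both <- scoring_panel_fixture("both")
  card <- score_panel(both$z, both$panel)
  expect_equal(card$site_totals["oral", ], co$site_totals["oral", ])
  expect_equal(card$site_totals["gut", ], cg$site_totals["gut", ])
  expect_error(grand_totals(co, structure(list(type_labels = c("X", "Y")),
                                          class = "score_card")),
               "labels differ")
})

test_that("an all-zero z panel scores 3 everywhere", {
  panel <- species_panel(sprintf("sp%02d", 1:14), rep("beneficial", 14),
                         rep("oral", 14))
  z <- matrix(0, 14, 4, dimnames = list(panel$species, c("SB", "SP", "HB", "HP")))
  card <- score_panel(z, panel)
  expect_equal(unname(card$site_totals["oral", ]), rep(42, 4))
})

test_that("raising a beneficial z never lowers its type total; harmful is the reverse", {
  panel <- species_panel(c("good", "bad"), c("beneficial", "harmful"),
                         c("oral", "oral"))
  types <- c("SB", "SP", "HB", "HP")
  set.seed(30)
  for (i in 1:20) {
    z <- matrix(rnorm(8), 2, dimnames = list(panel$species, types))
    base <- score_panel(reverse_harmful(z, panel), panel)$site_totals["oral", 1]
    zb <- z; zb["good", 1] <- zb["good", 1] + runif(1, 0, 2)
    up <- score_panel(reverse_harmful(zb, panel), panel)$site_totals["oral", 1]
    expect_gte(up, base)
    zh <- z; zh["bad", 1] <- zh["bad", 1] + runif(1, 0, 2)
    dn <- score_panel(reverse_harmful(zh, panel), panel)$site_totals["oral", 1]
    expect_lte(dn, base)
  }
})

test_that("cohort scoring reproduces the published card from back-computed means", {
  fix <- scoring_panel_fixture("oral")
  # pre-reversal z: harmful rows printed post-reversal, so undo the flip
  pre <- fix$z
  pre[fix$panel$role == "harmful", ] <- -pre[fix$panel$role == "harmful", ]
  # back-compute per-type means with arbitrary positive row scales
  scale <- seq(0.001, 0.0023, length.out = nrow(pre))
  centre <- seq(0.01, 0.023, length.out = nrow(pre))
  mu <- pre * scale + centre
  # one sample per type whose species abundances equal the planted means
  filler <- 1 - colSums(mu)
  vals <- t(rbind(mu, filler = filler))
  tab <- abundance_table(vals, "relative")
  rownames(tab$values) <- paste0("samp_", colnames(pre))
  assign <- data.frame(sample_id = rownames(tab$values), type = colnames(pre))
  card <- score_cohort(tab, assign, fix$panel)
  expect_equal(card$site_totals["oral", c("SB", "SP", "HB", "HP")],
               c(SB = 35, SP = 42, HB = 34, HP = 30))
  ref <- score_panel(fix$z, fix$panel)
  merged <- merge(card$table, ref$table, by = c("species", "type"))
  expect_equal(merged$quartile.x, merged$quartile.y)
})
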