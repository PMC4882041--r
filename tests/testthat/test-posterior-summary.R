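test_that("the HDI is the exhaustive shortest window with lower-interval tie-breaks", {
  x <- c(0, 1, 1, 2, 3, 4, 5, 6, 7, 9, 50)
  expect_equal(unname(hdi(x, mass = 0.8)), c(0, 7))  # 9 of 11 points kept
  expect_equal(unname(hdi(rep(5, 25))), c(5, 5))
  expect_error(hdi(3), "at least 2")

  set.seed(14)
  fixtures <- list(
    rnorm(11), rlnorm(100, 0, 1), c(rnorm(500, -3), rnorm(1500, 3)),
    sample(1:5, 200, replace = TRUE),  # heavy ties
    rnorm(2000)
  )
  for (x in fixtures) {
    for (mass in c(0.5, 0.8, 0.95)) {
      expect_equal(unname(hdi(x, mass)), hdi_bruteforce(x, mass))
    }
  }
})

test_that("the HDI contracts toward the symmetric interval for normal draws and never beats equal tails", {
  set.seed(3)
  z <- rnorm(1e5)
  h <- hdi(z, 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.03 / 1.96)
  set.seed(4)
  for (x in list(rlnorm(3000), rexp(3000), rnorm(3000))) {
    h <- hdi(x, 0.95)
    et <- unname(diff(quantile(x, c(0.025, 0.975))))
    expect_lte(h[["upper"]] - h[["lower"]], et + 1e-12)
  }
})

test_that("the inverse-variance-weighted grand mean matches hand-computed convex combinations", {
  a <- exact_draws(4000, 10, 1, seed = 1)
  b_eq <- exact_draws(4000, 20, 1, seed = 2)
  g1 <- weighted_grand_mean(cbind(a, b_eq))
  expect_equal(mean(g1), 15, tolerance = 1e-9)

  b_wide <- exact_draws(4000, 20, 2, seed = 2)  # variances 1 and 4
  g2 <- weighted_grand_mean(cbind(a, b_wide))
  expect_equal(mean(g2), (1 * 10 + 0.25 * 20) / 1.25, tolerance = 1e-9)
  expect_equal(unname(attr(g2, "weights")), c(0.8, 0.2), tolerance = 1e-9)

  # draw-wise convexity: the grand draw sits inside the per-draw envelope
  m <- cbind(a, b_wide, exact_draws(4000, 15, 3, seed = 3))
  g3 <- weighted_grand_mean(m)
  expect_true(all(g3 >= apply(m, 1, min) - 1e-12))
  expect_true(all(g3 <= apply(m, 1, max) + 1e-12))

  # identical phylum draws pass through unchanged
  g4 <- weighted_grand_mean(cbind(a, a + 0, a + 0))
  expect_equal(as.numeric(g4), a, tolerance = 1e-12)
  expect_error(weighted_grand_mean(cbind(a, rep(2, 4000))), "zero posterior variance")
})

test_that("pairwise contrasts flag separated phyla and are antisymmetric", {
  set.seed(6)
  draws <- cbind(A = rnorm(3000, 43, 1), B = rnorm(3000, 27, 1),
                 C = rnorm(3000, 43.1, 1))
  ct <- pairwise_contrasts(draws)
  ab <- ct[ct$phylum_a == "A" & ct$phylum_b == "B", ]
  expect_true(ab$significant)
  expect_gt(ab$hdi_low, 0)
  ac <- ct[ct$phylum_a == "A" & ct$phylum_b == "C", ]
  expect_false(ac$significant)
  # antisymmetry under pair swap
  ba <- ct[ct$phylum_a == "B" & ct$phylum_b == "A", ]
  expect_equal(ba$median, -ab$median)
  expect_equal(ba$hdi_low, -ab$hdi_high)
  expect_equal(ba$significant, ab$significant)
  # identical draw sets: difference ~ 0, never significant
  same <- pairwise_contrasts(cbind(X = draws[, 1], Y = draws[, 1]))
  expect_false(any(same$significant))
  expect_equal(same$median, c(0, 0))
})

test_that("variance decomposition sums to 100 and respects symmetry and limits", {
  const <- function(v) matrix(rep(v, each = 50), nrow = 50)
  eq <- variance_decomposition(const(c(2, 2, 2)))
  expect_equal(eq$percent, rep(100 / 3, 3), tolerance = 1e-12)
  lim <- variance_decomposition(const(c(3, 3, 0)))
  expect_equal(lim$percent, c(50, 50, 0), tolerance = 1e-12)
  set.seed(7)
  rand <- variance_decomposition(matrix(abs(rnorm(300, 5)), ncol = 3),
                                 drawwise = TRUE)
  expect_equal(sum(rand$percent), 100, tolerance = 1e-9)
  expect_equal(rowSums(attr(rand, "drawwise")), rep(100, 100), tolerance = 1e-9)
})

test_that("ratio summaries back-transform medians and HDIs from the log scale", {
  # degenerate log-ratio data: every ratio is exactly 2
  tab <- obs_tibble(rep(30, 24), phylum = rep(c("Chlorophyta", "Haptophyta"), 12),
                    species_key = rep(paste0("sp", 1:4), 6))
  tab$log_value <- log(2)
  fit <- fit_hierarchical(tab, response = "log_value",
                          config = sampler_config("test", chains = 2,
                                                  iterations = 1000),
                          seed = 5)
  s <- summarize_ratios(fit)
  expect_equal(s$median, rep(2, nrow(s)), tolerance = 1e-3)
  expect_lt(max(s$hdi_high - s$hdi_low), 1e-2)
  # monotone invariance: exp of the log-scale median is the ratio-scale median
  set.seed(8)
  lx <- rnorm(999)
  expect_equal(exp(median(lx)), median(exp(lx)), tolerance = 1e-12)
})

test_that("phylum summaries carry observation counts and bracket their medians", {
  g <- generate_dataset(synthetic_design("table3_protein"), seed = 21)
  fit <- fit_hierarchical(correct_protein(g$table),
                          config = sampler_config("test", chains = 2,
                                                  iterations = 2000),
                          seed = 22)
  s <- phylum_summary(fit)
  expect_equal(sum(s$n_obs[s$level == "phylum"]), 315)
  expect_true(all(s$hdi_low <= s$median & s$median <= s$hdi_high))
  expect_equal(s$name[s$level == "grand"], "Grand")
  p <- plot_phylum_medians(s, title = "protein (% dry weight)")
  expect_s3_class(p, "ggplot")
})
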