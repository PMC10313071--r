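test_that("standard curve efficiency and gates follow the slope arithmetic", {
  l10 <- rep(3:8, each = 3)
  # perfect 10-fold series with slope -log2(10)/... : slope -3.3219 doubles
  # template per cycle, efficiency 100 %
  cq <- 38 - 3.321928 * l10
  curve <- fit_standard_curve(l10, cq)
  expect_equal(curve$efficiency_pct, 100, tolerance = 1e-4)
  expect_equal(curve$r_squared, 1)
  expect_true(curve$passed)

  # slope -3.6 -> efficiency ~89.6 %, outside the 90-110 % gate
  curve36 <- fit_standard_curve(l10, 38 - 3.6 * l10)
  expect_equal(curve36$efficiency_pct, 100 * (10^(1 / 3.6) - 1),
               tolerance = 1e-10)
  expect_lt(curve36$efficiency_pct, 90)
  expect_false(curve36$passed)

  expect_error(fit_standard_curve(c(3, 3, 4), c(28, 28, 25)), "3 distinct")
  expect_error(fit_standard_curve(3:6, 20 + 3.3 * (3:6)), "negative")
})

test_that("quantification inverts the curve and respects the gates", {
  l10 <- 3:8
  curve <- fit_standard_curve(l10, 38 - 3.3219 * l10)
  expect_equal(quantify_copies(curve$intercept, curve), 1)
  expect_equal(quantify_copies(curve$intercept + curve$slope, curve), 10)
  # dilution and mass scaling
  expect_equal(quantify_copies(curve$intercept, curve, dilution_factor = 50,
                               mass_g = 0.25), 200)
  bad <- fit_standard_curve(l10, 38 - 3.6 * l10)
  expect_error(quantify_copies(30, bad), "refusing")
  expect_equal(quantify_copies(bad$intercept, bad, allow_failed_curve = TRUE), 1)
})

test_that("forward-simulated Cq with noisy standards recovers truth within 10 %", {
  # curve noise sigma = 0.1 on the 18-point dilution series; sample Cq from
  # the true line. The fitted slope/intercept error stays small enough that
  # a truth of 1e8 copies/g comes back within 10 %.
  set.seed(11)
  l10 <- rep(3:8, each = 3)
  true_slope <- -3.35; true_int <- 38.5
  for (i in 1:10) {
    cqs <- true_int + true_slope * l10 + rnorm(length(l10), 0, 0.1)
    curve <- fit_standard_curve(l10, cqs)
    expect_true(curve$passed)
    est <- quantify_copies(true_int + true_slope * 8, curve)
    expect_lt(abs(est / 1e8 - 1), 0.10)
  }
})

test_that("generated qPCR plates recover copy numbers within Cq-noise bounds", {
  cfg <- scenario_config(seed = 11, cq_noise_sd = 0.1)
  q <- gen_qpcr(cfg)
  for (g in c("nirS", "nosZ_II")) {
    std <- q$standards[q$standards$gene == g, ]
    curve <- fit_standard_curve(std$log10_copies, std$cq)
    expect_true(curve$passed)
    smp <- q$samples[q$samples$gene == g, ]
    est <- quantify_copies(smp$cq, curve, smp$dilution, smp$mass_g)
    truth <- q$truth$true_copies_per_g[q$truth$gene == g]
    # sample Cq noise 0.1 maps to ~7 % log-normal copy error (1 sd);
    # 4 sd bounds every sample
    expect_true(all(abs(log10(est / truth)) < 4 * 0.1 / abs(curve$slope)))
  }
})

test_that("abundance ratios combine genes per sample with NA on zero denominators", {
  ab <- expand.grid(sample_id = c("S1", "S2"),
                    gene = c("nirS", "nirK", "nosZ_I", "nosZ_II"),
                    stringsAsFactors = FALSE)
  ab$copies_per_g <- c(9, 5, 1, 5, 1, 1, 1, 1)  # S1: nirS9 nirK1 nosZ 1+1
  res <- abundance_ratios(ab)
  s1 <- res$per_sample[res$per_sample$sample_id == "S1", ]
  expect_equal(s1$nirS_nirK, 9)
  expect_equal(s1$nir_nosZ, 5)
  expect_equal(s1$nosZII_nosZI, 1)
  s2 <- res$per_sample[res$per_sample$sample_id == "S2", ]
  expect_equal(s2$nir_nosZ, 5)  # (5+5)/(1+1)
  expect_equal(res$summary$mean[res$summary$ratio == "nir_nosZ"], 5)

  ab0 <- ab
  ab0$copies_per_g[ab0$gene == "nosZ_I" | ab0$gene == "nosZ_II"] <- 0
  expect_warning(res0 <- abundance_ratios(ab0), "undefined")
  expect_true(all(is.na(res0$per_sample$nir_nosZ)))
})

test_that("synthetic qPCR cohort keeps nir/nosZ ratios in the observed field range", {
  cfg <- scenario_config(seed = 21)
  q <- gen_qpcr(cfg)
  genes <- c("nirS", "nirK", "nosZ_I", "nosZ_II")
  ab <- do.call(rbind, lapply(genes, function(g) {
    std <- q$standards[q$standards$gene == g, ]
    curve <- fit_standard_curve(std$log10_copies, std$cq)
    smp <- q$samples[q$samples$gene == g, ]
    data.frame(sample_id = smp$sample_id, gene = g,
               copies_per_g = quantify_copies(smp$cq, curve))
  }))
  res <- abundance_ratios(ab)
  # the generator's gene means put nir above nosZ on average, matching the
  # production/reduction imbalance the ratio diagnoses
  expect_gt(res$summary$mean[res$summary$ratio == "nir_nosZ"], 0.94)
})

test_that("exact-permutation Spearman matches the closed-form distribution", {
  # trivial monotone cases
  up <- rank_correlation(1:5, c(2, 4, 6, 9, 12))
  expect_equal(up$rho, 1)
  down <- rank_correlation(1:5, c(12, 9, 6, 4, 2))
  expect_equal(down$rho, -1)

  # full-enumeration p agrees with the exact null distribution in cor.test
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    mine <- rank_correlation(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$method, "exact permutation")
  }

  # rho = 0.786 at n = 7 is significant at the 5 % level
  xy <- rho786_xy()
  res <- rank_correlation(xy$x, xy$y)
  expect_equal(res$rho, 22 / 28, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)

  expect_warning(flat <- rank_correlation(1:5, rep(1, 5)), "constant")
  expect_true(is.na(flat$rho))
  expect_error(rank_correlation(1:3, 1:3), "at least 4")
})
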