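# Synthetic-data generator: exactness of the allocation, determinism,
# variance calibration, realized proportions, recovery harness.

test_that("species biomass sums to the plot total at machine precision", {
  truth <- di_truth(the_pool, sigma_u = 300)
  rec <- simulate_year(design2, truth, the_pool, year = 1, seed = 61)
  bio <- as.matrix(rec[, paste0("bio_", the_pool$species$abbr)])
  expect_lt(max(abs(rowSums(bio) - rec$y)), 1e-9)
  expect_true(all(bio >= 0))
  # absent species receive exactly zero
  P <- planted_proportions(design2, the_pool)
  expect_true(all(bio[P == 0] == 0))
})

test_that("simulation is deterministic under a fixed seed", {
  truth <- di_truth(the_pool, sigma_u = 200)
  a <- simulate_experiment(design2, truth, the_pool, years = 2, seed = 62)
  b <- simulate_experiment(design2, truth, the_pool, years = 2, seed = 62)
  expect_identical(a$records, b$records)
  c <- simulate_experiment(design2, truth, the_pool, years = 2, seed = 63)
  expect_false(identical(a$records$y, c$records$y))
})

test_that("with vanishing noise the totals equal the DI expectation", {
  # DE = none: y is exactly the proportion-weighted monoculture average
  # plus the block effect
  truth <- di_truth(the_pool, structure = "none", delta_P11 = NULL,
                    sigma = c(mono = 1e-9, focalmix = 1e-9, othermix = 1e-9),
                    allocation_conc = 1e7)
  rec <- simulate_year(design2, truth, the_pool, year = 1, seed = 64)
  P <- planted_proportions(design2, the_pool)
  expected <- drop(P %*% default_beta(the_pool)) +
    truth$alpha[design2$block]
  expect_lt(max(abs(rec$y - expected)), 1e-6)
})

test_that("the worked 4-species example reproduces the pair-sum oracle", {
  # delta = 93.6 at four species with 25% each: sum of the 6 pair products
  # is 6 * 0.0625 = 0.375, so the diversity effect contributes 35.1 g
  truth <- di_truth(the_pool, structure = "M2", delta = 93.6,
                    delta_P11 = NULL,
                    sigma = c(mono = 1e-9, focalmix = 1e-9, othermix = 1e-9))
  des4 <- design2[design2$richness == 4 &
                  design2$evenness == "high", ][1, , drop = FALSE]
  rec <- simulate_year(des4, truth, the_pool, year = 1, seed = 65)
  P <- planted_proportions(des4, the_pool)
  id_part <- drop(P %*% default_beta(the_pool)) + truth$alpha[des4$block]
  expect_equal(rec$y - id_part, 0.375 * 93.6, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("group variances of simulated totals match the truth", {
  truth <- di_truth(the_pool)
  # pool 30 independent runs of the 170-plot design so even the smallest
  # variance group (focal mixtures, 28 plots) has ~800 df
  tot <- NULL
  for (r in 1:30) {
    rec <- simulate_year(design5, truth, the_pool, year = 1, seed = 650 + r)
    md <- cbind(design5[, c("block", "pattern")],
                as.data.frame(planted_proportions(design5, the_pool)))
    g <- variance_groups(md, "mono_vs_focalmix_vs_othermix", the_pool)
    tot <- rbind(tot, data.frame(g = as.character(g), y = rec$y,
                                 plot = design5$plot_id))
  }
  # variance around the per-plot mean isolates the noise component
  for (gname in c("mono", "focalmix", "othermix")) {
    sub <- tot[tot$g == gname, ]
    resid <- sub$y - stats::ave(sub$y, sub$plot, FUN = mean)
    reps <- table(sub$plot)[1]
    vhat <- sum(resid^2) / (nrow(sub) - length(unique(sub$plot)))
    expect_lt(abs(vhat - truth$sigma2[[gname]]) / truth$sigma2[[gname]],
              0.15)
  }
})

test_that("focal-species mixtures are more productive and more variable", {
  truth <- di_truth(the_pool)  # focal beta high, positive focal DE modifier
  rec <- simulate_year(design5, truth, the_pool, year = 1, seed = 66)
  P <- planted_proportions(design5, the_pool)
  mix <- design5$pattern != "monoculture"
  hm <- P[, the_pool$focal] > 0
  expect_gt(mean(rec$y[mix & hm]), mean(rec$y[mix & !hm]))
  expect_gt(stats::sd(rec$y[mix & hm]), stats::sd(rec$y[mix & !hm]))
})

test_that("realized proportions are valid and feed next-year predictors", {
  bio1 <- matrix(0, 1, 16)
  bio1[1, 1:3] <- c(10, 30, 60)
  expect_equal(unname(realized_proportions(bio1, the_pool)[1, 1:3]),
               c(0.1, 0.3, 0.6))
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design2, truth, the_pool, years = 2, seed = 67)
  y1 <- sim$records[sim$records$year == 1, ]
  rp <- realized_proportions(y1, the_pool)
  expect_lt(max(abs(rowSums(rp) - 1)), 1e-9)
  mono <- y1$pattern == "monoculture"
  expect_true(all(rp[mono, ][rp[mono, ] > 0] == 1))
  md2 <- model_data(sim, 2, "realized", the_pool)
  expect_equal(as.matrix(md2[, the_pool$species$abbr]), rp,
               ignore_attr = TRUE)
  expect_error(model_data(sim, 1, "realized", the_pool), "preceding")
})

test_that("zero-biomass plots yield NA proportions with a warning", {
  bio <- matrix(c(rep(0, 16), rep(1, 16)), 2, byrow = TRUE)
  expect_warning(rp <- realized_proportions(bio, the_pool), "zero total")
  expect_true(all(is.na(rp[1, ])))
})

test_that("the recovery harness is unbiased under its own truth", {
  truth <- di_truth(the_pool, structure = "M2", delta = 93.6,
                    delta_P11 = NULL)
  rec <- recovery_experiment(truth,
    di_spec("M2", variance_structure = "mono_vs_focalmix_vs_othermix"),
    the_pool, n_replicates = 40, seed = 68)
  s <- rec$summary[rec$summary$term == "DE_AV", ]
  expect_lt(abs(s$bias), s$empirical_se)  # |bias| well under 1 MC-rep SE
  expect_gt(s$coverage, 0.85)
  # near-zero noise: exact recovery
  truth0 <- di_truth(the_pool, structure = "M2", delta = 93.6,
                     delta_P11 = NULL,
                     sigma = c(mono = 1e-9, focalmix = 1e-9,
                               othermix = 1e-9))
  rec0 <- recovery_experiment(truth0, di_spec("M2"), the_pool,
                              n_replicates = 3, seed = 69)
  expect_lt(abs(rec0$summary$bias[rec0$summary$term == "DE_AV"]), 1e-5)
})
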