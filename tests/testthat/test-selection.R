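# Model-comparison machinery and the selection cascade.

format_spec_public <- function(spec)
  paste(spec$structure, paste(spec$expansions, collapse = "+"),
        spec$variance_structure, spec$random_pairwise)

make_fits <- function(seed, vsname = "homoscedastic") {
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design5, truth, the_pool, years = 1, seed = seed)
  md <- model_data(sim, 1, "planted", the_pool)
  g <- variance_groups(md, vsname, the_pool)
  fits <- lapply(c(M1 = "M1", M2 = "M2", M3 = "M3", M4 = "M4"),
                 function(st) {
    mm <- build_design_matrix(md, di_spec(st), the_pool)
    fit_gls(md$y, mm, g)
  })
  c(fits, list(data = md, groups = g))
}

test_that("the F-test is zero for identical models and rejects non-nesting", {
  fits <- make_fits(51)
  r <- compare_nested_F(fits$M2, fits$M2)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  r12 <- compare_nested_F(fits$M1, fits$M2)
  expect_equal(r12$df1, 1L)
  expect_equal(r12$df2, 170L - 21L)
  # M3 and M4 are not nested in either direction
  expect_error(compare_nested_F(fits$M4, fits$M3), "not nested")
  expect_error(compare_nested_F(fits$M3, fits$M4), "not nested")
  # different responses are refused
  other <- make_fits(52)
  expect_error(compare_nested_F(fits$M1, other$M2), "different responses")
})

test_that("the F-test entry rule holds its size under the identity truth", {
  # M1 vs M2 at alpha = 0.05 under M1-true simulation
  truth <- di_truth(the_pool, structure = "none", delta_P11 = NULL,
                    variance_structure = "homoscedastic",
                    sigma = c(all = 120))
  rej <- vapply(1:400, function(r) {
    sim <- simulate_experiment(design5, truth, the_pool, years = 1,
                               seed = 6000 + r)
    md <- model_data(sim, 1, "planted", the_pool)
    g <- factor(rep("all", nrow(md)))
    f1 <- fit_gls(md$y, build_design_matrix(md, di_spec("M1"), the_pool), g)
    f2 <- fit_gls(md$y, build_design_matrix(md, di_spec("M2"), the_pool), g)
    compare_nested_F(f1, f2)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("F-test power grows monotonically with the interaction strength", {
  grid <- c(0, 150, 400)
  power <- vapply(grid, function(d) {
    rej <- vapply(1:60, function(r) {
      truth <- di_truth(the_pool, structure = "M2", delta = d,
                        delta_P11 = NULL)
      sim <- simulate_experiment(design5, truth, the_pool, years = 1,
                                 seed = 800 + r)
      md <- model_data(sim, 1, "planted", the_pool)
      g <- variance_groups(md, "mono_vs_focalmix_vs_othermix", the_pool)
      f1 <- fit_gls(md$y, build_design_matrix(md, di_spec("M1"), the_pool), g)
      f2 <- fit_gls(md$y, build_design_matrix(md, di_spec("M2"), the_pool), g)
      compare_nested_F(f1, f2)$p < 0.05
    }, TRUE)
    mean(rej)
  }, 1)
  expect_true(all(diff(power) > 0))
  expect_gt(power[3], 0.9)
})

test_that("likelihood-ratio tests behave at zero and on the boundary", {
  fits <- make_fits(53)
  r <- compare_lrt(fits$M2, fits$M2)
  expect_equal(r$X2, 0)
  # variance LRT needs matching fixed effects
  expect_error(compare_lrt(fits$M1, fits$M2, "variance"), "matching fixed")
  # boundary mixture: p = 1 at X2 = 0, halved tail otherwise
  expect_equal(compare_lrt(fits$M2, fits$M2, kind = "variance",
                           boundary = TRUE)$p, 1)
})

test_that("the cascade is deterministic and records every decision", {
  truth <- di_truth(the_pool)
  sim <- simulate_experiment(design5, truth, the_pool, years = 1, seed = 54)
  md <- model_data(sim, 1, "planted", the_pool)
  tr1 <- select_model(md, the_pool)
  tr2 <- select_model(md, the_pool)
  expect_identical(tr1$steps, tr2$steps)
  expect_identical(format_spec_public(tr1$final_spec),
                   format_spec_public(tr2$final_spec))
  expect_true(all(c("step", "statistic", "decision") %in% names(tr1$steps)))
  expect_gte(nrow(tr1$steps), 4L)
})

test_that("selected fixed parameter counts match the family accounting", {
  # (M2, {P11}) -> 16 + 4 + 2 = 22; (M3, {Sp, P11}) -> 16 + 4 + 48 = 68
  dat <- planted_frame(design5)
  mm_a <- build_design_matrix(dat, di_spec("M2", "P11"), the_pool)
  mm_b <- build_design_matrix(dat, di_spec("M3", c("Sp", "P11")), the_pool)
  expect_equal(ncol(mm_a$X), 22L)
  expect_equal(ncol(mm_b$X), 68L)
})

test_that("the cascade recovers an establishment-year-like truth", {
  # truth: average pairwise interaction whose strength scales with the
  # focal species' proportion (M2 + P11), at study scale and noise
  res <- vapply(1:200, function(r) {
    truth <- di_truth(the_pool)
    sim <- simulate_experiment(design5, truth, the_pool, years = 1,
                               seed = 1000 + r)
    md <- model_data(sim, 1, "planted", the_pool)
    sp <- select_model(md, the_pool,
                       test_random_pairwise = FALSE)$final_spec
    paste0(sp$structure, "+", paste(sp$expansions, collapse = "+"))
  }, "")
  tab <- sort(table(res), decreasing = TRUE)
  expect_equal(names(tab)[1], "M2+P11")    # modal outcome
  expect_gte(mean(res == "M2+P11"), 0.70)
  expect_gte(mean(grepl("P11", res)), 0.90)  # focal expansion detected
})

test_that("proportion-source comparison is zero for identical fits", {
  fits <- make_fits(55)
  r <- compare_proportion_sources(fits$M2, fits$M2)
  expect_equal(r$dAIC, 0)
  expect_equal(r$winner, "planted")
  other <- make_fits(56)
  expect_error(compare_proportion_sources(fits$M2, other$M2),
               "different responses")
})
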