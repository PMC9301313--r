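test_that("nested mean squares match the independent ANOVA oracle", {
  # 2 sites x 2 days x 2 reps hand dataset
  d <- data.frame(site = rep(1:2, each = 4), day = rep(c(1, 2, 1, 2), each = 2),
                  replicate = rep(1:2, 4), value = c(1, 2, 2, 3, 3, 4, 4, 5))
  ms <- nested_anova(d, "multisite")
  oracle <- aov_nested_ms(d, "site", "day")
  expect_equal(ms$MS_site, oracle$MS_top, tolerance = 1e-12)
  expect_equal(ms$MS_day, oracle$MS_mid, tolerance = 1e-12)
  expect_equal(ms$MS_error, oracle$MS_error, tolerance = 1e-12)

  # a handful of random balanced designs, both layouts
  for (s in 1:5) {
    sim <- simulate_precision_dataset(2, 0.01, 0.02, 0.05, n_top = 3,
                                      n_mid = 4, n_rep = 3, seed = s)
    ms <- nested_anova(sim, "multisite")
    oracle <- aov_nested_ms(sim, "site", "day")
    expect_equal(ms$MS_site, oracle$MS_top, tolerance = 1e-10)
    expect_equal(ms$MS_day, oracle$MS_mid, tolerance = 1e-10)
    expect_equal(ms$MS_error, oracle$MS_error, tolerance = 1e-10)

    sim2 <- simulate_precision_dataset(2, 0.01, 0.02, 0.05, n_top = 4,
                                       n_mid = 2, n_rep = 2,
                                       layout = "singlesite", seed = s)
    ms2 <- nested_anova(sim2, "singlesite")
    oracle2 <- aov_nested_ms(sim2, "day", "run")
    expect_equal(ms2$MS_day, oracle2$MS_top, tolerance = 1e-10)
    expect_equal(ms2$MS_run, oracle2$MS_mid, tolerance = 1e-10)
    expect_equal(ms2$MS_error, oracle2$MS_error, tolerance = 1e-10)
  }
})

test_that("identical measurements give zero mean squares", {
  d <- expand.grid(site = 1:2, day = 1:3, replicate = 1:2)
  d$value <- 1.7
  ms <- nested_anova(d, "multisite")
  expect_equal(ms$MS_site, 0)
  expect_equal(ms$MS_day, 0)
  expect_equal(ms$MS_error, 0)
})

test_that("unbalanced designs are rejected with the offending cell named", {
  d <- expand.grid(site = 1:2, day = 1:2, replicate = 1:3)
  d$value <- rnorm(nrow(d))
  d <- d[-1, ]  # drop one replicate from site 1, day 1
  expect_error(nested_anova(d, "multisite"), "unbalanced.*site.*1.*day.*1")
})

test_that("variance components follow the nested identities and truncate", {
  vc <- variance_components(list(MS_error = 0.1, MS_day = 0.2, MS_site = 0.3),
                            n_rep = 5, n_day = 5, layout = "multisite")
  expect_equal(unname(vc$components),
               c(0.1, (0.2 - 0.1) / 5, (0.3 - 0.2) / 25))
  expect_false(any(vc$truncated))

  # MS_day below MS_error: negative estimate truncated and flagged
  vc2 <- variance_components(list(MS_error = 0.2, MS_day = 0.1,
                                  MS_site = 0.3),
                             n_rep = 5, n_day = 5, layout = "multisite")
  expect_equal(vc2$components[["V_day"]], 0)
  expect_true(vc2$truncated[["V_day"]])
  expect_lt(vc2$raw[["V_day"]], 0)

  # singlesite identities
  vc3 <- variance_components(list(MS_error = 0.05, MS_run = 0.10,
                                  MS_day = 0.30),
                             n_rep = 2, n_run = 2, layout = "singlesite")
  expect_equal(unname(vc3$components),
               c(0.05, (0.10 - 0.05) / 2, (0.30 - 0.10) / 4))

  expect_error(variance_components(list(MS_error = 1, MS_day = 1,
                                        MS_site = 1),
                                   n_rep = 0, n_day = 5,
                                   layout = "multisite"), "n_rep")
})

test_that("precision tiers reproduce the published component arithmetic", {
  # sample at 0.4 mg/dl: V_error 0.012, mean 0.39
  p1 <- precision_estimates(list(V_error = 0.012, V_day = 0.001,
                                 V_site = 0.001), mean = 0.39)
  expect_equal(round(p1$SD[p1$tier == "repeatability"], 2), 0.11)
  expect_equal(round(p1$CV_pct[p1$tier == "repeatability"], 1), 28.1)

  # sample at 2.0 mg/dl: components 0.250 / 0.021 / 0.003, mean 2.30
  p5 <- precision_estimates(list(V_error = 0.250, V_day = 0.021,
                                 V_site = 0.003), mean = 2.30)
  expect_equal(round(p5$SD[p5$tier == "repeatability"], 3), 0.500)
  expect_equal(round(p5$SD[p5$tier == "reproducibility"], 2), 0.52)

  zero <- precision_estimates(list(V_error = 0, V_day = 0, V_site = 0),
                              mean = 1)
  expect_true(all(zero$SD == 0) && all(zero$CV_pct == 0))
  expect_error(precision_estimates(list(V_error = 0.1), mean = 0), "mean")
})

test_that("precision tiers are nested: repeatability <= within-lab <= reproducibility", {
  for (s in 1:10) {
    sim <- simulate_precision_dataset(1.5, 0.02, 0.01, 0.05, seed = 100 + s)
    est <- precision_analysis(sim, "multisite")[[1]]$estimates
    sds <- setNames(est$SD, est$tier)
    expect_lte(sds[["repeatability"]], sds[["within_laboratory"]] + 1e-12)
    expect_lte(sds[["within_laboratory"]], sds[["reproducibility"]] + 1e-12)
  }
})

test_that("adding between-site variance increases estimated reproducibility on average", {
  repro <- function(v_site, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_precision_dataset(1.5, v_site, 0.01, 0.04, seed = s)
      est <- precision_analysis(sim, "multisite")[[1]]$estimates
      est$SD[est$tier == "reproducibility"]
    }, numeric(1)))
  }
  seeds <- 1:40
  expect_gt(repro(0.05, seeds), repro(0, seeds))
})
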