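test_that("five-year truncation censors beyond 1825 days and is idempotent", {
  tab <- data.frame(id = paste0("p", 1:6),
                    time_days = c(2000, 1825, 100, 3650, 1826, 500),
                    event = c(1L, 1L, 0L, 0L, 1L, 1L))
  out <- censor_at_5_years(tab)
  expect_equal(out$time_days, c(1825, 1825, 100, 1825, 1825, 500))
  expect_equal(out$event, c(0L, 1L, 0L, 0L, 0L, 1L))
  expect_identical(censor_at_5_years(out), out)
  bad <- data.frame(id = "x", time_days = 0, event = 1L)
  expect_error(censor_at_5_years(bad), class = "itil_invalid_row", regexp = "x")
  expect_error(censor_at_5_years(data.frame(id = "y", time_days = 5, event = 2L)),
               class = "itil_invalid_row")
})

test_that("Kaplan-Meier curves start at 1 and identical groups give a null log-rank", {
  tab <- data.frame(time_days = c(100, 200, 300, 400, 500, 600),
                    event = c(1L, 0L, 1L, 1L, 0L, 1L))
  dup <- rbind(tab, tab)
  km <- km_logrank(dup, rep(c("a", "b"), each = 6))
  expect_lt(km$chisq, 1e-9)
  expect_gt(km$p_value, 0.99)
  expect_true(all(km$curves$surv <= 1))
  for (g in unique(km$curves$group)) {
    s <- km$curves$surv[km$curves$group == g]
    expect_true(all(diff(s) <= 0))
  }
  expect_error(km_logrank(tab, rep("a", 6)), class = "itil_invalid_argument")

  # all-censored subjects keep the curve flat at 1
  cens <- data.frame(time_days = rep(10, 8), event = rep(0L, 8))
  kmc <- survival::survfit(survival::Surv(time_days, event) ~ 1, data = cens)
  expect_true(all(kmc$surv == 1))
})

test_that("the log-rank test detects a strong planted hazard ratio", {
  hits <- 0
  for (s in 1:40) {
    tab <- with_seed(s, {
      t1 <- rexp(200, 1e-3); t2 <- rexp(200, 3e-3)
      data.frame(time_days = ceiling(c(t1, t2)),
                 event = rep(1L, 400),
                 grp = rep(c("high", "low"), each = 200))
    })
    hits <- hits + (km_logrank(tab, "grp")$p_value < 0.001)
  }
  expect_gte(hits, 38)   # >= 95% power
})

test_that("Cox fits report reciprocal hazards under group relabelling", {
  tab <- censor_at_5_years(generate_cohort(cohort_spec(n_patients = 500, seed = 11)))
  tab$low <- tab$til_class == "TIL-Low"
  tab$high <- !tab$low
  f1 <- cox_fit(tab, "low")
  f2 <- cox_fit(tab, "high")
  expect_equal(f1$table$HR, 1 / f2$table$HR, tolerance = 1e-6)
  expect_equal(f1$table$p, f2$table$p, tolerance = 1e-6)
  expect_error(cox_fit(tab, character()), class = "itil_invalid_argument")
  expect_error(cox_fit(tab, "nope"), class = "itil_invalid_argument")
  tab$const <- TRUE
  expect_error(cox_fit(tab, "const"), class = "itil_invalid_argument")
})

test_that("a null covariate's confidence interval covers 1 at the nominal rate", {
  cover <- 0
  for (s in 1:30) {
    tab <- with_seed(100 + s, {
      data.frame(time_days = ceiling(rexp(300, 1e-3)),
                 event = rbinom(300, 1, 0.8),
                 x = rbinom(300, 1, 0.5) == 1)
    })
    ci <- cox_fit(tab, "x")$table
    cover <- cover + (ci$ci_low <= 1 && ci$ci_high >= 1)
  }
  expect_gte(cover, 24)   # ~95% nominal with 30 draws
})

test_that("a multivariate fit handles the full covariate roster", {
  tab <- censor_at_5_years(generate_cohort(cohort_spec(n_patients = 600, seed = 12)))
  tab$til_low <- tab$til_class == "TIL-Low"
  covs <- c("age_decades", "gender", "site", "t4", "n2", "nodes_lt12",
            "grade_high", "lvi", "emvi", "mmr_deficient", "adjuvant_chemo",
            "til_low")
  f <- cox_fit(tab, covs)
  expect_equal(nrow(f$table), length(covs))
  expect_true(all(is.finite(f$table$HR)))
  expect_true(all(f$table$ci_low <= f$table$HR & f$table$HR <= f$table$ci_high))
  # the planted TIL effect dominates the null covariates
  expect_lt(f$table$p[f$table$covariate == "til_lowTRUE"], 0.01)
})

test_that("the cut-off search is deterministic and order-invariant", {
  tab <- censor_at_5_years(generate_cohort(cohort_spec(n_patients = 300, seed = 13)))
  r1 <- cutoff_search(tab, grid = 5:40, k_groups = 5, seed = 2)
  r2 <- cutoff_search(tab, grid = 5:40, k_groups = 5, seed = 2)
  expect_identical(r1$per_repeat, r2$per_repeat)

  shuffled <- with_seed(99, tab[sample(nrow(tab)), ])
  r3 <- cutoff_search(shuffled, grid = 5:40, k_groups = 5, seed = 2)
  expect_equal(r3$consensus, r1$consensus)

  single <- cutoff_search(tab, grid = 17, k_groups = 3, seed = 1)
  expect_equal(single$consensus, 17)
  expect_true(single$unanimous)

  expect_error(cutoff_search(tab, grid = numeric()), class = "itil_invalid_argument")
  # a grid beyond every score has no valid split
  expect_error(cutoff_search(tab, grid = 1e6), class = "itil_invalid_argument")
})

test_that("clinical risk requires all five features and flags any one of them", {
  df <- data.frame(t4 = c(TRUE, FALSE, FALSE, FALSE),
                   grade_high = c(FALSE, FALSE, NA, FALSE),
                   emvi = FALSE, lvi = FALSE,
                   nodes_lt12 = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(clinical_risk(df), c("high", "low", "unclassified", "high"))
  expect_error(clinical_risk(data.frame(t4 = TRUE)), class = "itil_invalid_argument")
})

test_that("null cohorts produce uniform log-rank p-values", {
  ps <- vapply(1:120, function(s) {
    tab <- censor_at_5_years(generate_cohort(
      cohort_spec(n_patients = 200, hazard_ratio = 1, seed = 5000 + s)))
    km_logrank(tab, tab$til_class)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
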