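sim_step_cohort <- function(n = 300, hr = 4, cut = 50, seed = 1,
                            lambda0 = 0.02, censor = 60) {
  set.seed(seed)
  x <- runif(n, 0, 100)
  rate <- lambda0 * hr^(x > cut)
  t_ev <- rexp(n, rate)
  list(x = x, time = pmin(t_ev, censor), event = as.integer(t_ev <= censor))
}

test_that("the log-rank scan agrees with survdiff at arbitrary thresholds", {
  d <- sim_step_cohort(n = 120, seed = 3)
  cand <- quantile(d$x, c(0.2, 0.4, 0.5, 0.6, 0.8), names = FALSE)
  chi <- invasivefront:::logrank_scan(d$x, d$time, d$event, cand)
  ref <- vapply(cand, function(ct)
    survival::survdiff(survival::Surv(d$time, d$event) ~ I(d$x <= ct))$chisq, 0)
  expect_equal(chi, ref, tolerance = 1e-10)
})

test_that("optimal_cutpoint recovers a planted step and corrects its p value", {
  d <- sim_step_cohort(n = 300, hr = 4, cut = 50, seed = 11)
  cp <- optimal_cutpoint(d$x, d$time, d$event,
                         cfg = list(n_sim = 100, seed = 1))
  expect_gt(cp$threshold, quantile(d$x, 0.25))
  expect_lt(cp$threshold, quantile(d$x, 0.75))
  expect_gte(cp$p_corrected, cp$p_naive)
  expect_lt(cp$p_corrected, 0.05)
  # threshold strictly inside the observed range
  expect_gt(cp$threshold, min(d$x))
  expect_lt(cp$threshold, max(d$x))
})

test_that("cut-point search validates its inputs", {
  expect_error(optimal_cutpoint(rep(1, 10), rexp(10), rep(1L, 10)),
               "constant")
  expect_error(optimal_cutpoint(runif(10), rexp(10), rep(0L, 10)),
               "2 events")
})

test_that("dichotomization splits strictly above each printed cut-off", {
  pts <- data.frame(
    n_buds = c(287, 288), n_minimal_lvi = c(16, 17), n_pdc = c(35, 36),
    tumor_stroma_pct = c(21, 21.5), area_pdc_um2 = c(35647, 35648))
  g <- dichotomize(pts)
  for (col in names(g)) {
    expect_identical(as.character(g[[col]]), c("low", "high"), info = col)
  }
  allzero <- dichotomize(data.frame(n_buds = rep(0, 5)))
  expect_true(all(allzero$n_buds_group == "low"))
})

test_that("Kaplan-Meier steps sit at event times and identical groups give p = 1", {
  tm <- c(2, 4, 4, 7, 9, 12); ev <- c(1, 1, 0, 1, 0, 1)
  km1 <- km_logrank(rep("a", 6), tm, ev)
  expect_true(is.na(km1$p))
  expect_setequal(km1$fit$time[km1$fit$n.event > 0], unique(tm[ev == 1]))
  dup <- km_logrank(rep(c("a", "b"), each = 6), c(tm, tm), c(ev, ev))
  expect_equal(dup$chisq, 0, tolerance = 1e-12)
  expect_equal(dup$p, 1, tolerance = 1e-12)
})

test_that("a planted hazard difference is detected by the log-rank test", {
  d <- sim_step_cohort(n = 500, hr = 4, cut = 50, seed = 5)
  km <- km_logrank(ifelse(d$x > 50, "high", "low"), d$time, d$event)
  expect_lt(km$p, 0.01)
})

test_that("BH adjustment matches the hand-coded step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("univariate Cox recovers a planted hazard ratio", {
  d <- sim_step_cohort(n = 800, hr = 4, cut = 50, seed = 13)
  res <- cox_univariate(as.integer(d$x > 50), d$time, d$event)
  expect_true(res$converged)
  expect_gt(res$ci_upper, res$hr)
  expect_lt(res$ci_lower, res$hr)
  expect_gt(res$ci_upper, 4 * 0.8)
  expect_lt(abs(log(res$hr) - log(4)), 0.35)
  expect_error(cox_univariate(rep(1, 10), rexp(10), rep(1L, 10)), "constant")
})

test_that("backward elimination keeps the informative covariate and drops noise", {
  set.seed(17)
  n <- 400
  x <- rbinom(n, 1, 0.4)
  noise <- matrix(rbinom(n * 4, 1, 0.5), n, 4,
                  dimnames = list(NULL, paste0("z", 1:4)))
  rate <- 0.02 * 3^x
  t_ev <- rexp(n, rate); censor <- 60
  dat <- data.frame(x = x, noise)
  res <- cox_backward_aic(dat, c("x", paste0("z", 1:4)),
                          pmin(t_ev, censor), as.integer(t_ev <= censor))
  expect_true("x" %in% res$retained)
  expect_lt(length(res$retained), 5L)
  # the stepwise AIC trace never increases
  expect_true(all(diff(res$trace$AIC) <= 1e-8))
})

test_that("collinear covariates are dropped with a warning before fitting", {
  set.seed(19)
  n <- 200
  a <- rbinom(n, 1, 0.5)
  dat <- data.frame(a = a, b = a, c = rbinom(n, 1, 0.5))
  t_ev <- rexp(n, 0.02 * 2^a)
  expect_warning(
    res <- cox_backward_aic(dat, c("a", "b", "c"), pmin(t_ev, 60),
                            as.integer(t_ev <= 60)),
    "collinear")
  expect_false("b" %in% res$retained)
})

test_that("the prognostic index matches brute-force rule evaluation on all 12 combinations", {
  grid <- expand.grid(area = c(10000, 40000), pt = c("pT3", "pT4"),
                      diff = c("well", "moderate", "poor"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    got <- build_npi(list(area_pdc_um2 = grid$area[i],
                          pt_stage = grid$pt[i],
                          differentiation = grid$diff[i]))
    want <- npi_oracle(grid$area[i], grid$pt[i], grid$diff[i])
    expect_identical(got$score, want$score)
    expect_identical(got$group, want$group)
  }
})

test_that("prognostic index component rules and error handling", {
  hi <- build_npi(list(area_pdc_um2 = 40000, pt_stage = "pT4",
                       differentiation = "moderate"))
  expect_identical(hi$group, "high")
  lo <- build_npi(list(area_pdc_um2 = 10000, pt_stage = "pT3",
                       differentiation = "poor"))
  expect_identical(lo$group, "low")
  expect_error(build_npi(list(pt_stage = "pT4", differentiation = "poor")),
               "missing component")
  expect_error(build_npi(list(area_pdc_um2 = NA, pt_stage = "pT4",
                              differentiation = "poor")),
               "missing component")
})
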