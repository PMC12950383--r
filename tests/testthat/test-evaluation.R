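test_that("IPCW C-index equals brute-force Harrell C without censoring", {
  set.seed(41)
  for (rep in 1:3) {
    n <- 200
    scores <- runif(n)
    time <- rexp(n, 0.3) + 1e-3
    event <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
    expect_equal(ipcw_cindex(scores, time, event),
                 brute_force_cindex(scores, time, event),
                 tolerance = 1e-12)
  }
})

test_that("C-index hits its deterministic anchors", {
  n <- 300
  time <- seq_len(n) / 10
  event <- rep(1L, n)
  expect_equal(ipcw_cindex(-time, time, event), 1)   # perfect ranking
  expect_equal(ipcw_cindex(time, time, event), 0)    # perfectly reversed
  expect_equal(ipcw_cindex(rep(0.5, n), time, event), 0.5)  # all tied
  co <- simulate_cohort(sim_config(n = 8000, seed = 42,
                                   beta_true = c(donor_sex_male = 0)))
  set.seed(876543)   # unrelated to the generator's internal streams
  expect_lt(abs(ipcw_cindex(runif(8000), co$time, co$event) - 0.5), 0.02)
})

test_that("tau_max restricts the index events", {
  set.seed(43)
  n <- 100
  scores <- runif(n)
  time <- rexp(n, 0.5) + 1e-3
  event <- rep(1L, n)
  tau <- median(time)
  expect_equal(ipcw_cindex(scores, time, event, tau_max = tau),
               brute_force_cindex(scores, time, event, tau_max = tau),
               tolerance = 1e-12)
})

test_that("bootstrap C-index is seed-reproducible with ordered BC CI", {
  set.seed(44)
  n <- 400
  co <- simulate_cohort(sim_config(n = n, seed = 44))
  sc <- suppressWarnings(edam_score(co))
  b1 <- bootstrap_cindex(sc$score, co$time, co$event, B = 25, seed = 7)
  b2 <- bootstrap_cindex(sc$score, co$time, co$event, B = 25, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_cindex(sc$score, co$time, co$event, B = 25, seed = 8)
  expect_false(identical(b1$replicates, b3$replicates))
  expect_lt(b1$ci[1], b1$ci[2])
  expect_equal(b1$estimate, ipcw_cindex(sc$score, co$time, co$event))
  expect_gt(b1$se, 0)
})

test_that("decile calibration is exact for perfectly calibrated input", {
  set.seed(45)
  pred <- runif(2000, 0.05, 0.6)
  cal <- decile_calibration(pred, pred)
  expect_equal(cal$slope, 1, tolerance = 1e-10)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(nrow(cal$table), 10L)
  expect_equal(sum(cal$table$n), 2000L)
  # affine distortion is read back exactly at the group level
  cal2 <- decile_calibration(pred, 0.05 + 0.7 * pred)
  expect_equal(cal2$slope, 0.7, tolerance = 1e-10)
  expect_equal(cal2$intercept, 0.05, tolerance = 1e-10)
  expect_warning(decile_calibration(rep(c(0.2, 0.4), 50), runif(100)),
                 "coarser")
})

test_that("calibration slope is exactly equivariant to lp scaling", {
  set.seed(46)
  n <- 1500
  lp <- rnorm(n, 0, 0.7)
  theta <- 1 - exp(-exp(-0.5 + lp)) + rnorm(n, 0, 0.1)
  c1 <- calibration_slope(lp, theta)
  c2 <- calibration_slope(lp / 2, theta)
  expect_equal(c2$slope, 2 * c1$slope, tolerance = 1e-7)
  expect_equal(c2$intercept, c1$intercept, tolerance = 1e-7)
  expect_lt(abs(c1$slope - 1), 3 * c1$slope_se)
})

test_that("DerSimonian-Laird pooling matches the textbook formulas", {
  est <- c(1.02, 0.95, 1.10, 0.88, 1.05)
  se <- c(0.05, 0.08, 0.06, 0.09, 0.07)
  got <- pool_random_effects(est, se)
  want <- hand_dl_pool(est, se)
  expect_equal(got$pooled, want$pooled, tolerance = 1e-10)
  expect_equal(got$se, want$se, tolerance = 1e-10)
  expect_equal(got$tau2, want$tau2, tolerance = 1e-10)
  expect_equal(got$q, want$q, tolerance = 1e-10)
  # homogeneous folds truncate tau2 at zero
  hom <- pool_random_effects(c(1.0, 1.001, 0.999), c(0.1, 0.1, 0.1))
  expect_equal(hom$tau2, 0)
  expect_error(pool_random_effects(1, 0.1), "length")
})

test_that("IECV refits per fold and pools transportable slopes", {
  co <- simulate_cohort(sim_config(n = 5000, seed = 47))
  ie <- iecv(co)
  expect_equal(nrow(ie$folds), 5L)
  expect_setequal(ie$folds$fold, 1:5)
  expect_equal(sum(ie$folds$n), 5000L)
  expect_gt(ie$pooled_slope$pooled, 0.7)
  expect_lt(ie$pooled_slope$pooled, 1.3)
  # the fold intercepts trade off against slopes below 1, so this is a
  # loose sanity bound at this cohort size, not a calibration claim
  expect_lt(abs(ie$pooled_intercept$pooled), 0.5)
  expect_error(iecv(co, fold = rep(1L, nrow(co))), "2 folds")
  expect_error(iecv(co, fold = c(rep(1L, 4999), 2L)), "at least 50")
})

test_that("IECV fold labels default to the UNOS super-regions", {
  co <- simulate_cohort(sim_config(n = 3000, seed = 48))
  ie <- iecv(co)
  expect_setequal(ie$folds$fold, sort(unique(super_region_fold(co$unos_region))))
  co$unos_region <- NULL
  expect_error(iecv(co), "unos_region")
})

test_that("reclassification partitions and measures the low-risk groups", {
  co <- simulate_cohort(sim_config(n = 8000, seed = 49))
  co <- add_synthetic_kdpi(co, seed = 2)
  sc <- suppressWarnings(edam_score(co))
  rep_ <- reclassification(sc$score, co$kdpi, co$time, co$event)
  expect_equal(sum(rep_$crosstab), 8000)
  expect_equal(rep_$n_standard, sum(co$kdpi < 0.20))
  expect_equal(rep_$n_extended, sum(sc$score < 0.80 & co$kdpi >= 0.20))
  expect_gt(rep_$n_extended, 0)
  # group CIFs agree with a direct Aalen-Johansen computation
  std <- co$kdpi < 0.20
  direct <- aalen_johansen(pmin(co$time[std], 10),
                           ifelse(co$time[std] > 10, 0L, co$event[std]),
                           cause = 1, t = 10)
  expect_equal(rep_$cif10_standard, direct, tolerance = 1e-12)
  expect_true(rep_$logrank$p.value >= 0 && rep_$logrank$p.value <= 1)
  # missing KDPI rows are excluded and counted
  kdpi2 <- co$kdpi; kdpi2[1:25] <- NA
  expect_message(r2 <- reclassification(sc$score, kdpi2, co$time,
                                        co$event), "25")
  expect_equal(r2$n_missing_kdpi, 25L)
  expect_equal(sum(r2$crosstab), 7975)
})

test_that("reclassification handles an empty extended group", {
  set.seed(50)
  n <- 300
  scores <- runif(n, 0.85, 0.99)   # nobody is EDAM low-risk
  kdpi <- runif(n)
  time <- rexp(n, 0.2) + 1e-3
  event <- sample(0:2, n, replace = TRUE)
  rep_ <- reclassification(scores, kdpi, time, event)
  expect_equal(rep_$n_extended, 0L)
  expect_null(rep_$logrank)
  expect_true(is.na(rep_$cif10_extended))
})
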