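test_that("noise-free pseudo-values are recovered to machine precision", {
  set.seed(1)
  n <- 500
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  beta <- c(`(Intercept)` = -0.8, x1 = 0.5, x2 = -0.3)
  eta <- beta[1] + drop(X %*% beta[-1])
  theta <- 1 - exp(-exp(eta))
  fit <- fit_pseudo_glm(X, theta)
  expect_lt(max(abs(fit$coefficients - beta)), 1e-8)
  expect_true(fit$diagnostics$converged)
  expect_lt(fit$diagnostics$rss, 1e-12)
  expect_equal(exp(fit$coefficients), fit$shr)
})

test_that("two-point design matches the closed-form cloglog solution", {
  # one binary covariate, noise-free group means: eta solves the link
  theta <- c(rep(0.2, 50), rep(0.6, 50))
  X <- cbind(g = c(rep(0, 50), rep(1, 50)))
  fit <- fit_pseudo_glm(X, theta)
  cl <- function(p) log(-log(1 - p))
  expect_equal(unname(fit$coefficients["(Intercept)"]), cl(0.2),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["g"]), cl(0.6) - cl(0.2),
               tolerance = 1e-8)
})

test_that("estimates and HC0 errors match glm + sandwich", {
  set.seed(2)
  n <- 800
  X <- cbind(x1 = rnorm(n), x2 = runif(n))
  eta <- -1 + 0.6 * X[, 1] - 0.4 * X[, 2]
  theta <- 1 - exp(-exp(eta)) + rnorm(n, 0, 0.15)
  fit <- fit_pseudo_glm(X, theta)
  g <- suppressWarnings(stats::glm(
    theta ~ X, family = stats::quasi(link = "cloglog",
                                     variance = "constant"),
    start = c(-1, 0.6, -0.4)))
  expect_equal(unname(fit$coefficients), unname(coef(g)),
               tolerance = 1e-6)
  V <- sandwich::vcovHC(g, type = "HC0")
  expect_equal(unname(fit$se), unname(sqrt(diag(V))), tolerance = 1e-5)
})

test_that("rank-deficient designs fail loudly, naming the column", {
  X <- cbind(a = rnorm(30), b = 0)
  expect_error(fit_pseudo_glm(X, runif(30, 0.1, 0.4)), "b")
})

test_that("predict is consistent with the stored fit", {
  set.seed(3)
  X <- cbind(x = rnorm(100))
  theta <- runif(100, 0.1, 0.5)
  fit <- fit_pseudo_glm(X, theta)
  expect_equal(predict(fit, X, type = "link"), fit$eta)
  expect_equal(predict(fit, X, type = "response"), fit$fitted)
})

test_that("univariable screening holds its level and finds real signal", {
  # level: one pure-noise covariate, alpha = 0.05
  set.seed(4)
  hits <- 0L
  nsim <- 400L
  for (s in seq_len(nsim)) {
    n <- 150
    co <- data.frame(x = rnorm(n))
    design <- structure(list(X = cbind(x = co$x),
                             groups = c(x = "x"), ref = list(),
                             terms = "x"), class = "design_matrix")
    theta <- runif(n, 0.1, 0.4)
    hits <- hits + length(univariable_screen(design, theta))
  }
  expect_gt(hits / nsim, 0.02)
  expect_lt(hits / nsim, 0.08)
  # power: strong signal retained, and factor blocks screen as one group
  set.seed(5)
  n <- 2000
  x <- rnorm(n)
  theta <- 1 - exp(-exp(-1 + 0.8 * x)) + rnorm(n, 0, 0.1)
  design <- structure(list(X = cbind(x = x, junk = rnorm(n)),
                           groups = c(x = "x", junk = "junk"),
                           ref = list(), terms = c("x", "junk")),
                      class = "design_matrix")
  kept <- univariable_screen(design, theta)
  expect_true("x" %in% kept)
  pv <- attr(kept, "p.values")
  expect_lt(pv["x"], 1e-10)
})

test_that("group soft-threshold solves the orthonormal one-group problem", {
  set.seed(6)
  n <- 60
  D <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  colnames(D) <- paste0("g", 1:3)
  y <- rnorm(n)
  z <- unname(drop(crossprod(D, y)))
  for (lam in c(0.05, 0.3, 2)) {
    sol <- edam:::gaussian_group_lasso(
      D, y, blocks = list(g = colnames(D)), lambda = lam)
    expected <- z * max(0, 1 - lam * sqrt(3) / sqrt(sum(z^2)))
    expect_equal(unname(sol$coefficients[, 1]), expected,
                 tolerance = 1e-8)
  }
  # at/above lambda_max the group is zeroed out
  lam_max <- sqrt(sum(z^2)) / sqrt(3)
  sol0 <- edam:::gaussian_group_lasso(D, y, blocks = list(g = colnames(D)),
                                      lambda = lam_max * 1.0001)
  expect_identical(sol0$selected[[1]], character(0))
  expect_equal(unname(sol0$coefficients[, 1]), rep(0, 3))
})

test_that("vanishing penalty reproduces the unpenalized refit", {
  co <- simulate_cohort(sim_config(n = 2000, seed = 17))
  theta <- pseudo_values(co$time, co$event, tau = 5)
  dm <- encode_design(co, c("donor_age", "donor_sex", "cause_of_death",
                            "donor_bmi"), drop_empty = TRUE)
  path <- group_lasso_bic(dm, theta, lambda = 1e-12)
  expect_setequal(path$selected, unique(dm$groups))
  full <- fit_pseudo_glm(dm, theta)
  expect_equal(path$coefficients,
               full$coefficients[names(path$coefficients)],
               tolerance = 1e-6)
})

test_that("huge penalty selects nothing and BIC picks signal over noise", {
  co <- simulate_cohort(sim_config(n = 4000, seed = 18,
                                   beta_true = c(donor_age = 0.03)))
  theta <- pseudo_values(co$time, co$event, tau = 5)
  dm <- encode_design(co, c("donor_age", "donor_cmv", "proteinuria"),
                      drop_empty = TRUE)
  expect_identical(group_lasso_bic(dm, theta, lambda = 1e6)$selected,
                   character(0))
  sel <- group_lasso_bic(dm, theta)
  expect_true("donor_age" %in% sel$selected)
  # the path is monotone in the number of active groups overall
  expect_equal(sel$n_groups_path[1], 0)
  expect_gte(utils::tail(sel$n_groups_path, 1), length(sel$selected))
})

test_that("post-selection refit restricts to selected groups", {
  co <- simulate_cohort(sim_config(n = 800, seed = 19))
  theta <- pseudo_values(co$time, co$event, tau = 5)
  dm <- encode_design(co, c("donor_age", "donor_sex"), drop_empty = TRUE)
  fit <- postselection_refit(dm, theta, "donor_age")
  expect_setequal(names(fit$coefficients), c("(Intercept)", "donor_age"))
  expect_error(postselection_refit(dm, theta, "bogus"), "not in design")
  expect_warning(f0 <- postselection_refit(dm, theta, character(0)),
                 "intercept-only")
  # intercept-only fit matches the cloglog transform of the mean
  expect_equal(unname(f0$fitted[1]), mean(theta), tolerance = 1e-8)
})

test_that("derive_model runs the full pipeline and exports donor terms", {
  # the default effect sizes are modest, so the BIC needs a cohort of this
  # size before the penalty log(n)*df is overcome by the fit improvement;
  # at a few thousand rows the null model can legitimately win
  co <- simulate_cohort(sim_config(n = 12000, seed = 20))
  model <- suppressWarnings(derive_model(co))
  expect_s3_class(model$fit, "pseudo_glm")
  expect_true(all(c("donor_age", "htn_duration") %in% model$screened))
  expect_true(length(model$selection$selected) >= 1)
  expect_true(all(names(model$donor_coefficients) %in%
                    names(model$fit$coefficients)))
  expect_false("(Intercept)" %in% names(model$donor_coefficients))
})

test_that("coefficient tables round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  write_coefficients(edam_coefficients(), f)
  back <- read_coefficients(f)
  expect_equal(back, unclass(edam_coefficients()),
               ignore_attr = TRUE)
  expect_identical(names(back), names(edam_coefficients()))
})
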