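#' IPCW Harrell's C-index for cause-1 events
#'
#' Inverse-probability-of-censoring-weighted concordance (Uno style) over
#' pairs whose index subject has a graft-failure event before `tau_max`.
#' A pair (i, j) is comparable when `event[i] == 1`, `time[i] < tau_max`
#' and `time[j] > time[i]` (or `time[j] == time[i]` with j free of the
#' cause-1 event); the pair weight is \eqn{1/\hat G(T_i^-)^2} with
#' \eqn{\hat G} the Kaplan-Meier estimate of the censoring distribution.
#' Concordance means the higher-score subject fails first; score ties
#' count one half. Without censoring this reduces exactly to classical
#' Harrell's C over the same pairs.
#'
#' @param scores Risk scores (higher = riskier), row-aligned with outcomes.
#' @param time,event Outcome vectors.
#' @param tau_max Upper time limit for index events; defaults to just
#'   beyond the largest observed time (all events comparable).
#' @return The concordance estimate in \[0, 1\].
#' @export
ipcw_cindex <- function(scores, time, event, tau_max = NULL) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n, n >= 2L)
  if (is.null(tau_max)) tau_max <- max(time) * (1 + 1e-12)
  G <- censoring_km(time, event)
  gi <- censoring_km_at(G, time)
  need <- event == 1 & time < tau_max
  if (any(need & gi <= 0))
    stop("censoring survival is zero at an event time; ",
         "use a smaller tau_max")
  w <- ifelse(need, 1 / gi^2, 0)
  res <- ipcw_cindex_cpp(as.numeric(scores), as.numeric(time),
                         as.integer(event), as.numeric(w),
                         as.numeric(tau_max))
  if (res$den <= 0) stop("no comparable pairs")
  res$num / res$den
}

#' Bootstrap uncertainty for the IPCW C-index
#'
#' Resamples rows with replacement, recomputes the IPCW C-index per
#' replicate, and reports the replicate standard error, the bootstrap bias
#' (replicate mean minus apparent estimate), and a bias-corrected 95%
#' percentile interval: with \eqn{z_0 = \Phi^{-1}} of the fraction of
#' replicates below the apparent value, the interval endpoints are the
#' replicate quantiles at \eqn{\Phi(2 z_0 \pm 1.96)}.
#'
#' @param scores,time,event Row-aligned inputs.
#' @param B Number of replicates (the published analysis used 50).
#' @param seed Integer seed; the result is reproducible given (seed, B).
#' @param tau_max Passed to [ipcw_cindex()].
#' @return A `cindex_result`: `estimate`, `se`, `bias`, `ci` (length 2),
#'   `B`, `dropped` (degenerate replicates), `replicates`.
#' @export
bootstrap_cindex <- function(scores, time, event, B = 50L, seed = 1L,
                             tau_max = NULL) {
  stopifnot(B >= 2L)
  apparent <- ipcw_cindex(scores, time, event, tau_max)
  n <- length(scores)
  set.seed(seed)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b] <- tryCatch(ipcw_cindex(scores[idx], time[idx], event[idx],
                                    tau_max),
                        error = function(e) NA_real_)
  }
  dropped <- sum(is.na(reps))
  if (dropped)
    warning(dropped, " degenerate replicate(s) dropped")
  reps_ok <- reps[!is.na(reps)]
  se <- stats::sd(reps_ok)
  bias <- mean(reps_ok) - apparent
  frac <- mean(reps_ok < apparent)
  z0 <- stats::qnorm(min(max(frac, 1 / (2 * length(reps_ok))),
                         1 - 1 / (2 * length(reps_ok))))
  probs <- stats::pnorm(2 * z0 + c(-1.96, 1.96))
  ci <- unname(stats::quantile(reps_ok, probs, type = 6))
  structure(list(estimate = apparent, se = se, bias = bias, ci = ci,
                 B = B, dropped = dropped, replicates = reps),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat("IPCW C-index:", format(x$estimate, digits = 3),
      sprintf("(bootstrap SE %.3f, bias %+.3f, BC 95%% CI %.3f-%.3f, B = %d)\n",
              x$se, x$bias, x$ci[1], x$ci[2], x$B))
  invisible(x)
}

#' Decile calibration of predicted risks against pseudo-values
#'
#' Groups subjects into 10 equally sized categories of predicted risk
#' (rank order, ties broken by row order), compares the mean predicted
#' risk with the mean observed pseudo-value per group, and summarizes with
#' an unweighted OLS line of observed on predicted across the 10 points:
#' ideal intercept 0 ("miscalibration-in-the-large") and slope 1.
#'
#' @param predicted Predicted risks in (0, 1).
#' @param theta Pseudo-value vector at the evaluation horizon.
#' @param groups Number of groups (default 10); lowered with a warning
#'   when fewer distinct predictions exist.
#' @return A `calibration_result`: `table` (per-group `n`, `predicted`,
#'   `observed`), `intercept`, `slope`.
#' @export
decile_calibration <- function(predicted, theta, groups = 10L) {
  n <- length(predicted)
  stopifnot(length(theta) == n, all(predicted > 0 & predicted < 1))
  nd <- length(unique(predicted))
  if (nd < groups) {
    warning("only ", nd, " distinct predictions; using coarser grouping")
    groups <- max(2L, nd)
  }
  ord <- order(predicted)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * groups / n)
  tab <- data.frame(
    group = seq_len(groups),
    n = as.integer(tabulate(grp, groups)),
    predicted = vapply(seq_len(groups),
                       function(g) mean(predicted[grp == g]), numeric(1)),
    observed = vapply(seq_len(groups),
                      function(g) mean(theta[grp == g]), numeric(1)))
  fit <- stats::lm(observed ~ predicted, data = tab)
  structure(list(table = tab,
                 intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2])),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Decile calibration: slope %.4f, intercept %+.4f over %d groups\n",
              x$slope, x$intercept, nrow(x$table)))
  invisible(x)
}

#' Calibration slope and intercept on the linear-predictor scale
#'
#' Regresses observed pseudo-values on a model's linear predictor with the
#' cloglog pseudo-value GLM (the IECV metric): the linear predictor's
#' coefficient is the calibration slope (ideal 1) and the model intercept
#' the calibration intercept (ideal 0). Exactly equivariant: scaling the
#' linear predictor by c scales the fitted slope by 1/c.
#'
#' @param lp Linear predictor on the held-out data.
#' @param theta Pseudo-values on the held-out data.
#' @return List with `intercept`, `slope`, `slope_se`, `intercept_se`,
#'   `fit`.
#' @export
calibration_slope <- function(lp, theta) {
  X <- matrix(lp, ncol = 1, dimnames = list(NULL, "lp"))
  f <- fit_pseudo_glm(X, theta, intercept = TRUE)
  list(intercept = unname(f$coefficients["(Intercept)"]),
       slope = unname(f$coefficients["lp"]),
       slope_se = unname(f$se["lp"]),
       intercept_se = unname(f$se["(Intercept)"]),
       fit = f)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Pools per-fold estimates with the DL moment estimator of the
#' between-fold variance (computed by `metafor::rma(method = "DL")`).
#'
#' @param estimates Numeric vector of fold estimates.
#' @param ses Their standard errors.
#' @return List with `pooled`, `se`, `ci` (95%), `tau2`, `q`.
#' @export
pool_random_effects <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses), length(estimates) >= 2L,
            all(ses > 0))
  fit <- metafor::rma(yi = estimates, sei = ses, method = "DL")
  list(pooled = as.numeric(fit$beta), se = fit$se,
       ci = c(fit$ci.lb, fit$ci.ub), tau2 = fit$tau2, q = fit$QE)
}

#' Internal-external cross-validation over super-region folds
#'
#' Leave-one-region-out transportability assessment: for each fold, the
#' model terms are refit on the other folds with the pseudo-value GLM
#' (dummy columns with fewer than 5 occupied training rows are dropped
#' from that fold's model), the held-out linear predictor is computed, held-out pseudo-values are
#' formed from the held-out outcomes, and the calibration slope and
#' intercept are estimated by [calibration_slope()]. Fold slopes (and
#' intercepts) are pooled by DerSimonian-Laird random-effects
#' meta-analysis.
#'
#' @param cohort A `cohort_table` with outcomes set.
#' @param terms Model terms (design columns) used for the fold fits.
#' @param fold Integer fold labels; by default derived from
#'   `cohort$unos_region` via [super_region_fold()].
#' @param horizon Pseudo-value horizon in years.
#' @param min_fold_n Minimum held-out fold size (default 50).
#' @return An `iecv_result`: `folds` (per-fold data.frame with `fold`,
#'   `n`, `intercept`, `slope`, `slope_se`), `pooled_slope`,
#'   `pooled_intercept` (each a [pool_random_effects()] result), `skipped`.
#' @export
iecv <- function(cohort, terms = .edam_terms, fold = NULL, horizon = 5,
                 min_fold_n = 50L) {
  if (is.null(fold)) {
    if (!"unos_region" %in% names(cohort) || anyNA(cohort$unos_region))
      stop("no fold labels and no usable unos_region column")
    fold <- super_region_fold(cohort$unos_region)
  }
  stopifnot(length(fold) == nrow(cohort))
  ids <- sort(unique(fold))
  if (length(ids) < 2L) stop("need at least 2 folds")
  if (any(table(fold) < min_fold_n))
    stop("every fold needs at least ", min_fold_n, " subjects")
  design <- encode_design(cohort, terms, drop_empty = TRUE)
  rows <- list(); skipped <- integer()
  for (f in ids) {
    test <- fold == f
    res <- tryCatch({
      # dummy columns need enough support in the training folds to be
      # estimable; ultra-rare levels are dropped from the fold model
      cols <- colSums(design$X[!test, , drop = FALSE] != 0) >= 5L
      train_fit <- fit_pseudo_glm(design$X[!test, cols, drop = FALSE],
        pseudo_values(cohort$time[!test], cohort$event[!test],
                      cause = 1, tau = horizon))
      lp <- predict(train_fit, design$X[test, cols, drop = FALSE],
                    type = "link")
      th <- pseudo_values(cohort$time[test], cohort$event[test],
                          cause = 1, tau = horizon)
      cal <- calibration_slope(lp, th)
      data.frame(fold = f, n = sum(test), intercept = cal$intercept,
                 slope = cal$slope, slope_se = cal$slope_se,
                 intercept_se = cal$intercept_se)
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- c(skipped, f) else rows[[length(rows) + 1]] <- res
  }
  if (length(skipped))
    warning("fold(s) skipped (non-convergence): ",
            paste(skipped, collapse = ", "))
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 pooled_slope = pool_random_effects(folds$slope,
                                                    folds$slope_se),
                 pooled_intercept = pool_random_effects(folds$intercept,
                                                        folds$intercept_se),
                 skipped = skipped, horizon = horizon),
            class = "iecv_result")
}

#' @export
print.iecv_result <- function(x, ...) {
  cat("Internal-external cross-validation over", nrow(x$folds),
      "fold(s) at", x$horizon, "years\n")
  print(within(x$folds, {slope <- signif(slope, 4)
                         intercept <- signif(intercept, 4)
                         slope_se <- signif(slope_se, 3)
                         intercept_se <- signif(intercept_se, 3)}),
        row.names = FALSE)
  ps <- x$pooled_slope; pi_ <- x$pooled_intercept
  cat(sprintf("  pooled slope %.3f (95%% CI %.3f-%.3f, tau2 %.4g)\n",
              ps$pooled, ps$ci[1], ps$ci[2], ps$tau2))
  cat(sprintf("  pooled intercept %+.4f (95%% CI %+.4f-%+.4f)\n",
              pi_$pooled, pi_$ci[1], pi_$ci[2]))
  invisible(x)
}

#' KDPI versus EDAM reclassification report
#'
#' Cross-tabulates KDPI bands (<= 0.20, 0.21-0.85, > 0.85) against
#' cohort-empirical EDAM score quintiles, forms the two mutually exclusive
#' low-risk groups — standard (KDPI < 0.20) and extended (EDAM < 0.80 and
#' KDPI >= 0.20) — and compares their 10-year death-censored graft-failure
#' experience with the Aalen-Johansen estimate and the log-rank test.
#'
#' @param scores EDAM scores.
#' @param kdpi KDPI percentiles in \[0, 1\]; rows with missing KDPI are
#'   excluded and counted.
#' @param time,event Outcome vectors.
#' @param horizon Comparison horizon in years (default 10).
#' @return A `reclassification_report`: `crosstab` (3 x 5 counts),
#'   `n_standard`, `n_extended`, `cif_standard`, `cif_extended` (each a
#'   `cif_estimate`), `cif10_standard`, `cif10_extended`, `logrank`,
#'   `n_missing_kdpi`, `quintile_breaks`.
#' @export
reclassification <- function(scores, kdpi, time, event, horizon = 10) {
  n0 <- length(scores)
  stopifnot(length(kdpi) == n0, length(time) == n0, length(event) == n0)
  keep <- !is.na(kdpi)
  n_missing <- sum(!keep)
  if (n_missing) message(n_missing, " row(s) without KDPI excluded")
  scores <- scores[keep]; kdpi <- kdpi[keep]
  time <- time[keep]; event <- event[keep]
  if (any(kdpi < 0 | kdpi > 1)) stop("kdpi must lie in [0, 1]")
  band <- cut(kdpi, c(-Inf, 0.20, 0.85, Inf),
              labels = c("<=0.20", "0.21-0.85", ">0.85"))
  qb <- stats::quantile(scores, probs = seq(0, 1, 0.2), names = FALSE)
  quint <- cut(scores, breaks = unique(qb), include.lowest = TRUE,
               labels = FALSE)
  crosstab <- table(kdpi_band = band, edam_quintile = quint)
  standard <- kdpi < 0.20
  extended <- scores < 0.80 & kdpi >= 0.20
  tcap <- pmin(time, horizon)
  ecap <- ifelse(time > horizon, 0L, event)
  grp <- ifelse(standard, "standard", ifelse(extended, "extended", NA))
  lr <- if (sum(standard) && sum(extended))
    logrank_test(tcap[!is.na(grp)], ecap[!is.na(grp)], grp[!is.na(grp)])
  else NULL
  cif_s <- if (sum(standard)) cif_estimate(tcap[standard], ecap[standard])
           else NULL
  cif_e <- if (sum(extended)) cif_estimate(tcap[extended], ecap[extended])
           else NULL
  at10 <- function(ci) if (is.null(ci)) NA_real_ else
    suppressWarnings(aalen_johansen(ci, cause = 1, t = horizon))
  structure(list(crosstab = crosstab, n_standard = sum(standard),
                 n_extended = sum(extended),
                 cif_standard = cif_s, cif_extended = cif_e,
                 cif10_standard = at10(cif_s), cif10_extended = at10(cif_e),
                 logrank = lr, n_missing_kdpi = n_missing,
                 quintile_breaks = qb, horizon = horizon),
            class = "reclassification_report")
}

#' @export
print.reclassification_report <- function(x, ...) {
  cat("KDPI x EDAM reclassification (", sum(x$crosstab), " kidneys )\n",
      sep = "")
  print(x$crosstab)
  cat(sprintf("  standard low-risk (KDPI < 0.20): n = %d, %g-y CIF %.4f\n",
              x$n_standard, x$horizon, x$cif10_standard))
  cat(sprintf("  extended low-risk (EDAM < 0.80, KDPI >= 0.20): n = %d, %g-y CIF %.4f\n",
              x$n_extended, x$horizon, x$cif10_extended))
  if (!is.null(x$logrank))
    cat("  log-rank p =", format.pval(x$logrank$p.value, digits = 4), "\n")
  invisible(x)
}
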