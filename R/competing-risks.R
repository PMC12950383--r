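#' Aalen-Johansen cumulative incidence estimate
#'
#' Nonparametric estimate of the cause-specific cumulative incidence
#' functions in the presence of competing risks, on the grid of distinct
#' observed times. The all-cause survival is the Kaplan-Meier estimate, and
#' at tied times events are handled before censorings (both contribute to
#' the risk set at that time). By construction
#' \eqn{\hat S(t) + \sum_k \hat F_k(t) = 1} on every grid point.
#'
#' @param time Positive follow-up times in years.
#' @param event Event codes: 0 censored, 1 graft failure, 2 death with a
#'   functioning graft (any nonnegative integer codes are accepted; 0 is
#'   censoring).
#' @return A `cif_estimate`: list with `time` (distinct observed times),
#'   `surv` (all-cause KM), `cif` (matrix, one column per cause),
#'   `n_risk`, `n_event` (matrix), `causes`.
#' @export
cif_estimate <- function(time, event) {
  n <- length(time)
  if (n < 1L) stop("empty input")
  stopifnot(length(event) == n, all(is.finite(time)), all(time > 0),
            all(event == round(event)), all(event >= 0))
  causes <- sort(unique(event[event > 0]))
  if (!length(causes)) causes <- 1L
  ut <- sort(unique(time))
  m <- length(ut)
  idx <- match(time, ut)
  d <- matrix(0, m, length(causes),
              dimnames = list(NULL, as.character(causes)))
  for (k in seq_along(causes))
    d[, k] <- tabulate(idx[event == causes[k]], m)
  d_all <- rowSums(d)
  n_at <- n - c(0, cumsum(tabulate(idx, m)))[seq_len(m)]
  surv <- cumprod(1 - d_all / n_at)
  surv_prev <- c(1, surv[-m])
  cif <- apply(d, 2, function(dk) cumsum(surv_prev * dk / n_at))
  cif <- matrix(cif, nrow = m, dimnames = list(NULL, as.character(causes)))
  structure(list(time = ut, surv = surv, cif = cif, n_risk = n_at,
                 n_event = d, causes = causes, n = n),
            class = "cif_estimate")
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat("Aalen-Johansen estimate: n =", x$n, ",", length(x$time),
      "distinct time(s), cause(s)", paste(x$causes, collapse = ", "), "\n")
  last <- length(x$time)
  cat("  at last time", format(x$time[last], digits = 4), ": S =",
      format(x$surv[last], digits = 4), ", F =",
      paste(format(x$cif[last, ], digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Cause-specific cumulative incidence at a time point
#'
#' \eqn{\hat F_k(t) = \sum_{t_j \le t} \hat S(t_j^-) d_k(t_j)/n(t_j)}.
#' A query beyond the last observed time returns the value at the last
#' time with a warning.
#'
#' @param time,event Outcome vectors, or a `cif_estimate` as first
#'   argument (then `event` is ignored).
#' @param cause Event code of interest (default 1).
#' @param t Time point (years, >= 0).
#' @return The estimated probability.
#' @export
aalen_johansen <- function(time, event = NULL, cause = 1, t) {
  est <- if (inherits(time, "cif_estimate")) time else cif_estimate(time, event)
  stopifnot(length(t) == 1L, is.finite(t), t >= 0)
  if (!as.character(cause) %in% colnames(est$cif))
    return(0)  # cause never observed
  if (t > max(est$time))
    warning("t beyond last observed time; returning the last value")
  j <- findInterval(t, est$time)
  if (j == 0L) 0 else unname(est$cif[j, as.character(cause)])
}

#' Jackknife pseudo-observations of the cumulative incidence
#'
#' Per-subject leave-one-out transform
#' \eqn{\theta_i(\tau) = n\hat F(\tau) - (n-1)\hat F^{(-i)}(\tau)} of the
#' Aalen-Johansen cause-specific cumulative incidence at horizon
#' \eqn{\tau}. Values may fall outside \[0, 1\]. The default path is an
#' exact O(m^2) scheme in compiled code that recomputes the leave-one-out
#' estimate once per distinct observed (time, event) pattern; it matches
#' the naive per-subject recomputation to numerical precision.
#'
#' @param time,event Outcome vectors (n >= 2).
#' @param cause Event code of interest.
#' @param tau Horizon in years (default 5).
#' @param method `"fast"` (compiled, exact) or `"naive"` (per-subject
#'   recomputation in R, used as its validation oracle).
#' @return A numeric vector of length n with attributes `tau` and `cause`.
#' @export
pseudo_values <- function(time, event, cause = 1, tau = 5,
                          method = c("fast", "naive")) {
  method <- match.arg(method)
  n <- length(time)
  if (n < 2L) stop("pseudo-values need at least 2 subjects")
  stopifnot(length(event) == n, all(is.finite(time)), all(time > 0),
            tau > 0)
  if (method == "naive") {
    full <- aalen_johansen(time, event, cause = cause, t = tau)
    loo <- vapply(seq_len(n), function(i)
      suppressWarnings(aalen_johansen(time[-i], event[-i],
                                      cause = cause, t = tau)),
      numeric(1))
    theta <- n * full - (n - 1) * loo
  } else {
    theta <- pseudo_cif_cpp(as.numeric(time), as.integer(event),
                            as.integer(cause), as.numeric(tau))
  }
  structure(theta, tau = tau, cause = cause)
}

#' Gray's K-sample test for equality of cumulative incidence functions
#'
#' Nonparametric comparison of the cause-specific cumulative incidence
#' across groups in the presence of competing risks, with weight
#' \eqn{\rho = 0} (the default of the reference `cmprsk::cuminc`
#' implementation, which performs the computation here).
#'
#' @param time,event Outcome vectors (0 = censored).
#' @param group Group labels (>= 2 nonempty groups).
#' @param cause Event code compared (default 1).
#' @return A `grays_test` list: `statistic` (chi-square), `df` (K - 1),
#'   `p.value`.
#' @export
grays_test <- function(time, event, group, cause = 1) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need at least 2 groups")
  if (any(table(group) == 0L)) stop("empty group")
  fit <- cmprsk::cuminc(ftime = time, fstatus = event, group = group,
                        cencode = 0)
  tests <- fit$Tests
  row <- match(as.character(cause), rownames(tests))
  if (is.na(row)) stop("cause ", cause, " not observed in any group")
  structure(list(statistic = unname(tests[row, "stat"]),
                 df = unname(tests[row, "df"]),
                 p.value = unname(tests[row, "pv"]),
                 cause = cause, k = nlevels(droplevels(group))),
            class = "grays_test")
}

#' @export
print.grays_test <- function(x, ...) {
  cat("Gray's test, cause", x$cause, ":", "chi-square =",
      format(x$statistic, digits = 5), "on", x$df, "df, p =",
      format.pval(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Log-rank test on death-censored graft failure
#'
#' Two-or-more-sample log-rank test treating graft failure (event code 1)
#' as the event and both administrative censoring (0) and death with a
#' functioning graft (2) as censoring, the framework used for the low-risk
#' group comparison. Computed by `survival::survdiff`.
#'
#' @param time,event Outcome vectors.
#' @param group Group labels.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  status <- as.integer(event == 1)
  sd <- survival::survdiff(survival::Surv(time, status) ~ group)
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Reverses the roles of events and censorings: censoring (code 0) is the
#' "event" and any failure or death is "censored". Used for inverse
#' probability of censoring weights.
#'
#' @param time,event Outcome vectors.
#' @return A `censoring_km`: list with `time`, `surv` and an evaluator
#'   usable through [censoring_km_at()].
#' @export
censoring_km <- function(time, event) {
  if (!length(time)) stop("empty input")
  fit <- survival::survfit(survival::Surv(time, event == 0) ~ 1)
  structure(list(time = fit$time, surv = fit$surv), class = "censoring_km")
}

#' Evaluate a censoring Kaplan-Meier curve
#'
#' @param G A `censoring_km`.
#' @param t Time(s) at which to evaluate.
#' @param left If `TRUE` (default) return the left limit
#'   \eqn{\hat G(t^-)}, the convention used by the IPCW weights.
#' @return Numeric vector of survival probabilities.
#' @export
censoring_km_at <- function(G, t, left = TRUE) {
  tt <- if (left) t - 1e-12 else t
  j <- findInterval(tt, G$time)
  ifelse(j == 0L, 1, c(1, G$surv)[j + 1L])
}
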