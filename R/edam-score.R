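#' The frozen published EDAM coefficients
#'
#' The 17 linear-predictor coefficients of the published donor-only score,
#' keyed by design-matrix column name. Exponentiated coefficients are the
#' subdistribution hazard ratios (SHRs) of the underlying competing-risks
#' model. The set is immutable; refit-derived alternatives can be supplied
#' wherever a coefficient vector is accepted.
#'
#' @return A named numeric vector of length 17 with attribute
#'   `version = "published-1.0"`.
#' @export
edam_coefficients <- function() {
  b <- c(
    donor_age             =  0.0126,
    cause_of_death_stroke =  0.118,
    cause_of_death_trauma = -0.031,
    cause_of_death_tumor  =  0.215,
    donor_bmi             = -0.0066,
    donor_cmv_positive    =  0.070,
    htn_duration_y0_5     =  0.164,
    htn_duration_y6_10    =  0.172,
    htn_duration_gt10     =  0.295,
    htn_duration_unknown  =  0.175,
    dm_duration_y0_5      =  0.221,
    dm_duration_y6_10     =  0.475,
    dm_duration_gt10      =  0.650,
    dm_duration_unknown   =  0.165,
    donor_creatinine      =  0.022,
    proteinuria_yes       =  0.044,
    donor_sex_male        = -0.069
  )
  attr(b, "version") <- "published-1.0"
  b
}

# donor fields feeding the score
.edam_terms <- c("donor_age", "donor_sex", "cause_of_death", "donor_bmi",
                 "donor_cmv", "htn_duration", "dm_duration",
                 "donor_creatinine", "proteinuria")

#' Compute the EDAM score for donors
#'
#' Evaluates the donor-only linear predictor \eqn{\eta = x'\beta} (no
#' intercept, exactly as published) and maps it through the inverse
#' complementary log-log link to the score
#' \eqn{s = 1 - \exp(-\exp(\eta)) \in (0,1)}, then assigns the 5-tier risk
#' category. The score is a monotone risk index, not a calibrated absolute
#' risk: without an intercept its absolute level is arbitrary.
#'
#' Donors with `donor_cmv = "unknown"` or `proteinuria = "unknown"` score
#' as the reference level (coefficient 0) with a warning: the published
#' equation carries no coefficient for those levels.
#'
#' @param donors A `cohort_table` or data.frame with the donor columns
#'   (`donor_age`, `donor_sex`, `cause_of_death`, `donor_bmi`,
#'   `donor_cmv`, `htn_duration`, `dm_duration`, `donor_creatinine`,
#'   `proteinuria`).
#' @param coefficients Named coefficient vector keyed by design column;
#'   defaults to the frozen published set.
#' @return An `edam_result` data.frame with columns `lp`, `score`,
#'   `category` (and `id` when present in `donors`).
#' @examples
#' d <- data.frame(donor_age = 40, donor_sex = "female",
#'                 cause_of_death = "anoxia", donor_bmi = 25,
#'                 donor_cmv = "negative", htn_duration = "none",
#'                 dm_duration = "none", donor_creatinine = 1,
#'                 proteinuria = "no")
#' edam_score(d)  # lp 0.361, score ~0.7618, category 1
#' @export
edam_score <- function(donors, coefficients = edam_coefficients()) {
  dm <- encode_design(donors, .edam_terms)
  if ("donor_cmv_unknown" %in% colnames(dm$X) &&
      any(dm$X[, "donor_cmv_unknown"] > 0) &&
      !"donor_cmv_unknown" %in% names(coefficients))
    warning("donor_cmv = 'unknown' scores as the reference level")
  if ("proteinuria_unknown" %in% colnames(dm$X) &&
      any(dm$X[, "proteinuria_unknown"] > 0) &&
      !"proteinuria_unknown" %in% names(coefficients))
    warning("proteinuria = 'unknown' scores as the reference level")
  absent <- setdiff(names(coefficients), colnames(dm$X))
  if (length(absent))
    stop("coefficient(s) with no matching design column: ",
         paste(absent, collapse = ", "))
  lp <- drop(dm$X[, names(coefficients), drop = FALSE] %*% coefficients)
  s <- 1 - exp(-exp(lp))
  out <- data.frame(lp = lp, score = s, category = edam_category(s))
  if ("id" %in% names(donors)) out <- cbind(id = donors$id, out)
  rownames(out) <- NULL
  class(out) <- c("edam_result", "data.frame")
  out
}

#' Five-tier EDAM risk category
#'
#' Half-open bins, boundary to the upper bin: scores below 0.80 are
#' category 1 (lower risk), then \[0.80, 0.85) is 2, \[0.85, 0.90) is 3,
#' \[0.90, 0.95) is 4, and 0.95 and above is 5.
#'
#' @param s Numeric vector of scores in (0, 1).
#' @return Integer vector of categories in 1..5.
#' @export
edam_category <- function(s) {
  if (any(!is.finite(s)) || any(s <= 0 | s > 1))
    stop("scores must lie in (0, 1)")
  findInterval(s, c(0, 0.80, 0.85, 0.90, 0.95))
}

#' Observed cumulative incidence by score interval
#'
#' Partitions the score range into fixed-width intervals and computes the
#' observed Aalen-Johansen graft-failure cumulative incidence at the given
#' horizon within each occupied interval. Empty intervals are absent from
#' the output.
#'
#' @param scores Numeric vector of scores in (0, 1\].
#' @param time,event Outcome vectors (years; 0 censored, 1 graft failure,
#'   2 death with function).
#' @param width Interval width, in (0, 0.5\].
#' @param horizon Horizon in years (default 10).
#' @param cause Event code whose incidence is profiled.
#' @return A data.frame with `bin_low`, `bin_high`, `n`, `cif`.
#' @export
centile_profile <- function(scores, time, event, width = 0.05,
                            horizon = 10, cause = 1) {
  stopifnot(width > 0, width <= 0.5, length(scores) == length(time),
            length(time) == length(event))
  breaks <- seq(0, 1 + width, by = width)
  bin <- findInterval(scores, breaks, rightmost.closed = FALSE)
  out <- lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(bin_low = breaks[b], bin_high = breaks[b + 1L],
               n = sum(idx),
               cif = aalen_johansen(time[idx], event[idx],
                                    cause = cause, t = horizon))
  })
  do.call(rbind, out)
}

#' Predicted cumulative incidence as a function of the score
#'
#' Fits a pseudo-value GLM (complementary log-log link) of the cause-1
#' cumulative incidence at the horizon on the score as sole covariate,
#' with intercept, then returns model-based incidence over a score grid.
#'
#' @param scores Numeric vector of scores.
#' @param time,event Outcome vectors.
#' @param horizon Horizon in years (5 or 10 in the published analyses; any
#'   positive value allowed).
#' @param grid Score grid over which to predict (default 0.5 to 1 in steps
#'   of 0.01).
#' @param cause Event code modelled.
#' @return A data.frame `score`, `cif`, with the fitted `pseudo_glm` as
#'   attribute `fit`.
#' @export
predicted_cif_curve <- function(scores, time, event, horizon = 5,
                                grid = seq(0.5, 1, by = 0.01), cause = 1) {
  stopifnot(all(grid > 0 & grid < 1 | grid == 1))
  theta <- pseudo_values(time, event, cause = cause, tau = horizon)
  X <- matrix(scores, ncol = 1, dimnames = list(NULL, "score"))
  fit <- fit_pseudo_glm(X, theta, intercept = TRUE)
  eta <- fit$coefficients["(Intercept)"] + fit$coefficients["score"] * grid
  structure(data.frame(score = grid, cif = 1 - exp(-exp(eta))), fit = fit)
}

#' Map UNOS regions (1-11) to the five geography-aligned super-regions
#'
#' Fold 1 pools the Northeast (regions 1, 9, 10), fold 2 the Upper
#' Midwest (2, 6), fold 3 the Midwest/Plains block (3), fold 4 the West
#' (4, 8), and fold 5 the South/Southeast (5, 7, 11).
#'
#' @param unos_region Integer vector with values in 1..11.
#' @return Integer fold identifiers in 1..5.
#' @export
super_region_fold <- function(unos_region) {
  if (any(is.na(unos_region)) ||
      any(unos_region != round(unos_region)) ||
      any(unos_region < 1 | unos_region > 11))
    stop("UNOS region must be an integer in 1..11")
  map <- c(1L, 2L, 3L, 4L, 5L, 2L, 5L, 4L, 1L, 1L, 5L)
  map[as.integer(unos_region)]
}

#' @export
print.edam_result <- function(x, ...) {
  cat("EDAM scores for", nrow(x), "donor(s)\n")
  cat("  score range:", format(min(x$score), digits = 4), "-",
      format(max(x$score), digits = 4), "\n")
  cat("  categories:", paste(sprintf("%d:%d", 1:5,
      tabulate(x$category, 5L)), collapse = " "), "\n")
  invisible(x)
}
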