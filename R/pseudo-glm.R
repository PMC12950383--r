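#' Pseudo-value GLM with complementary log-log link and sandwich errors
#'
#' Fits the estimating equation \eqn{\sum_i D_i' (\theta_i - \mu_i) = 0}
#' with mean \eqn{\mu_i = 1 - \exp(-\exp(\eta_i))},
#' \eqn{\eta_i = \beta_0 + x_i'\beta}, working variance 1 (quasi-Normal
#' working model — pseudo-values can lie outside \[0, 1\], so a binomial
#' variance would be ill-defined), and \eqn{D = \partial\mu/\partial\beta}.
#' This approximates Fine-Gray subdistribution-hazard regression of the
#' cause-specific cumulative incidence at the pseudo-value horizon;
#' exponentiated coefficients are subdistribution hazard ratios (SHRs).
#' Standard errors are HC0 sandwich:
#' \eqn{(D'D)^{-1} \left(\sum_i D_i' r_i^2 D_i\right) (D'D)^{-1}} with
#' residuals \eqn{r_i = \theta_i - \mu_i}.
#'
#' The solver is Gauss-Newton with step halving; with noise-free
#' \eqn{\theta = \mu(\eta)} it converges to the generating coefficients to
#' machine precision.
#'
#' @param X Numeric design matrix (no intercept column) or a
#'   `design_matrix` from [encode_design()].
#' @param theta Pseudo-value vector, row-aligned with `X`.
#' @param intercept Include an intercept during estimation (default TRUE).
#' @param max_iter,tol Solver controls: iteration cap and convergence
#'   tolerance on the maximum absolute gradient scaled by n.
#' @return A `pseudo_glm`: list with `coefficients`, `vcov` (sandwich),
#'   `se`, `conf.low`, `conf.high`, `p.value`, `shr`, `eta`, `fitted`,
#'   `diagnostics` (`converged`, `iterations`, `rss`, `bic`,
#'   `gradient_norm`), `summary` (coefficient table data.frame).
#' @export
fit_pseudo_glm <- function(X, theta, intercept = TRUE,
                           max_iter = 100L, tol = 1e-10) {
  if (inherits(X, "design_matrix")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(theta) == n, n >= 1L)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xt <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  p <- ncol(Xt)
  if (p == 0L) stop("empty design")
  qrx <- qr(Xt)
  if (qrx$rank < p) {
    dep <- colnames(Xt)[qrx$pivot[(qrx$rank + 1L):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  beta <- rep(0, p)
  obj <- function(b) {
    eta <- drop(Xt %*% b)
    mu <- 1 - exp(-exp(eta))
    sum((theta - mu)^2)
  }
  f_old <- obj(beta)
  iter <- 0L; converged <- FALSE; gnorm <- Inf
  repeat {
    iter <- iter + 1L
    eta <- drop(Xt %*% beta)
    w <- exp(eta - exp(eta))          # d mu / d eta
    mu <- 1 - exp(-exp(eta))
    r <- theta - mu
    D <- Xt * w
    g <- crossprod(D, r)
    gnorm <- max(abs(g)) / n
    if (gnorm < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    step <- tryCatch(solve(crossprod(D), g),
                     error = function(e) stop("singular working ",
                       "information at iteration ", iter))
    lam <- 1
    repeat {
      cand <- beta + lam * drop(step)
      f_new <- obj(cand)
      if (is.finite(f_new) && (f_new <= f_old || lam < 1e-8)) break
      lam <- lam / 2
    }
    beta <- cand; f_old <- f_new
  }
  if (!converged)
    stop("pseudo-value GLM did not converge after ", max_iter,
         " iterations (scaled gradient norm ", format(gnorm), ")")
  eta <- drop(Xt %*% beta)
  mu <- 1 - exp(-exp(eta))
  r <- theta - mu
  w <- exp(eta - exp(eta))
  D <- Xt * w
  bread <- solve(crossprod(D))
  meat <- crossprod(D * r)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(Xt), colnames(Xt))
  se <- sqrt(pmax(diag(V), 0))
  beta <- setNames(drop(beta), colnames(Xt))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  rss <- sum(r^2)
  tab <- data.frame(term = names(beta), estimate = beta, se = se,
                    conf.low = beta - 1.96 * se,
                    conf.high = beta + 1.96 * se,
                    p.value = pv, shr = exp(beta), row.names = NULL)
  structure(list(coefficients = beta, vcov = V, se = se,
                 conf.low = tab$conf.low, conf.high = tab$conf.high,
                 p.value = pv, shr = exp(beta),
                 eta = eta, fitted = mu, residuals = r,
                 intercept = intercept, n = n,
                 diagnostics = list(converged = converged,
                                    iterations = iter, rss = rss,
                                    bic = n * log(rss / n) + p * log(n),
                                    gradient_norm = gnorm),
                 summary = tab),
            class = "pseudo_glm")
}

#' @export
print.pseudo_glm <- function(x, ...) {
  cat("Pseudo-value cloglog GLM (robust HC0 errors), n =", x$n, "\n")
  tab <- x$summary
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pseudo_glm <- function(object, ...) object$coefficients

#' @export
vcov.pseudo_glm <- function(object, ...) object$vcov

#' Predict from a pseudo-value GLM
#'
#' @param object A `pseudo_glm`.
#' @param newdata Numeric matrix with the model's (non-intercept) columns.
#' @param type `"response"` (risk scale) or `"link"` (linear predictor).
#' @param ... Unused.
#' @export
predict.pseudo_glm <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  b <- object$coefficients
  if (object$intercept) {
    eta <- b[1L] + drop(newdata %*% b[-1L])
  } else eta <- drop(newdata %*% b)
  if (type == "link") eta else 1 - exp(-exp(eta))
}

#' LOESS diagnostic data for continuous predictors
#'
#' Working-residual diagnostic for linearity: for each requested column,
#' returns the partial residual \eqn{r_i/w_i + x_{ij}\beta_j} against the
#' predictor together with a `lowess` smooth. Visual only: no automatic
#' spline refit is performed.
#'
#' @param fit A `pseudo_glm`.
#' @param X The design matrix used for the fit.
#' @param columns Column names to profile (default: all).
#' @return Named list of lists `x`, `partial`, `smooth` (a list with `x`,
#'   `y`).
#' @export
fit_diagnostics_loess <- function(fit, X, columns = colnames(X)) {
  if (inherits(X, "design_matrix")) X <- X$X
  w <- exp(fit$eta - exp(fit$eta))
  out <- list()
  for (cn in columns) {
    b <- fit$coefficients[cn]
    part <- fit$residuals / pmax(w, 1e-12) + X[, cn] * b
    sm <- stats::lowess(X[, cn], part)
    out[[cn]] <- list(x = X[, cn], partial = part, smooth = sm)
  }
  out
}

#' Univariable screening of candidate terms
#'
#' Fits each term alone (multilevel factors as a block) with the
#' pseudo-value GLM and keeps terms whose group Wald test (sandwich
#' covariance) has p below `alpha`.
#'
#' @param design A `design_matrix` from [encode_design()].
#' @param theta Pseudo-value vector.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of retained group names; the per-group p-values
#'   are attached as attribute `p.values`.
#' @export
univariable_screen <- function(design, theta, alpha = 0.05) {
  stopifnot(inherits(design, "design_matrix"), alpha > 0, alpha < 1)
  grps <- unique(design$groups)
  if (!length(grps)) return(character())
  pv <- vapply(grps, function(g) {
    cols <- names(design$groups)[design$groups == g]
    f <- fit_pseudo_glm(design$X[, cols, drop = FALSE], theta)
    b <- f$coefficients[cols]
    V <- f$vcov[cols, cols, drop = FALSE]
    W <- drop(t(b) %*% solve(V, b))
    stats::pchisq(W, df = length(cols), lower.tail = FALSE)
  }, numeric(1))
  structure(grps[pv < alpha], p.values = pv)
}

#' Group LASSO path with BIC selection
#'
#' Selects predictor groups by solving the penalized working-Gaussian
#' problem obtained from a one-step linearization of the pseudo-value GLM
#' at its unpenalized solution:
#' \deqn{\tfrac12 \|y^* - D\beta\|^2 +
#'       \lambda \sum_g \sqrt{p_g} \|b_g\|_2,}
#' where \eqn{D} is the working design (derivative-weighted columns),
#' \eqn{y^*} the working response, and \eqn{b_g} the coefficients of group
#' \eqn{g} in within-group orthonormalized coordinates (the intercept is
#' unpenalized). The solution path is computed by block coordinate descent
#' with warm starts over a decreasing \eqn{\lambda} grid; the reported
#' selection minimizes \eqn{BIC(\lambda) = n\log(RSS/n) + df(\lambda)\log n}
#' with \eqn{df} the count of individual nonzero coefficients.
#'
#' Only the selected set matters downstream — the reported model is the
#' unpenalized post-selection refit, not the penalized coefficients.
#'
#' @param design A `design_matrix`.
#' @param theta Pseudo-value vector.
#' @param lambda Optional decreasing positive grid; by default 100
#'   log-spaced points from the data-derived \eqn{\lambda_{max}} (smallest
#'   value zeroing every group) down to \eqn{\lambda_{max} 10^{-4}}.
#' @param nlambda,lambda_min_ratio Grid controls when `lambda` is NULL.
#' @return A `group_lasso_path`: list with `selected` (group names at the
#'   BIC optimum), `coefficients` (the back-transformed penalized solution
#'   at the optimum, for inspection), `lambda_opt`, `lambda`, `bic`, `df`,
#'   `rss`, `n_groups_path`.
#' @export
group_lasso_bic <- function(design, theta, lambda = NULL, nlambda = 100L,
                            lambda_min_ratio = 1e-4) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X; n <- nrow(X)
  grps <- unique(design$groups)
  full <- fit_pseudo_glm(X, theta, intercept = TRUE)
  eta <- full$eta
  w <- exp(eta - exp(eta))
  D <- cbind(`(Intercept)` = 1, X) * w
  bfull <- full$coefficients
  ystar <- (theta - full$fitted) + drop(D %*% bfull)

  blocks <- c(list(`(Intercept)` = "(Intercept)"),
              lapply(setNames(grps, grps), function(g)
                names(design$groups)[design$groups == g]))
  path <- gaussian_group_lasso(D, ystar, blocks,
                               unpenalized = "(Intercept)",
                               lambda = lambda, nlambda = nlambda,
                               lambda_min_ratio = lambda_min_ratio)
  df <- 1 + vapply(path$selected, function(s)
    sum(vapply(s, function(g) length(blocks[[g]]), integer(1))), numeric(1))
  bic <- n * log(path$rss / n) + df * log(n)
  opt <- which.min(bic)
  structure(list(selected = path$selected[[opt]],
                 coefficients = path$coefficients[, opt],
                 lambda_opt = path$lambda[opt],
                 lambda = path$lambda, bic = bic, df = df, rss = path$rss,
                 n_groups_path = lengths(path$selected), groups = grps),
            class = "group_lasso_path")
}

# Gaussian group lasso on an explicit design:
#   min_beta 0.5 ||y - D beta||^2 + lambda * sum_g sqrt(p_g) ||b_g||_2
# where b_g are the within-group orthonormalized coordinates of beta_g
# and blocks named in `unpenalized` are left free. Solved by block
# coordinate descent with warm starts along a decreasing lambda grid;
# in orthonormal coordinates each block update is the closed-form group
# soft-threshold (1 - lambda*sqrt(p_g)/||z_g||)_+ z_g. Returns for each
# lambda the residual sum of squares, the nonzero penalized groups, and
# the coefficients back-transformed to the original columns of D.
gaussian_group_lasso <- function(D, y, blocks, unpenalized = character(),
                                 lambda = NULL, nlambda = 100L,
                                 lambda_min_ratio = 1e-4, tol = 1e-9) {
  Q <- R <- list()
  for (g in names(blocks)) {
    qrg <- qr(D[, blocks[[g]], drop = FALSE])
    if (qrg$rank < length(blocks[[g]]))
      stop("group '", g, "' is rank deficient in the working design")
    Q[[g]] <- qr.Q(qrg)
    R[[g]] <- qr.R(qrg)
  }
  pen <- setdiff(names(blocks), unpenalized)
  r0 <- y
  for (g in unpenalized)
    r0 <- r0 - Q[[g]] %*% crossprod(Q[[g]], r0)
  z0 <- vapply(pen, function(g)
    sqrt(sum(crossprod(Q[[g]], r0)^2)) / sqrt(ncol(Q[[g]])), numeric(1))
  if (is.null(lambda)) {
    lmax <- max(z0)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  if (!length(lambda)) stop("empty lambda grid")
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  lambda <- sort(lambda, decreasing = TRUE)

  b <- lapply(blocks, function(cols) rep(0, length(cols)))
  r <- y
  rss <- numeric(length(lambda))
  selected <- vector("list", length(lambda))
  coefs <- matrix(0, sum(lengths(blocks)), length(lambda),
                  dimnames = list(unlist(blocks, use.names = FALSE), NULL))
  for (li in seq_along(lambda)) {
    lam <- lambda[li]
    repeat {
      delta <- 0
      for (g in names(blocks)) {
        zg <- drop(crossprod(Q[[g]], r)) + b[[g]]
        if (g %in% unpenalized) bn <- zg
        else {
          nz <- sqrt(sum(zg^2))
          shr <- if (nz > 0) 1 - lam * sqrt(length(zg)) / nz else 0
          # clamp boundary floating noise (lambda exactly at the group's
          # activation point) to an exact zero
          bn <- if (shr > 1e-12) zg * shr else zg * 0
        }
        ch <- bn - b[[g]]
        if (any(ch != 0)) {
          r <- r - Q[[g]] %*% ch
          delta <- max(delta, max(abs(ch)))
          b[[g]] <- bn
        }
      }
      if (delta < tol) break
    }
    selected[[li]] <- pen[vapply(pen, function(g) any(b[[g]] != 0),
                                 logical(1))]
    rss[li] <- sum(r^2)
    coefs[, li] <- unlist(lapply(names(blocks), function(g)
      backsolve(R[[g]], b[[g]])), use.names = FALSE)
  }
  list(lambda = lambda, rss = rss, selected = selected,
       coefficients = coefs)
}

#' @export
print.group_lasso_path <- function(x, ...) {
  cat("Group-LASSO/BIC selection over", length(x$lambda), "lambda values\n")
  cat("  selected", length(x$selected), "of", length(x$groups),
      "group(s) at lambda =", format(x$lambda_opt, digits = 4), ":\n  ",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Post-selection refit
#'
#' Unpenalized pseudo-value GLM restricted to the columns of the selected
#' groups; this refit — not the penalized coefficients — is the reported
#' model. An empty selection yields an intercept-only fit with a warning.
#'
#' @param design A `design_matrix`.
#' @param theta Pseudo-value vector.
#' @param selected Character vector of selected group names.
#' @return A `pseudo_glm`.
#' @export
postselection_refit <- function(design, theta, selected) {
  stopifnot(inherits(design, "design_matrix"))
  extra <- setdiff(selected, design$groups)
  if (length(extra))
    stop("selected group(s) not in design: ", paste(extra, collapse = ", "))
  if (!length(selected)) {
    warning("empty selection; fitting intercept-only model")
    return(fit_pseudo_glm(matrix(numeric(0), nrow(design$X), 0), theta))
  }
  cols <- names(design$groups)[design$groups %in% selected]
  fit_pseudo_glm(design$X[, cols, drop = FALSE], theta)
}

#' Derive a donor risk model from a cohort
#'
#' The full derivation pipeline at a pseudo-value horizon: encode the
#' candidate terms, univariable screening at `alpha`, group-LASSO/BIC on
#' the survivors, and unpenalized post-selection refit. Donor and
#' adjustment (recipient/transplant) terms are both offered to selection;
#' the exported donor score keeps only donor-term coefficients and drops
#' the intercept, matching the published equation's form.
#'
#' @param cohort A `cohort_table` with outcomes set.
#' @param horizon Pseudo-value horizon in years (default 5).
#' @param donor_terms,adjust_terms Candidate donor and adjustment columns.
#' @param alpha Univariable screening level.
#' @return List with `fit` (post-selection `pseudo_glm`), `full_fit`
#'   (pre-LASSO model on screened terms), `screened`, `selection`
#'   (`group_lasso_path`), `donor_coefficients` (named vector for
#'   [edam_score()]), `horizon`.
#' @export
derive_model <- function(cohort, horizon = 5,
                         donor_terms = c(.edam_terms, "dcd", "en_bloc"),
                         adjust_terms = c("recip_age", "recip_sex",
                                          "ethnicity", "recip_diabetes",
                                          "dialysis_at_transplant",
                                          "recip_cmv", "waitlist_days",
                                          "hla_mismatch", "cpra",
                                          "cold_ischemia_hours"),
                         alpha = 0.05) {
  terms <- c(donor_terms, adjust_terms)
  # levels with almost no support cannot carry a stable coefficient;
  # require at least 5 occupied rows per dummy column
  design <- encode_design(cohort, terms, drop_empty = TRUE,
                          min_count = 5L)
  theta <- pseudo_values(cohort$time, cohort$event, cause = 1,
                         tau = horizon)
  screened <- univariable_screen(design, theta, alpha = alpha)
  if (!length(screened)) stop("no term survives univariable screening")
  d2 <- encode_design(cohort, screened, drop_empty = TRUE,
                      min_count = 5L)
  sel <- group_lasso_bic(d2, theta)
  fit <- postselection_refit(d2, theta, sel$selected)
  full_fit <- fit_pseudo_glm(d2, theta)
  donor_cols <- names(d2$groups)[d2$groups %in% intersect(sel$selected,
                                                          donor_terms)]
  donor_coefficients <- fit$coefficients[donor_cols]
  list(fit = fit, full_fit = full_fit, screened = screened,
       selection = sel, donor_coefficients = donor_coefficients,
       horizon = horizon)
}

#' Serialize a coefficient table to JSON
#'
#' @param fit A `pseudo_glm` (its summary table is written) or a named
#'   numeric vector of coefficients.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(fit, path) {
  obj <- if (inherits(fit, "pseudo_glm")) fit$summary
         else data.frame(term = names(fit), estimate = unname(fit),
                         shr = exp(unname(fit)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a coefficient table from JSON
#'
#' @param path JSON file written by [write_coefficients()].
#' @return Named numeric vector of coefficients.
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  setNames(as.numeric(obj$estimate), obj$term)
}
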