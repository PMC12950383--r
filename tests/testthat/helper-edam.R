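# Shared test oracles and factories. Oracles are deliberately naive,
# independent implementations of the package's efficient code paths.

# Brute-force Harrell's C over cause-1 index pairs (weights all 1; valid
# as an ipcw_cindex oracle only when no observation is censored).
brute_force_cindex <- function(scores, time, event, tau_max = Inf) {
  num <- den <- 0
  n <- length(scores)
  for (i in seq_len(n)) {
    if (event[i] != 1 || time[i] >= tau_max) next
    for (j in seq_len(n)) {
      if (j == i) next
      comparable <- time[j] > time[i] ||
        (time[j] == time[i] && event[j] != 1)
      if (!comparable) next
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# Textbook DerSimonian-Laird pooling from fixed-effect weights.
hand_dl_pool <- function(est, se) {
  w <- 1 / se^2
  ybar <- sum(w * est) / sum(w)
  q <- sum(w * (est - ybar)^2)
  k <- length(est)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * est) / sum(wr)
  list(pooled = pooled, se = sqrt(1 / sum(wr)), tau2 = tau2, q = q)
}

# A tiny valid cohort row, with every mandatory column set; fields can be
# overridden per test.
donor_row <- function(...) {
  base <- list(
    id = "d1", donor_age = 40, donor_sex = "female",
    cause_of_death = "anoxia", donor_bmi = 25, donor_cmv = "negative",
    htn_duration = "none", dm_duration = "none", donor_creatinine = 1,
    proteinuria = "no", dcd = FALSE, en_bloc = FALSE,
    recip_age = 50, recip_sex = "male", ethnicity = "white",
    recip_diabetes = FALSE, dialysis_at_transplant = TRUE,
    recip_cmv = "negative", prev_transplants = 0L, waitlist_days = 700,
    hla_mismatch = 4L, cpra = 0, cold_ischemia_hours = 16)
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

# One-covariate Fine-Gray mixture generator where the covariate IS the
# score: cloglog F1(t | s) = log(-log(1 - p(1 - e^-t))) + b0 + b1 s, so a
# pseudo-value GLM of the cumulative incidence on s is correctly
# specified with slope b1. Returns the cohort plus the analytic CIF.
sim_score_cohort <- function(n, b0 = -1, b1 = 2, p = 0.4,
                             censor_rate = 0.05, admin = 15, seed = 1) {
  set.seed(seed)
  s <- runif(n, 0.5, 0.95)
  gamma <- exp(b0 + b1 * s)
  f_inf <- 1 - (1 - p)^gamma
  is1 <- runif(n) < f_inf
  a <- 1 - runif(n) * f_inf
  t1 <- -log(1 - (1 - exp(log(a) / gamma)) / p)
  t2 <- rexp(n, rate = 0.03)
  latent <- ifelse(is1, t1, t2)
  cens <- rexp(n, rate = censor_rate)
  time <- pmax(pmin(latent, cens, admin), 1e-10)
  event <- integer(n)
  event[latent <= pmin(cens, admin) & is1] <- 1L
  event[latent <= pmin(cens, admin) & !is1] <- 2L
  list(score = s, time = time, event = event,
       cif = function(t, sc) 1 - (1 - p * (1 - exp(-t)))^exp(b0 + b1 * sc))
}
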