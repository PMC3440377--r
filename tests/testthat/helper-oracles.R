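# Independent oracles: deliberately naive loop/closed-form implementations
# used to cross-check the package's vectorized code paths.

# Brute-force Cox-model evaluation: explicit per-record, per-term loops
# over a declarative coefficient table (no shared code with the engine).
oracle_cox_risk <- function(model, profile_row) {
  B <- 0
  for (tm in model$terms) {
    active <- TRUE
    if (!is.na(tm$condition)) active <- isTRUE(profile_row[[tm$condition]])
    if (!active) next
    val <- 1
    for (f in tm$factors) {
      x <- profile_row[[f$field]]
      if (!is.na(f$cap)) x <- min(x, f$cap)
      if (f$transform == "log") x <- log(x)
      val <- val * x
    }
    B <- B + tm$beta * val
  }
  1 - model$baseline_survival ^ exp(B - model$mean_linear_predictor)
}

# Direct transcription of the stratified between-PSU variance for a total
# of weighted values; nested loops, no tapply.
oracle_total <- function(y, w, stratum, psu) {
  est <- sum(w * y)
  v <- 0
  for (h in unique(stratum)) {
    in_h <- stratum == h
    psus <- unique(psu[in_h])
    n_h <- length(psus)
    t_hj <- numeric(n_h)
    for (j in seq_along(psus)) {
      sel <- in_h & psu == psus[j]
      t_hj[j] <- sum(w[sel] * y[sel])
    }
    if (n_h > 1)
      v <- v + n_h / (n_h - 1) * sum((t_hj - mean(t_hj))^2)
  }
  list(estimate = est, se = sqrt(v))
}

# Brute-force domain ratio estimator with linearized scores.
oracle_proportion <- function(y, dom, w, stratum, psu) {
  wd <- sum(w[dom == 1])
  p <- sum(w[dom == 1] * y[dom == 1]) / wd
  z <- ifelse(dom == 1, w * (y - p) / wd, 0)
  v <- oracle_total(z, rep(1, length(z)), stratum, psu)
  list(estimate = p, se = v$se)
}

# Small random stratified designs for property tests.
random_design <- function(n_strata = sample(1:3, 1),
                          max_psu = 4, max_rec = 20) {
  rows <- list()
  for (h in seq_len(n_strata)) {
    n_psu <- sample(2:max_psu, 1)  # >= 2 avoids lonely PSUs
    for (j in seq_len(n_psu)) {
      n_rec <- sample(1:max_rec, 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = paste0("h", h), psu = paste0("h", h, "p", j),
        weight = stats::runif(n_rec, 0.5, 50),
        y = stats::rbinom(n_rec, 1, 0.4),
        dom = stats::rbinom(n_rec, 1, 0.7))
    }
  }
  dplyr::bind_rows(rows)
}

# Random physiologically plausible risk-factor profiles.
random_profiles <- function(n, sex = c("female", "male")) {
  sex <- match.arg(sex)
  tibble::tibble(
    sex = sex,
    age = stats::runif(n, if (sex == "female") 45 else 50, 79),
    total_cholesterol = stats::runif(n, 120, 320),
    hdl_cholesterol = stats::runif(n, 25, 100),
    systolic_bp = stats::runif(n, 90, 200),
    bp_medication = stats::runif(n) < 0.3,
    current_smoker = stats::runif(n) < 0.3,
    family_history = stats::runif(n) < 0.2,
    hscrp = exp(stats::rnorm(n, 0.7, 1)),
    diabetic = FALSE, hba1c = stats::runif(n, 4.5, 6.5))
}

# Assessed-cohort convenience for reclassification tests.
assessed_cohort <- function(n_women = 400, n_men = 350, seed = 99) {
  cohort <- simulate_cohort(cohort_config(n_women = n_women, n_men = n_men),
                            seed = seed)
  scr <- apply_inclusion(cohort$records)
  el <- scr[scr$included, ]
  el$diabetic <- FALSE
  assess_goals(add_risk_scores(el))
}
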