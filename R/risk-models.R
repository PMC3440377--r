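#' Declarative Cox-form ten-year risk models
#'
#' Both risk equations used here — the Framingham hard-CHD score and the
#' Reynolds Risk Score — share the Cox survival form
#' \deqn{risk = 1 - S_0^{\exp(B - M)}}
#' where \eqn{B} is a linear predictor over (possibly transformed)
#' covariates, \eqn{S_0} the ten-year baseline survival and \eqn{M} the
#' centering constant (the linear predictor at the development-cohort
#' means). A `cox_risk_model` stores the equation declaratively so
#' coefficient sets ship as data, not code.
#'
#' Each term is `beta * [condition] * prod(transform(min(x_f, cap_f)))`
#' over zero or more factors. Zero factors give an indicator main effect
#' (e.g. a smoking term); two factors give an interaction (the Framingham
#' equations interact log age with log total cholesterol and with
#' smoking, the latter with age capped). Caps apply on the raw covariate
#' scale before the transform.
#'
#' @param model_id Label for the model.
#' @param sex `"female"`, `"male"` or `"both"`; evaluation on profiles of
#'   another sex is an error.
#' @param baseline_survival \eqn{S_0 \in (0,1)}.
#' @param mean_linear_predictor Centering constant \eqn{M}.
#' @param terms List of terms; each a list with `label`, `beta`, optional
#'   `condition` (name of a logical column gating the term) and `factors`,
#'   a list of `list(field =, transform = "identity"|"log", cap = )`.
#' @return An object of class `cox_risk_model`.
#' @seealso [evaluate_cox_model()], [read_risk_models()]
#' @export
cox_risk_model <- function(model_id, sex, baseline_survival,
                           mean_linear_predictor, terms) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  sex <- match.arg(sex, c("female", "male", "both"))
  stopifnot(is.numeric(baseline_survival), length(baseline_survival) == 1L,
            baseline_survival > 0, baseline_survival < 1,
            is.numeric(mean_linear_predictor))
  terms <- lapply(terms, function(tm) {
    stopifnot(!is.null(tm$label), is.numeric(tm$beta))
    tm$condition <- tm$condition %||% NA_character_
    tm$factors <- lapply(tm$factors %||% list(), function(f) {
      stopifnot(!is.null(f$field))
      f$transform <- match.arg(f$transform %||% "identity",
                               c("identity", "log"))
      f$cap <- f$cap %||% NA_real_
      f
    })
    tm
  })
  structure(
    list(model_id = model_id, sex = sex,
         baseline_survival = baseline_survival,
         mean_linear_predictor = mean_linear_predictor, terms = terms),
    class = "cox_risk_model")
}

#' @export
print.cox_risk_model <- function(x, ...) {
  cat("<cox_risk_model> ", x$model_id, " (", x$sex, ")\n", sep = "")
  cat("  S0 =", x$baseline_survival, " M =", x$mean_linear_predictor, "\n")
  for (tm in x$terms) {
    fct <- vapply(tm$factors, function(f) {
      out <- if (f$transform == "log") paste0("ln(", f$field, ")") else f$field
      if (!is.na(f$cap)) out <- paste0(out, "[cap ", f$cap, "]")
      out
    }, character(1))
    cond <- if (!is.na(tm$condition)) paste0(" if ", tm$condition) else ""
    cat(sprintf("  %+.6f * %s%s\n", tm$beta,
                if (length(fct)) paste(fct, collapse = " * ") else "1", cond))
  }
  invisible(x)
}

# Active-term covariate checks shared by lp and risk evaluation.
term_values <- function(model, profiles) {
  n <- nrow(profiles)
  lp <- numeric(n)
  for (tm in model$terms) {
    if (!is.na(tm$condition)) {
      if (!tm$condition %in% names(profiles))
        stop("incomplete profile: missing covariate '", tm$condition, "'")
      active <- profiles[[tm$condition]]
      if (anyNA(active))
        stop("incomplete profile: missing covariate '", tm$condition, "'")
      active <- as.logical(active)
    } else {
      active <- rep(TRUE, n)
    }
    val <- rep(1, n)
    for (f in tm$factors) {
      if (!f$field %in% names(profiles))
        stop("incomplete profile: missing covariate '", f$field, "'")
      x <- as.numeric(profiles[[f$field]])
      if (anyNA(x[active]))
        stop("incomplete profile: missing covariate '", f$field, "'")
      if (!is.na(f$cap)) x <- pmin(x, f$cap)
      if (f$transform == "log") {
        if (any(x[active] <= 0))
          stop("domain error: non-positive '", f$field,
               "' under log transform")
        x <- log(x)
      }
      val <- val * x
    }
    lp <- lp + ifelse(active, tm$beta * val, 0)
  }
  lp
}

check_model_sex <- function(model, profiles) {
  if (model$sex != "both") {
    if (!"sex" %in% names(profiles))
      stop("incomplete profile: missing covariate 'sex'")
    if (any(profiles$sex != model$sex))
      stop("model '", model$model_id, "' is not applicable to sex '",
           paste(unique(profiles$sex[profiles$sex != model$sex]),
                 collapse = ","), "'")
  }
  invisible(TRUE)
}

#' Linear predictor of a Cox-form risk model
#'
#' The uncentered sum \eqn{B = \sum \beta \cdot t(x)} over active terms.
#'
#' @inheritParams evaluate_cox_model
#' @return Numeric vector, one value per profile row.
#' @export
cox_linear_predictor <- function(model, profiles) {
  stopifnot(inherits(model, "cox_risk_model"))
  profiles <- as_tibble(profiles)
  check_model_sex(model, profiles)
  term_values(model, profiles)
}

#' Evaluate a Cox-form risk model on risk-factor profiles
#'
#' Computes `1 - S0 ^ exp(B - M)` per profile row, clamped to `[0, 1]`.
#' Deterministic; inputs are never modified.
#'
#' @param model A [cox_risk_model()].
#' @param profiles Data frame of risk-factor profiles; must carry every
#'   covariate referenced by the model's active terms (`sex`, `age`,
#'   `total_cholesterol`, `hdl_cholesterol`, `systolic_bp`, flags ...).
#' @return Numeric vector of ten-year risk fractions in `[0, 1]`.
#' @export
#' @examples
#' m <- cox_risk_model("toy", "both", 0.95, 0,
#'   terms = list(list(label = "age", beta = 0.01,
#'                     factors = list(list(field = "age")))))
#' evaluate_cox_model(m, data.frame(age = c(50, 70)))
evaluate_cox_model <- function(model, profiles) {
  lp <- cox_linear_predictor(model, profiles)
  risk <- 1 - model$baseline_survival ^ exp(lp - model$mean_linear_predictor)
  pmin(pmax(risk, 0), 1)
}

model_from_spec <- function(spec) {
  cox_risk_model(spec$model_id, spec$sex, spec$baseline_survival,
                 spec$mean_linear_predictor, spec$terms)
}

#' Read and write risk-model coefficient files
#'
#' Coefficient sets live in JSON files, one block per model (term list,
#' baseline survival, centering constant), so transcriptions from the
#' source publications are versioned data. `write_risk_models()` writes
#' at full floating precision, so read -> write -> read round-trips to
#' identical models.
#'
#' @param path File path.
#' @return `read_risk_models()`: a named list of [cox_risk_model()]
#'   objects, keyed by `model_id`.
#' @export
read_risk_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(raw$models, model_from_spec)
  setNames(models, vapply(models, `[[`, character(1), "model_id"))
}

#' @rdname read_risk_models
#' @param models Named list of [cox_risk_model()] objects.
#' @export
write_risk_models <- function(models, path) {
  blocks <- lapply(unname(models), function(m) {
    list(model_id = m$model_id, sex = m$sex,
         baseline_survival = m$baseline_survival,
         mean_linear_predictor = m$mean_linear_predictor,
         terms = lapply(m$terms, function(tm) {
           out <- list(label = tm$label, beta = tm$beta)
           if (!is.na(tm$condition)) out$condition <- tm$condition
           out$factors <- lapply(tm$factors, function(f) {
             ff <- list(field = f$field, transform = f$transform)
             if (!is.na(f$cap)) ff$cap <- f$cap
             ff
           })
           out
         }))
  })
  jsonlite::write_json(list(models = blocks), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Built-in Framingham and Reynolds coefficient sets
#'
#' Loads the four shipped models: sex-specific Framingham hard-CHD
#' (`frs_hard_chd_women`, `frs_hard_chd_men`) and Reynolds Risk Score
#' (`rrs_women`, `rrs_men`), transcribed from the published equations.
#'
#' @return Named list of [cox_risk_model()] objects.
#' @export
default_risk_models <- function() {
  dir <- system.file("extdata", "coefficients", package = "cvreclass")
  c(read_risk_models(file.path(dir, "frs_hard_chd.json")),
    read_risk_models(file.path(dir, "rrs.json")))
}

dispatch_by_sex <- function(profiles, models, female_id, male_id) {
  profiles <- as_tibble(profiles)
  if (!"sex" %in% names(profiles) || anyNA(profiles$sex))
    stop("incomplete profile: missing covariate 'sex'")
  bad <- setdiff(unique(profiles$sex), c("female", "male"))
  if (length(bad)) stop("unknown sex value: ", paste(bad, collapse = ","))
  risk <- rep(NA_real_, nrow(profiles))
  for (s in c("female", "male")) {
    idx <- which(profiles$sex == s)
    if (!length(idx)) next
    id <- if (s == "female") female_id else male_id
    risk[idx] <- evaluate_cox_model(models[[id]], profiles[idx, , drop = FALSE])
  }
  risk
}

#' Ten-year Framingham hard-CHD risk
#'
#' Dispatches each profile to the sex-specific Framingham hard coronary
#' heart disease equation (myocardial infarction or coronary death).
#' Covariates: age, total and HDL cholesterol, systolic blood pressure,
#' antihypertensive treatment, current smoking. hs-CRP and family history
#' are not covariates and never affect the result.
#'
#' @param profiles Data frame with `sex`, `age`, `total_cholesterol`,
#'   `hdl_cholesterol`, `systolic_bp`, `bp_medication`, `current_smoker`.
#' @param models Coefficient set, by default [default_risk_models()].
#' @return Risk fractions in `[0, 1]`.
#' @export
#' @examples
#' \dontrun{
#' framingham_10yr_risk(data.frame(
#'   sex = "female", age = 64, total_cholesterol = 190,
#'   hdl_cholesterol = 46, systolic_bp = 130, bp_medication = FALSE,
#'   current_smoker = TRUE))
#' }
framingham_10yr_risk <- function(profiles, models = default_risk_models()) {
  dispatch_by_sex(profiles, models, "frs_hard_chd_women", "frs_hard_chd_men")
}

#' Ten-year Reynolds Risk Score
#'
#' Sex-dispatched Reynolds global cardiovascular risk (MI, stroke,
#' cardiovascular death, revascularization). Adds hs-CRP (log-transformed)
#' and parental family history to the classic covariates; women with
#' diabetes additionally contribute an HbA1c term. For non-diabetic
#' profiles the HbA1c term is exactly zero, and a missing `diabetic`
#' column is treated as non-diabetic (the analysis population excludes
#' diabetics upstream).
#'
#' @param profiles Data frame with the Framingham covariates plus `hscrp`
#'   (mg/L, strictly positive), `family_history`, and optionally
#'   `diabetic` + `hba1c`.
#' @inheritParams framingham_10yr_risk
#' @return Risk fractions in `[0, 1]`.
#' @export
reynolds_10yr_risk <- function(profiles, models = default_risk_models()) {
  profiles <- as_tibble(profiles)
  if (!"hscrp" %in% names(profiles))
    stop("incomplete profile: missing covariate 'hscrp'")
  if (!"diabetic" %in% names(profiles)) profiles$diabetic <- FALSE
  if (!"hba1c" %in% names(profiles)) profiles$hba1c <- 0
  # hba1c enters only where diabetic; a missing value there must error,
  # elsewhere it is inert
  profiles$hba1c <- ifelse(!profiles$diabetic & is.na(profiles$hba1c),
                           0, profiles$hba1c)
  dispatch_by_sex(profiles, models, "rrs_women", "rrs_men")
}

#' Score a cohort with both risk models
#'
#' Adds `frs_risk` and `rrs_risk` columns to a participant table. Records
#' are assumed pre-screened (non-diabetic, complete risk factors); see
#' [apply_inclusion()].
#'
#' @param data Participant tibble (one row per subject).
#' @param models Coefficient set, by default [default_risk_models()].
#' @return The input with `frs_risk` and `rrs_risk` appended.
#' @export
add_risk_scores <- function(data, models = default_risk_models()) {
  data <- as_tibble(data)
  data$frs_risk <- framingham_10yr_risk(data, models)
  data$rrs_risk <- reynolds_10yr_risk(data, models)
  data
}

#' The published worked-example profile
#'
#' A 64-year-old female current smoker with positive family history,
#' untreated systolic BP 130 mmHg, total cholesterol 190 mg/dL, HDL-C
#' 46 mg/dL, LDL-C 116 mg/dL (triglycerides 140 via Friedewald) and
#' hs-CRP 3 mg/L — the reference case whose scores are FRS 5.1% and
#' RRS 12.5%.
#'
#' @return One-row tibble.
#' @export
reference_profile <- function() {
  tibble(
    participant_id = "worked_example", sex = "female", age = 64,
    total_cholesterol = 190, hdl_cholesterol = 46, triglycerides = 140,
    fasting_hours = 10, systolic_bp = 130, bp_medication = FALSE,
    current_smoker = TRUE, family_history = TRUE, hscrp = 3,
    diabetic = FALSE, hba1c = NA_real_)
}

#' Validate a coefficient file against the worked example
#'
#' Guards coefficient transcriptions: evaluates the models on
#' [reference_profile()] and fails unless FRS rounds to 5.1% and RRS to
#' 12.5% at one decimal.
#'
#' @param models A named model list or a path/vector of paths to
#'   coefficient JSON files.
#' @return Invisibly, a tibble with the two checked scores.
#' @export
validate_coefficients <- function(models = default_risk_models()) {
  if (is.character(models))
    models <- do.call(c, lapply(models, read_risk_models))
  prof <- reference_profile()
  frs <- round(100 * framingham_10yr_risk(prof, models), 1)
  rrs <- round(100 * reynolds_10yr_risk(prof, models), 1)
  if (!isTRUE(frs == 5.1))
    stop("coefficient validation failed: worked-example FRS is ", frs,
         "%, expected 5.1%")
  if (!isTRUE(rrs == 12.5))
    stop("coefficient validation failed: worked-example RRS is ", rrs,
         "%, expected 12.5%")
  invisible(tibble(model = c("FRS", "RRS"), pct = c(frs, rrs)))
}
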