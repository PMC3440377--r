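#' Pipeline configuration
#'
#' Bundles the choices a full run needs: the input source (a participant
#' tibble, a [cohort_config()] to simulate from, or a path to a records
#' CSV), optional coefficient-file paths (defaults to the shipped
#' models), the LDL-C goal policy, the lonely-PSU strategy, an optional
#' output directory and the seed. Exactly one input source.
#'
#' `read_pipeline_config()` reads the same fields from a flat YAML file
#' (`input:` path, `coefficients:` list of paths, `goal_policy:`,
#' `lonely:`, `out_dir:`, `seed:`, optional `simulate:` block of
#' [cohort_config()] arguments).
#'
#' @param input Tibble of participant records, `cohort_config`, or path.
#' @param coefficients `NULL` for the shipped models, or character paths
#'   to coefficient JSON files.
#' @param goal_policy `"aggressive"` or `"standard"` (see
#'   [risk_categories()]).
#' @param lonely Lonely-PSU strategy (see [svy_total()]).
#' @param out_dir Optional directory for rendered reports.
#' @param seed Integer seed (used when `input` is a generator config).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input, coefficients = NULL,
                            goal_policy = c("aggressive", "standard"),
                            lonely = c("error", "centre", "certainty"),
                            out_dir = NULL, seed = 1L) {
  sources <- !is.null(input)
  if (!sources) stop("exactly one input source is required")
  if (is.character(input) && !file.exists(input))
    stop("input file does not exist: ", input)
  if (!is.null(coefficients)) {
    missing_files <- coefficients[!file.exists(coefficients)]
    if (length(missing_files))
      stop("coefficient file does not exist: ",
           paste(missing_files, collapse = ", "))
  }
  structure(list(input = input, coefficients = coefficients,
                 goal_policy = match.arg(goal_policy),
                 lonely = match.arg(lonely), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input <- if (!is.null(y$simulate)) do.call(cohort_config, y$simulate)
           else y$input
  pipeline_config(input = input, coefficients = y$coefficients,
                  goal_policy = y$goal_policy %||% "aggressive",
                  lonely = y$lonely %||% "error",
                  out_dir = y$out_dir, seed = y$seed %||% 1L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparison pipeline
#'
#' read -> eligibility waterfall -> dual risk scoring -> category, goal
#' and reclassification assessment -> survey-weighted reporting. Emits
#' the inclusion/exclusion waterfall, the subject-characteristics
#' summary, per-sex reclassification tables, per-sex marginal-homogeneity
#' tests, and a run manifest (config hash, seed, record counts). When
#' `config$out_dir` is set, the rendered delimited reports are written
#' there; re-running the same config and seed reproduces them
#' byte-identically.
#'
#' @param config A [pipeline_config()] (or a path to its YAML form).
#' @return List of class `cvr_report` with elements `waterfall`,
#'   `characteristics`, `reclass` (per-sex `cvr_reclass` objects),
#'   `mh_tests`, `assessed` (the per-subject table), `manifest`.
#' @export
#' @examples
#' cfg <- pipeline_config(cohort_config(n_women = 150, n_men = 120),
#'                        lonely = "centre", seed = 7)
#' rep <- run_pipeline(cfg)
#' rep$reclass$female
run_pipeline <- function(config) {
  if (is.character(config) && grepl("\\.ya?ml$", config))
    config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  records <- stage("read", {
    inp <- config$input
    if (inherits(inp, "cohort_config"))
      simulate_cohort(inp, seed = config$seed)$records
    else if (is.character(inp)) read_cohort(inp)
    else as_tibble(inp)
  })

  models <- stage("coefficients", {
    m <- if (is.null(config$coefficients)) default_risk_models()
         else do.call(c, lapply(config$coefficients, read_risk_models))
    validate_coefficients(m)
    m
  })

  screened <- stage("eligibility", apply_inclusion(records))
  waterfall <- stage("eligibility",
                     waterfall_summary(screened, lonely = config$lonely))

  eligible <- screened[screened$included, , drop = FALSE]
  if (nrow(eligible) == 0L)
    stop("pipeline stage 'eligibility' failed: empty eligible population",
         call. = FALSE)

  characteristics <- stage("characteristics",
                           summarize_cohort(eligible, lonely = config$lonely))

  assessed <- stage("scoring", {
    eligible$diabetic <- FALSE  # diabetics excluded upstream by design
    scored <- add_risk_scores(eligible, models)
    assess_goals(scored, goal_policy = config$goal_policy)
  })

  reclass <- stage("reclassification", {
    out <- lapply(intersect(c("female", "male"), unique(assessed$sex)),
                  function(s) reclassification_table(
                    assessed[assessed$sex == s, ], lonely = config$lonely))
    setNames(out, intersect(c("female", "male"), unique(assessed$sex)))
  })

  mh_tests <- stage("marginal_homogeneity", bind_rows(lapply(
    names(reclass), function(s) {
      d <- assessed[assessed$sex == s, ]
      res <- svy_marginal_homogeneity(
        d, match(as.character(d$frs_category), category_levels),
        match(as.character(d$rrs_category), category_levels),
        lonely = config$lonely)
      dplyr::bind_cols(tibble(sex = s), as_tibble(res))
    })))

  hashed <- unclass(config)
  hashed$out_dir <- NULL  # where a report lands does not change its content
  manifest <- list(
    config_hash = fnv1a_hash(paste(deparse(hashed), collapse = "")),
    seed = config$seed,
    goal_policy = config$goal_policy,
    n_input = nrow(records),
    n_included = nrow(eligible),
    n_women_included = sum(eligible$sex == "female"),
    n_men_included = sum(eligible$sex == "male"))

  report <- structure(
    list(waterfall = waterfall, characteristics = characteristics,
         reclass = reclass, mh_tests = mh_tests, assessed = assessed,
         manifest = manifest),
    class = "cvr_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.cvr_report <- function(x, ...) {
  cat("<cvr_report> ", x$manifest$n_included, "/", x$manifest$n_input,
      " records included (", x$manifest$n_women_included, " women, ",
      x$manifest$n_men_included, " men)\n", sep = "")
  for (s in names(x$reclass)) {
    cat("--", s, "--\n")
    print(x$reclass[[s]])
  }
  invisible(x)
}

#' Report-time number formatting
#'
#' `format_pct_ci()` renders a proportion with its 95% CI as e.g.
#' `"13.9% (11.6–16.1%)"`, one decimal, with CI bounds truncated to
#' `[0, 1]` at this (and only this) point. `format_millions()` renders a
#' weighted total as e.g. `"53.6±2.4"` (millions).
#'
#' @param p,lo,hi Proportion and CI bounds (fractions).
#' @return Character vector.
#' @export
format_pct_ci <- function(p, lo, hi) {
  lo <- pmin(pmax(lo, 0), 1)
  hi <- pmin(pmax(hi, 0), 1)
  sprintf("%.1f%% (%.1f–%.1f%%)", 100 * p, 100 * lo, 100 * hi)
}

#' @rdname format_pct_ci
#' @param total,se Weighted total and its SE (persons).
#' @export
format_millions <- function(total, se) {
  sprintf("%.1f±%.1f", total / 1e6, se / 1e6)
}

#' Render a report section as delimited text
#'
#' Formats a computed section with the report's precision rules: one
#' decimal on percentages, 95% CIs in parentheses, `"N/A"` for
#' structurally impossible cells, weighted totals in millions.
#' Deterministic.
#'
#' @param x A `cvr_reclass` object, the waterfall tibble, or any tibble
#'   (passed through).
#' @param ... Unused.
#' @return A tibble of formatted character columns, writable with
#'   [readr::write_csv()].
#' @export
render_table <- function(x, ...) UseMethod("render_table")

#' @export
render_table.cvr_reclass <- function(x, ...) {
  cell <- function(p, lo, hi) ifelse(is.na(p), "N/A",
                                     format_pct_ci(p, lo, hi))
  r <- x$rows
  body <- tibble(
    frs = as.character(r$frs_category),
    population_millions = sprintf("%.2f (%.2f–%.2f)",
                                  r$population / 1e6,
                                  pmax(r$population_ci_low, 0) / 1e6,
                                  r$population_ci_high / 1e6),
    pct_of_population = format_pct_ci(r$pct_of_population, r$pct_ci_low,
                                      r$pct_ci_high),
    rrs_increases_risk = cell(r$up, r$up_ci_low, r$up_ci_high),
    rrs_decreases_risk = cell(r$down, r$down_ci_low, r$down_ci_high),
    no_longer_at_goal = cell(r$no_longer_at_goal, r$no_longer_ci_low,
                             r$no_longer_ci_high),
    newly_at_goal = cell(r$newly_at_goal, r$newly_ci_low, r$newly_ci_high))
  t <- x$total
  total <- tibble(
    frs = "total",
    population_millions = sprintf("%.2f (%.2f–%.2f)",
                                  t$population / 1e6,
                                  pmax(t$population_ci_low, 0) / 1e6,
                                  t$population_ci_high / 1e6),
    pct_of_population = "100%",
    rrs_increases_risk = cell(t$up, t$up_ci_low, t$up_ci_high),
    rrs_decreases_risk = cell(t$down, t$down_ci_low, t$down_ci_high),
    no_longer_at_goal = cell(t$no_longer_at_goal, t$no_longer_ci_low,
                             t$no_longer_ci_high),
    newly_at_goal = cell(t$newly_at_goal, t$newly_ci_low, t$newly_ci_high))
  bind_rows(body, total)
}

#' @export
render_table.data.frame <- function(x, ...) {
  x <- as_tibble(x)
  if (all(c("reason", "n", "weighted_total") %in% names(x))) {
    return(tibble(reason = x$reason, subjects = x$n,
                  weighted_population_millions = ifelse(
                    is.na(x$se), sprintf("%.1f", x$weighted_total / 1e6),
                    format_millions(x$weighted_total, x$se))))
  }
  x
}

#' Write every rendered section of a report
#'
#' @param report A `cvr_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(render_table(report$waterfall),
                   file.path(dir, "waterfall.csv"))
  readr::write_csv(report$characteristics,
                   file.path(dir, "characteristics.csv"))
  for (s in names(report$reclass))
    readr::write_csv(render_table(report$reclass[[s]]),
                     file.path(dir, paste0("reclassification_", s, ".csv")))
  readr::write_csv(report$mh_tests, file.path(dir, "mh_tests.csv"))
  yaml::write_yaml(report$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
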