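#' Survey-weighted reclassification table
#'
#' Builds the sex-specific reclassification report: a 4x4 weighted
#' cross-tabulation of FRS category against RRS category, and per FRS
#' row the weighted population total, share of the population, and the
#' row-conditional percentages reclassified up, down, no longer at
#' LDL-C goal (`rrs_gt_frs`) and newly at goal (`rrs_lt_frs`) — each a
#' domain proportion with Taylor-linearized SE and 95% Wald CI. Row
#' percentages condition on the FRS category (the share of that
#' category experiencing the event). Structurally impossible cells (no
#' "down" from low, no "up" from high) are `NA` and rendered as
#' `"N/A"`.
#'
#' @param data Assessed cohort (see [assess_goals()]) for a single sex,
#'   with design columns `stratum`, `psu`, `weight`.
#' @param lonely Lonely-PSU strategy, see [svy_total()].
#' @return An object of class `cvr_reclass`: list with `xtab` (weighted
#'   4x4 matrix), `rows` (per-FRS-category tibble), `total` (overall
#'   tibble), `n_records`.
#' @export
reclassification_table <- function(data,
                                   lonely = c("error", "centre", "certainty")) {
  data <- as_tibble(data)
  lonely <- match.arg(lonely)
  if (nrow(data) == 0L) stop("empty input: no assessed records")
  need <- c("frs_category", "rrs_category", "direction",
            "clinically_significant", "stratum", "psu", "weight")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))

  xtab <- tapply(data$weight,
                 list(factor(data$frs_category, category_levels),
                      factor(data$rrs_category, category_levels)),
                 sum, default = 0)

  prop_row <- function(event, dom) {
    if (sum(dom) == 0)
      return(tibble(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, n_records = 0L,
                    design_df = NA_integer_))
    svy_proportion(data, event, domain = dom, lonely = lonely)
  }

  rows <- lapply(category_levels, function(cat) {
    dom <- as.integer(data$frs_category == cat)
    pop_e <- svy_total(data, dom, lonely = lonely)
    share_e <- svy_proportion(data, dom, lonely = lonely)
    up_e <- prop_row(as.integer(data$direction == "up"), dom)
    down_e <- prop_row(as.integer(data$direction == "down"), dom)
    same_e <- prop_row(as.integer(data$direction == "same"), dom)
    lost_e <- prop_row(as.integer(data$clinically_significant == "rrs_gt_frs"),
                       dom)
    gained_e <- prop_row(as.integer(data$clinically_significant == "rrs_lt_frs"),
                         dom)
    # structural impossibilities: nothing below low, nothing above high
    if (cat == "low") { down_e[, ] <- NA; gained_e[, ] <- NA }
    if (cat == "high") { up_e[, ] <- NA; lost_e[, ] <- NA }
    tibble(frs_category = cat,
           n = sum(dom),
           population = pop_e$estimate, population_se = pop_e$se,
           population_ci_low = pop_e$ci_low,
           population_ci_high = pop_e$ci_high,
           pct_of_population = share_e$estimate,
           pct_ci_low = share_e$ci_low, pct_ci_high = share_e$ci_high,
           up = up_e$estimate, up_ci_low = up_e$ci_low,
           up_ci_high = up_e$ci_high,
           down = down_e$estimate, down_ci_low = down_e$ci_low,
           down_ci_high = down_e$ci_high,
           same = same_e$estimate,
           no_longer_at_goal = lost_e$estimate,
           no_longer_ci_low = lost_e$ci_low,
           no_longer_ci_high = lost_e$ci_high,
           newly_at_goal = gained_e$estimate,
           newly_ci_low = gained_e$ci_low,
           newly_ci_high = gained_e$ci_high)
  })
  rows <- bind_rows(rows)

  tot_pop <- svy_total(data, rep(1, nrow(data)), lonely = lonely)
  overall <- function(event) svy_proportion(data, event, lonely = lonely)
  up_t <- overall(as.integer(data$direction == "up"))
  down_t <- overall(as.integer(data$direction == "down"))
  lost_t <- overall(as.integer(data$clinically_significant == "rrs_gt_frs"))
  gained_t <- overall(as.integer(data$clinically_significant == "rrs_lt_frs"))
  total <- tibble(
    n = nrow(data),
    population = tot_pop$estimate, population_se = tot_pop$se,
    population_ci_low = tot_pop$ci_low, population_ci_high = tot_pop$ci_high,
    up = up_t$estimate, up_ci_low = up_t$ci_low, up_ci_high = up_t$ci_high,
    down = down_t$estimate, down_ci_low = down_t$ci_low,
    down_ci_high = down_t$ci_high,
    no_longer_at_goal = lost_t$estimate,
    no_longer_ci_low = lost_t$ci_low, no_longer_ci_high = lost_t$ci_high,
    newly_at_goal = gained_t$estimate,
    newly_ci_low = gained_t$ci_low, newly_ci_high = gained_t$ci_high)

  structure(list(xtab = xtab, rows = rows, total = total,
                 n_records = nrow(data)),
            class = "cvr_reclass")
}

#' @export
print.cvr_reclass <- function(x, ...) {
  cat("Risk-category reclassification (", x$n_records, " records, ",
      format(round(x$total$population / 1e6, 1)), " M weighted)\n", sep = "")
  fmt <- function(p, lo, hi) {
    ifelse(is.na(p), "N/A", format_pct_ci(p, lo, hi))
  }
  for (i in seq_len(nrow(x$rows))) {
    r <- x$rows[i, ]
    cat(sprintf("  %-13s pop %6.2f M (%s)  up %s  down %s\n",
                r$frs_category, r$population / 1e6,
                format_pct_ci(r$pct_of_population, r$pct_ci_low,
                              r$pct_ci_high),
                fmt(r$up, r$up_ci_low, r$up_ci_high),
                fmt(r$down, r$down_ci_low, r$down_ci_high)))
  }
  t <- x$total
  cat(sprintf("  total: up %s, down %s, no longer at goal %s, newly at goal %s\n",
              format_pct_ci(t$up, t$up_ci_low, t$up_ci_high),
              format_pct_ci(t$down, t$down_ci_low, t$down_ci_high),
              format_pct_ci(t$no_longer_at_goal, t$no_longer_ci_low,
                            t$no_longer_ci_high),
              format_pct_ci(t$newly_at_goal, t$newly_ci_low,
                            t$newly_ci_high)))
  invisible(x)
}

#' @export
tidy.cvr_reclass <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$rows[, c("frs_category", "up", "down", "same", "no_longer_at_goal",
               "newly_at_goal")],
    cols = -1, names_to = "measure", values_to = "estimate")
  long
}

#' @export
glance.cvr_reclass <- function(x, ...) {
  t <- x$total
  tibble(n_records = x$n_records, population = t$population,
         up = t$up, down = t$down,
         no_longer_at_goal = t$no_longer_at_goal,
         newly_at_goal = t$newly_at_goal)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
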