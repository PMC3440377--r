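test_that("Friedewald arithmetic and the 400 mg/dL validity limit", {
  expect_equal(friedewald_ldl(190, 46, 140), 116)
  expect_equal(friedewald_ldl(200, 50, 150), 120)
  expect_true(is.na(friedewald_ldl(200, 50, 400)))
  expect_error(friedewald_ldl(200, -1, 100), "domain")
})

test_that("category cuts are half-open on the unrounded risk", {
  expect_equal(as.character(categorize_risk(c(0.051, 0.125))),
               c("low", "moderate_high"))
  # lower edges belong to the upper category
  expect_equal(as.character(categorize_risk(c(0, 0.0599, 0.06, 0.0999,
                                              0.10, 0.1999, 0.20, 1))),
               c("low", "low", "moderate", "moderate",
                 "moderate_high", "moderate_high", "high", "high"))
  expect_error(categorize_risk(1.2), "domain")
  expect_error(categorize_risk(-0.1), "domain")
})

test_that("goal attainment uses strict inequality on both paths", {
  expect_true(goal_attained(116, NA, FALSE, "low"))
  expect_false(goal_attained(116, NA, FALSE, "moderate_high"))
  expect_false(goal_attained(100, NA, FALSE, "moderate_high"))  # at goal
  # fallback: non-HDL 144 vs moderate non-HDL goal 160
  expect_true(goal_attained(NA, 144, TRUE, "moderate"))
  expect_false(goal_attained(NA, 160, TRUE, "moderate"))
  expect_error(goal_attained(NA, NA, FALSE, "low"), "missing lipids")
  # standard (non-optional) goal set relaxes moderate-high to 130
  expect_true(goal_attained(116, NA, FALSE, "moderate_high",
                            goal_policy = "standard"))
})

test_that("clinically significant reclassification follows attainment, not categories", {
  # worked example: low -> moderate_high, LDL 116 meets 160 but not 100
  r <- classify_reclassification("low", "moderate_high", TRUE, FALSE)
  expect_equal(as.character(r$direction), "up")
  expect_equal(as.character(r$clinically_significant), "rrs_gt_frs")
  # same categories: never clinically significant, whatever the attainment
  r2 <- classify_reclassification("moderate", "moderate", TRUE, FALSE)
  expect_equal(as.character(r2$direction), "same")
  expect_equal(as.character(r2$clinically_significant), "none")
  # enumerate the four attainment combinations on a down-move
  # (moderate_high -> moderate, goals 100 -> 130): attainment alone
  # decides significance. The (met FRS, failed RRS) combination cannot
  # arise from monotone goals — an LDL below 100 is below 130 too — and
  # the record-level coupling test below confirms it never occurs.
  combos <- expand.grid(af = c(TRUE, FALSE), ar = c(TRUE, FALSE))
  res <- classify_reclassification(rep("moderate_high", 4), rep("moderate", 4),
                                   combos$af, combos$ar)
  expect_equal(as.character(res$direction), rep("down", 4))
  expect_equal(as.character(res$clinically_significant),
               ifelse(!combos$af & combos$ar, "rrs_lt_frs",
                      ifelse(combos$af & !combos$ar, "rrs_gt_frs", "none")))
  # and the actual lipid logic produces exactly that combination
  af <- goal_attained(115, NA, FALSE, "moderate_high")
  ar <- goal_attained(115, NA, FALSE, "moderate")
  expect_false(af); expect_true(ar)
})

test_that("lipid path selection: Friedewald when valid, non-HDL fallback otherwise", {
  d <- tibble::tibble(
    total_cholesterol = c(190, 200, 200, 200),
    hdl_cholesterol = c(46, 50, 50, 50),
    triglycerides = c(140, 420, NA, 150),
    fasting_hours = c(10, 10, 10, 5))
  out <- derive_lipids(d)
  expect_equal(out$fallback_used, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$ldl_used, c(116, NA, NA, NA))
  expect_equal(out$nonhdl_used, c(NA, 150, 150, 150))
})

test_that("toy reclassification table matches hand computation", {
  # one stratum, four PSUs, four subjects with hand-assigned outcomes
  d <- tibble::tibble(
    stratum = "s", psu = paste0("p", 1:4), weight = c(1, 2, 3, 4), sex = "female",
    frs_category = factor(c("low", "low", "moderate", "moderate"),
                          levels = c("low", "moderate", "moderate_high", "high")),
    rrs_category = factor(c("low", "moderate", "moderate", "low"),
                          levels = c("low", "moderate", "moderate_high", "high")),
    direction = factor(c("same", "up", "same", "down"),
                       levels = c("up", "down", "same")),
    clinically_significant = factor(c("none", "rrs_gt_frs", "none",
                                      "rrs_lt_frs"),
                                    levels = c("none", "rrs_gt_frs",
                                               "rrs_lt_frs")))
  tab <- reclassification_table(d, lonely = "certainty")
  # weighted cross-tab by hand
  expect_equal(tab$xtab["low", "low"], 1)
  expect_equal(tab$xtab["low", "moderate"], 2)
  expect_equal(tab$xtab["moderate", "moderate"], 3)
  expect_equal(tab$xtab["moderate", "low"], 4)
  rows <- tab$rows
  # low row: weight 3, up share 2/3; moderate row: weight 7, down 4/7
  expect_equal(rows$up[rows$frs_category == "low"], 2 / 3)
  expect_equal(rows$down[rows$frs_category == "moderate"], 4 / 7)
  expect_equal(rows$no_longer_at_goal[rows$frs_category == "low"], 2 / 3)
  expect_equal(rows$newly_at_goal[rows$frs_category == "moderate"], 4 / 7)
  expect_equal(tab$total$up, 2 / 10)
  expect_equal(tab$total$down, 4 / 10)
})

test_that("reclassification invariants hold on a synthetic cohort", {
  a <- assessed_cohort(400, 350, seed = 99)
  for (s in c("female", "male")) {
    tab <- reclassification_table(a[a$sex == s, ], lonely = "centre")
    rows <- tab$rows
    occupied <- rows$n > 0
    # row conservation: up + down + same = 1 within each occupied row
    sums <- rowSums(cbind(ifelse(is.na(rows$up), 0, rows$up),
                          ifelse(is.na(rows$down), 0, rows$down),
                          rows$same))
    expect_equal(sums[occupied], rep(1, sum(occupied)), tolerance = 1e-12)
    # structural zeros never populated
    expect_true(is.na(rows$down[rows$frs_category == "low"]))
    expect_true(is.na(rows$newly_at_goal[rows$frs_category == "low"]))
    expect_true(is.na(rows$up[rows$frs_category == "high"]))
    expect_true(is.na(rows$no_longer_at_goal[rows$frs_category == "high"]))
    # clinically significant share is a subset of the reclassified share
    tot <- tab$total
    expect_lte(tot$no_longer_at_goal + tot$newly_at_goal,
               tot$up + tot$down + 1e-12)
    # direction coupling at the record level
    d <- a[a$sex == s, ]
    expect_true(all(d$direction[d$clinically_significant == "rrs_gt_frs"]
                    == "up"))
    expect_true(all(d$direction[d$clinically_significant == "rrs_lt_frs"]
                    == "down"))
  }
})

test_that("category shares sum to one and all-same cohorts show zero reclassification", {
  a <- assessed_cohort(250, 0, seed = 31)
  tab <- reclassification_table(a, lonely = "centre")
  expect_equal(sum(tab$rows$pct_of_population), 1, tolerance = 1e-12)
  # force both categories identical: diagonal table, zero movement
  forced <- a
  forced$rrs_category <- forced$frs_category
  cls <- classify_reclassification(forced$frs_category, forced$rrs_category,
                                   forced$attained_frs, forced$attained_frs)
  forced$direction <- cls$direction
  forced$clinically_significant <- cls$clinically_significant
  tab2 <- reclassification_table(forced, lonely = "centre")
  expect_equal(sum(tab2$xtab) - sum(diag(tab2$xtab)), 0)
  expect_equal(tab2$total$up, 0)
  expect_equal(tab2$total$down, 0)
  expect_error(reclassification_table(a[0, ]), "empty")
})
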