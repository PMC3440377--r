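models <- default_risk_models()
worked <- reference_profile()

test_that("worked-example profile scores FRS 5.1% and RRS 12.5%", {
  frs <- framingham_10yr_risk(worked, models)
  rrs <- reynolds_10yr_risk(worked, models)
  expect_equal(round(100 * frs, 1), 5.1)
  expect_equal(round(100 * rrs, 1), 12.5)
  # uncentered linear predictor of the women's Reynolds equation,
  # frozen from an independent hand evaluation of the published terms
  expect_equal(cox_linear_predictor(models$rrs_women, worked), 24.60103,
               tolerance = 1e-6)
})

test_that("FRS ignores hs-CRP and family history; RRS HbA1c inert unless diabetic", {
  base <- framingham_10yr_risk(worked, models)
  tweaked <- dplyr::mutate(worked, hscrp = 10, family_history = FALSE)
  expect_identical(framingham_10yr_risk(tweaked, models), base)
  rrs_base <- reynolds_10yr_risk(worked, models)
  with_a1c <- dplyr::mutate(worked, hba1c = 5.0)
  expect_identical(reynolds_10yr_risk(with_a1c, models), rrs_base)
})

test_that("single-covariate changes move risk as the equations dictate", {
  hi_sbp <- dplyr::mutate(worked, systolic_bp = 150)
  expect_gt(framingham_10yr_risk(hi_sbp, models),
            framingham_10yr_risk(worked, models))
  expect_equal(framingham_10yr_risk(hi_sbp, models),
               oracle_cox_risk(models$frs_hard_chd_women,
                               as.list(hi_sbp[1, ])),
               tolerance = 1e-12)
  no_fh <- dplyr::mutate(worked, family_history = FALSE)
  rrs_no_fh <- reynolds_10yr_risk(no_fh, models)
  expect_lt(rrs_no_fh, 0.125)
  expect_equal(rrs_no_fh,
               oracle_cox_risk(models$rrs_women, as.list(no_fh[1, ])),
               tolerance = 1e-12)
})

test_that("a profile at the centering constant yields exactly 1 - S0", {
  m <- cox_risk_model("centered", "both", baseline_survival = 0.9,
                      mean_linear_predictor = 0.05 * 60,
                      terms = list(list(label = "age", beta = 0.05,
                                        factors = list(list(field = "age")))))
  expect_equal(evaluate_cox_model(m, tibble::tibble(age = 60)), 1 - 0.9)
})

test_that("engine matches the brute-force oracle on random profiles, risks stay in [0,1]", {
  set.seed(401)
  for (s in c("female", "male")) {
    prof <- random_profiles(80, s)
    for (id in c(paste0("frs_hard_chd_", if (s == "female") "women" else "men"),
                 paste0("rrs_", if (s == "female") "women" else "men"))) {
      engine <- evaluate_cox_model(models[[id]], prof)
      oracle <- vapply(seq_len(nrow(prof)), function(i)
        oracle_cox_risk(models[[id]], as.list(prof[i, ])), numeric(1))
      expect_equal(engine, oracle, tolerance = 1e-12)
      expect_true(all(engine >= 0 & engine <= 1))
    }
  }
})

test_that("risk is monotone where the published equations guarantee it", {
  set.seed(402)
  bump <- function(prof, col, delta) {
    prof[[col]] <- prof[[col]] + delta
    prof
  }
  for (s in c("female", "male")) {
    prof <- random_profiles(40, s)
    # Reynolds: no interactions, every coefficient positive except HDL,
    # so monotone across the whole physiological box
    rrs_base <- reynolds_10yr_risk(prof, models)
    for (chg in list(c("age", 3), c("systolic_bp", 10),
                     c("total_cholesterol", 20), c("hscrp", 2))) {
      expect_true(all(reynolds_10yr_risk(
        bump(prof, chg[1], as.numeric(chg[2])), models) >= rrs_base))
    }
    for (flag in c("current_smoker", "family_history")) {
      flagged <- prof
      flagged[[flag]] <- TRUE
      expect_true(all(reynolds_10yr_risk(flagged, models) >= rrs_base))
    }
    # Framingham hard CHD: SBP and smoking are monotone everywhere (the
    # smoking age-interaction cap keeps the smoker effect positive)
    frs_base <- framingham_10yr_risk(prof, models)
    expect_true(all(framingham_10yr_risk(bump(prof, "systolic_bp", 10),
                                         models) >= frs_base))
    smoke <- prof
    smoke$current_smoker <- TRUE
    expect_true(all(framingham_10yr_risk(smoke, models) >= frs_base))
  }
  # The FRS age x TC interaction (and the men's quadratic age term) make
  # age and TC only locally monotone; check on the guaranteed subdomains.
  w <- random_profiles(40, "female")
  w$total_cholesterol <- runif(40, 120, 280)  # age slope positive below ~294
  expect_true(all(framingham_10yr_risk(bump(w, "age", 3), models) >=
                    framingham_10yr_risk(w, models)))
  expect_true(all(framingham_10yr_risk(bump(w, "total_cholesterol", 20),
                                       models) >=
                    framingham_10yr_risk(w, models)))  # TC slope > 0 to age 84
  m <- random_profiles(40, "male")
  m$age <- runif(40, 50, 72)                  # TC slope positive below ~77
  expect_true(all(framingham_10yr_risk(bump(m, "total_cholesterol", 20),
                                       models) >=
                    framingham_10yr_risk(m, models)))
})

test_that("incomplete or invalid profiles raise named errors", {
  expect_error(reynolds_10yr_risk(dplyr::select(worked, -hscrp), models),
               "hscrp")
  expect_error(framingham_10yr_risk(dplyr::select(worked, -systolic_bp),
                                    models),
               "systolic_bp")
  expect_error(
    evaluate_cox_model(models$rrs_women,
                       dplyr::mutate(worked, hscrp = -1)),
    "domain")
  expect_error(
    evaluate_cox_model(models$rrs_women, dplyr::mutate(worked, sex = "male")),
    "not applicable")
  expect_error(
    framingham_10yr_risk(dplyr::mutate(worked, systolic_bp = NA_real_),
                         models),
    "systolic_bp")
})

test_that("coefficient files round-trip bit-exactly", {
  tmp <- withr::local_tempfile(fileext = ".json")
  write_risk_models(models, tmp)
  back <- read_risk_models(tmp)
  expect_identical(names(back), names(models))
  for (id in names(models)) {
    expect_identical(back[[id]]$baseline_survival,
                     models[[id]]$baseline_survival)
    expect_identical(back[[id]]$mean_linear_predictor,
                     models[[id]]$mean_linear_predictor)
    expect_identical(back[[id]]$terms, models[[id]]$terms)
  }
  # second round trip is byte-stable too
  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_risk_models(back, tmp2)
  expect_identical(readLines(tmp), readLines(tmp2))
})

test_that("validate_coefficients guards transcriptions", {
  expect_silent(validate_coefficients(models))
  corrupted <- models
  corrupted$rrs_women$terms[[1]]$beta <- 0.2
  expect_error(validate_coefficients(corrupted), "12.5")
})
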