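base_row <- function(age = 40, mechanism = "blunt", sbp = 80,
                     rbc_units_4h = 0, transfer_in = 0, los_days = 3) {
  data.frame(age = age, mechanism = mechanism, sbp = sbp,
             rbc_units_4h = rbc_units_4h, transfer_in = transfer_in,
             los_days = los_days, stringsAsFactors = FALSE)
}

test_that("inclusion boundaries follow the stated criteria", {
  # age strictly > 16; SBP <= 90 inclusive
  expect_equal(nrow(apply_study_filters(base_row(age = 15))$cohort), 0)
  expect_equal(nrow(apply_study_filters(base_row(age = 16))$cohort), 0)
  expect_equal(nrow(apply_study_filters(base_row(age = 17))$cohort), 1)
  expect_equal(nrow(apply_study_filters(base_row(sbp = 90))$cohort), 1)
})

test_that("the shock disjunction is correct on all boundary combinations", {
  # brute-force check of (sbp <= 90) OR (rbc >= 4) over boundary values
  grid <- expand.grid(sbp = c(89, 90, 91, 120), rbc = c(0, 3, 4, 7))
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    base_row(sbp = grid$sbp[i], rbc_units_4h = grid$rbc[i])
  }))
  kept <- apply_study_filters(rows)$cohort
  expected <- grid$sbp <= 90 | grid$rbc >= 4
  expect_equal(nrow(kept), sum(expected))
  expect_setequal(paste(kept$sbp, kept$rbc_units_4h),
                  paste(grid$sbp, grid$rbc)[expected])
})

test_that("exclusions, attrition accounting and idempotence hold", {
  rows <- rbind(base_row(), base_row(transfer_in = 1),
                base_row(age = NA), base_row(los_days = NA),
                base_row(mechanism = "penetrating"))
  res <- apply_study_filters(rows)
  expect_equal(nrow(res$cohort), 1)
  # conservation: n_in = n_out + total excluded
  expect_equal(res$attrition$n_remaining[1],
               nrow(res$cohort) + sum(res$attrition$n_excluded))
  # remaining counts never increase
  expect_true(all(diff(res$attrition$n_remaining) <= 0))
  # idempotence
  res2 <- apply_study_filters(res$cohort)
  expect_equal(res2$cohort, res$cohort)
  expect_equal(sum(res2$attrition$n_excluded), 0)
})

test_that("a missing required column raises a schema error naming it", {
  bad <- base_row()
  bad$los_days <- NULL
  expect_error(apply_study_filters(bad), "los_days")
})

test_that("planted filter-failure counts are recovered exactly", {
  cfg <- quick_config(n = 8000, seed = 13)
  sim <- generate_cohort(cfg)
  raw <- sim$cohort
  res <- apply_study_filters(raw)
  att <- res$attrition
  get <- function(label) att$n_excluded[grepl(label, att$criterion,
                                              fixed = TRUE)]
  # independent recount of each (disjoint) planted failure
  expect_equal(get("age > 16"), sum(!is.na(raw$age) & raw$age <= 16))
  expect_equal(get("blunt"), sum(raw$mechanism != "blunt"))
  expect_equal(get("shock"),
               sum(!((!is.na(raw$sbp) & raw$sbp <= 90) |
                       raw$rbc_units_4h >= 4)))
  expect_equal(get("transferred"), sum(raw$transfer_in == 1))
  expect_equal(get("age recorded"), sum(is.na(raw$age)))
  expect_equal(get("length of stay"), sum(is.na(raw$los_days)))
})

test_that("REBOA labelling honours the code set and the 4-h window", {
  expect_equal(label_reboa("04L03DZ@2.00"), 1L)
  expect_equal(label_reboa(""), 0L)
  expect_equal(label_reboa(NA_character_), 0L)
  expect_equal(label_reboa("04L03DZ@5.50"), 0L)   # outside the window
  expect_equal(label_reboa("0W9G3ZZ@1.00"), 0L)   # not a REBOA code
  expect_equal(label_reboa("0W9G3ZZ@9.0;04L04ZZ@3.5"), 1L)
  expect_equal(label_reboa("04L03DZ@2.00", code_set = "XXXXXXX"), 0L)
  expect_error(label_reboa(c("04L03DZ@2.00", "garbage")), "row 2")
})

test_that("generated treatment labels equal code-derived labels", {
  sim <- generate_cohort(quick_config(n = 3000, seed = 5))
  expect_equal(label_reboa(sim$cohort$procedure_codes), sim$cohort$reboa)
})

test_that("derive_features computes BMI and guards the covariate set", {
  d <- data.frame(height = 180, weight = 81, bmi = NA_real_, age = 30)
  expect_equal(derive_features(d)$bmi, 25.0)   # 81 / 1.8^2

  d2 <- data.frame(height = 180, weight = 81, bmi = 31.4, age = 30)
  expect_equal(derive_features(d2)$bmi, 31.4)  # observed BMI untouched

  d3 <- data.frame(height = -5, weight = 81, bmi = NA_real_, age = 30)
  expect_error(derive_features(d3), "non-positive height")

  d4 <- data.frame(age = 30, iss = 25, gcs = 14)
  expect_warning(out <- derive_features(d4), "iss")
  expect_false("iss" %in% names(out))
  expect_true(all(c("age", "gcs") %in% names(out)))

  # bookkeeping columns are dropped silently from the model matrix
  d5 <- data.frame(age = 30, los_days = 4, reboa = 0, death_24h = 0)
  expect_silent(out5 <- derive_features(d5))
  expect_false("los_days" %in% names(out5))
  expect_true(all(c("reboa", "death_24h") %in% names(out5)))
})
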