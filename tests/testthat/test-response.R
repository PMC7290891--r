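test_that("BR boundaries are inclusive on the PR and PD sides", {
  expect_equal(classify_br(100, 50)$category, "PR")   # ratio exactly 50
  expect_equal(classify_br(100, 125)$category, "PD")  # ratio exactly 125
  expect_equal(classify_br(100, 80)$category, "SD")
  expect_equal(classify_br(100, 338)$category, "PD")  # +238%
  expect_equal(classify_br(100, 1)$category, "PR")    # -99%
  expect_equal(classify_br(10, 0)$category, "CR")     # undetectable under therapy
})

test_that("PSA-negative disease is not classifiable by BR", {
  r <- classify_br(NA, NA, psa_negative = TRUE, patient_id = "p2")
  expect_true(is.na(r$category))
  expect_error(classify_br(NA, 5), "psa_negative")
})

test_that("PERCIST: new lesion forces PD; boundaries and CR branch behave", {
  r <- classify_percist(10, 12, new_lesion = TRUE)  # ratio 120 but new lesion
  expect_equal(r$category, "PD")
  expect_true(r$pd_by_new_lesion_only)
  r2 <- classify_percist(10, 15, new_lesion = TRUE) # ratio 150: both drivers
  expect_equal(r2$category, "PD")
  expect_false(r2$pd_by_new_lesion_only)
  expect_equal(classify_percist(10, 7)$category, "PR")   # exactly 70%
  expect_equal(classify_percist(10, 13)$category, "PD")  # exactly 130%
  expect_equal(classify_percist(10, NA)$category, "CR")  # uptake resolved
  expect_equal(classify_percist(10, 0)$category, "CR")
  expect_true(is.na(classify_percist(NA, 12)$category))  # no baseline lesion
})

test_that("volume schemes: CR on vanished burden, NA on undefined ratio", {
  expect_equal(classify_volume("PSMA_TV", 120, 0)$category, "CR")
  expect_true(is.na(classify_volume("PSMA_TV", 0, 50)$category))
  expect_true(is.na(classify_volume("TL_PSMA", NA, 50)$category))
  expect_equal(classify_volume("PSMA_TV", 100, 313)$category, "PD") # +213%
  expect_equal(classify_volume("PSMA_TV", 100, 79)$category, "SD")  # -21%
  expect_equal(classify_volume("PSMA_TV", 100, 86)$category, "SD")  # -14%
  expect_equal(classify_volume("TL_PSMA", 100, 70)$category, "PR")
  expect_equal(classify_volume("TL_PSMA", 100, 130)$category, "PD")
})

test_that("every defined ratio maps to exactly one category", {
  grid <- seq(0, 500, by = 0.5)
  for (cuts in list(c(50, 125), c(70, 130))) {
    cats <- vapply(grid, petburden:::classify_ratio, character(1),
                   pr_max = cuts[1], pd_min = cuts[2])
    expect_false(any(is.na(cats)))
    expect_true(all(c("PR", "SD", "PD") %in% cats))
    # partition: category changes exactly at the two cutpoints
    expect_equal(sum(cats[-1] != cats[-length(cats)]), 2)
  }
})

test_that("the six printed disagreement cases are reproduced 6/6", {
  dc <- disagreement_cases()
  br <- vapply(seq_len(nrow(dc)), function(i)
    classify_br(100, 100 + dc$delta_psa_pct[i])$category, character(1))
  tv <- vapply(seq_len(nrow(dc)), function(i)
    classify_volume("PSMA_TV", 100,
                    100 + dc$delta_psma_tv_pct[i])$category, character(1))
  expect_equal(br, dc$br)
  expect_equal(tv, dc$dpsma_tv)
  expect_equal(sum(br == "PD"), 4)
})

test_that("cohort cross-tabulation reproduces the published agreement", {
  cc <- cohort_classifications()
  long <- rbind(
    data.frame(patient_id = cc$patient_id, scheme = "BR", category = cc$br),
    data.frame(patient_id = cc$patient_id, scheme = "PERCIST",
               category = cc$percist),
    data.frame(patient_id = cc$patient_id, scheme = "PSMA_TV",
               category = cc$dpsma_tv_a),
    data.frame(patient_id = cc$patient_id, scheme = "TL_PSMA",
               category = cc$dtl_psma_a))
  ct <- cross_tabulate(long)
  pw <- ct$pairwise
  row <- pw[pw$scheme_a == "BR" & pw$scheme_b == "PSMA_TV", ]
  expect_equal(row$n_disagree, 7)
  expect_equal(row$n_relevant, 6)
  expect_equal(row$n_compared, 18)  # 2 PSA-negative + 1 unusable baseline out
  expect_equal(unname(ct$counts["PERCIST", c("PR", "SD", "PD")]),
               c(4, 1, 16))
  expect_equal(unname(ct$counts["PSMA_TV", c("PR", "SD", "PD")]),
               c(7, 4, 9))
  expect_equal(unname(ct$counts["TL_PSMA", c("PR", "SD", "PD")]),
               c(7, 4, 9))
  # volume schemes agree for every classified patient
  row2 <- pw[pw$scheme_a == "PSMA_TV" & pw$scheme_b == "TL_PSMA", ]
  expect_equal(row2$n_disagree, 0)
  # both software tools give identical volume-scheme categories
  expect_identical(cc$dpsma_tv_a, cc$dpsma_tv_b)
  expect_identical(cc$dtl_psma_a, cc$dtl_psma_b)
})

test_that("identical scheme columns produce zero disagreements", {
  a <- data.frame(patient_id = 1:5, scheme = "BR",
                  category = c("PR", "SD", "PD", "PR", "PD"))
  b <- a; b$scheme <- "PSMA_TV"
  ct <- cross_tabulate(rbind(a, b))
  expect_equal(ct$pairwise$n_disagree, 0)
  expect_equal(ct$pairwise$n_relevant, 0)
  expect_equal(ct$pairwise$n_compared, 5)
})

test_that("new-lesion driven PD is counted both ways", {
  rows <- rbind(
    classify_percist(10, 12, TRUE, patient_id = "a"),  # PD by new lesion only
    classify_percist(10, 15, TRUE, patient_id = "b"),  # PD by both
    classify_percist(10, 15, FALSE, patient_id = "c")) # PD by SUV alone
  ct <- cross_tabulate(rows)
  expect_equal(ct$new_lesion_counts$any_new_lesion, 2)
  expect_equal(ct$new_lesion_counts$pd_by_new_lesion_only, 1)
})
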