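# Selection logic and scan mechanics. The full closed-loop parameter
# recoveries live with the acceptance checks; here the lexicographic filter
# is exercised on synthetic metric tables and the scan plumbing on tiny runs.

fake_report <- function(gamma = 100, mad = 0.5, d80 = NA, mx = NA,
                        dta = 1, p10 = NA) {
  r <- list(gamma_pass = gamma, mean_abs_diff = mad, max_abs_diff = mx,
            mean_dta = dta)
  if (!is.na(d80)) r$delta_d80 <- d80
  if (!is.na(mx)) r$max_abs_diff <- mx
  if (!is.na(p10)) r$delta_pdd10 <- p10
  structure(r, class = "metric_report")
}

test_that("a uniquely best gamma wins regardless of later criteria", {
  pc <- list(`5.8` = list(pdd = fake_report(gamma = 96, mad = 0.1, p10 = 0)),
             `6.0` = list(pdd = fake_report(gamma = 100, mad = 5, p10 = 3)),
             `6.2` = list(pdd = fake_report(gamma = 98, mad = 0.2, p10 = 0)))
  sel <- select_optimal(pc, "energy")
  expect_equal(sel$selected, 6.0)
  expect_equal(sel$trace[[1]]$criterion, "highest gamma pass rate")
})

test_that("tied gammas fall through to the PDD mean absolute difference", {
  pc <- list(`5.8` = list(pdd = fake_report(mad = 0.58, p10 = -0.17)),
             `6.0` = list(pdd = fake_report(mad = 0.36, p10 = 0.10)),
             `6.2` = list(pdd = fake_report(mad = 0.68, p10 = 1.2)))
  expect_equal(select_optimal(pc, "energy")$selected, 6.0)
})

test_that("identical rows tie-break toward the middle candidate", {
  same <- list(pdd = fake_report())
  pc <- list(`1` = same, `2` = same, `3` = same, `4` = same)
  sel <- select_optimal(pc, "energy")
  expect_true(sel$selected %in% c(2, 3))
  expect_match(sel$trace[[length(sel$trace)]]$criterion, "middle")
})

test_that("selection is invariant to candidate ordering", {
  pc <- list(`0.5` = list(cx = fake_report(gamma = 97, d80 = 0.71, mx = 8.95,
                                           dta = 2.1)),
             `1.0` = list(cx = fake_report(gamma = 98, d80 = 0.59, mx = 6.58,
                                           dta = 1.8)),
             `2.0` = list(cx = fake_report(gamma = 95, d80 = 0.90, mx = 9.15,
                                           dta = 2.9)))
  a <- select_optimal(pc, "spot")$selected
  b <- select_optimal(rev(pc), "spot")$selected
  expect_equal(a, b)
  expect_equal(a, 1.0)
})

test_that("empty tables and missing reference kinds are rejected", {
  expect_error(select_optimal(list(), "energy"), "empty")
  expect_error(scan_stage("energy", 6.0, electron_beam(),
                          list(crossline = NULL), 33, 780),
               "reference PDD")
})

test_that("a single-candidate scan is trivially selected with a trace", {
  fx <- generate_reference_dataset(
    pdd_params = list(mu = 0.0048, buildup = 0.18, depths = seq(1, 299, 2)))
  st <- scan_stage("energy", 6.0, electron_beam(), list(pdd = fx$pdd),
                   c(33, 33), 780)
  res <- run_parameter_scan(st, config = quick_config(1e5, seed = 3),
                            lateral_mm = 90)
  expect_equal(res$selected, 6.0)
  expect_equal(res$selection_trace[[1]]$criterion, "only candidate")
  expect_s3_class(res, "tuning_result")
  expect_true(all(c("gamma_pass", "mean_abs_diff") %in% names(res$table)))
})
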