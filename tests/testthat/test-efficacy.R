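# Vaccine-efficacy statistics on tick-infestation trials.

sub_nt <- c(677, 983, 832); ctl_nt <- c(1688, 1400, 1290)
sub_wt <- c(277, 258, 295); ctl_wt <- c(276, 254, 288)
sub_pplo <- c(0.32, 0.38, 0.35); ctl_pplo <- c(0.62, 0.53, 0.41)

test_that("summarize_metric gives the n-1 sample SD and display rounding", {
  s <- summarize_metric(sub_nt)
  expect_equal(s$mean_display, 831)
  expect_equal(s$sd_display, 153)
  expect_equal(summarize_metric(ctl_nt)$sd_display, 206)
  const <- summarize_metric(c(5, 5, 5))
  expect_equal(const$mean, 5)
  expect_equal(const$sd, 0)
  expect_error(summarize_metric(7), class = "quantavax_insufficient_data")
})

test_that("percent reduction clips negatives for display but keeps the raw value", {
  dt <- percent_reduction(sub_nt, ctl_nt)
  expect_equal(dt$percent, 43)
  dw <- percent_reduction(sub_wt, ctl_wt)
  expect_equal(dw$percent, 0)
  expect_lt(dw$raw_percent, 0)
  same <- percent_reduction(ctl_nt, ctl_nt)
  expect_equal(same$percent, 0)
  expect_equal(same$ratio, 1)
  expect_error(percent_reduction(sub_nt, c(0, 0, 0)),
               class = "quantavax_degenerate_control")
})

test_that("one-sided Welch p-values match a hand-computed Welch t", {
  # Independent closed form: t and Welch-Satterthwaite df by hand.
  hand_welch <- function(x, y) {
    se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
    t <- (mean(y) - mean(x)) / sqrt(se2)
    df <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                   (stats::var(y) / length(y))^2 / (length(y) - 1))
    stats::pt(t, df)
  }
  for (case in list(list(ctl_nt, sub_nt), list(ctl_pplo, sub_pplo),
                    list(c(10, 12, 9, 14), c(8, 7, 11)))) {
    expect_equal(welch_p(case[[1]], case[[2]]),
                 hand_welch(case[[1]], case[[2]]), tolerance = 1e-12)
  }
  expect_equal(welch_p(ctl_nt, sub_nt), 0.008, tolerance = 0.05)
  expect_equal(welch_p(ctl_pplo, sub_pplo), 0.049, tolerance = 0.02)
  expect_equal(welch_p(ctl_nt, ctl_nt), 0.5)
  expect_equal(welch_p(c(3, 3, 3), c(3, 3, 3)), 0.5)
  expect_error(welch_p(c(1), c(2, 3)), class = "quantavax_insufficient_data")
})

test_that("the trial fixture reproduces the full published SUB column", {
  trial <- table1_trial()
  s <- vaccine_efficacy(trial, "SUB")
  eff <- s$effects
  expect_equal(round_half_away(eff["DT", "mean_v"]), 831)
  expect_equal(round_half_away(eff["DT", "sd_v"]), 153)
  expect_equal(round_half_away(eff["DT", "mean_c"]), 1459)
  expect_equal(round_half_away(eff["DT", "sd_c"]), 206)
  expect_equal(eff$reduction_pct, c(43, 0, 2, 33))
  expect_equal(round_half_away(eff["DF", "mean_v"], 2), 0.35)
  expect_equal(unname(eff$significant), c(TRUE, FALSE, FALSE, TRUE))
  # DO not significant, so its ratio is gated to exactly 1.
  expect_identical(s$cro, 1)
  expect_equal(s$crt, mean(sub_nt) / mean(ctl_nt))
  expect_equal(s$efficacy_display, 62)
})

test_that("gating: no significant effect means E = 0; DW never enters E", {
  ctl <- data.frame(animal_id = 1:3, nt = ctl_nt, wt = ctl_wt,
                    pat = c(109, 121, 98), pplo = ctl_pplo)
  trial <- trial_table(ctl, list(same = ctl))
  s <- vaccine_efficacy(trial, "same")
  expect_identical(c(s$crt, s$cro, s$crf), c(1, 1, 1))
  expect_equal(s$efficacy_pct, 0)
  # A trial where only tick weight drops leaves E at 0.
  wt_only <- ctl
  wt_only$wt <- ctl_wt * 0.5
  s2 <- vaccine_efficacy(trial_table(ctl, list(w = wt_only)), "w")
  expect_true(s2$effects["DW", "significant"])
  expect_equal(s2$efficacy_pct, 0)
})

test_that("E is invariant under uniform rescaling of one metric in both arms", {
  trial <- table1_trial()
  e0 <- vaccine_efficacy(trial, "SUB")$efficacy_pct
  ctl <- trial$control; sub <- trial$groups$SUB
  for (col in c("nt", "pat", "pplo")) {
    ctl2 <- ctl; sub2 <- sub
    scale <- if (col == "nt") 3 else 2.5
    ctl2[[col]] <- if (col == "nt") ctl[[col]] * 3 else ctl[[col]] * scale
    sub2[[col]] <- if (col == "nt") sub[[col]] * 3 else sub[[col]] * scale
    e1 <- vaccine_efficacy(trial_table(ctl2, list(SUB = sub2)), "SUB")$efficacy_pct
    expect_equal(e1, e0, tolerance = 1e-12)
  }
})

test_that("gating monotonicity: forcing a ratio to 1 moves E toward 0", {
  s <- vaccine_efficacy(table1_trial(), "SUB")
  e_full <- 100 * (1 - s$crt * s$cro * s$crf)
  e_gated <- 100 * (1 - 1 * s$cro * s$crf)
  expect_lte(abs(e_gated), abs(e_full))
})

test_that("the ratio form reproduces the published field-trial worked example", {
  e <- efficacy_from_ratios(22 / 25, 240 / 300, 1.1 / 4.4)
  expect_equal(e$efficacy_pct, 82.4, tolerance = 1e-12)
  expect_equal(e$efficacy_display, 82)
  expect_equal(percent_reduction(22, c(25, 25))$percent, 12)
  expect_equal(efficacy_from_ratios(1, 1, 1)$efficacy_display, 0)
})

test_that("2^-ddCt fold changes follow the doubling rule", {
  cal <- list(target_ct = 25, reference_ct = 20)
  expect_equal(ddct_relative_expression(cal, cal), 1)
  expect_equal(ddct_relative_expression(list(target_ct = 24, reference_ct = 20), cal), 2)
  expect_equal(ddct_relative_expression(list(target_ct = 25 + 3.3219, reference_ct = 20), cal),
               0.1, tolerance = 1e-4)
  expect_error(ddct_relative_expression(list(target_ct = -1, reference_ct = 20), cal),
               class = "quantavax_value_error")
})

test_that("trial CSV reader enforces the schema", {
  bad <- tempfile(fileext = ".csv")
  writeLines("group,animal_id,nt,wt\ncontrol,c1,10,20", bad)
  expect_error(read_trial_csv(bad), class = "quantavax_schema_error")
  noctl <- tempfile(fileext = ".csv")
  writeLines("group,animal_id,nt,wt,pat,pplo\nA,a1,10,20,5,0.5", noctl)
  expect_error(read_trial_csv(noctl), class = "quantavax_schema_error")
})
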