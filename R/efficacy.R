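# Vaccine-efficacy statistics for tick infestation trials.
#
# A trial records, per animal, four tick-fitness metrics: number of engorged
# female ticks (nt), mean engorged female weight in mg (wt), oviposition as
# egg mass per tick in mg (pat), and egg fertility as larvae weight over egg
# weight (pplo). Percent effects DT/DW/DO/DF compare vaccinated group means
# against the control; vaccine efficacy combines the tick-number,
# oviposition and fertility ratios, each gated by a Welch test.

#' Build a trial table from per-animal records
#'
#' @param control data.frame of control-group animals with columns
#'   `animal_id`, `nt`, `wt`, `pat`, `pplo`.
#' @param groups named list of data.frames with the same columns, one per
#'   vaccinated group.
#' @param alpha significance level used to gate effects (default 0.05).
#' @return object of class `trial_table`.
#' @export
trial_table <- function(control, groups, alpha = 0.05) {
  check_animal_frame <- function(df, name) {
    need <- c("animal_id", "nt", "wt", "pat", "pplo")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0) {
      stop_quantavax(
        sprintf("group '%s' is missing columns: %s", name,
                paste(missing, collapse = ", ")),
        "quantavax_schema_error"
      )
    }
    if (nrow(df) == 0) {
      stop_quantavax(sprintf("group '%s' is empty", name), "quantavax_value_error")
    }
    for (col in c("nt", "wt", "pat", "pplo")) {
      assert_finite_numeric(df[[col]], sprintf("%s$%s", name, col))
    }
    if (any(df$nt < 0) || any(df$nt != round(df$nt))) {
      stop_quantavax(sprintf("group '%s': nt must be non-negative integers", name),
                     "quantavax_value_error")
    }
    df
  }
  control <- check_animal_frame(as.data.frame(control), "control")
  if (length(groups) == 0) {
    stop_quantavax("at least one vaccinated group is required", "quantavax_value_error")
  }
  if (is.null(names(groups)) || anyDuplicated(names(groups)) || any(names(groups) == "")) {
    stop_quantavax("groups must have unique non-empty names", "quantavax_value_error")
  }
  group_names <- names(groups)
  groups <- lapply(seq_along(groups), function(i) {
    check_animal_frame(as.data.frame(groups[[i]]), group_names[i])
  })
  names(groups) <- group_names
  structure(
    list(control = control, groups = groups, alpha = alpha),
    class = "trial_table"
  )
}

#' Read a trial table from CSV
#'
#' Expected columns: `group,animal_id,nt,wt,pat,pplo`; the control group
#' must be named `control` (case-insensitive).
#'
#' @param path CSV file path.
#' @param alpha significance level (default 0.05).
#' @return `trial_table` object.
#' @export
read_trial_csv <- function(path, alpha = 0.05) {
  if (!file.exists(path)) {
    stop_quantavax(sprintf("trial file not found: %s", path), "quantavax_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "animal_id", "nt", "wt", "pat", "pplo")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop_quantavax(sprintf("trial CSV missing columns: %s",
                           paste(missing, collapse = ", ")),
                   "quantavax_schema_error")
  }
  is_control <- tolower(df$group) == "control"
  if (!any(is_control)) {
    stop_quantavax("trial CSV has no 'control' group", "quantavax_schema_error")
  }
  cols <- c("animal_id", "nt", "wt", "pat", "pplo")
  groups <- split(df[!is_control, cols], df$group[!is_control])
  trial_table(df[is_control, cols], groups, alpha = alpha)
}

#' Mean and sample standard deviation of a metric
#'
#' @param values numeric vector of at least two finite observations.
#' @return list with `mean`, `sd` (n-1 denominator) and their display
#'   roundings (`mean_display`, `sd_display`).
#' @param digits decimals used for the display rounding: 0 for counts and
#'   weights, 2 for ratio-valued metrics.
#' @export
summarize_metric <- function(values, digits = 0) {
  assert_finite_numeric(values, "values")
  if (length(values) < 2) {
    stop_quantavax("at least two observations are required", "quantavax_insufficient_data")
  }
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sd = s,
       mean_display = round_half_away(m, digits),
       sd_display = round_half_away(s, digits))
}

#' Percent reduction of a metric relative to control
#'
#' Computes 100 * (1 - mean(vaccinated)/mean(control)). The displayed value
#' is clipped at 0 and rounded to integer; the raw (possibly negative)
#' value is returned alongside.
#'
#' @param vaccinated,control numeric vectors of per-animal observations.
#' @return list with `percent` (clipped, rounded), `raw_percent`, `ratio`.
#' @export
percent_reduction <- function(vaccinated, control) {
  assert_finite_numeric(vaccinated, "vaccinated")
  assert_finite_numeric(control, "control")
  mc <- mean(control)
  if (mc <= 0) {
    stop_quantavax("control mean must be positive", "quantavax_degenerate_control")
  }
  ratio <- mean(vaccinated) / mc
  raw <- 100 * (1 - ratio)
  list(percent = round_half_away(max(0, raw)),
       raw_percent = raw,
       ratio = ratio)
}

#' One-sided Welch test for a reduction
#'
#' Welch's unequal-variance t-test with the one-sided alternative that the
#' vaccinated mean is below the control mean. When both arms have zero
#' variance and equal means the t statistic is undefined; p = 0.5 is
#' returned by convention (no evidence in either direction).
#'
#' @param control,vaccinated numeric vectors (>= 2 values each).
#' @param sided `"one"` (default, reduction alternative) or `"two"`.
#' @return p-value.
#' @export
welch_p <- function(control, vaccinated, sided = c("one", "two")) {
  sided <- match.arg(sided)
  assert_finite_numeric(control, "control")
  assert_finite_numeric(vaccinated, "vaccinated")
  if (length(control) < 2 || length(vaccinated) < 2) {
    stop_quantavax("each arm needs at least two observations", "quantavax_insufficient_data")
  }
  if (stats::sd(control) == 0 && stats::sd(vaccinated) == 0) {
    if (mean(control) == mean(vaccinated)) {
      return(if (sided == "one") 0.5 else 1.0)
    }
    # Degenerate but decisive: zero variance, unequal means.
    less <- mean(vaccinated) < mean(control)
    return(if (sided == "two") 0 else if (less) 0 else 1)
  }
  alt <- if (sided == "one") "less" else "two.sided"
  stats::t.test(vaccinated, control, alternative = alt, var.equal = FALSE)$p.value
}

metric_defs <- function() {
  data.frame(
    metric = c("DT", "DW", "DO", "DF"),
    column = c("nt", "wt", "pat", "pplo"),
    digits = c(0, 0, 0, 2),
    stringsAsFactors = FALSE
  )
}

#' Vaccine efficacy for one group of a trial
#'
#' Computes the four effect statistics (DT on tick number, DW on tick
#' weight, DO on oviposition, DF on fertility) with one-sided Welch tests,
#' then the gated efficacy E = 100 * (1 - CRT * CRO * CRF) where CRT, CRO
#' and CRF are the vaccinated/control mean ratios of tick number,
#' oviposition and fertility. A ratio enters the product only when its
#' Welch test is significant at `alpha`; otherwise it is replaced by
#' exactly 1. Tick weight (DW) is reported but never enters E.
#'
#' @param trial `trial_table` object.
#' @param group name of the vaccinated group.
#' @param sided `"one"` (default) or `"two"` sided gating tests.
#' @return object of class `efficacy_summary`: list with `group`,
#'   `effects` (data.frame of per-metric results), `crt`, `cro`, `crf`,
#'   `efficacy_pct` (unrounded) and `efficacy_display` (integer percent).
#' @export
vaccine_efficacy <- function(trial, group, sided = "one") {
  stopifnot(inherits(trial, "trial_table"))
  if (!group %in% names(trial$groups)) {
    stop_quantavax(sprintf("no group named '%s' in trial", group), "quantavax_value_error")
  }
  gdf <- trial$groups[[group]]
  cdf <- trial$control
  defs <- metric_defs()
  effects <- do.call(rbind, lapply(seq_len(nrow(defs)), function(i) {
    col <- defs$column[i]
    sv <- summarize_metric(gdf[[col]], digits = defs$digits[i])
    sc <- summarize_metric(cdf[[col]], digits = defs$digits[i])
    red <- percent_reduction(gdf[[col]], cdf[[col]])
    p <- welch_p(cdf[[col]], gdf[[col]], sided = sided)
    data.frame(metric = defs$metric[i],
               mean_v = sv$mean, sd_v = sv$sd,
               mean_c = sc$mean, sd_c = sc$sd,
               reduction_pct = red$percent,
               raw_reduction_pct = red$raw_percent,
               ratio = red$ratio,
               p_value = p,
               significant = p < trial$alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(effects) <- effects$metric
  gate <- function(metric) {
    row <- effects[metric, ]
    if (row$significant) row$ratio else 1
  }
  crt <- gate("DT")
  cro <- gate("DO")
  crf <- gate("DF")
  e <- 100 * (1 - crt * cro * crf)
  structure(
    list(group = group, effects = effects,
         crt = crt, cro = cro, crf = crf,
         alpha = trial$alpha, sided = sided,
         efficacy_pct = e,
         efficacy_display = round_half_away(e)),
    class = "efficacy_summary"
  )
}

#' Vaccine efficacy from component ratios
#'
#' Direct form E = 100 * (1 - crt * cro * crf) for already-computed
#' vaccinated/control ratios of tick number, oviposition and fertility
#' (all treated as significant).
#'
#' @param crt,cro,crf component ratios (> 0).
#' @return list with `efficacy_pct` and integer `efficacy_display`.
#' @export
efficacy_from_ratios <- function(crt, cro, crf) {
  for (v in list(crt, cro, crf)) assert_finite_numeric(v, "ratio")
  if (any(c(crt, cro, crf) < 0)) {
    stop_quantavax("component ratios must be non-negative", "quantavax_value_error")
  }
  e <- 100 * (1 - crt * cro * crf)
  list(efficacy_pct = e, efficacy_display = round_half_away(e))
}

#' @export
print.efficacy_summary <- function(x, ...) {
  cat(sprintf("Vaccine efficacy summary: group '%s' (alpha = %g, %s-sided Welch)\n",
              x$group, x$alpha, x$sided))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %s: %s%% reduction (p = %.3f%s)\n",
                eff$metric[i], eff$reduction_pct[i], eff$p_value[i],
                if (eff$significant[i]) ", significant" else ""))
  }
  cat(sprintf("  CRT = %.4f, CRO = %.4f, CRF = %.4f\n", x$crt, x$cro, x$crf))
  cat(sprintf("  E = %d%%\n", as.integer(x$efficacy_display)))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target transcript relative to a reference gene and a
#' calibrator sample: 2^-((Ct_target - Ct_reference)_sample -
#' (Ct_target - Ct_reference)_calibrator).
#'
#' @param sample,calibrator lists or vectors with elements `target_ct` and
#'   `reference_ct` (PCR cycle-threshold values).
#' @return fold change (1 = no change; 2 = one doubling).
#' @export
ddct_relative_expression <- function(sample, calibrator) {
  get_ct <- function(x, what) {
    ct <- c(target = as.numeric(x[["target_ct"]]),
            reference = as.numeric(x[["reference_ct"]]))
    if (any(!is.finite(ct)) || any(ct <= 0)) {
      stop_quantavax(sprintf("%s Ct values must be finite and positive", what),
                     "quantavax_value_error")
    }
    ct
  }
  s <- get_ct(sample, "sample")
  k <- get_ct(calibrator, "calibrator")
  ddct <- (s["target"] - s["reference"]) - (k["target"] - k["reference"])
  unname(2^(-ddct))
}
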