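#' One-way ANOVA between groups of predictions
#'
#' Classical one-way decomposition: `F = MS_between / MS_within` with
#' `df = (k - 1, n - k)` and the p-value from the upper tail of the F
#' distribution.  With two groups, `F` equals the square of the
#' pooled-variance two-sample t statistic.  Degenerate cases: zero
#' within-group variance with separated means gives `F = Inf`, `p = 0`;
#' zero between-group variance gives `F = 0`, `p = 1`.
#'
#' @param values numeric vector (e.g. predicted trait values).
#' @param groups group labels; at least two groups, each with at least
#'   two members.
#' @return An object of class `anova_result`: list with `f_stat`,
#'   `p_value`, `df`, `group_means` and `stars`
#'   (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05).
#' @export
#' @examples
#' anova_two_group(c(1, 2, 3, 5, 6, 7), rep(c(0, 90), each = 3))
anova_two_group <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups)) {
    stop_nirdecon("values and groups must have equal length",
                  "nirdecon_shape_error")
  }
  counts <- table(groups)
  if (length(counts) < 2) {
    stop_nirdecon("need at least two groups", "nirdecon_validation_error")
  }
  if (any(counts < 2)) {
    stop_nirdecon(sprintf("group '%s' has fewer than 2 members",
                          names(counts)[counts < 2][1]),
                  "nirdecon_validation_error")
  }
  n <- length(values)
  k <- length(counts)
  gm <- c(tapply(values, groups, mean))
  ss_between <- sum(as.vector(counts) * (gm - mean(values))^2)
  ss_within <- sum((values - gm[groups])^2)
  df <- c(k - 1, n - k)
  if (ss_within == 0) {
    f <- if (ss_between == 0) 0 else Inf
  } else {
    f <- (ss_between / df[1]) / (ss_within / df[2])
  }
  p <- if (is.infinite(f)) 0 else pf(f, df[1], df[2], lower.tail = FALSE)
  structure(list(f_stat = f, p_value = p, df = df,
                 group_means = gm, stars = significance_stars(p)),
            class = "anova_result")
}

#' Significance stars for a p-value
#'
#' @param p p-value in \[0, 1\].
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for
#'   p < 0.05, otherwise `""`.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g %s\n",
              x$df[1], x$df[2], x$f_stat, x$p_value, x$stars))
  cat("group means:",
      paste(sprintf("%s = %.4g", names(x$group_means), x$group_means),
            collapse = ", "), "\n")
  invisible(x)
}

new_evaluation_report <- function(pretreatment, response, cal_metrics,
                                  val_metrics, chosen_lv, rmsecv,
                                  n_variables, anova = NULL,
                                  scores = NULL, confounder = NULL) {
  structure(list(
    pretreatment = pretreatment, response = response,
    cal_metrics = cal_metrics, val_metrics = val_metrics,
    chosen_lv = chosen_lv, rmsecv = rmsecv, n_variables = n_variables,
    anova = anova, scores = scores, confounder = confounder
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "%-10s %-6s vars %4d  LVs %2d  cal r2 %.3f rmse %.3g  val r2 %.3f rmse %.3g\n",
    x$pretreatment, x$response, x$n_variables, x$chosen_lv,
    x$cal_metrics$r2, x$cal_metrics$rmse,
    x$val_metrics$r2, x$val_metrics$rmse))
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}

# Fit one response on pre-processed calibration data, choose the
# component count by LOO CV, and score both sets.
calibrate_response <- function(pp_cal, pp_val, response, max_lv) {
  y_cal <- pp_cal$meta[[response]]
  y_val <- pp_val$meta[[response]]
  if (anyNA(y_cal)) {
    stop_nirdecon(sprintf("response '%s' missing in calibration metadata",
                          response), "nirdecon_validation_error")
  }
  cv <- loo_cv(pp_cal$absorbance, y_cal, max_lv)
  model <- fit_pls1(pp_cal$absorbance, y_cal, cv$chosen_lv,
                    wavenumbers = pp_cal$wavenumbers)
  cal_pred <- predict(model, pp_cal$absorbance)
  val_pred <- predict(model, pp_val$absorbance)
  list(model = model, cv = cv,
       cal_metrics = fit_metrics(y_cal, cal_pred),
       val_metrics = safe_metrics(y_val, val_pred),
       cal_pred = cal_pred, val_pred = val_pred)
}

# metrics, or NULL when the reference values are missing or degenerate
# (e.g. a single-angle validation set)
safe_metrics <- function(y, y_hat) {
  if (is.null(y) || anyNA(y) || var(y) == 0) return(NULL)
  fit_metrics(y, y_hat)
}

#' Compare pre-treatments on a common calibration/validation split
#'
#' Fits one PLS1 model per pre-treatment variant (component count chosen
#' by leave-one-out CV on the calibration set) and reports calibration
#' and validation metrics for each -- the full-spectrum model comparison
#' table of the workflow.
#'
#' @param s_cal,s_val calibration and validation [spectra_set()]s on the
#'   same wavenumber axis.
#' @param response metadata column to predict.
#' @param methods list of [preprocess_config()]s or character method
#'   names (default: all six variants).
#' @param max_lv maximum candidate component count.
#' @return List of `evaluation_report`s, one per method.
#' @export
pretreatment_grid <- function(s_cal, s_val, response,
                              methods = c("raw", "snv", "sg1", "sg2",
                                          "snv_sg1", "snv_sg2"),
                              max_lv = 12) {
  if (!isTRUE(all.equal(as.numeric(s_cal$wavenumbers),
                        as.numeric(s_val$wavenumbers)))) {
    stop_nirdecon("calibration and validation axes differ",
                  "nirdecon_shape_error")
  }
  lapply(methods, function(mth) {
    cfg <- if (is.character(mth)) preprocess_config(mth) else mth
    pp_cal <- apply_pretreatment(s_cal, cfg)
    pp_val <- apply_pretreatment(s_val, cfg)
    fit <- calibrate_response(pp_cal, pp_val, response, max_lv)
    new_evaluation_report(
      pretreatment = cfg$method, response = response,
      cal_metrics = fit$cal_metrics, val_metrics = fit$val_metrics,
      chosen_lv = fit$cv$chosen_lv, rmsecv = fit$cv$rmsecv_per_lv,
      n_variables = length(pp_cal$wavenumbers),
      scores = score_table(fit$model, pp_cal))
  })
}

score_table <- function(model, pp) {
  sc <- pls_scores(model, pp$absorbance)
  data.frame(
    sample_id = pp$meta$sample_id,
    score1 = sc[, 1],
    score2 = if (ncol(sc) >= 2) sc[, 2] else NA_real_,
    angle = pp$meta$angle,
    stringsAsFactors = FALSE
  )
}

maybe_anova <- function(pred, angle) {
  counts <- table(angle[!is.na(angle)])
  if (length(counts) < 2 || any(counts < 2)) {
    warning("ANOVA omitted: need two angle groups with >= 2 members each")
    return(NULL)
  }
  keep <- !is.na(angle)
  anova_two_group(pred[keep], angle[keep])
}

#' Full-spectrum versus sMC-deconfounded calibration report
#'
#' Runs the complete confounder-removal workflow on a calibration /
#' validation pair: (1) pre-treat both sets; (2) fit full-spectrum PLS1
#' models for the trait and the confounder, with LOO-CV component
#' choice; (3) compute sMC profiles for both responses on the
#' calibration set only (never on validation, to avoid selection
#' leakage); (4) apply the dual-response selection rule; (5) refit both
#' responses on the selected wavenumbers.  Each trait report carries a
#' one-way ANOVA of its predictions between the two angle groups --
#' the grain-angle artifact check -- plus the first two score vectors.
#'
#' @param s_cal,s_val calibration and validation [spectra_set()]s (raw;
#'   pre-treatment is applied inside).
#' @param trait metadata column of the trait (default `"ec"`).
#' @param confounder metadata column of the confounder (default
#'   `"angle"`).
#' @param preprocess a [preprocess_config()] (default SNV + 1st
#'   derivative, the variant that performs best on solid-wood spectra).
#' @param alpha sMC significance level.
#' @param top_k optional cap on the number of selected wavenumbers.
#' @param max_lv maximum candidate component count.
#' @param anova_set compute the angle ANOVA on `"validation"` (default)
#'   or `"calibration"` predictions.
#' @return An object of class `deconfound_report`: list with `full` and
#'   `reduced` (`evaluation_report`s for the trait, each with a
#'   `confounder` sub-report), `selection`
#'   ([select_deconfounded()]) and `preprocess`.
#' @export
deconfound_report <- function(s_cal, s_val, trait = "ec",
                              confounder = "angle",
                              preprocess = preprocess_config("snv_sg1"),
                              alpha = 0.05, top_k = NULL, max_lv = 12,
                              anova_set = c("validation", "calibration")) {
  anova_set <- match.arg(anova_set)
  if (is.character(preprocess)) preprocess <- preprocess_config(preprocess)
  pp_cal <- apply_pretreatment(s_cal, preprocess)
  pp_val <- apply_pretreatment(s_val, preprocess)

  fit_t <- calibrate_response(pp_cal, pp_val, trait, max_lv)
  fit_c <- calibrate_response(pp_cal, pp_val, confounder, max_lv)

  prof_t <- smc(pp_cal$absorbance, pp_cal$meta[[trait]],
                fit_t$model, alpha)
  prof_c <- smc(pp_cal$absorbance, pp_cal$meta[[confounder]],
                fit_c$model, alpha)
  sel <- select_deconfounded(prof_t, prof_c, top_k = top_k)

  red_t <- refit_on_selection(pp_cal, sel, trait, max_lv)
  red_c <- refit_on_selection(pp_cal, sel, confounder, max_lv)
  X_val_sel <- pp_val$absorbance[, sel$selected, drop = FALSE]

  anova_for <- function(pred_cal, pred_val) {
    if (anova_set == "validation") {
      maybe_anova(pred_val, pp_val$meta[[confounder]])
    } else {
      maybe_anova(pred_cal, pp_cal$meta[[confounder]])
    }
  }
  val_y <- function(resp) pp_val$meta[[resp]]

  conf_summary <- function(fit, val_pred) {
    list(chosen_lv = fit$cv$chosen_lv,
         cal_metrics = fit$cal_metrics,
         val_metrics = safe_metrics(val_y(confounder), val_pred))
  }

  full <- new_evaluation_report(
    pretreatment = preprocess$method, response = trait,
    cal_metrics = fit_t$cal_metrics, val_metrics = fit_t$val_metrics,
    chosen_lv = fit_t$cv$chosen_lv, rmsecv = fit_t$cv$rmsecv_per_lv,
    n_variables = length(pp_cal$wavenumbers),
    anova = anova_for(fit_t$cal_pred, fit_t$val_pred),
    scores = score_table(fit_t$model, pp_cal),
    confounder = conf_summary(fit_c, fit_c$val_pred))

  red_cal_pred_t <- predict(red_t$model,
                            pp_cal$absorbance[, sel$selected, drop = FALSE])
  red_val_pred_t <- predict(red_t$model, X_val_sel)
  red_val_pred_c <- predict(red_c$model, X_val_sel)
  red_scores <- pls_scores(red_t$model,
                           pp_cal$absorbance[, sel$selected, drop = FALSE])
  reduced <- new_evaluation_report(
    pretreatment = preprocess$method, response = trait,
    cal_metrics = fit_metrics(pp_cal$meta[[trait]], red_cal_pred_t),
    val_metrics = safe_metrics(val_y(trait), red_val_pred_t),
    chosen_lv = red_t$cv$chosen_lv, rmsecv = red_t$cv$rmsecv_per_lv,
    n_variables = sel$n_selected,
    anova = anova_for(red_cal_pred_t, red_val_pred_t),
    scores = data.frame(
      sample_id = pp_cal$meta$sample_id,
      score1 = red_scores[, 1],
      score2 = if (ncol(red_scores) >= 2) red_scores[, 2] else NA_real_,
      angle = pp_cal$meta$angle, stringsAsFactors = FALSE),
    confounder = list(
      chosen_lv = red_c$cv$chosen_lv,
      cal_metrics = fit_metrics(
        pp_cal$meta[[confounder]],
        predict(red_c$model,
                pp_cal$absorbance[, sel$selected, drop = FALSE])),
      val_metrics = safe_metrics(val_y(confounder), red_val_pred_c)))

  structure(list(full = full, reduced = reduced, selection = sel,
                 preprocess = preprocess),
            class = "deconfound_report")
}

#' @export
print.deconfound_report <- function(x, ...) {
  cat(sprintf("deconfound_report (pre-treatment: %s)\n",
              x$preprocess$method))
  cat("full spectrum:\n  ")
  print(x$full)
  cat(sprintf("reduced to %d wavenumbers:\n  ", x$selection$n_selected))
  print(x$reduced)
  fr2 <- function(r) if (!is.null(r$confounder$val_metrics))
    r$confounder$val_metrics$r2 else NA_real_
  cat(sprintf("confounder validation r2: full %.3f -> reduced %.3f\n",
              fr2(x$full), fr2(x$reduced)))
  invisible(x)
}
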