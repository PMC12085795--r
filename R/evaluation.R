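# Per-sex agreement battery between predicted and reference bone ages:
# MSE (and RMSE), MAE, Pearson r, ICC, Bland-Altman 95% limits of
# agreement, and the raw error range. All metrics operate at subject level
# (one pair per subject), on differences oriented predicted - reference.

#' Paired predicted / reference bone ages
#'
#' @param subject_id Character vector of subject ids.
#' @param reference Reference bone ages in years.
#' @param predicted Predicted bone ages in years.
#' @param sex Sex per subject (`"M"`/`"F"`), optional.
#' @return data.frame of class `paired_ages`.
#' @export
paired_ages <- function(subject_id, reference, predicted, sex = NA) {
  if (length(reference) != length(predicted) ||
      length(subject_id) != length(reference))
    skel_stop("subject_id, reference and predicted must have equal length",
              "skelage_domain_error")
  if (!all(is.finite(reference)) || !all(is.finite(predicted)))
    skel_stop("ages must be finite", "skelage_domain_error")
  structure(data.frame(subject_id = subject_id, reference = reference,
                       predicted = predicted, sex = sex,
                       stringsAsFactors = FALSE),
            class = c("paired_ages", "data.frame"))
}

.check_pairs <- function(pairs, n_min, what) {
  if (nrow(pairs) < n_min)
    skel_stop(sprintf("%s needs >= %d pairs, got %d", what, n_min,
                      nrow(pairs)), "skelage_domain_error")
  invisible(pairs)
}

#' Mean squared / absolute error
#'
#' @param pairs A [paired_ages()] table.
#' @return `ba_mse`: mean of squared differences (years^2); `ba_rmse`:
#'   its square root (years); `ba_mae`: mean absolute difference (years).
#' @export
ba_mse <- function(pairs) {
  .check_pairs(pairs, 1, "MSE")
  mean((pairs$predicted - pairs$reference)^2)
}

#' @rdname ba_mse
#' @export
ba_rmse <- function(pairs) sqrt(ba_mse(pairs))

#' @rdname ba_mse
#' @export
ba_mae <- function(pairs) {
  .check_pairs(pairs, 1, "MAE")
  mean(abs(pairs$predicted - pairs$reference))
}

#' Pearson correlation between predicted and reference ages
#'
#' @param pairs A [paired_ages()] table (n >= 3, both series with nonzero
#'   variance).
#' @return List with `r` and two-sided `p_value` (t transform).
#' @export
ba_pearson <- function(pairs) {
  .check_pairs(pairs, 3, "Pearson r")
  if (stats::sd(pairs$reference) < 1e-12 || stats::sd(pairs$predicted) < 1e-12)
    skel_stop("Pearson r undefined: a series has zero variance",
              "skelage_domain_error")
  ct <- stats::cor.test(pairs$predicted, pairs$reference, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Intraclass correlation coefficient
#'
#' Agreement between the reference and predicted series viewed as two
#' "raters" of n subjects. The default form is the two-way random-effects,
#' absolute-agreement, single-measure ICC(2,1), computed from the two-way
#' ANOVA mean squares (rows = subjects, columns = raters, k = 2):
#' `(MSR - MSE) / (MSR + MSE + (2/n) (MSC - MSE))`. ICC(3,1) (consistency,
#' mixed effects) is `(MSR - MSE) / (MSR + MSE)`.
#'
#' @param pairs A [paired_ages()] table (n >= 3).
#' @param form `"icc2_1"` (default) or `"icc3_1"`.
#' @return ICC estimate (scalar <= 1).
#' @export
ba_icc <- function(pairs, form = c("icc2_1", "icc3_1")) {
  form <- match.arg(form)
  .check_pairs(pairs, 3, "ICC")
  Y <- cbind(pairs$reference, pairs$predicted)
  n <- nrow(Y); k <- 2
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ss_total <- sum((Y - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  if (form == "icc2_1")
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  else
    (msr - mse) / (msr + (k - 1) * mse)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = predicted - reference`; returns the mean difference
#' and `mean(d) -/+ multiplier * sd(d)` (sd with n-1 denominator). The
#' default multiplier 1.96 gives the normal-theory 95% interval.
#'
#' @param pairs A [paired_ages()] table (n >= 2).
#' @param multiplier SD multiplier; default 1.96.
#' @return List with `mean_diff`, `loa_low`, `loa_high` (years).
#' @export
ba_loa <- function(pairs, multiplier = 1.96) {
  .check_pairs(pairs, 2, "limits of agreement")
  d <- pairs$predicted - pairs$reference
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - multiplier * s,
       loa_high = m + multiplier * s)
}

#' Range of estimation errors
#'
#' @param pairs A [paired_ages()] table (n >= 1).
#' @return Length-2 vector `(min, max)` of `predicted - reference`.
#' @export
ba_error_range <- function(pairs) {
  .check_pairs(pairs, 1, "error range")
  d <- pairs$predicted - pairs$reference
  c(min = min(d), max = max(d))
}

# compute one sex's metric block; metrics whose preconditions fail are
# reported as NA with the failure message kept alongside
.metric_block <- function(pairs, icc_form, loa_multiplier) {
  res <- list(n = nrow(pairs))
  notes <- character(0)
  grab <- function(name, fun) {
    v <- tryCatch(fun(), skelage_error = function(e) {
      notes[[name]] <<- conditionMessage(e)
      NA_real_
    })
    res[names(v) %||% name] <<- v
  }
  grab("mse", function() ba_mse(pairs))
  grab("rmse", function() ba_rmse(pairs))
  grab("mae", function() ba_mae(pairs))
  grab("pearson_r", function() ba_pearson(pairs)$r)
  grab("pearson_p", function() ba_pearson(pairs)$p_value)
  grab("icc", function() ba_icc(pairs, icc_form))
  grab("loa", function() ba_loa(pairs, loa_multiplier))
  grab("error_range", function() {
    er <- ba_error_range(pairs)
    list(error_min = er[["min"]], error_max = er[["max"]])
  })
  res$notes <- notes
  res
}

#' Evaluate trained models on one partition
#'
#' Builds per-sex [paired_ages()] from per-subject aggregated predictions
#' on the requested partition and computes the full agreement battery.
#' Metrics whose preconditions fail on a degenerate partition (e.g. n < 3
#' for r/ICC) are reported as `NA` with a note; the others are computed.
#'
#' @param models Named list `list(M = <sex_model>, F = <sex_model>)`.
#' @param features `feature_table` of the cohort.
#' @param split `split_assignment` from [split_cohort()].
#' @param partition `"validation"` (default), `"test"`, or `"train"`.
#' @param icc_form,loa_multiplier Passed to [ba_icc()] / [ba_loa()].
#' @return Object of class `eval_report`: per sex the metric block and the
#'   underlying `paired_ages`.
#' @export
evaluate_model <- function(models, features, split,
                           partition = c("validation", "test", "train"),
                           icc_form = "icc2_1", loa_multiplier = 1.96) {
  partition <- match.arg(partition)
  out <- list(partition = partition, icc_form = icc_form,
              loa_multiplier = loa_multiplier)
  for (sx in c("M", "F")) {
    model <- models[[sx]]
    if (is.null(model))
      skel_stop(sprintf("missing model for sex '%s'", sx),
                "skelage_domain_error")
    part <- split$partition[match(features$subject_id, split$subject_id)]
    rows <- features$sex == sx & !is.na(part) & part == partition
    sub <- features[rows, , drop = FALSE]
    if (nrow(sub) == 0)
      skel_stop(sprintf("partition '%s' has no subjects of sex '%s'",
                        partition, sx), "skelage_domain_error")
    ids <- unique(sub$subject_id)
    Xall <- .feature_matrix(sub)
    preds <- vapply(ids, function(id) {
      predict_bone_age(model, Xall[sub$subject_id == id, , drop = FALSE],
                       sex = sx)
    }, numeric(1))
    refs <- sub$reference_age[match(ids, sub$subject_id)]
    pairs <- paired_ages(ids, refs, unname(preds), sx)
    out[[sx]] <- c(.metric_block(pairs, icc_form, loa_multiplier),
                   list(pairs = pairs))
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report on '%s' partition (%s)\n", x$partition, x$icc_form))
  for (sx in c("M", "F")) {
    b <- x[[sx]]
    cat(sprintf(
      "  %s (n=%d): MSE %.3f  RMSE %.3f  MAE %.3f  r %.3f  ICC %.3f  LoA [%.2f, %.2f]  range [%.2f, %.2f]\n",
      sx, b$n, b$mse, b$rmse, b$mae, b$pearson_r, b$icc,
      b$loa_low, b$loa_high, b$error_min, b$error_max))
  }
  invisible(x)
}

# flatten a report to sex,metric,value rows
.report_rows <- function(report) {
  keep <- c("n", "mse", "rmse", "mae", "pearson_r", "pearson_p", "icc",
            "mean_diff", "loa_low", "loa_high", "error_min", "error_max")
  do.call(rbind, lapply(c("M", "F"), function(sx) {
    b <- report[[sx]]
    data.frame(sex = sx, metric = keep,
               value = vapply(keep, function(k)
                 as.numeric(b[[k]] %||% NA_real_), numeric(1)),
               stringsAsFactors = FALSE)
  }))
}

#' Write an evaluation report to disk
#'
#' Writes `report.json`, `report.csv` (`sex,metric,value`), and two PNG
#' figures: a predicted-vs-reference scatter and per-subject paired bars
#' of reference vs predicted age.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @param figures Write the PNG figures too? Default TRUE.
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir, figures = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- .report_rows(report)
  json <- list(partition = report$partition, icc_form = report$icc_form,
               loa_multiplier = report$loa_multiplier)
  for (sx in c("M", "F")) {
    b <- report[[sx]]
    json[[sx]] <- b[setdiff(names(b), "pairs")]
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  df <- rows
  df$value <- sprintf("%.12g", df$value)
  write.csv(df, file.path(dir, "report.csv"), row.names = FALSE,
            quote = FALSE)
  if (figures) {
    plot_agreement(report, file.path(dir, "scatter.png"))
    plot_paired_bars(report, file.path(dir, "paired_bars.png"))
  }
  invisible(dir)
}

#' Agreement figures
#'
#' `plot_agreement`: per-sex scatter of predicted vs reference age with
#' the identity line. `plot_paired_bars`: side-by-side bars of reference
#' and predicted age per subject (subjects ordered by reference age).
#'
#' @param report An `eval_report`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_agreement <- function(report, path) {
  grDevices::png(path, width = 900, height = 480)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  for (sx in c("M", "F")) {
    p <- report[[sx]]$pairs
    plot(p$reference, p$predicted, xlim = c(0, 19), ylim = c(0, 19),
         xlab = "Reference bone age (y)", ylab = "Predicted bone age (y)",
         main = sprintf("%s (n=%d, r=%.2f)", ifelse(sx == "M", "Boys", "Girls"),
                        report[[sx]]$n, report[[sx]]$pearson_r),
         pch = 19, col = "#00000080")
    graphics::abline(0, 1, col = "red")
  }
  grDevices::dev.off()
  invisible(path)
}

#' @rdname plot_agreement
#' @export
plot_paired_bars <- function(report, path) {
  grDevices::png(path, width = 1000, height = 560)
  graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  for (sx in c("M", "F")) {
    p <- report[[sx]]$pairs
    p <- p[order(p$reference), ]
    m <- t(as.matrix(p[, c("reference", "predicted")]))
    graphics::barplot(m, beside = TRUE, col = c("steelblue", "goldenrod"),
                      border = NA, names.arg = rep("", ncol(m)),
                      ylab = "Bone age (y)",
                      main = ifelse(sx == "M", "Boys", "Girls"))
    graphics::legend("topleft", c("Reference", "Predicted"), bty = "n",
                     fill = c("steelblue", "goldenrod"))
  }
  grDevices::dev.off()
  invisible(path)
}
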