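#' Validate a cohort table
#'
#' A cohort table is a data frame with one row per (subject, site,
#' wavelength, spatial frequency): columns `subject_id`, `group`
#' (`"patient"`/`"control"`), `site`, `wavelength`, `spatial_frequency`,
#' `mean_rd` (>= 0), `mrss` (integer 0-3, NA allowed), and optionally
#' `race` for stratified analyses.
#'
#' @param df data frame to validate.
#' @return The validated data frame (invisibly classed `cohort_table`).
#' @export
cohort_table <- function(df) {
  need <- c("subject_id", "group", "site", "wavelength", "spatial_frequency",
            "mean_rd", "mrss")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(df$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  if (any(df$mean_rd < 0, na.rm = TRUE)) stop("mean_rd must be >= 0")
  ok <- is.na(df$mrss) | df$mrss %in% 0:3
  if (!all(ok)) stop("mrss must be an integer in 0..3 or NA")
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Threshold-classifier ROC curve and AUC
#'
#' Builds the ROC curve of the binary classifier that labels an
#' observation "patient" when its value falls on the patient side of a
#' sliding threshold, and computes the area under it. Under the default
#' orientation (`"lower"`, patients have the lower reflectance) the AUC
#' equals the Mann-Whitney pair statistic: the fraction of
#' (patient, control) pairs with `patient < control`, ties counted 1/2.
#' The stored curve integrates (trapezoid) to the same value.
#'
#' @param patient_values,control_values numeric vectors (both nonempty).
#' @param orientation `"lower"` (lower value indicates patient) or
#'   `"higher"`.
#' @return An object of class `roc_result`: `auc`, `thresholds`,
#'   `sensitivities`, `specificities`, `n_patient`, `n_control`,
#'   `orientation`.
#' @export
#' @examples
#' roc_auc(c(0.2, 0.35), c(0.3, 0.4))$auc # 0.75
roc_auc <- function(patient_values, control_values,
                    orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (!length(patient_values) || !length(control_values))
    stop("both groups must be nonempty")
  # score such that larger = more patient-like
  sp <- if (orientation == "lower") -patient_values else patient_values
  sc <- if (orientation == "lower") -control_values else control_values
  np <- length(sp); nc <- length(sc)
  r <- rank(c(sp, sc)) # midranks handle ties
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nc)
  # curve: classify patient when score >= t, thresholds from +Inf down
  cuts <- sort(unique(c(sp, sc)), decreasing = TRUE)
  sens <- c(0, vapply(cuts, function(t) mean(sp >= t), numeric(1)))
  spec <- c(1, vapply(cuts, function(t) mean(sc < t), numeric(1)))
  thr <- c(Inf, cuts)
  if (orientation == "lower") thr <- -thr
  structure(list(auc = auc, thresholds = thr,
                 sensitivities = sens, specificities = spec,
                 n_patient = np, n_control = nc, orientation = orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d patients vs %d controls, %s-is-patient)\n",
              x$auc, x$n_patient, x$n_control, x$orientation))
  invisible(x)
}

# placement values of one scorer: V10 (per patient) and V01 (per control)
.placements <- function(sp, sc) {
  v10 <- vapply(sp, function(x) mean((x > sc) + 0.5 * (x == sc)), numeric(1))
  v01 <- vapply(sc, function(y) mean((sp > y) + 0.5 * (sp == y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scorings of the same observations (a paired
#' design, e.g. the same cohort measured at two wavelength/frequency
#' settings) using the placement-value covariance estimator: per-group
#' structural components give the variance of each AUC and their
#' covariance, and the AUC difference is referred to a standard normal.
#'
#' @param values_a,values_b the two per-observation scores, same length
#'   and order.
#' @param is_patient logical vector of the shared labels.
#' @param orientation as in [roc_auc()].
#' @return List with `auc_a`, `auc_b`, `z`, `p` (two-sided). A degenerate
#'   zero-variance difference returns `z = 0`, `p = 1` with a warning.
#' @export
delong_test <- function(values_a, values_b, is_patient,
                        orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (length(values_a) != length(values_b) ||
      length(values_a) != length(is_patient))
    stop("values_a, values_b and is_patient must be aligned (paired design)")
  sgn <- if (orientation == "lower") -1 else 1
  pa <- .placements(sgn * values_a[is_patient], sgn * values_a[!is_patient])
  pb <- .placements(sgn * values_b[is_patient], sgn * values_b[!is_patient])
  m <- sum(is_patient); n <- sum(!is_patient)
  if (m < 2 || n < 2) stop("need at least two observations per group")
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= .Machine$double.eps) {
    if (abs(pa$auc - pb$auc) > 1e-12)
      warning("zero variance estimate for a nonzero AUC difference")
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1))
  }
  z <- (pa$auc - pb$auc) / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)))
}

#' Spearman correlation of total Rd with total mRSS
#'
#' For one (wavelength, spatial frequency): per subject, sums the six
#' site-mean reflectances into a total Rd and the six site mRSS scores
#' into a total mRSS, then computes Spearman's rank correlation (average
#' ranks on ties). Subjects without a complete set of sites (or without
#' scores) are excluded and counted.
#'
#' @param cohort a [cohort_table()].
#' @param wavelength,spatial_frequency the grid cell to evaluate.
#' @param n_sites number of sites that constitutes a complete subject.
#' @param patients_only restrict to the patient group (the clinical
#'   convention: severity grading only spans the disease group; controls,
#'   which score 0 everywhere, would otherwise inflate the correlation).
#' @return List with `rho`, `n_subjects`, `n_excluded`.
#' @export
spearman_total <- function(cohort, wavelength, spatial_frequency,
                           n_sites = 6, patients_only = TRUE) {
  cohort <- cohort_table(cohort)
  if (patients_only)
    cohort <- cohort[cohort$group == "patient", , drop = FALSE]
  d <- cohort[cohort$wavelength == wavelength &
                cohort$spatial_frequency == spatial_frequency &
                !is.na(cohort$mrss) & !is.na(cohort$mean_rd), , drop = FALSE]
  spl <- split(d, d$subject_id, drop = TRUE)
  complete <- vapply(spl, function(s) length(unique(s$site)) >= n_sites, logical(1))
  n_excl <- sum(!complete)
  if (n_excl > 0)
    message(n_excl, " subject(s) excluded for incomplete site coverage")
  spl <- spl[complete]
  if (length(spl) < 3)
    stop("need at least 3 subjects with complete site coverage")
  tot_rd <- vapply(spl, function(s) sum(s$mean_rd), numeric(1))
  tot_mrss <- vapply(spl, function(s) sum(s$mrss), numeric(1))
  rho <- cor(rank(tot_rd), rank(tot_mrss))
  list(rho = rho, n_subjects = length(spl), n_excluded = n_excl)
}

#' Wilcoxon rank-sum test between patient and control values
#'
#' Two-sided rank-sum test; exact enumeration when the combined sample is
#' small (n <= 12) and untied, normal approximation with tie correction
#' otherwise.
#'
#' @param patient_values,control_values numeric vectors (both nonempty).
#' @return List with `U` (the Mann-Whitney statistic of the patient
#'   group) and `p`.
#' @export
rank_sum_test <- function(patient_values, control_values) {
  if (!length(patient_values) || !length(control_values))
    stop("both groups must be nonempty")
  combined <- c(patient_values, control_values)
  exact <- (length(combined) <= 12) && !anyDuplicated(combined)
  ht <- wilcox.test(patient_values, control_values, exact = exact,
                    correct = !exact)
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Rank-sum p-values over the wavelength x spatial-frequency grid
#'
#' Runs [rank_sum_test()] on the site-level patient vs control values of
#' every grid cell. No multiple-testing correction is applied by default
#' (mirroring the single-cell reporting convention); `adjust =
#' "bonferroni"` multiplies by the number of cells tested.
#'
#' @param cohort a [cohort_table()].
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Matrix of two-sided p-values (wavelength rows, frequency
#'   columns).
#' @export
rank_sum_grid <- function(cohort, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  cohort <- cohort_table(cohort)
  wls <- sort(unique(cohort$wavelength))
  fxs <- sort(unique(cohort$spatial_frequency))
  p <- matrix(NA_real_, length(wls), length(fxs), dimnames = list(wls, fxs))
  for (i in seq_along(wls)) for (j in seq_along(fxs)) {
    d <- cohort[cohort$wavelength == wls[i] &
                  cohort$spatial_frequency == fxs[j], , drop = FALSE]
    pv <- d$mean_rd[d$group == "patient"]
    cv <- d$mean_rd[d$group == "control"]
    if (length(pv) && length(cv)) p[i, j] <- rank_sum_test(pv, cv)$p
  }
  if (adjust == "bonferroni") p <- pmin(1, p * sum(!is.na(p)))
  p
}

#' Statistic heatmap over the wavelength x spatial-frequency grid
#'
#' Fills the grid by calling [roc_auc()] on site-level observations
#' (`statistic = "auc"`) or [spearman_total()] on subject-level totals
#' (`statistic = "spearman"`) for every (wavelength, fx) present in the
#' cohort, optionally restricted to one self-reported race stratum.
#' Missing cells are NA. The argmax is taken on the absolute value of the
#' statistic.
#'
#' @param cohort a [cohort_table()].
#' @param statistic `"auc"` or `"spearman"`.
#' @param stratum `"all"` or a value of the cohort's `race` column.
#' @param orientation passed to [roc_auc()].
#' @param n_sites complete-subject site count for the Spearman branch.
#' @return An object of class `heatmap_grid`: `values` (wavelength rows x
#'   frequency columns), `statistic`, `stratum`, and `argmax` (data frame
#'   of the maximizing cell(s)).
#' @export
build_heatmaps <- function(cohort, statistic = c("auc", "spearman"),
                           stratum = "all", orientation = "lower",
                           n_sites = 6) {
  statistic <- match.arg(statistic)
  cohort <- cohort_table(cohort)
  if (!identical(stratum, "all")) {
    if (is.null(cohort$race)) stop("cohort has no 'race' column to stratify on")
    cohort <- cohort[cohort$race == stratum, , drop = FALSE]
    if (!nrow(cohort)) stop("stratum '", stratum, "' selects no rows")
  }
  wls <- sort(unique(cohort$wavelength))
  fxs <- sort(unique(cohort$spatial_frequency))
  vals <- matrix(NA_real_, length(wls), length(fxs),
                 dimnames = list(wls, fxs))
  for (i in seq_along(wls)) for (j in seq_along(fxs)) {
    d <- cohort[cohort$wavelength == wls[i] &
                  cohort$spatial_frequency == fxs[j], , drop = FALSE]
    if (!nrow(d)) next
    vals[i, j] <- if (statistic == "auc") {
      p <- d$mean_rd[d$group == "patient"]
      c0 <- d$mean_rd[d$group == "control"]
      if (length(p) && length(c0)) roc_auc(p, c0, orientation)$auc else NA_real_
    } else {
      res <- tryCatch(suppressMessages(
        spearman_total(d, wls[i], fxs[j], n_sites = n_sites)),
        error = function(e) NULL)
      if (is.null(res)) NA_real_ else res$rho
    }
  }
  best <- which(abs(vals) == max(abs(vals), na.rm = TRUE), arr.ind = TRUE)
  argmax <- data.frame(wavelength = wls[best[, 1]],
                       spatial_frequency = fxs[best[, 2]],
                       value = vals[best])
  structure(list(values = vals, statistic = statistic, stratum = stratum,
                 argmax = argmax),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat("<heatmap_grid> ", x$statistic, " (stratum: ", x$stratum, ")\n", sep = "")
  print(round(x$values, 3))
  cat("argmax:\n"); print(x$argmax, row.names = FALSE)
  invisible(x)
}

#' Heatmap figure for a statistic grid
#'
#' Tile plot of the wavelength x spatial-frequency statistic grid
#' (requires ggplot2).
#'
#' @param grid a [build_heatmaps()] result.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_heatmap() requires ggplot2")
  df <- expand.grid(wavelength = as.numeric(rownames(grid$values)),
                    fx = as.numeric(colnames(grid$values)))
  df$value <- as.vector(grid$values)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(fx),
                                   y = factor(wavelength),
                                   fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", value)),
                       size = 3) +
    ggplot2::labs(x = expression(f[x] ~ (mm^-1)), y = "wavelength (nm)",
                  fill = grid$statistic) +
    ggplot2::theme_minimal()
}
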