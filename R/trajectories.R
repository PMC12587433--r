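# Longitudinal and lifespan analyses. All models stack the two TIV methods
# into long format (two rows per scan) with eTIV as the reference method,
# so "method" effects read as sbTIV - eTIV.

#' Stack eTIV and sbTIV into long format
#'
#' @param table a scan table with both methods present per row.
#' @return a data.frame with two rows per scan: `value_mm3` and a `method`
#'   factor (`etiv` reference, then `sbtiv`), other columns carried along.
#' @export
stack_methods <- function(table) {
  tab <- as.data.frame(table)
  if (anyNA(tab$etiv_mm3) || anyNA(tab$sbtiv_mm3)) {
    stop("both methods must be present on every scan to stack", call. = FALSE)
  }
  long <- rbind(
    transform(tab, value_mm3 = etiv_mm3, method = "etiv"),
    transform(tab, value_mm3 = sbtiv_mm3, method = "sbtiv"))
  long$method <- factor(long$method, levels = c("etiv", "sbtiv"))
  rownames(long) <- NULL
  long
}

#' Longitudinal method-comparison mixed model
#'
#' Fits, on the stacked two-rows-per-scan data,
#' `value ~ time * sex * method + (1 | participant)` with all two- and
#' three-way interactions. The time variable is age at scan for the
#' adolescent cohort and the gap (years) from each participant's initial
#' scan for the adult cohort, where true TIV is developmentally stable and
#' any systematic gap effect is measurement artefact.
#'
#' @param table a scan table with both methods and `scan_order`.
#' @param cohort `"adolescent"` or `"adult"`.
#' @return an [fit_lmm()] result; the time column is named `time_years` in
#'   the coefficient table.
#' @export
fit_longitudinal_model <- function(table, cohort = c("adolescent", "adult")) {
  cohort <- match.arg(cohort)
  tab <- as.data.frame(table)
  if (anyNA(tab$etiv_mm3) && anyNA(tab$sbtiv_mm3)) {
    stop("both methods are required on every scan", call. = FALSE)
  }
  n_scans <- table(tab$participant_id)
  if (all(n_scans < 2L)) {
    stop("no participant has 2 or more scans; longitudinal model needs",
         " repeated measures", call. = FALSE)
  }
  if (cohort == "adolescent") {
    tab$time_years <- tab$age_at_scan
  } else {
    first_age <- tapply(tab$age_at_scan, tab$participant_id, min)
    tab$time_years <- tab$age_at_scan - first_age[as.character(tab$participant_id)]
    if (any(tab$time_years < 0)) stop("negative gap from initial scan",
                                      call. = FALSE)
  }
  long <- stack_methods(tab)
  long$sex_female <- as.numeric(long$sex == "female")
  fit_lmm(long, model_spec(
    "value_mm3",
    c("time_years", "sex_female", "method",
      "time_years:sex_female", "time_years:method", "sex_female:method",
      "time_years:sex_female:method"),
    "participant_id"))
}

#' Paired preprocessing-by-method comparison
#'
#' For scans measured under two preprocessing pipelines and both TIV
#' methods, fits `value ~ preprocessing * method + (1 | participant)`
#' (`response = "value"`), or the deviation variant
#' `deviation ~ preprocessing + (1 | participant)`
#' (`response = "deviation"`).
#'
#' @param table a data.frame with `participant_id`, a two-level
#'   `preprocessing` column, and `etiv_mm3`/`sbtiv_mm3` per row.
#' @param response `"value"` or `"deviation"`.
#' @return an [fit_lmm()] result.
#' @export
paired_method_comparison <- function(table,
                                     response = c("value", "deviation")) {
  response <- match.arg(response)
  tab <- as.data.frame(table)
  if (!"preprocessing" %in% names(tab)) {
    stop("table needs a 'preprocessing' column", call. = FALSE)
  }
  levs <- unique(tab$preprocessing)
  if (length(levs) != 2L) {
    stop("preprocessing must have exactly 2 levels, got: ",
         paste(levs, collapse = ", "), call. = FALSE)
  }
  per <- table(tab$participant_id, tab$preprocessing)
  incomplete <- rownames(per)[apply(per, 1, function(r) any(r == 0L))]
  if (length(incomplete) > 0L) {
    stop("unpaired design; participant(s) missing a preprocessing cell: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  if (response == "value") {
    long <- stack_methods(tab)
    fit_lmm(long, model_spec(
      "value_mm3", c("preprocessing", "method", "preprocessing:method"),
      "participant_id"))
  } else {
    tab <- compute_deviation(tab)
    fit_lmm(tab, model_spec("deviation_mm3", "preprocessing",
                            "participant_id"))
  }
}

#' Spline-based lifespan trajectory
#'
#' Smooth lifespan trajectory of a TIV method: sex-specific cubic B-spline
#' bases for age (fixed interior knots at age quantiles, no smoothness
#' penalty) fitted inside the mixed-model engine with a participant random
#' intercept. A penalty-free fixed basis trades some smoothness control for
#' a much simpler and fully deterministic fit.
#'
#' @param table a scan table; needs an age span of at least 10 years and at
#'   least 100 scans.
#' @param method `"etiv"` or `"sbtiv"` (a harmonized prefix also works).
#' @param n_knots number of interior knots (default 8).
#' @param age_grid ages at which to evaluate the fitted curves (default: 81
#'   points across the observed range).
#' @return a list of class `"smooth_trajectory"`: `grid` (age, sex, fitted,
#'   se), `fit` (the [fit_lmm()] result), `knots`.
#' @export
fit_smooth_trajectory <- function(table, method = "sbtiv", n_knots = 8,
                                  age_grid = NULL) {
  tab <- as.data.frame(table)
  value_col <- paste0(method, "_mm3")
  stopifnot(value_col %in% names(tab))
  tab <- tab[!is.na(tab[[value_col]]), , drop = FALSE]
  span <- diff(range(tab$age_at_scan))
  if (!is.finite(span) || span < 10) {
    stop("degenerate age range: need a span of at least 10 years",
         call. = FALSE)
  }
  if (nrow(tab) < 100L) stop("need at least 100 scans", call. = FALSE)
  knots <- unique(quantile(tab$age_at_scan,
                           probs = seq_len(n_knots) / (n_knots + 1)))
  boundary <- range(tab$age_at_scan)
  basis <- splines::bs(tab$age_at_scan, knots = knots, degree = 3,
                       Boundary.knots = boundary)
  bn <- paste0("age_b", seq_len(ncol(basis)))
  for (j in seq_len(ncol(basis))) tab[[bn[j]]] <- basis[, j]
  tab$sex_female <- as.numeric(tab$sex == "female")
  terms <- c("sex_female", bn, paste0("sex_female:", bn))
  fit <- fit_lmm(tab, model_spec(value_col, terms, "participant_id"))

  if (is.null(age_grid)) {
    age_grid <- seq(boundary[1], boundary[2], length.out = 81)
  }
  gb <- predict(basis, age_grid)
  coef_names <- fit$coefficients$term
  grid <- do.call(rbind, lapply(c(0, 1), function(sf) {
    ctr <- matrix(0, nrow = length(age_grid), ncol = length(coef_names),
                  dimnames = list(NULL, coef_names))
    ctr[, "(Intercept)"] <- 1
    ctr[, "sex_female"] <- sf
    for (j in seq_len(ncol(gb))) {
      ctr[, bn[j]] <- gb[, j]
      ctr[, paste0("sex_female:", bn[j])] <- sf * gb[, j]
    }
    fitted <- drop(ctr %*% fit$coefficients$B)
    se <- sqrt(rowSums((ctr %*% fit$vcov_fixed) * ctr))
    data.frame(age = age_grid, sex = if (sf == 1) "female" else "male",
               fitted = fitted, se = se, stringsAsFactors = FALSE)
  }))
  structure(list(grid = grid, fit = fit, knots = knots,
                 method = method),
            class = "smooth_trajectory")
}
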