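# Method-agreement analytics: deviation and absolute error of eTIV against
# sbTIV as the reference, the small-eTIV failure split, the per-procedure
# summary table, factor models for ICC/deviation, body-size correlations,
# and the resampled three-scan ICC(2,k) reliability procedure.

#' Add deviation and absolute-error columns
#'
#' Deviation is eTIV - sbTIV; absolute error is |eTIV - sbTIV|; both mm^3.
#'
#' @param table a scan table with both methods present per row.
#' @return the table with `deviation_mm3` and `abs_error_mm3` added.
#' @export
compute_deviation <- function(table) {
  tab <- as.data.frame(table)
  if (anyNA(tab$etiv_mm3) || anyNA(tab$sbtiv_mm3)) {
    stop("both etiv_mm3 and sbtiv_mm3 must be present on every row",
         call. = FALSE)
  }
  tab$deviation_mm3 <- tab$etiv_mm3 - tab$sbtiv_mm3
  tab$abs_error_mm3 <- abs(tab$deviation_mm3)
  tab
}

#' Split a scan table at the small-eTIV threshold
#'
#' The registration-based method occasionally fails by gross
#' underestimation; scans at or below the threshold form the "small"
#' subgroup, scans strictly above it the "non-small" subgroup (the
#' non-small group is defined by *more than* the threshold, so a row
#' exactly at the threshold is small).
#'
#' @param table a scan table with `etiv_mm3` present.
#' @param threshold split point in mm^3 (default 1,200,000).
#' @return a list with elements `small` and `nonsmall`; the two partitions
#'   are disjoint and exhaustive.
#' @export
split_small_etiv <- function(table, threshold = 1200000) {
  tab <- as.data.frame(table)
  if (anyNA(tab$etiv_mm3)) {
    stop("etiv_mm3 must be present on every row", call. = FALSE)
  }
  small <- tab$etiv_mm3 <= threshold
  list(small = tab[small, , drop = FALSE],
       nonsmall = tab[!small, , drop = FALSE])
}

.summary_row <- function(procedure_id, tab, threshold) {
  n <- nrow(tab)
  icc <- function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    tryCatch(icc_single(cbind(d$etiv_mm3, d$sbtiv_mm3))$estimate,
             error = function(e) NA_real_)
  }
  ns <- tab[tab$etiv_mm3 > threshold, , drop = FALSE]
  data.frame(
    procedure_id = procedure_id, n = n,
    icc_2_1 = icc(tab), icc_2_1_nonsmall = icc(ns),
    mean_etiv = mean(tab$etiv_mm3), sd_etiv = sd(tab$etiv_mm3),
    mean_sbtiv = mean(tab$sbtiv_mm3), sd_sbtiv = sd(tab$sbtiv_mm3),
    mean_deviation = mean(tab$deviation_mm3),
    sd_deviation = sd(tab$deviation_mm3),
    mean_abs_error = mean(tab$abs_error_mm3),
    sd_abs_error = sd(tab$abs_error_mm3),
    stringsAsFactors = FALSE)
}

#' Per-procedure agreement summary table
#'
#' For each procedure, and for the pooled sample as an `Overall` row:
#' scan count, ICC(2,1) between eTIV and sbTIV (full sample and non-small
#' subgroup), and means/SDs of eTIV, sbTIV, deviation and absolute error.
#' Procedures with fewer than 2 scans get `NA` ICCs, not an error.
#'
#' @param table a scan table with both methods present.
#' @param threshold small-eTIV threshold, mm^3.
#' @return a data.frame, one row per procedure plus `Overall` (first row).
#' @export
procedure_summary_table <- function(table, threshold = 1200000) {
  tab <- compute_deviation(table)
  pieces <- lapply(split(tab, tab$procedure_id), function(d) {
    .summary_row(d$procedure_id[1], d, threshold)
  })
  out <- rbind(.summary_row("Overall", tab, threshold),
               do.call(rbind, pieces))
  rownames(out) <- NULL
  out
}

#' Linear model of per-procedure ICC on procedural factors
#'
#' Ordinary least squares of the per-procedure ICC(2,1) on protocol and
#' machine dummies, treatment-coded against the protocol and machine of a
#' reference procedure (conventionally the procedure with the highest ICC).
#'
#' @param rows a per-procedure summary (e.g. [procedure_summary_table()]
#'   without the `Overall` row) that also carries `protocol` and `machine`
#'   columns, or the design columns merged in.
#' @param reference_procedure procedure id whose protocol/machine become
#'   the reference levels.
#' @param response which column to model (default `icc_2_1`).
#' @return a list: `coefficients` (term, B, SE, t, p), `fit` (the `lm`).
#' @export
icc_factor_model <- function(rows, reference_procedure,
                             response = "icc_2_1") {
  rows <- as.data.frame(rows)
  rows <- rows[rows$procedure_id != "Overall", , drop = FALSE]
  needed <- c("procedure_id", response, "protocol", "machine")
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0L) {
    stop("rows lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(rows$protocol)) < 2L) {
    stop("need at least 2 protocol levels", call. = FALSE)
  }
  ref <- rows[rows$procedure_id == reference_procedure, , drop = FALSE]
  if (nrow(ref) != 1L) {
    stop("reference procedure '", reference_procedure, "' not found",
         call. = FALSE)
  }
  rows$protocol <- stats::relevel(factor(rows$protocol), ref = ref$protocol)
  rows$machine <- stats::relevel(factor(rows$machine), ref = ref$machine)

  fml <- as.formula(paste(response, "~ protocol + machine"))
  X <- model.matrix(fml, rows)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("protocol/machine design is confounded; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- lm(fml, data = rows)
  s <- coef(summary(fit))
  list(coefficients = data.frame(term = rownames(s), B = s[, 1], SE = s[, 2],
                                 t = s[, 3], p = s[, 4],
                                 row.names = NULL, stringsAsFactors = FALSE),
       fit = fit)
}

#' Mixed model for deviation or absolute error
#'
#' Models per-scan deviation (eTIV - sbTIV) or absolute error on protocol,
#' machine, age and sex, with crossed random intercepts for procedure and
#' participant.
#'
#' @param table a scan table with both methods and complete covariates.
#' @param response `"deviation"` or `"abs_error"`.
#' @param fixed fixed-effect terms (defaults to protocol, machine, age,
#'   sex indicator).
#' @param reference named list of reference levels for categorical terms.
#' @return an [fit_lmm()] result.
#' @export
deviation_factor_model <- function(table,
                                   response = c("deviation", "abs_error"),
                                   fixed = c("protocol", "machine",
                                             "age_at_scan", "sex_female"),
                                   reference = list()) {
  response <- match.arg(response)
  tab <- compute_deviation(table)
  tab$sex_female <- as.numeric(tab$sex == "female")
  resp_col <- paste0(response, "_mm3")
  fixed <- fixed[vapply(fixed, function(f) {
    cols <- strsplit(f, ":", fixed = TRUE)[[1]]
    all(vapply(cols, function(cc) length(unique(tab[[cc]])) > 1L, logical(1)))
  }, logical(1))]
  fit_lmm(tab, model_spec(resp_col, fixed,
                          c("procedure_id", "participant_id"), reference))
}

#' Sample three scans per eligible traveling subject
#'
#' Participants with fewer than 3 scans are excluded; for each retained
#' participant exactly 3 scans are drawn uniformly without replacement and
#' assigned to the 3 columns in random order. Because ICC(2,k) treats
#' columns as exchangeable raters, the random column assignment does not
#' affect the estimate's distribution.
#'
#' @param ts_table a traveling-subject scan table.
#' @param method `"etiv"`, `"sbtiv"`, or a harmonized column's prefix
#'   (e.g. `"etiv_harmonized"`).
#' @param seed optional RNG seed for this draw.
#' @return a [ratings_matrix()] of size (eligible participants) x 3.
#' @export
subsample_triples <- function(ts_table, method = "etiv", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- as.data.frame(ts_table)
  value_col <- paste0(method, "_mm3")
  stopifnot(value_col %in% names(tab))
  tab <- tab[!is.na(tab[[value_col]]), , drop = FALSE]
  counts <- table(tab$participant_id)
  eligible <- names(counts)[counts >= 3L]
  if (length(eligible) == 0L) {
    stop("no participant has 3 or more scans", call. = FALSE)
  }
  rows <- t(vapply(eligible, function(pid) {
    v <- tab[[value_col]][tab$participant_id == pid]
    sample(v, 3L)            # without replacement; random column order
  }, numeric(3)))
  ratings_matrix(rows, subject_ids = eligible,
                 column_labels = paste0("scan", 1:3))
}

#' Resampled cross-procedure ICC(2,k) reliability
#'
#' Repeats [subsample_triples()] + [icc_average()] `n_reps` times and
#' summarizes the replicate ICC(2,3) estimates. Deterministic given `seed`.
#'
#' @param ts_table a traveling-subject scan table.
#' @param method value-column prefix, see [subsample_triples()].
#' @param n_reps number of resampling replicates (study convention: 1000).
#' @param seed RNG seed.
#' @return an object of class `"resampling_result"`: `method`, `n_reps`,
#'   `per_replicate_icc`, `mean_icc`, `sd_icc`, `seed`,
#'   `n_participants_used`.
#' @export
resampled_icc2k <- function(ts_table, method = "etiv", n_reps = 1000,
                            seed = 1L) {
  set.seed(seed)
  reps <- numeric(n_reps)
  n_used <- NA_integer_
  for (r in seq_len(n_reps)) {
    m <- subsample_triples(ts_table, method)
    n_used <- nrow(m)
    reps[r] <- icc_average(m)$estimate
  }
  structure(list(method = method, n_reps = n_reps, per_replicate_icc = reps,
                 mean_icc = mean(reps), sd_icc = sd(reps), seed = seed,
                 n_participants_used = n_used),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "Resampled ICC(2,k) [%s]: mean = %.3f, SD = %.3f (%d reps, n = %d)\n",
    x$method, x$mean_icc, x$sd_icc, x$n_reps, x$n_participants_used))
  invisible(x)
}

#' Pearson correlations of body size and age with each method
#'
#' @param table a scan table with `body_height_cm`/`body_weight_kg`.
#' @param covariates covariate columns to correlate.
#' @return a data.frame (method, covariate, r, p, n).
#' @export
covariate_correlations <- function(table,
                                   covariates = c("age_at_scan",
                                                  "body_height_cm",
                                                  "body_weight_kg")) {
  tab <- as.data.frame(table)
  out <- list()
  for (mth in c("etiv_mm3", "sbtiv_mm3")) {
    for (cv in covariates) {
      ok <- complete.cases(tab[[mth]], tab[[cv]])
      if (sd(tab[[cv]][ok]) == 0) {
        stop("covariate '", cv, "' is constant; correlation undefined",
             call. = FALSE)
      }
      ct <- cor.test(tab[[mth]][ok], tab[[cv]][ok], method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        method = sub("_mm3$", "", mth), covariate = cv,
        r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Age and body-height model in older participants
#'
#' Ordinary least squares of each method on age and body height, restricted
#' to participants over `min_age` years, probing whether age-related
#' atrophy leaks into the TIV estimate (it should not: TIV is the cavity,
#' not the brain).
#'
#' @param table a scan table with `body_height_cm`.
#' @param min_age age cut (default 60; the subset is age > `min_age`).
#' @return a list with one coefficient table per method and `n`.
#' @export
elderly_model <- function(table, min_age = 60) {
  tab <- as.data.frame(table)
  tab <- tab[tab$age_at_scan > min_age &
               complete.cases(tab$etiv_mm3, tab$sbtiv_mm3,
                              tab$body_height_cm), , drop = FALSE]
  if (nrow(tab) < 4L) stop("elderly subset too small", call. = FALSE)
  one <- function(col) {
    s <- coef(summary(lm(tab[[col]] ~ age_at_scan + body_height_cm,
                         data = tab)))
    data.frame(term = rownames(s), B = s[, 1], SE = s[, 2], t = s[, 3],
               p = s[, 4], row.names = NULL, stringsAsFactors = FALSE)
  }
  list(etiv = one("etiv_mm3"), sbtiv = one("sbtiv_mm3"), n = nrow(tab))
}
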