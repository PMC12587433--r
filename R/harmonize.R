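# Traveling-subject harmonization.
#
# Because each traveling subject (TS) is scanned under many procedures with
# (in adults) a stable true TIV, procedure-specific additive biases are
# identifiable from TS data alone: fit value ~ procedure with a participant
# random intercept, and read the biases off the procedure fixed effects.
# Harmonization subtracts these offsets from any scan table.

#' Estimate per-procedure additive offsets from traveling-subject scans
#'
#' Fits `value ~ procedure + (1 | participant)` by REML and returns the
#' procedure fixed effects re-centered to sum to zero across the procedures
#' present (so harmonized values stay centered on the TS grand mean), or,
#' if `reference` names a procedure, re-centered so that procedure's offset
#' is zero.
#'
#' @param ts_table a scan table of traveling-subject scans (rows with
#'   `cohort_role == "traveling"` are used if the column distinguishes any).
#' @param method `"etiv"` or `"sbtiv"`.
#' @param reference optional procedure id whose offset is pinned to zero
#'   instead of the sum-to-zero centering.
#' @return an object of class `"harmonization_model"`: `method`, `offsets`
#'   (named, mm^3), `offset_se`, `participant_var`, `residual_var`,
#'   `n_ts_scans`, `n_travelers`, `centering`.
#' @export
estimate_procedure_offsets <- function(ts_table, method = c("etiv", "sbtiv"),
                                       reference = NULL) {
  method <- match.arg(method)
  tab <- as.data.frame(ts_table)
  if ("cohort_role" %in% names(tab) && any(tab$cohort_role == "traveling")) {
    tab <- tab[tab$cohort_role == "traveling", , drop = FALSE]
  }
  value_col <- paste0(method, "_mm3")
  tab <- tab[!is.na(tab[[value_col]]), , drop = FALSE]
  procs <- unique(tab$procedure_id)
  if (length(procs) < 2L) {
    stop("need traveling-subject scans on at least 2 procedures", call. = FALSE)
  }
  scans_per <- table(tab$participant_id)
  if (any(scans_per < 2L)) {
    warning(sum(scans_per < 2L),
            " traveler(s) with a single scan contribute no",
            " within-person contrast")
  }
  thin <- table(tab$procedure_id) < 2L
  if (any(thin)) {
    warning("procedure(s) with < 2 TS scans (offset estimated with",
            " inflated SE): ", paste(names(thin)[thin], collapse = ", "))
  }

  fit <- fit_lmm(tab, model_spec(value_col, "procedure_id", "participant_id"))
  lev <- levels(factor(tab$procedure_id))
  P <- length(lev)
  # treatment-coded effects d (reference level = 0) -> cell offsets
  d <- setNames(numeric(P), lev)
  co <- fit$coefficients
  eff_rows <- grep("^procedure_id", co$term)
  d[sub("^procedure_id", "", co$term[eff_rows])] <- co$B[eff_rows]

  # variance of each re-centered offset via contrasts of (d_2..d_P)
  V <- fit$vcov_fixed[co$term[eff_rows], co$term[eff_rows], drop = FALSE]
  if (is.null(reference)) {
    offsets <- d - mean(d)
    contrast <- function(j) {       # offset_j = sum_c w_c d_c, d over lev[-1]
      w <- rep(-1 / P, P - 1L)
      if (j > 1L) w[j - 1L] <- w[j - 1L] + 1
      w
    }
    centering <- "sum_to_zero"
  } else {
    if (!reference %in% lev) {
      stop("reference procedure '", reference, "' not present in TS data",
           call. = FALSE)
    }
    offsets <- d - d[reference]
    r <- match(reference, lev)
    contrast <- function(j) {
      w <- rep(0, P - 1L)
      if (j > 1L) w[j - 1L] <- 1
      if (r > 1L) w[r - 1L] <- w[r - 1L] - 1
      w
    }
    centering <- paste0("reference:", reference)
  }
  se <- vapply(seq_len(P), function(j) {
    w <- contrast(j)
    sqrt(drop(t(w) %*% V %*% w))
  }, numeric(1))

  structure(list(
    method = method, offsets = offsets, offset_se = setNames(se, lev),
    participant_var = unname(fit$var_components["participant_id"]),
    residual_var = unname(fit$var_components["residual"]),
    n_ts_scans = nrow(tab),
    n_travelers = length(unique(tab$participant_id)),
    centering = centering, fit = fit
  ), class = "harmonization_model")
}

#' Subtract procedure offsets from a scan table
#'
#' Adds a `<method>_harmonized_mm3` column equal to the raw value minus the
#' procedure's offset; the raw column is untouched.
#'
#' @param table a scan table.
#' @param model a [estimate_procedure_offsets()] result.
#' @param on_missing what to do for rows whose procedure has no estimated
#'   offset: `"error"` (default) or `"passthrough"` (keep the raw value,
#'   with a warning).
#' @return the table with the harmonized column added.
#' @export
apply_harmonization <- function(table, model,
                                on_missing = c("error", "passthrough")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(model, "harmonization_model"))
  tab <- as.data.frame(table)
  value_col <- paste0(model$method, "_mm3")
  out_col <- paste0(model$method, "_harmonized_mm3")
  idx <- match(tab$procedure_id, names(model$offsets))
  if (anyNA(idx)) {
    missing_procs <- unique(tab$procedure_id[is.na(idx)])
    if (on_missing == "error") {
      stop("procedure(s) without an estimated offset: ",
           paste(missing_procs, collapse = ", "),
           " (use on_missing = \"passthrough\" to keep raw values)",
           call. = FALSE)
    }
    warning("passing through raw values for procedure(s): ",
            paste(missing_procs, collapse = ", "))
  }
  offset <- ifelse(is.na(idx), 0, model$offsets[idx])
  tab[[out_col]] <- tab[[value_col]] - offset
  tab
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat("Traveling-subject harmonization (", x$method, "), ",
      x$n_travelers, " travelers / ", x$n_ts_scans, " scans, centering: ",
      x$centering, "\n", sep = "")
  print(data.frame(procedure_id = names(x$offsets),
                   offset_mm3 = round(unname(x$offsets), 1),
                   SE = round(unname(x$offset_se), 1)),
        row.names = FALSE)
  invisible(x)
}
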