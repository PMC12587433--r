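# Gaussian linear mixed models with one or two crossed random intercepts,
# fitted by REML through lme4, with Satterthwaite degrees of freedom from
# lmerTest. All responses in this package are Gaussian, so the study's
# "GLMMs" are linear mixed models.
#
# lme4's optimizer localizes the REML optimum in the variance-ratio
# parameter theta to roughly sqrt(machine-eps) because it uses function
# values only. A post-fit polish refines each interior theta coordinate by
# root-finding on a central-difference derivative of the profiled REML
# deviance, which localizes the optimum several orders of magnitude more
# tightly (the derivative carries slope information that pure function
# comparison cannot exploit). Variance components and fixed effects are
# reported at the polished optimum.

#' Specify a linear mixed model
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms over columns of the
#'   data (main effects and `a:b` interactions); empty means intercept-only.
#' @param random 1-2 grouping column names, each contributing a random
#'   intercept (two factors are crossed).
#' @param reference named list mapping categorical columns to their
#'   reference level (treatment coding).
#' @return a list of class `"model_spec"`.
#' @export
model_spec <- function(response, fixed = character(), random,
                       reference = list()) {
  stopifnot(is.character(response), length(response) == 1L,
            is.character(random), length(random) >= 1L, length(random) <= 2L)
  structure(list(response = response, fixed = fixed, random = random,
                 reference = reference), class = "model_spec")
}

#' Parse a model-spec config string
#'
#' Accepts strings of the form
#' `"deviation_mm3 ~ protocol + age_at_scan, random: participant_id + procedure_id"`.
#'
#' @param text the config string.
#' @return a [model_spec()].
#' @export
parse_model_spec <- function(text) {
  parts <- strsplit(text, ",\\s*random\\s*:")[[1]]
  if (length(parts) != 2L) {
    stop("model spec must look like 'y ~ terms, random: group [+ group2]'",
         call. = FALSE)
  }
  fml <- strsplit(parts[1], "~", fixed = TRUE)[[1]]
  if (length(fml) != 2L) stop("malformed fixed part: ", parts[1], call. = FALSE)
  response <- trimws(fml[1])
  fixed <- trimws(strsplit(fml[2], "+", fixed = TRUE)[[1]])
  fixed <- fixed[fixed != "" & fixed != "1"]
  random <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
  model_spec(response, fixed, random)
}

# Refine interior theta coordinates of an lmer fit by root-finding on the
# central-difference derivative of the profiled REML deviance. Returns the
# polished theta; coordinates at the boundary (theta ~ 0) are left alone.
.polish_theta <- function(devfun, theta, h = 1e-5, sweeps = NULL) {
  q <- length(theta)
  if (is.null(sweeps)) sweeps <- if (q > 1L) 3L else 1L
  th <- theta
  for (s in seq_len(sweeps)) {
    for (j in seq_len(q)) {
      if (th[j] < 1e-6) next  # boundary estimate; no interior root
      gfun <- function(t) {
        thp <- th; thm <- th
        thp[j] <- t + h; thm[j] <- t - h
        devfun(thp) - devfun(thm)
      }
      lo <- max(2 * h, th[j] - 0.05); hi <- th[j] + 0.05
      glo <- gfun(lo); ghi <- gfun(hi)
      tries <- 0L
      while (glo * ghi > 0 && tries < 6L) {
        lo <- max(2 * h, lo - 0.1); hi <- hi + 0.1
        glo <- gfun(lo); ghi <- gfun(hi)
        tries <- tries + 1L
      }
      if (glo * ghi > 0) next  # could not bracket; keep optimizer value
      th[j] <- uniroot(gfun, c(lo, hi), f.lower = glo, f.upper = ghi,
                       tol = 1e-13)$root
    }
  }
  th
}

.degenerate_fit <- function(data, spec, term_names, value) {
  coefs <- data.frame(
    term = term_names,
    B = c(value, rep(0, length(term_names) - 1L)),
    SE = 0, t = NA_real_, df = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE)
  vc <- setNames(rep(0, length(spec$random) + 1L),
                 c(spec$random, "residual"))
  structure(list(coefficients = coefs, var_components = vc,
                 reml_loglik = NA_real_, n_obs = nrow(data),
                 converged = TRUE, degenerate = TRUE, spec = spec,
                 theta = NULL, devfun = NULL, fit = NULL),
            class = "lmm_fit")
}

#' Fit a linear mixed model by REML
#'
#' Fits `response ~ fixed terms + (1 | g)` (optionally a second crossed
#' random intercept) by restricted maximum likelihood. Categorical terms are
#' treatment-coded against the reference levels named in the spec. Wald t
#' statistics use Satterthwaite denominator degrees of freedom.
#'
#' A constant (zero-variance) response returns a degenerate fit with
#' all-zero variance components and zero non-intercept coefficients rather
#' than an error, since downstream analyses legitimately produce such
#' responses on noise-free input.
#'
#' @param data a data.frame containing all referenced columns.
#' @param spec a [model_spec()], or a config string for [parse_model_spec()].
#' @return an object of class `"lmm_fit"`: `coefficients` (term, B, SE, t,
#'   df, p), `var_components` (one per grouping factor plus `residual`, in
#'   response units squared), `reml_loglik`, `n_obs`, `converged`.
#' @export
fit_lmm <- function(data, spec) {
  if (is.character(spec)) spec <- parse_model_spec(spec)
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  used <- unique(c(spec$response,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   spec$random))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[, used, drop = FALSE])) {
    stop("missing values in used columns are not supported", call. = FALSE)
  }
  for (col in used) {
    if (is.character(data[[col]]) || is.logical(data[[col]])) {
      data[[col]] <- factor(data[[col]])
    }
  }
  for (col in names(spec$reference)) {
    data[[col]] <- stats::relevel(factor(data[[col]]),
                                  ref = spec$reference[[col]])
  }
  for (g in spec$random) {
    if (nlevels(factor(data[[g]])) < 2L) {
      stop("grouping column '", g, "' needs at least 2 levels", call. = FALSE)
    }
  }

  fixed_part <- if (length(spec$fixed) == 0L) "1"
                else paste(spec$fixed, collapse = " + ")
  fixed_formula <- as.formula(paste(spec$response, "~", fixed_part))
  X <- model.matrix(fixed_formula, data)
  if (nrow(data) < ncol(X) + 2L) {
    stop("need at least n_fixed + 2 observations", call. = FALSE)
  }
  y <- data[[spec$response]]
  if (var(y) < .Machine$double.eps * max(1, mean(y)^2)) {
    return(.degenerate_fit(data, spec, colnames(X), y[1]))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient fixed design; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  full_formula <- as.formula(paste(
    spec$response, "~", fixed_part, "+",
    paste(sprintf("(1 | %s)", spec$random), collapse = " + ")))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
    calc.derivs = FALSE)
  f <- lme4::lmer(full_formula, data = data, REML = TRUE, control = ctrl)

  devfun <- lme4::lmer(full_formula, data = data, REML = TRUE, control = ctrl,
                       devFunOnly = TRUE)
  theta <- unname(lme4::getME(f, "theta"))
  theta <- .polish_theta(devfun, theta)
  dev_opt <- devfun(theta)  # also leaves the devfun state at theta
  rho <- environment(devfun)
  p <- ncol(X)
  sigma2 <- (rho$resp$wrss() + rho$pp$sqrL(1)) / (nrow(data) - p)
  beta <- rho$pp$beta(1)
  vcov_fixed <- as.matrix(sigma2 * rho$pp$unsc())
  dimnames(vcov_fixed) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_fixed))

  grp_names <- names(lme4::getME(f, "cnms"))
  vc <- setNames(c(theta^2 * sigma2, sigma2), c(grp_names, "residual"))
  # report in the order the spec listed the grouping factors
  vc <- vc[c(spec$random, "residual")]

  ft <- tryCatch(suppressWarnings(lmerTest::as_lmerModLmerTest(f)),
                 error = function(e) NULL)
  if (!is.null(ft)) {
    sdf <- tryCatch(suppressWarnings(coef(summary(ft))[, "df"]),
                    error = function(e) NULL)
  } else sdf <- NULL
  if (is.null(sdf) || anyNA(sdf)) {
    sdf <- rep(nrow(data) - p - length(spec$random), p)
  }

  tval <- beta / se
  coefs <- data.frame(term = colnames(X), B = unname(beta), SE = unname(se),
                      t = unname(tval), df = unname(sdf),
                      p = unname(2 * pt(-abs(tval), sdf)),
                      stringsAsFactors = FALSE)
  conv <- length(f@optinfo$conv$lme4) == 0L &&
    (is.null(f@optinfo$conv$opt) || f@optinfo$conv$opt == 0L)
  structure(list(coefficients = coefs, var_components = vc,
                 vcov_fixed = vcov_fixed,
                 reml_loglik = -dev_opt / 2, n_obs = nrow(data),
                 converged = conv, degenerate = FALSE, spec = spec,
                 theta = theta, devfun = devfun, fit = f),
            class = "lmm_fit")
}

#' Extract fixed-effect rows from a mixed-model fit
#'
#' @param fit an [fit_lmm()] result.
#' @param term_names terms to extract, as they appear in the coefficient
#'   table (categorical terms appear as `column` + level under treatment
#'   coding; the reference level is absorbed into the intercept and cannot
#'   be requested).
#' @return the matching rows of the coefficient table.
#' @export
recover_effects <- function(fit, term_names) {
  stopifnot(inherits(fit, "lmm_fit"))
  tab <- fit$coefficients
  unknown <- setdiff(term_names, tab$term)
  if (length(unknown) > 0L) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(tab$term, collapse = ", "),
         ". Categorical terms use treatment coding: the reference level",
         " is absorbed into the intercept.", call. = FALSE)
  }
  tab[match(term_names, tab$term), , drop = FALSE]
}

#' Evaluate the profiled REML deviance at a perturbed variance ratio
#'
#' Diagnostic: the deviance at the reported optimum should be no larger
#' than at any perturbation of theta.
#'
#' @param fit an [fit_lmm()] result (non-degenerate).
#' @param scale multiplicative perturbation(s) of theta.
#' @return deviance difference `dev(scale * theta) - dev(theta)` (>= 0 at a
#'   true optimum), one per scale.
#' @export
reml_perturbation_gap <- function(fit, scale = c(0.8, 1.2)) {
  stopifnot(inherits(fit, "lmm_fit"), !fit$degenerate)
  d0 <- fit$devfun(fit$theta)
  vapply(scale, function(s) fit$devfun(fit$theta * s) - d0, numeric(1))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (REML", if (x$degenerate) ", degenerate" else "",
      "), n = ", x$n_obs, "\n", sep = "")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat("Variance components:\n")
  print(round(x$var_components, 6))
  invisible(x)
}
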