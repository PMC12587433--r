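# Synthetic multi-site cohort generator.
#
# The generative model mirrors the additive-bias structure assumed by the
# harmonization analysis: participant i has a latent true TIV
#
#   TIV_i = mu + beta_sex * (I(male_i) - 1/2) + beta_height * (h_i - h_bar) + u_i,
#   u_i ~ N(0, sigma_subject^2),
#
# and a scan of participant i under procedure p yields, per method m,
#
#   y_ipm = TIV_i + bias_pm + eps,  eps ~ N(0, noise_pm^2).
#
# The registration-based method (eTIV) additionally carries a gross
# underestimation failure mode: with probability failure_prob the observed
# eTIV is TIV_i * U with U ~ Uniform(failure_shrink_range), emulating the
# off-diagonal failures seen in real multi-site data. sbTIV never fails.
#
# Defaults are anchored to the published per-procedure summary (bundled as
# extdata): per-procedure eTIV bias equals the printed mean deviation,
# per-procedure noise is split from the printed deviation SD, and sampling
# weights are proportional to the printed per-procedure n.

#' Default procedure specifications
#'
#' Builds the 30-procedure design table from the bundled published summary:
#' procedure id, machine model, vendor, protocol category, a sampling weight
#' proportional to the published per-procedure scan count, an additive eTIV
#' bias equal to the published mean deviation (sbTIV bias 0, anchoring the
#' sbTIV grand mean), and per-method noise SDs recovered from the published
#' deviation SD with `noise_sbtiv` fixed at 30,000 mm^3. Traveling-subject
#' eligibility excludes the two procedures with no published TS scans
#' (G and I), leaving 28.
#'
#' @param noise_sbtiv sbTIV within-procedure noise SD in mm^3.
#' @return a data.frame with one row per procedure (`procedure_id`, `site`,
#'   `machine`, `vendor`, `protocol`, `weight`, `bias_etiv`, `bias_sbtiv`,
#'   `noise_etiv`, `noise_sbtiv`, `ts_eligible`).
#' @export
default_procedures <- function(noise_sbtiv = 30000) {
  ref <- reference_summary_table(include_overall = FALSE)
  site_codes <- c(A = "JTD", B = "UOS", C = "UTI", D = "UTK", E = "ATR",
                  F = "TMG", G = "KPUM", H = "UKY", I = "NCNP", J = "SWA",
                  K = "UHI")
  site <- ifelse(ref$procedure_id %in% names(site_codes),
                 site_codes[ref$procedure_id],
                 paste0("SITE_", ref$procedure_id))
  noise_etiv <- sqrt(pmax(ref$deviation_sd^2 - noise_sbtiv^2, 20000^2))
  data.frame(
    procedure_id = ref$procedure_id,
    site = unname(site),
    machine = ref$mri_model,
    vendor = ref$vendor,
    protocol = ref$protocol,
    weight = ref$n,
    bias_etiv = ref$deviation_mean,
    bias_sbtiv = 0,
    noise_etiv = noise_etiv,
    noise_sbtiv = noise_sbtiv,
    ts_eligible = !(ref$procedure_id %in% c("G", "I")),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' Full parameterization of the multi-site generative model. Defaults place
#' the sbTIV grand mean at 1.58e6 mm^3 and the marginal between-participant
#' SD near 1.55e5 mm^3, matching the published overall summary; the
#' male-female true-TIV difference and the height slope are set at the
#' scale of the published body-size effects.
#'
#' @param n_participants participants in the main cohort.
#' @param procedures procedure design table, see [default_procedures()].
#' @param sigma_subject between-participant SD of true TIV net of sex and
#'   height effects, mm^3.
#' @param mu_tiv grand mean true TIV, mm^3 (sex coded centered, so this is
#'   the population mean at 50/50 sex and mean height).
#' @param beta_sex male minus female true-TIV difference, mm^3.
#' @param beta_height true-TIV slope on body height, mm^3 per cm.
#' @param height_mean,height_sd body-height distribution, cm.
#' @param age_range main-cohort age range, years.
#' @param adolescent_growth named vector `female_slope`, `male_slope`:
#'   within-person true-TIV growth during adolescence, mm^3 per year.
#' @param failure_prob probability that a scan's eTIV takes the gross
#'   underestimation failure mode.
#' @param failure_shrink_range interval within (0,1); a failed eTIV equals
#'   true TIV times a uniform draw from this interval.
#' @param seed integer RNG seed used by the simulators.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_participants = 2000,
                             procedures = default_procedures(),
                             sigma_subject = 100000,
                             mu_tiv = 1580000,
                             beta_sex = 130000,
                             beta_height = 11000,
                             height_mean = 165.4,
                             height_sd = 8.8,
                             age_range = c(10.5, 80.1),
                             adolescent_growth = c(female_slope = 8000,
                                                   male_slope = 20000),
                             failure_prob = 0.025,
                             failure_shrink_range = c(0.6, 0.85),
                             seed = 1L) {
  if (!is.data.frame(procedures) || nrow(procedures) == 0L) {
    stop("config error: procedures must be a non-empty data.frame",
         call. = FALSE)
  }
  needed <- c("procedure_id", "protocol", "bias_etiv", "bias_sbtiv",
              "noise_etiv", "noise_sbtiv")
  missing <- setdiff(needed, names(procedures))
  if (length(missing) > 0L) {
    stop("config error: procedures lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(procedures$weight)) procedures$weight <- 1
  if (is.null(procedures$ts_eligible)) procedures$ts_eligible <- TRUE
  if (is.null(procedures$site)) procedures$site <- procedures$procedure_id
  if (is.null(procedures$machine)) procedures$machine <- "machine"
  if (is.null(procedures$vendor)) procedures$vendor <- "vendor"
  stopifnot(sigma_subject > 0,
            all(procedures$noise_etiv > 0),
            all(procedures$noise_sbtiv > 0),
            failure_prob >= 0, failure_prob <= 1,
            length(failure_shrink_range) == 2L,
            failure_shrink_range[1] > 0, failure_shrink_range[2] < 1,
            failure_shrink_range[1] <= failure_shrink_range[2],
            all(c("female_slope", "male_slope") %in% names(adolescent_growth)))
  structure(list(
    n_participants = n_participants, procedures = procedures,
    sigma_subject = sigma_subject, mu_tiv = mu_tiv, beta_sex = beta_sex,
    beta_height = beta_height, height_mean = height_mean,
    height_sd = height_sd, age_range = age_range,
    adolescent_growth = adolescent_growth, failure_prob = failure_prob,
    failure_shrink_range = failure_shrink_range, seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Draw participant-level latent variables shared by all simulators.
.draw_participants <- function(config, n, age_range, id_prefix) {
  male <- runif(n) < 0.5
  height <- rnorm(n, config$height_mean, config$height_sd)
  weight <- 60.1 + 1.0 * (height - config$height_mean) + rnorm(n, 0, 10)
  age <- runif(n, age_range[1], age_range[2])
  u <- rnorm(n, 0, config$sigma_subject)
  true_tiv <- config$mu_tiv + config$beta_sex * (male - 0.5) +
    config$beta_height * (height - config$height_mean) + u
  data.frame(
    participant_id = sprintf("%s%05d", id_prefix, seq_len(n)),
    sex = ifelse(male, "male", "female"),
    body_height_cm = height, body_weight_kg = weight,
    age_at_scan = age, true_tiv = true_tiv,
    stringsAsFactors = FALSE
  )
}

# Observe one scan per row: procedure-indexed biases/noise plus the eTIV
# failure mode. `proc_idx` indexes config$procedures.
.observe <- function(config, true_tiv, proc_idx) {
  p <- config$procedures
  n <- length(true_tiv)
  fp <- if (!is.null(p$failure_prob_override)) {
    ifelse(is.na(p$failure_prob_override[proc_idx]),
           config$failure_prob, p$failure_prob_override[proc_idx])
  } else rep(config$failure_prob, n)
  etiv <- true_tiv + p$bias_etiv[proc_idx] + rnorm(n, 0, p$noise_etiv[proc_idx])
  sbtiv <- true_tiv + p$bias_sbtiv[proc_idx] + rnorm(n, 0, p$noise_sbtiv[proc_idx])
  failed <- runif(n) < fp
  if (any(failed)) {
    etiv[failed] <- true_tiv[failed] *
      runif(sum(failed), config$failure_shrink_range[1],
            config$failure_shrink_range[2])
  }
  list(etiv = etiv, sbtiv = sbtiv, failed = failed)
}

.assemble_table <- function(part, proc_idx, obs, config, cohort_role,
                            scan_order) {
  p <- config$procedures
  validate_scan_table(data.frame(
    participant_id = part$participant_id,
    procedure_id = p$procedure_id[proc_idx],
    site = p$site[proc_idx],
    machine = p$machine[proc_idx],
    vendor = p$vendor[proc_idx],
    protocol = p$protocol[proc_idx],
    age_at_scan = part$age_at_scan,
    sex = part$sex,
    etiv_mm3 = obs$etiv,
    sbtiv_mm3 = obs$sbtiv,
    cohort_role = cohort_role,
    body_height_cm = part$body_height_cm,
    body_weight_kg = part$body_weight_kg,
    scan_order = scan_order,
    true_tiv_mm3 = part$true_tiv,
    etiv_failed = obs$failed,
    stringsAsFactors = FALSE
  ))
}

#' Simulate a cross-sectional multi-site cohort
#'
#' One scan per participant; procedures are assigned by weighted sampling.
#' The returned scan table carries the latent `true_tiv_mm3` and the
#' `etiv_failed` indicator as extra columns for parameter-recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a validated `scan_table`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  part <- .draw_participants(config, n, config$age_range, "P")
  proc_idx <- sample.int(nrow(config$procedures), n, replace = TRUE,
                         prob = config$procedures$weight)
  obs <- .observe(config, part$true_tiv, proc_idx)
  .assemble_table(part, proc_idx, obs, config, "main", 1L)
}

#' Simulate a traveling-subject (TS) cohort
#'
#' Each traveler is assigned a uniformly sampled subset of distinct
#' TS-eligible procedures, with the subset size drawn uniformly from
#' `scans_per_traveler`; one scan per assigned procedure. True TIV is held
#' constant within traveler (TIV is stable in adults), so between-procedure
#' spread within a traveler reflects bias and noise only.
#'
#' @param config a [synthetic_config()].
#' @param n_travelers number of traveling participants.
#' @param scans_per_traveler integer range `c(min, max)` of scans per
#'   traveler; must lie within `[2, number of eligible procedures]`.
#' @param age_range traveler age range at scan, years.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a validated `scan_table` with `cohort_role = "traveling"`.
#' @export
simulate_traveling_subjects <- function(config, n_travelers = 134,
                                        scans_per_traveler = c(2, 9),
                                        age_range = c(19, 62),
                                        seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  procs <- which(config$procedures$ts_eligible)
  lo <- scans_per_traveler[1]; hi <- scans_per_traveler[length(scans_per_traveler)]
  if (lo < 2 || hi > length(procs)) {
    stop("config error: scans_per_traveler must lie within [2, ",
         length(procs), "] (number of TS-eligible procedures)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  part <- .draw_participants(config, n_travelers, age_range, "TS")
  n_scans <- if (lo == hi) rep(lo, n_travelers)
             else sample(lo:hi, n_travelers, replace = TRUE)
  rows <- vector("list", n_travelers)
  for (i in seq_len(n_travelers)) {
    k <- n_scans[i]
    idx <- sample(procs, k, replace = FALSE)
    obs <- .observe(config, rep(part$true_tiv[i], k), idx)
    rows[[i]] <- .assemble_table(part[rep(i, k), , drop = FALSE], idx, obs,
                                 config, "traveling", seq_len(k))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_scan_table(out)
}

#' Simulate a longitudinal cohort
#'
#' Adolescent mode adds sex-specific linear growth
#' (`config$adolescent_growth`, mm^3/year) to true TIV across scan ages;
#' adult mode holds true TIV constant. An optional `procedure_switch`
#' assigns each participant's first scan to one procedure and all later
#' scans to another, emulating designs where initial and follow-up scans
#' used different procedures.
#'
#' @param config a [synthetic_config()].
#' @param mode `"adolescent"` (baseline ages 10-14, follow-ups to 18) or
#'   `"adult"` (baseline 20-60, follow-up gaps 0.5-4 years).
#' @param n_participants participants in the cohort.
#' @param scans_per_participant integer range `c(min, max)` of scans.
#' @param procedure_switch optional `c(from, to)` procedure ids.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return a validated `scan_table`.
#' @export
simulate_longitudinal <- function(config, mode = c("adolescent", "adult"),
                                  n_participants = 200,
                                  scans_per_participant = c(2, 4),
                                  procedure_switch = NULL,
                                  seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  mode <- match.arg(mode)
  if (!is.null(procedure_switch)) {
    if (length(procedure_switch) != 2L ||
        !all(procedure_switch %in% config$procedures$procedure_id)) {
      stop("config error: procedure_switch must name two known procedures",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  base_range <- if (mode == "adolescent") c(10, 14) else c(20, 60)
  part <- .draw_participants(config, n_participants, base_range,
                             if (mode == "adolescent") "AL" else "UL")
  lo <- scans_per_participant[1]
  hi <- scans_per_participant[length(scans_per_participant)]
  n_scans <- if (lo == hi) rep(lo, n_participants)
             else sample(lo:hi, n_participants, replace = TRUE)
  growth <- config$adolescent_growth
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    k <- n_scans[i]
    gaps <- if (mode == "adolescent") {
      cumsum(c(0, runif(k - 1, 1, 2)))
    } else {
      cumsum(c(0, runif(k - 1, 0.5, 4)))
    }
    ages <- pmin(part$age_at_scan[i] + gaps,
                 if (mode == "adolescent") 18 else Inf)
    slope <- if (mode == "adolescent") {
      unname(growth[if (part$sex[i] == "male") "male_slope" else "female_slope"])
    } else 0
    tiv_t <- part$true_tiv[i] + slope * (ages - ages[1])
    if (is.null(procedure_switch)) {
      idx <- rep(sample.int(nrow(config$procedures), 1,
                            prob = config$procedures$weight), k)
    } else {
      idx <- c(match(procedure_switch[1], config$procedures$procedure_id),
               rep(match(procedure_switch[2], config$procedures$procedure_id),
                   k - 1))
    }
    obs <- .observe(config, tiv_t, idx)
    pr <- part[rep(i, k), , drop = FALSE]
    pr$age_at_scan <- ages
    pr$true_tiv <- tiv_t
    rows[[i]] <- .assemble_table(pr, idx, obs, config,
                                 paste0(if (mode == "adolescent") "adolescent"
                                        else "adult", "_long"),
                                 seq_len(k))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_scan_table(out)
}
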