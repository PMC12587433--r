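# Pipeline orchestration: one YAML config in, a directory of CSV results
# and a log out. All randomness flows from the single config seed (each
# stage derives a fixed offset of it), so a config + seed pair pins every
# output byte-for-byte.

.known_analyses <- c("agreement", "icc", "harmonize", "resample",
                     "trajectories")

#' Run the full analysis pipeline from a config
#'
#' The config (YAML file or equivalent list) names either an input scan
#' table (`input: {table: path}`) or a synthetic cohort spec
#' (`synthetic: {n_participants: ...}`), the analyses to run, an output
#' directory and a seed. Results are written as CSV plus a plain-text log;
#' outputs are a pure function of (input table, config, seed).
#'
#' Analyses: `icc` (overall ICC(2,1)/(2,k) between methods), `agreement`
#' (per-procedure summary table), `harmonize` (TS offsets for both
#' methods), `resample` (resampled three-scan ICC(2,k), before and - when
#' `harmonize` is also requested - after harmonization), `trajectories`
#' (adolescent and adult longitudinal method-comparison fits).
#'
#' @param config path to a YAML config, or a list with the same structure.
#' @return invisibly, a list with the computed result objects and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config error: out_dir is required",
                                      call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  analyses <- unlist(config$analyses %||% .known_analyses)
  unknown <- setdiff(analyses, .known_analyses)
  if (length(unknown) > 0L) {
    stop("config error: unknown analysis name(s): ",
         paste(unknown, collapse = ", "),
         "; known: ", paste(.known_analyses, collapse = ", "), call. = FALSE)
  }

  log_lines <- character()
  log_path <- file.path(out_dir, "run.log")
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    writeLines(log_lines, log_path)
  }
  say("tivagree pipeline, seed = ", seed)
  results <- list()
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    say("wrote ", name, " (", nrow(df), " rows)")
  }

  syn_cfg <- NULL
  if (!is.null(config$input$table)) {
    main <- read_scan_table(config$input$table,
                            config$input$dialect %||% "csv")
    say("read scan table: ", config$input$table, " (", nrow(main), " scans)")
  } else {
    syn_args <- config$synthetic %||% list()
    syn_args$seed <- seed
    syn_cfg <- do.call(synthetic_config, syn_args)
    main <- simulate_cohort(syn_cfg, seed = seed)
    say("simulated main cohort: ", nrow(main), " scans, ",
        length(unique(main$procedure_id)), " procedures")
    sidecar <- file.path(out_dir, "synthetic_truth.yaml")
    yaml::write_yaml(list(
      seed = seed, n_participants = syn_cfg$n_participants,
      mu_tiv = syn_cfg$mu_tiv, sigma_subject = syn_cfg$sigma_subject,
      beta_sex = syn_cfg$beta_sex, beta_height = syn_cfg$beta_height,
      failure_prob = syn_cfg$failure_prob,
      failure_shrink_range = syn_cfg$failure_shrink_range), sidecar)
    emit(as.data.frame(main), "scan_table.csv")
  }

  ts <- NULL
  if (!is.null(config$traveling)) {
    if (is.null(syn_cfg)) {
      ts_rows <- main[main$cohort_role == "traveling", , drop = FALSE]
      if (nrow(ts_rows) > 0L) ts <- ts_rows
    } else {
      tr <- config$traveling
      ts <- simulate_traveling_subjects(
        syn_cfg, n_travelers = tr$n_travelers %||% 134,
        scans_per_traveler = unlist(tr$scans_per_traveler %||% c(2, 9)),
        seed = seed + 1L)
      say("simulated TS cohort: ", nrow(ts), " scans from ",
          length(unique(ts$participant_id)), " travelers")
    }
  } else if ("cohort_role" %in% names(main) &&
             any(main$cohort_role == "traveling")) {
    ts <- main[main$cohort_role == "traveling", , drop = FALSE]
  }

  if ("icc" %in% analyses) {
    m <- ratings_from_table(main)
    s <- icc_single(m); a <- icc_average(m)
    results$icc <- list(single = s, average = a)
    emit(data.frame(form = c("single", "average"),
                    estimate = c(s$estimate, a$estimate),
                    f = c(s$f_statistic, a$f_statistic),
                    df1 = c(s$df1, a$df1), df2 = c(s$df2, a$df2),
                    p = c(s$p_value, a$p_value),
                    band = c(s$band, a$band)), "icc.csv")
  }

  if ("agreement" %in% analyses) {
    results$agreement <- procedure_summary_table(main)
    emit(results$agreement, "agreement_table.csv")
  }

  needs_ts <- intersect(analyses, c("harmonize", "resample"))
  if (length(needs_ts) > 0L && is.null(ts)) {
    stop("config error: analysis '", needs_ts[1], "' requires a traveling",
         " cohort; add a 'traveling:' section to the config or supply a",
         " table with cohort_role == \"traveling\" rows", call. = FALSE)
  }

  hmods <- NULL
  if ("harmonize" %in% analyses) {
    hmods <- list(etiv = estimate_procedure_offsets(ts, "etiv"),
                  sbtiv = estimate_procedure_offsets(ts, "sbtiv"))
    results$harmonization <- hmods
    emit(do.call(rbind, lapply(hmods, function(h) data.frame(
      method = h$method, procedure_id = names(h$offsets),
      offset_mm3 = unname(h$offsets), se = unname(h$offset_se)))),
      "harmonization_offsets.csv")
  }

  if ("resample" %in% analyses) {
    n_reps <- config$resample$n_reps %||% 1000
    rows <- list(); reps <- list()
    for (method in c("etiv", "sbtiv")) {
      rr <- resampled_icc2k(ts, method, n_reps = n_reps, seed = seed + 2L)
      rows[[method]] <- data.frame(method = method, stage = "raw",
                                   mean_icc = rr$mean_icc, sd_icc = rr$sd_icc,
                                   n_reps = rr$n_reps,
                                   n_participants = rr$n_participants_used)
      reps[[method]] <- data.frame(method = method, stage = "raw",
                                   replicate = seq_len(n_reps),
                                   icc = rr$per_replicate_icc)
      if (!is.null(hmods)) {
        ts_h <- apply_harmonization(ts, hmods[[method]])
        rh <- resampled_icc2k(ts_h, paste0(method, "_harmonized"),
                              n_reps = n_reps, seed = seed + 2L)
        rows[[paste0(method, "_h")]] <-
          data.frame(method = method, stage = "harmonized",
                     mean_icc = rh$mean_icc, sd_icc = rh$sd_icc,
                     n_reps = rh$n_reps,
                     n_participants = rh$n_participants_used)
        reps[[paste0(method, "_h")]] <-
          data.frame(method = method, stage = "harmonized",
                     replicate = seq_len(n_reps), icc = rh$per_replicate_icc)
      }
    }
    results$resampling <- do.call(rbind, rows)
    emit(results$resampling, "resampling_summary.csv")
    emit(do.call(rbind, reps), "resampling_replicates.csv")
  }

  if ("trajectories" %in% analyses) {
    if (is.null(syn_cfg)) {
      stop("config error: 'trajectories' currently requires a synthetic",
           " spec (longitudinal cohorts are generated)", call. = FALSE)
    }
    lcfg <- config$longitudinal %||% list()
    fits <- list()
    for (mode in c("adolescent", "adult")) {
      tab <- simulate_longitudinal(
        syn_cfg, mode = mode,
        n_participants = lcfg[[mode]]$n_participants %||% 200,
        seed = seed + if (mode == "adolescent") 3L else 4L)
      fits[[mode]] <- fit_longitudinal_model(tab, mode)
      emit(cbind(cohort = mode, fits[[mode]]$coefficients),
           paste0("trajectory_", mode, ".csv"))
    }
    results$trajectories <- fits
  }

  say("done: ", length(outputs), " output file(s)")
  invisible(list(results = results, outputs = outputs, log = log_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
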