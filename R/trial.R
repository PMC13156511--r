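#' Configuration of an in-silico hip-protector trial
#'
#' Bundles every stage's settings: the cohort stratum specification and size,
#' the covariate-to-oracle response link, the surrogate configuration, the
#' fall-configuration model, the classification thresholds, the compliance
#' rate used for adjusted relative risks, and the master seed.
#'
#' @param strata Stratum spec; defaults to [cohort_strata_defaults()].
#' @param n_per_stratum Subjects per sex-by-ethnicity stratum (35 gives the
#'   210-subject trial arm).
#' @param link A [default_response_link()].
#' @param surrogate A [surrogate_config()].
#' @param fall A [fall_config()].
#' @param frax_threshold FRAX-HFP high-risk cut in percent.
#' @param rr_threshold High-RR cut.
#' @param compliance Compliance rate for adjusted RRs.
#' @param force_protector_shift Optional numeric overriding every subject's
#'   protector shift (0 gives a null trial whose defined RRs are exactly 1).
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(strata = cohort_strata_defaults(),
                         n_per_stratum = 35,
                         link = default_response_link(),
                         surrogate = surrogate_config(),
                         fall = fall_config(),
                         frax_threshold = 2,
                         rr_threshold = 0.4,
                         compliance = 0.5,
                         force_protector_shift = NULL,
                         seed = 1) {
  structure(
    list(strata = strata, n_per_stratum = n_per_stratum, link = link,
         surrogate = surrogate, fall = fall,
         frax_threshold = frax_threshold, rr_threshold = rr_threshold,
         compliance = compliance,
         force_protector_shift = force_protector_shift,
         seed = as.integer(seed)),
    class = "trial_config"
  )
}

#' Validate and normalise a trial configuration
#'
#' Fills defaults for missing entries of a plain list and reports every
#' violation at once rather than stopping at the first.
#'
#' @param config A `trial_config` or plain named list of overrides.
#' @return A validated `trial_config`; errors aggregate all violations.
#' @export
#' @examples
#' validate_config(list())           # all defaults
validate_config <- function(config = list()) {
  if (inherits(config, "trial_config")) {
    cfg <- config
  } else {
    if (!is.list(config)) stop("config must be a list or trial_config")
    known <- names(formals(trial_config))
    unknown <- setdiff(names(config), known)
    if (length(unknown) > 0) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    }
    cfg <- do.call(trial_config, config)
  }
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  if (!is.data.frame(cfg$strata) || nrow(cfg$strata) < 1) {
    note("strata: must be a non-empty data.frame")
  }
  if (!is.numeric(cfg$n_per_stratum) || cfg$n_per_stratum < 1) {
    note("n_per_stratum: must be >= 1")
  }
  if (!inherits(cfg$link, "response_link")) note("link: not a response_link")
  if (!inherits(cfg$surrogate, "surrogate_config")) {
    note("surrogate: not a surrogate_config")
  } else {
    if (cfg$surrogate$budget < cfg$surrogate$n_initial) {
      note("surrogate$budget: smaller than n_initial")
    }
    if (cfg$surrogate$budget < 3) note("surrogate$budget: must be >= 3")
  }
  if (!inherits(cfg$fall, "fall_config")) {
    note("fall: not a fall_config (segment masses must sum to 1)")
  }
  if (cfg$frax_threshold < 0) note("frax_threshold: must be >= 0")
  if (cfg$rr_threshold < 0) note("rr_threshold: must be >= 0")
  if (cfg$compliance < 0 || cfg$compliance > 1) {
    note("compliance: must lie in [0, 1]")
  }
  if (!is.null(cfg$force_protector_shift) && cfg$force_protector_shift < 0) {
    note("force_protector_shift: must be >= 0")
  }
  if (is.na(cfg$seed)) note("seed: mandatory integer")
  if (length(problems) > 0) {
    stop("invalid trial configuration:\n  ",
         paste(problems, collapse = "\n  "))
  }
  cfg
}

#' Read a trial configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [trial_config()]; nested blocks
#' `surrogate`, `fall` and `link` are passed to [surrogate_config()],
#' [fall_config()] and [default_response_link()]. `seed` is a top-level key.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A validated `trial_config`.
#' @export
read_trial_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$surrogate)) raw$surrogate <- do.call(surrogate_config, raw$surrogate)
  if (!is.null(raw$fall)) {
    if (!is.null(raw$fall$segment_bounds)) raw$fall$segment_bounds <- as.numeric(raw$fall$segment_bounds)
    if (!is.null(raw$fall$segment_masses)) raw$fall$segment_masses <- as.numeric(raw$fall$segment_masses)
    raw$fall <- do.call(fall_config, raw$fall)
  }
  if (!is.null(raw$link)) raw$link <- do.call(default_response_link, raw$link)
  if (!is.null(raw$strata)) raw$strata <- as.data.frame(raw$strata)
  if (!is.null(seed)) raw$seed <- seed
  validate_config(raw)
}

#' Run an in-silico hip-protector trial
#'
#' End-to-end pipeline: generate the virtual cohort, assign each subject their
#' latent fracture-response parameters, fit the budgeted active-learning
#' surrogate twice per subject (with and without the hip protector, same
#' surrogate seed so a null protector yields identical curves), extract both
#' critical-velocity curves, integrate them to P_Fx and P_Fx_HP, and compute
#' the cohort report ([cohort_report()]). Deterministic given the master seed.
#'
#' @param config A `trial_config` (validated internally).
#' @param progress Print one line per subject.
#' @return A list of class `trial_result`: `cohort`, `risks` (per-subject
#'   `subject_id`, `p_fx`, `p_fx_hp`, `rr`), `report`, `oracle_calls`
#'   (per-subject call counts) and the validated `config`.
#' @export
run_trial <- function(config = trial_config(), progress = FALSE) {
  config <- validate_config(config)
  cohort <- generate_cohort(config$strata, config$n_per_stratum, config$seed)
  n <- nrow(cohort)
  grid <- seq(config$surrogate$angle_bounds[1], config$surrogate$angle_bounds[2],
              by = 1)
  risks <- vector("list", n)
  calls <- integer(n)
  for (i in seq_len(n)) {
    subj <- cohort[i, ]
    params <- assign_response_params(subj, config$link,
                                     seed = config$seed + 1000L + i)
    if (!is.null(config$force_protector_shift)) {
      params$protector_shift <- config$force_protector_shift
    }
    scfg <- config$surrogate
    scfg$seed <- config$seed + 2000L + i
    fit0 <- tryCatch(
      active_learning_loop(params, scfg, protector = FALSE),
      error = function(e) stop("surrogate stage failed for subject ",
                               subj$subject_id, ": ", conditionMessage(e))
    )
    fit1 <- tryCatch(
      active_learning_loop(params, scfg, protector = TRUE),
      error = function(e) stop("surrogate stage failed for subject ",
                               subj$subject_id, ": ", conditionMessage(e))
    )
    curve0 <- extract_critical_velocity(fit0$model, scfg, grid, protector = FALSE)
    curve1 <- extract_critical_velocity(fit1$model, scfg, grid, protector = TRUE)
    est <- risk_estimate(curve0, curve1, config$fall)
    risks[[i]] <- cbind(data.frame(subject_id = subj$subject_id), est)
    calls[i] <- fit0$n_oracle_calls + fit1$n_oracle_calls
    if (progress) {
      cat(sprintf("[%d/%d] %s  P_Fx %.2f%%  P_Fx_HP %.2f%%\n",
                  i, n, subj$subject_id, est$p_fx, est$p_fx_hp))
    }
  }
  risks <- do.call(rbind, risks)
  rownames(risks) <- NULL
  report <- cohort_report(cohort, risks, config)
  structure(
    list(cohort = cohort, risks = risks, report = report,
         oracle_calls = data.frame(subject_id = cohort$subject_id,
                                   n_oracle_calls = calls),
         config = config),
    class = "trial_result"
  )
}

#' Cohort-level statistics report
#'
#' Summarises per-subject risk estimates: mean/SD of P_Fx, P_Fx_HP and RR
#' (zero-baseline subjects excluded from RR) by sex and by sex-by-ethnicity;
#' high-RR counts against the 0.4 threshold; agreement, Cohen's kappa,
#' McNemar's test and reclassification of the P_Fx top-tertile classification
#' against the FRAX-HFP 2% rule; and compliance-adjusted mean RRs by sex.
#'
#' @param cohort Cohort data.frame (needs `subject_id`, `sex`, `ethnicity`,
#'   `frax_hfp`).
#' @param risks Per-subject risk data.frame (`subject_id`, `p_fx`, `p_fx_hp`,
#'   `rr`).
#' @param config A `trial_config` (thresholds and compliance are read from
#'   it).
#' @return A list of class `cohort_report`.
#' @export
cohort_report <- function(cohort, risks, config = trial_config()) {
  dat <- merge(cohort, risks, by = "subject_id", sort = FALSE)
  dat <- dat[order(match(dat$subject_id, cohort$subject_id)), ]

  summarise_group <- function(d) {
    rr_def <- d$rr[!is.na(d$rr)]
    data.frame(
      n = nrow(d),
      mean_p_fx = mean(d$p_fx), sd_p_fx = stats::sd(d$p_fx),
      mean_p_fx_hp = mean(d$p_fx_hp), sd_p_fx_hp = stats::sd(d$p_fx_hp),
      n_rr_defined = length(rr_def),
      mean_rr = if (length(rr_def) > 0) mean(rr_def) else NA_real_,
      sd_rr = if (length(rr_def) > 1) stats::sd(rr_def) else NA_real_,
      n_rr_high = sum(classify_rr(d$rr, config$rr_threshold) == "high",
                      na.rm = TRUE)
    )
  }
  by_sex <- do.call(rbind, lapply(split(dat, dat$sex), summarise_group))
  by_sex <- cbind(data.frame(sex = rownames(by_sex)), by_sex)
  rownames(by_sex) <- NULL
  key <- interaction(dat$sex, dat$ethnicity, sep = ":", drop = TRUE)
  by_stratum <- do.call(rbind, lapply(split(dat, key), summarise_group))
  by_stratum <- cbind(
    data.frame(stratum = rownames(by_stratum)), by_stratum
  )
  rownames(by_stratum) <- NULL

  frax_class <- classify_frax(dat$frax_hfp, config$frax_threshold)
  tert <- classify_pfx_tertile(dat$p_fx)
  counts <- agreement_counts(
    both_high = sum(frax_class == "high" & tert$class == "high"),
    both_low = sum(frax_class == "low" & tert$class == "low"),
    down = sum(frax_class == "high" & tert$class == "low"),
    up = sum(frax_class == "low" & tert$class == "high")
  )
  adj <- by_sex[, c("sex", "mean_rr")]
  adj$adjusted_rr <- compliance_adjust(adj$mean_rr, config$compliance)

  structure(
    list(
      n_subjects = nrow(dat),
      by_sex = by_sex,
      by_stratum = by_stratum,
      pfx_tertile_threshold = tert$threshold,
      agreement = counts,
      kappa = cohens_kappa(counts),
      mcnemar = mcnemar_test(counts),
      reclassification = reclassification(counts),
      compliance = config$compliance,
      adjusted_rr_by_sex = adj
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("In-silico trial report (", x$n_subjects, " subjects)\n", sep = "")
  cat("\nRisk by sex:\n")
  print(x$by_sex, digits = 3, row.names = FALSE)
  cat(sprintf("\nP_Fx top-tertile threshold: %.2f%%\n", x$pfx_tertile_threshold))
  cat(sprintf("FRAX vs P_Fx agreement: kappa = %.3f, McNemar p = %.3g (%s)\n",
              x$kappa, x$mcnemar$p_value, x$mcnemar$method))
  cat(sprintf("Down-classification %.2f%%, net down-classification %.2f%%\n",
              x$reclassification$down_pct, x$reclassification$net_down_pct))
  cat(sprintf("\nCompliance-adjusted RR (compliance %.0f%%):\n",
              100 * x$compliance))
  print(x$adjusted_rr_by_sex, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
print.trial_result <- function(x, ...) {
  cat("hipfxsim trial:", nrow(x$cohort), "subjects,",
      sum(x$oracle_calls$n_oracle_calls), "oracle simulations\n\n")
  print(x$report)
  invisible(x)
}
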