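#' Specification of a synthetic lesion-table cohort
#'
#' The voxel-free fast path: per-patient baseline and follow-up lesion
#' measurements are drawn directly from configured distributions, together
#' with the intended response class per criterion and class-dependent
#' survival. Defaults emulate a small multicenter melanoma cohort under
#' checkpoint-inhibitor therapy: 27 patients, baseline SUV_max log-normal
#' with mean 7.3 and SD 5.0, a scenario mix dominated by progression with
#' new-lesion appearance, and 2-year progression-free survival near 85%
#' for responders vs 10% for non-responders.
#'
#' @param n_patients number of patients (>= 0).
#' @param class_mix named non-negative weights over scenario kinds (see
#'   [scenario_spec()]); normalized to probabilities. Patients are
#'   allocated deterministically in these proportions (largest-remainder
#'   rounding), then the order is shuffled.
#' @param lesion_count_range integer range of baseline lesions per patient;
#'   capped at 5 so target selection never truncates.
#' @param organ_pool organ labels; at most two lesions share an organ.
#' @param suvmax_mean,suvmax_sd desired mean and SD of the baseline
#'   SUV_max distribution (log-normal parameters are derived from them).
#' @param suv_mean_ratio,suv_peak_ratio,sul_factor fixed ratios deriving
#'   SUV_mean, SUV_peak and SUL_peak from SUV_max (`sul_factor` is the
#'   LBM-over-weight scale, about 0.79 for a 70 kg / 170 cm male).
#' @param mtv_meanlog,mtv_sdlog log-normal parameters for per-lesion MTV (mL).
#' @param new_lesion_suv_max SUV_max of generated new lesions (chosen above
#'   the PERCIST measurability floor).
#' @param noise_cv multiplicative log-normal noise applied per lesion and
#'   time point to all metrics jointly (0 = noise-free).
#' @param liver_sul_mean,liver_sul_sd liver SUL reference statistics.
#' @param background_mean,background_sd follow-up background activity.
#' @param resolution_residual_suv residual SUV_max of a resolved lesion.
#' @param prog_hazard_responder,prog_hazard_nonresponder exponential
#'   progression hazards (per month) for responders (CMR/PMR) and
#'   non-responders; defaults invert 2-year PFS of 85% and 10%.
#' @param death_hazard_post_progression exponential hazard of death after
#'   progression (per month).
#' @param censoring_window_months administrative censoring drawn uniformly
#'   from this window.
#' @param seed integer RNG seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 27L,
                        class_mix = c(resolution = 3, strong_response = 5,
                                      stable = 4, growth = 3,
                                      growth_plus_new = 10,
                                      new_lesion_only = 2),
                        lesion_count_range = c(1L, 4L),
                        organ_pool = c("lymph_node", "bone", "soft_tissue",
                                       "bowel", "lung", "liver", "abdominal",
                                       "nasal_cavity", "salivary_gland",
                                       "adrenal", "pancreas", "vagina",
                                       "vulva", "anus"),
                        suvmax_mean = 7.3, suvmax_sd = 5.0,
                        suv_mean_ratio = 0.62, suv_peak_ratio = 0.85,
                        sul_factor = 0.79,
                        mtv_meanlog = log(4), mtv_sdlog = 0.6,
                        new_lesion_suv_max = 5.5,
                        noise_cv = 0.10,
                        liver_sul_mean = 1.9, liver_sul_sd = 0.2,
                        background_mean = 0.9, background_sd = 0.1,
                        resolution_residual_suv = 0.9,
                        prog_hazard_responder = -log(0.85) / 24,
                        prog_hazard_nonresponder = -log(0.10) / 24,
                        death_hazard_post_progression = log(2) / 10,
                        censoring_window_months = c(24, 68),
                        seed = 1L) {
  if (any(class_mix < 0)) stop("`class_mix` weights must be non-negative")
  if (sum(class_mix) <= 0) stop("`class_mix` must have positive total weight")
  bad <- setdiff(names(class_mix),
                 c("resolution", "strong_response", "stable", "growth",
                   "new_lesion_only", "growth_plus_new"))
  if (length(bad)) stop("unknown scenario kind(s): ", paste(bad, collapse = ", "))
  stopifnot(n_patients >= 0, suvmax_mean > 0, suvmax_sd > 0,
            suv_peak_ratio <= 1, suv_mean_ratio >= 0.4 * 1,
            sul_factor > 0, sul_factor <= 1, noise_cv >= 0,
            prog_hazard_responder >= 0, prog_hazard_nonresponder >= 0,
            death_hazard_post_progression > 0,
            length(censoring_window_months) == 2L,
            censoring_window_months[1] > 0,
            diff(censoring_window_months) >= 0,
            lesion_count_range[1] >= 1)
  structure(list(
    n_patients = as.integer(n_patients),
    class_mix = class_mix / sum(class_mix),
    lesion_count_range = pmin(as.integer(lesion_count_range), 5L),
    organ_pool = organ_pool,
    suvmax_mean = suvmax_mean, suvmax_sd = suvmax_sd,
    suv_mean_ratio = suv_mean_ratio, suv_peak_ratio = suv_peak_ratio,
    sul_factor = sul_factor,
    mtv_meanlog = mtv_meanlog, mtv_sdlog = mtv_sdlog,
    new_lesion_suv_max = new_lesion_suv_max,
    noise_cv = noise_cv,
    liver_sul_mean = liver_sul_mean, liver_sul_sd = liver_sul_sd,
    background_mean = background_mean, background_sd = background_sd,
    resolution_residual_suv = resolution_residual_suv,
    prog_hazard_responder = prog_hazard_responder,
    prog_hazard_nonresponder = prog_hazard_nonresponder,
    death_hazard_post_progression = death_hazard_post_progression,
    censoring_window_months = censoring_window_months,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Log-normal parameters matching a target mean and SD
#'
#' Inverts the log-normal moment equations: given the desired arithmetic
#' mean m and SD s, `sdlog^2 = log(1 + s^2/m^2)` and
#' `meanlog = log(m) - sdlog^2 / 2`.
#'
#' @param mean,sd desired arithmetic mean and SD (> 0).
#' @return List with `meanlog`, `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# deterministic largest-remainder allocation of n patients to the mix
allocate_classes <- function(n, mix) {
  if (n == 0L) return(character(0))
  exact <- n * mix
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

# one multiplicative log-normal noise factor per row, applied to all
# metrics jointly so ratio invariants (peak <= max etc.) survive
apply_row_noise <- function(frame, cv) {
  if (!nrow(frame) || cv == 0) return(frame)
  sdlog <- sqrt(log(1 + cv^2))
  fac <- exp(stats::rnorm(nrow(frame), -sdlog^2 / 2, sdlog))
  for (col in c("suv_max", "suv_mean", "suv_peak", "sul_peak", "tlg"))
    frame[[col]] <- frame[[col]] * fac
  frame
}

# intended class per criterion from the noise-free construction: plain sum
# arithmetic (selection caps never bind: <= 5 lesions, <= 2 per organ by
# construction)
intended_classes <- function(base, fu, spec) {
  liver_cut <- spec$liver_sul_mean + 2 * spec$liver_sul_sd
  floor_cut <- 1.5 * spec$liver_sul_mean + 2 * spec$liver_sul_sd
  bg_ceiling <- spec$background_mean + 2 * spec$background_sd
  is_new <- is.na(fu$mapped_baseline_id)
  n_new <- sum(is_new & fu$sul_peak >= floor_cut)
  mapped <- fu[!is_new, , drop = FALSE]
  # EORTC: summed SUV_max of the matched lesions
  fu_vals <- mapped$suv_max[match(base$lesion_id, mapped$mapped_baseline_id)]
  fu_vals[is.na(fu_vals)] <- spec$background_mean
  d_eortc <- 100 * (sum(fu_vals) - sum(base$suv_max)) / sum(base$suv_max)
  eortc <- if (n_new > 0) "PMD"
  else if (!nrow(fu) || all(fu$suv_max <= bg_ceiling)) "CMR"
  else if (d_eortc <= -25) "PMR"
  else if (d_eortc >= 25) "PMD"
  else "SMD"
  # PERCIST: summed SUL_peak, hottest per scan (= all rows here)
  b_sul <- sum(base$sul_peak)
  f_sul_all <- sum(fu$sul_peak)
  d_tlg <- if (sum(base$tlg) > 0)
    100 * (sum(fu$tlg) - sum(base$tlg)) / sum(base$tlg) else NA_real_
  d_percist <- 100 * (f_sul_all - b_sul) / b_sul
  percist <- if (n_new > 0) "PMD"
  else if (!is.na(d_tlg) && d_tlg >= 75) "PMD"
  else if (!nrow(fu) || all(fu$sul_peak < liver_cut)) "CMR"
  else if (d_percist >= 30) "PMD"
  else if (d_percist <= -30) "PMR"
  else "SMD"
  # imPERCIST: new lesions join the sum (all eligible here: < 5 baseline
  # targets or hotter than persisting disease)
  persist_peak <- if (nrow(mapped)) max(mapped$sul_peak) else -Inf
  elig <- is_new & (fu$sul_peak >= floor_cut) &
    (fu$sul_peak > persist_peak | nrow(base) < 5)
  f_sul_im <- sum(mapped$sul_peak) + sum(fu$sul_peak[elig])
  d_im <- 100 * (f_sul_im - b_sul) / b_sul
  impercist <- if (d_im >= 30) "PMD"
  else if (!nrow(fu) || all(fu$sul_peak < liver_cut)) "CMR"
  else if (d_im <= -30) "PMR"
  else "SMD"
  c(eortc = eortc, percist = percist, impercist = impercist)
}

#' Generate a synthetic lesion-level cohort
#'
#' Draws per-patient baseline lesions (log-normal SUV_max, fixed derived
#' metric ratios), applies the assigned response scenario to obtain the
#' noise-free follow-up measurements, records the intended response class
#' per criterion from that construction, and finally degrades both time
#' points with multiplicative log-normal noise. Identical spec and seed
#' give identical output.
#'
#' @param spec a [cohort_spec()].
#' @return List with `pairs` (list of [scan_pair()]), `truth` (data.frame:
#'   `patient_id`, `scenario`, intended `eortc`/`percist`/`impercist`),
#'   and `table` (the long lesion table, see [write_lesion_table()]).
#' @export
generate_lesion_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  if (spec$n_patients == 0L) {
    return(list(pairs = list(),
                truth = data.frame(patient_id = character(0),
                                   scenario = character(0),
                                   eortc = character(0),
                                   percist = character(0),
                                   impercist = character(0),
                                   stringsAsFactors = FALSE),
                table = empty_lesion_table()))
  }
  kinds <- sample(allocate_classes(spec$n_patients, spec$class_mix))
  lp <- lognormal_params(spec$suvmax_mean, spec$suvmax_sd)
  liver <- liver_reference_values(spec$liver_sul_mean, spec$liver_sul_sd)
  pairs <- vector("list", spec$n_patients)
  truth <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", p)
    kind <- kinds[p]
    counts <- seq(spec$lesion_count_range[1], spec$lesion_count_range[2])
    n_les <- if (length(counts) == 1L) counts else sample(counts, 1L)
    organs <- sample(rep(spec$organ_pool, 2L))[seq_len(n_les)]
    smax <- stats::rlnorm(n_les, lp$meanlog, lp$sdlog)
    mtv <- stats::rlnorm(n_les, spec$mtv_meanlog, spec$mtv_sdlog)
    base <- data.frame(
      lesion_id = sprintf("%s_B%02d", pid, seq_len(n_les)),
      organ = organs,
      suv_max = smax,
      suv_mean = spec$suv_mean_ratio * smax,
      suv_peak = spec$suv_peak_ratio * smax,
      sul_peak = spec$sul_factor * spec$suv_peak_ratio * smax,
      mtv_ml = mtv,
      tlg = spec$suv_mean_ratio * smax * mtv,
      stringsAsFactors = FALSE
    )
    scen <- scenario_spec(kind, new_lesion_peak_suv = spec$new_lesion_suv_max)
    fu <- followup_from_baseline(base, scen, spec)
    cls <- intended_classes(base, fu, spec)
    base_n <- apply_row_noise(base, spec$noise_cv)
    fu_n <- apply_row_noise(fu, spec$noise_cv)
    pairs[[p]] <- scan_pair(pid, base_n, fu_n,
                            liver_followup = liver, liver_baseline = liver,
                            background_mean = spec$background_mean,
                            background_sd = spec$background_sd)
    truth[[p]] <- data.frame(patient_id = pid, scenario = kind,
                             eortc = cls[["eortc"]],
                             percist = cls[["percist"]],
                             impercist = cls[["impercist"]],
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  list(pairs = pairs, truth = truth, table = pairs_to_table(pairs))
}

# noise-free follow-up rows for one patient under a scenario
followup_from_baseline <- function(base, scen, spec) {
  pid_prefix <- sub("_B.*$", "", base$lesion_id[1])
  if (scen$kind == "resolution") {
    fu <- base
    fu$lesion_id <- sub("_B", "_F", base$lesion_id)
    fu$mapped_baseline_id <- base$lesion_id
    resid <- spec$resolution_residual_suv
    fu$suv_max <- resid
    fu$suv_mean <- 0.9 * resid
    fu$suv_peak <- 0.95 * resid
    fu$sul_peak <- spec$sul_factor * 0.95 * resid
    fu$mtv_ml <- 0
    fu$tlg <- 0
    return(fu)
  }
  f <- scen$factor
  fu <- base
  fu$lesion_id <- sub("_B", "_F", base$lesion_id)
  fu$mapped_baseline_id <- base$lesion_id
  for (col in c("suv_max", "suv_mean", "suv_peak", "sul_peak", "tlg"))
    fu[[col]] <- f * fu[[col]]
  if (scen$n_new_lesions > 0L) {
    used <- table(base$organ)
    free <- setdiff(spec$organ_pool, names(used)[used >= 2])
    organs <- rep(free, length.out = scen$n_new_lesions)
    smax <- rep(scen$new_lesion_peak_suv, scen$n_new_lesions)
    mtv <- rep(exp(spec$mtv_meanlog), scen$n_new_lesions)
    fu <- rbind(fu, data.frame(
      lesion_id = sprintf("%s_N%02d", pid_prefix, seq_len(scen$n_new_lesions)),
      organ = organs,
      suv_max = smax,
      suv_mean = spec$suv_mean_ratio * smax,
      suv_peak = spec$suv_peak_ratio * smax,
      sul_peak = spec$sul_factor * spec$suv_peak_ratio * smax,
      mtv_ml = mtv,
      tlg = spec$suv_mean_ratio * smax * mtv,
      mapped_baseline_id = NA_character_,
      stringsAsFactors = FALSE
    ))
  }
  fu
}

#' Generate class-dependent survival records
#'
#' Progression times are exponential with a hazard set by responder status
#' (CMR/PMR vs SMD/PMD) under the chosen criterion; overall survival is
#' progression time plus an exponential post-progression survival time, so
#' OS >= PFS always. Both endpoints share one administrative censoring time
#' drawn uniformly from the censoring window. A zero hazard yields an
#' infinite latent time, i.e. certain censoring.
#'
#' @param truth data.frame with `patient_id` and a class column per
#'   criterion (as returned by [generate_lesion_cohort()]), or any frame
#'   with a `patient_id` and the chosen `criterion` column of
#'   CMR/PMR/SMD/PMD labels.
#' @param spec a [cohort_spec()] (hazards and censoring window).
#' @param criterion which class column drives the hazard.
#' @return List with `pfs` and `os` data.frames
#'   (`patient_id`, `time_months`, `event`, `stratum`, `response_class`).
#' @export
generate_survival <- function(truth, spec,
                              criterion = c("percist", "eortc", "impercist")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(spec, "cohort_spec"))
  if (!criterion %in% names(truth))
    stop("`truth` lacks a ", criterion, " column")
  set.seed(spec$seed + 104729L)  # decoupled stream from the lesion draw
  n <- nrow(truth)
  cls <- as.character(truth[[criterion]])
  responder <- cls %in% c("CMR", "PMR")
  haz <- ifelse(responder, spec$prog_hazard_responder,
                spec$prog_hazard_nonresponder)
  rexp0 <- function(n, rate) ifelse(rate > 0,
                                    stats::rexp(n, pmax(rate, 1e-300)), Inf)
  t_prog <- rexp0(n, haz)
  t_death <- t_prog + rexp0(n, rep(spec$death_hazard_post_progression, n))
  cens <- stats::runif(n, spec$censoring_window_months[1],
                       spec$censoring_window_months[2])
  stratum <- ifelse(responder, "responder", "non-responder")
  pfs <- data.frame(patient_id = truth$patient_id,
                    time_months = pmin(t_prog, cens),
                    event = as.integer(t_prog <= cens),
                    stratum = stratum, response_class = cls,
                    stringsAsFactors = FALSE)
  os <- data.frame(patient_id = truth$patient_id,
                   time_months = pmin(t_death, cens),
                   event = as.integer(t_death <= cens),
                   stratum = stratum, response_class = cls,
                   stringsAsFactors = FALSE)
  list(pfs = pfs, os = os)
}
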