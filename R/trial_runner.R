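# Virtual-trial orchestration: non-compartmental PK metrics, BSA dose
# banding, trough-target attainment, seeded replicate trials, and the
# bundled verification cohorts.

#' Non-compartmental PK metrics over an assessment interval
#'
#' Trapezoidal AUC; `auc_0_inf = AUC_0-t + C_last/lambda_z`, with lambda_z
#' fitted log-linearly over the terminal tail (points after t_max in the
#' final third of the interval, at least three); `cl_over_f = dose/AUC`
#' (AUC_0-inf for a single dose, AUC_tau otherwise); `cmin` is the
#' end-of-interval trough; `c24` the concentration 24 h after the interval
#' start.
#'
#' @param result a `simulation_result`.
#' @param dose dose administered in the assessed interval, mg.
#' @param interval `c(start, end)` of the assessment window, h (default the
#'   whole simulation).
#' @param single_dose treat the profile as a single dose (extrapolate to
#'   infinity for CL/F)?
#' @return a `pk_metrics` list: `cmax`, `tmax`, `cmin`, `c24`, `auc_tau`,
#'   `auc_0_inf`, `lambda_z`, `cl_over_f` (units mg/L, h, mg.h/L, L/h).
#' @export
nca_metrics <- function(result, dose, interval = NULL, single_dose = FALSE) {
  interval <- interval %||% range(result$times)
  sel <- result$times >= interval[1] - 1e-9 & result$times <= interval[2] +
    1e-9
  tt <- result$times[sel]
  cc <- result$plasma[sel]
  if (length(tt) < 3) stop("assessment interval not covered", call. = FALSE)
  imax <- which.max(cc)
  cmax <- cc[imax]
  tmax <- tt[imax] - interval[1]
  auc_tau <- .trapz(tt, cc)
  cmin <- cc[length(cc)]
  c24 <- if (interval[1] + 24 <= interval[2] + 1e-9)
    stats::approx(tt, cc, xout = interval[1] + 24)$y else NA_real_
  lambda_z <- NA_real_
  auc_inf <- NA_real_
  tail_start <- max(tt[imax], interval[2] - diff(interval) / 3)
  tail <- tt > tail_start + 1e-9 & cc > 0
  if (sum(tail) >= 3) {
    fit <- stats::lm(log(cc[tail]) ~ tt[tail])
    slope <- unname(stats::coef(fit)[2])
    if (is.finite(slope) && slope < 0) {
      lambda_z <- -slope
      auc_inf <- auc_tau + cc[length(cc)] / lambda_z
    }
  }
  if (single_dose && !is.finite(auc_inf))
    warning("terminal slope not estimable; AUC_0-inf missing",
            call. = FALSE)
  cl_over_f <- if (single_dose) dose / auc_inf else dose / auc_tau
  structure(list(cmax = cmax, tmax = tmax, cmin = cmin, c24 = c24,
                 auc_tau = auc_tau, auc_0_inf = auc_inf,
                 lambda_z = lambda_z, cl_over_f = cl_over_f),
            class = "pk_metrics")
}

#' BSA-banded dose with 50-mg rounding and adult-dose cap
#'
#' `round(dose_per_m2 * bsa)` to the nearest 50 mg (ties round up: half a
#' 100-mg tablet is the smallest dispensable unit), then capped at the
#' equivalent adult dose.
#'
#' @param dose_per_m2 mg/m^2.
#' @param bsa m^2.
#' @param adult_equivalent_cap cap in mg (170, 230, 340, 460 mg/m^2
#'   correspond to adult doses of 300, 400, 600, 800 mg).
#' @return dose in mg.
#' @export
dose_for_bsa <- function(dose_per_m2, bsa, adult_equivalent_cap = Inf) {
  if (!isTRUE(dose_per_m2 > 0) || !isTRUE(bsa > 0))
    stop("dose_per_m2 and bsa must be positive", call. = FALSE)
  raw <- dose_per_m2 * bsa
  rounded <- 50 * floor(raw / 50 + 0.5)
  min(rounded, adult_equivalent_cap)
}

# adult-equivalent caps for the standard BSA-normalised doses
BSA_DOSE_CAPS <- c("170" = 300, "230" = 400, "340" = 600, "460" = 800)

#' Fraction of troughs below/within/above the target window
#'
#' The efficacy/safety window is closed: boundary values count as within.
#'
#' @param cmin_values troughs, mg/L.
#' @param window `c(lower, upper)`, mg/L; default 1.0-3.2 mg/L
#'   (1,000-3,200 ng/ml).
#' @return named fractions `below`, `within`, `above` (summing to 1).
#' @export
target_attainment <- function(cmin_values, window = c(1.0, 3.2)) {
  if (!length(cmin_values)) stop("empty cmin list", call. = FALSE)
  below <- mean(cmin_values < window[1])
  above <- mean(cmin_values > window[2])
  c(below = below, within = 1 - below - above, above = above)
}

#' Ratio of predicted to observed parameter value
#'
#' @param predicted model prediction.
#' @param observed clinically reported value (> 0).
#' @return fold-difference (unitless).
#' @export
fold_difference <- function(predicted, observed) {
  if (!isTRUE(observed > 0)) stop("observed must be > 0", call. = FALSE)
  predicted / observed
}

#' Study design for a virtual trial
#'
#' @param n subjects per trial.
#' @param age_min,age_max,proportion_female population covariate ranges.
#' @param dose dose amount: mg if `per_m2 = FALSE`, else mg/m^2 (rounded to
#'   50 mg per individual and capped).
#' @param per_m2 is the dose BSA-normalised?
#' @param cap adult-equivalent cap, mg (defaults from the standard banding
#'   table when `per_m2`).
#' @param interval dosing interval, h.
#' @param n_days treatment duration, days.
#' @param n_trials number of replicate trials.
#' @param seed master seed; trial `k` uses `seed + k`.
#' @param age_bands optional named list of `c(min, max)` bands for per-band
#'   summaries.
#' @return a `study_design` object.
#' @export
study_design <- function(n, age_min, age_max, proportion_female = 0.4,
                         dose, per_m2 = FALSE, cap = NULL, interval = 24,
                         n_days = 1, n_trials = 10, seed = 1,
                         age_bands = NULL) {
  if (!isTRUE(n_trials >= 1)) stop("n_trials must be >= 1", call. = FALSE)
  if (per_m2 && is.null(cap)) {
    cap <- unname(BSA_DOSE_CAPS[as.character(dose)])
    if (is.na(cap)) cap <- Inf
  }
  if (!is.null(age_bands)) {
    b <- do.call(rbind, age_bands)
    o <- order(b[, 1])
    if (any(b[o, 1][-1] < b[o, 2][-nrow(b)]))
      stop("age bands must not overlap", call. = FALSE)
  }
  structure(list(n = n, age_min = age_min, age_max = age_max,
                 proportion_female = proportion_female, dose = dose,
                 per_m2 = per_m2, cap = cap %||% Inf, interval = interval,
                 n_days = n_days, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), age_bands = age_bands),
            class = "study_design")
}

#' Resolve the administered dose for one individual
#' @keywords internal
resolve_dose <- function(design, indiv) {
  if (design$per_m2) dose_for_bsa(design$dose, indiv$bsa, design$cap)
  else design$dose
}

# geometric mean and geometric CV% (log-scale convention)
.geo_mean <- function(x) exp(mean(log(x)))
.geo_cv <- function(x) 100 * sqrt(exp(stats::var(log(x))) - 1)

#' Run a seeded virtual study
#'
#' Simulates `n_trials` independently seeded populations under the design's
#' regimen and summarises day-1 and last-day (steady-state) metrics.
#' Multiple-dose designs are simulated for `n_days` plus a trailing washout
#' day is not added; day-1 CL/F uses the extrapolated AUC_0-inf of a
#' dedicated single-dose profile of the same individual (the first dose of a
#' chronic regimen has single-dose kinetics), while steady-state CL/F is
#' dose/AUC over the final dosing interval.  Results pool all individuals
#' across trials (geometric means and geometric CV%).
#'
#' @param design a [study_design()].
#' @param drug a `drug_parameters` object.
#' @param metrics_day1 compute day-1/single-dose metrics (adds one 96-h
#'   single-dose simulation per subject)?
#' @return a `trial_summary`.
#' @export
run_virtual_study <- function(design, drug, metrics_day1 = TRUE) {
  part <- predict_tissue_partition(drug$physchem)
  multiple <- design$n_days > 1
  rows <- list()
  for (trial in seq_len(design$n_trials)) {
    pop <- generate_population(population_spec(
      design$n, design$age_min, design$age_max, design$proportion_female,
      seed = design$seed + trial))
    for (ind in pop$individuals) {
      dose <- resolve_dose(design, ind)
      m1 <- mss <- NULL
      if (metrics_day1) {
        st1 <- simulation_settings(duration = 96, output_dt = 0.1,
                                   steady_state_compensation = FALSE)
        r1 <- simulate_pbpk(build_model(drug, ind, settings = st1,
                                        partition = part),
                            list(dose_event(0, dose, "oral")))
        m1 <- nca_metrics(r1, dose, single_dose = TRUE)
      }
      if (multiple) {
        dur <- design$n_days * 24
        stn <- simulation_settings(duration = dur, output_dt = 0.25)
        doses <- regimen(dose, design$interval,
                         n_doses = ceiling(dur / design$interval))
        rn <- simulate_pbpk(build_model(drug, ind, settings = stn,
                                        partition = part), doses)
        mss <- nca_metrics(rn, dose * design$interval / 24,
                           interval = c(dur - design$interval, dur))
      }
      rows[[length(rows) + 1]] <- data.frame(
        trial = trial, id = ind$id, age = ind$age, sex = ind$sex,
        bsa = ind$bsa, dose = dose,
        cmax_d1 = m1$cmax %||% NA_real_, tmax_d1 = m1$tmax %||% NA_real_,
        auc_inf_d1 = m1$auc_0_inf %||% NA_real_,
        auc24_d1 = if (!is.null(m1))
          .trapz(r1$times[r1$times <= 24], r1$plasma[r1$times <= 24])
        else NA_real_,
        cl_f_d1 = m1$cl_over_f %||% NA_real_,
        cmax_ss = mss$cmax %||% NA_real_, cmin_ss = mss$cmin %||% NA_real_,
        auc_tau_ss = mss$auc_tau %||% NA_real_,
        cl_f_ss = mss$cl_over_f %||% NA_real_)
    }
  }
  df <- do.call(rbind, rows)
  summarise_metric <- function(x) {
    x <- x[is.finite(x) & x > 0]
    if (!length(x)) return(c(geo_mean = NA_real_, geo_cv = NA_real_))
    c(geo_mean = .geo_mean(x), geo_cv = .geo_cv(x))
  }
  pooled <- sapply(df[, setdiff(names(df), c("trial", "id", "age", "sex",
                                             "bsa", "dose"))],
                   summarise_metric)
  bands <- NULL
  if (!is.null(design$age_bands) && multiple) {
    bands <- lapply(names(design$age_bands), function(b) {
      rg <- design$age_bands[[b]]
      sub <- df[df$age >= rg[1] & df$age < rg[2], ]
      data.frame(band = b, n = nrow(sub),
                 cmin_mean = mean(sub$cmin_ss),
                 cmin_sd = stats::sd(sub$cmin_ss),
                 within = unname(target_attainment(sub$cmin_ss)["within"]),
                 below = unname(target_attainment(sub$cmin_ss)["below"]))
    })
    bands <- do.call(rbind, bands)
  }
  structure(list(individuals = df, pooled = pooled, bands = bands,
                 design = design), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("<trial_summary>", nrow(x$individuals), "subjects (",
      x$design$n_trials, "trials x", x$design$n, ")\n")
  print(round(x$pooled, 3))
  if (!is.null(x$bands)) print(x$bands)
  invisible(x)
}

#' Bundled verification cohorts and reference values
#'
#' The clinical cohorts used for model verification.
#' `verification_cohorts()` gives one row per cohort (trial design and
#' regimen); `verification_metrics()` gives one row per (cohort, metric)
#' with the clinically observed value and the reference model prediction it
#' is compared against at the 1.25-fold criterion.  `population` tags the
#' rows so the adult subset can be asserted separately from the paediatric
#' one; `sparse` marks cohorts with very few subjects/samples whose metrics
#' are reported but not asserted.
#'
#' @return data.frame.
#' @export
verification_cohorts <- function() {
  data.frame(
    cohort = c("healthy_adult", "gist_adult", "gist_adult2", "pah_adult",
               "paed_gist", "paed_solid", "paed_cml", "paed_all"),
    n = c(12, 34, 50, 103, 33, 41, 26, 4),
    age_min = c(40, 28, 39, 18, 2, 6, 4, 6),
    age_max = c(58, 84, 82, 77, 22, 24, 17, 15),
    n_female = c(2, 6, 21, 83, 13, 14, 6, 2),
    dose = c(400, 400, 400, 400, 340, 440, 300, 300),
    per_m2 = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    n_days = c(1, 14, 14, 14, 14, 14, 14, 14),
    population = c("adult", "adult", "adult", "adult", "paediatric",
                   "paediatric", "paediatric", "paediatric"),
    sparse = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' @rdname verification_cohorts
#' @export
verification_metrics <- function() {
  data.frame(
    cohort = c("healthy_adult", "healthy_adult", "healthy_adult",
               "healthy_adult",
               "gist_adult", "gist_adult", "gist_adult2", "pah_adult",
               "paed_gist", "paed_gist", "paed_solid", "paed_solid",
               "paed_cml", "paed_all", "paed_all"),
    metric = c("cmax_d1", "tmax_d1", "auc_inf_d1", "cl_f_d1",
               "cl_f_d1", "cl_f_ss", "cl_f_ss", "cl_f_ss",
               "cl_f_d1", "cl_f_ss", "cl_f_d1", "cl_f_ss",
               "cmin_ss", "cmax_d1", "auc24_d1"),
    predicted = c(1.6, 2.6, 32.1, 12.5, 11.2, 10.7, 9.6, 9.8,
                  7.6, 6.8, 10.1, 8.7, 1.2, 3.3, 49),
    observed = c(1.8, 2.5, 32.6, 14.9, 10.9, 10.9, 9.1, 10.8,
                 7.8, 7.8, 10.8, 10.8, 1.4, 3.9, 55),
    stringsAsFactors = FALSE)
}

#' Re-simulate the verification cohorts
#'
#' Runs each bundled cohort design (10 seeded virtual trials by default) and
#' reports every bundled metric next to the reference prediction and the
#' observed value, with fold-differences.  Pooled metrics are geometric
#' means except the steady-state trough, which is the arithmetic cohort
#' mean (matching how the reference value is reported).
#'
#' @param drug a `drug_parameters` object.
#' @param cohorts subset of [verification_cohorts()] rows.
#' @param n_trials replicate trials per cohort.
#' @param seed master seed.
#' @return data.frame report, one row per (cohort, metric).
#' @export
verify_cohorts <- function(drug = builtin_imatinib(),
                           cohorts = verification_cohorts(), n_trials = 10,
                           seed = 1) {
  mets <- verification_metrics()
  mets <- mets[mets$cohort %in% cohorts$cohort, ]
  mets$simulated <- NA_real_
  for (i in seq_len(nrow(cohorts))) {
    ch <- cohorts[i, ]
    rows <- which(mets$cohort == ch$cohort)
    if (!length(rows)) next
    des <- study_design(ch$n, ch$age_min, ch$age_max,
                        proportion_female = ch$n_female / ch$n,
                        dose = ch$dose, per_m2 = ch$per_m2,
                        n_days = ch$n_days, n_trials = n_trials,
                        seed = seed + 1000 * i)
    need_d1 <- any(grepl("_d1$", mets$metric[rows]))
    ts <- run_virtual_study(des, drug, metrics_day1 = need_d1)
    for (r in rows) {
      m <- mets$metric[r]
      mets$simulated[r] <- if (m == "cmin_ss")
        mean(ts$individuals$cmin_ss)
      else unname(ts$pooled["geo_mean", m])
    }
  }
  mets <- merge(mets, cohorts[, c("cohort", "n", "population", "sparse")],
                by = "cohort", sort = FALSE)
  mets$fold_vs_predicted <- mets$simulated / mets$predicted
  mets$fold_vs_observed <- mets$simulated / mets$observed
  mets
}
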