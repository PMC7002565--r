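# Whole-body PBPK engine: model assembly, stiff integration with dose
# events, enzyme-pool dynamics, and derived outputs.

#' Dose event
#'
#' @param time dosing time, h.
#' @param amount dose, mg.
#' @param route `"oral"` or `"iv_infusion"`.
#' @param infusion_duration infusion length in h (iv only).
#' @return a `dose_event` object.
#' @export
dose_event <- function(time, amount, route = c("oral", "iv_infusion"),
                       infusion_duration = NULL) {
  route <- match.arg(route)
  if (!isTRUE(amount >= 0)) stop("amount must be >= 0", call. = FALSE)
  if (route == "iv_infusion" && !isTRUE(infusion_duration > 0))
    stop("infusion_duration must be > 0 for iv infusions", call. = FALSE)
  structure(list(time = time, amount = amount, route = route,
                 infusion_duration = infusion_duration),
            class = "dose_event")
}

#' Repeated-dose regimen helper
#'
#' @param amount dose per administration, mg.
#' @param interval dosing interval, h.
#' @param n_doses number of administrations.
#' @param route,infusion_duration as in [dose_event()].
#' @param start time of the first dose, h.
#' @return list of `dose_event`s.
#' @export
regimen <- function(amount, interval = 24, n_doses = 1, route = "oral",
                    infusion_duration = NULL, start = 0) {
  lapply(seq_len(n_doses) - 1L, function(k)
    dose_event(start + k * interval, amount, route, infusion_duration))
}

#' Simulation settings
#'
#' @param duration total simulated time, h.
#' @param output_dt output grid resolution, h.
#' @param solver_rel_tol,solver_abs_tol integrator tolerances.
#' @param mbi enable the victim's mechanism-based CYP3A4 autoinhibition
#'   (`"auto"`: on for multiple-dose regimens, off for single doses).
#' @param steady_state_compensation enable the pool-independent compensatory
#'   hepatic clearance (`"auto"` as for `mbi`).
#' @param peripheral_sampling also report the peripheral-vein-corrected
#'   concentration series.
#' @return a `simulation_settings` object.
#' @export
simulation_settings <- function(duration = 24, output_dt = 0.1,
                                solver_rel_tol = 1e-8,
                                solver_abs_tol = 1e-10,
                                mbi = "auto",
                                steady_state_compensation = "auto",
                                peripheral_sampling = FALSE) {
  if (!isTRUE(duration > 0)) stop("duration must be > 0", call. = FALSE)
  if (!isTRUE(solver_rel_tol > 0) || !isTRUE(solver_abs_tol > 0))
    stop("solver tolerances must be > 0", call. = FALSE)
  structure(list(duration = duration, output_dt = output_dt,
                 solver_rel_tol = solver_rel_tol,
                 solver_abs_tol = solver_abs_tol, mbi = mbi,
                 steady_state_compensation = steady_state_compensation,
                 peripheral_sampling = peripheral_sampling),
            class = "simulation_settings")
}

# turnover rate constants (1/h): hepatic CYP3A4, hepatic CYP2C8, gut CYP3A4
KDEG <- c(liver_cyp3a4 = 0.0193, liver_cyp2c8 = 0.0301,
          gut_cyp3a4 = 0.0288)

# compensatory-clearance coupling: 1 = proportional to the inactivated
# CYP3A4 fraction, 0 = unconditionally active whenever enabled
COMPENSATION_MODE <- 1

# gut CYP3A4 whole-gut intrinsic clearance at the adult baseline pool (L/h);
# small, consistent with negligible enterocyte metabolism of imatinib, but
# non-zero so intestinal induction/inactivation dynamics stay representable
GUT_CLINT_ADULT <- 0.2

#' Enzyme-pool turnover derivative
#'
#' `d(enz)/dt = kdeg * induction_scale - enz * (kdeg + kinact * Cu / (KIu +
#' Cu) + extra_inactivation)`.  At baseline (no victim, no perpetrator,
#' `enz = 1`) the derivative is zero; under constant saturating victim
#' concentration the pool settles at `kdeg / (kdeg + kinact)`; under constant
#' saturating inducer it settles at `Ind_max`.  Competitive inhibition does
#' not enter this equation (it scales apparent Km in the clearance terms).
#'
#' @param enz current pool as fraction of baseline (> 0).
#' @param unbound_site_conc_victim unbound victim concentration at the
#'   enzyme site, umol/L.
#' @param kdeg first-order degradation rate constant, 1/h.
#' @param mbi optional [mbi_params()] of the victim.
#' @param induction_scale perpetrator induction scale (>= 1).
#' @param extra_inactivation additional inactivation rate from perpetrators,
#'   1/h.
#' @return d(enz)/dt, 1/h.
#' @export
enzyme_dynamics_rhs <- function(enz, unbound_site_conc_victim = 0,
                                kdeg, mbi = NULL, induction_scale = 1,
                                extra_inactivation = 0) {
  if (!all(enz > 0)) stop("enz must be > 0", call. = FALSE)
  inact <- extra_inactivation
  if (!is.null(mbi))
    inact <- inact + mbi$kinact * unbound_site_conc_victim /
      (mbi$kiu + unbound_site_conc_victim)
  kdeg * induction_scale - enz * (kdeg + inact)
}

# canonical state names of the ODE system
.state_names <- function() {
  c("lumen", "arterial", "venous", TISSUES, "enz_liver_cyp3a4",
    "enz_liver_cyp2c8", "enz_gut_cyp3a4", "cum_renal", "cum_hepatic",
    "cum_bile", "cum_gut_wall", "cum_unabsorbed")
}

#' Assemble an integrable PBPK model
#'
#' Builds the full parameter set of the whole-body system for one individual:
#' tissue partition coefficients (tissue-composition method), the individual
#' clearance budget (IVIVE + retrograde residual), absorption and gut
#' first-pass constants, enzyme turnover constants and, optionally, the
#' perpetrator interaction constants.
#'
#' @param drug a `drug_parameters` object.
#' @param indiv an `individual`.
#' @param perpetrator optional `perpetrator_model` (see [perpetrator_model()]).
#' @param settings a [simulation_settings()].
#' @param partition optional precomputed `partition_set` (saves recomputing
#'   the drug-level Kp set across individuals).
#' @return a `pbpk_model` object.
#' @export
build_model <- function(drug, indiv, perpetrator = NULL,
                        settings = simulation_settings(),
                        partition = NULL) {
  part <- partition %||% predict_tissue_partition(drug$physchem)
  kp <- part$kp[TISSUES] * (drug$kp_scalar %||% 1)
  if (any(is.na(kp)))
    stop("build error: missing partition coefficient for ",
         paste(TISSUES[is.na(kp)], collapse = ", "), call. = FALSE)
  if (any(is.na(indiv$organ_flows[TISSUES])) ||
      any(is.na(indiv$organ_volumes[TISSUES])))
    stop("build error: individual lacks organ volumes/flows", call. = FALSE)
  bp <- drug$physchem$blood_to_plasma
  budget <- clearance_budget(drug, indiv)
  p1 <- drug$elimination[["NDMI_3A4"]]
  p2 <- drug$elimination[["NDMI_2C8"]]
  mbi_on <- !is.null(drug$mbi) && !identical(settings$mbi, FALSE)
  comp_on <- drug$additional_hlm_clint > 0 &&
    !identical(settings$steady_state_compensation, FALSE)
  cl_comp <- if (comp_on)
    .ulmin_to_Lh(drug$additional_hlm_clint, indiv$mppgl * indiv$liver_weight)
  else 0
  # biliary split at C -> 0 between the linear and saturable carriers
  b1 <- drug$transporters[["ABCB1"]]
  g2 <- drug$transporters[["ABCG2"]]
  cells <- indiv$hpgl * indiv$liver_weight * (indiv$transporter_activity %||% 1)
  cl_b1 <- if (!is.null(b1)) .ulmin_to_Lh(b1$clint_t * b1$raf, cells) else 0
  cl_g2 <- if (!is.null(g2)) .ulmin_to_Lh(g2$jmax / g2$km * g2$raf, cells)
  else 0
  pv <- numeric(79)
  pv[1] <- drug$absorption$ka * (indiv$ka_scale %||% 1)
  pv[2] <- drug$absorption$fa
  pv[3] <- drug$absorption$q_gut * indiv$bsa / reference_adult()$bsa
  pv[4] <- drug$absorption$fu_gut
  pv[5] <- bp
  pv[6] <- indiv$fu_plasma_individual %||% drug$physchem$fu_plasma
  pv[7] <- drug$physchem$molecular_weight
  pv[8] <- indiv$arterial_volume
  pv[9] <- indiv$venous_volume
  pv[10] <- indiv$cardiac_output
  pv[11:22] <- indiv$organ_volumes[TISSUES]
  pv[23:34] <- indiv$organ_flows[TISSUES]
  pv[35:46] <- kp / bp
  pv[47] <- budget$clu_int_by_pathway[["NDMI_3A4"]]
  pv[48] <- p1$km * p1$fu_incubation
  pv[49] <- budget$clu_int_by_pathway[["NDMI_2C8"]]
  pv[50] <- p2$km * p2$fu_incubation
  pv[51] <- budget$clu_int_by_pathway[["others_3A4"]]
  pv[52] <- budget$clu_int_by_pathway[["others_2C8"]]
  pv[53] <- cl_comp
  pv[54] <- cl_b1
  pv[55] <- cl_g2
  pv[56] <- if (!is.null(g2)) g2$km else 1
  pv[57] <- budget$cl_renal
  pv[58] <- GUT_CLINT_ADULT * (indiv$gut_cyp3a4 / GUT_CYP3A4_NMOL)
  pv[59] <- KDEG[["liver_cyp3a4"]]
  pv[60] <- KDEG[["liver_cyp2c8"]]
  pv[61] <- KDEG[["gut_cyp3a4"]]
  pv[62] <- if (mbi_on) drug$mbi$kinact else 0
  pv[63] <- if (mbi_on) drug$mbi$kiu else 1
  # perpetrator block
  pv[64] <- 1; pv[65] <- 1
  pv[66] <- 1; pv[67] <- 1; pv[68] <- 1; pv[69] <- 1
  pv[70] <- 1; pv[71] <- 1; pv[72] <- 1; pv[73] <- 1
  pv[74] <- 0; pv[75] <- 0
  pv[76] <- 0                                   # infusion rate, per segment
  pv[77] <- 0                                   # induction on total conc
  # hepatic MBI is driven by the same unbound liver-water concentration as
  # the metabolic clearance terms (site-concentration scale factor 1)
  pv[78] <- 1
  # compensatory clearance scales with the inactivated CYP3A4 fraction, so
  # it is absent at baseline and fully expressed once autoinhibition has
  # run to steady state (see the methods vignette; COMPENSATION_MODE = 0
  # would make it unconditionally active instead)
  pv[79] <- COMPENSATION_MODE
  if (!is.null(perpetrator)) {
    mp <- perpetrator$parameters
    pv[64] <- perpetrator$exposure$fu_perpetrator
    pv[65] <- if (!is.null(perpetrator$co_species))
      perpetrator$co_species$fu_perpetrator else 1
    ind3 <- mp$induction$CYP3A4
    ind2 <- mp$induction$CYP2C8
    if (!is.null(ind3)) { pv[66] <- ind3$ind_max; pv[67] <- ind3$ind_c50 }
    if (!is.null(ind2)) { pv[68] <- ind2$ind_max; pv[69] <- ind2$ind_c50 }
    if (!is.null(perpetrator$co_species)) {
      ci3 <- perpetrator$co_species$induction$CYP3A4
      ci2 <- perpetrator$co_species$induction$CYP2C8
      if (!is.null(ci3)) { pv[70] <- ci3$ind_max; pv[71] <- ci3$ind_c50 }
      if (!is.null(ci2)) { pv[72] <- ci2$ind_max; pv[73] <- ci2$ind_c50 }
    }
    ki3 <- mp$competitive_inhibition$CYP3A4
    ki2 <- mp$competitive_inhibition$CYP2C8
    if (!is.null(ki3)) pv[74] <- ki3$ki_u
    if (!is.null(ki2)) pv[75] <- ki2$ki_u
    if (identical(perpetrator$induction_basis, "unbound")) pv[77] <- 1
  }
  structure(list(parms = pv, drug = drug, indiv = indiv,
                 perpetrator = perpetrator, settings = settings,
                 partition = part, budget = budget,
                 kp = kp), class = "pbpk_model")
}

.segment_times <- function(doses, duration) {
  cuts <- c(0, duration)
  for (d in doses) {
    cuts <- c(cuts, d$time)
    if (d$route == "iv_infusion")
      cuts <- c(cuts, min(d$time + d$infusion_duration, duration))
  }
  sort(unique(pmin(pmax(cuts, 0), duration)))
}

#' Integrate a PBPK model over a dosing schedule
#'
#' Stiff (lsoda) integration, segmented at every dose boundary so oral doses
#' enter the gut lumen as exact impulses and infusions as exact zero-order
#' inputs.  Deterministic for fixed inputs.
#'
#' @param model a `pbpk_model` from [build_model()].
#' @param doses list of [dose_event()]s, sorted by time.
#' @param settings optional [simulation_settings()] overriding the model's.
#' @return a `simulation_result`: output grid `times` (h), `plasma` venous
#'   plasma concentration (mg/L), `tissue` concentration matrix (mg/L),
#'   `enzymes` pool matrix, `eliminated` cumulative amounts (mg),
#'   `lumen` amounts, and the dosing record.
#' @export
simulate_pbpk <- function(model, doses, settings = NULL) {
  settings <- settings %||% model$settings
  dur <- settings$duration
  times_dose <- vapply(doses, `[[`, 0, "time")
  if (is.unsorted(times_dose)) stop("doses must be sorted by time",
                                    call. = FALSE)
  doses_nominal <- doses
  tlag <- model$drug$absorption$tlag %||% 0
  if (tlag > 0)
    doses <- lapply(doses, function(d) {
      if (d$route == "oral") d$time <- d$time + tlag
      d
    })
  grid <- seq(0, dur, by = settings$output_dt)
  segs <- .segment_times(doses, dur)
  y <- c(numeric(15), 1, 1, 1, numeric(5))
  names(y) <- .state_names()
  pv <- model$parms
  forc <- .perpetrator_forcings(model, dur)
  out_all <- NULL
  for (k in seq_len(length(segs) - 1)) {
    t0 <- segs[k]; t1 <- segs[k + 1]
    for (d in doses)
      if (d$route == "oral" && abs(d$time - t0) < 1e-9)
        y["lumen"] <- y["lumen"] + d$amount
    rate <- 0
    for (d in doses)
      if (d$route == "iv_infusion" && d$time <= t0 + 1e-9 &&
          t0 + 1e-9 < d$time + d$infusion_duration)
        rate <- rate + d$amount / d$infusion_duration
    pv[76] <- rate
    tt <- unique(c(t0, grid[grid > t0 + 1e-12 & grid < t1 - 1e-12], t1))
    out <- deSolve::ode(y = y, times = tt, func = "pbpk_derivs",
                        parms = pv, dllname = "paedpbpk",
                        initfunc = "pbpk_initmod",
                        initforc = "pbpk_initforc", forcings = forc,
                        fcontrol = list(method = "linear", rule = 2),
                        nout = 1, outnames = "cu_liver_uM",
                        rtol = settings$solver_rel_tol,
                        atol = settings$solver_abs_tol, method = "lsoda")
    if (attr(out, "istate")[1] < 0)
      stop("integrator failure near t = ",
           signif(max(out[, "time"]), 4), " h", call. = FALSE)
    y <- out[nrow(out), 1 + seq_along(y)]
    names(y) <- .state_names()
    out_all <- rbind(out_all, if (k < length(segs) - 1)
      out[-nrow(out), , drop = FALSE] else out)
  }
  cn <- colnames(out_all)
  tiss <- out_all[, TISSUES, drop = FALSE]
  vt <- model$parms[11:22]
  conc_tissue <- sweep(tiss, 2, vt, "/")
  plasma <- out_all[, "venous"] / model$parms[9] /
    model$drug$physchem$blood_to_plasma
  res <- structure(list(
    times = out_all[, "time"],
    plasma = unname(plasma),
    tissue = conc_tissue,
    amounts = out_all[, c("lumen", "arterial", "venous", TISSUES)],
    enzymes = out_all[, c("enz_liver_cyp3a4", "enz_liver_cyp2c8",
                          "enz_gut_cyp3a4")],
    eliminated = out_all[, c("cum_renal", "cum_hepatic", "cum_bile",
                             "cum_gut_wall", "cum_unabsorbed")],
    cu_liver_uM = out_all[, "cu_liver_uM"],
    doses = doses, doses_nominal = doses_nominal, model = model,
    settings = settings),
    class = "simulation_result")
  if (isTRUE(settings$peripheral_sampling))
    res$peripheral <- peripheral_vein_concentration(res)
  res
}

# zero-forcing matrices unless a perpetrator exposure model is attached
.perpetrator_forcings <- function(model, duration) {
  tt <- c(0, duration)
  if (is.null(model$perpetrator))
    return(list(cbind(tt, 0), cbind(tt, 0)))
  grid <- seq(0, duration, by = 0.25)
  cp <- perpetrator_concentration(model$perpetrator$exposure, grid)
  cc <- if (!is.null(model$perpetrator$co_species))
    perpetrator_concentration(model$perpetrator$co_species$exposure, grid)
  else rep(0, length(grid))
  list(cbind(grid, cp), cbind(grid, cc))
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", length(x$times), "time points over",
      max(x$times), "h;", length(x$doses), "dose(s)\n")
  cat(sprintf("  Cmax %.3g mg/L at %.2f h; final plasma %.3g mg/L\n",
              max(x$plasma), x$times[which.max(x$plasma)],
              x$plasma[length(x$plasma)]))
  invisible(x)
}

#' Total drug accounted for at each output time
#'
#' Mass balance: lumen + body + cumulative eliminated must equal the total
#' administered up to each time.
#'
#' @param result a `simulation_result`.
#' @return data.frame with time, dosed, accounted and relative error.
#' @export
mass_balance <- function(result) {
  t <- result$times
  dosed <- vapply(t, function(ti) {
    s <- 0
    for (d in result$doses) {
      if (d$route == "oral" && d$time <= ti + 1e-9) s <- s + d$amount
      if (d$route == "iv_infusion") {
        frac <- max(0, min(1, (ti - d$time) / d$infusion_duration))
        s <- s + d$amount * frac
      }
    }
    s
  }, 0)
  accounted <- rowSums(result$amounts) + rowSums(result$eliminated)
  data.frame(time = t, dosed = dosed, accounted = accounted,
             rel_error = ifelse(dosed > 0, (accounted - dosed) / dosed, 0))
}

#' Peripheral-vein concentration correction
#'
#' Approximates the concentration measured at a peripheral (antecubital)
#' sampling site as the flow-weighted mix of the venous outflow plasma
#' concentrations of the surrounding tissues (adipose, muscle, skin).  At
#' distribution equilibrium, when every tissue outflow equals the central
#' venous concentration, the corrected series equals the central one.
#'
#' @param result a `simulation_result`.
#' @param weights named weights over `c("adipose","muscle","skin")`, summing
#'   to 1; default flow-weighted.
#' @return peripheral plasma concentration series, mg/L.
#' @export
peripheral_vein_concentration <- function(result, weights = NULL) {
  model <- result$model
  tissues <- c("adipose", "muscle", "skin")
  if (!all(tissues %in% colnames(result$tissue)))
    stop("result lacks the adipose/muscle/skin compartments", call. = FALSE)
  if (is.null(weights)) {
    q <- model$indiv$organ_flows[tissues]
    weights <- q / sum(q)
  } else {
    weights <- weights[tissues]
    if (any(is.na(weights)) || abs(sum(weights) - 1) > 1e-6)
      stop("config error: peripheral weights must cover adipose/muscle/skin ",
           "and sum to 1", call. = FALSE)
  }
  kp <- model$kp[tissues]
  couts <- sweep(result$tissue[, tissues, drop = FALSE], 2, kp, "/")
  unname(as.vector(couts %*% weights))
}
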