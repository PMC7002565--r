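test_that("enzyme turnover has the analytic fixed points", {
  kdeg <- 0.0193
  mbi <- mbi_params(kinact = 4.29, ki = 14.3, fu_incubation = 0.8)
  # baseline: no victim, no perpetrator, pool at 1 -> no drift
  expect_equal(enzyme_dynamics_rhs(1, 0, kdeg = kdeg, mbi = mbi), 0)
  # saturating victim: steady state at kdeg / (kdeg + kinact)
  ss <- kdeg / (kdeg + 4.29)
  expect_equal(ss, 0.00448, tolerance = 1e-3)
  expect_lt(abs(enzyme_dynamics_rhs(ss, 1e9, kdeg = kdeg, mbi = mbi)), 1e-8)
  # saturating inducer: steady state at Ind_max
  expect_equal(enzyme_dynamics_rhs(3.5, 0, kdeg = kdeg,
                                   induction_scale = 3.5), 0)
  expect_error(enzyme_dynamics_rhs(0, 0, kdeg = kdeg), "> 0")
})

test_that("mass is conserved and states stay non-negative", {
  res <- typical_400(duration = 48)
  mb <- mass_balance(res)
  expect_lt(max(abs(mb$rel_error[mb$dosed > 0])), 1e-6)
  expect_true(all(res$plasma >= -1e-10))
  expect_true(all(res$amounts >= -1e-10))
  # iv infusion route conserves mass too
  st <- simulation_settings(duration = 24, output_dt = 0.1)
  resi <- simulate_pbpk(build_model(builtin_imatinib(), reference_adult(),
                                    settings = st),
                        list(dose_event(1, 100, "iv_infusion",
                                        infusion_duration = 1)))
  mbi_ <- mass_balance(resi)
  expect_lt(max(abs(mbi_$rel_error[mbi_$dosed > 0])), 1e-6)
})

test_that("with all partitions at unity and no elimination the system
           equilibrates to dose over total volume", {
  mod <- build_model(drug_no_mbi(), reference_adult(),
                     settings = simulation_settings(duration = 300,
                                                    output_dt = 0.5))
  # white-box: neutralise partitioning and every clearance term
  mod$parms[35:46] <- 1            # Kp/B:P
  mod$parms[c(47, 49, 51:55, 57, 58)] <- 0
  res <- simulate_pbpk(mod, list(dose_event(0, 100, "iv_infusion",
                                            infusion_duration = 0.5)))
  vtot <- sum(mod$parms[8:9]) + sum(mod$parms[11:22])
  last <- length(res$times)
  cexp <- 100 / vtot
  concs <- c(res$amounts[last, "venous"] / mod$parms[9],
             res$tissue[last, ])
  expect_equal(unname(concs), rep(cexp, length(concs)), tolerance = 1e-4)
})

test_that("the linear system matches its closed-form (eigen) solution", {
  # iv bolus-like short infusion, no saturation (tiny dose), MBI off:
  # the PBPK system is then linear and its exact solution is the matrix
  # exponential assembled independently here
  mod <- build_model(drug_no_mbi(), reference_adult(),
                     settings = simulation_settings(duration = 48,
                                                    output_dt = 0.5,
                                                    mbi = FALSE))
  p <- mod$parms
  V <- p[11:22]; Q <- p[23:34]; Kpb <- p[35:46]
  co <- p[10]; v_art <- p[8]; v_ven <- p[9]
  tn <- c("lung", "adipose", "bone", "brain", "heart", "kidney", "muscle",
          "skin", "gut", "spleen", "liver", "rest")
  names(V) <- names(Q) <- names(Kpb) <- tn
  n <- 14  # arterial, venous, 12 tissues
  A <- matrix(0, n, n,
              dimnames = list(c("art", "ven", tn), c("art", "ven", tn)))
  out <- function(t) 1 / (V[t] * Kpb[t])          # outflow conc per amount
  A["ven", "ven"] <- -co / v_ven
  A["lung", "ven"] <- co / v_ven
  A["lung", "lung"] <- -co * out("lung")
  A["art", "lung"] <- co * out("lung")
  A["art", "art"] <- -co / v_art
  for (t in setdiff(tn, c("lung", "gut", "spleen", "liver"))) {
    A[t, "art"] <- Q[t] / v_art
    A[t, t] <- -Q[t] * out(t)
    A["ven", t] <- Q[t] * out(t)
  }
  # renal elimination from arterial plasma
  A["art", "art"] <- A["art", "art"] - p[57] / p[5] / v_art
  for (t in c("gut", "spleen")) {
    A[t, "art"] <- Q[t] / v_art
    A[t, t] <- -Q[t] * out(t)
    A["liver", t] <- Q[t] * out(t)
  }
  A["liver", "art"] <- Q["liver"] / v_art
  q_liv <- Q["liver"] + Q["gut"] + Q["spleen"]
  # at the linear limit saturable terms contribute their CL0 values
  cl_lin <- p[47] + p[49] + p[51] + p[52] + p[54] + p[55]
  fu_term <- p[6] / p[5]                          # unbound factor on outflow
  A["liver", "liver"] <- -(q_liv + cl_lin * fu_term) * out("liver")
  A["ven", "liver"] <- q_liv * out("liver")
  ev <- eigen(A)
  x0 <- numeric(n); names(x0) <- rownames(A)
  x0["ven"] <- 1e-3                               # 1 ug iv bolus
  coefs <- solve(ev$vectors, x0)
  closed_plasma <- function(tt) {
    sapply(tt, function(ti) {
      x <- Re(ev$vectors %*% (coefs * exp(ev$values * ti)))
      x[2] / v_ven / p[5]
    })
  }
  # engine: bolus approximated by a very short infusion
  res <- simulate_pbpk(mod, list(dose_event(0, 1e-3, "iv_infusion",
                                            infusion_duration = 1e-4)))
  sel <- res$times >= 1
  expect_equal(res$plasma[sel], closed_plasma(res$times[sel]),
               tolerance = 2e-3)
})

test_that("typical adult 400 mg oral dose peaks near the reference time", {
  res <- typical_400()
  m <- nca_metrics(res, 400, single_dose = TRUE)
  expect_lt(abs(m$tmax - 2.6), 0.5)
})

test_that("solver tolerances are converged and runs are deterministic", {
  res1 <- typical_400(duration = 48)
  st <- simulation_settings(duration = 48, output_dt = 0.1,
                            solver_rel_tol = 5e-9, solver_abs_tol = 5e-11,
                            steady_state_compensation = FALSE)
  res2 <- simulate_pbpk(build_model(builtin_imatinib(), reference_adult(),
                                    settings = st),
                        list(dose_event(0, 400, "oral")))
  auc1 <- sum(diff(res1$times) * (head(res1$plasma, -1) +
                                    tail(res1$plasma, -1)) / 2)
  auc2 <- sum(diff(res2$times) * (head(res2$plasma, -1) +
                                    tail(res2$plasma, -1)) / 2)
  expect_lt(abs(auc1 - auc2) / auc2, 1e-3)
  res3 <- typical_400(duration = 48)
  expect_identical(res1$plasma, res3$plasma)
})

test_that("an empty dose list yields identically zero concentrations", {
  mod <- build_model(builtin_imatinib(), reference_adult(),
                     settings = simulation_settings(duration = 12))
  res <- simulate_pbpk(mod, list())
  expect_true(all(res$plasma == 0))
  expect_true(all(res$eliminated == 0))
})

test_that("without autoinhibition repeated dosing reaches a periodic steady
           state with the single-dose clearance", {
  drug <- drug_no_mbi()
  st <- simulation_settings(duration = 24 * 12, output_dt = 0.25,
                            mbi = FALSE)
  res <- simulate_pbpk(build_model(drug, reference_adult(), settings = st),
                       regimen(400, 24, 12))
  mss <- nca_metrics(res, 400, interval = c(24 * 11, 24 * 12))
  m1 <- nca_metrics(typical_400(mbi = FALSE), 400, single_dose = TRUE)
  expect_lt(abs(mss$cl_over_f - m1$cl_over_f) / m1$cl_over_f, 0.02)
})

test_that("with autoinhibition and no compensation steady-state clearance
           falls below day 1", {
  drug <- builtin_imatinib()
  st <- simulation_settings(duration = 24 * 14, output_dt = 0.25,
                            steady_state_compensation = FALSE)
  res <- simulate_pbpk(build_model(drug, reference_adult(), settings = st),
                       regimen(400, 24, 14))
  mss <- nca_metrics(res, 400, interval = c(24 * 13, 24 * 14))
  m1 <- nca_metrics(typical_400(), 400, single_dose = TRUE)
  expect_lt(mss$cl_over_f, m1$cl_over_f)
  # enzyme pool is depressed at steady state
  expect_lt(res$enzymes[nrow(res$enzymes), "enz_liver_cyp3a4"], 0.6)
})

test_that("enzyme pools recover to baseline after washout", {
  kdeg <- 0.0193
  dur <- 24 + 5 / kdeg
  st <- simulation_settings(duration = dur, output_dt = 1,
                            steady_state_compensation = FALSE)
  res <- simulate_pbpk(build_model(builtin_imatinib(), reference_adult(),
                                   settings = st),
                       list(dose_event(0, 400, "oral")))
  pools <- res$enzymes[nrow(res$enzymes), ]
  expect_true(all(abs(pools - 1) < 0.01))
})

test_that("peripheral-vein correction mixes tissue outflows", {
  st <- simulation_settings(duration = 48, output_dt = 0.1,
                            peripheral_sampling = TRUE)
  mod <- build_model(builtin_imatinib(), reference_adult(), settings = st)
  res <- simulate_pbpk(mod, list(dose_event(1, 100, "iv_infusion",
                                            infusion_duration = 1)))
  # during the infusion the peripheral site lags the central vein
  during <- res$times > 1.1 & res$times <= 2
  expect_lt(max(res$peripheral[during]) / max(res$plasma[during]), 1)
  # at true distribution equilibrium (no elimination) the two sites agree
  mod0 <- mod
  mod0$parms[c(47, 49, 51:55, 57, 58, 62)] <- 0
  res0 <- simulate_pbpk(mod0, list(dose_event(0, 100, "iv_infusion",
                                              infusion_duration = 0.5)))
  res0$model <- mod0
  late0 <- which(res0$times > 40)
  per0 <- peripheral_vein_concentration(res0)
  expect_equal(per0[late0], res0$plasma[late0], tolerance = 1e-3)
  expect_error(peripheral_vein_concentration(res,
                                             weights = c(adipose = 0.5,
                                                         muscle = 0.4,
                                                         skin = 0.3)),
               "sum to 1")
})

test_that("unsorted doses and broken builds are refused", {
  mod <- build_model(builtin_imatinib(), reference_adult(),
                     settings = simulation_settings(duration = 24))
  expect_error(simulate_pbpk(mod, list(dose_event(5, 100, "oral"),
                                       dose_event(0, 100, "oral"))),
               "sorted")
  ind <- reference_adult()
  ind$organ_flows <- ind$organ_flows[-3]
  expect_error(build_model(builtin_imatinib(), ind,
                           settings = simulation_settings(duration = 1)),
               "build error")
  expect_error(dose_event(0, 10, "iv_infusion"), "infusion_duration")
  expect_error(dose_event(0, -1), ">= 0")
})
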