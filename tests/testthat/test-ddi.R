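test_that("perpetrator exposure modes evaluate correctly", {
  # constant: unbound concentration is the fu product at any time
  e <- perpetrator_exposure("constant_css", css = 10, fu_perpetrator = 0.25)
  expect_equal(perpetrator_unbound_liver_conc(e, c(0, 5, 500)),
               c(2.5, 2.5, 2.5))
  e2 <- perpetrator_exposure("constant_css", css = 10, onset = 24,
                             fu_perpetrator = 1)
  expect_equal(perpetrator_concentration(e2, c(0, 23.9, 24, 100)),
               c(0, 0, 10, 10))
  # forced profile hits its anchors and holds the last value
  pr <- data.frame(time = c(0, 10, 20), conc = c(1, 5, 2))
  ef <- perpetrator_exposure("forced_profile", profile = pr)
  expect_equal(perpetrator_concentration(ef, c(0, 10, 20)), c(1, 5, 2))
  expect_equal(perpetrator_concentration(ef, 50), 2)   # hold-last policy
  # one-compartment repeated dosing: average Css = dose rate / CL
  eo <- perpetrator_exposure("one_compartment", ka = 1, v = 50, cl = 5,
                             molecular_weight = 250,
                             doses = lapply(0:99, function(k)
                               list(time = 12 * k, amount = 120)))
  tt <- seq(1100, 1112, by = 0.05)
  avg <- mean(perpetrator_concentration(eo, tt))
  expect_equal(avg, 120 / 12 / 5 * 1000 / 250, tolerance = 0.01)
})

test_that("interaction terms reproduce the printed constants", {
  mods <- builtin_modulators()
  # no perpetrator concentration -> neutral terms
  keto0 <- perpetrator_model(mods$ketoconazole,
                             perpetrator_exposure("constant_css", css = 0,
                                                  fu_perpetrator = 0.01))
  t0 <- interaction_terms(keto0, 1)
  expect_equal(unname(t0$induction_scale), c(1, 1))
  expect_equal(unname(t0$km_scale), c(1, 1))
  # ketoconazole at unbound 15 nmol/L doubles the apparent CYP3A4 Km
  keto <- perpetrator_model(mods$ketoconazole,
                            perpetrator_exposure("constant_css", css = 1.5,
                                                 fu_perpetrator = 0.01))
  expect_equal(interaction_terms(keto, 1)$km_scale[["CYP3A4"]], 2)
  # rifampicin far above its IndC50 saturates CYP2C8 induction at 6.27
  rif <- perpetrator_model(mods$rifampicin,
                           perpetrator_exposure("constant_css", css = 1e4,
                                                fu_perpetrator = 0.15))
  expect_equal(interaction_terms(rif, 1)$induction_scale[["CYP2C8"]], 6.27,
               tolerance = 1e-3)
  # carbamazepine epoxide contributes additively on (scale - 1)
  cbz <- standard_perpetrator("carbamazepine", "adult")
  s <- interaction_terms(cbz, 200)$induction_scale[["CYP3A4"]]
  cbz_solo <- cbz
  cbz_solo$co_species <- NULL
  s_solo <- interaction_terms(cbz_solo, 200)$induction_scale[["CYP3A4"]]
  expect_gt(s, s_solo)
  expect_lt(s - 1, 2 * (s_solo - 1) + (3.5 - 1))
})

test_that("a neutral perpetrator leaves the victim untouched", {
  pop <- generate_population(population_spec(2, 30, 40, 0.5, seed = 21))
  dd <- simulate_ddi(builtin_imatinib(), null_modulator(), pop,
                     regimen(400, 24, 4), n_days = 4, lead_in_days = 1)
  r <- interaction_ratio(dd, "auc_last_day")
  expect_equal(unname(r$ratios), rep(1, 2), tolerance = 1e-8)
})

test_that("inducers depress and inhibitors raise victim exposure for every
           individual", {
  pop <- generate_population(population_spec(3, 20, 60, 0.4, seed = 22))
  doses <- regimen(400, 24, 7)
  rif <- standard_perpetrator("rifampicin", "adult", n_days = 10)
  keto <- standard_perpetrator("ketoconazole", "adult", n_days = 10)
  dd_rif <- simulate_ddi(builtin_imatinib(), rif, pop, doses, n_days = 7,
                         lead_in_days = 3)
  dd_keto <- simulate_ddi(builtin_imatinib(), keto, pop, doses, n_days = 7,
                          lead_in_days = 3)
  expect_true(all(interaction_ratio(dd_rif, "auc_last_day")$ratios < 1))
  expect_true(all(interaction_ratio(dd_keto, "auc_last_day")$ratios > 1))
})

test_that("matched induction and competitive inhibition cancel", {
  # synthesis doubled at saturation, apparent Km doubled by inhibition:
  # for a victim without autoinhibition the two effects neutralise
  css <- 100
  mp <- modulator_parameters(
    "balanced",
    induction = list(CYP3A4 = list(ind_max = 2, ind_c50 = 1e-4),
                     CYP2C8 = list(ind_max = 2, ind_c50 = 1e-4)),
    competitive_inhibition = list(CYP3A4 = list(ki_u = css),
                                  CYP2C8 = list(ki_u = css)),
    fu_plasma = 1)
  perp <- perpetrator_model(mp, perpetrator_exposure("constant_css",
                                                     css = css,
                                                     fu_perpetrator = 1))
  pop <- generate_population(population_spec(2, 30, 40, 0.5, seed = 23))
  dd <- simulate_ddi(drug_no_mbi(), perp, pop, regimen(400, 24, 4),
                     n_days = 4, lead_in_days = 14)
  r <- interaction_ratio(dd, "auc_last_day")
  expect_equal(unname(r$ratios), rep(1, 2), tolerance = 0.05)
})

test_that("interaction ratios are stable to the output grid", {
  pop <- generate_population(population_spec(2, 30, 40, 0.5, seed = 24))
  cbz <- standard_perpetrator("carbamazepine", "adult", n_days = 8)
  dd1 <- simulate_ddi(builtin_imatinib(), cbz, pop, regimen(400, 24, 5),
                      n_days = 5, lead_in_days = 3)
  r1 <- interaction_ratio(dd1, "auc_last_day")$mean
  # re-evaluate the same pair on a coarser grid by subsampling
  coarse <- lapply(dd1$pairs, function(pr) {
    thin <- function(res) {
      keep <- seq(1, length(res$times), by = 2)
      res$times <- res$times[keep]; res$plasma <- res$plasma[keep]
      res
    }
    list(control = thin(pr$control), treated = thin(pr$treated))
  })
  dd2 <- dd1; dd2$pairs <- coarse
  r2 <- interaction_ratio(dd2, "auc_last_day")$mean
  expect_lt(abs(r1 - r2) / r1, 0.01)
})

test_that("perpetrator model validation and co-species rules hold", {
  mods <- builtin_modulators()
  expect_error(perpetrator_model(mods$ketoconazole,
                                 perpetrator_exposure("constant_css",
                                                      css = 1),
                                 co_species = list()),
               "carbamazepine")
  expect_error(perpetrator_exposure("one_compartment", ka = 1),
               "one_compartment mode needs")
  expect_error(perpetrator_exposure("constant_css", css = 1,
                                    fu_perpetrator = 0), "fu_perpetrator")
})
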