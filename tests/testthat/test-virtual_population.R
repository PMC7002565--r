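test_that("body surface area follows the Gehan-George power law", {
  # oracle: direct evaluation of 0.0235 * H^0.42246 * W^0.51456
  expect_equal(body_surface_area(70, 170),
               0.0235 * 170^0.42246 * 70^0.51456, tolerance = 1e-12)
  # doubling weight at fixed height scales BSA by 2^0.51456
  expect_equal(body_surface_area(140, 170) / body_surface_area(70, 170),
               2^0.51456, tolerance = 1e-10)
  expect_error(body_surface_area(0, 170), "positive")
  expect_error(body_surface_area(70, -1), "positive")
  # DuBois alternative stays available and differs
  expect_false(isTRUE(all.equal(body_surface_area(70, 170, "dubois"),
                                body_surface_area(70, 170))))
})

test_that("liver volume power law: coefficient, value and monotonicity", {
  expect_equal(liver_volume(1), 0.722)
  expect_equal(liver_volume(1.73), 0.722 * 1.73^1.176, tolerance = 1e-12)
  expect_equal(round(liver_volume(1.73), 3), 1.376)
  bsa <- seq(0.4, 2.4, by = 0.1)
  expect_true(all(diff(liver_volume(bsa)) > 0))
  expect_error(liver_volume(0), "positive")
})

test_that("AAG ontogeny: boundary, half-saturation and asymptote", {
  expect_equal(aag_concentration(0), 0)
  expect_equal(aag_concentration(88.9 / 365), 0.887 / 2, tolerance = 1e-12)
  expect_lt(abs(aag_concentration(1e9) - 0.887), 1e-3)
  pna <- seq(0, 65, by = 0.25)
  a <- aag_concentration(pna)
  expect_true(all(diff(a) > 0))
  expect_true(all(a <= 0.887))
  expect_error(aag_concentration(-1), "non-negative")
})

test_that("unbound fraction rescaling: identity, limits and derived value", {
  expect_equal(paediatric_unbound_fraction(0.8, 0.8, 0.05), 0.05)
  expect_equal(paediatric_unbound_fraction(0, 0.8, 0.05), 1)
  expect_equal(paediatric_unbound_fraction(0.4, 0.8, 0.05),
               1 / (1 + 0.5 * 0.95 / 0.05), tolerance = 1e-12)
  expect_equal(round(paediatric_unbound_fraction(0.4, 0.8, 0.05), 4), 0.0952)
  expect_error(paediatric_unbound_fraction(0.4, 0.8, 0), "fu_adult")
  # fu decreases with age beyond birth towards the adult value
  fu <- paediatric_unbound_fraction(aag_concentration(seq(0.1, 30, 0.1)))
  expect_true(all(diff(fu) < 0))
})

test_that("enzyme ontogeny reproduces the maturation table", {
  o <- ontogeny_defaults()
  h3 <- o$hepatic_cyp3a4
  expect_equal(ontogeny_fraction(0, h3), 0.11)
  expect_equal(ontogeny_fraction(0.64, h3), 0.11 + (1.06 - 0.11) / 2,
               tolerance = 1e-12)
  expect_equal(ontogeny_fraction(1e6, h3), 1.06, tolerance = 1e-4)
  expect_equal(ontogeny_fraction(0, o$intestinal_cyp3a4), 0.42)
  expect_equal(ontogeny_fraction(0, o$hepatic_cyp2c8), 0.30)
  expect_equal(ontogeny_fraction(1e6, o$hepatic_cyp2c8), 1.00,
               tolerance = 1e-4)
  # non-decreasing in age for every parameter set
  pna <- seq(0, 30, by = 0.1)
  for (p in o) expect_true(all(diff(ontogeny_fraction(pna, p)) >= 0))
  expect_error(ontogeny_params(1, 0.5, 0.3, 0),
               "pna50 and hill_n")
  expect_error(ontogeny_params(1, 1.2, 0.3, 1), "f_birth")
})

test_that("population generation is seeded, stratified and bounded", {
  spec <- population_spec(100, 2, 5, proportion_female = 0.4, seed = 7)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1, p2)
  sexes <- vapply(p1$individuals, `[[`, "", "sex")
  expect_equal(sum(sexes == "F"), 40)
  ages <- vapply(p1$individuals, `[[`, 0, "age")
  expect_true(all(ages >= 2 & ages <= 5))
  expect_error(population_spec(10, 1, 5), "2")
})

test_that("young children have lower hepatic CYP3A4 maturation than adults", {
  young <- generate_population(population_spec(40, 2, 5, seed = 3))
  adult <- generate_population(population_spec(40, 18, 65, seed = 4))
  y_frac <- vapply(young$individuals, function(i) i$ontogeny[["CYP3A4"]], 0)
  a_mean <- mean(vapply(adult$individuals,
                        function(i) i$ontogeny[["CYP3A4"]], 0))
  expect_true(all(y_frac < a_mean))
})

test_that("each individual conserves blood flow and stays physiological", {
  pop <- generate_population(population_spec(30, 2, 65, seed = 11))
  for (ind in pop$individuals) {
    systemic <- setdiff(names(ind$organ_flows), "lung")
    expect_equal(sum(ind$organ_flows[systemic]), ind$cardiac_output,
                 tolerance = 1e-9)
    vols <- sum(ind$organ_volumes) + ind$venous_volume + ind$arterial_volume
    expect_lt(vols, ind$body_weight * 1.05)
    expect_true(ind$fu_plasma_individual > 0 &&
                  ind$fu_plasma_individual <= 1)
    expect_true(all(ind$organ_volumes > 0))
    expect_true(all(ind$organ_flows > 0))
  }
})

test_that("population export produces one row per individual", {
  pop <- generate_population(population_spec(5, 6, 11, seed = 2))
  df <- population_to_df(pop)
  expect_equal(nrow(df), 5)
  path <- tempfile(fileext = ".csv")
  population_to_df(pop, path)
  back <- read.csv(path)
  expect_equal(back$cyp3a4, df$cyp3a4, tolerance = 1e-6)
  unlink(path)
})
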