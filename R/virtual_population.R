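# Virtual-population generator: ontogeny functions (enzymes, AAG, liver
# volume), anthropometry sampling, organ sizes/flows, enzyme abundances with
# log-normal inter-individual variability.

#' Body surface area
#'
#' Gehan & George formula, `0.0235 * H^0.42246 * W^0.51456` (H in cm, W in
#' kg), widely used for paediatric oncology dosing; the DuBois alternative
#' (`0.007184 * H^0.725 * W^0.425`) is selectable.
#'
#' @param weight kg.
#' @param height cm.
#' @param formula `"gehan_george"` (default) or `"dubois"`.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(weight, height,
                              formula = c("gehan_george", "dubois")) {
  formula <- match.arg(formula)
  if (any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  switch(formula,
         gehan_george = 0.0235 * height^0.42246 * weight^0.51456,
         dubois = 0.007184 * height^0.725 * weight^0.425)
}

#' Liver volume from body surface area
#'
#' Power law `0.722 * BSA^1.176` (L).
#'
#' @param bsa body surface area, m^2.
#' @return liver volume, L.
#' @export
liver_volume <- function(bsa) {
  if (any(bsa <= 0)) stop("bsa must be positive", call. = FALSE)
  0.722 * bsa^1.176
}

#' Plasma alpha-1-acid glycoprotein ontogeny
#'
#' Sigmoidal maturation of plasma AAG with postnatal age:
#' `0.887 * (365*PNA)^0.38 / (88.9^0.38 + (365*PNA)^0.38)` g/L, i.e. zero at
#' birth, half the adult asymptote at about 89 days, saturating at
#' 0.887 g/L.
#'
#' @param pna postnatal age, years.
#' @return AAG concentration, g/L.
#' @export
aag_concentration <- function(pna) {
  if (any(pna < 0)) stop("pna must be non-negative", call. = FALSE)
  d <- 365 * pna
  0.887 * d^0.38 / (88.9^0.38 + d^0.38)
}

# Adult reference AAG (g/L): the ontogeny curve evaluated at the reference
# adult age of 30 years; anchors the unbound-fraction rescaling so that an
# adult recovers fu_adult exactly.
AAG_ADULT <- 0.887 * (365 * 30)^0.38 / (88.9^0.38 + (365 * 30)^0.38)

#' Paediatric unbound fraction from the AAG ratio
#'
#' Rescales the adult unbound fraction by the ratio of paediatric to adult
#' AAG under linear binding:
#' `fu_ped = 1 / (1 + (AAG_ped/AAG_adult) * (1 - fu_adult)/fu_adult)`.
#'
#' @param aag_ped paediatric AAG, g/L.
#' @param aag_adult adult AAG, g/L.
#' @param fu_adult adult unbound fraction, in (0, 1].
#' @return unbound fraction in (0, 1].
#' @export
paediatric_unbound_fraction <- function(aag_ped, aag_adult = AAG_ADULT,
                                        fu_adult = 0.05) {
  if (!all(fu_adult > 0 & fu_adult <= 1))
    stop("fu_adult must be in (0, 1]", call. = FALSE)
  if (any(aag_adult <= 0)) stop("aag_adult must be positive", call. = FALSE)
  if (any(aag_ped < 0)) stop("aag_ped must be non-negative", call. = FALSE)
  1 / (1 + (aag_ped / aag_adult) * (1 - fu_adult) / fu_adult)
}

#' Sigmoidal-Emax ontogeny parameters
#'
#' @param adult_max maximum expression as fraction of the adult reference.
#' @param f_birth fraction at birth.
#' @param pna50 maturation half-life, years.
#' @param hill_n Hill exponent.
#' @return an `ontogeny_params` object.
#' @export
ontogeny_params <- function(adult_max, f_birth, pna50, hill_n) {
  if (!isTRUE(f_birth >= 0 && f_birth <= adult_max))
    stop("need 0 <= f_birth <= adult_max", call. = FALSE)
  if (!isTRUE(pna50 > 0) || !isTRUE(hill_n > 0))
    stop("pna50 and hill_n must be > 0", call. = FALSE)
  structure(list(adult_max = adult_max, f_birth = f_birth, pna50 = pna50,
                 hill_n = hill_n), class = "ontogeny_params")
}

#' Built-in enzyme maturation parameter sets
#'
#' Hepatic CYP3A4 (Adult_max 1.06, PNA50 0.64 y, F_birth 0.11, n 1.91),
#' intestinal CYP3A4 (1.06, 2.36 y, 0.42, 1.00) and hepatic CYP2C8
#' (1.00, 0.02 y, 0.30, 1.00).
#'
#' @return named list of `ontogeny_params`.
#' @export
ontogeny_defaults <- function() {
  list(hepatic_cyp3a4 = ontogeny_params(1.06, 0.11, 0.64, 1.91),
       intestinal_cyp3a4 = ontogeny_params(1.06, 0.42, 2.36, 1.00),
       hepatic_cyp2c8 = ontogeny_params(1.00, 0.30, 0.02, 1.00))
}

#' Enzyme maturation as a fraction of the adult level
#'
#' `F(PNA) = F_birth + (Adult_max - F_birth) * PNA^n / (PNA50^n + PNA^n)`.
#'
#' @param pna postnatal age, years.
#' @param params an [ontogeny_params()] object.
#' @return fraction of the adult expression level.
#' @export
ontogeny_fraction <- function(pna, params) {
  if (any(pna < 0)) stop("pna must be non-negative", call. = FALSE)
  with(params,
       f_birth + (adult_max - f_birth) * pna^hill_n /
         (pna50^hill_n + pna^hill_n))
}

# Adult hepatic enzyme baselines (pmol/mg microsomal protein) and the
# intestinal CYP3A4 pool (nmol total); standard literature values.
ENZYME_BASELINES <- c(CYP3A4 = 137, CYP2C8 = 24)
GUT_CYP3A4_NMOL <- 70.5

# Inter-individual variability (log-normal CV) for system parameters.
# Fixed once so that the simulated adult CV of CL/F is ~50% (Table-2-scale
# cohorts report 51-54%); not re-fit per run.
POPULATION_CV <- c(cyp3a4 = 0.60, cyp2c8 = 0.55, mppgl = 0.30,
                   transporter = 0.30, aag = 0.30, weight = 0.11,
                   height = 0.04, ka = 0.30)

#' Population specification
#'
#' @param n number of individuals (>= 1).
#' @param age_min,age_max age range in years; `age_min >= 2` (the model's
#'   validity domain excludes children under 2).
#' @param proportion_female fraction of females; counts are exact
#'   (deterministic stratification), not binomial.
#' @param seed integer seed; identical seeds give bit-identical populations.
#' @param variability_cv optional named overrides of the default CV table.
#' @return a `population_spec` object.
#' @export
population_spec <- function(n, age_min, age_max, proportion_female = 0.4,
                            seed = 1, variability_cv = NULL) {
  if (!isTRUE(n >= 1)) stop("n must be >= 1", call. = FALSE)
  if (age_min < 2)
    stop("age_min below 2 years: the ontogeny model is only supported for ",
         "ages 2-65 (no neonatal/infant physiology)", call. = FALSE)
  if (age_max < age_min) stop("age_max < age_min", call. = FALSE)
  if (proportion_female < 0 || proportion_female > 1)
    stop("proportion_female must be in [0, 1]", call. = FALSE)
  cv <- POPULATION_CV
  if (!is.null(variability_cv)) cv[names(variability_cv)] <- variability_cv
  structure(list(n = as.integer(n), age_min = age_min, age_max = age_max,
                 proportion_female = proportion_female,
                 seed = as.integer(seed), variability_cv = cv),
            class = "population_spec")
}

# log-normal deviate with unit median and coefficient of variation cv
.rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Build one individual deterministically from its sampled covariates
#' @keywords internal
build_individual <- function(id, age, sex, weight, height, eta) {
  bsa <- body_surface_area(weight, height)
  lv <- liver_volume(bsa)
  lw <- lv * 1000 * LIVER_DENSITY      # g
  co <- cardiac_output(weight)
  vols <- organ_volumes(weight, sex, lv)
  flows <- organ_flows(co)
  onto <- ontogeny_defaults()
  onto30 <- c(CYP3A4 = ontogeny_fraction(30, onto$hepatic_cyp3a4),
              CYP2C8 = ontogeny_fraction(30, onto$hepatic_cyp2c8),
              gut3A4 = ontogeny_fraction(30, onto$intestinal_cyp3a4))
  frac <- c(CYP3A4 = ontogeny_fraction(age, onto$hepatic_cyp3a4),
            CYP2C8 = ontogeny_fraction(age, onto$hepatic_cyp2c8),
            gut3A4 = ontogeny_fraction(age, onto$intestinal_cyp3a4))
  rel <- frac / onto30                 # expression relative to 30-y adult
  abundance <- c(CYP3A4 = unname(ENZYME_BASELINES["CYP3A4"] * rel["CYP3A4"] *
                                   eta["cyp3a4"]),
                 CYP2C8 = unname(ENZYME_BASELINES["CYP2C8"] * rel["CYP2C8"] *
                                   eta["cyp2c8"]))
  gut_cyp3a4 <- GUT_CYP3A4_NMOL * unname(rel["gut3A4"])
  aag <- aag_concentration(age) * unname(eta["aag"])
  fu <- paediatric_unbound_fraction(aag)
  structure(list(
    id = id, age = age, sex = sex, body_weight = weight, height = height,
    bsa = bsa, liver_volume = lv, liver_weight = lw,
    organ_volumes = vols$tissues, venous_volume = vols$venous,
    arterial_volume = vols$arterial, organ_flows = flows,
    cardiac_output = co,
    mppgl = mppgl(age) * unname(eta["mppgl"]), hpgl = hpgl(age),
    enzyme_abundance = abundance, gut_cyp3a4 = gut_cyp3a4,
    ontogeny = frac, ontogeny_relative = rel,
    transporter_activity = unname(eta["transporter"]),
    ka_scale = unname(eta["ka"]),
    aag = aag, fu_plasma_individual = fu,
    haematocrit = if (sex == "F") 0.40 else 0.44),
    class = "individual")
}

#' Typical reference adult
#'
#' Male, 30 years, median adult anthropometry, all variability deviates at
#' their median (1).  This is the fixed individual on which the retrograde
#' clearance derivation and the clearance-budget calibrations are performed.
#'
#' @return an `individual` object.
#' @export
reference_adult <- function() {
  anth <- .median_anthropometry(30, "M")
  eta <- c(cyp3a4 = 1, cyp2c8 = 1, mppgl = 1, transporter = 1, aag = 1,
           ka = 1)
  ind <- build_individual(0L, 30, "M", anth$weight, anth$height, eta)
  # the reference adult is defined to have exactly the adult unbound fraction
  ind$fu_plasma_individual <- 0.05
  ind
}

#' Generate a seeded virtual population
#'
#' Samples, per individual: sex (exact stratification: `round(n *
#' proportion_female)` females, assigned to the first slots, then ages are
#' drawn uniformly over the age range), anthropometry (log-normal around the
#' sex/age growth-reference median), organ volumes and flows (reference
#' fractions scaled to body size; liver from the BSA power law), AAG
#' (log-normal around the ontogeny curve, giving the individual unbound
#' fraction), and enzyme abundances (adult baseline x ontogeny fraction x
#' log-normal deviate).  One RNG stream seeded from `spec$seed` is consumed
#' in a fixed per-individual order, so equal seeds give bit-identical
#' populations.
#'
#' @param spec a [population_spec()].
#' @return a `virtual_population` (list of `individual`s with the spec
#'   attached).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  n_f <- round(n * spec$proportion_female)
  sexes <- c(rep("F", n_f), rep("M", n - n_f))
  cv <- spec$variability_cv
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  inds <- vector("list", n)
  for (i in seq_len(n)) {
    age <- stats::runif(1, spec$age_min, spec$age_max)
    anth <- .median_anthropometry(age, sexes[i])
    weight <- anth$weight * .rlnorm_cv(1, cv["weight"])
    height <- anth$height * .rlnorm_cv(1, cv["height"])
    eta <- c(cyp3a4 = .rlnorm_cv(1, cv["cyp3a4"]),
             cyp2c8 = .rlnorm_cv(1, cv["cyp2c8"]),
             mppgl = .rlnorm_cv(1, cv["mppgl"]),
             transporter = .rlnorm_cv(1, cv["transporter"]),
             aag = .rlnorm_cv(1, cv["aag"]),
             ka = .rlnorm_cv(1, cv["ka"]))
    inds[[i]] <- build_individual(i, age, sexes[i], weight, height, eta)
  }
  structure(list(individuals = inds, spec = spec),
            class = "virtual_population")
}

#' @export
print.virtual_population <- function(x, ...) {
  ages <- vapply(x$individuals, `[[`, 0, "age")
  cat("<virtual_population> n =", length(x$individuals),
      sprintf("| ages %.1f-%.1f y | %d female | seed %d\n", min(ages),
              max(ages), sum(vapply(x$individuals, `[[`, "", "sex") == "F"),
              x$spec$seed))
  invisible(x)
}

#' Export a population to a data frame / CSV
#'
#' One row per individual with the scalar covariates (id, age, sex, weight,
#' height, BSA, liver volume, MPPGL, enzyme abundances, AAG, fu).
#'
#' @param pop a `virtual_population`.
#' @param path optional CSV path.
#' @return a data.frame (invisibly if written to file).
#' @export
population_to_df <- function(pop, path = NULL) {
  rows <- lapply(pop$individuals, function(ind)
    data.frame(id = ind$id, age = ind$age, sex = ind$sex,
               body_weight = ind$body_weight, height = ind$height,
               bsa = ind$bsa, liver_volume = ind$liver_volume,
               mppgl = ind$mppgl, hpgl = ind$hpgl,
               cyp3a4 = ind$enzyme_abundance[["CYP3A4"]],
               cyp2c8 = ind$enzyme_abundance[["CYP2C8"]],
               aag = ind$aag, fu_plasma = ind$fu_plasma_individual,
               cardiac_output = ind$cardiac_output))
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
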