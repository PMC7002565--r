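# System (physiology) parameters: anthropometry references, organ volume and
# blood-flow fractions, liver scaling factors, cardiac output.

#' Tissue compartments of the whole-body model
#'
#' Order is the canonical state ordering used by the ODE engine.
#' @keywords internal
TISSUES <- c("lung", "adipose", "bone", "brain", "heart", "kidney",
             "muscle", "skin", "gut", "spleen", "liver", "rest")

# Organ volumes as fraction of body weight (L/kg, density ~1), by sex.
# ICRP-style adult reference values; brain is capped at 1.45 L.  Liver is
# always overridden by the BSA power law (see liver_volume()).
.volume_fractions <- function(sex) {
  adipose <- if (sex == "F") 0.28 else 0.19
  muscle  <- if (sex == "F") 0.30 else 0.40
  c(lung = 0.0076, adipose = adipose, bone = 0.086, brain = 0.09,
    heart = 0.0047, kidney = 0.0044, muscle = muscle, skin = 0.0371,
    gut = 0.0171, spleen = 0.0026, liver = NA_real_, rest = NA_real_)
}

# Regional blood flows as fraction of cardiac output.  Gut and spleen drain
# into the portal vein; the liver receives hepatic artery + portal flow.
.flow_fractions <- c(lung = 1, adipose = 0.05, bone = 0.05, brain = 0.12,
                     heart = 0.04, kidney = 0.19, muscle = 0.17, skin = 0.05,
                     gut = 0.15, spleen = 0.03, liver = 0.065, rest = 0.085)

#' Reference growth table (height cm, weight kg) by age and sex
#'
#' Median height and weight for ages 2-20 years (growth-reference medians,
#' 50th percentile); values plateau into adulthood.  Used by
#' [generate_population()] to sample anthropometry.
#' @keywords internal
growth_reference <- function() {
  age <- 2:20
  m_h <- c(86.9, 95.3, 102.5, 109.2, 115.7, 122.0, 128.1, 133.7, 138.8,
           143.7, 149.3, 156.4, 163.8, 170.1, 173.4, 175.2, 176.1, 176.5,
           176.8)
  m_w <- c(12.7, 14.3, 16.3, 18.5, 21.0, 22.9, 25.6, 28.6, 32.0, 35.6,
           39.9, 45.3, 50.8, 56.0, 60.8, 64.4, 66.9, 68.9, 70.6)
  f_h <- c(85.5, 94.2, 101.0, 107.9, 115.4, 121.1, 126.8, 132.5, 138.6,
           144.7, 151.2, 157.1, 160.4, 162.1, 162.7, 163.1, 163.2, 163.3,
           163.3)
  f_w <- c(12.1, 13.9, 15.9, 18.0, 20.2, 22.4, 25.8, 29.1, 32.9, 37.0,
           41.5, 45.8, 49.4, 52.0, 53.9, 55.0, 56.2, 57.3, 58.0)
  data.frame(age = rep(age, 2), sex = rep(c("M", "F"), each = length(age)),
             height = c(m_h, f_h), weight = c(m_w, f_w),
             stringsAsFactors = FALSE)
}

.median_anthropometry <- function(age, sex) {
  g <- growth_reference()
  g <- g[g$sex == sex, ]
  a <- min(max(age, 2), 20)
  list(height = stats::approx(g$age, g$height, xout = a)$y,
       weight = stats::approx(g$age, g$weight, xout = a)$y)
}

#' Microsomal protein per gram of liver (MPPGL)
#'
#' Age-dependent scaling factor for microsome-based IVIVE, from the published
#' cubic log-polynomial (mg microsomal protein per g liver); ~40 mg/g at age
#' 30 with a decline in older adults and lower values in young children.
#'
#' @param age postnatal age in years.
#' @return mg microsomal protein per g liver.
#' @export
mppgl <- function(age) {
  if (any(age < 0)) stop("age must be non-negative")
  10^(1.407 + 0.0158 * age - 0.00038 * age^2 + 0.0000024 * age^3)
}

#' Hepatocellularity per gram of liver (HPGL)
#'
#' Adult hepatocellularity used to scale per-cell transporter kinetics to the
#' whole liver.  The value (89 million cells/g, inside the published adult
#' range of 74-131) is fixed by calibrating the hepatobiliary IVIVE chain so
#' that, in the reference adult, biliary clearance is 28% of overall imatinib
#' clearance -- the same anchor used to set the ABCG2 relative activity
#' factor.  No age dependence is applied.
#'
#' @param age postnatal age in years (accepted for interface symmetry).
#' @return million hepatocytes per g liver.
#' @export
hpgl <- function(age = 30) {
  rep(89, length(age))
}

#' Cardiac output
#'
#' Allometric cardiac output, 12 * BW^0.75 L/h (about 4.9 L/min for a 70-kg
#' adult), distributed over tissues with fixed regional fractions.
#'
#' @param weight body weight in kg.
#' @return cardiac output in L/h.
#' @export
cardiac_output <- function(weight) {
  if (any(weight <= 0)) stop("weight must be positive")
  12 * weight^0.75
}

# Liver density g/ml: converts the liver-volume power law to liver weight.
LIVER_DENSITY <- 1.08

# Blood volume fraction of body weight; split 2:1 venous:arterial.
BLOOD_FRACTION <- 0.075

#' Organ volumes (L) for one individual
#' @keywords internal
organ_volumes <- function(weight, sex, liver_vol) {
  vf <- .volume_fractions(sex)
  v <- vf * weight
  v["brain"] <- min(1.45, v["brain"])
  v["liver"] <- liver_vol
  blood <- BLOOD_FRACTION * weight
  listed <- sum(v[setdiff(names(v), "rest")], na.rm = TRUE)
  v["rest"] <- max(0.05 * weight, weight - listed - blood)
  list(tissues = v, venous = 2 / 3 * blood, arterial = 1 / 3 * blood)
}

#' Organ blood flows (L/h) for one individual
#'
#' Regional flows are fixed fractions of cardiac output; the non-lung tissue
#' flows sum exactly to cardiac output (the "rest" compartment takes the
#' balance), giving flow conservation by construction.
#' @keywords internal
organ_flows <- function(co) {
  q <- .flow_fractions * co
  q["lung"] <- co
  # exact conservation: recompute rest as the balance of systemic flows
  systemic <- setdiff(TISSUES, c("lung", "rest"))
  q["rest"] <- co - sum(q[systemic])
  q
}
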