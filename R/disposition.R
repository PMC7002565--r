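# Tissue partitioning (Rodgers-Rowland) and IVIVE of hepatic clearances,
# including the retrograde derivation of total intrinsic clearance from the
# observed oral clearance and the biliary (canalicular efflux) pathway.

# Tissue composition for the tissue-composition partitioning method:
# fractional extracellular/intracellular water, neutral lipid, neutral
# phospholipid, and acidic phospholipid content (mg/g).  Values from the
# published tables of the method for the tissues of the whole-body model.
TISSUE_COMPOSITION <- local({
  tc <- data.frame(
    tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "lung", "muscle", "skin", "spleen"),
    f_ew = c(0.135, 0.100, 0.162, 0.282, 0.320, 0.273, 0.161, 0.336, 0.118,
             0.382, 0.207),
    f_iw = c(0.017, 0.346, 0.620, 0.475, 0.456, 0.483, 0.573, 0.446, 0.630,
             0.291, 0.579),
    f_nl = c(0.853, 0.017, 0.039, 0.038, 0.014, 0.012, 0.014, 0.022, 0.010,
             0.060, 0.0077),
    f_np = c(0.0016, 0.0017, 0.0015, 0.0125, 0.0111, 0.0242, 0.0240, 0.0128,
             0.0072, 0.0044, 0.0113),
    ap = c(0.40, 0.67, 0.40, 2.41, 2.25, 5.03, 4.56, 3.91, 1.53, 1.32, 3.18))
  rownames(tc) <- tc$tissue
  tc
})

# blood-cell composition and compartment pH values used by the method
.BC <- list(f_iw = 0.603, f_nl = 0.0017, f_np = 0.0029, ap = 0.5)
.PH <- c(plasma = 7.4, intracellular = 7.0, blood_cell = 7.22)

.ionisation_term <- function(physchem, ph) {
  switch(physchem$ionisation_class,
         neutral = 0,
         monoprotic_base = 10^(physchem$pka_values[1] - ph),
         diprotic_base = 10^(physchem$pka_values[1] - ph) +
           10^(sum(physchem$pka_values) - 2 * ph),
         stop("unsupported ionisation class: ", physchem$ionisation_class,
              call. = FALSE))
}

#' Predict tissue-to-plasma partition coefficients (moderate-to-strong base)
#'
#' Tissue-composition partitioning for ionisable bases: neutral species
#' partition into tissue water and neutral lipid/phospholipid by
#' lipophilicity, and the cationic species binds acidic phospholipids with an
#' association constant back-calculated from the blood-cell partition (via
#' B:P, haematocrit and fu).  `Vss = sum(Kp_t * V_t) + V_plasma`, reported
#' per kg body weight for the reference adult.
#'
#' @param physchem a [phys_chem()] object (base or neutral).
#' @param fu unbound fraction in plasma.
#' @param haematocrit blood-cell volume fraction.
#' @return a `partition_set`: list with `kp` (named per-tissue ratios,
#'   plasma-referenced), `kpu_bc`, `ka_ap`, and `vss_per_kg` (L/kg).
#' @export
predict_tissue_partition <- function(physchem, fu = physchem$fu_plasma,
                                     haematocrit = 0.45) {
  P <- 10^physchem$log_p
  X <- .ionisation_term(physchem, .PH["intracellular"])
  Y <- .ionisation_term(physchem, .PH["plasma"])
  Z <- .ionisation_term(physchem, .PH["blood_cell"])
  neutral_lipid <- function(f_nl, f_np) (P * f_nl + (0.3 * P + 0.7) * f_np) /
    (1 + Y)
  ka_ap <- 0
  if (physchem$ionisation_class != "neutral") {
    kpu_bc <- (physchem$blood_to_plasma - (1 - haematocrit)) /
      (haematocrit * fu)
    if (kpu_bc <= 0)
      stop("inconsistent B:P / haematocrit / fu: blood-cell partition <= 0",
           call. = FALSE)
    ka_ap <- (kpu_bc - (1 + Z) / (1 + Y) * .BC$f_iw -
                neutral_lipid(.BC$f_nl, .BC$f_np)) * (1 + Y) / (.BC$ap * Z)
    ka_ap <- max(ka_ap, 0)
  } else kpu_bc <- NA_real_
  tc <- TISSUE_COMPOSITION
  kpu <- tc$f_ew + (1 + X) / (1 + Y) * tc$f_iw +
    ka_ap * tc$ap * X / (1 + Y) + neutral_lipid(tc$f_nl, tc$f_np)
  kp <- kpu * fu
  names(kp) <- tc$tissue
  ref <- reference_adult()
  vt <- ref$organ_volumes[names(kp)]
  # rest-of-body gets the median tissue Kp
  v_rest <- ref$organ_volumes[["rest"]]
  v_plasma <- (ref$venous_volume + ref$arterial_volume) *
    (1 - haematocrit) +
    (ref$venous_volume + ref$arterial_volume) * haematocrit *
    (if (is.na(kpu_bc)) 1 else kpu_bc * fu)
  vss <- (sum(kp * vt) + stats::median(kp) * v_rest + v_plasma) /
    ref$body_weight
  structure(list(kp = c(kp, rest = unname(stats::median(kp))),
                 kpu_bc = kpu_bc, ka_ap = ka_ap,
                 vss_per_kg = unname(vss)),
            class = "partition_set")
}

#' Whole-liver unbound intrinsic clearance of one CYP pathway
#'
#' Scales in vitro kinetics to the individual's whole liver.  Saturable
#' pathways use `Vmax * C / (Km_u + C)` with `Km_u = Km * fu_inc`;
#' recombinant-CYP kinetics are multiplied by ISEF and the individual's CYP
#' abundance (pmol/mg); HLM kinetics (and linear depletion clearances) are
#' taken per mg microsomal protein and scaled by the individual's relative
#' CYP expression.  Everything is then multiplied by MPPGL x liver weight.
#' At `site_conc = 0` the saturable form reduces to `Vmax/Km_u` scaling.
#'
#' @param pathway an [elimination_pathway()].
#' @param indiv an `individual`.
#' @param site_conc unbound enzyme-site concentration, umol/L.
#' @return clearance in L/h (unbound, whole liver).
#' @export
scale_enzyme_clearance <- function(pathway, indiv, site_conc = 0) {
  if (any(site_conc < 0)) stop("site_conc must be >= 0", call. = FALSE)
  mg <- indiv$mppgl * indiv$liver_weight
  rel_expr <- indiv$enzyme_abundance[[pathway$enzyme]] /
    ENZYME_BASELINES[[pathway$enzyme]]
  if (!is.null(pathway$clint)) {                       # linear
    per_mg <- pathway$clint / pathway$fu_incubation * rel_expr
    return(.ulmin_to_Lh(per_mg, mg))
  }
  km_u <- pathway$km * pathway$fu_incubation
  if (identical(pathway$system, "recombinant")) {
    # vmax per pmol CYP -> per mg via ISEF x abundance
    per_mg0 <- pathway$vmax * (pathway$isef %||% 1) *
      indiv$enzyme_abundance[[pathway$enzyme]]
  } else {
    per_mg0 <- pathway$vmax * rel_expr                 # already per mg
  }
  per_mg <- per_mg0 / (km_u + site_conc)               # ul/min/mg
  .ulmin_to_Lh(per_mg, mg)
}

#' Retrograde total unbound intrinsic clearance
#'
#' Inverts the well-stirred hepatic model for an orally dosed drug with
#' complete absorption: the apparent hepatic oral clearance equals
#' `CLu_int * fu_p`, so `CLu_int,total = (CL_oral - CL_renal) / fu_p`.
#' Performed once on the fixed reference adult; the resulting unassigned
#' CYP2C8 clearance is treated as a drug constant thereafter.
#'
#' @param cl_oral observed apparent oral clearance CL/F, L/h.
#' @param cl_renal renal clearance, L/h.
#' @param fu_plasma adult unbound fraction in plasma.
#' @return total unbound hepatic intrinsic clearance, L/h.
#' @export
retrograde_total_clint <- function(cl_oral, cl_renal = 0, fu_plasma = 0.05) {
  if (!isTRUE(cl_oral > cl_renal) || cl_renal < 0)
    stop("inconsistent clearances: need cl_oral > cl_renal >= 0",
         call. = FALSE)
  (cl_oral - cl_renal) / fu_plasma
}

#' Forward well-stirred oral hepatic clearance (round-trip check)
#' @param clu_int unbound intrinsic clearance, L/h.
#' @param fu_plasma unbound fraction in plasma.
#' @return apparent oral hepatic clearance, L/h.
#' @export
forward_oral_hepatic_clearance <- function(clu_int, fu_plasma = 0.05) {
  clu_int * fu_plasma
}

#' Unassigned CYP2C8 intrinsic clearance (budget residual)
#'
#' `CLu_int,others,2C8 = CLu_int,total - (CLu_int,bile + NDMI_3A4 + NDMI_2C8
#' + others_3A4)`, floored at zero with a warning if the known components
#' exceed the total.
#'
#' @param clu_total total unbound intrinsic clearance, L/h.
#' @param cl_bile_int biliary intrinsic clearance, L/h.
#' @param ndmi_3a4,ndmi_2c8,others_3a4 known metabolic components, L/h.
#' @return residual clearance, L/h.
#' @export
clint_others_cyp2c8 <- function(clu_total, cl_bile_int, ndmi_3a4, ndmi_2c8,
                                others_3a4) {
  res <- clu_total - (cl_bile_int + ndmi_3a4 + ndmi_2c8 + others_3a4)
  if (res < 0) {
    warning("known clearance components exceed the retrograde total by ",
            sprintf("%.3g", -res), " L/h; residual CYP2C8 clearance floored",
            " at 0", call. = FALSE)
    res <- 0
  }
  res
}

#' Biliary (canalicular efflux) clearance
#'
#' ABCB1 (linear) + ABCG2 (saturable) efflux, each multiplied by its relative
#' activity factor and scaled by hepatocellularity (HPGL x liver weight) and
#' the individual's transporter activity deviate.  Linear in concentration at
#' low `site_conc`.
#'
#' @param transporters list of [transporter_pathway()].
#' @param indiv an `individual`.
#' @param site_conc unbound site concentration, umol/L.
#' @return intrinsic biliary clearance, L/h.
#' @export
biliary_clearance <- function(transporters, indiv, site_conc = 0) {
  if (any(site_conc < 0)) stop("site_conc must be >= 0", call. = FALSE)
  cells <- indiv$hpgl * indiv$liver_weight      # million cells
  act <- indiv$transporter_activity %||% 1
  per_cell <- 0
  for (tp in transporters) {
    per_cell <- per_cell + if (!is.null(tp$clint_t)) tp$clint_t * tp$raf
    else tp$jmax / (tp$km + site_conc) * tp$raf
  }
  .ulmin_to_Lh(per_cell * act, cells)
}

#' Clearance budget for a drug in one individual
#'
#' Assembles the full low-concentration clearance budget: per-pathway
#' whole-liver unbound intrinsic clearances, biliary efflux, the retrograde
#' total (computed on the reference adult and used to fix the unassigned
#' CYP2C8 residual as a drug constant, here rescaled to the individual), and
#' the renal route.  Fractions are referenced to total systemic clearance
#' (hepatic apparent-oral + renal) of the individual.
#'
#' @param drug a `drug_parameters` object.
#' @param indiv an `individual` (default: the reference adult).
#' @param cl_oral_observed observed adult CL/F used by the retrograde step,
#'   L/h.
#' @return a `clearance_set`: named pathway clearances (L/h), `cl_bile_int`,
#'   `clu_int_total`, `cl_renal`, `fraction_biliary`, `fm` per enzyme.
#' @export
clearance_budget <- function(drug, indiv = reference_adult(),
                             cl_oral_observed = 14.4) {
  ref <- reference_adult()
  fu_adult <- drug$physchem$fu_plasma
  clu_total_ref <- retrograde_total_clint(cl_oral_observed,
                                          drug$renal_clearance, fu_adult)
  by_path_ref <- vapply(drug$elimination[c("NDMI_3A4", "NDMI_2C8",
                                           "others_3A4")],
                        scale_enzyme_clearance, 0, indiv = ref)
  bile_ref <- biliary_clearance(drug$transporters, ref)
  residual_ref <- clint_others_cyp2c8(clu_total_ref, bile_ref,
                                      by_path_ref[["NDMI_3A4"]],
                                      by_path_ref[["NDMI_2C8"]],
                                      by_path_ref[["others_3A4"]])
  # residual as a per-mg drug constant (ul/min/mg at adult CYP2C8 expression)
  mg_ref <- ref$mppgl * ref$liver_weight
  residual_per_mg <- residual_ref * 1e6 / 60 / mg_ref
  # now the individual
  by_path <- vapply(drug$elimination[c("NDMI_3A4", "NDMI_2C8",
                                       "others_3A4")],
                    scale_enzyme_clearance, 0, indiv = indiv)
  rel_2c8 <- indiv$enzyme_abundance[["CYP2C8"]] / ENZYME_BASELINES[["CYP2C8"]]
  residual <- .ulmin_to_Lh(residual_per_mg * rel_2c8,
                           indiv$mppgl * indiv$liver_weight)
  bile <- biliary_clearance(drug$transporters, indiv)
  paths <- c(by_path, others_2C8 = unname(residual))
  clu_total <- sum(paths) + bile
  fu_i <- indiv$fu_plasma_individual %||% fu_adult
  cl_hep_oral <- clu_total * fu_i
  cl_renal <- drug$renal_clearance * indiv$bsa / ref$bsa
  cl_total_sys <- cl_hep_oral + cl_renal
  fm <- c(CYP3A4 = unname(paths[["NDMI_3A4"]] + paths[["others_3A4"]]),
          CYP2C8 = unname(paths[["NDMI_2C8"]] + paths[["others_2C8"]])) /
    clu_total
  structure(list(clu_int_by_pathway = paths, cl_bile_int = bile,
                 clu_int_total = clu_total, residual_per_mg = residual_per_mg,
                 cl_renal = cl_renal, cl_hepatic_oral = cl_hep_oral,
                 cl_total_systemic = cl_total_sys,
                 fraction_biliary = unname(bile / clu_total * cl_hep_oral /
                                             cl_total_sys),
                 fm = fm), class = "clearance_set")
}

#' @export
print.clearance_set <- function(x, ...) {
  cat("<clearance_set>\n")
  cat("  CLu_int total:", sprintf("%.1f", x$clu_int_total), "L/h\n")
  for (p in names(x$clu_int_by_pathway))
    cat(sprintf("    %-11s %8.2f L/h\n", p, x$clu_int_by_pathway[[p]]))
  cat(sprintf("    %-11s %8.2f L/h\n", "bile", x$cl_bile_int))
  cat(sprintf("  CL/F hepatic %.2f + renal %.2f L/h; biliary fraction %.3f\n",
              x$cl_hepatic_oral, x$cl_renal, x$fraction_biliary))
  cat(sprintf("  fm: CYP3A4 %.2f, CYP2C8 %.2f\n", x$fm[["CYP3A4"]],
              x$fm[["CYP2C8"]]))
  invisible(x)
}
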