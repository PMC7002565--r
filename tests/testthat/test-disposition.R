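test_that("tissue partitioning behaves like the base method", {
  d <- builtin_imatinib()
  part <- predict_tissue_partition(d$physchem)
  expect_true(all(part$kp > 0))
  # printed reference: Vss 1.8 L/kg, 25% band
  expect_lt(abs(part$vss_per_kg - 1.8) / 1.8, 0.25)
  # neutral compounds ignore pKa entirely
  n1 <- phys_chem(300, 2, "neutral", numeric(), 1, 0.1)
  n2 <- phys_chem(300, 2, "neutral", c(9, 4), 1, 0.1)
  expect_equal(predict_tissue_partition(n1)$kp,
               predict_tissue_partition(n2)$kp)
  # unsupported ionisation class is refused at construction
  expect_error(phys_chem(300, 2, "zwitterion", c(9, 4), 1, 0.1),
               "ionisation_class")
})

test_that("enzyme clearance scaling follows the IVIVE chain", {
  ref <- reference_adult()
  mg <- ref$mppgl * ref$liver_weight
  # HLM pathway at C -> 0 reduces to Vmax/Km at the microsomal level
  p2 <- elimination_pathway("NDMI_2C8", "CYP2C8", vmax = 56.4, km = 7.49,
                            fu_incubation = 1, system = "HLM")
  per_mg <- scale_enzyme_clearance(p2, ref, 0) * 1e6 / 60 / mg
  expect_equal(per_mg, 56.4 / 7.49, tolerance = 1e-10)
  expect_equal(round(per_mg, 2), 7.53)
  # ISEF = 0 silences recombinant pathways
  p0 <- elimination_pathway("NDMI_3A4", "CYP3A4", vmax = 3, km = 10.54,
                            fu_incubation = 0.96, isef = 0,
                            system = "recombinant")
  expect_equal(scale_enzyme_clearance(p0, ref), 0)
  # doubling MPPGL doubles whole-liver clearance
  ref2 <- ref
  ref2$mppgl <- 2 * ref$mppgl
  expect_equal(scale_enzyme_clearance(p2, ref2),
               2 * scale_enzyme_clearance(p2, ref))
  # saturable clearance is non-increasing in site concentration
  cl <- vapply(c(0, 1, 5, 20, 100), function(cc)
    scale_enzyme_clearance(p2, ref, cc), 0)
  expect_true(all(diff(cl) < 0))
  expect_error(scale_enzyme_clearance(p2, ref, -1), ">= 0")
})

test_that("retrograde well-stirred derivation inverts exactly", {
  for (cl in c(5, 14.4, 30)) {
    clu <- retrograde_total_clint(cl, 0.5, 0.05)
    expect_equal(forward_oral_hepatic_clearance(clu, 0.05) + 0.5, cl,
                 tolerance = 1e-12)
  }
  expect_equal(retrograde_total_clint(14.4, 0.5, 0.05), 13.9 / 0.05)
  expect_error(retrograde_total_clint(0.5, 0.5), "inconsistent")
  expect_error(retrograde_total_clint(0.4, 0.5), "inconsistent")
})

test_that("unassigned CYP2C8 clearance is the floored budget residual", {
  expect_equal(clint_others_cyp2c8(10, 2, 3, 1, 1), 3)
  expect_equal(clint_others_cyp2c8(7, 2, 3, 1, 1), 0)
  expect_warning(res <- clint_others_cyp2c8(5, 2, 3, 1, 1), "floored")
  expect_equal(res, 0)
})

test_that("biliary clearance scales carriers by RAF and hepatocellularity", {
  ref <- reference_adult()
  expect_equal(biliary_clearance(list(), ref), 0)
  g2 <- transporter_pathway("ABCG2", jmax = 89.4, km = 4.37, raf = 0.38)
  # Michaelis-Menten midpoint: at site_conc = Km the clearance halves
  expect_equal(biliary_clearance(list(g2), ref, 4.37),
               biliary_clearance(list(g2), ref, 0) / 2, tolerance = 1e-12)
  # RAF enters linearly
  g2b <- transporter_pathway("ABCG2", jmax = 89.4, km = 4.37, raf = 0.19)
  expect_equal(biliary_clearance(list(g2b), ref),
               biliary_clearance(list(g2), ref) / 2, tolerance = 1e-12)
})

test_that("the reference-adult clearance budget is additive and anchored", {
  bud <- clearance_budget(builtin_imatinib())
  total <- sum(bud$clu_int_by_pathway) + bud$cl_bile_int
  expect_equal(total, bud$clu_int_total, tolerance = 1e-9)
  expect_equal(bud$clu_int_total, 13.9 / 0.05, tolerance = 1e-9)
  # biliary share of overall clearance ~28%
  expect_lt(abs(bud$fraction_biliary - 0.28), 0.02)
  # all scalings are homogeneous degree 1 in liver weight
  ref2 <- reference_adult()
  ref2$liver_weight <- 2 * ref2$liver_weight
  bud2 <- clearance_budget(builtin_imatinib(), ref2)
  expect_equal(bud2$cl_bile_int, 2 * bud$cl_bile_int, tolerance = 1e-9)
  expect_equal(bud2$clu_int_by_pathway[["NDMI_3A4"]],
               2 * bud$clu_int_by_pathway[["NDMI_3A4"]], tolerance = 1e-9)
})
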