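# Virtual experiments. The heavyweight panel checks (full transfection panel,
# dose scans, sensitivity table) live in the acceptance suite; here each
# experiment's mechanics are verified on focused cases.

test_that("inert constructs leave the SW480 steady state exactly unchanged", {
  pan <- run_transfection_panel(classes = c("D", "F"))
  expect_equal(pan$change_vs_baseline, c(1, 1), tolerance = 1e-9)
})

test_that("dose scans hit the untransfected limit at dose 0", {
  # a transfected type at dose 0 must reproduce the reduced model without it
  d <- run_dose_scan("SW480", "C", doses = c(0, 1))
  base <- run_transfection_panel(classes = "F")   # identical to untransfected
  expect_equal(d$BCAT_total[1], attr(base, "baseline_nM"), tolerance = 1e-6)
  expect_lt(d$BCAT_total[2], d$BCAT_total[1])
})

test_that("pulse-chase recovers exact first-order decay when rates are uniform", {
  # with kdeg_fast set equal to kdeg_slow, degradation is uniform first-order
  # regardless of phosphorylation: half-life = ln2/k exactly
  k <- log(2) / 3600
  p <- default_parameters(list(kdeg_slow = k, kdeg_fast = k))
  pc <- run_pulse_chase(cell_model("normal", params = p), params = p)
  expect_equal(pc$half_life_s, log(2) / k, tolerance = 1e-3)
  # the S33/S37 mutant decays at kdeg_slow exactly, matching the closed form
  pm <- run_pulse_chase(cell_model("normal", s33_37_mutant = TRUE))
  expect_equal(pm$curve$relative,
               exp(-default_parameters()$kdeg_slow * pm$curve$time),
               tolerance = 1e-6)
  expect_true(all(diff(pm$curve$bcat) <= 1e-9))   # monotone non-increasing
})

test_that("cohort and shutoff protocols agree where dynamics are linear", {
  # for the mutant the decay is first-order under both protocols
  cellm <- cell_model("normal", s33_37_mutant = TRUE)
  sh <- run_pulse_chase(cellm, "shutoff")
  co <- run_pulse_chase(cellm, "cohort")
  expect_equal(co$half_life_s, sh$half_life_s, tolerance = 1e-3)
  # wild type: the protocols differ, but only modestly (tested as a sanity
  # bound, not an identity)
  sw <- run_pulse_chase(cell_model("normal"), "shutoff")
  cw <- run_pulse_chase(cell_model("normal"), "cohort")
  expect_lt(abs(log(cw$half_life_s / sw$half_life_s)), log(2))
})

test_that("LiCl folds act at t = 0 and drive the phospho pools down", {
  cur1 <- run_licl(fold = 1, t_max = 1800, n_points = 8L)
  expect_true(all(abs(cur1$pS45 - 1) < 1e-4))
  expect_true(all(abs(cur1$pS33_37 - 1) < 1e-4))
  cur20 <- run_licl(fold = 20, t_max = 2 * 3600, n_points = 16L)
  expect_equal(cur20$pS45[1], 1)
  expect_equal(cur20$pS33_37[1], 1)
  # the GSK-dependent signal collapses and stays far below its untreated
  # level throughout (S45, fed by the unaffected CK1alpha, does not fall)
  expect_lt(min(cur20$pS33_37), 0.15)
  expect_true(all(cur20$pS33_37[-1] < 0.5))
  expect_gt(cur20$pS45[16], cur20$pS33_37[16])
  # complete inhibition sends S33/37 phosphorylation to zero
  cur_inf <- run_licl(fold = 1e9, t_max = 8 * 3600, n_points = 12L)
  expect_lt(cur_inf$pS33_37[12], 0.02)
})

test_that("interface ablation recomputes rates on the same network", {
  ab <- run_interface_ablation()
  expect_setequal(ab$interface, c("bcat_apc_15aa", "bcat_axin", "apc_axin"))
  expect_true(all(ab$relative_level > 0))
})

test_that("the phospho-ratio scan has the documented limits", {
  ph <- run_apc_phospho_scan(ratios = c(0, 1), doses = 1)
  # the default ratio reproduces the unmodified SW480 baseline
  base <- run_transfection_panel(classes = "F")
  expect_equal(ph$bcat_relative[ph$ratio == 1] * 35,
               attr(base, "baseline_nM"), tolerance = 1e-6)
  # never-phosphorylated APC1338 cannot sequester: lower beta-catenin
  expect_lt(ph$bcat_relative[ph$ratio == 0], ph$bcat_relative[ph$ratio == 1])
})

test_that("sensitivity coefficients are finite, convergent, and null for inert parameters", {
  cell <- cell_model("normal")
  # a parameter that does not enter the normal-cell model (the truncated-APC
  # affinity) has coefficient 0
  s0 <- local_sensitivity(cell, parameters = "KD2_bap_1338")
  expect_equal(s0$coefficient, 0, tolerance = 1e-8)
  # ksyn: near +1 (degradation approximately first order in total pool)
  s1 <- local_sensitivity(cell, parameters = c("ksyn", "kdeg_slow"))
  expect_true(all(is.finite(s1$coefficient)))
  expect_gt(s1$coefficient[1], 0.5)
  # central differences converge at second order: halving delta moves the
  # coefficient by O(delta^2)
  sa <- local_sensitivity(cell, parameters = "kp_bcat", delta = 0.2)
  sb <- local_sensitivity(cell, parameters = "kp_bcat", delta = 0.1)
  sc <- local_sensitivity(cell, parameters = "kp_bcat", delta = 0.05)
  d1 <- abs(sa$coefficient - sc$coefficient)
  d2 <- abs(sb$coefficient - sc$coefficient)
  expect_lt(d2, d1)
})

test_that("the ksyn sensitivity is exactly +1 in the binding-ablated limit", {
  p <- default_parameters(list(kf1_bap = 0, kf2_bap = 0, kf_ba = 0, kf_apa = 0,
                               kf_ga = 0, kf_ca = 0))
  s <- local_sensitivity(cell_model("normal", params = p),
                         parameters = "ksyn", params = p)
  expect_equal(s$coefficient, 1, tolerance = 1e-4)
})
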