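# Mass-action dynamics: closed-form equilibria, conservation along
# trajectories, steady-state uniqueness, and observable evaluation.

test_that("an isolated binding pair relaxes to its closed-form equilibrium", {
  types <- list(molecule_type("A", "b"), molecule_type("B", "a"))
  bind <- mini_bind("ab", "A", "b", "B", "a", "KD_ab")
  KD <- 100
  cell <- mini_cell(types, list(bind, mini_rev(bind)),
                    seeds = list(list(type = "A", conc_param = NA, dose = 100),
                                 list(type = "B", conc_param = NA, dose = 100)),
                    params = list(kf = 1e-3, chi = 1e4, KD_ab = KD))
  net <- compile_network(expand_network(cell, caps = c(A = 1L, B = 1L)))
  ss <- find_steady_state(net)
  # [C] solves C^2 - (A0+B0+KD) C + A0 B0 = 0 (take the physical root)
  A0 <- 100; B0 <- 100
  Ceq <- ((A0 + B0 + KD) - sqrt((A0 + B0 + KD)^2 - 4 * A0 * B0)) / 2
  dimer <- which(vapply(net$species, function(g) length(g$type) == 2L, TRUE))
  expect_equal(ss$state[dimer], Ceq, tolerance = 1e-3)
  # and the simulated trajectory reaches it too
  tc <- simulate_network(net, times = c(0, 1e5))
  expect_equal(unname(tc$states[2, dimer]), Ceq, tolerance = 1e-3)
})

test_that("all rates zero gives a constant trajectory; empty network a zero derivative", {
  types <- list(molecule_type("A", "b"), molecule_type("B", "a"))
  bind <- mini_bind("ab", "A", "b", "B", "a", "KD_ab")
  cell <- mini_cell(types, list(bind, mini_rev(bind)),
                    seeds = list(list(type = "A", conc_param = NA, dose = 7),
                                 list(type = "B", conc_param = NA, dose = 3)),
                    params = list(kf = 0, chi = 0, KD_ab = 100))
  net <- compile_network(expand_network(cell, caps = c(A = 1L, B = 1L)))
  tc <- simulate_network(net, times = seq(0, 1e4, length.out = 5))
  expect_true(all(abs(sweep(tc$states, 2, tc$states[1, ])) < 1e-9))
  dy <- engine_deriv(net, initial_state(net, cell$params))
  expect_true(all(dy == 0))
})

test_that("protein totals are conserved along base-model trajectories", {
  net <- get_network(cell_model("normal"))
  tc <- simulate_network(net, times = c(0, 10, 1e3, 1e5, 1e6))
  for (ty in c("APC", "AXIN", "GSK3B", "CK1A")) {
    tot <- total_of_type(net, ty, tc$states)
    expect_lt(max(abs(tot / tot[1] - 1)), 1e-6)
  }
  # beta-catenin is created and destroyed: its total genuinely moves
  bc <- total_of_type(net, "BCAT", tc$states)
  expect_gt(max(bc), 10)
  expect_equal(bc[1], 0)
  # Axin total at steady state equals the 10 nM seed
  ss <- find_steady_state(net)
  expect_equal(total_of_type(net, "AXIN", ss$state), 10, tolerance = 1e-8)
})

test_that("the steady state is independent of beta-catenin initialization", {
  net <- get_network(cell_model("normal"))
  p <- net$cell$params
  ss0 <- find_steady_state(net, init = initial_state(net, p, bcat_init = 0))
  ss70 <- find_steady_state(net, init = initial_state(net, p, bcat_init = 70))
  ss35 <- find_steady_state(net, init = initial_state(net, p, bcat_init = 35))
  b <- function(ss) evaluate_observable(net, "BCAT_total", ss$state)
  expect_equal(b(ss70), b(ss0), tolerance = 1e-3)
  expect_equal(b(ss35), b(ss0), tolerance = 1e-3)
  expect_lt(max(abs(ss70$state - ss0$state)) / max(ss0$state), 1e-3)
})

test_that("with all binding ablated the steady state is ksyn/kdeg_slow", {
  p <- default_parameters(list(kf1_bap = 0, kf2_bap = 0, kf_ba = 0, kf_apa = 0,
                               kf_ga = 0, kf_ca = 0))
  net <- get_network(cell_model("normal", params = p))
  ss <- find_steady_state(net, params = p)
  expect_equal(evaluate_observable(net, "BCAT_total", ss$state, p),
               ksyn_nm(p) / p$kdeg_slow, tolerance = 1e-6)
})

test_that("observables match a hand enumeration on a fixture state", {
  cell <- cell_model("normal")
  net <- get_network(cell)
  tt <- cell$types
  # locate fixture species by canonical identity with hand-built graphs
  find_sp <- function(g) {
    i <- which(net$canon == canonical_string(g))
    stopifnot(length(i) == 1L)
    i
  }
  y <- numeric(length(net$species))
  # 2 nM free BCAT, 3 nM free AXIN, 5 nM BCAT-AXIN dimer (S45~p),
  # 4 nM APC-BCAT dimer via the 15-aa interface
  y[find_sp(species_graph(tt, "BCAT"))] <- 2
  y[find_sp(species_graph(tt, "AXIN"))] <- 3
  y[find_sp(species_graph(tt, c("BCAT", "AXIN"),
                          states = list(c(S45 = "p"), NULL),
                          bonds = list(list(1, "arm34", 2, "bcat"))))] <- 5
  y[find_sp(species_graph(tt, c("APC", "BCAT"),
                          bonds = list(list(1, "aa15", 2, "arm59"))))] <- 4
  expect_equal(evaluate_observable(net, "BCAT_total", y), 11)
  expect_equal(evaluate_observable(net, "pS45_total", y), 5)
  expect_equal(evaluate_observable(net, "pS33_37_total", y), 0)
  expect_equal(evaluate_observable(net, "frac_bcat_with_axin", y), 5 / 11)
  expect_equal(evaluate_observable(net, "frac_axin_with_bcat", y), 5 / 8)
  expect_equal(evaluate_observable(net, "bcat_direct_apc", y), 4 / 11)
  # all-free state: fraction of Axin with beta-catenin is 0; with no Axin at
  # all the fraction is flagged undefined
  y2 <- numeric(length(y)); y2[find_sp(species_graph(tt, "BCAT"))] <- 1
  expect_equal(evaluate_observable(net, "frac_bcat_with_axin", y2), 0)
  expect_true(is.na(evaluate_observable(net, "frac_axin_with_bcat", y2)))
})
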