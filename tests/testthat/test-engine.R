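# Rule engine: matching, rule application, rate assignment, and network
# expansion, checked against closed forms and the independent brute-force
# oracle.

test_that("matching finds exactly the admissible embeddings", {
  cell <- cell_model("normal")
  tt <- cell$types
  free_axin <- species_graph(tt, "AXIN")
  # free Axin offers one binding site for beta-catenin
  expect_length(match_rule(cell, "bcat_axin", free_axin), 1L)
  # an occupied site no longer matches
  dimer <- species_graph(tt, c("AXIN", "BCAT"),
                         bonds = list(list(1, "bcat", 2, "arm34")))
  expect_length(match_rule(cell, "bcat_axin", dimer), 0L)
  expect_length(match_rule(cell, "bcat_axin_rev", dimer), 1L)
  # S45 phosphorylation needs a CK1alpha-loaded Axin in the same complex:
  # the linear APC-bridged complex qualifies once the kinase is bound
  linear <- species_graph(tt, c("APC", "BCAT", "AXIN", "CK1A"),
    bonds = list(list(1, "aa15", 2, "arm59"), list(1, "samp", 3, "rgs"),
                 list(3, "ck1", 4, "ax")))
  expect_length(match_rule(cell, "phos_bcat_s45", linear), 1L)
  no_kinase <- species_graph(tt, c("APC", "BCAT", "AXIN"),
    bonds = list(list(1, "aa15", 2, "arm59"), list(1, "samp", 3, "rgs")))
  expect_length(match_rule(cell, "phos_bcat_s45", no_kinase), 0L)
  # the 20-aa repeat only binds when phosphorylated
  apc_u <- species_graph(tt, "APC")
  apc_p <- species_graph(tt, "APC", states = list(c(r20_3 = "p")))
  expect_length(match_rule(cell, "bcat_APC_20aa", apc_u), 0L)
  expect_length(match_rule(cell, "bcat_APC_20aa", apc_p), 1L)
})

test_that("degradation releases binding partners and splits complexes", {
  cell <- cell_model("normal")
  tt <- cell$types
  # cyclic ternary complex: deleting beta-catenin leaves one APC-Axin complex
  cyc <- species_graph(tt, c("APC", "BCAT", "AXIN"),
    bonds = list(list(1, "aa15", 2, "arm59"), list(2, "arm34", 3, "bcat"),
                 list(1, "samp", 3, "rgs")))
  frags <- dcx:::sg_delete_molecule(cyc, 2L)
  expect_length(frags, 1L)
  expect_setequal(tt$names[frags[[1]]$type], c("APC", "AXIN"))
  # bridging complex without the SAMP-RGS bond: two fragments
  bridge <- species_graph(tt, c("APC", "BCAT", "AXIN"),
    bonds = list(list(1, "aa15", 2, "arm59"), list(2, "arm34", 3, "bcat")))
  frags <- dcx:::sg_delete_molecule(bridge, 2L)
  expect_length(frags, 2L)
  expect_setequal(vapply(frags, function(f) paste(sort(tt$names[f$type]),
                                                  collapse = "+"), ""),
                  c("APC", "AXIN"))
})

test_that("rates follow the intracomplex/intermolecular/unbinding rules", {
  p <- default_parameters()
  net <- get_network(cell_model("normal"))
  k <- reaction_rates(net, p)
  rx <- net$reactions
  rule_names <- vapply(net$crules, `[[`, "", "name")[rx$rule]
  # intermolecular 15-aa binding: kf per nM per s
  inter <- which(rule_names == "bcat_APC_15aa" & !rx$intra & rx$mult == 1L)
  expect_true(length(inter) > 0)
  expect_true(all(k[inter] == p$kf1_bap))
  # intracomplex closure of the same interface: kf * chi per s
  intra <- which(rule_names == "bcat_APC_15aa" & rx$intra & rx$mult == 1L)
  expect_true(length(intra) > 0)
  expect_true(all(k[intra] == p$kf1_bap * p$chi))
  # unbinding at kf * KD, for every binding interface
  rev15 <- which(rule_names == "bcat_APC_15aa_rev" & rx$mult == 1L)
  expect_true(all(k[rev15] == p$kf * 273))
  for (nm in c("bcat_axin", "gsk_axin", "APC_axin")) {
    kd <- p[[net$crules[[paste0(nm, "_rev")]]$kd_param]]
    i <- which(rule_names == paste0(nm, "_rev") & rx$mult == 1L)
    expect_true(all(abs(k[i] - p$kf * kd) < 1e-12))
  }
})

test_that("ablation zeroes forward rates only; inhibition folds divide GSK rates", {
  p <- default_parameters()
  cell <- cell_model("normal", ablations = "apc_axin")
  net <- get_network(cell)
  k <- reaction_rates(net, p)
  rule_names <- vapply(net$crules, `[[`, "", "name")[net$reactions$rule]
  expect_true(all(k[rule_names == "APC_axin"] == 0))
  expect_true(all(k[rule_names == "APC_axin_rev"] > 0))
  expect_true(all(k[rule_names == "bcat_axin"] > 0))
  # 20-fold GSK inhibition divides S33/37 and APC-repeat phosphorylation only
  net0 <- get_network(cell_model("normal"))
  k1 <- reaction_rates(net0, p, gsk_fold = 1)
  k20 <- reaction_rates(net0, p, gsk_fold = 20)
  rn <- vapply(net0$crules, `[[`, "", "name")[net0$reactions$rule]
  gsk <- rn %in% c("phos_bcat_s3337", "phos_APC_r20")
  expect_equal(k20[gsk], k1[gsk] / 20)
  expect_equal(k20[!gsk], k1[!gsk])
})

test_that("a toy reversible pair expands to 3 species and 2 reactions", {
  types <- list(molecule_type("A", "b"), molecule_type("B", "a"))
  bind <- mini_bind("ab", "A", "b", "B", "a", "KD_ab")
  cell <- mini_cell(types, list(bind, mini_rev(bind)),
                    seeds = list(list(type = "A", conc_param = NA, dose = 100),
                                 list(type = "B", conc_param = NA, dose = 100)),
                    params = list(kf = 1e-3, chi = 1e4, KD_ab = 50))
  net <- expand_network(cell, caps = c(A = 1L, B = 1L))
  expect_length(net$species, 3L)
  expect_equal(nrow(net$reactions), 2L)
  # empty rule list: seeds only, no reactions
  net0 <- expand_network(mini_cell(types, list(),
    seeds = list(list(type = "A", conc_param = NA, dose = 1)),
    params = list(kf = 1e-3, chi = 1)), caps = c(A = 1L, B = 1L))
  expect_length(net0$species, 1L)
  expect_equal(nrow(net0$reactions), 0L)
})

test_that("expansion agrees with the brute-force oracle on randomized mini-models", {
  set.seed(7)
  for (trial in 1:6) {
    kds <- round(10^stats::runif(3, 0, 2.5), 3)
    kflip <- round(10^stats::runif(2, -3, -1), 5)
    types <- list(molecule_type("S", c("x", "y")),
                  molecule_type("A", c("a", "s"), list(s = c("u", "p"))),
                  molecule_type("B", "b"))
    b1 <- mini_bind("sa", "S", "x", "A", "a", "KD1")
    b2 <- mini_bind("sb", "S", "y", "B", "b", "KD2")
    b3 <- mini_bind("ab_p", "A", "a", "B", "b", "KD3", require_a = c(s = "p"))
    rules <- list(b1, mini_rev(b1), b2, mini_rev(b2),
                  mini_flip("flip_up", "A", "s", "u", "p", "k_up",
                            context = list(list(type = "B", site_bound = "b"))),
                  mini_flip("flip_dn", "A", "s", "p", "u", "k_dn"))
    if (trial %% 2 == 0) rules <- c(rules, list(b3, mini_rev(b3)))
    caps <- c(S = 1L, A = sample(1:2, 1), B = sample(1:2, 1))
    params <- list(kf = 1e-3, chi = 10^stats::runif(1, 2, 4),
                   KD1 = kds[1], KD2 = kds[2], KD3 = kds[3],
                   k_up = kflip[1], k_dn = kflip[2])
    cell <- mini_cell(types, rules,
                      seeds = list(list(type = "S", conc_param = NA, dose = 10),
                                   list(type = "A", conc_param = NA, dose = 20),
                                   list(type = "B", conc_param = NA, dose = 30)),
                      params = params)
    net <- expand_network(cell, caps = caps)
    oracle <- oracle_expand(cell, caps)
    # species sets agree one-to-one
    expect_length(oracle$species, length(net$species))
    map <- match_species(net, oracle)
    expect_false(anyNA(map))
    expect_length(unique(map), length(map))
    # mass-action derivatives agree at random states (rate-for-rate check)
    for (rep in 1:5) {
      y <- stats::runif(length(net$species), 0, 5)
      dy_engine <- engine_deriv(net, y)
      y_o <- numeric(length(y)); y_o[map] <- y   # engine state, oracle indexing
      dy_o <- oracle_deriv(oracle, y_o)
      expect_equal(dy_engine, dy_o[map], tolerance = 1e-12)
    }
  }
})

test_that("base-model expansion is closed and counts are reproducible", {
  cell <- cell_model("SW480")
  net <- expand_network(cell)
  net2 <- expand_network(cell)
  expect_identical(net$canon, net2$canon)   # deterministic discovery order
  expect_true(check_closure(net))
  # every reaction conserves APC/Axin/GSK/CK1a counts; beta-catenin changes
  # only via synthesis (+1) and degradation (-1)
  comp <- net$comp
  tt <- cell$types
  kinds <- vapply(net$crules, `[[`, "", "kind")[net$reactions$rule]
  for (r in seq_len(nrow(net$reactions))) {
    rx <- net$reactions[r, ]
    before <- colSums(comp[c(rx$ra, rx$rb)[c(rx$ra, rx$rb) > 0], , drop = FALSE])
    after <- colSums(comp[net$products[[r]], , drop = FALSE])
    if (length(before) == 0L) before <- numeric(ncol(comp))
    if (length(after) == 0L) after <- numeric(ncol(comp))
    d <- after - before
    bc <- match("BCAT", tt$names)
    expect_true(all(d[-bc] == 0))
    expect_true(d[bc] == switch(kinds[r], synthesize = 1L, degrade = -1L, 0L))
  }
})

test_that("the silent-first-repeat encoding changes the species count, not the dynamics", {
  cP <- cell_model("normal", apc_r20_1 = "phosphosite")
  netP <- compile_network(expand_network(cP))
  expect_length(netP$species, 654L)
  ssP <- find_steady_state(netP)
  netN <- get_network(cell_model("normal"))
  ssN <- find_steady_state(netN)
  expect_equal(evaluate_observable(netP, "BCAT_total", ssP$state),
               evaluate_observable(netN, "BCAT_total", ssN$state),
               tolerance = 1e-6)
})

test_that("stoichiometry caps bound complex growth and guards fire", {
  cell <- cell_model("normal")
  n1 <- length(expand_network(cell, caps = c(BCAT = 1L, AXIN = 1L, GSK3B = 1L,
                                             CK1A = 1L, APC = 1L))$species)
  n2 <- length(expand_network(cell)$species)
  expect_equal(n1, 212L)
  expect_equal(n2, 340L)
  expect_error(expand_network(cell, caps = c(BCAT = 1L, AXIN = 2L, GSK3B = 2L,
                                             CK1A = 2L, APC = 1L),
                              max_species = 50L), "max_species")
  expect_error(expand_network(cell, caps = c(WRONG = 1L)), "unknown type")
})
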