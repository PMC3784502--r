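# Canonicalization of site graphs: exactness (equal strings iff isomorphic)
# against an independent permutation-search isomorphism test.

test_that("canonical strings are invariant to molecule ordering", {
  tt <- mini_tt()
  g1 <- species_graph(tt, c("A", "B"), bonds = list(list(1, "x", 2, "y")))
  g2 <- species_graph(tt, c("B", "A"), bonds = list(list(2, "x", 1, "y")))
  expect_equal(canonical_string(g1), canonical_string(g2))

  # free molecule with any state ordering
  gA <- species_graph(tt, "A", states = list(c(s = "p")))
  expect_equal(canonical_string(gA), canonical_string(gA))
})

test_that("distinct bonding patterns canonicalize differently", {
  cell <- cell_model("normal")
  tt <- cell$types
  # APC-BCAT bonded via the 15-aa interface vs via the phospho 20-aa repeat
  g_a <- species_graph(tt, c("APC", "BCAT"),
                       bonds = list(list(1, "aa15", 2, "arm59")))
  g_b <- species_graph(tt, c("APC", "BCAT"),
                       states = list(c(r20_3 = "p"), NULL),
                       bonds = list(list(1, "r20_3", 2, "arm34")))
  expect_false(canonical_string(g_a) == canonical_string(g_b))
  expect_false(naive_iso(g_a, g_b))
})

test_that("cyclic complexes are invariant under relabelling", {
  cell <- cell_model("normal")
  tt <- cell$types
  mk <- function(ord) {
    # cyclic APC-BCAT-AXIN: aa15-arm59, arm34-bcat, samp-rgs
    idx <- match(c("APC", "BCAT", "AXIN"), ord)
    species_graph(tt, ord,
      states = list(NULL, NULL, NULL)[order(idx)],
      bonds = list(list(idx[1], "aa15", idx[2], "arm59"),
                   list(idx[2], "arm34", idx[3], "bcat"),
                   list(idx[1], "samp", idx[3], "rgs")))
  }
  s1 <- canonical_string(mk(c("APC", "BCAT", "AXIN")))
  s2 <- canonical_string(mk(c("AXIN", "APC", "BCAT")))
  s3 <- canonical_string(mk(c("BCAT", "AXIN", "APC")))
  expect_equal(s1, s2)
  expect_equal(s1, s3)
})

test_that("canonicalization is exact on random isomorphic and modified pairs", {
  tt <- mini_tt()
  set.seed(42)
  n_equal <- 0L; n_diff <- 0L
  for (i in 1:1000) {
    g <- random_species(tt, n_mol = sample(2:4, 1))
    h <- shuffle_species(g)
    expect_equal(canonical_string(g), canonical_string(h))
    n_equal <- n_equal + 1L
  }
  # perturbed copies: flip a state or drop a bond, then require different
  # strings whenever the pair is non-isomorphic by brute force
  for (i in 1:300) {
    g <- random_species(tt, n_mol = sample(2:4, 1))
    h <- g
    statefuls <- which(vapply(seq_along(h$state),
                              function(m) any(h$state[[m]] > 0L), TRUE))
    if (length(statefuls) && stats::runif(1) < 0.6) {
      m <- statefuls[sample.int(length(statefuls), 1)]
      s <- which(h$state[[m]] > 0L)[1]
      h$state[[m]][s] <- 3L - h$state[[m]][s]   # toggle u <-> p
      h <- dcx:::sg_make(h$type, h$state, h$bonds)
    } else if (nrow(h$bonds) > 0L) {
      frags <- dcx:::sg_remove_bond(h, nrow(h$bonds))
      if (length(frags) != 1L) next   # keep it connected
      h <- frags[[1]]
    } else next
    h <- shuffle_species(h)
    iso <- naive_iso(g, h)
    expect_equal(canonical_string(g) == canonical_string(h), iso)
    if (!iso) n_diff <- n_diff + 1L
  }
  expect_gte(n_equal, 1000L)
  expect_gte(n_diff, 100L)   # the perturbations genuinely exercised the check
})

test_that("canonicalization rejects disconnected graphs and splits components", {
  tt <- mini_tt()
  g <- dcx:::sg_make(c(1L, 2L), list(c(0L, 1L), 0L))  # A and B, no bond
  expect_error(canonical_string(g), "disconnected")
  bonded <- species_graph(tt, c("A", "B"), bonds = list(list(1, "x", 2, "y")))
  frags <- dcx:::sg_remove_bond(bonded, 1L)
  expect_length(frags, 2L)
  expect_setequal(vapply(frags, function(f) tt$names[f$type], ""), c("A", "B"))
})

test_that("species labels render sites, states and bonds readably", {
  cell <- cell_model("normal")
  tt <- cell$types
  g <- species_graph(tt, c("APC", "BCAT"),
                     states = list(c(r20_3 = "p"), c(S45 = "p")),
                     bonds = list(list(1, "aa15", 2, "arm59")))
  lab <- species_label(g, tt)
  expect_match(lab, "APC\\(")
  expect_match(lab, "r20_3~p")
  expect_match(lab, "aa15!1")
  expect_match(lab, "arm59!1")
  expect_match(lab, "S45~p")
})
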