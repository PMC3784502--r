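# Helpers: minimal cell-model skeletons for engine tests, an independent
# brute-force expansion oracle, and random site-graph generators.

# a bare cell-model skeleton around arbitrary molecule types and rules
mini_cell <- function(types, rules, seeds, params) {
  tt <- dcx:::type_table(types)
  names(rules) <- vapply(rules, `[[`, "", "name")
  if (!inherits(params, "dcx_params")) class(params) <- "dcx_params"
  structure(list(background = "mini", pools = list(), constructs = list(),
                 ablations = character(), gsk_inhibition_fold = 1,
                 s33_37_mutant = FALSE, apcE_affinity = "full_r3",
                 types = tt, rules = rules, seeds = seeds, params = params),
            class = "dcx_cell")
}

mini_bind <- function(name, ta, sa, tb, sb, kd_param, state_a = NA_character_,
                      state_b = NA_character_, require_a = NULL,
                      require_b = NULL) {
  dcx:::bind_rule(name,
                  dcx:::side(ta, sa, state = state_a, require = require_a),
                  dcx:::side(tb, sb, state = state_b, require = require_b),
                  rate_param = "kf", kd_param = kd_param)
}

mini_rev <- function(bind) {
  list(name = paste0(bind$name, "_rev"), kind = "unbind", a = bind$a, b = bind$b,
       kd_param = bind$kd_param, interface = NA_character_, gsk_mediated = FALSE)
}

mini_flip <- function(name, type, site, from, to, rate_param,
                      context = list(), site_unbound = FALSE) {
  list(name = name, kind = "state_change",
       subject = list(type = type, site = site, from = from, to = to,
                      require = NULL, site_unbound = site_unbound),
       context = context, rate_param = rate_param, gsk_mediated = FALSE)
}

# ---------------------------------------------------------------------------
# Independent oracle: naive isomorphism by full permutation search, naive
# reachability by direct enumeration over all species/site combinations, and
# a derivative evaluator that sums per-embedding fluxes without grouping.
# Shares only the raw graph record layout with the engine; identity testing,
# rule application and rate accumulation are implemented separately.

all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_perms(n - 1L)) out[[length(out) + 1L]] <- c(i, rest[p])
  }
  out
}

naive_iso <- function(g1, g2) {
  n <- length(g1$type)
  if (n != length(g2$type)) return(FALSE)
  if (!identical(sort(g1$type), sort(g2$type))) return(FALSE)
  bondset <- function(g, old2new) {
    if (nrow(g$bonds) == 0L) return(character())
    sort(apply(g$bonds, 1, function(b) {
      e1 <- paste0(old2new[b[1]], ".", b[2])
      e2 <- paste0(old2new[b[3]], ".", b[4])
      paste(sort(c(e1, e2)), collapse = "-")
    }))
  }
  target_bonds <- bondset(g2, seq_len(n))
  target_states <- unlist(g2$state)
  for (p in all_perms(n)) {          # p[new position] = old index in g1
    if (!all(g1$type[p] == g2$type)) next
    if (!identical(as.integer(unlist(g1$state[p])), as.integer(target_states))) next
    old2new <- integer(n); old2new[p] <- seq_len(n)
    if (identical(bondset(g1, old2new), target_bonds)) return(TRUE)
  }
  FALSE
}

# raw graph record helpers (independent of the engine's transformation code)
o_graph <- function(type, state, bonds = matrix(integer(), 0, 4)) {
  list(type = type, state = state, bonds = bonds)
}

o_site_free <- function(g, m, s) {
  b <- g$bonds
  !any((b[, 1] == m & b[, 2] == s) | (b[, 3] == m & b[, 4] == s))
}

o_components <- function(g) {
  n <- length(g$type)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    if (nrow(g$bonds)) for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 3]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(seq_len(n), comp)
}

o_extract <- function(g, keep) {
  keep <- sort(keep)
  remap <- integer(length(g$type)); remap[keep] <- seq_along(keep)
  b <- g$bonds
  if (nrow(b)) {
    b <- b[b[, 1] %in% keep, , drop = FALSE]
    b[, 1] <- remap[b[, 1]]; b[, 3] <- remap[b[, 3]]
  }
  o_graph(g$type[keep], g$state[keep], b)
}

o_merge_bond <- function(g1, g2, m1, s1, m2, s2) {
  off <- length(g1$type)
  b2 <- g2$bonds
  if (nrow(b2)) { b2[, 1] <- b2[, 1] + off; b2[, 3] <- b2[, 3] + off }
  o_graph(c(g1$type, g2$type), c(g1$state, g2$state),
          rbind(g1$bonds, b2, c(m1, s1, m2 + off, s2)))
}

# convert an engine graph (with bnd_* fields) to the raw record
as_o <- function(g) o_graph(g$type, g$state, g$bonds)

# oracle expansion: returns list(species = list of raw graphs,
#   instances = list of per-embedding reaction instances with fields
#   reactants (indices), products (indices), rate)
oracle_expand <- function(cell, caps) {
  tt <- cell$types
  n_types <- length(tt$names)
  capv <- rep(Inf, n_types)
  capv[match(names(caps), tt$names)] <- caps
  params <- cell$params
  crules <- dcx:::compile_rules(cell)

  species <- list()
  find_sp <- function(g) {
    for (i in seq_along(species)) if (naive_iso(species[[i]], g)) return(i)
    0L
  }
  add_sp <- function(g) {
    if (any(tabulate(g$type, n_types) > capv)) return(NA_integer_)
    i <- find_sp(g)
    if (i == 0L) { species[[length(species) + 1L]] <<- g; i <- length(species) }
    i
  }
  for (sd in cell$seeds) {
    ty <- match(sd$type, tt$names)
    add_sp(o_graph(ty, list(tt$templates[[ty]])))
  }

  side_ok <- function(g, m, sd) {
    if (g$type[m] != sd$ty || !o_site_free(g, m, sd$si)) return(FALSE)
    if (sd$st != 0L && g$state[[m]][sd$si] != sd$st) return(FALSE)
    if (!is.null(sd$req) && !all(g$state[[m]][sd$req[, 1]] == sd$req[, 2]))
      return(FALSE)
    TRUE
  }

  instances <- list()
  # iterate to closure; every round, re-derive all instances from scratch
  repeat {
    n0 <- length(species)
    instances <- list()
    for (rid in seq_along(crules)) {
      cr <- crules[[rid]]
      if (cr$kind == "bind") {
        rate_bi <- params[[cr$rate_param]]
        rate_uni <- params[[cr$rate_param]] * params$chi
        sym <- identical(cr$a, cr$b)
        for (i in seq_along(species)) for (j in seq_along(species)) {
          gi <- species[[i]]; gj <- species[[j]]
          for (ma in seq_along(gi$type)) for (mb in seq_along(gj$type)) {
            if (!side_ok(gi, ma, cr$a) || !side_ok(gj, mb, cr$b)) next
            prod <- o_merge_bond(gi, gj, ma, cr$a$si, mb, cr$b$si)
            pid <- add_sp(prod)
            if (is.na(pid)) next
            # identical patterns on both sides double-count ordered copies of
            # the same species: the standard symmetry factor 1/2 applies
            r_eff <- if (sym && i == j) rate_bi / 2 else rate_bi
            instances[[length(instances) + 1L]] <-
              list(reactants = c(i, j), products = pid, rate = r_eff)
          }
        }
        # intracomplex closures within one species
        for (i in seq_along(species)) {
          gi <- species[[i]]
          for (ma in seq_along(gi$type)) for (mb in seq_along(gi$type)) {
            if (ma == mb) next
            if (!side_ok(gi, ma, cr$a) || !side_ok(gi, mb, cr$b)) next
            prod <- o_graph(gi$type, gi$state,
                            rbind(gi$bonds, c(ma, cr$a$si, mb, cr$b$si)))
            pid <- add_sp(prod)
            if (is.na(pid)) next
            instances[[length(instances) + 1L]] <-
              list(reactants = i, products = pid, rate = rate_uni)
          }
        }
      } else if (cr$kind == "unbind") {
        rate <- params$kf * params[[cr$kd_param]]
        for (i in seq_along(species)) {
          gi <- species[[i]]
          if (!nrow(gi$bonds)) next
          for (r in seq_len(nrow(gi$bonds))) {
            b <- gi$bonds[r, ]
            fwd <- gi$type[b[1]] == cr$a$ty && b[2] == cr$a$si &&
                   gi$type[b[3]] == cr$b$ty && b[4] == cr$b$si
            rev <- gi$type[b[3]] == cr$a$ty && b[4] == cr$a$si &&
                   gi$type[b[1]] == cr$b$ty && b[2] == cr$b$si
            if (!fwd && !rev) next
            g2 <- o_graph(gi$type, gi$state, gi$bonds[-r, , drop = FALSE])
            comps <- o_components(g2)
            pids <- vapply(comps, function(k) add_sp(o_extract(g2, k)), 0L)
            instances[[length(instances) + 1L]] <-
              list(reactants = i, products = pids, rate = rate)
          }
        }
      } else if (cr$kind == "state_change") {
        rate <- params[[cr$rate_param]]
        for (i in seq_along(species)) {
          gi <- species[[i]]
          # one instance per (subject molecule, context tuple)
          for (m in seq_along(gi$type)) {
            s <- cr$subject
            if (gi$type[m] != s$ty) next
            if (gi$state[[m]][s$si] != s$from) next
            if (s$site_unbound && !o_site_free(gi, m, s$si)) next
            ok <- TRUE
            if (!is.null(s$req))
              ok <- all(gi$state[[m]][s$req[, 1]] == s$req[, 2])
            if (!ok) next
            ctx_counts <- vapply(cr$context, function(cx) {
              ms <- which(gi$type == cx$ty)
              if (cx$si == 0L) length(ms)
              else sum(vapply(ms, function(mm) !o_site_free(gi, mm, cx$si), TRUE))
            }, 0L)
            if (length(ctx_counts) && any(ctx_counts == 0L)) next
            st <- gi$state; st[[m]][s$si] <- s$to
            pid <- add_sp(o_graph(gi$type, st, gi$bonds))
            n_inst <- if (length(ctx_counts)) prod(ctx_counts) else 1L
            for (dup in seq_len(n_inst))
              instances[[length(instances) + 1L]] <-
                list(reactants = i, products = pid, rate = rate)
          }
        }
      }
    }
    if (length(species) == n0) break
  }
  list(species = species, instances = instances)
}

# time derivative from per-embedding instances
oracle_deriv <- function(oracle, y) {
  dy <- numeric(length(oracle$species))
  for (inst in oracle$instances) {
    v <- inst$rate * prod(y[inst$reactants])
    for (r in inst$reactants) dy[r] <- dy[r] - v
    for (p in inst$products) dy[p] <- dy[p] + v
  }
  dy
}

# map engine species indices to oracle indices (must be a bijection)
match_species <- function(net, oracle) {
  eng <- lapply(net$species, as_o)
  idx <- vapply(eng, function(g) {
    hits <- which(vapply(oracle$species, naive_iso, TRUE, g2 = g))
    if (length(hits) != 1L) NA_integer_ else hits
  }, 0L)
  idx
}

# engine-side derivative at a state
engine_deriv <- function(net, y) {
  oc <- dcx:::ode_compiled(net)
  k <- reaction_rates(net, net$cell$params)
  dcx:::make_deriv(oc, k)(0, y, NULL)[[1]]
}

# random connected species graph over a fixed small type alphabet
random_species <- function(tt, n_mol = 3L) {
  n_types <- length(tt$names)
  repeat {
    ty <- sample.int(n_types, n_mol, replace = TRUE)
    st <- lapply(ty, function(t) {
      v <- tt$templates[[t]]
      v[v > 0L] <- vapply(which(v > 0L), function(s) {
        labs <- tt$types[[t]]$states[[tt$types[[t]]$sites[s]]]
        sample.int(length(labs), 1L)
      }, 0L)
      v
    })
    # try random bonds between free sites of distinct molecules until connected
    free <- do.call(rbind, lapply(seq_len(n_mol), function(m)
      cbind(m, seq_along(st[[m]]))))
    bonds <- matrix(integer(), 0, 4)
    used <- rep(FALSE, nrow(free))
    for (tries in seq_len(12L)) {
      open <- which(!used)
      if (length(open) < 2L) break
      pick <- sample(open, 2L)
      a <- free[pick[1], ]; b <- free[pick[2], ]
      if (a[1] == b[1]) next
      bonds <- rbind(bonds, c(a[1], a[2], b[1], b[2]))
      used[pick] <- TRUE
      g <- dcx:::sg_make(ty, st, bonds)
      if (dcx:::sg_connected(g)) return(g)
    }
    g <- dcx:::sg_make(ty, st, bonds)
    if (dcx:::sg_connected(g)) return(g)
    if (n_mol == 1L) return(dcx:::sg_make(ty, st))
  }
}

# random relabelling of a graph's molecules (an isomorphic copy)
shuffle_species <- function(g) {
  n <- length(g$type)
  p <- sample.int(n)          # p[old] = new
  inv <- integer(n); inv[p] <- seq_len(n)
  b <- g$bonds
  if (nrow(b)) { b[, 1] <- p[b[, 1]]; b[, 3] <- p[b[, 3]] }
  dcx:::sg_make(g$type[inv], g$state[inv], b)
}

# the standard two-site mini alphabet used by several graph tests
mini_tt <- function() {
  dcx:::type_table(list(
    molecule_type("A", c("x", "s"), list(s = c("u", "p"))),
    molecule_type("B", c("y")),
    molecule_type("C", c("z1", "z2"))
  ))
}
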