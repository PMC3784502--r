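# Rule engine: matching of rule patterns against species graphs, rule
# application, and breadth-first expansion of a rule set into a finite
# mass-action reaction network.
#
# Intracomplex binding is detected structurally at expansion time: when both
# reactant sites of a binding rule are free and co-resident in one species,
# the bond closure is a unimolecular reaction with forward rate kf * chi
# (high local concentration of tethered partners); when they live on two
# species, the reaction is bimolecular with rate kf. Unbinding always
# proceeds at kf * KD regardless of context.

# --- rule compilation: names -> integer ids --------------------------------

compile_side <- function(tt, s) {
  ty <- type_id(tt, s$type)
  si <- site_id(tt, ty, s$site)
  st <- if (is.na(s$state)) 0L else state_id(tt, ty, si, s$state)
  req <- compile_require(tt, ty, s$require)
  list(ty = ty, si = si, st = st, req = req)
}

compile_require <- function(tt, ty, require) {
  if (is.null(require) || !length(require)) return(NULL)
  cbind(
    site = vapply(names(require), function(nm) site_id(tt, ty, nm), 0L),
    state = vapply(seq_along(require), function(k)
      state_id(tt, ty, site_id(tt, ty, names(require)[k]), require[[k]]), 0L)
  )
}

compile_rules <- function(cell) {
  tt <- cell$types
  lapply(cell$rules, function(r) {
    cr <- list(name = r$name, kind = r$kind, gsk_mediated = isTRUE(r$gsk_mediated),
               rate_param = r$rate_param, kd_param = r$kd_param,
               interface = if (is.null(r$interface)) NA_character_ else r$interface)
    if (r$kind %in% c("bind", "unbind")) {
      cr$a <- compile_side(tt, r$a)
      cr$b <- compile_side(tt, r$b)
    } else if (r$kind == "state_change") {
      ty <- type_id(tt, r$subject$type)
      si <- site_id(tt, ty, r$subject$site)
      cr$subject <- list(ty = ty, si = si,
                         from = state_id(tt, ty, si, r$subject$from),
                         to = state_id(tt, ty, si, r$subject$to),
                         req = compile_require(tt, ty, r$subject$require),
                         site_unbound = isTRUE(r$subject$site_unbound))
      cr$context <- lapply(r$context, function(cx) {
        cty <- type_id(tt, cx$type)
        list(ty = cty,
             si = if (is.na(cx$site_bound)) 0L else site_id(tt, cty, cx$site_bound))
      })
    } else if (r$kind == "degrade") {
      ty <- type_id(tt, r$subject$type)
      cr$subject <- list(ty = ty, req = compile_require(tt, ty, r$subject$require))
    } else if (r$kind == "synthesize") {
      cr$product <- type_id(tt, r$product)
    }
    cr
  })
}

# --- matching --------------------------------------------------------------

mol_satisfies <- function(g, m, req) {
  if (is.null(req)) return(TRUE)
  st <- g$state[[m]]
  all(st[req[, 1L]] == req[, 2L])
}

# molecules/sites matching one side of a binding rule with the site FREE;
# returns integer vector of molecule indices (site index is fixed per side)
side_matches <- function(g, sd) {
  ms <- which(g$type == sd$ty)
  if (!length(ms)) return(integer())
  keep <- vapply(ms, function(m) {
    if (g$bnd_r[[m]][sd$si] != 0L) return(FALSE)
    if (sd$st != 0L && g$state[[m]][sd$si] != sd$st) return(FALSE)
    mol_satisfies(g, m, sd$req)
  }, TRUE)
  ms[keep]
}

# number of molecules satisfying a co-complex context item
context_count <- function(g, cx) {
  ms <- which(g$type == cx$ty)
  if (!length(ms)) return(0L)
  if (cx$si == 0L) return(length(ms))
  sum(vapply(ms, function(m) g$bnd_r[[m]][cx$si] != 0L, TRUE))
}

#' Match a rule pattern against a species graph
#'
#' Exposes the engine's matcher: returns all embeddings of the reactant
#' pattern of \code{rule} in \code{g}. For binding rules, an embedding is a
#' pair of free matching sites (intracomplex orientation); for unbinding, a
#' bond; for state changes and degradation, a subject molecule (for state
#' changes, only when all co-complex context requirements are met).
#'
#' @param cell a \code{dcx_cell}
#' @param rule_name name of a rule of \code{cell}
#' @param g species graph
#' @return list of embeddings (named integer vectors). For binding rules each
#'   embedding is one molecule matching one reactant pattern (\code{side} 1
#'   or 2) with the rule's site free; the pairing of sides (intermolecular
#'   across species, or intracomplex within one) happens at expansion time.
#' @export
match_rule <- function(cell, rule_name, g) {
  cr <- compile_rules(cell)[[rule_name]]
  if (is.null(cr)) stop("unknown rule: ", rule_name)
  switch(cr$kind,
    bind = {
      c(lapply(side_matches(g, cr$a), function(m) c(side = 1L, mol = m)),
        lapply(side_matches(g, cr$b), function(m) c(side = 2L, mol = m)))
    },
    unbind = {
      rows <- unbind_matches(g, cr)
      lapply(rows, function(r) c(bond = r))
    },
    state_change = {
      subj <- state_change_subjects(g, cr)
      k <- state_change_context_mult(g, cr)
      if (k == 0L) list() else lapply(subj, function(m) c(mol = m))
    },
    degrade = {
      ms <- which(g$type == cr$subject$ty)
      ms <- ms[vapply(ms, function(m) mol_satisfies(g, m, cr$subject$req), TRUE)]
      lapply(ms, function(m) c(mol = m))
    },
    synthesize = list()
  )
}

unbind_matches <- function(g, cr) {
  b <- g$bonds
  if (!nrow(b)) return(integer())
  hits <- integer()
  for (r in seq_len(nrow(b))) {
    ta <- g$type[b[r, 1L]]; tb <- g$type[b[r, 3L]]
    if (ta == cr$a$ty && b[r, 2L] == cr$a$si && tb == cr$b$ty && b[r, 4L] == cr$b$si)
      hits <- c(hits, r)
    else if (tb == cr$a$ty && b[r, 4L] == cr$a$si && ta == cr$b$ty && b[r, 2L] == cr$b$si)
      hits <- c(hits, r)
  }
  hits
}

state_change_subjects <- function(g, cr) {
  s <- cr$subject
  ms <- which(g$type == s$ty)
  ms[vapply(ms, function(m) {
    if (g$state[[m]][s$si] != s$from) return(FALSE)
    if (s$site_unbound && g$bnd_r[[m]][s$si] != 0L) return(FALSE)
    mol_satisfies(g, m, s$req)
  }, TRUE)]
}

state_change_context_mult <- function(g, cr) {
  if (!length(cr$context)) return(1L)
  k <- 1L
  for (cx in cr$context) {
    n <- context_count(g, cx)
    if (n == 0L) return(0L)
    k <- k * n
  }
  k
}

# --- expansion -------------------------------------------------------------

#' Default per-complex stoichiometry caps
#'
#' Network expansion is kept finite by capping the copy number of each
#' molecule type within a single complex. Defaults: 1 beta-catenin, 1 of each
#' APC form, 2 Axin (one engaged through the beta-catenin ARM 3-4 site, one
#' through the APC SAMP repeats), 2 of each kinase (one per Axin).
#'
#' @param cell a \code{dcx_cell}
#' @return named integer vector, type name -> cap
#' @export
default_caps <- function(cell) {
  nms <- cell$types$names
  caps <- stats::setNames(rep(1L, length(nms)), nms)
  caps[c("AXIN", "GSK3B", "CK1A")] <- 2L
  caps
}

new_rxn_store <- function() {
  env <- new.env(parent = emptyenv())
  env$ra <- integer(); env$rb <- integer(); env$rule <- integer()
  env$intra <- logical(); env$mult <- integer(); env$products <- list()
  env$keys <- new.env(parent = emptyenv())
  env
}

add_reaction <- function(store, ra, rb, rule, intra, mult, products) {
  key <- paste(rule, ra, rb, intra, paste(products, collapse = ","), sep = "|")
  if (!is.null(store$keys[[key]])) return(invisible(FALSE))
  store$keys[[key]] <- TRUE
  n <- length(store$ra) + 1L
  store$ra[n] <- ra; store$rb[n] <- rb; store$rule[n] <- rule
  store$intra[n] <- intra; store$mult[n] <- mult
  store$products[[n]] <- products
  invisible(TRUE)
}

#' Expand a rule set into a reaction network
#'
#' Breadth-first closure: every rule is applied to every species (and species
#' pair, for intermolecular binding), products are canonicalized and added if
#' new, until a fixed point. Products whose per-complex composition exceeds
#' the stoichiometry caps are discarded. Species are numbered in discovery
#' order, which is deterministic.
#'
#' @param cell a \code{dcx_cell}
#' @param caps named integer vector of per-complex copy-number caps (default
#'   \code{\link{default_caps}})
#' @param max_species hard ceiling on the number of species (guards against
#'   runaway expansion; exceeded => error with diagnostics)
#' @param max_rounds hard ceiling on closure iterations
#' @return an object of class \code{dcx_network}: species graphs, canonical
#'   strings, composition matrix, reaction table (reactant/product indices,
#'   rule id, intracomplex flag, embedding multiplicity), seeds, caps
#' @examples
#' cell <- cell_model("SW480")
#' net <- expand_network(cell)
#' net
#' @export
expand_network <- function(cell, caps = default_caps(cell),
                           max_species = 50000L, max_rounds = 100L) {
  tt <- cell$types
  crules <- compile_rules(cell)
  n_types <- length(tt$names)
  capv <- rep(Inf, n_types)
  hit <- match(names(caps), tt$names)
  if (anyNA(hit)) stop("caps name unknown type(s): ",
                       paste(names(caps)[is.na(hit)], collapse = ", "))
  capv[hit] <- as.numeric(caps)

  bind_ids <- which(vapply(crules, function(r) r$kind == "bind", TRUE))
  uni_ids <- which(vapply(crules, function(r)
    r$kind %in% c("unbind", "state_change", "degrade"), TRUE))
  syn_ids <- which(vapply(crules, function(r) r$kind == "synthesize", TRUE))

  species <- list(); canon <- character()
  comp <- matrix(0L, 0L, n_types)
  amatch <- list(); bmatch <- list()   # per species x bind rule: free-site molecule lists
  index <- new.env(parent = emptyenv())
  store <- new_rxn_store()

  add_species <- function(g) {
    key <- canonical_string(g)
    i <- index[[key]]
    if (!is.null(i)) return(i)
    cmp <- sg_composition(g, n_types)
    if (any(cmp > capv)) return(NA_integer_)
    i <- length(species) + 1L
    if (i > max_species)
      stop("expansion exceeded max_species = ", max_species,
           " (", length(store$ra), " reactions so far); raise the ceiling ",
           "or tighten the stoichiometry caps")
    species[[i]] <<- g
    canon[i] <<- key
    comp <<- rbind(comp, cmp)
    amatch[[i]] <<- lapply(crules[bind_ids], function(r) side_matches(g, r$a))
    bmatch[[i]] <<- lapply(crules[bind_ids], function(r) side_matches(g, r$b))
    index[[key]] <- i
    i
  }

  # seed species: free molecules, default (unmodified) states
  seed_idx <- integer(length(cell$seeds))
  for (k in seq_along(cell$seeds)) {
    ty <- type_id(tt, cell$seeds[[k]]$type)
    g <- sg_make(ty, list(tt$templates[[ty]]))
    seed_idx[k] <- add_species(g)
  }
  if (anyNA(seed_idx)) stop("a seed species violates the stoichiometry caps")

  # synthesis: zeroth-order creation of the free unmodified product
  for (rid in syn_ids) {
    ty <- crules[[rid]]$product
    g <- sg_make(ty, list(tt$templates[[ty]]))
    pid <- add_species(g)
    add_reaction(store, 0L, 0L, rid, FALSE, 1L, pid)
  }

  apply_unimolecular <- function(s) {
    g <- species[[s]]
    for (rid in uni_ids) {
      cr <- crules[[rid]]
      if (cr$kind == "unbind") {
        rows <- unbind_matches(g, cr)
        if (!length(rows)) next
        groups <- list()
        for (r in rows) {
          frags <- sg_remove_bond(g, r)
          pids <- sort(vapply(frags, add_species, 0L))
          key <- paste(pids, collapse = ",")
          groups[[key]] <- c(groups[[key]], list(pids))
        }
        for (key in names(groups))
          add_reaction(store, s, 0L, rid, FALSE, length(groups[[key]]),
                       groups[[key]][[1]])
      } else if (cr$kind == "state_change") {
        cmult <- state_change_context_mult(g, cr)
        if (cmult == 0L) next
        subj <- state_change_subjects(g, cr)
        if (!length(subj)) next
        groups <- list()
        for (m in subj) {
          g2 <- sg_set_state(g, m, cr$subject$si, cr$subject$to)
          pid <- add_species(g2)
          key <- as.character(pid)
          groups[[key]] <- c(groups[[key]], pid)
        }
        for (key in names(groups))
          add_reaction(store, s, 0L, rid, FALSE,
                       cmult * length(groups[[key]]), groups[[key]][[1]])
      } else if (cr$kind == "degrade") {
        ms <- which(g$type == cr$subject$ty)
        ms <- ms[vapply(ms, function(m) mol_satisfies(g, m, cr$subject$req), TRUE)]
        for (m in ms) {
          frags <- sg_delete_molecule(g, m)
          pids <- if (length(frags)) sort(vapply(frags, add_species, 0L)) else integer()
          add_reaction(store, s, 0L, rid, FALSE, 1L, pids)
        }
      }
    }
    # intracomplex bond closure: both sites free within one species
    for (k in seq_along(bind_ids)) {
      ma <- amatch[[s]][[k]]; mb <- bmatch[[s]][[k]]
      if (!length(ma) || !length(mb)) next
      cr <- crules[[bind_ids[k]]]
      groups <- list()
      for (a in ma) for (b in mb) {
        if (a == b && cr$a$si == cr$b$si) next
        if (a == b) next  # a site pair on one molecule cannot close a bond here
        g2 <- sg_add_bond(g, a, cr$a$si, b, cr$b$si)
        pid <- add_species(g2)
        key <- as.character(pid)
        groups[[key]] <- c(groups[[key]], pid)
      }
      for (key in names(groups))
        add_reaction(store, s, 0L, bind_ids[k], TRUE,
                     length(groups[[key]]), groups[[key]][[1]])
    }
  }

  apply_bimolecular_pair <- function(f, u) {
    # both orientations: side a in f + side b in u, and vice versa
    for (k in seq_along(bind_ids)) {
      cr <- crules[[bind_ids[k]]]
      for (orient in 1:2) {
        if (orient == 1L) { i <- f; j <- u } else {
          if (f == u) break
          i <- u; j <- f
        }
        ma <- amatch[[i]][[k]]; mb <- bmatch[[j]][[k]]
        if (!length(ma) || !length(mb)) next
        gi <- species[[i]]; gj <- species[[j]]
        off <- sg_n(gi)
        gm <- sg_merge(gi, gj)
        groups <- list()
        for (a in ma) for (b in mb) {
          g2 <- sg_add_bond(gm, a, cr$a$si, b + off, cr$b$si)
          pid <- add_species(g2)
          if (is.na(pid)) next
          key <- as.character(pid)
          groups[[key]] <- c(groups[[key]], pid)
        }
        for (key in names(groups)) {
          mult <- length(groups[[key]])
          # identical reactant species with symmetric sides would double-count
          if (i == j && identical(cr$a, cr$b)) mult <- mult / 2
          add_reaction(store, i, j, bind_ids[k], FALSE, mult, groups[[key]][[1]])
        }
      }
    }
  }

  frontier <- seq_along(species)
  rounds <- 0L
  while (length(frontier)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("expansion failed to close after ", max_rounds, " rounds (",
           length(species), " species); the rule set may generate unbounded polymers")
    n_before <- length(species)
    for (f in frontier) {
      apply_unimolecular(f)
      # pairs (f, u) with u <= f: every unordered pair is visited exactly once
      comp_f <- comp[f, ]
      for (u in seq_len(f)) {
        if (any(comp_f + comp[u, ] > capv)) next
        apply_bimolecular_pair(f, u)
      }
    }
    frontier <- if (length(species) > n_before) (n_before + 1L):length(species) else integer()
  }

  rxn <- data.frame(ra = store$ra, rb = store$rb, rule = store$rule,
                    intra = store$intra, mult = store$mult)
  structure(list(cell = cell, species = species, canon = canon, comp = comp,
                 reactions = rxn, products = store$products,
                 seed_idx = seed_idx, caps = caps, rounds = rounds,
                 crules = crules),
            class = "dcx_network")
}

#' @export
print.dcx_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      nrow(x$reactions), "reactions\n")
  cat("  caps:", paste(names(x$caps), x$caps, sep = "=", collapse = ", "), "\n")
  cat("  closure reached in", x$rounds, "rounds\n")
  invisible(x)
}

#' Verify closure of a reaction network
#'
#' Re-applies every rule to every species (and every admissible species pair)
#' and checks that each product is either a member of the network or exceeds
#' the stoichiometry caps. Returns TRUE invisibly or stops with the first
#' violation.
#'
#' @param net a \code{dcx_network}
#' @return TRUE (invisibly)
#' @export
check_closure <- function(net) {
  cell <- net$cell
  net2 <- expand_network(cell, caps = net$caps)
  if (!identical(sort(net2$canon), sort(net$canon)))
    stop("network is not closed: re-expansion changed the species set")
  invisible(TRUE)
}

#' Export a network as plain-text tables
#'
#' @param net a \code{dcx_network}
#' @return list of two data.frames: \code{species} (index, canonical label,
#'   composition) and \code{reactions} (reactants, products, rule, intracomplex
#'   flag, multiplicity)
#' @export
network_tables <- function(net) {
  tt <- net$cell$types
  labs <- vapply(net$species, species_label, "", tt = tt)
  compdf <- as.data.frame(net$comp)
  names(compdf) <- tt$names
  spec <- cbind(data.frame(index = seq_along(labs), species = labs), compdf)
  rx <- net$reactions
  rxn <- data.frame(
    index = seq_len(nrow(rx)),
    reactants = vapply(seq_len(nrow(rx)), function(i) {
      r <- rx[i, ]
      paste(c(if (r$ra > 0) r$ra, if (r$rb > 0) r$rb), collapse = "+")
    }, ""),
    products = vapply(net$products, function(p) paste(p, collapse = "+"), ""),
    rule = vapply(net$crules[rx$rule], `[[`, "", "name"),
    intracomplex = rx$intra,
    multiplicity = rx$mult
  )
  list(species = spec, reactions = rxn)
}
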