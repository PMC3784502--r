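# Site graphs: connected complexes of molecule instances with binding sites,
# internal site states, and bonds. The unit of chemical identity in the model.
#
# Internal representation (all integer, for speed during network expansion):
#   type   integer vector, molecule type id per molecule instance
#   state  list of integer vectors, one per molecule: internal-state index per
#          site (0 for pure binding sites)
#   bonds  k x 4 integer matrix: (mol_a, site_a, mol_b, site_b)
#   bnd_m / bnd_s / bnd_r  per-molecule integer vectors: bound partner molecule,
#          partner site, and bond row (0 when the site is free)

#' Define a molecule type
#'
#' @param name type name (e.g. \code{"BCAT"})
#' @param sites character vector of site names
#' @param states named list mapping a site name to its ordered internal-state
#'   labels; sites absent from the list are pure binding sites
#' @return a \code{dcx_moltype} list
#' @export
molecule_type <- function(name, sites = character(), states = list()) {
  stopifnot(!anyDuplicated(sites))
  bad <- setdiff(names(states), sites)
  if (length(bad)) stop("state labels for unknown site(s): ", paste(bad, collapse = ", "))
  for (s in names(states)) {
    if (anyDuplicated(states[[s]])) stop("duplicate state labels on site ", s)
  }
  structure(list(name = name, sites = sites, states = states),
            class = "dcx_moltype")
}

#' Assemble a model type table
#' @param types list of \code{dcx_moltype}
#' @return a \code{dcx_typetable} with name lookup
#' @keywords internal
type_table <- function(types) {
  nms <- vapply(types, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate molecule type names")
  # integer state template per type: 0 for stateless sites, 1 = first label
  templates <- lapply(types, function(tp) {
    v <- integer(length(tp$sites))
    has <- tp$sites %in% names(tp$states)
    v[has] <- 1L
    v
  })
  structure(list(types = types, names = nms, templates = templates),
            class = "dcx_typetable")
}

type_id <- function(tt, name) {
  i <- match(name, tt$names)
  if (is.na(i)) stop("unknown molecule type: ", name)
  i
}

site_id <- function(tt, type, site) {
  tp <- tt$types[[type]]
  i <- match(site, tp$sites)
  if (is.na(i)) stop("unknown site ", site, " on type ", tp$name)
  i
}

state_id <- function(tt, type, site_idx, label) {
  tp <- tt$types[[type]]
  labs <- tp$states[[tp$sites[[site_idx]]]]
  i <- match(label, labs)
  if (is.na(i)) stop("unknown state label ", label)
  i
}

# Construct a species graph from integer parts; derives the per-site bond index.
sg_make <- function(type, state, bonds = NULL) {
  n <- length(type)
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 4)
  bnd_m <- bnd_s <- bnd_r <- lapply(state, function(s) integer(length(s)))
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1L]; sa <- bonds[r, 2L]; b <- bonds[r, 3L]; sb <- bonds[r, 4L]
      if (bnd_r[[a]][sa] != 0L || bnd_r[[b]][sb] != 0L)
        stop("site participates in more than one bond")
      bnd_m[[a]][sa] <- b; bnd_s[[a]][sa] <- sb; bnd_r[[a]][sa] <- r
      bnd_m[[b]][sb] <- a; bnd_s[[b]][sb] <- sa; bnd_r[[b]][sb] <- r
    }
  }
  list(type = type, state = state, bonds = bonds,
       bnd_m = bnd_m, bnd_s = bnd_s, bnd_r = bnd_r)
}

#' Build a species graph by name
#'
#' Convenience constructor used in examples, seeds and tests.
#'
#' @param tt type table (internal to a cell model; see \code{\link{cell_model}})
#' @param molecules character vector of type names
#' @param states list (one element per molecule) of named character vectors,
#'   site name -> state label; omitted sites take the first (default) label
#' @param bonds list of length-4 vectors \code{c(mol_a, site_a, mol_b, site_b)}
#'   with sites given by name
#' @return species graph
#' @export
species_graph <- function(tt, molecules, states = NULL, bonds = NULL) {
  ty <- vapply(molecules, function(nm) type_id(tt, nm), 0L)
  st <- lapply(seq_along(ty), function(i) {
    v <- tt$templates[[ty[[i]]]]
    if (!is.null(states) && length(states) >= i && length(states[[i]])) {
      for (s in names(states[[i]])) {
        si <- site_id(tt, ty[[i]], s)
        v[si] <- state_id(tt, ty[[i]], si, states[[i]][[s]])
      }
    }
    v
  })
  bm <- NULL
  if (!is.null(bonds) && length(bonds)) {
    bm <- t(vapply(bonds, function(b) {
      a <- as.integer(b[[1]]); bb <- as.integer(b[[3]])
      c(a, site_id(tt, ty[[a]], b[[2]]), bb, site_id(tt, ty[[bb]], b[[4]]))
    }, integer(4)))
  }
  g <- sg_make(ty, st, bm)
  if (!sg_connected(g)) stop("species graph must be connected")
  g
}

sg_n <- function(g) length(g$type)

# connected components as list of molecule index vectors
sg_components <- function(g) {
  n <- sg_n(g)
  comp <- integer(n)
  nc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue)) {
      m <- queue[[1]]; queue <- queue[-1]
      nb <- g$bnd_m[[m]]
      nb <- nb[nb != 0L]
      for (b in nb) if (comp[b] == 0L) { comp[b] <- nc; queue <- c(queue, b) }
    }
  }
  split(seq_len(n), comp)
}

sg_connected <- function(g) length(sg_components(g)) <= 1L

# extract the induced subgraph on molecule set `keep` (must be a union of
# components, so no bonds are cut)
sg_subgraph <- function(g, keep) {
  keep <- sort(keep)
  idx <- integer(sg_n(g)); idx[keep] <- seq_along(keep)
  b <- g$bonds
  if (nrow(b)) {
    sel <- b[, 1L] %in% keep
    b <- b[sel, , drop = FALSE]
    b[, 1L] <- idx[b[, 1L]]; b[, 3L] <- idx[b[, 3L]]
  }
  sg_make(g$type[keep], g$state[keep], b)
}

# disjoint union of two graphs (no bond between them yet)
sg_merge <- function(g1, g2) {
  off <- sg_n(g1)
  b2 <- g2$bonds
  if (nrow(b2)) { b2[, 1L] <- b2[, 1L] + off; b2[, 3L] <- b2[, 3L] + off }
  sg_make(c(g1$type, g2$type), c(g1$state, g2$state), rbind(g1$bonds, b2))
}

sg_add_bond <- function(g, a, sa, b, sb) {
  sg_make(g$type, g$state, rbind(g$bonds, c(a, sa, b, sb)))
}

# remove the bond at row r; returns list of resulting connected components
sg_remove_bond <- function(g, r) {
  g2 <- sg_make(g$type, g$state, g$bonds[-r, , drop = FALSE])
  lapply(sg_components(g2), function(k) sg_subgraph(g2, k))
}

sg_set_state <- function(g, m, s, val) {
  st <- g$state
  st[[m]][s] <- val
  g$state <- st
  g
}

# delete molecule m (with all its bonds); returns list of connected components
# (empty list if the graph was a monomer)
sg_delete_molecule <- function(g, m) {
  keep <- setdiff(seq_len(sg_n(g)), m)
  if (!length(keep)) return(list())
  idx <- integer(sg_n(g)); idx[keep] <- seq_along(keep)
  b <- g$bonds
  if (nrow(b)) {
    sel <- b[, 1L] != m & b[, 3L] != m
    b <- b[sel, , drop = FALSE]
    b[, 1L] <- idx[b[, 1L]]; b[, 3L] <- idx[b[, 3L]]
  }
  g2 <- sg_make(g$type[keep], g$state[keep], b)
  lapply(sg_components(g2), function(k) sg_subgraph(g2, k))
}

# ---------------------------------------------------------------------------
# Canonicalization: exact canonical labelling of the site graph, by brute
# force over permutations of molecules within isomorphism-invariant classes.
# Two graphs map to the same string iff they are isomorphic as labelled site
# graphs. Complexes in this model are tiny (<= ~9 molecules, <= 2-3 per type),
# so the permutation search is cheap.

.perm_cache <- new.env(parent = emptyenv())
perms <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- if (n == 1L) list(1L) else {
    out <- list()
    sub <- perms(n - 1L)
    for (i in seq_len(n)) {
      others <- setdiff(seq_len(n), i)
      for (s in sub) out[[length(out) + 1L]] <- c(i, others[s])
    }
    out
  }
  .perm_cache[[key]] <- p
  p
}

# isomorphism-invariant key per molecule: type, states, sorted multiset of
# bond endpoint descriptors (own site, partner type, partner site)
mol_keys <- function(g) {
  n <- sg_n(g)
  out <- character(n)
  for (m in seq_len(n)) {
    bm <- g$bnd_m[[m]]
    bound <- which(bm != 0L)
    desc <- if (length(bound)) {
      d <- paste0(bound, ":", g$type[bm[bound]], ".", g$bnd_s[[m]][bound])
      paste(sort(d), collapse = ",")
    } else ""
    out[m] <- paste0(g$type[m], "|", paste(g$state[[m]], collapse = ""), "|", desc)
  }
  out
}

# string for a fixed molecule ordering `ord` (ord[k] = original index of the
# k-th molecule); bonds are numbered in order of first appearance
sg_string_ordered <- function(g, ord) {
  nb <- nrow(g$bonds)
  bondnum <- integer(nb)
  nxt <- 0L
  pos <- integer(sg_n(g)); pos[ord] <- seq_along(ord)
  toks <- character(length(ord))
  for (k in seq_along(ord)) {
    m <- ord[[k]]
    st <- g$state[[m]]
    br <- g$bnd_r[[m]]
    site_toks <- character(length(st))
    for (s in seq_along(st)) {
      r <- br[s]
      if (r != 0L) {
        if (bondnum[r] == 0L) { nxt <- nxt + 1L; bondnum[r] <- nxt }
        site_toks[s] <- paste0(st[s], "!", bondnum[r])
      } else site_toks[s] <- as.character(st[s])
    }
    toks[k] <- paste0(g$type[m], "(", paste(site_toks, collapse = ","), ")")
  }
  paste(toks, collapse = ".")
}

#' Canonical string of a species graph
#'
#' Exact canonicalization (not hashing): molecules are first ordered by an
#' isomorphism-invariant key; all permutations within tied key groups are then
#' tried and the lexicographically smallest bond-numbered string is returned.
#' Two graphs yield the same string iff they are isomorphic.
#'
#' @param g species graph (must be connected)
#' @return canonical string (opaque; see \code{\link{species_label}} for a
#'   human-readable rendering)
#' @export
canonical_string <- function(g) {
  if (!sg_connected(g)) stop("cannot canonicalize a disconnected species graph")
  n <- sg_n(g)
  if (n == 1L) return(sg_string_ordered(g, 1L))
  keys <- mol_keys(g)
  base <- order(keys)
  groups <- split(seq_len(n), keys)[unique(keys[base])]
  sizes <- lengths(groups)
  if (all(sizes == 1L)) return(sg_string_ordered(g, base))
  # enumerate orderings: cartesian product of in-group permutations
  group_perms <- lapply(groups, function(gr) {
    if (length(gr) == 1L) list(gr) else lapply(perms(length(gr)), function(p) gr[p])
  })
  best <- NULL
  idx <- rep(1L, length(group_perms))
  npg <- vapply(group_perms, length, 0L)
  repeat {
    ord <- unlist(lapply(seq_along(group_perms), function(i) group_perms[[i]][[idx[i]]]),
                  use.names = FALSE)
    s <- sg_string_ordered(g, ord)
    if (is.null(best) || s < best) best <- s
    # next index tuple
    k <- length(idx)
    while (k >= 1L) {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= npg[k]) break
      idx[k] <- 1L; k <- k - 1L
    }
    if (k < 1L) break
  }
  best
}

#' Human-readable label of a species graph
#'
#' Renders the canonical ordering with molecule, site and state names, in a
#' BNGL-like syntax, e.g. \code{"APC(aa15!1,r20_3~p,samp).BCAT(arm34,arm59!1,S45~u,S33_37~u)"}.
#'
#' @param g species graph
#' @param tt type table
#' @return character label
#' @export
species_label <- function(g, tt) {
  n <- sg_n(g)
  keys <- mol_keys(g)
  ord <- order(keys)
  nb <- nrow(g$bonds)
  bondnum <- integer(nb); nxt <- 0L
  toks <- character(n)
  for (k in seq_along(ord)) {
    m <- ord[[k]]
    tp <- tt$types[[g$type[m]]]
    st <- g$state[[m]]
    br <- g$bnd_r[[m]]
    site_toks <- character(length(st))
    for (s in seq_along(st)) {
      lab <- tp$sites[[s]]
      if (st[s] != 0L) lab <- paste0(lab, "~", tp$states[[tp$sites[[s]]]][st[s]])
      r <- br[s]
      if (r != 0L) {
        if (bondnum[r] == 0L) { nxt <- nxt + 1L; bondnum[r] <- nxt }
        lab <- paste0(lab, "!", bondnum[r])
      }
      site_toks[s] <- lab
    }
    toks[k] <- paste0(tp$name, "(", paste(site_toks, collapse = ","), ")")
  }
  paste(toks, collapse = ".")
}

# composition: counts per type id
sg_composition <- function(g, n_types) {
  tabulate(g$type, nbins = n_types)
}
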