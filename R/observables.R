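# Observables: weighted pattern-count sums over species concentrations.
# An observable carries a numerator weight function (species graph -> weight)
# and an optional denominator; fractions are flagged undefined (NA) when the
# denominator vanishes.

#' Define an observable
#'
#' @param name observable name
#' @param weight function(g, tt, params) returning the per-species weight
#'   (e.g. the number of matching molecules in the species)
#' @param denom NULL for plain weighted sums, a weight function for fractions,
#'   or a function(params) returning a normalizing constant
#' @param denom_const logical; TRUE when \code{denom} is a constant-returning
#'   function of the parameters
#' @return a \code{dcx_observable}
#' @export
make_observable <- function(name, weight, denom = NULL, denom_const = FALSE) {
  structure(list(name = name, weight = weight, denom = denom,
                 denom_const = denom_const), class = "dcx_observable")
}

# --- species-level counting helpers (the "patterns" of the built-ins) ------

count_type <- function(g, tt, type) sum(g$type == match(type, tt$names))

count_state <- function(g, tt, type, site, state) {
  ty <- match(type, tt$names)
  ms <- which(g$type == ty)
  if (!length(ms)) return(0L)
  si <- site_id(tt, ty, site)
  st <- state_id(tt, ty, si, state)
  sum(vapply(ms, function(m) g$state[[m]][si] == st, TRUE))
}

# number of molecules of `type` bonded directly to any molecule whose type is
# in `partners`
count_direct_bond <- function(g, tt, type, partners) {
  ty <- match(type, tt$names)
  pt <- match(partners, tt$names)
  ms <- which(g$type == ty)
  if (!length(ms)) return(0L)
  sum(vapply(ms, function(m) {
    nb <- g$bnd_m[[m]]
    any(g$type[nb[nb != 0L]] %in% pt)
  }, TRUE))
}

apc_pool_names <- function(cell) vapply(cell$pools, `[[`, "", "name")

#' Built-in observables
#'
#' \describe{
#'   \item{BCAT_total}{total beta-catenin over all species (nM)}
#'   \item{BCAT_relative}{total beta-catenin divided by the nominal normal-cell
#'     level \code{BCAT_tot} (35 nM)}
#'   \item{frac_axin_with_bcat}{fraction of Axin in species that also contain
#'     beta-catenin}
#'   \item{frac_bcat_with_axin}{fraction of beta-catenin in species that also
#'     contain Axin (directly or indirectly associated)}
#'   \item{bcat_direct_apc}{fraction of beta-catenin bonded directly to any
#'     APC form}
#'   \item{pS45_total, pS33_37_total}{total beta-catenin phosphorylated at
#'     S45 / at the S33/S37 cluster (nM)}
#' }
#'
#' @param cell a \code{dcx_cell} (determines the APC pool types)
#' @return named list of \code{dcx_observable}
#' @export
builtin_observables <- function(cell) {
  apc <- apc_pool_names(cell)
  list(
    BCAT_total = make_observable("BCAT_total",
      function(g, tt, p) count_type(g, tt, "BCAT")),
    BCAT_relative = make_observable("BCAT_relative",
      function(g, tt, p) count_type(g, tt, "BCAT"),
      denom = function(p) p$BCAT_tot, denom_const = TRUE),
    frac_axin_with_bcat = make_observable("frac_axin_with_bcat",
      function(g, tt, p) if (count_type(g, tt, "BCAT") > 0) count_type(g, tt, "AXIN") else 0,
      denom = function(g, tt, p) count_type(g, tt, "AXIN")),
    frac_bcat_with_axin = make_observable("frac_bcat_with_axin",
      function(g, tt, p) if (count_type(g, tt, "AXIN") > 0) count_type(g, tt, "BCAT") else 0,
      denom = function(g, tt, p) count_type(g, tt, "BCAT")),
    bcat_direct_apc = make_observable("bcat_direct_apc",
      function(g, tt, p) count_direct_bond(g, tt, "BCAT", apc),
      denom = function(g, tt, p) count_type(g, tt, "BCAT")),
    pS45_total = make_observable("pS45_total",
      function(g, tt, p) count_state(g, tt, "BCAT", "S45", "p")),
    pS33_37_total = make_observable("pS33_37_total",
      function(g, tt, p) count_state(g, tt, "BCAT", "S33_37", "p"))
  )
}

#' Observable for direct binding to one APC pool
#'
#' Fraction of beta-catenin bonded directly to the named APC form (used for
#' the sequestration dose scans, where the endogenous and transfected pools
#' must be distinguished).
#' @param type APC pool type name (e.g. \code{"APC1338"})
#' @return a \code{dcx_observable}
#' @export
bcat_direct_to <- function(type) {
  make_observable(paste0("bcat_direct_", type),
    function(g, tt, p) count_direct_bond(g, tt, "BCAT", type),
    denom = function(g, tt, p) count_type(g, tt, "BCAT"))
}

resolve_observable <- function(net, obs) {
  if (inherits(obs, "dcx_observable")) return(obs)
  if (is.character(obs) && length(obs) == 1L) {
    builtins <- builtin_observables(net$cell)
    if (!obs %in% names(builtins)) stop("unknown built-in observable: ", obs)
    return(builtins[[obs]])
  }
  stop("observable must be a dcx_observable or a built-in name")
}

observable_weights <- function(net, obs, params) {
  tt <- net$cell$types
  w <- vapply(net$species, function(g) as.numeric(obs$weight(g, tt, params)), 0)
  d <- NULL
  if (!is.null(obs$denom) && !obs$denom_const)
    d <- vapply(net$species, function(g) as.numeric(obs$denom(g, tt, params)), 0)
  list(w = w, d = d)
}

#' Evaluate an observable on a state
#'
#' @param net a \code{dcx_network}
#' @param obs a \code{dcx_observable} or built-in name
#' @param state numeric state vector (nM), or a matrix with one state per row
#' @param params parameter set (default: the cell model's)
#' @return numeric value(s); NA where a fraction's denominator is 0
#' @export
evaluate_observable <- function(net, obs, state, params = NULL) {
  if (is.null(params)) params <- net$cell$params
  obs <- resolve_observable(net, obs)
  wd <- observable_weights(net, obs, params)
  if (is.matrix(state)) {
    num <- as.vector(state %*% wd$w)
    den <- if (!is.null(wd$d)) as.vector(state %*% wd$d)
           else if (obs$denom_const) rep(obs$denom(params), nrow(state))
           else rep(1, nrow(state))
  } else {
    num <- sum(state * wd$w)
    den <- if (!is.null(wd$d)) sum(state * wd$d)
           else if (obs$denom_const) obs$denom(params)
           else 1
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

evaluate_observables <- function(net, observables, states, params, times = NULL) {
  if (is.null(names(observables)))
    names(observables) <- vapply(observables, function(o)
      if (is.character(o)) o else o$name, "")
  vals <- lapply(observables, function(o) evaluate_observable(net, o, states, params))
  df <- as.data.frame(vals)
  if (!is.null(times)) df <- cbind(time = times, df)
  df
}

#' Total concentration of a molecule type
#'
#' Sums type copy number times species concentration; used for conservation
#' checks (APC, Axin, GSK-3beta, CK1alpha totals are invariant along any
#' trajectory; beta-catenin changes only via synthesis and degradation).
#'
#' @param net a \code{dcx_network}
#' @param type molecule type name
#' @param state state vector or matrix
#' @return numeric total(s) in nM
#' @export
total_of_type <- function(net, type, state) {
  ti <- match(type, net$cell$types$names)
  if (is.na(ti)) stop("unknown type: ", type)
  w <- net$comp[, ti]
  if (is.matrix(state)) as.vector(state %*% w) else sum(state * w)
}
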