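# Virtual experiments: transfection panels, dose scans, pulse-chase
# half-lives, LiCl kinase inhibition, interface ablation, APC-phosphorylation
# scans, Axin-association scans, and local sensitivity analysis.
#
# All experiments are pure functions of (cell model, parameters): re-running
# with the same configuration reproduces outputs exactly. Expanded networks
# are cached per model structure (rule set + molecule types); scenarios that
# differ only in doses, rate values, ablations or inhibition folds reuse the
# cached network.

.network_cache <- new.env(parent = emptyenv())

structure_signature <- function(cell) {
  paste(cell$background,
        paste(vapply(cell$pools, function(p) paste0(p$name, ":", p$class), ""),
              collapse = ","),
        cell$s33_37_mutant, cell$apcE_affinity, cell$apc_r20_1, sep = "|")
}

#' Expanded network for a cell model, with caching
#'
#' @param cell a \code{dcx_cell}
#' @param caps stoichiometry caps (default \code{\link{default_caps}})
#' @return a compiled \code{dcx_network} whose \code{cell} field is the given
#'   cell (so doses, ablations and inhibition folds are current)
#' @export
get_network <- function(cell, caps = default_caps(cell)) {
  key <- paste(structure_signature(cell),
               paste(names(caps), caps, collapse = ","), sep = "#")
  net <- .network_cache[[key]]
  if (is.null(net)) {
    net <- compile_network(expand_network(cell, caps = caps))
    .network_cache[[key]] <- net
  }
  net$cell <- cell
  net
}

#' Clear the network cache
#' @export
clear_network_cache <- function() {
  rm(list = ls(.network_cache), envir = .network_cache)
  invisible(NULL)
}

steady_observable <- function(net, obs, params = NULL, init = NULL, ...) {
  ss <- find_steady_state(net, init = init, params = params, ...)
  vapply(obs, function(o) evaluate_observable(net, o, ss$state,
                                              params %||% net$cell$params), 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- transfection panel ----------------------------------------------------

#' Steady-state effect of transfecting APC constructs
#'
#' Simulates transfection of each construct class at a fixed dose over the
#' endogenous background and reports the steady-state beta-catenin level
#' relative to the nominal normal-cell level (35 nM), together with the
#' untransfected baseline.
#'
#' @param background \code{"SW480"} (default) or \code{"normal"}
#' @param classes construct classes to transfect
#' @param dose transfected amount (nM)
#' @param params parameter set (default \code{default_parameters()})
#' @return data.frame: class, bcat_nM, bcat_relative (to 35 nM), and
#'   change_vs_baseline (ratio to the untransfected background)
#' @export
run_transfection_panel <- function(background = "SW480",
                                   classes = c("A", "B", "C", "D", "E", "F"),
                                   dose = 100, params = default_parameters()) {
  stopifnot(dose >= 0)
  base_cell <- cell_model(background, params = params)
  base_net <- get_network(base_cell)
  base <- steady_observable(base_net, list("BCAT_total"))
  rows <- lapply(classes, function(cl) {
    cell <- cell_model(background, transfections = list(list(class = cl, dose = dose)),
                       params = params)
    net <- get_network(cell)
    v <- steady_observable(net, list("BCAT_total"))
    data.frame(class = cl, bcat_nM = v, bcat_relative = v / params$BCAT_tot,
               change_vs_baseline = v / base)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_nM") <- unname(base)
  rownames(out) <- NULL
  out
}

# --- dose scans ------------------------------------------------------------

#' Dose-response scan of a transfected APC construct
#'
#' Steady-state beta-catenin level as a function of the exogenously expressed
#' amount of one construct class, in units of the endogenous 100 nM. A dose of
#' x adds x * 100 nM of the construct on top of the endogenous pool (for the
#' class matching the endogenous protein this makes the total (1+x) * 100 nM).
#'
#' @param background \code{"normal"} or \code{"SW480"}
#' @param class construct class \code{"A".."F"}
#' @param doses relative dose grid (default log-spaced over [0.01, 10])
#' @param params parameter set
#' @param observables extra observables evaluated at each dose
#' @return data.frame with dose, bcat_nM, bcat_relative and any extra
#'   observables; class \code{dcx_dose_curve}
#' @export
run_dose_scan <- function(background, class,
                          doses = 10^seq(-2, 1, length.out = 13),
                          params = default_parameters(),
                          observables = NULL) {
  stopifnot(all(doses >= 0), !is.unsorted(doses))
  endo_class <- if (background == "normal") "A" else "B"
  merged <- class == endo_class
  # build at a reference dose; individual doses enter through seed scaling
  cell <- cell_model(background,
                     transfections = if (!merged) list(list(class = class, dose = 100)),
                     params = params)
  net <- get_network(cell)
  scaled_type <- if (merged) cell$pools[[1]]$name else paste0("APC_", class)
  obs <- c(list(BCAT_total = "BCAT_total"), observables)
  rows <- lapply(doses, function(x) {
    scale <- if (merged) 1 + x else x
    init <- initial_state(net, params,
                          dose_scale = stats::setNames(scale, scaled_type))
    v <- steady_observable(net, obs, init = init)
    cbind(data.frame(dose = x), as.data.frame(as.list(v)))
  })
  out <- do.call(rbind, rows)
  out$bcat_relative <- out$BCAT_total / params$BCAT_tot
  attr(out, "background") <- background
  attr(out, "class") <- class
  class(out) <- c("dcx_dose_curve", "data.frame")
  out
}

# --- pulse-chase half-life -------------------------------------------------

half_life_from_curve <- function(times, values) {
  target <- values[1] / 2
  below <- which(values <= target)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(0)
  # log-linear interpolation between the bracketing points
  t1 <- times[i - 1L]; t2 <- times[i]
  v1 <- log(values[i - 1L]); v2 <- log(values[i])
  t1 + (log(target) - v1) * (t2 - t1) / (v2 - v1)
}

#' Simulated pulse-chase half-life of beta-catenin
#'
#' Brings the cell to steady state, then tracks the decay of the pre-existing
#' beta-catenin pool and reports the time at which it reaches half its initial
#' value.
#'
#' Protocols: \code{"shutoff"} (default) stops synthesis at t = 0 and follows
#' total beta-catenin — the decaying pool sees destruction machinery that is
#' progressively less loaded. \code{"cohort"} follows a labelled cohort
#' embedded in an unperturbed steady state: label kinetics are linear with
#' coefficients given by the steady-state reaction fluxes, so the machinery
#' loading stays fixed while the label decays.
#'
#' @param cell a \code{dcx_cell} (e.g. \code{cell_model("normal")}, optionally
#'   with \code{s33_37_mutant = TRUE})
#' @param protocol \code{"shutoff"} or \code{"cohort"}
#' @param params parameter set (default: the cell's)
#' @param n_points time points on the reported decay curve
#' @return a \code{dcx_halflife}: list with \code{half_life_s},
#'   \code{half_life_min}, \code{protocol}, and the decay \code{curve}
#'   (data.frame time, bcat, relative)
#' @export
run_pulse_chase <- function(cell, protocol = c("shutoff", "cohort"),
                            params = NULL, n_points = 60L) {
  protocol <- match.arg(protocol)
  if (is.null(params)) params <- cell$params
  net <- get_network(cell)
  ss <- find_steady_state(net, params = params)
  x0 <- evaluate_observable(net, "BCAT_total", ss$state, params)
  if (x0 <= 0) stop("no beta-catenin at steady state")
  # initial per-capita loss rate sets the horizon scale
  k0 <- total_degradation_flux(net, params, ss$state) / x0
  horizon <- 4 * log(2) / k0
  if (protocol == "shutoff") {
    repeat {
      times <- seq(0, horizon, length.out = n_points)
      tc <- simulate_network(net, times, init = ss$state, params = params,
                             ksyn_off = TRUE, observables = list("BCAT_total"))
      vals <- tc$observables$BCAT_total
      if (min(vals) <= x0 / 2 || horizon > 1e9) break
      horizon <- horizon * 4
    }
  } else {
    lab <- cohort_label_curve(net, params, ss$state, horizon, n_points)
    repeat {
      if (min(lab$value) <= x0 / 2 || horizon > 1e9) break
      horizon <- horizon * 4
      lab <- cohort_label_curve(net, params, ss$state, horizon, n_points)
    }
    times <- lab$time; vals <- lab$value
    tc <- NULL
  }
  if (protocol == "shutoff") { times <- tc$times; vals <- tc$observables$BCAT_total }
  hl <- half_life_from_curve(times, vals)
  structure(list(half_life_s = hl, half_life_min = hl / 60, protocol = protocol,
                 curve = data.frame(time = times, bcat = vals,
                                    relative = vals / x0)),
            class = "dcx_halflife")
}

total_degradation_flux <- function(net, params, state) {
  k <- reaction_rates(net, params)
  rx <- net$reactions
  deg <- vapply(net$crules[rx$rule], function(cr) cr$kind == "degrade", TRUE)
  sum(k[deg] * state[rx$ra[deg]])
}

# label kinetics of a cohort embedded in a steady state: for each reaction
# with flux v consuming the (unique) beta-catenin-carrying reactant s, label
# leaves s at rate v/y_s and enters the beta-catenin-carrying product (none,
# for degradation). Valid when at most one beta-catenin per complex.
cohort_label_curve <- function(net, params, ystar, horizon, n_points) {
  ti <- match("BCAT", net$cell$types$names)
  if (any(net$comp[, ti] > 1L))
    stop("cohort protocol requires at most one beta-catenin per complex")
  k <- reaction_rates(net, params)
  rx <- net$reactions
  nb <- net$comp[, ti]
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_len(nrow(rx))) {
    reac <- c(if (rx$ra[r] > 0L) rx$ra[r], if (rx$rb[r] > 0L) rx$rb[r])
    s <- reac[nb[reac] > 0L]
    if (length(s) != 1L || ystar[s] <= 0) next
    v <- k[r] * prod(ystar[reac])
    rate <- v / ystar[s]
    ii <- c(ii, s); jj <- c(jj, s); xx <- c(xx, -rate)
    prods <- net$products[[r]]
    q <- prods[nb[prods] > 0L]
    if (length(q) == 1L) { ii <- c(ii, q); jj <- c(jj, s); xx <- c(xx, rate) }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = rep(length(ystar), 2))
  l0 <- nb * ystar
  times <- seq(0, horizon, length.out = n_points)
  out <- deSolve::ode(y = l0, times = times,
                      func = function(t, y, p) list(as.vector(A %*% y)),
                      parms = NULL, method = "lsodes")
  data.frame(time = out[, 1], value = rowSums(out[, -1, drop = FALSE]))
}

#' @export
print.dcx_halflife <- function(x, ...) {
  cat(sprintf("Pulse-chase (%s protocol): half-life %.4g min (%.4g h)\n",
              x$protocol, x$half_life_min, x$half_life_min / 60))
  invisible(x)
}

# --- LiCl kinase inhibition ------------------------------------------------

#' LiCl treatment: fold-inhibition of GSK-3beta at steady state
#'
#' Brings the untreated cell to steady state, then divides the rates of
#' GSK-3beta-mediated phosphorylation (beta-catenin S33/S37 and the APC 20-aa
#' repeats) by \code{fold} at t = 0 and follows phosphorylation of S45 and
#' S33/S37, each normalized to its untreated steady-state level. CK1alpha
#' activity is unaffected.
#'
#' @param cell a \code{dcx_cell} (default: normal cell)
#' @param fold inhibition fold (>= 1)
#' @param t_max simulated time after treatment (s)
#' @param n_points time points
#' @param params parameter set
#' @return data.frame: time (s), pS45, pS33_37 (both relative to t = 0)
#' @export
run_licl <- function(cell = cell_model("normal"), fold = 20,
                     t_max = 4 * 3600, n_points = 60L, params = NULL) {
  stopifnot(fold >= 1)
  if (is.null(params)) params <- cell$params
  net <- get_network(cell)
  ss <- find_steady_state(net, params = params, gsk_fold = 1)
  times <- seq(0, t_max, length.out = n_points)
  tc <- simulate_network(net, times, init = ss$state, params = params,
                         gsk_fold = fold,
                         observables = list("pS45_total", "pS33_37_total"))
  p45_0 <- tc$observables$pS45_total[1]
  p33_0 <- tc$observables$pS33_37_total[1]
  data.frame(time = times,
             pS45 = tc$observables$pS45_total / p45_0,
             pS33_37 = tc$observables$pS33_37_total / p33_0)
}

# --- interface ablation ----------------------------------------------------

#' Ablation of the cyclic core-complex interfaces
#'
#' For each of the three protein-protein interfaces of the closed/cyclic
#' APC-Axin-beta-catenin core (beta-catenin ARM 5-9 with the APC 15-aa
#' repeats; beta-catenin ARM 3-4 with Axin; APC SAMP with Axin RGS), sets the
#' corresponding association rate constant to 0 in the normal-cell model and
#' reports the steady-state beta-catenin level relative to the unablated
#' cell.
#'
#' @param params parameter set
#' @return data.frame: interface, bcat_nM, relative_level
#' @export
run_interface_ablation <- function(params = default_parameters()) {
  interfaces <- c("bcat_apc_15aa", "bcat_axin", "apc_axin")
  base_cell <- cell_model("normal", params = params)
  net <- get_network(base_cell)
  base <- steady_observable(net, list("BCAT_total"))
  rows <- lapply(interfaces, function(iface) {
    cell <- cell_model("normal", ablations = iface, params = params)
    neti <- get_network(cell)   # same structure; rates differ via cell$ablations
    v <- steady_observable(neti, list("BCAT_total"))
    data.frame(interface = iface, bcat_nM = v, relative_level = v / base)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_nM") <- unname(base)
  rownames(out) <- NULL
  out
}

# --- APC phosphorylation scan ----------------------------------------------

#' Effect of APC 20-aa-repeat phosphorylation on beta-catenin
#'
#' In the SW480 background, scans the ratio of the APC phosphorylation to
#' dephosphorylation rate constants (default ratio 1: the two are equal; 0:
#' APC is never phosphorylated; Inf: always phosphorylated) and, at each
#' ratio, the APC1338 dose. Reports steady-state beta-catenin and the
#' fraction of Axin in complex with beta-catenin.
#'
#' @param ratios kp_apc / kdp_apc ratio grid (may include 0 and Inf)
#' @param doses relative APC1338 dose grid (total amount, in units of 100 nM)
#' @param params parameter set
#' @return data.frame: ratio, dose, bcat_relative, frac_axin_with_bcat
#' @export
run_apc_phospho_scan <- function(ratios = c(0, 0.1, 1, Inf),
                                 doses = 10^seq(-2, 1, length.out = 9),
                                 params = default_parameters()) {
  stopifnot(all(ratios >= 0))
  cell <- cell_model("SW480", params = params)
  net <- get_network(cell)
  endo <- cell$pools[[1]]$name
  rows <- list()
  for (rt in ratios) {
    p <- params
    if (is.infinite(rt)) {
      p <- set_parameters(p, list(kdp_apc = 0))
    } else {
      p <- set_parameters(p, list(kp_apc = rt * params$kdp_apc))
    }
    for (x in doses) {
      init <- initial_state(net, p, dose_scale = stats::setNames(x, endo))
      ss <- find_steady_state(net, init = init, params = p)
      rows[[length(rows) + 1L]] <- data.frame(
        ratio = rt, dose = x,
        bcat_relative = evaluate_observable(net, "BCAT_relative", ss$state, p),
        frac_axin_with_bcat = evaluate_observable(net, "frac_axin_with_bcat",
                                                  ss$state, p))
    }
  }
  do.call(rbind, rows)
}

# --- Axin association scan -------------------------------------------------

#' Sequestration scan: beta-catenin association with Axin and APC
#'
#' Scans the total amount of the endogenous APC form (APC1338 in SW480,
#' full-length APC in a normal cell) relative to its nominal 100 nM and
#' reports, at steady state, the fraction of beta-catenin associated
#' (directly or indirectly) with Axin and the fraction bound directly to the
#' scanned APC form.
#'
#' @param background \code{"SW480"} or \code{"normal"}
#' @param rel_grid total APC amount relative to 100 nM
#' @param params parameter set
#' @return data.frame: rel_apc, frac_bcat_with_axin, bcat_direct_apc,
#'   bcat_relative
#' @export
run_axin_association_scan <- function(background = "SW480",
                                      rel_grid = 10^seq(-2, 1, length.out = 13),
                                      params = default_parameters()) {
  cell <- cell_model(background, params = params)
  net <- get_network(cell)
  endo <- cell$pools[[1]]$name
  obs <- list(frac_bcat_with_axin = "frac_bcat_with_axin",
              bcat_direct_apc = bcat_direct_to(endo),
              BCAT_relative = "BCAT_relative")
  rows <- lapply(rel_grid, function(x) {
    init <- initial_state(net, params, dose_scale = stats::setNames(x, endo))
    v <- steady_observable(net, obs, init = init)
    data.frame(rel_apc = x, frac_bcat_with_axin = v[[1]],
               bcat_direct_apc = v[[2]], bcat_relative = v[[3]])
  })
  do.call(rbind, rows)
}

# --- local sensitivity -----------------------------------------------------

#' Local sensitivity of steady-state beta-catenin to the parameters
#'
#' Normalized local sensitivity coefficients S = (p / Y) (dY / dp) of the
#' steady-state total beta-catenin level, by central finite differences with
#' relative step \code{delta}.
#'
#' @param cell a \code{dcx_cell} (default: normal cell)
#' @param parameters parameter names (default: every rate constant,
#'   dissociation constant, total and the enhancement factor)
#' @param delta relative finite-difference step
#' @param params parameter set
#' @return data.frame: parameter, value, coefficient
#' @export
local_sensitivity <- function(cell = cell_model("normal"),
                              parameters = NULL, delta = 0.05,
                              params = NULL) {
  stopifnot(delta > 0, delta < 1)
  if (is.null(params)) params <- cell$params
  if (is.null(parameters))
    parameters <- setdiff(names(params), c("volume", "BCAT_tot"))
  net <- get_network(cell)
  ss0 <- find_steady_state(net, params = params)
  y0 <- evaluate_observable(net, "BCAT_total", ss0$state, params)
  coef <- vapply(parameters, function(nm) {
    p0 <- params[[nm]]
    if (p0 == 0) return(0)
    up <- set_parameters(params, stats::setNames(list(p0 * (1 + delta)), nm))
    dn <- set_parameters(params, stats::setNames(list(p0 * (1 - delta)), nm))
    # totals enter through the seeds (they are conserved along trajectories),
    # so perturbing them requires a fresh initial state; rate perturbations
    # can be warm-started from the unperturbed steady state
    init_for <- function(p) if (grepl("_tot$", nm)) initial_state(net, p) else ss0$state
    yu <- evaluate_observable(net, "BCAT_total",
            find_steady_state(net, init = init_for(up), params = up)$state, up)
    yd <- evaluate_observable(net, "BCAT_total",
            find_steady_state(net, init = init_for(dn), params = dn)$state, dn)
    (yu - yd) / (2 * delta * y0)
  }, 0)
  data.frame(parameter = parameters,
             value = unlist(params[parameters]),
             coefficient = unname(coef), row.names = NULL)
}
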