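# Deterministic mass-action dynamics of an expanded reaction network:
# rate resolution, sparse stoichiometry, stiff integration (lsodes),
# steady-state location by long-horizon integration.

#' Resolve reaction rate constants
#'
#' Maps each reaction of the network to its numeric rate constant under a
#' parameter set: intermolecular binding at the interface's association rate
#' constant (per nM per s), intracomplex bond closure at kf * chi (per s),
#' unbinding at kf * KD, state changes and degradation at their first-order
#' constants, synthesis at the zeroth-order rate in nM/s. Embedding
#' multiplicity is folded in. Rates of GSK-3beta-mediated phosphorylation are
#' divided by \code{gsk_fold}; interfaces listed in the cell model's
#' \code{ablations} get forward rate 0 (unbinding is unaffected).
#'
#' @param net a \code{dcx_network}
#' @param params a \code{dcx_params}
#' @param gsk_fold inhibition fold (default: the cell model's value)
#' @param ksyn_off logical; TRUE sets the synthesis rate to 0 (pulse-chase
#'   shutoff protocol)
#' @return numeric vector of rate constants, one per reaction
#' @export
reaction_rates <- function(net, params, gsk_fold = NULL, ksyn_off = FALSE) {
  cell <- net$cell
  if (is.null(gsk_fold)) gsk_fold <- cell$gsk_inhibition_fold
  rx <- net$reactions
  crules <- net$crules
  k <- numeric(nrow(rx))
  for (i in seq_len(nrow(rx))) {
    cr <- crules[[rx$rule[i]]]
    v <- switch(cr$kind,
      bind = {
        fwd <- if (!is.na(cr$interface) && cr$interface %in% cell$ablations) 0
               else params[[cr$rate_param]]
        if (rx$intra[i]) fwd * params$chi else fwd
      },
      unbind = params$kf * params[[cr$kd_param]],
      state_change = {
        r0 <- params[[cr$rate_param]]
        if (cr$gsk_mediated) r0 / gsk_fold else r0
      },
      degrade = params[[cr$rate_param]],
      synthesize = if (ksyn_off) 0 else ksyn_nm(params)
    )
    k[i] <- v * rx$mult[i]
  }
  k
}

#' Initial state of a network
#'
#' Seeds: endogenous/transfected APC pools at their doses, Axin, GSK-3beta and
#' CK1alpha at their totals, beta-catenin at \code{bcat_init} (default 0; the
#' steady state is initialization-independent). All other species start at 0.
#'
#' @param net a \code{dcx_network}
#' @param params a \code{dcx_params}
#' @param bcat_init initial free unmodified beta-catenin (nM)
#' @param dose_scale named numeric vector scaling the seed dose of specific
#'   APC pools (by type name); used by dose scans
#' @return named numeric state vector (nM), one entry per species
#' @export
initial_state <- function(net, params, bcat_init = 0, dose_scale = NULL) {
  cell <- net$cell
  y <- numeric(length(net$species))
  for (kk in seq_along(cell$seeds)) {
    sd <- cell$seeds[[kk]]
    conc <- if (!is.na(sd$conc_param)) params[[sd$conc_param]]
            else if (!is.null(sd$dose)) sd$dose
            else bcat_init
    if (sd$type == "BCAT") conc <- bcat_init
    if (!is.null(dose_scale) && sd$type %in% names(dose_scale))
      conc <- conc * dose_scale[[sd$type]]
    y[net$seed_idx[kk]] <- conc
  }
  names(y) <- paste0("S", seq_along(y))
  y
}

# compile the ODE right-hand side: sparse stoichiometry and index vectors
compile_ode <- function(net) {
  rx <- net$reactions
  nr <- nrow(rx)
  ns <- length(net$species)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (r in seq_len(nr)) {
    if (rx$ra[r] > 0L) { ii <- c(ii, rx$ra[r]); jj <- c(jj, r); xx <- c(xx, -1) }
    if (rx$rb[r] > 0L) { ii <- c(ii, rx$rb[r]); jj <- c(jj, r); xx <- c(xx, -1) }
    for (p in net$products[[r]]) { ii <- c(ii, p); jj <- c(jj, r); xx <- c(xx, 1) }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ns, nr))
  ia <- which(rx$ra > 0L); ib <- which(rx$rb > 0L)
  # Jacobian sparsity: d(dy_i)/d(y_j) nonzero when species j is a reactant of a
  # reaction that changes species i
  jnz <- new.env(parent = emptyenv())
  Ssum <- Matrix::summary(S)
  rows_of <- split(Ssum$i, Ssum$j)
  for (r in seq_len(nr)) {
    reac <- c(if (rx$ra[r] > 0L) rx$ra[r], if (rx$rb[r] > 0L) rx$rb[r])
    rows <- rows_of[[as.character(r)]]
    for (j in reac) for (i in rows) jnz[[paste(i, j)]] <- c(i, j)
  }
  inz <- do.call(rbind, as.list(jnz))
  # ensure a full diagonal (required by some sparse solvers, harmless otherwise)
  inz <- unique(rbind(inz, cbind(seq_len(ns), seq_len(ns))))
  inz <- inz[order(inz[, 2L], inz[, 1L]), , drop = FALSE]  # lsodes wants column-sorted
  list(S = S, ia = ia, ib = ib, ra = rx$ra, rb = rx$rb, inz = inz)
}

ode_compiled <- function(net) {
  if (is.null(net$ode)) compile_ode(net) else net$ode
}

#' Precompile the ODE structure of a network
#'
#' Attaches the sparse stoichiometry matrix and Jacobian sparsity pattern to
#' the network so repeated simulations (dose scans, calibration) skip the
#' setup cost.
#' @param net a \code{dcx_network}
#' @return the network with an \code{ode} component
#' @export
compile_network <- function(net) {
  net$ode <- compile_ode(net)
  net
}

make_deriv <- function(oc, k) {
  force(oc); force(k)
  function(t, y, p) {
    v <- k
    v[oc$ia] <- v[oc$ia] * y[oc$ra[oc$ia]]
    v[oc$ib] <- v[oc$ib] * y[oc$rb[oc$ib]]
    list(as.vector(oc$S %*% v))
  }
}

# lsodes with the network's Jacobian sparsity and an adequate work array
integrate_lsodes <- function(y, times, deriv, oc, rtol, atol) {
  nnz <- nrow(oc$inz)
  lrw <- as.integer(min(2e8, 30 * length(y) + 60 * nnz + 20000))
  deSolve::ode(y = y, times = times, func = deriv, parms = NULL,
               method = "lsodes", sparsetype = "sparseusr", inz = oc$inz,
               nnz = nnz, lrw = lrw, rtol = rtol, atol = atol)
}

#' Simulate a network time course
#'
#' Integrates the mass-action ODEs with the stiff sparse solver
#' \code{deSolve::lsodes}, using the network's exact Jacobian sparsity
#' pattern.
#'
#' @param net a \code{dcx_network} (ideally \code{\link{compile_network}}ed)
#' @param times numeric time grid (s), starting at 0
#' @param init initial state (default \code{\link{initial_state}})
#' @param params parameter set (default: the cell model's)
#' @param observables optional named list of observables
#'   (\code{\link{make_observable}} or names of \code{\link{builtin_observables}})
#' @param gsk_fold,ksyn_off passed to \code{\link{reaction_rates}}
#' @param rtol,atol integration tolerances
#' @return a \code{dcx_timecourse}: list with \code{times}, \code{states}
#'   (matrix time x species), \code{observables} (data.frame time x observable)
#' @export
simulate_network <- function(net, times, init = NULL, params = NULL,
                             observables = NULL, gsk_fold = NULL,
                             ksyn_off = FALSE, rtol = 1e-8, atol = 1e-10) {
  if (is.null(params)) params <- net$cell$params
  if (is.null(init)) init <- initial_state(net, params)
  stopifnot(all(init > -1e-9), !is.unsorted(times))
  oc <- ode_compiled(net)
  k <- reaction_rates(net, params, gsk_fold = gsk_fold, ksyn_off = ksyn_off)
  out <- integrate_lsodes(pmax(init, 0), times, make_deriv(oc, k), oc,
                          rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1], ")")
  states <- unname(out[, -1, drop = FALSE])
  neg <- min(states)
  if (neg < -1e-6)
    warning("trajectory dipped below 0 by ", format(-neg), " nM; check tolerances")
  states[states < 0] <- 0
  tc <- structure(list(times = out[, 1], states = states, net = net,
                       params = params), class = "dcx_timecourse")
  if (!is.null(observables))
    tc$observables <- evaluate_observables(net, observables, states, params,
                                           times = out[, 1])
  tc
}

#' Locate the steady state of a network
#'
#' Integrates from \code{init} over doubling horizons until the scaled
#' residual max_i |dy_i/dt| / max(y_i, floor) drops below \code{tol}.
#' Long-horizon integration (rather than root finding) guarantees the
#' physically reachable steady state is selected.
#'
#' @param net a \code{dcx_network}
#' @param init initial state (default \code{\link{initial_state}})
#' @param params parameter set (default: the cell model's)
#' @param tol residual tolerance (1/s)
#' @param floor concentration floor in the residual scaling (nM)
#' @param t0 first integration horizon (s)
#' @param max_doublings horizon-doubling ceiling
#' @param gsk_fold,ksyn_off passed to \code{\link{reaction_rates}}
#' @return a \code{dcx_steady}: list with \code{state}, \code{residual},
#'   \code{horizon}, \code{iterations}
#' @export
find_steady_state <- function(net, init = NULL, params = NULL, tol = 1e-10,
                              floor = 1e-6, t0 = 2e5, max_doublings = 12L,
                              gsk_fold = NULL, ksyn_off = FALSE) {
  if (is.null(params)) params <- net$cell$params
  if (is.null(init)) init <- initial_state(net, params)
  oc <- ode_compiled(net)
  k <- reaction_rates(net, params, gsk_fold = gsk_fold, ksyn_off = ksyn_off)
  deriv <- make_deriv(oc, k)
  y <- pmax(init, 0)
  horizon <- t0
  total <- 0
  for (it in seq_len(max_doublings)) {
    out <- integrate_lsodes(y, c(0, horizon), deriv, oc,
                            rtol = 1e-10, atol = 1e-12)
    if (attr(out, "istate")[1] < 0)
      stop("steady-state integration failed (istate = ", attr(out, "istate")[1], ")")
    y <- pmax(unname(out[nrow(out), -1]), 0)
    total <- total + horizon
    resid <- max(abs(deriv(0, y, NULL)[[1]]) / pmax(y, floor))
    if (resid < tol)
      return(structure(list(state = y, residual = resid, horizon = total,
                            iterations = it, net = net, params = params),
                       class = "dcx_steady"))
    horizon <- horizon * 2
  }
  stop("no steady state after t = ", format(total),
       " s; residual = ", format(resid))
}

#' @export
print.dcx_steady <- function(x, ...) {
  cat("Steady state:", length(x$state), "species; residual",
      format(x$residual, digits = 3), "1/s after t =", format(x$horizon), "s\n")
  tot <- evaluate_observable(x$net, "BCAT_total", x$state, x$params)
  cat("  total beta-catenin:", format(tot, digits = 6), "nM\n")
  invisible(x)
}

#' @export
print.dcx_timecourse <- function(x, ...) {
  cat("Time course:", length(x$times), "time points,",
      ncol(x$states), "species\n")
  if (!is.null(x$observables)) {
    cat("  observables:\n")
    print(utils::head(x$observables))
  }
  invisible(x)
}
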