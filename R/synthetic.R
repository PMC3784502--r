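# Synthetic pseudo-experimental datasets with the statistical structure the
# calibration assumes: model-generated curves under multiplicative lognormal
# noise, with the generating ("true") parameters recorded for recovery
# scoring.
#
# Noise model: obs = truth * exp(eps), eps ~ N(0, sdlog) with
# sdlog^2 = log(1 + cv^2), so that E[log obs] = log truth and the coefficient
# of variation of obs is cv. All observables are positive concentrations or
# fractions, hence multiplicative noise.

# memo for noise-free generator curves: the generators are pure functions of
# (params, design), so replicate datasets differing only in seed reuse the
# simulated curve
.curve_cache <- new.env(parent = emptyenv())

cached_curve <- function(key, compute) {
  k <- content_digest(key)
  v <- .curve_cache[[k]]
  if (is.null(v)) {
    v <- compute()
    .curve_cache[[k]] <- v
  }
  v
}

noise_factors <- function(n, cv, rng) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

new_dataset <- function(kind, design, truth, obs, true_params, cv, seed, meta) {
  structure(list(kind = kind, design = design, truth = truth, obs = obs,
                 true_params = true_params, cv = cv, seed = seed, meta = meta),
            class = "dcx_dataset")
}

#' @export
print.dcx_dataset <- function(x, ...) {
  cat(sprintf("Synthetic %s dataset: %d points, cv = %g, seed = %s\n",
              x$kind, length(x$design), x$cv, format(x$seed)))
  invisible(x)
}

#' Synthetic pulse-chase decay dataset
#'
#' Generates a normalized beta-catenin decay curve from the model (pulse-chase
#' from steady state) and applies multiplicative lognormal noise. With
#' \code{anchor_t0 = TRUE} (default) the noisy curve is renormalized to its
#' t = 0 value, so the normalized observable anchors at exactly 1.
#'
#' @param params generating parameter set
#' @param protocol \code{"shutoff"} or \code{"cohort"}
#' @param n_points number of time points (>= 3)
#' @param cv noise coefficient of variation
#' @param seed RNG seed (same seed => identical dataset)
#' @param mutant logical; TRUE generates the S33/S37-mutant decay (pure
#'   first-order at \code{kdeg_slow})
#' @param anchor_t0 see above
#' @return a \code{dcx_dataset} (kind \code{"decay"}): design = times (s),
#'   truth = noise-free normalized curve, obs = noisy observations
#' @export
gen_decay <- function(params = default_parameters(), protocol = "shutoff",
                      n_points = 12L, cv = 0.05, seed = 1L, mutant = TRUE,
                      anchor_t0 = TRUE) {
  stopifnot(n_points >= 3)
  curve <- cached_curve(
    list("decay", unclass(params), protocol, n_points, mutant),
    function() {
      cell <- cell_model("normal", s33_37_mutant = mutant, params = params)
      run_pulse_chase(cell, protocol = protocol, params = params,
                      n_points = n_points)$curve
    })
  times <- curve$time
  truth <- curve$relative
  obs <- with_seed(seed, {
    o <- truth * noise_factors(length(truth), cv)
    if (anchor_t0) o <- o / o[1]
    o
  })
  new_dataset("decay", times, truth, obs,
              true_params = unclass(params)[c("kdeg_slow", "kdeg_fast",
                                              "kp_bcat", "kdp_bcat")],
              cv = cv, seed = seed,
              meta = list(protocol = protocol, mutant = mutant,
                          anchor_t0 = anchor_t0))
}

#' Synthetic LiCl phospho-decay dataset
#'
#' Normalized pS45 and pS33/S37 time courses after fold-inhibition of
#' GSK-3beta, with multiplicative lognormal noise.
#'
#' @inheritParams gen_decay
#' @param fold GSK-3beta inhibition fold
#' @param t_max simulated time after treatment (s)
#' @return a \code{dcx_dataset} (kind \code{"licl"}); truth and obs are
#'   two-column matrices (pS45, pS33_37)
#' @export
gen_licl <- function(params = default_parameters(), fold = 20, n_points = 12L,
                     cv = 0.05, seed = 1L, t_max = 4 * 3600, anchor_t0 = TRUE) {
  stopifnot(n_points >= 3)
  cur <- cached_curve(list("licl", unclass(params), fold, n_points, t_max),
    function() run_licl(cell_model("normal", params = params), fold = fold,
                        t_max = t_max, n_points = n_points, params = params))
  truth <- cbind(pS45 = cur$pS45, pS33_37 = cur$pS33_37)
  obs <- with_seed(seed, {
    o <- truth * matrix(noise_factors(length(truth), cv), nrow(truth))
    if (anchor_t0) o <- sweep(o, 2, o[1, ], "/")
    o
  })
  new_dataset("licl", cur$time, truth, obs,
              true_params = unclass(params)[c("kp_bcat", "kdp_bcat", "kp_apc")],
              cv = cv, seed = seed,
              meta = list(fold = fold, anchor_t0 = anchor_t0))
}

#' Synthetic dose-response dataset
#'
#' Steady-state relative beta-catenin level versus transfected construct
#' dose, with multiplicative lognormal noise.
#'
#' @inheritParams gen_decay
#' @param background \code{"normal"} or \code{"SW480"}
#' @param class construct class
#' @param doses relative dose grid
#' @return a \code{dcx_dataset} (kind \code{"dose_response"})
#' @export
gen_dose_response <- function(params = default_parameters(),
                              background = "SW480", class = "B",
                              doses = 10^seq(-2, 1, length.out = 9),
                              cv = 0.05, seed = 1L) {
  cur <- cached_curve(list("dose", unclass(params), background, class, doses),
    function() run_dose_scan(background, class, doses = doses, params = params))
  truth <- cur$bcat_relative
  obs <- with_seed(seed, truth * noise_factors(length(truth), cv))
  new_dataset("dose_response", doses, truth, obs,
              true_params = unclass(params)[c("kp_bcat", "kdeg_fast", "chi")],
              cv = cv, seed = seed,
              meta = list(background = background, class = class))
}
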