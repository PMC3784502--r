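# Plot and convenience methods for the package's classed objects.

#' Plot a simulated time course
#'
#' @param x a \code{dcx_timecourse} with observables
#' @param log_time logical; log-scale the time axis
#' @param ... passed to \code{matplot}
#' @export
plot.dcx_timecourse <- function(x, log_time = FALSE, ...) {
  if (is.null(x$observables)) stop("simulate with observables= to plot")
  df <- x$observables
  t <- df$time / 60
  y <- as.matrix(df[setdiff(names(df), "time")])
  graphics::matplot(t, y, type = "l", lty = 1, lwd = 2,
                    xlab = "time (min)", ylab = "observable",
                    log = if (log_time) "x" else "", ...)
  graphics::legend("topright", colnames(y), col = seq_len(ncol(y)), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Plot a dose-response curve
#'
#' @param x a \code{dcx_dose_curve} from \code{\link{run_dose_scan}}
#' @param ... passed to \code{plot}
#' @export
plot.dcx_dose_curve <- function(x, ...) {
  graphics::plot(x$dose, x$bcat_relative, log = "x", type = "b", pch = 16,
                 xlab = "exogenous APC (relative to endogenous 100 nM)",
                 ylab = "beta-catenin (relative to normal 35 nM)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Plot a pulse-chase decay curve
#'
#' @param x a \code{dcx_halflife}
#' @param ... passed to \code{plot}
#' @export
plot.dcx_halflife <- function(x, ...) {
  graphics::plot(x$curve$time / 60, x$curve$relative, type = "l", lwd = 2,
                 xlab = "time (min)", ylab = "remaining fraction", ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$half_life_min, lty = 3)
  invisible(x)
}

#' Simulate a cell model
#'
#' S3 \code{simulate} method: expands the model's network (cached), then
#' integrates the mass-action ODEs from the seed state.
#'
#' @param object a \code{dcx_cell}
#' @param nsim unused (deterministic dynamics)
#' @param seed unused
#' @param times time grid (s)
#' @param observables observables to record (default: total and relative
#'   beta-catenin and the phospho pools)
#' @param ... passed to \code{\link{simulate_network}}
#' @return a \code{dcx_timecourse}
#' @export
simulate.dcx_cell <- function(object, nsim = 1, seed = NULL,
                              times = seq(0, 24 * 3600, length.out = 97),
                              observables = list("BCAT_total", "BCAT_relative",
                                                 "pS45_total", "pS33_37_total"),
                              ...) {
  net <- get_network(object)
  simulate_network(net, times, observables = observables, ...)
}

#' Summary of a cell model's steady state
#'
#' @param object a \code{dcx_cell}
#' @param ... unused
#' @return named list: steady-state observables, residual, network size
#' @export
summary.dcx_cell <- function(object, ...) {
  net <- get_network(object)
  ss <- find_steady_state(net)
  obs <- c("BCAT_total", "BCAT_relative", "frac_axin_with_bcat",
           "frac_bcat_with_axin", "pS45_total", "pS33_37_total")
  vals <- vapply(obs, function(o) evaluate_observable(net, o, ss$state), 0)
  out <- list(background = object$background, species = length(net$species),
              reactions = nrow(net$reactions), observables = vals,
              residual = ss$residual)
  class(out) <- "summary.dcx_cell"
  out
}

#' @export
print.summary.dcx_cell <- function(x, ...) {
  cat("Cell model (", x$background, "): ", x$species, " species, ",
      x$reactions, " reactions\n", sep = "")
  cat("Steady state (residual ", format(x$residual, digits = 3), " 1/s):\n", sep = "")
  print(round(x$observables, 5))
  invisible(x)
}
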