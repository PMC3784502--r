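# Model parameters: rate constants, dissociation constants, totals, volume.
# Units: concentrations in nM, time in s, volume in L, throughout.

#' Avogadro constant (1/mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Default kinetic parameters of the destruction-complex model
#'
#' Returns the full parameter set of the model: a shared bimolecular
#' association rate constant \code{kf} (with per-interface copies that ablation
#' scenarios may zero), equilibrium dissociation constants for the six binding
#' interfaces, phosphorylation/dephosphorylation rate constants, beta-catenin
#' synthesis and degradation rate constants, the intracomplex enhancement
#' factor \code{chi}, the cytoplasmic volume, and total protein concentrations.
#'
#' Dissociation rate constants are never stored: for every binding interface
#' the reverse rate constant is \code{kf * KD}, exactly.
#'
#' Provenance of each value is recorded in the \code{"provenance"} attribute:
#' \describe{
#'   \item{literature}{taken from published affinity/abundance estimates
#'     (e.g. \code{KD1_bap} = 273 nM for the beta-catenin ARM 5-9 interaction
#'     with the APC 15-aa repeat region; \code{KD2_bap_1338} = 80 nM for ARM
#'     3-4 binding the phosphorylated first 20-aa repeat of truncated APC).}
#'   \item{derived}{fixed by an arithmetic identity: \code{volume} from the
#'     10 nM = 3,154 copies/cell conversion; \code{kdeg_slow} = ln2 / 4.5 h,
#'     the slow half-life of degradation-resistant beta-catenin.}
#'   \item{assumed}{order-of-magnitude choices where no measurement exists
#'     (\code{kf}, \code{chi}, the four 100 nM dissociation constants).}
#'   \item{calibrated}{set by behavioural calibration against the steady-state
#'     beta-catenin level, the wild-type and S33/S37-mutant half-lives and the
#'     10-min phospho-decay anchor; see \code{\link{calibrate}}.}
#' }
#'
#' @param overrides named list or numeric vector of parameter values replacing
#'   defaults. Unknown names are an error.
#' @return an object of class \code{dcx_params}: a named list of numeric
#'   scalars with a \code{provenance} attribute.
#' @examples
#' p <- default_parameters()
#' p$KD1_bap                        # 273 nM
#' p$kf * p$KD1_bap                 # dissociation rate constant, 1/s
#' nm_to_copies(100, p$volume)      # 31540 copies/cell
#' @export
default_parameters <- function(overrides = NULL) {
  volume <- 3154 / (10e-9 * AVOGADRO)   # L; from 10 nM <-> 3,154 copies/cell
  p <- list(
    # association rate constants (per nM per s); one shared scale, per-interface
    # copies so that single interfaces can be ablated (set to 0)
    kf       = 1e-3,
    kf1_bap  = 1e-3,   # beta-catenin ARM 5-9 <-> APC 15-aa repeats
    kf2_bap  = 1e-3,   # beta-catenin ARM 3-4 <-> phospho APC 20-aa repeat
    kf_ba    = 1e-3,   # beta-catenin ARM 3-4 <-> Axin
    kf_apa   = 1e-3,   # APC SAMP <-> Axin RGS
    kf_ga    = 1e-3,   # GSK-3beta <-> Axin GID
    kf_ca    = 1e-3,   # CK1alpha <-> Axin
    chi      = 1e4,    # intracomplex enhancement factor (nM)
    # dissociation constants (nM)
    KD1_bap      = 273,
    KD2_bap_full = 80 / 300,  # phospho third 20-aa repeat, full-length APC
    KD2_bap_1338 = 80,        # phospho first 20-aa repeat, truncated APC
    KD_ba        = 300,
    KD_apa       = 100,
    KD_ga        = 100,
    KD_ca        = 100,
    # phosphorylation / dephosphorylation (1/s)
    kp_bcat  = 3e-3,            # provisional; calibrated
    kdp_bcat = log(2) / 600,    # provisional anchor; calibrated to 10-min decay
    kp_apc   = 3e-2,            # provisional; calibrated (kp_apc == kdp_apc)
    kdp_apc  = 3e-2,
    # beta-catenin synthesis and degradation
    kdeg_slow = log(2) / (4.5 * 3600),  # 1/s
    kdeg_fast = 1e-2,                   # provisional; calibrated
    ksyn      = 4.0,                    # molecules per s (see ksyn_nm)
    volume    = volume,                 # L
    # total concentrations (nM)
    BCAT_tot = 35, APC_tot = 100, AXIN_tot = 10,
    GSK_tot = 100, CK1A_tot = 100
  )
  prov <- c(
    kf = "assumed", kf1_bap = "assumed", kf2_bap = "assumed", kf_ba = "assumed",
    kf_apa = "assumed", kf_ga = "assumed", kf_ca = "assumed", chi = "assumed",
    KD1_bap = "literature", KD2_bap_full = "assumed", KD2_bap_1338 = "literature",
    KD_ba = "calibrated", KD_apa = "assumed", KD_ga = "assumed", KD_ca = "assumed",
    kp_bcat = "calibrated", kdp_bcat = "calibrated", kp_apc = "calibrated",
    kdp_apc = "calibrated", kdeg_slow = "derived", kdeg_fast = "calibrated",
    ksyn = "literature", volume = "derived",
    BCAT_tot = "literature", APC_tot = "literature", AXIN_tot = "literature",
    GSK_tot = "literature", CK1A_tot = "assumed"
  )
  # calibrated values (behavioural calibration of the base model; see the
  # methods vignette and calibrate()). Overridable like any other entry.
  p[names(CALIBRATED_DEFAULTS)] <- CALIBRATED_DEFAULTS
  cls <- structure(p, class = "dcx_params", provenance = prov)
  if (!is.null(overrides)) cls <- set_parameters(cls, overrides)
  cls
}

# Calibrated rate constants for the base (normal-cell) model. These are the
# package's default working values; calibrate() regenerates them from the
# behavioural targets at run time.
CALIBRATED_DEFAULTS <- list(
  kp_bcat   = 4.726254e-02,
  kdp_bcat  = 9.627524e-04,
  kp_apc    = 3e-2,
  kdp_apc   = 3e-2,
  kdeg_fast = 1e-2
)

#' Replace parameter values
#'
#' @param params a \code{dcx_params} object
#' @param overrides named list/vector of replacement values
#' @return modified \code{dcx_params}; provenance of touched entries becomes
#'   \code{"override"}
#' @export
set_parameters <- function(params, overrides) {
  stopifnot(inherits(params, "dcx_params"))
  overrides <- as.list(overrides)
  bad <- setdiff(names(overrides), names(params))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (any(!vapply(overrides, function(x) is.numeric(x) && length(x) == 1L, TRUE)))
    stop("parameter overrides must be numeric scalars")
  prov <- attr(params, "provenance")
  for (nm in names(overrides)) {
    v <- as.numeric(overrides[[nm]])
    if (is.na(v) || v < 0) stop("parameter ", nm, " must be a non-negative number")
    params[[nm]] <- v
    prov[[nm]] <- "override"
  }
  attr(params, "provenance") <- prov
  params
}

#' Beta-catenin synthesis rate in concentration units
#'
#' Converts the zeroth-order synthesis rate from molecules per second to
#' nM per second using the cytoplasmic volume.
#' @param params a \code{dcx_params} object
#' @return synthesis rate in nM/s
#' @export
ksyn_nm <- function(params) {
  params$ksyn / (AVOGADRO * params$volume) * 1e9
}

#' Concentration/copy-number conversions
#'
#' @param conc_nm concentration in nM
#' @param copies copy number per cell
#' @param volume cytoplasmic volume in L
#' @return copies per cell (numeric, not rounded), or nM
#' @export
nm_to_copies <- function(conc_nm, volume) conc_nm * 1e-9 * AVOGADRO * volume

#' @rdname nm_to_copies
#' @export
copies_to_nm <- function(copies, volume) copies / (AVOGADRO * volume) * 1e9

#' @export
print.dcx_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Destruction-complex model parameters (nM, s):\n")
  df <- data.frame(value = unlist(x), provenance = prov[names(x)])
  print(format(df, digits = 6))
  invisible(x)
}
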