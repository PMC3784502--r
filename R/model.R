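# Model definition: the five destruction-complex proteins, APC construct
# classes, scenario assembly (backgrounds, transfections, ablations, kinase
# inhibition) and the rule inventory.
#
# Protein sites:
#   BCAT  arm34 (ARM repeats 3-4; binds Axin or a phosphorylated APC 20-aa
#         repeat, mutually exclusively), arm59 (ARM repeats 5-9; binds the APC
#         15-aa repeats), S45~u/p (CK1alpha substrate), S33_37~u/p (GSK-3beta
#         substrate; the lumped S33/S37/T41 cluster)
#   APC   aa15 (15-aa repeat region), r20_1~u/p or r20_3~u/p (first/third
#         20-aa repeat, the only two resolved; binding requires the
#         phosphorylated state), samp (SAMP repeats; bind the Axin RGS domain)
#   AXIN  rgs, bcat, gid (GSK-3beta interaction domain), ck1
#   GSK3B ax;  CK1A ax

#' APC construct classes
#'
#' The six functional classes of APC constructs used in simulated
#' transfections. Class membership is defined by which of the three modelled
#' APC regions a construct retains:
#' \tabular{lll}{
#'  A \tab 15-aa repeats, 20-aa repeats (third-repeat affinity), SAMP \tab full-length APC\cr
#'  B \tab 15-aa repeats, first 20-aa repeat \tab APC1338 (SW480)\cr
#'  C \tab 15-aa repeats only \tab \cr
#'  D \tab first 20-aa repeat only \tab \cr
#'  E \tab 20-aa repeats and SAMP \tab \cr
#'  F \tab none of the modelled sites \tab inert\cr
#' }
#'
#' @param label one of \code{"A".."F"}
#' @param apcE_affinity for class E only: \code{"full_r3"} (default; the
#'   complete 20-aa region is retained, so the high-affinity third repeat is
#'   used) or \code{"truncated_r1"} (first-repeat affinity, as for APC1338)
#' @return a \code{dcx_construct} list with fields \code{label},
#'   \code{present_sites}, \code{r20_site} (\code{"r20_1"}, \code{"r20_3"} or
#'   \code{NA}) and \code{r20_kd} (name of the dissociation-constant
#'   parameter, or \code{NA})
#' @export
construct_class <- function(label, apcE_affinity = c("full_r3", "truncated_r1")) {
  label <- match.arg(label, c("A", "B", "C", "D", "E", "F"))
  apcE_affinity <- match.arg(apcE_affinity)
  def <- switch(label,
    A = list(sites = c("aa15", "r20", "samp"), r20_site = "r20_3", r20_kd = "KD2_bap_full"),
    B = list(sites = c("aa15", "r20"),         r20_site = "r20_1", r20_kd = "KD2_bap_1338"),
    C = list(sites = "aa15",                   r20_site = NA,      r20_kd = NA),
    D = list(sites = "r20",                    r20_site = "r20_1", r20_kd = "KD2_bap_1338"),
    E = if (apcE_affinity == "full_r3")
          list(sites = c("r20", "samp"), r20_site = "r20_3", r20_kd = "KD2_bap_full")
        else
          list(sites = c("r20", "samp"), r20_site = "r20_1", r20_kd = "KD2_bap_1338"),
    F = list(sites = character(), r20_site = NA, r20_kd = NA)
  )
  structure(list(label = label, present_sites = def$sites,
                 r20_site = def$r20_site, r20_kd = def$r20_kd),
            class = "dcx_construct")
}

# molecule type for an APC construct class, named `name`; `extra_r20_1`
# additionally carries the first 20-aa repeat as a phosphorylatable but
# non-binding site (an encoding convention for full-length APC, whose
# low-affinity first-repeat interaction is omitted)
apc_molecule_type <- function(name, construct, extra_r20_1 = FALSE) {
  sites <- character(); states <- list()
  if ("aa15" %in% construct$present_sites) sites <- c(sites, "aa15")
  if (extra_r20_1 && !identical(construct$r20_site, "r20_1")) {
    sites <- c(sites, "r20_1")
    states[["r20_1"]] <- c("u", "p")
  }
  if ("r20" %in% construct$present_sites) {
    sites <- c(sites, construct$r20_site)
    states[[construct$r20_site]] <- c("u", "p")
  }
  if ("samp" %in% construct$present_sites) sites <- c(sites, "samp")
  molecule_type(name, sites, states)
}

#' Build a configured cell model
#'
#' Assembles molecule types, the rule inventory, and seed species for a
#' scenario: a genetic background (\code{"normal"}: 100 nM endogenous
#' full-length APC; \code{"SW480"}: 100 nM endogenous APC1338), zero or more
#' transfected APC constructs, optional ablation of the protein-protein
#' interfaces of the cyclic core complex, optional fold-inhibition of
#' GSK-3beta-mediated phosphorylation (LiCl treatment), and the
#' S33/S37-phosphorylation-deficient beta-catenin mutant.
#'
#' Seed species are the free, unmodified proteins: APC forms at
#' \code{APC_tot} (endogenous) plus each transfected dose, Axin, GSK-3beta and
#' CK1alpha at their totals, and beta-catenin at 0 nM (it is synthesized de
#' novo; its steady state is initialization-independent).
#'
#' A transfected construct identical in class to the endogenous protein
#' (class A in a normal cell, class B in an SW480 cell) is merged into the
#' endogenous pool rather than duplicated as a distinct type.
#'
#' @param background \code{"normal"} or \code{"SW480"}
#' @param transfections list of \code{list(class = "A", dose = 100)} entries
#'   (dose in nM), or NULL
#' @param ablations character subset of \code{c("bcat_apc_15aa", "bcat_axin",
#'   "apc_axin")}; the corresponding association rate constants are set to 0
#'   (the rules remain, so the reaction network is unchanged in structure)
#' @param gsk_inhibition_fold divisor (>= 1) applied to the rates of
#'   GSK-3beta-mediated phosphorylation (beta-catenin S33/S37 and the APC
#'   20-aa repeats); CK1alpha-mediated phosphorylation is unaffected
#' @param s33_37_mutant logical; TRUE removes the S33/S37 phosphorylation rule
#' @param params a \code{dcx_params} object (default \code{default_parameters()})
#' @param apcE_affinity passed to \code{\link{construct_class}}
#' @param apc_r20_1 encoding convention for full-length APC (class A): the
#'   low-affinity first 20-aa repeat interaction is always omitted, but the
#'   site itself can either be dropped from the molecule type
#'   (\code{"omitted"}, default) or carried as a phosphorylatable non-binding
#'   site (\code{"phosphosite"}). The choice does not alter the dynamics of
#'   any reported observable; it changes the size of the expanded network
#'   (each reachable phospho-state doubles the APC-containing species)
#' @return an object of class \code{dcx_cell} with elements \code{types}
#'   (type table), \code{rules}, \code{seeds}, \code{params} and the scenario
#'   fields
#' @examples
#' cell <- cell_model("SW480", transfections = list(list(class = "A", dose = 100)))
#' cell
#' @export
cell_model <- function(background = c("normal", "SW480"),
                       transfections = NULL,
                       ablations = character(),
                       gsk_inhibition_fold = 1,
                       s33_37_mutant = FALSE,
                       params = default_parameters(),
                       apcE_affinity = c("full_r3", "truncated_r1"),
                       apc_r20_1 = c("omitted", "phosphosite")) {
  background <- match.arg(background)
  apcE_affinity <- match.arg(apcE_affinity)
  apc_r20_1 <- match.arg(apc_r20_1)
  stopifnot(gsk_inhibition_fold >= 1)
  ok_abl <- c("bcat_apc_15aa", "bcat_axin", "apc_axin")
  if (length(ablations) && !all(ablations %in% ok_abl))
    stop("unknown interface(s): ", paste(setdiff(ablations, ok_abl), collapse = ", "))

  endo_class <- if (background == "normal") "A" else "B"
  endo_name <- if (background == "normal") "APC" else "APC1338"

  # APC pools: endogenous + transfections (same-class doses merged)
  pools <- list(list(name = endo_name, class = endo_class,
                     dose = params$APC_tot, endogenous = TRUE))
  if (!is.null(transfections)) {
    for (tr in transfections) {
      cls <- match.arg(tr$class, c("A", "B", "C", "D", "E", "F"))
      dose <- as.numeric(tr$dose)
      if (is.na(dose) || dose < 0) stop("transfection dose must be >= 0")
      if (cls == endo_class) {
        pools[[1]]$dose <- pools[[1]]$dose + dose
      } else {
        nm <- paste0("APC_", cls)
        hit <- which(vapply(pools, function(p) p$name == nm, TRUE))
        if (length(hit)) pools[[hit]]$dose <- pools[[hit]]$dose + dose
        else pools[[length(pools) + 1L]] <- list(name = nm, class = cls,
                                                 dose = dose, endogenous = FALSE)
      }
    }
  }

  constructs <- lapply(pools, function(p) construct_class(p$class, apcE_affinity))
  types <- c(
    list(
      molecule_type("BCAT", c("arm34", "arm59", "S45", "S33_37"),
                    list(S45 = c("u", "p"), S33_37 = c("u", "p"))),
      molecule_type("AXIN", c("rgs", "bcat", "gid", "ck1")),
      molecule_type("GSK3B", "ax"),
      molecule_type("CK1A", "ax")
    ),
    lapply(seq_along(pools), function(i)
      apc_molecule_type(pools[[i]]$name, constructs[[i]],
                        extra_r20_1 = apc_r20_1 == "phosphosite" &&
                          pools[[i]]$class == "A"))
  )
  tt <- type_table(types)

  rules <- build_rules(tt, pools, constructs,
                       ablations = ablations,
                       s33_37_mutant = s33_37_mutant,
                       extra_r20_1 = apc_r20_1 == "phosphosite")

  seeds <- c(
    list(list(type = "AXIN",  conc_param = "AXIN_tot"),
         list(type = "GSK3B", conc_param = "GSK_tot"),
         list(type = "CK1A",  conc_param = "CK1A_tot"),
         list(type = "BCAT",  conc_param = NA)),          # synthesized de novo
    lapply(pools, function(p)
      list(type = p$name, conc_param = NA, dose = p$dose,
           endogenous = p$endogenous))
  )

  structure(list(background = background, pools = pools, constructs = constructs,
                 ablations = ablations, gsk_inhibition_fold = gsk_inhibition_fold,
                 s33_37_mutant = s33_37_mutant, apcE_affinity = apcE_affinity,
                 apc_r20_1 = apc_r20_1,
                 types = tt, rules = rules, seeds = seeds, params = params),
            class = "dcx_cell")
}

# ---------------------------------------------------------------------------
# Rule inventory.
#
# A rule is a list with fields:
#   name, kind ("bind" | "unbind" | "state_change" | "synthesize" | "degrade")
#   bind:    a/b = list(type, site, state = label or NA, require = named labels)
#            rate_param (forward kf name), kd_param, interface (or NA)
#   unbind:  same a/b; rate = kf * KD (generated from each bind rule)
#   state_change: subject = list(type(s), site, from, to, require,
#            site_unbound = TRUE/FALSE), context = list of
#            list(type, site_bound) co-complex requirements, rate_param,
#            gsk_mediated (TRUE => divided by the LiCl inhibition fold)
#   synthesize: product type (created free and unmodified), rate_param
#   degrade: subject = list(type, require), rate_param; deletion releases all
#            binding partners (the remainder splits into components)

bind_rule <- function(name, a, b, rate_param, kd_param, interface = NA_character_) {
  list(name = name, kind = "bind", a = a, b = b,
       rate_param = rate_param, kd_param = kd_param, interface = interface,
       gsk_mediated = FALSE)
}

side <- function(type, site, state = NA_character_, require = NULL) {
  list(type = type, site = site, state = state, require = require)
}

build_rules <- function(tt, pools, constructs, ablations, s33_37_mutant,
                        extra_r20_1 = FALSE) {
  rules <- list()
  add <- function(r) rules[[length(rules) + 1L]] <<- r

  # recruitment of the kinases to Axin
  add(bind_rule("gsk_axin", side("GSK3B", "ax"), side("AXIN", "gid"), "kf_ga", "KD_ga"))
  add(bind_rule("ck1a_axin", side("CK1A", "ax"), side("AXIN", "ck1"), "kf_ca", "KD_ca"))
  # direct binding of beta-catenin ARM 3-4 to Axin (competes with phospho-APC)
  add(bind_rule("bcat_axin", side("BCAT", "arm34"), side("AXIN", "bcat"),
                "kf_ba", "KD_ba", interface = "bcat_axin"))

  for (i in seq_along(pools)) {
    nm <- pools[[i]]$name
    cc <- constructs[[i]]
    if ("aa15" %in% cc$present_sites)
      add(bind_rule(paste0("bcat_", nm, "_15aa"),
                    side("BCAT", "arm59"), side(nm, "aa15"),
                    "kf1_bap", "KD1_bap", interface = "bcat_apc_15aa"))
    if ("r20" %in% cc$present_sites) {
      add(bind_rule(paste0("bcat_", nm, "_20aa"),
                    side("BCAT", "arm34"), side(nm, cc$r20_site, state = "p"),
                    "kf2_bap", cc$r20_kd))
      # the 20-aa repeat region is phosphorylated (CK1e then GSK-3beta, the
      # former implicit) when APC is colocalized, via Axin, with Axin-bound
      # GSK-3beta; it is dephosphorylated (PP2A, implicit) only when APC is in
      # complex with Axin and the repeat is not shielded by a bound partner
      add(list(name = paste0("phos_", nm, "_r20"), kind = "state_change",
               subject = list(type = nm, site = cc$r20_site, from = "u", to = "p",
                              require = NULL, site_unbound = TRUE),
               context = list(list(type = "AXIN", site_bound = "gid")),
               rate_param = "kp_apc", gsk_mediated = TRUE))
      add(list(name = paste0("dephos_", nm, "_r20"), kind = "state_change",
               subject = list(type = nm, site = cc$r20_site, from = "p", to = "u",
                              require = NULL, site_unbound = TRUE),
               context = list(list(type = "AXIN", site_bound = NA)),
               rate_param = "kdp_apc", gsk_mediated = FALSE))
    }
    if ("samp" %in% cc$present_sites)
      add(bind_rule(paste0(nm, "_axin"),
                    side(nm, "samp"), side("AXIN", "rgs"),
                    "kf_apa", "KD_apa", interface = "apc_axin"))
    # encoding convention: the silent first 20-aa repeat on full-length APC
    # is phosphorylated/dephosphorylated like the binding-competent repeat
    if (extra_r20_1 && pools[[i]]$class == "A") {
      add(list(name = paste0("phos_", nm, "_r20_1"), kind = "state_change",
               subject = list(type = nm, site = "r20_1", from = "u", to = "p",
                              require = NULL, site_unbound = TRUE),
               context = list(list(type = "AXIN", site_bound = "gid")),
               rate_param = "kp_apc", gsk_mediated = TRUE))
      add(list(name = paste0("dephos_", nm, "_r20_1"), kind = "state_change",
               subject = list(type = nm, site = "r20_1", from = "p", to = "u",
                              require = NULL, site_unbound = TRUE),
               context = list(list(type = "AXIN", site_bound = NA)),
               rate_param = "kdp_apc", gsk_mediated = FALSE))
    }
  }

  # beta-catenin phosphorylation: S45 by Axin-bound CK1alpha, then S33/S37 by
  # Axin-bound GSK-3beta; both require colocalization with the kinase-loaded
  # Axin in one complex, and proceed with first-order kinetics
  add(list(name = "phos_bcat_s45", kind = "state_change",
           subject = list(type = "BCAT", site = "S45", from = "u", to = "p",
                          require = NULL, site_unbound = FALSE),
           context = list(list(type = "AXIN", site_bound = "ck1")),
           rate_param = "kp_bcat", gsk_mediated = FALSE))
  if (!s33_37_mutant)
    add(list(name = "phos_bcat_s3337", kind = "state_change",
             subject = list(type = "BCAT", site = "S33_37", from = "u", to = "p",
                            require = c(S45 = "p"), site_unbound = FALSE),
             context = list(list(type = "AXIN", site_bound = "gid")),
             rate_param = "kp_bcat", gsk_mediated = TRUE))
  # dephosphorylation of beta-catenin: context-free first-order at both sites
  # (the phosphorylation sites are never occupied by a binding partner)
  add(list(name = "dephos_bcat_s45", kind = "state_change",
           subject = list(type = "BCAT", site = "S45", from = "p", to = "u",
                          require = NULL, site_unbound = FALSE),
           context = list(), rate_param = "kdp_bcat", gsk_mediated = FALSE))
  add(list(name = "dephos_bcat_s3337", kind = "state_change",
           subject = list(type = "BCAT", site = "S33_37", from = "p", to = "u",
                          require = NULL, site_unbound = FALSE),
           context = list(), rate_param = "kdp_bcat", gsk_mediated = FALSE))

  # synthesis (zeroth order) and degradation (first order, slow when S33/S37
  # is unphosphorylated, fast when phosphorylated, regardless of bound state;
  # degradation releases all binding partners)
  add(list(name = "bcat_synth", kind = "synthesize", product = "BCAT",
           rate_param = "ksyn", gsk_mediated = FALSE))
  add(list(name = "bcat_deg_slow", kind = "degrade",
           subject = list(type = "BCAT", require = c(S33_37 = "u")),
           rate_param = "kdeg_slow", gsk_mediated = FALSE))
  add(list(name = "bcat_deg_fast", kind = "degrade",
           subject = list(type = "BCAT", require = c(S33_37 = "p")),
           rate_param = "kdeg_fast", gsk_mediated = FALSE))

  # reversible binding: generate the unbinding partner of every bind rule
  n0 <- length(rules)
  for (j in seq_len(n0)) {
    r <- rules[[j]]
    if (r$kind != "bind") next
    add(list(name = paste0(r$name, "_rev"), kind = "unbind", a = r$a, b = r$b,
             kd_param = r$kd_param, interface = r$interface, gsk_mediated = FALSE))
  }

  names(rules) <- vapply(rules, `[[`, "", "name")
  rules
}

#' Rule inventory of a cell model
#'
#' @param cell a \code{dcx_cell}
#' @return data.frame with one row per rule: name, kind, rate parameter,
#'   dissociation-constant parameter (binding rules), interface tag and
#'   whether the rate is divided by the GSK-3beta inhibition fold
#' @export
rule_table <- function(cell) {
  rs <- cell$rules
  data.frame(
    name = vapply(rs, `[[`, "", "name"),
    kind = vapply(rs, `[[`, "", "kind"),
    rate_param = vapply(rs, function(r) if (is.null(r$rate_param)) NA_character_ else r$rate_param, ""),
    kd_param = vapply(rs, function(r) if (is.null(r$kd_param)) NA_character_ else r$kd_param, ""),
    interface = vapply(rs, function(r) if (is.null(r$interface)) NA_character_ else r$interface, ""),
    gsk_mediated = vapply(rs, `[[`, TRUE, "gsk_mediated"),
    row.names = NULL
  )
}

#' Molecule types of a cell model
#' @param cell a \code{dcx_cell}
#' @return named list of \code{dcx_moltype}
#' @export
molecule_types <- function(cell) {
  stats::setNames(cell$types$types, cell$types$names)
}

#' @export
print.dcx_cell <- function(x, ...) {
  cat("Destruction-complex cell model\n")
  cat("  background:", x$background, "\n")
  for (p in x$pools)
    cat(sprintf("  APC pool: %s (class %s) %g nM%s\n", p$name,
                x$constructs[[which(vapply(x$pools, function(q) q$name == p$name, TRUE))]]$label,
                p$dose, if (p$endogenous) " [endogenous]" else ""))
  if (length(x$ablations)) cat("  ablated interfaces:", paste(x$ablations, collapse = ", "), "\n")
  if (x$gsk_inhibition_fold > 1) cat("  GSK-3beta inhibition fold:", x$gsk_inhibition_fold, "\n")
  if (x$s33_37_mutant) cat("  S33/S37-mutant beta-catenin\n")
  cat("  molecule types:", paste(x$types$names, collapse = ", "), "\n")
  cat("  rules:", length(x$rules), "\n")
  invisible(x)
}
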