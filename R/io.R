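# Configuration documents, result serialization, and BNGL-dialect model
# export/import.

#' Load and validate a configuration document
#'
#' JSON configuration with blocks:
#' \describe{
#'   \item{parameters}{named overrides of \code{\link{default_parameters}}
#'     entries (e.g. \code{kf1_bap}, \code{kf_ba}, \code{kf_apa}, the KD
#'     values, \code{chi})}
#'   \item{scenario}{\code{background}, \code{transfections} (list of
#'     \code{{class, dose_nM}}), \code{ablations}, \code{licl_fold},
#'     \code{s33_37_mutant}, \code{apcE_affinity}}
#'   \item{caps}{per-complex stoichiometry caps by molecule type}
#'   \item{tolerances}{\code{ss_tol} (steady-state residual), \code{rtol}}
#'   \item{seeds}{\code{rng} integer seed}
#' }
#' Unknown keys anywhere are rejected, with the offending key path named.
#'
#' @param path JSON file path
#' @return a validated \code{dcx_config} list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  validate_config(raw)
}

#' @rdname load_config
#' @param config a list with the structure described above
#' @export
validate_config <- function(config) {
  top_ok <- c("parameters", "scenario", "caps", "tolerances", "seeds")
  bad <- setdiff(names(config), top_ok)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(config$parameters)) {
    bad <- setdiff(names(config$parameters), names(default_parameters()))
    if (length(bad)) stop("unknown config key(s): ",
                          paste0("parameters.", bad, collapse = ", "))
  }
  if (!is.null(config$scenario)) {
    sc_ok <- c("background", "transfections", "ablations", "licl_fold",
               "s33_37_mutant", "apcE_affinity")
    bad <- setdiff(names(config$scenario), sc_ok)
    if (length(bad)) stop("unknown config key(s): ",
                          paste0("scenario.", bad, collapse = ", "))
    for (tr in config$scenario$transfections) {
      bad <- setdiff(names(tr), c("class", "dose_nM"))
      if (length(bad)) stop("unknown config key(s): ",
                            paste0("scenario.transfections.", bad, collapse = ", "))
    }
  }
  if (!is.null(config$tolerances)) {
    bad <- setdiff(names(config$tolerances), c("ss_tol", "rtol"))
    if (length(bad)) stop("unknown config key(s): ",
                          paste0("tolerances.", bad, collapse = ", "))
  }
  if (!is.null(config$seeds)) {
    bad <- setdiff(names(config$seeds), "rng")
    if (length(bad)) stop("unknown config key(s): ",
                          paste0("seeds.", bad, collapse = ", "))
  }
  structure(config, class = "dcx_config")
}

#' Build a cell model from a configuration
#'
#' @param config a \code{dcx_config} (or path to one)
#' @return a \code{dcx_cell}
#' @export
cell_from_config <- function(config) {
  if (is.character(config)) config <- load_config(config)
  sc <- config$scenario %||% list()
  params <- default_parameters(config$parameters)
  trs <- NULL
  if (!is.null(sc$transfections))
    trs <- lapply(sc$transfections, function(tr)
      list(class = tr$class, dose = tr$dose_nM))
  cell_model(background = sc$background %||% "normal",
             transfections = trs,
             ablations = unlist(sc$ablations) %||% character(),
             gsk_inhibition_fold = sc$licl_fold %||% 1,
             s33_37_mutant = isTRUE(sc$s33_37_mutant),
             params = params,
             apcE_affinity = sc$apcE_affinity %||% "full_r3")
}

# small stable content digest (FNV-1a, 32 bit) for provenance headers;
# the multiply is split into 16-bit halves so every intermediate stays
# below 2^53 and the arithmetic is exact
content_digest <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n")) %% 65536
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h0 <- bitwXor(as.integer(h %% 65536), as.integer(b))
    h1 <- h %/% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a result table with a provenance sidecar
#'
#' Writes a long-format CSV (stable column order) plus a JSON sidecar holding
#' the configuration digest and any metadata; two runs with equal
#' configuration produce byte-identical files.
#'
#' @param table data.frame of results
#' @param path output CSV path (sidecar gets extension \code{.json})
#' @param config configuration object used to produce the results (digested
#'   into the sidecar)
#' @param meta named list of extra metadata
#' @return invisibly, the sidecar list
#' @export
write_results <- function(table, path, config = NULL, meta = list()) {
  utils::write.csv(table, path, row.names = FALSE)
  sidecar <- c(list(digest = content_digest(list(config, names(table)))), meta)
  jsonlite::write_json(sidecar, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a result table written by \code{\link{write_results}}
#' @param path CSV path
#' @return data.frame
#' @export
read_results <- function(path) utils::read.csv(path)

# ---------------------------------------------------------------------------
# BNGL-dialect export: molecule types, parameters, seed species and rules in
# a BioNetGen-flavoured plain-text form, suitable for eyeballing and for
# cross-checking against an external rule-based engine. Intracomplex rate
# enhancement is engine-side (structural), so binding rules are annotated
# with "intramolecular_chi" rather than duplicated per bridge context; the
# dialect is versioned and the package can re-parse its own output.

fmt_side <- function(s) {
  tok <- s$site
  if (!is.na(s$state)) tok <- paste0(tok, "~", s$state)
  req <- ""
  if (!is.null(s$require) && length(s$require))
    req <- paste0(",", paste0(names(s$require), "~", unlist(s$require), collapse = ","))
  paste0(s$type, "(", tok, req, ")")
}

#' Export a cell model in a BNGL-like dialect
#'
#' @param cell a \code{dcx_cell}
#' @return character scalar (the model text)
#' @export
export_bngl <- function(cell) {
  tt <- cell$types
  out <- c("# dcx BNGL-dialect export v1",
           paste0("# background: ", cell$background),
           "begin molecule types")
  for (tp in tt$types) {
    toks <- vapply(seq_along(tp$sites), function(i) {
      s <- tp$sites[[i]]
      if (s %in% names(tp$states))
        paste0(s, paste0("~", tp$states[[s]], collapse = ""))
      else s
    }, "")
    out <- c(out, paste0("  ", tp$name, "(", paste(toks, collapse = ","), ")"))
  }
  out <- c(out, "end molecule types", "begin parameters")
  p <- cell$params
  for (nm in names(p))
    out <- c(out, sprintf("  %s %.12g", nm, p[[nm]]))
  out <- c(out, "end parameters", "begin seed species")
  for (sd in cell$seeds) {
    conc <- if (!is.na(sd$conc_param)) sd$conc_param
            else if (!is.null(sd$dose)) format(sd$dose) else "0"
    out <- c(out, paste0("  ", sd$type, "() ", conc))
  }
  out <- c(out, "end seed species", "begin rules")
  for (r in cell$rules) {
    line <- switch(r$kind,
      bind = sprintf("  %s: %s + %s -> bond  rate %s  KD %s  intramolecular_chi%s",
                     r$name, fmt_side(r$a), fmt_side(r$b), r$rate_param,
                     r$kd_param,
                     if (!is.na(r$interface)) paste0("  interface ", r$interface) else ""),
      unbind = sprintf("  %s: %s . %s -> unbind  rate kf*%s",
                       r$name, fmt_side(r$a), fmt_side(r$b), r$kd_param),
      state_change = {
        ctx <- if (length(r$context))
          paste0("  context ", paste(vapply(r$context, function(cx)
            paste0(cx$type, if (!is.na(cx$site_bound)) paste0("(", cx$site_bound, "!+)")
                   else ""), ""), collapse = " & "))
        else ""
        req <- if (!is.null(r$subject$require) && length(r$subject$require))
          paste0(", ", paste0(names(r$subject$require), "~",
                              unlist(r$subject$require), collapse = ","))
        else ""
        sprintf("  %s: %s(%s~%s -> ~%s%s%s) rate %s%s%s",
                r$name, r$subject$type, r$subject$site, r$subject$from,
                r$subject$to,
                if (isTRUE(r$subject$site_unbound)) " unbound" else "", req,
                r$rate_param,
                if (isTRUE(r$gsk_mediated)) "/licl_fold" else "", ctx)
      },
      synthesize = sprintf("  %s: 0 -> %s()  rate %s", r$name, r$product,
                           r$rate_param),
      degrade = {
        req <- if (!is.null(r$subject$require))
          paste0("(", paste0(names(r$subject$require), "~",
                             unlist(r$subject$require), collapse = ","), ")")
        else "()"
        sprintf("  %s: %s%s -> 0  rate %s  release_partners", r$name,
                r$subject$type, req, r$rate_param)
      })
    out <- c(out, line)
  }
  out <- c(out, "end rules")
  paste(out, collapse = "\n")
}

# parse one "Type(site~state,extra~state)" side token back into a rule side
parse_side <- function(txt) {
  m <- regmatches(txt, regexec("^([A-Za-z0-9_]+)\\(([^)]*)\\)$", txt))[[1]]
  toks <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  main <- toks[1]
  state <- NA_character_
  if (grepl("~", main, fixed = TRUE)) {
    parts <- strsplit(main, "~", fixed = TRUE)[[1]]
    main <- parts[1]; state <- parts[2]
  }
  require <- NULL
  if (length(toks) > 1) {
    kv <- strsplit(toks[-1], "~", fixed = TRUE)
    require <- stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
  }
  side(m[2], main, state = state, require = require)
}

#' Re-parse a BNGL-dialect export
#'
#' Parses text produced by \code{\link{export_bngl}} back into a rule list
#' (binding, unbinding, state-change, synthesis, degradation specifications),
#' for round-trip validation. Only the package's own dialect is supported;
#' general BNGL is out of scope.
#'
#' @param text character scalar or vector of lines
#' @return list of rules in the same form as \code{cell$rules}
#' @export
parse_bngl <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  inside <- FALSE
  rules <- list()
  for (ln in lines) {
    if (ln == "begin rules") { inside <- TRUE; next }
    if (ln == "end rules") break
    if (!inside || ln == "" || startsWith(ln, "#")) next
    nm <- sub(":.*$", "", ln)
    body <- trimws(sub("^[^:]+:", "", ln))
    r <- if (grepl("-> bond", body, fixed = TRUE)) {
      sides <- strsplit(sub(" *-> bond.*$", "", body), " \\+ ")[[1]]
      iface <- if (grepl("interface ", body))
        sub("^.*interface +([a-z0-9_]+).*$", "\\1", body) else NA_character_
      bind_rule(nm, parse_side(sides[1]), parse_side(sides[2]),
                rate_param = sub("^.*rate +([A-Za-z0-9_]+).*$", "\\1", body),
                kd_param = sub("^.*KD +([A-Za-z0-9_]+).*$", "\\1", body),
                interface = iface)
    } else if (grepl("-> unbind", body, fixed = TRUE)) {
      sides <- strsplit(sub(" *-> unbind.*$", "", body), " \\. ")[[1]]
      list(name = nm, kind = "unbind", a = parse_side(sides[1]),
           b = parse_side(sides[2]),
           kd_param = sub("^.*rate kf\\*([A-Za-z0-9_]+).*$", "\\1", body),
           interface = NA_character_, gsk_mediated = FALSE)
    } else if (grepl("^0 -> ", body)) {
      list(name = nm, kind = "synthesize",
           product = sub("^0 -> ([A-Za-z0-9_]+)\\(\\).*$", "\\1", body),
           rate_param = sub("^.*rate +([A-Za-z0-9_]+).*$", "\\1", body),
           gsk_mediated = FALSE)
    } else if (grepl("-> 0", body, fixed = TRUE)) {
      subj <- sub(" *-> 0.*$", "", body)
      m <- regmatches(subj, regexec("^([A-Za-z0-9_]+)\\(([^)]*)\\)", subj))[[1]]
      req <- NULL
      if (nzchar(m[3])) {
        kv <- strsplit(strsplit(m[3], ",")[[1]], "~")
        req <- stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
      }
      list(name = nm, kind = "degrade",
           subject = list(type = m[2], require = req),
           rate_param = sub("^.*rate +([A-Za-z0-9_]+).*$", "\\1", body),
           gsk_mediated = FALSE)
    } else {
      # state change:
      #   Type(site~from -> ~to[ unbound][, req~state]) rate k[/licl_fold][ context ...]
      m <- regmatches(body, regexec(
        "^([A-Za-z0-9_]+)\\(([A-Za-z0-9_]+)~([a-z]+) -> ~([a-z]+)( unbound)?(, [^)]*)?\\) rate ([A-Za-z0-9_]+)(/licl_fold)?", body))[[1]]
      ctx <- list()
      if (grepl("context", body)) {
        cm <- sub("^.*context +", "", body)
        for (tok in strsplit(cm, " & ", fixed = TRUE)[[1]]) {
          if (grepl("\\(", tok)) {
            ctx[[length(ctx) + 1L]] <- list(
              type = sub("\\(.*$", "", tok),
              site_bound = sub("^.*\\(([A-Za-z0-9_]+)!\\+\\).*$", "\\1", tok))
          } else ctx[[length(ctx) + 1L]] <- list(type = tok, site_bound = NA_character_)
        }
      }
      req <- NULL
      if (nzchar(m[7])) {
        kv <- strsplit(strsplit(sub("^, ", "", m[7]), ",")[[1]], "~")
        req <- stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
      }
      list(name = nm, kind = "state_change",
           subject = list(type = m[2], site = m[3], from = m[4], to = m[5],
                          require = req, site_unbound = nzchar(m[6])),
           context = ctx,
           rate_param = m[8], gsk_mediated = nzchar(m[9]))
    }
    rules[[nm]] <- r
  }
  rules
}
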