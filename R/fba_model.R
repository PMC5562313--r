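#' Construct a constraint-based metabolic model
#'
#' A light container for flux balance analysis: stoichiometric matrix,
#' reaction bounds, an objective reaction, and the annotations the colony
#' simulator needs (the glucose/oxygen/acetate exchange reactions, the biomass
#' reaction, and the ATP species whose biomass coefficient carries the
#' growth-associated maintenance, GAM).
#'
#' @param S Stoichiometric matrix (metabolites x reactions) with dimnames.
#' @param lb,ub Reaction lower/upper bounds (mmol/gDCW/hr; exchange fluxes
#'   negative for uptake).
#' @param objective Id of the objective (biomass) reaction.
#' @param exchanges Named list with elements `glucose`, `oxygen`, `acetate`
#'   giving the ids of the corresponding exchange reactions.
#' @param atp_met Id of the ATP metabolite consumed by the biomass reaction
#'   (used to set GAM); may be `NA` if GAM fitting is not needed.
#' @param id Model identifier.
#' @return An object of class `fba_model`.
#' @export
fba_model <- function(S, lb, ub, objective, exchanges, atp_met = NA_character_,
                      id = "model") {
  S <- as.matrix(S)
  stopifnot(
    length(lb) == ncol(S), length(ub) == ncol(S), all(lb <= ub),
    !is.null(colnames(S)), !is.null(rownames(S)),
    objective %in% colnames(S)
  )
  for (ex in c("glucose", "oxygen", "acetate")) {
    if (!is.null(exchanges[[ex]]) && !exchanges[[ex]] %in% colnames(S)) {
      stop("exchange reaction for ", ex, " ('", exchanges[[ex]],
           "') not in model", call. = FALSE)
    }
  }
  structure(
    list(S = S, lb = as.numeric(lb), ub = as.numeric(ub),
         objective = objective, exchanges = exchanges, atp_met = atp_met,
         id = id),
    class = "fba_model"
  )
}

#' @export
print.fba_model <- function(x, ...) {
  cat("<fba_model> ", x$id, ": ", nrow(x$S), " metabolites x ", ncol(x$S),
      " reactions; objective ", x$objective, "\n", sep = "")
  invisible(x)
}

set_bound <- function(model, rxn, lb = NULL, ub = NULL) {
  i <- match(rxn, colnames(model$S))
  if (is.na(i)) stop("unknown reaction '", rxn, "'", call. = FALSE)
  if (!is.null(lb)) model$lb[i] <- lb
  if (!is.null(ub)) model$ub[i] <- ub
  model
}

set_gam <- function(model, gam) {
  if (is.na(model$atp_met)) stop("model has no ATP metabolite annotated", call. = FALSE)
  model$S[model$atp_met, model$objective] <- -abs(gam)
  model
}

#' Solve a flux balance analysis problem
#'
#' Maximizes the objective reaction flux subject to steady state (`S v = 0`)
#' and the bound constraints, via the simplex LP solver in \pkg{pracma}
#' (variables shifted to be non-negative).
#'
#' @param model An [fba_model()].
#' @return List with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   (optimal flux through the objective reaction) and `fluxes` (named vector).
#' @export
fba_solve <- function(model) {
  S <- model$S
  n <- ncol(S)
  ub <- pmin(model$ub, 1e4)  # finite cap for the simplex tableau
  cc <- numeric(n)
  cc[match(model$objective, colnames(S))] <- 1
  fail <- list(status = "infeasible", objective = NA_real_,
               fluxes = stats::setNames(rep(NA_real_, n), colnames(S)))

  # every candidate solution is verified against the ORIGINAL constraints,
  # so fallback attempts (tiny deterministic bound perturbations around
  # degenerate vertices, then a second simplex implementation) are safe
  validate <- function(x, lb_used) {
    if (is.null(x) || length(x) != n || any(!is.finite(x))) return(NULL)
    v <- x + lb_used
    if (max(abs(S %*% v)) > 1e-6 || any(v < lb_used - 1e-6) ||
        any(v > ub + 1e-6)) return(NULL)
    v
  }
  try_pracma <- function(lb_used) {
    res <- tryCatch(
      suppressWarnings(
        pracma::linprog(cc, A = diag(n), b = ub - lb_used, Aeq = S,
                        beq = as.vector(-S %*% lb_used),
                        maximize = TRUE, maxiter = 5000L)),
      error = function(e) NULL)
    validate(if (!is.null(res)) res$x, lb_used)
  }
  try_boot <- function(lb_used) {
    res <- tryCatch(
      suppressWarnings(
        boot::simplex(a = cc, A1 = diag(n), b1 = ub - lb_used,
                      A3 = S, b3 = as.vector(-S %*% lb_used),
                      maxi = TRUE, n.iter = 5000L)),
      error = function(e) NULL)
    validate(if (!is.null(res) && res$solved == 1) as.numeric(res$soln),
             lb_used)
  }
  for (eps in c(0, 1e-9, 1e-7, 1e-5)) {
    lb_used <- model$lb - eps * (1 + abs(model$lb))
    v <- try_pracma(lb_used)
    if (is.null(v)) v <- try_boot(lb_used)
    if (!is.null(v)) {
      names(v) <- colnames(S)
      return(list(status = "optimal", objective = unname(v[model$objective]),
                  fluxes = v))
    }
  }
  fail
}

#' A miniature aerobic/fermentative E. coli network
#'
#' A six-reaction core network (plus exchanges) that reproduces the
#' qualitative physiology the simulator relies on: respiration of glucose
#' (high ATP yield, consumes oxygen), fermentation of glucose to acetate
#' (low ATP yield), aerobic acetate respiration, anabolism of a biomass
#' precursor from either carbon source (the acetate route pays an extra ATP
#' cost, as gluconeogenesis does), and a biomass reaction whose ATP
#' coefficient is the growth-associated maintenance. It serves as the
#' packaged stand-in for a genome-scale model in examples and tests; it is a
#' synthetic toy network, not a curated reconstruction.
#'
#' @param gam Growth-associated maintenance, mmolATP/gDCW.
#' @param v_glc_max,v_o2_max Maximal glucose and oxygen uptake magnitudes.
#' @param yield_glc Glucose demand of biomass formation, mmol glucose/gDCW.
#' @return An [fba_model()].
#' @export
mini_ecoli_model <- function(gam = 60, v_glc_max = 10, v_o2_max = 15,
                             yield_glc = 5) {
  mets <- c("glc", "o2", "ac", "atp", "prec")
  rxns <- c("EX_glc", "EX_o2", "EX_ac", "FERM", "OX", "ACOX", "ANA_G",
            "ANA_A", "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["glc", "EX_glc"] <- -1
  S["o2", "EX_o2"] <- -1
  S["ac", "EX_ac"] <- -1
  S[, "FERM"] <- c(-1, 0, 2, 2.5, 0)     # glc -> 2 ac + 2.5 atp
  S[, "OX"] <- c(-1, -6, 0, 23.5, 0)     # glc + 6 o2 -> 23.5 atp
  S[, "ACOX"] <- c(0, -2, -1, 8, 0)      # ac + 2 o2 -> 8 atp
  S[, "ANA_G"] <- c(-1, 0, 0, 0, 2)      # glc -> 2 precursor
  S[, "ANA_A"] <- c(0, 0, -1, -2, 1)     # ac + 2 atp -> precursor
  S[, "BIOMASS"] <- c(0, 0, 0, -gam, -2 * yield_glc)
  fba_model(
    S,
    lb = c(-v_glc_max, -v_o2_max, 0, 0, 0, 0, 0, 0, 0),
    ub = c(0, 0, Inf, Inf, Inf, Inf, Inf, Inf, Inf),
    objective = "BIOMASS",
    exchanges = list(glucose = "EX_glc", oxygen = "EX_o2", acetate = "EX_ac"),
    atp_met = "atp",
    id = "mini_ecoli"
  )
}

#' Read a BiGG-dialect JSON metabolic model
#'
#' Parses the JSON layout used by the BiGG Models database (reactions with a
#' `metabolites` stoichiometry map, `lower_bound`/`upper_bound`, and an
#' `objective_coefficient`).
#'
#' @param path Path to a `.json` model file.
#' @param exchanges Named list mapping `glucose`, `oxygen`, `acetate` to
#'   exchange reaction ids; defaults to the canonical BiGG ids.
#' @param atp_met ATP metabolite id (BiGG default `atp_c`).
#' @return An [fba_model()].
#' @export
read_bigg_json <- function(path,
                           exchanges = list(glucose = "EX_glc__D_e",
                                            oxygen = "EX_o2_e",
                                            acetate = "EX_ac_e"),
                           atp_met = "atp_c") {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  rxns <- m$reactions
  met_ids <- vapply(m$metabolites, function(x) x$id, character(1))
  rxn_ids <- vapply(rxns, function(x) x$id, character(1))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rxns))
  obj <- NULL
  for (k in seq_along(rxns)) {
    r <- rxns[[k]]
    st <- r$metabolites
    if (length(st) > 0) S[names(st), k] <- as.numeric(unlist(st))
    lb[k] <- r$lower_bound
    ub[k] <- r$upper_bound
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      obj <- r$id
    }
  }
  if (is.null(obj)) stop("model declares no objective reaction", call. = FALSE)
  if (!atp_met %in% met_ids) atp_met <- NA_character_
  fba_model(S, lb, ub, obj, exchanges, atp_met = atp_met,
            id = if (!is.null(m$id)) m$id else basename(path))
}

# fbc attributes may keep their namespace prefix after stripping
fbc_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}

#' Read an SBML Level 3 model with flux-balance constraints
#'
#' A minimal reader for SBML L3V1 documents using the `fbc` (version 2)
#' package: species, reactions with `speciesReference` stoichiometries,
#' flux bounds resolved through `fbc:lowerFluxBound`/`fbc:upperFluxBound`
#' parameters, and the active objective.
#'
#' @inheritParams read_bigg_json
#' @return An [fba_model()].
#' @export
read_sbml_model <- function(path,
                            exchanges = list(glucose = "EX_glc__D_e",
                                             oxygen = "EX_o2_e",
                                             acetate = "EX_ac_e"),
                            atp_met = "atp_c") {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_ids <- xml2::xml_attr(sp, "id")
  # boundary-condition species are not balanced
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  met_ids <- met_ids[!boundary]
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxn_ids <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- numeric(length(rx))
  for (k in seq_along(rx)) {
    r <- rx[[k]]
    for (ref in xml2::xml_find_all(r, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      if (s %in% met_ids) {
        S[s, k] <- S[s, k] - as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      }
    }
    for (ref in xml2::xml_find_all(r, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      if (s %in% met_ids) {
        S[s, k] <- S[s, k] + as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      }
    }
    lbid <- fbc_attr(r, "lowerFluxBound")
    ubid <- fbc_attr(r, "upperFluxBound")
    lb[k] <- if (!is.na(lbid)) pval[[lbid]] else -Inf
    ub[k] <- if (!is.na(ubid)) pval[[ubid]] else Inf
  }
  objref <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (inherits(objref, "xml_missing")) {
    stop("SBML model declares no fbc objective", call. = FALSE)
  }
  obj <- fbc_attr(objref, "reaction")
  if (!atp_met %in% met_ids) atp_met <- NA_character_
  fba_model(S, lb, ub, obj, exchanges, atp_met = atp_met,
            id = xml2::xml_attr(xml2::xml_find_first(doc, ".//model"), "id"))
}

#' Write an [fba_model()] as minimal SBML L3 + fbc
#'
#' Mainly used to produce small round-trip fixtures; emits species, reactions
#' with stoichiometries, bound parameters, and the objective.
#'
#' @param model An [fba_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">')
  w('  <model id="', esc(model$id), '" fbc:strict="true">')
  w('    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>')
  w('    <listOfSpecies>')
  for (m in rownames(model$S)) {
    w('      <species id="', esc(m), '" compartment="c" constant="false" ',
      'boundaryCondition="false" hasOnlySubstanceUnits="false"/>')
  }
  w('    </listOfSpecies>')
  w('    <listOfParameters>')
  bnd_id <- function(k, side) paste0("bnd_", side, "_", k)
  for (k in seq_along(model$lb)) {
    w('      <parameter id="', bnd_id(k, "lb"), '" value="',
      format(model$lb[k], digits = 17), '" constant="true"/>')
    w('      <parameter id="', bnd_id(k, "ub"), '" value="',
      format(min(model$ub[k], 1e6), digits = 17), '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  for (k in seq_len(ncol(model$S))) {
    rid <- colnames(model$S)[k]
    w('      <reaction id="', esc(rid), '" reversible="true" fast="false" ',
      'fbc:lowerFluxBound="', bnd_id(k, "lb"), '" fbc:upperFluxBound="',
      bnd_id(k, "ub"), '">')
    col <- model$S[, k]
    rea <- which(col < 0)
    pro <- which(col > 0)
    if (length(rea)) {
      w('        <listOfReactants>')
      for (i in rea) {
        w('          <speciesReference species="', esc(rownames(model$S)[i]),
          '" stoichiometry="', format(-col[i], digits = 17),
          '" constant="true"/>')
      }
      w('        </listOfReactants>')
    }
    if (length(pro)) {
      w('        <listOfProducts>')
      for (i in pro) {
        w('          <speciesReference species="', esc(rownames(model$S)[i]),
          '" stoichiometry="', format(col[i], digits = 17),
          '" constant="true"/>')
      }
      w('        </listOfProducts>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  w('        <fbc:listOfFluxObjectives>')
  w('          <fbc:fluxObjective fbc:reaction="', esc(model$objective),
    '" fbc:coefficient="1"/>')
  w('        </fbc:listOfFluxObjectives>')
  w('      </fbc:objective>')
  w('    </fbc:listOfObjectives>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}
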