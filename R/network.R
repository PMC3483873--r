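COMPARTMENTS <- c("extracellular", "membrane", "cytoplasm", "nucleus", "endosome")

RATE_LAW_FORMS <- c("mass_action_irreversible", "mass_action_reversible",
                    "michaelis_menten", "expression")

#' Define a chemical species
#'
#' A species is a named pool of molecules in one compartment with a
#' non-negative initial concentration. All concentrations in the package are
#' expressed in nanomolar (nM); constructors that accept other units (see
#' [egf_dose_to_concentration()]) convert at the boundary.
#'
#' @param id Unique short identifier, e.g. `"EGF"`, `"ppERK"`.
#' @param initial_amount Initial concentration in nM (non-negative).
#' @param compartment One of `"extracellular"`, `"membrane"`, `"cytoplasm"`,
#'   `"nucleus"`, `"endosome"`.
#' @param display_name Free-text name; defaults to `id`.
#' @param is_constant If `TRUE` the species is clamped (time derivative forced
#'   to zero), as for a drug bath held at fixed concentration.
#' @return An object of class `egfr_species`.
#' @export
species <- function(id, initial_amount = 0, compartment = "cytoplasm",
                    display_name = id, is_constant = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(initial_amount) || length(initial_amount) != 1L ||
      is.na(initial_amount) || initial_amount < 0) {
    stop("initial_amount must be a single non-negative number (nM), got ",
         deparse(initial_amount), " for species '", id, "'")
  }
  compartment <- match.arg(compartment, COMPARTMENTS)
  structure(list(id = id, display_name = display_name,
                 compartment = compartment,
                 initial_amount = as.numeric(initial_amount),
                 is_constant = isTRUE(is_constant)),
            class = "egfr_species")
}

#' Define a kinetic rate law
#'
#' Three closed forms are supported: irreversible mass action
#' (\eqn{v = k_1 \prod [X_i]}), reversible mass action
#' (\eqn{v = k_1 \prod [X_i] - k_{r1} \prod [Y_j]}), and Michaelis-Menten
#' (\eqn{v = k_2 E_t [S] / (K_m + [S])}, so \eqn{V_{max} = k_2 E_t} is always
#' derived from the catalytic constant and the current enzyme total, never
#' stored). A fourth form, `"expression"`, holds an arbitrary arithmetic
#' expression over species and parameter identifiers and exists so that SBML
#' kinetic laws that match none of the closed forms can still be evaluated.
#'
#' Units: first-order constants are s^-1, second-order constants nM^-1 s^-1,
#' `Km` is nM.
#'
#' @param form One of `"mass_action_irreversible"`, `"mass_action_reversible"`,
#'   `"michaelis_menten"`, `"expression"`.
#' @param k1 Forward rate constant.
#' @param kr1 Reverse rate constant (reversible mass action only).
#' @param k2 Catalytic rate constant (Michaelis-Menten only).
#' @param Km Michaelis constant in nM, strictly positive (Michaelis-Menten
#'   only).
#' @param Vmax Optional maximal rate in nM/s for a Michaelis-Menten law whose
#'   enzyme is folded into the rate (no explicit modifier).
#' @param math For `form = "expression"`: a string or R expression over
#'   species/parameter ids.
#' @return An object of class `egfr_rate_law`.
#' @export
rate_law <- function(form, k1 = NULL, kr1 = NULL, k2 = NULL, Km = NULL,
                     Vmax = NULL, math = NULL) {
  form <- match.arg(form, RATE_LAW_FORMS)
  chk <- function(x, nm, strict_pos = FALSE) {
    if (is.null(x)) return(NULL)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (strict_pos && x <= 0) || (!strict_pos && x < 0)) {
      stop("rate constant '", nm, "' must be a single ",
           if (strict_pos) "positive" else "non-negative", " number")
    }
    as.numeric(x)
  }
  k1 <- chk(k1, "k1"); kr1 <- chk(kr1, "kr1"); k2 <- chk(k2, "k2")
  Vmax <- chk(Vmax, "Vmax")
  Km <- chk(Km, "Km", strict_pos = TRUE)
  if (form == "mass_action_irreversible" && is.null(k1))
    stop("mass_action_irreversible requires k1")
  if (form == "mass_action_reversible" && (is.null(k1) || is.null(kr1)))
    stop("mass_action_reversible requires k1 and kr1")
  if (form == "michaelis_menten") {
    if (is.null(Km)) stop("michaelis_menten requires Km > 0")
    if (is.null(k2) && is.null(Vmax))
      stop("michaelis_menten requires k2 (with an enzyme modifier) or Vmax")
  }
  if (form == "expression") {
    if (is.null(math)) stop("expression form requires math")
    if (is.character(math)) math <- str2lang(math)
  }
  structure(list(form = form, k1 = k1, kr1 = kr1, k2 = k2, Km = Km,
                 Vmax = Vmax, math = math),
            class = "egfr_rate_law")
}

#' Compute an irreversible or reversible mass-action rate
#'
#' Returns \eqn{k_1 \prod [X_i] - k_{r1} \prod [Y_j]} (the reverse term only
#' for the reversible form). The sign convention is positive = net forward.
#' Pass each reactant concentration once per stoichiometric unit (a reactant
#' with coefficient 2 appears twice).
#'
#' @param law An `egfr_rate_law` with a mass-action form.
#' @param reactant_concentrations Numeric vector of reactant concentrations
#'   (nM), one entry per stoichiometric unit.
#' @param product_concentrations Product concentrations for the reversible
#'   form (ignored, and must be absent, for the irreversible form).
#' @return Reaction rate in nM/s.
#' @export
mass_action_rate <- function(law, reactant_concentrations,
                             product_concentrations = NULL) {
  stopifnot(inherits(law, "egfr_rate_law"))
  if (!law$form %in% c("mass_action_irreversible", "mass_action_reversible"))
    stop("law form '", law$form, "' is not a mass-action form")
  if (any(reactant_concentrations < 0) || any(product_concentrations < 0))
    stop("concentrations must be non-negative")
  if (law$form == "mass_action_irreversible") {
    if (!is.null(product_concentrations))
      stop("irreversible mass action takes no product concentrations")
    return(law$k1 * prod(reactant_concentrations))
  }
  if (is.null(product_concentrations))
    stop("reversible mass action requires product concentrations")
  law$k1 * prod(reactant_concentrations) -
    law$kr1 * prod(product_concentrations)
}

#' Compute a Michaelis-Menten rate
#'
#' \eqn{v = k_2 E_t [S] / (K_m + [S])}; the maximal rate
#' \eqn{V_{max} = k_2 E_t} is derived on demand from the catalytic constant
#' and the enzyme total, so the rate is monotone non-decreasing in the
#' substrate and bounded above by \eqn{V_{max}}. At \eqn{[S] = K_m} the rate
#' is exactly half of \eqn{V_{max}}.
#'
#' @param law An `egfr_rate_law` with `form = "michaelis_menten"`.
#' @param substrate Substrate concentration, nM (non-negative).
#' @param enzyme_total Total enzyme concentration \eqn{E_t}, nM
#'   (non-negative). Ignored when the law carries `Vmax` directly.
#' @return Reaction rate in nM/s.
#' @export
michaelis_menten_rate <- function(law, substrate, enzyme_total = NULL) {
  stopifnot(inherits(law, "egfr_rate_law"))
  if (law$form != "michaelis_menten")
    stop("law form '", law$form, "' is not michaelis_menten")
  if (is.null(law$Km) || law$Km <= 0) stop("Km must be > 0")
  if (substrate < 0) stop("substrate concentration must be non-negative")
  vmax <- if (!is.null(law$Vmax)) law$Vmax else {
    if (is.null(enzyme_total)) stop("enzyme_total required when Vmax not set")
    if (enzyme_total < 0) stop("enzyme_total must be non-negative")
    law$k2 * enzyme_total
  }
  vmax * substrate / (law$Km + substrate)
}

normalize_side <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.character(x)) {
    tab <- table(x)
    x <- stats::setNames(as.numeric(tab), names(tab))
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be named by species id")
  if (any(x <= 0) || any(x != round(x)))
    stop(what, " coefficients must be positive integers")
  x
}

#' Define a reaction
#'
#' @param id Unique reaction identifier.
#' @param reactants,products Either a character vector of species ids (each
#'   occurrence counts one stoichiometric unit) or a named numeric vector of
#'   positive integer coefficients.
#' @param modifiers Character vector of species ids acting as catalysts
#'   (enzymes); modifiers are not consumed and contribute zero to the
#'   stoichiometry matrix.
#' @param rate_law An [rate_law()] object. A `michaelis_menten` law requires
#'   exactly one reactant (the substrate) and at least one modifier unless the
#'   enzyme is folded into `Vmax`.
#' @return An object of class `egfr_reaction`.
#' @export
reaction <- function(id, reactants, products, rate_law,
                     modifiers = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(rate_law, "egfr_rate_law"))
  reactants <- normalize_side(reactants, "reactants")
  products <- normalize_side(products, "products")
  if (rate_law$form == "michaelis_menten") {
    if (length(reactants) != 1L || reactants[[1L]] != 1L)
      stop("michaelis_menten reaction '", id,
           "' must have exactly one substrate with coefficient 1")
    if (length(modifiers) == 0L && is.null(rate_law$Vmax))
      stop("michaelis_menten reaction '", id,
           "' needs an enzyme modifier or a Vmax")
  }
  structure(list(id = id, reactants = reactants, products = products,
                 modifiers = as.character(modifiers), rate_law = rate_law),
            class = "egfr_reaction")
}

#' Define an assignment rule
#'
#' An assignment rule fixes a species (or parameter) to an arithmetic
#' expression over other declared identifiers, re-evaluated at every
#' right-hand-side evaluation (SBML assignment-rule semantics). A species
#' governed by a rule is not integrated; its derivative is forced to zero.
#'
#' @param id Rule identifier.
#' @param target Species or parameter id the rule assigns.
#' @param math Expression (string or R language object) over declared ids.
#' @return An object of class `egfr_rule`.
#' @export
assignment_rule <- function(id, target, math) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(target), length(target) == 1L)
  if (is.character(math)) math <- str2lang(math)
  structure(list(id = id, target = target, math = math), class = "egfr_rule")
}

hoist_parameters <- function(reactions) {
  params <- numeric(0)
  for (rx in reactions) {
    for (f in c("k1", "kr1", "k2", "Km", "Vmax")) {
      if (!is.null(rx$rate_law[[f]]))
        params[paste(rx$id, f, sep = "_")] <- rx$rate_law[[f]]
    }
  }
  params
}

#' Assemble a reaction network
#'
#' Collects species, reactions, rules and global parameters into one model
#' object and checks referential integrity. Rate constants supplied inside
#' rate laws are hoisted into the global parameter table under
#' `"<reaction id>_<constant>"` names (e.g. `"bind_EGF_k1"`); the parameter
#' table is the live source of values for simulation, so [set_parameter()]
#' edits take effect without rebuilding reactions.
#'
#' @param name Model name.
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param rules List of [assignment_rule()] objects.
#' @param parameters Named numeric vector of additional global constants.
#' @param metadata List of provenance notes (source, applied modifications).
#' @return An object of class `egfr_network`.
#' @export
reaction_network <- function(name, species = list(), reactions = list(),
                             rules = list(), parameters = numeric(0),
                             metadata = list()) {
  sp_ids <- vapply(species, function(s) s$id, character(1))
  if (anyDuplicated(sp_ids)) {
    stop("duplicate species ids: ",
         paste(unique(sp_ids[duplicated(sp_ids)]), collapse = ", "))
  }
  rx_ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(rx_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", "))
  }
  params <- c(hoist_parameters(reactions), parameters)
  if (anyDuplicated(names(params)))
    stop("duplicate parameter names after hoisting")
  net <- structure(list(name = name,
                        species = stats::setNames(species, sp_ids),
                        reactions = stats::setNames(reactions, rx_ids),
                        rules = rules, parameters = params,
                        metadata = metadata),
                   class = "egfr_network")
  bad <- integrity_violations(net)
  if (length(bad)) stop("referential integrity: ", paste(bad, collapse = "; "))
  net
}

integrity_violations <- function(net) {
  sp_ids <- names(net$species)
  known <- c(sp_ids, names(net$parameters))
  bad <- character(0)
  for (rx in net$reactions) {
    refs <- c(names(rx$reactants), names(rx$products), rx$modifiers)
    miss <- setdiff(refs, sp_ids)
    if (length(miss))
      bad <- c(bad, paste0("reaction '", rx$id, "' references unknown species ",
                           paste(miss, collapse = ", ")))
    if (rx$rate_law$form == "expression") {
      miss <- setdiff(all.vars(rx$rate_law$math), c(known, "time", "t"))
      if (length(miss))
        bad <- c(bad, paste0("reaction '", rx$id,
                             "' rate expression references unknown ids ",
                             paste(miss, collapse = ", ")))
    }
  }
  for (rl in net$rules) {
    if (!rl$target %in% known)
      bad <- c(bad, paste0("rule '", rl$id, "' targets unknown id '",
                           rl$target, "'"))
    miss <- setdiff(all.vars(rl$math), c(known, "time", "t"))
    if (length(miss))
      bad <- c(bad, paste0("rule '", rl$id, "' references unknown ids ",
                           paste(miss, collapse = ", ")))
  }
  bad
}

#' @export
print.egfr_network <- function(x, ...) {
  cat("<egfr_network> ", x$name, "\n", sep = "")
  cat("  species:    ", length(x$species), "\n")
  cat("  reactions:  ", length(x$reactions), "\n")
  cat("  parameters: ", length(x$parameters), "\n")
  cat("  rules:      ", length(x$rules), "\n")
  if (length(x$metadata$modifications))
    cat("  modifications:",
        paste(vapply(x$metadata$modifications, `[[`, character(1), "label"),
              collapse = "; "), "\n")
  invisible(x)
}

#' Species ids of a network
#' @param network An `egfr_network`.
#' @return Character vector of species ids in declaration order.
#' @export
species_ids <- function(network) names(network$species)

#' Initial state vector of a network
#' @param network An `egfr_network`.
#' @return Named numeric vector of initial concentrations (nM).
#' @export
initial_state <- function(network) {
  vapply(network$species, function(s) s$initial_amount, numeric(1))
}

#' Edit a species' initial concentration
#' @param network An `egfr_network`.
#' @param id Species id.
#' @param value New initial concentration, nM (non-negative).
#' @return The modified network.
#' @export
set_initial <- function(network, id, value) {
  if (!id %in% names(network$species))
    stop("unknown species '", id, "'")
  if (value < 0) stop("initial concentration must be non-negative")
  network$species[[id]]$initial_amount <- as.numeric(value)
  network
}

#' Edit a global parameter
#' @param network An `egfr_network`.
#' @param id Parameter name (see [reaction_network()] for hoisted names).
#' @param value New value.
#' @return The modified network.
#' @export
set_parameter <- function(network, id, value) {
  if (!id %in% names(network$parameters))
    stop("unknown parameter '", id, "'")
  network$parameters[[id]] <- as.numeric(value)
  network
}

#' @rdname set_parameter
#' @export
get_parameter <- function(network, id) {
  if (!id %in% names(network$parameters))
    stop("unknown parameter '", id, "'")
  network$parameters[[id]]
}

#' Stoichiometry matrix
#'
#' Entry (i, j) is the net stoichiometric coefficient of species i in
#' reaction j (products minus reactants). Modifiers contribute zero, so a
#' catalyst's column entries cancel across its catalytic cycle.
#'
#' @param network An `egfr_network` that passes referential integrity.
#' @return Integer matrix of dimension species x reactions, with dimnames.
#' @export
stoichiometry_matrix <- function(network) {
  bad <- integrity_violations(network)
  if (length(bad)) stop("integrity error: ", paste(bad, collapse = "; "))
  sp <- species_ids(network)
  S <- matrix(0, nrow = length(sp), ncol = length(network$reactions),
              dimnames = list(sp, names(network$reactions)))
  for (j in seq_along(network$reactions)) {
    rx <- network$reactions[[j]]
    S[names(rx$reactants), j] <- S[names(rx$reactants), j] - rx$reactants
    S[names(rx$products), j] <- S[names(rx$products), j] + rx$products
  }
  S
}

rewrite_expr <- function(e, sp_index, par_names) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!is.na(sp_index[nm])) return(str2lang(sprintf("y[%dL]", sp_index[nm])))
    if (nm %in% par_names) return(str2lang(sprintf("p[[\"%s\"]]", nm)))
    if (nm %in% c("time", "t")) return(quote(t))
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- rewrite_expr(e[[i]], sp_index, par_names)
    return(e)
  }
  e
}

side_expr <- function(side, sp_index) {
  terms <- mapply(function(nm, co) {
    if (co == 1) sprintf("y[%dL]", sp_index[nm])
    else sprintf("y[%dL]^%d", sp_index[nm], as.integer(co))
  }, names(side), side)
  paste(terms, collapse = " * ")
}

#' Compile a network into a fast ODE right-hand-side function
#'
#' Generates (once) an R function `f(t, y, p)` returning
#' `list(derivatives, rates)` in deSolve's expected form, with per-reaction
#' rate expressions unrolled. Negative excursions of the state are clamped to
#' zero for rate evaluation only. Constant species and rule-governed species
#' have derivative zero; assignment rules are applied to the working state
#' before rates are evaluated.
#'
#' @param network An `egfr_network`.
#' @return A list with elements `func` (the generated function), `S`
#'   (stoichiometry matrix), `y0` (initial state), `parms` (parameter vector).
#' @export
compile_network <- function(network) {
  S <- stoichiometry_matrix(network)
  sp <- species_ids(network)
  sp_index <- stats::setNames(seq_along(sp), sp)
  nr <- length(network$reactions)
  pnames <- names(network$parameters)
  lines <- character(nr)
  for (j in seq_len(nr)) {
    rx <- network$reactions[[j]]
    law <- rx$rate_law
    pref <- function(f) sprintf("p[[\"%s_%s\"]]", rx$id, f)
    expr <- switch(law$form,
      mass_action_irreversible = {
        if (length(rx$reactants) == 0L) pref("k1")
        else paste(pref("k1"), "*", side_expr(rx$reactants, sp_index))
      },
      mass_action_reversible = paste0(
        pref("k1"), " * ", side_expr(rx$reactants, sp_index), " - ",
        pref("kr1"), " * ", side_expr(rx$products, sp_index)),
      michaelis_menten = {
        s_i <- sp_index[names(rx$reactants)[1L]]
        vmax <- if (!is.null(law$Vmax)) pref("Vmax")
                else sprintf("%s * y[%dL]", pref("k2"), sp_index[rx$modifiers[1L]])
        sprintf("%s * y[%dL] / (%s + y[%dL])", vmax, s_i, pref("Km"), s_i)
      },
      expression = paste(deparse(rewrite_expr(law$math, sp_index, pnames)),
                         collapse = " ")
    )
    lines[j] <- sprintf("v[%dL] <- %s", j, expr)
  }
  rule_lines <- vapply(network$rules, function(rl) {
    tgt <- sp_index[rl$target]
    if (is.na(tgt)) return("")  # parameter rules handled below
    sprintf("y[%dL] <- %s", tgt,
            paste(deparse(rewrite_expr(rl$math, sp_index, pnames)),
                  collapse = " "))
  }, character(1))
  zero_idx <- sort(unique(c(
    which(vapply(network$species, function(s) s$is_constant, logical(1))),
    unname(sp_index[vapply(network$rules, `[[`, character(1), "target")])
  )))
  zero_idx <- zero_idx[!is.na(zero_idx)]
  body_txt <- paste(c(
    "function(t, y, p) {",
    "  y <- pmax(y, 0)",
    rule_lines[nzchar(rule_lines)],
    sprintf("  v <- numeric(%dL)", nr),
    paste0("  ", lines),
    "  if (anyNA(v) || any(is.infinite(v))) {",
    "    bad <- which(!is.finite(v))",
    "    stop(\"non-finite rate in reaction(s): \",",
    "         paste(rxids[bad], collapse = \", \"))",
    "  }",
    "  d <- as.vector(S %*% v)",
    if (length(zero_idx))
      sprintf("  d[c(%s)] <- 0", paste(zero_idx, collapse = ", ")) else NULL,
    "  list(d)",
    "}"), collapse = "\n")
  env <- new.env(parent = asNamespace("egfrsim"))
  env$S <- S
  env$rxids <- names(network$reactions)
  func <- eval(str2lang(body_txt), env)
  list(func = func, S = S, y0 = initial_state(network),
       parms = network$parameters, species = sp)
}

#' Evaluate the ODE right-hand side at a state
#'
#' The derivative vector is the stoichiometry matrix times the per-reaction
#' rate vector, with assignment rules applied first and constant species
#' forced to zero derivative.
#'
#' @param network An `egfr_network`.
#' @param state Named or unnamed numeric vector of concentrations (nM), in
#'   species declaration order when unnamed.
#' @param time Simulation time, s (only used by time-dependent expressions).
#' @return Named numeric vector of derivatives, nM/s.
#' @export
ode_rhs <- function(network, state, time = 0) {
  comp <- compile_network(network)
  if (!is.null(names(state))) state <- state[comp$species]
  if (length(state) != length(comp$species))
    stop("state length ", length(state), " != species count ",
         length(comp$species))
  if (any(state < 0)) stop("state concentrations must be non-negative")
  d <- comp$func(time, as.numeric(state), comp$parms)[[1L]]
  stats::setNames(d, comp$species)
}

#' Validate a network and report composition counts
#'
#' Produces a report (never an error) listing referential-integrity
#' violations, negative constants or initial amounts, species unreachable by
#' any reaction, and the species/reaction/parameter/rule counts.
#'
#' @param network An `egfr_network`.
#' @return A list of class `egfr_validation` with elements `counts`
#'   (species, reactions, parameters, rules), `violations` (character),
#'   `unreachable` (character) and `ok` (logical).
#' @export
validate_network <- function(network) {
  violations <- integrity_violations(network)
  for (s in network$species) {
    if (s$initial_amount < 0)
      violations <- c(violations,
                      paste0("species '", s$id, "' has negative initial amount"))
  }
  neg <- names(network$parameters)[network$parameters < 0]
  if (length(neg))
    violations <- c(violations,
                    paste0("negative parameter(s): ", paste(neg, collapse = ", ")))
  used <- unique(unlist(lapply(network$reactions, function(rx)
    c(names(rx$reactants), names(rx$products), rx$modifiers))))
  unreachable <- setdiff(species_ids(network), used)
  counts <- c(species = length(network$species),
              reactions = length(network$reactions),
              parameters = length(network$parameters),
              rules = length(network$rules))
  structure(list(counts = counts, violations = violations,
                 unreachable = unreachable,
                 ok = length(violations) == 0L),
            class = "egfr_validation")
}

#' @export
print.egfr_validation <- function(x, ...) {
  cat("network validation:", if (x$ok) "OK" else "VIOLATIONS", "\n")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = ", "), "\n")
  if (length(x$violations))
    cat("  violations:\n", paste("   -", x$violations, collapse = "\n"), "\n")
  if (length(x$unreachable))
    cat("  unreachable species:", paste(x$unreachable, collapse = ", "), "\n")
  invisible(x)
}

#' Conserved moieties of a network
#'
#' Left null vectors of the stoichiometry matrix; any linear combination of
#' concentrations with these weights is invariant under the dynamics of an
#' unclamped network.
#'
#' @param network An `egfr_network`.
#' @param tol Singular-value threshold for the null space.
#' @return Matrix with one column per conserved combination (species weights).
#' @export
conserved_moieties <- function(network, tol = 1e-10) {
  S <- stoichiometry_matrix(network)
  sv <- svd(S, nu = nrow(S))
  d <- c(sv$d, rep(0, nrow(S) - length(sv$d)))
  v <- sv$u[, d < tol, drop = FALSE]
  rownames(v) <- rownames(S)
  v
}
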