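# independent minimal SBML interpreter used as a cross-check oracle: parses
# a document with bare xml2 calls and its own MathML translator (no package
# reader involved), builds an RHS closure and integrates it with deSolve.
oracle_mathml <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "math") return(oracle_mathml(xml2::xml_children(node)[[1]]))
  if (nm == "ci") return(as.symbol(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    if (identical(xml2::xml_attr(node, "type"), "e-notation")) {
      txt <- strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]]
      parts <- as.numeric(txt[nzchar(txt)])
      return(parts[1] * 10^parts[2])
    }
    return(as.numeric(xml2::xml_text(node)))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- switch(xml2::xml_name(kids[[1]]), plus = "+", minus = "-",
                 times = "*", divide = "/", power = "^",
                 stop("oracle: unknown op"))
    args <- lapply(kids[-1], oracle_mathml)
    e <- args[[1]]
    if (length(args) == 1L && op == "-") return(call("-", e))
    for (a in args[-1]) e <- call(op, e, a)
    return(e)
  }
  stop("oracle: unknown MathML node ", nm)
}

oracle_simulate <- function(path, times) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*")
  ids <- xml2::xml_attr(ns, "id")
  y0 <- as.numeric(xml2::xml_attr(ns, "initialConcentration"))
  names(y0) <- ids
  fixed <- xml2::xml_attr(ns, "boundaryCondition") == "true"
  pn <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*")
  pars <- as.list(stats::setNames(as.numeric(xml2::xml_attr(pn, "value")),
                                  xml2::xml_attr(pn, "id")))
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  stoich <- matrix(0, length(ids), length(rx),
                   dimnames = list(ids, xml2::xml_attr(rx, "id")))
  laws <- vector("list", length(rx))
  for (j in seq_along(rx)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx[[j]], sprintf(
        ".//*[local-name()='%s']/*", side))
      sgn <- if (side == "listOfReactants") -1 else 1
      for (r in refs) {
        st <- xml2::xml_attr(r, "stoichiometry")
        stoich[xml2::xml_attr(r, "species"), j] <-
          stoich[xml2::xml_attr(r, "species"), j] +
          sgn * ifelse(is.na(st), 1, as.numeric(st))
      }
    }
    laws[[j]] <- oracle_mathml(xml2::xml_find_first(
      rx[[j]], ".//*[local-name()='kineticLaw']/*[local-name()='math']"))
  }
  rhs <- function(t, y, p) {
    env <- c(as.list(pmax(y, 0)), pars)
    v <- vapply(laws, function(e) eval(e, env), numeric(1))
    d <- as.vector(stoich %*% v)
    d[fixed] <- 0
    list(d)
  }
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  out[, -1, drop = FALSE]
}

test_that("SBML round trip is a fixpoint of the network representation", {
  net <- build_normal_model()
  f1 <- tempfile(fileext = ".xml")
  f2 <- tempfile(fileext = ".xml")
  info <- write_sbml(net, f1)
  expect_s3_class(info, "egfr_sbml_info")
  expect_equal(info$level, 2L)
  net2 <- suppressMessages(read_sbml(f1))
  # same species, initials, law forms and constants as the source network
  expect_setequal(species_ids(net2), species_ids(net))
  expect_equal(initial_state(net2)[species_ids(net)], initial_state(net))
  forms <- function(n) vapply(n$reactions, function(r) r$rate_law$form,
                              character(1), USE.NAMES = TRUE)
  expect_equal(forms(net2)[names(forms(net))], forms(net))
  common <- intersect(names(net$parameters), names(net2$parameters))
  expect_setequal(common, names(net$parameters))
  expect_equal(unlist(net2$parameters[common]),
               unlist(net$parameters[common]), tolerance = 1e-9)
  # write(read(f)) then read again: identical network (modulo float text)
  suppressMessages(write_sbml(net2, f2))
  net3 <- suppressMessages(read_sbml(f2))
  expect_equal(initial_state(net3), initial_state(net2))
  expect_equal(net3$parameters[sort(names(net3$parameters))],
               net2$parameters[sort(names(net2$parameters))],
               tolerance = 1e-12)
  # the info report's counts equal the parsed network's
  inf2 <- net2$metadata$sbml
  expect_equal(unname(inf2$counts["species"]), length(net2$species))
  expect_equal(unname(inf2$counts["reactions"]), length(net2$reactions))
  expect_equal(unname(inf2$counts["parameters"]), length(net2$parameters))
  expect_equal(unname(inf2$counts["rules"]), length(net2$rules))
})

test_that("kinetic-law classification reproduces the original math", {
  # one reaction of every closed form plus a genuinely opaque law
  net <- reaction_network(
    "forms",
    species = list(species("A", 10, "cytoplasm"),
                   species("B", 5, "cytoplasm"),
                   species("C", 1, "cytoplasm"),
                   species("Enz", 2, "cytoplasm")),
    reactions = list(
      reaction("r_ma", c("A", "B"), "C",
               rate_law("mass_action_irreversible", k1 = 0.123)),
      reaction("r_rev", "A", c(B = 2),
               rate_law("mass_action_reversible", k1 = 0.4, kr1 = 0.07)),
      reaction("r_mmk", "A", "C",
               rate_law("michaelis_menten", k2 = 0.9, Km = 17),
               modifiers = "Enz"),
      reaction("r_mmv", "B", "C",
               rate_law("michaelis_menten", Vmax = 3.5, Km = 60)),
      reaction("r_opaque", "C", "A",
               rate_law("expression",
                        math = quote(0.2 * C^2 / (1 + 0.1 * B))))))
  f <- tempfile(fileext = ".xml")
  write_sbml(net, f)
  got <- suppressMessages(read_sbml(f))
  law <- function(n, id) {
    i <- match(id, vapply(n$reactions, `[[`, character(1), "id"))
    n$reactions[[i]]$rate_law
  }
  expect_equal(law(got, "r_ma")$form, "mass_action_irreversible")
  expect_equal(law(got, "r_ma")$k1, 0.123, tolerance = 1e-9)
  expect_equal(law(got, "r_rev")$form, "mass_action_reversible")
  expect_equal(law(got, "r_rev")$k1, 0.4, tolerance = 1e-9)
  expect_equal(law(got, "r_rev")$kr1, 0.07, tolerance = 1e-9)
  expect_equal(law(got, "r_mmk")$form, "michaelis_menten")
  expect_equal(law(got, "r_mmk")$k2, 0.9, tolerance = 1e-9)
  expect_equal(law(got, "r_mmk")$Km, 17, tolerance = 1e-9)
  expect_equal(law(got, "r_mmv")$Vmax, 3.5, tolerance = 1e-9)
  expect_equal(law(got, "r_mmv")$Km, 60, tolerance = 1e-9)
  expect_equal(law(got, "r_opaque")$form, "expression")
  # classified laws reproduce the opaque math on random states within 1e-10
  set.seed(7)
  for (i in 1:100) {
    st <- stats::runif(4, 0, 50)
    names(st) <- c("A", "B", "C", "Enz")
    want <- c(0.123 * st["A"] * st["B"],
              0.4 * st["A"] - 0.07 * st["B"]^2,
              0.9 * st["Enz"] * st["A"] / (17 + st["A"]),
              3.5 * st["B"] / (60 + st["B"]),
              0.2 * st["C"]^2 / (1 + 0.1 * st["B"]))
    have <- c(
      mass_action_rate(law(got, "r_ma"), st[c("A", "B")]),
      mass_action_rate(law(got, "r_rev"), st["A"], st[c("B", "B")]),
      michaelis_menten_rate(law(got, "r_mmk"), st[["A"]], st[["Enz"]]),
      michaelis_menten_rate(law(got, "r_mmv"), st[["B"]]),
      eval(law(got, "r_opaque")$math, as.list(st)))
    expect_equal(unname(have), unname(want), tolerance = 1e-10)
  }
})

test_that("minimal and empty documents are handled", {
  f <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="tiny">',
    '    <listOfCompartments><compartment id="cytoplasm" size="1"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="X" compartment="cytoplasm" initialConcentration="4"/>',
    '    </listOfSpecies>',
    '  </model>', '</sbml>'), f)
  net <- suppressMessages(suppressWarnings(read_sbml(f)))
  expect_length(net$species, 1L)
  expect_length(net$reactions, 0L)
  expect_equal(initial_state(net)[["X"]], 4)
  # empty network writes a valid document that reads back empty
  fe <- tempfile(fileext = ".xml")
  write_sbml(reaction_network("void"), fe)
  back <- suppressMessages(suppressWarnings(read_sbml(fe)))
  expect_length(back$species, 0L)
  expect_length(back$reactions, 0L)
})

test_that("unsupported constructs raise explicit errors, never silent skips", {
  frame <- function(body) c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m">',
    '    <listOfCompartments><compartment id="cytoplasm" size="1"/></listOfCompartments>',
    '    <listOfSpecies><species id="X" compartment="cytoplasm" initialConcentration="1"/></listOfSpecies>',
    body, '  </model>', '</sbml>')
  check <- function(body, pattern) {
    f <- tempfile(fileext = ".xml")
    writeLines(frame(body), f)
    expect_error(suppressWarnings(suppressMessages(read_sbml(f))), pattern)
  }
  check('<listOfEvents><event id="e"/></listOfEvents>', "unsupported.*event")
  check(paste0('<listOfRules><rateRule variable="X">',
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               '<cn>1</cn></math></rateRule></listOfRules>'),
        "unsupported.*rateRule")
  check(paste0('<listOfRules><algebraicRule>',
               '<math xmlns="http://www.w3.org/1998/Math/MathML">',
               '<ci>X</ci></math></algebraicRule></listOfRules>'),
        "unsupported.*algebraicRule")
  check(paste0('<listOfFunctionDefinitions><functionDefinition id="f"/>',
               '</listOfFunctionDefinitions>'),
        "unsupported.*functionDefinition")
})

test_that("format errors and unit policy are reported", {
  # well-formed XML that is not SBML
  f <- tempfile(fileext = ".xml")
  writeLines("<html><body>hello</body></html>", f)
  expect_error(read_sbml(f), "root element")
  # not XML at all
  f2 <- tempfile(fileext = ".txt")
  writeLines("just text", f2)
  expect_error(read_sbml(f2), "not parseable XML")
  # missing file
  expect_error(read_sbml(tempfile()), "not found")
  # undeclared units: loud assumption of nM
  f3 <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m">',
    '    <listOfCompartments><compartment id="cytoplasm" size="1"/></listOfCompartments>',
    '    <listOfSpecies><species id="X" compartment="cytoplasm" initialConcentration="2"/></listOfSpecies>',
    '  </model>', '</sbml>'), f3)
  expect_warning(net <- suppressMessages(read_sbml(f3)), "assumed to be nM")
  expect_match(paste(net$metadata$sbml$unresolved, collapse = " "),
               "assumed nM")
  # declared micromolar substance: amounts convert to nM on load
  f4 <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m">',
    '    <listOfUnitDefinitions>',
    '      <unitDefinition id="substance">',
    '        <listOfUnits><unit kind="mole" scale="-6"/></listOfUnits>',
    '      </unitDefinition>',
    '    </listOfUnitDefinitions>',
    '    <listOfCompartments><compartment id="cytoplasm" size="1"/></listOfCompartments>',
    '    <listOfSpecies><species id="X" compartment="cytoplasm" initialConcentration="2"/></listOfSpecies>',
    '  </model>', '</sbml>'), f4)
  net4 <- suppressMessages(read_sbml(f4))
  expect_equal(initial_state(net4)[["X"]], 2000)  # 2 uM = 2000 nM
})

test_that("an independent document interpreter matches internal simulation", {
  # dual-solver oracle: the written document is re-derived by a separate
  # minimal SBML interpreter defined in this file and integrated on its own
  for (net in list(enzyme_network(), build_normal_model())) {
    if (!is.null(net$species[["EGF"]]))
      net <- set_initial(net, "EGF", egf_dose_to_concentration(50))
    f <- tempfile(fileext = ".xml")
    write_sbml(net, f)
    times <- seq(0, 300, by = 5)
    mine <- simulate_network(net, solver_options(rel_tol = 1e-8,
                                                 abs_tol = 1e-10),
                             times = times)
    theirs <- oracle_simulate(f, times)
    # the oracle integrates reactions only; rule-assigned read-out species
    # are outside its scope
    ruled <- vapply(net$rules, `[[`, character(1), "target")
    cols <- setdiff(colnames(mine$values), ruled)
    scale <- max(abs(mine$values[, cols]), 1)
    expect_lt(max(abs(mine$values[, cols] - theirs[, cols])) / scale, 1e-6)
  }
})
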