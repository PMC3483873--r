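test_that("mass-action rates match hand-computed values", {
  irrev <- rate_law("mass_action_irreversible", k1 = 0.003)
  # hand multiplication: 0.003 * 10 * 5 = 0.15
  expect_equal(mass_action_rate(irrev, c(A = 10, B = 5)), 0.003 * 10 * 5)
  expect_equal(mass_action_rate(irrev, c(A = 10, B = 5)), 0.15)
  # empty pool
  expect_identical(mass_action_rate(irrev, c(A = 0, B = 5)), 0)
  # detailed-balance point of a reversible law: k1*[A][B] = kr1*[AB]
  rev <- rate_law("mass_action_reversible", k1 = 0.02, kr1 = 0.1)
  ab <- 0.02 * 4 * 25 / 0.1
  expect_equal(mass_action_rate(rev, c(A = 4, B = 25), c(AB = ab)), 0)
  # stoichiometric powers: 2A -> ... at [A]=3 gives k1*9
  expect_equal(mass_action_rate(irrev, c(A = 3)[c(1, 1)]), 0.003 * 9)
})

test_that("Michaelis-Menten rate is half-maximal exactly at [S] = Km", {
  vlaw <- rate_law("michaelis_menten", Vmax = 7, Km = 40)
  expect_identical(michaelis_menten_rate(vlaw, substrate = 40), 7 / 2)
  expect_identical(michaelis_menten_rate(vlaw, substrate = 0), 0)
  # saturation limit
  expect_equal(michaelis_menten_rate(vlaw, substrate = 1e6 * 40), 7,
               tolerance = 1e-4)
  # enzyme-scaled form: k2 * E * S / (Km + S)
  klaw <- rate_law("michaelis_menten", k2 = 0.5, Km = 40)
  expect_identical(michaelis_menten_rate(klaw, substrate = 40,
                                         enzyme_total = 6), 0.5 * 6 / 2)
})

test_that("rate-law constructor rejects inconsistent definitions", {
  expect_error(rate_law("michaelis_menten", k2 = 1, Km = -5), "Km")
  expect_error(rate_law("mass_action_irreversible"), "k1")
  expect_error(rate_law("nonsense", k1 = 1))
})

test_that("stoichiometry matrix encodes reaction topology", {
  net <- decay_network()
  S <- stoichiometry_matrix(net)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(unname(S[, 1]), c(-1, 1))
  expect_equal(S["S", "r_decay"], -1)
  # catalytic cycle: E column sums to zero across the two reactions
  S2 <- stoichiometry_matrix(enzyme_network())
  expect_equal(sum(S2["E", ]), 0)
  expect_equal(unname(S2[, "r_bind"]),
               unname(c(E = -1, S = -1, ES = 1, P = 0)))
})

test_that("generated derivatives agree with a hand-written RHS", {
  # independent oracle: the enzyme network's ODEs written out by hand
  net <- enzyme_network(kon = 0.01, koff = 1, kcat = 0.1)
  f <- function(t, y) ode_rhs(net, y, t)
  hand <- function(y) {
    v1 <- 0.01 * y[["E"]] * y[["S"]] - 1 * y[["ES"]]
    v2 <- 0.1 * y[["ES"]]
    c(E = -v1 + v2, S = -v1, ES = v1 - v2, P = v2)
  }
  states <- list(c(E = 5, S = 100, ES = 0, P = 0),
                 c(E = 1, S = 3, ES = 7, P = 2),
                 c(E = 0.2, S = 0, ES = 0.5, P = 10))
  for (y in states)
    expect_equal(f(0, y)[names(y)], hand(y), tolerance = 1e-12)
  # all-zero state with no zeroth-order reactions: all derivatives zero
  expect_equal(unname(f(0, c(E = 0, S = 0, ES = 0, P = 0))),
               c(0, 0, 0, 0))
})

test_that("first-order decay derivatives follow the closed form", {
  d <- ode_rhs(decay_network(k1 = 0.1), c(S = 1, P = 0))
  expect_equal(d[["S"]], -0.1)
  expect_equal(d[["P"]], 0.1)
})

test_that("conserved moieties annihilate the stoichiometry matrix", {
  net <- enzyme_network()
  S <- stoichiometry_matrix(net)
  cm <- conserved_moieties(net)
  expect_gte(ncol(cm), 2L)  # enzyme total and substrate total
  # each left null vector is orthogonal to every reaction column
  expect_lt(max(abs(t(cm) %*% S)), 1e-12)
  # derivative weighted by a conserved moiety sums to zero
  d <- ode_rhs(net, c(E = 2, S = 50, ES = 3, P = 1))
  expect_lt(max(abs(t(cm) %*% d)), 1e-12)
})

test_that("network validation counts and flags integrity violations", {
  empty <- reaction_network("empty")
  v <- validate_network(empty)
  expect_true(v$ok)
  expect_equal(unname(v$counts),
               c(0L, 0L, 0L, 0L)[seq_along(v$counts)])
  # a reaction referencing an unknown species is rejected at assembly
  expect_error(reaction_network(
    "bad",
    species = list(species("A", 1, "cytoplasm")),
    reactions = list(reaction("r1", "A", "GHOST",
                              rate_law("mass_action_irreversible", k1 = 1)))),
    "GHOST")
  # ... and reported (never thrown) by validation when it appears later
  bad <- decay_network()
  bad$reactions[[1]]$products <- c(GHOST = 1)
  vb <- validate_network(bad)
  expect_false(vb$ok)
  expect_length(vb$violations, 1L)
  expect_match(vb$violations, "GHOST")
})

test_that("rate constants hoist to namespaced global parameters", {
  net <- enzyme_network(kon = 0.01, koff = 1, kcat = 0.1)
  expect_equal(get_parameter(net, "r_bind_k1"), 0.01)
  expect_equal(get_parameter(net, "r_bind_kr1"), 1)
  expect_equal(get_parameter(net, "r_cat_k1"), 0.1)
  net2 <- set_parameter(net, "r_cat_k1", 0.2)
  expect_equal(get_parameter(net2, "r_cat_k1"), 0.2)
  # the edit reaches the compiled dynamics
  d <- ode_rhs(net2, c(E = 0, S = 0, ES = 1, P = 0))
  expect_equal(d[["P"]], 0.2)
})

test_that("Michaelis-Menten approximates the full mass-action mechanism", {
  # fast binding equilibrium: Km = (koff + kcat) / kon
  kon <- 1; koff <- 100; kcat <- 0.5
  full <- enzyme_network(kon = kon, koff = koff, kcat = kcat,
                         e0 = 2, s0 = 100)
  reduced <- mm_network(kcat = kcat, Km = (koff + kcat) / kon,
                        e0 = 2, s0 = 100)
  opts <- solver_options(t_end = 400, grid_dt = 1, rel_tol = 1e-9,
                         abs_tol = 1e-12)
  pf <- evaluate_observable(simulate_network(full, opts), "P")
  pr <- evaluate_observable(simulate_network(reduced, opts), "P")
  # quasi-steady-state product curves agree within 2% of the final level
  expect_lt(max(abs(pf$value - pr$value)) / max(pf$value), 0.02)
})

test_that("reaction construction enforces the MM substrate contract", {
  mm <- rate_law("michaelis_menten", k2 = 1, Km = 10)
  expect_error(reaction("r", c("A", "B"), "C", mm, modifiers = "E"),
               "substrate")
  expect_error(reaction("r", c(A = 2), "C", mm, modifiers = "E"),
               "substrate")
  expect_error(reaction("r", "A", "C", mm), "modifier|Vmax")
})

test_that("assignment rules evaluate within the compiled system", {
  net <- reaction_network(
    "ruled",
    species = list(species("A", 10, "cytoplasm"),
                   species("Atrack", 0, "cytoplasm")),
    reactions = list(reaction("r_out", "A", character(0),
                              rate_law("mass_action_irreversible",
                                       k1 = 0.1))),
    rules = list(assignment_rule("rule_track", "Atrack",
                                 quote(2 * A))))
  traj <- simulate_network(net, solver_options(t_end = 10, grid_dt = 1))
  expect_equal(traj$values[, "Atrack"], 2 * traj$values[, "A"],
               tolerance = 1e-8)
})
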