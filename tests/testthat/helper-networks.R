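# small synthetic networks shared across test files

# S -> P, first order
decay_network <- function(k1 = 0.01, s0 = 1) {
  reaction_network(
    "decay",
    species = list(species("S", s0, "cytoplasm"),
                   species("P", 0, "cytoplasm")),
    reactions = list(
      reaction("r_decay", "S", "P",
               rate_law("mass_action_irreversible", k1 = k1))))
}

# E + S <-> ES -> E + P, full mass action
enzyme_network <- function(kon = 0.01, koff = 1, kcat = 0.1,
                           e0 = 5, s0 = 100) {
  reaction_network(
    "enzyme",
    species = list(species("E", e0, "cytoplasm"),
                   species("S", s0, "cytoplasm"),
                   species("ES", 0, "cytoplasm"),
                   species("P", 0, "cytoplasm")),
    reactions = list(
      reaction("r_bind", c("E", "S"), "ES",
               rate_law("mass_action_reversible", k1 = kon, kr1 = koff)),
      reaction("r_cat", "ES", c("E", "P"),
               rate_law("mass_action_irreversible", k1 = kcat))))
}

# same catalytic step expressed as a Michaelis-Menten law with E as modifier
mm_network <- function(kcat = 0.1, Km = 110, e0 = 5, s0 = 100) {
  reaction_network(
    "mm",
    species = list(species("E", e0, "cytoplasm"),
                   species("S", s0, "cytoplasm"),
                   species("P", 0, "cytoplasm")),
    reactions = list(
      reaction("r_cat", "S", "P",
               rate_law("michaelis_menten", k2 = kcat, Km = Km),
               modifiers = "E")))
}

# fabricate a trajectory object carrying given series (for feature oracles)
fake_trajectory <- function(times, values_by_species) {
  m <- do.call(cbind, values_by_species)
  colnames(m) <- names(values_by_species)
  structure(list(times = times, values = m, network = NULL,
                 options = NULL, clipped = 0L),
            class = "egfr_trajectory")
}

fast_opts <- function(...) solver_options(grid_dt = 2, ...)
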