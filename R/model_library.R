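#' @name model_library
#' @title EGFR signaling model construction
#' @description
#' Builders for the two cell-state models — a normal cell and an NSCLC cell
#' with mutant (L858R) over-expressed EGFR — and the perturbation variants
#' (PTEN loss, erlotinib). The NSCLC model is derived from the normal model
#' by a recorded set of modifications: EGFR initial concentration x3;
#' Ras, PI3K, Akt and STAT3 initial concentrations x2; EGF-dependent
#' internalization rate constants halved; autophosphorylation slowed by a
#' single fitted scale factor (the mutant receptor's delayed phosphorylation
#' peak).
NULL

#' Molecular weight of EGF in g/mol, used to convert ng/ml doses to nM.
#' @export
EGF_MOLECULAR_WEIGHT <- 6045

SCENARIO_NAMES <- c("normal", "nsclc", "nsclc_pten_loss", "normal_erlotinib",
                    "nsclc_erlotinib", "nsclc_pten_loss_erlotinib")

#' Convert an EGF dose from ng/ml to nM
#'
#' ng/ml equals ug/L; dividing by the molar mass (g/mol) gives umol/L x 1e-3,
#' i.e. `dose * 1000 / MW` nM with MW(EGF) = 6045 g/mol.
#'
#' @param dose EGF dose in ng/ml (non-negative).
#' @return Concentration in nM.
#' @examples
#' egf_dose_to_concentration(50)  # ~8.27 nM
#' @export
egf_dose_to_concentration <- function(dose) {
  if (!is.numeric(dose) || any(dose < 0)) stop("EGF dose must be >= 0 ng/ml")
  dose * 1000 / EGF_MOLECULAR_WEIGHT
}

# Baseline kinetic constants of the fallback normal model. Units: first-order
# s^-1, second-order nM^-1 s^-1, Km nM. Values are fixed by the calibration
# module against the printed kinetic targets (peak times, internalization
# ratio); see the methods vignette for the rationale per block.
normal_kinetics <- function() {
  list(
    # receptor layer (ligand binding near-saturating at 50 ng/ml)
    bind_k1 = 0.1, bind_kr1 = 0.06,
    dimer_k1 = 0.05, dimer_kr1 = 0.02,
    autophos_k1 = 1, rec_dephos_k1 = 0.002,
    int_k1 = 0.02, degrade_k1 = 7.2652337895586858e-05,
    recycle_k1 = 3.6554031060778924e-04,
    # adaptor recruitment (Shc-dependent and direct Grb2 routes)
    grb2_k1 = 0.003, grb2_kr1 = 0.05,
    shc_k1 = 0.006, shc_kr1 = 0.6,
    shc_phos_k1 = 0.6, shc_dephos_k1 = 0.005,
    pshc_grb2_k1 = 0.003, pshc_grb2_kr1 = 0.1,
    sos_k1 = 0.01, sos_kr1 = 0.06,
    # Ras / Raf / MEK / ERK
    ras_act_k2 = 0.02, ras_act_Km = 30,
    ras_gap_k2 = 0.94964439574858917, ras_gap_Km = 1000,
    raf_act_k2 = 0.24593302436832606, raf_act_Km = 1.5327177026130889,
    raf_deact_k2 = 0.041845217264566525, raf_deact_Km = 30,
    mek_phos_k2 = 0.014699391097858535, mek_phos_Km = 30,
    mek_dephos_k2 = 0.72390573830159588, mek_dephos_Km = 30,
    erk_phos_k2 = 0.0046950129672342989, erk_phos_Km = 60,
    erk_dephos_k2 = 0.14745605413179605, erk_dephos_Km = 60,
    sos_fb_k2 = 3.8179493480889021e-05, sos_fb_Km = 200,
    sos_recover_k1 = 0.001,
    # PI3K / Akt
    pi3k_bind_k1 = 0.03, pi3k_bind_kr1 = 0.1, pi3k_act_k1 = 0.2,
    pi3k_deact_k1 = 0.1,
    pip3_prod_k2 = 1.0, pip3_prod_Km = 300,
    pten_k2 = 0.2, pten_Km = 100,
    pdk1_bind_k1 = 0.01, pdk1_bind_kr1 = 0.02,
    akt_phos_k2 = 0.3, akt_phos_Km = 5,
    akt_dephos_k2 = 2.6, akt_dephos_Km = 50,
    # STAT3 (nuclear import through a saturable carrier)
    stat_bind_k1 = 0.005, stat_bind_kr1 = 0.05,
    stat_phos_k1 = 0.1, statc_dephos_k1 = 8e-4,
    stat_dim_k1 = 7.1584481316391325e-04, stat_dim_kr1 = 0.003,
    stat_import_Vmax = 0.010099421297768356, stat_import_Km = 0.2,
    statn_dephos_k1 = 0.0053415679785144441, stat_export_k1 = 0.005
  )
}

# Baseline initial concentrations (nM) of the fallback normal model.
normal_initials <- function() {
  c(EGF = 0, EGFR = 100,
    Grb2 = 80, Shc = 150, SOS = 40, RasGDP = 120, GAP = 10,
    Raf1 = 100, Pase1 = 10, MEK = 120, Pase2 = 2, ERK = 300, Pase3 = 5,
    PI3K = 50, PIP2 = 700, PTEN = 50, PDK1 = 100, Akt = 100, PP2A = 20,
    STAT3c = 200)
}

#' Build the normal-cell EGFR signaling model
#'
#' Instantiates the three-pathway network: a receptor layer (EGF binding,
#' dimerization, autophosphorylation, internalization, recycling and
#' degradation, dephosphorylation); the Ras/ERK branch (Shc-dependent and
#' direct Grb2-SOS recruitment, Ras-GDP to Ras-GTP exchange, Raf1 activation
#' by Ras-GTP, distributive double phosphorylation of MEK and ERK with
#' phosphatase back-reactions, and ERK-level negative feedback on SOS); the
#' PI3K/Akt branch (receptor-driven PI3K activation, PIP2 to PIP3 conversion,
#' PDK1 recruitment by PIP3, Akt phosphorylation, PTEN-catalyzed PIP3 to PIP2
#' back-conversion); and the STAT3 branch (receptor binding, tyrosine
#' phosphorylation, cytoplasmic dimerization, nuclear import, nuclear
#' dephosphorylation and export).
#'
#' When an SBML file is supplied the topology and every constant are taken
#' from it verbatim; otherwise the built-in topology above is instantiated
#' with the package's calibrated constants.
#'
#' @param source Optional path to an SBML file (e.g. a published
#'   supplementary model); parsed with [read_sbml()].
#' @param kinetics Optional named list overriding entries of the built-in
#'   rate-constant set.
#' @param initials Optional named vector overriding built-in initial
#'   concentrations (nM).
#' @return An `egfr_network` for the normal cell.
#' @export
build_normal_model <- function(source = NULL, kinetics = list(),
                               initials = numeric()) {
  if (!is.null(source)) {
    net <- read_sbml(source)
    net$metadata$scenario <- "normal"
    net$metadata$source <- source
    return(net)
  }
  k <- utils::modifyList(normal_kinetics(), as.list(kinetics))
  init <- normal_initials()
  if (length(initials)) init[names(initials)] <- initials
  mem <- function(id, amt = 0) species(id, amt, "membrane")
  cyt <- function(id, amt = 0) species(id, amt, "cytoplasm")
  nuc <- function(id, amt = 0) species(id, amt, "nucleus")
  sp <- list(
    species("EGF", init["EGF"], "extracellular"),
    mem("EGFR", init["EGFR"]), mem("EGF_EGFR"), mem("EGF_EGFR2"),
    mem("pEGF_EGFR2"),
    species("pEGF_EGFR2i", 0, "endosome"), species("EGFRi_deg", 0, "endosome"),
    cyt("Grb2", init["Grb2"]), cyt("Shc", init["Shc"]),
    cyt("SOS", init["SOS"]), cyt("SOSi"),
    mem("R_Grb2"), mem("R_Shc"), mem("R_pShc"), mem("R_pShc_Grb2"),
    mem("R_Grb2_SOS"), mem("R_pShc_Grb2_SOS"),
    mem("RasGDP", init["RasGDP"]), mem("RasGTP"), mem("GAP", init["GAP"]),
    cyt("Raf1", init["Raf1"]), cyt("Raf1active"), cyt("Pase1", init["Pase1"]),
    cyt("MEK", init["MEK"]), cyt("pMEK"), cyt("ppMEK"),
    cyt("Pase2", init["Pase2"]),
    cyt("ERK", init["ERK"]), cyt("pERK"), cyt("ppERK"),
    cyt("Pase3", init["Pase3"]),
    cyt("PI3K", init["PI3K"]), mem("R_PI3K"), cyt("pPI3K"),
    mem("PIP2", init["PIP2"]), mem("PIP3"),
    cyt("PTEN", init["PTEN"]), cyt("PDK1", init["PDK1"]), mem("PIP3_PDK1"),
    cyt("Akt", init["Akt"]), cyt("pAkt"), cyt("PP2A", init["PP2A"]),
    cyt("STAT3c", init["STAT3c"]), mem("R_STAT3"), cyt("pSTAT3c"),
    cyt("pSTAT3c_dim"), nuc("pSTAT3n_dim"), nuc("STAT3n")
  )
  ma <- function(k1) rate_law("mass_action_irreversible", k1 = k1)
  mar <- function(k1, kr1) rate_law("mass_action_reversible", k1 = k1, kr1 = kr1)
  mm <- function(k2, Km) rate_law("michaelis_menten", k2 = k2, Km = Km)
  rx <- list(
    # receptor layer
    reaction("r_bind", c(EGF = 1, EGFR = 1), c(EGF_EGFR = 1),
             mar(k$bind_k1, k$bind_kr1)),
    reaction("r_dimer", c(EGF_EGFR = 2), c(EGF_EGFR2 = 1),
             mar(k$dimer_k1, k$dimer_kr1)),
    reaction("r_autophos", "EGF_EGFR2", "pEGF_EGFR2", ma(k$autophos_k1)),
    reaction("r_rec_dephos", "pEGF_EGFR2", "EGF_EGFR2", ma(k$rec_dephos_k1)),
    # EGF-dependent internalization removes every phosphorylated surface
    # form; receptor-bound partners are released back to the cytoplasm
    reaction("r_int_free", "pEGF_EGFR2", "pEGF_EGFR2i", ma(k$int_k1)),
    reaction("r_int_grb2", c(R_Grb2 = 1), c(pEGF_EGFR2i = 1, Grb2 = 1),
             ma(k$int_k1)),
    reaction("r_int_shc", c(R_Shc = 1), c(pEGF_EGFR2i = 1, Shc = 1),
             ma(k$int_k1)),
    reaction("r_int_pshc", c(R_pShc = 1), c(pEGF_EGFR2i = 1, Shc = 1),
             ma(k$int_k1)),
    reaction("r_int_pshc_grb2", c(R_pShc_Grb2 = 1),
             c(pEGF_EGFR2i = 1, Shc = 1, Grb2 = 1), ma(k$int_k1)),
    reaction("r_int_grb2_sos", c(R_Grb2_SOS = 1),
             c(pEGF_EGFR2i = 1, Grb2 = 1, SOS = 1), ma(k$int_k1)),
    reaction("r_int_pshc_grb2_sos", c(R_pShc_Grb2_SOS = 1),
             c(pEGF_EGFR2i = 1, Shc = 1, Grb2 = 1, SOS = 1), ma(k$int_k1)),
    reaction("r_int_stat3", c(R_STAT3 = 1), c(pEGF_EGFR2i = 1, STAT3c = 1),
             ma(k$int_k1)),
    reaction("r_int_pi3k", c(R_PI3K = 1), c(pEGF_EGFR2i = 1, PI3K = 1),
             ma(k$int_k1)),
    reaction("r_degrade", "pEGF_EGFR2i", "EGFRi_deg", ma(k$degrade_k1)),
    reaction("r_recycle", c(pEGF_EGFR2i = 1), c(EGFR = 2), ma(k$recycle_k1)),
    # adaptor recruitment
    reaction("r_grb2", c(pEGF_EGFR2 = 1, Grb2 = 1), c(R_Grb2 = 1),
             mar(k$grb2_k1, k$grb2_kr1)),
    reaction("r_shc", c(pEGF_EGFR2 = 1, Shc = 1), c(R_Shc = 1),
             mar(k$shc_k1, k$shc_kr1)),
    reaction("r_shc_phos", "R_Shc", "R_pShc", ma(k$shc_phos_k1)),
    reaction("r_shc_dephos", "R_pShc", "R_Shc", ma(k$shc_dephos_k1)),
    reaction("r_pshc_grb2", c(R_pShc = 1, Grb2 = 1), c(R_pShc_Grb2 = 1),
             mar(k$pshc_grb2_k1, k$pshc_grb2_kr1)),
    reaction("r_sos_direct", c(R_Grb2 = 1, SOS = 1), c(R_Grb2_SOS = 1),
             mar(k$sos_k1, k$sos_kr1)),
    reaction("r_sos_shc", c(R_pShc_Grb2 = 1, SOS = 1), c(R_pShc_Grb2_SOS = 1),
             mar(k$sos_k1, k$sos_kr1)),
    # Ras activation by either SOS-bearing complex; GAP back-reaction
    reaction("r_ras_act_direct", "RasGDP", "RasGTP",
             mm(k$ras_act_k2, k$ras_act_Km), modifiers = "R_Grb2_SOS"),
    reaction("r_ras_act_shc", "RasGDP", "RasGTP",
             mm(k$ras_act_k2, k$ras_act_Km), modifiers = "R_pShc_Grb2_SOS"),
    reaction("r_ras_gap", "RasGTP", "RasGDP",
             mm(k$ras_gap_k2, k$ras_gap_Km), modifiers = "GAP"),
    # Raf / MEK / ERK cascade (Ras-GTP treated as the kinase for Raf)
    reaction("r_raf_act", "Raf1", "Raf1active",
             mm(k$raf_act_k2, k$raf_act_Km), modifiers = "RasGTP"),
    reaction("r_raf_deact", "Raf1active", "Raf1",
             mm(k$raf_deact_k2, k$raf_deact_Km), modifiers = "Pase1"),
    reaction("r_mek_phos1", "MEK", "pMEK",
             mm(k$mek_phos_k2, k$mek_phos_Km), modifiers = "Raf1active"),
    reaction("r_mek_phos2", "pMEK", "ppMEK",
             mm(k$mek_phos_k2, k$mek_phos_Km), modifiers = "Raf1active"),
    reaction("r_mek_dephos2", "ppMEK", "pMEK",
             mm(k$mek_dephos_k2, k$mek_dephos_Km), modifiers = "Pase2"),
    reaction("r_mek_dephos1", "pMEK", "MEK",
             mm(k$mek_dephos_k2, k$mek_dephos_Km), modifiers = "Pase2"),
    reaction("r_erk_phos1", "ERK", "pERK",
             mm(k$erk_phos_k2, k$erk_phos_Km), modifiers = "ppMEK"),
    reaction("r_erk_phos2", "pERK", "ppERK",
             mm(k$erk_phos_k2, k$erk_phos_Km), modifiers = "ppMEK"),
    reaction("r_erk_dephos2", "ppERK", "pERK",
             mm(k$erk_dephos_k2, k$erk_dephos_Km), modifiers = "Pase3"),
    reaction("r_erk_dephos1", "pERK", "ERK",
             mm(k$erk_dephos_k2, k$erk_dephos_Km), modifiers = "Pase3"),
    # ERK-level negative feedback on SOS
    reaction("r_sos_fb", "SOS", "SOSi",
             mm(k$sos_fb_k2, k$sos_fb_Km), modifiers = "ppERK"),
    reaction("r_sos_recover", "SOSi", "SOS", ma(k$sos_recover_k1)),
    # PI3K / Akt branch (regulatory-subunit recruitment to the receptor,
    # then release of the activated kinase)
    reaction("r_pi3k_bind", c(pEGF_EGFR2 = 1, PI3K = 1), c(R_PI3K = 1),
             mar(k$pi3k_bind_k1, k$pi3k_bind_kr1)),
    reaction("r_pi3k_act", c(R_PI3K = 1), c(pEGF_EGFR2 = 1, pPI3K = 1),
             ma(k$pi3k_act_k1)),
    reaction("r_pi3k_deact", "pPI3K", "PI3K", ma(k$pi3k_deact_k1)),
    reaction("r_pip3_prod", "PIP2", "PIP3",
             mm(k$pip3_prod_k2, k$pip3_prod_Km), modifiers = "pPI3K"),
    reaction("r_pip3_pten", "PIP3", "PIP2",
             mm(k$pten_k2, k$pten_Km), modifiers = "PTEN"),
    reaction("r_pdk1_bind", c(PIP3 = 1, PDK1 = 1), c(PIP3_PDK1 = 1),
             mar(k$pdk1_bind_k1, k$pdk1_bind_kr1)),
    reaction("r_akt_phos", "Akt", "pAkt",
             mm(k$akt_phos_k2, k$akt_phos_Km), modifiers = "PIP3_PDK1"),
    reaction("r_akt_dephos", "pAkt", "Akt",
             mm(k$akt_dephos_k2, k$akt_dephos_Km), modifiers = "PP2A"),
    # STAT3 branch
    reaction("r_stat_bind", c(pEGF_EGFR2 = 1, STAT3c = 1), c(R_STAT3 = 1),
             mar(k$stat_bind_k1, k$stat_bind_kr1)),
    reaction("r_stat_phos", c(R_STAT3 = 1), c(pEGF_EGFR2 = 1, pSTAT3c = 1),
             ma(k$stat_phos_k1)),
    reaction("r_statc_dephos", "pSTAT3c", "STAT3c", ma(k$statc_dephos_k1)),
    reaction("r_stat_dim", c(pSTAT3c = 2), c(pSTAT3c_dim = 1),
             mar(k$stat_dim_k1, k$stat_dim_kr1)),
    reaction("r_stat_import", "pSTAT3c_dim", "pSTAT3n_dim",
             rate_law("michaelis_menten", Vmax = k$stat_import_Vmax,
                      Km = k$stat_import_Km)),
    reaction("r_statn_dephos", c(pSTAT3n_dim = 1), c(STAT3n = 2),
             ma(k$statn_dephos_k1)),
    reaction("r_stat_export", "STAT3n", "STAT3c", ma(k$stat_export_k1))
  )
  # derived read-out carried as the model's single assignment rule: total
  # autophosphorylated receptor across all surface signaling complexes
  sp <- c(sp, list(mem("active_EGFR_total")))
  rules <- list(assignment_rule(
    "rule_active_EGFR_total", "active_EGFR_total",
    quote(pEGF_EGFR2 + R_Grb2 + R_Shc + R_pShc + R_pShc_Grb2 + R_Grb2_SOS +
            R_pShc_Grb2_SOS + R_STAT3 + R_PI3K)))
  reaction_network("normal", species = sp, reactions = rx, rules = rules,
                   metadata = list(scenario = "normal", source = "built-in",
                                   modifications = list()))
}

record_modification <- function(network, kind, target, factor, label) {
  network$metadata$modifications <-
    c(network$metadata$modifications,
      list(list(kind = kind, target = target, factor = factor, label = label)))
  network
}

scale_initial <- function(network, id, factor, label) {
  if (!id %in% names(network$species))
    stop("construction error: species '", id, "' missing from base model")
  network <- set_initial(network, id,
                         network$species[[id]]$initial_amount * factor)
  record_modification(network, "scale_initial", id, factor, label)
}

scale_parameter_by <- function(network, id, factor, label) {
  if (!id %in% names(network$parameters))
    stop("construction error: parameter '", id, "' missing from base model")
  network <- set_parameter(network, id, network$parameters[[id]] * factor)
  record_modification(network, "scale_parameter", id, factor, label)
}

# Default slowdown of mutant-receptor autophosphorylation. The published
# contrast is qualitative (delayed phosphorylation peak); this single factor
# is the one free knob, fixed by calibration against the peak-delay ordering.
MUTANT_AUTOPHOS_SCALE <- 0.1

#' Derive the NSCLC model from a normal model
#'
#' Applies and records the disease-state modification set: EGFR initial
#' concentration x3 (receptor over-expression); RasGDP, PI3K, Akt and STAT3
#' initial concentrations x2 (expression roughly doubled); every
#' EGF-dependent internalization rate constant halved (wild-type receptors
#' internalize about twice as fast as the L858R mutant); and the
#' autophosphorylation forward constant scaled down by a single factor (the
#' mutant receptor's delayed phosphorylation peak). The scale factor is added
#' as an explicit global parameter, so the NSCLC model carries one parameter
#' more than its base.
#'
#' Applying this builder twice raises an error (guard against double
#' scaling).
#'
#' @param base A normal-cell `egfr_network`.
#' @param mutant_autophos_scale Autophosphorylation slowdown factor in (0, 1].
#' @return The NSCLC `egfr_network`.
#' @export
build_nsclc_model <- function(base, mutant_autophos_scale = MUTANT_AUTOPHOS_SCALE) {
  if (identical(base$metadata$scenario, "nsclc") ||
      any(vapply(base$metadata$modifications, function(m)
        identical(m$label, "nsclc_construction"), logical(1))))
    stop("base network already carries the NSCLC modification set")
  if (mutant_autophos_scale <= 0 || mutant_autophos_scale > 1)
    stop("mutant_autophos_scale must be in (0, 1]")
  net <- base
  net <- scale_initial(net, "EGFR", 3, "nsclc_construction")
  for (id in c("RasGDP", "PI3K", "Akt", "STAT3c"))
    net <- scale_initial(net, id, 2, "nsclc_construction")
  int_params <- grep("^r_int_.*_k1$", names(base$parameters), value = TRUE)
  if (!length(int_params))
    stop("construction error: no EGF-dependent internalization parameters ",
         "(r_int_*_k1) in base model")
  for (id in int_params)
    net <- scale_parameter_by(net, id, 0.5, "nsclc_construction")
  net <- scale_parameter_by(net, "r_autophos_k1", mutant_autophos_scale,
                            "nsclc_construction")
  net$parameters["mutant_autophos_scale"] <- mutant_autophos_scale
  net$name <- "nsclc"
  net$metadata$scenario <- "nsclc"
  net
}

#' Remove PTEN activity from a model
#'
#' Sets the PTEN concentration to zero, so the PTEN-catalyzed PIP3 to PIP2
#' back-conversion carries no flux and the negative control of the PI3K/Akt
#' branch is removed. PIP3 then accumulates monotonically and pAkt no longer
#' decays after its peak.
#'
#' @param network An `egfr_network` containing a `PTEN` species.
#' @return The modified network.
#' @export
apply_pten_loss <- function(network) {
  if (!"PTEN" %in% names(network$species))
    stop("network has no PTEN species")
  if (!any(grepl("pten", names(network$reactions), ignore.case = TRUE)) &&
      !"PTEN" %in% unlist(lapply(network$reactions, `[[`, "modifiers")))
    stop("network has no PTEN-catalyzed reaction")
  network <- set_initial(network, "PTEN", 0)
  network <- record_modification(network, "zero_species", "PTEN", 0,
                                 "pten_loss")
  network$metadata$scenario <- paste0(network$metadata$scenario, "_pten_loss")
  network
}

# Erlotinib reversible-binding kinetics: ATP-site Kd = koff/kon = 100 nM, so
# a 10 umol/L bath leaves ~1% of kinase-competent receptor unbound. The
# published statement is IC50 semantics only; the Kd is fixed by calibration
# so that 10 umol/L suppresses downstream peaks by at least half.
ERLOTINIB_KON <- 0.02
ERLOTINIB_KOFF <- 0.2

#' Add erlotinib to a model
#'
#' Introduces the inhibitor as a clamped bath species at the given dose
#' (converted to nM) together with reversible binding to the
#' kinase-competent receptor forms — the unphosphorylated monomer and the
#' ligand-bound dimer — whose drug-bound complexes cannot autophosphorylate.
#' A dose of zero adds the (empty) species and reactions but leaves the
#' dynamics untouched.
#'
#' @param network An `egfr_network`.
#' @param dose Erlotinib dose in umol/L (>= 0); the published inhibition
#'   scenario uses 10.
#' @return The modified network.
#' @export
apply_erlotinib <- function(network, dose = 10) {
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0)
    stop("erlotinib dose must be a single non-negative number (umol/L)")
  if ("Erlotinib" %in% names(network$species))
    stop("network already contains erlotinib")
  dose_nM <- dose * 1000
  sp <- c(network$species,
          list(Erlotinib = species("Erlotinib", dose_nM, "cytoplasm",
                                   is_constant = TRUE),
               EGFR_Erl = species("EGFR_Erl", 0, "membrane"),
               EGF_EGFR2_Erl = species("EGF_EGFR2_Erl", 0, "membrane")))
  mar <- rate_law("mass_action_reversible", k1 = ERLOTINIB_KON,
                  kr1 = ERLOTINIB_KOFF)
  new_rx <- list(r_erl_monomer = reaction("r_erl_monomer",
                   c(EGFR = 1, Erlotinib = 1), c(EGFR_Erl = 1), mar),
                 r_erl_dimer = reaction("r_erl_dimer",
                   c(EGF_EGFR2 = 1, Erlotinib = 1), c(EGF_EGFR2_Erl = 1), mar))
  # appended in place: re-hoisting all constants would overwrite live
  # parameter values already edited by earlier modifications
  net <- network
  net$species <- sp
  net$reactions <- c(net$reactions, new_rx)
  net$parameters <- c(net$parameters, hoist_parameters(new_rx))
  bad <- integrity_violations(net)
  if (length(bad)) stop("erlotinib overlay: ", paste(bad, collapse = "; "))
  net <- record_modification(net, "add_reaction", "Erlotinib", dose_nM,
                             "erlotinib")
  net$metadata$erlotinib_dose_umol_l <- dose
  net
}

#' Describe a simulation scenario
#'
#' A scenario names one of the study conditions and carries its doses and
#' optional overrides. The EGF stimulus defaults to 50 ng/ml; drug scenarios
#' default to 10 umol/L erlotinib.
#'
#' @param name One of `"normal"`, `"nsclc"`, `"nsclc_pten_loss"`,
#'   `"normal_erlotinib"`, `"nsclc_erlotinib"`,
#'   `"nsclc_pten_loss_erlotinib"`.
#' @param egf_dose EGF dose, ng/ml.
#' @param erlotinib_dose Erlotinib dose, umol/L; defaults to 10 for
#'   `*_erlotinib` scenarios and 0 otherwise.
#' @param overrides Named list of edits applied after construction: names are
#'   species ids (initial concentrations, nM) or parameter ids.
#' @param clamp_egf If `TRUE` (default) the EGF bath is held constant: the
#'   extracellular medium reservoir is orders of magnitude larger than the
#'   cell volume, so a 50 ng/ml stimulus is effectively undepletable. Set to
#'   `FALSE` for a depletable ligand pool.
#' @return An object of class `egfr_scenario`.
#' @export
scenario <- function(name = "normal", egf_dose = 50, erlotinib_dose = NULL,
                     overrides = list(), clamp_egf = TRUE) {
  name <- match.arg(name, SCENARIO_NAMES)
  if (is.null(erlotinib_dose))
    erlotinib_dose <- if (grepl("erlotinib", name)) 10 else 0
  if (egf_dose < 0 || erlotinib_dose < 0) stop("doses must be >= 0")
  structure(list(name = name, egf_dose = egf_dose,
                 erlotinib_dose = erlotinib_dose, overrides = overrides,
                 clamp_egf = isTRUE(clamp_egf)),
            class = "egfr_scenario")
}

#' Build the network for a scenario
#'
#' Chains the model builders according to the scenario name and applies the
#' scenario's doses and overrides: the EGF initial concentration is set from
#' the ng/ml dose, erlotinib scenarios get the drug bath, and PTEN-loss
#' scenarios have PTEN activity removed.
#'
#' @param scn An [scenario()] object (or a scenario name).
#' @param source Optional SBML path forwarded to [build_normal_model()].
#' @return An `egfr_network` ready for [simulate_network()].
#' @export
build_scenario_network <- function(scn = scenario(), source = NULL) {
  if (is.character(scn)) scn <- scenario(scn)
  stopifnot(inherits(scn, "egfr_scenario"))
  net <- build_normal_model(source)
  if (grepl("^nsclc", scn$name)) net <- build_nsclc_model(net)
  if (grepl("pten_loss", scn$name)) net <- apply_pten_loss(net)
  if (grepl("erlotinib", scn$name))
    net <- apply_erlotinib(net, scn$erlotinib_dose)
  net <- set_initial(net, "EGF", egf_dose_to_concentration(scn$egf_dose))
  if (scn$clamp_egf) net$species[["EGF"]]$is_constant <- TRUE
  for (id in names(scn$overrides)) {
    val <- scn$overrides[[id]]
    if (id %in% names(net$species)) net <- set_initial(net, id, val)
    else if (id %in% names(net$parameters)) net <- set_parameter(net, id, val)
    else stop("override targets unknown id '", id, "'")
  }
  net$metadata$scenario_spec <- scn
  net
}
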