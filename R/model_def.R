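# Model definition: species, parameters, reactions, conservation groups,
# readouts. Amount units are molecules/cell for surface and intracellular
# species; extracellular ligand and drugs are clamped concentrations in nM.
# Time unit is minutes throughout.

#' @importFrom stats approx median quantile rnorm rlnorm runif sd cor pt setNames
#' @importFrom utils head modifyList
NULL

# ---- species table -------------------------------------------------------

.species_table <- function() {
  sp <- function(name, compartment, role, initial, clamped = FALSE)
    data.frame(name = name, compartment = compartment, role = role,
               initial = initial, clamped = clamped, stringsAsFactors = FALSE)
  rbind(
    sp("HGF",        "extracellular", "ligand",   0, TRUE),
    sp("Met",        "surface",   "receptor", 23000),
    sp("Itg",        "surface",   "integrin", 96000),
    sp("Met_Itg",    "surface",   "complex",  34000),
    sp("Met_HGF",    "surface",   "complex",  0),
    sp("Met_Itg_HGF","surface",   "complex",  0),
    sp("pMet",       "surface",   "complex",  0),
    sp("pMet_Itg",   "surface",   "complex",  0),
    sp("Met_i",      "endosomal", "receptor", 2500),
    sp("Met_Itg_i",  "endosomal", "complex",  900),
    sp("pMet_i",     "endosomal", "complex",  0),
    sp("pMet_Itg_i", "endosomal", "complex",  0),
    sp("Itg_i",      "endosomal", "integrin", 20000),
    sp("Met_deg",    "endosomal", "receptor", 0),
    sp("Itg_deg",    "endosomal", "integrin", 0),
    sp("Gab1",  "cytosolic", "signaling_inactive", 40000),
    sp("aGab1", "cytosolic", "signaling_active",   0),
    sp("Grb2",  "cytosolic", "signaling_inactive", 100000),
    sp("aGrb2", "cytosolic", "signaling_active",   0),
    sp("PI3K",  "cytosolic", "signaling_inactive", 100000),
    sp("aPI3K", "cytosolic", "signaling_active",   0),
    sp("PIP2",  "cytosolic", "signaling_inactive", 500000),
    sp("PIP3",  "cytosolic", "signaling_active",   0),
    sp("Akt",   "cytosolic", "signaling_inactive", 200000),
    sp("pAkt",  "cytosolic", "signaling_active",   0),
    sp("PDK1",  "cytosolic", "signaling_inactive", 150000),
    sp("aPDK1", "cytosolic", "signaling_active",   0),
    sp("SOS",   "cytosolic", "signaling_inactive", 30000),
    sp("aSOS",  "cytosolic", "signaling_active",   0),
    sp("Ras",   "cytosolic", "signaling_inactive", 200000),
    sp("aRas",  "cytosolic", "signaling_active",   0),
    sp("Raf",   "cytosolic", "signaling_inactive", 40000),
    sp("aRaf",  "cytosolic", "signaling_active",   0),
    sp("MEK",   "cytosolic", "signaling_inactive", 400000),
    sp("pMEK",  "cytosolic", "signaling_active",   0),
    sp("ERK",   "cytosolic", "signaling_inactive", 600000),
    sp("pERK",  "cytosolic", "signaling_active",   0),
    sp("RSK",   "cytosolic", "signaling_inactive", 100000),
    sp("pRSK",  "cytosolic", "signaling_active",   0),
    sp("ppRSK", "cytosolic", "signaling_active",   0),
    sp("AXT050",  "extracellular", "drug", 0, TRUE),
    sp("AXT_Itg", "surface",       "complex", 0),
    sp("Cabo",    "extracellular", "drug", 0, TRUE),
    sp("Met_Cabo","surface",       "complex", 0),
    sp("Rilo",    "extracellular", "drug", 0, TRUE),
    sp("Rilo_HGF","extracellular", "drug", 0, TRUE),
    sp("Sor",     "extracellular", "drug", 0, TRUE),
    sp("Meti_s",  "extracellular", "drug", 0, TRUE),
    sp("PDK1i_s", "extracellular", "drug", 0, TRUE),
    sp("MEKi_s",  "extracellular", "drug", 0, TRUE),
    sp("PI3Ki_s", "extracellular", "drug", 0, TRUE),
    sp("ERKi_s",  "extracellular", "drug", 0, TRUE)
  )
}

# ---- parameter table -----------------------------------------------------
# `free` marks the globally calibrated set (56 parameters).  The 13 fixed
# parameters are literature-style binding constants for ligand and drugs,
# the node-inhibitor strengths fitted in the separate validation step, and
# the ligand unit conversion (mature HGF ~80 kDa: 1 ng/ml = 0.0125 nM).
# Values below are this package's synthetic reference calibration (see the
# methods vignette); they are not a published parameter set.

.parameter_table <- function() {
  pr <- function(name, value, free = TRUE)
    data.frame(name = name, value = value, free = free,
               stringsAsFactors = FALSE)
  tab <- rbind(
    # ligand binding (fixed)
    pr("kon_HGF",      0.12,  FALSE),   # nM^-1 min^-1
    pr("koff_HGF",     0.04,  FALSE),   # min^-1
    # receptor/integrin interaction and trafficking (free)
    pr("kon_MetItg",   2e-05),          # molec^-1 min^-1
    pr("koff_MetItg",  0.2),
    pr("kact_Met",     1.0),
    pr("kdeact_pMet",  0.08),
    pr("kdeact_pMeti", 0.02),
    pr("kint_Met",     0.01),
    pr("kint_pMet",    0.5),
    pr("kint_MetItg",  0.003),
    pr("kint_pMetItg", 0.12),
    pr("kdeg_Meti",    0.06),
    pr("kdeg_MetItgi", 0.008),
    pr("krec_Meti",    0.005),
    pr("krec_MetItgi", 0.1),
    pr("ksyn_Met",     110),            # molecules/cell/min
    pr("kdeg_Met0",    0.0015),
    pr("ksyn_Itg",     380),
    pr("kdeg_Itg0",    0.002),
    pr("kint_Itg",     0.01),
    pr("krec_Itg",     0.04),
    pr("kdeg_Itgi",    0.008),
    # adapter layer
    pr("kact_Gab1",    2e-05),
    pr("kdeact_Gab1",  0.15),
    pr("kact_Grb2",    1e-05),
    pr("kdeact_Grb2",  0.15),
    # PI3K node with feedback inputs
    pr("kact_PI3K",    1e-05),
    pr("kdeact_PI3K",  0.3),
    pr("kbas_PI3K",    0.004),
    pr("kfb_ERK_PI3K", 1e-08),
    pr("kfb_Ras_PI3K", 1.2e-06),
    # lipid second messenger
    pr("kact_PIP2",    2e-06),
    pr("kdeact_PIP3",  0.2),
    # PDK1 / Akt
    pr("kact_PDK1",    2e-06),
    pr("kdeact_PDK1",  0.5),
    pr("kact_Akt",     1e-05),
    pr("kdeact_Akt",   1.0),
    # SOS with RSK negative feedback
    pr("kact_SOS",     2e-05),
    pr("kdeact_SOS",   0.3),
    pr("kbas_SOS",     0.003),
    pr("kfb_RSK_SOS",  2e-04),
    # Ras / Raf with ERK positive feedback and Akt-side suppression
    pr("kact_Ras",     2e-05),
    pr("kdeact_Ras",   0.5),
    pr("kact_Raf",     1e-05),
    pr("kdeact_Raf",   1.0),
    pr("kfb_ERK_Raf",  2e-07),
    pr("kfb_Akt_Raf",  5e-06),
    # MEK with PDK1 crosstalk, ERK, RSK
    pr("kact_MEK",     5e-05),
    pr("kdeact_MEK",   1.5),
    pr("kact_MEK_PDK1",2e-06),
    pr("kact_ERK",     2e-05),
    pr("kdeact_ERK",   0.7),
    pr("kact_RSK",     5e-06),
    pr("kdeact_RSK",   1.0),
    pr("kact_RSK2",    1e-06),
    pr("kdeact_RSK2",  0.5),
    # sorafenib (strength and dose-occupancy scale; calibrated)
    pr("s_Sor",        1.0),
    pr("K_inh_Sor",    200),            # nM
    # drug binding constants and node-inhibitor strengths (fixed)
    pr("kon_AXT",      0.002, FALSE),   # nM^-1 min^-1 (Kd 1 uM)
    pr("koff_AXT",     2.0,   FALSE),
    pr("kon_Cabo",     0.06,  FALSE),   # nM^-1 min^-1 (Kd ~1.3 nM)
    pr("koff_Cabo",    0.078, FALSE),
    pr("Kd_Rilo",      0.2,   FALSE),   # nM
    pr("s_Meti",       0.9,   FALSE),
    pr("s_PDK1i",      0.9,   FALSE),
    pr("s_MEKi",       0.85,  FALSE),
    pr("s_PI3Ki",      0.9,   FALSE),
    pr("s_ERKi",       0.9,   FALSE),
    pr("f_HGF",        0.0125, FALSE)   # nM per ng/ml
  )
  # apply the frozen reference calibration (reference_calibration.R)
  if (exists(".REFERENCE_PARAMS")) {
    v <- .REFERENCE_PARAMS
    tab$value[match(names(v), tab$name)] <- unname(v)
  }
  # calibration bounds: two decades around the reference value
  tab$lower <- tab$value / 100
  tab$upper <- tab$value * 100
  tab
}

# ---- reactions -----------------------------------------------------------
# Declarative reaction list; `rate` is an R expression in species and
# parameter names.  This list is the structural source of truth used by the
# SBML writer, the generic (expression-evaluating) right-hand side, and the
# stoichiometry checks; the fast hand-coded RHS in rhs.R mirrors it and is
# tested for exact agreement.

.reaction_list <- function() {
  rx <- function(id, reactants, products, rate, modifiers = character())
    list(id = id, reactants = reactants, products = products,
         rate = rate, modifiers = modifiers)
  sact <- "(pMet + pMet_Itg + pMet_i + pMet_Itg_i)*(1 - s_Meti*Meti_s)"
  list(
    rx("syn_Met",        c(),                c(Met = 1),          "ksyn_Met"),
    rx("degsurf_Met",    c(Met = 1),         c(Met_deg = 1),      "kdeg_Met0*Met"),
    rx("degsurf_MetItg", c(Met_Itg = 1),     c(Met_deg = 1, Itg = 1),
       "kdeg_Met0*Met_Itg"),
    rx("syn_Itg",        c(),                c(Itg = 1),          "ksyn_Itg"),
    rx("degsurf_Itg",    c(Itg = 1),         c(Itg_deg = 1),      "kdeg_Itg0*Itg"),
    rx("bind_MetItg",    c(Met = 1, Itg = 1),c(Met_Itg = 1),      "kon_MetItg*Met*Itg"),
    rx("unbind_MetItg",  c(Met_Itg = 1),     c(Met = 1, Itg = 1), "koff_MetItg*Met_Itg"),
    rx("bind_HGF_Met",   c(Met = 1),         c(Met_HGF = 1),      "kon_HGF*HGF*Met", "HGF"),
    rx("unbind_HGF_Met", c(Met_HGF = 1),     c(Met = 1),          "koff_HGF*Met_HGF"),
    rx("bind_HGF_MetItg",c(Met_Itg = 1),     c(Met_Itg_HGF = 1),  "kon_HGF*HGF*Met_Itg", "HGF"),
    rx("unbind_HGF_MetItg", c(Met_Itg_HGF = 1), c(Met_Itg = 1),   "koff_HGF*Met_Itg_HGF"),
    rx("bind_MetHGF_Itg",c(Met_HGF = 1, Itg = 1), c(Met_Itg_HGF = 1), "kon_MetItg*Met_HGF*Itg"),
    rx("unbind_MetItgHGF", c(Met_Itg_HGF = 1), c(Met_HGF = 1, Itg = 1), "koff_MetItg*Met_Itg_HGF"),
    rx("act_Met",        c(Met_HGF = 1),     c(pMet = 1),         "kact_Met*Met_HGF"),
    rx("act_MetItg",     c(Met_Itg_HGF = 1), c(pMet_Itg = 1),     "kact_Met*Met_Itg_HGF"),
    rx("deact_pMet",     c(pMet = 1),        c(Met = 1),          "kdeact_pMet*pMet"),
    rx("deact_pMetItg",  c(pMet_Itg = 1),    c(Met_Itg = 1),      "kdeact_pMet*pMet_Itg"),
    rx("int_Met",        c(Met = 1),         c(Met_i = 1),        "kint_Met*Met"),
    rx("int_pMet",       c(pMet = 1),        c(pMet_i = 1),       "kint_pMet*pMet"),
    rx("int_MetItg",     c(Met_Itg = 1),     c(Met_Itg_i = 1),    "kint_MetItg*Met_Itg"),
    rx("int_pMetItg",    c(pMet_Itg = 1),    c(pMet_Itg_i = 1),   "kint_pMetItg*pMet_Itg"),
    rx("deact_pMet_i",   c(pMet_i = 1),      c(Met_i = 1),        "kdeact_pMeti*pMet_i"),
    rx("deact_pMetItg_i",c(pMet_Itg_i = 1),  c(Met_Itg_i = 1),    "kdeact_pMeti*pMet_Itg_i"),
    rx("deg_Met_i",      c(Met_i = 1),       c(Met_deg = 1),      "kdeg_Meti*Met_i"),
    rx("deg_pMet_i",     c(pMet_i = 1),      c(Met_deg = 1),      "kdeg_Meti*pMet_i"),
    rx("deg_MetItg_i",   c(Met_Itg_i = 1),   c(Met_deg = 1, Itg_deg = 1), "kdeg_MetItgi*Met_Itg_i"),
    rx("deg_pMetItg_i",  c(pMet_Itg_i = 1),  c(Met_deg = 1, Itg_deg = 1), "kdeg_MetItgi*pMet_Itg_i"),
    rx("rec_Met_i",      c(Met_i = 1),       c(Met = 1),          "krec_Meti*Met_i"),
    rx("rec_pMet_i",     c(pMet_i = 1),      c(pMet = 1),         "krec_Meti*pMet_i"),
    rx("rec_MetItg_i",   c(Met_Itg_i = 1),   c(Met_Itg = 1),      "krec_MetItgi*Met_Itg_i"),
    rx("rec_pMetItg_i",  c(pMet_Itg_i = 1),  c(pMet_Itg = 1),     "krec_MetItgi*pMet_Itg_i"),
    rx("int_Itg",        c(Itg = 1),         c(Itg_i = 1),        "kint_Itg*Itg"),
    rx("rec_Itg",        c(Itg_i = 1),       c(Itg = 1),          "krec_Itg*Itg_i"),
    rx("deg_Itg_i",      c(Itg_i = 1),       c(Itg_deg = 1),      "kdeg_Itgi*Itg_i"),
    rx("bind_AXT_Itg",   c(Itg = 1),         c(AXT_Itg = 1),      "kon_AXT*AXT050*Itg", "AXT050"),
    rx("unbind_AXT_Itg", c(AXT_Itg = 1),     c(Itg = 1),          "koff_AXT*AXT_Itg"),
    rx("bind_Cabo_Met",  c(Met = 1),         c(Met_Cabo = 1),     "kon_Cabo*Cabo*Met", "Cabo"),
    rx("unbind_Cabo_Met",c(Met_Cabo = 1),    c(Met = 1),          "koff_Cabo*Met_Cabo"),
    # the ATP-competitive inhibitor reaches integrin-bound Met too; the
    # drug-bound receptor does not hold the heterodimer together
    rx("bind_Cabo_MetItg", c(Met_Itg = 1),   c(Met_Cabo = 1, Itg = 1),
       "kon_Cabo*Cabo*Met_Itg", "Cabo"),
    rx("deg_Met_Cabo",   c(Met_Cabo = 1),    c(Met_deg = 1),      "kdeg_Met0*Met_Cabo"),
    rx("act_Gab1",  c(Gab1 = 1),  c(aGab1 = 1),
       paste0("kact_Gab1*Gab1*", sact),
       c("pMet", "pMet_Itg", "pMet_i", "pMet_Itg_i", "Meti_s")),
    rx("deact_Gab1", c(aGab1 = 1), c(Gab1 = 1), "kdeact_Gab1*aGab1"),
    rx("act_Grb2",  c(Grb2 = 1),  c(aGrb2 = 1),
       paste0("kact_Grb2*Grb2*", sact),
       c("pMet", "pMet_Itg", "pMet_i", "pMet_Itg_i", "Meti_s")),
    rx("deact_Grb2", c(aGrb2 = 1), c(Grb2 = 1), "kdeact_Grb2*aGrb2"),
    rx("act_PI3K",  c(PI3K = 1),  c(aPI3K = 1),
       "(kact_PI3K*aGab1 + kbas_PI3K + kfb_ERK_PI3K*pERK*(1 - s_ERKi*ERKi_s) + kfb_Ras_PI3K*aRas)*PI3K",
       c("aGab1", "pERK", "aRas", "ERKi_s")),
    rx("deact_PI3K", c(aPI3K = 1), c(PI3K = 1), "kdeact_PI3K*aPI3K"),
    rx("act_PIP2",  c(PIP2 = 1),  c(PIP3 = 1),
       "kact_PIP2*PIP2*aPI3K*(1 - s_PI3Ki*PI3Ki_s)", c("aPI3K", "PI3Ki_s")),
    rx("deact_PIP3", c(PIP3 = 1), c(PIP2 = 1), "kdeact_PIP3*PIP3"),
    rx("act_PDK1",  c(PDK1 = 1),  c(aPDK1 = 1), "kact_PDK1*PDK1*PIP3", "PIP3"),
    rx("deact_PDK1", c(aPDK1 = 1), c(PDK1 = 1), "kdeact_PDK1*aPDK1"),
    rx("act_Akt",   c(Akt = 1),   c(pAkt = 1),
       "kact_Akt*Akt*aPDK1*(1 - s_PDK1i*PDK1i_s)", c("aPDK1", "PDK1i_s")),
    rx("deact_Akt", c(pAkt = 1),  c(Akt = 1), "kdeact_Akt*pAkt"),
    rx("act_SOS",   c(SOS = 1),   c(aSOS = 1),
       "(kact_SOS*aGrb2 + kbas_SOS)*SOS/(1 + kfb_RSK_SOS*ppRSK)",
       c("aGrb2", "ppRSK")),
    rx("deact_SOS", c(aSOS = 1),  c(SOS = 1), "kdeact_SOS*aSOS"),
    rx("act_Ras",   c(Ras = 1),   c(aRas = 1), "kact_Ras*Ras*aSOS", "aSOS"),
    rx("deact_Ras", c(aRas = 1),  c(Ras = 1), "kdeact_Ras*aRas"),
    rx("act_Raf",   c(Raf = 1),   c(aRaf = 1),
       "kact_Raf*Raf*aRas*(1 + kfb_ERK_Raf*pERK*(1 - s_ERKi*ERKi_s))/(1 + kfb_Akt_Raf*pAkt)",
       c("aRas", "pERK", "pAkt", "ERKi_s")),
    rx("deact_Raf", c(aRaf = 1),  c(Raf = 1), "kdeact_Raf*aRaf"),
    rx("act_MEK",   c(MEK = 1),   c(pMEK = 1),
       "(kact_MEK*aRaf*(1 - s_Sor*Sor/(Sor + K_inh_Sor)) + kact_MEK_PDK1*aPDK1*(1 - s_PDK1i*PDK1i_s))*MEK",
       c("aRaf", "aPDK1", "Sor", "PDK1i_s")),
    rx("deact_MEK", c(pMEK = 1),  c(MEK = 1), "kdeact_MEK*pMEK"),
    rx("act_ERK",   c(ERK = 1),   c(pERK = 1),
       "kact_ERK*ERK*pMEK*(1 - s_MEKi*MEKi_s)", c("pMEK", "MEKi_s")),
    rx("deact_ERK", c(pERK = 1),  c(ERK = 1), "kdeact_ERK*pERK"),
    rx("act_RSK",   c(RSK = 1),   c(pRSK = 1),
       "kact_RSK*RSK*pERK*(1 - s_ERKi*ERKi_s)", c("pERK", "ERKi_s")),
    rx("deact_RSK", c(pRSK = 1),  c(RSK = 1), "kdeact_RSK*pRSK"),
    rx("act_RSK2",  c(pRSK = 1),  c(ppRSK = 1),
       "kact_RSK2*pRSK*pERK*(1 - s_ERKi*ERKi_s)", c("pERK", "ERKi_s")),
    rx("deact_RSK2", c(ppRSK = 1), c(pRSK = 1), "kdeact_RSK2*ppRSK")
  )
}

# ---- conservation groups and readouts ------------------------------------

.conservation_groups <- function() {
  list(
    Gab1 = c("Gab1", "aGab1"),
    Grb2 = c("Grb2", "aGrb2"),
    PI3K = c("PI3K", "aPI3K"),
    PIP  = c("PIP2", "PIP3"),
    Akt  = c("Akt", "pAkt"),
    PDK1 = c("PDK1", "aPDK1"),
    SOS  = c("SOS", "aSOS"),
    Ras  = c("Ras", "aRas"),
    Raf  = c("Raf", "aRaf"),
    MEK  = c("MEK", "pMEK"),
    ERK  = c("ERK", "pERK"),
    RSK  = c("RSK", "pRSK", "ppRSK")
  )
}

.readout_defs <- function() {
  list(
    pAkt          = "pAkt",
    pERK          = "pERK",
    pMEK          = "pMEK",
    pRSK          = "pRSK",
    ppRSK         = "ppRSK",
    pMet_surface  = c("pMet", "pMet_Itg"),
    pMet_internal = c("pMet_i", "pMet_Itg_i"),
    pMet_total    = c("pMet", "pMet_Itg", "pMet_i", "pMet_Itg_i")
  )
}

# species whose amounts count toward each Met / Itg receptor pool (the
# degraded sinks are excluded; used for internalized-fraction readouts)
.met_pools <- function() {
  list(
    surface  = c("Met", "Met_Itg", "Met_HGF", "Met_Itg_HGF", "pMet",
                 "pMet_Itg", "Met_Cabo"),
    internal = c("Met_i", "Met_Itg_i", "pMet_i", "pMet_Itg_i")
  )
}

# proteins addressable by virtual-patient fold-change scaling; value is
# either a conservation group (total abundance scaled) or a synthesis rate
.scalable_proteins <- function() {
  c(.conservation_groups()[c("Gab1", "Grb2", "PI3K", "Akt", "PDK1", "SOS",
                             "Ras", "Raf", "MEK", "ERK", "RSK")],
    list(Met = "ksyn_Met", Itg = "ksyn_Itg"))
}

#' Build the reference HGF/Met pathway model
#'
#' Constructs the full reaction network: HGF binding to Met and to the
#' Met/alpha5beta1-integrin heterodimer, receptor activation (independent of
#' integrin binding), trafficking with integrin-dependent internalization,
#' degradation and recycling rates, and the downstream Akt and ERK cascades
#' with RSK-to-SOS negative feedback, ERK-to-Raf positive feedback,
#' PDK1-to-MEK crosstalk, ERK- and Ras-driven PI3K activation, and
#' Akt-side suppression of Raf.  Drug species for the integrin-binding
#' peptide AXT050, cabozantinib, rilotumumab, sorafenib, and the
#' calibration-time node inhibitors are part of the network.
#'
#' The parameterization is this package's synthetic reference calibration:
#' abundances are order-of-magnitude hepatocyte estimates and rate constants
#' were calibrated against the published anchor measurements (50% receptor
#' internalization at 15 min; dominant endosomal phospho-receptor at steady
#' state; sorafenib dose response).  The model has 52 species and 69
#' parameters of which 56 are free (subject to global calibration).
#'
#' @param parameters optional named numeric vector overriding reference
#'   parameter values.
#' @return an object of class `pathway_model`.
#' @export
build_reference_model <- function(parameters = NULL) {
  species <- .species_table()
  if (exists(".REFERENCE_INITIAL")) {
    v <- .REFERENCE_INITIAL
    species$initial[match(names(v), species$name)] <- unname(v)
  }
  params <- .parameter_table()
  if (!is.null(parameters)) {
    unknown <- setdiff(names(parameters), params$name)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    params$value[match(names(parameters), params$name)] <- unname(parameters)
  }
  model <- structure(list(
    species = species,
    parameters = params,
    reactions = .reaction_list(),
    groups = .conservation_groups(),
    readouts = .readout_defs(),
    met_pools = .met_pools(),
    scalable = .scalable_proteins(),
    cache = new.env(parent = emptyenv())
  ), class = "pathway_model")
  validate_model(model)
  model
}

#' Validate the structural consistency of a pathway model
#'
#' Checks that species names are unique, all rate-law symbols resolve to a
#' species or parameter, reaction stoichiometry leaves every conservation
#' group invariant, and readouts reference existing species.
#'
#' @param model a `pathway_model`.
#' @return the model, invisibly; signals an error naming the offending
#'   entity otherwise.
#' @export
validate_model <- function(model) {
  sp <- model$species
  if (anyDuplicated(sp$name))
    stop("duplicate species name: ", sp$name[duplicated(sp$name)][1])
  if (any(sp$initial < 0))
    stop("negative initial amount for species: ",
         sp$name[sp$initial < 0][1])
  known <- c(sp$name, model$parameters$name)
  smat <- stoichiometry_matrix(model)
  for (r in model$reactions) {
    syms <- all.vars(str2lang(r$rate))
    bad <- setdiff(syms, known)
    if (length(bad))
      stop("reaction '", r$id, "' references unknown symbol: ",
           paste(bad, collapse = ", "))
    for (nm in c(names(r$reactants), names(r$products)))
      if (!nm %in% sp$name)
        stop("reaction '", r$id, "' references unknown species: ", nm)
  }
  for (g in names(model$groups)) {
    mem <- model$groups[[g]]
    bad <- setdiff(mem, sp$name)
    if (length(bad))
      stop("conservation group '", g, "' references unknown species: ",
           paste(bad, collapse = ", "))
    net <- colSums(smat[mem, , drop = FALSE])
    if (any(abs(net) > 0))
      stop("conservation group '", g, "' is not conserved by reaction: ",
           colnames(smat)[which(abs(net) > 0)][1])
  }
  for (rd in names(model$readouts)) {
    bad <- setdiff(model$readouts[[rd]], sp$name)
    if (length(bad))
      stop("readout '", rd, "' references unknown species: ",
           paste(bad, collapse = ", "))
  }
  invisible(model)
}

#' Stoichiometry matrix of a model
#'
#' @param model a `pathway_model`.
#' @return numeric matrix, species x reactions.
#' @export
stoichiometry_matrix <- function(model) {
  sp <- model$species$name
  smat <- matrix(0, length(sp), length(model$reactions),
                 dimnames = list(sp, vapply(model$reactions, `[[`, "", "id")))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (nm in names(r$reactants))
      smat[nm, j] <- smat[nm, j] - r$reactants[[nm]]
    for (nm in names(r$products))
      smat[nm, j] <- smat[nm, j] + r$products[[nm]]
  }
  smat
}

#' Named vector of model parameter values
#' @param model a `pathway_model`.
#' @return named numeric vector.
#' @export
model_params <- function(model)
  setNames(model$parameters$value, model$parameters$name)

#' Replace parameter values in a model
#'
#' @param model a `pathway_model`.
#' @param values named numeric vector of replacement values.
#' @return the modified model (caches invalidated).
#' @export
set_params <- function(model, values) {
  idx <- match(names(values), model$parameters$name)
  if (anyNA(idx))
    stop("unknown parameter(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "))
  model$parameters$value[idx] <- unname(values)
  model$cache <- new.env(parent = emptyenv())
  model
}

#' Replace initial amounts in a model
#' @param model a `pathway_model`.
#' @param values named numeric vector of initial amounts.
#' @return the modified model.
#' @export
set_initial <- function(model, values) {
  idx <- match(names(values), model$species$name)
  if (anyNA(idx))
    stop("unknown species: ",
         paste(names(values)[is.na(idx)], collapse = ", "))
  model$species$initial[idx] <- unname(values)
  model$cache <- new.env(parent = emptyenv())
  model
}

#' @export
print.pathway_model <- function(x, ...) {
  cat("HGF/Met pathway model:", nrow(x$species), "species,",
      nrow(x$parameters), "parameters (", sum(x$parameters$free),
      "free ),", length(x$reactions), "reactions\n")
  invisible(x)
}
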