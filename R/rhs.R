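# Derivative evaluation.  Two routes:
#  * make_rhs(): fast hand-coded derivatives for the reference network,
#    with parameters resolved into the closure once per simulation;
#  * make_generic_rhs(): evaluates the declarative rate-law expressions and
#    applies the stoichiometry matrix.  Works for any model (including
#    imported SBML) and serves as the structural oracle for the fast path.

# species index constants for the reference network (order of .species_table)
.SPI <- c(
  HGF = 1L, Met = 2L, Itg = 3L, Met_Itg = 4L, Met_HGF = 5L,
  Met_Itg_HGF = 6L, pMet = 7L, pMet_Itg = 8L, Met_i = 9L, Met_Itg_i = 10L,
  pMet_i = 11L, pMet_Itg_i = 12L, Itg_i = 13L, Met_deg = 14L, Itg_deg = 15L,
  Gab1 = 16L, aGab1 = 17L, Grb2 = 18L, aGrb2 = 19L, PI3K = 20L, aPI3K = 21L,
  PIP2 = 22L, PIP3 = 23L, Akt = 24L, pAkt = 25L, PDK1 = 26L, aPDK1 = 27L,
  SOS = 28L, aSOS = 29L, Ras = 30L, aRas = 31L, Raf = 32L, aRaf = 33L,
  MEK = 34L, pMEK = 35L, ERK = 36L, pERK = 37L, RSK = 38L, pRSK = 39L,
  ppRSK = 40L, AXT050 = 41L, AXT_Itg = 42L, Cabo = 43L, Met_Cabo = 44L,
  Rilo = 45L, Rilo_HGF = 46L, Sor = 47L, Meti_s = 48L, PDK1i_s = 49L,
  MEKi_s = 50L, PI3Ki_s = 51L, ERKi_s = 52L)

# TRUE when the model's species set matches the native reference layout
.is_native <- function(model) {
  identical(model$species$name, names(.SPI)) &&
    identical(sort(model$parameters$name), sort(.parameter_table()$name))
}

#' Build the fast derivative function for the reference network
#'
#' Returns `function(t, y, ...)` in the form deSolve expects.  Clamped
#' (boundary) species have zero derivatives.
#'
#' @param model a `pathway_model` with the native reference structure.
#' @return derivative function.
#' @keywords internal
make_rhs <- function(model) {
  p <- as.list(model_params(model))
  clamped <- which(model$species$clamped)
  with(p, {
    function(t, y, ...) {
      d <- numeric(52L)
      HGF <- y[1L]; Met <- y[2L]; Itg <- y[3L]; Met_Itg <- y[4L]
      Met_HGF <- y[5L]; Met_Itg_HGF <- y[6L]; pMet <- y[7L]
      pMet_Itg <- y[8L]; Met_i <- y[9L]; Met_Itg_i <- y[10L]
      pMet_i <- y[11L]; pMet_Itg_i <- y[12L]; Itg_i <- y[13L]
      Gab1 <- y[16L]; aGab1 <- y[17L]; Grb2 <- y[18L]; aGrb2 <- y[19L]
      PI3K <- y[20L]; aPI3K <- y[21L]; PIP2 <- y[22L]; PIP3 <- y[23L]
      Akt <- y[24L]; pAkt <- y[25L]; PDK1 <- y[26L]; aPDK1 <- y[27L]
      SOS <- y[28L]; aSOS <- y[29L]; Ras <- y[30L]; aRas <- y[31L]
      Raf <- y[32L]; aRaf <- y[33L]; MEK <- y[34L]; pMEK <- y[35L]
      ERK <- y[36L]; pERK <- y[37L]; RSK <- y[38L]; pRSK <- y[39L]
      ppRSK <- y[40L]; AXT050 <- y[41L]; AXT_Itg <- y[42L]; Cabo <- y[43L]
      Met_Cabo <- y[44L]; Sor <- y[47L]; Meti_s <- y[48L]; PDK1i_s <- y[49L]
      MEKi_s <- y[50L]; PI3Ki_s <- y[51L]; ERKi_s <- y[52L]

      fMet  <- 1 - s_Meti * Meti_s
      fPDK1 <- 1 - s_PDK1i * PDK1i_s
      fMEK  <- 1 - s_MEKi * MEKi_s
      fPI3K <- 1 - s_PI3Ki * PI3Ki_s
      fERK  <- 1 - s_ERKi * ERKi_s
      fRaf  <- 1 - s_Sor * Sor / (Sor + K_inh_Sor)
      Sact  <- (pMet + pMet_Itg + pMet_i + pMet_Itg_i) * fMet

      v_bind_MI   <- kon_MetItg * Met * Itg - koff_MetItg * Met_Itg
      v_bind_HM   <- kon_HGF * HGF * Met - koff_HGF * Met_HGF
      v_bind_HMI  <- kon_HGF * HGF * Met_Itg - koff_HGF * Met_Itg_HGF
      v_bind_MHI  <- kon_MetItg * Met_HGF * Itg - koff_MetItg * Met_Itg_HGF
      v_act_M     <- kact_Met * Met_HGF
      v_act_MI    <- kact_Met * Met_Itg_HGF
      v_dea_pM    <- kdeact_pMet * pMet
      v_dea_pMI   <- kdeact_pMet * pMet_Itg
      v_int_M     <- kint_Met * Met
      v_int_pM    <- kint_pMet * pMet
      v_int_MI    <- kint_MetItg * Met_Itg
      v_int_pMI   <- kint_pMetItg * pMet_Itg
      v_dea_pMi   <- kdeact_pMeti * pMet_i
      v_dea_pMIi  <- kdeact_pMeti * pMet_Itg_i
      v_deg_Mi    <- kdeg_Meti * Met_i
      v_deg_pMi   <- kdeg_Meti * pMet_i
      v_deg_MIi   <- kdeg_MetItgi * Met_Itg_i
      v_deg_pMIi  <- kdeg_MetItgi * pMet_Itg_i
      v_rec_Mi    <- krec_Meti * Met_i
      v_rec_pMi   <- krec_Meti * pMet_i
      v_rec_MIi   <- krec_MetItgi * Met_Itg_i
      v_rec_pMIi  <- krec_MetItgi * pMet_Itg_i
      v_int_I     <- kint_Itg * Itg
      v_rec_I     <- krec_Itg * Itg_i
      v_deg_Ii    <- kdeg_Itgi * Itg_i
      v_axt       <- kon_AXT * AXT050 * Itg - koff_AXT * AXT_Itg
      v_cabo      <- kon_Cabo * Cabo * Met - koff_Cabo * Met_Cabo
      v_caboI     <- kon_Cabo * Cabo * Met_Itg
      v_deg0_MI   <- kdeg_Met0 * Met_Itg

      d[2L] <- ksyn_Met - kdeg_Met0 * Met - v_bind_MI - v_bind_HM -
        v_int_M + v_dea_pM + v_rec_Mi - v_cabo
      d[3L] <- ksyn_Itg - kdeg_Itg0 * Itg - v_bind_MI - v_bind_MHI -
        v_int_I + v_rec_I - v_axt + v_caboI + v_deg0_MI
      d[4L] <- v_bind_MI - v_bind_HMI + v_dea_pMI - v_int_MI + v_rec_MIi -
        v_caboI - v_deg0_MI
      d[5L] <- v_bind_HM - v_bind_MHI - v_act_M
      d[6L] <- v_bind_HMI + v_bind_MHI - v_act_MI
      d[7L] <- v_act_M - v_dea_pM - v_int_pM + v_rec_pMi
      d[8L] <- v_act_MI - v_dea_pMI - v_int_pMI + v_rec_pMIi
      d[9L] <- v_int_M + v_dea_pMi - v_deg_Mi - v_rec_Mi
      d[10L] <- v_int_MI + v_dea_pMIi - v_deg_MIi - v_rec_MIi
      d[11L] <- v_int_pM - v_dea_pMi - v_deg_pMi - v_rec_pMi
      d[12L] <- v_int_pMI - v_dea_pMIi - v_deg_pMIi - v_rec_pMIi
      d[13L] <- v_int_I - v_rec_I - v_deg_Ii
      d[14L] <- kdeg_Met0 * Met + v_deg0_MI + v_deg_Mi + v_deg_pMi +
        v_deg_MIi + v_deg_pMIi + kdeg_Met0 * Met_Cabo
      d[15L] <- kdeg_Itg0 * Itg + v_deg_MIi + v_deg_pMIi + v_deg_Ii
      d[42L] <- v_axt
      d[44L] <- v_cabo + v_caboI - kdeg_Met0 * Met_Cabo

      v_Gab1 <- kact_Gab1 * Gab1 * Sact - kdeact_Gab1 * aGab1
      v_Grb2 <- kact_Grb2 * Grb2 * Sact - kdeact_Grb2 * aGrb2
      v_PI3K <- (kact_PI3K * aGab1 + kbas_PI3K +
                   kfb_ERK_PI3K * pERK * fERK +
                   kfb_Ras_PI3K * aRas) * PI3K - kdeact_PI3K * aPI3K
      v_PIP  <- kact_PIP2 * PIP2 * aPI3K * fPI3K - kdeact_PIP3 * PIP3
      v_PDK1 <- kact_PDK1 * PDK1 * PIP3 - kdeact_PDK1 * aPDK1
      v_Akt  <- kact_Akt * Akt * aPDK1 * fPDK1 - kdeact_Akt * pAkt
      v_SOS  <- (kact_SOS * aGrb2 + kbas_SOS) * SOS /
        (1 + kfb_RSK_SOS * ppRSK) - kdeact_SOS * aSOS
      v_Ras  <- kact_Ras * Ras * aSOS - kdeact_Ras * aRas
      v_Raf  <- kact_Raf * Raf * aRas *
        (1 + kfb_ERK_Raf * pERK * fERK) / (1 + kfb_Akt_Raf * pAkt) -
        kdeact_Raf * aRaf
      v_MEK  <- (kact_MEK * aRaf * fRaf +
                   kact_MEK_PDK1 * aPDK1 * fPDK1) * MEK - kdeact_MEK * pMEK
      v_ERK  <- kact_ERK * ERK * pMEK * fMEK - kdeact_ERK * pERK
      v_RSK  <- kact_RSK * RSK * pERK * fERK - kdeact_RSK * pRSK
      v_RSK2 <- kact_RSK2 * pRSK * pERK * fERK - kdeact_RSK2 * ppRSK

      d[16L] <- -v_Gab1;  d[17L] <- v_Gab1
      d[18L] <- -v_Grb2;  d[19L] <- v_Grb2
      d[20L] <- -v_PI3K;  d[21L] <- v_PI3K
      d[22L] <- -v_PIP;   d[23L] <- v_PIP
      d[24L] <- -v_Akt;   d[25L] <- v_Akt
      d[26L] <- -v_PDK1;  d[27L] <- v_PDK1
      d[28L] <- -v_SOS;   d[29L] <- v_SOS
      d[30L] <- -v_Ras;   d[31L] <- v_Ras
      d[32L] <- -v_Raf;   d[33L] <- v_Raf
      d[34L] <- -v_MEK;   d[35L] <- v_MEK
      d[36L] <- -v_ERK;   d[37L] <- v_ERK
      d[38L] <- -v_RSK
      d[39L] <- v_RSK - v_RSK2
      d[40L] <- v_RSK2

      d[clamped] <- 0
      list(d)
    }
  })
}

#' Build a generic derivative function from declarative rate laws
#'
#' Evaluates every reaction's rate expression in an environment holding the
#' current state and the parameter values, then applies the stoichiometry
#' matrix.  Slower than [make_rhs()] but valid for any `pathway_model`,
#' including models imported from SBML.
#'
#' @param model a `pathway_model`.
#' @return derivative function `function(t, y, ...)`.
#' @keywords internal
make_generic_rhs <- function(model) {
  smat <- stoichiometry_matrix(model)
  exprs <- lapply(model$reactions, function(r) str2lang(r$rate))
  pars <- as.list(model_params(model))
  spnames <- model$species$name
  clamped <- which(model$species$clamped)
  env <- list2env(pars, parent = baseenv())
  function(t, y, ...) {
    for (i in seq_along(spnames)) assign(spnames[i], y[i], envir = env)
    v <- vapply(exprs, eval, 0, envir = env)
    if (any(!is.finite(v)))
      stop("non-finite rate in reaction '",
           model$reactions[[which(!is.finite(v))[1]]]$id, "'")
    d <- as.numeric(smat %*% v)
    d[clamped] <- 0
    list(d)
  }
}

#' Evaluate the model derivative at a state
#'
#' @param model a `pathway_model`.
#' @param state named (or model-ordered) numeric vector of species amounts.
#' @param t time in minutes (the system is autonomous; included for
#'   interface completeness).
#' @param fast use the hand-coded path when the model is the native
#'   reference network.
#' @return named derivative vector d(state)/dt.
#' @export
derivatives <- function(model, state, t = 0, fast = TRUE) {
  if (length(state) != nrow(model$species))
    stop("state length ", length(state), " != species count ",
         nrow(model$species))
  if (!is.null(names(state)))
    state <- state[model$species$name]
  if (any(state < 0))
    stop("negative species amount in state")
  f <- if (fast && .is_native(model)) make_rhs(model) else
    make_generic_rhs(model)
  d <- f(t, as.numeric(state))[[1]]
  if (any(!is.finite(d)))
    stop("non-finite derivative")
  setNames(d, model$species$name)
}
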