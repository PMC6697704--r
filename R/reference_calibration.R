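# Frozen reference calibration (generated; see the methods vignette for
# how these values were obtained).  .REFERENCE_PARAMS carries the
# calibrated rate constants; .REFERENCE_INITIAL holds the matching basal
# steady-state amounts used as initial values.

.REFERENCE_PARAMS <- c(
  kon_MetItg = 7.962143411e-06, koff_MetItg = 5.023772863e-01, kint_Met = 1e-02,
  kint_pMet = 6.294627059e-01, kint_MetItg = 6e-05, kint_pMetItg = 3.014263718e-01,
  kdeg_Meti = 1.507131859e-01, kdeg_MetItgi = 5.047658756e-03, krec_Meti = 5.011872336e-04,
  krec_MetItgi = 1e-01, kdeact_pMet = 8e-02, kdeact_pMeti = 2e-02,
  kon_HGF = 3e-01, kbas_PI3K = 4e-05, kbas_SOS = 1.503561701e-03,
  kact_SOS = 2.517850824e-06, kdeact_SOS = 3e-01, kact_Raf = 1.995262315e-05,
  kact_MEK = 6.294627059e-05, kact_MEK_PDK1 = 2e-08, kact_ERK = 1.261914689e-05,
  kdeact_ERK = 1.758320502e+00, kfb_RSK_SOS = 6.32455532e-05, kfb_Ras_PI3K = 1.2e-08,
  kact_PI3K = 3.16227766e-05, kdeact_PI3K = 1.892872033e+00, kact_Akt = 2.511886432e-05,
  kfb_ERK_Raf = 1.002374467e-06, kfb_Akt_Raf = 5e-08, K_inh_Sor = 5.023772863e+01,
  kact_Gab1 = 3.169786385e-06, Kd_Rilo = 5e-02
)

.REFERENCE_INITIAL <- c(
  HGF = 0e+00, Met = 7.9128048e+03, Itg = 1.040065308e+05,
  Met_Itg = 1.30049436e+04, Met_HGF = 0e+00, Met_Itg_HGF = 0e+00,
  pMet = 0e+00, pMet_Itg = 0e+00, Met_i = 5.233102e+02,
  Met_Itg_i = 7.4293e+00, pMet_i = 0e+00, pMet_Itg_i = 0e+00,
  Itg_i = 2.16725636e+04, Gab1 = 4e+04, aGab1 = 0e+00,
  Grb2 = 1e+05, aGrb2 = 0e+00, PI3K = 9.9968487e+04,
  aPI3K = 3.1513e+01, PIP2 = 4.998424846e+05, PIP3 = 1.575154e+02,
  Akt = 1.995266292e+05, pAkt = 4.733708e+02, PDK1 = 1.499055503e+05,
  aPDK1 = 9.44497e+01, SOS = 2.98691301e+04, aSOS = 1.308699e+02,
  Ras = 1.989584926e+05, aRas = 1.0415074e+03, Raf = 3.9142243e+04,
  aRaf = 8.57757e+02, MEK = 3.861017546e+05, pMEK = 1.38982454e+04,
  ERK = 5.455809304e+05, pERK = 5.44190696e+04, RSK = 7.68220441e+04,
  pRSK = 2.09029208e+04, ppRSK = 2.275035e+03, AXT050 = 0e+00,
  AXT_Itg = 0e+00, Cabo = 0e+00, Met_Cabo = 0e+00,
  Rilo = 0e+00, Rilo_HGF = 0e+00, Sor = 0e+00,
  Meti_s = 0e+00, PDK1i_s = 0e+00, MEKi_s = 0e+00,
  PI3Ki_s = 0e+00, ERKi_s = 0e+00
)
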