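#' Physico-chemical constants
#'
#' Monoisotopic residue masses (Da) for the 20 canonical amino acids, the
#' proton and water masses used for precursor m/z computation, the fragment
#' ion-type offsets applied to singly charged residue masses, and the
#' Kyte-Doolittle hydropathy scale used as the default additive retention
#' coefficient table of the corpus simulator.
#'
#' @name rtvarlab-constants
#' @keywords internal
NULL

# monoisotopic residue masses, Da
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

# integer mass offsets added to singly charged residue masses per ion series
ION_OFFSETS <- c(a = -27, b = 1, y = 19, c = 18, z = 2)

# Kyte-Doolittle hydropathy: default additive retention coefficient scale
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# canonical residue alphabet, fixed order (defines the model vocabulary)
RESIDUES <- sort(names(RESIDUE_MASS))

# alternative (non-modal) m/z acquisition windows used by the simulator
ALT_FILTER_POOL <- list(
  c(300, 1650), c(375, 1575), c(400, 1600), c(350, 1400), c(300, 1800),
  c(345, 1505), c(380, 1500), c(200, 2000), c(335, 1365), c(400, 1250),
  c(360, 1300), c(310, 1590)
)
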