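# shared fixtures: tissue-like optics and small grids used across tests
opt_tissue <- function() optical_properties(1.0, 0.01)

# frozen oracle values, computed by independent symbolic evaluation before
# the implementation was written
ORACLE_KAPPA_TISSUE <- 0.174068951855
ORACLE_PSF_0_5 <- 0.115931590947       # default parse, rho = 0, d = 5 mm
ORACLE_PSF_0_5_R2 <- 0.0181731102963   # r-squared parse variant
ORACLE_PHI_2_10_11 <- 0.491006895019   # phi(alpha = 2, s_th = 10, s = 11)
GAUSS_FWHM_FACTOR <- 2.35482004503     # 2 sqrt(2 ln 2)

# small lookup table shared by several test files (built once per session)
small_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut))
      lut <<- build_lookup_table(depth_range = c(3, 5), diameter_range = c(2, 4),
                                 step = 0.25, optical = opt_tissue())
    lut
  }
})
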