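# Published Anatolian-buffalo estimates bundled as plain data builders.
# These per-trait variance components, heritabilities and correlation
# matrices for the eleven yearling traits (body weight BW; wither height WH;
# rump height RH; body length BL; chest width CW; hip width HW; chest
# circumference CC; cannon-bone circumference CBC; ultrasound longissimus
# muscle area LMA and depth LMD; subcutaneous fat thickness SFT) serve as
# simulator defaults and as inputs for the selection-response calculations.

#' Trait names of the yearling buffalo analysis
#' @return character vector of the 11 trait codes.
#' @export
buffalo_traits <- function() {
  c("BW", "WH", "RH", "BL", "CW", "HW", "CC", "CBC", "LMA", "LMD", "SFT")
}

#' Published variance components and heritabilities per trait
#'
#' Animal-model REML estimates (additive, maternal, residual and phenotypic
#' variance, in squared trait units) with direct, maternal and total
#' heritability for each of the 11 yearling traits.
#'
#' @return data.frame with columns `trait`, `n`, `sigma2_a`, `sigma2_m`,
#'   `sigma2_e`, `sigma2_p`, `h2_direct`, `h2_maternal`, `h2_total`.
#' @export
buffalo_variance_components <- function() {
  data.frame(
    trait = buffalo_traits(),
    n = c(261L, 272L, 272L, 272L, 272L, 272L, 272L, 272L, 104L, 313L, 313L),
    sigma2_a = c(260.172, 10.391, 12.321, 13.746, 3.612, 4.536, 29.698,
                 0.248, 0.016, 0.053, 0.004),
    sigma2_m = c(503.610, 0.002, 0.923, 9.111, 2.337, 2.685, 28.433,
                 0.837, 0.010, 0.088, 0.002),
    sigma2_e = c(16.163, 11.139, 12.812, 8.296, 3.982, 3.275, 10.173,
                 0.014, 15.291, 0.036, 0.001),
    sigma2_p = c(779.945, 21.534, 26.056, 31.153, 9.931, 10.498, 68.305,
                 1.099, 15.294, 0.178, 0.008),
    h2_direct = c(0.334, 0.483, 0.473, 0.441, 0.364, 0.432, 0.435, 0.226,
                  0.0001, 0.300, 0.539),
    h2_maternal = c(0.646, 0.000, 0.035, 0.292, 0.235, 0.256, 0.416, 0.761,
                    0.000, 0.496, 0.315),
    h2_total = c(0.656, 0.483, 0.491, 0.587, 0.481, 0.560, 0.643, 0.606,
                 0.001, 0.547, 0.697),
    stringsAsFactors = FALSE)
}

#' @noRd
.cor_from_upper <- function(upper) {
  traits <- buffalo_traits()
  m <- diag(1, 11)
  dimnames(m) <- list(traits, traits)
  k <- 1L
  for (i in 1:10) for (j in (i + 1):11) {
    m[i, j] <- m[j, i] <- upper[k]
    k <- k + 1L
  }
  m
}

#' Published genetic correlations among the 11 traits
#'
#' EBV-based (Calo-type) genetic correlation matrix.
#'
#' @return symmetric 11x11 matrix with unit diagonal.
#' @export
buffalo_genetic_correlations <- function() {
  .cor_from_upper(c(
    # BW vs ...
    0.78, 0.79, 0.82, 0.69, 0.62, 0.88, 0.76, 0.71, 0.75, 0.65,
    # WH vs ...
    0.90, 0.75, 0.51, 0.54, 0.76, 0.63, 0.51, 0.56, 0.50,
    # RH vs ...
    0.75, 0.53, 0.56, 0.78, 0.67, 0.53, 0.59, 0.52,
    # BL vs ...
    0.51, 0.57, 0.72, 0.67, 0.62, 0.64, 0.54,
    # CW vs ...
    0.02, 0.63, 0.55, 0.38, 0.57, 0.46,
    # HW vs ...
    0.60, 0.60, 0.46, 0.45, 0.49,
    # CC vs ...
    0.74, 0.65, 0.67, 0.59,
    # CBC vs ...
    0.68, 0.67, 0.61,
    # LMA vs ...
    0.82, 0.56,
    # LMD vs ...
    0.53))
}

#' Published phenotypic correlations among the 11 traits
#'
#' Pearson correlations of the fixed-effect-adjusted records.
#'
#' @return symmetric 11x11 matrix with unit diagonal.
#' @export
buffalo_phenotypic_correlations <- function() {
  .cor_from_upper(c(
    0.73, 0.77, 0.77, 0.69, 0.56, 0.85, 0.76, 0.67, 0.73, 0.62,
    0.90, 0.75, 0.51, 0.53, 0.77, 0.63, 0.49, 0.56, 0.50,
    0.75, 0.53, 0.56, 0.79, 0.67, 0.52, 0.59, 0.52,
    0.51, 0.57, 0.72, 0.67, 0.61, 0.65, 0.53,
    0.02, 0.64, 0.56, 0.35, 0.56, 0.46,
    0.60, 0.60, 0.46, 0.46, 0.48,
    0.76, 0.64, 0.67, 0.60,
    0.68, 0.67, 0.62,
    0.83, 0.54,
    0.53))
}

#' Published sex and birth-season least-square-mean contrasts
#'
#' Differences of the published least-square means (male - female and
#' spring - summer) per trait, in trait units; used as the simulator's
#' default fixed-effect sizes so that simulated ANOVAs have realistic power.
#'
#' @return data.frame with `trait`, `sex_diff`, `season_diff`.
#' @export
buffalo_fixed_effect_contrasts <- function() {
  data.frame(
    trait = buffalo_traits(),
    sex_diff = c(182.83 - 168.00, 109.00 - 107.70, 112.46 - 111.24,
                 104.84 - 102.64, 34.09 - 33.77, 31.50 - 29.62,
                 136.07 - 134.30, 16.02 - 15.36, 19.49 - 19.24,
                 3.149 - 3.024, 0.647 - 0.664),
    season_diff = c(177.13 - 173.70, 108.39 - 108.31, 111.36 - 112.33,
                    103.70 - 103.77, 35.43 - 32.43, 29.03 - 32.08,
                    135.43 - 134.93, 15.74 - 15.64, 19.25 - 19.48,
                    3.121 - 3.052, 0.647 - 0.663),
    stringsAsFactors = FALSE)
}

#' Published overall least-square means per trait
#' @return named numeric vector of the 11 trait means (trait units).
#' @export
buffalo_trait_means <- function() {
  stats::setNames(
    c(175.41, 108.35, 111.85, 103.74, 33.93, 30.56, 135.18, 15.69,
      19.36, 3.086, 0.655),
    buffalo_traits())
}

#' Published selection-response matrix
#'
#' The published direct (diagonal, trait units at unit selection intensity)
#' and relative correlated (off-diagonal; row = auxiliary/selected trait,
#' column = responding trait) responses, as printed.  Three printed cells
#' are internally inconsistent with the published heritabilities and
#' genetic correlations (each duplicates a neighbouring printed value);
#' their positions are available as `attr(, "print_inconsistent")`.
#'
#' @return 11x11 matrix (rows = selected trait); attribute
#'   `print_inconsistent` is a 2-column matrix of row/col trait names.
#' @export
buffalo_response_matrix_published <- function() {
  traits <- buffalo_traits()
  m <- rbind(
    c(9.3278, 0.6486, 0.6638, 0.7136, 0.6610, 0.5452, 0.7711, 0.9239,
      41.0328, 0.7914, 0.5117),
    c(0.9380, 2.2413, 0.9095, 0.7849, 0.5875, 0.5710, 0.7600, 0.9210,
      35.4441, 0.7106, 0.4733),
    c(0.9401, 0.8906, 2.4144, 0.7767, 0.6042, 0.5860, 0.8134, 0.9693,
      36.4507, 0.7408, 0.4871),
    c(0.9422, 0.7166, 0.7242, 2.4614, 0.5614, 0.5759, 0.7249, 0.9359,
      41.1729, 0.7760, 0.4884),
    c(0.7203, 0.4427, 0.4649, 0.4633, 1.1471, 0.0184, 0.5763, 0.6980,
      22.9263, 0.6279, 0.3780),
    c(0.7051, 0.5107, 0.5352, 0.5642, 0.0218, 1.3997, 0.5979, 0.8295,
      30.2343, 0.5400, 0.4387),
    c(1.0043, 0.7212, 0.7480, 0.7151, 0.6887, 0.6021, 3.5951, 1.0266,
      42.8704, 0.8068, 0.5300),
    c(0.6252, 0.4309, 0.4631, 0.4796, 0.4334, 0.4340, 0.5334, 0.2369,
      32.3268, 0.5815, 0.3950),
    c(0.0123, 0.0088, 0.0077, 0.0093, 0.0063, 0.0070, 0.0099, 0.0143,
      0.0004, 0.0150, 0.0076),
    c(0.7108, 0.4413, 0.5279, 0.5279, 0.5175, 0.3750, 0.5564, 0.7719,
      44.9132, 0.1266, 0.3954),
    c(0.8257, 0.5282, 0.5970, 0.5970, 0.5598, 0.5473, 0.6568, 0.9420,
      41.1133, 0.7104, 0.0482))
  dimnames(m) <- list(selected = traits, response = traits)
  attr(m, "print_inconsistent") <- rbind(
    c("LMD", "RH"),   # duplicates the printed (LMD, BL) cell
    c("SFT", "RH"),   # duplicates the printed (SFT, BL) cell
    c("WH", "CC"))    # equals rG(WH, CC) with the h-ratio dropped
  m
}

#' Published candidate-SNP genotype counts
#'
#' Genotype class counts observed at the LCORL (AX-85166825) and HMGA2
#' (AX-85179490) loci; the PLAG1 and NCAPG variants screened were
#' monomorphic.
#'
#' @return named list of named integer vectors.
#' @export
buffalo_snp_counts <- function() {
  list(LCORL = c(TT = 227L, CT = 9L),
       HMGA2 = c(CC = 162L, CT = 70L, TT = 3L))
}
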