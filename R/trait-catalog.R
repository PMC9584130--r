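#' The 28-trait physiological catalogue
#'
#' Returns the trait schema used throughout the package: one row per
#' physiological trait with its baseline and follow-up (chronic-phase)
#' moments and its composite-phenotype block membership. The moments are
#' those of a published 883-subject male acclimatization cohort (baseline at
#' 50 m, chronic phase after ~1 month above 4300 m); the 14-block mapping is
#' the composite-phenotype structure reported for that cohort (LV1..LV14).
#'
#' Units follow clinical convention: cell counts in 10^9/L or 10^12/L, HGB
#' and MCHC in g/L, HCT as a fraction, volumes in fL, enzymes in U/L,
#' bilirubin and CREA in umol/L, BUN in mmol/L, pressures in mmHg, FVC in
#' dL-scaled spirometer units, temperature in degrees C, SpO2 in %, and the
#' Lake Louise acute-mountain-sickness score in points (0-15).
#'
#' @return A data.frame with columns `name`, `baseline_mean`, `baseline_sd`,
#'   `chronic_mean`, `chronic_sd`, `block_id`.
#' @export
#' @examples
#' tc <- trait_catalog()
#' tc[tc$name == "HGB", ]
trait_catalog <- function() {
  data.frame(
    name = c("ALT", "AST", "AST/ALT", "TBIL", "DBIL", "IBIL", "BUN", "CREA",
             "WBC", "LYM%", "LYM#", "RBC", "HGB", "HCT", "MCV", "MCH",
             "MCHC", "PLT", "PCT", "MPV", "PDW", "FVC", "SBP", "DBP", "HR",
             "Body temperature", "SPO2", "LLS"),
    baseline_mean = c(19.11, 15.64, 0.85, 11.94, 2.69, 9.25, 5.08, 58.32,
                      6.21, 36.16, 2.21, 4.88, 150.15, 0.44, 90.60, 30.91,
                      341.07, 206.88, 2.01, 9.78, 13.79, 444.45, 110.88,
                      73.21, 66.49, 36.22, 97.76, 0.88),
    baseline_sd = c(8.14, 5.83, 0.18, 1.77, 0.61, 1.24, 1.12, 10.38, 1.34,
                    7.48, 0.52, 0.39, 10.05, 0.03, 5.14, 2.34, 17.94, 42.79,
                    0.42, 1.26, 2.25, 38.26, 10.45, 8.65, 9.57, 0.12, 2.08,
                    1.59),
    chronic_mean = c(15.02, 46.05, 3.91, 14.51, 5.70, 8.81, 6.21, 113.02,
                     8.21, 40.61, 3.31, 5.73, 179.59, 0.50, 87.39, 31.39,
                     359.14, 258.94, 2.72, 10.54, 18.03, 412.31, 124.34,
                     75.98, 87.16, 36.38, 85.82, 1.40),
    chronic_sd = c(9.08, 15.24, 2.54, 24.90, 1.70, 24.95, 1.17, 12.20, 1.70,
                   10.71, 0.99, 0.48, 13.46, 0.04, 4.89, 2.18, 16.24, 51.49,
                   0.51, 0.62, 2.53, 59.16, 12.94, 9.61, 10.99, 0.29, 3.80,
                   1.73),
    block_id = c(9L, 9L, 9L, 10L, 10L, 10L, 11L, 11L, 4L, 4L, 4L, 5L, 5L,
                 5L, 6L, 6L, 6L, 7L, 7L, 6L, 8L, 1L, 3L, 3L, 2L, 14L, 13L,
                 12L),
    stringsAsFactors = FALSE, check.names = FALSE
  )
}

# Planted within-block (signed) correlation matrices for the multi-trait
# blocks. Solved so that the standardized Cronbach alpha and the two leading
# eigenvalues of each block's correlation matrix reproduce the published
# unidimensionality diagnostics (not equicorrelation, which those
# diagnostics rule out for the 3- and 4-trait blocks: e.g. the liver block's
# second eigenvalue of 1.31 forces a negative AST/ALT-vs-ALT entry, and the
# hemoglobin-concentration block's 1.01 forces the MCH/MCHC vs MPV/MCV sign
# split). The bilirubin block is adjusted for rank-space cohesion (see
# vignette): the printed Pearson diagnostics there reflect the arithmetic
# identity IBIL = TBIL - DBIL in strongly skewed data and would detach DBIL
# entirely in a Gaussian emulation.
#
# Trait order within each matrix follows trait_catalog() order.
block_cor_catalog <- function() {
  list(
    `3` = matrix(c(1, .538, .538, 1), 2, 2,
                 dimnames = rep(list(c("SBP", "DBP")), 2)),
    `4` = matrix(c(1, -.27, .39,  -.27, 1, .75,  .39, .75, 1), 3, 3,
                 dimnames = rep(list(c("WBC", "LYM%", "LYM#")), 2)),
    `5` = matrix(c(1, .614, .614,  .614, 1, .93,  .614, .93, 1), 3, 3,
                 dimnames = rep(list(c("RBC", "HGB", "HCT")), 2)),
    `6` = matrix(c(1, -.49, -.49, -.01,  -.49, 1, .90, -.49,
                   -.49, .90, 1, -.49,  -.01, -.49, -.49, 1), 4, 4,
                 dimnames = rep(list(c("MCV", "MCH", "MCHC", "MPV")), 2)),
    `7` = matrix(c(1, .887, .887, 1), 2, 2,
                 dimnames = rep(list(c("PLT", "PCT")), 2)),
    `9` = matrix(c(1, .35, -.35,  .35, 1, .30,  -.35, .30, 1), 3, 3,
                 dimnames = rep(list(c("ALT", "AST", "AST/ALT")), 2)),
    `10` = matrix(c(1, .35, .98,  .35, 1, .20,  .98, .20, 1), 3, 3,
                  dimnames = rep(list(c("TBIL", "DBIL", "IBIL")), 2)),
    `11` = matrix(c(1, .439, .439, 1), 2, 2,
                  dimnames = rep(list(c("BUN", "CREA")), 2))
  )
}
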