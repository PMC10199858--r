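#' Published summary statistics the simulator is calibrated to
#'
#' Returns the summary statistics reported by the six-patient anti-LAG-3
#' antibody dose-escalation imaging study that the cohort generator
#' emulates.  These numbers are the calibration anchors of the package: the
#' plasma model, the occupancy model and the tumor kinetic defaults are all
#' derived from them by the `calibrate*()` functions, and the acceptance
#' checks compare simulated cohorts back against them.
#'
#' @return A list with components:
#' \describe{
#'   \item{plasma_mean}{matrix of mean plasma activity concentrations
#'     (\%IA/L), doses 4/44/604 mg by times 90/138 h post injection.}
#'   \item{spleen_ki}{named numeric, mean spleen net irreversible uptake
#'     rate Ki (uL g^-1 h^-1) at the three mass doses.}
#'   \item{tumor_t2p_median}{named numeric, median lesion-level
#'     tumor-to-plasma ratios: 4 mg at 90 and 138 h, 44 and 604 mg at 138 h.}
#'   \item{tumor_t2p_iqr}{matrix of the corresponding interquartile ranges.}
#'   \item{patient_mean_t2p_138h}{named numeric, per-patient mean
#'     tumor-to-plasma ratio at 138 h in the 4-mg cycle (six patients).}
#'   \item{patient_arm}{named numeric, cycle-2 mass dose per patient.}
#'   \item{patient_ihc_lag3_pct}{named numeric, percent LAG-3 positive
#'     immune cells per tumor area (NA where no biopsy was evaluable).}
#'   \item{n_lesions}{total number of tumor lesions (20).}
#'   \item{lesion_volume}{list with mean and range of lesion volume, mL.}
#'   \item{receptor_synthesis_rate}{reported receptor re-synthesis rate,
#'     fraction per hour, anchoring the default maximal trapping rate.}
#' }
#' @examples
#' referenceCohortSummaries()$spleen_ki
#' @export
referenceCohortSummaries <- function() {
  list(
    plasma_mean = matrix(c(6.2, 3.2, 11.9, 10.0, 14.5, 11.9), nrow = 3,
                         byrow = TRUE,
                         dimnames = list(c("4", "44", "604"), c("90", "138"))),
    spleen_ki = c(`4` = 30.06, `44` = 2.91, `604` = 0.67),
    tumor_t2p_median = c(`4mg_90h` = 1.63, `4mg_138h` = 2.70,
                         `44mg_138h` = 0.67, `604mg_138h` = 0.58),
    tumor_t2p_iqr = matrix(c(0.37, 2.89, 0.85, 4.62, 0.50, 0.85, 0.42, 0.75),
                           nrow = 4, byrow = TRUE,
                           dimnames = list(c("4mg_90h", "4mg_138h",
                                             "44mg_138h", "604mg_138h"),
                                           c("q1", "q3"))),
    patient_mean_t2p_138h = c(`1` = 3.20, `2` = 3.02, `3` = 3.44,
                              `6` = 0.83, `9` = 1.43, `10` = 3.59),
    patient_arm = c(`1` = 604, `2` = 604, `3` = 604,
                    `6` = 44, `9` = 44, `10` = 44),
    patient_ihc_lag3_pct = c(`1` = 10, `2` = 5, `3` = NA,
                             `6` = 1, `9` = 5, `10` = 30),
    n_lesions = 20L,
    lesion_volume = list(mean = 16.6, range = c(3.6, 109.12)),
    receptor_synthesis_rate = 0.1
  )
}

#' Physical half-life of zirconium-89
#'
#' @return 78.41 hours.
#' @examples
#' zr89HalfLife()
#' @export
zr89HalfLife <- function() 78.41
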