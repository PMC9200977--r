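## Stimulus protocol constants: four chromatic conditions against a
## 0.04 cd/m^2 mesopic background. Dim stimuli probe the transient
## (rod/cone-driven) PLR at all 54 grid targets; bright stimuli probe the
## sustained melanopsin-driven PLR at 4 targets.

.CONDITIONS <- c("dim_red", "dim_blue", "bright_red", "bright_blue")
.EYES <- c("right", "left")
.BACKGROUND_CD_M2 <- 0.04

## The 17 PLR kinetic parameters, in canonical order.
.PLR_PARAMS <- c("AC", "PPC", "PRL", "LMP",
                 "MCV", "LMCV", "MCA", "LMCA", "MCD", "LMCD",
                 "MRV", "LMRV", "MRA", "LMRA", "MRD", "LMRD", "PRP")

#' Stimulus specification for a chromatic pupilloperimetry condition
#'
#' Returns the protocol constants for one stimulus condition: dim red
#' (624 nm, 1000 cd/m^2) and dim blue (485 nm, 170 cd/m^2) presented for
#' 1 s with 4 s of recording at all 54 grid targets; bright red and bright
#' blue (6000 cd/m^2) presented for 8 s with 16 s of recording at 4
#' targets (two central, two peripheral).
#'
#' @param condition one of `"dim_red"`, `"dim_blue"`, `"bright_red"`,
#'   `"bright_blue"`
#' @return named list: `condition`, `wavelength_nm`, `luminance_cd_m2`,
#'   `background_cd_m2`, `stim_duration_s`, `record_duration_s`,
#'   `n_targets`, `targets` (grid indices stimulated)
#' @examples
#' stimulusSpec("dim_blue")$record_duration_s  # 4
#' @export
stimulusSpec <- function(condition = .CONDITIONS) {
  condition <- match.arg(condition)
  bright <- grepl("^bright", condition)
  blue <- grepl("blue$", condition)
  list(
    condition = condition,
    wavelength_nm = if (blue) 485 else 624,
    luminance_cd_m2 = if (bright) 6000 else if (blue) 170 else 1000,
    background_cd_m2 = .BACKGROUND_CD_M2,
    stim_duration_s = if (bright) 8 else 1,
    record_duration_s = if (bright) 16 else 4,
    n_targets = if (bright) 4L else 54L,
    ## bright stimuli: two central (y = +/-3, |x| = 3 nasal side) and two
    ## peripheral targets; dim stimuli use the whole grid
    targets = if (bright) c(23L, 32L, 5L, 54L) else 1:54
  )
}

#' All four stimulus specifications
#' @return named list of [stimulusSpec()] results for every condition
#' @export
stimulusSpecs <- function() {
  setNames(lapply(.CONDITIONS, stimulusSpec), .CONDITIONS)
}

#' The 17 PLR kinetic parameter names
#'
#' Abbreviations, in the package's canonical order: contraction amplitude
#' (AC, mm), percentage of pupil contraction (PPC, %), pupil response
#' latency (PRL, s), latency of maximal pupil contraction (LMP, s), maximal
#' contraction velocity/acceleration/deceleration (MCV mm/s, MCA mm/s^2,
#' MCD mm/s^2) with their latencies (LMCV, LMCA, LMCD, s), the redilation
#' counterparts (MRV, MRA, MRD and LMRV, LMRA, LMRD), and percent pupil
#' recovery at the end of the recording (PRP, %).
#'
#' @return character vector of length 17
#' @export
plrParameters <- function() .PLR_PARAMS
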