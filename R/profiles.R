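#' Group-level signal and behavior profiles
#'
#' The generator's ground truth for what distinguishes the three groups.
#' Signal profiles encode progressive spectral slowing along the AD spectrum:
#' a monotone shift of the individual alpha peak (10.5 / 9.5 / 8.5 Hz for
#' SCD / MCI / AD), rising theta and falling alpha relative power, a steeper
#' aperiodic (1/f) exponent, and a smaller, later question-locked evoked
#' deflection. Behavior profiles hold the task accuracy and reaction-time
#' calibration targets (group means and between-/within-subject SDs).
#'
#' A scalar \code{effectSize} rescales every between-group difference about
#' the grand mean: at 0 the three groups share one distribution (null
#' calibration), at 1 the defaults apply, and larger values give cohorts with
#' stronger separation for parameter-recovery runs.
#'
#' @param effectSize non-negative scalar separability dial.
#' @return data.frame with one row per group (\code{SCD}, \code{MCI},
#'   \code{AD}).
#' @examples
#' groupSignalProfiles()
#' groupBehaviorProfiles(effectSize = 0)
#' @export
groupSignalProfiles <- function(effectSize = 1) {
  stopifnot(is.numeric(effectSize), length(effectSize) == 1L, effectSize >= 0)
  base <- data.frame(
    group = GROUPS,
    aperiodic_exponent = c(1.0, 1.2, 1.4),
    p_delta = c(0.15, 0.18, 0.22),
    p_theta = c(0.15, 0.22, 0.30),
    p_alpha = c(0.45, 0.35, 0.25),
    p_beta  = c(0.18, 0.18, 0.16),
    p_gamma = c(0.07, 0.07, 0.07),
    alpha_peak_hz = c(10.5, 9.5, 8.5),
    erp_amplitude_uV = c(6.0, 4.5, 3.0),
    erp_latency_ms = c(300, 360, 420),
    stringsAsFactors = FALSE)
  out <- scaleEffect(base, effectSize)
  # keep realized parameters physical after scaling
  out$alpha_peak_hz <- pmin(13, pmax(6, out$alpha_peak_hz))
  pw <- c("p_delta", "p_theta", "p_alpha", "p_beta", "p_gamma")
  out[pw] <- lapply(out[pw], function(x) pmax(x, 0.005))
  out[pw] <- out[pw] / rowSums(out[pw])
  out$erp_amplitude_uV <- pmax(out$erp_amplitude_uV, 0.1)
  out$erp_latency_ms <- pmax(out$erp_latency_ms, 150)
  out$aperiodic_exponent <- pmax(out$aperiodic_exponent, 0.3)
  # between-subject variability (SDs; *_frac are multiplicative log-normal CVs)
  out$sd_exponent <- 0.10
  out$sd_power_frac <- 0.10
  out$sd_alpha_peak <- 0.30
  out$sd_erp_amp_frac <- 0.20
  out$sd_erp_latency <- 25
  # absolute power budget (microvolts^2), common to all groups
  out$osc_power_uv2 <- 200
  out$aperiodic_power_uv2 <- 100
  out
}

#' @rdname groupSignalProfiles
#' @export
groupBehaviorProfiles <- function(effectSize = 1) {
  stopifnot(is.numeric(effectSize), length(effectSize) == 1L, effectSize >= 0)
  base <- data.frame(
    group = GROUPS,
    acc_mean = c(0.900, 0.735, 0.640),
    acc_sd = c(0.13, 0.216, 0.237),
    rt_mean_ms = c(1312.816, 1924.975, 2751.7),
    rt_between_sd_ms = c(491.698, 942.935, 1204.215),
    rt_within_sd_ms = c(1155.313, 1683.482, 2090.829),
    rt_within_sd_between_sd_ms = c(695.829, 927.305, 862.255),
    stringsAsFactors = FALSE)
  out <- scaleEffect(base, effectSize)
  out$acc_mean <- pmin(0.98, pmax(0.05, out$acc_mean))
  num <- setdiff(names(out)[vapply(out, is.numeric, TRUE)], "acc_mean")
  out[num] <- lapply(out[num], function(x) pmax(x, 1e-3))
  out
}

# shrink/stretch group means about the grand mean by the effect-size dial
scaleEffect <- function(df, effectSize) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) mean(x) + effectSize * (x - mean(x)))
  df
}

#' Canonical 19-channel montage
#'
#' The ordered 10/20 channel subset the analysis is restricted to.
#' @return character vector of 19 channel names.
#' @export
montage19 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4",
    "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Default 64-channel acquisition montage
#'
#' The full recording montage emulating a 64-electrode 10/10 cap; contains
#' the canonical 19-channel subset.
#' @return character vector of 64 channel names.
#' @export
montage64 <- function() {
  extra <- c("Fpz", "AF3", "AFz", "AF4", "F9", "F5", "F1", "F2", "F6", "F10",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "C5", "C1", "C2", "C6", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2",
    "CP4", "CP6", "TP8", "P7", "P5", "P1", "P2", "P6", "P8", "PO7",
    "PO3", "POz", "PO4", "PO8", "Oz", "Iz")
  c(montage19(), extra)
}
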