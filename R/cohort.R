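#' Sample a synthetic cohort of subject profiles
#'
#' Draws per-subject realized signal and behavior parameters around the group
#' profiles (see \code{\link{groupSignalProfiles}}). Positive-valued
#' parameters (relative band powers, evoked amplitude, reaction-time moments)
#' vary multiplicatively (log-normal, mean-preserving); location parameters
#' (alpha peak, aperiodic exponent, evoked latency) vary additively
#' (Gaussian, clamped to physical bounds). Per-subject task accuracy is drawn
#' from a Beta distribution moment-matched to the group accuracy mean/SD.
#'
#' @param nScd,nMci,nAd non-negative group sizes (study default 20/28/10).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   arguments.
#' @param effectSize separability dial passed to the group profiles.
#' @return data.frame with one row per subject: identifiers, group, realized
#'   signal parameters and realized behavior parameters. Attributes
#'   \code{seed} and \code{effect_size} record the draw.
#' @examples
#' cohort <- sampleCohort(5, 5, 5, seed = 1)
#' table(cohort$group)
#' @export
sampleCohort <- function(nScd = 20, nMci = 28, nAd = 10, seed = 1,
                         effectSize = 1) {
  counts <- c(SCD = nScd, MCI = nMci, AD = nAd)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("group sizes must be non-negative integers")
  sig <- groupSignalProfiles(effectSize)
  beh <- groupBehaviorProfiles(effectSize)
  withSeed(seed, {
    rows <- lapply(GROUPS, function(g) {
      n <- counts[[g]]
      if (n == 0L) return(NULL)
      s <- sig[sig$group == g, ]
      b <- beh[beh$group == g, ]
      pw <- c("p_delta", "p_theta", "p_alpha", "p_beta", "p_gamma")
      p <- vapply(pw, function(k) rlnormMean(n, s[[k]], s[[k]] * s$sd_power_frac),
                  numeric(n))
      p <- matrix(p, nrow = n)
      p <- p / rowSums(p)
      colnames(p) <- pw
      df <- data.frame(
        subject_id = sprintf("%s%02d", g, seq_len(n)),
        group = g,
        aperiodic_exponent = pmax(0.3, rnorm(n, s$aperiodic_exponent, s$sd_exponent)),
        p,
        alpha_peak_hz = pmin(13, pmax(6, rnorm(n, s$alpha_peak_hz, s$sd_alpha_peak))),
        erp_amplitude_uV = rlnormMean(n, s$erp_amplitude_uV,
                                      s$erp_amplitude_uV * s$sd_erp_amp_frac),
        erp_latency_ms = pmax(150, rnorm(n, s$erp_latency_ms, s$sd_erp_latency)),
        osc_power_uv2 = s$osc_power_uv2 * rlnormMean(n, 1, 0.1),
        aperiodic_power_uv2 = s$aperiodic_power_uv2 * rlnormMean(n, 1, 0.1),
        acc_prob = rbetaMoment(n, b$acc_mean, b$acc_sd),
        rt_mean_ms = rlnormMean(n, b$rt_mean_ms, b$rt_between_sd_ms),
        rt_sd_ms = rlnormMean(n, b$rt_within_sd_ms, b$rt_within_sd_between_sd_ms),
        stringsAsFactors = FALSE)
      df
    })
    rows <- Filter(Negate(is.null), rows)
    cohort <- if (length(rows))
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(subject_id = character(), group = character())
    attr(cohort, "seed") <- as.integer(seed)
    attr(cohort, "effect_size") <- effectSize
    cohort
  })
}

# log-normal draws with exact mean m and sd s (mean-preserving multiplicative
# between-subject variation)
rlnormMean <- function(n, m, s) {
  if (s <= 0 || m <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Beta draws moment-matched to (m, s); if s exceeds the attainable SD it is
# shrunk to 95% of the Bernoulli bound
rbetaMoment <- function(n, m, s) {
  smax <- sqrt(m * (1 - m))
  s <- min(s, 0.95 * smax)
  nu <- m * (1 - m) / s^2 - 1
  rbeta(n, m * nu, (1 - m) * nu)
}

# evaluate an expression under a fixed RNG state, restoring the caller's
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# derive a child seed from a base seed and a stream label (stays < 2^31)
childSeed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
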