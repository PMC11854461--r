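#' Synthesize a continuous EEG recording for one subject
#'
#' Generates a multichannel recording from the subject's realized spectral
#' parameters: independent broadband sources with a 1/f aperiodic background
#' plus Gaussian-shaped band oscillations (delta, theta, alpha at the
#' subject's individual alpha peak, beta, gamma), mixed into channels through
#' a fixed random spatial mixing matrix (unit-norm rows, so every channel
#' carries the subject's power spectrum while the channel covariance is
#' non-diagonal), plus white sensor noise. Task (\code{SQT}) recordings embed
#' the 10-trial protocol timeline (2 s Ready, question audio, 10 s response
#' window, 2 s inter-trial interval) with \code{question_onset},
#' \code{question_offset} and \code{response} events, and add an evoked
#' deflection time-locked to each question offset with the subject's
#' amplitude and latency. \code{REST} recordings are unbroken eyes-closed
#' background activity.
#'
#' @param subject one row of a \code{\link{sampleCohort}} data.frame.
#' @param condition \code{"REST"} or \code{"SQT"}.
#' @param protocol an \linkS4class{SQTProtocol} (required for SQT).
#' @param seed integer seed; the recording is deterministic given arguments.
#' @param channels channel name vector (\code{\link{montage64}} by default;
#'   use \code{\link{montage19}} for the fast profile).
#' @param samplingRate acquisition rate in Hz (default 2048).
#' @param behavior optional precomputed \code{\link{sampleBehavior}} records
#'   used to place response events; sampled internally when \code{NULL}.
#' @param restDuration rest recording duration in seconds (>= 60).
#' @return a \linkS4class{RawRecording}.
#' @export
synthesizeRecording <- function(subject, condition = c("REST", "SQT"),
                                protocol = loadProtocol(), seed = 1,
                                channels = montage64(), samplingRate = 2048,
                                behavior = NULL, restDuration = 62) {
  condition <- match.arg(condition)
  subject <- asSubjectRow(subject)
  checkSubjectParams(subject)
  fs <- samplingRate
  nch <- length(channels)
  if (condition == "SQT" && is.null(behavior))
    behavior <- sampleBehavior(subject, protocol,
                               seed = childSeed(seed, subject$subject_id, "beh"))

  withSeed(childSeed(seed, subject$subject_id, condition), {
    if (condition == "REST") {
      stopifnot(restDuration >= 60)
      n <- round(restDuration * fs)
      events <- emptyEvents()
    } else {
      q <- questionTable(protocol)
      lead <- as.integer(3 * fs); ready <- as.integer(2 * fs)
      respwin <- as.integer(10 * fs); iti <- as.integer(2 * fs)
      cur <- lead
      onset <- offset <- integer(10)
      for (i in 1:10) {
        onset[i] <- cur + ready
        offset[i] <- onset[i] + as.integer(round(q$listening_time_ms[i] * fs / 1000))
        cur <- offset[i] + respwin + iti
      }
      n <- cur + as.integer(2 * fs)
      resp <- offset + ifelse(is.na(behavior$rt_ms), NA,
                              as.integer(round(behavior$rt_ms * fs / 1000)))
      resp <- as.integer(resp)
      respTrials <- which(!is.na(resp))
      events <- rbind(
        data.frame(type = "question_onset", trial = 1:10, sample_index = onset),
        data.frame(type = "question_offset", trial = 1:10, sample_index = offset),
        if (length(respTrials))
          data.frame(type = "response", trial = respTrials,
                     sample_index = resp[respTrials]))
      events <- events[order(events$sample_index), ]
      rownames(events) <- NULL
    }

    nsrc <- min(nch, 16L)
    src <- matrix(0, nsrc, n)
    for (k in seq_len(nsrc)) src[k, ] <- synthSource(n, fs, subject)
    A <- matrix(rnorm(nch * nsrc), nch, nsrc)
    A <- A / sqrt(rowSums(A^2))
    sig <- A %*% src + matrix(rnorm(nch * n, sd = 2), nch, n)

    if (condition == "SQT") {
      w <- erpWaveform(fs, subject$erp_amplitude_uV, subject$erp_latency_ms)
      topo <- erpTopography(channels)
      for (o in offset) {
        idx <- (o + 1L):min(n, o + length(w))
        sig[, idx] <- sig[, idx] + outer(topo, w[seq_along(idx)])
      }
    }

    new("RawRecording", subjectId = as.character(subject$subject_id),
        condition = condition, samplingRate = fs, channels = channels,
        signal = sig, events = events,
        misc = list(seed = seed, behavior = behavior))
  })
}

checkSubjectParams <- function(subject) {
  pw <- c("p_delta", "p_theta", "p_alpha", "p_beta", "p_gamma")
  need <- c(pw, "aperiodic_exponent", "alpha_peak_hz", "erp_amplitude_uV",
            "erp_latency_ms", "osc_power_uv2", "aperiodic_power_uv2")
  miss <- setdiff(need, names(subject))
  if (length(miss))
    stop("subject profile lacks parameters: ", paste(miss, collapse = ", "))
  vals <- unlist(subject[need])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("subject parameters out of bounds (non-positive or non-finite)")
  if (subject$alpha_peak_hz < 6 || subject$alpha_peak_hz > 13)
    stop("subject parameters out of bounds: alpha peak outside [6, 13] Hz")
  invisible(TRUE)
}

emptyEvents <- function() {
  data.frame(type = character(), trial = integer(), sample_index = integer())
}

# oscillatory band layout: centre/width in Hz; alpha tracks the subject peak
bandLayout <- function(subject) {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    mu = c(2.5, 6, subject$alpha_peak_hz, 20, 40),
    sigma = c(1.0, 1.2, 1.2, 4, 6),
    power = subject$osc_power_uv2 *
      unlist(subject[c("p_delta", "p_theta", "p_alpha", "p_beta", "p_gamma")]))
}

# one-sided model PSD (uV^2/Hz) at frequencies f
modelPsd <- function(f, subject) {
  chi <- subject$aperiodic_exponent
  apInt <- if (abs(chi - 1) < 1e-9) log(45 / 2) else
    (45^(1 - chi) - 2^(1 - chi)) / (1 - chi)
  a0 <- subject$aperiodic_power_uv2 / apInt
  s <- a0 * pmax(f, 1)^(-chi)
  bl <- bandLayout(subject)
  for (i in seq_len(nrow(bl)))
    s <- s + bl$power[i] * dnorm(f, bl$mu[i], bl$sigma[i])
  s
}

#' Analytic band power of the generator model
#'
#' Closed-form integral of the subject's model PSD over a frequency band;
#' the oracle the spectral-fidelity tests compare Welch estimates against.
#'
#' @param subject one cohort row.
#' @param fLow,fHigh band edges in Hz (fLow >= 1).
#' @return band power in microvolts^2.
#' @export
analyticBandPower <- function(subject, fLow, fHigh) {
  subject <- asSubjectRow(subject)
  stopifnot(fLow >= 1, fHigh > fLow)
  chi <- subject$aperiodic_exponent
  apInt <- if (abs(chi - 1) < 1e-9) log(45 / 2) else
    (45^(1 - chi) - 2^(1 - chi)) / (1 - chi)
  a0 <- subject$aperiodic_power_uv2 / apInt
  ap <- if (abs(chi - 1) < 1e-9) a0 * log(fHigh / fLow) else
    a0 * (fHigh^(1 - chi) - fLow^(1 - chi)) / (1 - chi)
  bl <- bandLayout(subject)
  ap + sum(bl$power * (pnorm(fHigh, bl$mu, bl$sigma) - pnorm(fLow, bl$mu, bl$sigma)))
}

# frequency-domain synthesis of one source with the subject's model PSD
synthSource <- function(n, fs, subject) {
  nf <- floor((n - 1) / 2)
  f <- (1:nf) * fs / n
  s2 <- modelPsd(f, subject) / 2        # two-sided PSD
  amp <- sqrt(fs * n * s2 / 2)
  X <- complex(real = rnorm(nf) * amp, imaginary = rnorm(nf) * amp)
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- X
  spec[n:(n - nf + 1)] <- Conj(X)
  Re(fft(spec, inverse = TRUE)) / n
}

# biphasic question-locked deflection (positive bump, smaller negative rebound)
erpWaveform <- function(fs, amp, latencyMs) {
  t <- seq(0, 0.9, by = 1 / fs)
  lat <- latencyMs / 1000
  amp * (exp(-0.5 * ((t - lat) / 0.05)^2) -
         0.6 * exp(-0.5 * ((t - lat - 0.15) / 0.08)^2))
}

# centro-parietal emphasis for the evoked response
erpTopography <- function(channels) {
  w <- rep(0.4, length(channels))
  names(w) <- channels
  strong <- c(Cz = 1, Pz = 1, CPz = 1, C3 = 0.8, C4 = 0.8, P3 = 0.8, P4 = 0.8,
              CP1 = 0.9, CP2 = 0.9, Fz = 0.6, C1 = 0.9, C2 = 0.9)
  hit <- intersect(names(strong), channels)
  w[hit] <- strong[hit]
  unname(w)
}

#' Welch band-power estimate of a recording
#'
#' Average modified periodogram (Hann window, 50\% overlap) of the mean over
#' channels... power is integrated over the requested band. Used to verify
#' the generator's spectral calibration.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param fLow,fHigh band edges in Hz.
#' @param channel channel name or index to estimate from (first channel by
#'   default).
#' @param segSeconds Welch segment length in seconds.
#' @return estimated band power in microvolts^2.
#' @export
bandPower <- function(rec, fLow, fHigh, channel = 1L, segSeconds = 4) {
  fs <- rec@samplingRate
  x <- rec@signal[channel, ]
  nseg <- round(segSeconds * fs)
  step <- nseg %/% 2
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(win^2)
  f <- (0:(nseg - 1)) * fs / nseg
  psd <- rep(0, nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * win
    psd <- psd + Mod(fft(seg))^2 / (u * fs)
  }
  psd <- psd / length(starts)
  sel <- f >= fLow & f <= fHigh
  2 * sum(psd[sel]) * fs / nseg       # one-sided integral
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds frontally dominant eye-blink transients (raised-cosine bursts with a
#' shared spatial pattern at Poisson-distributed times) and a 60 Hz line-noise
#' sinusoid on all channels. The injected blink times, blink spatial pattern
#' and line amplitude are stored in \code{rec@misc$artifacts} so downstream
#' artifact-removal tests have a ground-truth oracle.
#'
#' @param rec a \linkS4class{RawRecording}.
#' @param blinkRatePerMin expected blink rate (per minute, >= 0).
#' @param lineNoiseAmpUv 60 Hz sinusoid amplitude in microvolts (>= 0).
#' @param seed integer seed.
#' @return the recording with artifacts added.
#' @export
injectArtifacts <- function(rec, blinkRatePerMin = 12, lineNoiseAmpUv = 0,
                            seed = 1) {
  stopifnot(blinkRatePerMin >= 0, lineNoiseAmpUv >= 0)
  if (blinkRatePerMin == 0 && lineNoiseAmpUv == 0) {
    rec@misc$artifacts <- list(blink_samples = integer(),
                               line_noise_amp = 0)
    return(rec)
  }
  fs <- rec@samplingRate
  n <- ncol(rec@signal)
  withSeed(childSeed(seed, rec@subjectId, "artifacts"), {
    sig <- rec@signal
    blinkSamples <- integer()
    topo <- blinkTopography(rec@channels)
    if (blinkRatePerMin > 0) {
      nBlink <- rpois(1, blinkRatePerMin * n / fs / 60)
      if (nBlink > 0) {
        len <- round(0.3 * fs)
        wave <- 120 * (0.5 - 0.5 * cos(2 * pi * seq_len(len) / (len + 1)))
        blinkSamples <- sort(sample.int(n - len, nBlink))
        for (b in blinkSamples) {
          idx <- b:(b + len - 1)
          sig[, idx] <- sig[, idx] + outer(topo, wave)
        }
      }
    }
    if (lineNoiseAmpUv > 0) {
      t <- (0:(n - 1)) / fs
      line <- lineNoiseAmpUv * sin(2 * pi * 60 * t)
      sig <- sweep(sig, 2, line, "+")
    }
    rec@signal <- sig
    rec@misc$artifacts <- list(blink_samples = blinkSamples,
                               blink_pattern = topo,
                               blink_len = if (blinkRatePerMin > 0) round(0.3 * fs) else 0L,
                               line_noise_amp = lineNoiseAmpUv)
    rec
  })
}

blinkTopography <- function(channels) {
  w <- rep(0.05, length(channels))
  names(w) <- channels
  strong <- c(Fp1 = 1, Fp2 = 1, Fpz = 1, AF3 = 0.8, AF4 = 0.8, AFz = 0.8,
              F7 = 0.45, F8 = 0.45, F3 = 0.55, F4 = 0.55, Fz = 0.55,
              F1 = 0.5, F2 = 0.5)
  hit <- intersect(names(strong), channels)
  w[hit] <- strong[hit]
  unname(w)
}

#' Sample task behavior for one subject
#'
#' Draws the 10-trial behavioral record. Trial correctness is Bernoulli with
#' the subject's realized accuracy probability. Reaction times follow a
#' log-normal whose parameters are numerically moment-matched so that the
#' RTs recorded inside the 10 s response window have the subject's realized
#' mean and within-subject SD (the generative SD is first inflated to
#' compensate the downward bias of a 10-trial sample SD under a skewed
#' distribution, so the observable mean stdRT is calibrated). Correct trials
#' always receive an in-window RT; trials destined incorrect draw from the
#' unconditional distribution, and a draw beyond the window becomes a
#' non-response (no key, no RT, scored incorrect) - so non-responses occur
#' exactly when the sampled RT exceeds the window, and scored accuracy stays
#' calibrated to the subject's accuracy parameter.
#'
#' @param subject one cohort row.
#' @param protocol an \linkS4class{SQTProtocol}.
#' @param seed integer seed.
#' @return data.frame with columns \code{subject_id}, \code{trial_index},
#'   \code{response_key} (\code{O}/\code{X}/\code{none}), \code{correct},
#'   \code{rt_ms} (NA for non-responses).
#' @export
sampleBehavior <- function(subject, protocol = loadProtocol(), seed = 1) {
  subject <- asSubjectRow(subject)
  stopifnot(!is.null(subject$acc_prob), !is.null(subject$rt_mean_ms),
            !is.null(subject$rt_sd_ms))
  q <- questionTable(protocol)
  win <- responseWindow(protocol)
  sInfl <- inflateSampleSd(subject$rt_mean_ms, subject$rt_sd_ms)
  par <- truncLnormParams(subject$rt_mean_ms, sInfl, win)
  pResp <- stats::plnorm(win, par[1], par[2])
  withSeed(childSeed(seed, subject$subject_id, "behavior"), {
    correct <- rbinom(10, 1, subject$acc_prob) == 1L
    rt <- numeric(10)
    # correct trials: conditional (in-window) draw; incorrect: raw draw,
    # with the out-of-window tail becoming a non-response
    u <- runif(10)
    rt[correct] <- stats::qlnorm(u[correct] * pResp, par[1], par[2])
    rt[!correct] <- rlnorm(sum(!correct), par[1], par[2])
    responded <- correct | rt <= win
    other <- ifelse(q$correct_key == "O", "X", "O")
    key <- ifelse(!responded, "none", ifelse(correct, q$correct_key, other))
    data.frame(subject_id = as.character(subject$subject_id),
               trial_index = 1:10, response_key = key, correct = correct,
               rt_ms = ifelse(responded, pmin(rt, win), NA_real_),
               stringsAsFactors = FALSE)
  })
}

# inflate a target observable (10-trial sample) SD to the generative SD,
# using a simulation-derived bias curve for skewed (log-normal) RTs:
# E[sampleSD]/trueSD ~= 1.0122 - 0.1533 cv - 0.0078 cv^2
inflateSampleSd <- function(m, s) {
  if (s <= 0) return(s)
  sTrue <- s
  for (i in 1:4) {
    cv <- min(sTrue / m, 2.5)
    r <- max(1.0122 - 0.1533 * cv - 0.0078 * cv^2, 0.55)
    sTrue <- min(s / r, 2.5 * m)
  }
  sTrue
}

# log-normal parameters (meanlog, sdlog) whose conditional-on-(X <= q)
# moments match the target mean m and sd s
truncLnormParams <- function(m, s, q) {
  stopifnot(m > 0, s >= 0, q > 0)
  if (s <= 1e-9) return(c(log(min(m, q)), 1e-6))
  sdl0 <- sqrt(log(1 + (s / m)^2))
  p0 <- c(log(m) - sdl0^2 / 2, log(sdl0))
  if (stats::plnorm(q, p0[1], exp(p0[2])) > 0.9999) return(c(p0[1], exp(p0[2])))
  lq <- log(q)
  obj <- function(p) {
    mu <- p[1]; sg <- exp(p[2])
    P <- pnorm((lq - mu) / sg)
    if (P < 1e-8) return(1e6)
    e1 <- exp(mu + sg^2 / 2) * pnorm((lq - mu - sg^2) / sg) / P
    e2 <- exp(2 * mu + 2 * sg^2) * pnorm((lq - mu - 2 * sg^2) / sg) / P
    v <- max(e2 - e1^2, 0)
    ((e1 - m) / m)^2 + ((sqrt(v) - s) / s)^2
  }
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  c(fit$par[1], exp(fit$par[2]))
}

#' Write a synthetic cohort to disk
#'
#' Emits the text artifacts of a cohort: one behavior CSV over all subjects,
#' one event CSV per recording, and a JSON manifest (subject ids, groups,
#' file paths, seeds). Recordings themselves stay in memory (returned
#' invisibly) unless \code{writeRecordings = TRUE}, in which case each is
#' saved as an RDS file.
#'
#' @param cohort a \code{\link{sampleCohort}} data.frame.
#' @param dir output directory (created if needed).
#' @param conditions conditions to synthesize.
#' @param protocol an \linkS4class{SQTProtocol}.
#' @param seed integer base seed.
#' @param channels,samplingRate acquisition profile.
#' @param writeRecordings save full signals as RDS.
#' @return invisibly, a list with \code{recordings}, \code{behavior} and
#'   \code{manifest}.
#' @export
writeCohort <- function(cohort, dir, conditions = c("REST", "SQT"),
                        protocol = loadProtocol(), seed = 1,
                        channels = montage19(), samplingRate = 512,
                        writeRecordings = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- list(); behs <- list(); entries <- list()
  for (i in seq_len(nrow(cohort))) {
    sub <- cohort[i, ]
    beh <- sampleBehavior(sub, protocol, seed = childSeed(seed, sub$subject_id, "beh"))
    behs[[i]] <- beh
    files <- list()
    for (cond in conditions) {
      rec <- synthesizeRecording(sub, cond, protocol, seed = seed,
                                 channels = channels,
                                 samplingRate = samplingRate, behavior = beh)
      key <- paste(sub$subject_id, cond, sep = "_")
      evFile <- file.path(dir, paste0("events_", key, ".csv"))
      write.csv(rec@events, evFile, row.names = FALSE)
      files[[cond]] <- basename(evFile)
      if (writeRecordings) {
        rdsFile <- file.path(dir, paste0("recording_", key, ".rds"))
        saveRDS(rec, rdsFile)
        files[[paste0(cond, "_signal")]] <- basename(rdsFile)
      }
      recs[[key]] <- rec
    }
    entries[[i]] <- list(subject_id = sub$subject_id, group = sub$group,
                         files = files)
  }
  behavior <- do.call(rbind, behs)
  write.csv(behavior, file.path(dir, "behavior.csv"), row.names = FALSE)
  manifest <- list(seed = seed, effect_size = attr(cohort, "effect_size"),
                   sampling_rate = samplingRate, channels = channels,
                   subjects = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(recordings = recs, behavior = behavior, manifest = manifest))
}

# normalize a one-row cohort data.frame (or already-list profile) to a list
asSubjectRow <- function(subject) {
  if (is.data.frame(subject)) as.list(subject[1, , drop = FALSE])
  else as.list(subject)
}
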