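#' Simulation parameters for synthetic physiological records
#'
#' Bundles everything the synthetic generator needs: the MAP process (a
#' smoothed mean-reverting diffusion with superimposed hypotension episodes),
#' the mechanistic coupling from MAP to the derived features, cuff timing and
#' noise, and waveform synthesis settings. Defaults emulate an adult
#' intraoperative record: MAP around 80 mmHg with slow drift in the
#' 50-150 mmHg operating range, cuff readings every 5 minutes equal to the
#' arterial value plus Gaussian error (mean 0, sd 3.1 mmHg), waveforms at
#' 125 Hz and derived series at 1 Hz.
#'
#' @param duration_s record length, seconds. Full records must be at least
#'   one hour (3600 s); [generate_record()] enforces this.
#' @param map_baseline mean-reversion level of the MAP process, mmHg.
#' @param map_reversion_rate reversion rate of the MAP process, 1/s.
#' @param map_volatility diffusion volatility, mmHg per sqrt(s).
#' @param map_smooth_s width (s) of the smoothing window applied to the
#'   diffusion so second-to-second gradients stay physiological (< 2 mmHg/s).
#' @param episode_rate hypotension episodes per hour.
#' @param episode_depth nominal episode depth, mmHg (per-episode depth is
#'   jittered by +/-30%).
#' @param episode_duration_s episode length, seconds (raised-cosine dip).
#' @param cuff_interval_s cuff measurement interval, seconds; 180, 300 and
#'   600 are the conventional settings.
#' @param cuff_noise_mu,cuff_noise_sigma cuff error model: reading =
#'   arterial MAP + N(mu, sigma^2), mmHg.
#' @param true_mech_params [mechanistic_params()] used as the ground-truth
#'   coupling from MAP to (HR, PI, NRA).
#' @param feature_noise_sd dimensionless noise level for the observed derived
#'   features; 1.0 corresponds to about 1 mmHg of MAP-scale residual (see
#'   [simulate_latent_features()]).
#' @param waveform_fs waveform sampling rate; fixed at 125 Hz.
#' @param derived_fs derived-series rate; fixed at 1 Hz.
#' @param seed integer seed; every generator is a pure function of
#'   (params, seed).
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(duration_s = 3600, map_baseline = 80,
                       map_reversion_rate = 1 / 300, map_volatility = 0.6,
                       map_smooth_s = 9, episode_rate = 2, episode_depth = 12,
                       episode_duration_s = 240, cuff_interval_s = 300,
                       cuff_noise_mu = 0, cuff_noise_sigma = 3.1,
                       true_mech_params = mechanistic_params(),
                       feature_noise_sd = 1, waveform_fs = 125,
                       derived_fs = 1, seed = 1L) {
  stopifnot_scalar(duration_s, "duration_s", lo = 1)
  stopifnot_scalar(cuff_interval_s, "cuff_interval_s", lo = 1)
  stopifnot_scalar(cuff_noise_sigma, "cuff_noise_sigma", lo = 0)
  stopifnot_scalar(feature_noise_sd, "feature_noise_sd", lo = 0)
  if (waveform_fs != 125) stop("waveform_fs is fixed at 125 Hz")
  if (derived_fs != 1) stop("derived_fs is fixed at 1 Hz")
  stopifnot(inherits(true_mech_params, "mechanistic_params"))
  structure(list(
    duration_s = as.integer(duration_s), map_baseline = map_baseline,
    map_reversion_rate = map_reversion_rate, map_volatility = map_volatility,
    map_smooth_s = as.integer(map_smooth_s), episode_rate = episode_rate,
    episode_depth = episode_depth,
    episode_duration_s = as.integer(episode_duration_s),
    cuff_interval_s = as.integer(cuff_interval_s),
    cuff_noise_mu = cuff_noise_mu, cuff_noise_sigma = cuff_noise_sigma,
    true_mech_params = true_mech_params,
    feature_noise_sd = feature_noise_sd, waveform_fs = 125L, derived_fs = 1L,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate a 1 Hz mean arterial pressure trajectory
#'
#' MAP is modelled as an Ornstein-Uhlenbeck process around `map_baseline`
#' (exact discretization at 1 Hz), smoothed with a short moving-average
#' window so that second-to-second gradients remain physiological, plus
#' raised-cosine hypotension dips arriving as a Poisson process. Values are
#' clipped to \[40, 160\] mmHg. Identical `(params, seed)` give a bitwise
#' identical series.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed (defaults to `params$seed`).
#' @return numeric vector of length `duration_s` (sample i is the MAP over
#'   second \[i-1, i)).
#' @export
simulate_map_trajectory <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$duration_s
  if (n <= 0) stop("duration_s must be positive")
  with_seed(seed, {
    th <- params$map_reversion_rate
    vol <- params$map_volatility
    w <- max(1L, params$map_smooth_s)
    # simulate with a left runway of w samples so smoothing stays causal-ish
    # and the first sample is already stationary
    m <- n + w
    if (th > 0) {
      a <- exp(-th)
      s_step <- vol * sqrt((1 - a^2) / (2 * th))
      s_stat <- vol / sqrt(2 * th)
    } else {
      a <- 1
      s_step <- vol
      s_stat <- 0
    }
    x <- numeric(m)
    x[1] <- rnorm(1, 0, s_stat)
    eps <- rnorm(m - 1, 0, s_step)
    for (i in seq_len(m - 1)) x[i + 1] <- a * x[i] + eps[i]
    if (w > 1L) {
      x <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
      x <- x[!is.na(x)]
    }
    x <- params$map_baseline + x[seq_len(n)]
    # hypotension episodes
    n_ep <- rpois(1, params$episode_rate * n / 3600)
    if (n_ep > 0 && params$episode_depth > 0) {
      starts <- runif(n_ep, 0, n)
      depths <- params$episode_depth * runif(n_ep, 0.7, 1.3)
      for (k in seq_len(n_ep)) {
        t0 <- starts[k]
        idx <- which(seq_len(n) - 1 >= t0 &
                       seq_len(n) - 1 < t0 + params$episode_duration_s)
        if (length(idx)) {
          u <- ((idx - 1) - t0) / params$episode_duration_s
          x[idx] <- x[idx] - depths[k] * 0.5 * (1 - cos(2 * base::pi * u))
        }
      }
    }
    clip(x, 40, 160)
  })
}

# fixed per-feature noise scales: calibrated once so that feature_noise_sd = 1
# induces ~1 mmHg of MAP-scale residual at the default operating point
# (HR 75 bpm, PI 5 %, NRA 0.38, default mechanistic parameters), split
# equally across the three features
.feature_noise_scale <- c(hr = 0.8635, pi = 0.2357, nra = 0.011285)

#' Simulate latent derived features consistent with the mechanistic model
#'
#' Draws smooth HR and PI processes, then solves the Ohm-Poiseuille identity
#' pointwise for NRA so that, with zero feature noise, the forward formula
#' applied to the latent features reproduces the MAP series exactly. HR is
#' partially coupled to MAP (heart rate rises with pressure under this
#' generator) with an added slow fluctuation; PI follows a slow log-scale
#' fluctuation. Where the solved NRA falls outside (0, 1) it is clamped and
#' the identity is restored by adjusting HR (then PI) within physiological
#' bounds; samples where no consistent solution exists count toward a 5%
#' rejection budget.
#'
#' Observed features add Gaussian noise `feature_noise_sd` times a fixed
#' per-feature scale (0.864 bpm for HR, 0.236 for PI, 0.0113 for NRA),
#' calibrated so `feature_noise_sd = 1` yields about 1 mmHg of residual when
#' the noisy features are pushed through the mechanistic formula.
#'
#' @param map_1hz numeric MAP series, values in (0, 200) mmHg.
#' @param true_mech_params [mechanistic_params()] with positive `alpha`.
#' @param feature_noise_sd noise level (0 = noise-free).
#' @param seed integer seed.
#' @return list with observed series `hr`, `pi`, `nra`, latent (noise-free)
#'   series `latent_hr`, `latent_pi`, `latent_nra`, and `n_inconsistent`.
#' @export
simulate_latent_features <- function(map_1hz, true_mech_params,
                                     feature_noise_sd = 1, seed = 1L) {
  stopifnot(inherits(true_mech_params, "mechanistic_params"))
  if (true_mech_params$alpha <= 0) {
    stop("true_mech_params$alpha must be positive (degenerate coupling)")
  }
  if (any(map_1hz <= 0 | map_1hz >= 200)) {
    stop("map_1hz values must lie in (0, 200) mmHg")
  }
  n <- length(map_1hz)
  p <- true_mech_params
  with_seed(seed, {
    ou <- function(n, tau, sd_stat) {
      a <- exp(-1 / tau)
      x <- numeric(n)
      x[1] <- rnorm(1, 0, sd_stat)
      eps <- rnorm(n - 1, 0, sd_stat * sqrt(1 - a^2))
      for (i in seq_len(n - 1)) x[i + 1] <- a * x[i] + eps[i]
      x
    }
    hr <- clip(75 + 0.4 * (map_1hz - 80) + ou(n, 60, 3), 40, 140)
    pi <- clip(5 * exp(ou(n, 120, 0.15)), 0.11, 20)
    lnterm <- log(1 + 1 / pi) + p$beta

    solve_nra <- function(hr) (map_1hz - p$delta) / (p$alpha * lnterm * hr) -
      p$beta_prime
    nra <- solve_nra(hr)
    bad <- nra <= 0.01 | nra >= 0.99
    n_bad0 <- sum(bad)
    if (n_bad0 > 0) {
      # clamp NRA, restore the identity through HR
      nra[bad] <- clip(nra[bad], 0.01, 0.99)
      hr_fix <- (map_1hz[bad] - p$delta) /
        (p$alpha * lnterm[bad] * (nra[bad] + p$beta_prime))
      hr[bad] <- clip(hr_fix, 40, 140)
      still <- bad
      still[bad] <- abs(hr[bad] - hr_fix) > 1e-9
      if (any(still)) {
        # last resort: restore through the log-perfusion term
        need <- (map_1hz[still] - p$delta) /
          (p$alpha * (nra[still] + p$beta_prime) * hr[still]) - p$beta
        need <- clip(need, log(1 + 1 / 20), log(1 + 1 / 0.11))
        pi[still] <- 1 / (exp(need) - 1)
        lnterm[still] <- need + p$beta
      }
    }
    resid <- map_1hz - mechanistic_predict(hr, pi, nra, p)
    n_inconsistent <- sum(abs(resid) > 1e-9)
    if (n_inconsistent > 0.05 * n) {
      stop(sprintf(
        "no consistent NRA solution in (0,1) for %.1f%% of samples (> 5%%): %s",
        100 * n_inconsistent / n,
        "mechanistic parameters incompatible with this MAP range"))
    }
    s <- feature_noise_sd * .feature_noise_scale
    list(
      hr = clip(hr + rnorm(n, 0, s[["hr"]]), 40, 140),
      pi = clip(pi + rnorm(n, 0, s[["pi"]]), 0.11, 20),
      nra = clip(nra + rnorm(n, 0, s[["nra"]]), 0.001, 0.999),
      latent_hr = hr, latent_pi = pi, latent_nra = nra,
      n_inconsistent = n_inconsistent)
  })
}

# unit pulse template sampled at `ns` points over one beat: foot at 0,
# systolic peak at 1, dicrotic notch at relative height `nra`
.pulse_template <- function(ns, nra) {
  u <- (seq_len(ns) - 1) / ns
  u_p <- 0.22; u_n <- 0.45; u_d <- 0.60
  bump <- 0.2 * (1 - nra)          # dicrotic lobe height above the notch
  y <- numeric(ns)
  s1 <- u < u_p
  y[s1] <- 0.5 * (1 - cos(base::pi * u[s1] / u_p))
  s2 <- u >= u_p & u < u_n
  y[s2] <- nra + (1 - nra) * 0.5 * (1 + cos(base::pi * (u[s2] - u_p) / (u_n - u_p)))
  s3 <- u >= u_n & u < u_d
  y[s3] <- nra + bump * 0.5 * (1 - cos(base::pi * (u[s3] - u_n) / (u_d - u_n)))
  s4 <- u >= u_d
  y[s4] <- (nra + bump) * 0.5 * (1 + cos(base::pi * (u[s4] - u_d) / (1 - u_d)))
  y
}

#' Synthesize beat-resolved PPG and ECG waveforms at 125 Hz
#'
#' PPG is built beat by beat from a two-lobe template (systolic lobe plus a
#' dicrotic lobe separated by the notch) on a DC baseline of 1.0 arbitrary
#' unit. Within each beat the pulsatile amplitude is solved so that
#' `100 * AC / DC` (DC = beat mean of the raw PPG) equals the target PI at
#' that second, and the notch height is placed so that
#' `(notch - foot) / (peak - foot)` equals the target NRA. Beat period comes
#' from the target HR. The ECG is a nuisance channel carrying an R-spike per
#' beat plus low-amplitude noise.
#'
#' @param hr_1hz,pi_1hz,nra_1hz target feature series on a common 1 Hz grid.
#' @param seed integer seed (ECG noise).
#' @param ppg_noise_sd additive PPG noise, signal units (default 0:
#'   noise-free morphology).
#' @return list with `ppg`, `ecg` (length `125 * duration`), and
#'   `beat_times` (seconds, strictly increasing; one entry per beat foot).
#' @export
synthesize_waveforms <- function(hr_1hz, pi_1hz, nra_1hz, seed = 1L,
                                 ppg_noise_sd = 0) {
  n <- length(hr_1hz)
  stopifnot(length(pi_1hz) == n, length(nra_1hz) == n)
  if (any(is.na(hr_1hz)) || any(hr_1hz <= 0)) {
    stop("hr_1hz must be positive everywhere")
  }
  fs <- 125L
  nw <- n * fs
  with_seed(seed, {
    ppg <- numeric(nw)
    ecg <- rnorm(nw, 0, 0.02)
    beat_times <- numeric(0)
    t <- 0
    baseline <- 1.0
    while (t < n) {
      sec <- min(n, floor(t) + 1)
      period <- 60 / hr_1hz[sec]
      i0 <- round(t * fs) + 1
      i1 <- min(nw, round((t + period) * fs))
      if (i0 > nw) break
      ns <- i1 - i0 + 1
      if (ns >= 4) {
        nra <- clip(nra_1hz[sec], 0.001, 0.999)
        tmpl <- .pulse_template(ns, nra)
        m_bar <- mean(tmpl)
        p_frac <- pi_1hz[sec] / 100
        amp <- p_frac * baseline / (1 - p_frac * m_bar)
        ppg[i0:i1] <- baseline + amp * tmpl
        ecg[i0] <- ecg[i0] + 1
        if (i1 > i0) ecg[i0 + 1] <- ecg[i0 + 1] - 0.2
        beat_times <- c(beat_times, t)
      }
      t <- t + period
    }
    if (ppg_noise_sd > 0) ppg <- ppg + rnorm(nw, 0, ppg_noise_sd)
    list(ppg = ppg, ecg = ecg, beat_times = beat_times)
  })
}

#' Synthesize intermittent cuff measurements
#'
#' One event at t = 0 and every `cuff_interval_s` thereafter, up to and
#' including the record end; the reading equals the arterial MAP at the event
#' time plus Gaussian error `N(mu, sigma^2)`. The arterial value at time t is
#' the 1 Hz sample covering t (the final sample for t at the record end).
#'
#' @param map_1hz arterial MAP series, 1 Hz.
#' @param cuff_interval_s interval between events, seconds (> 0).
#' @param mu,sigma cuff error mean and sd, mmHg (`sigma >= 0`).
#' @param seed integer seed.
#' @return data.frame with columns `time_s`, `map_mmHg`.
#' @export
synthesize_cuff <- function(map_1hz, cuff_interval_s, mu = 0, sigma = 3.1,
                            seed = 1L) {
  if (cuff_interval_s <= 0) stop("cuff_interval_s must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  n <- length(map_1hz)
  times <- seq(0, n, by = cuff_interval_s)
  arterial <- map_1hz[pmin(floor(times), n - 1) + 1]
  with_seed(seed, {
    vals <- arterial + rnorm(length(times), mu, sigma)
    data.frame(time_s = times, map_mmHg = clip(vals, 20, 250))
  })
}

#' Generate a complete synthetic patient record with ground truth
#'
#' Chains the four generators: MAP trajectory, mechanistically consistent
#' latent features, beat-resolved waveforms (built from the latent,
#' noise-free features), and noisy cuff events. The record's derived channels
#' carry the noisy observed features; the returned ground truth retains the
#' latent series, beat times and true mechanistic parameters for
#' parameter-recovery and oracle tests.
#'
#' @param params a [sim_params()] object; `duration_s` must be >= 3600 (one
#'   hour, the minimum accepted record length).
#' @return list with `record` (a [physio_record()]) and `truth` (class
#'   `ground_truth`: `map_1hz`, `beat_times`, `latent_hr`, `latent_pi`,
#'   `latent_nra`, `true_mech_params`).
#' @export
#' @examples
#' rec <- generate_record(sim_params(duration_s = 3600, seed = 7))
#' print(rec$record)
generate_record <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$duration_s < 3600) {
    stop("duration_s must be at least 3600 s (minimum accepted record length)")
  }
  seeds <- derive_seeds(params$seed, 4L)
  map <- simulate_map_trajectory(params, seed = seeds[1])
  feats <- simulate_latent_features(map, params$true_mech_params,
                                    params$feature_noise_sd, seed = seeds[2])
  waves <- synthesize_waveforms(feats$latent_hr, feats$latent_pi,
                                feats$latent_nra, seed = seeds[3])
  cuff <- synthesize_cuff(map, params$cuff_interval_s, params$cuff_noise_mu,
                          params$cuff_noise_sigma, seed = seeds[4])
  record <- physio_record(
    patient_id = sprintf("synth-%06d", params$seed %% 1000000L),
    ppg = waves$ppg, ecg = waves$ecg,
    hr = feats$hr, pi = feats$pi, nra = feats$nra, map_ref = map,
    cuff_events = cuff, duration_s = params$duration_s)
  truth <- structure(list(
    map_1hz = map, beat_times = waves$beat_times,
    latent_hr = feats$latent_hr, latent_pi = feats$latent_pi,
    latent_nra = feats$latent_nra,
    true_mech_params = params$true_mech_params), class = "ground_truth")
  list(record = record, truth = truth)
}

#' Inject artifacts into a record
#'
#' Returns a modified copy of the record with named corruption patterns
#' applied; samples outside the artifact windows are bitwise unchanged.
#' Supported types:
#' \describe{
#'   \item{missing_run}{marks the window missing (mask TRUE, value `NA`).}
#'   \item{flatline}{holds the channel at its value at the window start (or
#'     at `magnitude` if given).}
#'   \item{level_shift}{adds `magnitude`, with an optional raised-cosine
#'     onset over `ramp_s` seconds (default 0 = step).}
#'   \item{spike_train}{adds spikes of height `magnitude` every
#'     `spike_period_s` seconds (default 10) within the window.}
#' }
#'
#' @param record a [physio_record()].
#' @param artifacts list of artifact specs; each a list with `type`,
#'   `channel` (one of ppg, ecg, hr, pi, nra, map_ref), `start_s`,
#'   `length_s`, and optionally `magnitude`, `ramp_s`, `spike_period_s`.
#' @param seed integer seed (reserved for stochastic artifact types; current
#'   types are deterministic).
#' @return a modified [physio_record()].
#' @export
inject_artifacts <- function(record, artifacts, seed = 1L) {
  stopifnot(inherits(record, "physio_record"))
  if (length(artifacts) == 0) return(record)
  dur <- record$meta$duration_s
  for (a in artifacts) {
    type <- match.arg(a$type,
                      c("missing_run", "flatline", "level_shift", "spike_train"))
    ch <- match.arg(a$channel, c("ppg", "ecg", "hr", "pi", "nra", "map_ref"))
    fs <- if (ch %in% c("ppg", "ecg")) record$meta$fs_wave else 1L
    start_s <- a$start_s
    length_s <- a$length_s
    if (start_s < 0 || length_s <= 0 || start_s + length_s > dur) {
      stop(sprintf("artifact window [%g, %g) outside record [0, %d)",
                   start_s, start_s + length_s, dur))
    }
    i0 <- floor(start_s * fs) + 1
    i1 <- min(length(record[[ch]]$value), ceiling((start_s + length_s) * fs))
    idx <- i0:i1
    if (type == "missing_run") {
      record[[ch]]$missing[idx] <- TRUE
      record[[ch]]$value[idx] <- NA_real_
    } else if (type == "flatline") {
      level <- a$magnitude %||% record[[ch]]$value[i0]
      if (is.na(level)) level <- 0
      record[[ch]]$value[idx] <- level
      record[[ch]]$missing[idx] <- FALSE
    } else if (type == "level_shift") {
      mag <- a$magnitude %||% 0
      ramp_s <- a$ramp_s %||% 0
      shift <- rep(mag, length(idx))
      if (ramp_s > 0) {
        nr <- min(length(idx), round(ramp_s * fs))
        shift[seq_len(nr)] <- mag * 0.5 * (1 - cos(base::pi * seq_len(nr) / nr))
      }
      record[[ch]]$value[idx] <- record[[ch]]$value[idx] + shift
    } else if (type == "spike_train") {
      mag <- a$magnitude %||% 0
      period <- a$spike_period_s %||% 10
      at <- seq(i0, i1, by = max(1, round(period * fs)))
      record[[ch]]$value[at] <- record[[ch]]$value[at] + mag
    }
  }
  record
}

#' Simulation parameters for a cohort of synthetic patients
#'
#' Builds one [sim_params()] per patient from a shared base, with seeded
#' inter-patient variability: each patient draws their own MAP operating
#' point (`map_baseline`, normal sd 6 mmHg, clipped to \[70, 92\]) and their
#' own mechanistic intercept `delta` (coupled to the operating point with
#' slope 0.8 plus normal sd 6 mmHg, clipped to \[15, min(45, baseline - 41)\]),
#' plus a private record seed. The intercept jitter emulates inter-patient
#' differences in vascular tone: it shifts the whole feature-to-MAP map by a
#' patient-specific offset that no amount of feature observation can reveal,
#' which is precisely what cuff calibration is for. Its spread (~6-7 mmHg)
#' is deliberately about twice the cuff error sd, so a single cuff reading
#' carries real information about the patient's offset — in a cohort where
#' the offset spread were smaller than the cuff noise, calibration would be
#' worthless and calibrated estimators untestable. The coupling to the
#' operating point keeps the notch-amplitude solution inside (0, 1) across
#' hypotensive dips (low-pressure patients get low intercepts).
#'
#' @param n_patients number of patients.
#' @param base a [sim_params()] used as the template.
#' @param seed integer cohort seed.
#' @return list of `sim_params`, one per patient.
#' @export
cohort_params <- function(n_patients, base = sim_params(), seed = 1L) {
  stopifnot(inherits(base, "sim_params"), n_patients >= 1)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
    baselines <- clip(rnorm(n_patients, base$map_baseline, 6), 70, 92)
    d0 <- base$true_mech_params$delta
    deltas <- clip(d0 + 0.8 * (baselines - 80) + rnorm(n_patients, 0, 6),
                   15, pmin(45, baselines - 41))
    lapply(seq_len(n_patients), function(i) {
      p <- base
      p$seed <- seeds[i]
      p$map_baseline <- baselines[i]
      p$true_mech_params$delta <- deltas[i]
      p
    })
  })
}
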