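#' Behaviour profile for the gaze simulator
#'
#' A behaviour profile holds the generative parameters of one participant
#' type: a phase schedule of AOI attention weights, fixation/saccade
#' dynamics, blink statistics and the pupil response model.
#'
#' @param label `"expert"` or `"novice"` (free-form labels allowed).
#' @param phase_schedule data frame with columns `phase`, `start_s`,
#'   `end_s`, plus one weight column per region name; weights must be
#'   nonnegative and sum to 1 within each phase.
#' @param fix_median_ms,fix_sigma median (ms) and log-scale sigma of the
#'   lognormal fixation-duration distribution.
#' @param jitter_sd_px within-fixation positional jitter sd, pixels per
#'   axis.  Must satisfy `jitter_sd_px <= ivt_threshold * dt / 4` at the
#'   scenario's sampling interval so that within-fixation speeds stay below
#'   the velocity threshold with probability > 0.999.
#' @param saccade_ms `c(min, max)` saccade duration, ms.
#' @param blink_per_min blink rate (Poisson), per minute.
#' @param blink_ms `c(min, max)` blink duration, ms.
#' @param pupil_baseline_mm baseline pupil diameter.
#' @param pupil_amp_mm amplitude of the anomaly-locked dilation response.
#' @param pupil_lag_s lag of the pupil response behind anomaly onset.
#' @param pupil_noise_sd per-eye measurement noise sd, mm.
#' @return List of class `behavior_profile`.
#' @export
behavior_profile <- function(label, phase_schedule,
                             fix_median_ms = 300, fix_sigma = 0.4,
                             jitter_sd_px = 0.25,
                             saccade_ms = c(20, 60),
                             blink_per_min = 15, blink_ms = c(100, 300),
                             pupil_baseline_mm = 3.2, pupil_amp_mm = 0.5,
                             pupil_lag_s = 1, pupil_noise_sd = 0.05) {
  req <- c("phase", "start_s", "end_s")
  stopifnot(is.data.frame(phase_schedule), all(req %in% names(phase_schedule)))
  wcols <- setdiff(names(phase_schedule), req)
  if (length(wcols) < 2L) stop("phase_schedule needs at least two region weight columns")
  w <- as.matrix(phase_schedule[wcols])
  if (any(w < 0)) stop("AOI weights must be nonnegative")
  if (any(abs(rowSums(w) - 1) > 1e-9)) stop("AOI weights must sum to 1 in every phase")
  if (any(phase_schedule$start_s >= phase_schedule$end_s)) {
    stop("each phase needs start_s < end_s")
  }
  structure(list(label = label, phase_schedule = phase_schedule,
                 regions = wcols,
                 fix_median_ms = fix_median_ms, fix_sigma = fix_sigma,
                 jitter_sd_px = jitter_sd_px, saccade_ms = saccade_ms,
                 blink_per_min = blink_per_min, blink_ms = blink_ms,
                 pupil_baseline_mm = pupil_baseline_mm,
                 pupil_amp_mm = pupil_amp_mm, pupil_lag_s = pupil_lag_s,
                 pupil_noise_sd = pupil_noise_sd),
            class = "behavior_profile")
}

#' Default five-minute monitoring scenario
#'
#' The reference scenario every default ships with: a five-minute (300 s)
#' recording at 300 Hz on a synthetic 1920x1080 display carrying two named
#' AOIs over the right-hand indicator tracks of a scrolling well-log panel
#' (stand-in rectangles; the geometry is synthetic), an anomaly present from
#' 2:00 to 2:50, and a cohort of 23 novices plus 1 expert.
#'
#' @param seed integer seed driving all cohort randomness.
#' @return List of class `scenario_config` with elements `duration_s`,
#'   `rate_hz`, `screen_w`, `screen_h`, `scheme` ([aoi_scheme()]),
#'   `anomaly_s`, `n_novices`, `n_experts`, `seed`.
#' @export
default_scenario <- function(seed = 1) {
  scheme <- aoi_scheme(
    data.frame(name = c("AOI II", "AOI III"),
               x0 = c(1150, 1510), y0 = c(100, 100),
               x1 = c(1500, 1880), y1 = c(1000, 1000)),
    screen = c(1920, 1080), complement_name = "AOI I")
  structure(list(duration_s = 300, rate_hz = 300,
                 screen_w = 1920, screen_h = 1080,
                 scheme = scheme, anomaly_s = c(120, 170),
                 n_novices = 23, n_experts = 1, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default expert and novice behaviour profiles
#'
#' Both profiles share identical pre-anomaly (and post-anomaly) attention
#' weights — 70% on the full-log complement region, 15% on each named AOI —
#' so that every expert/novice difference is isolated to the anomaly
#' response: during the anomaly the expert shifts 70% of attention onto
#' AOI III (the confirming indicators) with a 0.5 mm pupil dilation, while
#' the novice stays on the complement region (75%, only 10% on AOI III)
#' with a damped 0.2 mm dilation.
#'
#' @param anomaly_s anomaly window in seconds, `c(start, end)`.
#' @param duration_s scenario duration in seconds.
#' @return `list(expert =, novice =)` of [behavior_profile()]s.
#' @export
default_profiles <- function(anomaly_s = c(120, 170), duration_s = 300) {
  sched <- function(anomaly_w) {
    rbind(
      data.frame(phase = "pre", start_s = 0, end_s = anomaly_s[1L],
                 `AOI I` = 0.70, `AOI II` = 0.15, `AOI III` = 0.15,
                 check.names = FALSE),
      cbind(data.frame(phase = "anomaly", start_s = anomaly_s[1L],
                       end_s = anomaly_s[2L]),
            as.data.frame(as.list(anomaly_w), check.names = FALSE)),
      data.frame(phase = "post", start_s = anomaly_s[2L], end_s = duration_s,
                 `AOI I` = 0.70, `AOI II` = 0.15, `AOI III` = 0.15,
                 check.names = FALSE))
  }
  list(
    expert = behavior_profile(
      "expert",
      sched(c("AOI I" = 0.15, "AOI II" = 0.15, "AOI III" = 0.70)),
      pupil_amp_mm = 0.5),
    novice = behavior_profile(
      "novice",
      sched(c("AOI I" = 0.75, "AOI II" = 0.15, "AOI III" = 0.10)),
      pupil_amp_mm = 0.2))
}

# uniform draw inside a named region of the scheme; the complement is
# rejection-sampled uniformly on the screen outside every named rectangle
sample_region_points <- function(region, n, scheme) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  named <- match(region, scheme$aois$name)
  if (!is.na(named)) {
    a <- scheme$aois[named, ]
    return(cbind(x = stats::runif(n, a$x0, a$x1), y = stats::runif(n, a$y0, a$y1)))
  }
  x <- numeric(n); y <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    px <- stats::runif(length(need), 0, scheme$screen_w)
    py <- stats::runif(length(need), 0, scheme$screen_h)
    inside <- rep(FALSE, length(need))
    for (i in seq_len(nrow(scheme$aois))) {
      a <- scheme$aois[i, ]
      inside <- inside | (px >= a$x0 & px < a$x1 & py >= a$y0 & py < a$y1)
    }
    x[need[!inside]] <- px[!inside]
    y[need[!inside]] <- py[!inside]
    need <- need[inside]
  }
  cbind(x = x, y = y)
}

# smooth anomaly-locked dilation: raised cosine over the lagged window
pupil_bump <- function(t_ms, profile, anomaly_s) {
  t0 <- (anomaly_s[1L] + profile$pupil_lag_s) * 1000
  t1 <- (anomaly_s[2L] + profile$pupil_lag_s) * 1000
  b <- numeric(length(t_ms))
  inw <- t_ms >= t0 & t_ms < t1
  b[inw] <- profile$pupil_amp_mm * 0.5 * (1 - cos(2 * pi * (t_ms[inw] - t0) / (t1 - t0)))
  b
}

#' Simulate one gaze recording
#'
#' Generates a raw gaze sample stream with the statistical structure the
#' analysis pipeline assumes, together with its ground truth: alternating
#' fixation/saccade events (AOI drawn from the active phase's weight map,
#' fixation centre uniform inside the chosen region, lognormal durations,
#' Gaussian within-fixation jitter, linear constant-velocity saccades),
#' Poisson-scheduled blinks that blank gaze validity and both pupil
#' channels, and per-eye pupil diameters sharing one latent signal
#' (baseline + smooth anomaly-locked dilation) plus independent noise.
#' Blinks overlay the event timeline, so the event durations partition the
#' recording as fixations + saccades while blink spans are tracked
#' separately.
#'
#' @param profile a [behavior_profile()].
#' @param scenario a `scenario_config` ([default_scenario()]).
#' @param seed integer; the simulation is fully reproducible from it.
#' @param ivt_threshold velocity threshold used only for the jitter
#'   feasibility check (px/ms).
#' @return List of class `gaze_simulation`: `recording` (a
#'   [gaze_recording()]) and `truth`, a list with `fixations` (data frame
#'   `onset_ms`, `offset_ms`, `cx`, `cy`, `aoi`, `phase`), `saccades`,
#'   `blinks`, `pupil` (data frame `t_ms`, `d` of the latent noise-free
#'   signal) and `phase_schedule`.
#' @export
simulate_recording <- function(profile, scenario, seed,
                               ivt_threshold = 0.42) {
  set.seed(as.integer(seed))
  dt <- 1000 / scenario$rate_hz
  if (profile$jitter_sd_px > ivt_threshold * dt / 4) {
    stop(sprintf(
      "configuration error: jitter sd %.3g px exceeds threshold*dt/4 = %.3g px",
      profile$jitter_sd_px, ivt_threshold * dt / 4))
  }
  dur_ms <- scenario$duration_s * 1000
  sched <- profile$phase_schedule

  # --- event timeline: fixation, saccade, fixation, ... ------------------
  n_ev <- ceiling(dur_ms / (profile$fix_median_ms * 0.5)) + 16L
  fix_d <- stats::rlnorm(n_ev, log(profile$fix_median_ms), profile$fix_sigma)
  sac_d <- stats::runif(n_ev, profile$saccade_ms[1L], profile$saccade_ms[2L])
  ev_dur <- as.vector(rbind(fix_d, sac_d))          # f1 s1 f2 s2 ...
  ev_end <- cumsum(ev_dur)
  n_keep <- which(ev_end >= dur_ms)[1L]
  if (is.na(n_keep)) stop("internal: event horizon too short")  # nocov
  ev_dur <- ev_dur[seq_len(n_keep)]
  ev_start <- c(0, cumsum(ev_dur))[seq_len(n_keep)]
  ev_end <- pmin(ev_start + ev_dur, dur_ms)
  is_fix <- (seq_len(n_keep) %% 2L) == 1L

  # AOI of each fixation, drawn from the weights of the phase of its onset
  fi <- which(is_fix)
  phase_idx <- findInterval(ev_start[fi] / 1000, sched$start_s,
                            rightmost.closed = TRUE)
  phase_idx[phase_idx < 1L] <- 1L
  phase_idx[phase_idx > nrow(sched)] <- nrow(sched)
  aoi <- character(length(fi))
  for (p in seq_len(nrow(sched))) {
    inp <- phase_idx == p
    if (!any(inp)) next
    w <- as.numeric(sched[p, profile$regions])
    aoi[inp] <- sample(profile$regions, sum(inp), replace = TRUE, prob = w)
  }
  cx <- numeric(length(fi)); cy <- numeric(length(fi))
  for (rg in unique(aoi)) {
    sel <- aoi == rg
    pts <- sample_region_points(rg, sum(sel), scenario$scheme)
    cx[sel] <- pts[, "x"]; cy[sel] <- pts[, "y"]
  }

  # --- samples ------------------------------------------------------------
  n_samp <- floor(dur_ms / dt)
  t <- (seq_len(n_samp) - 1L) * dt
  ev_of <- findInterval(t, ev_start)
  fix_of <- match(ev_of, fi)                        # fixation number or NA
  x <- numeric(n_samp); y <- numeric(n_samp)
  infix <- !is.na(fix_of)
  x[infix] <- cx[fix_of[infix]] + stats::rnorm(sum(infix), 0, profile$jitter_sd_px)
  y[infix] <- cy[fix_of[infix]] + stats::rnorm(sum(infix), 0, profile$jitter_sd_px)
  if (any(!infix)) {
    si <- which(!infix)
    sac_ev <- ev_of[si]
    from <- pmin(pmax((sac_ev + 1L) %/% 2L, 1L), length(fi))  # preceding fixation
    to <- pmin(from + 1L, length(fi))
    frac <- (t[si] - ev_start[sac_ev]) / ev_dur[sac_ev]
    x[si] <- cx[from] + frac * (cx[to] - cx[from])
    y[si] <- cy[from] + frac * (cy[to] - cy[from])
  }

  # --- blinks (overlay: gaze + pupil validity drop) -----------------------
  n_blink <- stats::rpois(1L, profile$blink_per_min * scenario$duration_s / 60)
  blink_on <- sort(stats::runif(n_blink, 0, dur_ms))
  blink_dur <- stats::runif(n_blink, profile$blink_ms[1L], profile$blink_ms[2L])
  blink_off <- pmin(blink_on + blink_dur, dur_ms)
  in_blink <- rep(FALSE, n_samp)
  for (b in seq_len(n_blink)) {
    in_blink <- in_blink | (t >= blink_on[b] & t < blink_off[b])
  }

  # --- pupil channels -----------------------------------------------------
  latent <- profile$pupil_baseline_mm + pupil_bump(t, profile, scenario$anomaly_s)
  pl <- latent + stats::rnorm(n_samp, 0, profile$pupil_noise_sd)
  pr <- latent + stats::rnorm(n_samp, 0, profile$pupil_noise_sd)
  pl[in_blink] <- NA_real_
  pr[in_blink] <- NA_real_
  x[in_blink] <- NA_real_
  y[in_blink] <- NA_real_
  valid <- !in_blink

  recording <- gaze_recording(
    data.frame(t_ms = t, x = x, y = y, pupil_l = pl, pupil_r = pr,
               valid_l = valid, valid_r = valid),
    rate_hz = scenario$rate_hz,
    screen = c(scenario$screen_w, scenario$screen_h))

  truth <- list(
    fixations = data.frame(onset_ms = ev_start[fi], offset_ms = ev_end[fi],
                           cx = cx, cy = cy, aoi = aoi,
                           phase = sched$phase[phase_idx]),
    saccades = data.frame(onset_ms = ev_start[!is_fix], offset_ms = ev_end[!is_fix]),
    blinks = data.frame(onset_ms = blink_on, offset_ms = blink_off),
    pupil = data.frame(t_ms = t, d = latent),
    phase_schedule = sched)
  structure(list(recording = recording, truth = truth, profile = profile,
                 scenario = scenario, seed = as.integer(seed)),
            class = "gaze_simulation")
}

#' @export
print.gaze_simulation <- function(x, ...) {
  cat(sprintf("<gaze_simulation> profile \"%s\", seed %d\n", x$profile$label, x$seed))
  print(x$recording)
  cat(sprintf("  truth: %d fixations, %d blinks\n",
              nrow(x$truth$fixations), nrow(x$truth$blinks)))
  invisible(x)
}

# small multiplicative perturbation of a novice profile for one participant
jitter_profile <- function(profile, sd_log = 0.1) {
  sched <- profile$phase_schedule
  w <- as.matrix(sched[profile$regions])
  w <- w * exp(matrix(stats::rnorm(length(w), 0, sd_log), nrow(w)))
  w <- w / rowSums(w)
  sched[profile$regions] <- w
  profile$phase_schedule <- sched
  profile$fix_median_ms <- profile$fix_median_ms * exp(stats::rnorm(1L, 0, sd_log))
  profile$pupil_amp_mm <- profile$pupil_amp_mm * stats::runif(1L, 0.8, 1.2)
  profile
}

#' Simulate a full study cohort
#'
#' Generates the scenario's cohort — by default 23 novices (each with a
#' small multiplicative perturbation of the novice profile, emulating
#' between-participant variability) and 1 expert — from distinct seeds
#' derived deterministically from the scenario seed.
#'
#' @param scenario a `scenario_config`; its `seed` drives everything.
#' @param profiles `list(expert =, novice =)`; default [default_profiles()]
#'   at the scenario's anomaly window.
#' @return List of class `gaze_cohort`: `simulations` (list of
#'   `gaze_simulation`, experts first) and `manifest` (data frame `id`,
#'   `profile`, `seed`).
#' @export
simulate_cohort <- function(scenario = default_scenario(),
                            profiles = NULL) {
  if (is.null(profiles)) {
    profiles <- default_profiles(anomaly_s = scenario$anomaly_s,
                                 duration_s = scenario$duration_s)
  }
  n <- scenario$n_experts + scenario$n_novices
  set.seed(scenario$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- c(sprintf("expert_%02d", seq_len(scenario$n_experts)),
           sprintf("novice_%02d", seq_len(scenario$n_novices)))
  labels <- c(rep("expert", scenario$n_experts), rep("novice", scenario$n_novices))
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- if (labels[i] == "expert") profiles$expert else {
      set.seed(seeds[i] + 1L)
      jitter_profile(profiles$novice)
    }
    sims[[i]] <- simulate_recording(prof, scenario, seed = seeds[i])
  }
  names(sims) <- ids
  manifest <- data.frame(id = ids, profile = labels, seed = seeds)
  structure(list(simulations = sims, manifest = manifest, scenario = scenario),
            class = "gaze_cohort")
}

#' @export
print.gaze_cohort <- function(x, ...) {
  cat(sprintf("<gaze_cohort> %d recordings (%d expert, %d novice), scenario seed %d\n",
              nrow(x$manifest), sum(x$manifest$profile == "expert"),
              sum(x$manifest$profile == "novice"), x$scenario$seed))
  invisible(x)
}

#' Scenario phases as a data frame (ms)
#'
#' @param scenario a `scenario_config`.
#' @return Data frame `phase`, `start_ms`, `end_ms` for pre/anomaly/post.
#' @export
scenario_phases <- function(scenario) {
  data.frame(phase = c("pre", "anomaly", "post"),
             start_ms = c(0, scenario$anomaly_s[1L] * 1000,
                          scenario$anomaly_s[2L] * 1000),
             end_ms = c(scenario$anomaly_s[1L] * 1000,
                        scenario$anomaly_s[2L] * 1000,
                        scenario$duration_s * 1000))
}
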