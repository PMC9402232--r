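## Seed handling: every sampler takes an explicit seed and restores the caller's
## RNG state, so simulations are reproducible without side effects.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Draw bond lifetimes at given forces
#'
#' Forward simulation of any bond model. The slip model uses the inverse CDF
#' tau = -log(U)/k(F); the two-state slip mixture samples the component then
#' the exponential; the catch bond samples exact first-passage paths of the
#' bound-state Markov chain (vectorized Gillespie), so draws match the
#' analytic distribution exactly.
#'
#' @param model A \code{bond_model}.
#' @param forces Signed forces, pN, one per draw.
#' @param cfg A \code{\link{physical_config}}.
#' @param seed Integer seed; the same seed gives identical output.
#' @return Numeric vector of lifetimes, s, same length as \code{forces}.
#' @export
sample_lifetimes <- function(model, forces, cfg = physical_config(), seed = NULL) {
  if (length(forces) == 0L) return(numeric(0))
  stopifnot(all(is.finite(forces)))
  with_seed(seed, .sample_lifetimes(model, forces, cfg))
}

.sample_lifetimes <- function(model, forces, cfg) UseMethod(".sample_lifetimes")

.sample_lifetimes.slip_model <- function(model, forces, cfg) {
  k <- transition_rate(model$bu, forces, cfg)
  -log(stats::runif(length(forces))) / k
}

.sample_lifetimes.two_state_slip_model <- function(model, forces, cfg) {
  n <- length(forces)
  k1 <- transition_rate(model$b1u, forces, cfg)
  k2 <- transition_rate(model$b2u, forces, cfg)
  in1 <- stats::runif(n) < model$p1
  k <- ifelse(in1, k1, k2)
  -log(stats::runif(n)) / k
}

.sample_lifetimes.catch_model <- function(model, forces, cfg) {
  n <- length(forces)
  k10 <- transition_rate(model$t10, forces, cfg)
  k12 <- transition_rate(model$t12, forces, cfg)
  k21 <- transition_rate(model$t21, forces, cfg)
  k20 <- transition_rate(model$t20, forces, cfg)
  if (all(k10 + k20 <= 0)) stop("all exit rates zero: no absorption")
  state <- ifelse(stats::runif(n) < model$pi0[1], 1L, 2L)
  tau <- numeric(n)
  active <- seq_len(n)
  while (length(active)) {
    s <- state[active]
    exit_rate <- ifelse(s == 1L, k10[active] + k12[active],
                        k20[active] + k21[active])
    tau[active] <- tau[active] + stats::rexp(length(active), exit_rate)
    # branch: from 1 go to 0 w.p. k10/(k10+k12); from 2 to 0 w.p. k20/(k20+k21)
    p_absorb <- ifelse(s == 1L, k10[active] / (k10[active] + k12[active]),
                       k20[active] / (k20[active] + k21[active]))
    absorbed <- stats::runif(length(active)) < p_absorb
    state[active] <- ifelse(s == 1L, 2L, 1L)      # survivors switch state
    active <- active[!absorbed]
  }
  tau
}

#' Single Gillespie first-passage path of the catch bond
#'
#' Simulates jumps among bound states 1 and 2 until absorption in the unbound
#' state 0, starting from a draw of the initial occupancy. Serves as the
#' stochastic oracle for the analytic first-passage distribution.
#'
#' @param model A \code{\link{catch_model}}.
#' @param force Signed force, pN.
#' @param cfg A \code{\link{physical_config}}.
#' @param seed Integer seed.
#' @return List with \code{lifetime} (s) and \code{path} (visited bound states,
#'   ending in 0).
#' @export
gillespie_first_passage <- function(model, force, cfg = physical_config(),
                                    seed = NULL) {
  k10 <- transition_rate(model$t10, force, cfg)
  k12 <- transition_rate(model$t12, force, cfg)
  k21 <- transition_rate(model$t21, force, cfg)
  k20 <- transition_rate(model$t20, force, cfg)
  if (k10 + k20 <= 0) stop("all exit rates zero: no absorption")
  with_seed(seed, {
    state <- if (stats::runif(1) < model$pi0[1]) 1L else 2L
    path <- state
    t_total <- 0
    repeat {
      rates <- if (state == 1L) c(to0 = k10, switch = k12) else c(to0 = k20, switch = k21)
      total <- sum(rates)
      t_total <- t_total + stats::rexp(1, total)
      if (stats::runif(1) < rates[["to0"]] / total) {
        path <- c(path, 0L)
        break
      }
      state <- if (state == 1L) 2L else 1L
      path <- c(path, state)
    }
    list(lifetime = t_total, path = path)
  })
}

#' Default force samplers for the two assays
#'
#' Constant-force assay: truncated Gaussian centred at 6 pN (sd 2.5) clipped
#' to (0.5, 13] pN, mimicking the concentration of measured interactions
#' between 4 and 8 pN. Low-force assay: uniform on 0.2-2.5 pN.
#'
#' @param assay "constant" or "low".
#' @return Function of n returning n force magnitudes, pN.
#' @export
default_force_sampler <- function(assay = c("constant", "low")) {
  assay <- match.arg(assay)
  if (assay == "constant") {
    function(n) {
      out <- numeric(0)
      while (length(out) < n) {
        f <- stats::rnorm(2 * (n - length(out)) + 8, mean = 6, sd = 2.5)
        out <- c(out, f[f > 0.5 & f <= 13])
      }
      out[seq_len(n)]
    }
  } else {
    function(n) stats::runif(n, 0.2, 2.5)
  }
}

#' Simulate a force-lifetime dataset with multi-step events
#'
#' Each binding event carries M load-bearing molecules with i.i.d. lifetimes
#' drawn from the model at the event's force; the force decays in M discrete
#' rupture steps and the recorded last-step lifetime is the gap between the
#' largest and second-largest rupture times (for M = 1, the single lifetime).
#' Molecules are treated as independent: load redistribution between them is
#' ignored. Forces are signed per simulated filament orientation.
#'
#' @param model A \code{bond_model}.
#' @param n_events Number of binding events (one last-step record each).
#' @param molecules_per_event Either a fixed integer >= 1, or a function of n
#'   returning n integers >= 1 (e.g. 1 + rpois). Default: 60% single-step,
#'   then geometric tail.
#' @param force_sampler Function of n returning force magnitudes, pN.
#' @param assay "constant" or "low"; also selects the default force sampler.
#' @param n_filaments Number of filaments events are spread over.
#' @param p_negative Per-filament probability that a given event loads toward
#'   the filament's negative end (force sign -). Default 0.5 (symmetric).
#' @param construct Label stored in the \code{construct} column.
#' @param cfg A \code{\link{physical_config}}.
#' @param seed Integer seed.
#' @return \code{data.frame} of last-step records with columns
#'   \code{construct, filament_id, event_id, assay, n_steps, is_last_step,
#'   force_pN, lifetime_s}.
#' @export
simulate_dataset <- function(model, n_events,
                             molecules_per_event = NULL,
                             force_sampler = NULL,
                             assay = c("constant", "low"),
                             n_filaments = max(1L, n_events %/% 50L),
                             p_negative = 0.5,
                             construct = "synthetic",
                             cfg = physical_config(),
                             seed = NULL) {
  assay <- match.arg(assay)
  stopifnot(n_events >= 1)
  if (is.null(force_sampler)) force_sampler <- default_force_sampler(assay)
  if (is.null(molecules_per_event)) {
    molecules_per_event <- function(n) {
      ifelse(stats::runif(n) < 0.6, 1L, 1L + stats::rgeom(n, prob = 0.5) + 1L)
    }
  } else if (is.numeric(molecules_per_event) && length(molecules_per_event) == 1L) {
    m_fixed <- as.integer(molecules_per_event)
    stopifnot(m_fixed >= 1L)
    molecules_per_event <- function(n) rep(m_fixed, n)
  }
  stopifnot(is.function(molecules_per_event), is.function(force_sampler))
  with_seed(seed, {
    M <- as.integer(molecules_per_event(n_events))
    if (any(M < 1L)) stop("molecules_per_event produced a count < 1")
    fmag <- force_sampler(n_events)
    filament <- sample.int(n_filaments, n_events, replace = TRUE)
    sgn <- ifelse(stats::runif(n_events) < p_negative, -1, 1)
    force <- sgn * fmag
    # all molecule lifetimes, grouped by event
    taus <- sample_lifetimes(model, rep(force, M), cfg)
    idx <- rep(seq_len(n_events), M)
    last_step <- vapply(split(taus, idx), function(tt) {
      if (length(tt) == 1L) tt else {
        s <- sort(tt, decreasing = TRUE)
        s[1] - s[2]
      }
    }, numeric(1))
    data.frame(construct = construct,
               filament_id = sprintf("f%03d", filament),
               event_id = sprintf("e%06d", seq_len(n_events)),
               assay = assay,
               n_steps = M,
               is_last_step = TRUE,
               force_pN = force,
               lifetime_s = unname(last_step),
               stringsAsFactors = FALSE)
  })
}

#' Raw optical-trap trace container
#'
#' @param force Summed-force series, pN.
#' @param fs Sampling rate, Hz.
#' @param waveform Descriptor of the stage waveform (list).
#' @param stiffness Trap stiffness, pN/nm.
#' @param metadata List (seed, construct, ...).
#' @param truth Optional ground-truth annotation \code{data.frame}.
#' @return Object of class \code{trap_trace}.
#' @export
trap_trace <- function(force, fs, waveform = NULL, stiffness = 0.125,
                       metadata = list(), truth = NULL) {
  stopifnot(fs > 0, all(is.finite(force)))
  structure(list(force = as.numeric(force), fs = fs, waveform = waveform,
                 stiffness = stiffness, metadata = metadata, truth = truth),
            class = "trap_trace")
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf("trap_trace: %d samples at %g Hz (%.3f s)\n",
              length(x$force), x$fs, length(x$force) / x$fs))
  if (!is.null(x$truth)) cat(sprintf("  %d ground-truth events\n", nrow(x$truth)))
  invisible(x)
}

#' Synthesize a constant-force assay trace
#'
#' Builds a summed-force time series: Gaussian noise around a baseline, and
#' for each scheduled event a 5-ms linear loading ramp up to the event force
#' followed by discrete plateaus that step down at the rupture times (one per
#' releasing molecule), the final plateau being the last-step lifetime.
#' Ground-truth annotations are attached for testing the detector.
#'
#' @param events \code{data.frame} with columns \code{t_start} (s, ramp onset),
#'   \code{force_pN} (per-molecule force share, pN, > 0; this is the force of
#'   the final plateau), and \code{lifetimes} (list column: per-molecule
#'   rupture times, s, measured from loading end). Rupture k occurs at
#'   loading end + sort(lifetimes)[k]; with M molecules bound the summed
#'   force is M * force_pN, stepping down by force_pN at each rupture.
#' @param duration Total trace length, s.
#' @param fs Sampling rate, Hz (>= 2000).
#' @param noise_sd Gaussian noise sd, pN.
#' @param baseline Baseline force, pN.
#' @param stiffness Trap stiffness, pN/nm.
#' @param loading_ms Loading-ramp duration, ms.
#' @param seed Integer seed.
#' @return A \code{\link{trap_trace}} whose \code{truth} table holds one row
#'   per event: onset, rupture boundaries, n_steps, last-step lifetime/force.
#' @export
simulate_constant_force_trace <- function(events, duration, fs = 40000,
                                          noise_sd = 0.5, baseline = 0,
                                          stiffness = 0.125, loading_ms = 5,
                                          seed = NULL) {
  stopifnot(fs >= 2000, duration > 0)
  n <- round(duration * fs)
  ramp_n <- round(loading_ms / 1000 * fs)
  with_seed(seed, {
    force <- rep(baseline, n)
    truth <- NULL
    if (!is.null(events) && nrow(events) > 0) {
      events <- events[order(events$t_start), , drop = FALSE]
      prev_end <- -Inf
      for (i in seq_len(nrow(events))) {
        ev <- events[i, ]
        lt <- if (!is.null(ev$lifetimes)) sort(unlist(ev$lifetimes)) else {
          stop("events need a 'lifetimes' list column")
        }
        m <- length(lt)
        i0 <- round(ev$t_start * fs) + 1L
        load_end <- i0 + ramp_n
        bounds <- load_end + round(lt * fs)        # rupture sample indices
        if (ev$t_start <= prev_end) stop("overlapping events")
        if (max(bounds) > n) stop("event extends past trace end")
        # plateau forces: m molecules each bearing force_pN, stepping to 0
        plateau <- ev$force_pN * (m:1)
        force[i0:load_end] <- baseline +
          seq(0, plateau[1], length.out = load_end - i0 + 1L)
        seg_start <- load_end
        for (k in seq_len(m)) {
          force[(seg_start + 1L):bounds[k]] <- baseline + plateau[k]
          seg_start <- bounds[k]
        }
        prev_end <- max(bounds) / fs
        last_lt <- if (m == 1L) lt[1] else lt[m] - lt[m - 1L]
        truth <- rbind(truth, data.frame(
          event_id = i, t_start = ev$t_start,
          t_load_end = load_end / fs,
          t_end = max(bounds) / fs,
          n_steps = m,
          last_step_lifetime_s = last_lt,
          last_step_force_pN = plateau[m],
          boundaries = I(list(bounds / fs))))
      }
    }
    noisy <- force + stats::rnorm(n, sd = noise_sd)
    trap_trace(noisy, fs, waveform = list(kind = "trapezoidal"),
               stiffness = stiffness,
               metadata = list(seed = seed, noise_sd = noise_sd,
                               baseline = baseline, clean = force),
               truth = truth)
  })
}

#' Synthesize a low-force assay trace
#'
#' Outside binding intervals the summed force is Gaussian noise only; inside,
#' the high-frequency stage oscillation is transmitted to the beads (scaled by
#' \code{coupling}, with configurable harmonics so part of the transmitted
#' power falls above the 300 Hz detection band) on top of a mean force offset
#' drawn uniformly in 0.2-2.5 pN.
#'
#' @param binding_intervals Two-column matrix of (start, end) times, s; must
#'   be disjoint.
#' @param duration Trace length, s.
#' @param fs Sampling rate, Hz.
#' @param waveform List with \code{frequency_hz} (default 150) and
#'   \code{amplitude_nm} (default 25).
#' @param coupling Dimensionless transmission factor (>= 0) applied to the
#'   stage motion times stiffness.
#' @param harmonics Relative amplitudes of the fundamental and harmonics.
#' @param noise_sd Gaussian noise sd, pN.
#' @param stiffness Trap stiffness, pN/nm.
#' @param offset_range Range of the mean force offset during binding, pN.
#' @param seed Integer seed.
#' @return A \code{\link{trap_trace}} with ground-truth intervals and offsets.
#' @export
simulate_lowforce_trace <- function(binding_intervals, duration, fs = 1000,
                                    waveform = list(frequency_hz = 150,
                                                    amplitude_nm = 25),
                                    coupling = 1, harmonics = c(1, 0.5, 0.25),
                                    noise_sd = 0.1, stiffness = 0.125,
                                    offset_range = c(0.2, 2.5), seed = NULL) {
  if (coupling < 0) stop("coupling must be >= 0")
  n <- round(duration * fs)
  tt <- seq_len(n) / fs
  iv <- binding_intervals
  if (!is.null(iv) && nrow(iv) > 1) {
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2])) stop("binding intervals must be disjoint")
  }
  with_seed(seed, {
    force <- stats::rnorm(n, sd = noise_sd)
    amp0 <- coupling * stiffness * waveform$amplitude_nm
    offs <- numeric(if (is.null(iv)) 0 else nrow(iv))
    if (!is.null(iv)) {
      for (i in seq_len(nrow(iv))) {
        sel <- tt >= iv[i, 1] & tt < iv[i, 2]
        offs[i] <- stats::runif(1, offset_range[1], offset_range[2])
        osc <- 0
        for (h in seq_along(harmonics)) {
          osc <- osc + harmonics[h] * amp0 *
            sin(2 * pi * h * waveform$frequency_hz * tt[sel])
        }
        force[sel] <- force[sel] + offs[i] + osc
      }
    }
    truth <- if (is.null(iv) || nrow(iv) == 0) NULL else {
      data.frame(t_start = iv[, 1], t_end = iv[, 2],
                 lifetime_s = iv[, 2] - iv[, 1], offset_pN = offs)
    }
    trap_trace(force, fs,
               waveform = c(list(kind = "sinusoidal"), waveform),
               stiffness = stiffness,
               metadata = list(seed = seed, coupling = coupling,
                               noise_sd = noise_sd),
               truth = truth)
  })
}
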