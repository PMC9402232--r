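#' Down-sample a trace by block averaging
#'
#' Non-overlapping block means, e.g. 40 kHz raw data to the 1 kHz series used
#' for force-lifetime analysis.
#'
#' @param trace A \code{\link{trap_trace}}.
#' @param target_fs Target sampling rate, Hz; must divide the trace rate.
#' @return A \code{\link{trap_trace}} at \code{target_fs}.
#' @export
decimate_trace <- function(trace, target_fs) {
  stopifnot(inherits(trace, "trap_trace"))
  if (target_fs > trace$fs) stop("target_fs exceeds trace sampling rate")
  fac <- trace$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) stop("sampling_rate not divisible by target_fs")
  fac <- as.integer(round(fac))
  n_out <- length(trace$force) %/% fac
  x <- trace$force[seq_len(n_out * fac)]
  out <- colMeans(matrix(x, nrow = fac))
  trap_trace(out, target_fs, waveform = trace$waveform,
             stiffness = trace$stiffness,
             metadata = c(trace$metadata, list(decimated_from_hz = trace$fs)),
             truth = trace$truth)
}

## Second derivative of a Gaussian kernel, truncated at +/- 4 sigma,
## normalized so a unit step yields a response with unit-area lobes.
.dog2_kernel <- function(sigma_n) {
  half <- max(2L, ceiling(4 * sigma_n))
  s <- seq(-half, half)
  k <- (s^2 / sigma_n^4 - 1 / sigma_n^2) * exp(-s^2 / (2 * sigma_n^2))
  k - mean(k)  # exact zero response to constants despite truncation
}

## Convolve with reflected boundaries; returns same-length response.
.conv_reflect <- function(x, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  if (length(x) <= half) stop("series shorter than kernel")
  xp <- c(rev(x[seq_len(half) + 1L]), x, rev(x[length(x) - seq_len(half)]))
  out <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(out[(half + 1L):(half + length(x))])
}

#' Change points by Gaussian second-derivative convolution
#'
#' Convolves the series with the second derivative of a Gaussian kernel
#' (truncated at 4 sigma, reflected boundaries) and reports zero-crossings of
#' the response flanked by an extremum pair whose lobes both exceed
#' \code{min_amplitude} in magnitude with opposite sign -- a force step of
#' height h produces an antisymmetric lobe pair at the step location.
#'
#' @param x Numeric series (force, pN).
#' @param fs Sampling rate, Hz.
#' @param sigma_s Gaussian kernel width, s (default 5 ms).
#' @param min_amplitude Minimum lobe magnitude of the convolution response.
#' @return Integer vector of change-point sample indices (may be empty).
#' @export
gaussian_dog2_changepoints <- function(x, fs, sigma_s = 0.005, min_amplitude) {
  stopifnot(sigma_s > 0, min_amplitude >= 0)
  sigma_n <- sigma_s * fs
  resp <- .conv_reflect(x, .dog2_kernel(sigma_n))
  n <- length(resp)
  sgn <- sign(resp)
  cross <- which(sgn[-n] * sgn[-1] < 0)
  if (!length(cross)) return(integer(0))
  half <- max(2L, ceiling(4 * sigma_n))
  # a genuine step's response lobes peak at +/- sigma from the crossing, so
  # search only +/- 2 sigma: this rejects phantom crossings formed between
  # the trailing/leading lobes of two nearby same-direction steps
  flank <- max(2L, ceiling(2 * sigma_n))
  keep <- vapply(cross, function(i) {
    lo <- max(1L, i - flank); hi <- min(n, i + flank)
    before <- resp[lo:i]; after <- resp[(i + 1L):hi]
    e1 <- before[which.max(abs(before))]
    e2 <- after[which.max(abs(after))]
    abs(e1) >= min_amplitude && abs(e2) >= min_amplitude && e1 * e2 < 0
  }, logical(1))
  cross <- cross[keep]
  if (!length(cross)) return(integer(0))
  # collapse crossings closer than one kernel width to their lobe-weighted middle
  grp <- cumsum(c(TRUE, diff(cross) > half))
  as.integer(round(tapply(cross, grp, function(ii) mean(range(ii)))))
}

## Two-segment least-squares split of x[lo:hi]: returns the split index (last
## sample of the left segment, absolute), the step size, and the SS gain.
.lsq_split <- function(x, lo, hi, min_len = 5L) {
  if (hi <= lo) return(NULL)
  seg <- x[lo:hi]
  n <- length(seg)
  if (n < 2L * min_len + 1L) return(NULL)
  cs <- cumsum(seg); cs2 <- cumsum(seg^2)
  k <- min_len:(n - min_len)
  ssl <- cs2[k] - cs[k]^2 / k
  ssr <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  cost <- ssl + ssr
  kb <- k[which.min(cost)]
  ss0 <- cs2[n] - cs[n]^2 / n
  list(split = lo + kb - 1L,
       step = abs(cs[kb] / kb - (cs[n] - cs[kb]) / (n - kb)),
       gain = ss0 - min(cost))
}

## robust baseline: median of samples below the central mass + threshold
.baseline_stats <- function(force, binding_threshold) {
  med <- stats::median(force)
  low <- force[force < med + binding_threshold / 2]
  if (!length(low)) stop("no baseline region found")
  list(level = stats::median(low), sd = stats::mad(low))
}

#' Detect and annotate constant-force binding events
#'
#' Works on a trace decimated to ~1 kHz. The baseline is estimated from
#' inter-event regions; an event is an excursion above baseline +
#' \code{binding_threshold}. Interior change points (Gaussian
#' second-derivative detector) partition the event into plateaus. Events that
#' do not survive the 5-ms loading phase are marked excluded
#' ("loading_phase"), as are events in which the force drops more than 1.5 pN
#' below baseline ("slackening").
#'
#' @param trace A \code{\link{trap_trace}} (typically 1 kHz).
#' @param binding_threshold Force above baseline that defines an event, pN.
#' @param sigma_s Change-point kernel width, s.
#' @param min_amplitude Minimum change-point lobe amplitude; default 5x the
#'   response SD of the baseline region.
#' @param loading_ms Loading-phase duration excluded from the first plateau
#'   and used for the survival filter, ms.
#' @param slackening_pN Slackening exclusion threshold below baseline, pN.
#' @return \code{data.frame} of detected events: \code{event_id, t_start_s,
#'   t_end_s, n_steps, last_step_lifetime_s, last_step_force_pN,
#'   baseline_pN, excluded_reason} plus a list column \code{boundaries_s}.
#' @export
annotate_constant_force_events <- function(trace, binding_threshold = 1.5,
                                           sigma_s = 0.005,
                                           min_amplitude = NULL,
                                           loading_ms = 5,
                                           slackening_pN = 1.5) {
  stopifnot(inherits(trace, "trap_trace"))
  x <- trace$force
  fs <- trace$fs
  # short running mean tames per-sample noise for event delimitation only;
  # plateau forces and change points still come from the raw series
  sm_n <- max(1L, round(0.009 * fs))
  xs_pad <- stats::filter(c(rep(x[1], sm_n), x, rep(x[length(x)], sm_n)),
                          rep(1 / sm_n, sm_n), sides = 2)
  xs <- as.numeric(xs_pad[(sm_n + 1L):(sm_n + length(x))])
  bl <- .baseline_stats(xs, binding_threshold)
  base <- bl$level
  above <- xs > base + binding_threshold
  # hysteresis: extend each run outward while the smoothed force stays above
  # half the threshold, so weak final plateaus are not clipped
  lowbar <- xs > base + binding_threshold / 2
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs_i <- which(r$values & r$lengths >= 2L)
  seg <- NULL
  for (j in runs_i) {
    i0 <- starts[j]; i1 <- ends[j]
    while (i0 > 1L && lowbar[i0 - 1L]) i0 <- i0 - 1L
    while (i1 < length(x) && lowbar[i1 + 1L]) i1 <- i1 + 1L
    seg <- rbind(seg, c(i0, i1))
  }
  if (!is.null(seg)) {
    # merge overlapping/nearby segments (gaps < 10 ms)
    seg <- seg[order(seg[, 1]), , drop = FALSE]
    merged <- seg[1, , drop = FALSE]
    if (nrow(seg) > 1) for (j in 2:nrow(seg)) {
      if (seg[j, 1] - merged[nrow(merged), 2] < 0.010 * fs) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], seg[j, 2])
      } else merged <- rbind(merged, seg[j, , drop = FALSE])
    }
    seg <- merged
  }
  above <- rep(FALSE, length(x))
  if (!is.null(seg)) for (j in seq_len(nrow(seg))) {
    above[seg[j, 1]:seg[j, 2]] <- TRUE
  }
  if (is.null(seg)) {
    return(data.frame(event_id = integer(0), t_start_s = numeric(0),
                      t_end_s = numeric(0), n_steps = integer(0),
                      last_step_lifetime_s = numeric(0),
                      last_step_force_pN = numeric(0),
                      baseline_pN = numeric(0),
                      excluded_reason = character(0)))
  }
  # calibrate min_amplitude on the baseline (event-free) response
  if (is.null(min_amplitude)) {
    base_idx <- which(!above)
    if (length(base_idx) < 10 * sigma_s * fs) stop("no baseline region found")
    resp_bl <- .conv_reflect(x[base_idx], .dog2_kernel(sigma_s * fs))
    min_amplitude <- 5 * stats::sd(resp_bl)
  }
  load_n <- round(loading_ms / 1000 * fs)
  edge_n <- round(0.012 * fs)  # search radius for change-point edge refinement
  out <- vector("list", nrow(seg))
  for (j in seq_len(nrow(seg))) {
    i0 <- seg[j, 1]; i1 <- seg[j, 2]
    # change points inside the event (pad with margins of baseline)
    pad <- round(6 * sigma_s * fs)
    lo <- max(1L, i0 - pad); hi <- min(length(x), i1 + pad)
    cps <- gaussian_dog2_changepoints(x[lo:hi], fs, sigma_s, min_amplitude) +
      lo - 1L
    # refine the event edges to the nearest change point: the loading ramp and
    # the final detachment are themselves the sharpest steps in the segment
    near0 <- cps[abs(cps - i0) <= edge_n]
    if (length(near0)) i0 <- near0[which.min(abs(near0 - i0))]
    near1 <- cps[abs(cps - i1) <= edge_n]
    if (length(near1)) i1 <- near1[which.min(abs(near1 - i1))]
    t_start <- i0 / fs; t_end <- i1 / fs
    # interior boundaries: strictly inside the plateau region (exclude the
    # loading edge at event start and the final detachment edge at event end)
    interior <- cps[cps > i0 + load_n + 2L & cps < i1 - edge_n]
    # refine each boundary by a local two-plateau least-squares split: the
    # convolution zero-crossing drifts when two ruptures fall within a few
    # kernel widths of each other
    w_ref <- round(0.015 * fs)
    interior <- sort(unique(vapply(interior, function(p) {
      sp <- .lsq_split(x, max(i0 + load_n, p - w_ref), min(i1 - 2L, p + w_ref))
      as.integer(if (is.null(sp)) p else sp$split)
    }, integer(1))))
    # residual scan for ruptures the convolution merged: split any plateau
    # whose best two-segment division has a step of at least the binding
    # threshold (noise on >= 8-sample means is far smaller)
    segs <- cbind(c(i0 + load_n, interior + 1L), c(interior, i1 - edge_n))
    repeat {
      added <- FALSE
      for (r in seq_len(nrow(segs))) {
        sp <- .lsq_split(x, segs[r, 1], segs[r, 2], min_len = 8L)
        if (!is.null(sp) && sp$step >= binding_threshold &&
            !any(abs(sp$split - c(interior, i0 + load_n, i1)) < 10L)) {
          interior <- sort(c(interior, sp$split))
          added <- TRUE
        }
      }
      if (!added) break
      segs <- cbind(c(i0 + load_n, interior + 1L), c(interior, i1 - edge_n))
    }
    bounds <- sort(unique(c(interior, i1)))
    n_steps <- length(bounds)
    last_lo <- if (n_steps == 1L) i0 + load_n else interior[length(interior)]
    last_step_lifetime <- (i1 - last_lo) / fs
    last_step_force <- mean(x[(last_lo + 1L):i1]) - base
    excluded <- NA_character_
    if ((i1 - i0 - load_n) / fs * 1000 < loading_ms) excluded <- "loading_phase"
    # slackening is a sustained drop, so test the smoothed series: during the
    # event and in a short window after detachment
    post <- xs[seq(i1 + 1L, min(length(xs), i1 + round(0.05 * fs)))]
    if (length(post) && any(post < base - slackening_pN)) excluded <- "slackening"
    if (min(xs[i0:i1]) < base - slackening_pN) excluded <- "slackening"
    out[[j]] <- data.frame(event_id = j, t_start_s = t_start, t_end_s = t_end,
                           n_steps = n_steps,
                           last_step_lifetime_s = last_step_lifetime,
                           last_step_force_pN = last_step_force,
                           baseline_pN = base,
                           excluded_reason = excluded,
                           boundaries_s = I(list(bounds / fs)))
  }
  do.call(rbind, out)
}

#' Sliding-window high-band spectral power
#'
#' 256-point periodogram in a window sliding one sample at a time; at each
#' position the power in frequency bins above \code{f_min} is summed. Used to
#' detect low-force binding through transmitted stage oscillation.
#'
#' @param trace A \code{\link{trap_trace}} at ~1 kHz.
#' @param window Window length, samples.
#' @param f_min Lower edge of the summed band, Hz; must be below Nyquist.
#' @return \code{data.frame} with \code{time_s} (window centres) and
#'   \code{power} (summed high-band periodogram power).
#' @export
lowforce_band_power <- function(trace, window = 256L, f_min = 300) {
  stopifnot(inherits(trace, "trap_trace"))
  fs <- trace$fs
  if (f_min >= fs / 2) stop("f_min must be below the Nyquist frequency")
  x <- trace$force
  if (length(x) < window) stop("trace shorter than the analysis window")
  # windows as columns: x[i..i+window-1]
  W <- matrix(0, nrow = window, ncol = length(x) - window + 1L)
  for (k in seq_len(window)) W[k, ] <- x[k:(length(x) - window + k)]
  X <- stats::mvfft(W)
  freqs <- (seq_len(window) - 1L) * fs / window
  half <- window %/% 2L
  band <- which(freqs > f_min & seq_len(window) <= half + 1L & freqs > 0)
  p <- colSums(abs(X[band, , drop = FALSE])^2) / window
  centers <- (seq_len(ncol(W)) + (window - 1L) / 2) / fs
  out <- data.frame(time_s = centers, power = p)
  attr(out, "window_s") <- window / fs
  out
}

#' Threshold the high-band power into binding events
#'
#' Maximal runs where the high-band power exceeds \code{factor} times the
#' baseline mean become events; the lifetime is the run duration and the
#' event force is the mean force offset relative to baseline during the run.
#'
#' @param power \code{data.frame} from \code{\link{lowforce_band_power}}.
#' @param baseline_mean Mean high-band power of an event-free (baseline)
#'   recording; must be > 0.
#' @param factor Threshold multiplier (default 1.8, i.e. 180% of the mean).
#' @param trace Optional originating \code{\link{trap_trace}} used to compute
#'   per-event mean force offsets.
#' @param min_duration_s Discard runs shorter than this, s.
#' @return \code{data.frame}: \code{event_id, t_start_s, t_end_s, lifetime_s,
#'   force_pN}.
#' @export
detect_lowforce_events <- function(power, baseline_mean, factor = 1.8,
                                   trace = NULL, min_duration_s = 0) {
  if (!nrow(power)) stop("empty power series")
  stopifnot(baseline_mean > 0)
  above <- power$power > factor * baseline_mean
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) {
    return(data.frame(event_id = integer(0), t_start_s = numeric(0),
                      t_end_s = numeric(0), lifetime_s = numeric(0),
                      force_pN = numeric(0)))
  }
  # a window centred within half a window of the event still overlaps it, so
  # raw runs are smeared by ~half a window per edge; shrink accordingly
  half_w <- if (!is.null(attr(power, "window_s"))) attr(power, "window_s") / 2 else 0
  t0 <- power$time_s[starts[runs]] + half_w
  t1 <- power$time_s[ends[runs]] - half_w
  t1 <- pmax(t1, t0 + 1e-9)
  out <- data.frame(event_id = seq_along(runs),
                    t_start_s = t0,
                    t_end_s = t1,
                    lifetime_s = t1 - t0,
                    force_pN = NA_real_)
  out <- out[out$lifetime_s >= min_duration_s, , drop = FALSE]
  out$event_id <- seq_len(nrow(out))
  if (!is.null(trace) && nrow(out)) {
    tt <- seq_along(trace$force) / trace$fs
    inside <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(out))) {
      inside <- inside | (tt >= out$t_start_s[i] & tt < out$t_end_s[i])
    }
    base <- mean(trace$force[!inside])
    for (i in seq_len(nrow(out))) {
      sel <- tt >= out$t_start_s[i] & tt < out$t_end_s[i]
      out$force_pN[i] <- mean(trace$force[sel]) - base
    }
  }
  out
}
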