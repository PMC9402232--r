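#' Binned mean lifetimes versus force magnitude
#'
#' Equal-width bins over |F|; per-bin mean lifetime and event count (the
#' counts drive the area-scaled markers of the standard force-lifetime plot).
#' Empty bins are omitted.
#'
#' @param records Force-lifetime records.
#' @param bin_width Bin width, pN.
#' @param range Force range c(lo, hi), pN; default spans the data.
#' @return \code{data.frame}: \code{bin_center_pN, mean_lifetime_s, count}.
#' @export
binned_mean_lifetimes <- function(records, bin_width = 2, range = NULL) {
  stopifnot(bin_width > 0)
  if (!nrow(records)) {
    return(data.frame(bin_center_pN = numeric(0), mean_lifetime_s = numeric(0),
                      count = integer(0)))
  }
  f <- abs(records$force_pN)
  if (is.null(range)) range <- c(0, max(f) + 1e-9)
  breaks <- seq(range[1], range[2] + bin_width, by = bin_width)
  bin <- cut(f, breaks, right = FALSE)
  keep <- !is.na(bin)
  agg <- tapply(records$lifetime_s[keep], bin[keep], mean)
  cnt <- table(bin[keep])
  centers <- breaks[-length(breaks)] + bin_width / 2
  nonempty <- which(cnt > 0)
  data.frame(bin_center_pN = centers[nonempty],
             mean_lifetime_s = as.numeric(agg[nonempty]),
             count = as.integer(cnt[nonempty]))
}

#' Empirical survival function of lifetimes
#'
#' Step function S(tau) = fraction of lifetimes strictly greater than tau,
#' evaluated at the sorted observed lifetimes (no censoring).
#'
#' @param lifetimes Positive lifetimes, s (or a records \code{data.frame}).
#' @return \code{data.frame}: \code{tau_s}, \code{survival}.
#' @export
empirical_survival <- function(lifetimes) {
  if (is.data.frame(lifetimes)) lifetimes <- lifetimes$lifetime_s
  stopifnot(all(lifetimes > 0))
  tau <- sort(lifetimes)
  n <- length(tau)
  data.frame(tau_s = tau, survival = 1 - seq_len(n) / n)
}

#' Two-sample comparison of lifetime distributions
#'
#' Compares two uncensored lifetime samples, either by the log-rank test
#' (via \code{survival::survdiff}) or the two-sample Kolmogorov-Smirnov test.
#' Used e.g. to check that low-force assay lifetimes are statistically
#' indistinguishable from constant-force lifetimes in the overlapping 0-2.5
#' pN range.
#'
#' @param a,b Lifetime vectors (or records \code{data.frame}s).
#' @param method "logrank" or "ks".
#' @return List with \code{statistic}, \code{p_value}, \code{method}.
#' @export
compare_survival <- function(a, b, method = c("logrank", "ks")) {
  method <- match.arg(method)
  if (is.data.frame(a)) a <- a$lifetime_s
  if (is.data.frame(b)) b <- b$lifetime_s
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (method == "ks") {
    kt <- suppressWarnings(stats::ks.test(a, b))
    list(statistic = unname(kt$statistic), p_value = kt$p.value, method = "ks")
  } else {
    df <- data.frame(time = c(a, b), status = 1,
                     group = rep(c("a", "b"), c(length(a), length(b))))
    sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
    p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    list(statistic = unname(sd$chisq), p_value = p, method = "logrank")
  }
}

#' Sliding-window lifetime ratios between two datasets
#'
#' Lifetime ratio LR(c) = mean lifetime of \code{a} / mean lifetime of
#' \code{b} within the force window [c - w/2, c + w/2) on |F|, slid across
#' the force range; reported only where both windows hold at least
#' \code{min_count} records. The summary mean LR is the unweighted mean of
#' the reported per-window ratios.
#'
#' @param a,b Records \code{data.frame}s (numerator, denominator).
#' @param window Window width, pN (default 4).
#' @param range Window-centre range, pN (default c(0, 13)).
#' @param step Centre step, pN.
#' @param min_count Minimum records per window in each dataset.
#' @return Object of class \code{lifetime_ratio_curve}: \code{data.frame}
#'   (\code{center_pN, lr, n_a, n_b}) with attribute \code{mean_lr}.
#' @export
sliding_lifetime_ratio <- function(a, b, window = 4, range = c(0, 13),
                                   step = 0.5, min_count = 5) {
  stopifnot(window > 0, step > 0)
  centers <- seq(range[1], range[2], by = step)
  fa <- abs(a$force_pN); fb <- abs(b$force_pN)
  rows <- lapply(centers, function(cc) {
    ia <- fa >= cc - window / 2 & fa < cc + window / 2
    ib <- fb >= cc - window / 2 & fb < cc + window / 2
    if (sum(ia) < min_count || sum(ib) < min_count) return(NULL)
    data.frame(center_pN = cc,
               lr = mean(a$lifetime_s[ia]) / mean(b$lifetime_s[ib]),
               n_a = sum(ia), n_b = sum(ib))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no force window satisfies min_count in both datasets")
  out <- do.call(rbind, rows)
  attr(out, "mean_lr") <- mean(out$lr)
  attr(out, "window") <- window
  attr(out, "min_count") <- min_count
  class(out) <- c("lifetime_ratio_curve", "data.frame")
  out
}

#' @export
print.lifetime_ratio_curve <- function(x, ...) {
  cat(sprintf("lifetime_ratio_curve: %d windows, mean LR = %.3f\n",
              nrow(x), attr(x, "mean_lr")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Bootstrap confidence envelope for lifetime-ratio curves
#'
#' Resamples both datasets independently with replacement, recomputes the
#' sliding LR curve, and reports percentile bands per window centre plus a
#' CI on the mean LR (90% by default, as for the study's LR envelopes).
#'
#' @param a,b Records \code{data.frame}s.
#' @param n_boot Number of bootstrap replicates.
#' @param level Confidence level, percent.
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{sliding_lifetime_ratio}}.
#' @return List: \code{curve} (point LR curve with \code{lower}/\code{upper}),
#'   \code{mean_lr}, \code{mean_lr_ci}, \code{n_boot}, \code{level}.
#' @export
bootstrap_lr_ci <- function(a, b, n_boot = 1000, level = 90, seed = 1, ...) {
  stopifnot(n_boot >= 2)
  point <- sliding_lifetime_ratio(a, b, ...)
  centers <- point$center_pN
  res <- with_seed(seed, {
    lr_mat <- matrix(NA_real_, nrow = n_boot, ncol = length(centers))
    mean_lr <- numeric(n_boot)
    for (bb in seq_len(n_boot)) {
      ra <- a[sample.int(nrow(a), replace = TRUE), , drop = FALSE]
      rb <- b[sample.int(nrow(b), replace = TRUE), , drop = FALSE]
      cv <- tryCatch(sliding_lifetime_ratio(ra, rb, ...),
                     error = function(e) NULL)
      if (is.null(cv)) { mean_lr[bb] <- NA; next }
      lr_mat[bb, match(cv$center_pN, centers)] <- cv$lr
      mean_lr[bb] <- attr(cv, "mean_lr")
    }
    list(lr_mat = lr_mat, mean_lr = mean_lr[is.finite(mean_lr)])
  })
  alpha <- (100 - level) / 200
  point$lower <- apply(res$lr_mat, 2, stats::quantile, probs = alpha, na.rm = TRUE)
  point$upper <- apply(res$lr_mat, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  list(curve = point,
       mean_lr = attr(point, "mean_lr"),
       mean_lr_ci = stats::quantile(res$mean_lr, c(alpha, 1 - alpha),
                                    names = FALSE),
       n_boot = n_boot, level = level, seed = seed)
}

#' Per-filament directionality of binding lifetimes
#'
#' For each actin filament, events are split by force sign in the trap frame;
#' the inferred barbed (+) end is assigned to the sign group with the shorter
#' mean lifetime (ties: the F > 0 group), so the pooled (-)/(+) mean-lifetime
#' ratio is >= 1 by construction and represents the maximum directional
#' asymmetry consistent with the data. The event-count ratio (-)/(+) is
#' reported alongside, with percentile bootstrap CIs from resampling events
#' within the pooled groups.
#'
#' @param records Records with \code{filament_id} and signed \code{force_pN}.
#' @param n_boot Bootstrap replicates for the CI.
#' @param level Confidence level, percent.
#' @param per_filament Average ratios per filament instead of pooling events?
#' @param seed Integer seed.
#' @return Object of class \code{directionality_summary}: pooled
#'   \code{lifetime_ratio} and \code{count_ratio} ((-)/(+)), bootstrap CI,
#'   and the per-filament table.
#' @export
directionality_summary <- function(records, n_boot = 1000, level = 95,
                                   per_filament = FALSE, seed = 1) {
  stopifnot(all(c("filament_id", "force_pN", "lifetime_s") %in% names(records)))
  split_fil <- split(records, records$filament_id)
  assigned <- lapply(split_fil, function(rf) {
    neg <- rf[rf$force_pN < 0, , drop = FALSE]
    pos <- rf[rf$force_pN >= 0, , drop = FALSE]
    if (!nrow(neg) || !nrow(pos)) {
      warning("filament ", rf$filament_id[1],
              " has events of only one force sign; contributes to one group only",
              call. = FALSE)
      grp <- if (nrow(neg)) "minus" else "plus"
      rf$implied <- grp
      return(rf)
    }
    m_neg <- mean(neg$lifetime_s); m_pos <- mean(pos$lifetime_s)
    # (+) end goes to the shorter-mean group; ties to the F > 0 group
    plus_is_pos <- m_pos <= m_neg
    rf$implied <- ifelse((rf$force_pN >= 0) == plus_is_pos, "plus", "minus")
    rf
  })
  pooled <- do.call(rbind, assigned)
  ratio_of <- function(df) {
    mn <- df$lifetime_s[df$implied == "minus"]
    mp <- df$lifetime_s[df$implied == "plus"]
    c(lifetime_ratio = mean(mn) / mean(mp),
      count_ratio = length(mn) / length(mp))
  }
  point <- if (per_filament) {
    per <- vapply(assigned, function(df) {
      if (length(unique(df$implied)) < 2) return(c(NA, NA))
      ratio_of(df)
    }, numeric(2))
    c(lifetime_ratio = mean(per[1, ], na.rm = TRUE),
      count_ratio = mean(per[2, ], na.rm = TRUE))
  } else ratio_of(pooled)
  boot <- with_seed(seed, {
    mn <- pooled$lifetime_s[pooled$implied == "minus"]
    mp <- pooled$lifetime_s[pooled$implied == "plus"]
    vapply(seq_len(n_boot), function(i) {
      mean(sample(mn, replace = TRUE)) / mean(sample(mp, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (100 - level) / 200
  structure(list(lifetime_ratio = unname(point["lifetime_ratio"]),
                 count_ratio = unname(point["count_ratio"]),
                 lifetime_ratio_ci = stats::quantile(boot, c(alpha, 1 - alpha),
                                                     names = FALSE),
                 level = level, n_boot = n_boot,
                 per_filament = per_filament,
                 n_minus = sum(pooled$implied == "minus"),
                 n_plus = sum(pooled$implied == "plus"),
                 assigned = pooled, seed = seed),
            class = "directionality_summary")
}

#' @export
print.directionality_summary <- function(x, ...) {
  cat(sprintf(
    "directionality: lifetime ratio (-)/(+) = %.3f (%g%% CI %.3f-%.3f), count ratio = %.3f\n",
    x$lifetime_ratio, x$level, x$lifetime_ratio_ci[1], x$lifetime_ratio_ci[2],
    x$count_ratio))
  cat(sprintf("  events: %d implied (-), %d implied (+)\n", x$n_minus, x$n_plus))
  invisible(x)
}

#' Force-lifetime summary plot
#'
#' Binned mean lifetimes with area-scaled markers and, optionally, model
#' mean-lifetime curves with bootstrap envelopes.
#'
#' @param records Records \code{data.frame}.
#' @param model Optional \code{bond_model} whose curve to overlay.
#' @param envelope Optional envelope from \code{\link{mean_lifetime_envelope}}.
#' @param bin_width Bin width, pN.
#' @param cfg A \code{\link{physical_config}}.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the binned table.
#' @export
plot_force_lifetime <- function(records, model = NULL, envelope = NULL,
                                bin_width = 2, cfg = physical_config(), ...) {
  binned <- binned_mean_lifetimes(records, bin_width)
  plot(binned$bin_center_pN, binned$mean_lifetime_s,
       cex = 2 * sqrt(binned$count / max(binned$count)),
       xlab = "Force (pN)", ylab = "Mean lifetime (s)", pch = 21,
       bg = "grey80", ...)
  if (!is.null(envelope)) {
    graphics::polygon(c(envelope$force_pN, rev(envelope$force_pN)),
                      c(envelope$lower, rev(envelope$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
  }
  if (!is.null(model)) {
    fg <- seq(min(binned$bin_center_pN), max(binned$bin_center_pN),
              length.out = 100)
    graphics::lines(fg, mean_lifetime_curve(model, fg, cfg)$mean_lifetime_s,
                    col = "steelblue", lwd = 2)
  }
  invisible(binned)
}
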