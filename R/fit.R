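#' Negative log-likelihood of a bond model
#'
#' -sum log f(tau_i | F_i) over last-step force-lifetime records, computed in
#' log space.
#'
#' @param model A \code{bond_model}.
#' @param records \code{data.frame} with columns \code{force_pN},
#'   \code{lifetime_s} (see \code{\link{read_records}}).
#' @param cfg A \code{\link{physical_config}}.
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(model, records, cfg = physical_config()) {
  tau <- records$lifetime_s
  force <- records$force_pN
  if (any(tau <= 0)) stop("non-positive lifetime in records")
  if (any(!is.finite(force))) stop("non-finite force in records")
  -sum(bond_density(model, tau, force, cfg, log = TRUE))
}

## ---- free-parameter packing ------------------------------------------------
## Rates are optimized as log10(k0); distances linearly. Fixed parameters are
## excluded from the free vector.

.default_bounds <- function() list(log10_k0 = c(-3, 3), x = c(-5, 20))

## parameter template for a model kind: a data.frame of slots
.param_slots <- function(model_kind, directional = FALSE) {
  tr <- switch(model_kind,
    slip = "bu",
    two_state_slip = c("b1u", "b2u"),
    catch = c("t10", "t12", "t21", "t20"),
    stop("unknown model kind: ", model_kind))
  slots <- NULL
  for (nm in tr) {
    slots <- rbind(slots, data.frame(transition = nm, what = "log10_k0"))
    if (directional) {
      slots <- rbind(slots,
                     data.frame(transition = nm, what = c("x_minus", "x_plus")))
    } else {
      slots <- rbind(slots, data.frame(transition = nm, what = "x"))
    }
  }
  if (model_kind == "two_state_slip") {
    slots <- rbind(slots, data.frame(transition = ".", what = "p1"))
  }
  slots$name <- ifelse(slots$what == "p1", "p1",
                       paste(slots$transition, slots$what, sep = "."))
  slots
}

.build_model <- function(model_kind, theta_full, slots, directional, pi0 = c(1, 0),
                         fixed_flags = NULL) {
  g <- function(tr_name) {
    sel <- slots$transition == tr_name
    k0 <- 10^theta_full[slots$name[sel & slots$what == "log10_k0"]]
    if (directional) {
      bell_transition(k0,
                      x_minus = theta_full[slots$name[sel & slots$what == "x_minus"]],
                      x_plus = theta_full[slots$name[sel & slots$what == "x_plus"]])
    } else {
      bell_transition(k0, x = theta_full[slots$name[sel & slots$what == "x"]])
    }
  }
  switch(model_kind,
    slip = slip_model(g("bu")),
    two_state_slip = two_state_slip_model(
      min(max(theta_full[["p1"]], 0), 1), g("b1u"), g("b2u")),
    catch = catch_model(g("t10"), g("t12"), g("t21"), g("t20"), pi0 = pi0))
}

.slot_bounds <- function(slots, bounds) {
  lower <- ifelse(slots$what == "log10_k0", bounds$log10_k0[1],
                  ifelse(slots$what == "p1", 0, bounds$x[1]))
  upper <- ifelse(slots$what == "log10_k0", bounds$log10_k0[2],
                  ifelse(slots$what == "p1", 1, bounds$x[2]))
  names(lower) <- names(upper) <- slots$name
  list(lower = lower, upper = upper)
}

.make_fit_result <- function(model_kind, model, theta_full, free_names, logL,
                             n_obs, converged, seed, method, extra = list()) {
  n_free <- length(free_names)
  res <- c(list(model_kind = model_kind, model = model,
                theta = theta_full, free = free_names,
                theta_free = theta_full[free_names],
                logL = logL, n_obs = n_obs, n_free = n_free,
                aic = 2 * n_free - 2 * logL,
                bic = n_free * log(n_obs) - 2 * logL,
                converged = converged, seed = seed, method = method),
           extra)
  class(res) <- "bond_fit"
  res
}

#' @export
print.bond_fit <- function(x, ...) {
  cat(sprintf("%s model fit (%s): n = %d, logL = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$model_kind, x$method, x$n_obs, x$logL, x$aic, x$bic))
  print(signif(x$theta, 4))
  invisible(x)
}

#' Local maximum-likelihood fit of slip-type models
#'
#' Bounded quasi-Newton (L-BFGS-B) minimization of the negative
#' log-likelihood for the one-state slip and two-state slip models, with
#' seeded multi-start. Rates are optimized as log10(k0).
#'
#' @param model_kind "slip" or "two_state_slip".
#' @param records Force-lifetime records (\code{force_pN}, \code{lifetime_s}).
#' @param init Optional named vector of starting values on the internal scale
#'   (\code{<transition>.log10_k0}, \code{<transition>.x}, \code{p1}).
#' @param bounds List with \code{log10_k0} and \code{x} ranges.
#' @param fixed Named numeric vector of parameters (internal names) held at
#'   the given values.
#' @param directional Fit direction-split distance parameters x_minus/x_plus?
#' @param cfg A \code{\link{physical_config}}.
#' @param n_restarts Number of seeded random restarts.
#' @param seed Integer seed (restart initial points).
#' @return A \code{bond_fit}: fitted model, log-likelihood, AIC/BIC,
#'   convergence diagnostics.
#' @export
fit_mle_local <- function(model_kind = c("slip", "two_state_slip"),
                          records, init = NULL, bounds = .default_bounds(),
                          fixed = NULL, directional = FALSE,
                          cfg = physical_config(),
                          n_restarts = 10, seed = 1) {
  model_kind <- match.arg(model_kind)
  slots <- .param_slots(model_kind, directional)
  bb <- .slot_bounds(slots, bounds)
  fixed_names <- names(fixed)
  stopifnot(all(fixed_names %in% slots$name))
  free_names <- setdiff(slots$name, fixed_names)
  if (!is.null(init)) stopifnot(all(names(init) %in% slots$name))

  obj <- function(th_free) {
    th <- stats::setNames(numeric(nrow(slots)), slots$name)
    th[fixed_names] <- fixed
    th[free_names] <- th_free
    m <- .build_model(model_kind, th, slots, directional)
    nll <- tryCatch(negative_log_likelihood(m, records, cfg),
                    error = function(e) NA_real_)
    if (!is.finite(nll)) 1e10 else nll
  }

  starts <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(i) {
      s <- stats::runif(length(free_names), bb$lower[free_names],
                        bb$upper[free_names])
      names(s) <- free_names
      # moment-based anchor for the first start
      if (i == 1L) {
        kb <- grepl("log10_k0$", free_names)
        s[kb] <- pmin(pmax(log10(1 / mean(records$lifetime_s)),
                           bb$lower[free_names][kb]), bb$upper[free_names][kb])
        s[free_names == "p1"] <- 0.5
        s[grepl("\\.x", free_names)] <- 0.2
      }
      if (!is.null(init)) {
        ov <- intersect(names(init), free_names)
        s[ov] <- init[ov]
      }
      s
    })
  })

  best <- NULL
  n_ok <- 0L
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B",
                   lower = bb$lower[free_names], upper = bb$upper[free_names],
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("all restarts failed to converge (", n_ok, " completed)")
  }
  th <- stats::setNames(numeric(nrow(slots)), slots$name)
  th[fixed_names] <- fixed
  th[free_names] <- best$par
  model <- .build_model(model_kind, th, slots, directional)
  .make_fit_result(model_kind, model, th, free_names, -best$value,
                   nrow(records), best$convergence == 0, seed, "L-BFGS-B",
                   extra = list(n_restarts = n_restarts, directional = directional,
                                fixed = fixed, bounds = bounds))
}

#' Genetic-algorithm global fit of the two-state catch bond
#'
#' Minimizes the negative log-likelihood over the eight catch-bond parameters
#' (or their direction-split variants) with a generational genetic algorithm:
#' tournament selection (k = 3), uniform crossover, Gaussian mutation in
#' log-rate / linear-distance space, elitism 2. Candidates whose zero-force
#' mean lifetime exceeds \code{max_zero_force_mean} (100 s) receive an
#' infinite objective. The best individual is polished with L-BFGS-B.
#'
#' @param records Force-lifetime records.
#' @param epochs GA generations (100 for full fits; 20 for bootstrap refits).
#' @param population Population size.
#' @param directional Direction-split distance parameters?
#' @param fixed Named numeric vector of parameters held constant (internal
#'   names, e.g. \code{t10.x = 0}).
#' @param bounds List with \code{log10_k0} and \code{x} ranges.
#' @param pi0 Initial bound-state occupancy.
#' @param max_zero_force_mean Constraint on mean lifetime at F = 0, s.
#' @param mutation_p Per-gene mutation probability.
#' @param cfg A \code{\link{physical_config}}.
#' @param seed Integer seed; fits are fully deterministic given the seed.
#' @return A \code{bond_fit} with the fitted \code{\link{catch_model}}.
#' @export
fit_catch_genetic <- function(records, epochs = 100, population = 200,
                              directional = FALSE, fixed = NULL,
                              bounds = .default_bounds(), pi0 = c(1, 0),
                              max_zero_force_mean = 100, mutation_p = 0.2,
                              cfg = physical_config(), seed = 1) {
  if (!nrow(records)) stop("records must be non-empty")
  slots <- .param_slots("catch", directional)
  bb <- .slot_bounds(slots, bounds)
  fixed_names <- names(fixed)
  if (!all(fixed_names %in% slots$name)) {
    stop("unknown fixed parameter(s): ",
         paste(setdiff(fixed_names, slots$name), collapse = ", "))
  }
  free_names <- setdiff(slots$name, fixed_names)
  if (!length(free_names)) stop("no free parameters to fit")
  lower <- bb$lower[free_names]; upper <- bb$upper[free_names]
  rng <- upper - lower

  th_template <- stats::setNames(numeric(nrow(slots)), slots$name)
  th_template[fixed_names] <- fixed

  tau <- records$lifetime_s; force <- records$force_pN
  nll_of <- function(th_free, penalized = TRUE) {
    th <- th_template
    th[free_names] <- th_free
    m <- .build_model("catch", th, slots, directional, pi0 = pi0)
    if (penalized && zero_force_mean(m, cfg) > max_zero_force_mean) return(Inf)
    v <- tryCatch(-sum(bond_density(m, tau, force, cfg, log = TRUE)),
                  error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }

  ga <- with_seed(seed, {
    pop <- matrix(stats::runif(population * length(free_names)),
                  nrow = population)
    pop <- sweep(sweep(pop, 2, rng, "*"), 2, lower, "+")
    fitv <- apply(pop, 1, nll_of)
    for (g in seq_len(epochs)) {
      ord <- order(fitv)
      elite <- pop[ord[1:2], , drop = FALSE]
      # tournament selection, k = 3
      pick <- function(n) {
        idx <- matrix(sample.int(population, 3 * n, replace = TRUE), ncol = 3)
        sel <- apply(idx, 1, function(ii) ii[which.min(fitv[ii])])
        pop[sel, , drop = FALSE]
      }
      n_child <- population - 2L
      pa <- pick(n_child); pb <- pick(n_child)
      mask <- matrix(stats::runif(n_child * length(free_names)) < 0.5,
                     nrow = n_child)
      child <- ifelse(mask, pa, pb)
      mut <- matrix(stats::runif(n_child * length(free_names)) < mutation_p,
                    nrow = n_child)
      noise <- matrix(stats::rnorm(n_child * length(free_names)),
                      nrow = n_child) * rep(0.1 * rng, each = n_child)
      child <- child + mut * noise
      child <- pmin(pmax(child, rep(lower, each = n_child)),
                    rep(upper, each = n_child))
      pop <- rbind(elite, child)
      fitv <- apply(pop, 1, nll_of)
    }
    list(pop = pop, fitv = fitv)
  })
  best_idx <- which.min(ga$fitv)
  if (!is.finite(ga$fitv[best_idx])) {
    stop("infeasible fixed-parameter configuration: no candidate satisfied ",
         "the zero-force mean-lifetime constraint")
  }
  polish_obj <- function(v) {
    val <- nll_of(v, penalized = FALSE)
    if (!is.finite(val)) return(1e10)
    th <- th_template; th[free_names] <- v
    m <- .build_model("catch", th, slots, directional, pi0 = pi0)
    zf <- zero_force_mean(m, cfg)
    if (zf > max_zero_force_mean) val <- 1e8 + (zf - max_zero_force_mean)
    val
  }
  # polish the few best (distinct) individuals: the GA locates the basin,
  # the quasi-Newton step finds its floor
  ord <- order(ga$fitv)
  cand <- unique(round(ga$pop[ord[seq_len(min(5L, length(ord)))], ,
                              drop = FALSE], 10))
  best_par <- ga$pop[best_idx, ]
  best_val <- ga$fitv[best_idx]
  polished <- FALSE
  for (i in seq_len(nrow(cand))) {
    st <- cand[i, ]
    names(st) <- free_names
    pol <- tryCatch(
      stats::optim(st, polish_obj, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value < best_val) {
      best_val <- pol$value
      best_par <- pol$par
      polished <- TRUE
    }
  }
  th <- th_template
  th[free_names] <- best_par
  logL <- -best_val
  use_pol <- polished
  model <- .build_model("catch", th, slots, directional, pi0 = pi0)
  .make_fit_result("catch", model, th, free_names, logL, nrow(records),
                   TRUE, seed, "GA+L-BFGS-B",
                   extra = list(epochs = epochs, population = population,
                                directional = directional, fixed = fixed,
                                bounds = bounds, pi0 = pi0,
                                polished = use_pol))
}

#' Information criteria and fit comparison
#'
#' AIC = 2 n_free - 2 logL; BIC = n_free ln(n_obs) - 2 logL. The comparison
#' report adds delta-AIC/delta-BIC relative to the best candidate.
#'
#' @param fit A \code{bond_fit}.
#' @return \code{information_criteria}: named vector (aic, bic).
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "bond_fit"))
  c(aic = fit$aic, bic = fit$bic)
}

#' @rdname information_criteria
#' @param ... \code{bond_fit} objects (optionally named).
#' @return \code{compare_fits}: \code{data.frame} with logL, n_free, AIC,
#'   BIC, delta_aic, delta_bic per fit.
#' @export
compare_fits <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "bond_fit")) {
    fits <- fits[[1]]
  }
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$model_kind, character(1))
  out <- data.frame(model = nm,
                    logL = vapply(fits, function(f) f$logL, numeric(1)),
                    n_free = vapply(fits, function(f) f$n_free, numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)),
                    bic = vapply(fits, function(f) f$bic, numeric(1)))
  out$delta_aic <- out$aic - min(out$aic)
  out$delta_bic <- out$bic - min(out$bic)
  out
}

#' Empirical bootstrap of an MLE fit
#'
#' Resamples the records with replacement (replicate size = n_obs by default,
#' matching the study's N = 1001 draws from its pooled dataset), refits each
#' replicate, and reports percentile confidence intervals. Catch-model
#' replicates use a reduced GA epoch count (default 20).
#'
#' @param records Force-lifetime records.
#' @param model_kind "slip", "two_state_slip" or "catch".
#' @param n_boot Number of bootstrap replicates (10,000 in the study; scale
#'   down for exploratory runs).
#' @param level Confidence level, percent (default 95: 2.5/97.5 percentiles).
#' @param resample_size Records per replicate; default n_obs.
#' @param boot_epochs GA epochs per catch replicate.
#' @param boot_restarts Local-optimizer restarts per slip-type replicate;
#'   replicates start from the point estimate, so 1 is usually enough.
#' @param max_fail_frac Error out if more than this fraction of refits fail.
#' @param fit_args List of extra arguments passed to the fitter (fixed,
#'   bounds, directional, ...).
#' @param point_fit Optional precomputed \code{bond_fit} used as the point
#'   estimate and replicate starting point.
#' @param cfg A \code{\link{physical_config}}.
#' @param seed Integer seed.
#' @return Object of class \code{bootstrap_summary}: replicate parameter
#'   table, percentile CIs, the point fit, n_boot, level and seed.
#' @export
bootstrap_mle <- function(records, model_kind, n_boot = 10000, level = 95,
                          resample_size = NULL, boot_epochs = 20,
                          boot_restarts = 2, max_fail_frac = 0.05,
                          fit_args = list(),
                          point_fit = NULL, cfg = physical_config(), seed = 1) {
  stopifnot(n_boot >= 2)
  n <- nrow(records)
  if (is.null(resample_size)) resample_size <- n
  if (is.null(point_fit)) {
    point_fit <- if (model_kind == "catch") {
      do.call(fit_catch_genetic, c(list(records = records, cfg = cfg, seed = seed),
                                   fit_args))
    } else {
      do.call(fit_mle_local, c(list(model_kind = model_kind, records = records,
                                    cfg = cfg, seed = seed), fit_args))
    }
  }
  idx_mat <- with_seed(seed + 1L, {
    matrix(sample.int(n, n_boot * resample_size, replace = TRUE),
           nrow = n_boot)
  })
  reps <- vector("list", n_boot)
  n_fail <- 0L
  rep_args_catch <- fit_args[setdiff(names(fit_args), "epochs")]
  rep_args_local <- fit_args[setdiff(names(fit_args), c("n_restarts", "init"))]
  for (b in seq_len(n_boot)) {
    rb <- records[idx_mat[b, ], , drop = FALSE]
    fit_b <- tryCatch({
      if (model_kind == "catch") {
        do.call(fit_catch_genetic,
                c(list(records = rb, epochs = boot_epochs, cfg = cfg,
                       seed = seed + 1L + b), rep_args_catch))
      } else {
        do.call(fit_mle_local,
                c(list(model_kind = model_kind, records = rb,
                       init = point_fit$theta_free, n_restarts = boot_restarts,
                       cfg = cfg, seed = seed + 1L + b), rep_args_local))
      }
    }, error = function(e) NULL)
    if (is.null(fit_b)) n_fail <- n_fail + 1L else reps[[b]] <- fit_b$theta
  }
  if (n_fail / n_boot > max_fail_frac) {
    stop(sprintf("bootstrap refit failure rate %.1f%% exceeds %.1f%%",
                 100 * n_fail / n_boot, 100 * max_fail_frac))
  }
  tab <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  alpha <- (100 - level) / 200
  ci <- t(apply(tab, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  # natural-scale parameter table (k0 instead of log10 k0)
  nat <- function(m) {
    out <- m
    kb <- grepl("log10_k0$", colnames(m))
    out[, kb] <- 10^m[, kb]
    colnames(out) <- sub("log10_k0$", "k0", colnames(m))
    out
  }
  structure(list(model_kind = model_kind, n_boot = n_boot,
                 n_failed = n_fail, level = level,
                 replicates = tab, replicates_natural = nat(tab),
                 ci = ci,
                 ci_natural = {x <- nat(t(ci)); t(x)},
                 point_fit = point_fit, fit_args = fit_args,
                 boot_epochs = boot_epochs, cfg = cfg, seed = seed),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap_summary: %s model, %d replicates (%d failed), %g%% CIs\n",
              x$model_kind, x$n_boot, x$n_failed, x$level))
  print(signif(cbind(estimate = x$point_fit$theta[colnames(x$replicates)],
                     x$ci), 4))
  invisible(x)
}

#' Bootstrap envelope of the mean-lifetime curve
#'
#' Per force-grid point, the percentile band of the model mean lifetime
#' <tau>(F) across bootstrap replicates.
#'
#' @param bs A \code{bootstrap_summary}.
#' @param force_grid Forces, pN.
#' @param level Band level, percent.
#' @return \code{data.frame}: \code{force_pN, lower, upper} (s), plus the
#'   point-estimate curve in \code{mean_lifetime_s}.
#' @export
mean_lifetime_envelope <- function(bs, force_grid, level = 95) {
  stopifnot(inherits(bs, "bootstrap_summary"), nrow(bs$replicates) > 0)
  slots <- .param_slots(bs$model_kind,
                        directional = isTRUE(bs$fit_args$directional))
  fixed <- bs$fit_args$fixed
  pi0 <- if (!is.null(bs$fit_args$pi0)) bs$fit_args$pi0 else c(1, 0)
  curves <- apply(bs$replicates, 1, function(th) {
    m <- .build_model(bs$model_kind, th, slots,
                      isTRUE(bs$fit_args$directional), pi0 = pi0)
    vapply(force_grid, function(f) bond_mean_lifetime(m, f, bs$cfg), numeric(1))
  })
  curves <- matrix(curves, nrow = length(force_grid))
  alpha <- (100 - level) / 200
  point <- vapply(force_grid,
                  function(f) bond_mean_lifetime(bs$point_fit$model, f, bs$cfg),
                  numeric(1))
  data.frame(force_pN = force_grid,
             mean_lifetime_s = point,
             lower = apply(curves, 1, stats::quantile, probs = alpha),
             upper = apply(curves, 1, stats::quantile, probs = 1 - alpha))
}
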