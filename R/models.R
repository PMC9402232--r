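#' Physical configuration for rate laws
#'
#' Bundles the thermal energy used by the Bell-Evans rate law. Forces are
#' signed in the instrument frame; only the magnitude enters the exponential,
#' while the sign selects the direction-specific distance parameter of a
#' directional transition.
#'
#' @param kBT Thermal energy in pN nm. The default 4.11 corresponds to
#'   T = 298 K. All fitted distance parameters scale with this choice.
#' @return An object of class \code{physical_config}.
#' @export
physical_config <- function(kBT = 4.11) {
  stopifnot(is.numeric(kBT), length(kBT) == 1L, is.finite(kBT), kBT > 0)
  structure(list(kBT = kBT), class = "physical_config")
}

#' A single Bell-Evans transition
#'
#' One kinetic transition with zero-force rate \code{k0} (1/s) and distance
#' parameter \code{x} (nm). A transition may instead carry a pair
#' \code{x_minus}/\code{x_plus} used when load points toward the pointed (-)
#' or barbed (+) end of the filament. A negative distance means the rate is
#' decreased by force.
#'
#' @param k0 Zero-force rate, 1/s; must be >= 0 (zero switches a transition
#'   off, e.g. to decouple the two bound states).
#' @param x Distance parameter, nm (nondirectional transitions).
#' @param x_minus,x_plus Direction-specific distance parameters, nm. Supply
#'   both (and omit \code{x}) for a directional transition.
#' @param fixed_k0,fixed_x Logical; hold the parameter constant during fitting.
#' @return An object of class \code{bell_transition}.
#' @export
bell_transition <- function(k0, x = NULL, x_minus = NULL, x_plus = NULL,
                            fixed_k0 = FALSE, fixed_x = FALSE) {
  stopifnot(is.numeric(k0), length(k0) == 1L, is.finite(k0), k0 >= 0)
  k0 <- as.numeric(k0)
  directional <- is.null(x)
  if (directional) {
    stopifnot(!is.null(x_minus), !is.null(x_plus),
              is.finite(x_minus), is.finite(x_plus))
    x_minus <- as.numeric(x_minus); x_plus <- as.numeric(x_plus)
  } else {
    stopifnot(length(x) == 1L, is.finite(x))
    x <- as.numeric(x)
  }
  structure(list(k0 = k0, x = x, x_minus = x_minus, x_plus = x_plus,
                 directional = directional,
                 fixed_k0 = isTRUE(fixed_k0), fixed_x = isTRUE(fixed_x)),
            class = "bell_transition")
}

#' Evaluate a Bell-Evans transition rate
#'
#' Computes k(F) = k0 exp(|F| x / kBT). For directional transitions the
#' distance is \code{x_minus} when F < 0 and \code{x_plus} when F >= 0.
#'
#' @param transition A \code{\link{bell_transition}}.
#' @param force Signed force(s), pN. Vectorized.
#' @param cfg A \code{\link{physical_config}}.
#' @return Rate(s) in 1/s, strictly positive.
#' @examples
#' transition_rate(bell_transition(0.49, 0.48), 0)    # 0.49
#' transition_rate(bell_transition(0.22, 0.55), 6)    # ~0.491
#' @export
transition_rate <- function(transition, force, cfg = physical_config()) {
  if (any(!is.finite(force))) stop("non-finite force in rate evaluation")
  x <- if (transition$directional) {
    ifelse(force < 0, transition$x_minus, transition$x_plus)
  } else {
    transition$x
  }
  transition$k0 * exp(abs(force) * x / cfg$kBT)
}

#' One-state slip bond model
#'
#' A single bound state B whose dissociation rate to the unbound state U
#' follows the Bell-Evans law; lifetimes are exponential at each force.
#'
#' @param bu \code{\link{bell_transition}} for B -> U.
#' @return Object of class \code{c("slip_model", "bond_model")}.
#' @export
slip_model <- function(bu) {
  stopifnot(inherits(bu, "bell_transition"))
  structure(list(bu = bu), class = c("slip_model", "bond_model"))
}

#' Two-state slip bond (exponential mixture) model
#'
#' Binding occurs in one of two non-interconverting bound states B1 (with
#' probability \code{p1}) or B2, each dissociating with its own Bell-Evans
#' rate; lifetimes are a two-component exponential mixture.
#'
#' @param p1 Probability of observing state-1 binding, in [0, 1].
#' @param b1u,b2u \code{\link{bell_transition}}s for B1 -> U and B2 -> U.
#' @return Object of class \code{c("two_state_slip_model", "bond_model")}.
#' @export
two_state_slip_model <- function(p1, b1u, b2u) {
  stopifnot(is.numeric(p1), length(p1) == 1L, p1 >= 0, p1 <= 1,
            inherits(b1u, "bell_transition"), inherits(b2u, "bell_transition"))
  structure(list(p1 = as.numeric(p1), b1u = b1u, b2u = b2u),
            class = c("two_state_slip_model", "bond_model"))
}

#' Two-bound-state catch bond model
#'
#' Kinetic scheme with a weak bound state 1, a strong bound state 2 and the
#' unbound state 0. Force accelerates the dissociations 1->0 and 2->0 and the
#' strengthening transition 1->2, but (via a negative distance parameter)
#' slows 2->1, so mean lifetime can increase with load. The observed lifetime
#' is the first-passage time to state 0.
#'
#' @param t10,t12,t21,t20 \code{\link{bell_transition}}s for the four
#'   transitions 1->0, 1->2, 2->1 and 2->0.
#' @param pi0 Initial occupancy of bound states (pi1, pi2); non-negative,
#'   summing to 1. Default c(1, 0): binding initiates in the weak state.
#' @return Object of class \code{c("catch_model", "bond_model")}.
#' @export
catch_model <- function(t10, t12, t21, t20, pi0 = c(1, 0)) {
  for (tr in list(t10, t12, t21, t20)) stopifnot(inherits(tr, "bell_transition"))
  stopifnot(is.numeric(pi0), length(pi0) == 2L, all(pi0 >= 0))
  pi0 <- as.numeric(pi0)
  if (abs(sum(pi0) - 1) > 1e-9) stop("pi0 must sum to 1")
  structure(list(t10 = t10, t12 = t12, t21 = t21, t20 = t20, pi0 = pi0),
            class = c("catch_model", "bond_model"))
}

#' Sub-generator of the catch-bond bound-state chain
#'
#' Assembles the 2x2 sub-generator Q over bound states (1, 2) and the exit
#' rate vector r to the unbound state 0 at a given force. Rows of the full
#' generator (Q augmented with r) sum to zero.
#'
#' @param model A \code{\link{catch_model}}.
#' @param force Signed force, pN (scalar).
#' @param cfg A \code{\link{physical_config}}.
#' @return List with elements \code{Q} (2x2 matrix) and \code{r} (length 2).
#' @export
catch_generator <- function(model, force, cfg = physical_config()) {
  k10 <- transition_rate(model$t10, force, cfg)
  k12 <- transition_rate(model$t12, force, cfg)
  k21 <- transition_rate(model$t21, force, cfg)
  k20 <- transition_rate(model$t20, force, cfg)
  Q <- matrix(c(-(k10 + k12), k12, k21, -(k20 + k21)), 2, 2, byrow = TRUE)
  list(Q = Q, r = c(k10, k20))
}

## Closed-form ingredients of the 2x2 phase-type survival/density at force F.
## S(t) = pi exp(Qt) 1, f(t) = pi exp(Qt) r, with
## exp(Qt) = e^{mu t}[cosh(dt) I + sinh(dt)/d (Q - mu I)],
## mu = tr(Q)/2, d = sqrt(((a-d22)/2)^2 + k12 k21) >= 0. Continuous at d = 0.
## Vectorized over force. Returns per-force scalars.
.catch_core <- function(model, force, cfg) {
  k10 <- transition_rate(model$t10, force, cfg)
  k12 <- transition_rate(model$t12, force, cfg)
  k21 <- transition_rate(model$t21, force, cfg)
  k20 <- transition_rate(model$t20, force, cfg)
  a <- -(k10 + k12); b <- k12; cc <- k21; d22 <- -(k20 + k21)
  mu <- (a + d22) / 2
  disc <- sqrt(((a - d22) / 2)^2 + b * cc)
  # slow eigenvalue mu + disc computed cancellation-free via
  # disc^2 - mu^2 = -det(Q), with det(Q) in its expanded all-positive form
  detQ <- k10 * k20 + k10 * k21 + k12 * k20
  lam_slow <- -detQ / (disc - mu)
  p <- model$pi0
  list(k10 = k10, k20 = k20,
       mu = mu, disc = disc, lam_slow = lam_slow,
       # pi (Q - mu I) 1 and pi r, pi (Q - mu I) r: linear coefficients
       A_S = p[1] + p[2],
       B_S = p[1] * (a + b) + p[2] * (cc + d22) - mu * (p[1] + p[2]),
       A_f = p[1] * k10 + p[2] * k20,
       B_f = p[1] * (a * k10 + b * k20) + p[2] * (cc * k10 + d22 * k20) -
         mu * (p[1] * k10 + p[2] * k20))
}

## e^{mu t}[cosh(dt) A + sinh(dt)/d B], computed in log-safe form and
## continuous through d -> 0 where sinh(dt)/d -> t. lam_slow is the slow
## eigenvalue mu + disc supplied cancellation-free by .catch_core.
.phase2_eval <- function(t, mu, disc, lam_slow, A, B, log = FALSE) {
  u <- disc * t
  # sinh(u)/disc = exp(u) * (-expm1(-2u)) / (2 disc); limit t as disc -> 0
  sin_term <- ifelse(disc > 1e-14, -expm1(-2 * u) / (2 * disc), t * exp(-u))
  bracket <- (1 + exp(-2 * u)) * A / 2 + sin_term * B
  lg <- lam_slow * t + log(pmax(bracket, .Machine$double.xmin))
  if (log) lg else exp(lg)
}

#' Lifetime distribution of a bond model at a force
#'
#' Expresses the lifetime distribution at force F as an exponential mixture:
#' one term for the slip model, two for the two-state slip mixture and for
#' the catch bond (via eigendecomposition of the bound-state sub-generator).
#' Survival weights sum to 1; for the catch bond individual weights may fall
#' outside [0, 1] while the density remains non-negative.
#'
#' @param model A \code{bond_model}.
#' @param force Signed force, pN (scalar).
#' @param cfg A \code{\link{physical_config}}.
#' @return Object of class \code{lifetime_distribution}: list with
#'   \code{weights}, \code{rates} (1/s), \code{force}, \code{mean} (s), and
#'   \code{degenerate} flag (equal eigenvalues; weights then describe the
#'   limiting (1 + c t) e^{-rt} form only approximately and evaluation
#'   functions use the exact closed form instead).
#' @export
lifetime_distribution <- function(model, force, cfg = physical_config()) {
  UseMethod("lifetime_distribution")
}

#' @export
lifetime_distribution.slip_model <- function(model, force, cfg = physical_config()) {
  stopifnot(is.finite(force))
  k <- transition_rate(model$bu, force, cfg)
  structure(list(weights = 1, rates = k, force = force, mean = 1 / k,
                 degenerate = FALSE, model = model, cfg = cfg),
            class = "lifetime_distribution")
}

#' @export
lifetime_distribution.two_state_slip_model <- function(model, force,
                                                       cfg = physical_config()) {
  stopifnot(is.finite(force))
  k1 <- transition_rate(model$b1u, force, cfg)
  k2 <- transition_rate(model$b2u, force, cfg)
  w <- c(model$p1, 1 - model$p1)
  structure(list(weights = w, rates = c(k1, k2), force = force,
                 mean = w[1] / k1 + w[2] / k2,
                 degenerate = FALSE, model = model, cfg = cfg),
            class = "lifetime_distribution")
}

#' @export
lifetime_distribution.catch_model <- function(model, force, cfg = physical_config()) {
  stopifnot(is.finite(force))
  co <- .catch_core(model, force, cfg)
  lam <- c(co$lam_slow, co$mu - co$disc)
  if (any(lam >= 0)) stop("bound-state chain has no absorption at this force")
  degen <- co$disc <= 1e-10 * abs(co$mu)
  if (degen) {
    w <- c(co$A_S / 2, co$A_S / 2)  # nominal split; evaluation uses exact form
  } else {
    w <- c((co$A_S + co$B_S / co$disc) / 2, (co$A_S - co$B_S / co$disc) / 2)
  }
  structure(list(weights = w, rates = -lam, force = force,
                 mean = catch_mean(model, force, cfg),
                 degenerate = degen, model = model, cfg = cfg),
            class = "lifetime_distribution")
}

#' @export
print.lifetime_distribution <- function(x, ...) {
  cat(sprintf("Lifetime distribution at F = %g pN\n", x$force))
  cat("  rates (1/s): ", paste(signif(x$rates, 4), collapse = ", "), "\n")
  cat("  survival weights: ", paste(signif(x$weights, 4), collapse = ", "), "\n")
  cat(sprintf("  mean lifetime: %g s\n", x$mean))
  invisible(x)
}

#' Density, survival and log-density of a bond model
#'
#' Vectorized over observation pairs (tau_i, F_i); \code{force} recycles to
#' the length of \code{tau}. Computation is in log space so likelihoods of
#' lifetimes up to 1e4 s do not underflow.
#'
#' @param model A \code{bond_model}.
#' @param tau Lifetimes, s (non-negative).
#' @param force Signed force(s), pN.
#' @param cfg A \code{\link{physical_config}}.
#' @param log Return log-density?
#' @return Numeric vector of densities (1/s) or survival probabilities.
#' @export
bond_density <- function(model, tau, force, cfg = physical_config(), log = FALSE) {
  UseMethod("bond_density")
}

#' @export
bond_density.slip_model <- function(model, tau, force, cfg = physical_config(),
                                    log = FALSE) {
  k <- transition_rate(model$bu, force, cfg)
  lg <- base::log(k) - k * tau
  if (log) lg else exp(lg)
}

#' @export
bond_density.two_state_slip_model <- function(model, tau, force,
                                              cfg = physical_config(), log = FALSE) {
  k1 <- transition_rate(model$b1u, force, cfg)
  k2 <- transition_rate(model$b2u, force, cfg)
  p1 <- model$p1
  if (p1 == 1) {
    lg <- base::log(k1) - k1 * tau
  } else if (p1 == 0) {
    lg <- base::log(k2) - k2 * tau
  } else {
    l1 <- base::log(p1) + base::log(k1) - k1 * tau
    l2 <- base::log1p(-p1) + base::log(k2) - k2 * tau
    m <- pmax(l1, l2)
    lg <- m + base::log(exp(l1 - m) + exp(l2 - m))
  }
  if (log) lg else exp(lg)
}

#' @export
bond_density.catch_model <- function(model, tau, force, cfg = physical_config(),
                                     log = FALSE) {
  force <- rep_len(force, length(tau))
  co <- .catch_core(model, force, cfg)
  .phase2_eval(tau, co$mu, co$disc, co$lam_slow, co$A_f, co$B_f, log = log)
}

#' @rdname bond_density
#' @export
bond_survival <- function(model, tau, force, cfg = physical_config()) {
  UseMethod("bond_survival")
}

#' @export
bond_survival.slip_model <- function(model, tau, force, cfg = physical_config()) {
  k <- transition_rate(model$bu, force, cfg)
  exp(-k * tau)
}

#' @export
bond_survival.two_state_slip_model <- function(model, tau, force,
                                               cfg = physical_config()) {
  k1 <- transition_rate(model$b1u, force, cfg)
  k2 <- transition_rate(model$b2u, force, cfg)
  model$p1 * exp(-k1 * tau) + (1 - model$p1) * exp(-k2 * tau)
}

#' @export
bond_survival.catch_model <- function(model, tau, force, cfg = physical_config()) {
  force <- rep_len(force, length(tau))
  co <- .catch_core(model, force, cfg)
  .phase2_eval(tau, co$mu, co$disc, co$lam_slow, co$A_S, co$B_S, log = FALSE)
}

## Mean first-passage time -pi Q^{-1} 1 in closed form; vectorized over force.
catch_mean <- function(model, force, cfg = physical_config()) {
  k10 <- transition_rate(model$t10, force, cfg)
  k12 <- transition_rate(model$t12, force, cfg)
  k21 <- transition_rate(model$t21, force, cfg)
  k20 <- transition_rate(model$t20, force, cfg)
  a <- -(k10 + k12); b <- k12; cc <- k21; d22 <- -(k20 + k21)
  det <- k10 * k20 + k10 * k21 + k12 * k20  # a*d22 - b*cc, cancellation-free
  p <- model$pi0
  -(p[1] * (d22 - b) + p[2] * (a - cc)) / det
}

#' Mean bond lifetime as a function of force
#'
#' Closed-form mean of the lifetime distribution, <tau>(F), the quantity the
#' study compares against binned data and for which bootstrap envelopes are
#' constructed.
#'
#' @param model A \code{bond_model}.
#' @param force Vector of signed forces, pN.
#' @param cfg A \code{\link{physical_config}}.
#' @return \code{data.frame} with columns \code{force_pN}, \code{mean_lifetime_s}.
#' @export
mean_lifetime_curve <- function(model, force, cfg = physical_config()) {
  stopifnot(all(is.finite(force)))
  m <- vapply(force, function(f) bond_mean_lifetime(model, f, cfg), numeric(1))
  data.frame(force_pN = force, mean_lifetime_s = m)
}

#' @rdname mean_lifetime_curve
#' @export
bond_mean_lifetime <- function(model, force, cfg = physical_config()) {
  UseMethod("bond_mean_lifetime")
}

#' @export
bond_mean_lifetime.slip_model <- function(model, force, cfg = physical_config()) {
  1 / transition_rate(model$bu, force, cfg)
}

#' @export
bond_mean_lifetime.two_state_slip_model <- function(model, force,
                                                    cfg = physical_config()) {
  model$p1 / transition_rate(model$b1u, force, cfg) +
    (1 - model$p1) / transition_rate(model$b2u, force, cfg)
}

#' @export
bond_mean_lifetime.catch_model <- function(model, force, cfg = physical_config()) {
  catch_mean(model, force, cfg)
}

#' Mean lifetime at zero force
#'
#' The quantity constrained during catch-bond fitting: candidate parameter
#' sets with a zero-force mean lifetime above 100 s are rejected.
#'
#' @inheritParams mean_lifetime_curve
#' @return Mean lifetime at F = 0, s.
#' @export
zero_force_mean <- function(model, cfg = physical_config()) {
  bond_mean_lifetime(model, 0, cfg)
}

## ---- JSON serialization ----------------------------------------------------

.tr_to_list <- function(tr) {
  out <- list(k0 = tr$k0)
  if (tr$directional) {
    out$x_minus <- tr$x_minus; out$x_plus <- tr$x_plus
  } else {
    out$x <- tr$x
  }
  out$fixed_k0 <- tr$fixed_k0; out$fixed_x <- tr$fixed_x
  out
}

.tr_from_list <- function(l) {
  bell_transition(k0 = l$k0, x = l$x, x_minus = l$x_minus, x_plus = l$x_plus,
                  fixed_k0 = isTRUE(l$fixed_k0), fixed_x = isTRUE(l$fixed_x))
}

#' Serialize a bond model to JSON (and back)
#'
#' Round trip is bit-exact: numbers are written at full precision.
#'
#' @param model A \code{bond_model}.
#' @param path Optional file path; if \code{NULL} the JSON string is returned.
#' @param cfg Optional \code{\link{physical_config}} recorded alongside.
#' @return \code{model_to_json}: JSON string (invisibly, if written to file).
#'   \code{model_from_json}: the reconstructed \code{bond_model} (with
#'   attribute \code{"kBT"} if one was recorded).
#' @export
model_to_json <- function(model, path = NULL, cfg = NULL) {
  l <- if (inherits(model, "slip_model")) {
    list(kind = "slip", transitions = list("B->U" = .tr_to_list(model$bu)))
  } else if (inherits(model, "two_state_slip_model")) {
    list(kind = "two_state_slip",
         transitions = list("B1->U" = .tr_to_list(model$b1u),
                            "B2->U" = .tr_to_list(model$b2u)),
         p1 = model$p1)
  } else if (inherits(model, "catch_model")) {
    list(kind = "catch",
         transitions = list("1->0" = .tr_to_list(model$t10),
                            "1->2" = .tr_to_list(model$t12),
                            "2->1" = .tr_to_list(model$t21),
                            "2->0" = .tr_to_list(model$t20)),
         pi0 = model$pi0)
  } else stop("unknown model class")
  if (!is.null(cfg)) l$kBT <- cfg$kBT
  # I(17) significant digits: doubles survive the round trip bit-exactly
  js <- jsonlite::toJSON(l, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname model_to_json
#' @param json JSON string or file path.
#' @export
model_from_json <- function(json) {
  txt <- if (length(json) == 1L && file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else paste(json, collapse = "\n")
  l <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  tr <- l$transitions
  m <- switch(l$kind,
    slip = slip_model(.tr_from_list(tr[["B->U"]])),
    two_state_slip = two_state_slip_model(l$p1, .tr_from_list(tr[["B1->U"]]),
                                          .tr_from_list(tr[["B2->U"]])),
    catch = catch_model(.tr_from_list(tr[["1->0"]]), .tr_from_list(tr[["1->2"]]),
                        .tr_from_list(tr[["2->1"]]), .tr_from_list(tr[["2->0"]]),
                        pi0 = unlist(l$pi0)),
    stop("unknown model kind: ", l$kind))
  if (!is.null(l$kBT)) attr(m, "kBT") <- l$kBT
  m
}
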