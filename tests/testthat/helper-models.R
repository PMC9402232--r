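# Shared fixtures for the test suite. All synthetic inputs are built in code.

cfg_default <- physical_config()

# slip truth used throughout: the ternary-deletion-style point values
slip_ref <- function() slip_model(bell_transition(0.49, 0.48))

# a well-conditioned catch bond: clear weak/strong separation, catch regime
# peaking near 9 pN, all rates well inside the fitting bounds
catch_ref <- function() {
  catch_model(bell_transition(5, 0.1),    # 1 -> 0
              bell_transition(0.5, 2.0),  # 1 -> 2
              bell_transition(5, -1.5),   # 2 -> 1
              bell_transition(0.2, 0.4))  # 2 -> 0
}

# the decoupled-limit fixture: no interconversion, start in state 1
catch_decoupled <- function(k10 = 2) {
  catch_model(bell_transition(k10, 0), bell_transition(0, 0),
              bell_transition(0, 0), bell_transition(1, 0))
}

records_from <- function(force, lifetime, filament = "f001",
                         construct = "test", assay = "constant") {
  data.frame(construct = construct, filament_id = filament,
             event_id = sprintf("e%06d", seq_along(force)),
             assay = assay, n_steps = 1L, is_last_step = TRUE,
             force_pN = force, lifetime_s = lifetime,
             stringsAsFactors = FALSE)
}

# KS statistic of a sample against an analytic survival function
ks_against <- function(x, survival_fun) {
  xs <- sort(x)
  n <- length(xs)
  cdf <- 1 - survival_fun(xs)
  max(pmax(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf)))
}
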