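## Alpha-function synaptic dynamics as a second-order linear ODE with unit DC
## gain: hddot = (F - h)/tau^2 - 2*hdot/tau, so a constant presynaptic firing
## rate F gives steady-state h = F.  The impulse response is proportional to
## t*exp(-t/tau), peaking at t = tau.

#' Synapse specification
#'
#' @param tau synaptic time constant, ms (e.g. 10 for pyramidal/AMPA-like,
#'   2 for fast GABA-A, 20 for slow GABA-B)
#' @param g coupling constant, uA/cm2 per Hz of presynaptic firing
#' @param delay axonal/synaptic delay, ms
#' @param sign +1 excitatory, -1 inhibitory
#' @export
synapse_spec <- function(tau, g, delay = 0, sign = 1) {
  stopifnot(tau > 0, delay >= 0, sign %in% c(-1, 1))
  structure(list(tau = tau, g = g, delay = delay, sign = sign),
            class = "mnm_synapse")
}

#' Normalized alpha kernel
#'
#' `alpha(t) = t * exp(-t/tau) / tau^2`, normalized to unit DC gain
#' (integral 1); zero for `t < 0`.
#'
#' @param t time, ms
#' @param tau time constant, ms
#' @export
alpha_kernel <- function(t, tau) {
  ifelse(t < 0, 0, t * exp(-t / tau) / tau^2)
}

#' Advance the synaptic state by one step
#'
#' Exact update of the critically damped second-order system over a step of
#' length `dt` during which the presynaptic firing rate is held at `F`.
#'
#' @param state list with elements `h` and `dh`
#' @param F presynaptic firing rate over the step, Hz
#' @param dt step, ms
#' @param tau synaptic time constant, ms
#' @return updated `list(h =, dh =)`
#' @export
step_synapse <- function(state, F, dt, tau) {
  if (dt > tau / 10 * 1.0000001)
    warning("dt exceeds tau/10; synaptic input is assumed constant per step")
  u0 <- state$h - F
  du0 <- state$dh
  c1 <- du0 + u0 / tau
  E <- exp(-dt / tau)
  u <- (u0 + c1 * dt) * E
  du <- (du0 - c1 * dt / tau) * E
  list(h = u + F, dh = du)
}

#' Integrate the synaptic ODE over a firing-rate series
#'
#' @param F numeric vector of presynaptic firing rates sampled every `dt`
#' @param dt sampling step, ms
#' @param tau time constant, ms
#' @param init initial `list(h =, dh =)`
#' @return numeric vector of `h` values aligned with `F`
#' @export
integrate_synapse <- function(F, dt, tau, init = list(h = 0, dh = 0)) {
  h <- numeric(length(F))
  st <- init
  h[1] <- st$h
  for (i in seq_along(F)[-1]) {
    st <- step_synapse(st, F[i - 1], dt, tau)
    h[i] <- st$h
  }
  h
}

#' Read a delayed value from a conductance history
#'
#' Linear interpolation of `h(t - D)` in the sampled history; times before
#' the start of the history return the first value (warm-up).
#'
#' @param times sample times, ms (sorted)
#' @param values sampled `h` values
#' @param D delay, ms
#' @return delayed values aligned with `times`
#' @export
delayed_read <- function(times, values, D = 0) {
  stopifnot(D >= 0, length(times) == length(values))
  if (D == 0) return(values)
  approx(times, values, xout = pmax(times - D, times[1]), rule = 2)$y
}
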