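## The coupled excitatory-inhibitory mass network: two mass elements sharing
## one extracellular potassium bath, coupled through alpha-function synapses,
## with firing rates relaxing toward the mass transfer functions
## (a discretized Wilson-Cowan form).

#' Couple an excitatory and an inhibitory mass into a network
#'
#' @param E,I fitted mass parametrizations of kinds `"E"` and `"I"`
#' @param g_EI excitatory-to-inhibitory coupling, uA/cm2 per Hz
#' @param g_IE inhibitory-to-excitatory coupling, uA/cm2 per Hz
#' @param lambda_E,lambda_I firing-rate relaxation time constants, ms
#' @param tau_E,tau_I synaptic time constants, ms
#' @param dnuK shared potassium Nernst-potential shift of the common bath, mV
#' @param I_I_inj constant external current to the inhibitory mass, uA/cm2
#' @return object of class `"mnm_network"`
#' @export
mnm_network <- function(E, I, g_EI = 0.2, g_IE = 0.04,
                        lambda_E = 1, lambda_I = 1, tau_E = 10, tau_I = 20,
                        dnuK = 0, I_I_inj = 0) {
  stopifnot(inherits(E, "mnm_mass"), inherits(I, "mnm_mass"),
            E$mass_kind == "E", I$mass_kind == "I",
            lambda_E > 0, lambda_I > 0, tau_E > 0, tau_I > 0,
            g_EI >= 0, g_IE >= 0)
  structure(list(E = E, I = I, g_EI = g_EI, g_IE = g_IE,
                 lambda_E = lambda_E, lambda_I = lambda_I,
                 tau_E = tau_E, tau_I = tau_I, dnuK = dnuK,
                 I_I_inj = I_I_inj),
            class = "mnm_network")
}

#' @export
print.mnm_network <- function(x, ...) {
  cat("<E-I mass network>\n")
  cat(sprintf("  g_EI = %g, g_IE = %g uA/cm2 per Hz; lambda = (%g, %g) ms; tau = (%g, %g) ms\n",
              x$g_EI, x$g_IE, x$lambda_E, x$lambda_I, x$tau_E, x$tau_I))
  cat(sprintf("  shared dnuK = %g mV; I_I,inj = %g uA/cm2\n", x$dnuK, x$I_I_inj))
  invisible(x)
}

## ---- stimulus protocols -------------------------------------------------

.new_stimulus <- function(tbreak, ibreak, kind) {
  stopifnot(length(tbreak) == length(ibreak), !is.unsorted(tbreak))
  structure(list(tbreak = tbreak, ibreak = ibreak,
                 duration = max(tbreak), kind = kind),
            class = "mnm_stimulus")
}

#' Stimulus protocols for the network
#'
#' Piecewise-linear, continuous drive waveforms delivered to the excitatory
#' mass: a constant step, a symmetric triangular ramp, or a train of
#' ramp-fronted pulses with increasing amplitudes.
#'
#' @param amplitude,peak,amplitudes current level(s), uA/cm2
#' @param duration total protocol duration, ms
#' @param base baseline current, uA/cm2
#' @param period,duty,ramp pulse-train period (ms), on-fraction, and rise/fall
#'   ramp (ms)
#' @return object of class `"mnm_stimulus"` (fields `tbreak`, `ibreak`)
#' @export
stim_constant <- function(amplitude, duration) {
  .new_stimulus(c(0, duration), c(amplitude, amplitude), "constant")
}

#' @rdname stim_constant
#' @export
stim_ramp <- function(peak, duration, base = 0) {
  .new_stimulus(c(0, duration / 2, duration), c(base, peak, base),
                "symmetric_ramp")
}

#' @rdname stim_constant
#' @export
stim_pulse_train <- function(amplitudes, period = 2000, duty = 0.75,
                             ramp = 250, base = 0) {
  stopifnot(duty > 0, duty < 1, ramp > 0, duty * period + ramp < period)
  tb <- 0; ib <- base
  for (k in seq_along(amplitudes)) {
    t0 <- (k - 1) * period
    tb <- c(tb, t0 + ramp, t0 + duty * period, t0 + duty * period + ramp)
    ib <- c(ib, amplitudes[k], amplitudes[k], base)
    if (k < length(amplitudes)) { tb <- c(tb, k * period); ib <- c(ib, base) }
  }
  tb <- c(tb, length(amplitudes) * period); ib <- c(ib, base)
  .new_stimulus(tb, ib, "pulse_train")
}

## ---- integration --------------------------------------------------------

#' Integrate the coupled network
#'
#' Fixed-step RK4 integration (compiled) of the six-dimensional system
#' (two firing rates, two second-order synaptic conductances).  At each step
#' the total currents are `X_E = I_E,inj(t) - g_IE * h_I` and
#' `X_I = I_I,inj + g_EI * h_E` (the pump current and its potassium
#' dependence live inside the mass thresholds, see [total_current()]); the
#' firing rates relax toward the mass transfer functions evaluated on those
#' currents.
#'
#' @param object network from [mnm_network()]
#' @param nsim,seed unused (deterministic); part of the generic signature
#' @param stimulus drive waveform from [stim_constant()], [stim_ramp()] or
#'   [stim_pulse_train()]
#' @param dt integration step, ms
#' @param out_dt output sampling interval, ms
#' @param init optional initial state
#'   `c(FR_E, FR_I, h_E, dh_E, h_I, dh_I)`
#' @param ... unused
#' @return data.frame of class `"mnm_net_traj"` with columns
#'   `t, I_E_inj, FR_E, FR_I, h_E, h_I, Q_E, Q_I, regime`
#' @export
simulate.mnm_network <- function(object, nsim = 1, seed = NULL,
                                 stimulus, dt = 0.05, out_dt = 0.5,
                                 init = NULL, ...) {
  stopifnot(inherits(stimulus, "mnm_stimulus"))
  if (dt > min(object$lambda_E, object$lambda_I, object$tau_E,
               object$tau_I) / 10)
    warning("dt exceeds one tenth of the fastest time constant")
  thE <- thresholds_and_maxima(object$E, object$dnuK, warn_extrapolate = FALSE)
  thI <- thresholds_and_maxima(object$I, object$dnuK, warn_extrapolate = FALSE)
  ## pump slots are zero: the thresholds are steady-state currents that
  ## already contain the pump (see total_current)
  par <- c(thE$i_th1, thE$i_th2, thE$M1, 0,
           thI$i_th1, thI$i_th2, thI$M1, 0,
           object$g_EI, object$g_IE, object$lambda_E, object$lambda_I,
           object$tau_E, object$tau_I, object$I_I_inj)
  if (is.null(init)) init <- numeric(6)
  thin <- max(1L, as.integer(round(out_dt / dt)))
  nstep <- as.numeric(round(stimulus$duration / dt))
  m <- .Call(mnm_net_rk4, as.numeric(par), as.numeric(stimulus$tbreak),
             as.numeric(stimulus$ibreak), as.numeric(dt), nstep,
             as.integer(thin), as.numeric(init))
  out <- as.data.frame(m)
  names(out) <- c("t", "I_E_inj", "FR_E", "FR_I", "h_E", "h_I", "Q_E", "Q_I")
  out$regime <- .regime_row(out)
  class(out) <- c("mnm_net_traj", "data.frame")
  attr(out, "network") <- object
  attr(out, "stimulus_kind") <- stimulus$kind
  out
}

## instantaneous regime label per row
.regime_row <- function(df, fr_eps = 0.5) {
  ifelse(df$FR_E < fr_eps & df$Q_E > 1, "DB",
  ifelse(df$FR_E >= fr_eps & df$Q_I > 1, "RAE",
  ifelse(df$FR_E < fr_eps & df$Q_E < 0, "NF", "F")))
}

#' Classify the network regime over a trajectory window
#'
#' Labels a (near-steady-state) window by its cycle-averaged state: `NF`
#' (excitatory mass silent, subthreshold), `F` (both masses firing), `RAE`
#' (runaway excitation: excitatory firing with the inhibitory mass in
#' depolarization block), or `DB` (excitatory mass in depolarization block).
#' An oscillatory window is labelled by its means and flagged.
#'
#' @param window data.frame rows of a trajectory from
#'   [simulate.mnm_network()]
#' @param fr_eps firing-rate threshold for "silent", Hz
#' @return character label with attributes `oscillatory` and `means`
#' @export
classify_regime <- function(window, fr_eps = 0.5) {
  m <- colMeans(window[, c("FR_E", "FR_I", "Q_E", "Q_I")])
  osc <- stats::sd(window$FR_E) > max(0.1 * abs(m[["FR_E"]]), fr_eps)
  lab <- if (m[["FR_E"]] < fr_eps && m[["Q_E"]] > 1) "DB"
         else if (m[["FR_E"]] >= fr_eps && m[["Q_I"]] > 1) "RAE"
         else if (m[["FR_E"]] < fr_eps && m[["Q_E"]] < 0) "NF"
         else "F"
  structure(lab, oscillatory = osc, means = m)
}

#' Hysteresis scan with a slow symmetric ramp
#'
#' Drives the network with a symmetric triangular ramp and locates, on the
#' rising and falling phases separately, the injected currents at which the
#' inhibitory and excitatory masses enter and leave depolarization block
#' (crossings of the normalized currents Q through 1).  The bistable interval
#' is bounded by the falling-phase recovery and rising-phase entry of the
#' inhibitory mass.
#'
#' @param network network from [mnm_network()]
#' @param peak ramp peak, uA/cm2
#' @param duration total ramp duration (up plus down), ms
#' @param dt,out_dt integration and output steps, ms
#' @param sustain minimal time (ms) a threshold crossing must persist to
#'   count as a transition; brief excursions during the low-drive
#'   oscillatory regime are ignored
#' @return list with elements `rising` (`I_db_entry`, `E_db_entry`),
#'   `falling` (`E_db_exit`, `I_db_exit`), `bistable` (`lower`, `upper`) and
#'   the trajectory as `trajectory`
#' @export
hysteresis_scan <- function(network, peak, duration = 40000, dt = 0.05,
                            out_dt = 0.5, sustain = 50) {
  traj <- simulate(network, stimulus = stim_ramp(peak, duration), dt = dt,
                   out_dt = out_dt)
  half <- duration / 2
  up <- traj[traj$t <= half, ]
  down <- traj[traj$t > half, ]
  run_len <- max(1L, as.integer(round(sustain / out_dt)))
  ## first index opening a run of at least `sustain` ms satisfying cond;
  ## brief oscillatory excursions through the threshold do not count
  sustained_start <- function(cond) {
    r <- rle(cond)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= run_len)
    if (length(ok) == 0) return(NA_integer_)
    ends[ok[1]] - r$lengths[ok[1]] + 1L
  }
  cross <- function(df, col) {
    i <- sustained_start(df[[col]] >= 1)
    if (is.na(i)) NA_real_ else df$I_E_inj[i]
  }
  exit_of <- function(df, col) {
    was_in <- df[[col]] >= 1
    if (!any(was_in)) return(NA_real_)
    sub <- df[seq(which(was_in)[1], nrow(df)), , drop = FALSE]
    i <- sustained_start(sub[[col]] < 1)
    if (is.na(i)) NA_real_ else sub$I_E_inj[i]
  }
  I_entry <- cross(up, "Q_I")
  E_entry <- cross(up, "Q_E")
  E_exit <- exit_of(down, "Q_E")
  I_exit <- exit_of(down, "Q_I")
  list(rising = c(I_db_entry = I_entry, E_db_entry = E_entry),
       falling = c(E_db_exit = E_exit, I_db_exit = I_exit),
       bistable = c(lower = I_exit, upper = I_entry),
       trajectory = traj)
}

#' @export
plot.mnm_net_traj <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$t / 1000, x$FR_E, type = "l", col = "blue", xlab = "time (s)",
       ylab = "FR (Hz)", ...)
  graphics::lines(x$t / 1000, x$FR_I, col = "red")
  graphics::legend("topleft", c("FR_E", "FR_I"), col = c("blue", "red"),
                   lty = 1, bty = "n")
  plot(x$t / 1000, x$I_E_inj, type = "l", xlab = "time (s)",
       ylab = expression(I[E, inj] ~ (mu * A / cm^2)))
  invisible(x)
}
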