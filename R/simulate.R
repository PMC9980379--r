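## ODE simulation of the single-neuron models and reduction of traces to
## time-averaged outputs.

.neuron_parms <- function(spec, I_inj, dnuK, I_extra) {
  Ko <- nernst_Ko(dnuK, spec$K_o_hat, spec$RT_F)
  c(kind = if (spec$kind == "WB") 1 else 2,
    C_m = spec$C_m, g_Na = spec$g_Na, g_K = spec$g_K, g_L = spec$g_L,
    nu_Na = spec$nu_Na, nu_l = spec$nu_l, nu_K = spec$nu_K_hat + dnuK,
    psi = spec$psi, rho = spec$rho, K_o_hat = spec$K_o_hat, K_o = Ko,
    g_KAHP = spec$g_KAHP, q_hat = spec$q_hat,
    I_inj = I_inj, I_extra = I_extra,
    exp_m = spec$exp_m, exp_n = spec$exp_n)
}

#' Simulate a neuron model
#'
#' Integrates the membrane ODEs with an adaptive stiff-capable solver
#' (compiled right-hand side, `deSolve::lsoda`) and returns dense output of
#' the membrane potential, gating variables and the instantaneous
#' transmembrane potassium flux.
#'
#' @inheritParams neuron_derivs
#' @param duration total simulated time, ms
#' @param dt_out output sampling interval, ms
#' @param init initial state `c(V, n, h)`; default is the voltage-clamped
#'   steady state at -64 mV
#' @param rtol,atol,max_step solver tolerances and maximal internal step (ms)
#' @param seed unused (the integration is deterministic); accepted for
#'   interface uniformity
#' @return data.frame with columns `time, V, n, h, kflux` and the call
#'   parameters as attributes
#' @export
simulate_neuron <- function(spec, I_inj, dnuK = 0, duration = 2500,
                            dt_out = 0.05, init = NULL, I_extra = 0,
                            rtol = 1e-8, atol = 1e-10, max_step = 0.1,
                            seed = NULL) {
  stopifnot(inherits(spec, "mnm_neuron"), duration > 0, dt_out > 0)
  if (is.null(init)) {
    g <- gate_steady(spec, -64)
    init <- c(V = -64, n = g[1, "n"], h = g[1, "h"])
  } else init <- setNames(as.numeric(init), c("V", "n", "h"))
  p <- .neuron_parms(spec, I_inj, dnuK, I_extra)
  times <- seq(0, duration, by = dt_out)
  run <- function(hmax) {
    deSolve::ode(y = init, times = times, func = "mnm_derivs",
                 parms = p, dllname = "mnm", initfunc = "mnm_initmod",
                 nout = 1, outnames = "kflux",
                 method = "lsoda", rtol = rtol, atol = atol, hmax = hmax)
  }
  out <- suppressWarnings(run(max_step))
  if (nrow(out) < length(times)) {
    ## retry once with a tighter step before giving up
    out <- suppressWarnings(run(max_step / 10))
    if (nrow(out) < length(times))
      stop(sprintf(
        "stiff-solver failure at I_inj = %g, dnuK = %g (integration stopped at t = %g ms)",
        I_inj, dnuK, max(out[, 1])))
  }
  res <- as.data.frame(out)
  names(res) <- c("time", "V", "n", "h", "kflux")
  attr(res, "I_inj") <- I_inj
  attr(res, "dnuK") <- dnuK
  attr(res, "spec_kind") <- spec$kind
  res
}

## trapezoidal mean of y over uniform-or-not time grid
.trapz_mean <- function(t, y) {
  if (length(t) < 2) return(mean(y))
  dt <- diff(t)
  sum((y[-1] + y[-length(y)]) / 2 * dt) / (t[length(t)] - t[1])
}

## upward threshold crossings with a refractory lockout (ms)
.spike_times <- function(t, V, threshold = 0, refractory = 2) {
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1L
  if (length(up) > 1) {
    keep <- logical(length(up)); keep[1] <- TRUE; last <- t[up[1]]
    for (i in seq_along(up)[-1]) {
      if (t[up[i]] - last > refractory) { keep[i] <- TRUE; last <- t[up[i]] }
    }
    up <- up[keep]
  }
  t[up]
}

#' Reduce a voltage trace to its time-averaged outputs
#'
#' Computes the mean firing rate, mean membrane potential and mean potassium
#' flux over the post-transient window and assigns the dynamical regime:
#' `F` (firing) if any spike occurs in the window; otherwise `DB`
#' (depolarization block) if the mean potassium flux is positive and the mean
#' potential depolarized, else `NF` (not firing).
#'
#' @param trace output of [simulate_neuron()]
#' @param transient initial time discarded before averaging, ms
#' @param spike_threshold upward-crossing voltage defining a spike, mV
#' @param refractory spike-detection lockout, ms
#' @param db_kflux_min,db_vm_min thresholds of the DB signature (positive mean
#'   flux, depolarized mean potential)
#' @return one-row data.frame: `I_inj, dnuK, mean_FR` (Hz), `mean_Vm` (mV),
#'   `mean_Kflux` (uA/cm2), `regime`, `n_spikes`, `sim_duration`, and a
#'   logical `fr_unreliable` flag raised when the window holds fewer than two
#'   inter-spike intervals
#' @export
summarize_trace <- function(trace, transient = 500, spike_threshold = 0,
                            refractory = 2, db_kflux_min = 0.5,
                            db_vm_min = -50) {
  t <- trace$time
  if (max(t) <= transient) stop("trace shorter than the transient")
  sel <- t >= transient
  ts <- t[sel]
  window <- max(ts) - min(ts)
  spk <- .spike_times(ts, trace$V[sel], spike_threshold, refractory)
  n_spikes <- length(spk)
  mean_FR <- n_spikes / (window / 1000)    # Hz
  mean_Vm <- .trapz_mean(ts, trace$V[sel])
  mean_KF <- .trapz_mean(ts, trace$kflux[sel])
  regime <- if (n_spikes > 0) "F"
            else if (mean_KF > db_kflux_min && mean_Vm > db_vm_min) "DB"
            else "NF"
  fr_unreliable <- n_spikes > 0 && n_spikes < 3
  data.frame(I_inj = attr(trace, "I_inj") %||% NA_real_,
             dnuK = attr(trace, "dnuK") %||% NA_real_,
             mean_FR = mean_FR, mean_Vm = mean_Vm, mean_Kflux = mean_KF,
             regime = regime, n_spikes = n_spikes,
             sim_duration = max(t), fr_unreliable = fr_unreliable,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep a neuron model over injected current and potassium shift
#'
#' One simulation and summary per grid point.  Individual-point failures are
#' recorded as `NA` rows rather than aborting the sweep.
#'
#' @inheritParams simulate_neuron
#' @inheritParams summarize_trace
#' @param I_inj,dnuK numeric grids (sorted)
#' @param ... passed to [simulate_neuron()]
#' @return data.frame with one row per (I_inj, dnuK) pair, columns as in
#'   [summarize_trace()]
#' @export
sweep_neuron <- function(spec, I_inj, dnuK = 0, duration = 2500,
                         transient = 500, ...) {
  grid <- expand.grid(I_inj = I_inj, dnuK = dnuK)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      tr <- simulate_neuron(spec, grid$I_inj[i], grid$dnuK[i],
                            duration = duration, ...)
      summarize_trace(tr, transient = transient)
    }, error = function(e) {
      data.frame(I_inj = grid$I_inj[i], dnuK = grid$dnuK[i],
                 mean_FR = NA_real_, mean_Vm = NA_real_,
                 mean_Kflux = NA_real_, regime = NA_character_,
                 n_spikes = NA_integer_, sim_duration = NA_real_,
                 fr_unreliable = NA, stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}
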