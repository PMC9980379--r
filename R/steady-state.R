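## Fixed points, Jacobian spectra, and the firing-onset / depolarization-block
## bifurcation boundaries as functions of the potassium Nernst potential.
## Fixed points are parametrized by the membrane potential: at a given V the
## gates sit at their steady values and the steady-state current ISS(V) is the
## injected current that makes V a fixed point.

#' Steady-state current at a voltage-parametrized fixed point
#'
#' Algebraic evaluation (no integration) of the injected current for which
#' `Vm` is a fixed point of the model at Nernst shift `dnuK`:
#' the sum of the potassium, sodium, leak, pump and (for the accommodating
#' model) accommodation currents with gates at steady state.
#'
#' @inheritParams neuron_derivs
#' @param Vm membrane potential(s), mV
#' @return steady-state current(s), uA/cm2
#' @export
iss_of_vm <- function(spec, Vm, dnuK = 0) {
  nuK <- spec$nu_K_hat + dnuK
  g <- gate_steady(spec, Vm)
  spec$g_K * g[, "n"]^spec$exp_n * (Vm - nuK) +
    spec$g_Na * g[, "m"]^spec$exp_m * g[, "h"] * (Vm - spec$nu_Na) +
    spec$g_L * (Vm - spec$nu_l) +
    pump_current_shift(spec, dnuK) +
    spec$g_KAHP * spec$q_hat * (Vm - nuK)
}

#' Jacobian of the reduced (V, n, h) system at a fixed point
#'
#' The sodium activation gate is instantaneous (m = m_inf(V)), so the system
#' is three-dimensional.  The Jacobian is evaluated analytically at the fixed
#' point (V, n_inf(V), h_inf(V)) with the injected current implicitly at
#' ISS(V).
#'
#' @inheritParams iss_of_vm
#' @param Vm membrane potential (scalar), mV
#' @return 3x3 numeric matrix (rows/cols V, n, h)
#' @export
neuron_jacobian <- function(spec, Vm, dnuK = 0) {
  nuK <- spec$nu_K_hat + dnuK
  g <- gate_steady(spec, Vm)
  dg <- .gate_steady_dv(spec, Vm)
  r <- rate_functions(spec, Vm)
  dr <- .rate_functions_dv(spec, Vm)
  m <- g[1, "m"]; n <- g[1, "n"]; h <- g[1, "h"]
  J <- matrix(0, 3, 3, dimnames = list(c("V", "n", "h"), c("V", "n", "h")))
  J[1, 1] <- -(spec$g_K * n^spec$exp_n +
               spec$g_Na * h * (spec$exp_m * m^(spec$exp_m - 1) *
                                dg[1, "m"] * (Vm - spec$nu_Na) +
                                m^spec$exp_m) +
               spec$g_L + spec$g_KAHP * spec$q_hat) / spec$C_m
  J[1, 2] <- -spec$g_K * spec$exp_n * n^(spec$exp_n - 1) * (Vm - nuK) / spec$C_m
  J[1, 3] <- -spec$g_Na * m^spec$exp_m * (Vm - spec$nu_Na) / spec$C_m
  J[2, 1] <- spec$psi * (dr[1, "alpha_n"] * (1 - n) - dr[1, "beta_n"] * n)
  J[2, 2] <- -spec$psi * (r[1, "alpha_n"] + r[1, "beta_n"])
  J[3, 1] <- spec$psi * (dr[1, "alpha_h"] * (1 - h) - dr[1, "beta_h"] * h)
  J[3, 3] <- -spec$psi * (r[1, "alpha_h"] + r[1, "beta_h"])
  J
}

#' Largest real part of the Jacobian eigenvalues at a fixed point
#'
#' @inheritParams neuron_jacobian
#' @param full if `TRUE`, return all eigenvalues instead of the largest real
#'   part
#' @return largest real part (1/ms), or the complex eigenvalue vector
#' @export
jacobian_spectrum <- function(spec, Vm, dnuK = 0, full = FALSE) {
  ev <- eigen(neuron_jacobian(spec, Vm, dnuK), only.values = TRUE)$values
  if (full) ev else max(Re(ev))
}

#' Fixed-point record at a given membrane potential
#'
#' @inheritParams neuron_jacobian
#' @return one-row data.frame: `Vm, n_inf, m_inf, h_inf, ISS, max_re_eig,
#'   stable, nu_K`
#' @export
fixed_point <- function(spec, Vm, dnuK = 0) {
  g <- gate_steady(spec, Vm)
  lam <- jacobian_spectrum(spec, Vm, dnuK)
  data.frame(Vm = Vm, n_inf = g[1, "n"], m_inf = g[1, "m"], h_inf = g[1, "h"],
             ISS = unname(iss_of_vm(spec, Vm, dnuK)), max_re_eig = lam,
             stable = lam < 0, nu_K = spec$nu_K_hat + dnuK)
}

## all zero crossings of max_re_eig over a V scan, refined by uniroot
.eig_crossings <- function(spec, dnuK, V_range, V_step, tol = 1e-6) {
  Vg <- seq(V_range[1], V_range[2], by = V_step)
  ev <- vapply(Vg, function(v) jacobian_spectrum(spec, v, dnuK), numeric(1))
  idx <- which(diff(sign(ev)) != 0)
  vapply(idx, function(i)
    uniroot(function(v) jacobian_spectrum(spec, v, dnuK),
            c(Vg[i], Vg[i + 1]), tol = tol)$root,
    numeric(1))
}

#' Trace the firing-onset and depolarization-block boundaries
#'
#' For each Nernst shift, scans the membrane potential for zero crossings of
#' the largest Jacobian eigenvalue real part (bisection-refined), and maps
#' the lowest and highest crossing through [iss_of_vm()] to the firing-onset
#' current `ISS_F` and the DB-onset current `ISS_DB`.  Rows where the firing
#' (unstable) region does not exist -- fewer than two crossings, or crossings
#' whose currents are not ordered `ISS_F < ISS_DB` (the bistable upper
#' triangle at high potassium) -- are marked absent.
#'
#' @inheritParams iss_of_vm
#' @param dnuK numeric grid of Nernst shifts, mV
#' @param V_range,V_step membrane-potential scan window and step, mV
#' @return data.frame of class `"mnm_boundaries"`: `dnuK, nu_K, iss_f,
#'   iss_db, V_f, V_db, exists`
#' @export
trace_boundaries <- function(spec, dnuK = seq(0, 20, by = 1),
                             V_range = c(-100, 20), V_step = 0.25) {
  stopifnot(all(is.finite(dnuK)), !is.unsorted(dnuK))
  rows <- lapply(dnuK, function(d) {
    cr <- .eig_crossings(spec, d, V_range, V_step)
    if (length(cr) >= 2) {
      vf <- cr[1]; vdb <- cr[length(cr)]
      isf <- unname(iss_of_vm(spec, vf, d))
      isdb <- unname(iss_of_vm(spec, vdb, d))
      ok <- isf < isdb
      data.frame(dnuK = d, nu_K = spec$nu_K_hat + d,
                 iss_f = if (ok) isf else NA_real_,
                 iss_db = if (ok) isdb else NA_real_,
                 V_f = if (ok) vf else NA_real_,
                 V_db = if (ok) vdb else NA_real_, exists = ok)
    } else {
      data.frame(dnuK = d, nu_K = spec$nu_K_hat + d, iss_f = NA_real_,
                 iss_db = NA_real_, V_f = NA_real_, V_db = NA_real_,
                 exists = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mnm_boundaries", "data.frame")
  attr(out, "spec_kind") <- spec$kind
  out
}

#' Time-averaged maxima along the shifted DB boundary
#'
#' Simulates the neuron at `I_inj = ISS_DB - delta` for each traced row and
#' records the mean firing rate (M1), mean membrane potential (M2) and mean
#' potassium flux (M3) there.  The shift `delta` keeps the sampling line out
#' of the zone bordering DB where the limit cycle has already terminated (the
#' fixed point stabilizes after the spiking solution has died, so the last
#' part of the window between `ISS_F` and `ISS_DB` is already non-firing).
#' Starting from a small fraction of the firing window, the shift fraction is
#' escalated geometrically until every sampled row fires, and one uniform
#' fraction is used for the whole line, so the maxima are measured as close
#' to the DB boundary as the dynamics allow along a smooth curve.
#'
#' @param spec neuron model specification
#' @param boundaries output of [trace_boundaries()]
#' @param shift_frac initial fraction of the firing window `ISS_DB - ISS_F`
#'   used as the shift
#' @param shift_floor minimal shift, uA/cm2
#' @param grow escalation factor applied while the shifted point does not fire
#' @param max_tries maximal number of escalations before erroring
#' @param duration,transient simulation length and discarded transient, ms
#' @param ... passed to [simulate_neuron()]
#' @return the boundary frame with columns `delta, M1, M2, M3` appended
#' @export
maxima_along_shifted_db <- function(spec, boundaries, shift_frac = 0.05,
                                    shift_floor = 0.1, grow = 1.6,
                                    max_tries = 8, duration = 2500,
                                    transient = 500, ...) {
  stopifnot(inherits(boundaries, "mnm_boundaries"))
  out <- boundaries
  out$delta <- NA_real_
  out$M1 <- NA_real_; out$M2 <- NA_real_; out$M3 <- NA_real_
  live <- which(out$exists)
  frac <- shift_frac
  for (try in seq_len(max_tries)) {
    ok <- TRUE
    for (i in live) {
      window <- out$iss_db[i] - out$iss_f[i]
      delta <- max(frac * window, shift_floor)
      if (delta >= window)
        stop(sprintf(
          "shifted DB line left the firing window at dnuK = %g (shift fraction %.3g)",
          out$dnuK[i], frac))
      I <- out$iss_db[i] - delta
      tr <- simulate_neuron(spec, I, out$dnuK[i], duration = duration, ...)
      s <- summarize_trace(tr, transient = transient)
      if (s$mean_FR <= 0) { ok <- FALSE; break }
      out$delta[i] <- delta
      out$M1[i] <- s$mean_FR; out$M2[i] <- s$mean_Vm
      out$M3[i] <- s$mean_Kflux
    }
    if (ok) {
      attr(out, "shift_frac_used") <- frac
      return(out)
    }
    frac <- frac * grow   # the whole line moves; all rows are re-measured
  }
  stop(sprintf(
    "no firing on the shifted DB line after %d escalations of the shift fraction",
    max_tries))
}
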