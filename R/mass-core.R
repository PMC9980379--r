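## Evaluation of the neural-mass functionals: thresholds, maxima, normalized
## current Q, and the three outputs.  These are pure algebraic functions of
## the fitted parametrization; this is the plug-in-replacement mass element.

## Horner evaluation, coefficients in increasing powers
.polyval <- function(coefs, x) {
  y <- rep(coefs[length(coefs)], length(x))
  for (k in rev(seq_len(length(coefs) - 1))) y <- y * x + coefs[k]
  y
}

## least-squares polynomial fit, centered for conditioning, coefficients
## returned in increasing powers of the *raw* predictor
.polyfit <- function(x, y, degree) {
  stopifnot(length(x) >= degree + 2)
  x0 <- mean(x)
  z <- x - x0
  X <- outer(z, 0:degree, `^`)
  kap <- kappa(X, exact = TRUE)
  if (kap > 1e10)
    stop("polynomial design matrix condition number ", format(kap, digits = 3),
         " exceeds 1e10; rescale the nu_K grid")
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  ## expand sum_k beta_k (x - x0)^k into raw powers of x
  raw <- numeric(degree + 1)
  for (k in 0:degree) {
    for (j in 0:k) {
      raw[j + 1] <- raw[j + 1] + beta[k + 1] * choose(k, j) * (-x0)^(k - j)
    }
  }
  list(coefficients = raw, residuals = fit$residuals,
       fitted = y - fit$residuals, kappa = kap,
       rms = sqrt(mean(fit$residuals^2)))
}

## pump current of a mass at a Nernst shift (intracellular sodium nominal)
.mass_pump <- function(param, dnuK) {
  Ko <- param$K_o_hat * exp(dnuK / param$RT_F)
  param$rho / (2 * (1 + exp(param$K_o_hat - Ko)))
}

#' Thresholds and maxima of a mass at a given potassium shift
#'
#' Evaluates the fitted threshold lines and maxima polynomials at
#' `nu_K = nu_K_hat + dnuK`: the firing threshold `i_th1`, depolarization
#' threshold `i_th2` (both in steady-state current, uA/cm2), and the maximal
#' mean firing rate `M1` (Hz), mean membrane potential `M2` (mV) and mean
#' potassium flux `M3` (uA/cm2) attained along the shifted DB boundary.
#' Values outside the fitted `dnuK` range are linear/polynomial continuations
#' and are flagged with a warning.
#'
#' @param param a fitted mass parametrization from [mnm_fit()] or
#'   [make_fixture_mass()]
#' @param dnuK Nernst-potential shift(s), mV
#' @param warn_extrapolate warn when `dnuK` leaves the fitted window
#' @return data.frame: `dnuK, nu_K, i_th1, i_th2, M1, M2, M3, I_pump`
#' @export
thresholds_and_maxima <- function(param, dnuK = 0, warn_extrapolate = TRUE) {
  stopifnot(inherits(param, "mnm_mass"))
  outside <- dnuK < param$dnuK_range[1] | dnuK > param$dnuK_range[2]
  if (warn_extrapolate && any(outside))
    warning(sprintf(
      "%d of %d dnuK value(s) outside the fitted range [%g, %g]; using polynomial continuation",
      sum(outside), length(dnuK), param$dnuK_range[1], param$dnuK_range[2]))
  nuK <- param$nu_K_hat + dnuK
  cf <- param$coefficients
  data.frame(dnuK = dnuK, nu_K = nuK,
             i_th1 = .polyval(cf$th1, nuK),
             i_th2 = .polyval(cf$th2, nuK),
             M1 = .polyval(cf$M1, nuK),
             M2 = .polyval(cf$M2, nuK),
             M3 = .polyval(cf$M3, nuK),
             I_pump = .mass_pump(param, dnuK))
}

#' Total current received by a mass
#'
#' `X_tot = I_inj + sum(sign * g * h)` over the synaptic contributions;
#' excitatory inputs carry sign +1, inhibitory sign -1 (the signs are
#' explicit, not folded into the coupling constants).
#'
#' The firing and DB thresholds of a mass are fits of the steady-state
#' current, which already contains the pump current and its potassium
#' dependence; re-adding the pump to the total current would double-count it
#' (and would push the excitatory mass, whose onset threshold lies below the
#' pump current, into spontaneous firing at zero input).  Set `pump = TRUE`
#' to obtain the literal injected-plus-pump total instead.
#'
#' @inheritParams thresholds_and_maxima
#' @param I_inj injected current, uA/cm2
#' @param synapses list of `list(g =, h =, sign =)` contributions; `g` in
#'   uA/cm2 per Hz, `h` in Hz, `sign` +1 or -1
#' @param pump whether to add the pump current explicitly (see Details)
#' @return total current, uA/cm2
#' @export
total_current <- function(param, I_inj, dnuK = 0, synapses = list(),
                          pump = FALSE) {
  syn <- 0
  for (s in synapses) {
    if (!s$sign %in% c(-1, 1))
      stop("synaptic sign must be +1 (excitatory) or -1 (inhibitory)")
    syn <- syn + s$sign * s$g * s$h
  }
  I_inj + (if (pump) .mass_pump(param, dnuK) else 0) + syn
}

## stable fixed-point closure for the mean potential and flux outside the
## firing window: solve ISS(V) = X_tot on the NF or DB branch (X_tot is in
## the same steady-state-current scale as the thresholds)
.fp_closure <- function(param, X_tot, dnuK, branch = c("NF", "DB")) {
  branch <- match.arg(branch)
  spec <- param$spec
  if (is.null(spec)) return(c(Vm = NA_real_, Kflux = NA_real_))
  I <- X_tot
  dat <- param$data[param$data$exists, , drop = FALSE]
  vf <- approx(dat$dnuK, dat$V_f, xout = dnuK, rule = 2)$y
  vdb <- approx(dat$dnuK, dat$V_db, xout = dnuK, rule = 2)$y
  rng <- if (branch == "NF") c(-130, vf) else c(vdb, 60)
  f <- function(v) iss_of_vm(spec, v, dnuK) - I
  flo <- f(rng[1]); fhi <- f(rng[2])
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    ## near the threshold the fitted i_th and the exact crossing differ by the
    ## fit residual; clamp to the branch endpoint
    V <- if (abs(flo) < abs(fhi)) rng[1] else rng[2]
  } else {
    V <- uniroot(f, rng, tol = 1e-8)$root
  }
  g <- gate_steady(spec, V)
  c(Vm = V, Kflux = unname(kflux_instant(spec, V, g[1, "n"], dnuK)))
}

#' Evaluate the mass functionals
#'
#' Computes the normalized current `Q = (X_tot - i_th1)/(i_th2 - i_th1)` and
#' the three mass outputs.  Inside the firing window (`Q` in `[0, 1]`):
#' `FR = M1 * Q^p_FR`, `Vm = C1 + (M2 - C1) * Q^p_Vm`,
#' `Kflux = C2 + (M3 - C2) * Q^p_KF`, so that the outputs start at
#' `(0, C1, C2)` at the firing threshold and reach the maxima `(M1, M2, M3)`
#' at the DB threshold.  Outside the window the firing rate is identically
#' zero and the mean potential and flux are taken from the stable fixed point
#' of the underlying neuron model (NF branch for `Q < 0`, DB branch for
#' `Q > 1`) when that model is available.
#'
#' @inheritParams thresholds_and_maxima
#' @param X_tot total input current(s), uA/cm2 (see [total_current()])
#' @param dnuK Nernst-potential shift (scalar), mV
#' @param closure `"fixed_point"` to fill `Vm`/`Kflux` outside the firing
#'   window from the stable fixed point, `"none"` to return `NA` there
#' @return data.frame: `X_tot, Q, regime` (`NF`/`F`/`DB`), `FR` (Hz),
#'   `Vm` (mV), `Kflux` (uA/cm2)
#' @export
evaluate_mass <- function(param, X_tot, dnuK = 0,
                          closure = c("fixed_point", "none"),
                          warn_extrapolate = TRUE) {
  stopifnot(inherits(param, "mnm_mass"), length(dnuK) == 1)
  closure <- match.arg(closure)
  th <- thresholds_and_maxima(param, dnuK, warn_extrapolate = warn_extrapolate)
  w <- th$i_th2 - th$i_th1
  if (w <= 0) {
    warning(sprintf(
      "degenerate firing window at dnuK = %g (i_th2 <= i_th1); regime decided by sign of X_tot - i_th1", dnuK))
    Q <- ifelse(X_tot < th$i_th1, -Inf, Inf)
  } else {
    Q <- (X_tot - th$i_th1) / w
  }
  e <- param$exponents
  regime <- ifelse(Q < 0, "NF", ifelse(Q > 1, "DB", "F"))
  FR <- ifelse(regime == "F", th$M1 * pmax(Q, 0)^e[["FR"]], 0)
  Vm <- ifelse(regime == "F",
               param$C1 + (th$M2 - param$C1) * pmax(Q, 0)^e[["Vm"]], NA_real_)
  KF <- ifelse(regime == "F",
               param$C2 + (th$M3 - param$C2) * pmax(Q, 0)^e[["KF"]], NA_real_)
  if (closure == "fixed_point" && any(regime != "F")) {
    for (i in which(regime != "F")) {
      fp <- .fp_closure(param, X_tot[i], dnuK,
                        branch = if (regime[i] == "NF") "NF" else "DB")
      Vm[i] <- fp[["Vm"]]; KF[i] <- fp[["Kflux"]]
    }
  }
  data.frame(X_tot = X_tot, Q = Q, regime = regime, FR = FR, Vm = Vm,
             Kflux = KF, stringsAsFactors = FALSE)
}
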