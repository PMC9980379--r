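## Neuron model specifications.  The activation-coefficient tables are the
## canonical published ones; conductances, reversal potentials, pump strength
## and concentrations can be overridden.

.wb_activation <- data.frame(
  rate = c("alpha_m", "beta_m", "alpha_n", "beta_n", "alpha_h", "beta_h"),
  form = c("xratio", "expf", "xratio", "expf", "expf", "logistic"),
  a  = c(0.1, 4, 0.01, 0.125, 0.07, 1),
  V0 = c(35, 60, 34, 44, 58, 28),
  b  = c(10, 18, 10, 80, 20, 10),
  stringsAsFactors = FALSE
)

## Pinsky-Rinzel somatic rates, shifted by -60 mV to the standard voltage
## convention (rest near -60 mV, nu_Na = +60, nu_K = -75).
.sean_activation <- data.frame(
  rate = c("alpha_m", "beta_m", "alpha_n", "beta_n", "alpha_h", "beta_h"),
  form = c("xratio", "xratio_rev", "xratio", "expf", "expf", "logistic"),
  a  = c(0.32, 0.28, 0.016, 0.25, 0.128, 4),
  V0 = c(46.9, 19.9, 24.9, 40, 43, 20),
  b  = c(4, 5, 5, 40, 18, 5),
  stringsAsFactors = FALSE
)

.validate_neuron <- function(spec) {
  pos <- c("C_m", "g_Na", "g_K", "g_L", "rho")
  for (f in pos)
    if (!is.finite(spec[[f]]) || spec[[f]] < 0)
      stop("parameter ", f, " must be finite and non-negative (got ",
           spec[[f]], ")")
  if (spec$C_m <= 0) stop("parameter C_m must be strictly positive")
  stopifnot(spec$K_i > 0, spec$K_o_hat > 0, spec$Na_i_hat > 0, spec$RT_F > 0)
  if (spec$kind == "WB" && !is.null(spec$g_KAHP) && spec$g_KAHP != 0)
    stop("the WB spec has no accommodation conductance")
  spec
}

.new_neuron <- function(fields) {
  spec <- structure(fields, class = "mnm_neuron")
  .validate_neuron(spec)
}

#' Wang-Buzsaki inhibitory interneuron model
#'
#' Single-compartment conductance-based interneuron with transient sodium
#' (instantaneous activation m_inf^3, inactivation h), delayed-rectifier
#' potassium (n^4), leak, and a sodium-potassium pump.  Gating kinetics of n
#' and h are scaled by `psi`.  Defaults are the canonical published values
#' with the potassium Nernst potential at -90 mV and pump strength 1.25.
#'
#' @param C_m membrane capacitance, uF/cm2
#' @param g_Na,g_K,g_L maximal conductances, mS/cm2
#' @param nu_Na,nu_l sodium and leak reversal potentials, mV
#' @param nu_K_hat nominal potassium Nernst potential, mV
#' @param psi gating rate scale (dimensionless)
#' @param rho pump strength, uA/cm2
#' @param Na_i_hat,K_o_hat,K_i nominal ion concentrations, mM
#' @param RT_F thermal voltage, mV
#' @return an object of class `"mnm_neuron"`
#' @export
wb_neuron <- function(C_m = 1, g_Na = 35, g_K = 9, g_L = 0.1,
                      nu_Na = 55, nu_l = -65, nu_K_hat = -90, psi = 5,
                      rho = 1.25, Na_i_hat = 25, K_o_hat = 4.77, K_i = 140,
                      RT_F = mnm_RTF) {
  .new_neuron(list(
    kind = "WB", C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
    nu_Na = nu_Na, nu_l = nu_l, nu_K_hat = nu_K_hat, psi = psi,
    rho = rho, Na_i_hat = Na_i_hat, K_o_hat = K_o_hat, K_i = K_i,
    RT_F = RT_F, g_KAHP = 0, q_hat = 0, exp_m = 3, exp_n = 4,
    activation = .wb_activation))
}

#' Single-compartment excitatory accommodating neuron (SEAN)
#'
#' Reduction of the Pinsky-Rinzel pyramidal-cell soma to one compartment,
#' retaining the transient sodium current (instantaneous m_inf^2, inactivation
#' h), the delayed-rectifier potassium current (first power of n), leak, the
#' sodium-potassium pump, and the calcium-gated after-hyperpolarization
#' (accommodation) potassium current with its gate held at the fixed value
#' `q_hat = q_inf(Ca = 0.2)`; slow accommodation enters as an additive current
#' correction to the injected current (see `I_extra` in [simulate_neuron()]).
#'
#' @inheritParams wb_neuron
#' @param g_KAHP accommodation conductance, mS/cm2
#' @param q_hat fixed accommodation gate value (dimensionless)
#' @return an object of class `"mnm_neuron"`
#' @export
sean_neuron <- function(C_m = 3, g_Na = 30, g_K = 15, g_L = 0.1,
                        nu_Na = 60, nu_l = -60, nu_K_hat = -75,
                        rho = 1.25, Na_i_hat = 25, K_o_hat = 8.38, K_i = 140,
                        g_KAHP = 0.8, q_hat = q_inf(0.2), RT_F = mnm_RTF) {
  .new_neuron(list(
    kind = "SEAN", C_m = C_m, g_Na = g_Na, g_K = g_K, g_L = g_L,
    nu_Na = nu_Na, nu_l = nu_l, nu_K_hat = nu_K_hat, psi = 1,
    rho = rho, Na_i_hat = Na_i_hat, K_o_hat = K_o_hat, K_i = K_i,
    RT_F = RT_F, g_KAHP = g_KAHP, q_hat = q_hat, exp_m = 2, exp_n = 1,
    activation = .sean_activation))
}

#' @export
print.mnm_neuron <- function(x, ...) {
  cat(sprintf("<%s neuron model>\n", x$kind))
  cat(sprintf("  C_m = %g uF/cm2; g_Na = %g, g_K = %g, g_L = %g mS/cm2\n",
              x$C_m, x$g_Na, x$g_K, x$g_L))
  cat(sprintf("  nu_K_hat = %g, nu_Na = %g, nu_l = %g mV\n",
              x$nu_K_hat, x$nu_Na, x$nu_l))
  cat(sprintf("  pump rho = %g uA/cm2; K_o_hat = %g mM; Na_i_hat = %g mM\n",
              x$rho, x$K_o_hat, x$Na_i_hat))
  if (x$kind == "SEAN")
    cat(sprintf("  g_KAHP = %g mS/cm2 at fixed gate q_hat = %.5f\n",
                x$g_KAHP, x$q_hat))
  invisible(x)
}

#' Time derivatives of the membrane state
#'
#' Reference (pure-R) evaluation of the model right-hand side; the compiled
#' version used by [simulate_neuron()] is identical.
#'
#' @inheritParams rate_functions
#' @param state numeric vector `c(V, n, h)`
#' @param I_inj injected current, uA/cm2
#' @param dnuK potassium Nernst-potential shift, mV
#' @param I_extra additive current hook (e.g. slow accommodation), uA/cm2
#' @return numeric vector `c(dV, dn, dh)` (mV/ms, 1/ms, 1/ms)
#' @export
neuron_derivs <- function(spec, state, I_inj, dnuK = 0, I_extra = 0) {
  V <- state[[1]]; n <- state[[2]]; h <- state[[3]]
  nuK <- spec$nu_K_hat + dnuK
  r <- rate_functions(spec, V)
  minf <- r[, "alpha_m"] / (r[, "alpha_m"] + r[, "beta_m"])
  IK <- spec$g_K * n^spec$exp_n * (V - nuK)
  INa <- spec$g_Na * minf^spec$exp_m * h * (V - spec$nu_Na)
  IL <- spec$g_L * (V - spec$nu_l)
  Ip <- pump_current_shift(spec, dnuK)
  Iahp <- spec$g_KAHP * spec$q_hat * (V - nuK)
  terms <- c(IK = IK, INa = INa, IL = IL, Ipump = Ip, IKAHP = Iahp)
  if (any(!is.finite(terms)))
    stop("non-finite membrane current in term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  dV <- (I_inj + I_extra - IK - INa - IL - Ip - Iahp) / spec$C_m
  dn <- spec$psi * (r[, "alpha_n"] * (1 - n) - r[, "beta_n"] * n)
  dh <- spec$psi * (r[, "alpha_h"] * (1 - h) - r[, "beta_h"] * h)
  c(dV = unname(dV), dn = unname(dn), dh = unname(dh))
}

#' Instantaneous transmembrane potassium flux
#'
#' Net potassium current: delayed-rectifier channel plus accommodation current
#' minus twice the pump current (the pump imports two potassium ions per
#' cycle), so that the flux is negative at rest and positive in
#' depolarization block.
#'
#' @inheritParams neuron_derivs
#' @param V,n membrane potential (mV) and potassium activation gate
#' @export
kflux_instant <- function(spec, V, n, dnuK = 0) {
  nuK <- spec$nu_K_hat + dnuK
  spec$g_K * n^spec$exp_n * (V - nuK) +
    spec$g_KAHP * spec$q_hat * (V - nuK) -
    2 * pump_current_shift(spec, dnuK)
}
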