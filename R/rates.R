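#' @useDynLib mnm, .registration = TRUE
#' @importFrom stats approx median quantile setNames simulate uniroot
#' @importFrom utils write.csv
NULL

#' Thermal voltage RT/F used throughout (mV)
#'
#' The Nernst prefactor k_B T / e at physiological temperature.
#' @export
mnm_RTF <- 26.64

## ---- rate-function machinery -------------------------------------------
## Each gating rate is one of four algebraic families:
##   xratio : a*x/(1 - exp(-x/b))   (removable singularity at x = 0)
##   xratio_rev : a*x/(exp(x/b) - 1)
##   expf   : a*exp(-x/b)
##   logistic : a/(1 + exp(-x/b))
## with x = V + V0.  The same tables drive the R and the compiled evaluators.

.rate_eval <- function(form, a, V0, b, V) {
  x <- V + V0
  switch(form,
    xratio = ifelse(abs(x) < 1e-7, a * b, a * x / (1 - exp(-x / b))),
    xratio_rev = ifelse(abs(x) < 1e-7, a * b, a * x / (exp(x / b) - 1)),
    expf = a * exp(-x / b),
    logistic = a / (1 + exp(-x / b)),
    stop("unknown rate form: ", form)
  )
}

.rate_deriv <- function(form, a, V0, b, V) {
  x <- V + V0
  switch(form,
    xratio = {
      u <- 1 - exp(-x / b)
      ifelse(abs(x) < 1e-5,
             a * (0.5 + x / (6 * b)),
             a * (u - x * exp(-x / b) / b) / u^2)
    },
    xratio_rev = {
      u <- exp(x / b) - 1
      ifelse(abs(x) < 1e-5,
             a * (-0.5 + x / (6 * b)),
             a * (u - x * exp(x / b) / b) / u^2)
    },
    expf = -a * exp(-x / b) / b,
    logistic = {
      s <- 1 / (1 + exp(-x / b))
      (a / b) * s * (1 - s)
    },
    stop("unknown rate form: ", form)
  )
}

.rate_names <- c("alpha_m", "beta_m", "alpha_n", "beta_n", "alpha_h", "beta_h")

#' Voltage-dependent gating rate functions
#'
#' Evaluates the six opening/closing rates (alpha and beta for m, n, h) of a
#' neuron model at the given membrane potentials.  Removable singularities of
#' the x/(1-exp(-x/b)) forms are evaluated by their analytic limit a*b.
#'
#' @param spec a neuron model specification from [wb_neuron()] or [sean_neuron()]
#' @param Vm membrane potential(s), mV
#' @return matrix with one row per voltage and columns
#'   `alpha_m, beta_m, alpha_n, beta_n, alpha_h, beta_h` (1/ms)
#' @export
rate_functions <- function(spec, Vm) {
  stopifnot(inherits(spec, "mnm_neuron"), all(is.finite(Vm)))
  tab <- spec$activation
  out <- vapply(seq_len(nrow(tab)), function(i)
    .rate_eval(tab$form[i], tab$a[i], tab$V0[i], tab$b[i], Vm),
    numeric(length(Vm)))
  out <- matrix(out, nrow = length(Vm), ncol = 6,
                dimnames = list(NULL, .rate_names))
  if (any(!is.finite(out)) || any(out < 0)) {
    bad <- which(!is.finite(out) | out < 0, arr.ind = TRUE)
    stop("non-finite or negative gating rate for ",
         paste(unique(colnames(out)[bad[, 2]]), collapse = ", "),
         " -- check the activation coefficients of the ", spec$kind, " spec")
  }
  out
}

## dV derivatives of the six rates (same layout as rate_functions)
.rate_functions_dv <- function(spec, Vm) {
  tab <- spec$activation
  out <- vapply(seq_len(nrow(tab)), function(i)
    .rate_deriv(tab$form[i], tab$a[i], tab$V0[i], tab$b[i], Vm),
    numeric(length(Vm)))
  matrix(out, nrow = length(Vm), ncol = 6,
         dimnames = list(NULL, .rate_names))
}

#' Steady-state gating variables
#'
#' @inheritParams rate_functions
#' @return matrix with columns `m`, `n`, `h` (the voltage-clamped steady
#'   values alpha/(alpha+beta))
#' @export
gate_steady <- function(spec, Vm) {
  r <- rate_functions(spec, Vm)
  cbind(m = r[, 1] / (r[, 1] + r[, 2]),
        n = r[, 3] / (r[, 3] + r[, 4]),
        h = r[, 5] / (r[, 5] + r[, 6]))
}

## dV of the steady-state gates
.gate_steady_dv <- function(spec, Vm) {
  r <- rate_functions(spec, Vm)
  d <- .rate_functions_dv(spec, Vm)
  dinf <- function(a, b, da, db) (da * b - a * db) / (a + b)^2
  cbind(m = dinf(r[, 1], r[, 2], d[, 1], d[, 2]),
        n = dinf(r[, 3], r[, 4], d[, 3], d[, 4]),
        h = dinf(r[, 5], r[, 6], d[, 5], d[, 6]))
}

## ---- pump and Nernst utilities ------------------------------------------

#' Sodium-potassium pump current
#'
#' Product-of-logistics pump model: strictly positive and monotonically
#' increasing in both intracellular sodium and extracellular potassium.
#'
#' @inheritParams rate_functions
#' @param Na_i intracellular sodium (mM); defaults to the nominal value, which
#'   is held constant throughout the package
#' @param K_o extracellular potassium (mM); defaults to nominal
#' @return pump current, uA/cm2
#' @export
pump_current <- function(spec, Na_i = spec$Na_i_hat, K_o = spec$K_o_hat) {
  stopifnot(all(Na_i > 0), all(K_o > 0))
  spec$rho / ((1 + exp((spec$Na_i_hat - Na_i) / 3)) *
              (1 + exp(spec$K_o_hat - K_o)))
}

#' Pump current at a given potassium Nernst-potential shift
#'
#' Converts the shift to an extracellular concentration via the Nernst
#' relation and evaluates [pump_current()] with intracellular sodium nominal.
#'
#' @inheritParams rate_functions
#' @param dnuK shift of the potassium Nernst potential from nominal, mV
#' @export
pump_current_shift <- function(spec, dnuK = 0) {
  pump_current(spec, K_o = nernst_Ko(dnuK, spec$K_o_hat, spec$RT_F))
}

#' Potassium Nernst-potential shift from concentrations, and inverse
#'
#' `nernst_shift()` maps an extracellular potassium concentration to the shift
#' of the Nernst potential from its nominal value,
#' `dnuK = RT/F * log(K_o / K_o_hat)` (intracellular potassium assumed
#' constant); `nernst_Ko()` is its exact inverse, and `nominal_Ko()` gives the
#' extracellular concentration implied by a nominal Nernst potential and the
#' intracellular concentration.
#'
#' @param K_o extracellular potassium, mM
#' @param K_o_hat nominal extracellular potassium, mM
#' @param RT_F thermal voltage, mV
#' @return shift in mV (`nernst_shift`), concentration in mM (others)
#' @export
nernst_shift <- function(K_o, K_o_hat, RT_F = mnm_RTF) {
  if (any(K_o <= 0) || any(K_o_hat <= 0))
    stop("concentrations must be strictly positive")
  RT_F * log(K_o / K_o_hat)
}

#' @rdname nernst_shift
#' @param dnuK Nernst-potential shift, mV
#' @export
nernst_Ko <- function(dnuK, K_o_hat, RT_F = mnm_RTF) {
  if (any(K_o_hat <= 0)) stop("concentrations must be strictly positive")
  K_o_hat * exp(dnuK / RT_F)
}

#' @rdname nernst_shift
#' @param nuK_hat nominal Nernst potential, mV
#' @param K_i intracellular potassium, mM
#' @export
nominal_Ko <- function(nuK_hat, K_i = 140, RT_F = mnm_RTF) {
  if (any(K_i <= 0)) stop("concentrations must be strictly positive")
  K_i * exp(nuK_hat / RT_F)
}

#' Steady calcium activation of the accommodation gate
#'
#' q_inf(Ca) = alpha_q/(alpha_q + beta_q) with alpha_q = min(2e-5 * Ca, 0.01)
#' and beta_q = 0.001; the accommodating neuron holds the gate at
#' `q_inf(Ca = 0.2)`.
#'
#' @param Ca calcium concentration (model units)
#' @export
q_inf <- function(Ca) {
  aq <- pmin(2e-5 * Ca, 0.01)
  aq / (aq + 0.001)
}
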