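## Analytic regime boundaries of the coupled E-I network in injected-current,
## potassium and coupling space: firing onset (FO), bistability (BS), runaway
## excitation (RAE) and depolarization block (DB).

#' Firing-onset boundary of the coupled network
#'
#' The injected current at which the excitatory mass starts firing.  Neither
#' mass fires below onset, so there is no synaptic term and
#' `I_FO = i_th1^E(nu_K)` (the threshold is a steady-state current, pump
#' included; see [total_current()]).
#'
#' @param E_param fitted E-mass parametrization
#' @param dnuK Nernst shift(s), mV
#' @return injected current(s), uA/cm2
#' @export
firing_onset_boundary <- function(E_param, dnuK = 0) {
  th <- thresholds_and_maxima(E_param, dnuK, warn_extrapolate = FALSE)
  th$i_th1
}

#' Runaway-excitation boundary
#'
#' The injected current at which the excitatory drive pushes the inhibitory
#' mass into depolarization block.  Working in absolute currents: the
#' inhibitory mass enters DB when its total current reaches `i_th2^I`, which
#' requires a presynaptic rate `FR_E = (i_th2^I - I_I,inj)/g_EI`; inverting
#' the excitatory transfer function gives the required
#' `Q_E = (FR_E / M1^E)^2` and total current
#' `X_E = i_th1^E + Q_E (i_th2^E - i_th1^E)`; just below the boundary the
#' inhibitory mass fires at its maximum, so
#' `I_RAE = X_E + g_IE * M1^I`.
#'
#' @param E_param,I_param fitted mass parametrizations
#' @param g_EI,g_IE coupling constants, uA/cm2 per Hz
#' @param dnuK Nernst shift(s), mV
#' @param I_I_inj external current to the inhibitory mass, uA/cm2
#' @return injected current(s), uA/cm2; `NA` where the excitatory mass cannot
#'   drive the inhibitory mass into DB (required rate exceeds `M1^E`)
#' @export
rae_boundary <- function(E_param, I_param, g_EI = 0.2, g_IE = 0.04,
                         dnuK = 0, I_I_inj = 0) {
  stopifnot(g_EI > 0, g_IE >= 0)
  thE <- thresholds_and_maxima(E_param, dnuK, warn_extrapolate = FALSE)
  thI <- thresholds_and_maxima(I_param, dnuK, warn_extrapolate = FALSE)
  FR_E <- (thI$i_th2 - I_I_inj) / g_EI
  Q_E <- (FR_E / thE$M1)^(1 / E_param$exponents[["FR"]])
  out <- thE$i_th1 + Q_E * (thE$i_th2 - thE$i_th1) + g_IE * thI$M1
  out[FR_E > thE$M1 | FR_E < 0] <- NA_real_
  out
}

#' Bistability boundary
#'
#' Lower edge of the bistable band: the runaway-excitation boundary minus the
#' inhibitory current lost when the inhibitory mass (firing at its maximum
#' `M1^I`) drops out: `I_BS = I_RAE - g_IE * M1^I`.
#'
#' @inheritParams rae_boundary
#' @param I_RAE optional precomputed RAE boundary
#' @export
bistability_boundary <- function(E_param, I_param, g_EI = 0.2, g_IE = 0.04,
                                 dnuK = 0, I_I_inj = 0, I_RAE = NULL) {
  if (is.null(I_RAE))
    I_RAE <- rae_boundary(E_param, I_param, g_EI, g_IE, dnuK, I_I_inj)
  thI <- thresholds_and_maxima(I_param, dnuK, warn_extrapolate = FALSE)
  I_RAE - g_IE * thI$M1
}

#' Depolarization-block boundary of the excitatory mass
#'
#' The bare boundary is the injected current at which the excitatory mass
#' itself blocks with the inhibitory mass already silent:
#' `I_DB,bare = i_th2^E`.  The effective boundary applies the
#' crossing rule: wherever the runaway-excitation boundary lies below the
#' bare line, the network is committed to the pathological branch as soon as
#' the inhibitory mass fails, and the reported DB onset is capped at the RAE
#' boundary: `I_DB,eff = min(I_DB,bare, I_RAE)`.
#'
#' @inheritParams rae_boundary
#' @param I_RAE precomputed RAE boundary (`NA` allowed where absent)
#' @return data.frame with columns `db_bare` and `db_eff`
#' @export
db_boundary <- function(E_param, dnuK = 0, I_RAE = NA_real_) {
  th <- thresholds_and_maxima(E_param, dnuK, warn_extrapolate = FALSE)
  bare <- th$i_th2
  eff <- ifelse(is.na(I_RAE), bare, pmin(bare, I_RAE))
  data.frame(db_bare = bare, db_eff = eff)
}

#' Atlas of regime boundaries
#'
#' Computes all four analytic boundaries over a grid of potassium shifts (at
#' fixed coupling) or over a grid of coupling ratios (at fixed potassium).
#' The firing-onset and bare-DB curves are also the boundaries of the
#' uncoupled excitatory mass.
#'
#' @inheritParams rae_boundary
#' @param dnuK grid of Nernst shifts (mode `"dnuK"`), or a scalar (mode
#'   `"ratio"`)
#' @param ratio optional grid of coupling ratios `g_IE / g_IE_hat`; if given,
#'   the atlas sweeps coupling at fixed `dnuK`
#' @param g_IE_hat nominal inhibitory-to-excitatory coupling used with
#'   `ratio`
#' @return data.frame of class `"mnm_atlas"`: grid variable(s), `fo`, `bs`,
#'   `rae`, `db_bare`, `db_eff`
#' @export
regime_atlas <- function(E_param, I_param, g_EI = 0.2, g_IE = 0.04,
                         dnuK = seq(0, 20, by = 1), ratio = NULL,
                         g_IE_hat = 0.04, I_I_inj = 0) {
  if (is.null(ratio)) {
    grid <- data.frame(dnuK = dnuK, g_IE = g_IE)
  } else {
    stopifnot(length(dnuK) == 1)
    grid <- data.frame(dnuK = dnuK, g_IE = ratio * g_IE_hat, ratio = ratio)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$dnuK[i]; g <- grid$g_IE[i]
    rae <- tryCatch(rae_boundary(E_param, I_param, g_EI, g, d, I_I_inj),
                    error = function(e) NA_real_)
    db <- db_boundary(E_param, d, rae)
    cbind(grid[i, , drop = FALSE],
          data.frame(fo = firing_onset_boundary(E_param, d),
                     bs = bistability_boundary(E_param, I_param, g_EI, g, d,
                                               I_I_inj, I_RAE = rae),
                     rae = rae, db_bare = db$db_bare, db_eff = db$db_eff))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mnm_atlas", "data.frame")
  out
}

#' @export
plot.mnm_atlas <- function(x, ...) {
  xv <- if ("ratio" %in% names(x)) x$ratio else x$dnuK
  xl <- if ("ratio" %in% names(x)) "g_IE / g_IE_hat" else "dnuK (mV)"
  rng <- range(c(x$fo, x$bs, x$rae, x$db_bare, x$db_eff), na.rm = TRUE)
  plot(xv, x$db_bare, type = "l", col = "red", lty = 2, ylim = rng,
       xlab = xl, ylab = expression(I[E, inj] ~ (mu * A / cm^2)), ...)
  graphics::lines(xv, x$db_eff, col = "red")
  graphics::lines(xv, x$rae, col = "darkgreen")
  graphics::lines(xv, x$bs, col = "orange")
  graphics::lines(xv, x$fo, col = "blue")
  graphics::legend("topright",
                   c("FO", "BS", "RAE", "DB (effective)", "DB (bare)"),
                   col = c("blue", "orange", "darkgreen", "red", "red"),
                   lty = c(1, 1, 1, 1, 2), bty = "n")
  invisible(x)
}
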