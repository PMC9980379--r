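## Serialization of mass parametrizations (JSON with full numeric precision),
## tidy CSV exports, and a seeded fixture generator for fast tests.

.mass_schema_version <- "1.0"

#' Write and read a mass parametrization
#'
#' The parametrization is stored as JSON with full numeric precision so that
#' a load-dump-load cycle reproduces the evaluation exactly.  The underlying
#' neuron model is stored as its constructor arguments (the activation tables
#' are canonical and rebuilt by kind).
#'
#' @param param fitted mass from [mnm_fit()]
#' @param path file path
#' @export
write_mass_json <- function(param, path) {
  stopifnot(inherits(param, "mnm_mass"))
  spec <- param$spec
  spec_f <- if (is.null(spec)) NULL else
    spec[c("kind", "C_m", "g_Na", "g_K", "g_L", "nu_Na", "nu_l", "nu_K_hat",
           "psi", "rho", "Na_i_hat", "K_o_hat", "K_i", "RT_F", "g_KAHP",
           "q_hat")]
  payload <- list(
    schema_version = .mass_schema_version,
    mass_kind = param$mass_kind,
    nu_K_hat = param$nu_K_hat, rho = param$rho, K_o_hat = param$K_o_hat,
    RT_F = param$RT_F,
    coefficients = param$coefficients,
    exponents = as.list(param$exponents),
    C1 = param$C1, C2 = param$C2,
    orders = as.list(param$orders),
    dnuK_range = param$dnuK_range,
    shift_frac = param$shift_frac, shift_floor = param$shift_floor,
    duration = param$duration, transient = param$transient,
    fit_rms = as.list(param$fit_rms),
    data = param$data,
    spec = spec_f)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mass_json
#' @export
read_mass_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema_version, .mass_schema_version))
    stop("unsupported mass schema version: ", p$schema_version)
  spec <- NULL
  if (!is.null(p$spec) && !is.null(p$spec$kind)) {
    s <- p$spec
    spec <- if (s$kind == "WB")
      wb_neuron(C_m = s$C_m, g_Na = s$g_Na, g_K = s$g_K, g_L = s$g_L,
                nu_Na = s$nu_Na, nu_l = s$nu_l, nu_K_hat = s$nu_K_hat,
                psi = s$psi, rho = s$rho, Na_i_hat = s$Na_i_hat,
                K_o_hat = s$K_o_hat, K_i = s$K_i, RT_F = s$RT_F)
    else
      sean_neuron(C_m = s$C_m, g_Na = s$g_Na, g_K = s$g_K, g_L = s$g_L,
                  nu_Na = s$nu_Na, nu_l = s$nu_l, nu_K_hat = s$nu_K_hat,
                  rho = s$rho, Na_i_hat = s$Na_i_hat, K_o_hat = s$K_o_hat,
                  K_i = s$K_i, g_KAHP = s$g_KAHP, q_hat = s$q_hat,
                  RT_F = s$RT_F)
  }
  dat <- as.data.frame(p$data)
  class(dat) <- c("mnm_boundaries", "data.frame")
  structure(list(
    mass_kind = p$mass_kind, spec = spec,
    nu_K_hat = p$nu_K_hat, rho = p$rho, K_o_hat = p$K_o_hat, RT_F = p$RT_F,
    coefficients = lapply(p$coefficients, as.numeric),
    exponents = unlist(p$exponents),
    C1 = p$C1, C2 = p$C2,
    orders = unlist(p$orders),
    dnuK_range = as.numeric(p$dnuK_range),
    data = dat,
    residuals = NULL,
    fit_rms = unlist(p$fit_rms),
    shift_frac = p$shift_frac, shift_floor = p$shift_floor,
    duration = p$duration, transient = p$transient,
    call = NULL), class = "mnm_mass")
}

#' Tidy CSV exports
#'
#' `write_boundaries_csv()` writes the traced boundary and maxima samples of
#' a fitted mass (`nu_k, iss_f, iss_db, m1, m2, m3`); `write_sweep_csv()`
#' writes a neuron sweep (`I_inj, dnuK, mean_FR, mean_Vm, mean_Kflux, regime,
#' n_spikes`).
#'
#' @param x a fitted mass, or a sweep data.frame from [sweep_neuron()]
#' @param path file path
#' @export
write_boundaries_csv <- function(x, path) {
  dat <- if (inherits(x, "mnm_mass")) x$data else x
  out <- data.frame(nu_k = dat$nu_K, iss_f = dat$iss_f, iss_db = dat$iss_db,
                    m1 = dat$M1, m2 = dat$M2, m3 = dat$M3)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boundaries_csv
#' @export
write_sweep_csv <- function(x, path) {
  out <- x[, c("I_inj", "dnuK", "mean_FR", "mean_Vm", "mean_Kflux",
               "regime", "n_spikes")]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic mass parametrization for fast tests
#'
#' Generates a structurally valid parametrization (correct polynomial orders,
#' exponents and offsets, ordered thresholds over the standard potassium
#' window) from smooth synthetic boundary curves with small seeded jitter.
#' The numbers resemble the fitted masses but are synthetic: no neuron model
#' is attached, so fixed-point closures are unavailable.
#'
#' @param mass_kind `"I"` or `"E"`
#' @param seed integer seed for the jitter
#' @return object of class `"mnm_mass"` with `spec = NULL`
#' @export
make_fixture_mass <- function(mass_kind = c("I", "E"), seed = 1) {
  mass_kind <- match.arg(mass_kind)
  set.seed(seed)
  dn <- seq(0, 20, by = 2)
  if (mass_kind == "I") {
    nu_hat <- -90; Ko_hat <- 4.77
    iss_f <- 0.47 + 0.30 * (1 - exp(-dn / 6))
    iss_db <- 25.4 - 0.85 * dn
    M1 <- 420 - 4.2 * dn
    M2 <- -33 + 0.05 * dn
    M3 <- 47 - 0.9 * dn
    V_f <- rep(-60, length(dn)); V_db <- rep(-29.4, length(dn))
  } else {
    nu_hat <- -75; Ko_hat <- 8.38
    iss_f <- 0.05 + 0.005 * dn
    iss_db <- 91.8 - 3.8 * dn
    M1 <- 244 - 1.0 * dn
    M2 <- -36.6 + 0.1 * dn
    M3 <- 144 - 3.3 * dn
    V_f <- rep(-61.8, length(dn)); V_db <- rep(-27.6, length(dn))
  }
  jit <- function(y) y * (1 + 0.002 * stats::rnorm(length(y)))
  dat <- data.frame(dnuK = dn, nu_K = nu_hat + dn,
                    iss_f = jit(iss_f), iss_db = jit(iss_db),
                    V_f = V_f, V_db = V_db, exists = TRUE,
                    delta = 0.2 * (iss_db - iss_f),
                    M1 = jit(M1), M2 = jit(M2), M3 = jit(M3))
  ## the synthetic curves are taken as boundary values directly
  dat$M1_b <- dat$M1; dat$M2_b <- dat$M2; dat$M3_b <- dat$M3
  class(dat) <- c("mnm_boundaries", "data.frame")
  ord <- .default_orders[[mass_kind]]
  targets <- list(th1 = dat$iss_f, th2 = dat$iss_db,
                  M1 = dat$M1, M2 = dat$M2, M3 = dat$M3)
  fits <- lapply(names(targets), function(nm)
    .polyfit(dat$nu_K, targets[[nm]], ord[[nm]]))
  names(fits) <- names(targets)
  structure(list(
    mass_kind = mass_kind, spec = NULL,
    nu_K_hat = nu_hat, rho = 1.25, K_o_hat = Ko_hat, RT_F = mnm_RTF,
    coefficients = lapply(fits, `[[`, "coefficients"),
    exponents = .default_exponents[[mass_kind]],
    C1 = .default_C1[[mass_kind]], C2 = .default_C2[[mass_kind]],
    orders = ord, dnuK_range = range(dn), data = dat,
    residuals = lapply(fits, `[[`, "residuals"),
    fit_rms = vapply(fits, `[[`, numeric(1), "rms"),
    shift_frac = 0.2, shift_floor = 0.1,
    duration = NA_real_, transient = NA_real_,
    call = NULL, seed = seed), class = "mnm_mass")
}
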