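## Forward models for single-quantum CPMG relaxation dispersion under
## two-site chemical exchange (A <-> B, ground state A heavily populated).

#' Two-site exchange parameter set
#'
#' Bundles the parameters of a two-site exchange process probed by
#' single-quantum \eqn{^{13}}C CPMG experiments: the exchange rate constant
#' \eqn{k_{ex} = k_{AB} + k_{BA}}, the excited-state population \eqn{p_B},
#' the absolute \eqn{^{13}}C chemical-shift difference between the states
#' (ppm, field independent) and one exchange-free baseline rate
#' \eqn{R_{2,0}} per static field.  A single \eqn{R_{2,0}} is shared by the
#' ground and excited state at each field, the standard identifiability
#' constraint for CPMG data.  Only \eqn{|\Delta\omega|} is identifiable from
#' single-quantum CPMG, so `dw_ppm` is non-negative.
#'
#' @param k_ex Exchange rate constant, s^-1 (> 0).
#' @param p_B Excited-state population, fraction in `[0, 0.5)`.
#' @param dw_ppm Absolute 13C shift difference between states, ppm (>= 0).
#' @param r20 Named numeric vector of exchange-free transverse relaxation
#'   rates, s^-1, one per field label (all >= 0).
#' @return An object of class `exchange_params`.
#' @examples
#' exchange_params(1640, 0.042, 1.0, c("11.7T" = 12, "18.8T" = 15))
#' @export
exchange_params <- function(k_ex, p_B, dw_ppm, r20) {
  stopifnot(is.numeric(k_ex), length(k_ex) == 1L,
            is.numeric(p_B), length(p_B) == 1L,
            is.numeric(dw_ppm), length(dw_ppm) == 1L,
            is.numeric(r20), length(r20) >= 1L)
  if (!is.finite(k_ex) || k_ex <= 0)
    stop("k_ex must be a finite positive rate (s^-1)", call. = FALSE)
  if (!is.finite(p_B) || p_B < 0 || p_B >= 0.5)
    stop("p_B must lie in [0, 0.5)", call. = FALSE)
  if (!is.finite(dw_ppm) || dw_ppm < 0)
    stop("dw_ppm must be >= 0", call. = FALSE)
  if (is.null(names(r20)) || any(!nzchar(names(r20))))
    stop("r20 must be a named vector keyed by field label", call. = FALSE)
  if (any(!is.finite(r20)) || any(r20 < 0))
    stop("every R2,0 must be finite and >= 0", call. = FALSE)
  structure(list(k_ex = unname(k_ex), p_B = unname(p_B),
                 dw_ppm = unname(dw_ppm), r20_by_field = r20),
            class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf("Two-site exchange: k_ex = %.4g s-1, p_B = %.4g, |dw| = %.4g ppm\n",
              x$k_ex, x$p_B, x$dw_ppm))
  cat("R2,0 by field:", paste(sprintf("%s = %.4g s-1", names(x$r20_by_field),
                                      x$r20_by_field), collapse = ", "), "\n")
  invisible(x)
}

#' Static-field context
#'
#' Describes one spectrometer field: its label (used to key profiles and
#' baseline rates), the \eqn{^{13}}C Larmor frequency in MHz and optionally
#' the static field in tesla.  The ppm-to-rad/s conversion is
#' \eqn{\Delta\omega = \delta_{ppm} \cdot 2\pi \cdot \nu_{13C}} with
#' \eqn{\nu_{13C}} in MHz.
#'
#' @param label Character field label, e.g. `"18.8T"`.
#' @param larmor_13c_mhz 13C Larmor frequency, MHz (> 0).
#' @param b0_tesla Optional static field, tesla.
#' @return An object of class `field_context`.
#' @export
field_context <- function(label, larmor_13c_mhz, b0_tesla = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!is.numeric(larmor_13c_mhz) || length(larmor_13c_mhz) != 1L ||
      !is.finite(larmor_13c_mhz) || larmor_13c_mhz <= 0)
    stop("larmor_13c_mhz must be a positive frequency in MHz", call. = FALSE)
  structure(list(label = label, larmor_13c_mhz = larmor_13c_mhz,
                 b0_tesla = b0_tesla),
            class = "field_context")
}

#' Convert a ppm shift difference to rad/s at a given field
#'
#' @param dw_ppm Shift difference, ppm.
#' @param field A [field_context()].
#' @return Angular frequency difference, rad/s.
#' @export
dw_rad_s <- function(dw_ppm, field) {
  stopifnot(inherits(field, "field_context"))
  dw_ppm * 2 * pi * field$larmor_13c_mhz
}

#' CPMG schedule (constant-time experiment)
#'
#' A constant relaxation period `t_relax` and the set of CPMG refocusing
#' frequencies \eqn{\nu_{CPMG} = 1/(2t)}, with \eqn{t} the delay between
#' consecutive 180-degree pulses.  For every frequency the implied number of
#' refocusing pulses \eqn{n = 2 \nu T_{relax}} is rounded to the nearest even
#' integer; frequencies implying fewer than two pulses are rejected.
#'
#' @param nu_cpmg Numeric vector of refocusing frequencies, s^-1 (> 0).
#' @param t_relax Constant relaxation period, s (> 0; default 0.02).
#' @return An object of class `cpmg_schedule`.
#' @examples
#' cpmg_schedule(c(100, 200, 500, 1000, 3000))
#' @export
cpmg_schedule <- function(nu_cpmg, t_relax = 0.02) {
  if (!is.numeric(t_relax) || length(t_relax) != 1L || !is.finite(t_relax) ||
      t_relax <= 0)
    stop("t_relax must be a positive duration in seconds", call. = FALSE)
  if (!is.numeric(nu_cpmg) || length(nu_cpmg) == 0L ||
      any(!is.finite(nu_cpmg)) || any(nu_cpmg <= 0))
    stop("all nu_cpmg values must be finite and > 0", call. = FALSE)
  n <- n_refocusing_pulses(nu_cpmg, t_relax)
  if (any(n < 2L))
    stop("nu_cpmg values ", paste(nu_cpmg[n < 2L], collapse = ", "),
         " imply fewer than two refocusing pulses in t_relax", call. = FALSE)
  structure(list(t_relax = t_relax, nu_cpmg = as.numeric(nu_cpmg)),
            class = "cpmg_schedule")
}

#' Even refocusing pulse count implied by a CPMG frequency
#'
#' @param nu Refocusing frequency (or vector), s^-1.
#' @param t_relax Constant relaxation period, s.
#' @return Integer vector of pulse counts (nearest even integer).
#' @export
n_refocusing_pulses <- function(nu, t_relax) {
  as.integer(2 * round(nu * t_relax))
}

## Vectorised core: exact numerical propagation of the two-site single-
## quantum magnetisation.  The complex 2x2 evolution matrix in the
## ground-state rotating frame is
##   L = [[-R20 - kAB, kBA], [kAB, -R20 - kBA - i*dw]].
## Each 180-degree pulse complex-conjugates the magnetisation, so the
## two-echo block (tau-180-tau)(tau-180-tau) has the linear propagator
##   Q = E Ec Ec E,  E = expm(L*tau), Ec = Conj(E),
## and with an even pulse count n the end point is Q^(n/2) applied to the
## equilibrium start (pA, pB).  expm of the 2x2 is evaluated by the
## Sylvester formula; the matrix power by binary exponentiation.  All four
## matrix entries are carried as complex vectors across nu, so the whole
## dispersion curve is computed in a handful of vector operations.
.bm_core <- function(k_ex, p_B, dw_rad, r20, t_relax, nu) {
  p_A <- 1 - p_B
  k_ab <- p_B * k_ex
  k_ba <- p_A * k_ex
  n <- pmax(2L, as.integer(2 * round(nu * t_relax)))
  tau <- t_relax / (2 * n)

  a <- complex(real = -r20 - k_ab)
  b <- complex(real = k_ba)
  cc <- complex(real = k_ab)
  d <- complex(real = -r20 - k_ba, imaginary = -dw_rad)

  s <- (a + d) / 2
  q <- sqrt(((a - d) / 2)^2 + b * cc)
  qt <- q * tau
  ch <- cosh(qt)
  sh <- ifelse(Mod(qt) < 1e-8, tau * (1 + qt^2 / 6), sinh(qt) / q)
  es <- exp(s * tau)
  e11 <- es * (ch + sh * (a - s))
  e12 <- es * sh * b
  e21 <- es * sh * cc
  e22 <- es * (ch + sh * (d - s))

  ## F = E %*% Conj(E); Q = F %*% Conj(F)
  f11 <- e11 * Conj(e11) + e12 * Conj(e21)
  f12 <- e11 * Conj(e12) + e12 * Conj(e22)
  f21 <- e21 * Conj(e11) + e22 * Conj(e21)
  f22 <- e21 * Conj(e12) + e22 * Conj(e22)
  q11 <- f11 * Conj(f11) + f12 * Conj(f21)
  q12 <- f11 * Conj(f12) + f12 * Conj(f22)
  q21 <- f21 * Conj(f11) + f22 * Conj(f21)
  q22 <- f21 * Conj(f12) + f22 * Conj(f22)

  ## Q^(n/2) by binary exponentiation, vectorised across nu
  m <- n %/% 2L
  p11 <- rep(1 + 0i, length(nu)); p12 <- rep(0i, length(nu))
  p21 <- rep(0i, length(nu));     p22 <- rep(1 + 0i, length(nu))
  while (any(m > 0L)) {
    odd <- m %% 2L == 1L
    if (any(odd)) {
      t11 <- p11 * q11 + p12 * q21; t12 <- p11 * q12 + p12 * q22
      t21 <- p21 * q11 + p22 * q21; t22 <- p21 * q12 + p22 * q22
      p11[odd] <- t11[odd]; p12[odd] <- t12[odd]
      p21[odd] <- t21[odd]; p22[odd] <- t22[odd]
    }
    m <- m %/% 2L
    if (any(m > 0L)) {
      t11 <- q11 * q11 + q12 * q21; t12 <- q11 * q12 + q12 * q22
      t21 <- q21 * q11 + q22 * q21; t22 <- q21 * q12 + q22 * q22
      q11 <- t11; q12 <- t12; q21 <- t21; q22 <- t22
    }
  }
  m_a <- p11 * p_A + p12 * p_B
  -log(Mod(m_a) / p_A) / t_relax
}

.check_nu <- function(nu, t_relax) {
  if (!is.numeric(nu) || length(nu) == 0L || any(!is.finite(nu)) ||
      any(nu <= 0))
    stop("nu must be finite and > 0", call. = FALSE)
  if (any(n_refocusing_pulses(nu, t_relax) < 2L))
    stop("nu implies fewer than two refocusing pulses in t_relax",
         call. = FALSE)
  invisible(nu)
}

#' Bloch-McConnell effective relaxation rate for a CPMG experiment
#'
#' Numerically propagates the two-site single-quantum magnetisation through
#' the CPMG echo train (delay-180-delay blocks filling the constant
#' relaxation period with an even pulse count) and returns
#' \eqn{R_{2,eff} = -\ln(|M_A(T)|/M_A(0))/T}.  Magnetisation starts on the
#' equilibrium populations \eqn{(p_A, p_B)}.  Exactly flat output
#' (\eqn{R_{2,eff} = R_{2,0}}) is returned when `dw_ppm = 0` or `p_B = 0`,
#' where exchange is invisible.
#'
#' @param params An [exchange_params()] whose `r20_by_field` contains the
#'   field's label.
#' @param field A [field_context()].
#' @param schedule A [cpmg_schedule()].
#' @param nu Refocusing frequencies, s^-1 (default: the whole schedule).
#' @return Numeric vector of effective relaxation rates, s^-1.
#' @examples
#' fld <- field_context("18.8T", 201.2)
#' sch <- cpmg_schedule(c(100, 200, 1000, 3000))
#' par <- exchange_params(1640, 0.042, 1.0, c("18.8T" = 15))
#' bm_r2eff(par, fld, sch)
#' @export
bm_r2eff <- function(params, field, schedule, nu = schedule$nu_cpmg) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(field, "field_context"),
            inherits(schedule, "cpmg_schedule"))
  .check_nu(nu, schedule$t_relax)
  r20 <- .r20_for(params, field$label)
  if (params$dw_ppm == 0 || params$p_B == 0)
    return(rep(r20, length(nu)))
  out <- .bm_core(params$k_ex, params$p_B, dw_rad_s(params$dw_ppm, field),
                  r20, schedule$t_relax, nu)
  if (any(!is.finite(out)))
    stop(sprintf(paste0("numerical failure propagating k_ex = %g, p_B = %g, ",
                        "dw_ppm = %g, R2,0 = %g at %s"),
                 params$k_ex, params$p_B, params$dw_ppm, r20, field$label),
         call. = FALSE)
  out
}

.r20_for <- function(params, label) {
  r20 <- unname(params$r20_by_field[label])
  if (length(r20) != 1L || is.na(r20))
    stop("params carry no R2,0 for field label '", label, "'", call. = FALSE)
  r20
}

#' Closed-form effective relaxation rate (Carver-Richards family)
#'
#' Evaluates the closed-form solution of the same two-site single-quantum
#' model.  With `exact = TRUE` (default) the full solution is returned: the
#' Carver-Richards eigenvalue term plus the exact treatment of the second
#' eigenmode and of the equilibrium initial condition, which is exact when
#' the two states share one \eqn{R_{2,0}} and therefore matches
#' [bm_r2eff()] to numerical precision.  With `exact = FALSE` the classic
#' Carver-Richards expression is returned; it keeps only the dominant
#' eigenvalue and is a good approximation except where its derivation
#' assumptions break down, most visibly for slow exchange combined with a
#' large population-weighted shift difference, where it can deviate by
#' several s^-1.
#'
#' @inheritParams bm_r2eff
#' @param exact Logical; include the exact minor-mode/initial-condition
#'   amplitude (default `TRUE`).
#' @return Numeric vector of effective relaxation rates, s^-1.
#' @export
carver_richards_r2eff <- function(params, field, schedule,
                                  nu = schedule$nu_cpmg, exact = TRUE) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(field, "field_context"),
            inherits(schedule, "cpmg_schedule"))
  .check_nu(nu, schedule$t_relax)
  r20 <- .r20_for(params, field$label)
  if (params$dw_ppm == 0 || params$p_B == 0)
    return(rep(r20, length(nu)))
  k_ex <- params$k_ex
  p_B <- params$p_B
  p_A <- 1 - p_B
  dw <- dw_rad_s(params$dw_ppm, field)
  t_relax <- schedule$t_relax
  n <- pmax(2L, as.integer(2 * round(nu * t_relax)))
  tcp <- t_relax / n               # realised inter-pulse delay

  psi <- k_ex^2 - dw^2
  zeta <- -2 * dw * k_ex * (p_A - p_B)
  root <- sqrt(psi^2 + zeta^2)
  d_p <- 0.5 * (1 + (psi + 2 * dw^2) / root)
  d_m <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  eta_p <- tcp / sqrt(2) * sqrt(psi + root)
  eta_m <- tcp / sqrt(2) * sqrt(-psi + root)
  v <- d_p * cosh(eta_p) - d_m * cos(eta_m)
  cr <- r20 + k_ex / 2 - suppressWarnings(acosh(v)) / (2 * tcp)
  if (!exact) return(cr)

  ## Exact closed form: both eigenvalues of the two-echo propagator are
  ## lam_pm = g * (v +/- sqrt(v^2 - 1)), g = exp(-2*tcp*(R20 + kex/2)),
  ## and the surviving ground-state amplitude is
  ##   M_A(T) = lam_p^m a_p + lam_m^m a_m,  m = n/2,
  ## with projections a_pm = (Q11 pA + Q12 pB - lam_mp pA)/(lam_p - lam_m).
  ## Q's first row is evaluated from the Sylvester form of expm(L tau).
  tau <- tcp / 2
  a <- complex(real = -r20 - p_B * k_ex)
  b <- complex(real = p_A * k_ex)
  cc <- complex(real = p_B * k_ex)
  d <- complex(real = -r20 - p_A * k_ex, imaginary = -dw)
  s <- (a + d) / 2
  q <- sqrt(((a - d) / 2)^2 + b * cc)
  qt <- q * tau
  ch <- cosh(qt)
  sh <- ifelse(Mod(qt) < 1e-8, tau * (1 + qt^2 / 6), sinh(qt) / q)
  es <- exp(s * tau)
  e11 <- es * (ch + sh * (a - s)); e12 <- es * sh * b
  e21 <- es * sh * cc;             e22 <- es * (ch + sh * (d - s))
  f11 <- e11 * Conj(e11) + e12 * Conj(e21)
  f12 <- e11 * Conj(e12) + e12 * Conj(e22)
  f21 <- e21 * Conj(e11) + e22 * Conj(e21)
  f22 <- e21 * Conj(e12) + e22 * Conj(e22)
  q11 <- f11 * Conj(f11) + f12 * Conj(f21)
  q12 <- f11 * Conj(f12) + f12 * Conj(f22)

  g <- exp(-2 * tcp * (r20 + k_ex / 2))
  w <- sqrt(as.complex(v^2 - 1))
  lam_p <- g * (v + w)
  lam_m <- g * (v - w)
  m <- n %/% 2L
  num <- q11 * p_A + q12 * p_B
  sep <- lam_p - lam_m
  tiny <- Mod(sep) < 1e-12 * pmax(Mod(lam_p), Mod(lam_m))
  a_p <- (num - lam_m * p_A) / sep
  a_m <- (lam_p * p_A - num) / sep
  m_a <- lam_p^m * a_p + lam_m^m * a_m
  ## degenerate pair: Q^m -> lam^m I + m lam^(m-1) (Q - lam I)
  if (any(tiny)) {
    lam <- (lam_p + lam_m) / 2
    m_a[tiny] <- (lam^m * p_A + m * lam^(m - 1) * (num - lam * p_A))[tiny]
  }
  -log(Mod(m_a) / p_A) / t_relax
}

#' Fast-exchange limit of the exchange contribution
#'
#' Analytic limit \eqn{R_{ex} = p_A p_B \Delta\omega^2 / k_{ex}} (rad/s
#' units for \eqn{\Delta\omega}), valid when \eqn{k_{ex} \gg \Delta\omega}.
#'
#' @inheritParams bm_r2eff
#' @return Exchange contribution at zero refocusing frequency, s^-1.
#' @examples
#' rex_fast_limit(exchange_params(1640, 0.042, 1.0, c("18.8T" = 15)),
#'                field_context("18.8T", 201.2))
#' @export
rex_fast_limit <- function(params, field) {
  stopifnot(inherits(params, "exchange_params"),
            inherits(field, "field_context"))
  if (params$k_ex <= 0)
    stop("k_ex must be > 0 for the fast-exchange limit", call. = FALSE)
  dw <- dw_rad_s(params$dw_ppm, field)
  (1 - params$p_B) * params$p_B * dw^2 / params$k_ex
}

#' Noiseless dispersion curve over a schedule
#'
#' @inheritParams bm_r2eff
#' @return A data frame with columns `nu_cpmg` and `r2eff` (s^-1), one row
#'   per schedule frequency, in the schedule's order.
#' @export
dispersion_curve <- function(params, field, schedule) {
  stopifnot(inherits(schedule, "cpmg_schedule"))
  if (length(schedule$nu_cpmg) == 0L)
    stop("schedule is empty", call. = FALSE)
  data.frame(nu_cpmg = schedule$nu_cpmg,
             r2eff = bm_r2eff(params, field, schedule))
}
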