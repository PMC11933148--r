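## Fixed-step RK4 with macro-step subdivision.

#' Macro-step subdivision policy
#'
#' The follower's communication steps are tiled with `n = ceiling(dt / h_max)`
#' equal internal substeps of size `h = dt / n`, so every substep is at most
#' `h_max` (default 100 microseconds) and the substeps sum to `dt` exactly.
#'
#' @param h_max Maximum internal step (s).
#' @return An object of class `subdivision_policy`.
#' @export
#' @examples
#' subdivide(1e-3, subdivision_policy())   # 10 substeps of 100 us
subdivision_policy <- function(h_max = 1e-4) {
  if (!(is.finite(h_max) && h_max > 0)) stop("h_max must be positive")
  structure(list(h_max = h_max), class = "subdivision_policy")
}

#' Subdivide a macro step
#'
#' @param dt Macro step (s), `> 0`.
#' @param pol A [subdivision_policy()].
#' @return List with substep count `n` and size `h` (`n * h == dt`).
#' @export
subdivide <- function(dt, pol = subdivision_policy()) {
  if (!(is.finite(dt) && dt > 0)) stop("dt must be positive")
  n <- ceiling(dt / pol$h_max - 1e-12)
  list(n = n, h = dt / n)
}

#' Classical fourth-order Runge-Kutta step
#'
#' One explicit RK4 update with stage weights 1/6, 1/3, 1/3, 1/6.
#'
#' @param rhs Derivative function `function(t, y, ...)` returning dy/dt.
#' @param s State vector.
#' @param t Time (s).
#' @param h Step (s), `> 0`.
#' @param ... Passed through to `rhs`.
#' @return State at `t + h`.
#' @export
rk4_step <- function(rhs, s, t, h, ...) {
  if (!(is.finite(h) && h > 0)) stop("h must be positive")
  k1 <- rhs(t, s, ...)
  k2 <- rhs(t + h / 2, s + h / 2 * k1, ...)
  k3 <- rhs(t + h / 2, s + h / 2 * k2, ...)
  k4 <- rhs(t + h, s + h * k3, ...)
  out <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  bad <- which(!is.finite(out))
  if (length(bad))
    stop(sprintf("numerical error: non-finite state component %s after RK4 step",
                 paste(if (is.null(names(s))) bad else names(s)[bad],
                       collapse = ", ")))
  out
}

#' Integrate across one macro step with subdivided RK4
#'
#' Applies `n = ceiling(dt / h_max)` equal RK4 substeps.  External inputs are
#' held over the macro step (zero-order hold): `rhs` sees them via `...`.
#'
#' @param rhs Derivative function `function(t, y, ...)`.
#' @param s State at `t`.
#' @param t Start time (s).
#' @param dt Macro step (s), `> 0`.
#' @param pol A [subdivision_policy()].
#' @param ... Held inputs, passed to `rhs` unchanged on every substep.
#' @return State at exactly `t + dt`.
#' @export
integrate_macro_step <- function(rhs, s, t, dt, pol = subdivision_policy(), ...) {
  sub <- subdivide(dt, pol)
  for (i in seq_len(sub$n))
    s <- rk4_step(rhs, s, t + (i - 1) * sub$h, sub$h, ...)
  s
}
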