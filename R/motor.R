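#' Flagellar motor specification
#'
#' Parameters of the sigmoidal map from CheY-P concentration to the
#' clockwise (CW, tumble-producing) rotational bias of the flagellar motors:
#'
#' `Bias = 1 / (1 + prefactor * (Yp_star / Yp)^hill_exponent)`
#'
#' where `Yp_star` is the cell's unstimulated steady-state CheY-P level. The
#' curve is strictly increasing in `Yp`, passes through
#' `1 / (1 + prefactor)` (about 0.21 with the defaults) at `Yp = Yp_star`,
#' and shifts along the concentration axis with each cell's own `Yp_star`,
#' so that cells with different total protein content share the same
#' unstimulated bias but respond to absolute CheY-P changes differently.
#'
#' @param hill_exponent Hill coefficient (default 5.5).
#' @param prefactor Dimensionless prefactor (default 3.7).
#' @param yp_star Reference CheY-P concentration in uM, or `NA` if it is to
#'   be filled in per cell from the cascade steady state.
#' @return An object of class `rt_motor_spec`.
#' @export
motor_spec <- function(hill_exponent = 5.5, prefactor = 3.7, yp_star = NA_real_) {
  stopifnot(hill_exponent > 0, prefactor > 0,
            is.na(yp_star) || yp_star > 0)
  structure(list(hill_exponent = hill_exponent, prefactor = prefactor,
                 yp_star = yp_star),
            class = "rt_motor_spec")
}

#' Clockwise (tumble) bias at a CheY-P concentration
#'
#' @param Yp CheY-P concentration(s) in uM, > 0 (vectorised).
#' @param spec A [motor_spec()] with `yp_star` set.
#' @return Bias value(s) in (0, 1): the probability that a timestep produces
#'   a tumble.
#' @examples
#' ms <- motor_spec(yp_star = 4.043)
#' cw_bias(4.043, ms)  # 1 / 4.7
#' @export
cw_bias <- function(Yp, spec) {
  stopifnot(inherits(spec, "rt_motor_spec"))
  if (is.na(spec$yp_star)) stop("motor spec has no reference yp_star", call. = FALSE)
  if (any(!is.finite(Yp)) || any(Yp <= 0))
    stop("'Yp' must be positive", call. = FALSE)
  1 / (1 + spec$prefactor * (spec$yp_star / Yp)^spec$hill_exponent)
}

#' Per-step run/tumble decision
#'
#' A timestep is a tumble exactly when `bias > r`, where `r` is a uniform
#' draw on `[0, 1]`; ties go to running. Over many steps at fixed bias the
#' tumble count is binomial with success probability equal to the bias.
#'
#' @param bias Bias value(s) in `[0, 1]`.
#' @param r Uniform draw(s) in `[0, 1]`; defaults to fresh draws from the
#'   session RNG.
#' @return Character vector, `"tumble"` or `"run"`.
#' @export
decide_flagellar_state <- function(bias, r = stats::runif(length(bias))) {
  stopifnot(all(bias >= 0 & bias <= 1), all(r >= 0 & r <= 1),
            length(r) == length(bias))
  ifelse(bias > r, "tumble", "run")
}
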