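#' Static chemoattractant fields
#'
#' Declarative descriptions of the stationary ligand profiles a simulation is
#' run in. Three kinds exist: a radially symmetric exponential hump
#' (concentration `scaling * (l0 + exp(-((x - cx)^2 + (y - cy)^2) / d))`, in
#' mM), a spatially constant level, and a two-ligand combination holding one
#' MeAsp and one serine component. Fields are immutable and time-independent;
#' there is no ligand diffusion, degradation or consumption.
#'
#' @param l0 Minimum (background) concentration in mM, reached far from the
#'   peak. Must be non-negative.
#' @param d Steepness divisor applied to the squared distance from the
#'   center (dimensionless in domain units); smaller `d` gives a steeper,
#'   narrower hump. Must be positive.
#' @param center Numeric length-2, `(x, y)` coordinates of the peak.
#' @param scaling Positive multiplicative factor applied to the whole
#'   profile, so the peak concentration is `scaling * (l0 + 1)`.
#' @param species Ligand species name, one of `"meAsp"` or `"serine"`.
#' @param level Concentration (mM) of a constant field.
#' @param meAsp,serine Component specs (exponential or constant) for the
#'   respective species.
#' @return A field spec object inheriting from class `rt_field`.
#' @examples
#' f <- exponential_field(l0 = 0.1, d = 10)
#' eval_field_at(f, c(0, 0))   # peak: 1.1 mM
#' field_peak(f)
#' @seealso [eval_field_at()], [field_peak()], [meAsp_serine_field()]
#' @export
exponential_field <- function(l0 = 0.1, d = 1, center = c(0, 0), scaling = 1,
                              species = c("meAsp", "serine")) {
  species <- match.arg(species)
  stopifnot(is.numeric(l0), length(l0) == 1L, is.finite(l0),
            is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(center), length(center) == 2L, all(is.finite(center)),
            is.numeric(scaling), length(scaling) == 1L, is.finite(scaling))
  if (l0 < 0) stop("'l0' must be >= 0", call. = FALSE)
  if (d <= 0) stop("'d' must be > 0", call. = FALSE)
  if (scaling <= 0) stop("'scaling' must be > 0", call. = FALSE)
  structure(list(l0 = l0, d = d, center = as.numeric(center),
                 scaling = scaling, species = species),
            class = c("rt_exponential_field", "rt_field"))
}

#' @rdname exponential_field
#' @export
constant_field <- function(level, species = c("meAsp", "serine")) {
  species <- match.arg(species)
  stopifnot(is.numeric(level), length(level) == 1L, is.finite(level))
  if (level < 0) stop("'level' must be >= 0", call. = FALSE)
  structure(list(level = level, species = species),
            class = c("rt_constant_field", "rt_field"))
}

#' @rdname exponential_field
#' @export
two_ligand_field <- function(meAsp, serine) {
  if (!inherits(meAsp, "rt_field") || !inherits(serine, "rt_field"))
    stop("both components must be field specs", call. = FALSE)
  if (meAsp$species != "meAsp" || serine$species != "serine")
    stop("components must carry species 'meAsp' and 'serine' respectively",
         call. = FALSE)
  structure(list(meAsp = meAsp, serine = serine),
            class = c("rt_two_ligand_field", "rt_field"))
}

#' Spatially distinct MeAsp and serine gradients
#'
#' Convenience constructor for the two-attractant arena: an exponential MeAsp
#' hump scaled by `omega` centred at `(-x_a, 0)` and an exponential serine
#' hump scaled by `upsilon` centred at `(-x_s, 0)`, both with unit steepness
#' divisor. With the defaults `x_a = 1`, `x_s = -1` the MeAsp peak sits at
#' `(-1, 0)` and the serine peak at `(1, 0)`, with peak concentrations
#' `omega * (la0 + 1)` and `upsilon * (ls0 + 1)` mM.
#'
#' @param omega MeAsp scaling factor.
#' @param upsilon Serine scaling factor.
#' @param la0,ls0 Minimum concentrations (mM) of the two humps.
#' @param x_a,x_s Offsets entering the exponents as `(x + x_a)` and
#'   `(x + x_s)`, i.e. peaks at `x = -x_a` and `x = -x_s`.
#' @return A `two_ligand_field()` spec.
#' @export
meAsp_serine_field <- function(omega = 1, upsilon = 1, la0 = 0.1, ls0 = 0.1,
                               x_a = 1, x_s = -1) {
  two_ligand_field(
    meAsp  = exponential_field(l0 = la0, d = 1, center = c(-x_a, 0),
                               scaling = omega, species = "meAsp"),
    serine = exponential_field(l0 = ls0, d = 1, center = c(-x_s, 0),
                               scaling = upsilon, species = "serine"))
}

#' Evaluate a field spec at a position
#'
#' Returns the concentration of every ligand species the spec describes, as a
#' named numeric vector in mM. Exponential components evaluate to
#' `scaling * (l0 + exp(-((x - cx)^2 + (y - cy)^2) / d))`; constant components
#' return their level everywhere.
#'
#' @param spec A field spec created by [exponential_field()],
#'   [constant_field()] or [two_ligand_field()].
#' @param position Numeric length-2 `(x, y)`, finite.
#' @return Named numeric vector of concentrations (mM), one entry per species.
#' @examples
#' eval_field_at(exponential_field(l0 = 0.1, d = 1), c(1, 0)) # 0.1 + exp(-1)
#' @export
eval_field_at <- function(spec, position) {
  stopifnot(is.numeric(position), length(position) == 2L,
            all(is.finite(position)))
  UseMethod("eval_field_at")
}

#' @export
eval_field_at.rt_exponential_field <- function(spec, position) {
  r2 <- (position[1] - spec$center[1])^2 + (position[2] - spec$center[2])^2
  out <- spec$scaling * (spec$l0 + exp(-r2 / spec$d))
  names(out) <- spec$species
  out
}

#' @export
eval_field_at.rt_constant_field <- function(spec, position) {
  out <- spec$level
  names(out) <- spec$species
  out
}

#' @export
eval_field_at.rt_two_ligand_field <- function(spec, position) {
  c(eval_field_at(spec$meAsp, position), eval_field_at(spec$serine, position))
}

#' @export
eval_field_at.default <- function(spec, position) {
  stop("unknown field spec type: ", paste(class(spec), collapse = "/"),
       call. = FALSE)
}

#' Location and value of a field's concentration peak
#'
#' For an exponential spec the unique maximum sits at the center with value
#' `scaling * (l0 + 1)`. Constant fields have no unique peak and raise an
#' error. Two-ligand fields return one peak per species.
#'
#' @inheritParams eval_field_at
#' @return For single-species specs, `list(position =, concentration =)`; for
#'   two-ligand specs a named list of such entries (`meAsp`, `serine`).
#' @examples
#' field_peak(exponential_field(l0 = 0.1, scaling = 5))$concentration # 5.5
#' @export
field_peak <- function(spec) UseMethod("field_peak")

#' @export
field_peak.rt_exponential_field <- function(spec) {
  list(position = spec$center,
       concentration = spec$scaling * (spec$l0 + 1))
}

#' @export
field_peak.rt_constant_field <- function(spec) {
  stop("constant field has no unique peak", call. = FALSE)
}

#' @export
field_peak.rt_two_ligand_field <- function(spec) {
  list(meAsp = field_peak(spec$meAsp), serine = field_peak(spec$serine))
}

#' @export
field_peak.default <- function(spec) {
  stop("unknown field spec type: ", paste(class(spec), collapse = "/"),
       call. = FALSE)
}

#' Background (far-field) concentrations of a field spec
#'
#' The concentration each species tends to far from any peak:
#' `scaling * l0` for exponential components, the level itself for constant
#' ones. Used to define the unstimulated state a cell's reference CheY-P
#' level is computed at.
#'
#' @inheritParams eval_field_at
#' @return Named numeric vector of concentrations (mM).
#' @export
background_concentrations <- function(spec) UseMethod("background_concentrations")

#' @export
background_concentrations.rt_exponential_field <- function(spec) {
  out <- spec$scaling * spec$l0
  names(out) <- spec$species
  out
}

#' @export
background_concentrations.rt_constant_field <- function(spec) {
  out <- spec$level
  names(out) <- spec$species
  out
}

#' @export
background_concentrations.rt_two_ligand_field <- function(spec) {
  c(background_concentrations(spec$meAsp),
    background_concentrations(spec$serine))
}

#' @export
print.rt_field <- function(x, ...) {
  if (inherits(x, "rt_two_ligand_field")) {
    cat("<two-ligand field>\n")
    cat("  meAsp :", format_field(x$meAsp), "\n")
    cat("  serine:", format_field(x$serine), "\n")
  } else {
    cat("<field>", format_field(x), "\n")
  }
  invisible(x)
}

format_field <- function(x) {
  if (inherits(x, "rt_constant_field"))
    sprintf("constant %s = %g mM", x$species, x$level)
  else
    sprintf("exponential %s: l0=%g mM, d=%g, center=(%g, %g), scaling=%g",
            x$species, x$l0, x$d, x$center[1], x$center[2], x$scaling)
}

# internal: per-species encoding used by the compiled engine.
# each species -> c(type, p1..p5): type 0 absent, 1 exponential
# (l0, d, cx, cy, scaling), 2 constant (level, 0, 0, 0, 0)
encode_field <- function(spec) {
  enc_one <- function(s) {
    if (is.null(s)) return(c(0, 0, 0, 0, 0, 0))
    if (inherits(s, "rt_exponential_field"))
      return(c(1, s$l0, s$d, s$center[1], s$center[2], s$scaling))
    if (inherits(s, "rt_constant_field"))
      return(c(2, s$level, 0, 0, 0, 0))
    stop("unknown field component", call. = FALSE)
  }
  comp <- split_species(spec)
  rbind(meAsp = enc_one(comp$meAsp), serine = enc_one(comp$serine))
}

# internal: view any field spec as list(meAsp =, serine =) (NULL if absent)
split_species <- function(spec) {
  if (inherits(spec, "rt_two_ligand_field"))
    return(list(meAsp = spec$meAsp, serine = spec$serine))
  if (inherits(spec, "rt_field")) {
    out <- list(meAsp = NULL, serine = NULL)
    out[[spec$species]] <- spec
    return(out)
  }
  stop("not a field spec", call. = FALSE)
}
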