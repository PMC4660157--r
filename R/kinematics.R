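#' Swimming kinematics specification
#'
#' Constants governing cell motion. One domain unit corresponds to
#' `domain_unit_mm` millimetres (default 0.2 mm, i.e. the default
#' `[-2, 2]^2` domain is an 800 um square arena, chosen so that an
#' unstimulated run-and-tumble random walk explores the whole domain within
#' a ~12 minute experiment); the swim speed is given in um/s and converted
#' internally to domain units per second. Headings are measured clockwise
#' from the
#' positive y axis, so a run displaces by
#' `(c sin(theta), c cos(theta)) * dt`. A tumble first rotates the heading
#' by a random angle of random sign drawn uniformly from
#' `[turn_range[1], turn_range[2]]` degrees (mean absolute turn 58 degrees
#' with the defaults) and then translates for the full timestep along the
#' new heading: tumbles are much shorter than runs, so they are folded into
#' a single reorient-and-move step.
#'
#' @param speed Swim speed during a run, um/s (default 29).
#' @param turn_range Numeric length-2, minimum and maximum absolute turning
#'   angle in degrees (defaults 18 and 98).
#' @param boundary `"solid"` (cells are returned to the wall they swam
#'   into) or `"periodic"` (cells re-appear on the opposite side).
#' @param domain Numeric length-4 `c(xmin, xmax, ymin, ymax)`, default the
#'   square `[-2, 2]^2` (mm).
#' @param speed_sd Optional per-cell speed jitter (um/s, standard
#'   deviation); 0 disables it and every cell swims at `speed`.
#' @param domain_unit_mm Physical length of one domain unit, in mm.
#' @return An object of class `rt_kinematic_spec`.
#' @export
kinematic_spec <- function(speed = 29, turn_range = c(18, 98),
                           boundary = c("solid", "periodic"),
                           domain = c(-2, 2, -2, 2), speed_sd = 0,
                           domain_unit_mm = 0.2) {
  boundary <- match.arg(boundary)
  stopifnot(speed > 0, length(turn_range) == 2L,
            turn_range[1] >= 0, turn_range[1] < turn_range[2],
            length(domain) == 4L, domain[1] < domain[2], domain[3] < domain[4],
            speed_sd >= 0, domain_unit_mm > 0)
  structure(list(speed = speed,
                 speed_domain = speed * 1e-3 / domain_unit_mm,
                 turn_range = as.numeric(turn_range), boundary = boundary,
                 domain = as.numeric(domain), speed_sd = speed_sd,
                 domain_unit_mm = domain_unit_mm),
            class = "rt_kinematic_spec")
}

#' Straight-run displacement
#'
#' Advances a position along the current heading for `dt` seconds:
#' `x <- x + c sin(theta) dt`, `y <- y + c cos(theta) dt`. The heading is
#' unchanged (a run applies no reorientation). The displacement magnitude is
#' exactly `c * dt` for any heading.
#'
#' @param position Numeric length-2 `(x, y)` in domain units (mm).
#' @param heading Heading in radians, clockwise from the +y axis.
#' @param spec A [kinematic_spec()].
#' @param dt Timestep in seconds.
#' @return The new position (no boundary correction applied; see
#'   [apply_boundary()]).
#' @export
run_step <- function(position, heading, spec, dt) {
  stopifnot(inherits(spec, "rt_kinematic_spec"), dt > 0)
  c(position[1] + spec$speed_domain * sin(heading) * dt,
    position[2] + spec$speed_domain * cos(heading) * dt)
}

#' Tumble reorientation
#'
#' Draws a turning angle `theta_r = s * u` with equiprobable sign `s` and
#' `u ~ Uniform(turn_range[1], turn_range[2])` degrees, and returns the new
#' heading `theta + theta_r` wrapped to `[0, 2*pi)`.
#'
#' @inheritParams run_step
#' @param u Optional numeric length-2 of uniform draws in `[0, 1)` (sign,
#'   magnitude), e.g. from [rng_uniforms()] for replayable trajectories;
#'   defaults to fresh draws from the session RNG.
#' @return New heading in radians.
#' @export
tumble_reorient <- function(heading, spec, u = stats::runif(2)) {
  stopifnot(inherits(spec, "rt_kinematic_spec"), length(u) == 2L)
  s <- if (u[1] < 0.5) 1 else -1
  turn <- spec$turn_range[1] + u[2] * (spec$turn_range[2] - spec$turn_range[1])
  wrap_angle(heading + s * turn * pi / 180)
}

#' Tumble: reorient, then move
#'
#' Applies [tumble_reorient()] and then translates for the full timestep
#' along the new heading, so the per-step displacement magnitude is
#' `c * dt` whether the cell runs or tumbles.
#'
#' @inheritParams tumble_reorient
#' @inheritParams run_step
#' @return `list(position =, heading =)`.
#' @export
tumble_step <- function(position, heading, spec, dt, u = stats::runif(2)) {
  heading <- tumble_reorient(heading, spec, u)
  list(position = run_step(position, heading, spec, dt), heading = heading)
}

#' Boundary handling
#'
#' Corrects a position that may have left the domain. Solid boundaries clamp
#' each coordinate independently to its interval, as if the cell swam into a
#' wall (a cell ending a step at `(2.05, 1)` in the default domain is
#' returned to `(2, 1)`); periodic boundaries wrap each coordinate by the
#' domain width (an exit at `(1, 2)` re-enters at `(1, -2)`). Interior
#' positions are unchanged.
#'
#' @inheritParams run_step
#' @return The corrected position.
#' @export
apply_boundary <- function(position, spec) {
  stopifnot(inherits(spec, "rt_kinematic_spec"))
  d <- spec$domain
  switch(spec$boundary,
    solid = c(min(max(position[1], d[1]), d[2]),
              min(max(position[2], d[3]), d[4])),
    periodic = c(d[1] + (position[1] - d[1]) %% (d[2] - d[1]),
                 d[3] + (position[2] - d[3]) %% (d[4] - d[3])),
    stop("unknown boundary mode: ", spec$boundary, call. = FALSE))
}

# internal: wrap to [0, 2*pi)
wrap_angle <- function(theta) theta %% (2 * pi)
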