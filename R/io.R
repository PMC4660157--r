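#' Load a simulation configuration from a YAML file
#'
#' Reads a structured key-value file and returns a validated
#' [simulation_config()] with defaults filled in (0.0144 s timestep, 50,000
#' steps, the `[-2, 2]^2` mm domain, reference kinematics and cascade
#' parameters). Unknown keys are rejected by name. An empty file yields the
#' all-defaults configuration with a single-ligand exponential field. A
#' `preset` key (or `preset = ` argument to [preset_config()]) selects one
#' of the named experiment set-ups.
#'
#' Recognised top-level keys: `preset`, `n_cells`, `n_steps`, `dt`, `seed`,
#' `record_stride`, `beta`, `init`, `field` (with `type` one of
#' `exponential`, `constant`, `two_ligand`; keys `l0_mM`, `d`, `center`,
#' `scaling`, `level_mM`, `species`, and for `two_ligand` nested `meAsp` /
#' `serine` blocks or `omega` / `upsilon` shortcuts), `motor`
#' (`hill_exponent`, `prefactor`), `kinematics` (`speed_um_per_s`,
#' `turn_min_deg`, `turn_max_deg`, `boundary`, `domain`), and `cascade`
#' (`totals`, `rates`, receptor keys under `receptor`).
#'
#' @param path Path to a YAML file.
#' @return An `rt_simulation_config`.
#' @seealso [preset_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

#' Named experiment presets
#'
#' Ready-made configurations for the reference experiments:
#' `"fig7_shallow"`, `"fig7_intermediate"`, `"fig7_steep"` are 100-cell
#' populations with the eight-value `beta` ladder (1/4 ... 10) in
#' single-ligand exponential gradients with steepness `d` = 10, 1 and 0.1;
#' `"fig10_grid"` is the 50-cell two-attractant arena template (combine
#' with [run_two_ligand_grid()]).
#'
#' @param preset Preset name.
#' @param ... Overrides passed as top-level config keys (e.g. `n_cells`,
#'   `seed`).
#' @return An `rt_simulation_config`.
#' @export
preset_config <- function(preset = c("fig7_shallow", "fig7_intermediate",
                                     "fig7_steep", "fig10_grid"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    fig7_shallow = list(n_cells = 100, beta = c(1/4, 1/2, 1, 2, 4, 6, 8, 10),
                        field = list(type = "exponential", l0_mM = 0.1, d = 10)),
    fig7_intermediate = list(n_cells = 100, beta = c(1/4, 1/2, 1, 2, 4, 6, 8, 10),
                             field = list(type = "exponential", l0_mM = 0.1, d = 1)),
    fig7_steep = list(n_cells = 100, beta = c(1/4, 1/2, 1, 2, 4, 6, 8, 10),
                      field = list(type = "exponential", l0_mM = 0.1, d = 0.1)),
    fig10_grid = list(n_cells = 50,
                      field = list(type = "two_ligand", omega = 1, upsilon = 1)))
  config_from_list(utils::modifyList(base, list(...)))
}

# internal: build a simulation_config from a plain list, rejecting unknown keys
config_from_list <- function(raw) {
  if (!is.null(raw$preset)) {
    preset <- raw$preset
    raw$preset <- NULL
    return(do.call(preset_config, c(list(preset = preset), raw)))
  }
  known <- c("n_cells", "n_steps", "dt", "seed", "record_stride", "beta",
             "init", "field", "motor", "kinematics", "cascade")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key: '", bad[1], "'", call. = FALSE)

  field <- field_from_list(raw$field)
  motor <- do.call(motor_spec, check_keys(raw$motor %||% list(),
                                          c("hill_exponent", "prefactor"),
                                          "motor"))
  kin_raw <- check_keys(raw$kinematics %||% list(),
                        c("speed_um_per_s", "turn_min_deg", "turn_max_deg",
                          "boundary", "domain", "speed_sd", "domain_unit_mm"),
                        "kinematics")
  kin_args <- list()
  if (!is.null(kin_raw$speed_um_per_s)) kin_args$speed <- kin_raw$speed_um_per_s
  if (!is.null(kin_raw$turn_min_deg) || !is.null(kin_raw$turn_max_deg))
    kin_args$turn_range <- c(kin_raw$turn_min_deg %||% 18,
                             kin_raw$turn_max_deg %||% 98)
  if (!is.null(kin_raw$boundary)) kin_args$boundary <- kin_raw$boundary
  if (!is.null(kin_raw$domain)) kin_args$domain <- unlist(kin_raw$domain)
  if (!is.null(kin_raw$speed_sd)) kin_args$speed_sd <- kin_raw$speed_sd
  if (!is.null(kin_raw$domain_unit_mm))
    kin_args$domain_unit_mm <- kin_raw$domain_unit_mm
  kinematics <- do.call(kinematic_spec, kin_args)
  params <- cascade_from_list(raw$cascade)

  args <- list(field = field, params = params, motor = motor,
               kinematics = kinematics)
  for (k in c("n_cells", "n_steps", "dt", "seed", "record_stride", "init"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$beta)) args$beta <- unlist(raw$beta)
  do.call(simulation_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_keys <- function(x, known, where) {
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config key: '", where, ".", bad[1], "'", call. = FALSE)
  x
}

field_from_list <- function(f) {
  if (is.null(f)) return(exponential_field(l0 = 0.1, d = 1))
  type <- f$type %||% "exponential"
  if (type == "exponential") {
    f <- check_keys(f, c("type", "l0_mM", "d", "center", "scaling", "species"),
                    "field")
    exponential_field(l0 = f$l0_mM %||% 0.1, d = f$d %||% 1,
                      center = unlist(f$center %||% c(0, 0)),
                      scaling = f$scaling %||% 1,
                      species = f$species %||% "meAsp")
  } else if (type == "constant") {
    f <- check_keys(f, c("type", "level_mM", "species"), "field")
    constant_field(level = f$level_mM, species = f$species %||% "meAsp")
  } else if (type == "two_ligand") {
    f <- check_keys(f, c("type", "meAsp", "serine", "omega", "upsilon",
                         "la0_mM", "ls0_mM", "x_a", "x_s"), "field")
    if (!is.null(f$meAsp) || !is.null(f$serine)) {
      two_ligand_field(
        meAsp = field_from_list(utils::modifyList(f$meAsp, list(species = "meAsp"))),
        serine = field_from_list(utils::modifyList(f$serine, list(species = "serine"))))
    } else {
      meAsp_serine_field(omega = f$omega %||% 1, upsilon = f$upsilon %||% 1,
                         la0 = f$la0_mM %||% 0.1, ls0 = f$ls0_mM %||% 0.1,
                         x_a = f$x_a %||% 1, x_s = f$x_s %||% -1)
    }
  } else stop("unknown field type: '", type, "'", call. = FALSE)
}

cascade_from_list <- function(cs) {
  if (is.null(cs)) return(default_cascade_params())
  cs <- check_keys(cs, c("totals", "rates", "receptor"), "cascade")
  def <- default_cascade_params()
  totals <- utils::modifyList(as.list(def$totals), cs$totals %||% list())
  rates <- utils::modifyList(as.list(def$rates), cs$rates %||% list())
  rec <- if (is.null(cs$receptor)) def$receptor else {
    r <- check_keys(cs$receptor,
                    c("n_cluster", "tar_fraction", "tsr_fraction",
                      "K_tar_off_mM", "K_tar_on_mM", "K_tsr_off_mM",
                      "K_tsr_on_mM", "m_offset", "m_slope", "m_range"),
                    "cascade.receptor")
    receptor_spec(
      n_cluster = r$n_cluster %||% 24,
      tar_fraction = r$tar_fraction %||% 0.375,
      tsr_fraction = r$tsr_fraction %||% 0.625,
      K_tar = c(off = r$K_tar_off_mM %||% 0.02, on = r$K_tar_on_mM %||% 0.5),
      K_tsr = c(off = r$K_tsr_off_mM %||% 0.001, on = r$K_tsr_on_mM %||% 1.0),
      m_offset = r$m_offset %||% 1.0, m_slope = r$m_slope %||% 0.5,
      m_range = unlist(r$m_range %||% c(0, 10)))
  }
  cascade_params(totals = unlist(totals), rates = unlist(rates), receptor = rec)
}

#' Write and read trajectory tables
#'
#' Plain-CSV round trip for trajectory records. Numeric columns are written
#' with 17 significant digits so that write-then-read reproduces every field
#' at full double precision. The first line is a comment naming the units.
#'
#' @param records Trajectory data frame (e.g. `sim$trajectories`).
#' @param path File path.
#' @return `read_trajectories()` returns the data frame;
#'   `write_trajectories()` returns `path` invisibly.
#' @export
write_trajectories <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: time s; x,y mm; theta rad; Yp uM; m methyl units; bias probability/step", con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed trajectory file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (col in intersect(c("time", "x", "y", "theta", "Yp", "m", "bias", "beta"),
                        names(out)))
    out[[col]] <- as.numeric(out[[col]])
  out
}

#' Write a simulation run to a directory
#'
#' Writes `trajectories.csv`, `initial.csv`, `final.csv` and a
#' `manifest.json` (config echo, master seed, package version, start/end
#' timestamps, output file list with row counts) sufficient to re-run the
#' simulation bit-identically on the same platform. The manifest is written
#' last, after all data files, and atomically (write-then-rename).
#'
#' @param sim An `rt_simulation`.
#' @param dir Output directory (created if needed).
#' @param started Optional POSIXct start time to record.
#' @return The manifest as a list, invisibly.
#' @export
write_run <- function(sim, dir, started = Sys.time()) {
  stopifnot(inherits(sim, "rt_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(trajectories = "trajectories.csv", initial = "initial.csv",
                final = "final.csv")
  write_trajectories(sim$trajectories, file.path(dir, files$trajectories))
  utils::write.csv(sim$initial, file.path(dir, files$initial), row.names = FALSE)
  utils::write.csv(sim$final, file.path(dir, files$final), row.names = FALSE)
  manifest <- list(
    package = "runtumble",
    version = as.character(utils::packageVersion("runtumble")),
    seed = sim$config$seed,
    config = config_echo(sim$config),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(list(trajectories = sim$trajectories,
                          initial = sim$initial, final = sim$final),
                     nrow))
  tmp <- file.path(dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(manifest)
}

# internal: plain-list echo of a config for the manifest
config_echo <- function(cfg) {
  list(n_cells = cfg$n_cells, n_steps = cfg$n_steps, dt = cfg$dt,
       seed = cfg$seed, record_stride = cfg$record_stride, init = cfg$init,
       beta = cfg$beta,
       field = unclass_deep(cfg$field),
       motor = unclass(cfg$motor),
       kinematics = unclass(cfg$kinematics),
       cascade = list(totals = as.list(cfg$params$totals),
                      rates = as.list(cfg$params$rates),
                      receptor = unclass(cfg$params$receptor)))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, function(e) if (is.list(e)) unclass_deep(e) else unclass(e))
  else x
}

#' Deterministic test fixtures
#'
#' Small, fully deterministic datasets for exercising the metrics and I/O
#' layers without running a simulation: `"toy_trajectories"` (3 stationary
#' cells over 5 recorded steps at integer coordinates, hand-computable
#' distances), `"hill_curve"` (a noiseless 10-point Hill curve; pass `K`
#' and `n` to control it), and `"uniform_field_cells"` (cell positions
#' uniform over the default domain).
#'
#' @param kind Fixture name.
#' @param seed Seed for the kinds that draw random numbers.
#' @param ... Generator parameters: `K`, `n`, `upsilon` for `"hill_curve"`;
#'   `n_cells` for `"uniform_field_cells"`.
#' @return A data frame.
#' @export
make_fixture <- function(kind = c("toy_trajectories", "hill_curve",
                                  "uniform_field_cells"), seed = 1, ...) {
  kind <- match.arg(kind)
  opts <- list(...)
  switch(kind,
    toy_trajectories = {
      cells <- data.frame(cell = 1:3, x = c(1, 0, -2), y = c(0, 2, -1),
                          beta = c(1, 1, 4))
      do.call(rbind, lapply(0:4, function(s)
        data.frame(step = s, time = s * 1.0, cell = cells$cell,
                   beta = cells$beta, x = cells$x, y = cells$y,
                   theta = 0, Yp = 4, m = 3, bias = 0.2, state = "run")))
    },
    hill_curve = {
      K <- opts$K %||% 1e-3
      n <- opts$n %||% 3
      u <- opts$upsilon %||% 10^seq(-6, -1, length.out = 10)
      data.frame(upsilon = u, fraction = u^n / (K^n + u^n))
    },
    uniform_field_cells = {
      n_cells <- opts$n_cells %||% 20
      u <- rng_uniforms(seed, 0, 2L * n_cells)
      data.frame(cell = seq_len(n_cells),
                 x = -2 + 4 * u[seq_len(n_cells)],
                 y = -2 + 4 * u[n_cells + seq_len(n_cells)])
    })
}
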