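#' Mean distance-to-peak timecourse
#'
#' Per recorded step, the mean Euclidean distance of the cells from a peak
#' position, optionally grouped by a trajectory column (by default the
#' `beta` subpopulation label). Empty groups are dropped with a warning.
#'
#' @param x An `rt_simulation` or its `trajectories` data frame.
#' @param peak Numeric length-2 peak position.
#' @param by Name of the grouping column, or `NULL` for the whole
#'   population.
#' @return Data frame with `step`, `time` (if available), the grouping
#'   column (if any), `mean_distance` and `n`.
#' @export
mean_distance_timecourse <- function(x, peak, by = "beta") {
  traj <- if (inherits(x, "rt_simulation")) x$trajectories else x
  stopifnot(is.data.frame(traj), nrow(traj) > 0,
            all(c("step", "x", "y") %in% names(traj)),
            is.numeric(peak), length(peak) == 2L)
  traj$..dist <- sqrt((traj$x - peak[1])^2 + (traj$y - peak[2])^2)
  keys <- list(step = traj$step)
  if (!is.null(by)) {
    if (!by %in% names(traj)) stop("no column '", by, "' to group by", call. = FALSE)
    keys[[by]] <- traj[[by]]
  }
  agg <- stats::aggregate(traj$..dist, keys, function(v) c(mean(v), length(v)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    mean_distance = agg$x[, 1], n = agg$x[, 2])
  if ("time" %in% names(traj)) {
    dt <- traj$time[match(out$step, traj$step)]
    out <- cbind(out[1], time = dt, out[-1])
  }
  out[order(out$step), , drop = FALSE]
}

#' Attraction classification of final positions
#'
#' Counts the cells attracted to each ligand in the two-peak arena: final
#' `x` below the threshold means attracted to MeAsp (whose peak is in the
#' left half-domain), above it to serine. Cells sitting exactly at the
#' threshold belong to neither and are reported separately, so
#' `meAsp + serine + boundary` always equals the number of cells.
#'
#' @param final Data frame of final positions with a column `x`, e.g. the
#'   `final` element of an `rt_simulation`.
#' @param threshold Dividing line on `x` (default 0, midway between peaks
#'   at -1 and +1).
#' @return List with counts `meAsp`, `serine`, `boundary`.
#' @export
attraction_counts <- function(final, threshold = 0) {
  stopifnot(is.data.frame(final), "x" %in% names(final))
  list(meAsp = sum(final$x < threshold),
       serine = sum(final$x > threshold),
       boundary = sum(final$x == threshold))
}

#' Accumulation ratio
#'
#' Ratio of final to initial mean population distance to a peak. A value
#' well below 1 indicates accumulation about that peak; about 1, no
#' accumulation.
#'
#' @param initial,final Data frames with columns `x`, `y` (initial and
#'   final cell positions).
#' @param peak Numeric length-2 peak position.
#' @return The scalar ratio.
#' @export
accumulation_ratio <- function(initial, final, peak) {
  stopifnot(is.data.frame(initial), is.data.frame(final),
            all(c("x", "y") %in% names(initial)),
            all(c("x", "y") %in% names(final)),
            nrow(initial) == nrow(final), length(peak) == 2L)
  d0 <- mean(sqrt((initial$x - peak[1])^2 + (initial$y - peak[2])^2))
  d1 <- mean(sqrt((final$x - peak[1])^2 + (final$y - peak[2])^2))
  if (d0 == 0) stop("initial mean distance is zero; ratio undefined", call. = FALSE)
  d1 / d0
}

#' Least-squares Hill fit of attraction against ligand scaling
#'
#' Fits `f(u) = u^n / (K^n + u^n)` to the fraction of cells attracted to
#' serine as a function of the serine scaling `upsilon`, by unweighted
#' nonlinear least squares with a multi-start over a log-spaced grid of `K`
#' values (scalings span several decades, so a single local fit is not
#' reliable).
#'
#' @param upsilon Scaling values (>= 4 distinct, positive).
#' @param fraction Fractions in `[0, 1]`, one per scaling.
#' @return An object of class `rt_hill_fit`: list with `K`, `n`,
#'   `residual` (sum of squares), `fitted` (function of upsilon), and the
#'   underlying `nls` fit.
#' @examples
#' u <- 10^seq(-6, -1, length.out = 10)
#' f <- u^3.166 / (2.71e-3^3.166 + u^3.166)
#' hill_fit(u, f)
#' @export
hill_fit <- function(upsilon, fraction) {
  stopifnot(length(upsilon) == length(fraction), all(upsilon > 0),
            all(fraction >= -1e-9 & fraction <= 1 + 1e-9))
  if (length(unique(upsilon)) < 4)
    stop("need at least 4 distinct upsilon values", call. = FALSE)
  if (all(fraction <= 0) || all(fraction >= 1))
    stop("degenerate data: all fractions at one extreme; Hill fit undefined",
         call. = FALSE)
  dat <- data.frame(u = upsilon, f = pmin(pmax(fraction, 0), 1))
  K_grid <- 10^seq(log10(min(upsilon)), log10(max(upsilon)), length.out = 9)
  best <- NULL
  for (K0 in K_grid) for (n0 in c(1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ u^n / (K^n + u^n), data = dat,
                        start = list(K = K0, n = n0),
                        lower = c(K = min(upsilon) * 1e-3, n = 0.1),
                        upper = c(K = max(upsilon) * 1e3, n = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(resid(fit)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) stop("Hill fit failed for all starts", call. = FALSE)
  cf <- coef(best$fit)
  structure(list(K = unname(cf[["K"]]), n = unname(cf[["n"]]),
                 residual = best$ss,
                 fitted = function(u) u^cf[["n"]] / (cf[["K"]]^cf[["n"]] + u^cf[["n"]]),
                 fit = best$fit),
            class = "rt_hill_fit")
}

#' @export
print.rt_hill_fit <- function(x, ...) {
  cat(sprintf("<Hill fit> K = %.4g, n = %.4g (residual SS %.3g)\n",
              x$K, x$n, x$residual))
  invisible(x)
}
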