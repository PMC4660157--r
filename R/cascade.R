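#' Receptor signalling-team specification
#'
#' Parameters of the mixed-cluster Monod-Wyman-Changeux (MWC) receptor model.
#' A signalling team of `n_cluster` receptor dimers, composed of Tar (MeAsp
#' binding) and Tsr (serine binding) fractions, is either active or inactive
#' according to a free energy combining a methylation-dependent offset with
#' one log-occupancy term per ligand species:
#'
#' `F = n_cluster * ( m_offset - m_slope * m
#'      + tar_fraction * log((1 + [La]/K_off_tar) / (1 + [La]/K_on_tar))
#'      + tsr_fraction * log((1 + [Ls]/K_off_tsr) / (1 + [Ls]/K_on_tsr)) )`
#'
#' in units of kT, with team activity `Phi = 1/(1 + exp(F))`. The low-affinity
#' binding of MeAsp to Tsr is neglected, appropriate at the chemoattractant
#' concentrations the simulator targets.
#'
#' @param n_cluster Number of receptor dimers per team (>= 1).
#' @param tar_fraction,tsr_fraction Composition weights, non-negative with
#'   sum <= 1.
#' @param K_tar,K_tsr Named numeric `c(off =, on =)` dissociation constants
#'   (mM) of the inactive (`off`) and active (`on`) receptor conformations,
#'   with `0 < off < on`.
#' @param m_offset,m_slope Methylation free-energy function
#'   `f_m(m) = m_offset - m_slope * m` (kT per team member, `m_slope > 0`).
#' @param m_range Allowed methylation interval `c(min, max)`; the adaptation
#'   dynamics are clamped at these boundaries.
#' @return An object of class `rt_receptor_spec`.
#' @export
receptor_spec <- function(n_cluster = 24, tar_fraction = 0.375,
                          tsr_fraction = 0.625,
                          K_tar = c(off = 0.02, on = 0.5),
                          K_tsr = c(off = 0.001, on = 1.0),
                          m_offset = 1.0, m_slope = 0.5,
                          m_range = c(0, 10)) {
  stopifnot(n_cluster >= 1, tar_fraction >= 0, tsr_fraction >= 0,
            tar_fraction + tsr_fraction <= 1 + 1e-12,
            m_slope > 0, length(m_range) == 2L, m_range[1] < m_range[2])
  for (K in list(K_tar, K_tsr)) {
    if (!all(c("off", "on") %in% names(K)))
      stop("dissociation constants must be named c(off =, on =)", call. = FALSE)
    if (!(K[["off"]] > 0 && K[["off"]] < K[["on"]]))
      stop("invalid receptor spec: need 0 < K_off < K_on", call. = FALSE)
  }
  structure(list(n_cluster = n_cluster, tar_fraction = tar_fraction,
                 tsr_fraction = tsr_fraction,
                 K_tar = K_tar, K_tsr = K_tsr,
                 m_offset = m_offset, m_slope = m_slope,
                 m_range = as.numeric(m_range)),
            class = "rt_receptor_spec")
}

#' Signalling-cascade parameter set
#'
#' Total protein concentrations, rate constants and receptor spec of the
#' intracellular chemotaxis pathway of one cell. The dynamic state is
#' `(m, Ap, Bp, Yp)` -- mean receptor methylation and the phosphorylated
#' CheA, CheB and CheY concentrations -- and evolves as
#'
#' * `dm/dt  = k_R * [R]_T * (1 - Phi) - k_B * Bp * Phi`
#' * `dAp/dt = k_A * Phi * ([A]_T - Ap) - k_y * Ap * ([Y]_T - Yp)
#'             - k_b * Ap * ([B]_T - Bp)`
#' * `dYp/dt = k_y * Ap * ([Y]_T - Yp) - k_z * [Z]_T * Yp - g_Y * Yp`
#' * `dBp/dt = k_b * Ap * ([B]_T - Bp) - g_B * Bp`
#'
#' where `Phi` is the receptor-team activity at the current ligand
#' concentrations and methylation level. CheR methylates inactive receptors
#' and phosphorylated CheB demethylates active ones, which yields integral
#' feedback: the steady-state activity (hence CheY-P) is independent of the
#' ambient ligand level, i.e. the pathway adapts perfectly as long as the
#' methylation level stays inside its configured range.
#'
#' @param totals Named numeric `c(A =, B =, R =, Y =, Z =)`, total protein
#'   concentrations in uM (CheA, CheB, CheR, CheY, CheZ).
#' @param rates Named numeric with entries `k_A` (CheA autophosphorylation,
#'   1/s, scaled by activity), `k_y`, `k_b` (phosphotransfer to CheY / CheB,
#'   1/(uM s)), `k_z` (CheZ-mediated CheY-P dephosphorylation, 1/(uM s)),
#'   `g_Y`, `g_B` (spontaneous dephosphorylation, 1/s), `k_R` (methylation,
#'   methyl units/(uM s)), `k_B` (CheB-P demethylation, methyl units/(uM s)).
#'   Either of `k_z` and `g_Y` may be zero (not both).
#' @param receptor A [receptor_spec()].
#' @param beta Scalar recorded as the multiple of the base parameter set this
#'   cell's totals correspond to (see [scale_protein_totals()]).
#' @return An object of class `rt_cascade_params`.
#' @seealso [default_cascade_params()], [steady_state()], [integrate_cascade()]
#' @export
cascade_params <- function(totals, rates, receptor = receptor_spec(), beta = 1) {
  need_tot <- c("A", "B", "R", "Y", "Z")
  need_rat <- c("k_A", "k_y", "k_b", "k_z", "g_Y", "g_B", "k_R", "k_B")
  if (!all(need_tot %in% names(totals)))
    stop("totals must name ", paste(need_tot, collapse = ", "), call. = FALSE)
  if (!all(need_rat %in% names(rates)))
    stop("rates must name ", paste(need_rat, collapse = ", "), call. = FALSE)
  totals <- as.numeric(totals[need_tot]); names(totals) <- need_tot
  rates <- as.numeric(rates[need_rat]); names(rates) <- need_rat
  if (any(totals <= 0)) stop("all totals must be positive", call. = FALSE)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (rates[["k_z"]] + rates[["g_Y"]] <= 0)
    stop("need a CheY-P dephosphorylation route (k_z or g_Y > 0)", call. = FALSE)
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  stopifnot(inherits(receptor, "rt_receptor_spec"))
  structure(list(totals = totals, rates = rates, receptor = receptor,
                 beta = beta),
            class = "rt_cascade_params")
}

#' Default cascade parameter set
#'
#' The package's reference parameterisation. Rate constants are on the
#' literature scale for the E. coli pathway (sub-second phosphorylation
#' kinetics, ~10 s adaptation), and the two methylation rates were calibrated
#' once so that the unstimulated steady state at a 0.1 mM MeAsp background
#' gives a CheY-P reference level of 4.043 uM and an adaptation time of
#' about 8 s for a 0.1 to 0.2 mM step. Every coefficient is configuration:
#' the whole set can be replaced by any other parameterisation of the same
#' cascade structure without touching code.
#'
#' @param beta Optional scalar multiple applied to all totals, via
#'   [scale_protein_totals()].
#' @return An `rt_cascade_params` object.
#' @export
default_cascade_params <- function(beta = 1) {
  p <- cascade_params(
    totals = c(A = 5, B = 2, R = 0.3, Y = 9.7, Z = 1.1),
    rates = c(k_A = 16, k_y = 5, k_b = 1.5, k_z = 5,
              g_Y = 0.1, g_B = 1, k_R = 0.2, k_B = 0.10070),
    receptor = receptor_spec())
  if (beta != 1) p <- scale_protein_totals(p, beta) else p
}

#' Cascade state vector
#'
#' @param m Mean methylation level (dimensionless).
#' @param Ap,Bp,Yp Phosphorylated CheA, CheB, CheY concentrations (uM).
#' @return Named numeric vector `c(m, Ap, Bp, Yp)`.
#' @export
cascade_state <- function(m, Ap, Bp, Yp) {
  c(m = as.numeric(m), Ap = as.numeric(Ap),
    Bp = as.numeric(Bp), Yp = as.numeric(Yp))
}

# internal: fill missing species with 0 and validate
conc_pair <- function(concentrations) {
  out <- c(meAsp = 0, serine = 0)
  if (length(concentrations)) {
    if (is.null(names(concentrations)) && length(concentrations) == 1L)
      names(concentrations) <- "meAsp"
    bad <- setdiff(names(concentrations), c("meAsp", "serine"))
    if (length(bad)) stop("unknown ligand species: ", bad[1], call. = FALSE)
    out[names(concentrations)] <- as.numeric(concentrations)
  }
  if (any(out < 0)) stop("ligand concentrations must be >= 0", call. = FALSE)
  out
}

# internal: the two ligand log-occupancy terms (per team member, kT)
ligand_terms <- function(receptor, concentrations) {
  cc <- conc_pair(concentrations)
  la <- receptor$tar_fraction *
    log((1 + cc[["meAsp"]] / receptor$K_tar[["off"]]) /
        (1 + cc[["meAsp"]] / receptor$K_tar[["on"]]))
  ls <- receptor$tsr_fraction *
    log((1 + cc[["serine"]] / receptor$K_tsr[["off"]]) /
        (1 + cc[["serine"]] / receptor$K_tsr[["on"]]))
  la + ls
}

#' Receptor-team free energy and activity
#'
#' `receptor_free_energy()` evaluates the mixed-cluster MWC free energy (kT)
#' at methylation level `m` and the given ligand concentrations;
#' `receptor_activity()` maps a free energy to the probability
#' `Phi = 1/(1 + exp(F))` that the team is in its kinase-activating state.
#'
#' @param receptor A [receptor_spec()].
#' @param m Methylation level.
#' @param concentrations Named numeric (mM), entries `meAsp` and/or `serine`.
#' @param F Free energy in kT.
#' @return Free energy (kT), or activity in (0, 1).
#' @examples
#' receptor_activity(0)        # 0.5
#' receptor_activity(log(3))   # 0.25
#' @export
receptor_free_energy <- function(receptor, m, concentrations) {
  stopifnot(inherits(receptor, "rt_receptor_spec"), is.finite(m))
  receptor$n_cluster *
    (receptor$m_offset - receptor$m_slope * m +
       ligand_terms(receptor, concentrations))
}

#' @rdname receptor_free_energy
#' @export
receptor_activity <- function(F) {
  stopifnot(all(is.finite(F)))
  1 / (1 + exp(F))
}

#' Time derivatives of the cascade state
#'
#' Right-hand side of the four-variable pathway model described in
#' [cascade_params()]. At the boundaries of the configured methylation range
#' an outward-pointing `dm/dt` is forced to zero (the adaptation system is
#' clamped, standard practice for bounded methylation states).
#'
#' @param state Named numeric `c(m, Ap, Bp, Yp)` (see [cascade_state()]).
#' @param params An [cascade_params()] object.
#' @param concentrations Named ligand concentrations (mM).
#' @return Named numeric derivative vector `c(m, Ap, Bp, Yp)` (per second).
#' @export
cascade_derivatives <- function(state, params, concentrations) {
  stopifnot(inherits(params, "rt_cascade_params"))
  lt <- ligand_terms(params$receptor, concentrations)
  cascade_derivatives_fast(state, params, lt)
}

# internal hot path: ligand terms precomputed (frozen within an ABM step)
cascade_derivatives_fast <- function(state, params, lig_term) {
  to <- params$totals; ra <- params$rates; rc <- params$receptor
  m <- state[[1]]; Ap <- state[[2]]; Bp <- state[[3]]; Yp <- state[[4]]
  F <- rc$n_cluster * (rc$m_offset - rc$m_slope * m + lig_term)
  phi <- 1 / (1 + exp(F))
  dm <- ra[["k_R"]] * to[["R"]] * (1 - phi) - ra[["k_B"]] * Bp * phi
  if ((m <= rc$m_range[1] && dm < 0) || (m >= rc$m_range[2] && dm > 0)) dm <- 0
  dAp <- ra[["k_A"]] * phi * (to[["A"]] - Ap) -
    ra[["k_y"]] * Ap * (to[["Y"]] - Yp) -
    ra[["k_b"]] * Ap * (to[["B"]] - Bp)
  dYp <- ra[["k_y"]] * Ap * (to[["Y"]] - Yp) -
    ra[["k_z"]] * to[["Z"]] * Yp - ra[["g_Y"]] * Yp
  dBp <- ra[["k_b"]] * Ap * (to[["B"]] - Bp) - ra[["g_B"]] * Bp
  c(m = dm, Ap = dAp, Bp = dBp, Yp = dYp)
}

#' Advance the cascade state over a time interval
#'
#' Integrates the pathway ODEs with the ligand concentrations held fixed
#' (quasi-static within one agent-based timestep), using a stiff-capable
#' adaptive integrator (`deSolve::lsoda`). State bounds
#' (`0 <= Xp <= [X]_T`, methylation range) are enforced on the result.
#'
#' @inheritParams cascade_derivatives
#' @param dt Time interval in seconds (> 0; `dt = 0` returns the state
#'   unchanged).
#' @param rtol,atol Integrator tolerances.
#' @return The advanced state, a named numeric `c(m, Ap, Bp, Yp)`.
#' @export
integrate_cascade <- function(state, params, concentrations, dt,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(dt >= 0)
  if (dt == 0) return(state)
  lt <- ligand_terms(params$receptor, concentrations)
  rhs <- function(t, y, parms) list(cascade_derivatives_fast(y, params, lt))
  out <- deSolve::lsoda(y = state, times = c(0, dt), func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("cascade integration failed; state: ",
         paste(sprintf("%s=%.6g", names(state), state), collapse = ", "),
         call. = FALSE)
  clamp_state(out[nrow(out), c("m", "Ap", "Bp", "Yp")], params)
}

# internal: enforce state invariants
clamp_state <- function(state, params) {
  to <- params$totals; mr <- params$receptor$m_range
  cascade_state(
    m = min(max(state[["m"]], mr[1]), mr[2]),
    Ap = min(max(state[["Ap"]], 0), to[["A"]]),
    Bp = min(max(state[["Bp"]], 0), to[["B"]]),
    Yp = min(max(state[["Yp"]], 0), to[["Y"]]))
}

#' Steady state of the cascade at fixed ligand concentrations
#'
#' Long-time integration (ten times the slowest configured timescale)
#' followed by Newton polishing of the root of [cascade_derivatives()],
#' to an absolute tolerance of 1e-9 on all derivatives. Deterministic for
#' fixed parameters. Because of the pathway's integral feedback the
#' phosphorylated concentrations at steady state are independent of the
#' ligand level; only the methylation level shifts (perfect adaptation),
#' unless the methylation range clamps.
#'
#' @inheritParams cascade_derivatives
#' @param tol Absolute tolerance on the derivative max-norm.
#' @return Named numeric steady state `c(m, Ap, Bp, Yp)`, with the receptor
#'   activity attached as attribute `"activity"`.
#' @examples
#' ss <- steady_state(default_cascade_params(), c(meAsp = 0.1))
#' ss[["Yp"]]  # reference CheY-P level, ~4.04 uM
#' @export
steady_state <- function(params, concentrations, tol = 1e-9) {
  stopifnot(inherits(params, "rt_cascade_params"))
  lt <- ligand_terms(params$receptor, concentrations)
  to <- params$totals; ra <- params$rates; rc <- params$receptor
  # start from a mid-range guess and integrate past the slowest timescale
  y0 <- cascade_state(m = mean(rc$m_range), Ap = to[["A"]] / 2,
                      Bp = to[["B"]] / 2, Yp = to[["Y"]] / 2)
  slow <- max(1 / max(ra[["k_R"]] * to[["R"]], 1e-6),
              1 / max(ra[["k_B"]] * to[["B"]], 1e-6),
              1 / max(ra[["k_z"]] * to[["Z"]] + ra[["g_Y"]], 1e-6),
              1 / max(ra[["g_B"]], 1e-6))
  y <- integrate_cascade(y0, params, concentrations, dt = 10 * slow)
  # Newton polish with finite-difference Jacobian
  f <- function(y) unname(cascade_derivatives_fast(y, params, lt))
  for (it in seq_len(50)) {
    fy <- f(y)
    if (max(abs(fy)) < tol) break
    J <- matrix(0, 4, 4)
    h <- pmax(abs(y), 1e-3) * 1e-7
    for (j in 1:4) {
      yj <- y; yj[j] <- yj[j] + h[j]
      J[, j] <- (f(yj) - fy) / h[j]
    }
    step <- tryCatch(solve(J, fy), error = function(e) fy * 0)
    y <- clamp_state(cascade_state(y[1] - step[1], y[2] - step[2],
                                   y[3] - step[3], y[4] - step[4]), params)
  }
  if (max(abs(f(y))) >= sqrt(tol))
    stop("steady-state solver failed to converge", call. = FALSE)
  F <- rc$n_cluster * (rc$m_offset - rc$m_slope * y[["m"]] + lt)
  structure(y, activity = receptor_activity(F))
}

# internal: move a known steady state to other ligand concentrations by
# shifting the methylation level along the adapted manifold (closed form,
# valid because f_m is linear and adaptation is perfect). Returns NULL if the
# required methylation falls outside the configured range.
shift_adapted_state <- function(ss, params, concentrations) {
  rc <- params$receptor
  Fstar <- log(1 / attr(ss, "activity") - 1)
  m <- (rc$m_offset + ligand_terms(rc, concentrations) -
          Fstar / rc$n_cluster) / rc$m_slope
  clamped <- m < rc$m_range[1] || m > rc$m_range[2]
  m <- min(max(m, rc$m_range[1]), rc$m_range[2])
  out <- cascade_state(m, ss[["Ap"]], ss[["Bp"]], ss[["Yp"]])
  attr(out, "activity") <- attr(ss, "activity")
  attr(out, "clamped") <- clamped
  out
}

#' Scale all total protein concentrations
#'
#' Multiplies every total in `{A, B, R, Y, Z}` by `beta`, leaving rate
#' constants and the receptor spec untouched, and records the cumulative
#' scalar in the returned object's `beta` field. This is the mechanism for
#' emulating cell-to-cell variation in protein expression: all proteins are
#' scaled together because operon structure keeps their ratios approximately
#' constant.
#'
#' @param params An [cascade_params()] object.
#' @param beta Positive scalar multiple.
#' @return A new `rt_cascade_params` object.
#' @export
scale_protein_totals <- function(params, beta) {
  stopifnot(inherits(params, "rt_cascade_params"))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a positive scalar", call. = FALSE)
  params$totals <- params$totals * beta
  params$beta <- params$beta * beta
  params
}

#' Response of the cascade to a step change in ligand
#'
#' Starting from the steady state at `L_before`, the ligand concentration of
#' one species is switched to `L_after` and the CheY-P trajectory recorded.
#' `step_response()` returns the full diagnostic; `adaptation_time()` just
#' the recovery time: the first time after the post-step extremum at which
#' CheY-P comes back within a fraction `frac` (default 10 percent) of the gap
#' between that extremum and its final steady value. A zero-amplitude step
#' returns 0.
#'
#' @param params An [cascade_params()] object.
#' @param L_before,L_after Ligand concentrations (mM) before and after the
#'   step.
#' @param species Which species steps (`"meAsp"` or `"serine"`).
#' @param frac Recovery fraction defining the adaptation time.
#' @param t_max Horizon of the post-step integration (s).
#' @param dt_grid Output grid spacing (s).
#' @return `step_response()`: a list with `adaptation_time`, `amplitude`
#'   (|extremum - pre-step|, uM), `Yp_pre`, `Yp_extremum`, `Yp_final`, and the
#'   trajectory as a data frame `(time, m, Ap, Bp, Yp)`.
#'   `adaptation_time()`: the scalar time in seconds.
#' @export
step_response <- function(params, L_before, L_after, species = "meAsp",
                          frac = 0.1, t_max = 400, dt_grid = 0.02) {
  conc0 <- stats::setNames(L_before, species)
  conc1 <- stats::setNames(L_after, species)
  ss <- steady_state(params, conc0)
  if (L_before == L_after) {
    return(list(adaptation_time = 0, amplitude = 0, Yp_pre = ss[["Yp"]],
                Yp_extremum = ss[["Yp"]], Yp_final = ss[["Yp"]],
                trajectory = NULL))
  }
  lt <- ligand_terms(params$receptor, conc1)
  rhs <- function(t, y, parms) list(cascade_derivatives_fast(y, params, lt))
  tt <- seq(0, t_max, by = dt_grid)
  y0 <- cascade_state(ss[["m"]], ss[["Ap"]], ss[["Bp"]], ss[["Yp"]])
  out <- deSolve::lsoda(y0, tt, rhs, NULL, rtol = 1e-9, atol = 1e-11)
  Yp <- out[, "Yp"]
  Yp_final <- Yp[length(Yp)]
  i_ext <- which.max(abs(Yp - ss[["Yp"]]))
  Yp_ext <- Yp[i_ext]
  gap <- Yp_final - Yp_ext
  t_ad <- 0
  if (abs(gap) > 0) {
    # recovered once within frac*gap of the final level, past the extremum
    rec <- abs(Yp - Yp_final) <= frac * abs(gap)
    rec[seq_len(i_ext)] <- FALSE
    i_rec <- which(rec)[1]
    t_ad <- if (is.na(i_rec)) NA_real_ else tt[i_rec]
  }
  list(adaptation_time = t_ad,
       amplitude = abs(Yp_ext - ss[["Yp"]]),
       Yp_pre = ss[["Yp"]], Yp_extremum = Yp_ext, Yp_final = Yp_final,
       trajectory = as.data.frame(out))
}

#' @rdname step_response
#' @export
adaptation_time <- function(params, L_before, L_after, species = "meAsp",
                            frac = 0.1, t_max = 400) {
  step_response(params, L_before, L_after, species, frac, t_max)$adaptation_time
}

#' Logarithmic sensitivity of receptor activity to ligand
#'
#' The dimensionless gain `S = -d ln(Phi) / d ln([L])`, estimated by central
#' differences at the locally adapted operating point: the methylation level
#' is first set to its steady value for concentration `L` and then held fixed
#' while `L` is perturbed. `S` vanishes far below the inactive-state
#' dissociation constant (negligible occupancy) and far above the
#' active-state one (saturation), and is positive in between.
#'
#' @param params An [cascade_params()] object.
#' @param L Ligand concentration (mM, > 0).
#' @param species `"meAsp"` or `"serine"`.
#' @param rel_h Half-width of the central difference on the log axis.
#' @return The sensitivity estimate (dimensionless).
#' @export
sensitivity <- function(params, L, species = "meAsp", rel_h = 0.02) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0)
    stop("'L' must be a positive scalar concentration", call. = FALSE)
  rc <- params$receptor
  ss <- steady_state(params, stats::setNames(L, species))
  m <- ss[["m"]]
  lnPhi <- function(Lx) {
    F <- receptor_free_energy(rc, m, stats::setNames(Lx, species))
    log(receptor_activity(F))
  }
  -(lnPhi(L * exp(rel_h)) - lnPhi(L * exp(-rel_h))) / (2 * rel_h)
}

#' @export
print.rt_cascade_params <- function(x, ...) {
  cat("<cascade parameters> beta =", x$beta, "\n")
  cat("  totals (uM):",
      paste(sprintf("%s=%.4g", names(x$totals), x$totals), collapse = "  "), "\n")
  cat("  rates      :",
      paste(sprintf("%s=%.4g", names(x$rates), x$rates), collapse = "  "), "\n")
  cat("  receptor   : n =", x$receptor$n_cluster,
      sprintf("(Tar %.2g / Tsr %.2g), m in [%g, %g]\n",
              x$receptor$tar_fraction, x$receptor$tsr_fraction,
              x$receptor$m_range[1], x$receptor$m_range[2]))
  invisible(x)
}
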