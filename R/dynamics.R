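# Overdamped time integration.
#
# Node motion follows the overdamped Langevin equations with the
# stochastic force set to zero: C dx/dt = -grad E.  Explicit (forward)
# Euler is used; the trajectories of interest are quasi-static, so the
# step size is limited by stability rather than accuracy.

#' Integrator configuration
#'
#' @param dt time step.  The default keeps the per-step displacement well
#'   below the smallest spring rest length for the default parameter set.
#' @param max_steps step budget for [relax()].
#' @param force_tolerance per-node force magnitude below which the tissue
#'   counts as relaxed.
#' @param energy_check_every cadence (in steps) of the divergence check
#'   in [relax()].
#' @param safety_fraction a step moving any node farther than this
#'   fraction of the smallest spring rest length raises a stability
#'   error.
#' @param refresh_every cadence (in steps) at which [relax()] re-pairs
#'   adhesion springs and rebuilds the exclusion pair list.
#' @param clamp if TRUE, a node whose step displacement would exceed the
#'   safety limit is moved by the limit along its force direction
#'   instead of raising a stability error.  Off by default; the
#'   simulation driver enables it so that brief strong contacts (for
#'   example during mitotic rounding) do not force a globally small
#'   time step.
#' @param method `"euler"` for the physical overdamped dynamics, or
#'   `"fire"` for inertia-accelerated quasi-static equilibration (see
#'   [fire_relax()]); both descend the same energy and share its
#'   minima, but FIRE reaches them orders of magnitude faster.  The
#'   driver uses FIRE for shape scenarios without division, where only
#'   the equilibrium is of interest.
#' @return an `integrator_config` list.
#' @export
integrator_config <- function(dt = 0.002, max_steps = 20000L,
                              force_tolerance = 5e-3,
                              energy_check_every = 50L,
                              safety_fraction = 0.5,
                              refresh_every = 1L,
                              clamp = FALSE,
                              method = c("euler", "fire")) {
  stopifnot(dt > 0, max_steps >= 0, force_tolerance > 0,
            energy_check_every > 0, safety_fraction > 0, refresh_every >= 1)
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 force_tolerance = force_tolerance,
                 energy_check_every = as.integer(energy_check_every),
                 safety_fraction = safety_fraction,
                 refresh_every = as.integer(refresh_every),
                 clamp = isTRUE(clamp),
                 method = match.arg(method)),
            class = "integrator_config")
}

min_rest_length <- function(tis) {
  L0 <- tis$springs$L0[tis$springs$active & tis$springs$L0 > 0]
  if (!length(L0)) Inf else min(L0)
}

#' Advance the tissue by one time step
#'
#' Every mobile node moves by `dt * force / damping`; immobile nodes stay
#' put; the clock advances by `dt`.  Deterministic (the stochastic force
#' is zero).  Uses the cached interaction pair lists; call
#' [refresh_adhesion_pairs()] (or [relax()], which does so on a cadence)
#' to re-pair.
#'
#' @param tis tissue.
#' @param cfg [integrator_config()].
#' @param params parameter list.
#' @return the advanced tissue.
#' @export
step <- function(tis, cfg, params) {
  cf <- compute_forces(tis, params)
  tis <- cf$tis
  disp <- cf$forces * (cfg$dt / tis$damping)
  move <- tis$mobile & tis$alive
  dm <- sqrt(rowSums(disp[move, , drop = FALSE]^2))
  lim <- cfg$safety_fraction * min_rest_length(tis)
  if (max(dm) > lim) {
    if (cfg$clamp) {
      scale <- pmin(1, lim / pmax(dm, 1e-300))
      disp[move, ] <- disp[move, , drop = FALSE] * scale
    } else {
      stop(sprintf(paste0("stability error: displacement %.3g exceeds %.3g ",
                          "(%.0f%% of the smallest rest length); reduce dt"),
                   max(dm), lim, 100 * cfg$safety_fraction))
    }
  }
  tis$pos[move, ] <- tis$pos[move, , drop = FALSE] +
    disp[move, , drop = FALSE]
  tis$time <- tis$time + cfg$dt
  tis
}

#' Relax a tissue toward mechanical equilibrium
#'
#' Steps until the largest per-node force magnitude drops below
#' `cfg$force_tolerance` or `cfg$max_steps` is reached.  Interaction
#' pairs are refreshed every `cfg$refresh_every` steps.  If the total
#' energy increases over consecutive divergence checks, a stability
#' error is raised.
#'
#' @param tis tissue.
#' @param cfg [integrator_config()].
#' @param params parameter list.
#' @return the relaxed tissue; `tis$meta$relax_info` records the number
#'   of steps and which stopping criterion fired (`"force_tolerance"` or
#'   `"max_steps"`).
#' @export
relax <- function(tis, cfg, params) {
  e_prev <- Inf
  rising <- 0L
  steps_done <- 0L
  criterion <- "max_steps"
  for (s in seq_len(cfg$max_steps)) {
    if ((s - 1L) %% cfg$refresh_every == 0L) {
      tis <- refresh_adhesion_pairs(tis, params)
    }
    cf <- compute_forces(tis, params)
    tis <- cf$tis
    fmag <- sqrt(rowSums(cf$forces[tis$mobile & tis$alive, ,
                                   drop = FALSE]^2))
    if (!length(fmag) || max(fmag) < cfg$force_tolerance) {
      criterion <- "force_tolerance"
      break
    }
    disp <- cf$forces * (cfg$dt / tis$damping)
    move <- tis$mobile & tis$alive
    dm <- sqrt(rowSums(disp[move, , drop = FALSE]^2))
    lim <- cfg$safety_fraction * min_rest_length(tis)
    if (max(dm) > lim) {
      if (cfg$clamp) {
        scale <- pmin(1, lim / pmax(dm, 1e-300))
        disp[move, ] <- disp[move, , drop = FALSE] * scale
      } else {
        stop(sprintf("stability error: displacement %.3g exceeds %.3g; reduce dt",
                     max(dm), lim))
      }
    }
    tis$pos[move, ] <- tis$pos[move, , drop = FALSE] + disp[move, , drop = FALSE]
    tis$time <- tis$time + cfg$dt
    steps_done <- s
    if (s %% cfg$energy_check_every == 0L) {
      # the rise threshold sits above the floating-point noise of the
      # energy summation (~1e-11 on energies of order 10)
      if (cf$energy > e_prev + 1e-9 * (1 + abs(e_prev))) {
        rising <- rising + 1L
        if (rising >= 3L) {
          stop("stability error: energy increasing across consecutive checks")
        }
      } else rising <- 0L
      e_prev <- cf$energy
    }
  }
  tis$meta$relax_info <- list(steps = steps_done, criterion = criterion)
  tis
}


#' FIRE quasi-static equilibration
#'
#' Fast Inertial Relaxation Engine: gradient descent with adaptive
#' inertia, the standard accelerated minimizer for particle systems.
#' The forces are identical to those of the overdamped dynamics, so the
#' minima are the same; only the path and the (non-physical) step count
#' differ.  Used to equilibrate shape scenarios where the quasi-static
#' end state, not the transient, is of interest.
#'
#' @param tis tissue.
#' @param cfg [integrator_config()]; `dt` seeds the adaptive step.
#' @param params parameter list.
#' @param steps iteration budget.
#' @param max_disp hard cap on the per-iteration node displacement.
#' @return the relaxed tissue.
#' @export
fire_relax <- function(tis, cfg, params, steps, max_disp = 0.1) {
  v <- matrix(0, nrow(tis$pos), 2L)
  dt <- cfg$dt
  dt_max <- 10 * cfg$dt
  alpha <- 0.1
  n_pos <- 0L
  for (s in seq_len(steps)) {
    if ((s - 1L) %% cfg$refresh_every == 0L) {
      tis <- refresh_adhesion_pairs(tis, params)
    }
    cf <- compute_forces(tis, params)
    tis <- cf$tis
    if (nrow(v) < nrow(tis$pos)) {  # nodes added by remodeling
      v <- rbind(v, matrix(0, nrow(tis$pos) - nrow(v), 2L))
    }
    f <- cf$forces
    move <- tis$mobile & tis$alive
    P <- sum(v[move, ] * f[move, ])
    if (P > 0) {
      n_pos <- n_pos + 1L
      vn <- sqrt(sum(v[move, ]^2))
      fn <- sqrt(sum(f[move, ]^2))
      v[move, ] <- (1 - alpha) * v[move, , drop = FALSE] +
        alpha * vn * f[move, , drop = FALSE] / max(fn, 1e-12)
      if (n_pos > 5L) {
        dt <- min(dt * 1.1, dt_max)
        alpha <- alpha * 0.99
      }
    } else {
      v[] <- 0
      dt <- dt * 0.5
      alpha <- 0.1
      n_pos <- 0L
    }
    v[move, ] <- v[move, , drop = FALSE] + dt * f[move, , drop = FALSE]
    disp <- dt * v
    dmax <- sqrt(max(rowSums(disp[move, , drop = FALSE]^2)))
    if (dmax > max_disp) disp <- disp * (max_disp / dmax)
    tis$pos[move, ] <- tis$pos[move, , drop = FALSE] +
      disp[move, , drop = FALSE]
  }
  tis
}
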