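# Run configuration, scenario presets, the simulation driver, and
# snapshot input/output.

#' Construct a run configuration
#'
#' @param geometry list: `kind` ("flat" or "curved"), `n_columnar`,
#'   `n_squamous`, `cell_width`, `cell_height`, `curvature` (for
#'   curved), `nodes_per_edge`, `nucleus_nodes`, `nucleus_radius`.
#' @param params mechanical parameters, see [default_params()].
#' @param profiles list of [parameter_profile()] objects.
#' @param growth list: `enabled` flag and `params` from
#'   [growth_params()].
#' @param integrator an [integrator_config()].
#' @param schedule list: `steps`, `pair_every` (interaction re-pairing
#'   cadence), `growth_every` (growth/cycle update cadence),
#'   `remodel_every` (ECM remodeling cadence), `snapshot_every`, and
#'   `warmup_steps` (initial steps run at a quarter time step to absorb
#'   the contractile-activation transient; Euler mode only).
#' @param seed integer seed; mandatory when growth is enabled.
#' @param output_dir optional directory for snapshot output.
#' @return an `sce_config` object.
#' @export
sce_config <- function(geometry = list(), params = default_params(),
                       profiles = list(),
                       growth = list(enabled = FALSE,
                                     params = growth_params()),
                       integrator = integrator_config(),
                       schedule = list(), seed = 1L, output_dir = NULL) {
  geo <- utils::modifyList(list(
    kind = "flat", n_columnar = 20L, n_squamous = 5L,
    cell_width = 1, cell_height = 4, curvature = 0,
    nodes_per_edge = list(basal = 4L, lateral = 8L, apical = 4L),
    nucleus_nodes = 3L, nucleus_radius = 0.18), geometry)
  sch <- utils::modifyList(list(
    steps = 8000L, pair_every = 10L, growth_every = 5L,
    remodel_every = 100L, snapshot_every = 2000L,
    warmup_steps = 400L), schedule)
  cfg <- structure(list(geometry = geo, params = params,
                        profiles = profiles, growth = growth,
                        integrator = integrator, schedule = sch,
                        seed = seed, output_dir = output_dir),
                   class = "sce_config")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg an `sce_config`.
#' @return TRUE invisibly; stops with the offending field otherwise.
#' @export
validate_config <- function(cfg) {
  geo <- cfg$geometry
  if (!geo$kind %in% c("flat", "curved")) {
    stop("configuration error: geometry$kind must be 'flat' or 'curved'")
  }
  if (geo$n_columnar < 2) stop("configuration error: geometry$n_columnar")
  if (geo$cell_width <= 0) stop("configuration error: geometry$cell_width")
  if (geo$cell_height <= 0) stop("configuration error: geometry$cell_height")
  if (geo$kind == "curved" &&
      abs(geo$curvature) * geo$n_columnar * geo$cell_width >= 2 * pi) {
    stop("configuration error: geometry$curvature (arc self-overlaps)")
  }
  for (pr in cfg$profiles) {
    if (!inherits(pr, "parameter_profile")) {
      stop("configuration error: profiles must be parameter_profile objects")
    }
  }
  if (isTRUE(cfg$growth$enabled) &&
      (is.null(cfg$seed) || !is.finite(cfg$seed))) {
    stop("determinism error: a seed is mandatory when division is enabled")
  }
  sch <- cfg$schedule
  for (f in c("steps", "pair_every", "growth_every", "remodel_every",
              "snapshot_every")) {
    if (is.null(sch[[f]]) || sch[[f]] < 0) {
      stop("configuration error: schedule$", f)
    }
  }
  invisible(TRUE)
}

build_from_config <- function(cfg) {
  geo <- cfg$geometry
  if (geo$kind == "curved" && abs(geo$curvature) > 1e-12) {
    build_curved_tissue(geo$n_columnar, geo$curvature, geo$n_squamous,
                        geo$cell_width, geo$cell_height,
                        geo$nodes_per_edge, cfg$params,
                        geo$nucleus_nodes, geo$nucleus_radius)
  } else {
    build_flat_tissue(geo$n_columnar, geo$n_squamous, geo$cell_width,
                      geo$cell_height, geo$nodes_per_edge, cfg$params,
                      geo$nucleus_nodes, geo$nucleus_radius)
  }
}

#' Run a simulation
#'
#' Executes the schedule: every step the forces are evaluated and the
#' overdamped update applied; interaction pairs are re-paired every
#' `pair_every` steps; growth, cell-cycle, rounding and division
#' updates run every `growth_every` steps (when growth is enabled);
#' ECM remodeling every `remodel_every` steps; snapshots (with shape
#' metrics) every `snapshot_every` steps.  The run is fully
#' reproducible from (config, seed).
#'
#' @param cfg an [sce_config()].
#' @param quiet suppress per-snapshot log lines.
#' @return an `sce_run` list: `config`, final `tissue`, `snapshots`,
#'   `events`, and a `log` data frame (time, energy, cells, max
#'   force).
#' @export
run_simulation <- function(cfg, quiet = TRUE) {
  validate_config(cfg)
  set.seed(cfg$seed)
  params <- cfg$params
  icfg <- cfg$integrator
  sch <- cfg$schedule
  gon <- isTRUE(cfg$growth$enabled)
  gpar <- cfg$growth$params

  tis <- build_from_config(cfg)
  tis <- apply_profiles(tis, cfg$profiles, params)
  if (gon) {
    # initial growth-progress values are drawn mirror-symmetrically so
    # that a spatially homogeneous division rate gives a mirror-
    # symmetric division pattern; compartment differences then come
    # from the patterned cycle rate alone
    ids <- columnar_ids(tis)
    n <- length(ids)
    half <- (n + 1L) %/% 2L
    draws <- stats::runif(half, 0, gpar$gp0_max)
    gp0 <- draws[pmin(seq_len(n), n + 1L - seq_len(n))]
    for (k in seq_len(n)) {
      tis$cells[[ids[k]]]$gp0 <- gp0[k]
      tis$cells[[ids[k]]]$gp <- gp0[k]
    }
  }

  if (identical(icfg$method, "fire")) {
    if (gon) {
      stop("configuration error: FIRE equilibration cannot be combined ",
           "with division (growth needs the physical time axis)")
    }
    snapshots <- list(make_snapshot(tis, params))
    log <- data.frame(step = integer(), time = numeric(),
                      energy = numeric(), cells = integer(),
                      max_force = numeric())
    done <- 0L
    chunk0 <- if (sch$snapshot_every > 0L) sch$snapshot_every else
      sch$steps
    while (done < sch$steps) {
      chunk <- min(chunk0, sch$steps - done)
      tis <- fire_relax(tis, icfg, params, chunk)
      done <- done + chunk
      if (sch$remodel_every > 0L) {
        for (nm in names(tis$ecm)) tis <- remodel_ecm(tis, nm, params)
      }
      cf <- compute_forces(tis, params)
      tis <- cf$tis
      fmax <- sqrt(max(rowSums(
        cf$forces[tis$mobile & tis$alive, , drop = FALSE]^2)))
      ncell <- sum(vapply(tis$cells, function(c) c$type == "columnar",
                          logical(1L)))
      log <- rbind(log, data.frame(step = done, time = tis$time,
                                   energy = cf$energy, cells = ncell,
                                   max_force = fmax))
      if (!quiet) {
        message(sprintf("fire %d E=%.4g maxF=%.3g", done, cf$energy, fmax))
      }
      snapshots[[length(snapshots) + 1L]] <- make_snapshot(tis, params)
    }
    run <- structure(list(config = cfg, tissue = tis,
                          snapshots = snapshots, events = character(),
                          log = log),
                     class = "sce_run")
    if (!is.null(cfg$output_dir)) {
      write_snapshot(snapshots[[length(snapshots)]], cfg$output_dir)
      write_manifest(run, cfg$output_dir)
    }
    return(run)
  }

  # warmup: the freshly activated contractile springs are far from rest,
  # so the first few hundred steps run at a quarter of the time step to
  # absorb the initial transient
  if (sch$steps > 0L && !is.null(sch$warmup_steps) && sch$warmup_steps > 0L) {
    wcfg <- icfg
    wcfg$dt <- icfg$dt / 4
    for (s in seq_len(sch$warmup_steps)) {
      if ((s - 1L) %% sch$pair_every == 0L) {
        tis <- refresh_adhesion_pairs(tis, params)
      }
      tis <- step(tis, wcfg, params)
    }
  }
  events <- character()
  log <- data.frame(step = integer(), time = numeric(), energy = numeric(),
                    cells = integer(), max_force = numeric())
  snapshots <- list(make_snapshot(tis, params))

  steps <- sch$steps
  if (steps == 0L) {
    return(structure(list(config = cfg, tissue = tis,
                          snapshots = snapshots, events = events,
                          log = log),
                     class = "sce_run"))
  }
  for (s in seq_len(steps)) {
    if ((s - 1L) %% sch$pair_every == 0L) {
      tis <- refresh_adhesion_pairs(tis, params)
    }
    tis <- step(tis, icfg, params)
    if (gon && s %% sch$growth_every == 0L) {
      gu <- growth_update(tis, gpar, params, icfg$dt * sch$growth_every)
      tis <- gu$tis
      if (length(gu$events)) {
        events <- c(events, paste0("t=", signif(tis$time, 6), " ",
                                   gu$events))
        if (any(grepl("in_plane", gu$events))) {
          tis <- update_ap_positions(tis)
          tis <- apply_profiles(tis, cfg$profiles, params)
        }
      }
    }
    if (sch$remodel_every > 0L && s %% sch$remodel_every == 0L) {
      for (nm in names(tis$ecm)) tis <- remodel_ecm(tis, nm, params)
    }
    if (sch$snapshot_every > 0L && s %% sch$snapshot_every == 0L) {
      cf <- compute_forces(tis, params)
      tis <- cf$tis
      fmax <- sqrt(max(rowSums(
        cf$forces[tis$mobile & tis$alive, , drop = FALSE]^2)))
      ncell <- sum(vapply(tis$cells, function(c) c$type == "columnar",
                          logical(1L)))
      log <- rbind(log, data.frame(step = s, time = tis$time,
                                   energy = cf$energy, cells = ncell,
                                   max_force = fmax))
      if (!quiet) {
        message(sprintf("step %d t=%.2f E=%.4g cells=%d maxF=%.3g",
                        s, tis$time, cf$energy, ncell, fmax))
      }
      snapshots[[length(snapshots) + 1L]] <- make_snapshot(tis, params)
    }
  }
  if (sch$snapshot_every == 0L || steps %% sch$snapshot_every != 0L) {
    snapshots[[length(snapshots) + 1L]] <- make_snapshot(tis, params)
  }
  run <- structure(list(config = cfg, tissue = tis, snapshots = snapshots,
                        events = events, log = log),
                   class = "sce_run")
  if (!is.null(cfg$output_dir)) {
    write_snapshot(snapshots[[length(snapshots)]], cfg$output_dir)
    write_manifest(run, cfg$output_dir)
  }
  run
}

# ---------------------------------------------------------------------------
# Scenario presets

PRESET_NAMES <- c("control", "medial_contractility_ratio",
                  "medial_ecm_stiffening", "lateral_adhesion",
                  "basal_tension", "pressure_gradient",
                  "ccl_100", "ccl_400", "ccl_50", "prolif_only",
                  "prolif_plus_adhB", "prolif_plus_ecm",
                  "prolif_plus_apical")

#' Scenario presets
#'
#' Complete run configurations for the in-silico case studies:
#' \describe{
#' \item{control}{flat start, spatially uniform profiles with basal
#'   contractility dominant over apical; no division.  Evolves into a
#'   bent shape with near-uniform basal curvature.}
#' \item{medial_contractility_ratio}{apical contractility patterned
#'   (a, 1, a) and basal (1, a, 1) with a < 1: the medial
#'   apical-to-basal contractility ratio is raised, flattening the
#'   medial domain.}
#' \item{medial_ecm_stiffening}{regional ECM stiffness raised in the
#'   medial third.}
#' \item{lateral_adhesion}{cell-ECM adhesion raised in the lateral
#'   thirds.}
#' \item{basal_tension}{basal membrane rest length raised medially
#'   (lower basal tension, wider basal surface, shorter cells).}
#' \item{pressure_gradient}{target areas decreasing away from the
#'   center of the pouch.}
#' \item{ccl_100 / ccl_400 / ccl_50}{curved start with division
#'   enabled; posterior cell cycle length equal to, four times, or half
#'   the anterior one.}
#' \item{prolif_only}{posterior proliferation raised by half.}
#' \item{prolif_plus_adhB / prolif_plus_ecm / prolif_plus_apical}{on
#'   top of the posterior proliferation increase, posterior cell-ECM
#'   adhesion x1.5, posterior ECM stiffness x2, or posterior apical
#'   contractility x4.}
#' }
#'
#' @param name preset name.
#' @param seed run seed.
#' @param n_columnar tissue size (columnar cells).
#' @param steps schedule length override (NULL keeps the preset's
#'   default).
#' @return an [sce_config()].
#' @export
preset <- function(name, seed = 1L, n_columnar = 20L, steps = NULL) {
  if (!name %in% PRESET_NAMES) {
    stop("unknown preset '", name, "'; available: ",
         paste(PRESET_NAMES, collapse = ", "))
  }
  a <- 0.25
  shape_profiles <- switch(
    name,
    medial_contractility_ratio = list(
      parameter_profile("k_api_cont", c(a, 1, a), "thirds"),
      parameter_profile("k_bas_cont", c(1, a, 1), "thirds")),
    medial_ecm_stiffening = list(
      parameter_profile("k_ecm_c", c(1, 25, 1), "thirds")),
    lateral_adhesion = list(
      parameter_profile("k_adhB", c(2.5, 1, 2.5), "thirds")),
    basal_tension = list(
      parameter_profile("L0_memb_basal", c(1, 1.6, 1), "thirds")),
    pressure_gradient = list(
      parameter_profile("omega0", c(0.75, 1, 0.75), "thirds")),
    list())
  growth_profiles <- switch(
    name,
    ccl_400 = list(parameter_profile("delta", c(1, 0.25), "compartments")),
    ccl_50 = list(parameter_profile("delta", c(1, 2), "compartments")),
    prolif_only = list(parameter_profile("delta", c(1, 1.5),
                                         "compartments")),
    prolif_plus_adhB = list(
      parameter_profile("delta", c(1, 1.5), "compartments"),
      parameter_profile("k_adhB", c(1, 1.5), "compartments")),
    prolif_plus_ecm = list(
      parameter_profile("delta", c(1, 1.5), "compartments"),
      parameter_profile("k_ecm_c", c(1, 2), "compartments")),
    prolif_plus_apical = list(
      parameter_profile("delta", c(1, 1.5), "compartments"),
      parameter_profile("k_api_cont", c(1, 4), "compartments")),
    NULL)
  is_growth <- name %in% c("ccl_100", "ccl_400", "ccl_50", "prolif_only",
                           "prolif_plus_adhB", "prolif_plus_ecm",
                           "prolif_plus_apical")
  if (is_growth) {
    sce_config(
      geometry = list(kind = "curved", curvature = 0.05,
                      n_columnar = n_columnar),
      profiles = if (is.null(growth_profiles)) list() else growth_profiles,
      growth = list(enabled = TRUE,
                    params = growth_params(p_inplane = 1)),
      integrator = integrator_config(dt = 0.0025, clamp = TRUE),
      schedule = list(steps = if (is.null(steps)) 7200L else steps,
                      snapshot_every = 3600L),
      seed = seed)
  } else {
    # shape scenarios report quasi-static equilibria: FIRE equilibration
    sce_config(
      geometry = list(kind = "flat", n_columnar = n_columnar),
      profiles = shape_profiles,
      growth = list(enabled = FALSE, params = growth_params()),
      integrator = integrator_config(method = "fire", refresh_every = 10L),
      schedule = list(steps = if (is.null(steps)) 6000L else steps,
                      snapshot_every = 3000L),
      seed = seed)
  }
}

# ---------------------------------------------------------------------------
# Snapshots

#' Snapshot of the simulation state
#'
#' Tables for nodes, springs and cells plus the shape metrics of the
#' moment, suitable for delimited-text output.
#'
#' @param tis tissue.
#' @param params parameter list.
#' @param window curvature window.
#' @return an `sce_snapshot` list of data frames plus `time`.
#' @export
make_snapshot <- function(tis, params, window = 3L) {
  nodes <- data.frame(id = seq_len(nrow(tis$pos)), class = tis$class,
                      cell = tis$cellid, x = tis$pos[, 1L],
                      y = tis$pos[, 2L], mobile = tis$mobile,
                      alive = tis$alive)
  cells <- do.call(rbind, lapply(tis$cells, function(cc) {
    data.frame(id = cc$id, type = cc$type,
               compartment = ifelse(is.na(cc$compartment), "",
                                    cc$compartment),
               ap_position = cc$ap_position,
               omega = cell_area(tis, cc$id), omega0 = cc$omega0,
               gp = cc$gp, division_count = cc$division_count,
               mitotic = !is.null(cc$mitotic), suspended = cc$suspended,
               height = if (cc$type == "columnar")
                 cell_height(tis, cc$id) else NA_real_,
               db_bar = if (length(cc$nuc))
                 nuclear_position(tis, cc$id)$db_bar else NA_real_)
  }))
  sm <- shape_metrics(tis, window)
  curvature <- data.frame(position = sm$positions, kappa = sm$kappa,
                          kappa_norm = sm$normalized$kappa)
  structure(list(time = tis$time, nodes = nodes,
                 springs = tis$springs, cells = cells,
                 curvature = curvature),
            class = "sce_snapshot")
}

fmt_table <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  df
}

#' Write a snapshot as delimited text
#'
#' One tab-separated file per table plus a small JSON header; readable
#' by any external tool and by [read_snapshot()].
#'
#' @param snap an `sce_snapshot`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_snapshot <- function(snap, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("nodes", "springs", "cells", "curvature")) {
    utils::write.table(fmt_table(snap[[nm]]),
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(schema = "sce_snapshot/1", time = snap$time),
                       file.path(dir, "snapshot.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a snapshot written by [write_snapshot()]
#' @param dir snapshot directory.
#' @return an `sce_snapshot`.
#' @export
read_snapshot <- function(dir) {
  hdr_path <- file.path(dir, "snapshot.json")
  if (!file.exists(hdr_path)) stop("schema error: missing snapshot.json")
  hdr <- jsonlite::read_json(hdr_path)
  if (is.null(hdr$schema) || !identical(hdr$schema, "sce_snapshot/1")) {
    stop("schema error: unknown snapshot schema")
  }
  out <- list(time = as.numeric(hdr$time))
  for (nm in c("nodes", "springs", "cells", "curvature")) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) stop("schema error: missing table ", nm)
    out[[nm]] <- utils::read.table(f, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  }
  structure(out, class = "sce_snapshot")
}

write_manifest <- function(run, dir) {
  cfg <- run$config
  manifest <- list(
    schema = "sce_run/1",
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    steps = cfg$schedule$steps,
    final_time = run$tissue$time,
    package_version = as.character(utils::packageVersion("episce")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 17)),
             collapse = "\n")
  # small rolling hash; enough to detect config drift in a manifest
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}
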