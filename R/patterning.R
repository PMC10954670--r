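# Spatial parameter patterning along the anterior-posterior axis.
#
# Profiles are piecewise-constant multipliers of the base mechanical
# parameters, evaluated at each cell's normalized arc position
# l / L_AP in [-0.5, 0.5].  They survive tissue growth because cells
# re-evaluate their segment after every division.  The canonical
# perturbations pattern the apical contractility as (a, 1.0, a) and the
# basal contractility as (1.0, a, 1.0) over three equal thirds.

PROFILE_PARAMETERS <- c("k_api_cont", "k_bas_cont", "k_ecm_c", "k_adhB",
                        "k_memb_basal", "k_memb_lateral",
                        "L0_memb_basal", "L0_memb_lateral",
                        "omega0", "delta",
                        "intensity_apical", "intensity_basal")

#' Piecewise-constant spatial parameter profile
#'
#' @param parameter name of the parameter the profile scales; one of
#'   `"k_api_cont"`, `"k_bas_cont"`, `"k_ecm_c"`, `"k_adhB"`,
#'   `"k_memb_basal"`, `"k_memb_lateral"`, `"L0_memb_basal"`,
#'   `"L0_memb_lateral"`, `"omega0"`, `"delta"`, `"intensity_apical"`,
#'   `"intensity_basal"`.
#' @param values one multiplier per segment (relative to the base
#'   parameter value).
#' @param scheme `"thirds"` (three equal arc segments:
#'   lateral-medial-lateral), `"compartments"` (anterior | posterior),
#'   or `"breakpoints"` (explicit interior breakpoints in
#'   `[-0.5, 0.5]`).
#' @param breaks interior breakpoints for `scheme = "breakpoints"`.
#' @return a `parameter_profile` object.
#' @export
parameter_profile <- function(parameter, values,
                              scheme = c("thirds", "compartments",
                                         "breakpoints"),
                              breaks = NULL) {
  scheme <- match.arg(scheme)
  if (!parameter %in% PROFILE_PARAMETERS) {
    stop("configuration error: unknown profile parameter '", parameter,
         "'; known: ", paste(PROFILE_PARAMETERS, collapse = ", "))
  }
  breaks <- switch(scheme,
                   thirds = c(-1 / 6, 1 / 6),
                   compartments = 0,
                   breakpoints = sort(breaks))
  if (length(values) != length(breaks) + 1L) {
    stop("configuration error: profile '", parameter, "' needs ",
         length(breaks) + 1L, " values, got ", length(values))
  }
  if (!all(is.finite(values))) {
    stop("configuration error: non-finite profile values")
  }
  structure(list(parameter = parameter, scheme = scheme,
                 breaks = breaks, values = as.numeric(values)),
            class = "parameter_profile")
}

#' Evaluate a profile at a normalized position
#'
#' Piecewise-constant lookup.  A position exactly on a breakpoint is
#' assigned to the left segment; positions outside `[-0.5, 0.5]` are
#' clamped to the nearest segment with a warning.
#'
#' @param profile a [parameter_profile()].
#' @param ap_position normalized position(s) `l / L_AP`.
#' @return profile value(s).
#' @export
evaluate_profile <- function(profile, ap_position) {
  p <- ap_position
  out_of_range <- p < -0.5 | p > 0.5
  if (any(out_of_range)) {
    warning("position outside [-0.5, 0.5]; clamped to nearest segment")
    p <- pmin(pmax(p, -0.5), 0.5)
  }
  seg <- vapply(p, function(x) sum(x > profile$breaks), numeric(1L)) + 1L
  profile$values[seg]
}

#' Apply spatial profiles to a tissue
#'
#' Re-derives every profiled parameter from its base value times the
#' owning cell's (or ECM segment's) segment multiplier.  The operation
#' is idempotent: applying the same profile list twice yields identical
#' parameters.  Call again after divisions so daughters inherit by
#' position (done automatically by [run_simulation()]).
#'
#' @param tis tissue (with up-to-date `ap_position`s; see
#'   [update_ap_positions()]).
#' @param profiles list of [parameter_profile()] objects.
#' @param params parameter list.
#' @return the re-parameterized tissue.
#' @export
apply_profiles <- function(tis, profiles, params) {
  for (pr in profiles) {
    if (!inherits(pr, "parameter_profile")) {
      stop("configuration error: profiles must be parameter_profile objects")
    }
  }
  # reset factors, then collect per-cell multipliers
  for (k in seq_along(tis$cells)) tis$cells[[k]]$factors <- list()
  for (pr in profiles) {
    for (k in seq_along(tis$cells)) {
      cc <- tis$cells[[k]]
      if (cc$type != "columnar") next
      tis$cells[[k]]$factors[[pr$parameter]] <-
        evaluate_profile(pr, cc$ap_position)
    }
  }
  fac <- function(cell, name) {
    f <- tis$cells[[cell]]$factors[[name]]
    if (is.null(f)) 1 else f
  }

  sp <- tis$springs
  mitotic_ids <- vapply(tis$cells, function(c) {
    if (is.null(c$mitotic)) NA_integer_ else c$id
  }, integer(1L))
  mitotic_ids <- mitotic_ids[!is.na(mitotic_ids)]
  # contractile stiffness (mitotic cells keep their boosted constriction)
  for (role in c(ROLE_CONT_APICAL, ROLE_CONT_BASAL)) {
    name <- if (role == ROLE_CONT_APICAL) "k_api_cont" else "k_bas_cont"
    rows <- which(sp$role == role & !(sp$cell %in% mitotic_ids))
    if (length(rows)) {
      f <- vapply(sp$cell[rows], fac, numeric(1L), name = name)
      sp$k[rows] <- sp$k_base[rows] * f
    }
  }
  # membrane stiffness / rest length by edge membership
  memb_rows <- which(sp$role == ROLE_MEMBRANE & !is.na(sp$cell))
  if (length(memb_rows)) {
    for (k in seq_along(tis$cells)) {
      cc <- tis$cells[[k]]
      if (cc$type != "columnar") next
      rows <- memb_rows[sp$cell[memb_rows] == cc$id]
      if (!length(rows)) next
      in_basal <- sp$i[rows] %in% cc$basal & sp$j[rows] %in% cc$basal
      lat <- c(cc$lat_left, cc$lat_right,
               cc$basal[c(1L, length(cc$basal))],
               cc$apical[c(1L, length(cc$apical))])
      in_lat <- (sp$i[rows] %in% lat & sp$j[rows] %in% lat) & !in_basal
      sp$k[rows[in_basal]] <- sp$k_base[rows[in_basal]] *
        fac(cc$id, "k_memb_basal")
      sp$L0[rows[in_basal]] <- sp$L0_base[rows[in_basal]] *
        fac(cc$id, "L0_memb_basal")
      sp$k[rows[in_lat]] <- sp$k_base[rows[in_lat]] *
        fac(cc$id, "k_memb_lateral")
      sp$L0[rows[in_lat]] <- sp$L0_base[rows[in_lat]] *
        fac(cc$id, "L0_memb_lateral")
    }
  }
  # regional ECM stiffness (columnar chain): a stiffer matrix is stiffer
  # in both stretching and bending, so the profile scales the segment
  # springs and the chain's bending springs together
  pr_ecm <- Filter(function(p) p$parameter == "k_ecm_c", profiles)
  if (length(pr_ecm)) {
    pr <- pr_ecm[[length(pr_ecm)]]
    chain <- tis$ecm[["columnar"]]
    chain_id <- which(names(tis$ecm) == "columnar")
    xr <- range(tis$pos[chain$nodes, 1L])
    rows <- which(sp$role == ROLE_ECM_SEGMENT & sp$chain == chain_id)
    if (length(rows)) {
      mid <- (tis$pos[sp$i[rows], 1L] + tis$pos[sp$j[rows], 1L]) / 2
      l <- (mid - xr[1L]) / (xr[2L] - xr[1L]) - 0.5
      sp$k[rows] <- sp$k_base[rows] * evaluate_profile(pr, l)
    }
    bd <- tis$bends
    brows <- which(bd$chain == chain_id & !is.na(bd$chain))
    if (length(brows)) {
      l <- (tis$pos[bd$b[brows], 1L] - xr[1L]) / (xr[2L] - xr[1L]) - 0.5
      bd$k[brows] <- bd$k_base[brows] * evaluate_profile(pr, l)
      tis$bends <- bd
    }
  }
  tis$springs <- sp

  # per-cell scalar parameters
  for (k in seq_along(tis$cells)) {
    cc <- tis$cells[[k]]
    if (cc$type != "columnar") next
    f_om <- fac(cc$id, "omega0")
    base_om <- if (is.null(cc$omega0_base)) cc$omega0_init else cc$omega0_base
    grown <- cc$omega0 - cc$omega0_init  # growth offset accrued so far
    tis$cells[[k]]$omega0_base <- base_om
    tis$cells[[k]]$omega0_init <- base_om * f_om
    tis$cells[[k]]$omega0 <- base_om * f_om + max(0, grown)
    tis$cells[[k]]$delta_fac <- fac(cc$id, "delta")
    tis$cells[[k]]$intensity_apical <- fac(cc$id, "intensity_apical")
    tis$cells[[k]]$intensity_basal <- fac(cc$id, "intensity_basal")
  }
  # adhesion factors take effect at the next re-pairing
  tis <- refresh_adhesion_pairs(tis, params)
  tis <- allocate_all_contractile(tis, params)
  tis
}

#' Contractile spring allocation for one cell
#'
#' The number of apical and basal contractile springs of a non-mitotic
#' columnar cell depends on the cell height and the local actin
#' intensity: `n = round(intensity * H_available / spacing)` where
#' `H_available` is the lateral span above (below) the nucleus and
#' `spacing` is the nominal spring spacing.  Apical springs connect
#' laterally opposed node pairs strictly above the nucleus centroid,
#' basal springs strictly below; counts saturate at the discretization
#' limit.
#'
#' @param tis tissue.
#' @param id columnar cell id.
#' @param params parameter list.
#' @return list with `n_apical`, `n_basal` and the chosen spring row
#'   indices (`rows_apical`, `rows_basal`).
#' @export
allocate_contractile_springs <- function(tis, id, params) {
  cc <- tis$cells[[id]]
  ia <- max(0, min(1, cc$intensity_apical))
  ib <- max(0, min(1, cc$intensity_basal))
  nuc_y <- if (length(cc$nuc)) mean(tis$pos[cc$nuc, 2L]) else NA_real_
  sp <- tis$springs
  rows <- which(sp$role %in% c(ROLE_CONT_APICAL, ROLE_CONT_BASAL) &
                  sp$cell == id)
  if (!length(rows)) {
    return(list(n_apical = 0L, n_basal = 0L,
                rows_apical = integer(), rows_basal = integer()))
  }
  # heights measured along the apicobasal axis of the cell
  bc <- colMeans(tis$pos[cc$basal, , drop = FALSE])
  ac <- colMeans(tis$pos[cc$apical, , drop = FALSE])
  axis <- (ac - bc) / sqrt(sum((ac - bc)^2))
  lev <- ((tis$pos[sp$i[rows], 1L] + tis$pos[sp$j[rows], 1L]) / 2 - bc[1L]) *
    axis[1L] +
    ((tis$pos[sp$i[rows], 2L] + tis$pos[sp$j[rows], 2L]) / 2 - bc[2L]) *
    axis[2L]
  nuc_lev <- sum((colMeans(tis$pos[cc$nuc, , drop = FALSE]) - bc) * axis)
  margin <- tis$meta$geometry$nucleus_radius
  H <- sqrt(sum((ac - bc)^2))
  spacing <- params$contractile$spacing
  above <- rows[lev > nuc_lev + margin]
  below <- rows[lev < nuc_lev - margin]
  n_ap <- min(length(above), round(ia * (H - nuc_lev - margin) / spacing))
  n_ba <- min(length(below), round(ib * (nuc_lev - margin) / spacing))
  n_ap <- as.integer(max(0, n_ap)); n_ba <- as.integer(max(0, n_ba))
  # apical springs fill from the apical pole, basal from the basal pole
  sel_ap <- above[order(-lev[match(above, rows)])][seq_len(n_ap)]
  sel_ba <- below[order(lev[match(below, rows)])][seq_len(n_ba)]
  list(n_apical = n_ap, n_basal = n_ba,
       rows_apical = sel_ap, rows_basal = sel_ba)
}

#' Re-allocate interphase contractile springs for all columnar cells
#'
#' Applies [allocate_contractile_springs()] to every non-mitotic
#' columnar cell: the chosen springs become active at their patterned
#' stiffness and rest length; all other candidates are deactivated.
#' Mitotic cells are left alone (their constriction springs are managed
#' by the rounding update).
#'
#' @param tis tissue.
#' @param params parameter list.
#' @return updated tissue.
#' @export
allocate_all_contractile <- function(tis, params) {
  sp <- tis$springs
  for (cc in tis$cells) {
    if (cc$type != "columnar" || !is.null(cc$mitotic)) next
    alloc <- allocate_contractile_springs(tis, cc$id, params)
    rows <- which(sp$role %in% c(ROLE_CONT_APICAL, ROLE_CONT_BASAL) &
                    sp$cell == cc$id)
    sp$active[rows] <- FALSE
    on <- c(alloc$rows_apical, alloc$rows_basal)
    sp$active[on] <- TRUE
    sp$L0[on] <- sp$L0_base[on]
  }
  tis$springs <- sp
  tis$excl <- NULL
  tis
}
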