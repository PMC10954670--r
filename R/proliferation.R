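# Cell growth, mitotic rounding, interkinetic nuclear migration and
# division.
#
# Each columnar cell carries a growth progress gp in [0, 1): gp advances
# at rate delta (per unit time) unless the cell is suspended because a
# lateral neighbor is mitotic.  Crossing gp_mit starts mitotic rounding:
# apical contractile springs depolymerize, and a basal constriction
# front H0 ramps up from the basal point, progressively activating
# boosted constriction springs; the resulting basal squeeze pushes the
# nucleus apically (interkinetic nuclear migration emerges from the
# forces, the nucleus is never dragged).  At gp >= 1 the cell divides:
# with probability p_inplane the division plane is built from the
# centerline and two daughters enter the cross-section; otherwise the
# new cell leaves the plane and the remaining cell ramps its target
# area back down to the initial value.

#' Grow the target area of a cell
#'
#' Linear ramp `Omega0 <- min(Omega0 + epsilon * dt, Omega0_max)` with
#' `Omega0_max = omega0_max_factor * Omega0_init` (< 2x, because the
#' cross-section does not double even when the 3D volume does).
#'
#' @param tis tissue.
#' @param id cell id (must not be suspended).
#' @param gp growth parameters, see [growth_params()].
#' @param dt time increment.
#' @return updated tissue.
#' @export
grow_target_area <- function(tis, id, gp, dt) {
  cc <- tis$cells[[id]]
  cap <- gp$omega0_max_factor * cc$omega0_init
  tis$cells[[id]]$omega0 <- min(cc$omega0 + gp$epsilon * dt, cap)
  tis
}

neighbors_of <- function(tis, id) {
  ro <- tis$meta$row_order
  k <- match(id, ro)
  if (is.na(k)) return(integer())
  nb <- ro[c(k - 1L, k + 1L)]
  nb <- nb[!is.na(nb)]
  nb[vapply(nb, function(n) tis$cells[[n]]$type == "columnar", logical(1L))]
}

neighbor_mitotic <- function(tis, id) {
  any(vapply(neighbors_of(tis, id),
             function(n) !is.null(tis$cells[[n]]$mitotic), logical(1L)))
}

#' Advance the cell cycle of one cell
#'
#' Adds `delta * delta_fac * dt` to the growth progress unless the cell
#' is suspended or has exhausted its division budget.  Returns the phase
#' event: `"enter_rounding"` when gp first exceeds `gp_mit` (and no
#' lateral neighbor is mitotic), `"divide"` when a mitotic cell reaches
#' gp >= 1, otherwise `"none"`.
#'
#' @param tis tissue.
#' @param id cell id.
#' @param gp growth parameters.
#' @param dt time increment.
#' @return list `(tis, event)`.
#' @export
advance_cycle <- function(tis, id, gp, dt) {
  cc <- tis$cells[[id]]
  if (cc$division_count >= gp$max_divisions || cc$suspended) {
    return(list(tis = tis, event = "none"))
  }
  tis$cells[[id]]$gp <- cc$gp + gp$delta * cc$delta_fac * dt
  cc <- tis$cells[[id]]
  if (is.null(cc$mitotic) && cc$gp > gp$gp_mit && !neighbor_mitotic(tis, id)) {
    return(list(tis = tis, event = "enter_rounding"))
  }
  if (!is.null(cc$mitotic) && cc$gp >= 1) {
    return(list(tis = tis, event = "divide"))
  }
  list(tis = tis, event = "none")
}

# restore patterned stiffness on contractile candidates of a cell
set_contractile_k <- function(tis, id) {
  fac <- tis$cells[[id]]$factors
  f <- function(name) if (is.null(fac[[name]])) 1 else fac[[name]]
  sp <- tis$springs
  rows <- which(sp$role == ROLE_CONT_APICAL & sp$cell == id)
  sp$k[rows] <- sp$k_base[rows] * f("k_api_cont")
  rows <- which(sp$role == ROLE_CONT_BASAL & sp$cell == id)
  sp$k[rows] <- sp$k_base[rows] * f("k_bas_cont")
  tis$springs <- sp
  tis
}

#' Start mitotic rounding of a columnar cell
#'
#' Deactivates the apical contractile springs (actin depolymerization),
#' initializes the mitotic state with the basal point (mean of the
#' basal membrane node coordinates) and a constriction front at
#' `h0_init = 0`, and boosts the volume-exclusion coefficient of the
#' cell's nodes to keep tightly packed membranes from interpenetrating
#' while the cell rounds up.
#'
#' @param tis tissue.
#' @param id columnar, non-mitotic cell id.
#' @param gp growth parameters.
#' @param params parameter list.
#' @return updated tissue.
#' @export
enter_mitotic_rounding <- function(tis, id, gp, params) {
  cc <- tis$cells[[id]]
  if (cc$type != "columnar") {
    stop("state error: only columnar cells undergo mitotic rounding")
  }
  if (!is.null(cc$mitotic)) stop("state error: cell is already mitotic")
  basal_point <- colMeans(tis$pos[cc$basal, , drop = FALSE])
  tis$cells[[id]]$mitotic <- list(
    h0_init = 0, h_rate = gp$h_rate, h0_current = 0,
    basal_point = basal_point,
    boost_factor_contractile = gp$contractile_boost,
    boost_factor_exclusion = gp$exclusion_boost,
    omega0_postdiv = NA_real_)
  sp <- tis$springs
  sp$active[sp$role == ROLE_CONT_APICAL & sp$cell == id] <- FALSE
  sp$active[sp$role == ROLE_CONT_BASAL & sp$cell == id] <- FALSE
  tis$springs <- sp
  nodes <- c(cc$memb, cc$nuc)
  tis$emult[nodes] <- gp$exclusion_boost
  tis$excl <- NULL
  tis
}

#' Advance the basal constriction front of a mitotic cell
#'
#' Ramps `h0_current <- h0_init + h_rate * (elapsed rounding time)` and
#' activates every basal constriction spring whose two membrane nodes
#' both lie within `h0_current` of the basal point, at boosted stiffness
#' and a short mitotic rest length.  Once active a spring stays active,
#' so the active count is non-decreasing through rounding.
#'
#' @param tis tissue.
#' @param id mitotic cell id.
#' @param gp growth parameters.
#' @param params parameter list.
#' @param dt time increment.
#' @return updated tissue.
#' @export
update_rounding <- function(tis, id, gp, params, dt) {
  cc <- tis$cells[[id]]
  if (is.null(cc$mitotic)) stop("state error: cell is not mitotic")
  mit <- cc$mitotic
  mit$h0_current <- mit$h0_current + mit$h_rate * dt
  tis$cells[[id]]$mitotic <- mit
  sp <- tis$springs
  rows <- which(sp$role == ROLE_CONT_BASAL & sp$cell == id & !sp$active)
  if (length(rows)) {
    di <- sqrt((tis$pos[sp$i[rows], 1L] - mit$basal_point[1L])^2 +
                 (tis$pos[sp$i[rows], 2L] - mit$basal_point[2L])^2)
    dj <- sqrt((tis$pos[sp$j[rows], 1L] - mit$basal_point[1L])^2 +
                 (tis$pos[sp$j[rows], 2L] - mit$basal_point[2L])^2)
    on <- rows[pmax(di, dj) < mit$h0_current]
    if (length(on)) {
      fac <- cc$factors[["k_bas_cont"]]
      if (is.null(fac)) fac <- 1
      sp$active[on] <- TRUE
      sp$k[on] <- sp$k_base[on] * fac * mit$boost_factor_contractile
      sp$L0[on] <- params$contractile$L0_mitotic
      tis$springs <- sp
    }
  }
  tis
}

#' Division centerline of a cell
#'
#' The division plane is the centerline built from the midpoints of
#' laterally opposed node pairs, ordered basal to apical (with the
#' basal- and apical-edge midpoints as endpoints).  The planar spindle
#' orientation of wild-type columnar cells makes this the lateral
#' division plane.
#'
#' @param tis tissue.
#' @param id cell id.
#' @return list with `centerline` (matrix, basal to apical) and `pairs`
#'   (the lateral node id pairs used).
#' @export
construct_division_plane <- function(tis, id) {
  cc <- tis$cells[[id]]
  poly <- tis$pos[cc$memb, , drop = FALSE]
  if (!is_simple_polygon(poly)) {
    stop("geometry error: cell polygon self-intersects")
  }
  lp <- lat_pairs(cc)
  mids <- (tis$pos[lp[, 1L], , drop = FALSE] +
             tis$pos[lp[, 2L], , drop = FALSE]) / 2
  bmid <- basal_edge_midpoint(tis, cc$basal)
  amid <- basal_edge_midpoint(tis, rev(cc$apical))
  centerline <- unname(rbind(bmid, mids, amid))
  list(centerline = centerline, pairs = lp)
}

# arc-length midpoint of an ordered node chain
basal_edge_midpoint <- function(tis, ids) {
  v <- tis$pos[ids, , drop = FALSE]
  if (nrow(v) == 1L) return(v[1L, ])
  s <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
  half <- s[length(s)] / 2
  k <- findInterval(half, s)
  k <- min(k, nrow(v) - 1L)
  t <- if (s[k + 1L] > s[k]) (half - s[k]) / (s[k + 1L] - s[k]) else 0
  v[k, ] + t * (v[k + 1L, ] - v[k, ])
}

#' Divide a mitotic cell
#'
#' Draws from the run's random stream: with probability `p_inplane` the
#' division is in-plane and two daughters replace the parent (their
#' membranes are the parent's lateral walls plus the centerline shifted
#' slightly toward each side); otherwise the new cell leaves the
#' cross-section and the parent is reset with its target area ramping
#' back down to the initial value.  Both branches restore the
#' contractile spring constants, re-activate apical springs via the
#' standard allocation, clear the exclusion boost, draw fresh growth
#' progress, and increment the division count.
#'
#' @param tis tissue.
#' @param id mitotic cell id with gp >= 1.
#' @param gp growth parameters.
#' @param params parameter list.
#' @return list `(tis, outcome)` with outcome `"in_plane"` or
#'   `"out_of_plane"`.
#' @export
divide_cell <- function(tis, id, gp, params) {
  cc <- tis$cells[[id]]
  if (is.null(cc$mitotic)) stop("state error: cell is not mitotic")
  in_plane <- stats::runif(1) < gp$p_inplane
  if (in_plane &&
      !is_simple_polygon(tis$pos[cc$memb, , drop = FALSE])) {
    # a transiently self-intersecting membrane has no usable centerline;
    # the division is treated as out-of-plane (the new cell leaves the
    # cross-section) instead of constructing a degenerate plane
    in_plane <- FALSE
  }
  if (!in_plane) {
    tis$cells[[id]]$mitotic <- NULL
    tis$cells[[id]]$ramp_down <- TRUE
    tis$cells[[id]]$omega0_postdiv <- cc$omega0
    tis$cells[[id]]$gp0 <- stats::runif(1, 0, gp$gp0_max)
    tis$cells[[id]]$gp <- tis$cells[[id]]$gp0
    tis$cells[[id]]$division_count <- cc$division_count + 1L
    tis$emult[c(cc$memb, cc$nuc)] <- 1
    tis <- set_contractile_k(tis, id)
    tis <- allocate_all_contractile(tis, params)
    tis$excl <- NULL
    tis$meta$division_log <- rbind(
      tis$meta$division_log,
      data.frame(time = tis$time, parent = id, daughter = NA_integer_,
                 outcome = "out_of_plane", parent_area = cell_area(tis, id),
                 daughters_area = NA_real_))
    return(list(tis = tis, outcome = "out_of_plane"))
  }

  # ---- in-plane: build two daughters -------------------------------------
  off <- 0.17 * params$morse$mm$xi
  plane <- construct_division_plane(tis, id)
  lp <- plane$pairs
  m <- nrow(lp)
  Cmid <- plane$centerline[1L + seq_len(m), , drop = FALSE]
  bmid <- plane$centerline[1L, ]
  amid <- plane$centerline[m + 2L, ]

  unit_to <- function(from, to) {
    d <- to - from
    n <- sqrt(sum(d^2))
    if (n < 1e-12) c(0, 0) else d / n
  }
  dirL <- t(vapply(seq_len(m), function(j) {
    unit_to(Cmid[j, ], tis$pos[lp[j, 1L], ])
  }, numeric(2L)))
  CL <- Cmid + off * dirL
  CR <- Cmid - off * dirL

  B <- cc$basal; A <- cc$apical  # A is in cycle order (right to left)
  nb <- length(B); na_ <- length(A)
  split_chain <- function(ids) {
    n <- length(ids)
    if (n %% 2L == 1L) {
      mid <- (n + 1L) %/% 2L
      list(first = ids[seq_len(mid - 1L)], second = ids[(mid + 1L):n],
           dead = ids[mid])
    } else {
      list(first = ids[seq_len(n %/% 2L)], second = ids[(n %/% 2L + 1L):n],
           dead = integer())
    }
  }
  sb <- split_chain(B)    # first = left part, second = right part
  sa <- split_chain(A)    # first = right part, second = left part
  dirB <- unit_to(bmid, tis$pos[B[1L], ])
  dirA <- unit_to(amid, tis$pos[A[na_], ])
  bmidL <- bmid + off * dirB; bmidR <- bmid - off * dirB
  amidL <- amid + off * dirA; amidR <- amid - off * dirA

  dmp <- tis$meta$params_damping
  res <- add_nodes(tis, rbind(CL, bmidL, amidL, CR, bmidR, amidR),
                   NODE_MEMBRANE, cellid = id, damping = dmp$membrane)
  tis <- res$tis
  idCL <- res$idx[seq_len(m)]
  idbL <- res$idx[m + 1L]; idaL <- res$idx[m + 2L]
  idCR <- res$idx[m + 2L + seq_len(m)]
  idbR <- res$idx[2L * m + 3L]; idaR <- res$idx[2L * m + 4L]

  parent_area <- cell_area(tis, id)
  right_id <- length(tis$cells) + 1L

  membL <- c(sb$first, idbL, idCL, idaL, sa$second, cc$lat_left)
  membR <- c(idbR, sb$second, cc$lat_right, sa$first, idaR, rev(idCR))

  # deaths: dropped chain middles and the parent nucleus
  dead <- c(sb$dead, sa$dead, cc$nuc)
  tis$alive[dead] <- FALSE
  tis$cellid[dead] <- NA_integer_
  tis$mobile[dead] <- FALSE

  # strip the parent's springs, bends and contractile candidates
  tis$springs <- tis$springs[is.na(tis$springs$cell) |
                               tis$springs$cell != id, , drop = FALSE]
  tis$bends <- tis$bends[is.na(tis$bends$cell) |
                           tis$bends$cell != id, , drop = FALSE]
  # adhesion springs may reference dead nodes; drop them, re-pair below
  keep <- tis$alive[tis$springs$i] & tis$alive[tis$springs$j]
  tis$springs <- tis$springs[keep, , drop = FALSE]

  geo <- tis$meta$geometry
  make_daughter <- function(tis, did, memb, basal, lat_right, apical,
                            lat_left) {
    tis$cellid[memb] <- did
    ctr <- polygon_centroid(tis$pos[memb, , drop = FALSE])
    resn <- add_nodes(tis, nucleus_ring_coords(ctr, geo$nucleus_nodes,
                                               geo$nucleus_radius),
                      NODE_NUCLEUS, cellid = did, damping = dmp$nucleus)
    tis <- resn$tis
    rec <- new_cell_record(did, "columnar", memb = memb, nuc = resn$idx,
                           basal = basal, lat_right = lat_right,
                           apical = apical, lat_left = lat_left,
                           omega0 = cc$omega0_init)
    rec$omega0_base <- if (is.null(cc$omega0_base)) cc$omega0_init else
      cc$omega0_base
    rec$omega0_init <- rec$omega0_base
    # daughters are born with their created area as the momentary target
    # (the growth ramp then raises it); an instant jump to the class
    # target would kick the integrator with a large pressure force
    rec$omega0 <- min(abs(polygon_area(tis$pos[memb, , drop = FALSE])),
                      rec$omega0_init)
    rec$division_count <- cc$division_count + 1L
    rec$gp0 <- stats::runif(1, 0, gp$gp0_max)
    rec$gp <- rec$gp0
    rec$delta_fac <- cc$delta_fac
    rec$factors <- cc$factors
    rec$compartment <- cc$compartment
    rec$ap_position <- cc$ap_position
    tis$cells[[did]] <- rec
    tis <- add_membrane_cycle(tis, memb, did, params$membrane$k,
                              params$membrane$k_bend)
    # floor the rest lengths of freshly cut membranes so short slivers
    # near the offset corners do not dominate the stability guard
    rows <- which(tis$springs$role == ROLE_MEMBRANE & tis$springs$cell == did)
    tis$springs$L0[rows] <- pmax(tis$springs$L0[rows], 0.08)
    tis$springs$L0_base[rows] <- pmax(tis$springs$L0_base[rows], 0.08)
    tis <- add_contractile_candidates(tis, rec, params)
    tis <- set_contractile_k(tis, did)
    tis
  }

  tis <- make_daughter(tis, id, membL,
                       basal = c(sb$first, idbL), lat_right = idCL,
                       apical = c(idaL, sa$second), lat_left = cc$lat_left)
  tis <- make_daughter(tis, right_id, membR,
                       basal = c(idbR, sb$second), lat_right = cc$lat_right,
                       apical = c(sa$first, idaR), lat_left = rev(idCR))

  # clear the parent's exclusion boost from the daughters
  tis$emult[c(membL, membR,
              tis$cells[[id]]$nuc, tis$cells[[right_id]]$nuc)] <- 1

  ro <- tis$meta$row_order
  k <- match(id, ro)
  tis$meta$row_order <- append(ro, right_id, after = k)

  tis <- update_ap_positions(tis)
  tis <- refresh_adhesion_pairs(tis, params)
  tis <- allocate_all_contractile(tis, params)
  tis$excl <- NULL

  daughters_area <- cell_area(tis, id) + cell_area(tis, right_id)
  tis$meta$last_division <- list(parent_area = parent_area,
                                 daughters_area = daughters_area,
                                 ids = c(id, right_id))
  tis$meta$division_log <- rbind(
    tis$meta$division_log,
    data.frame(time = tis$time, parent = id, daughter = right_id,
               outcome = "in_plane", parent_area = parent_area,
               daughters_area = daughters_area))
  list(tis = tis, outcome = "in_plane")
}

#' Suspend cells whose lateral neighbor is mitotic
#'
#' Cell-cycle advancement is suspended while an immediate lateral
#' neighbor undergoes mitotic rounding (cells under high external
#' stress do not enter mitosis); the flag clears when the neighbor
#' completes division.
#'
#' @param tis tissue.
#' @return tissue with updated suspension flags.
#' @export
apply_neighbor_suspension <- function(tis) {
  for (cc in tis$cells) {
    if (cc$type != "columnar") next
    tis$cells[[cc$id]]$suspended <-
      is.null(cc$mitotic) && neighbor_mitotic(tis, cc$id)
  }
  tis
}

#' One growth/cycle update for the whole tissue
#'
#' Applies, in order: neighbor suspension, target-area growth or
#' post-division ramp-down, cell-cycle advance, mitotic-rounding entry
#' and update, and division, for every columnar cell.
#'
#' @param tis tissue.
#' @param gp growth parameters.
#' @param params parameter list.
#' @param dt time increment covered by this update.
#' @return list `(tis, events)` where events is a character vector of
#'   "<event>:<cell id>" entries.
#' @export
growth_update <- function(tis, gp, params, dt) {
  tis <- apply_neighbor_suspension(tis)
  ids <- vapply(tis$cells, `[[`, integer(1L), "id")
  types <- vapply(tis$cells, `[[`, character(1L), "type")
  events <- character()
  for (id in ids[types == "columnar"]) {
    cc <- tis$cells[[id]]
    if (isTRUE(cc$ramp_down)) {
      om <- max(cc$omega0 - gp$epsilon * dt, cc$omega0_init)
      tis$cells[[id]]$omega0 <- om
      if (om <= cc$omega0_init) tis$cells[[id]]$ramp_down <- FALSE
    } else if (!cc$suspended && cc$division_count < gp$max_divisions) {
      tis <- grow_target_area(tis, id, gp, dt)
    }
    adv <- advance_cycle(tis, id, gp, dt)
    tis <- adv$tis
    if (adv$event == "enter_rounding") {
      tis <- enter_mitotic_rounding(tis, id, gp, params)
      events <- c(events, paste0("enter_rounding:", id))
    }
    if (!is.null(tis$cells[[id]]$mitotic)) {
      tis <- update_rounding(tis, id, gp, params, dt)
    }
    if (adv$event == "divide") {
      dv <- divide_cell(tis, id, gp, params)
      tis <- dv$tis
      events <- c(events, paste0(dv$outcome, ":", id))
    }
  }
  list(tis = tis, events = events)
}
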