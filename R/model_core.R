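# Tissue construction: node/cell/ECM bookkeeping and initial geometries.
#
# A tissue is a list with class "sce_tissue" holding flat node arrays
# (positions plus per-node attributes), spring and bending-spring tables,
# a list of cell records, ECM chain descriptors and the simulation clock.
# Node classes: 1 = membrane, 2 = nucleus, 3 = ECM.  Dead nodes (removed
# by cell division) keep their slot but have alive = FALSE and take part
# in no interaction.

NODE_MEMBRANE <- 1L
NODE_NUCLEUS <- 2L
NODE_ECM <- 3L

ROLE_MEMBRANE <- 1L
ROLE_CONT_APICAL <- 2L
ROLE_CONT_BASAL <- 3L
ROLE_ADH_LATERAL <- 4L
ROLE_ADH_APICAL <- 5L
ROLE_ADH_BASAL <- 6L
ROLE_ECM_SEGMENT <- 7L

FORM_QUADRATIC <- 1L
FORM_COSINE <- 2L

# data.frame constructor without the deparse/row-name overhead of
# data.frame(); all columns must have equal length
fast_df <- function(...) {
  x <- list(...)
  n <- length(x[[1L]])
  for (k in seq_along(x)) if (length(x[[k]]) == 1L) x[[k]] <- rep(x[[k]], n)
  structure(x, class = "data.frame", row.names = .set_row_names(n))
}

empty_springs <- function() {
  data.frame(i = integer(), j = integer(), role = integer(),
             k_base = numeric(), k = numeric(),
             L0_base = numeric(), L0 = numeric(),
             active = logical(), cell = integer(), chain = integer())
}

empty_bends <- function() {
  data.frame(a = integer(), b = integer(), c = integer(), form = integer(),
             k_base = numeric(), k = numeric(), theta0 = numeric(),
             cell = integer(), chain = integer())
}

new_tissue <- function(params) {
  structure(list(
    pos = matrix(numeric(), 0L, 2L),
    class = integer(), cellid = integer(), damping = numeric(),
    mobile = logical(), emult = numeric(), alive = logical(),
    springs = empty_springs(), bends = empty_bends(),
    cells = list(),
    ecm = list(),
    excl = NULL,
    time = 0,
    meta = list(params_damping = params$damping)
  ), class = "sce_tissue")
}

add_nodes <- function(tis, xy, class, cellid = NA_integer_,
                      damping = 1, mobile = TRUE, emult = 1) {
  xy <- matrix(xy, ncol = 2L)
  n <- nrow(xy)
  idx <- nrow(tis$pos) + seq_len(n)
  tis$pos <- rbind(tis$pos, xy)
  tis$class <- c(tis$class, rep_len(class, n))
  tis$cellid <- c(tis$cellid, rep_len(cellid, n))
  tis$damping <- c(tis$damping, rep_len(damping, n))
  tis$mobile <- c(tis$mobile, rep_len(mobile, n))
  tis$emult <- c(tis$emult, rep_len(emult, n))
  tis$alive <- c(tis$alive, rep_len(TRUE, n))
  list(tis = tis, idx = idx)
}

# Membrane springs + bending triplets around a closed node cycle, with
# rest geometry taken from the current positions.
add_membrane_cycle <- function(tis, ids, cell_id, k, k_bend) {
  n <- length(ids)
  nxt <- c(ids[-1L], ids[1L])
  L <- sqrt(rowSums((tis$pos[nxt, , drop = FALSE] -
                       tis$pos[ids, , drop = FALSE])^2))
  tis$springs <- rbind(tis$springs, data.frame(
    i = ids, j = nxt, role = ROLE_MEMBRANE,
    k_base = k, k = k, L0_base = L, L0 = L,
    active = TRUE, cell = cell_id, chain = 0L))
  prv <- c(ids[n], ids[-n])
  th <- interior_angles(tis$pos, prv, ids, nxt)
  tis$bends <- rbind(tis$bends, data.frame(
    a = prv, b = ids, c = nxt, form = FORM_QUADRATIC,
    k_base = k_bend, k = k_bend, theta0 = th,
    cell = cell_id, chain = 0L))
  tis
}

# Rectangle-wall node coordinates in counterclockwise order starting at
# the basal-left corner; returns coordinates plus range index lists.
rect_wall_coords <- function(x0, y0, w, h, seg_basal, seg_lateral, seg_apical) {
  nb <- seg_basal + 1L; nl <- seg_lateral + 1L; na <- seg_apical + 1L
  fb <- seq(0L, seg_basal) / seg_basal
  fl <- seq(1L, seg_lateral - 1L) / seg_lateral
  fa <- seq(seg_apical, 0L) / seg_apical
  basal <- cbind(x0 + w * fb, rep(y0, nb))
  latR <- cbind(rep(x0 + w, length(fl)), y0 + h * fl)
  apical <- cbind(x0 + w * fa, rep(y0 + h, na))
  latL <- cbind(rep(x0, length(fl)), y0 + h * rev(fl))
  coords <- rbind(basal, latR, apical, latL)
  m <- length(fl)
  list(coords = coords,
       basal = seq_len(nb),
       lat_right = nb + seq_len(m),
       apical = nb + m + seq_len(na),
       lat_left = nb + m + na + seq_len(m))
}

new_cell_record <- function(id, type, memb, nuc, basal, lat_right, apical,
                            lat_left, omega0, k_vol = NA_real_) {
  list(id = id, type = type, k_vol = k_vol,
       memb = memb, nuc = nuc,
       basal = basal, lat_right = lat_right, apical = apical,
       lat_left = lat_left,
       omega0 = omega0, omega0_init = omega0,
       gp = 0, gp0 = 0, delta_fac = 1, suspended = FALSE,
       mitotic = NULL, division_count = 0L,
       compartment = NA_character_, ap_position = NA_real_,
       intensity_apical = 1, intensity_basal = 1,
       factors = list())
}

# Nucleus ring: small ring of nucleus nodes around a center point.  The
# ring is mirror-symmetric about the vertical axis through its center.
nucleus_ring_coords <- function(center, n_nodes, radius) {
  if (n_nodes == 1L) return(matrix(center, 1L, 2L))
  ang <- pi / 2 + 2 * pi * (seq_len(n_nodes) - 1L) / n_nodes
  cbind(center[1L] + radius * cos(ang), center[2L] + radius * sin(ang))
}

# Candidate contractile springs of a columnar cell: one lateral
# left-right node pair per interior lateral level.  Pairs above the
# nucleus center are apical candidates, pairs below are basal.  Which
# candidates are active in interphase is decided by
# allocate_contractile_springs().
add_contractile_candidates <- function(tis, cell, params) {
  lp <- lat_pairs(cell)
  # the basal- and apical-most pairs link the bottoms (tops) of the two
  # lateral sides through the corner nodes: contraction there shortens
  # the basal (apical) surface itself, not just the cell waist
  corners <- rbind(
    c(cell$basal[1L], cell$basal[length(cell$basal)]),
    c(cell$apical[length(cell$apical)], cell$apical[1L]))
  lp <- rbind(corners[1L, , drop = FALSE], lp, corners[2L, , drop = FALSE])
  if (nrow(lp) == 0L) return(tis)
  nuc_y <- if (length(cell$nuc)) mean(tis$pos[cell$nuc, 2L]) else
    mean(tis$pos[cell$memb, 2L])
  ylev <- (tis$pos[lp[, 1L], 2L] + tis$pos[lp[, 2L], 2L]) / 2
  role <- ifelse(ylev > nuc_y, ROLE_CONT_APICAL, ROLE_CONT_BASAL)
  k <- ifelse(role == ROLE_CONT_APICAL, params$contractile$k_apical,
              params$contractile$k_basal)
  L0 <- ifelse(role == ROLE_CONT_APICAL, params$contractile$L0_apical,
               params$contractile$L0_basal)
  tis$springs <- rbind(tis$springs, data.frame(
    i = lp[, 1L], j = lp[, 2L], role = role,
    k_base = k, k = k, L0_base = L0, L0 = L0,
    active = FALSE, cell = cell$id, chain = 0L))
  tis
}

#' Lateral node pairs of a cell
#'
#' Matrix of laterally opposed membrane node ids (left, right), ordered
#' basal to apical.  These are the anchor pairs for contractile springs
#' and the midpoint sources for the division centerline.
#' @param cell a cell record.
#' @return two-column integer matrix.
#' @keywords internal
lat_pairs <- function(cell) {
  l <- rev(cell$lat_left)   # stored top->bottom in cycle order
  r <- cell$lat_right       # stored bottom->top
  m <- min(length(l), length(r))
  cbind(left = l[seq_len(m)], right = r[seq_len(m)])
}

add_ecm_chain <- function(tis, xs, ys, spacing, params, theta0 = NULL) {
  res <- add_nodes(tis, cbind(xs, ys), NODE_ECM,
                   damping = tis$meta$params_damping$ecm)
  tis <- res$tis; ids <- res$idx
  n <- length(ids)
  i <- ids[-n]; j <- ids[-1L]
  L <- sqrt(rowSums((tis$pos[j, , drop = FALSE] -
                       tis$pos[i, , drop = FALSE])^2))
  chain_id <- length(tis$ecm) + 1L
  tis$springs <- rbind(tis$springs, data.frame(
    i = i, j = j, role = ROLE_ECM_SEGMENT,
    k_base = params$ecm$k, k = params$ecm$k, L0_base = L, L0 = L,
    active = TRUE, cell = NA_integer_, chain = chain_id))
  if (n >= 3L) {
    a <- ids[seq_len(n - 2L)]; b <- ids[seq_len(n - 2L) + 1L]
    c_ <- ids[seq_len(n - 2L) + 2L]
    th0 <- if (is.null(theta0)) rep(params$ecm$theta0, n - 2L) else
      interior_angles(tis$pos, a, b, c_)
    tis$bends <- rbind(tis$bends, data.frame(
      a = a, b = b, c = c_, form = FORM_COSINE,
      k_base = params$ecm$k_bend, k = params$ecm$k_bend, theta0 = th0,
      cell = NA_integer_, chain = chain_id))
  }
  tis$ecm[[chain_id]] <- list(nodes = ids,
                              tension_threshold = params$ecm$tension_threshold)
  list(tis = tis, chain = chain_id)
}

#' Build a flat epithelial cross-section
#'
#' Constructs a mirror-symmetric flat tissue: a row of columnar cells
#' (apical side up), a squamous layer above them, boundary cells capping
#' the two ends of the columnar row, an ECM chain under the columnar
#' basal surface and a second ECM chain over the squamous outer surface.
#' The outermost lateral nodes of the boundary cells are immobile and
#' anchor the tissue against rigid-body drift.
#'
#' @param n_columnar number of columnar cells (>= 2).
#' @param n_squamous number of squamous cells (>= 2); the default is odd
#'   so that no squamous cell wall sits exactly on the tissue midline
#'   (an odd layout keeps nearest-partner adhesion pairing free of
#'   midline ties, preserving mirror symmetry to machine precision).
#' @param cell_width,cell_height columnar cell dimensions (length units).
#' @param nodes_per_edge list with elements `basal`, `lateral`, `apical`:
#'   membrane segments per columnar cell edge.
#' @param params mechanical parameters, see [default_params()].
#' @param nucleus_nodes number of nucleus nodes per columnar cell (>= 1).
#' @param nucleus_radius radius of the nucleus node ring.
#' @return an `sce_tissue` object.
#' @export
build_flat_tissue <- function(n_columnar,
                              n_squamous = 2L * max(1L, n_columnar %/% 8L) + 1L,
                              cell_width = 1, cell_height = 4,
                              nodes_per_edge = list(basal = 4L, lateral = 8L,
                                                    apical = 4L),
                              params = default_params(),
                              nucleus_nodes = 3L, nucleus_radius = 0.18) {
  if (!is.numeric(n_columnar) || n_columnar < 2)
    stop("configuration error: n_columnar must be >= 2")
  if (!is.numeric(n_squamous) || n_squamous < 2)
    stop("configuration error: n_squamous must be >= 2")
  if (cell_width <= 0) stop("configuration error: cell_width must be > 0")
  if (cell_height <= 0) stop("configuration error: cell_height must be > 0")
  if (nucleus_nodes < 1) stop("configuration error: nucleus_nodes must be >= 1")
  n_columnar <- as.integer(n_columnar); n_squamous <- as.integer(n_squamous)

  w <- cell_width; h <- cell_height
  W <- n_columnar * w
  sb <- as.integer(nodes_per_edge$basal)
  sl <- as.integer(nodes_per_edge$lateral)
  sa <- as.integer(nodes_per_edge$apical)
  if (sb < 2 || sl < 2 || sa < 2)
    stop("configuration error: nodes_per_edge entries must be >= 2 segments")

  tis <- new_tissue(params)
  dmp <- params$damping

  # --- columnar cells -----------------------------------------------------
  for (i in seq_len(n_columnar)) {
    x0 <- w * (i - 1 - n_columnar / 2)
    rc <- rect_wall_coords(x0, 0, w, h, sb, sl, sa)
    id <- length(tis$cells) + 1L
    res <- add_nodes(tis, rc$coords, NODE_MEMBRANE, cellid = id,
                     damping = dmp$membrane)
    tis <- res$tis; ids <- res$idx
    ctr <- c(x0 + w / 2, h / 2)
    resn <- add_nodes(tis, nucleus_ring_coords(ctr, nucleus_nodes,
                                               nucleus_radius),
                      NODE_NUCLEUS, cellid = id, damping = dmp$nucleus)
    tis <- resn$tis
    cell <- new_cell_record(id, "columnar",
                            memb = ids, nuc = resn$idx,
                            basal = ids[rc$basal],
                            lat_right = ids[rc$lat_right],
                            apical = ids[rc$apical],
                            lat_left = ids[rc$lat_left],
                            omega0 = w * h,
                            k_vol = params$area$k_vol)
    tis$cells[[id]] <- cell
    tis <- add_membrane_cycle(tis, ids, id, params$membrane$k,
                              params$membrane$k_bend)
    tis <- add_contractile_candidates(tis, cell, params)
  }

  # --- boundary cells ------------------------------------------------------
  # half a cell wide: keeps the basal node grid commensurate with the
  # ECM node grid, so every basal adhesion spring is born at rest
  wb <- 0.5 * w
  for (side in c(-1, 1)) {
    x0 <- if (side < 0) -W / 2 - wb else W / 2
    rc <- rect_wall_coords(x0, 0, wb, h, 2L, sl, 2L)
    id <- length(tis$cells) + 1L
    res <- add_nodes(tis, rc$coords, NODE_MEMBRANE, cellid = id,
                     damping = dmp$membrane)
    tis <- res$tis; ids <- res$idx
    # boundary cells cap the row: stiffer than columnar cells so the
    # one-sided contraction of the last columnar cell does not make the
    # free ends curl much more than the interior
    kb_fac <- if (is.null(params$boundary_stiffness)) 1 else
      params$boundary_stiffness
    cell <- new_cell_record(id, "boundary",
                            memb = ids, nuc = integer(),
                            basal = ids[rc$basal],
                            lat_right = ids[rc$lat_right],
                            apical = ids[rc$apical],
                            lat_left = ids[rc$lat_left],
                            omega0 = wb * h,
                            k_vol = params$area$k_vol * kb_fac)
    tis$cells[[id]] <- cell
    tis <- add_membrane_cycle(tis, ids, id, params$membrane$k * kb_fac,
                              params$membrane$k_bend * kb_fac)
  }
  # No nodes are anchored: all forces are internal (pairwise or
  # shape-derived), so the net force and torque vanish and the tissue
  # neither drifts nor spins under the deterministic dynamics; anchoring
  # the ends would suppress the global bending mode.

  # --- squamous layer ------------------------------------------------------
  hs <- 0.6 * w
  gap_a <- params$adhesion$L0_apical
  ws <- W / n_squamous
  # even segment count puts a membrane node at each squamous cell center
  ssb <- 2L * max(1L, as.integer(round(ws / w)))
  for (i in seq_len(n_squamous)) {
    x0 <- ws * (i - 1 - n_squamous / 2)
    rc <- rect_wall_coords(x0, h + gap_a, ws, hs, ssb, 1L, ssb)
    id <- length(tis$cells) + 1L
    res <- add_nodes(tis, rc$coords, NODE_MEMBRANE, cellid = id,
                     damping = dmp$membrane)
    tis <- res$tis; ids <- res$idx
    # squamous polarity is inverted: apical surface faces the columnar
    # layer (bottom edge), basal surface faces the outer ECM (top edge)
    cell <- new_cell_record(id, "squamous",
                            memb = ids, nuc = integer(),
                            basal = rev(ids[rc$apical]),
                            lat_right = ids[rc$lat_right],
                            apical = ids[rc$basal],
                            lat_left = ids[rc$lat_left],
                            omega0 = ws * hs,
                            k_vol = params$area$k_vol)
    tis$cells[[id]] <- cell
    # the squamous (peripodial) layer is a thin, compliant epithelium:
    # its membranes are much softer than the columnar ones so it can
    # follow columnar-layer bending instead of bracing it
    ksq <- if (is.null(params$membrane$k_squamous)) params$membrane$k else
      params$membrane$k_squamous
    kbsq <- if (is.null(params$membrane$k_bend_squamous))
      params$membrane$k_bend else params$membrane$k_bend_squamous
    tis <- add_membrane_cycle(tis, ids, id, ksq, kbsq)
  }

  # --- ECM chains -----------------------------------------------------------
  g <- params$adhesion$L0_basal
  span <- W / 2 + wb
  # the ECM grid matches the basal membrane node spacing (and includes a
  # node exactly on the midline): every basal node starts with an ECM
  # node directly beneath it, and nearest-partner pairing has no
  # midline tie, preserving mirror symmetry exactly
  m <- 2L * as.integer(round(span / (0.25 * w))) + 1L
  xs <- ((seq_len(m) - 1L) - (m - 1L) / 2) * (2 * span / (m - 1L))
  res <- add_ecm_chain(tis, xs, rep(-g, m), 0.25 * w, params)
  tis <- res$tis
  names(tis$ecm)[res$chain] <- "columnar"
  ytop <- h + gap_a + hs + g
  m2 <- 2L * as.integer(round(span / (0.5 * w))) + 1L
  xs2 <- ((seq_len(m2) - 1L) - (m2 - 1L) / 2) * (2 * span / (m2 - 1L))
  res <- add_ecm_chain(tis, xs2, rep(ytop, m2), 0.5 * w, params)
  tis <- res$tis
  names(tis$ecm)[res$chain] <- "squamous"

  tis$meta$geometry <- list(kind = "flat", n_columnar = n_columnar,
                            n_squamous = n_squamous, cell_width = w,
                            cell_height = h,
                            nodes_per_edge = list(basal = sb, lateral = sl,
                                                  apical = sa),
                            nucleus_nodes = as.integer(nucleus_nodes),
                            nucleus_radius = nucleus_radius)
  tis$meta$row_order <- c(n_columnar + 1L, seq_len(n_columnar),
                          n_columnar + 2L)
  tis <- update_ap_positions(tis)
  tis <- allocate_all_contractile(tis, params)
  tis
}

#' Build a curved (pre-bent) cross-section
#'
#' Maps the flat construction onto a circular arc of the given signed
#' curvature using an area-preserving polar map: a point `(x, y)` of the
#' flat tissue (basal surface at `y = 0`) goes to radius
#' `r = sqrt(R^2 - 2*R*y)` and polar angle `x / R`, with `R = 1/curvature`.
#' Positive curvature bends the basal surface toward the apical side.
#' Spring rest lengths and rest angles are re-derived from the mapped
#' geometry, so the curved tissue is born near mechanical rest.
#'
#' @param curvature signed curvature of the basal surface (1/length).
#' @inheritParams build_flat_tissue
#' @return an `sce_tissue` object.
#' @export
build_curved_tissue <- function(n_columnar,
                                curvature,
                                n_squamous = 2L * max(1L, n_columnar %/% 8L) + 1L,
                                cell_width = 1, cell_height = 4,
                                nodes_per_edge = list(basal = 4L,
                                                      lateral = 8L,
                                                      apical = 4L),
                                params = default_params(),
                                nucleus_nodes = 3L, nucleus_radius = 0.18) {
  tis <- build_flat_tissue(n_columnar, n_squamous, cell_width, cell_height,
                           nodes_per_edge, params, nucleus_nodes,
                           nucleus_radius)
  if (abs(curvature) < 1e-12) return(tis)
  W <- n_columnar * cell_width + 1.2 * cell_width
  if (abs(curvature) * W >= 2 * pi)
    stop("configuration error: curvature too large, arc self-overlaps")
  R <- 1 / abs(curvature)
  ymax <- max(tis$pos[, 2L])
  if (R <= 2 * ymax * 1.05)
    stop("configuration error: curvature too large for tissue height")
  s <- sign(curvature)
  x <- tis$pos[, 1L]; y <- s * tis$pos[, 2L]
  r <- sqrt(R^2 - 2 * R * y)
  phi <- x / R
  tis$pos <- cbind(r * sin(phi), s * (R - r * cos(phi)))

  # re-derive rest geometry from the mapped configuration
  sp <- tis$springs
  recalc <- sp$role %in% c(ROLE_MEMBRANE, ROLE_ECM_SEGMENT)
  L <- sqrt(rowSums((tis$pos[sp$j[recalc], , drop = FALSE] -
                       tis$pos[sp$i[recalc], , drop = FALSE])^2))
  sp$L0_base[recalc] <- L; sp$L0[recalc] <- L
  tis$springs <- sp
  bd <- tis$bends
  bd$theta0 <- interior_angles(tis$pos, bd$a, bd$b, bd$c)
  tis$bends <- bd
  for (k in seq_along(tis$cells)) {
    cc <- tis$cells[[k]]
    tis$cells[[k]]$omega0 <- abs(polygon_area(tis$pos[cc$memb, , drop = FALSE]))
    tis$cells[[k]]$omega0_init <- tis$cells[[k]]$omega0
  }
  tis$meta$geometry$kind <- "curved"
  tis$meta$geometry$curvature <- curvature
  tis <- update_ap_positions(tis)
  tis
}

#' Normalized anterior-posterior positions of columnar cells
#'
#' Assigns each columnar cell its normalized arc position `l / L_AP` in
#' `[-0.5, 0.5]` along the columnar basal surface, and the compartment
#' label (`anterior` for `l < 0`, `posterior` otherwise).  Called after
#' construction and after every division so that daughters inherit their
#' parameters by position.
#' @param tis tissue.
#' @return the tissue with updated cell records.
#' @export
update_ap_positions <- function(tis) {
  colcells <- columnar_ids(tis)
  bp <- basal_polyline(tis)
  seglen <- sqrt(rowSums(diff(bp)^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  for (id in colcells) {
    cc <- tis$cells[[id]]
    ctr <- colMeans(tis$pos[cc$basal, , drop = FALSE])
    d2 <- (bp[, 1L] - ctr[1L])^2 + (bp[, 2L] - ctr[2L])^2
    l <- arc[which.min(d2)] / total - 0.5
    tis$cells[[id]]$ap_position <- l
    tis$cells[[id]]$compartment <-
      if (l < 0) "anterior" else "posterior"
  }
  tis
}

#' Columnar cell ids in row order (left to right)
#' @param tis tissue.
#' @return integer vector of cell ids.
#' @export
columnar_ids <- function(tis) {
  ids <- vapply(tis$cells, function(c) c$id, integer(1L))
  types <- vapply(tis$cells, function(c) c$type, character(1L))
  ids <- ids[types == "columnar"]
  ctr <- vapply(ids, function(id) {
    mean(tis$pos[tis$cells[[id]]$basal, 1L])
  }, numeric(1L))
  # order along the row; for curved tissues the basal x still increases
  # monotonically left to right
  ids[order(ctr)]
}

#' Current polygon area of a cell
#' @param tis tissue.
#' @param id cell id.
#' @return area (positive).
#' @export
cell_area <- function(tis, id) {
  abs(polygon_area(tis$pos[tis$cells[[id]]$memb, , drop = FALSE]))
}

#' Global tissue validity check
#'
#' Verifies that every cell polygon is simple, has positive
#' (counterclockwise) orientation and finite coordinates, that spring and
#' bending tables reference live nodes, and that the apical/basal/lateral
#' ranges partition each membrane cycle.
#' @param tis tissue.
#' @return TRUE invisibly; stops with a descriptive error otherwise.
#' @export
tissue_validate <- function(tis) {
  if (!all(is.finite(tis$pos[tis$alive, ]))) {
    stop("tissue invalid: non-finite node positions")
  }
  for (cc in tis$cells) {
    v <- tis$pos[cc$memb, , drop = FALSE]
    if (polygon_area(v) <= 0)
      stop(sprintf("tissue invalid: cell %d not counterclockwise", cc$id))
    if (!is_simple_polygon(v))
      stop(sprintf("tissue invalid: cell %d polygon self-intersects", cc$id))
    parts <- c(cc$basal, cc$lat_right, cc$apical, cc$lat_left)
    if (!setequal(parts, cc$memb) || length(parts) != length(cc$memb))
      stop(sprintf("tissue invalid: ranges of cell %d do not partition the membrane",
                   cc$id))
  }
  sp <- tis$springs
  if (nrow(sp) && !all(tis$alive[sp$i] & tis$alive[sp$j]))
    stop("tissue invalid: spring references a dead node")
  bd <- tis$bends
  if (nrow(bd) && !all(tis$alive[bd$a] & tis$alive[bd$b] & tis$alive[bd$c]))
    stop("tissue invalid: bending spring references a dead node")
  invisible(TRUE)
}
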