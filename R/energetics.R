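# Potential energies, forces, and interaction-pair bookkeeping.
#
# The node equations of motion are overdamped: each node class moves down
# the gradient of the summed potential energy, divided by its damping
# coefficient.  Nucleus nodes feel the nucleus-size Morse term and volume
# exclusion; membrane nodes feel membrane elasticity and bending, apical
# and basal contractility, volume exclusion, the area constraint and the
# three adhesion terms; ECM nodes feel ECM stretching and bending, volume
# exclusion, and cell-ECM adhesion.  The bookkeeping here routes each
# term to the right node classes; the heavy lifting is done by the
# compiled kernel.

#' Linear spring energy
#'
#' `E = 1/2 k (L - L0)^2`, the form shared by membrane elasticity,
#' all three adhesion types, actomyosin contractile springs and ECM
#' segments.
#'
#' @param k spring stiffness (>= 0).
#' @param length current spring length.
#' @param rest rest length.
#' @return energy (vectorized).
#' @export
spring_energy <- function(k, length, rest) {
  if (any(k < 0)) stop("parameter error: spring stiffness k must be >= 0")
  0.5 * k * (length - rest)^2
}

#' Bending spring energy
#'
#' Quadratic form `1/2 k (theta - theta0)^2` (cell membranes) or cosine
#' form `k (1 - cos(theta - theta0))` (ECM chains), where `theta` is the
#' interior angle at the middle node of the triplet.
#'
#' @param triplet 3 x 2 matrix of node positions (a, b, c); the angle is
#'   measured at b.
#' @param k bending stiffness.
#' @param theta0 rest angle (radians).
#' @param form `"quadratic"` or `"cosine"`.
#' @return energy.
#' @export
bending_energy <- function(triplet, k, theta0,
                           form = c("quadratic", "cosine")) {
  form <- match.arg(form)
  tri <- as.matrix(triplet)
  th <- interior_angle(tri[1L, ], tri[2L, ], tri[3L, ])
  d <- atan2(sin(th - theta0), cos(th - theta0))
  if (form == "quadratic") 0.5 * k * d^2 else k * (1 - cos(d))
}

#' Morse volume-exclusion energy
#'
#' `E(d) = U exp(-d/xi) - W exp(-d/gamma)`, truncated at the cutoff and
#' shifted by its cutoff value so the truncated potential is continuous.
#' Returns exactly 0 at and beyond the cutoff.
#'
#' @param p a [morse_params()] object.
#' @param distance node-pair distance (vectorized, >= 0).
#' @return energy.
#' @export
morse_energy <- function(p, distance) {
  stopifnot(inherits(p, "morse_params"), all(distance >= 0))
  e <- p$U * exp(-distance / p$xi) - p$W * exp(-distance / p$gamma) - p$shift
  e[distance >= p$cutoff] <- 0
  e
}

#' Area (2D volume) constraint energy
#'
#' `E_vol = k_vol (Omega - Omega0)^2` (no 1/2 prefactor), enforcing
#' conservation of the cytoplasmic cross-sectional area.
#'
#' @param area current polygon area `Omega` (> 0).
#' @param omega0 target area `Omega0`.
#' @param k_vol constraint strength.
#' @return energy.
#' @export
area_energy <- function(area, omega0, k_vol) {
  if (any(area <= 0))
    stop("geometry error: degenerate polygon, non-positive area")
  k_vol * (area - omega0)^2
}

# ---------------------------------------------------------------------------
# Interaction-pair bookkeeping

# Morse interaction class of a node pair, given node classes and cell ids.
# Returns one of "mm", "nm", "nn", "nx", "me", "ne" or NA (no interaction).
pair_class <- function(cl_i, cl_j, cell_i, cell_j, params) {
  same <- !is.na(cell_i) & !is.na(cell_j) & cell_i == cell_j
  out <- rep(NA_character_, length(cl_i))
  mm <- cl_i == NODE_MEMBRANE & cl_j == NODE_MEMBRANE
  out[mm & !same] <- "mm"
  if (isTRUE(params$same_cell_membrane_exclusion)) out[mm & same] <- "mm"
  nm <- (cl_i == NODE_NUCLEUS & cl_j == NODE_MEMBRANE) |
    (cl_i == NODE_MEMBRANE & cl_j == NODE_NUCLEUS)
  out[nm] <- "nm"
  nn <- cl_i == NODE_NUCLEUS & cl_j == NODE_NUCLEUS
  out[nn & same] <- "nn"
  if (isTRUE(params$nucleus_cross_cell)) out[nn & !same] <- "nx"
  me <- (cl_i == NODE_MEMBRANE & cl_j == NODE_ECM) |
    (cl_i == NODE_ECM & cl_j == NODE_MEMBRANE)
  out[me] <- "me"
  ne <- (cl_i == NODE_NUCLEUS & cl_j == NODE_ECM) |
    (cl_i == NODE_ECM & cl_j == NODE_NUCLEUS)
  out[ne] <- "ne"
  out
}

#' Build the volume-exclusion pair list
#'
#' Finds all node pairs of eligible interaction classes within each
#' class's Morse cutoff plus a skin margin (so the list remains valid
#' between periodic rebuilds while node displacements stay below the
#' skin).  Pairs already connected by an active spring are excluded, as
#' are membrane pairs within the same cell (configurable).
#'
#' @param tis tissue.
#' @param params parameter list (see [default_params()]).
#' @return data frame of pairs with per-pair Morse coefficients; the
#'   repulsion coefficient `U` carries the volume-exclusion boost of
#'   mitotic cells.
#' @export
find_exclusion_pairs <- function(tis, params) {
  alive <- which(tis$alive)
  pos <- tis$pos
  skin <- params$exclusion_skin
  rc <- max(vapply(params$morse, function(p) p$cutoff, numeric(1L))) + skin

  # sweep along x: candidate pairs within rc in x
  ordx <- alive[order(pos[alive, 1L])]
  xs <- pos[ordx, 1L]
  n <- length(ordx)
  hi <- findInterval(xs + rc, xs)
  cnt <- hi - seq_len(n)
  if (sum(cnt) == 0L) return(empty_excl())
  I <- rep.int(seq_len(n), cnt)
  J <- sequence(cnt) + I
  i <- ordx[I]; j <- ordx[J]

  dx <- pos[i, 1L] - pos[j, 1L]; dy <- pos[i, 2L] - pos[j, 2L]
  d2 <- dx * dx + dy * dy
  keep <- d2 <= rc * rc
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(empty_excl())

  pcl <- pair_class(tis$class[i], tis$class[j],
                    tis$cellid[i], tis$cellid[j], params)
  keep <- !is.na(pcl)
  i <- i[keep]; j <- j[keep]; pcl <- pcl[keep]
  if (!length(i)) return(empty_excl())

  # per-class range filter
  cuts <- vapply(params$morse, function(p) p$cutoff, numeric(1L))[pcl] + skin
  d2 <- (pos[i, 1L] - pos[j, 1L])^2 + (pos[i, 2L] - pos[j, 2L])^2
  keep <- d2 <= cuts * cuts
  i <- i[keep]; j <- j[keep]; pcl <- pcl[keep]
  if (!length(i)) return(empty_excl())

  # drop pairs already connected by an active spring
  sp <- tis$springs
  if (nrow(sp)) {
    act <- sp$active
    N <- nrow(tis$pos)
    skey <- pmin(sp$i[act], sp$j[act]) * (N + 1) + pmax(sp$i[act], sp$j[act])
    pkey <- pmin(i, j) * (N + 1) + pmax(i, j)
    keep <- !(pkey %in% skey)
    i <- i[keep]; j <- j[keep]; pcl <- pcl[keep]
  }
  if (!length(i)) return(empty_excl())

  mp <- params$morse
  U <- unname(vapply(mp, `[[`, numeric(1L), "U")[pcl])
  W <- unname(vapply(mp, `[[`, numeric(1L), "W")[pcl])
  xi <- unname(vapply(mp, `[[`, numeric(1L), "xi")[pcl])
  ga <- unname(vapply(mp, `[[`, numeric(1L), "gamma")[pcl])
  cut <- unname(vapply(mp, `[[`, numeric(1L), "cutoff")[pcl])
  boost <- pmax(tis$emult[i], tis$emult[j])
  Ub <- U * boost
  fast_df(i = i, j = j, class = pcl,
          U = Ub, W = W, xi = xi, gamma = ga,
          cutoff = cut,
          shift = Ub * exp(-cut / xi) - W * exp(-cut / ga))
}

empty_excl <- function() {
  data.frame(i = integer(), j = integer(), class = character(),
             U = numeric(), W = numeric(), xi = numeric(),
             gamma = numeric(), cutoff = numeric(), shift = numeric())
}

# Nearest-partner pairing between a set of source nodes and target
# nodes; returns data.frame(src, tgt) for sources with a target within
# max_range.  Exact distance ties (which occur on the symmetric built
# lattice) are broken by a mirror-symmetric rule so that pairing never
# injects asymmetry: prefer the target whose owning cell's center is
# closer to the source (for coincident corner nodes of adjacent cells),
# then the target closer to the tissue midline (for targets straddling
# a source, e.g. ECM nodes around a basal node).
nearest_within <- function(pos, src, tgt, max_range,
                           src_cell_cx = NULL, tgt_cell_cx = NULL) {
  if (!length(src) || !length(tgt)) {
    return(fast_df(src = integer(), tgt = integer()))
  }
  d2 <- outer(pos[src, 1L], pos[tgt, 1L], "-")^2 +
    outer(pos[src, 2L], pos[tgt, 2L], "-")^2
  if (is.null(tgt_cell_cx)) {
    key_cell <- outer(rep(1, length(src)), abs(pos[tgt, 1L]))
  } else if (is.null(src_cell_cx)) {
    key_cell <- abs(outer(pos[src, 1L], tgt_cell_cx, "-"))
  } else {
    key_cell <- abs(outer(src_cell_cx, tgt_cell_cx, "-"))
  }
  key_mid <- outer(rep(1, length(src)), abs(pos[tgt, 1L]))
  score <- d2 + 1e-9 * key_cell + 1e-12 * key_mid
  best <- max.col(-score, ties.method = "first")
  bd2 <- d2[cbind(seq_along(src), best)]
  keep <- bd2 <= max_range^2
  fast_df(src = src[keep], tgt = tgt[best][keep])
}

#' Rebuild adhesion springs by nearest-neighbor pairing
#'
#' Re-derives all adhesion springs from the current geometry: each basal
#' membrane node of a columnar (squamous) cell pairs with its nearest
#' node of the corresponding ECM chain within `max_range` (Integrin,
#' `k_adhB`); lateral membrane nodes of adjacent cells in the columnar
#' row pair with the nearest lateral node of the neighbor (E-cadherin,
#' `k_adhL`); columnar apical nodes pair with the nearest squamous
#' apical node (`k_adhA`).  Pairs beyond `max_range` dissolve.  Cell-ECM
#' stiffness carries the cell's `k_adhB` profile factor.
#'
#' @param tis tissue.
#' @param params parameter list.
#' @return tissue with refreshed adhesion springs.
#' @export
refresh_adhesion_pairs <- function(tis, params) {
  sp <- tis$springs
  # Integrin-mediated cell-ECM adhesions are long-lived: existing basal
  # pairs persist (so the ECM is mechanically coupled to the basal
  # surface instead of slipping along it) and dissolve only beyond
  # max_range; E-cadherin (lateral) and columnar-squamous (apical)
  # adhesion re-pairs by nearest neighbor, which lets cells slide
  # along each other during growth and rounding.
  adh <- params$adhesion
  keep_basal <- sp$role == ROLE_ADH_BASAL
  if (any(keep_basal)) {
    d <- sqrt(rowSums((tis$pos[sp$j[keep_basal], , drop = FALSE] -
                         tis$pos[sp$i[keep_basal], , drop = FALSE])^2))
    ok <- d <= adh$max_range &
      tis$alive[sp$i[keep_basal]] & tis$alive[sp$j[keep_basal]]
    keep_basal[keep_basal] <- ok
  }
  basal_kept <- sp[keep_basal, , drop = FALSE]
  sp <- sp[!(sp$role %in% c(ROLE_ADH_LATERAL, ROLE_ADH_APICAL,
                            ROLE_ADH_BASAL)), , drop = FALSE]

  adhB_fac <- vapply(tis$cells, function(c) {
    f <- c$factors[["k_adhB"]]
    if (is.null(f)) 1 else f
  }, numeric(1L))
  fac_of <- function(cells) {
    out <- adhB_fac[cells]
    out[is.na(out)] <- 1
    out
  }
  if (nrow(basal_kept)) {  # persistent pairs track their profile factor
    basal_kept$k <- basal_kept$k_base * fac_of(basal_kept$cell)
  }
  add <- list(basal_kept)

  # --- basal: membrane <-> ECM -------------------------------------------
  for (chain_name in c("columnar", "squamous")) {
    chain <- tis$ecm[[chain_name]]
    if (is.null(chain)) next
    cells <- Filter(function(c) c$type == chain_name ||
                      (chain_name == "columnar" && c$type == "boundary"),
                    tis$cells)
    src <- unlist(lapply(cells, `[[`, "basal"), use.names = FALSE)
    src <- setdiff(src, basal_kept$i)  # only unpaired nodes seek a partner
    hit <- nearest_within(tis$pos, src, chain$nodes, adh$max_range)
    if (nrow(hit)) {
      kfac <- fac_of(tis$cellid[hit$src])
      add[[length(add) + 1L]] <- fast_df(
        i = hit$src, j = hit$tgt, role = ROLE_ADH_BASAL,
        k_base = adh$k_basal, k = adh$k_basal * kfac,
        L0_base = adh$L0_basal, L0 = adh$L0_basal,
        active = TRUE, cell = tis$cellid[hit$src], chain = 0L)
    }
  }

  # --- lateral: adjacent cells in the columnar row -------------------------
  ro <- tis$meta$row_order
  lat_sets <- c(
    lapply(seq_len(length(ro) - 1L), function(k) {
      a <- tis$cells[[ro[k]]]; b <- tis$cells[[ro[k + 1L]]]
      list(a = c(a$lat_right,
                 a$basal[length(a$basal)], a$apical[1L]),
           b = c(b$lat_left, b$basal[1L],
                 b$apical[length(b$apical)]))
    }),
    local({
      sq <- tis$meta$squamous_order
      if (is.null(sq) || length(sq) < 2L) return(list())
      lapply(seq_len(length(sq) - 1L), function(k) {
        a <- tis$cells[[sq[k]]]; b <- tis$cells[[sq[k + 1L]]]
        list(a = a$lat_right, b = b$lat_left)
      })
    })
  )
  for (pairset in lat_sets) {
    h1 <- nearest_within(tis$pos, pairset$a, pairset$b, adh$max_range)
    h2 <- nearest_within(tis$pos, pairset$b, pairset$a, adh$max_range)
      ii <- c(pmin(h1$src, h1$tgt), pmin(h2$src, h2$tgt))
    jj <- c(pmax(h1$src, h1$tgt), pmax(h2$src, h2$tgt))
    keep <- !duplicated(ii * (nrow(tis$pos) + 1) + jj)
    hit <- fast_df(i = ii[keep], j = jj[keep])
    if (nrow(hit)) {
      add[[length(add) + 1L]] <- fast_df(
        i = hit$i, j = hit$j, role = ROLE_ADH_LATERAL,
        k_base = adh$k_lateral, k = adh$k_lateral,
        L0_base = adh$L0_lateral, L0 = adh$L0_lateral,
        active = TRUE, cell = NA_integer_, chain = 0L)
    }
  }

  # --- apical: columnar <-> squamous ---------------------------------------
  colc <- Filter(function(c) c$type == "columnar", tis$cells)
  sqc <- Filter(function(c) c$type == "squamous", tis$cells)
  src <- unlist(lapply(colc, `[[`, "apical"), use.names = FALSE)
  tgt <- unlist(lapply(sqc, `[[`, "apical"), use.names = FALSE)
  sq_cx <- vapply(sqc, function(c) mean(tis$pos[c$memb, 1L]), numeric(1L))
  names(sq_cx) <- vapply(sqc, `[[`, integer(1L), "id")
  col_cx <- vapply(colc, function(c) mean(tis$pos[c$memb, 1L]), numeric(1L))
  names(col_cx) <- vapply(colc, `[[`, integer(1L), "id")
  hit <- nearest_within(tis$pos, src, tgt, adh$max_range,
                        src_cell_cx = col_cx[as.character(tis$cellid[src])],
                        tgt_cell_cx = sq_cx[as.character(tis$cellid[tgt])])
  if (nrow(hit)) {
    add[[length(add) + 1L]] <- fast_df(
      i = hit$src, j = hit$tgt, role = ROLE_ADH_APICAL,
      k_base = adh$k_apical, k = adh$k_apical,
      L0_base = adh$L0_apical, L0 = adh$L0_apical,
      active = TRUE, cell = NA_integer_, chain = 0L)
  }

  tis$springs <- do.call(rbind, c(list(sp), add))
  tis$excl <- NULL  # spring-connected pairs changed; rebuild lazily
  tis
}

# assemble flat argument lists for the compiled kernel
engine_args <- function(tis, params) {
  if (is.null(tis$excl)) tis$excl <- find_exclusion_pairs(tis, params)
  sp <- tis$springs; bd <- tis$bends; ex <- tis$excl
  polys <- lapply(tis$cells, `[[`, "memb")
  lens <- vapply(polys, length, integer(1L))
  list(tis = tis,
       args = list(
         pos = tis$pos,
         si = sp$i, sj = sp$j, sk = sp$k, sL0 = sp$L0, sact = sp$active,
         ba = bd$a, bb = bd$b, bc = bd$c, bform = bd$form,
         bk = bd$k, bth0 = bd$theta0,
         mi = ex$i, mj = ex$j, mU = ex$U, mW = ex$W,
         mxi = ex$xi, mga = ex$gamma, mcut = ex$cutoff, mshift = ex$shift,
         poly = as.integer(unlist(polys, use.names = FALSE)),
         polyoff = as.integer(c(0L, cumsum(lens))),
         kvol = vapply(tis$cells, function(c) {
           if (is.finite(c$k_vol)) c$k_vol else params$area$k_vol
         }, numeric(1L)),
         omega0 = vapply(tis$cells, `[[`, numeric(1L), "omega0")))
}

#' Total potential energy of the tissue
#'
#' Sum over all active springs, bending triplets, in-range Morse pairs
#' and per-cell area constraints.
#'
#' @param tis tissue.
#' @param params parameter list.
#' @return scalar energy.
#' @export
total_energy <- function(tis, params) {
  ea <- engine_args(tis, params)
  res <- do.call(engine_eval, c(ea$args, list(want_forces = FALSE)))
  if (!is.finite(res$energy)) stop("numeric error: non-finite energy")
  res$energy
}

#' Forces on every node
#'
#' The negative gradient of [total_energy()] with respect to each node
#' position.  Immobile nodes report their force but are never moved by
#' the integrator; dead nodes report zero.
#'
#' @param tis tissue.
#' @param params parameter list.
#' @return list with `forces` (N x 2 matrix), `energy`, `areas`
#'   (per-cell), and the tissue with a refreshed exclusion-pair cache.
#' @export
compute_forces <- function(tis, params) {
  ea <- engine_args(tis, params)
  res <- do.call(engine_eval, c(ea$args, list(want_forces = TRUE)))
  if (!all(is.finite(res$forces[tis$alive, ])))
    stop("numeric error: non-finite force")
  list(forces = res$forces, energy = res$energy, areas = res$areas,
       tis = ea$tis)
}
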