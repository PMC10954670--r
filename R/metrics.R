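# Tissue-shape metrics: local basal curvature, cell height, relative
# nuclear position, and their domain summaries.  The same routines apply
# to simulation snapshots and to digitized experimental point sets read
# from delimited text.

#' Basal polyline of the columnar layer
#'
#' Ordered vertices (left to right) along the basal surfaces of the
#' columnar cells.  Consecutive near-coincident vertices (shared walls
#' of adjacent cells) are collapsed.
#'
#' @param tis tissue.
#' @return matrix of `(x, y)` vertices.
#' @export
basal_polyline <- function(tis) {
  ids <- columnar_ids(tis)
  pts <- do.call(rbind, lapply(ids, function(id) {
    tis$pos[tis$cells[[id]]$basal, , drop = FALSE]
  }))
  if (nrow(pts) > 1L) {
    d <- sqrt(rowSums(diff(pts)^2))
    pts <- pts[c(TRUE, d > 1e-9), , drop = FALSE]
  }
  pts
}

#' Local signed curvature of a polyline
#'
#' Menger curvature: at each interior vertex, the reciprocal
#' circumradius of the circle through the vertex and its neighbors
#' `window` positions away, signed positive when the polyline bends
#' toward the apical side (left turn when traversed left to right with
#' apical up).  Endpoints are padded with the nearest interior
#' estimate.  Collinear triplets give curvature 0.
#'
#' @param polyline vertex matrix (>= 5 vertices).
#' @param window neighbor offset (>= 2 recommended; >= 1 accepted).
#' @return numeric vector of per-vertex signed curvature.
#' @export
local_curvature <- function(polyline, window = 3L) {
  v <- as.matrix(polyline)
  n <- nrow(v)
  if (n < 5L) stop("polyline must have at least 5 vertices")
  if (any(sqrt(rowSums(diff(v)^2)) < 1e-12))
    stop("polyline has coincident consecutive vertices")
  w <- as.integer(window)
  if (w < 1L) stop("window must be >= 1")
  w <- min(w, (n - 1L) %/% 2L)
  kap <- rep(NA_real_, n)
  idx <- (1L + w):(n - w)
  p <- v[idx - w, , drop = FALSE]
  q <- v[idx, , drop = FALSE]
  r <- v[idx + w, , drop = FALSE]
  a <- sqrt(rowSums((q - p)^2))
  b <- sqrt(rowSums((r - q)^2))
  cc <- sqrt(rowSums((r - p)^2))
  cross <- (q[, 1L] - p[, 1L]) * (r[, 2L] - q[, 2L]) -
    (q[, 2L] - p[, 2L]) * (r[, 1L] - q[, 1L])
  kap[idx] <- 2 * cross / (a * b * cc)
  kap[seq_len(w)] <- kap[1L + w]
  kap[(n - w + 1L):n] <- kap[n - w]
  kap
}

#' Arc-length positions along a polyline, normalized to [-0.5, 0.5]
#' @param polyline vertex matrix.
#' @return per-vertex normalized arc positions `l / L_AP`.
#' @export
arc_positions <- function(polyline) {
  v <- as.matrix(polyline)
  s <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
  total <- s[length(s)]
  if (total <= 0) stop("geometry error: polyline has zero arc length")
  s / total - 0.5
}

#' Normalize a curvature profile by total arc length
#'
#' Multiplies per-vertex curvature by the polyline's total arc length,
#' giving a dimensionless profile: a uniform arc of any size maps to a
#' constant, and rescaling the tissue leaves the profile unchanged.
#'
#' @param kappa per-vertex curvature from [local_curvature()].
#' @param polyline the polyline the curvature was measured on.
#' @return data frame with `position` (`l / L_AP`) and `kappa`
#'   (dimensionless).
#' @export
normalize_curvature <- function(kappa, polyline) {
  v <- as.matrix(polyline)
  s <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
  total <- s[length(s)]
  if (total <= 0) stop("geometry error: polyline has zero arc length")
  data.frame(position = s / total - 0.5, kappa = kappa * total)
}

#' Domain summary ratio of a curvature profile
#'
#' Mean absolute curvature over the numerator domain divided by the mean
#' over the denominator domain.  With `scheme = "thirds"` the domains
#' are the outer thirds (lateral) over the middle third (medial) of the
#' arc; with `scheme = "halves"` the right half (posterior, `l > 0`)
#' over the left half (anterior).
#'
#' @param kappa per-vertex curvature.
#' @param positions per-vertex normalized arc positions in
#'   `[-0.5, 0.5]`.
#' @param scheme `"thirds"` or `"halves"`.
#' @return the ratio; `Inf` (with a warning) if the denominator domain
#'   mean is zero.
#' @export
domain_curvature_ratio <- function(kappa, positions,
                                   scheme = c("thirds", "halves")) {
  scheme <- match.arg(scheme)
  stopifnot(length(kappa) == length(positions))
  if (scheme == "thirds") {
    num <- abs(positions) > 1 / 6
    den <- !num
  } else {
    num <- positions > 0
    den <- !num
  }
  mnum <- mean(abs(kappa[num]))
  mden <- mean(abs(kappa[den]))
  if (mden == 0) {
    warning("denominator domain has zero mean curvature; ratio is infinite")
    return(Inf)
  }
  mnum / mden
}

#' Cell height
#'
#' Distance between the centroid of the basal edge nodes and the
#' centroid of the apical edge nodes (not the bounding-box height).
#'
#' @param tis tissue.
#' @param id cell id.
#' @return height (length units).
#' @export
cell_height <- function(tis, id) {
  cc <- tis$cells[[id]]
  if (!length(cc$basal) || !length(cc$apical))
    stop("type error: cell has no apical/basal ranges")
  bc <- colMeans(tis$pos[cc$basal, , drop = FALSE])
  ac <- colMeans(tis$pos[cc$apical, , drop = FALSE])
  sqrt(sum((ac - bc)^2))
}

#' Relative nuclear position
#'
#' `d_B` is the distance from the nucleus centroid to the basal-edge
#' centroid, `d_A` to the apical-edge centroid; the relative position is
#' `db_bar = d_B / (d_A + d_B)`, 0 at the basal surface and 1 at the
#' apical surface.
#'
#' @param tis tissue.
#' @param id cell id (must have nucleus nodes).
#' @return list with `d_B`, `d_A`, `db_bar`.
#' @export
nuclear_position <- function(tis, id) {
  cc <- tis$cells[[id]]
  if (!length(cc$nuc)) stop("cell has no nucleus nodes")
  nc <- colMeans(tis$pos[cc$nuc, , drop = FALSE])
  bc <- colMeans(tis$pos[cc$basal, , drop = FALSE])
  ac <- colMeans(tis$pos[cc$apical, , drop = FALSE])
  d_B <- sqrt(sum((nc - bc)^2))
  d_A <- sqrt(sum((nc - ac)^2))
  if (d_A + d_B == 0) stop("geometry error: degenerate cell, d_A + d_B = 0")
  list(d_B = d_B, d_A = d_A, db_bar = d_B / (d_A + d_B))
}

#' Medial-to-lateral ratio of mean relative nuclear position
#'
#' Mean `db_bar` over non-mitotic columnar cells of the medial domain
#' (middle third of the arc) divided by the mean over the lateral
#' domains (outer thirds).  Mitotic cells are excluded because their
#' nuclei are transiently apical.
#'
#' @param tis tissue.
#' @param include_mitotic include mitotic cells (for comparison runs).
#' @return the ratio.
#' @export
medial_lateral_db_ratio <- function(tis, include_mitotic = FALSE) {
  ids <- columnar_ids(tis)
  keep <- vapply(ids, function(id) {
    include_mitotic || is.null(tis$cells[[id]]$mitotic)
  }, logical(1L))
  ids <- ids[keep]
  db <- vapply(ids, function(id) nuclear_position(tis, id)$db_bar,
               numeric(1L))
  pos <- vapply(ids, function(id) tis$cells[[id]]$ap_position, numeric(1L))
  med <- abs(pos) <= 1 / 6
  if (!any(med) || all(med)) stop("empty medial or lateral domain")
  mean(db[med]) / mean(db[!med])
}

#' Full shape-metric summary of a tissue
#'
#' @param tis tissue.
#' @param window curvature window, see [local_curvature()].
#' @return list with the basal curvature profile (raw and normalized,
#'   with arc positions), per-cell heights and nuclear positions, and
#'   the lateral/medial and posterior/anterior curvature ratios.
#' @export
shape_metrics <- function(tis, window = 3L) {
  bp <- basal_polyline(tis)
  kap <- local_curvature(bp, window)
  ap <- arc_positions(bp)
  norm <- normalize_curvature(kap, bp)
  ids <- columnar_ids(tis)
  heights <- vapply(ids, function(id) cell_height(tis, id), numeric(1L))
  db <- vapply(ids, function(id) {
    if (length(tis$cells[[id]]$nuc)) nuclear_position(tis, id)$db_bar
    else NA_real_
  }, numeric(1L))
  list(polyline = bp, kappa = kap, positions = ap,
       normalized = norm,
       cell_ids = ids, heights = heights, db_bar = db,
       # a perfectly flat snapshot (e.g. at t = 0) has zero-mean domains;
       # the summary ratios are then Inf and the warning is not useful
       lateral_medial_ratio =
         suppressWarnings(domain_curvature_ratio(kap, ap, "thirds")),
       posterior_anterior_ratio =
         suppressWarnings(domain_curvature_ratio(kap, ap, "halves")))
}

#' Read a delimited point set
#'
#' Reads `x,y` rows (comma, tab or whitespace separated; optional
#' header) into a vertex matrix usable with the curvature metrics, for
#' digitized experimental polylines and nucleus centroids.
#'
#' @param path file path.
#' @return two-column numeric matrix.
#' @export
read_pointset <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = header, sep = sep,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("could not parse point set: ", path)
  m <- as.matrix(df[, 1:2])
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("could not parse point set: ", path)
  colnames(m) <- c("x", "y")
  m
}
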