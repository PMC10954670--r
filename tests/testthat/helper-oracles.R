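# Shared fixtures and independent (naive) oracles used across tests.

# small tissue with adhesion pairs in place
toy_tissue <- function(n_col = 3L, params = default_params(), ...) {
  t <- build_flat_tissue(n_col, params = params, ...)
  refresh_adhesion_pairs(t, params)
}

# naive term-by-term re-summation of the total energy, independent of
# the compiled kernel: plain R loops over the same tables
naive_total_energy <- function(tis, params) {
  E <- 0
  sp <- tis$springs
  for (r in seq_len(nrow(sp))) {
    if (!sp$active[r]) next
    L <- sqrt(sum((tis$pos[sp$j[r], ] - tis$pos[sp$i[r], ])^2))
    E <- E + 0.5 * sp$k[r] * (L - sp$L0[r])^2
  }
  bd <- tis$bends
  for (r in seq_len(nrow(bd))) {
    a <- tis$pos[bd$a[r], ]; b <- tis$pos[bd$b[r], ]; c <- tis$pos[bd$c[r], ]
    u <- a - b; v <- c - b
    th <- (atan2(u[2], u[1]) - atan2(v[2], v[1])) %% (2 * pi)
    d <- atan2(sin(th - bd$theta0[r]), cos(th - bd$theta0[r]))
    E <- E + if (bd$form[r] == 1L) 0.5 * bd$k[r] * d^2 else
      bd$k[r] * (1 - cos(d))
  }
  ex <- if (is.null(tis$excl)) find_exclusion_pairs(tis, params) else tis$excl
  for (r in seq_len(nrow(ex))) {
    d <- sqrt(sum((tis$pos[ex$i[r], ] - tis$pos[ex$j[r], ])^2))
    if (d < ex$cutoff[r]) {
      E <- E + ex$U[r] * exp(-d / ex$xi[r]) -
        ex$W[r] * exp(-d / ex$gamma[r]) - ex$shift[r]
    }
  }
  for (cc in tis$cells) {
    A <- polygon_area(tis$pos[cc$memb, , drop = FALSE])
    kv <- if (is.finite(cc$k_vol)) cc$k_vol else params$area$k_vol
    E <- E + kv * (A - cc$omega0)^2
  }
  unname(E)
}

# central finite-difference force for node i, with the pair list frozen
fd_force <- function(tis, params, i, h = 1e-6) {
  if (is.null(tis$excl)) tis$excl <- find_exclusion_pairs(tis, params)
  out <- numeric(2L)
  for (d in 1:2) {
    tp <- tis; tp$pos[i, d] <- tp$pos[i, d] + h
    tm <- tis; tm$pos[i, d] <- tm$pos[i, d] - h
    out[d] <- -(total_energy(tp, params) - total_energy(tm, params)) / (2 * h)
  }
  out
}

# brute-force all-pairs exclusion list (ids only), the O(n^2) oracle
brute_exclusion_pairs <- function(tis, params) {
  alive <- which(tis$alive)
  out <- list()
  sp <- tis$springs
  N <- nrow(tis$pos)
  skey <- pmin(sp$i[sp$active], sp$j[sp$active]) * (N + 1) +
    pmax(sp$i[sp$active], sp$j[sp$active])
  for (a in seq_along(alive)) {
    for (b in seq_len(a - 1L)) {
      i <- alive[b]; j <- alive[a]
      pcl <- episce:::pair_class(tis$class[i], tis$class[j],
                                 tis$cellid[i], tis$cellid[j], params)
      if (is.na(pcl)) next
      d <- sqrt(sum((tis$pos[i, ] - tis$pos[j, ])^2))
      if (d > params$morse[[pcl]]$cutoff + params$exclusion_skin) next
      if ((min(i, j) * (N + 1) + max(i, j)) %in% skey) next
      out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(matrix(integer(), 0L, 2L))
  do.call(rbind, out)
}

pair_key <- function(i, j, N) pmin(i, j) * (N + 1) + pmax(i, j)

# reflect a tissue's coordinates about the vertical midline
mirror_x <- function(pos) cbind(-pos[, 1L], pos[, 2L])

# check that two point sets of the same node class match node-for-node
expect_pointsets_equal <- function(a, b, tol = 1e-12) {
  expect_equal(nrow(a), nrow(b))
  used <- rep(FALSE, nrow(b))
  for (r in seq_len(nrow(a))) {
    d <- sqrt((b[, 1L] - a[r, 1L])^2 + (b[, 2L] - a[r, 2L])^2)
    d[used] <- Inf
    k <- which.min(d)
    expect_lt(d[k], tol)
    used[k] <- TRUE
  }
  invisible(TRUE)
}

# sample a circle as a polyline
circle_polyline <- function(R, n = 100L, t0 = -pi / 3, t1 = pi / 3) {
  tt <- seq(t0, t1, length.out = n)
  cbind(R * sin(tt), R * (1 - cos(tt)))
}
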