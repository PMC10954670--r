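test_that("curvature of sampled circles matches 1/R", {
  for (R in c(2, 10)) {
    pl <- circle_polyline(R, n = 100L)
    kap <- local_curvature(pl, window = 3L)
    interior <- kap[4:(length(kap) - 3)]
    expect_true(all(abs(interior - 1 / R) / (1 / R) < 0.01))
  }
  # straight line: exactly zero everywhere
  line <- cbind(seq(0, 10, length.out = 50), rep(0, 50))
  expect_true(all(local_curvature(line) == 0))
})

test_that("curvature estimator converges with sampling density", {
  # on an ellipse (varying curvature) the window-averaged estimate
  # approaches the pointwise value as the sampling gets denser
  a <- 3; b <- 1
  apex_err <- vapply(c(100L, 200L, 400L), function(n) {
    tt <- seq(-pi / 4, pi / 4, length.out = n)
    pl <- cbind(a * cos(tt), b * sin(tt))
    kap <- local_curvature(pl, window = 3L)
    abs(kap[which.min(abs(tt))] - a / b^2) / (a / b^2)
  }, numeric(1L))
  expect_true(all(diff(apex_err) < 0))
  # circles are reproduced essentially exactly at any density
  for (n in c(30L, 100L)) {
    kap <- local_curvature(circle_polyline(3, n = n), window = 3L)
    expect_equal(kap[4:(length(kap) - 3)],
                 rep(1 / 3, length(kap) - 6), tolerance = 1e-9)
  }
})

test_that("ellipse apex curvature matches the analytic value", {
  # kappa(t) = a b / (a^2 sin^2 t + b^2 cos^2 t)^(3/2); at the apex
  # t = 0 (the major-axis end) this is a / b^2
  a <- 3; b <- 1
  tt <- seq(-pi / 4, pi / 4, length.out = 400L)
  pl <- cbind(a * cos(tt), b * sin(tt))
  kap <- local_curvature(pl, window = 3L)
  apex <- which.min(abs(tt))
  expect_equal(abs(kap[apex]), a / b^2, tolerance = 0.02)
  # and away from the apex the analytic profile is matched too
  k_true <- a * b / (a^2 * sin(tt)^2 + b^2 * cos(tt)^2)^1.5
  interior <- 4:(length(tt) - 3)
  expect_equal(abs(kap[interior]), k_true[interior], tolerance = 0.02)
})

test_that("curvature sign flips under reflection, |kappa| summaries do not", {
  pl <- circle_polyline(5, n = 80L)
  kap <- local_curvature(pl)
  refl <- cbind(pl[, 1L], -pl[, 2L])
  kap_r <- local_curvature(refl)
  expect_equal(kap_r, -kap, tolerance = 1e-9)
  pos <- arc_positions(pl)
  expect_equal(domain_curvature_ratio(kap, pos),
               domain_curvature_ratio(kap_r, pos), tolerance = 1e-9)
})

test_that("curvature metrics are invariant to rigid motion", {
  pl <- circle_polyline(4, n = 60L)
  th <- 0.7
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- pl %*% t(Rm) + matrix(rep(c(5, -3), each = nrow(pl)), ncol = 2L)
  expect_equal(local_curvature(moved), local_curvature(pl),
               tolerance = 1e-9)
})

test_that("normalized curvature is scale-invariant and flags zero length", {
  # semicircle: normalized curvature = pi at any radius
  for (R in c(1, 7)) {
    pl <- circle_polyline(R, n = 200L, t0 = -pi / 2, t1 = pi / 2)
    norm <- normalize_curvature(local_curvature(pl), pl)
    interior <- norm$kappa[4:(nrow(norm) - 3)]
    expect_equal(mean(interior), pi, tolerance = 0.01)
  }
  pl <- circle_polyline(2, n = 50L)
  n1 <- normalize_curvature(local_curvature(pl), pl)
  pl3 <- pl * 3
  n3 <- normalize_curvature(local_curvature(pl3), pl3)
  expect_equal(n1$kappa, n3$kappa, tolerance = 1e-9)
  expect_equal(n1$position, n3$position, tolerance = 1e-12)
  # straight segment: all zeros
  line <- cbind(seq_len(20), rep(1, 20))
  expect_true(all(normalize_curvature(local_curvature(line), line)$kappa == 0))
})

test_that("domain curvature ratios behave on synthetic profiles", {
  pos <- seq(-0.5, 0.5, length.out = 300L)
  # uniform arc: ratio 1
  expect_equal(domain_curvature_ratio(rep(0.2, 300L), pos), 1)
  # medial half the lateral value: ratio 2
  kap <- ifelse(abs(pos) > 1 / 6, 1, 0.5)
  expect_equal(domain_curvature_ratio(kap, pos), 2, tolerance = 0.01)
  # flat medial: flagged infinite
  kap0 <- ifelse(abs(pos) > 1 / 6, 1, 0)
  expect_warning(r <- domain_curvature_ratio(kap0, pos), "infinite")
  expect_identical(r, Inf)
  # mirror reflection leaves the thirds ratio unchanged
  expect_equal(domain_curvature_ratio(rev(kap), rev(-pos)),
               domain_curvature_ratio(kap, pos), tolerance = 1e-12)
})

test_that("cell height uses edge centroids, not the bounding box", {
  params <- default_params()
  t <- build_flat_tissue(3, cell_height = 4, params = params)
  expect_equal(cell_height(t, 2L), 4, tolerance = 1e-12)
  # shear the middle cell: height is the centroid-to-centroid distance
  cc <- t$cells[[2L]]
  shear <- 0.5
  t$pos[cc$memb, 1L] <- t$pos[cc$memb, 1L] +
    shear * t$pos[cc$memb, 2L] / 4
  bc <- colMeans(t$pos[cc$basal, , drop = FALSE])
  ac <- colMeans(t$pos[cc$apical, , drop = FALSE])
  expect_equal(cell_height(t, 2L), sqrt(sum((ac - bc)^2)), tolerance = 1e-12)
  expect_lt(cell_height(t, 2L), 4 + shear)  # not the bounding box
  expect_gt(cell_height(t, 2L), 4)
})

test_that("relative nuclear position endpoints and midpoint are exact", {
  params <- default_params()
  t <- build_flat_tissue(3, params = params)
  cc <- t$cells[[2L]]
  bc <- colMeans(t$pos[cc$basal, , drop = FALSE])
  ac <- colMeans(t$pos[cc$apical, , drop = FALSE])
  place <- function(t, p) {
    ctr <- colMeans(t$pos[cc$nuc, , drop = FALSE])
    t$pos[cc$nuc, ] <- t$pos[cc$nuc, ] +
      matrix(rep(p - ctr, each = length(cc$nuc)), ncol = 2L)
    t
  }
  expect_equal(nuclear_position(place(t, bc), 2L)$db_bar, 0)
  expect_equal(nuclear_position(place(t, ac), 2L)$db_bar, 1)
  expect_equal(nuclear_position(place(t, (ac + bc) / 2), 2L)$db_bar, 0.5)
})

test_that("medial/lateral nuclear ratio excludes mitotic cells", {
  params <- default_params()
  t <- build_flat_tissue(6, params = params)
  r0 <- medial_lateral_db_ratio(t)
  expect_equal(r0, 1, tolerance = 0.05)  # symmetric build
  # fake-mark a medial cell mitotic after pushing its nucleus apically
  mid <- columnar_ids(t)[3L]
  cc <- t$cells[[mid]]
  ac <- colMeans(t$pos[cc$apical, , drop = FALSE])
  ctr <- colMeans(t$pos[cc$nuc, , drop = FALSE])
  t$pos[cc$nuc, ] <- t$pos[cc$nuc, ] +
    matrix(rep(ac - ctr, each = length(cc$nuc)), ncol = 2L)
  t$cells[[mid]]$mitotic <- list(dummy = TRUE)
  r_excl <- medial_lateral_db_ratio(t)
  r_incl <- medial_lateral_db_ratio(t, include_mitotic = TRUE)
  expect_lt(r_excl, r_incl)
})

test_that("point sets round-trip through delimited text", {
  pl <- circle_polyline(2, n = 25L)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = pl[, 1L], y = pl[, 2L]), f,
                   row.names = FALSE)
  got <- read_pointset(f)
  expect_equal(unname(got), unname(pl), tolerance = 1e-12)
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(pl, f2, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  got2 <- read_pointset(f2)
  expect_equal(unname(got2), unname(pl), tolerance = 1e-6)
})
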