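test_that("scalar energy terms match their closed forms", {
  # linear spring
  expect_equal(spring_energy(2, 3, 3), 0)
  expect_equal(spring_energy(2, 4, 3), 1.0)
  expect_equal(spring_energy(1.5, 0.5, 2.0), 1.6875)
  expect_error(spring_energy(-1, 1, 1), "parameter error")

  # bending, both forms
  tri_straight <- rbind(c(-1, 0), c(0, 0), c(1, 0))
  expect_equal(bending_energy(tri_straight, 2, pi, "quadratic"), 0)
  expect_equal(bending_energy(tri_straight, 1, pi, "cosine"), 0)
  tri_right <- rbind(c(0, 1), c(0, 0), c(1, 0))  # interior angle pi/2
  expect_equal(bending_energy(tri_right, 1, 0, "cosine"), 1.0)
  expect_equal(bending_energy(tri_right, 2, pi / 2 - 0.5, "quadratic"), 0.25)
  expect_error(bending_energy(rbind(c(0, 0), c(0, 0), c(1, 0)), 1, pi),
               "collocated")

  # Morse: value at the origin, the worked mid-range value, and the cutoff
  p <- morse_params(U = 0.5, W = 0.2, xi = 1, gamma = 2, cutoff = 50)
  expect_equal(morse_energy(p, 0), 0.5 - 0.2, tolerance = 1e-10)
  expect_equal(morse_energy(p, 1), 0.5 * exp(-1) - 0.2 * exp(-0.5),
               tolerance = 1e-10)
  expect_identical(morse_energy(p, 60), 0)
  expect_identical(morse_energy(p, 50), 0)

  # area constraint (no 1/2 prefactor)
  expect_equal(area_energy(2, 2, 10), 0)
  expect_equal(area_energy(2.5, 2, 10), 2.5)
  expect_equal(area_energy(1.5, 2, 10), 2.5)
  expect_error(area_energy(-1, 2, 10), "geometry error")
})

test_that("morse_params enforces an adequate cutoff", {
  expect_error(morse_params(1, 0, 0.1, 0.2, cutoff = 0.5), "cutoff")
  p <- morse_params(1, 0, 0.1, 0.2, cutoff = 0.6)
  expect_equal(p$shift, exp(-6), tolerance = 1e-12)
})

test_that("total energy matches a naive term-by-term oracle", {
  params <- default_params()
  t <- toy_tissue(3, params)
  set.seed(7)
  t$pos <- t$pos + matrix(rnorm(length(t$pos), 0, 0.02), ncol = 2L)
  t$excl <- find_exclusion_pairs(t, params)
  e_fast <- total_energy(t, params)
  e_naive <- naive_total_energy(t, params)
  expect_equal(e_fast, e_naive, tolerance = 1e-12)
  expect_lt(abs(e_fast - e_naive) / abs(e_naive), 1e-12)
})

test_that("a rest-built single-cell tissue has zero energy", {
  params <- default_params()
  t <- build_flat_tissue(2, params = params)
  # deactivate contractile springs; keep only rest-length terms
  t$springs$active[t$springs$role %in% c(2L, 3L)] <- FALSE
  # membrane springs, bends and areas are all at rest by construction
  sp <- t$springs
  memb_rows <- sp$role == 1L
  L <- sqrt(rowSums((t$pos[sp$j[memb_rows], ] - t$pos[sp$i[memb_rows], ])^2))
  expect_equal(L, sp$L0[memb_rows], tolerance = 1e-12)
  areas <- vapply(seq_along(t$cells), function(i) cell_area(t, i),
                  numeric(1L))
  omega0 <- vapply(t$cells, `[[`, numeric(1L), "omega0")
  expect_equal(areas, omega0, tolerance = 1e-12)
})

test_that("deactivated springs contribute no energy or force", {
  params <- default_params()
  t <- toy_tissue(2, params)
  e1 <- total_energy(t, params)
  f1 <- compute_forces(t, params)$forces
  t2 <- t
  rows <- which(t2$springs$role == 3L & t2$springs$active)
  expect_gt(length(rows), 0L)
  t2$springs$active[rows] <- FALSE
  e2 <- total_energy(t2, params)
  f2 <- compute_forces(t2, params)$forces
  expect_false(isTRUE(all.equal(e1, e2)))
  # deactivating twice changes nothing further
  t3 <- t2
  t3$springs$k[rows] <- 99
  expect_equal(total_energy(t3, params), e2)
  expect_equal(compute_forces(t3, params)$forces, f2)
})

test_that("exclusion pair list matches the brute-force oracle", {
  params <- default_params()
  t <- toy_tissue(3, params)
  set.seed(11)
  t$pos <- t$pos + matrix(rnorm(length(t$pos), 0, 0.05), ncol = 2L)
  got <- find_exclusion_pairs(t, params)
  want <- brute_exclusion_pairs(t, params)
  N <- nrow(t$pos)
  expect_setequal(pair_key(got$i, got$j, N),
                  pair_key(want[, 1L], want[, 2L], N))
  # each unordered pair appears exactly once
  expect_false(any(duplicated(pair_key(got$i, got$j, N))))
})

test_that("distant objects generate no exclusion pairs", {
  params <- default_params()
  t <- toy_tissue(2, params)
  # push the squamous layer far away; cross-layer pairs must disappear
  sq <- which(!is.na(t$cellid) &
                t$cellid %in% which(vapply(t$cells, function(c)
                  c$type == "squamous", logical(1L))))
  t$pos[sq, 2L] <- t$pos[sq, 2L] + 100
  ex <- find_exclusion_pairs(t, params)
  cross <- (t$cellid[ex$i] %in% t$cellid[sq]) !=
    (t$cellid[ex$j] %in% t$cellid[sq])
  expect_equal(sum(cross), 0L)
})

test_that("adhesion pairing is nearest-neighbor within range and dissolves beyond", {
  params <- default_params()
  t <- build_flat_tissue(3, params = params)
  t <- refresh_adhesion_pairs(t, params)
  sp <- t$springs
  basal_rows <- which(sp$role == 6L)
  expect_gt(length(basal_rows), 0L)
  # every columnar basal node within range is paired
  col_ids <- columnar_ids(t)
  basal_nodes <- unlist(lapply(t$cells[col_ids], `[[`, "basal"))
  expect_true(all(basal_nodes %in% c(sp$i[basal_rows], sp$j[basal_rows])))
  # nearest-node property: no eligible partner is strictly closer
  chain <- t$ecm$columnar$nodes
  for (r in basal_rows[seq_len(min(20L, length(basal_rows)))]) {
    src <- sp$i[r]; tgt <- sp$j[r]
    d <- sqrt(sum((t$pos[src, ] - t$pos[tgt, ])^2))
    dall <- sqrt((t$pos[chain, 1L] - t$pos[src, 1L])^2 +
                   (t$pos[chain, 2L] - t$pos[src, 2L])^2)
    expect_lte(d, min(dall) + 1e-12)
  }
  # moving the ECM out of range dissolves all basal adhesion
  t2 <- t
  t2$pos[t2$ecm$columnar$nodes, 2L] <-
    t2$pos[t2$ecm$columnar$nodes, 2L] - 10
  t2 <- refresh_adhesion_pairs(t2, params)
  expect_equal(sum(t2$springs$role == 6L &
                     t2$springs$i %in% basal_nodes), 0L)
})

test_that("analytic forces match central finite differences", {
  params <- default_params()
  set.seed(123)
  for (rep in 1:4) {
    t <- toy_tissue(2, params)
    t$pos <- t$pos + matrix(rnorm(length(t$pos), 0, 0.03), ncol = 2L)
    t$excl <- find_exclusion_pairs(t, params)
    F <- compute_forces(t, params)$forces
    idx <- sample(which(t$alive), 6L)
    for (i in idx) {
      fd <- fd_force(t, params, i)
      expect_equal(F[i, ], fd, tolerance = 1e-5)
    }
  }
})

test_that("translation invariance and zero net force", {
  params <- default_params()
  t <- toy_tissue(3, params)
  set.seed(5)
  t$pos <- t$pos + matrix(rnorm(length(t$pos), 0, 0.02), ncol = 2L)
  t$excl <- find_exclusion_pairs(t, params)
  e0 <- total_energy(t, params)
  f0 <- compute_forces(t, params)$forces
  expect_equal(colSums(f0[t$alive, ]), c(0, 0), tolerance = 1e-10)
  t2 <- t
  t2$pos <- t2$pos + matrix(rep(c(3.1, -2.7), each = nrow(t2$pos)), ncol = 2L)
  expect_equal(total_energy(t2, params), e0, tolerance = 1e-10)
})

test_that("isolated pair forces obey Newton's third law", {
  # two nodes coupled by one spring, built by hand
  params <- default_params()
  t <- toy_tissue(2, params)
  t$excl <- find_exclusion_pairs(t, params)
  F <- compute_forces(t, params)$forces
  expect_equal(colSums(F[t$alive, ]), c(0, 0), tolerance = 1e-10)
})
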