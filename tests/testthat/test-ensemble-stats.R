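test_that("an ensemble of identical conformations has zero RMSF", {
  one <- gen_ring_assembly(n_rings = 1)
  ens <- dplyr::bind_rows(one, dplyr::mutate(one, model = 2L),
                          dplyr::mutate(one, model = 3L))
  prof <- rmsf(ens, exclude_align_resno = integer(0))
  expect_true(all(prof$rmsf < 1e-10))
  expect_error(rmsf(one), ">= 2")
})

test_that("two-state loop RMSF matches the closed form d*sqrt(p(1-p))", {
  for (p in c(0.5, 0.2)) {
    ens <- gen_loop_ensemble(n_conf = 30, occupancy = p, displacement_A = 10,
                             jitter_A = 0, seed = 17)
    tr <- attr(ens, "truth")
    prof <- rmsf(ens, exclude_align_resno = tr$loop_resno)
    p_hat <- colMeans(tr$states)  # realized occupancies per chain
    chains <- unique(ens$chain)
    for (j in seq_along(chains)) {
      expected <- 10 * sqrt(p_hat[j] * (1 - p_hat[j]))
      measured <- mean(prof$rmsf[prof$chain == chains[j] &
                                   prof$resno %in% tr$loop_resno])
      expect_equal(measured, expected, tolerance = 0.01)
    }
    # non-loop residues are rigid
    base <- prof$rmsf[!prof$resno %in% tr$loop_resno]
    expect_true(all(base < 0.1))
  }
})

test_that("minimum distances equal an all-pairs brute-force oracle", {
  # trivial: two single-atom residues 3 A apart
  m <- dplyr::bind_rows(
    tibble::tibble(model = 1L, chain = "A", resno = 1L, resid = "GLY",
                   elety = "CA", element = "C", x = 0, y = 0, z = 0,
                   occ = 1, b = 0),
    tibble::tibble(model = 1L, chain = "A", resno = 2L, resid = "GLY",
                   elety = "CA", element = "C", x = 3, y = 0, z = 0,
                   occ = 1, b = 0))
  m2 <- dplyr::mutate(m, model = 2L)
  dd <- min_distance_distribution(dplyr::bind_rows(m, m2), 1, 2)
  expect_equal(dd$distance, c(3, 3))

  # multi-atom residues vs O(n^2) double loop
  set.seed(31)
  for (rep in 1:5) {
    nA <- sample(3:20, 1); nB <- sample(3:20, 1)
    resA <- tibble::tibble(model = 1L, chain = "A", resno = 10L,
                           resid = "ARG",
                           elety = sprintf("X%d", seq_len(nA)), element = "C",
                           x = rnorm(nA), y = rnorm(nA), z = rnorm(nA),
                           occ = 1, b = 0)
    resB <- tibble::tibble(model = 1L, chain = "A", resno = 20L,
                           resid = "GLU",
                           elety = sprintf("Y%d", seq_len(nB)), element = "C",
                           x = rnorm(nB) + 5, y = rnorm(nB), z = rnorm(nB),
                           occ = 1, b = 0)
    ens <- dplyr::bind_rows(resA, resB,
                            dplyr::mutate(resA, model = 2L),
                            dplyr::mutate(resB, model = 2L))
    dd <- min_distance_distribution(ens, 10, 20)
    orc <- oracle_min_distance(as.matrix(resA[, c("x", "y", "z")]),
                               as.matrix(resB[, c("x", "y", "z")]))
    expect_equal(dd$distance, rep(orc, 2), tolerance = 1e-12)
  }
})

test_that("distance outputs are invariant under global rigid transforms", {
  ens <- gen_loop_ensemble(n_conf = 5, seed = 41)
  tr <- attr(ens, "truth")
  d0 <- min_distance_distribution(ens, tr$contact_resno, tr$tip_resno)
  set.seed(42)
  R <- rotation_matrix(runif(1, 0, 360), rnorm(3))
  shift <- rnorm(3, sd = 20)
  ens2 <- ens
  xyz <- as.matrix(ens[, c("x", "y", "z")])
  ens2[, c("x", "y", "z")] <- as.data.frame(
    sweep(xyz %*% t(R), 2, shift, "+"))
  d1 <- min_distance_distribution(ens2, tr$contact_resno, tr$tip_resno)
  expect_equal(d1$distance, d0$distance, tolerance = 1e-9)
})

test_that("hydrogens are excluded by default but retainable", {
  m <- dplyr::bind_rows(
    tibble::tibble(model = 1L, chain = "A", resno = 1L, resid = "GLY",
                   elety = c("CA", "HA"), element = c("C", "H"),
                   x = c(0, 1), y = 0, z = 0, occ = 1, b = 0),
    tibble::tibble(model = 1L, chain = "A", resno = 2L, resid = "GLY",
                   elety = "CA", element = "C", x = 3, y = 0, z = 0,
                   occ = 1, b = 0))
  ens <- dplyr::bind_rows(m, dplyr::mutate(m, model = 2L))
  expect_equal(min_distance_distribution(ens, 1, 2)$distance[1], 3)
  expect_equal(
    min_distance_distribution(ens, 1, 2, exclude_hydrogens = FALSE)$distance[1],
    2)
})

test_that("KDE integrates to one and hits the normal density closed form", {
  set.seed(51)
  x <- rnorm(10000)
  k <- kde_density(x, bandwidth_adjust = 1)
  integral <- sum(k$density) * diff(k$grid[1:2])
  expect_lt(abs(integral - 1), 1e-3)
  at0 <- approx(k$grid, k$density, xout = 0)$y
  expect_lt(abs(at0 - dnorm(0)) / dnorm(0), 0.05)
  # error paths
  expect_error(kde_density(rep(1, 5)), "zero-variance")
  expect_error(kde_density(1), ">= 2")
})

test_that("KDE bandwidth follows Scott's rule times the adjustment", {
  set.seed(52)
  x <- rnorm(500, sd = 2)
  k1 <- kde_density(x, bandwidth_adjust = 1)
  k2 <- kde_density(x, bandwidth_adjust = 2)
  expect_equal(attr(k1, "bandwidth"), sd(x) * 500^(-1 / 5))
  expect_equal(attr(k2, "bandwidth"), 2 * attr(k1, "bandwidth"))
})

test_that("histogram counts are conserved and match per-sample assignment", {
  # one sample per bin
  x <- seq(0.5, 149.5, by = 1)
  h <- histogram_counts(x, bins = 150)
  expect_true(all(h$count == 1))
  # random input: conservation + enumeration oracle
  set.seed(61)
  for (rep in 1:5) {
    y <- rnorm(sample(50:500, 1))
    hh <- histogram_counts(y, bins = 150)
    expect_equal(sum(hh$count), length(y))
    expect_equal(hh$count, oracle_histogram(y, attr(hh, "edges")))
  }
  # degenerate single-value sample
  h1 <- histogram_counts(rep(2, 7), bins = 10)
  expect_equal(sum(h1$count), 7)
})

test_that("distance-difference matrix is zero for identical models and rigid-invariant", {
  a <- gen_ring_assembly(n_rings = 1, n_res = 20)
  d0 <- ca_distance_difference(a, a, chain = "A")
  expect_true(all(d0$matrix == 0))
  expect_equal(dim(d0$matrix), c(20, 20))

  # perturb one residue; matrix must be symmetric, zero-diagonal, and
  # invariant to a rigid transform of either model
  b <- a
  i <- b$chain == "A" & b$resno == 7
  b[i, c("x", "y", "z")] <- b[i, c("x", "y", "z")] + 2
  d1 <- ca_distance_difference(a, b, chain = "A")
  expect_equal(d1$matrix, t(d1$matrix))
  expect_true(all(diag(d1$matrix) == 0))
  expect_true(7L %in% c(d1$max_pair$res_i, d1$max_pair$res_j))

  R <- rotation_matrix(33, c(1, 1, 0))
  b2 <- b
  xyz <- as.matrix(b[, c("x", "y", "z")])
  b2[, c("x", "y", "z")] <- as.data.frame(sweep(xyz %*% t(R), 2, c(5, 5, 5), "+"))
  d2 <- ca_distance_difference(a, b2, chain = "A")
  expect_equal(d2$matrix, d1$matrix, tolerance = 1e-9)
})

test_that("distance-difference matrix matches a hand-computed 5-residue toy", {
  mk <- function(coords, model = 1L) {
    tibble::tibble(model = model, chain = "A", resno = 1:5, resid = "GLY",
                   elety = "CA", element = "C",
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   occ = 1, b = 0)
  }
  A <- mk(cbind(c(0, 1, 2, 3, 4), 0, 0))
  B <- mk(cbind(c(0, 1, 2, 3, 5), 0, 0))  # residue 5 moved +1 in x
  d <- ca_distance_difference(A, B, chain = "A")
  # hand computation: only pairs involving residue 5 change, by -1
  expect_equal(d$matrix[5, 1], abs(4 - 0) - abs(5 - 0))
  expect_equal(d$matrix[5, 4], abs(4 - 3) - abs(5 - 3))
  expect_equal(d$matrix[2, 3], 0)
  expect_equal(abs(d$max_pair$difference), 1)
})

test_that("residue exclusions are applied and mismatches reported", {
  a <- gen_ring_assembly(n_rings = 1, n_res = 20)
  d <- ca_distance_difference(a, a, chain = "A", exclusions = c(5:8, 19))
  expect_equal(length(d$residues), 15)
  expect_false(any(d$residues %in% c(5:8, 19)))
  b <- a[!(a$chain == "A" & a$resno == 3), ]
  expect_error(ca_distance_difference(a, b, chain = "A"), "differ")
})

test_that("single CA pair distances match the cross-chain matrix entry", {
  a <- gen_ring_assembly(n_rings = 1, n_res = 20)
  d <- ca_pair_distance(a, "A", 4, "B", 11)
  expect_equal(d$pairing, "cross-chain")
  # oracle: full cross-chain CA distance matrix via dist()
  ca_a <- as.matrix(a[a$chain == "A" & a$elety == "CA", c("x", "y", "z")])
  ca_b <- as.matrix(a[a$chain == "B" & a$elety == "CA", c("x", "y", "z")])
  D <- as.matrix(stats::dist(rbind(ca_a, ca_b)))[1:20, 21:40]
  expect_equal(d$distance, D[4, 11], tolerance = 1e-12)
  # trivial constructed check
  m <- tibble::tibble(model = 1L, chain = "A", resno = c(1L, 2L),
                      resid = "GLY", elety = "CA", element = "C",
                      x = c(0, 10), y = 0, z = 0, occ = 1, b = 0)
  expect_equal(ca_pair_distance(m, "A", 1, res_b = 2)$distance, 10)
  expect_error(ca_pair_distance(m, "A", 1, "Z", 2), "not found")
})
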