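test_that("queen adjacency on rectangular grids has the expected neighbor counts", {
  lat <- build_lattice(3, 3)
  # row-major enumeration: corners 1,3,7,9; center 5
  expect_equal(lat$n_i[c(1, 3, 7, 9)], rep(3L, 4))
  expect_equal(lat$n_i[c(2, 4, 6, 8)], rep(5L, 4))
  expect_equal(lat$n_i[5], 8L)

  strip <- build_lattice(1, 2)
  expect_equal(strip$n_i, c(1L, 1L))

  lat5 <- build_lattice(4, 5)
  corners <- which(lat5$n_i == 3)
  expect_length(corners, 4)
  expect_true(all(lat5$n_i %in% c(3L, 5L, 8L)))
})

test_that("degenerate grids are rejected", {
  expect_error(build_lattice(1, 1), "single-cell")
  expect_error(build_lattice(0, 3), "positive")
  expect_error(build_lattice(2, -1), "positive")
})

test_that("adjacency is symmetric and irreflexive", {
  for (dims in list(c(2, 2), c(3, 4), c(1, 6))) {
    lat <- build_lattice(dims[1], dims[2])
    for (i in seq_len(lat$n_cells)) {
      nb <- lat$adjacency[[i]]
      expect_false(i %in% nb)
      for (k in nb) expect_true(i %in% lat$adjacency[[k]])
    }
    expect_true(all(lat$n_i >= 1))
  }
})

test_that("CAR full conditional is the neighbor mean with variance tau2/n_i", {
  lat <- build_lattice(2, 2)  # every cell has the other 3 as neighbors
  f <- car_field(c(9, 1, 2, 3), tau2 = 2, lat)
  fc <- car_full_conditional(f, 1)
  expect_equal(fc$mean, 2)
  expect_equal(fc$variance, 2 / 3)

  f0 <- car_field(c(9, 0, 0, 0), tau2 = 17, lat)
  expect_equal(car_full_conditional(f0, 1)$mean, 0)

  expect_error(car_full_conditional(f, "nope"), "unknown cell")
  expect_error(car_full_conditional(f, 99), "unknown cell")
})

test_that("full conditionals agree with the joint-precision oracle", {
  for (dims in list(c(3, 3), c(4, 4))) {
    lat <- build_lattice(dims[1], dims[2])
    set.seed(42)
    vals <- rnorm(lat$n_cells)
    vals <- vals - mean(vals)
    tau2 <- 1.7
    f <- car_field(vals, tau2, lat)
    K <- car_structure_matrix(lat)
    for (i in seq_len(lat$n_cells)) {
      fc <- car_full_conditional(f, i)
      # conditional of the Gaussian with precision K / tau2
      mean_oracle <- -sum(K[i, -i] * vals[-i]) / K[i, i]
      var_oracle <- tau2 / K[i, i]
      expect_equal(fc$mean, mean_oracle, tolerance = 1e-10)
      expect_equal(fc$variance, var_oracle, tolerance = 1e-10)
    }
  }
})

test_that("lattice symmetries commute with the CAR conditional", {
  lat <- build_lattice(3, 3)
  set.seed(1)
  vals <- rnorm(9)
  # 180-degree rotation of the 3x3 grid is the index reversal
  perm <- 9:1
  f <- car_field(vals, 1, lat)
  f_rot <- car_field(vals[perm], 1, lat)
  for (i in 1:9) {
    a <- car_full_conditional(f, i)
    b <- car_full_conditional(f_rot, which(perm == i))
    expect_equal(a$mean, b$mean)
    expect_equal(a$variance, b$variance)
  }
})

test_that("conditional variance decreases with neighbor count", {
  lat <- build_lattice(3, 3)
  f <- car_field(rnorm(9), tau2 = 1, lat)
  v <- vapply(1:9, function(i) car_full_conditional(f, i)$variance,
              numeric(1))
  expect_true(all(v[lat$n_i == 8] < v[lat$n_i == 5]))
  expect_true(all(v[lat$n_i == 5] < v[lat$n_i == 3]))
})

test_that("constrained joint draws sum to zero and are reproducible", {
  lat <- build_lattice(4, 3)
  f1 <- sample_intrinsic_car(lat, tau2 = 1.3, rng_seed = 11)
  f2 <- sample_intrinsic_car(lat, tau2 = 1.3, rng_seed = 11)
  f3 <- sample_intrinsic_car(lat, tau2 = 1.3, rng_seed = 12)
  expect_lt(abs(sum(f1$values)), 1e-9)
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, f3$values))
})

test_that("a disconnected lattice is rejected by the joint sampler", {
  # hand-built two-component "lattice": two 1x2 strips with no links between
  lat <- structure(list(
    n_cells = 4L, n_rows = 2L, n_cols = 2L,
    cell_id = paste0("c", 0:3), row = c(0L, 0L, 1L, 1L),
    col = c(0L, 1L, 0L, 1L),
    adjacency = list(2L, 1L, 4L, 3L), n_i = rep(1L, 4)),
    class = "atlas_lattice")
  expect_error(sample_intrinsic_car(lat, 1, 1), "disconnected")
})
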