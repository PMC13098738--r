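test_that("energy is conserved and tallies are seed-deterministic", {
  m <- skin_model(851)
  t1 <- simulate_pencil_beam(m, 851, 5000, seed = 11)
  expect_lt(abs(energy_closure(t1)), 1e-6)
  t2 <- simulate_pencil_beam(m, 851, 5000, seed = 11)
  expect_identical(t1$exit_weight, t2$exit_weight)
  expect_identical(t1$exit_radius, t2$exit_radius)
  expect_identical(t1$zmax, t2$zmax)
  expect_identical(t1$path_lengths, t2$path_lengths)
  t3 <- simulate_pencil_beam(m, 851, 5000, seed = 12)
  expect_false(identical(t1$exit_weight, t3$exit_weight))
  # zmax within the slab, weights in (0, 1], radii >= 0
  expect_true(all(t1$zmax > 0 & t1$zmax <= sum(m$thickness_mm)))
  expect_true(all(t1$exit_weight > 0 & t1$exit_weight <= 1))
  expect_true(all(t1$exit_radius >= 0))
})

test_that("a purely absorbing medium returns nothing from depth", {
  m <- homog_model(mua = 5, musp = 1e-9, n = 1.37)
  t <- simulate_pencil_beam(m, 800, 2000, seed = 1)
  expect_length(t$exit_weight, 0)
  expect_equal((t$total_absorbed_weight + t$specular_weight +
                  t$total_transmitted_weight) / t$n_launched, 1,
               tolerance = 1e-9)
})

test_that("hankel_rd collapses to the total at fx = 0 and is non-increasing in fx", {
  m <- skin_model(731)
  t <- simulate_pencil_beam(m, 731, 3e4, seed = 5)
  fx <- c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5)
  h <- hankel_rd(t, fx)
  expect_identical(h$rd[1], sum(t$exit_weight) / t$n_launched)
  # monotone decrease, allowing 3 sigma per comparison
  expect_true(all(diff(h$rd) < 3 * sqrt(h$se[-1]^2 + h$se[-8]^2)))
  expect_true(all(h$rd >= 0 & h$rd <= 1))
  expect_error(hankel_rd(t, -0.1), ">= 0")
  empty <- manual_tally(numeric(0), numeric(0), numeric(0), 100)
  expect_error(hankel_rd(empty, 0), "no detected photons")
})

test_that("single-photon tallies follow the transform arithmetic", {
  t1 <- manual_tally(exit_weight = 0.37, exit_radius = 4.2, zmax = 0.30,
                     n_launched = 10)
  h <- hankel_rd(t1, 0)
  expect_equal(h$rd, 0.037)
  d <- pzmax_distribution(t1, 0, z_edges = seq(0, 10, by = 0.1))
  expect_equal(sum(d$pzmax), 0.037)
  k <- findInterval(0.30, seq(0, 10, by = 0.1), left.open = TRUE,
                    rightmost.closed = TRUE)
  expect_equal(d$pzmax[k], 0.037)
  expect_true(all(d$pzmax[-k] == 0))
})

test_that("Pzmax partitions Rd(fx) exactly at every frequency", {
  m <- skin_model(851)
  t <- simulate_pencil_beam(m, 851, 2e4, seed = 21)
  fx <- c(0, 0.05, 0.15, 0.3, 0.5)
  h <- hankel_rd(t, fx)
  for (i in seq_along(fx)) {
    d <- pzmax_distribution(t, fx[i])
    expect_equal(sum(d$pzmax), h$rd[i], tolerance = 1e-12)
  }
  # at fx = 0 the distribution is nonnegative everywhere
  d0 <- pzmax_distribution(t, 0)
  expect_true(all(d0$pzmax >= 0))
  expect_error(pzmax_distribution(t, 0.1, z_edges = seq(0, 1, by = 0.025)),
               "do not span")
})

test_that("higher spatial frequency probes shallower depths", {
  m <- skin_model(851)
  t <- simulate_pencil_beam(m, 851, 5e4, seed = 31)
  d0 <- pzmax_distribution(t, 0)
  d5 <- pzmax_distribution(t, 0.5)
  mids <- (d0$z_edges[-1] + d0$z_edges[-length(d0$z_edges)]) / 2
  mean_z <- function(d) sum(mids * d$pzmax) / sum(d$pzmax)
  expect_lt(mean_z(d5), mean_z(d0))
})

test_that("pMC reweighting is exact for null and single-record cases and keeps energy closed", {
  m <- skin_model(691)
  t <- simulate_pencil_beam(m, 691, 5000, seed = 41)
  expect_identical(pmc_reweight(t, "epidermis", 0), t)

  pl <- matrix(c(1.0, 0.2, 0.3, 0.1), 1, 4,
               dimnames = list(NULL, m$layer_names))
  t1 <- manual_tally(0.5, 1, 0.4, 10, path_lengths = pl,
                     layer_names = m$layer_names,
                     boundaries_mm = m$boundaries_mm)
  r1 <- pmc_reweight(t1, "epidermis", 0.1)
  expect_equal(r1$exit_weight, 0.5 * exp(-0.1))

  r <- pmc_reweight(t, "epidermis", 0.5)
  expect_lt(abs(energy_closure(r)), 1e-9)
  expect_error(pmc_reweight(t, "nonexistent", 0.1), "no layer named")
})

test_that("pMC agrees with a direct simulation of the perturbed absorption", {
  m <- homog_model(mua = 0.02, musp = 1.5, n = 1.4)
  t_b <- simulate_pencil_beam(m, 800, 4e4, seed = 51)
  dmua <- 0.08
  t_pmc <- pmc_reweight(t_b, "medium", dmua)
  m2 <- homog_model(mua = 0.02 + dmua, musp = 1.5, n = 1.4)
  t_dir <- simulate_pencil_beam(m2, 800, 4e4, seed = 5100)
  fx <- c(0, 0.05, 0.1, 0.2, 0.5)
  h1 <- hankel_rd(t_pmc, fx)
  h2 <- hankel_rd(t_dir, fx)
  z <- abs(h1$rd - h2$rd) / sqrt(h1$se^2 + h2$se^2)
  expect_true(all(z < 3))
})

test_that("delta_rd_grid vanishes for identical models under common random numbers", {
  m <- skin_model(811)
  g <- delta_rd_grid(m, m, 811, c(0, 0.1, 0.3), n_photons = 2000, seed = 61)
  expect_true(all(g$delta_rd == 0))
  expect_error(delta_rd_grid(m, m, 700, 0.1, n_photons = 10, seed = 1),
               "every requested wavelength")
})

test_that("dermal scattering reduction lowers reflectance at low frequency", {
  base <- skin_model(c(691, 851))
  pert <- apply_scleroderma_perturbation(base)
  g <- delta_rd_grid(base, pert, c(691, 851), c(0, 0.1, 0.2, 0.3),
                     n_photons = 4e4, seed = 71, melanin_level = 0.02)
  expect_true(all(g$delta_rd < -3 * g$mc_standard_error))
})

test_that("optimal_fx takes the argmax with the lower-fx tie break", {
  g <- structure(list(
    wavelengths = 700,
    spatial_frequencies = c(0.05, 0.1, 0.15),
    delta_rd = matrix(c(-0.01, -0.03, -0.02), 1)), class = "delta_rd_grid")
  expect_equal(as.vector(optimal_fx(g)), 0.1)
  g$delta_rd <- matrix(c(-0.03, -0.01, 0.03), 1)
  expect_equal(as.vector(optimal_fx(g)), 0.05) # exact |.| tie -> lower fx
})

test_that("layer contributions partition the total reflectance change", {
  base <- skin_model(851)
  pert <- apply_scleroderma_perturbation(base)
  t_b <- simulate_pencil_beam(base, 851, 2e4, seed = 81)
  t_p <- simulate_pencil_beam(pert, 851, 2e4, seed = 81)
  d_b <- pzmax_distribution(t_b, 0.15)
  d_p <- pzmax_distribution(t_p, 0.15)
  contrib <- layer_contributions(d_b, d_p, base)
  expect_named(contrib, base$layer_names)
  expect_equal(sum(contrib), sum(d_p$pzmax) - sum(d_b$pzmax), tolerance = 1e-12)
  # identical distributions -> all zero
  z <- layer_contributions(d_b, d_b, base)
  expect_true(all(z == 0))
  d_bad <- pzmax_distribution(t_p, 0.2)
  expect_error(layer_contributions(d_b, d_bad, base), "share z_edges")
})

test_that("radial overflow weight is kept in Rd(0) and warned about", {
  t_far <- manual_tally(c(0.5, 0.5), c(1, 80), c(0.1, 0.2), 10)
  expect_warning(h <- hankel_rd(t_far, 0), "beyond r_max")
  expect_equal(h$rd, 0.1) # nothing dropped
})
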