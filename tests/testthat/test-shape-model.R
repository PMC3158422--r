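test_that("isolated-atom calibration matches the closed forms", {
  rt <- radius_table()
  g <- build_gaussians(conformer("C", matrix(0, 1, 3)), rt)
  expect_equal(g$alpha, pi * (3 * 2 * sqrt(2) / (4 * pi))^(2 / 3) / 1.70^2,
               tolerance = 1e-12)
  # amplitude-weighted integral equals the hard-sphere volume
  expect_equal(g$p * (pi / g$alpha)^1.5, (4 / 3) * pi * 1.70^3,
               tolerance = 1e-10)

  gf <- build_gaussians(conformer("F", matrix(0, 1, 3)), rt)
  v_sphere <- (4 / 3) * pi * 1.47^3
  expect_equal(monopole_volume(gf), v_sphere, tolerance = 1e-10)
  expect_equal(self_overlap_volume(gf), v_sphere, tolerance = 1e-10)
  expect_equal(analytic_volume(gf), v_sphere, tolerance = 1e-10)
  q <- quadrupoles(gf)
  expect_equal(unname(q$q), rep(1 / (2 * gf$alpha), 3), tolerance = 1e-10)
})

test_that("construction rejects degenerate inputs", {
  expect_error(conformer(character(), matrix(0, 0, 3)), "no atoms")
  expect_error(conformer("H", matrix(0, 1, 3)), "no atoms")  # H dropped
  expect_error(conformer("C", matrix(c(0, 0, NA), 1, 3)), "finite")
  strict <- radius_table(default = NA)
  expect_error(build_gaussians(conformer("Xx", matrix(0, 1, 3)), strict),
               "Xx")
  g <- build_gaussians(conformer("C", matrix(0, 1, 3)), radius_table())
  expect_error(analytic_volume(g, max_order = 0), "max_order")
})

test_that("monopole volume is the atomic-volume sum, independent of pose", {
  rt <- radius_table()
  two <- function(d) build_gaussians(
    conformer(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0))), rt)
  v1 <- (4 / 3) * pi * 1.70^3
  expect_equal(monopole_volume(two(1.0)), 2 * v1, tolerance = 1e-12)
  expect_equal(monopole_volume(two(50)), 2 * v1, tolerance = 1e-12)
})

test_that("volumes agree with grid-quadrature oracles", {
  rt <- radius_table()
  conf <- random_conformer(8, seed = 31, id = "g8")
  g <- build_gaussians(conf, rt)
  expect_equal(monopole_volume(g), grid_density_integral(g, power = 1),
               tolerance = 0.005)
  expect_equal(self_overlap_volume(g), grid_density_integral(g, power = 2),
               tolerance = 0.005)

  # two bonded carbons, the worst case for the pairwise overlap term
  g2 <- build_gaussians(
    conformer(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0))), rt)
  expect_equal(self_overlap_volume(g2), grid_density_integral(g2, 2),
               tolerance = 0.005)
})

test_that("self-overlap is additive for far-separated fragments", {
  rt <- radius_table()
  g1 <- build_gaussians(chain_conformer(3), rt)
  far <- chain_conformer(3)
  far$coords <- far$coords + 100
  gb <- build_gaussians(
    conformer(c(rep("C", 3), rep("C", 3)),
              rbind(chain_conformer(3)$coords, far$coords)), rt)
  expect_equal(self_overlap_volume(gb),
               2 * self_overlap_volume(g1), tolerance = 1e-12)
  expect_equal(analytic_volume(gb), 2 * analytic_volume(g1),
               tolerance = 1e-9)
})

test_that("analytic volume matches inclusion-exclusion limits and MC", {
  rt <- radius_table()
  # two coincident calibrated atoms collapse to a single sphere at order 2
  g0 <- build_gaussians(
    conformer(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0))), rt)
  expect_equal(analytic_volume(g0, max_order = 2), (4 / 3) * pi * 1.70^3,
               tolerance = 1e-9)

  chain <- chain_conformer(6)
  g <- build_gaussians(chain, rt)
  mc <- mc_union_volume(chain$coords, atom_radius(rt, chain$elements),
                        n_points = 1e7, seed = 5)
  expect_equal(analytic_volume(g, max_order = 3), mc, tolerance = 0.03)
})

test_that("self-overlap exceeds monopole volume for bonded systems", {
  g <- build_gaussians(chain_conformer(6), radius_table())
  expect_gt(self_overlap_volume(g), monopole_volume(g))
})

test_that("quadrupoles obey ordering, axial symmetry and the Rg identity", {
  rt <- radius_table()
  # axial pair: two equal atoms on x -> Qy = Qz = isotropic single-atom value
  g2 <- build_gaussians(
    conformer(c("C", "C"), rbind(c(-1, 0, 0), c(1, 0, 0))), rt)
  q2 <- quadrupoles(g2)
  iso <- 1 / (2 * g2$alpha[1])
  expect_gt(q2$q[["qx"]], q2$q[["qy"]])
  expect_equal(q2$q[["qy"]], iso, tolerance = 1e-12)
  expect_equal(q2$q[["qz"]], iso, tolerance = 1e-12)

  for (seed in 1:20) {
    d <- shape_descriptors(random_conformer(
      5 + seed, seed = seed, id = "q"), rt)
    expect_true(d$qx >= d$qy && d$qy >= d$qz && d$qz > 0)
    expect_equal(d$qx + d$qy + d$qz, d$rg^2, tolerance = 1e-9)
    expect_equal(det(d$principal_axes), 1, tolerance = 1e-9)
  }
})

test_that("descriptors are invariant under proper rigid motion", {
  rt <- radius_table()
  fields <- c("v_an", "v_mp", "v_so", "qx", "qy", "qz", "rg")
  for (seed in 1:20) {
    conf <- random_conformer(5 + seed %% 16, seed = seed, id = "inv")
    moved <- random_rigid_copy(conf, seed = seed + 1000)
    d0 <- shape_descriptors(conf, rt)
    d1 <- shape_descriptors(moved, rt)
    for (f in fields) {
      expect_equal(d1[[f]], d0[[f]], tolerance = 1e-8)
    }
  }
})

test_that("descriptors are even under reflection", {
  rt <- radius_table()
  conf <- random_conformer(12, seed = 77, id = "chiral")
  mirror <- conf
  mirror$coords[, 1] <- -mirror$coords[, 1]
  d0 <- shape_descriptors(conf, rt)
  d1 <- shape_descriptors(mirror, rt)
  for (f in c("v_an", "v_mp", "v_so", "qx", "qy", "qz", "rg")) {
    expect_equal(d1[[f]], d0[[f]], tolerance = 1e-9)
  }
})

test_that("volume-scaled quadrupoles are the normalized ones times V_mp", {
  conf <- random_conformer(10, seed = 3, id = "sc")
  dn <- shape_descriptors(conf, quad_scale = "normalized")
  dv <- shape_descriptors(conf, quad_scale = "volume")
  expect_equal(dv$qx, dn$qx * dn$v_mp, tolerance = 1e-12)
  expect_equal(dv$qz, dn$qz * dn$v_mp, tolerance = 1e-12)
})
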