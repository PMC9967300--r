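test_that("the coupling prefactor reproduces the unit case, scaling laws and dye ratios", {
  p1 <- coupling_params(refractive_index = 1)
  expect_equal(coupling_prefactor(1, 1, 1, 1, p1), K_CM_ORACLE, tolerance = 1e-12)
  expect_equal(K_CM_ORACLE, 5.034, tolerance = 2e-4)  # magnitude sanity
  # n = 1 -> 2 divides J_o by 4
  p2 <- coupling_params(refractive_index = 2)
  expect_equal(coupling_prefactor(1, 1, 1, 1, p2), K_CM_ORACLE / 4, tolerance = 1e-12)
  # dye substitution ratio: (13.73 / 12.99)^2 at fixed geometry
  jo_h <- coupling_prefactor(12.99, 12.99, 1.4, 1.4, p1)
  jo_me <- coupling_prefactor(13.73, 13.73, 1.4, 1.4, p1)
  expect_equal(jo_me / jo_h, (13.73 / 12.99)^2, tolerance = 1e-12)
  expect_error(coupling_prefactor(12.99, 12.99, 0, 1.4, p1), "positive")
})

test_that("energy units are explicit and mutually consistent", {
  # 1 cm^-1 = 0.12398 meV, independent of geometry
  a <- coupling_params(1.33, "cm-1")
  b <- coupling_params(1.33, "meV")
  expect_equal(b$K / a$K, 0.1239842, tolerance = 1e-6)
})

test_that("extended-dipole coupling equals the independent four-point-charge oracle", {
  set.seed(407)
  p <- coupling_params()
  for (i in 1:200) {
    dm <- random_dipole(l = runif(1, 0.8, 1.8), mu_mag = runif(1, 10, 15))
    dn <- random_dipole(l = runif(1, 0.8, 1.8), mu_mag = runif(1, 10, 15))
    if (min(extended_dipole_coupling(dm, dn, p)$distances) < 0.05) next
    expect_equal(extended_dipole_coupling(dm, dn, p)$J_mn,
                 coulomb_coupling_oracle(dm, dn, p$n),
                 tolerance = 1e-12)
  }
})

test_that("coupling is exchange-symmetric and rigid-motion invariant", {
  set.seed(408)
  p <- coupling_params()
  for (i in 1:30) {
    dm <- random_dipole(); dn <- random_dipole()
    expect_equal(extended_dipole_coupling(dm, dn, p)$J_mn,
                 extended_dipole_coupling(dn, dm, p)$J_mn, tolerance = 1e-12)
    Q <- random_rotation(); shift <- rnorm(3)
    tr <- function(d) extended_dipole(
      drop(Q %*% d$c) + shift, drop(Q %*% d$mu_hat),
      drop(Q %*% d$r) + shift, drop(Q %*% d$s) + shift, d$mu_mag)
    expect_equal(extended_dipole_coupling(tr(dm), tr(dn), p)$J_mn,
                 extended_dipole_coupling(dm, dn, p)$J_mn, tolerance = 1e-10)
  }
})

test_that("cofacial geometries couple positively, head-to-tail negatively", {
  p <- coupling_params()
  mk <- function(c0, mu) extended_dipole(c0, mu, c0 + 0.7 * mu, c0 - 0.7 * mu, 12.99)
  # side-by-side parallel (H) above one another
  expect_gt(extended_dipole_coupling(mk(c(0, 0, 0), c(1, 0, 0)),
                                     mk(c(0, 0, 0.6), c(1, 0, 0)), p)$J_mn, 0)
  # collinear head-to-tail with a gap wider than the bridge
  expect_lt(extended_dipole_coupling(mk(c(0, 0, 0), c(1, 0, 0)),
                                     mk(c(2.0, 0, 0), c(1, 0, 0)), p)$J_mn, 0)
})

test_that("coupling scales linearly in each dipole magnitude and as n^-2", {
  set.seed(409)
  dm <- random_dipole(mu_mag = 10); dn <- random_dipole(mu_mag = 10)
  base <- extended_dipole_coupling(dm, dn, coupling_params(1.33))$J_mn
  dm3 <- dm; dm3$mu_mag <- 30
  expect_equal(extended_dipole_coupling(dm3, dn, coupling_params(1.33))$J_mn,
               3 * base, tolerance = 1e-12)
  expect_equal(extended_dipole_coupling(dm, dn, coupling_params(2.66))$J_mn,
               base / 4, tolerance = 1e-12)
})

test_that("the extended dipole converges monotonically to the point-dipole limit", {
  p <- coupling_params()
  R <- 3
  mk_pair <- function(l) {
    dm <- extended_dipole(c(0, 0, 0), c(0, 0, 1),
                          c(0, 0, l / 2), c(0, 0, -l / 2), 12.99)
    dn <- extended_dipole(c(R, 0, 0), c(0, 1, 1) / sqrt(2),
                          c(R, l / (2 * sqrt(2)), l / (2 * sqrt(2))),
                          c(R, -l / (2 * sqrt(2)), -l / (2 * sqrt(2))), 12.99)
    list(dm = dm, dn = dn)
  }
  ref <- point_dipole_coupling(mk_pair(0.01)$dm, mk_pair(0.01)$dn, p)
  errs <- vapply(c(1e-1, 1e-2, 1e-3) * R, function(l) {
    pr <- mk_pair(l)
    abs(extended_dipole_coupling(pr$dm, pr$dn, p)$J_mn -
          point_dipole_coupling(pr$dm, pr$dn, p)) / abs(ref)
  }, 1)
  expect_lt(errs[2], 1e-3)          # 0.1% at l = R/100
  expect_true(all(diff(errs) < 0))  # error shrinks with l/R
})

test_that("point-dipole coupling agrees with the orientation-factor magnitude", {
  set.seed(410)
  p <- coupling_params()
  for (i in 1:25) {
    dm <- random_dipole(mu_mag = 12.99); dn <- random_dipole(mu_mag = 12.99)
    g <- dimer_distance(dm, dn)
    k2 <- kappa_squared(dm$mu_hat, dn$mu_hat, g$R_hat)
    expect_equal(abs(point_dipole_coupling(dm, dn, p)),
                 p$K * 12.99^2 * sqrt(k2) / (p$n^2 * g$R^3), tolerance = 1e-9)
  }
  # H geometry: positive, equal to K mu^2 / (n^2 R^3)
  dm <- extended_dipole(c(0, 0, 0), c(0, 0, 1), c(0, 0, 0.7), c(0, 0, -0.7), 12.99)
  dn <- extended_dipole(c(2, 0, 0), c(0, 0, 1), c(2, 0, 0.7), c(2, 0, -0.7), 12.99)
  expect_equal(point_dipole_coupling(dm, dn, p),
               p$K * 12.99^2 / (p$n^2 * 8), tolerance = 1e-12)
})

test_that("the coupling series matches per-frame single calls and is constant for constant input", {
  fix <- ideal_dimer_trajectory(rep(0.6, 4))
  cs <- coupling_series(fix$traj, fix$sel)
  expect_equal(length(unique(round(cs$J_mn, 10))), 1L)
  sim <- generate_dimer_trajectory(generator_config(n_frames = 20, seed = 31,
                                                    orientation_jitter = 15))
  p <- coupling_params()
  series <- coupling_series(sim$trajectory, sim$selections, p = p)
  expect_equal(mean(series$J_mn), sum(series$J_mn) / nrow(series), tolerance = 1e-12)
  for (f in c(0L, 7L, 19L)) {
    dm <- extract_extended_dipole(sim$trajectory, sim$selections[[1]], f)
    dn <- extract_extended_dipole(sim$trajectory, sim$selections[[2]], f)
    expect_equal(series$J_mn[f + 1], extended_dipole_coupling(dm, dn, p)$J_mn,
                 tolerance = 1e-10)
  }
})

test_that("near-coincident bridge endpoints are rejected with the offending pair", {
  dm <- extended_dipole(c(0, 0, 0), c(1, 0, 0), c(0.7, 0, 0), c(-0.7, 0, 0), 12.99)
  dn <- extended_dipole(c(0.00005, 0, 0), c(1, 0, 0),
                        c(0.70005, 0, 0), c(-0.69995, 0, 0), 12.99)
  expect_error(extended_dipole_coupling(dm, dn), "d_rr")
})
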