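# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# Minimal trajectory: n_atoms single-carbon atoms, coords supplied per frame.
toy_trajectory <- function(coords, residue_id = NULL, masses = NULL, times = NULL) {
  na <- nrow(coords[[1]])
  atoms <- tibble::tibble(
    atom_index = seq_len(na),
    atom_name = paste0("C", seq_len(na)),
    element = "C",
    mass = masses %||% rep(12.0107, na),
    residue_id = residue_id %||% rep(1L, na)
  )
  trajectory(atoms, coords, times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A dye whose squarate carbons sit at (+-0.1, +-0.1, 0) and whose benzene
# rings are regular pentagons centered exactly at far/near centers (placed in
# the y-z plane so the geometric center is exact).
ideal_dye_coords <- function(far = c(1, 0, 0), near = c(-1, 0, 0)) {
  ring <- function(center) {
    a <- (0:4) * 2 * pi / 5
    t(vapply(a, function(t) center + c(0, 0.14 * cos(t), 0.14 * sin(t)), numeric(3)))
  }
  rbind(
    cbind(c(0.1, 0.1, -0.1, -0.1), c(0.1, -0.1, 0.1, -0.1), 0),
    ring(far),
    ring(near)
  )
}

ideal_dye_selection <- function(offset = 0L, name = "SQ-H2", residue_id = 1L) {
  dye_selection(name, residue_id,
                squarate_carbons = offset + 1:4,
                ring_far = offset + 5:9,
                ring_near = offset + 10:14)
}

# Two ideal dyes stacked cofacially along z at separation R; packing AB flips
# dye 2 about z. Returns list(traj, sel).
ideal_dimer_trajectory <- function(R_values, packing = "AA") {
  d1 <- ideal_dye_coords()
  d2 <- ideal_dye_coords()
  if (packing == "AB") d2 <- d2 %*% diag(c(-1, -1, 1))
  coords <- lapply(R_values, function(R) {
    top <- d2
    top[, 3] <- top[, 3] + R
    rbind(d1, top)
  })
  traj <- toy_trajectory(coords, residue_id = rep(1:2, each = nrow(d1)))
  sel <- selection_config(ideal_dye_selection(0L),
                          ideal_dye_selection(nrow(d1), residue_id = 2L))
  list(traj = traj, sel = sel)
}

# Random extended dipole with its center in a box, random orientation, and a
# bridge of length l along mu_hat (plus an optional transverse offset so the
# r-s axis need not be parallel to mu_hat).
random_dipole <- function(l = 1.4, mu_mag = 12.99, center_scale = 2) {
  cc <- rnorm(3) * center_scale
  mu <- unit_vec_test(rnorm(3))
  mid <- cc + rnorm(3) * 0.05
  extended_dipole(c = cc, mu_hat = mu,
                  r = mid + mu * l / 2, s = mid - mu * l / 2,
                  mu_mag = mu_mag)
}

unit_vec_test <- function(v) v / sqrt(sum(v^2))

# Conversion constant recomputed here from scratch (CODATA), kept separate
# from the package's internal value on purpose.
K_CM_ORACLE <- local({
  debye <- 1e-21 / 299792458
  (debye^2 / (4 * pi * 8.8541878128e-12 * 1e-27)) / (6.62607015e-34 * 2.99792458e10)
})

# Independent four-point-charge Coulomb oracle for the extended-dipole
# coupling: charges +-q_i = mu_i / l_i at the bridge termini, pairwise
# Coulomb sum with the same dielectric screening.
coulomb_coupling_oracle <- function(dm, dn, n_medium = 1.33) {
  q1 <- dm$mu_mag / dm$l
  q2 <- dn$mu_mag / dn$l
  pts1 <- list(list(q = +q1, p = dm$r), list(q = -q1, p = dm$s))
  pts2 <- list(list(q = +q2, p = dn$r), list(q = -q2, p = dn$s))
  e <- 0
  for (a in pts1) for (b in pts2)
    e <- e + a$q * b$q / sqrt(sum((a$p - b$p)^2))
  K_CM_ORACLE * e / n_medium^2
}

# Small rigid transform utilities for equivariance checks.
random_rotation <- function() {
  axis <- unit_vec_test(rnorm(3))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

transform_trajectory <- function(traj, Q, shift) {
  coords <- lapply(traj$coords, function(m) m %*% t(Q) + rep(shift, each = nrow(m)))
  trajectory(traj$atoms, coords, traj$times)
}
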