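#' Coupling parameters
#'
#' Collects the medium and unit conventions for the exciton hopping
#' calculation. The conversion constant `K` is the Coulomb energy of two
#' 1-Debye charges-distance products at 1 nm in vacuum, recomputed from
#' CODATA constants (about 5.0341 cm^-1 per D^2/nm^3); couplings scale with
#' the inverse square of the refractive index of the medium.
#'
#' @param refractive_index Refractive index `n` of the medium (> 0). Default
#'   1.33 (aqueous buffer).
#' @param energy_unit `"cm-1"` (default) or `"meV"`.
#' @return A list of class `coupling_params` with `n`, `energy_unit`, `K`.
#' @export
coupling_params <- function(refractive_index = 1.33, energy_unit = c("cm-1", "meV")) {
  energy_unit <- match.arg(energy_unit)
  assert_that(refractive_index > 0, "refractive index must be positive")
  structure(list(
    n = refractive_index,
    energy_unit = energy_unit,
    K = if (energy_unit == "cm-1") .const$K_cm else .const$K_meV
  ), class = "coupling_params")
}

#' Extended-dipole coupling prefactor J_o
#'
#' `J_o = K * mu_m * mu_n / (n^2 * l_m * l_n)`: the homodimer form prints
#' `|mu|^2`; the product generalization reduces to it when the magnitudes are
#' equal.
#'
#' @param mu_mag_m,mu_mag_n Transition dipole magnitudes (Debye, > 0).
#' @param l_m,l_n Pi-bridge lengths (nm, > 0).
#' @param p A [coupling_params()].
#' @return `J_o` in the configured energy unit.
#' @export
coupling_prefactor <- function(mu_mag_m, mu_mag_n, l_m, l_n, p = coupling_params()) {
  assert_that(all(c(mu_mag_m, mu_mag_n) > 0), "dipole magnitudes must be positive")
  assert_that(all(c(l_m, l_n) > 0), "bridge lengths must be positive")
  p$K * mu_mag_m * mu_mag_n / (p$n^2 * l_m * l_n)
}

#' Exciton hopping parameter in the extended dipole approximation
#'
#' Each transition dipole is replaced by opposite point charges at the
#' pi-bridge termini `r` and `s` (the terminal benzene ring centers), and the
#' four Coulomb terms are summed:
#' `J_mn = J_o * (1/|r1-r2| - 1/|r1-s2| - 1/|s1-r2| + 1/|s1-s2|)`.
#' Cofacial (H) geometries give positive J, head-to-tail (J-aggregate)
#' geometries negative J under this sign convention.
#'
#' @param dm,dn `extended_dipole` objects (dye m = 1, dye n = 2).
#' @param p A [coupling_params()].
#' @return A list of class `coupling_result` with `J_o`, `J_mn`, and the four
#'   endpoint distances `d_rr`, `d_rs`, `d_sr`, `d_ss` (nm).
#' @export
extended_dipole_coupling <- function(dm, dn, p = coupling_params()) {
  d <- c(
    d_rr = vec_norm(dm$r - dn$r),
    d_rs = vec_norm(dm$r - dn$s),
    d_sr = vec_norm(dm$s - dn$r),
    d_ss = vec_norm(dm$s - dn$s)
  )
  bad <- names(d)[d <= 1e-4]
  if (length(bad) > 0)
    stop("near-coincident bridge endpoints (pair ", paste(bad, collapse = ", "),
         "): distance below 1e-4 nm", call. = FALSE)
  J_o <- coupling_prefactor(dm$mu_mag, dn$mu_mag, dm$l, dn$l, p)
  structure(list(
    J_o = J_o,
    J_mn = J_o * (1 / d[["d_rr"]] - 1 / d[["d_rs"]] - 1 / d[["d_sr"]] + 1 / d[["d_ss"]]),
    distances = d
  ), class = "coupling_result")
}

#' Point-dipole coupling (ideal-dipole reference)
#'
#' The limit of the extended dipole expression as the bridge length shrinks:
#' `J = K * mu_m * mu_n * (mu_hat_m . mu_hat_n - 3 (mu_hat_m . R_hat)(mu_hat_n . R_hat)) / (n^2 R^3)`.
#' Useful as a cross-check: the extended-dipole value converges to this as
#' `l / R -> 0`.
#'
#' @inheritParams extended_dipole_coupling
#' @return Coupling energy in the configured unit.
#' @export
point_dipole_coupling <- function(dm, dn, p = coupling_params()) {
  g <- dimer_distance(dm, dn)
  orient <- sum(dm$mu_hat * dn$mu_hat) -
    3 * sum(dm$mu_hat * g$R_hat) * sum(dn$mu_hat * g$R_hat)
  p$K * dm$mu_mag * dn$mu_mag * orient / (p$n^2 * g$R^3)
}

#' Per-frame coupling series
#'
#' Evaluates the extended-dipole coupling for every frame of a trajectory.
#'
#' @param traj A [trajectory()].
#' @param sel A [selection_config()].
#' @param params Dye parameter table.
#' @param p A [coupling_params()].
#' @return A tibble with `frame_index`, `time`, `J_mn` and the four endpoint
#'   distances (for audit).
#' @export
coupling_series <- function(traj, sel, params = dye_parameters(), p = coupling_params()) {
  sm <- extended_dipole_series(traj, sel[[1]], params = params)
  sn <- extended_dipole_series(traj, sel[[2]], params = params)
  coupling_from_dipole_series(sm, sn, p)
}

# Internal: vectorized Eq.-1 evaluation on two aligned dipole series.
coupling_from_dipole_series <- function(sm, sn, p = coupling_params()) {
  assert_that(nrow(sm) == nrow(sn), "dipole series are not frame-aligned")
  pd <- function(ax, ay, az, bx, by, bz)
    sqrt((ax - bx)^2 + (ay - by)^2 + (az - bz)^2)
  d_rr <- pd(sm$rx, sm$ry, sm$rz, sn$rx, sn$ry, sn$rz)
  d_rs <- pd(sm$rx, sm$ry, sm$rz, sn$sx, sn$sy, sn$sz)
  d_sr <- pd(sm$sx, sm$sy, sm$sz, sn$rx, sn$ry, sn$rz)
  d_ss <- pd(sm$sx, sm$sy, sm$sz, sn$sx, sn$sy, sn$sz)
  too_close <- which(pmin(d_rr, d_rs, d_sr, d_ss) <= 1e-4)
  if (length(too_close) > 0)
    stop("near-coincident bridge endpoints in frame(s) ",
         paste(head(sm$frame_index[too_close], 5), collapse = ", "), call. = FALSE)
  J_o <- p$K * sm$mu_mag * sn$mu_mag / (p$n^2 * sm$l * sn$l)
  tibble::tibble(
    frame_index = sm$frame_index,
    time = sm$time,
    J_mn = J_o * (1 / d_rr - 1 / d_rs - 1 / d_sr + 1 / d_ss),
    d_rr = d_rr, d_rs = d_rs, d_sr = d_sr, d_ss = d_ss
  )
}
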