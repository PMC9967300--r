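#' Per-dye atom selection
#'
#' Identifies the atoms defining one dye's extended-dipole geometry: the four
#' squarate carbons (whose mass-weighted center is the dye center), and the
#' two terminal benzene rings. `ring_far` is the ring furthest from the
#' linker: the transition dipole direction points from the dye center toward
#' its geometric center, along the long axis of the dye. Atom indices are
#' 1-based.
#'
#' @param name Dye name (used to look up `|mu|` in the dye parameter table).
#' @param residue_id Residue id of the dye.
#' @param squarate_carbons Exactly 4 atom indices.
#' @param ring_far,ring_near At least 5 atom indices each; disjoint.
#' @return A list of class `dye_selection`.
#' @export
dye_selection <- function(name, residue_id, squarate_carbons, ring_far, ring_near) {
  assert_that(length(squarate_carbons) == 4, "exactly 4 squarate carbons are required")
  assert_that(length(ring_far) >= 5, "ring_far needs at least 5 atoms")
  assert_that(length(ring_near) >= 5, "ring_near needs at least 5 atoms")
  assert_that(length(intersect(ring_far, ring_near)) == 0,
              "ring selections must be disjoint")
  structure(list(
    name = name, residue_id = as.integer(residue_id),
    squarate_carbons = as.integer(squarate_carbons),
    ring_far = as.integer(ring_far), ring_near = as.integer(ring_near)
  ), class = "dye_selection")
}

#' Selection configuration for a dye dimer
#'
#' @param ... Two (or more) [dye_selection()] objects, in configuration order;
#'   the first is dye m, the second dye n.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(...) {
  dyes <- list(...)
  assert_that(length(dyes) >= 2, "a dimer selection needs two dye selections")
  assert_that(all(vapply(dyes, inherits, TRUE, "dye_selection")),
              "all arguments must be dye_selection objects")
  structure(dyes, class = "selection_config")
}

#' Transition-dipole magnitudes for the packaged squaraine dyes
#'
#' Returns the TDDFT transition-dipole magnitudes (Debye) for the three
#' squaraine variants, as consumed constants: SQ-H2 12.99 D, SQ-Cl2 13.41 D,
#' SQ-Me2 13.73 D. The same table ships as
#' `system.file("extdata", "dye_parameters.csv", package = "sqdimer")`.
#'
#' @return A tibble with columns `dye`, `mu_debye`.
#' @export
dye_parameters <- function() {
  tibble::tibble(
    dye = c("SQ-H2", "SQ-Cl2", "SQ-Me2"),
    mu_debye = c(12.99, 13.41, 13.73)
  )
}

#' Look up a dye's transition-dipole magnitude
#'
#' @param dye_name Dye name.
#' @param params A dye parameter table (`dye`, `mu_debye`); defaults to
#'   [dye_parameters()].
#' @return `|mu|` in Debye.
#' @export
dye_mu <- function(dye_name, params = dye_parameters()) {
  i <- match(dye_name, params$dye)
  assert_that(!is.na(i), paste("unknown dye:", dye_name))
  mu <- params$mu_debye[i]
  assert_that(mu > 0, "transition dipole magnitude must be positive")
  mu
}

#' Extended-dipole representation of one dye in one frame
#'
#' Builds the geometric objects the coupling and orientation stages consume:
#' the dye center `c` (mass-weighted center of the four squarate carbons),
#' the transition-dipole unit vector `mu_hat` (from `c` toward the unweighted
#' geometric center of the far benzene ring), and the pi-conjugation bridge
#' termini `r` (far ring center, the end `mu_hat` points toward) and `s`
#' (near ring center), with bridge length `l = |r - s|`.
#'
#' @param traj A [trajectory()].
#' @param dye A [dye_selection()].
#' @param frame 0-based frame index.
#' @param mu_mag Transition dipole magnitude in Debye; defaults to looking up
#'   `dye$name` in `params`.
#' @param params Dye parameter table for the lookup.
#' @return A list of class `extended_dipole` with elements `c`, `mu_hat`,
#'   `r`, `s`, `l`, `mu_mag`.
#' @export
extract_extended_dipole <- function(traj, dye, frame = 0L, mu_mag = NULL,
                                    params = dye_parameters()) {
  coords <- frame_coords(traj, frame)
  mu_mag <- mu_mag %||% dye_mu(dye$name, params)
  cc <- com_of(coords, dye$squarate_carbons, traj$atoms$mass)
  far <- colMeans(coords[dye$ring_far, , drop = FALSE])
  near <- colMeans(coords[dye$ring_near, , drop = FALSE])
  axis <- far - cc
  if (vec_norm(axis) < 1e-6)
    stop("degenerate dye geometry: far ring center coincides with the squarate center",
         call. = FALSE)
  d <- structure(list(
    c = cc, mu_hat = unit_vec(axis), r = far, s = near,
    l = vec_norm(far - near), mu_mag = mu_mag
  ), class = "extended_dipole")
  assert_that(d$l > 0, "bridge length must be positive")
  assert_that(sum(d$mu_hat * (d$r - d$s)) > 0,
              "bridge axis points against mu_hat; check ring_far/ring_near")
  d
}

#' Construct an extended dipole directly from geometry
#'
#' Mostly useful for tests and idealized geometries.
#'
#' @param c Dye center (nm).
#' @param mu_hat Dipole direction (normalized internally).
#' @param r,s Bridge termini (nm); `r` is the end `mu_hat` points toward.
#' @param mu_mag `|mu|` in Debye.
#' @return An `extended_dipole`.
#' @export
extended_dipole <- function(c, mu_hat, r, s, mu_mag) {
  d <- structure(list(
    c = as.numeric(c), mu_hat = unit_vec(as.numeric(mu_hat)),
    r = as.numeric(r), s = as.numeric(s),
    l = vec_norm(as.numeric(r) - as.numeric(s)), mu_mag = mu_mag
  ), class = "extended_dipole")
  assert_that(d$l > 0, "bridge length must be positive")
  assert_that(d$mu_mag > 0, "transition dipole magnitude must be positive")
  assert_that(sum(d$mu_hat * (d$r - d$s)) > 0,
              "r must be the terminus mu_hat points toward")
  d
}

#' Transition dipole vector
#'
#' @param d An `extended_dipole`.
#' @return `mu_mag * mu_hat`, in Debye.
#' @export
dipole_vector <- function(d) d$mu_mag * d$mu_hat

#' Extended dipoles for every frame of a trajectory
#'
#' @inheritParams extract_extended_dipole
#' @return A tibble with one row per frame: `frame_index`, `time`, dye center
#'   (`cx`, `cy`, `cz`), dipole direction (`mux`, `muy`, `muz`), bridge
#'   termini (`rx` ... `sz`), bridge length `l` and `mu_mag`.
#' @export
extended_dipole_series <- function(traj, dye, mu_mag = NULL, params = dye_parameters()) {
  mu_mag <- mu_mag %||% dye_mu(dye$name, params)
  nf <- n_frames(traj)
  rows <- lapply(seq_len(nf) - 1L, function(f) {
    d <- extract_extended_dipole(traj, dye, f, mu_mag = mu_mag)
    c(d$c, d$mu_hat, d$r, d$s, d$l)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("cx", "cy", "cz", "mux", "muy", "muz",
                   "rx", "ry", "rz", "sx", "sy", "sz", "l")
  dplyr::bind_cols(
    tibble::tibble(frame_index = seq_len(nf) - 1L, time = traj$times),
    tibble::as_tibble(m),
    tibble::tibble(mu_mag = mu_mag)
  )
}

# Internal: one row of an extended_dipole_series back to an extended_dipole.
dipole_from_row <- function(row) {
  extended_dipole(
    c = c(row$cx, row$cy, row$cz),
    mu_hat = c(row$mux, row$muy, row$muz),
    r = c(row$rx, row$ry, row$rz),
    s = c(row$sx, row$sy, row$sz),
    mu_mag = row$mu_mag
  )
}
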