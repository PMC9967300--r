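#' Construct a trajectory object
#'
#' A trajectory is an ordered set of frames of all-atom coordinates together
#' with per-atom bookkeeping (name, element, mass, residue id). Coordinates
#' are always stored in nanometres; readers convert on the way in
#' (PDB and XYZ files are in Angstrom, GRO files are already in nm).
#'
#' @param atoms A data frame with one row per atom and columns `atom_index`
#'   (1-based, unique), `atom_name`, `element`, `mass` (Da, > 0) and
#'   `residue_id` (integer >= 1). An optional `res_name` column is carried
#'   through to file writers.
#' @param coords A list of numeric matrices, one per frame, each
#'   `n_atoms x 3`, in nm.
#' @param times Numeric vector of frame times in ns (non-decreasing). Defaults
#'   to `0, 1, 2, ...`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, times = NULL) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("atom_index", "atom_name", "element", "mass", "residue_id")
  missing_cols <- setdiff(req, names(atoms))
  assert_that(length(missing_cols) == 0,
              paste("atoms is missing columns:", paste(missing_cols, collapse = ", ")))
  assert_that(!anyDuplicated(atoms$atom_index), "atom_index values must be unique")
  assert_that(all(atoms$mass > 0), "all atom masses must be positive")
  assert_that(all(atoms$residue_id >= 1), "residue ids must be >= 1")
  assert_that(is.list(coords) && length(coords) >= 1, "coords must be a non-empty list of matrices")
  na <- nrow(atoms)
  for (k in seq_along(coords)) {
    m <- coords[[k]]
    if (!is.matrix(m) || nrow(m) != na || ncol(m) != 3)
      stop(sprintf("frame %d: expected a %d x 3 coordinate matrix", k - 1L, na), call. = FALSE)
    if (!all(is.finite(m)))
      stop(sprintf("frame %d: non-finite coordinates", k - 1L), call. = FALSE)
    dimnames(coords[[k]]) <- NULL
  }
  if (is.null(times)) times <- as.numeric(seq_along(coords) - 1L)
  assert_that(length(times) == length(coords), "times must have one entry per frame")
  assert_that(!is.unsorted(times), "frame times must be non-decreasing")
  structure(
    list(atoms = atoms, coords = coords, times = as.numeric(times)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %d residues, t = [%g, %g] ns\n",
              n_frames(x), n_atoms(x), length(unique(x$atoms$residue_id)),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A [trajectory()].
#' @return An integer count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Coordinates of one frame
#'
#' @param traj A [trajectory()].
#' @param frame 0-based frame index (frames are numbered from 0 like the
#'   per-frame tables the analysis functions return).
#' @return An `n_atoms x 3` matrix in nm.
#' @export
frame_coords <- function(traj, frame) {
  assert_that(frame >= 0 && frame < n_frames(traj), "frame index out of range")
  traj$coords[[frame + 1L]]
}

# Internal: mass-weighted center of a set of atom rows in one coordinate matrix.
com_of <- function(coords, atom_indices, masses) {
  assert_that(length(atom_indices) >= 1, "empty atom selection")
  m <- masses[atom_indices]
  drop(crossprod(coords[atom_indices, , drop = FALSE], m)) / sum(m)
}

#' Mass-weighted residue center of mass per frame
#'
#' Computes the mass-weighted mean position of a set of atoms in every frame
#' (or a subset of frames). All atoms in the selection are used, hydrogens
#' included when present.
#'
#' @param traj A [trajectory()].
#' @param atom_indices Integer vector of 1-based atom indices (non-empty).
#' @param frames Optional integer vector of 0-based frame indices; default all.
#' @return A tibble with columns `frame_index`, `time`, `x`, `y`, `z` (nm).
#' @export
residue_center_of_mass <- function(traj, atom_indices, frames = NULL) {
  assert_that(length(atom_indices) >= 1, "empty atom selection")
  assert_that(all(atom_indices >= 1 & atom_indices <= n_atoms(traj)),
              "atom indices out of range")
  if (is.null(frames)) frames <- seq_len(n_frames(traj)) - 1L
  masses <- traj$atoms$mass
  out <- t(vapply(frames, function(f) com_of(traj$coords[[f + 1L]], atom_indices, masses),
                  numeric(3)))
  tibble::tibble(
    frame_index = as.integer(frames),
    time = traj$times[frames + 1L],
    x = out[, 1], y = out[, 2], z = out[, 3]
  )
}

#' Discard equilibration frames and stride a trajectory
#'
#' Drops the first `ceiling(skip_fraction * n_frames)` frames (the
#' equilibration period, expressed as a fraction of the run so the rule scales
#' to any trajectory length; 0.05 reproduces skipping 0.1 us of a 2 us run),
#' then keeps every `stride`-th of the remaining frames, preserving order.
#'
#' @param traj A [trajectory()].
#' @param skip_fraction Fraction of leading frames to drop, in `[0, 1)`.
#' @param stride Keep every `stride`-th frame (integer >= 1).
#' @return A [trajectory()] with the retained frames.
#' @export
slice_trajectory <- function(traj, skip_fraction = 0, stride = 1L) {
  assert_that(skip_fraction >= 0 && skip_fraction < 1, "skip_fraction must be in [0, 1)")
  assert_that(stride >= 1, "stride must be >= 1")
  nf <- n_frames(traj)
  drop_n <- ceiling(skip_fraction * nf)
  keep <- if (drop_n > 0) seq_len(nf)[-seq_len(drop_n)] else seq_len(nf)
  if (length(keep) == 0) stop("slicing removed every frame", call. = FALSE)
  keep <- keep[seq(1L, length(keep), by = as.integer(stride))]
  trajectory(traj$atoms, traj$coords[keep], traj$times[keep])
}

#' Residue map constructor
#'
#' The residue map labels every residue id appearing in a trajectory with a
#' type and the strand it belongs to. Residue ids must be contiguous within
#' each strand.
#'
#' @param residue_id Integer vector of residue ids (unique).
#' @param label Character vector, each one of `"nucleotide"`, `"linker"`,
#'   `"dye"`, `"other"`.
#' @param strand Character vector, each one of `"A"`, `"B"`, `"C"`, `"D"`,
#'   `"none"`.
#' @return A tibble of class `residue_map`.
#' @export
residue_map <- function(residue_id, label, strand = "none") {
  rm <- tibble::tibble(
    residue_id = as.integer(residue_id),
    label = as.character(label),
    strand = rep_len(as.character(strand), length(residue_id))
  )
  assert_that(!anyDuplicated(rm$residue_id), "residue ids must be unique")
  assert_that(all(rm$label %in% c("nucleotide", "linker", "dye", "other")),
              "labels must be nucleotide/linker/dye/other")
  assert_that(all(rm$strand %in% c("A", "B", "C", "D", "none")),
              "strands must be A/B/C/D/none")
  for (s in setdiff(unique(rm$strand), "none")) {
    ids <- sort(rm$residue_id[rm$strand == s])
    assert_that(all(diff(ids) == 1L),
                sprintf("residue ids of strand %s are not contiguous", s))
  }
  class(rm) <- c("residue_map", class(rm))
  rm
}

# Internal: check a residue map against a trajectory's atoms.
validate_residue_map <- function(rmap, traj) {
  ids <- unique(traj$atoms$residue_id)
  missing_ids <- setdiff(ids, rmap$residue_id)
  assert_that(length(missing_ids) == 0,
              paste("residues present in trajectory but not in map:",
                    paste(missing_ids, collapse = ", ")))
  dye_ids <- rmap$residue_id[rmap$label == "dye"]
  for (d in dye_ids)
    assert_that(any(traj$atoms$residue_id == d),
                sprintf("dye residue %d has no atoms", d))
  invisible(TRUE)
}
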