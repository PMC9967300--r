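#' Pairwise frame-frame RMSD matrix
#'
#' RMSD over a fixed atom selection between every pair of frames. With
#' `superpose = TRUE` (default) frame j is optimally rigid-superposed onto
#' frame i over the same selection (Kabsch) before the deviation is measured,
#' the usual convention for GROMOS-style clustering; `superpose = FALSE`
#' compares raw coordinates.
#'
#' @param traj A [trajectory()].
#' @param atom_selection Integer vector of 1-based atom indices (e.g. all
#'   atoms of both dye residues).
#' @param superpose Logical; superpose frames before measuring (default TRUE).
#' @return A symmetric `n_frames x n_frames` matrix in nm with zero diagonal.
#' @export
pairwise_rmsd <- function(traj, atom_selection, superpose = TRUE) {
  assert_that(length(atom_selection) >= 1, "empty atom selection")
  assert_that(n_frames(traj) >= 2, "need at least two frames")
  assert_that(all(atom_selection >= 1 & atom_selection <= n_atoms(traj)),
              "atom indices out of range")
  nf <- n_frames(traj)
  na <- length(atom_selection)
  cube <- array(0, dim = c(na, 3L, nf))
  for (k in seq_len(nf))
    cube[, , k] <- traj$coords[[k]][atom_selection, , drop = FALSE]
  pairwise_rmsd_cpp(cube, superpose)
}

#' Greedy GROMOS clustering of frames
#'
#' Iteratively takes the frame with the largest number of neighbors within
#' the RMSD cutoff (ties broken toward the lowest frame index), forms a
#' cluster of that frame plus its neighbors, removes them, and repeats until
#' no frames remain. Singleton clusters are allowed.
#'
#' @param m RMSD matrix from [pairwise_rmsd()].
#' @param cutoff Neighbor cutoff in nm (default 0.05).
#' @return An object of class `cluster_set`: list with `clusters` (tibble:
#'   `cluster`, `center_frame`, `n_members`, `fraction`), `assignment`
#'   (integer vector, cluster id per frame, 0-based frames), `n_frames`,
#'   `cutoff`, `min_fraction` (NA until filtered), `discarded_fraction`.
#' @export
gromos_cluster <- function(m, cutoff = 0.05) {
  assert_that(is.matrix(m) && nrow(m) == ncol(m), "m must be a square matrix")
  nf <- nrow(m)
  neighbor <- m <= cutoff
  alive <- rep(TRUE, nf)
  assignment <- integer(nf)
  centers <- integer(0)
  sizes <- integer(0)
  cl <- 0L
  while (any(alive)) {
    counts <- rowSums(neighbor[, alive, drop = FALSE]) * alive
    center <- which.max(counts)  # which.max takes the first (lowest index) tie
    members <- which(neighbor[center, ] & alive)
    cl <- cl + 1L
    assignment[members] <- cl
    centers <- c(centers, center)
    sizes <- c(sizes, length(members))
    alive[members] <- FALSE
  }
  structure(list(
    clusters = tibble::tibble(
      cluster = seq_len(cl),
      center_frame = as.integer(centers - 1L),
      n_members = sizes,
      fraction = sizes / nf
    ),
    assignment = assignment,
    n_frames = nf,
    cutoff = cutoff,
    min_fraction = NA_real_,
    discarded_fraction = 0
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) over %d frames (cutoff %.3f nm",
              nrow(x$clusters), x$n_frames, x$cutoff))
  if (!is.na(x$min_fraction))
    cat(sprintf("; filtered at > %.0f%%, %.1f%% of frames discarded",
                100 * x$min_fraction, 100 * x$discarded_fraction))
  cat(")\n")
  invisible(x)
}

#' Discard minor clusters
#'
#' Retains clusters whose frame fraction is strictly greater than
#' `min_fraction` (default 0.05, i.e. "more than 5% of frames"), discarding
#' minor clusters interpreted as transition states. Frames of discarded
#' clusters get assignment `NA`.
#'
#' @param cs A `cluster_set`.
#' @param min_fraction Retention threshold (strictly greater than).
#' @return A filtered `cluster_set` recording the discarded frame fraction.
#' @export
filter_clusters <- function(cs, min_fraction = 0.05) {
  keep <- cs$clusters$fraction > min_fraction
  if (!any(keep))
    stop("all clusters fall at or below the minimum fraction; ",
         "review the RMSD cutoff", call. = FALSE)
  kept <- cs$clusters[keep, ]
  old_ids <- kept$cluster
  kept$cluster <- seq_len(nrow(kept))
  assignment <- match(cs$assignment, old_ids)
  cs$clusters <- kept
  cs$assignment <- assignment
  cs$min_fraction <- min_fraction
  cs$discarded_fraction <- 1 - sum(kept$fraction)
  cs
}

#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_frames = x$n_frames,
    cutoff = x$cutoff,
    largest_fraction = max(x$clusters$fraction),
    discarded_fraction = x$discarded_fraction
  )
}
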