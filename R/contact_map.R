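# Internal: residue CoM matrix (n_res x 3) for one frame, residues grouped
# once up front by the caller.
residue_com_matrix <- function(coords, groups, masses) {
  t(vapply(groups, function(idx) com_of(coords, idx, masses), numeric(3)))
}

residue_groups <- function(traj, residue_ids) {
  g <- lapply(residue_ids, function(rid) which(traj$atoms$residue_id == rid))
  empty <- residue_ids[lengths(g) == 0]
  assert_that(length(empty) == 0,
              paste("residue(s) with no atoms:", paste(empty, collapse = ", ")))
  g
}

#' Boolean residue contact matrix for a single frame
#'
#' Residues are in contact when their centers of mass lie within `cutoff`
#' (boundary included: exactly `cutoff` counts as contact). The diagonal is
#' `TRUE`.
#'
#' @param traj A [trajectory()].
#' @param rmap A [residue_map()].
#' @param frame 0-based frame index.
#' @param cutoff Contact cutoff in nm (default 1.2, the nonbonded
#'   electrostatic cutoff of the simulations the criterion mirrors).
#' @return A symmetric logical matrix with residue ids as dimnames.
#' @export
frame_contacts <- function(traj, rmap, frame = 0L, cutoff = 1.2) {
  validate_residue_map(rmap, traj)
  ids <- sort(rmap$residue_id)
  groups <- residue_groups(traj, ids)
  com <- residue_com_matrix(frame_coords(traj, frame), groups, traj$atoms$mass)
  d <- as.matrix(dist(com))
  m <- d <= cutoff
  diag(m) <- TRUE
  dimnames(m) <- list(ids, ids)
  m
}

#' Residue-residue contact probability over a trajectory
#'
#' For every residue pair, the fraction of frames in which the residue
#' centers of mass are within `cutoff` of each other; a pair within the
#' cutoff for the entire trajectory has probability 1.
#'
#' @inheritParams frame_contacts
#' @return An object of class `contact_map`: list with `P` (symmetric
#'   probability matrix, unit diagonal), `residues` (the residue map, sorted
#'   by id), `cutoff` and `n_frames`.
#' @export
contact_probability <- function(traj, rmap, cutoff = 1.2) {
  validate_residue_map(rmap, traj)
  assert_that(n_frames(traj) >= 1, "empty trajectory")
  ids <- sort(rmap$residue_id)
  groups <- residue_groups(traj, ids)
  masses <- traj$atoms$mass
  nres <- length(ids)
  acc <- matrix(0, nres, nres)
  for (k in seq_len(n_frames(traj))) {
    com <- residue_com_matrix(traj$coords[[k]], groups, masses)
    acc <- acc + (as.matrix(dist(com)) <= cutoff)
  }
  P <- acc / n_frames(traj)
  diag(P) <- 1
  dimnames(P) <- list(ids, ids)
  res <- rmap[order(rmap$residue_id), ]
  structure(list(P = P, residues = res, cutoff = cutoff,
                 n_frames = n_frames(traj)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d residues, cutoff %.2f nm, %d frames\n",
              nrow(x$P), x$cutoff, x$n_frames))
  invisible(x)
}

#' Tidy a contact map into a long tibble
#'
#' @param x A `contact_map`.
#' @param ... Unused.
#' @return A tibble with `residue_i`, `residue_j`, `probability`, plus the
#'   label and strand of each residue.
#' @export
tidy.contact_map <- function(x, ...) {
  ids <- as.integer(rownames(x$P))
  long <- tidyr::expand_grid(residue_i = ids, residue_j = ids)
  long$probability <- as.vector(t(x$P))
  meta <- x$residues
  long |>
    dplyr::left_join(meta, by = c(residue_i = "residue_id")) |>
    dplyr::rename(label_i = "label", strand_i = "strand") |>
    dplyr::left_join(meta, by = c(residue_j = "residue_id")) |>
    dplyr::rename(label_j = "label", strand_j = "strand")
}

#' @rdname tidy.contact_map
#' @export
glance.contact_map <- function(x, ...) {
  off <- x$P[upper.tri(x$P)]
  tibble::tibble(
    n_residues = nrow(x$P),
    n_frames = x$n_frames,
    cutoff = x$cutoff,
    mean_probability = mean(off),
    n_contacts = sum(off > 0)
  )
}

#' Per-dye contact summary
#'
#' For each dye residue, counts the non-dye residues whose contact
#' probability with the dye is at least `threshold`, and lists their ids and
#' strands.
#'
#' @param cm A `contact_map`.
#' @param threshold Probability threshold in `[0, 1]` (default 0.5).
#' @return A tibble with `dye_residue`, `n_contacts`, and a list-column
#'   `contacts` of tibbles (`residue_id`, `label`, `strand`, `probability`).
#' @export
dye_contact_summary <- function(cm, threshold = 0.5) {
  dye_ids <- cm$residues$residue_id[cm$residues$label == "dye"]
  assert_that(length(dye_ids) > 0, "no dye residues in the residue map")
  ids <- as.integer(rownames(cm$P))
  purrr::map_dfr(dye_ids, function(d) {
    p <- cm$P[as.character(d), ]
    other <- cm$residues$label[match(ids, cm$residues$residue_id)] != "dye"
    hit <- other & p >= threshold
    tibble::tibble(
      dye_residue = d,
      n_contacts = sum(hit),
      contacts = list(tibble::tibble(
        residue_id = ids[hit],
        label = cm$residues$label[match(ids[hit], cm$residues$residue_id)],
        strand = cm$residues$strand[match(ids[hit], cm$residues$residue_id)],
        probability = unname(p[hit])
      ))
    )
  })
}

#' Contact map heat map
#'
#' Renders the probability matrix as a tile plot with a logarithmic color
#' scale (zero-probability pairs are blank); dye rows/columns are marked with
#' dashed magenta lines.
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_map <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$probability > 0 & d$residue_i != d$residue_j, ]
  dye_ids <- object$residues$residue_id[object$residues$label == "dye"]
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$residue_i, .data$residue_j,
                                       fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10", limits = c(NA, 1),
                                  name = "contact\nprobability") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue ID", y = "residue ID") +
    ggplot2::theme_minimal()
  if (length(dye_ids) > 0)
    p <- p +
      ggplot2::geom_hline(yintercept = dye_ids, linetype = "dashed",
                          color = "magenta", linewidth = 0.3) +
      ggplot2::geom_vline(xintercept = dye_ids, linetype = "dashed",
                          color = "magenta", linewidth = 0.3)
  p
}
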