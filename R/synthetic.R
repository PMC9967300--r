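#' Configuration for the synthetic dimer trajectory generator
#'
#' The generator emulates the statistical structure of a dye-dimer MD
#' ensemble without simulating any physics: two rigid squaraine-like dyes
#' fluctuate about an ideal H-aggregate (cofacial) geometry with a
#' configurable center-center distance distribution, packing (parallel AA or
#' antiparallel AB), and small random orientation jitter; optionally a
#' contiguous block of frames is re-based on a second geometry (a planted
#' conformer switch), and a mock four-arm junction scaffold can be added for
#' contact-map work.
#'
#' Defaults describe the reference ensemble used throughout the package: a
#' BC-like H-aggregate (dyes displaced from the junction core) with mean
#' separation 0.6 nm, sd 0.1 nm, 10 degrees of orientation jitter, 10,000
#' frames, seed 1234.
#'
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed for the generator's single pseudorandom stream.
#' @param packing `"AA"` (parallel, face-to-face) or `"AB"` (antiparallel).
#' @param placement `"junction_core"` (AC-like, dyes at the junction center)
#'   or `"displaced"` (BC-like, dyes shifted 1.5 nm outward along one arm).
#'   Only affects [generate_mock_hj()].
#' @param mean_R,sd_R Center-center distance distribution in nm
#'   (normal, truncated below at 0.3 nm so bridge endpoints can never
#'   collide). `mean_R` must exceed 0.3.
#' @param orientation_jitter Standard deviation, in degrees, of the small
#'   random rotation applied independently to each dye每 frame (axis uniform
#'   on the sphere).
#' @param conformer_switch Optional list with `fraction` (of trailing frames
#'   re-based on the second geometry) and any of `mean_R`, `sd_R`, `packing`,
#'   `orientation_jitter` overriding the base values for that block.
#' @param hj_arms List describing the mock junction: `residues_per_arm`,
#'   `rise` (nm between consecutive arm residues), `offset` (nm from the
#'   junction origin to the first residue).
#' @param dye Dye name (keys the packaged `|mu|` table).
#' @param dye_mu Optional explicit `|mu|` in Debye (overrides the table).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_frames = 10000L, seed = 1234L,
                             packing = c("AA", "AB"),
                             placement = c("displaced", "junction_core"),
                             mean_R = 0.6, sd_R = 0.1,
                             orientation_jitter = 10,
                             conformer_switch = NULL,
                             hj_arms = list(residues_per_arm = 7L, rise = 0.34,
                                            offset = 0.5),
                             dye = "SQ-H2", dye_mu = NULL) {
  packing <- match.arg(packing)
  placement <- match.arg(placement)
  assert_that(n_frames >= 1, "n_frames must be >= 1")
  assert_that(mean_R > 0.3, "mean_R must exceed the 0.3 nm truncation floor")
  assert_that(sd_R >= 0, "sd_R must be non-negative")
  assert_that(orientation_jitter >= 0, "orientation_jitter must be non-negative")
  if (!is.null(conformer_switch)) {
    assert_that(is.list(conformer_switch) && !is.null(conformer_switch$fraction),
                "conformer_switch needs a 'fraction' entry")
    assert_that(conformer_switch$fraction > 0 && conformer_switch$fraction < 1,
                "conformer_switch$fraction must be in (0, 1)")
  }
  structure(list(
    n_frames = as.integer(n_frames), seed = as.integer(seed),
    packing = packing, placement = placement,
    mean_R = mean_R, sd_R = sd_R,
    orientation_jitter = orientation_jitter,
    conformer_switch = conformer_switch,
    hj_arms = hj_arms, dye = dye, dye_mu = dye_mu
  ), class = "generator_config")
}

#' Rigid template dye
#'
#' A planar squaraine-like atom set: four "squarate" carbons on a 0.2 nm
#' square at the center, two 6-carbon hexagonal rings (0.139 nm C-C radius)
#' with centers at +/- 0.7 nm along the long (x) axis, and a linker-side
#' marker atom beyond the near (-x) ring. The transition dipole direction of
#' the template is +x, the bridge length 1.4 nm.
#'
#' @return A tibble with `atom_name`, `element`, `mass`, `role` (one of
#'   `squarate`, `ring_far`, `ring_near`, `linker`) and coordinates
#'   `x`, `y`, `z` in nm.
#' @export
build_template_dye <- function() {
  hex <- function(cx) {
    a <- (0:5) * pi / 3
    cbind(cx + 0.139 * cos(a), 0.139 * sin(a), 0)
  }
  xyz <- rbind(
    cbind(c(0.1, 0.1, -0.1, -0.1), c(0.1, -0.1, 0.1, -0.1), 0),  # squarate
    hex(0.7),    # far ring (+x)
    hex(-0.7),   # near ring (-x)
    c(-0.95, 0, 0)  # linker marker
  )
  tibble::tibble(
    atom_name = paste0("C", 1:17),
    element = "C",
    mass = 12.0107,
    role = c(rep("squarate", 4), rep("ring_far", 6), rep("ring_near", 6), "linker"),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# Internal: resolve conformer-block parameters against the base config.
conformer_params <- function(cfg, alt = FALSE) {
  if (!alt || is.null(cfg$conformer_switch))
    return(list(mean_R = cfg$mean_R, sd_R = cfg$sd_R, packing = cfg$packing,
                jitter = cfg$orientation_jitter))
  cs <- cfg$conformer_switch
  list(
    mean_R = cs$mean_R %||% cfg$mean_R,
    sd_R = cs$sd_R %||% cfg$sd_R,
    packing = cs$packing %||% cfg$packing,
    jitter = cs$orientation_jitter %||% cfg$orientation_jitter
  )
}

#' Generate a synthetic two-dye trajectory
#'
#' Per frame, dye 1 sits at the reference pose (template centered at the
#' origin, long axis along x) and dye 2 is placed cofacially above it along
#' the stacking normal (z) at a separation drawn from
#' `Normal(mean_R, sd_R)` truncated below at 0.3 nm. Under AB packing dye 2
#' is first rotated 180 degrees about the stacking normal. Both dyes are then
#' perturbed by independent small random rotations about their own centers
#' (axis uniform on the sphere, angle `~ Normal(0, orientation_jitter)`).
#' With a `conformer_switch`, the trailing block of frames is re-based on the
#' second geometry. All randomness comes from one stream seeded with
#' `cfg$seed`, drawn in frame-major order, so output is fully reproducible;
#' the caller's RNG state is untouched.
#'
#' @param cfg A [generator_config()].
#' @return A list of class `dimer_simulation` with `trajectory`,
#'   `residue_map`, `selections` (a [selection_config()]), `ground_truth`
#'   (per-frame tibble of sampled R, conformer id and packing, never read by
#'   the analysis pipeline) and `config`.
#' @export
generate_dimer_trajectory <- function(cfg) {
  assert_that(inherits(cfg, "generator_config"), "cfg must be a generator_config")
  tpl <- build_template_dye()
  tpl_xyz <- as.matrix(tpl[, c("x", "y", "z")])
  nt <- nrow(tpl)
  flip <- rotation_matrix(c(0, 0, 1), 180)
  n_alt <- if (is.null(cfg$conformer_switch)) 0L
           else round(cfg$conformer_switch$fraction * cfg$n_frames)
  first_alt <- cfg$n_frames - n_alt + 1L

  coords <- vector("list", cfg$n_frames)
  R_true <- numeric(cfg$n_frames)
  conformer <- integer(cfg$n_frames)
  with_seed(cfg$seed, {
    for (f in seq_len(cfg$n_frames)) {
      alt <- f >= first_alt && n_alt > 0L
      pp <- conformer_params(cfg, alt)
      # truncated-normal separation draw (rejection; floor 0.3 nm)
      repeat {
        R <- rnorm(1, pp$mean_R, pp$sd_R)
        if (R >= 0.3) break
      }
      a1 <- random_unit_vector(); th1 <- rnorm(1, 0, pp$jitter)
      a2 <- random_unit_vector(); th2 <- rnorm(1, 0, pp$jitter)
      d1 <- tpl_xyz %*% t(rotation_matrix(a1, th1))
      base2 <- if (pp$packing == "AB") tpl_xyz %*% t(flip) else tpl_xyz
      d2 <- base2 %*% t(rotation_matrix(a2, th2))
      d2[, 3] <- d2[, 3] + R
      coords[[f]] <- rbind(d1, d2)
      R_true[f] <- R
      conformer[f] <- if (alt) 2L else 1L
    }
  })

  atoms <- tibble::tibble(
    atom_index = seq_len(2L * nt),
    atom_name = rep(tpl$atom_name, 2),
    element = rep(tpl$element, 2),
    mass = rep(tpl$mass, 2),
    residue_id = rep(1:2, each = nt),
    res_name = "DYE"
  )
  traj <- trajectory(atoms, coords)
  rmap <- residue_map(1:2, label = "dye", strand = "none")
  sel_idx <- function(offset) dye_selection(
    name = cfg$dye, residue_id = if (offset == 0) 1L else 2L,
    squarate_carbons = offset + which(tpl$role == "squarate"),
    ring_far = offset + which(tpl$role == "ring_far"),
    ring_near = offset + which(tpl$role == "ring_near")
  )
  sel <- selection_config(sel_idx(0L), sel_idx(nt))
  packing_of <- ifelse(conformer == 2L, conformer_params(cfg, TRUE)$packing, cfg$packing)
  gt <- tibble::tibble(
    frame_index = seq_len(cfg$n_frames) - 1L,
    time = traj$times,
    conformer = conformer,
    R_true = R_true,
    packing = packing_of
  )
  structure(list(trajectory = traj, residue_map = rmap, selections = sel,
                 ground_truth = gt, config = cfg),
            class = "dimer_simulation")
}

#' @export
print.dimer_simulation <- function(x, ...) {
  cat(sprintf("<dimer_simulation> %d frames, packing %s, mean_R %.2f nm, seed %d\n",
              x$config$n_frames, x$config$packing, x$config$mean_R, x$config$seed))
  invisible(x)
}

#' Add a mock four-arm junction scaffold to a dimer simulation
#'
#' Appends four arms of single-pseudo-atom residues (unit mass; only their
#' centers of mass matter for contact maps) radiating from the junction
#' origin in a planar X along +x, +y, -x, -y, labeled strands A-D with
#' contiguous residue ids. With `placement = "junction_core"` the dyes remain
#' at the junction origin (AC-like); with `"displaced"` both dyes are shifted
#' 1.5 nm outward along the A arm (BC-like), which by construction reduces
#' their arm contacts. Arm residues get mild per-frame Gaussian positional
#' noise (sd 0.05 nm) from a stream seeded with `cfg$seed + 1`.
#'
#' @param sim A `dimer_simulation` from [generate_dimer_trajectory()].
#' @return A `dimer_simulation` whose trajectory and residue map include the
#'   arm residues (dye atom indices and selections are unchanged).
#' @export
generate_mock_hj <- function(sim) {
  cfg <- sim$config
  arms <- cfg$hj_arms
  npa <- arms$residues_per_arm
  dirs <- list(A = c(1, 0, 0), B = c(0, 1, 0), C = c(-1, 0, 0), D = c(0, -1, 0))
  base <- do.call(rbind, lapply(dirs, function(d)
    t(vapply(seq_len(npa) - 1L, function(k) (arms$offset + k * arms$rise) * d,
             numeric(3)))))
  n_arm <- nrow(base)  # 4 * npa
  dye_atoms <- sim$trajectory$atoms
  n_dye <- nrow(dye_atoms)
  shift <- if (cfg$placement == "displaced") c(1.5, 0, 0) else c(0, 0, 0)

  nf <- n_frames(sim$trajectory)
  coords <- vector("list", nf)
  with_seed(cfg$seed + 1L, {
    for (f in seq_len(nf)) {
      dye_xyz <- sweep(sim$trajectory$coords[[f]], 2, shift, `+`)
      noise <- matrix(rnorm(3L * n_arm, 0, 0.05), n_arm, 3)
      coords[[f]] <- rbind(dye_xyz, base + noise)
    }
  })

  arm_atoms <- tibble::tibble(
    atom_index = n_dye + seq_len(n_arm),
    atom_name = "P",
    element = "P",
    mass = 1,
    residue_id = 2L + seq_len(n_arm),
    res_name = "DNA"
  )
  atoms <- dplyr::bind_rows(dye_atoms, arm_atoms)
  traj <- trajectory(atoms, coords, sim$trajectory$times)
  rmap <- residue_map(
    residue_id = c(1:2, 2L + seq_len(n_arm)),
    label = c("dye", "dye", rep("nucleotide", n_arm)),
    strand = c("none", "none", rep(names(dirs), each = npa))
  )
  out <- sim
  out$trajectory <- traj
  out$residue_map <- rmap
  out
}

#' Parameter-recovery report for a synthetic run
#'
#' Compares ground-truth generator parameters with the values the analysis
#' pipeline recovers: mean center distance R, mean kappa-squared (against the
#' noiseless base-geometry value 1 for the cofacial template), the sign of
#' kappa-prime (packing diagnostic), and - when a conformer switch was
#' planted and a filtered cluster set is supplied - the conformer fractions.
#' Tolerances are sampling-based: 3 standard errors for mean R, a
#' jitter-scaled band for kappa-squared, and 5 percentage points for
#' fractions.
#'
#' @param sim A `dimer_simulation`.
#' @param geometry The [dimer_geometry()] table computed from it.
#' @param clusters Optional filtered `cluster_set` for conformer-fraction
#'   recovery.
#' @return A tibble with `quantity`, `true`, `estimated`, `abs_error`,
#'   `tolerance`, `pass`.
#' @export
parameter_recovery_report <- function(sim, geometry, clusters = NULL) {
  cfg <- sim$config
  gt <- sim$ground_truth
  n <- nrow(gt)
  jit_rad <- cfg$orientation_jitter * pi / 180
  rows <- list()

  tol_R <- max(3 * cfg$sd_R / sqrt(n), 1e-9)
  rows$mean_R <- tibble::tibble(
    quantity = "mean_R", true = mean(gt$R_true),
    estimated = mean(geometry$R), tolerance = tol_R
  )
  rows$kappa_sq <- tibble::tibble(
    quantity = "mean_kappa_sq", true = 1,
    estimated = mean(geometry$kappa_sq),
    tolerance = max(6 * jit_rad^2, 1e-9)
  )
  true_sign <- if (cfg$packing == "AA") 1 else -1
  rows$kp <- tibble::tibble(
    quantity = "kappa_prime_sign", true = true_sign,
    estimated = sign(mean(geometry$kappa_prime)), tolerance = 0
  )
  if (!is.null(cfg$conformer_switch) && !is.null(clusters)) {
    true_frac <- sort(as.vector(table(gt$conformer)) / n, decreasing = TRUE)
    est_frac <- sort(clusters$clusters$fraction, decreasing = TRUE)
    length(est_frac) <- length(true_frac)  # pad with NA if fewer clusters
    rows$frac <- tibble::tibble(
      quantity = paste0("conformer_fraction_", seq_along(true_frac)),
      true = true_frac, estimated = est_frac, tolerance = 0.05
    )
  }
  out <- dplyr::bind_rows(rows)
  out$abs_error <- abs(out$estimated - out$true)
  out$pass <- !is.na(out$abs_error) & out$abs_error <= out$tolerance
  out[, c("quantity", "true", "estimated", "abs_error", "tolerance", "pass")]
}
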