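# Independently coded greedy reference for the GROMOS procedure.
gromos_oracle <- function(m, cutoff) {
  nf <- nrow(m)
  alive <- rep(TRUE, nf)
  clusters <- list()
  while (any(alive)) {
    best <- -1L; center <- NA_integer_
    for (i in which(alive)) {
      cnt <- sum(m[i, alive] <= cutoff)
      if (cnt > best) { best <- cnt; center <- i }  # first max = lowest index
    }
    members <- which(alive & m[center, ] <= cutoff)
    clusters[[length(clusters) + 1L]] <- list(center = center, members = members)
    alive[members] <- FALSE
  }
  clusters
}

test_that("pairwise RMSD reproduces closed-form toy cases", {
  m0 <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  traj <- toy_trajectory(list(m0, m0, m0 + 1))  # frame 3 translated by (1,1,1)
  r_fit <- pairwise_rmsd(traj, 1:2, superpose = TRUE)
  r_raw <- pairwise_rmsd(traj, 1:2, superpose = FALSE)
  expect_equal(r_fit[1, 2], 0)
  expect_equal(r_raw[1, 2], 0)
  expect_equal(r_fit[1, 3], 0, tolerance = 1e-9)       # translation removed
  expect_equal(r_raw[1, 3], sqrt(3), tolerance = 1e-12)
  expect_equal(diag(r_fit), rep(0, 3))
  expect_identical(r_raw, t(r_raw))
  # 0.1 nm displacement on one of two atoms, no superposition
  m1 <- m0; m1[2, 1] <- m1[2, 1] + 0.1
  tr2 <- toy_trajectory(list(m0, m1))
  expect_equal(pairwise_rmsd(tr2, 1:2, superpose = FALSE)[1, 2],
               sqrt(0.01 / 2), tolerance = 1e-12)
})

test_that("superposed RMSD agrees with bio3d's Kabsch fit", {
  set.seed(413)
  frames <- lapply(1:5, function(i) matrix(rnorm(24), 8, 3))
  traj <- toy_trajectory(frames)
  ours <- pairwise_rmsd(traj, 1:8, superpose = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    ref <- bio3d::rmsd(as.vector(t(frames[[i]])), as.vector(t(frames[[j]])),
                       fit = TRUE)  # bio3d reports 3 decimals
    expect_equal(ours[i, j], ref, tolerance = 1e-3)
  }
})

test_that("GROMOS clustering matches trivial and planted cases", {
  # all frames mutually within cutoff -> one cluster
  m_all <- matrix(0.01, 4, 4); diag(m_all) <- 0
  cs <- gromos_cluster(m_all, 0.05)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$n_members, 4L)
  expect_equal(cs$clusters$fraction, 1)
  # planted 60/40 split, tight within, far between
  n <- 10
  m <- matrix(1, n, n)
  within <- function(i, j) (i <= 6 && j <= 6) || (i > 6 && j > 6)
  for (i in 1:n) for (j in 1:n) if (within(i, j)) m[i, j] <- 0.01
  diag(m) <- 0
  cs2 <- gromos_cluster(m, 0.05)
  expect_equal(sort(cs2$clusters$n_members), c(4L, 6L))
  expect_equal(sum(cs2$clusters$fraction), 1)
  # memberships partition the frames
  expect_true(all(cs2$assignment %in% cs2$clusters$cluster))
  expect_equal(length(cs2$assignment), n)
})

test_that("clustering follows the greedy reference including the tie-break", {
  # frames {1,2}, {3,4} are two equal-size tight pairs; 5, 6 isolated:
  # tie between centers 1 and 3 must resolve to the lowest frame index
  m <- matrix(1, 6, 6)
  m[1, 2] <- m[2, 1] <- 0.01
  m[3, 4] <- m[4, 3] <- 0.01
  diag(m) <- 0
  cs <- gromos_cluster(m, 0.05)
  ref <- gromos_oracle(m, 0.05)
  expect_equal(nrow(cs$clusters), length(ref))
  expect_equal(cs$clusters$center_frame + 1L,
               vapply(ref, function(x) x$center, 1L))
  for (k in seq_along(ref))
    expect_equal(which(cs$assignment == k), ref[[k]]$members)
  expect_equal(cs$clusters$center_frame[1], 0L)  # frame 0 beat the tied frame 2
  # random matrix agreement with the reference
  set.seed(414)
  d <- as.matrix(dist(matrix(rnorm(40), 20, 2))) / 10
  cs2 <- gromos_cluster(d, 0.08)
  ref2 <- gromos_oracle(d, 0.08)
  expect_equal(cs2$clusters$center_frame + 1L, vapply(ref2, function(x) x$center, 1L))
})

test_that("relabeling frames permutes clusters without changing their composition", {
  set.seed(415)
  pts <- rbind(matrix(rnorm(24, 0, 0.1), 12, 2), matrix(rnorm(16, 5, 0.1), 8, 2))
  m <- as.matrix(dist(pts))
  perm <- sample(20)
  cs_a <- gromos_cluster(m, 1)
  cs_b <- gromos_cluster(m[perm, perm], 1)
  sets_a <- lapply(cs_a$clusters$cluster, function(k) sort(which(cs_a$assignment == k)))
  sets_b <- lapply(cs_b$clusters$cluster, function(k) sort(perm[cs_b$assignment == k]))
  expect_setequal(vapply(sets_a, paste, "", collapse = ","),
                  vapply(sets_b, paste, "", collapse = ","))
})

test_that("cluster filtering keeps strictly-greater-than-threshold clusters", {
  mk <- function(fracs, n = 100) {
    sizes <- round(fracs * n)
    cs <- list(
      clusters = tibble::tibble(cluster = seq_along(sizes),
                                center_frame = 0L, n_members = sizes,
                                fraction = sizes / n),
      assignment = rep(seq_along(sizes), sizes), n_frames = n,
      cutoff = 0.05, min_fraction = NA_real_, discarded_fraction = 0)
    class(cs) <- "cluster_set"
    cs
  }
  f <- filter_clusters(mk(c(0.5, 0.3, 0.15, 0.05)))
  expect_equal(nrow(f$clusters), 3L)  # 0.05 is not > 0.05
  expect_equal(f$discarded_fraction, 0.05, tolerance = 1e-12)
  expect_equal(nrow(filter_clusters(mk(1))$clusters), 1L)
  f2 <- filter_clusters(mk(c(0.96, 0.04)))
  expect_equal(nrow(f2$clusters), 1L)
  expect_true(all(is.na(f2$assignment[97:100])))
  expect_error(filter_clusters(mk(c(0.04, 0.03)), min_fraction = 0.05), "cutoff")
})

test_that("time-series summary uses the population sd and matches a two-pass oracle", {
  expect_equal(unlist(time_series_summary(rep(3.2, 7))[, c("mean", "sd")]),
               c(mean = 3.2, sd = 0))
  expect_equal(unlist(time_series_summary(c(0, 1))[, c("mean", "sd")]),
               c(mean = 0.5, sd = 0.5))
  set.seed(416)
  x <- rnorm(1000, 5, 2)
  s <- time_series_summary(x)
  m1 <- sum(x) / length(x)
  s1 <- sqrt(sum((x - m1)^2) / length(x))
  expect_equal(s$mean, m1, tolerance = 1e-12)
  expect_equal(s$sd, s1, tolerance = 1e-12)
  expect_error(time_series_summary(numeric(0)), "empty")
})

test_that("GROMOS summary on identical frames reduces to the single-frame values", {
  fix <- ideal_dimer_trajectory(rep(0.6, 6))
  rm_mat <- pairwise_rmsd(fix$traj, seq_len(n_atoms(fix$traj)))
  cs <- gromos_cluster(rm_mat, 0.05)
  gs <- gromos_summary(cs, fix$traj, fix$sel)
  expect_equal(nrow(gs$cluster_values), 1L)
  expect_equal(gs$cluster_values$R, 0.6, tolerance = 1e-10)
  expect_equal(gs$cluster_values$kappa_sq, 1, tolerance = 1e-10)
  g1 <- dimer_geometry(fix$traj, fix$sel)[1, ]
  expect_equal(gs$cluster_values$kappa_prime, g1$kappa_prime, tolerance = 1e-10)
  expect_true(all(gs$summary$sd == 0))
})

test_that("two mirrored packing clusters average to kappa_prime zero", {
  aa <- ideal_dimer_trajectory(rep(0.6, 6), "AA")
  ab <- ideal_dimer_trajectory(rep(0.6, 6), "AB")
  traj <- trajectory(aa$traj$atoms, c(aa$traj$coords, ab$traj$coords))
  rm_mat <- pairwise_rmsd(traj, seq_len(n_atoms(traj)))
  cs <- gromos_cluster(rm_mat, 0.05)
  expect_equal(nrow(cs$clusters), 2L)
  gs <- gromos_summary(cs, traj, aa$sel)
  expect_equal(mean(gs$cluster_values$kappa_prime), 0, tolerance = 1e-9)
  expect_equal(sort(gs$cluster_values$kappa_prime), c(-1, 1), tolerance = 1e-9)
})

test_that("planted conformers recover their noiseless per-cluster coupling", {
  cfg <- generator_config(n_frames = 200, seed = 61, sd_R = 0.002,
                          orientation_jitter = 0.5, mean_R = 0.6,
                          conformer_switch = list(fraction = 0.4, mean_R = 1.1))
  sim <- generate_dimer_trajectory(cfg)
  rm_mat <- pairwise_rmsd(sim$trajectory, seq_len(n_atoms(sim$trajectory)))
  cs <- filter_clusters(gromos_cluster(rm_mat, 0.05))
  expect_equal(nrow(cs$clusters), 2L)
  gs <- gromos_summary(cs, sim$trajectory, sim$selections)
  # noiseless references from ideal template dipoles at each planted distance
  noiseless_J <- function(R) {
    tpl <- extended_dipole(c(0, 0, 0), c(1, 0, 0), c(0.7, 0, 0), c(-0.7, 0, 0), 12.99)
    top <- extended_dipole(c(0, 0, R), c(1, 0, 0), c(0.7, 0, R), c(-0.7, 0, R), 12.99)
    extended_dipole_coupling(tpl, top)$J_mn
  }
  got <- sort(gs$cluster_values$J_mn)
  want <- sort(c(noiseless_J(0.6), noiseless_J(1.1)))
  expect_equal(got, want, tolerance = 0.02)
})

test_that("2D histograms preserve counts and marginals", {
  h1 <- histogram2d(rep(1, 7), rep(2, 7), bins = 3)
  expect_equal(sum(h1$counts), 7L)
  expect_equal(sum(h1$counts > 0), 1L)
  # uniform grid fixture: one observation per cell of a 3x4 grid
  g <- expand.grid(x = 1:3, y = 1:4)
  h2 <- histogram2d(g$x, g$y, x_edges = seq(0.5, 3.5, 1), y_edges = seq(0.5, 4.5, 1))
  expect_equal(h2$counts, matrix(1L, 3, 4))
  # marginals equal 1D histograms
  set.seed(417)
  x <- rnorm(500); y <- rnorm(500)
  xe <- seq(min(x), max(x), length.out = 11)
  ye <- seq(min(y), max(y), length.out = 11)
  h3 <- histogram2d(x, y, x_edges = xe, y_edges = ye)
  expect_equal(rowSums(h3$counts),
               as.vector(table(cut(x, xe, include.lowest = TRUE))),
               ignore_attr = TRUE)
  expect_equal(colSums(h3$counts),
               as.vector(table(cut(y, ye, include.lowest = TRUE))),
               ignore_attr = TRUE)
  expect_error(histogram2d(1:3, 1:4), "same length")
  expect_s3_class(autoplot(h3), "ggplot")
})
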