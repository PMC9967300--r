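#' Mean and standard deviation of a per-frame metric
#'
#' Time-series ensemble summary: arithmetic mean over frames and the
#' population standard deviation (divisor `n`, a documented choice; with
#' thousands of frames the sample/population distinction is negligible).
#'
#' @param values Numeric vector (non-empty).
#' @return A tibble with `n`, `mean`, `sd`.
#' @export
time_series_summary <- function(values) {
  assert_that(length(values) >= 1, "empty metric series")
  m <- mean(values)
  tibble::tibble(
    n = length(values),
    mean = m,
    sd = sqrt(mean((values - m)^2))
  )
}

#' Time-series summary table over all dimer metrics
#'
#' @param geometry A [dimer_geometry()] tibble.
#' @param coupling Optional [coupling_series()] tibble (adds a `J_mn` row).
#' @return A tibble with `method = "time_series"`, `metric`, `mean`, `sd`.
#' @export
summarize_time_series <- function(geometry, coupling = NULL) {
  metrics <- c("R", "alpha", "theta_m", "theta_n", "kappa_sq", "kappa_prime")
  vals <- lapply(metrics, function(m) geometry[[m]])
  names(vals) <- metrics
  if (!is.null(coupling)) vals$J_mn <- coupling$J_mn
  purrr::imap_dfr(vals, function(v, nm) {
    s <- time_series_summary(v)
    tibble::tibble(method = "time_series", metric = nm, mean = s$mean, sd = s$sd)
  })
}

# Internal: cluster-average one dye's dipole series over member frames.
# Centers and bridge endpoints are averaged componentwise; the mean dipole
# direction is renormalized (flagged degenerate if its norm collapses).
average_dipole_rows <- function(series, rows) {
  sub <- series[rows, ]
  mu <- c(mean(sub$mux), mean(sub$muy), mean(sub$muz))
  degenerate <- vec_norm(mu) < 1e-6
  list(
    dipole = if (degenerate) NULL else extended_dipole(
      c = c(mean(sub$cx), mean(sub$cy), mean(sub$cz)),
      mu_hat = mu,
      r = c(mean(sub$rx), mean(sub$ry), mean(sub$rz)),
      s = c(mean(sub$sx), mean(sub$sy), mean(sub$sz)),
      mu_mag = sub$mu_mag[1]
    ),
    degenerate = degenerate
  )
}

#' GROMOS-cluster ensemble summary
#'
#' For each retained cluster, averages the dye geometry (centers, bridge
#' endpoints; mean dipole direction renormalized) over the member frames,
#' then evaluates the orientation metrics and the extended-dipole coupling on
#' the cluster-average geometry. The summary reports the unweighted mean and
#' population sd across cluster values, plus fraction-weighted versions.
#'
#' @param cs A (typically filtered) `cluster_set`.
#' @param traj The [trajectory()] the clusters index into.
#' @param sel A [selection_config()].
#' @param params Dye parameter table.
#' @param p A [coupling_params()].
#' @param fold Folding convention for the angle metrics.
#' @return A list of class `gromos_summary`: `cluster_values` (one row per
#'   cluster with fraction and all metrics) and `summary` (tibble with
#'   `method = "gromos"`, `metric`, `mean`, `sd`, `mean_weighted`,
#'   `sd_weighted`).
#' @export
gromos_summary <- function(cs, traj, sel, params = dye_parameters(),
                           p = coupling_params(),
                           fold = c("as_printed", "reflect_180")) {
  fold <- match.arg(fold)
  assert_that(nrow(cs$clusters) >= 1, "empty cluster set")
  assert_that(cs$n_frames == n_frames(traj),
              "cluster set and trajectory disagree on frame count")
  sm <- extended_dipole_series(traj, sel[[1]], params = params)
  sn <- extended_dipole_series(traj, sel[[2]], params = params)
  rows <- purrr::map_dfr(seq_len(nrow(cs$clusters)), function(i) {
    members <- which(cs$assignment == cs$clusters$cluster[i])
    am <- average_dipole_rows(sm, members)
    an <- average_dipole_rows(sn, members)
    if (am$degenerate || an$degenerate) {
      return(tibble::tibble(
        cluster = cs$clusters$cluster[i], fraction = cs$clusters$fraction[i],
        degenerate_mu = TRUE, R = NA_real_, alpha = NA_real_,
        theta_m = NA_real_, theta_n = NA_real_, kappa_sq = NA_real_,
        kappa_prime = NA_real_, J_mn = NA_real_
      ))
    }
    dm <- am$dipole; dn <- an$dipole
    g <- dimer_distance(dm, dn)
    tibble::tibble(
      cluster = cs$clusters$cluster[i],
      fraction = cs$clusters$fraction[i],
      degenerate_mu = FALSE,
      R = g$R,
      alpha = fold_angle(oblique_angle(dm$mu_hat, dn$mu_hat), fold),
      theta_m = fold_angle(slip_angle(g$R_hat, dm$mu_hat), fold),
      theta_n = fold_angle(slip_angle(g$R_hat, dn$mu_hat), fold),
      kappa_sq = kappa_squared(dm$mu_hat, dn$mu_hat, g$R_hat),
      kappa_prime = kappa_prime(dm$mu_hat, dn$mu_hat),
      J_mn = extended_dipole_coupling(dm, dn, p)$J_mn
    )
  })
  metrics <- c("R", "alpha", "theta_m", "theta_n", "kappa_sq", "kappa_prime", "J_mn")
  w <- rows$fraction / sum(rows$fraction)
  summary <- purrr::map_dfr(metrics, function(m) {
    v <- rows[[m]]
    mw <- sum(w * v)
    tibble::tibble(
      method = "gromos", metric = m,
      mean = mean(v), sd = sqrt(mean((v - mean(v))^2)),
      mean_weighted = mw, sd_weighted = sqrt(sum(w * (v - mw)^2))
    )
  })
  structure(list(cluster_values = rows, summary = summary),
            class = "gromos_summary")
}

#' @export
tidy.gromos_summary <- function(x, ...) x$summary

#' @export
glance.gromos_summary <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$cluster_values),
    retained_fraction = sum(x$cluster_values$fraction),
    any_degenerate_mu = any(x$cluster_values$degenerate_mu)
  )
}

#' @export
print.gromos_summary <- function(x, ...) {
  cat(sprintf("<gromos_summary> %d cluster(s)\n", nrow(x$cluster_values)))
  print(x$summary)
  invisible(x)
}

#' Two-dimensional histogram of per-frame values
#'
#' Bins two aligned per-frame series (e.g. R vs kappa-squared, or R vs J) on
#' a rectangular grid. The total count equals the number of observations.
#'
#' @param x,y Equal-length numeric vectors.
#' @param bins Number of bins per axis when explicit edges are not given.
#' @param x_edges,y_edges Optional explicit bin edges (sorted, covering the
#'   data range).
#' @param xlab,ylab Axis labels carried to [autoplot()].
#' @return An object of class `histogram2d` with `x_edges`, `y_edges`,
#'   `counts` (matrix, x-bins in rows), and labels.
#' @export
histogram2d <- function(x, y, bins = 50, x_edges = NULL, y_edges = NULL,
                        xlab = "x", ylab = "y") {
  assert_that(length(x) == length(y), "x and y must have the same length")
  assert_that(length(x) >= 1, "empty input")
  edges_for <- function(v, edges) {
    if (!is.null(edges)) return(sort(edges))
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }
  xe <- edges_for(x, x_edges)
  ye <- edges_for(y, y_edges)
  xi <- cut(x, xe, include.lowest = TRUE, labels = FALSE)
  yi <- cut(y, ye, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(xi) & !is.na(yi)
  counts <- matrix(0L, length(xe) - 1, length(ye) - 1)
  for (k in which(keep)) counts[xi[k], yi[k]] <- counts[xi[k], yi[k]] + 1L
  structure(list(x_edges = xe, y_edges = ye, counts = counts,
                 n = length(x), n_binned = sum(keep),
                 xlab = xlab, ylab = ylab),
            class = "histogram2d")
}

#' @export
tidy.histogram2d <- function(x, ...) {
  xm <- (x$x_edges[-1] + x$x_edges[-length(x$x_edges)]) / 2
  ym <- (x$y_edges[-1] + x$y_edges[-length(x$y_edges)]) / 2
  g <- tidyr::expand_grid(x_bin = seq_along(xm), y_bin = seq_along(ym))
  g$x_mid <- xm[g$x_bin]
  g$y_mid <- ym[g$y_bin]
  g$count <- x$counts[cbind(g$x_bin, g$y_bin)]
  g
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf("<histogram2d> %d x %d bins, %d observations\n",
              nrow(x$counts), ncol(x$counts), x$n))
  invisible(x)
}

#' 2D histogram tile plot with a logarithmic color scale
#'
#' @param object A `histogram2d`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.histogram2d <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$count > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x_mid, .data$y_mid, fill = .data$count)) +
    ggplot2::geom_tile(width = diff(object$x_edges)[1],
                       height = diff(object$y_edges)[1]) +
    ggplot2::scale_fill_viridis_c(trans = "log10", name = "count") +
    ggplot2::labs(x = object$xlab, y = object$ylab) +
    ggplot2::theme_minimal()
}
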