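#' Zero-lag Butterworth low-pass filtering of a trajectory
#'
#' Conditions motion-capture signals with the standard biomechanics
#' recipe: a 2nd-order Butterworth low-pass applied forward and backward
#' (zero phase lag, effective 4th order).  The cutoff is applied directly
#' (no forward-backward cutoff correction) unless `correct_fc = TRUE`,
#' which pre-warps the cutoff by `(2^(1/2) - 1)^(-1/4)` so the cascaded
#' filter is -3 dB at `fc`.
#'
#' @param traj a [trajectory()].
#' @param fc cutoff frequency, Hz (default 6).
#' @param correct_fc apply the two-pass cutoff correction? Default
#'   `FALSE`, the common convention.
#' @return A filtered `trajectory` with the same length and time stamps.
#' @export
butterworth_zero_lag <- function(traj, fc = 6, correct_fc = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  fs <- traj$sample_rate
  if (fc >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  n <- length(traj$times)
  if (n < 9) stop("signal too short to filter (need at least 3x the ",
                  "filter order after edge padding)")
  fc_design <- if (correct_fc) fc / (2^(1 / 2) - 1)^(1 / 4) else fc
  bf <- signal::butter(2, fc_design / (fs / 2), type = "low")
  disp <- apply(traj$displacement, 2, function(x) {
    # reflective padding keeps filtfilt's edge transients off the data
    np <- min(n - 1, 3 * ceiling(fs / fc))
    xp <- c(2 * x[1] - rev(x[2:(np + 1)]), x,
            2 * x[n] - rev(x[(n - np):(n - 1)]))
    y <- signal::filtfilt(bf, xp)
    y[(np + 1):(np + n)]
  })
  trajectory(traj$times, disp, traj$sample_rate,
             waveform = attr(traj, "waveform"))
}

#' Relative mean absolute error between key-point trajectories
#'
#' \deqn{\mathrm{RMAE} = \frac{1}{N}\sum_{i=1}^{N}
#'   \left|\frac{D_{EXP,i} - D_{FEM,i}}{D_{EXP,i}}\right|}
#' computed over the `N` retained frames of one displacement axis.
#' Frames where the experimental displacement magnitude is below `eps`
#' are excluded from the mean (the ratio is unstable near zero) and
#' counted in the report.
#'
#' @param exp,sim experimental and simulated [trajectory()] objects with
#'   equal length and aligned time stamps, or plain numeric vectors.
#' @param axis axis to compare: `"X"`, `"Y"` or `"Z"` (ignored for
#'   numeric-vector input).
#' @param eps exclusion threshold on `|D_EXP|`, mm (default 0.5).
#' @return A list of class `rmae_result`: `rmae` (fraction; multiply by
#'   100 for percent), `n_used`, `excluded_frames`.
#' @examples
#' rmae(c(10, 20), c(9, 22))$rmae   # (0.1 + 0.1) / 2 = 0.10
#' @export
rmae <- function(exp, sim, axis = "Y", eps = 0.5) {
  get_axis <- function(z) {
    if (inherits(z, "trajectory")) z$displacement[, axis] else as.numeric(z)
  }
  de <- get_axis(exp); ds <- get_axis(sim)
  if (length(de) != length(ds)) {
    stop("experimental and simulated series must have equal length")
  }
  if (inherits(exp, "trajectory") && inherits(sim, "trajectory") &&
      max(abs(exp$times - sim$times)) > 1e-9) {
    stop("trajectories are not time-aligned")
  }
  keep <- abs(de) >= eps
  if (!any(keep)) stop("all frames excluded: |D_EXP| < eps everywhere")
  structure(list(rmae = mean(abs((de[keep] - ds[keep]) / de[keep])),
                 n_used = sum(keep),
                 excluded_frames = sum(!keep)),
            class = "rmae_result")
}

#' @export
print.rmae_result <- function(x, ...) {
  cat("RMAE:", signif(100 * x$rmae, 4), "% over", x$n_used, "frames (",
      x$excluded_frames, "excluded )\n")
  invisible(x)
}

#' Time sequence of triangulated surfaces
#'
#' @param frames list of surface frames, each a list with `nodes`
#'   (n x 3, mm) and `triangles` (t x 3 vertex indices).
#' @param times frame time stamps, s.
#' @return Object of class `surface_sequence`.
#' @export
surface_sequence <- function(frames, times = seq_along(frames) - 1) {
  stopifnot(length(frames) >= 1, length(times) == length(frames))
  for (f in frames) {
    stopifnot(is.matrix(f$nodes) || is.data.frame(f$nodes),
              ncol(f$nodes) == 3, all(is.finite(as.matrix(f$nodes))))
  }
  structure(list(frames = frames, times = times,
                 n_frame = length(frames)),
            class = "surface_sequence")
}

#' Surface-to-surface distance between simulated and reference surfaces
#'
#' For every simulated node of every frame, finds the nearest point on
#' the reference frame's triangulated surface (exact point-to-triangle
#' projection, not point-to-vertex) and averages the Euclidean distances
#' over all nodes and frames:
#' \deqn{d = \frac{1}{N_{frame} N_{node}} \sum_{i=1}^{N_{frame}}
#'   \sum_{j=1}^{N_{node}} \lVert n_j^{(i)} - m_j^{(i)} \rVert}
#' With `mode = "squared"` the squared distances are averaged instead
#' (units mm^2).
#'
#' @param sim a [surface_sequence()] whose frame nodes are the simulated
#'   points (triangles optional).
#' @param ref a [surface_sequence()] of reference (scanned) surfaces with
#'   valid triangles; must have the same number of frames.
#' @param mode `"euclidean"` (default) or `"squared"`.
#' @return A list of class `surface_distance_result`: `d` (mm, or mm^2
#'   for squared mode), `per_frame`, `n_frame`, `n_node`.
#' @export
surface_distance <- function(sim, ref, mode = c("euclidean", "squared")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "surface_sequence"),
            inherits(ref, "surface_sequence"))
  if (sim$n_frame != ref$n_frame) {
    stop("simulated and reference sequences must have equal frame counts")
  }
  per_frame <- numeric(sim$n_frame)
  n_node <- nrow(as.matrix(sim$frames[[1]]$nodes))
  for (i in seq_len(sim$n_frame)) {
    pts <- as.matrix(sim$frames[[i]]$nodes)
    rf <- ref$frames[[i]]
    tris <- rf$triangles
    if (is.null(tris) || nrow(tris) == 0) {
      stop("reference frame ", i, " has no triangles")
    }
    if (nrow(pts) == 0) stop("simulated frame ", i, " is empty")
    dd <- point_triangle_distances(pts, as.matrix(rf$nodes),
                                   matrix(as.integer(tris), ncol = 3))
    per_frame[i] <- if (mode == "euclidean") mean(dd) else mean(dd^2)
  }
  structure(list(d = mean(per_frame), per_frame = per_frame,
                 n_frame = sim$n_frame, n_node = n_node, mode = mode),
            class = "surface_distance_result")
}

#' @export
print.surface_distance_result <- function(x, ...) {
  cat("surface-to-surface d =", signif(x$d, 5),
      if (x$mode == "euclidean") "mm" else "mm^2",
      "over", x$n_frame, "frames x", x$n_node, "nodes\n")
  invisible(x)
}

#' Validation report: RMAE per key point and surface distance
#'
#' Convenience wrapper producing the model-validation summary: RMAE of
#' the X and Y displacement of each supplied key point, plus the
#' surface-to-surface distance when surface sequences are given.
#' Displacements are measured from each signal's first frame (standing
#' datum) before the comparison.
#'
#' @param exp_points,sim_points named lists of [trajectory()] objects
#'   (same names, e.g. `clavicle`, `nipple`).
#' @param sim_surface,ref_surface optional [surface_sequence()]s.
#' @param eps RMAE near-zero exclusion threshold, mm.
#' @return A list of class `validation_report` with elements `rmae`
#'   (data frame: point, axis, rmae_pct, n_used, excluded) and
#'   `surface_d` (mm or `NA`).
#' @export
validation_report <- function(exp_points, sim_points,
                              sim_surface = NULL, ref_surface = NULL,
                              eps = 0.5) {
  stopifnot(identical(names(exp_points), names(sim_points)))
  rebase <- function(tr) {
    tr$displacement <- sweep(tr$displacement, 2, tr$displacement[1, ])
    tr
  }
  rows <- list()
  for (nm in names(exp_points)) {
    for (ax in c("X", "Y")) {
      r <- rmae(rebase(exp_points[[nm]]), rebase(sim_points[[nm]]),
                axis = ax, eps = eps)
      rows[[length(rows) + 1]] <- data.frame(
        point = nm, axis = ax, rmae_pct = 100 * r$rmae,
        n_used = r$n_used, excluded = r$excluded_frames)
    }
  }
  sd <- NA_real_
  if (!is.null(sim_surface) && !is.null(ref_surface)) {
    sd <- surface_distance(sim_surface, ref_surface)$d
  }
  structure(list(rmae = do.call(rbind, rows), surface_d = sd),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  print(x$rmae, row.names = FALSE)
  if (!is.na(x$surface_d)) {
    cat("surface-to-surface d =", signif(x$surface_d, 5), "mm\n")
  }
  invisible(x)
}

#' Extract the deformed breast surface sequence from a simulation
#'
#' Builds a [surface_sequence()] of the skin triangles restricted to the
#' breast surface (or any node set) across the frames of a
#' `simulation_result`.
#'
#' @param result a `simulation_result`.
#' @param mesh the `labelled_tet_mesh` the simulation ran on.
#' @param nodes node set to keep (default the `breast_surface` set).
#' @param frames frame indices to extract (default all).
#' @return A [surface_sequence()].
#' @export
extract_surface_sequence <- function(result, mesh,
                                     nodes = mesh$node_sets$breast_surface,
                                     frames = seq_along(result$times)) {
  stopifnot(inherits(result, "simulation_result"))
  keep_tri <- matrixStats_all_in(mesh$shells, nodes)
  tris <- mesh$shells[keep_tri, , drop = FALSE]
  remap <- match(seq_len(nrow(mesh$nodes)), nodes)
  tris <- matrix(remap[tris], ncol = 3)
  out <- lapply(frames, function(i) {
    u <- matrix(result$nodal_displacement[, i], ncol = 3, byrow = TRUE)
    list(nodes = mesh$nodes[nodes, , drop = FALSE] +
           u[nodes, , drop = FALSE],
         triangles = tris)
  })
  surface_sequence(out, times = result$times[frames])
}

# rows of m whose entries are all contained in set
matrixStats_all_in <- function(m, set) {
  inset <- matrix(m %in% set, nrow = nrow(m))
  rowSums(inset) == ncol(m)
}
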