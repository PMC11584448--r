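#' Detect gait events from the driven clavicle trajectory
#'
#' Identifies the four analysis instants of half a running gait cycle
#' from the vertical (Y) component of the driven motion: `t2` and `t4`
#' are the highest and lowest vertical displacement moments within the
#' analysed half-cycle; `t1` and `t3` are the mid-phase instants (the
#' upward and downward zero crossings of the waveform).  On synthetic
#' trajectories built by [build_synthetic_gait()] the waveform phase is
#' known exactly; for other input the phase is estimated from the mean
#' crossings of the vertical signal.
#'
#' @param driven a [trajectory()] of the driven (clavicle) point.
#' @param half_cycle half gait-cycle duration, s; taken from the
#'   synthetic waveform attribute when present.
#' @param cycle which half-cycle to analyse (1 = first complete one).
#' @return Object of class `gait_events` with fields `t1 < t2 < t3 < t4`
#'   (s), the corresponding frame indices `f1..f4`, and the analysed
#'   `window`.
#' @export
detect_events <- function(driven, half_cycle = NULL, cycle = 1L) {
  stopifnot(inherits(driven, "trajectory"))
  y <- driven$displacement[, "Y"]
  if (diff(range(y)) < 1e-9) stop("flat vertical signal: no gait events")
  wf <- attr(driven, "waveform")
  if (!is.null(wf)) {
    t0 <- wf$t0
    P <- wf$half_cycle
  } else {
    if (is.null(half_cycle)) stop("half_cycle required for non-synthetic ",
                                  "trajectories")
    P <- half_cycle
    ym <- y - mean(y)
    up <- which(ym[-1] >= 0 & ym[-length(ym)] < 0)
    if (!length(up)) stop("no upward crossing found in vertical signal")
    t0 <- driven$times[up[1]]
  }
  lo <- t0 + (cycle - 1) * P
  hi <- lo + P
  if (hi > max(driven$times) + 1e-9) {
    stop("trajectory does not cover half-cycle ", cycle)
  }
  idx <- which(driven$times >= lo - 1e-9 & driven$times <= hi + 1e-9)
  f2 <- idx[which.max(y[idx])]
  f4 <- idx[which.min(y[idx])]
  t1 <- lo; t3 <- lo + P / 2
  f1 <- which.min(abs(driven$times - t1))
  f3 <- which.min(abs(driven$times - t3))
  ev <- list(t1 = t1, t2 = driven$times[f2], t3 = t3,
             t4 = driven$times[f4],
             f1 = f1, f2 = f2, f3 = f3, f4 = f4,
             window = c(lo, hi))
  if (!(ev$t1 < ev$t2 && ev$t2 < ev$t3 && ev$t3 < ev$t4)) {
    stop("detected events violate t1 < t2 < t3 < t4; the vertical ",
         "waveform does not match the expected half-cycle structure")
  }
  class(ev) <- "gait_events"
  ev
}

#' @export
print.gait_events <- function(x, ...) {
  cat("gait events (s): t1 =", signif(x$t1, 4), " t2 =", signif(x$t2, 4),
      " t3 =", signif(x$t3, 4), " t4 =", signif(x$t4, 4), "\n")
  invisible(x)
}

# representative node per component: the node of the component lying
# closest to the nipple axis at the component's most anterior extent --
# the material point of largest excursion, mirroring how per-component
# displacement is read off a nephogram
component_nodes <- function(mesh) {
  g <- attr(mesh, "geometry")
  nd <- mesh$nodes
  z_rel <- nd[, 3] - (sqrt(g$chest_curvature_radius^2 - nd[, 1]^2) -
                        g$chest_curvature_radius) - g$t_sl
  r_pl <- sqrt((nd[, 1] - g$xc)^2 + (nd[, 2] - g$yc)^2)
  cen <- (nd[mesh$tets[, 1], ] + nd[mesh$tets[, 2], ] +
          nd[mesh$tets[, 3], ] + nd[mesh$tets[, 4], ]) / 4
  zw_c <- sqrt(g$chest_curvature_radius^2 - cen[, 1]^2) -
    g$chest_curvature_radius
  zc_rel <- cen[, 3] - zw_c - g$t_sl
  rc_pl <- sqrt((cen[, 1] - g$xc)^2 + (cen[, 2] - g$yc)^2)
  pick_anterior <- function(comp) {
    # most anterior element of the component near the nipple axis; its
    # four nodes average to a material point inside the component
    els <- which(mesh$element_component == comp)
    if (!length(els)) stop("no elements labelled '", comp, "'")
    near <- els[rc_pl[els] < 0.35 * g$rb]
    if (!length(near)) near <- els
    mesh$tets[near[which.max(zc_rel[near])], ]
  }
  pick_centroidal <- function(comp) {
    # element nearest the component's volume centroid (for the gland
    # this is the lobe ring, the canonical glandular material point)
    els <- which(mesh$element_component == comp)
    if (!length(els)) stop("no elements labelled '", comp, "'")
    ctr <- colMeans(cen[els, , drop = FALSE])
    mesh$tets[els[which.min(colSums((t(cen[els, , drop = FALSE]) -
                                       ctr)^2))], ]
  }
  list(nipple = mesh$node_sets$nipple,
       ligament = pick_anterior("ligament"),
       gland = pick_centroidal("gland"),
       pectoralis = pick_anterior("pectoralis"),
       clavicle = mesh$node_sets$clavicle)
}

#' Per-component displacement and acceleration histories
#'
#' For a representative material point of each component (the nipple
#' node, the most anterior ligament / gland / pectoralis node near the
#' nipple axis, and the driven clavicle node), returns the total
#' displacement magnitude (vector sum of the three directions) and total
#' acceleration magnitude per frame, together with each component's
#' maxima.
#'
#' @param result a `simulation_result` from [solve_dynamic()] (or
#'   [solve_static()], in which case accelerations are zero).
#' @param mesh the mesh the simulation ran on.
#' @return A list of class `component_kinematics`: `times`,
#'   `displacement` and `acceleration` (frames x components matrices,
#'   mm and mm/s^2), `nodes` (the representative node ids) and `maxima`
#'   (data frame with per-component peak values and times).
#' @export
extract_component_kinematics <- function(result, mesh) {
  stopifnot(inherits(result, "simulation_result"))
  reps <- component_nodes(mesh)
  nf <- length(result$times)
  getmag <- function(M, nodes) {
    if (is.null(M)) return(rep(0, nf))
    # mean motion vector of the representative nodes, then magnitude
    acc <- matrix(0, 3, nf)
    for (node in nodes) {
      rows <- 3 * (node - 1) + 1:3
      acc <- acc + matrix(M[rows, , drop = FALSE], nrow = 3)
    }
    sqrt(colSums((acc / length(nodes))^2))
  }
  disp <- vapply(reps, function(nd)
    getmag(result$nodal_displacement, nd), numeric(nf))
  acc <- vapply(reps, function(nd)
    getmag(result$nodal_acceleration, nd), numeric(nf))
  maxima <- data.frame(
    component = names(reps),
    node = vapply(reps, function(x) x[1], numeric(1)),
    max_displacement = apply(disp, 2, max),
    t_max_displacement = result$times[apply(disp, 2, which.max)],
    max_acceleration = apply(acc, 2, max),
    t_max_acceleration = result$times[apply(acc, 2, which.max)])
  structure(list(times = result$times, displacement = disp,
                 acceleration = acc, nodes = reps, maxima = maxima),
            class = "component_kinematics")
}

#' Geometric regions of interest on the synthetic anatomy
#'
#' Defines the named element sets used by the regional stress analysis,
#' constructed geometrically from the mesh metadata: the Cooper's
#' ligament anterior/posterior sheets and radial septa `L1`..`L8`; the
#' ligament contact areas `area_A` (posterior sheet away from the
#' centre, backed by adipose), `area_B` (central posterior sheet,
#' attached to the pectoralis) and `area_C` (ligament in contact with
#' the glandular lobes); pectoralis patches `N1`..`N9` (anterior side:
#' centre + 8 sectors) and `B1`, `B2` (posterior side: centre + rim);
#' gland areas `gland_D` (rear), `gland_E` (bottom), `gland_F` (top),
#' `gland_G` (front, the duct confluence); and the adipose shell
#' adjacent to the gland (`adipose_near_gland`).  Only non-empty sets
#' are returned (coarse meshes may not resolve every patch).
#'
#' @param mesh a `labelled_tet_mesh` from [build_anatomy()].
#' @return Named list of element index vectors.
#' @export
regional_element_sets <- function(mesh) {
  g <- attr(mesh, "geometry")
  comp <- mesh$element_component
  part <- mesh$element_part
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  zw <- sqrt(g$chest_curvature_radius^2 - cen[, 1]^2) -
    g$chest_curvature_radius
  z_rel <- cen[, 3] - zw - g$t_sl
  dx <- cen[, 1] - g$xc; dy <- cen[, 2] - g$yc
  r_pl <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)

  sets <- list()
  lig <- comp == "ligament"
  sets$lig_anterior <- which(lig & part == "anterior")
  sets$lig_posterior <- which(lig & part == "posterior")
  for (k in 1:8) sets[[paste0("L", k)]] <- which(lig & part == paste0("L", k))

  # distance from each centroid to the nearest lobe centre
  if (any(lig)) {
    dl <- rep(Inf, nrow(cen))
    for (l in seq_len(nrow(g$lobe_xy))) {
      dd <- sqrt((cen[, 1] - g$lobe_xy[l, 1])^2 +
                 (cen[, 2] - g$lobe_xy[l, 2])^2 +
                 (z_rel - g$lobe_zrel[l])^2)
      dl <- pmin(dl, dd)
    }
    near_gland <- dl < 0.5 * max(g$lobe_diam) + 4
    sets$area_C <- which(lig & near_gland)
    sets$area_B <- which(lig & part == "posterior" & r_pl < 0.4 * g$rb &
                           !near_gland)
    sets$area_A <- which(lig & part == "posterior" & r_pl >= 0.4 * g$rb &
                           !near_gland)
    sets$adipose_near_gland <- which(comp == "adipose" & dl <
                                       0.5 * max(g$lobe_diam) + 4)
  }

  pec <- comp == "pectoralis"
  if (any(pec)) {
    tp_mid <- z_rel[pec]                       # in (-t_pec, 0)
    anterior <- pec & z_rel > -0.5 * g$params$pec_center_thickness
    posterior <- pec & !anterior
    sets$N1 <- which(anterior & r_pl < 0.25 * g$rb)
    sector <- floor(((th + pi) %% (2 * pi)) / (pi / 4)) + 1
    for (k in 1:8) {
      sets[[paste0("N", k + 1)]] <- which(anterior & sector == k &
                                            r_pl >= 0.25 * g$rb &
                                            r_pl < 0.9 * g$rb)
    }
    sets$B1 <- which(posterior & r_pl < 0.4 * g$rb)
    sets$B2 <- which(posterior & r_pl >= 0.4 * g$rb & r_pl < g$R_pec)
  }

  gl <- comp == "gland"
  if (any(gl)) {
    front <- gl & (part == "body" | z_rel > g$h0 - 0.22 * g$rb)
    rest <- gl & !front
    hloc <- g$protrusion * sqrt(pmax(0, 1 - (r_pl / g$rb)^2))
    sets$gland_G <- which(front)
    sets$gland_D <- which(rest & z_rel < 0.38 * hloc)
    deep <- gl & !front & z_rel >= 0.38 * hloc
    sets$gland_E <- which(deep & dy < 0)
    sets$gland_F <- which(deep & dy >= 0)
  }

  sets[vapply(sets, length, integer(1)) > 0]
}

#' Regional mean von Mises stress histories
#'
#' Volume-weighted mean of the per-element von Mises stress over each
#' region of interest, per frame, plus the location and time of each
#' region's peak.
#'
#' @param result a `simulation_result` with a stored stress history.
#' @param mesh the mesh the simulation ran on.
#' @param regions named list of element index vectors (default:
#'   [regional_element_sets()]).
#' @return A list of class `regional_stress`: `times`, `mean_history`
#'   (regions x frames matrix, kPa) and `peaks` (data frame: region,
#'   peak stress, time and element of the peak).
#' @export
regional_stress_summary <- function(result, mesh, regions = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(result$element_von_mises)) {
    stop("simulation result carries no stress history ",
         "(run with store_stress = TRUE)")
  }
  if (is.null(regions)) regions <- regional_element_sets(mesh)
  empty <- vapply(regions, length, integer(1)) == 0
  if (any(empty)) {
    stop("empty region(s): ", paste(names(regions)[empty], collapse = ", "))
  }
  vm <- result$element_von_mises
  vol <- tet_volumes(mesh)
  hist <- t(vapply(regions, function(el) {
    w <- vol[el] / sum(vol[el])
    as.numeric(crossprod(w, vm[el, , drop = FALSE]))
  }, numeric(ncol(vm))))
  rownames(hist) <- names(regions)
  peaks <- do.call(rbind, lapply(names(regions), function(nm) {
    el <- regions[[nm]]
    sub <- vm[el, , drop = FALSE]
    pk <- arrayInd(which.max(sub), dim(sub))
    data.frame(region = nm,
               peak_mean = max(hist[nm, ]),
               t_peak_mean = result$times[which.max(hist[nm, ])],
               peak_element = el[pk[1]],
               peak_value = sub[pk[1], pk[2]],
               t_peak = result$times[pk[2]])
  }))
  structure(list(times = result$times, mean_history = hist, peaks = peaks),
            class = "regional_stress")
}

#' Per-direction ligament stress maxima (M-node analogues)
#'
#' For each radial ligament septum `L1`..`L8`, selects the
#' maximum-stress element of the septum's anterior side (the half of the
#' septum nearest the skin) at the `t4` frame, and reports that
#' element's full stress history peak.  These are the analogues of
#' tracking the most-loaded anterior ligament material point in each
#' direction across the gait cycle.
#'
#' @param result a `simulation_result` with a stress history.
#' @param mesh the mesh the simulation ran on.
#' @param events a [detect_events()] result giving `t4` and the analysed
#'   window.
#' @return Data frame with one row per direction: `direction`,
#'   `element`, `vm_t4` (kPa), `peak` (kPa), `t_peak` (s).
#' @export
ligament_direction_maxima <- function(result, mesh, events) {
  stopifnot(inherits(result, "simulation_result"),
            !is.null(result$element_von_mises))
  g <- attr(mesh, "geometry")
  tms <- result$times
  win <- which(tms >= events$window[1] & tms <= events$window[2])
  f4 <- which.min(abs(tms - events$t4))
  vm <- result$element_von_mises
  cen <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
          mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  zrel <- cen[, 3] - (sqrt(g$chest_curvature_radius^2 - cen[, 1]^2) -
                        g$chest_curvature_radius) - g$t_sl
  r <- sqrt((cen[, 1] - g$xc)^2 + (cen[, 2] - g$yc)^2)
  hloc <- g$protrusion * sqrt(pmax(0, 1 - (r / g$rb)^2))
  regs <- regional_element_sets(mesh)
  out <- list()
  for (k in 1:8) {
    nm <- paste0("L", k)
    if (is.null(regs[[nm]])) next
    els <- regs[[nm]]
    ant <- els[zrel[els] > 0.45 * hloc[els]]
    if (!length(ant)) next
    Mk <- ant[which.max(vm[ant, f4])]
    h <- vm[Mk, win]
    out[[nm]] <- data.frame(direction = nm, element = Mk,
                            vm_t4 = vm[Mk, f4], peak = max(h),
                            t_peak = tms[win][which.max(h)])
  }
  do.call(rbind, out)
}

#' Desk-scale simulation configuration
#'
#' Bundles the anatomy, materials, driven-motion and solver settings of
#' a complete simulation.  The default configuration is the package's
#' standard synthetic study: the default anatomy meshed at reduced
#' resolution (suitable for interactive use), the reference material
#' table, a 120 Hz synthetic running trajectory (0.38 s half gait
#' cycle, 60 mm vertical and 25 mm mediolateral peak-to-peak, 0.5 mm
#' marker noise) low-pass filtered at 6 Hz, and 0.005 s implicit time
#' steps covering one half-cycle.
#'
#' @param params an [anatomy_params()] object.
#' @param materials named material list (default [material_table()]).
#' @param duration,amp_y,amp_x,noise_sd,half_cycle gait settings passed
#'   to [build_synthetic_gait()].
#' @param dt,n_steps time integration settings.
#' @param filter_fc Butterworth cutoff for the driven motion, Hz.
#' @param ramp_half_cycles smooth-start window: the driven displacement
#'   is tapered on with a C1 smoothstep over this many half-cycles so
#'   the undamped model is not jump-started (which would ring
#'   indefinitely); gait events are analysed in the following
#'   half-cycle.
#' @param seed RNG seed for the trajectory noise.
#' @return A list of class `sim_config`.
#' @export
default_config <- function(params = anatomy_params(mesh_size_fine = 10,
                                                   mesh_size_coarse = 16,
                                                   n_cap_layers = 4),
                           materials = material_table(),
                           duration = 0.85, half_cycle = 0.38,
                           amp_y = 70, amp_x = 15, noise_sd = 0.5,
                           dt = 0.005, n_steps = 146, filter_fc = 6,
                           ramp_half_cycles = 1, seed = 1L) {
  structure(list(params = params, materials = materials,
                 duration = duration, half_cycle = half_cycle,
                 amp_y = amp_y, amp_x = amp_x, noise_sd = noise_sd,
                 dt = dt, n_steps = as.integer(n_steps),
                 filter_fc = filter_fc,
                 ramp_half_cycles = ramp_half_cycles,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Run the full synthetic simulation pipeline
#'
#' Builds the anatomy, generates and filters the driven trajectory,
#' solves the gravity pre-load and the implicit transient dynamics, and
#' detects the gait events.
#'
#' @param config a [default_config()] object.
#' @param mesh optional pre-built mesh (so sweeps re-use the geometry).
#' @param store_stress keep the von Mises history?
#' @return A list of class `breast_simulation`: `mesh`, `trajectory`
#'   (filtered), `applied_trajectory` (filtered and ramp-tapered, as
#'   driven), `raw_trajectory`, `static`, `dynamic`, `events`.
#' @export
run_breast_simulation <- function(config = default_config(), mesh = NULL,
                                  store_stress = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(mesh)) mesh <- build_anatomy(config$params)
  raw <- build_synthetic_gait(duration = config$duration,
                              half_cycle = config$half_cycle,
                              amp_y = config$amp_y, amp_x = config$amp_x,
                              noise_sd = config$noise_sd,
                              seed = config$seed)
  traj <- butterworth_zero_lag(raw, fc = config$filter_fc)
  # C1 smooth start: taper the drive on over the ramp window so the
  # undamped system is not excited impulsively at t = 0
  ramp <- config$ramp_half_cycles * config$half_cycle
  applied <- traj
  if (ramp > 0) {
    tau <- pmin(1, traj$times / ramp)
    env <- tau^3 * (10 - 15 * tau + 6 * tau^2)  # C2 quintic smoothstep
    applied$displacement <- traj$displacement * env
  }
  bcs <- boundary_conditions(mesh)
  st <- solve_static(mesh, config$materials, bcs, store_stress = FALSE)
  dyn <- solve_dynamic(mesh, config$materials, bcs, applied,
                       dt = config$dt, n_steps = config$n_steps,
                       static = st, store_stress = store_stress)
  structure(list(mesh = mesh, trajectory = traj,
                 applied_trajectory = applied, raw_trajectory = raw,
                 static = st, dynamic = dyn,
                 events = detect_events(traj,
                                        cycle = config$ramp_half_cycles + 1)),
            class = "breast_simulation")
}

#' Internal stiffness sweep of the gland or ligament material
#'
#' Re-runs the transient simulation over a grid of Young's moduli for
#' one internal component, holding every other material fixed, and
#' relates the nipple's total displacement at the four gait events to
#' the stiffness by ordinary least squares.  The default grids are five
#' levels with a 2.5 kPa gradient for the gland (5--15 kPa) and five
#' levels with a 20 kPa gradient for the ligaments (80--160 kPa).
#'
#' @param base_config a [default_config()] object.
#' @param component `"gland"` or `"ligament"`.
#' @param E_values Young's modulus grid, kPa (defaults above).
#' @param mesh optional pre-built mesh shared across runs.
#' @return A list of class `sweep_result`: `component`, `E_values`,
#'   `events` (the gait-event times), `peak_displacement` (E x event
#'   matrix of nipple total displacement, mm), `fits` (data frame:
#'   event, slope mm/kPa, Pearson r), `failed` (logical per E).
#' @export
stiffness_sweep <- function(base_config = default_config(),
                            component = c("gland", "ligament"),
                            E_values = NULL, mesh = NULL) {
  component <- match.arg(component)
  if (is.null(E_values)) E_values <- default_sweep_grid(component)
  stopifnot(all(E_values > 0))
  if (is.null(mesh)) mesh <- build_anatomy(base_config$params)
  nE <- length(E_values)
  peak <- matrix(NA_real_, nE, 4,
                 dimnames = list(NULL, c("t1", "t2", "t3", "t4")))
  failed <- logical(nE)
  events <- NULL
  nip <- mesh$node_sets$nipple
  for (i in seq_len(nE)) {
    cfg <- base_config
    m <- cfg$materials[[component]]
    cfg$materials[[component]] <- constitutive_model(
      "neo_hookean", E = E_values[i], v = m$v, density = m$density)
    sim <- tryCatch(
      run_breast_simulation(cfg, mesh = mesh, store_stress = FALSE),
      error = function(e) NULL)
    if (is.null(sim)) { failed[i] <- TRUE; next }
    if (is.null(events)) events <- sim$events
    rows <- 3 * (nip - 1) + 1:3
    um <- sqrt(colSums(sim$dynamic$nodal_displacement[rows, ]^2))
    for (ev in 1:4) {
      tev <- sim$events[[c("t1", "t2", "t3", "t4")[ev]]]
      fr <- which.min(abs(sim$dynamic$times - tev))
      peak[i, ev] <- um[fr]
    }
  }
  ok <- !failed
  fits <- do.call(rbind, lapply(1:4, function(ev) {
    if (sum(ok) >= 2) {
      sl <- stats::coef(stats::lm(peak[ok, ev] ~ E_values[ok]))[2]
      r <- stats::cor(E_values[ok], peak[ok, ev])
    } else {
      sl <- NA_real_; r <- NA_real_
    }
    data.frame(event = c("t1", "t2", "t3", "t4")[ev],
               slope = as.numeric(sl), correlation = r)
  }))
  structure(list(component = component, E_values = E_values,
                 events = events, peak_displacement = peak,
                 fits = fits, failed = failed),
            class = "sweep_result")
}

#' Default stiffness-sweep grids
#'
#' Young's modulus levels of the sweep experiments: five levels with a
#' 2.5 kPa gradient around the glandular reference (10 kPa) and five
#' levels with a 20 kPa gradient around the ligament reference
#' (100 kPa).
#'
#' @param component `"gland"` or `"ligament"`.
#' @return Numeric vector of Young's moduli in kPa.
#' @export
default_sweep_grid <- function(component = c("gland", "ligament")) {
  component <- match.arg(component)
  if (component == "gland") c(5, 7.5, 10, 12.5, 15)
  else c(80, 100, 120, 140, 160)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("stiffness sweep of", x$component, "over",
      paste(x$E_values, collapse = ", "), "kPa\n")
  print(cbind(E_kPa = x$E_values, round(x$peak_displacement, 3)))
  print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Write sweep results as tidy CSV
#'
#' One row per (E, event) with the nipple peak displacement, matching
#' the layout `E_kPa,event,peak_disp_mm`.
#'
#' @param sweep a `sweep_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- expand.grid(E_kPa = sweep$E_values,
                    event = colnames(sweep$peak_displacement))
  df$peak_disp_mm <- as.vector(sweep$peak_displacement)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
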