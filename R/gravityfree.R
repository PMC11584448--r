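#' Settings for the gravity-free inverse iteration
#'
#' @param tol convergence tolerance on the maximum breast-surface nodal
#'   mismatch, mm (default 0.1).
#' @param max_iter maximum fixed-point iterations (default 30).
#' @param relaxation step factor `alpha` in (0, 1] applied to the
#'   geometric correction (default 1; halved automatically when an
#'   update inverts elements).
#' @return An object of class `inverse_settings`.
#' @export
inverse_settings <- function(tol = 0.1, max_iter = 30, relaxation = 1) {
  stopifnot(tol > 0, max_iter >= 1, relaxation > 0, relaxation <= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 relaxation = relaxation),
            class = "inverse_settings")
}

#' Estimate the gravity-free (unloaded) reference configuration
#'
#' A scanned standing posture is already deformed by gravity; simulating
#' motion from it would double-count the gravity pre-load.  This routine
#' recovers the stress-free reference geometry by fixed-point iteration:
#' the initial guess applies reversed (upward) gravity to the loaded
#' geometry, then each iteration deforms the current reference estimate
#' under downward gravity, compares the result with the target (scanned)
#' geometry, and moves the reference nodes by the (relaxed) mismatch:
#' \deqn{X^{k+1} = X^k + \alpha\,(x_\mathrm{target} - \phi_g(X^k))}
#' where \eqn{\phi_g} is the static gravity solve.  Convergence is
#' declared when the maximum nodal mismatch over the breast surface drops
#' below `settings$tol`.
#'
#' @param mesh_loaded a `labelled_tet_mesh` in the gravity-loaded state
#'   (the observation; its surface is the target shape).
#' @param materials named list of [constitutive_model()]s.
#' @param settings an [inverse_settings()] object.
#' @param bcs optional [boundary_conditions()]; defaults to gravity
#'   `c(0, -9800, 0)` with the mesh's torso base driven (held) and the
#'   sagittal symmetry plane constrained.
#' @param ... further arguments passed to [solve_static()]
#'   (e.g. `load_steps`).
#' @return A list with `mesh` (the unloaded `labelled_tet_mesh`, same
#'   topology, updated node positions), `iterations`, `residuals`
#'   (per-iteration max surface mismatch, mm), `converged`, and
#'   `deformed` (the unloaded mesh re-deformed under gravity, for
#'   inspection).
#' @export
estimate_unloaded <- function(mesh_loaded, materials,
                              settings = inverse_settings(),
                              bcs = NULL, ...) {
  stopifnot(inherits(mesh_loaded, "labelled_tet_mesh"),
            inherits(settings, "inverse_settings"))
  if (is.null(bcs)) bcs <- boundary_conditions(mesh_loaded)
  surf <- mesh_loaded$node_sets$breast_surface
  if (!length(surf)) stop("mesh has no breast_surface node set")
  x_target <- mesh_loaded$nodes

  if (sqrt(sum(bcs$gravity^2)) == 0) {
    return(list(mesh = mesh_loaded, iterations = 1L, residuals = 0,
                converged = TRUE, deformed = mesh_loaded))
  }

  cache <- new.env(parent = emptyenv())  # pattern shared across solves
  deform <- function(m) {
    st <- solve_static(m, materials, bcs, store_stress = FALSE,
                       cache = cache, ...)
    m$nodes + matrix(st$nodal_displacement[, 1], ncol = 3, byrow = TRUE)
  }
  mismatch <- function(xdef) {
    max(sqrt(rowSums((x_target[surf, , drop = FALSE] -
                        xdef[surf, , drop = FALSE])^2)))
  }

  # initializer: reversed gravity applied to the loaded geometry
  bcs_up <- bcs
  bcs_up$gravity <- -bcs$gravity
  st_up <- solve_static(mesh_loaded, materials, bcs_up,
                        store_stress = FALSE, cache = cache, ...)
  ref <- mesh_loaded
  ref$nodes <- mesh_loaded$nodes +
    matrix(st_up$nodal_displacement[, 1], ncol = 3, byrow = TRUE)

  alpha <- settings$relaxation
  residuals <- numeric(0)
  grow <- 0L
  xdef <- NULL
  for (it in seq_len(settings$max_iter)) {
    xdef <- tryCatch(deform(ref), error = function(e) NULL)
    if (is.null(xdef)) {
      # inverted elements: relax the previous update and retry
      alpha <- alpha / 2
      if (alpha < 1 / 64) stop("inverse iteration failed: repeated ",
                               "element inversion")
      ref$nodes <- ref_prev + alpha * correction
      next
    }
    r <- mismatch(xdef)
    residuals <- c(residuals, r)
    if (r < settings$tol) {
      def_mesh <- ref; def_mesh$nodes <- xdef
      return(list(mesh = ref, iterations = it, residuals = residuals,
                  converged = TRUE, deformed = def_mesh))
    }
    nres <- length(residuals)
    grow <- if (nres >= 2 && residuals[nres] > residuals[nres - 1])
      grow + 1L else 0L
    if (grow >= 3L) {
      stop("inverse iteration diverging; residual history: ",
           paste(signif(residuals, 4), collapse = ", "))
    }
    correction <- x_target - xdef
    ref_prev <- ref$nodes
    ref$nodes <- ref$nodes + alpha * correction
  }
  def_mesh <- ref
  if (!is.null(xdef)) def_mesh$nodes <- xdef
  list(mesh = ref, iterations = settings$max_iter, residuals = residuals,
       converged = FALSE, deformed = def_mesh)
}
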