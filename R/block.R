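#' Structured block mesh for solver verification
#'
#' Builds a rectangular single- or multi-component block meshed with the
#' same Freudenthal tetrahedral subdivision used by [build_anatomy()].
#' Useful for convergence studies and oracle tests of the solver
#' (hanging-block deflection, uniaxial stretch, energy balance) where an
#' analytic or refined reference exists.
#'
#' @param lx,ly,lz block edge lengths, mm.
#' @param nx,ny,nz element subdivisions per direction.
#' @param component label applied to every tet.
#' @param origin corner position (default the origin).
#' @return A `labelled_tet_mesh` without shells.  Node sets: the six
#'   faces `xmin`..`zmax`, plus the solver-facing aliases `torso_base`
#'   (= `ymax`, the hanging support), `symmetry_plane` (empty),
#'   `breast_surface` (= `ymin`), `nipple` (centre of `ymin`) and
#'   `clavicle` (first `ymax` node).
#' @export
block_mesh <- function(lx = 20, ly = 20, lz = 20, nx = 2, ny = 2, nz = 2,
                       component = "soft_layer", origin = c(0, 0, 0)) {
  xb <- origin[1] + lx * (0:nx) / nx
  yb <- origin[2] + ly * (0:ny) / ny
  zb <- origin[3] + lz * (0:nz) / nz
  nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L
  nodes <- cbind(rep(xb, times = nny * nnz),
                 rep(rep(yb, each = nnx), times = nnz),
                 rep(zb, each = nnx * nny))
  nid <- function(i, j, k) (k - 1L) * (nnx * nny) + (j - 1L) * nnx + i
  ci <- rep(seq_len(nx), times = ny * nz)
  cj <- rep(rep(seq_len(ny), each = nx), times = nz)
  ck <- rep(seq_len(nz), each = nx * ny)
  corner <- function(di, dj, dk) nid(ci + di, cj + dj, ck + dk)
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)
  tets <- rbind(cbind(c000, c100, c110, c111),
                cbind(c000, c010, c110, c111),
                cbind(c000, c100, c101, c111),
                cbind(c000, c001, c101, c111),
                cbind(c000, c010, c011, c111),
                cbind(c000, c001, c011, c111))
  v <- tet_signed_volume(nodes[tets[, 1], , drop = FALSE],
                         nodes[tets[, 2], , drop = FALSE],
                         nodes[tets[, 3], , drop = FALSE],
                         nodes[tets[, 4], , drop = FALSE])
  flip <- v < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]; tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
  }
  face <- function(which) {
    switch(which,
           xmin = which(abs(nodes[, 1] - min(xb)) < 1e-9),
           xmax = which(abs(nodes[, 1] - max(xb)) < 1e-9),
           ymin = which(abs(nodes[, 2] - min(yb)) < 1e-9),
           ymax = which(abs(nodes[, 2] - max(yb)) < 1e-9),
           zmin = which(abs(nodes[, 3] - min(zb)) < 1e-9),
           zmax = which(abs(nodes[, 3] - max(zb)) < 1e-9))
  }
  ymin <- face("ymin")
  ctr <- colMeans(nodes[ymin, , drop = FALSE])
  nip <- ymin[which.min(colSums((t(nodes[ymin, , drop = FALSE]) - ctr)^2))]
  mesh <- structure(
    list(nodes = nodes, tets = tets,
         patch = rep(seq_len(nx * ny * nz), times = 6L),
         shells = matrix(integer(0), 0, 3),
         shell_thickness = numeric(0),
         element_component = rep(component, nrow(tets)),
         element_part = rep(NA_character_, nrow(tets)),
         shell_component = character(0),
         node_sets = list(xmin = face("xmin"), xmax = face("xmax"),
                          ymin = ymin, ymax = face("ymax"),
                          zmin = face("zmin"), zmax = face("zmax"),
                          torso_base = face("ymax"),
                          symmetry_plane = integer(0),
                          breast_surface = ymin,
                          nipple = nip,
                          clavicle = face("ymax")[1])),
    class = "labelled_tet_mesh")
  validate_mesh(mesh)
  mesh
}
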