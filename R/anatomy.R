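#' Parameters of the synthetic multi-component breast anatomy
#'
#' Collects and validates the geometric parameters of the parametric
#' idealization used in place of subject-specific scan data: a curved
#' chest-wall plate carrying a 25 mm subcutaneous soft-tissue layer, a
#' tapering pectoralis major slab, a superellipsoid breast cap of adipose
#' tissue containing 18 glandular lobes (two concentric circular arrays)
#' with tapering ducts gathered in a circular body under the nipple, a
#' Cooper's-ligament network (eight radial septa closed by anterior and
#' posterior sheets), and a 1.5 mm skin membrane over the whole surface.
#' Only the left half of the torso is generated; the sagittal plane
#' `x = 0` is the symmetry plane.
#'
#' All lengths are in mm.  The plan-view mesh resolution is
#' `mesh_size_fine` inside the central region containing the gland,
#' ligaments, pectoralis and neighbouring adipose/soft-layer tissue and
#' `mesh_size_coarse` elsewhere; through-thickness resolution is set by
#' `n_soft_layers` and `n_cap_layers`.
#'
#' @param breast_base_radius radius of the breast footprint on the chest
#'   wall (default 60).
#' @param breast_protrusion height of the breast apex above the torso
#'   surface (default 50).
#' @param soft_layer_thickness thickness of the subcutaneous soft-tissue
#'   layer between the rigid chest wall and the breast (default 25).
#' @param skin_thickness skin shell thickness (default 1.5).
#' @param n_lobes number of glandular lobes (default 18; split roughly
#'   1:2 between the inner and outer circular arrays).
#' @param lobe_diameter_range range the per-lobe diameters are drawn from
#'   uniformly (default 15--18).
#' @param duct_diameter_range duct diameter taper range, thick at the
#'   lobe to thin at the nipple (default 2--4).
#' @param pec_center_thickness,pec_edge_thickness pectoralis major slab
#'   thickness at the centre of the breast footprint and at its edge
#'   (defaults 12 and 4).
#' @param ligament_shell_thickness nominal thickness of the ligament
#'   septa (default 3; capture on the mesh is widened to the local
#'   element size so the septa stay connected).
#' @param mesh_size_fine,mesh_size_coarse plan-view element sizes
#'   (defaults 4 and 8).
#' @param n_soft_layers,n_cap_layers through-thickness element layers in
#'   the torso slab below the pectoralis and in the breast cap.
#' @param torso_pad,top_band,chest_curvature_radius torso plan margins
#'   and chest-wall curvature; default to `breast_base_radius/3`,
#'   `0.8*breast_base_radius` and `5*breast_base_radius` so that the
#'   whole domain scales geometrically with the breast.
#' @param seed integer RNG seed controlling lobe diameters and placement.
#' @return An object of class `anatomy_params`.
#' @seealso [build_anatomy()]
#' @export
anatomy_params <- function(breast_base_radius = 60,
                           breast_protrusion = 50,
                           soft_layer_thickness = 25,
                           skin_thickness = 1.5,
                           n_lobes = 18,
                           lobe_diameter_range = c(15, 18),
                           duct_diameter_range = c(2, 4),
                           pec_center_thickness = 12,
                           pec_edge_thickness = 4,
                           ligament_shell_thickness = 3,
                           mesh_size_fine = 4,
                           mesh_size_coarse = 8,
                           n_soft_layers = 1,
                           n_cap_layers = 4,
                           torso_pad = NULL,
                           top_band = NULL,
                           chest_curvature_radius = NULL,
                           seed = 1L) {
  p <- list(breast_base_radius = breast_base_radius,
            breast_protrusion = breast_protrusion,
            soft_layer_thickness = soft_layer_thickness,
            skin_thickness = skin_thickness,
            n_lobes = as.integer(n_lobes),
            lobe_diameter_range = sort(lobe_diameter_range),
            duct_diameter_range = sort(duct_diameter_range),
            pec_center_thickness = pec_center_thickness,
            pec_edge_thickness = pec_edge_thickness,
            ligament_shell_thickness = ligament_shell_thickness,
            mesh_size_fine = mesh_size_fine,
            mesh_size_coarse = mesh_size_coarse,
            n_soft_layers = as.integer(n_soft_layers),
            n_cap_layers = as.integer(n_cap_layers),
            torso_pad = if (is.null(torso_pad)) breast_base_radius / 3
                        else torso_pad,
            top_band = if (is.null(top_band)) 0.8 * breast_base_radius
                       else top_band,
            chest_curvature_radius = if (is.null(chest_curvature_radius))
                5 * breast_base_radius else chest_curvature_radius,
            seed = as.integer(seed))
  lens <- c(p$breast_base_radius, p$breast_protrusion,
            p$soft_layer_thickness, p$skin_thickness,
            p$lobe_diameter_range, p$duct_diameter_range,
            p$pec_center_thickness, p$pec_edge_thickness,
            p$ligament_shell_thickness, p$mesh_size_fine,
            p$mesh_size_coarse, p$torso_pad, p$top_band,
            p$chest_curvature_radius)
  if (!all(is.finite(lens)) || any(lens <= 0)) {
    stop("all anatomy lengths must be positive and finite")
  }
  if (p$n_lobes < 1L) stop("n_lobes must be >= 1")
  if (p$mesh_size_fine > p$mesh_size_coarse) {
    stop("mesh_size_fine must not exceed mesh_size_coarse")
  }
  if (p$n_cap_layers < 3L) stop("n_cap_layers must be >= 3")
  if (p$n_soft_layers < 1L) stop("n_soft_layers must be >= 1")
  if (p$pec_center_thickness >= p$soft_layer_thickness) {
    stop("pectoralis thickness must be smaller than the soft-tissue layer")
  }
  class(p) <- "anatomy_params"
  p
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# graded 1-D breakpoints: coarse outside [a, b], fine inside
graded_breaks <- function(L, a, b, h_fine, h_coarse) {
  a <- max(0, min(a, L)); b <- max(a, min(b, L))
  seg <- function(from, to, h) {
    if (to - from < 1e-9) return(numeric(0))
    n <- max(1L, ceiling((to - from) / h))
    from + (to - from) * seq_len(n) / n
  }
  unique(c(0, seg(0, a, h_coarse), seg(a, b, h_fine), seg(b, L, h_coarse)))
}

# signed volumes of tets given 4 corner coordinate matrices (n x 3)
tet_signed_volume <- function(a, b, c, d) {
  u <- b - a; v <- c - a; w <- d - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  (cx * w[, 1] + cy * w[, 2] + cz * w[, 3]) / 6
}

#' Signed volumes of the tetrahedra of a mesh
#' @param mesh a `labelled_tet_mesh`.
#' @return Numeric vector of signed volumes (mm^3), one per tet.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes
  tet_signed_volume(nd[mesh$tets[, 1], , drop = FALSE],
                    nd[mesh$tets[, 2], , drop = FALSE],
                    nd[mesh$tets[, 3], , drop = FALSE],
                    nd[mesh$tets[, 4], , drop = FALSE])
}

#' Build the synthetic multi-component breast mesh
#'
#' Generates the conforming labelled tetrahedral + shell mesh described in
#' [anatomy_params()].  The mesh is produced from a terrain-following
#' structured grid (Freudenthal 6-tet subdivision of hexahedral cells), so
#' every interface between components shares nodes by construction ("glued"
#' sub-models).  Component labels are assigned per element:
#' `soft_layer`, `pectoralis` (tapering slab directly behind the breast),
#' `adipose`, `gland` (lobes, ducts, circular body), `ligament` (anterior
#' sheet under the skin, posterior sheet over the pectoralis restricted to
#' the upper two-thirds of the breast, and eight radial septa L1--L8), and
#' `skin` shell triangles on the outer surface.
#'
#' @param params an [anatomy_params()] object.
#' @return An object of class `labelled_tet_mesh` with fields
#'   `nodes` (n x 3, mm), `tets` (m x 4 indices, positively oriented),
#'   `patch` (mean-dilatation patch id per tet: the parent hexahedral
#'   cell), `shells` (s x 3 indices), `shell_thickness`,
#'   `element_component` (per-tet label), `element_part` (sub-part
#'   label: `L1`..`L8`, `anterior`, `posterior`, `lobe`, `duct`,
#'   `body`, or `NA`), `shell_component` (`"skin"`), and `node_sets`
#'   (named lists of node indices: `nipple`, `clavicle`,
#'   `symmetry_plane`, `torso_base`, `breast_surface`).  Geometry
#'   metadata used by downstream analyses is attached as attribute
#'   `geometry`.
#' @examples
#' \donttest{
#' mesh <- build_anatomy(anatomy_params(mesh_size_fine = 9,
#'                                      mesh_size_coarse = 16))
#' table(mesh$element_component)
#' }
#' @export
build_anatomy <- function(params = anatomy_params()) {
  stopifnot(inherits(params, "anatomy_params"))
  p <- params
  rb <- p$breast_base_radius
  prot <- p$breast_protrusion
  t_sl <- p$soft_layer_thickness
  pad <- p$torso_pad
  xc <- pad + rb; yc <- pad + rb
  Lx <- 2 * rb + 2 * pad
  Ly <- 2 * rb + 2 * pad + p$top_band
  Rc <- p$chest_curvature_radius
  if (Rc <= Lx) stop("chest_curvature_radius must exceed the torso width")
  h_cut <- p$mesh_size_fine
  R_pec <- 1.25 * rb

  cap_h <- function(r) {
    h <- prot * sqrt(pmax(0, 1 - (r / rb)^2))
    h[h < h_cut] <- 0
    h
  }
  zwall <- function(x) sqrt(Rc^2 - x^2) - Rc
  pec_t <- function(r) {
    p$pec_edge_thickness + (p$pec_center_thickness - p$pec_edge_thickness) *
      pmax(0, 1 - (r / R_pec)^2)
  }

  ## ---- glandular lobe layout -------------------------------------------
  # Ring radii: adjacent lobe centres on a ring of n lobes are separated by
  # 2 R sin(pi/n); requiring a clearance factor of 1.1 on the largest lobe
  # diameter gives R >= 1.1 d_max / (2 sin(pi/n)).  The outer ring is
  # additionally pushed one clearance distance beyond the inner ring.
  d_rng <- p$lobe_diameter_range
  d_max <- d_rng[2]
  n_in <- max(1L, round(p$n_lobes / 3))
  n_out <- p$n_lobes - n_in
  sep <- 1.1 * d_max
  R_in <- if (n_in > 1) sep / (2 * sin(pi / n_in)) else 0.3 * rb
  R_out <- if (n_out > 0) {
    max(sep / (2 * sin(pi / n_out)), R_in + sep)
  } else R_in
  if (R_out + d_max / 2 > 0.85 * rb) {
    stop("infeasible anatomy: ", p$n_lobes, " lobes of diameter up to ",
         d_max, " mm cannot be contained in a breast of base radius ",
         rb, " mm")
  }
  if (cap_h(R_out) < 0.6 * d_max) {
    stop("infeasible anatomy: breast protrusion too small to contain ",
         "the outer lobe ring")
  }

  lob <- with_seed(p$seed, {
    diam <- stats::runif(p$n_lobes, d_rng[1], d_rng[2])
    duct_d <- stats::runif(p$n_lobes, p$duct_diameter_range[1],
                           p$duct_diameter_range[2])
    ring <- rep(c("inner", "outer"), c(n_in, n_out))
    th <- c(2 * pi * seq_len(n_in) / n_in,
            if (n_out > 0) 2 * pi * seq_len(n_out) / n_out + pi / n_out)
    list(diam = diam, duct_d = duct_d, ring = ring, th = th)
  })
  Rring <- ifelse(lob$ring == "inner", R_in, R_out)
  lobe_xy <- cbind(xc + Rring * cos(lob$th), yc + Rring * sin(lob$th))
  lobe_zrel <- 0.45 * cap_h(Rring)
  r_body <- 0.1 * rb
  h0 <- cap_h(0)
  body_zrel <- h0 - 0.1 * rb - c(0.13 * rb, 0)  # short cylinder below apex
  duct_end <- cbind(xc + r_body * cos(lob$th), yc + r_body * sin(lob$th),
                    mean(body_zrel))

  ## ---- structured grid --------------------------------------------------
  fr <- 0.85 * rb
  xb <- graded_breaks(Lx, xc - fr, xc + fr, p$mesh_size_fine,
                      p$mesh_size_coarse)
  yb <- graded_breaks(Ly, yc - fr, yc + fr, p$mesh_size_fine,
                      p$mesh_size_coarse)
  nnx <- length(xb); nny <- length(yb)
  npl <- 1L + p$n_soft_layers + 1L + p$n_cap_layers

  X2 <- matrix(xb, nnx, nny)
  Y2 <- matrix(yb, nnx, nny, byrow = TRUE)
  R2 <- sqrt((X2 - xc)^2 + (Y2 - yc)^2)
  ZW <- matrix(zwall(xb), nnx, nny)
  TP <- pec_t(R2)
  H2 <- cap_h(R2)

  nc <- p$n_cap_layers
  zs <- array(0, dim = c(nnx, nny, npl))
  zs[, , 1] <- ZW
  for (k in seq_len(p$n_soft_layers)) {
    zs[, , 1 + k] <- ZW + (t_sl - TP) * k / p$n_soft_layers
  }
  zs[, , 1 + p$n_soft_layers + 1] <- ZW + t_sl
  # cap layer breakpoints: thin bottom and top layers sized for the
  # ligament sheets, equal interior layers
  t_edge <- pmin(p$ligament_shell_thickness, H2 / 4)
  for (kc in seq_len(nc)) {
    frac_mid <- if (nc > 2) (kc - 1) / (nc - 2) else 1
    brk <- if (kc == nc) H2 else if (kc == nc - 1) H2 - t_edge else
      t_edge + (H2 - 2 * t_edge) * frac_mid
    zs[, , 1 + p$n_soft_layers + 1 + kc] <- ZW + t_sl + brk
  }

  nodes0 <- cbind(rep(as.vector(X2), npl),
                  rep(as.vector(Y2), npl),
                  as.vector(zs))
  nid <- function(i, j, k) (k - 1L) * (nnx * nny) + (j - 1L) * nnx + i

  # merge coincident nodes (cap planes collapse onto the torso surface
  # outside the breast footprint)
  key <- paste(round(nodes0[, 1], 6), round(nodes0[, 2], 6),
               round(nodes0[, 3], 6))
  first <- !duplicated(key)
  remap <- match(key, key[first])   # compact id of the first occurrence
  nodes <- nodes0[first, , drop = FALSE]

  ## ---- hexahedral cells -> Freudenthal tets -----------------------------
  ci <- rep(seq_len(nnx - 1L), times = (nny - 1L) * (npl - 1L))
  cj <- rep(rep(seq_len(nny - 1L), each = nnx - 1L), times = npl - 1L)
  ck <- rep(seq_len(npl - 1L), each = (nnx - 1L) * (nny - 1L))
  corner <- function(di, dj, dk) nid(ci + di, cj + dj, ck + dk)
  c000 <- corner(0L, 0L, 0L); c100 <- corner(1L, 0L, 0L)
  c010 <- corner(0L, 1L, 0L); c110 <- corner(1L, 1L, 0L)
  c001 <- corner(0L, 0L, 1L); c101 <- corner(1L, 0L, 1L)
  c011 <- corner(0L, 1L, 1L); c111 <- corner(1L, 1L, 1L)
  # six path-tetrahedra of the unit cube (consistent across faces)
  tets0 <- rbind(cbind(c000, c100, c110, c111),
                 cbind(c000, c010, c110, c111),
                 cbind(c000, c100, c101, c111),
                 cbind(c000, c001, c101, c111),
                 cbind(c000, c010, c011, c111),
                 cbind(c000, c001, c011, c111))
  ncell <- (nnx - 1L) * (nny - 1L) * (npl - 1L)
  layer_k <- rep(ck, times = 6L)
  hexid <- rep(seq_len(ncell), times = 6L)
  tets0 <- matrix(remap[tets0], ncol = 4L)

  vol <- tet_signed_volume(nodes[tets0[, 1], , drop = FALSE],
                           nodes[tets0[, 2], , drop = FALSE],
                           nodes[tets0[, 3], , drop = FALSE],
                           nodes[tets0[, 4], , drop = FALSE])
  voltol <- 1e-7 * p$mesh_size_fine^3
  keep <- abs(vol) > voltol
  tets <- tets0[keep, , drop = FALSE]
  layer_k <- layer_k[keep]
  hexid <- hexid[keep]
  patch <- match(hexid, unique(hexid))   # mean-dilatation patches
  vol <- vol[keep]
  flip <- vol < 0
  if (any(flip)) {
    tmp <- tets[flip, 3L]
    tets[flip, 3L] <- tets[flip, 4L]
    tets[flip, 4L] <- tmp
    vol[flip] <- -vol[flip]
  }
  if (any(vol <= 0)) {
    stop("mesh generation failure: inverted tetrahedra remain")
  }

  ## ---- component labels -------------------------------------------------
  cen <- (nodes[tets[, 1], , drop = FALSE] + nodes[tets[, 2], , drop = FALSE] +
          nodes[tets[, 3], , drop = FALSE] + nodes[tets[, 4], , drop = FALSE]) / 4
  r_c <- sqrt((cen[, 1] - xc)^2 + (cen[, 2] - yc)^2)
  z_rel <- cen[, 3] - zwall(cen[, 1]) - t_sl     # height above torso surface
  pec_layer <- 1L + p$n_soft_layers
  kc <- layer_k - pec_layer                      # cap layer index (1..nc)

  comp <- rep("adipose", nrow(tets))
  part <- rep(NA_character_, nrow(tets))
  comp[layer_k <= p$n_soft_layers] <- "soft_layer"
  comp[layer_k == pec_layer] <- ifelse(r_c[layer_k == pec_layer] < R_pec,
                                       "pectoralis", "soft_layer")
  in_cap <- layer_k > pec_layer

  # gland: lobes (ellipsoids stretched toward the duct), ducts, body
  is_gland <- rep(FALSE, nrow(tets))
  gland_part <- rep(NA_character_, nrow(tets))
  idx_cap <- which(in_cap)
  if (length(idx_cap)) {
    pc <- cbind(cen[idx_cap, 1], cen[idx_cap, 2], z_rel[idx_cap])
    # circular body near the nipple
    body <- r_c[idx_cap] <= r_body &
      pc[, 3] >= body_zrel[1] & pc[, 3] <= body_zrel[2]
    g <- body
    gp <- ifelse(body, "body", NA_character_)
    for (l in seq_len(p$n_lobes)) {
      cl <- c(lobe_xy[l, ], lobe_zrel[l])
      el <- c(duct_end[l, 1], duct_end[l, 2], duct_end[l, 3])
      ax <- el - cl; ax <- ax / sqrt(sum(ax^2))
      dm <- lob$diam[l]
      a_l <- 0.65 * dm; b_l <- 0.5 * dm
      t <- sweep(pc, 2, cl)
      s <- t %*% ax
      q2 <- rowSums(t^2) - s^2
      inside <- (s / a_l)^2 + q2 / b_l^2 <= 1
      # duct segment
      w <- el - cl; L2 <- sum(w^2)
      sd <- pmin(1, pmax(0, (t %*% w) / L2))
      dd2 <- rowSums((t - sd %*% t(w))^2)
      rduct <- pmax((lob$duct_d[l] * (1 - sd) + p$duct_diameter_range[1] * sd) / 2,
                    0.45 * p$mesh_size_fine)
      induct <- dd2 <= rduct^2 & !inside
      gp[inside & !g] <- "lobe"
      gp[induct & !g] <- "duct"
      g <- g | inside | induct
    }
    is_gland[idx_cap] <- g
    gland_part[idx_cap] <- gp
  }

  # ligament network
  is_lig <- rep(FALSE, nrow(tets))
  lig_part <- rep(NA_character_, nrow(tets))
  if (length(idx_cap)) {
    ic <- idx_cap
    post <- kc[ic] == 1L & (cen[ic, 2] - yc) > -rb / 3 & r_c[ic] < 0.92 * rb
    ant <- kc[ic] == nc & r_c[ic] >= r_body
    sept <- rep(FALSE, length(ic))
    sept_id <- rep(NA_integer_, length(ic))
    th_sep <- (seq_len(8) - 0.5) * pi / 4   # L1..L8, offset from the lobes
    capture <- max(p$ligament_shell_thickness, 0.5 * p$mesh_size_fine)
    dx <- cen[ic, 1] - xc; dy <- cen[ic, 2] - yc
    for (sidx in seq_along(th_sep)) {
      th <- th_sep[sidx]
      along <- dx * cos(th) + dy * sin(th)
      perp <- abs(-dx * sin(th) + dy * cos(th))
      hit <- along > r_body & perp <= capture / 2 & r_c[ic] < 0.88 * rb &
        kc[ic] > 1L & kc[ic] < nc
      sept_id[hit & !sept] <- sidx
      sept <- sept | hit
    }
    lig <- (post | ant | sept) & !is_gland[ic]
    is_lig[ic] <- lig
    lp <- rep(NA_character_, length(ic))
    lp[sept] <- paste0("L", sept_id[sept])
    lp[post] <- "posterior"
    lp[ant] <- "anterior"
    lig_part[ic][lig] <- lp[lig]
  }

  comp[in_cap] <- "adipose"
  comp[is_lig] <- "ligament"
  comp[is_gland] <- "gland"
  part[is_lig] <- lig_part[is_lig]
  part[is_gland] <- gland_part[is_gland]

  ## ---- skin shells on the outer surface ---------------------------------
  top <- npl
  q00 <- remap[nid(rep(seq_len(nnx - 1L), nny - 1L),
                   rep(seq_len(nny - 1L), each = nnx - 1L), top)]
  q10 <- remap[nid(rep(seq_len(nnx - 1L) + 1L, nny - 1L),
                   rep(seq_len(nny - 1L), each = nnx - 1L), top)]
  q01 <- remap[nid(rep(seq_len(nnx - 1L), nny - 1L),
                   rep(seq_len(nny - 1L) + 1L, each = nnx - 1L), top)]
  q11 <- remap[nid(rep(seq_len(nnx - 1L) + 1L, nny - 1L),
                   rep(seq_len(nny - 1L) + 1L, each = nnx - 1L), top)]
  shells <- rbind(cbind(q00, q10, q11), cbind(q00, q11, q01))

  ## ---- node sets --------------------------------------------------------
  nd <- nodes
  on_sym <- which(abs(nd[, 1]) < 1e-8)
  base_ids <- sort(unique(remap[nid(rep(seq_len(nnx), nny),
                                    rep(seq_len(nny), each = nnx), 1L)]))
  top_ids <- sort(unique(remap[nid(rep(seq_len(nnx), nny),
                                   rep(seq_len(nny), each = nnx), top)]))
  rtop <- sqrt((nd[top_ids, 1] - xc)^2 + (nd[top_ids, 2] - yc)^2)
  breast_surface <- top_ids[cap_h(rtop) > 0]
  apex <- c(xc, yc, zwall(xc) + t_sl + h0)
  nip <- top_ids[which.min(colSums((t(nd[top_ids, , drop = FALSE]) - apex)^2))]
  clav_target <- c(0.15 * Lx, Ly, zwall(0.15 * Lx))
  clav <- base_ids[which.min(colSums(
    (t(nd[base_ids, , drop = FALSE]) - clav_target)^2))]

  mesh <- structure(
    list(nodes = nodes,
         tets = tets,
         patch = patch,
         shells = shells,
         shell_thickness = rep(p$skin_thickness, nrow(shells)),
         element_component = comp,
         element_part = part,
         shell_component = rep("skin", nrow(shells)),
         node_sets = list(nipple = nip,
                          clavicle = clav,
                          symmetry_plane = on_sym,
                          torso_base = base_ids,
                          breast_surface = breast_surface)),
    class = "labelled_tet_mesh")
  attr(mesh, "geometry") <- list(
    params = p, xc = xc, yc = yc, Lx = Lx, Ly = Ly, t_sl = t_sl,
    rb = rb, protrusion = prot, h0 = h0, r_body = r_body, R_pec = R_pec,
    R_in = R_in, R_out = R_out, lobe_xy = lobe_xy, lobe_zrel = lobe_zrel,
    lobe_diam = lob$diam, septa_angles = (seq_len(8) - 0.5) * pi / 4,
    layer_k = layer_k, cap_layer = kc, pec_layer_index = pec_layer,
    n_cap_layers = nc, chest_curvature_radius = Rc)
  validate_mesh(mesh)
  mesh
}

# internal sanity checks run after generation
validate_mesh <- function(mesh) {
  stopifnot(all(mesh$tets >= 1), all(mesh$tets <= nrow(mesh$nodes)),
            all(mesh$shells >= 1), all(mesh$shells <= nrow(mesh$nodes)))
  v <- tet_volumes(mesh)
  if (any(v <= 0)) stop("mesh generation failure: non-positive tet volume")
  stopifnot(length(mesh$element_component) == nrow(mesh$tets),
            all(mesh$element_component %in%
                  c("soft_layer", "adipose", "pectoralis", "ligament",
                    "gland", "skin")))
  ns <- mesh$node_sets
  stopifnot(all(vapply(ns, function(s) all(s >= 1 & s <= nrow(mesh$nodes)),
                       logical(1))))
  invisible(mesh)
}

#' @export
print.labelled_tet_mesh <- function(x, ...) {
  cat("<labelled_tet_mesh>", nrow(x$nodes), "nodes,", nrow(x$tets),
      "tets,", nrow(x$shells), "skin shells\n")
  print(table(x$element_component))
  invisible(x)
}

#' Component volumes of a labelled mesh
#' @param mesh a `labelled_tet_mesh`.
#' @return Named numeric vector of summed tet volumes (mm^3) per component.
#' @export
component_volumes <- function(mesh) {
  v <- tet_volumes(mesh)
  tapply(v, mesh$element_component, sum)
}

#' Synthetic running trajectory of the clavicle base point
#'
#' Builds a uniformly sampled displacement trajectory emulating the
#' vertical and mediolateral motion of a clavicle marker during treadmill
#' running: the vertical (Y) component is a sinusoid with one maximum
#' (the `t2` analogue) and one minimum (`t4`) per half gait cycle, the
#' mediolateral (X) sway completes one cycle per full gait cycle, and the
#' anteroposterior (Z) component is zero.  Independent Gaussian noise of
#' standard deviation `noise_sd` is added to every sample, mimicking
#' marker jitter.  The mid-phase upward and downward zero crossings of
#' the vertical waveform define the `t1` and `t3` analogues.
#'
#' @param duration total duration, s.
#' @param sample_rate sampling rate, Hz (default 120).
#' @param half_cycle duration of half a gait cycle, s (default 0.38).
#' @param amp_y,amp_x peak-to-peak amplitudes, mm.
#' @param asym second-harmonic asymmetry of the vertical waveform
#'   (default 0.1, matching the modest crest/trough displacement
#'   asymmetry of a clavicle during running): the trough is deeper than
#'   the crest by a factor `(1+asym)/(1-asym)`; `0` gives a pure
#'   sinusoid.  The extremum times and the sinusoidal peak-to-peak
#'   amplitude are unchanged.
#' @param impact_depth,impact_width foot-strike braking pulse: a
#'   Gaussian dip of this depth (mm, default 5) and width (s, standard
#'   deviation, default 0.03) superposed on each trough.  This carries
#'   the ground-reaction braking spike of running -- a large upward
#'   acceleration concentrated at `t4` -- without unloading the crest;
#'   `impact_depth = 0` disables it.
#' @param noise_sd additive Gaussian noise SD, mm.
#' @param seed RNG seed for the noise realization.
#' @return An object of class `trajectory`: `times` (s),
#'   `displacement` (n x 3 matrix, columns X/Y/Z, mm), `sample_rate`,
#'   with the waveform phase stored in attribute `waveform`.
#' @export
build_synthetic_gait <- function(duration = 3, sample_rate = 120,
                                 half_cycle = 0.38, amp_y = 70,
                                 amp_x = 15, asym = 0.1,
                                 impact_depth = 5, impact_width = 0.03,
                                 noise_sd = 0.5, seed = 1L) {
  stopifnot(duration > 0, half_cycle > 0, sample_rate > 0, noise_sd >= 0,
            asym >= 0, asym < 0.5, impact_depth >= 0, impact_width > 0)
  n <- round(duration * sample_rate)
  times <- (seq_len(n) - 1) / sample_rate
  t0 <- 0.092 * half_cycle    # phase offset: vertical max at ~0.34 half-cycle
  th <- 2 * pi * (times - t0) / half_cycle
  Y <- amp_y / 2 * (sin(th) + asym / 2 * (cos(2 * th) - 1))
  # foot-strike braking pulse centred on each trough (theta = 3pi/2 mod 2pi)
  if (impact_depth > 0) {
    dphi <- ((th - 3 * pi / 2 + pi) %% (2 * pi)) - pi
    dt4 <- dphi * half_cycle / (2 * pi)
    Y <- Y - impact_depth * exp(-dt4^2 / (2 * impact_width^2))
  }
  X <- amp_x / 2 * sin(pi * (times - t0) / half_cycle)
  Z <- rep(0, n)
  disp <- cbind(X = X, Y = Y, Z = Z)
  if (noise_sd > 0) {
    disp <- disp + with_seed(seed, matrix(stats::rnorm(3 * n, 0, noise_sd),
                                          n, 3))
  }
  trajectory(times, disp, sample_rate,
             waveform = list(t0 = t0, half_cycle = half_cycle,
                             amp_y = amp_y, amp_x = amp_x))
}

#' Construct a trajectory object
#'
#' @param times strictly increasing, uniformly spaced times in s.
#' @param displacement n x 3 matrix of marker displacements (mm),
#'   columns X (mediolateral), Y (vertical), Z (anteroposterior).
#' @param sample_rate sampling rate in Hz; must match the time spacing.
#' @param waveform optional list describing a synthetic waveform phase.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, displacement, sample_rate = NULL,
                       waveform = NULL) {
  displacement <- as.matrix(displacement)
  stopifnot(length(times) == nrow(displacement), ncol(displacement) == 3,
            all(is.finite(times)), all(is.finite(displacement)))
  if (length(times) > 1) {
    dtv <- diff(times)
    if (any(dtv <= 0) || diff(range(dtv)) > 1e-9 * mean(dtv)) {
      stop("trajectory times must be strictly increasing and uniform")
    }
    if (is.null(sample_rate)) sample_rate <- 1 / mean(dtv)
    if (abs(mean(dtv) - 1 / sample_rate) > 1e-9 / sample_rate) {
      stop("sample_rate inconsistent with time spacing")
    }
  }
  colnames(displacement) <- c("X", "Y", "Z")
  structure(list(times = times, displacement = displacement,
                 sample_rate = sample_rate),
            class = "trajectory", waveform = waveform)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$times), "frames at", x$sample_rate, "Hz (",
      signif(max(x$times), 4), "s )\n")
  invisible(x)
}

#' Read and write marker trajectories as CSV
#'
#' CSV layout: `time_s,marker,dx_mm,dy_mm,dz_mm`, one row per frame per
#' marker.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @param marker marker name written to / selected from the file.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a `trajectory`.
#' @export
write_trajectory_csv <- function(traj, path, marker = "clavicle") {
  stopifnot(inherits(traj, "trajectory"))
  df <- data.frame(time_s = traj$times, marker = marker,
                   dx_mm = traj$displacement[, 1],
                   dy_mm = traj$displacement[, 2],
                   dz_mm = traj$displacement[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, marker = NULL) {
  df <- utils::read.csv(path)
  need <- c("time_s", "marker", "dx_mm", "dy_mm", "dz_mm")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns ", paste(need, collapse = ","))
  }
  if (is.null(marker)) marker <- df$marker[1]
  df <- df[df$marker == marker, , drop = FALSE]
  trajectory(df$time_s, cbind(df$dx_mm, df$dy_mm, df$dz_mm))
}
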