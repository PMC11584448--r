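# shared fixtures, built once per test run

MT <- material_table()

# random deformation gradients near the identity (positive J)
random_F <- function(n, scale = 0.1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      F <- diag(3) + matrix(rnorm(9, 0, scale), 3)
      if (det(F) > 0.3) return(F)
    }
  })
}

# quarter hanging column with roller supports (clean uniaxial-ish field)
roller_column <- function(n, material = "soft_layer") {
  mesh <- block_mesh(10, 40, 10, n, 4 * n, n, component = material)
  bcs <- boundary_conditions(
    mesh, driven = integer(0), symmetry = integer(0),
    extra_fixed = list(list(nodes = mesh$node_sets$ymax, comp = 2),
                       list(nodes = mesh$node_sets$xmin, comp = 1),
                       list(nodes = mesh$node_sets$zmin, comp = 3)))
  list(mesh = mesh, bcs = bcs)
}

# pure-R brute force nearest point-to-triangle distance (oracle for the
# spatially pruned C++ implementation)
brute_point_tri <- function(pts, verts, tris) {
  pt_tri <- function(p, a, b, c) {
    ab <- b - a; ac <- c - a; ap <- p - a
    d1 <- sum(ab * ap); d2 <- sum(ac * ap)
    if (d1 <= 0 && d2 <= 0) return(sum(ap^2))
    bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
    if (d3 >= 0 && d4 <= d3) return(sum(bp^2))
    vc <- d1 * d4 - d3 * d2
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      v <- d1 / (d1 - d3); q <- a + v * ab - p; return(sum(q^2))
    }
    cp <- p - c; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
    if (d6 >= 0 && d5 <= d6) return(sum(cp^2))
    vb <- d5 * d2 - d1 * d6
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      w <- d2 / (d2 - d6); q <- a + w * ac - p; return(sum(q^2))
    }
    va <- d3 * d6 - d5 * d4
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
      q <- b + w * (c - b) - p; return(sum(q^2))
    }
    den <- 1 / (va + vb + vc)
    v <- vb * den; w <- vc * den
    q <- a + v * ab + w * ac - p
    sum(q^2)
  }
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    sqrt(min(vapply(seq_len(nrow(tris)), function(t) {
      pt_tri(p, verts[tris[t, 1], ], verts[tris[t, 2], ],
             verts[tris[t, 3], ])
    }, numeric(1))))
  }, numeric(1))
}

# random closed-ish triangle surface (a jittered sphere triangulation)
random_sphere_mesh <- function(n_theta = 10, n_phi = 20, jitter = 0.1,
                               seed = 1) {
  set.seed(seed)
  th <- seq(0.1, pi - 0.1, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(th = th, ph = ph)
  r <- 10 * (1 + jitter * rnorm(nrow(g)))
  verts <- cbind(r * sin(g$th) * cos(g$ph),
                 r * sin(g$th) * sin(g$ph),
                 r * cos(g$th))
  idx <- matrix(seq_len(nrow(g)), n_theta, n_phi)
  tris <- NULL
  for (j in seq_len(n_phi)) {
    jn <- if (j == n_phi) 1 else j + 1
    for (i in seq_len(n_theta - 1)) {
      tris <- rbind(tris,
                    c(idx[i, j], idx[i + 1, j], idx[i + 1, jn]),
                    c(idx[i, j], idx[i + 1, jn], idx[i, jn]))
    }
  }
  list(nodes = verts, triangles = tris)
}
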