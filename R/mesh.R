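# Triangulated surface meshes. A surface_mesh is a plain list:
#   vertices : n x 3 numeric matrix (mm)
#   faces    : m x 3 integer matrix (1-based vertex indices)
#   labels   : named list of integer vertex-index vectors marking anatomical
#              patches ("condyle_medial", "plateau_lateral", "shaft", ...)
# Meshes built from several watertight bodies keep each body edge-closed;
# bodies may interpenetrate (no CSG union is attempted).

#' Construct a triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param labels named list of integer vertex-index vectors marking patches.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, labels = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) kt_parameter_error("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) kt_parameter_error("faces must be an m x 3 matrix")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    kt_parameter_error("face indices out of range")
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (length(x$labels))
    cat(sprintf("; labels: %s", paste(names(x$labels), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Rigidly transform a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param T 4x4 rigid transform.
#' @return The transformed mesh (labels preserved).
#' @export
transform_mesh <- function(mesh, T) {
  mesh$vertices <- transform_points(T, mesh$vertices)
  mesh
}

#' Mirror a mesh across the sagittal plane
#'
#' Negates the medial-lateral coordinate (model y axis) and flips the face
#' winding so the surface orientation stays consistent. Used to map left-knee
#' geometry into the right-knee convention.
#'
#' @param mesh a [surface_mesh()].
#' @return The mirrored mesh.
#' @export
mirror_mesh <- function(mesh) {
  mesh$vertices[, 2L] <- -mesh$vertices[, 2L]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return A 2 x 3 matrix: row 1 mins, row 2 maxs (mm).
#' @export
mesh_bbox <- function(mesh) {
  rbind(min = apply(mesh$vertices, 2L, min),
        max = apply(mesh$vertices, 2L, max))
}

#' Extract the vertices of a labelled patch
#'
#' @param mesh a [surface_mesh()].
#' @param label patch name present in `mesh$labels`.
#' @return Matrix of patch vertex coordinates.
#' @export
mesh_patch <- function(mesh, label) {
  idx <- mesh$labels[[label]]
  if (is.null(idx))
    kt_parameter_error(sprintf("mesh has no patch labelled '%s'", label))
  mesh$vertices[idx, , drop = FALSE]
}

# Merge meshes, offsetting face indices and labels. Each input body stays
# edge-closed; no boolean union.
merge_meshes <- function(...) {
  parts <- list(...)
  off <- 0L
  verts <- list(); faces <- list(); labels <- list()
  for (p in parts) {
    verts[[length(verts) + 1L]] <- p$vertices
    faces[[length(faces) + 1L]] <- p$faces + off
    for (nm in names(p$labels))
      labels[[nm]] <- c(labels[[nm]], p$labels[[nm]] + off)
    off <- off + nrow(p$vertices)
  }
  surface_mesh(do.call(rbind, verts), do.call(rbind, faces), labels)
}

# TRUE when every undirected edge borders exactly two faces.
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

## ---- primitive shapes ------------------------------------------------------

#' Icosphere mesh
#'
#' Sphere tessellated by recursive subdivision of an icosahedron, with all
#' vertices projected onto the sphere. `subdivisions` may be given directly
#' or derived from a target edge length.
#'
#' @param radius sphere radius (mm).
#' @param center sphere center (mm).
#' @param subdivisions number of 4-to-1 subdivision passes.
#' @param edge target edge length (mm); used when `subdivisions` is `NULL`.
#' @return A [surface_mesh()].
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = NULL,
                      edge = NULL) {
  stopifnot_scalar_number(radius, "radius", positive = TRUE)
  if (is.null(subdivisions)) {
    if (is.null(edge)) kt_parameter_error("give 'subdivisions' or 'edge'")
    # icosahedron edge is ~1.0515 R; each pass halves the edge
    subdivisions <- max(0L, ceiling(log2(1.0515 * radius / edge)))
  }
  phi <- (1 + sqrt(5)) / 2
  v <- matrix(c(-1, phi, 0,  1, phi, 0, -1, -phi, 0,  1, -phi, 0,
                0, -1, phi,  0, 1, phi,  0, -1, -phi, 0, 1, -phi,
                phi, 0, -1,  phi, 0, 1, -phi, 0, -1, -phi, 0, 1),
              ncol = 3L, byrow = TRUE)
  v <- v / sqrt(rowSums(v^2))
  f <- matrix(c(1,12,6, 1,6,2, 1,2,8, 1,8,11, 1,11,12,
                2,6,10, 6,12,5, 12,11,3, 11,8,7, 8,2,9,
                4,10,5, 4,5,3, 4,3,7, 4,7,9, 4,9,10,
                5,10,6, 3,5,12, 7,3,11, 9,7,8, 10,9,2),
              ncol = 3L, byrow = TRUE)
  for (s in seq_len(subdivisions)) {
    e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    uk <- unique(key)
    mid_id <- match(key, uk) + nrow(v)
    ue <- e[!duplicated(key), , drop = FALSE]
    mids <- (v[ue[, 1L], , drop = FALSE] + v[ue[, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m <- nrow(f)
    a <- f[, 1L]; b <- f[, 2L]; cc <- f[, 3L]
    ab <- mid_id[seq_len(m)]
    bc <- mid_id[m + seq_len(m)]
    ca <- mid_id[2L * m + seq_len(m)]
    f <- rbind(cbind(a, ab, ca), cbind(b, bc, ab), cbind(cc, ca, bc),
               cbind(ab, bc, ca))
  }
  surface_mesh(sweep(v * radius, 2L, -as.numeric(center)), f)
}

#' Capped cylinder mesh along the z axis
#'
#' @param radius cylinder radius (mm).
#' @param z_from,z_to axial extent (mm).
#' @param center_xy x/y position of the axis (mm).
#' @param n_seg number of segments around the circumference.
#' @param n_axial number of rings along the axis (>= 2).
#' @return A closed [surface_mesh()].
#' @export
cylinder_mesh <- function(radius, z_from, z_to, center_xy = c(0, 0),
                          n_seg = 64L, n_axial = 2L) {
  centers <- cbind(center_xy[1L], center_xy[2L],
                   seq(z_from, z_to, length.out = max(2L, n_axial)))
  tube_mesh(centers, radius, n_seg = n_seg)
}

#' Tube mesh along a polyline of ring centers
#'
#' Generalized cylinder: circular rings of constant `radius` placed in planes
#' perpendicular to the z axis at each center, stitched and capped. Useful for
#' straight or bent synthetic bone shafts.
#'
#' @param centers k x 3 matrix of ring centers, ordered along the tube.
#' @param radius tube radius (mm).
#' @param n_seg segments per ring.
#' @return A closed [surface_mesh()].
#' @export
tube_mesh <- function(centers, radius, n_seg = 64L) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k < 2L) kt_parameter_error("tube needs at least 2 ring centers")
  th <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  ring <- cbind(radius * cos(th), radius * sin(th), 0)
  verts <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(ring, 2L, -centers[i, ])))
  # side quads
  faces <- list()
  for (i in seq_len(k - 1L)) {
    a <- (i - 1L) * n_seg + seq_len(n_seg)
    b <- c(a[-1L], a[1L])
    cc <- a + n_seg
    d <- b + n_seg
    faces[[i]] <- rbind(cbind(a, b, cc), cbind(b, d, cc))
  }
  # caps (fan around ring centroid vertex)
  c0 <- nrow(verts) + 1L
  c1 <- nrow(verts) + 2L
  verts <- rbind(verts, centers[1L, ], centers[k, ])
  a <- seq_len(n_seg); b <- c(a[-1L], a[1L])
  cap0 <- cbind(b, a, c0)
  a2 <- (k - 1L) * n_seg + seq_len(n_seg); b2 <- c(a2[-1L], a2[1L])
  cap1 <- cbind(a2, b2, c1)
  surface_mesh(verts, rbind(do.call(rbind, faces), cap0, cap1))
}

#' Rectangular slab with a height-field top surface
#'
#' A watertight block over `[x[1],x[2]] x [y[1],y[2]]` with flat bottom at
#' `z_bottom` and top height `z_top_fun(x, y)`. Used for the synthetic tibial
#' plateau (medial flat, lateral tilted).
#'
#' @param x_range,y_range numeric length-2 extents (mm).
#' @param z_bottom bottom height (mm).
#' @param z_top_fun vectorized function of (x, y) giving top height (mm).
#' @param edge approximate grid edge length (mm).
#' @return A closed [surface_mesh()] with label `top` on the top-grid vertices.
#' @export
slab_mesh <- function(x_range, y_range, z_bottom, z_top_fun, edge = 1) {
  nx <- max(2L, ceiling(diff(x_range) / edge) + 1L)
  ny <- max(2L, ceiling(diff(y_range) / edge) + 1L)
  xs <- seq(x_range[1L], x_range[2L], length.out = nx)
  ys <- seq(y_range[1L], y_range[2L], length.out = ny)
  g <- expand.grid(x = xs, y = ys)            # x varies fastest
  ztop <- z_top_fun(g$x, g$y)
  top <- cbind(g$x, g$y, ztop)
  bot <- cbind(g$x, g$y, z_bottom)
  nv <- nrow(top)
  verts <- rbind(top, bot)
  idx <- function(i, j) (j - 1L) * nx + i     # into the top grid
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
  top_f <- rbind(cbind(a, b, d), cbind(a, d, cc))
  bot_f <- top_f[, c(1L, 3L, 2L)] + nv
  wall <- function(edge_top) {
    k <- length(edge_top)
    a <- edge_top[-k]; b <- edge_top[-1L]
    rbind(cbind(a, a + nv, b), cbind(b, a + nv, b + nv))
  }
  s1 <- idx(seq_len(nx), 1L)                  # y = ymin, walk +x
  s2 <- idx(nx, seq_len(ny))                  # x = xmax, walk +y
  s3 <- idx(rev(seq_len(nx)), ny)             # y = ymax, walk -x
  s4 <- idx(1L, rev(seq_len(ny)))             # x = xmin, walk -y
  faces <- rbind(top_f, bot_f, wall(s1), wall(s2), wall(s3), wall(s4))
  surface_mesh(verts, faces, labels = list(top = seq_len(nv)))
}

#' Axis-aligned rectangular box mesh
#'
#' @param center box center (mm).
#' @param dims length-3 extents along x, y, z (mm).
#' @return A closed [surface_mesh()] (12 triangles).
#' @export
box_mesh <- function(center, dims) {
  h <- as.numeric(dims) / 2
  s <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  v <- sweep(as.matrix(s) * rep(h, each = 8L), 2L, -as.numeric(center))
  # vertex order: x fastest, then y, then z
  f <- matrix(c(1,3,4, 1,4,2,   # z min
                5,8,7, 5,6,8,   # z max
                1,2,6, 1,6,5,   # y min
                3,7,8, 3,8,4,   # y max
                1,5,7, 1,7,3,   # x min
                2,4,8, 2,8,6),  # x max
              ncol = 3L, byrow = TRUE)
  surface_mesh(v, f)
}

## ---- planar cross sections -------------------------------------------------

#' Intersect a mesh with a plane
#'
#' Returns the intersection contours as chained polylines. Each contour is a
#' matrix of 3-D points lying on the plane, flagged closed or open.
#'
#' @param mesh a [surface_mesh()].
#' @param pl a [plane()].
#' @return List of contours, each `list(points = <k x 3>, closed = <flag>)`.
#' @export
mesh_cross_section <- function(mesh, pl) {
  d <- plane_distance(pl, mesh$vertices)
  d[abs(d) < 1e-9] <- 1e-9                     # nudge off exact coincidence
  f <- mesh$faces
  dv <- matrix(d[f], ncol = 3L)
  pos <- dv > 0
  crossed <- which(rowSums(pos) %in% c(1L, 2L))
  if (!length(crossed))
    kt_geometry_error("plane does not intersect the mesh")
  edge_pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  seg_keys <- matrix(NA_character_, length(crossed), 2L)
  seg_pts <- vector("list", 0L)
  pt_of_key <- new.env(parent = emptyenv())
  for (si in seq_along(crossed)) {
    fi <- crossed[si]
    ks <- character(0L)
    for (ep in edge_pairs) {
      i <- f[fi, ep[1L]]; j <- f[fi, ep[2L]]
      if ((d[i] > 0) != (d[j] > 0)) {
        key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
        if (is.null(pt_of_key[[key]])) {
          t0 <- d[i] / (d[i] - d[j])
          pt_of_key[[key]] <- mesh$vertices[i, ] +
            t0 * (mesh$vertices[j, ] - mesh$vertices[i, ])
        }
        ks <- c(ks, key)
      }
    }
    seg_keys[si, ] <- ks[1:2]
  }
  # chain segments: nodes are edge keys, segments connect two nodes
  keys <- unique(as.vector(seg_keys))
  a <- match(seg_keys[, 1L], keys)
  b <- match(seg_keys[, 2L], keys)
  nseg <- length(a)
  adj <- vector("list", length(keys))
  for (s in seq_len(nseg)) {
    adj[[a[s]]] <- c(adj[[a[s]]], s)
    adj[[b[s]]] <- c(adj[[b[s]]], s)
  }
  used <- logical(nseg)
  contours <- list()
  deg <- lengths(adj)
  for (start_node in order(deg)) {             # open chains start at degree-1
    for (s0 in adj[[start_node]]) {
      if (used[s0]) next
      node_path <- integer(0L)
      node <- start_node
      s <- s0
      repeat {
        used[s] <- TRUE
        node_path <- c(node_path, node)
        node <- if (a[s] == node) b[s] else a[s]
        nxt <- adj[[node]][!used[adj[[node]]]]
        if (!length(nxt)) break
        s <- nxt[1L]
      }
      closed <- (node == node_path[1L]) && length(node_path) >= 3L
      if (!closed) node_path <- c(node_path, node)
      pts <- do.call(rbind, lapply(keys[node_path],
                                   function(k) pt_of_key[[k]]))
      contours[[length(contours) + 1L]] <- list(points = pts, closed = closed)
    }
  }
  contours
}

# Largest closed contour by planar area; geometry error if none closed.
largest_closed_contour <- function(contours, pl) {
  closed <- Filter(function(ct) ct$closed, contours)
  if (!length(closed))
    kt_geometry_error("cross-section contour is open (mesh not closed at this level)")
  areas <- vapply(closed, function(ct) polygon_area_centroid(ct$points, pl)$area,
                  numeric(1L))
  closed[[which.max(areas)]]
}
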