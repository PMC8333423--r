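#' Tetrahedral mesh container
#'
#' A `tet_mesh` holds the geometric substrate of every assembly: node
#' coordinates in millimetres and tetrahedral connectivity, plus optional
#' named node/element sets (used for boundary regions) and per-element
#' scalar fields (used for densities read from mesh files).
#'
#' Indices are 1-based throughout the package; file readers and writers
#' translate to each format's on-disk convention. On construction every
#' tetrahedron is reordered to positive signed volume (assembly assumes
#' positive Jacobians).
#'
#' @param nodes numeric matrix, one row per node, 3 columns (x, y, z in mm).
#' @param tets integer matrix, one row per tetrahedron, 4 columns of
#'   1-based node indices.
#' @param node_sets named list of integer vectors (1-based node indices).
#' @param elem_sets named list of integer vectors (1-based element indices).
#' @param fields named list of per-element numeric vectors (e.g. densities).
#' @return an object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, node_sets = list(), elem_sets = list(),
                     fields = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns (x, y, z)")
  if (ncol(tets) != 4L) stop("tets must have 4 columns")
  if (nrow(nodes) < 4L) stop("a tetrahedral mesh needs at least 4 nodes")
  if (nrow(tets) < 1L) stop("a tetrahedral mesh needs at least 1 element")
  if (anyNA(nodes) || anyNA(tets)) stop("NA in mesh arrays")
  if (min(tets) < 1L || max(tets) > nrow(nodes))
    stop("tet connectivity references node indices outside 1..", nrow(nodes))
  used <- sort(unique(as.vector(tets)))
  if (length(used) < nrow(nodes)) {
    # drop nodes not referenced by any tet, remapping indices and node sets
    remap <- integer(nrow(nodes))
    remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    tets[] <- remap[tets]
    node_sets <- lapply(node_sets, function(s) remap[s][remap[s] > 0L])
  }
  mesh <- structure(
    list(nodes = nodes, tets = tets,
         node_sets = node_sets, elem_sets = elem_sets, fields = fields),
    class = "tet_mesh")
  mesh <- orient_tets(mesh)
  vols <- tet_volumes(mesh)
  if (any(vols <= 0))
    stop("mesh contains degenerate (zero-volume) tetrahedra: ",
         paste(utils::head(which(vols <= 0)), collapse = ", "))
  for (nm in names(fields)) {
    if (length(fields[[nm]]) != nrow(tets))
      stop("field '", nm, "' has length ", length(fields[[nm]]),
           ", expected one value per element (", nrow(tets), ")")
  }
  for (nm in names(node_sets)) {
    s <- node_sets[[nm]]
    if (length(s) && (min(s) < 1L || max(s) > nrow(nodes)))
      stop("node set '", nm, "' references invalid node indices")
  }
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("tet_mesh:", nrow(x$nodes), "nodes,", nrow(x$tets), "tets\n")
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("  bbox [%.3g, %.3g] x [%.3g, %.3g] x [%.3g, %.3g] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  if (length(x$node_sets))
    cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  if (length(x$fields))
    cat("  cell fields:", paste(names(x$fields), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra
#'
#' @param mesh a `tet_mesh` (or a bare list with `nodes` and `tets`).
#' @return numeric vector of signed volumes (mm^3), one per element.
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes
  tt <- mesh$tets
  a <- nd[tt[, 2], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  b <- nd[tt[, 3], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  c_ <- nd[tt[, 4], , drop = FALSE] - nd[tt[, 1], , drop = FALSE]
  # det [a b c] / 6 via scalar triple product a . (b x c)
  bxc <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
               b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
               b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  rowSums(a * bxc) / 6
}

#' Canonicalize tetrahedron orientation
#'
#' Swaps two vertices of every negatively oriented tetrahedron so that all
#' signed volumes are positive.
#'
#' @param mesh a `tet_mesh`-like list.
#' @return the mesh with positively oriented connectivity.
#' @export
orient_tets <- function(mesh) {
  v <- tet_volumes(mesh)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- mesh$tets[neg, 3L]
    mesh$tets[neg, 3L] <- mesh$tets[neg, 4L]
    mesh$tets[neg, 4L] <- tmp
  }
  mesh
}

# Kuhn split of one hexahedral cell into 6 tetrahedra sharing the main
# diagonal; translation-invariant, hence conforming on structured grids.
# Rows index the 6 tets; columns give local corner ids (1..8, x fastest).
.kuhn_template <- local({
  corners <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx_of <- function(p) 1L + p[1] + 2L * p[2] + 4L * p[3]
  t(apply(perms, 1, function(pm) {
    p <- c(0, 0, 0)
    path <- idx_of(p)
    for (ax in pm) {
      p[ax] <- 1
      path <- c(path, idx_of(p))
    }
    path
  }))
})

#' Generate a structured box mesh
#'
#' Builds a deterministic structured tetrahedral mesh of the box
#' `[0, Lx] x [0, Ly] x [0, Lz]`: `nx * ny * nz` hexahedral cells, each split
#' into 6 tetrahedra by the Kuhn template (all cell tets share the main
#' diagonal, so the mesh is conforming). Node count is
#' `(nx+1)(ny+1)(nz+1)`; total volume equals `Lx*Ly*Lz` exactly up to
#' rounding. Face node sets `xmin`, `xmax`, `ymin`, `ymax`, `zmin`, `zmax`
#' are attached for boundary conditions.
#'
#' @param lengths numeric length-3, box edge lengths (mm), all > 0.
#' @param divisions integer length-3, cells per axis, all >= 1.
#' @return a `tet_mesh` with `6 * nx * ny * nz` positively oriented tets.
#' @export
generate_box_mesh <- function(lengths, divisions) {
  lengths <- as.numeric(lengths)
  divisions <- as.integer(divisions)
  if (length(lengths) != 3L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be 3 positive numbers")
  if (length(divisions) != 3L || any(is.na(divisions)) || any(divisions < 1L))
    stop("divisions must be 3 integers >= 1")
  nx <- divisions[1]; ny <- divisions[2]; nz <- divisions[3]
  xs <- seq(0, lengths[1], length.out = nx + 1L)
  ys <- seq(0, lengths[2], length.out = ny + 1L)
  zs <- seq(0, lengths[3], length.out = nz + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))  # x fastest
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)

  cells <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  # global ids of the 8 corners of every cell, x fastest corner order
  corner_offsets <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  corner_ids <- matrix(0L, nrow(cells), 8L)
  for (c8 in 1:8) {
    corner_ids[, c8] <- nid(cells$i + corner_offsets[c8, 1],
                            cells$j + corner_offsets[c8, 2],
                            cells$k + corner_offsets[c8, 3])
  }
  tets <- matrix(0L, 6L * nrow(cells), 4L)
  for (t6 in 1:6) {
    rows <- seq.int(t6, by = 6L, length.out = nrow(cells))
    tets[rows, ] <- corner_ids[, .kuhn_template[t6, ], drop = FALSE]
  }

  on_face <- function(coord, val) which(abs(nodes[, coord] - val) == 0)
  node_sets <- list(
    xmin = on_face(1, 0), xmax = on_face(1, lengths[1]),
    ymin = on_face(2, 0), ymax = on_face(2, lengths[2]),
    zmin = on_face(3, 0), zmax = on_face(3, lengths[3]))
  tet_mesh(nodes, tets, node_sets = node_sets)
}

#' Mesh quality report
#'
#' Reports element-volume statistics and flags degenerate elements, defined
#' as elements with volume `<= eps * mean(volume)`. Degeneracies are
#' reported, never raised.
#'
#' @param mesh a `tet_mesh`.
#' @param eps relative volume threshold for flagging (default 1e-9).
#' @return list with `n_nodes`, `n_tets`, `total_volume`, `min_volume`,
#'   `max_volume`, `mean_volume`, `min_shape` (6*sqrt(2)*V/l_rms^3, 1 for the
#'   regular tet), and `degenerate` (flagged element indices).
#' @export
mesh_quality <- function(mesh, eps = 1e-9) {
  vols <- tet_volumes(mesh)
  nd <- mesh$nodes
  tt <- mesh$tets
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  l2 <- 0
  for (p in 1:6) {
    d <- nd[tt[, pairs[p, 1]], , drop = FALSE] - nd[tt[, pairs[p, 2]], , drop = FALSE]
    l2 <- l2 + rowSums(d * d)
  }
  l_rms <- sqrt(l2 / 6)
  shape <- 6 * sqrt(2) * vols / l_rms^3
  list(n_nodes = nrow(nd), n_tets = nrow(tt),
       total_volume = sum(vols),
       min_volume = min(vols), max_volume = max(vols),
       mean_volume = mean(vols),
       min_shape = min(shape),
       degenerate = which(vols <= eps * mean(vols)))
}
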