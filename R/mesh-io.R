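#' Read a tetrahedral mesh
#'
#' Reads a 3D unstructured mesh with tetrahedral cells from a VTK legacy
#' ASCII file (`DATASET UNSTRUCTURED_GRID`, cell type 10) or a Gmsh 4.1
#' ASCII file (element type 4). Per-cell scalar data (VTK `CELL_DATA`
#' `SCALARS` blocks, Gmsh `$ElementData` blocks) are preserved by name in
#' the returned mesh's `fields`. Tetrahedra are reoriented to positive
#' signed volume on read.
#'
#' @param path file path.
#' @param format one of `"auto"` (by extension: `.vtk` / `.msh`),
#'   `"vtk-legacy"`, `"gmsh-ascii"`.
#' @return a `tet_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "vtk-legacy", "gmsh-ascii")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("mesh file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     vtk = "vtk-legacy",
                     msh = "gmsh-ascii",
                     stop("cannot infer mesh format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  switch(format,
         "vtk-legacy" = read_vtk_legacy(path),
         "gmsh-ascii" = read_gmsh_ascii(path))
}

#' Write a tetrahedral mesh
#'
#' Writes a `tet_mesh` (plus optional per-element scalar fields) so that
#' [read_mesh()] recovers coordinates to full precision and fields by name.
#' Fields stored on the mesh itself are written too; `fields` arguments
#' override same-named mesh fields.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file path.
#' @param format `"vtk-legacy"` or `"gmsh-ascii"` (default from extension).
#' @param fields named list of per-element numeric vectors.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "vtk-legacy", "gmsh-ascii"),
                       fields = list()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vtk = "vtk-legacy", msh = "gmsh-ascii",
                     stop("cannot infer mesh format from extension '.", ext, "'"))
  }
  all_fields <- mesh$fields
  for (nm in names(fields)) all_fields[[nm]] <- fields[[nm]]
  for (nm in names(all_fields)) {
    if (length(all_fields[[nm]]) != nrow(mesh$tets))
      stop("field '", nm, "' has length ", length(all_fields[[nm]]),
           " but mesh has ", nrow(mesh$tets), " elements")
  }
  switch(format,
         "vtk-legacy" = write_vtk_legacy(mesh, path, all_fields),
         "gmsh-ascii" = write_gmsh_ascii(mesh, path, all_fields))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_vtk_legacy <- function(mesh, path, fields, point_vectors = list()) {
  n_nodes <- nrow(mesh$nodes)
  n_tets <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "tet_mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(paste("POINTS", n_nodes, "double"))
  wl(apply(mesh$nodes, 1, function(r) paste(fmt_num(r), collapse = " ")))
  wl(paste("CELLS", n_tets, 5L * n_tets))
  wl(apply(mesh$tets - 1L, 1, function(r) paste(c(4L, r), collapse = " ")))
  wl(paste("CELL_TYPES", n_tets))
  wl(as.character(rep(10L, n_tets)))
  if (length(fields)) {
    wl(paste("CELL_DATA", n_tets))
    for (nm in names(fields)) {
      wl(paste("SCALARS", nm, "double", 1), "LOOKUP_TABLE default")
      wl(fmt_num(fields[[nm]]))
    }
  }
  if (length(point_vectors)) {
    wl(paste("POINT_DATA", n_nodes))
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      wl(paste("VECTORS", nm, "double"))
      wl(apply(v, 1, function(r) paste(fmt_num(r), collapse = " ")))
    }
  }
  invisible(path)
}

read_vtk_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks_of <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  if (length(lines) < 5 || !grepl("^# vtk DataFile", lines[1]))
    stop("not a VTK legacy file: ", path)
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("only ASCII VTK legacy files are supported")
  ds <- grep("^DATASET", lines, value = TRUE)
  if (!length(ds) || !grepl("UNSTRUCTURED_GRID", ds[1]))
    stop("only DATASET UNSTRUCTURED_GRID is supported")

  # flatten the numeric body: section-keyword driven scan
  i_pts <- grep("^POINTS", lines)[1]
  if (is.na(i_pts)) stop("VTK file has no POINTS section")
  n_nodes <- as.integer(toks_of(lines[i_pts])[2])
  scan_nums <- function(start, count) {
    vals <- numeric(0)
    i <- start
    while (length(vals) < count && i <= length(lines)) {
      vals <- c(vals, as.numeric(toks_of(lines[i])))
      i <- i + 1
    }
    if (length(vals) < count) stop("truncated VTK section at line ", start)
    list(vals = vals[seq_len(count)], next_line = i)
  }
  pts <- scan_nums(i_pts + 1, 3L * n_nodes)
  nodes <- matrix(pts$vals, ncol = 3, byrow = TRUE)

  i_cells <- grep("^CELLS", lines)[1]
  if (is.na(i_cells)) stop("VTK file has no CELLS section")
  hdr <- as.integer(toks_of(lines[i_cells])[2:3])
  n_cells <- hdr[1]
  cell_raw <- scan_nums(i_cells + 1, hdr[2])$vals
  i_types <- grep("^CELL_TYPES", lines)[1]
  if (is.na(i_types)) stop("VTK file has no CELL_TYPES section")
  types <- as.integer(scan_nums(i_types + 1, n_cells)$vals)

  # walk the ragged connectivity list
  conn <- vector("list", n_cells)
  pos <- 1
  for (cidx in seq_len(n_cells)) {
    npts <- as.integer(cell_raw[pos])
    conn[[cidx]] <- as.integer(cell_raw[pos + seq_len(npts)])
    pos <- pos + npts + 1
  }
  keep <- which(types == 10L)
  if (!length(keep))
    stop("no tetrahedra (VTK cell type 10) in ", path)
  tets <- do.call(rbind, conn[keep]) + 1L
  if (ncol(tets) != 4L) stop("malformed tetrahedral connectivity in ", path)

  fields <- list()
  i_cd <- grep("^CELL_DATA", lines)[1]
  if (!is.na(i_cd)) {
    n_cd <- as.integer(toks_of(lines[i_cd])[2])
    i <- i_cd + 1
    while (i <= length(lines)) {
      if (grepl("^SCALARS", lines[i])) {
        nm <- toks_of(lines[i])[2]
        i <- i + 1
        if (i <= length(lines) && grepl("^LOOKUP_TABLE", lines[i])) i <- i + 1
        sc <- scan_nums(i, n_cd)
        vals <- sc$vals
        i <- sc$next_line
        fields[[nm]] <- vals[keep]
      } else if (grepl("^POINT_DATA", lines[i])) {
        break
      } else {
        i <- i + 1
      }
    }
  }
  tet_mesh(nodes, tets, fields = fields)
}

write_gmsh_ascii <- function(mesh, path, fields) {
  n_nodes <- nrow(mesh$nodes)
  n_tets <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  wl("$Nodes", paste(1, n_nodes, 1, n_nodes), paste(3, 1, 0, n_nodes))
  wl(as.character(seq_len(n_nodes)))
  wl(apply(mesh$nodes, 1, function(r) paste(fmt_num(r), collapse = " ")))
  wl("$EndNodes")
  wl("$Elements", paste(1, n_tets, 1, n_tets), paste(3, 1, 4, n_tets))
  wl(apply(cbind(seq_len(n_tets), mesh$tets), 1, paste, collapse = " "))
  wl("$EndElements")
  for (nm in names(fields)) {
    wl("$ElementData", "1", paste0("\"", nm, "\""), "1", "0.0",
       "3", "0", "1", as.character(n_tets))
    wl(paste(seq_len(n_tets), fmt_num(fields[[nm]])))
    wl("$EndElementData")
  }
  invisible(path)
}

read_gmsh_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  toks_of <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("not a Gmsh file: ", path)
  ver <- as.numeric(toks_of(fmt[1])[1])
  if (is.na(ver) || ver < 4 || ver >= 5)
    stop("unsupported Gmsh format version ", fmt[1], " (need 4.x ASCII)")

  nsec <- sec("Nodes")
  if (is.null(nsec)) stop("Gmsh file has no $Nodes section")
  hdr <- as.numeric(toks_of(nsec[1]))
  n_blocks <- hdr[1]; n_nodes <- hdr[2]
  tag <- integer(0)
  xyz <- matrix(0, 0, 3)
  i <- 2
  for (b in seq_len(n_blocks)) {
    bh <- as.numeric(toks_of(nsec[i]))
    nb <- bh[4]
    if (bh[3] != 0) stop("parametric node blocks are not supported")
    tags_b <- as.integer(vapply(nsec[i + seq_len(nb)], function(s) toks_of(s)[1], ""))
    coords_b <- t(vapply(nsec[i + nb + seq_len(nb)],
                         function(s) as.numeric(toks_of(s))[1:3], numeric(3)))
    tag <- c(tag, tags_b)
    xyz <- rbind(xyz, coords_b)
    i <- i + 2 * nb + 1
  }
  if (length(tag) != n_nodes) stop("inconsistent node count in ", path)
  # gmsh tags may be sparse; map tag -> row
  remap <- integer(max(tag))
  remap[tag] <- seq_along(tag)

  esec <- sec("Elements")
  if (is.null(esec)) stop("Gmsh file has no $Elements section")
  ehdr <- as.numeric(toks_of(esec[1]))
  tets <- NULL
  elem_tag <- integer(0)
  i <- 2
  for (b in seq_len(ehdr[1])) {
    bh <- as.numeric(toks_of(esec[i]))
    etype <- bh[3]; nb <- bh[4]
    rows <- t(vapply(esec[i + seq_len(nb)], function(s) as.numeric(toks_of(s)),
                     numeric(if (etype == 4) 5 else length(toks_of(esec[i + 1])))))
    if (etype == 4) {
      tets <- rbind(tets, rows[, 2:5, drop = FALSE])
      elem_tag <- c(elem_tag, as.integer(rows[, 1]))
    }
    i <- i + nb + 1
  }
  if (is.null(tets)) stop("no tetrahedra (Gmsh element type 4) in ", path)
  tets <- matrix(remap[as.integer(tets)], ncol = 4)
  if (any(tets == 0L)) stop("element references unknown node tag in ", path)

  fields <- list()
  idx <- which(lines == "$ElementData")
  for (i0 in idx) {
    i1 <- match("$EndElementData", lines[i0:length(lines)]) + i0 - 1
    body <- lines[(i0 + 1):(i1 - 1)]
    n_str <- as.integer(body[1])
    nm <- gsub("^\"|\"$", "", body[2])
    p <- 2 + n_str                       # numRealTags line
    n_real <- as.integer(body[p]); p <- p + 1 + n_real   # numIntegerTags line
    n_int <- as.integer(body[p])
    ints <- as.integer(body[p + seq_len(n_int)])
    nvals <- ints[3]
    p <- p + n_int                       # last header line; data follows
    dat <- t(vapply(body[p + seq_len(nvals)],
                    function(s) as.numeric(toks_of(s))[1:2], numeric(2)))
    v <- numeric(nrow(tets))
    pos <- match(as.integer(dat[, 1]), elem_tag)
    v[pos] <- dat[, 2]
    fields[[nm]] <- v
  }
  tet_mesh(xyz, tets, fields = fields)
}

#' Export mode shapes to a VTK file
#'
#' Writes the mesh with one 3-component `POINT_DATA` vector field per mode
#' (`mode_001`, `mode_002`, ...) so mode shapes can be inspected in ParaView.
#'
#' @param mesh the `tet_mesh` the eigenvectors live on.
#' @param pairs an `eigen_pairs` object (full-DOF vectors).
#' @param path output `.vtk` path.
#' @return the path, invisibly.
#' @export
export_modes_vtk <- function(mesh, pairs, path) {
  n_nodes <- nrow(mesh$nodes)
  pv <- list()
  for (i in seq_along(pairs$lambdas)) {
    v <- pairs$vectors[, i]
    pv[[sprintf("mode_%03d", i)]] <- matrix(v, ncol = 3, byrow = TRUE)
  }
  write_vtk_legacy(mesh, path, mesh$fields, point_vectors = pv)
  invisible(path)
}
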