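#' Generate a synthetic fixture on disk
#'
#' Writes a deterministic mesh file, per-element density field and boundary
#' spec so the whole pipeline can be exercised with no external data. The
#' fixtures emulate the algebraic structure of density-graded bone FE
#' models, not anatomical geometry:
#' \describe{
#'   \item{`box`}{free cube, uniform ash density; the rigid-spectrum
#'     fixture. Defaults: 20 mm edges, (3,3,3) divisions, 0.8 g/cm^3.}
#'   \item{`cantilever`}{beam with one end face fixed (`fixed_end` node
#'     set, FEMP-I); defaults 100 x 10 x 10 mm, (10,2,2) divisions,
#'     uniform 1.0 g/cm^3.}
#'   \item{`two_tet`}{5-node, 2-element mesh sized for dense oracles;
#'     fixed face (1,2,3).}
#'   \item{`gradient_beam`}{cantilever whose ash density ramps linearly
#'     along the axis between `rho_from` and `rho_to` (defaults 0.3 and
#'     1.2 g/cm^3, trabecular-to-cortical range), element value taken at
#'     the element centroid.}
#' }
#'
#' @param kind fixture kind.
#' @param dir output directory (created if missing).
#' @param lengths,divisions box/beam geometry overrides.
#' @param rho uniform ash density (g/cm^3) for `box`/`cantilever`/`two_tet`.
#' @param rho_from,rho_to density ramp bounds for `gradient_beam`.
#' @param format mesh format to write (`"vtk-legacy"` or `"gmsh-ascii"`).
#' @return list with `mesh_path`, `bc_path`, `mesh` (the `tet_mesh`),
#'   `bc` (the `bc_spec`), `density_field` (field name).
#' @export
make_fixture <- function(kind = c("box", "cantilever", "two_tet", "gradient_beam"),
                         dir = tempdir(),
                         lengths = NULL, divisions = NULL, rho = NULL,
                         rho_from = 0.3, rho_to = 1.2,
                         format = c("vtk-legacy", "gmsh-ascii")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "vtk-legacy") "vtk" else "msh"

  if (kind == "two_tet") {
    nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
    tets <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
    mesh <- tet_mesh(nodes, tets,
                     node_sets = list(base = c(1L, 2L, 3L)))
    dens <- rep(if (is.null(rho)) 1.0 else rho, nrow(tets))
    bc <- bc_spec("FEMP-I", fixed_sets = "base")
  } else {
    if (is.null(lengths))
      lengths <- if (kind == "box") c(20, 20, 20) else c(100, 10, 10)
    if (is.null(divisions))
      divisions <- if (kind == "box") c(3, 3, 3) else c(10, 2, 2)
    mesh <- generate_box_mesh(lengths, divisions)
    if (kind == "gradient_beam") {
      ctr_x <- colMeans(matrix(mesh$nodes[t(mesh$tets), 1], nrow = 4))
      dens <- rho_from + (rho_to - rho_from) * ctr_x / lengths[1]
    } else {
      dens <- rep(if (is.null(rho)) { if (kind == "box") 0.8 else 1.0 } else rho,
                  nrow(mesh$tets))
    }
    bc <- if (kind == "box") bc_spec("FEMP-II")
          else bc_spec("FEMP-I", fixed_sets = "xmin")
    if (kind != "box") mesh$node_sets$fixed_end <- mesh$node_sets$xmin
  }

  mesh$fields[["rho_ash_gcm3"]] <- dens
  mesh_path <- file.path(dir, paste0(kind, ".", ext))
  write_mesh(mesh, mesh_path, format = format)
  bc_path <- file.path(dir, paste0(kind, "_bc.json"))
  bc_json <- list(mode = bc$mode)
  if (bc$mode == "FEMP-I") {
    bc_json$fixed_nodes <- resolve_fixed_nodes(mesh, bc)
  }
  jsonlite::write_json(bc_json, bc_path, auto_unbox = TRUE, digits = NA)
  list(mesh_path = mesh_path, bc_path = bc_path, mesh = mesh, bc = bc,
       density_field = "rho_ash_gcm3")
}

#' Run configuration
#'
#' Validated bundle of everything one pipeline run needs. `density_kind`
#' says what the named per-element field contains (`"rho_ash"` used
#' directly, `"rho_ha"` converted first); an optional second field supplies
#' the mass density (`"rho_eff"` directly or `"ct"` scaled by `b`).
#'
#' @param mesh_path mesh file path.
#' @param format mesh format (`"auto"`, `"vtk-legacy"`, `"gmsh-ascii"`).
#' @param density_field per-element field name on the mesh.
#' @param density_kind `"rho_ash"` or `"rho_ha"`.
#' @param eff_field,eff_kind optional mass-density field and its kind.
#' @param b CT scaling coefficient (g/cm^3 per CT unit), default 658.
#' @param nu Poisson ratio, default 0.3.
#' @param bc_mode `"FEMP-I"` or `"FEMP-II"`.
#' @param fixed_nodes,fixed_sets FEMP-I fixed nodes / named node sets.
#' @param n_modes deformable eigenpairs to compute, default 10.
#' @param k_policy `"first_mode"`, `"per_mode"`, `"user_node"`.
#' @param n_hat eigenpairs in the static-stiffness sum, default 10.
#' @param solver_tol,max_iter,seed eigensolver settings.
#' @param out_csv,out_json,out_modes_vtk optional output paths.
#' @return object of class `run_config`.
#' @export
run_config <- function(mesh_path, format = "auto",
                       density_field = "rho_ash_gcm3",
                       density_kind = c("rho_ash", "rho_ha"),
                       eff_field = NULL, eff_kind = c("rho_eff", "ct"),
                       b = 658, nu = 0.3,
                       bc_mode = c("FEMP-II", "FEMP-I"),
                       fixed_nodes = integer(0), fixed_sets = character(0),
                       n_modes = 10, k_policy = "first_mode", n_hat = 10,
                       solver_tol = 1e-8, max_iter = 500, seed = 0,
                       out_csv = NULL, out_json = NULL, out_modes_vtk = NULL) {
  density_kind <- match.arg(density_kind)
  eff_kind <- match.arg(eff_kind)
  bc_mode <- match.arg(bc_mode)
  if (!file.exists(mesh_path)) stop("mesh file not found: ", mesh_path)
  if (n_modes < 1) stop("n_modes must be >= 1")
  if (n_hat < 1) stop("n_hat must be >= 1")
  structure(list(mesh_path = mesh_path, format = format,
                 density_field = density_field, density_kind = density_kind,
                 eff_field = eff_field, eff_kind = eff_kind, b = b, nu = nu,
                 bc_mode = bc_mode, fixed_nodes = as.integer(fixed_nodes),
                 fixed_sets = fixed_sets,
                 n_modes = as.integer(n_modes), k_policy = k_policy,
                 n_hat = as.integer(n_hat), solver_tol = solver_tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 out_csv = out_csv, out_json = out_json,
                 out_modes_vtk = out_modes_vtk),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file with [run_config()] keys; a `bc` sub-object with
#'   `mode` / `fixed_nodes` / `fixed_node_sets` is also accepted.
#' @param ... overrides applied on top of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$bc)) {
    raw$bc_mode <- raw$bc$mode
    if (!is.null(raw$bc$fixed_nodes)) raw$fixed_nodes <- raw$bc$fixed_nodes
    if (!is.null(raw$bc$fixed_node_sets)) raw$fixed_sets <- raw$bc$fixed_node_sets
    raw$bc <- NULL
  }
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  # resolve mesh path relative to the config file
  if (!is.null(raw$mesh_path) && !file.exists(raw$mesh_path)) {
    cand <- file.path(dirname(path), raw$mesh_path)
    if (file.exists(cand)) raw$mesh_path <- cand
  }
  do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
}

#' Run the full eigenmetric pipeline
#'
#' materials -> assembly -> constraints -> eigensolve -> metrics -> export.
#' Progress and diagnostics (counts, rigid modes, residuals, timings) go to
#' `message()`; outputs are written when paths are configured.
#'
#' @param config a `run_config`.
#' @param quiet suppress progress messages.
#' @return the `eigenmetrics_record`, invisibly, with the `eigen_pairs`
#'   attached as attribute `"pairs"` and the `fe_system` as `"system"`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[bonemodal] ", ...)
  t0 <- proc.time()[3]
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", what, "] ", conditionMessage(e), call. = FALSE))
  }
  mesh <- stage("read_mesh", read_mesh(config$mesh_path, config$format))
  say("mesh: ", nrow(mesh$nodes), " nodes, ", nrow(mesh$tets), " tets")
  material <- stage("materials", material_from_mesh(
    mesh, config$density_field, kind = config$density_kind,
    eff_field = config$eff_field, eff_kind = config$eff_kind,
    b = config$b, nu = config$nu))
  bc <- stage("bc", bc_spec(config$bc_mode, fixed_nodes = config$fixed_nodes,
                            fixed_sets = config$fixed_sets))
  system <- stage("assemble", assemble(mesh, material, bc))
  say("assembled: ", system$n_dofs_full, " DOFs, ",
      length(system$constrained_dofs), " constrained")
  pairs <- stage("eigensolve", solve_smallest_eigenpairs(
    system, n = config$n_modes, tol = config$solver_tol,
    max_iter = config$max_iter, seed = config$seed))
  say("eigensolve: ", pairs$iterations, " iterations, rigid_count = ",
      pairs$rigid_count, ", max residual ",
      format(max(pairs$residuals), digits = 3))
  record <- stage("metrics", compute_record(
    system, pairs, k_policy = config$k_policy, n_hat = config$n_hat))
  say(record$S_label, " S = ", format(record$S, digits = 6),
      " N/mm at node ", record$k)

  if (!is.null(config$out_csv))
    stage("export_csv", export_metrics_csv(record, config$out_csv,
                                           mesh_path = config$mesh_path))
  if (!is.null(config$out_json))
    stage("export_json", export_metrics_json(record, config, pairs,
                                             config$out_json))
  if (!is.null(config$out_modes_vtk))
    stage("export_modes", export_modes_vtk(mesh, pairs, config$out_modes_vtk))
  say(sprintf("done in %.2f s", proc.time()[3] - t0))
  attr(record, "pairs") <- pairs
  attr(record, "system") <- system
  invisible(record)
}

#' Export an eigenmetrics record to CSV
#'
#' One row per specimen: `lambda_i`, `f_i`, `s_i` for `i = 1..n_hat`,
#' then `k`, `S`, `S_directional`, `policy`, `rigid_count`, `bc_mode`.
#'
#' @param record an `eigenmetrics_record`.
#' @param path output CSV path.
#' @param mesh_path provenance column (optional).
#' @return the path, invisibly.
#' @export
export_metrics_csv <- function(record, path, mesh_path = NA_character_) {
  n <- length(record$lambdas)
  row <- c(stats::setNames(as.list(record$lambdas), sprintf("lambda_%d", 1:n)),
           stats::setNames(as.list(record$f), sprintf("f_%d", 1:n)),
           stats::setNames(as.list(record$s), sprintf("s_%d", 1:n)),
           list(k = record$k, S = record$S,
                S_directional = record$S_directional,
                n_hat = record$n_hat, policy = record$policy,
                rigid_count = record$rigid_count, bc_mode = record$bc_mode,
                mesh = mesh_path))
  utils::write.csv(as.data.frame(row, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Export an eigenmetrics record with provenance to JSON
#'
#' @param record an `eigenmetrics_record`.
#' @param config the `run_config` that produced it.
#' @param pairs the `eigen_pairs`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
export_metrics_json <- function(record, config, pairs, path) {
  out <- list(
    metrics = list(lambdas = record$lambdas, frequencies_hz = record$f,
                   modal_stiffness_nmm = record$s, k = record$k,
                   k_direction = record$k_direction,
                   S_nmm = record$S, S_directional_nmm = record$S_directional,
                   S_label = record$S_label, n_hat = record$n_hat,
                   policy = record$policy),
    spectral = list(rigid_count = pairs$rigid_count,
                    residuals = pairs$residuals,
                    iterations = pairs$iterations,
                    solver_tol = pairs$solver_tol, seed = pairs$seed),
    provenance = list(mesh = config$mesh_path,
                      density_field = config$density_field,
                      density_kind = config$density_kind,
                      b = config$b, nu = config$nu, bc_mode = config$bc_mode,
                      package_version = as.character(utils::packageVersion("bonemodal"))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Mesh-convergence study on a refinable fixture
#'
#' Rebuilds a box/cantilever/gradient-beam fixture at each requested
#' division level, runs the eigensolve, and applies [convergence_check()]
#' (default 5% on the first five deformable eigenvalues) between
#' consecutive levels.
#'
#' @param kind fixture kind (as in [make_fixture()], refinable kinds only).
#' @param division_levels list of length-3 division vectors, coarse to
#'   fine, at least 2.
#' @param lengths geometry (fixture default when NULL).
#' @param n_modes eigenpairs per level (>= 5 recommended).
#' @param tol relative-change tolerance (default 0.05).
#' @param seed eigensolver seed.
#' @param quiet suppress messages.
#' @return list with `lambdas` (per level), `checks` (per consecutive
#'   pair), `pass` (overall: last comparison passes).
#' @export
converge_study <- function(kind = c("cantilever", "box", "gradient_beam"),
                           division_levels, lengths = NULL, n_modes = 5,
                           tol = 0.05, seed = 0, quiet = FALSE) {
  kind <- match.arg(kind)
  if (length(division_levels) < 2)
    stop("need at least 2 refinement levels")
  lam <- list()
  for (lv in seq_along(division_levels)) {
    dir <- tempfile("conv")
    fx <- make_fixture(kind, dir = dir, lengths = lengths,
                       divisions = division_levels[[lv]])
    cfg <- run_config(fx$mesh_path, bc_mode = fx$bc$mode,
                      fixed_nodes = if (fx$bc$mode == "FEMP-I")
                        resolve_fixed_nodes(fx$mesh, fx$bc) else integer(0),
                      n_modes = n_modes, n_hat = n_modes, seed = seed)
    rec <- run_pipeline(cfg, quiet = quiet)
    lam[[lv]] <- rec$lambdas
    unlink(dir, recursive = TRUE)
  }
  checks <- list()
  for (lv in seq_len(length(lam) - 1))
    checks[[lv]] <- convergence_check(lam[[lv]], lam[[lv + 1]], tol = tol,
                                      n_compare = min(5, n_modes))
  list(lambdas = lam, checks = checks,
       pass = checks[[length(checks)]]$pass)
}
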