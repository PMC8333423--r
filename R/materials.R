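#' Effective mass density from CT attenuation
#'
#' Linear calibration of (normalized, dimensionless) CT values to an
#' effective mass density used for the mass matrix only — it does not feed
#' the elasticity law. The default scaling coefficient is 658 g/cm^3 per
#' CT unit.
#'
#' @param ct scalar or per-element numeric vector of CT values, >= 0.
#' @param b scaling coefficient (g/cm^3 per CT unit), default 658.
#' @return effective density in g/cm^3, same shape as `ct`.
#' @export
effective_density <- function(ct, b = 658) {
  if (any(!is.finite(ct))) stop("non-finite CT value")
  if (any(ct < 0))
    stop("negative CT value: input must be normalized, non-negative attenuation")
  b * ct
}

#' Ash density from hydroxyapatite-equivalent density
#'
#' Affine conversion `rho_ash = 0.877 * rho_HA + 0.08` (g/cm^3).
#'
#' @param rho_ha hydroxyapatite-equivalent density (g/cm^3), >= 0.
#' @return ash density (g/cm^3).
#' @export
ash_from_ha <- function(rho_ha) {
  if (any(!is.finite(rho_ha))) stop("non-finite density")
  if (any(rho_ha < 0)) stop("negative hydroxyapatite density")
  0.877 * rho_ha + 0.08
}

#' Young's modulus from ash density
#'
#' Piecewise density-elasticity power law (modulus in MPa, density in
#' g/cm^3):
#' \deqn{E(\rho) = 10200 \rho^{2.01} \quad (\rho \ge 0.486)}
#' \deqn{E(\rho) = 2389 \quad (0.3 \le \rho < 0.486)}
#' \deqn{E(\rho) = 33900 \rho^{2.2} \quad (\rho < 0.3)}
#' The printed branch bounds overlap at 0.3; branches are evaluated
#' top-down, so exactly 0.3 takes the constant middle branch (the
#' discrepancy with the lower power law there is ~0.4%). No modulus floor
#' is applied: E(0) = 0, which downstream material validation rejects.
#'
#' @param rho_ash ash density (g/cm^3), scalar or per-element vector, >= 0.
#' @return Young's modulus in MPa, same shape.
#' @export
youngs_modulus <- function(rho_ash) {
  if (any(!is.finite(rho_ash))) stop("non-finite density")
  if (any(rho_ash < 0)) stop("negative ash density")
  E <- numeric(length(rho_ash))
  hi <- rho_ash >= 0.486
  mid <- !hi & rho_ash >= 0.3
  lo <- rho_ash < 0.3
  E[hi] <- 10200 * rho_ash[hi]^2.01
  E[mid] <- 2389
  E[lo] <- 33900 * rho_ash[lo]^2.2
  E
}

# one-time unit conversion: g/cm^3 -> tonne/mm^3, so that with mm, N and
# MPa the eigenvalues are rad^2/s^2 and stiffnesses N/mm
GCM3_TO_TONNE_MM3 <- 1e-9

#' Per-element isotropic material field
#'
#' Couples a mesh with per-element ash density, derived Young's modulus and
#' a global Poisson ratio. Material is element-constant (one value per
#' tetrahedron, no interpolation). The mass density `rho_eff` defaults to
#' `rho_ash` when not supplied — a documented approximation for synthetic
#' fixtures where only an ash density is defined.
#'
#' @param mesh a `tet_mesh`.
#' @param rho_ash per-element ash density (g/cm^3) or a scalar recycled to
#'   all elements.
#' @param rho_eff optional per-element effective mass density (g/cm^3);
#'   defaults to `rho_ash`.
#' @param nu global Poisson ratio, default 0.3; must satisfy 0 <= nu < 0.5.
#' @return object of class `material_field` with fields `rho_ash`, `E`
#'   (MPa), `nu`, `rho_eff` (g/cm^3).
#' @export
build_material_field <- function(mesh, rho_ash, rho_eff = NULL, nu = 0.3) {
  ne <- nrow(mesh$tets)
  if (length(rho_ash) == 1L) rho_ash <- rep(as.numeric(rho_ash), ne)
  if (length(rho_ash) != ne)
    stop("rho_ash has length ", length(rho_ash), ", mesh has ", ne, " elements")
  if (is.null(rho_eff)) rho_eff <- rho_ash
  if (length(rho_eff) == 1L) rho_eff <- rep(as.numeric(rho_eff), ne)
  if (length(rho_eff) != ne)
    stop("rho_eff has length ", length(rho_eff), ", mesh has ", ne, " elements")
  if (any(rho_ash < 0)) stop("negative ash density")
  if (any(rho_eff < 0)) stop("negative effective density")
  if (!is.finite(nu) || nu < 0 || nu >= 0.5)
    stop("Poisson ratio must satisfy 0 <= nu < 0.5 (got ", nu, ")")
  E <- youngs_modulus(rho_ash)
  if (any(E <= 0))
    stop("element with nonpositive Young's modulus (ash density too small); ",
         "offending elements: ", paste(utils::head(which(E <= 0)), collapse = ", "))
  structure(list(rho_ash = rho_ash, E = E, nu = nu, rho_eff = rho_eff),
            class = "material_field")
}

#' @export
print.material_field <- function(x, ...) {
  cat("material_field:", length(x$E), "elements\n")
  cat(sprintf("  E [MPa]: %.4g .. %.4g, nu = %.3g\n", min(x$E), max(x$E), x$nu))
  cat(sprintf("  rho_ash [g/cm^3]: %.4g .. %.4g; rho_eff: %.4g .. %.4g\n",
              min(x$rho_ash), max(x$rho_ash), min(x$rho_eff), max(x$rho_eff)))
  invisible(x)
}

#' Build a material field from a named density field on the mesh
#'
#' Resolves one of the conventional per-element density fields carried in
#' mesh `CELL_DATA` into a `material_field`:
#' \describe{
#'   \item{`ct`}{normalized CT values; `rho_eff = b * ct` feeds the mass
#'     matrix; Young's modulus requires an additional ash or HA density and
#'     is not derivable from `ct` alone here.}
#'   \item{`rho_ha`}{hydroxyapatite-equivalent density, converted via
#'     [ash_from_ha()].}
#'   \item{`rho_ash`}{ash density, used directly.}
#'   \item{`rho_eff`}{effective mass density override.}
#' }
#'
#' @param mesh a `tet_mesh` carrying the named field(s).
#' @param density_field field name present in `mesh$fields`.
#' @param kind one of `"rho_ash"`, `"rho_ha"`; what the field contains.
#' @param eff_field optional name of a `rho_eff` / `ct` field for the mass
#'   density; `eff_kind` says which.
#' @param eff_kind `"rho_eff"` or `"ct"`.
#' @param b CT scaling coefficient (used when `eff_kind = "ct"`).
#' @param nu global Poisson ratio.
#' @return a `material_field`.
#' @export
material_from_mesh <- function(mesh, density_field,
                               kind = c("rho_ash", "rho_ha"),
                               eff_field = NULL, eff_kind = c("rho_eff", "ct"),
                               b = 658, nu = 0.3) {
  kind <- match.arg(kind)
  eff_kind <- match.arg(eff_kind)
  if (is.null(mesh$fields[[density_field]]))
    stop("mesh has no per-element field '", density_field, "'")
  raw <- mesh$fields[[density_field]]
  rho_ash <- switch(kind, rho_ash = raw, rho_ha = ash_from_ha(raw))
  rho_eff <- NULL
  if (!is.null(eff_field)) {
    if (is.null(mesh$fields[[eff_field]]))
      stop("mesh has no per-element field '", eff_field, "'")
    rho_eff <- switch(eff_kind,
                      rho_eff = mesh$fields[[eff_field]],
                      ct = effective_density(mesh$fields[[eff_field]], b = b))
  }
  build_material_field(mesh, rho_ash, rho_eff = rho_eff, nu = nu)
}
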