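#' Pointwise norm of a full-DOF eigenvector
#'
#' Reshapes a full-DOF vector into per-node (x, y, z) triples and returns
#' the Euclidean magnitude at every node. Constrained nodes (zeros in the
#' back-expanded vector) get 0.
#'
#' @param v numeric vector, length 3 x node count, DOF order
#'   (n1x, n1y, n1z, n2x, ...).
#' @return numeric vector, one magnitude per node.
#' @export
pointwise_norm <- function(v) {
  v <- as.numeric(v)
  if (length(v) %% 3L != 0L)
    stop("vector length ", length(v), " is not divisible by 3")
  comp <- matrix(v, nrow = 3)
  sqrt(colSums(comp^2))
}

#' Compliance-maximum node
#'
#' Index of the maximum of a per-node eigenvector-magnitude field: the node
#' where the structure's stiffness is potentially lowest. Ties are broken
#' by the smallest node index.
#'
#' @param norm_field per-node magnitudes from [pointwise_norm()].
#' @return 1-based node index.
#' @export
argmax_compliance <- function(norm_field) {
  if (!length(norm_field)) stop("empty norm field")
  if (all(norm_field == 0))
    stop("all-zero norm field: no deformation to locate")
  which.max(norm_field)  # which.max returns the first maximum: tie rule
}

#' Modal stiffness
#'
#' `s_i = lambda_i / (||u_i||[k])^2` for a mass-normalized eigenvector:
#' the i-th eigenvalue rescaled by the squared nodal magnitude at the
#' compliance-maximum node, in N/mm under the mm-N-MPa-tonne-s unit system.
#'
#' @param lambda eigenvalue (rad^2/s^2), > 0 (deformable).
#' @param norm_field per-node magnitudes of the mass-normalized
#'   eigenvector.
#' @param k node index (typically from [argmax_compliance()]).
#' @return modal stiffness in N/mm.
#' @export
modal_stiffness <- function(lambda, norm_field, k) {
  if (lambda <= 0) stop("modal stiffness needs a positive (deformable) eigenvalue")
  a <- norm_field[k]
  if (!is.finite(a) || a == 0)
    stop("node ", k, " is a vibration node of this mode (zero magnitude); ",
         "use a per-mode compliance maximum instead")
  lambda / a^2
}

#' Truncated modal-superposition static stiffness
#'
#' Reconstructs the static stiffness at node `k` from the smallest
#' eigenpairs via the receptance sum
#' `1/S = sum_{i=1}^{n_hat} (||u_i||[k])^2 / lambda_i`
#' over deformable, mass-normalized modes. The squared nodal norm makes
#' this the *trace* of the 3x3 nodal receptance block: with the full
#' spectrum it equals the sum of the three axis point-load compliances at
#' `k` (see [static_compliance()]). With `direction` given, squared
#' projections `(u_i(k) . d)^2` are used instead, which with the full
#' spectrum equals the directional compliance of a point load along `d`.
#' Modes with zero magnitude at `k` contribute zero compliance.
#'
#' @param pairs an `eigen_pairs` (deformable, mass-normalized, ascending).
#' @param k node index.
#' @param n_hat number of eigenpairs in the sum (default 10; capped with a
#'   warning at the number available).
#' @param direction optional length-3 direction for the directional form.
#' @return list with `S` (N/mm), `compliances` (per-mode terms, mm/N),
#'   `n_hat` (as used), `directional` (logical).
#' @export
static_stiffness <- function(pairs, k, n_hat = 10, direction = NULL) {
  nav <- length(pairs$lambdas)
  if (nav < 1L) stop("no deformable eigenpairs")
  if (n_hat > nav) {
    warning("n_hat = ", n_hat, " exceeds the ", nav,
            " available eigenpairs; using all ", nav)
    n_hat <- nav
  }
  n_hat <- as.integer(n_hat)
  if (n_hat < 1L) stop("n_hat must be >= 1")
  if (any(pairs$lambdas[seq_len(n_hat)] <= 0))
    stop("nonpositive eigenvalue among the first ", n_hat,
         " pairs: rigid modes must be removed first")
  dofs <- node_dofs(k)
  comp <- numeric(n_hat)
  for (i in seq_len(n_hat)) {
    uk <- pairs$vectors[dofs, i]
    amp2 <- if (is.null(direction)) sum(uk^2) else {
      d <- direction / sqrt(sum(direction^2))
      sum(uk * d)^2
    }
    comp[i] <- amp2 / pairs$lambdas[i]
  }
  total <- sum(comp)
  if (total == 0)
    stop("zero compliance at node ", k, " over the first ", n_hat, " modes")
  list(S = 1 / total, compliances = comp, n_hat = n_hat,
       directional = !is.null(direction))
}

#' Natural undamped frequency
#'
#' `f = sqrt(lambda) / (2 pi)` in Hz for eigenvalues in rad^2/s^2.
#'
#' @param lambda eigenvalue(s), >= 0 (tiny negative round-off below
#'   `-tol` raises an error; values in `[-tol, 0]` are clamped to 0).
#' @param tol round-off tolerance (default 1e-8 relative to `max(lambda)`).
#' @return frequency/ies in Hz.
#' @export
natural_frequency <- function(lambda, tol = 1e-8) {
  floor_ <- -tol * max(abs(lambda), 1)
  if (any(lambda < floor_))
    stop("negative eigenvalue beyond round-off tolerance")
  sqrt(pmax(lambda, 0)) / (2 * pi)
}

#' Compute the full eigenmetrics record
#'
#' Orchestrates the eigenmetric: per-mode pointwise norms, the
#' compliance-maximum node `k`, modal stiffnesses `s_i`, the truncated
#' static stiffness `S` (both the norm/trace form and the directional form
#' along the mode-1 direction at `k`), and natural frequencies `f_i`.
#'
#' `k_policy` controls where stiffnesses are evaluated:
#' \describe{
#'   \item{`first_mode`}{(default) `k` is the argmax of mode 1's norm
#'     field and is used for every `s_i` and for `S`.}
#'   \item{`per_mode`}{each `s_i` uses its own mode's argmax; `S` still
#'     uses mode 1's `k` (the superposition needs one fixed point).}
#'   \item{`user_node`}{`k` is supplied by the caller via `user_k`.}
#' }
#'
#' For a free (FEMP-II) system the static quantity has no direct static
#' counterpart (the unconstrained static problem is ill-posed); it is
#' computed identically over deformable modes and labeled
#' `"free-interface modal stiffness"` in the record.
#'
#' @param system the `fe_system` (for constraint bookkeeping and labels).
#' @param pairs deformable `eigen_pairs`.
#' @param k_policy `"first_mode"`, `"per_mode"`, or `"user_node"`.
#' @param n_hat eigenpairs in the static-stiffness sum (default 10).
#' @param user_k node index when `k_policy = "user_node"`.
#' @return object of class `eigenmetrics_record`: `norm_fields` (node x
#'   mode matrix), `k`, `k_direction` (unit 3-vector of mode 1 at `k`),
#'   `k_per_mode`, `s` (N/mm), `S`, `S_directional`, `compliances`,
#'   `f` (Hz), `n_hat`, `policy`, `rigid_count`, `bc_mode`, `S_label`.
#' @export
compute_record <- function(system, pairs,
                           k_policy = c("first_mode", "per_mode", "user_node"),
                           n_hat = 10, user_k = NULL) {
  k_policy <- match.arg(k_policy)
  nmodes <- length(pairs$lambdas)
  if (nmodes < 1L) stop("no deformable eigenpairs")
  norm_fields <- vapply(seq_len(nmodes),
                        function(i) pointwise_norm(pairs$vectors[, i]),
                        numeric(system$n_nodes))
  k_per_mode <- vapply(seq_len(nmodes),
                       function(i) argmax_compliance(norm_fields[, i]),
                       integer(1))
  k <- switch(k_policy,
              first_mode = k_per_mode[1],
              per_mode = k_per_mode[1],
              user_node = {
                if (is.null(user_k)) stop("user_node policy needs user_k")
                as.integer(user_k)
              })
  uk1 <- pairs$vectors[node_dofs(k), 1]
  if (sqrt(sum(uk1^2)) == 0)
    stop("mode 1 has zero magnitude at node ", k)
  k_direction <- uk1 / sqrt(sum(uk1^2))

  s <- vapply(seq_len(nmodes), function(i) {
    ki <- if (k_policy == "per_mode") k_per_mode[i] else k
    modal_stiffness(pairs$lambdas[i], norm_fields[, i], ki)
  }, numeric(1))

  n_hat_used <- min(n_hat, nmodes)
  if (n_hat > nmodes)
    warning("n_hat = ", n_hat, " exceeds the ", nmodes,
            " available eigenpairs; using all ", nmodes)
  Ssum <- static_stiffness(pairs, k, n_hat = n_hat_used)
  Sdir <- static_stiffness(pairs, k, n_hat = n_hat_used,
                           direction = k_direction)
  f <- natural_frequency(pairs$lambdas)

  structure(
    list(norm_fields = norm_fields, k = k, k_direction = k_direction,
         k_per_mode = k_per_mode, s = s,
         S = Ssum$S, S_directional = Sdir$S,
         compliances = Ssum$compliances,
         f = f, lambdas = pairs$lambdas, n_hat = n_hat_used,
         policy = k_policy, rigid_count = pairs$rigid_count,
         bc_mode = system$bc$mode,
         S_label = if (length(system$constrained_dofs)) "static stiffness"
                   else "free-interface modal stiffness"),
    class = "eigenmetrics_record")
}

#' @export
print.eigenmetrics_record <- function(x, ...) {
  cat("eigenmetrics_record (", x$bc_mode, ", policy ", x$policy, ")\n", sep = "")
  cat(sprintf("  k = node %d, direction (%.3f, %.3f, %.3f)\n",
              x$k, x$k_direction[1], x$k_direction[2], x$k_direction[3]))
  cat(sprintf("  %s S = %.6g N/mm (n_hat = %d); directional S = %.6g N/mm\n",
              x$S_label, x$S, x$n_hat, x$S_directional))
  cat("  s_i [N/mm]:", paste(format(x$s, digits = 5), collapse = ", "), "\n")
  cat("  f_i [Hz]:  ", paste(format(x$f, digits = 5), collapse = ", "), "\n")
  invisible(x)
}
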