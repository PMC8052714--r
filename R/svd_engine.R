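#' Construct an SVD stopping policy
#'
#' The QR phase of the Golub-Kahan-Reinsch factorization can be run to full
#' convergence, capped at a fixed number of implicit-shift steps, or guarded
#' against ill-conditioned steps: with `"ill_conditioned_guard"` (the
#' default), a diagonal block whose adjacent diagonal entries differ by less
#' than `near_equal_ratio` (relative) is frozen rather than rotated further,
#' reflecting the numerical hazard of nearly equal singular values. Whatever
#' the policy, the accumulated orthogonal factors together with the current
#' middle matrix reproduce the input to roundoff.
#'
#' @param mode `"ill_conditioned_guard"`, `"full_convergence"` or
#'   `"max_sweeps"`.
#' @param off_diagonal_tol Relative tolerance below which a superdiagonal
#'   entry is considered converged and zeroed.
#' @param max_sweeps Implicit-shift QR step budget for `"max_sweeps"` mode.
#' @param near_equal_ratio Relative gap under which two adjacent diagonal
#'   entries count as "nearly equal" for the guard.
#' @return A `stop_policy` list.
#' @export
stop_policy <- function(mode = c("ill_conditioned_guard", "full_convergence",
                                 "max_sweeps"),
                        off_diagonal_tol = 1e-12, max_sweeps = 100L,
                        near_equal_ratio = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(off_diagonal_tol > 0, near_equal_ratio > 0, max_sweeps >= 0)
  structure(list(mode = mode, off_diagonal_tol = off_diagonal_tol,
                 max_sweeps = as.integer(max_sweeps),
                 near_equal_ratio = near_equal_ratio),
            class = "stop_policy")
}

policy_mode_code <- function(policy) {
  match(policy$mode, c("full_convergence", "max_sweeps", "ill_conditioned_guard")) - 1L
}

#' Golub-Kahan bidiagonalization
#'
#' Factors a matrix with at least as many rows as columns as
#' `K = P B Q^T` with `B` upper bidiagonal, via Householder reflections.
#'
#' @param K Numeric matrix, `nrow(K) >= ncol(K)`, finite entries.
#' @return List with `P` (economy, rows x cols), `d` (diagonal of `B`),
#'   `e` (superdiagonal) and `Q`.
#' @export
bidiagonalize <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) < ncol(K)) stop("bidiagonalize expects rows >= cols; transpose first")
  res <- .cpp_bidiag(K)
  res$d <- as.numeric(res$d)
  res$e <- as.numeric(res$e)
  res
}

#' Factor a characterization matrix by the early-stoppable SVD
#'
#' Runs Golub-Kahan bidiagonalization followed by implicit-shift QR sweeps
#' under the given stopping policy. Wide matrices are factored through their
#' transpose; economy-size factors are returned (one left singular vector per
#' row of a wide `K`). Singular values are non-negative and sorted
#' descending; each LSV column is sign-fixed so its largest-magnitude
#' component is positive.
#'
#' @param K A numeric matrix or a `system_snapshot`.
#' @param policy A [stop_policy()].
#' @return An `svd_factors` object: `U`, `sigma`, `Vt`, `sweeps_used`,
#'   `stopped_early`, `converged`, `recon_error` (relative Frobenius residual
#'   of `U diag(sigma) Vt` against `K`) and `middle_error` (residual using
#'   the full middle matrix including unconverged superdiagonals).
#' @export
svd_factorize <- function(K, policy = stop_policy()) {
  if (inherits(K, "system_snapshot")) K <- snapshot_matrix(K)
  K <- as.matrix(K)
  res <- .cpp_gkr(K, policy_mode_code(policy), policy$off_diagonal_tol,
                  policy$max_sweeps, policy$near_equal_ratio, TRUE)
  res$sigma <- as.numeric(res$sigma)
  res$policy <- policy
  structure(res, class = "svd_factors")
}

#' @export
print.svd_factors <- function(x, ...) {
  cat(sprintf(
    "<svd_factors> %d LSVs; sweeps=%d%s; recon_error=%.2e\n",
    length(x$sigma), x$sweeps_used,
    if (isTRUE(x$stopped_early)) " (stopped early)" else "", x$recon_error))
  invisible(x)
}

#' Minimum-norm least-squares solution from SVD factors
#'
#' Computes `a = V Sigma^+ U^T dxdt`, treating singular values below
#' `rank_tol * max(sigma)` as zero. Among all least-squares solutions of the
#' underdetermined system this is the one of minimum Euclidean norm.
#'
#' @param factors An `svd_factors`.
#' @param dxdt Rate vector (one entry per matrix row).
#' @param rank_tol Relative rank threshold. The characterization matrix has
#'   full row rank whenever all concentrations are positive, so effective
#'   rank deficiency signals degenerate input and is reported in the result.
#' @return A `solution_vector`: `a`, `rank_used`, `residual`
#'   (`||K a - dxdt|| / ||dxdt||`, computed from the factors).
#' @export
pseudo_solve <- function(factors, dxdt, rank_tol = 1e-12) {
  stopifnot(inherits(factors, "svd_factors"))
  dxdt <- as.numeric(dxdt)
  if (length(dxdt) != nrow(factors$U)) stop("dxdt length does not match factors")
  s <- factors$sigma
  keep <- s > rank_tol * max(s, 0) & s > 0
  if (!any(keep) && any(dxdt != 0)) {
    warning("all singular values below tolerance with nonzero dxdt: unsolvable direction")
  }
  w <- drop(crossprod(factors$U, dxdt))
  w[keep] <- w[keep] / s[keep]
  w[!keep] <- 0
  a <- drop(crossprod(factors$Vt, w))
  # residual through the factorization
  pred <- drop(factors$U %*% (s * drop(factors$Vt %*% a)))
  nb <- sqrt(sum(dxdt^2))
  res <- if (nb > 0) sqrt(sum((pred - dxdt)^2)) / nb else sqrt(sum(pred^2))
  structure(list(a = a, rank_used = sum(keep), residual = res),
            class = "solution_vector")
}

#' Machine-precision back-computation quality check
#'
#' Recomputes the characterization matrix from `U diag(sigma) Vt` and the
#' rate vector from `K a`, and reports whether both relative errors fall
#' within bounds. For early-stopped factorizations the rate-residual bound is
#' reported but not asserted, since the discarded superdiagonal mass is then
#' expected to leave a residual.
#'
#' @param factors An `svd_factors`.
#' @param solution A `solution_vector` from the same snapshot.
#' @param K The characterization matrix (or `system_snapshot`).
#' @param dxdt The rate vector.
#' @param recon_bound Bound on the relative reconstruction error.
#' @param residual_bound Bound on the relative rate residual.
#' @return A list report with the achieved errors, the bounds, flags per
#'   check and an overall `pass`.
#' @export
quality_check <- function(factors, solution, K, dxdt,
                          recon_bound = 1e-8, residual_bound = 1e-6) {
  if (inherits(K, "system_snapshot")) K <- snapshot_matrix(K)
  K <- as.matrix(K)
  dxdt <- as.numeric(dxdt)
  Khat <- factors$U %*% (factors$sigma * factors$Vt)
  nk <- sqrt(sum(K^2))
  recon <- if (nk > 0) sqrt(sum((Khat - K)^2)) / nk else sqrt(sum(Khat^2))
  pred <- drop(K %*% solution$a)
  nb <- sqrt(sum(dxdt^2))
  resid <- if (nb > 0) sqrt(sum((pred - dxdt)^2)) / nb else sqrt(sum(pred^2))
  recon_ok <- recon <= recon_bound
  resid_ok <- resid <= residual_bound
  pass <- recon_ok && (isTRUE(factors$stopped_early) || resid_ok)
  list(recon_error = recon, residual = resid,
       recon_bound = recon_bound, residual_bound = residual_bound,
       recon_ok = recon_ok, residual_ok = resid_ok,
       stopped_early = isTRUE(factors$stopped_early), pass = pass)
}
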