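#' Monod growth rate
#'
#' Specific growth rate at local substrate concentration `N`:
#' `mu = mu_max * N / (K_N + N)`.
#'
#' @param strain_max_rate maximum specific growth rate (any time unit).
#' @param N local substrate concentration (mg litre^-1), `>= 0`.
#' @param K_N half-saturation constant (mg litre^-1).
#' @return Growth rate in the units of `strain_max_rate`.
#' @examples
#' local_growth_rate(14.1, 1.18, 1.18)  # half-saturation: 7.05
#' @export
local_growth_rate <- function(strain_max_rate, N, K_N) {
  if (any(N < 0)) stop("substrate concentration must be non-negative", call. = FALSE)
  strain_max_rate * N / (K_N + N)
}

#' Quasi-steady nutrient field
#'
#' Solves `D_N * laplacian(N) = R(N)` over the lattice with a Monod sink
#' `R = q_max * (M_eff / dV) * N / (K_N + N)` per node, where `M_eff` is the
#' cost-weighted mass of actively consuming (uninfected, non-halted) cells,
#' so that substrate consumption exactly balances growth / yield. Boundary
#' conditions: `N = N_max` on all nodes at or above the bulk boundary layer
#' (global front maximum + `h`), no-flux at the substratum, periodic
#' laterally. Substrate diffusion equilibrates in seconds over the domain,
#' far faster than one iteration, so a quasi-steady solve per iteration is
#' used. The Monod nonlinearity is handled by Picard iteration of sparse
#' direct solves to a relative tolerance of 1e-6 (max 1e4 iterations).
#'
#' @param state a simulation state; the previous field warm-starts the solve.
#' @param tol relative convergence tolerance on `max|dN| / N_max`.
#' @param max_iter Picard iteration cap; exceeding it is an error carrying
#'   the residual norm.
#' @return An `nx` by `ny` matrix of concentrations (mg litre^-1).
#' @export
solve_nutrients <- function(state, tol = 1e-6, max_iter = 1e4) {
  p <- state$p
  nx <- p$nx; ny <- p$ny; dl <- p$dl

  # effective consuming biomass density per node (mg / L)
  Beff <- matrix(0, nx, ny)
  act <- which(!state$b_inf & !state$b_halt)
  if (length(act) > 0) {
    contrib <- (1 - p$strains$cost[state$b_strain[act]]) * state$b_mass[act]
    agg <- rowsum(contrib, state$b_node[act])
    Beff[as.integer(rownames(agg))] <- agg / p$dV * 1e18  # g/um^3 -> mg/L
  }

  fr <- max(front_rows(occupancy_matrix(state)))
  # first Dirichlet row: lowest row whose bottom edge is at/above front + h
  iy_d <- min(ny, floor((fr * dl + p$h_um) / dl) + 1L)
  n_int <- iy_d - 1L
  out <- matrix(p$N_max, nx, ny)
  if (n_int < 1L || all(Beff == 0)) return(out)

  m <- nx * n_int
  idx <- function(x, y) x + nx * (y - 1L)  # x,y 1-based within interior block
  xs <- rep(seq_len(nx), n_int)
  ys <- rep(seq_len(n_int), each = nx)
  cD <- p$D_N_um2_h / dl^2

  # Laplacian triplets (fixed for a given iy_d)
  left <- idx(ifelse(xs == 1L, nx, xs - 1L), ys)
  right <- idx(ifelse(xs == nx, 1L, xs + 1L), ys)
  has_dn <- ys > 1L
  has_up_int <- ys < n_int
  down <- idx(xs[has_dn], ys[has_dn] - 1L)
  up <- idx(xs[has_up_int], ys[has_up_int] + 1L)
  deg <- 2L + as.integer(has_dn) + 1L  # up neighbour always exists (interior or Dirichlet)
  ii <- c(seq_len(m), seq_len(m), which(has_dn), which(has_up_int))
  jj <- c(left, right, down, up)
  vv <- rep(cD, length(ii))
  top_adj <- ys == n_int  # coupled to the Dirichlet layer
  b <- ifelse(top_adj, -cD * p$N_max, 0)

  N_old <- state$N[, seq_len(n_int), drop = FALSE]
  if (is.null(dim(N_old)) || any(dim(N_old) != c(nx, n_int))) {
    N_old <- matrix(p$N_max, nx, n_int)
  }
  Bv <- as.numeric(Beff[, seq_len(n_int)])
  for (it in seq_len(max_iter)) {
    k <- p$q_max_h * Bv / (p$K_N + pmax(as.numeric(N_old), 0))
    A <- Matrix::sparseMatrix(
      i = c(ii, seq_len(m)), j = c(jj, seq_len(m)),
      x = c(vv, -cD * deg - k), dims = c(m, m)
    )
    N_new <- as.numeric(Matrix::solve(A, b))
    delta <- max(abs(N_new - as.numeric(N_old))) / p$N_max
    N_old <- matrix(N_new, nx, n_int)
    if (delta < tol) {
      out[, seq_len(n_int)] <- N_old
      return(out)
    }
  }
  stop("nutrient solver did not converge within ", max_iter,
       " iterations (residual ", signif(delta, 4), ")", call. = FALSE)
}

stage_nutrients <- function(state) {
  state$N <- solve_nutrients(state)
  invisible(state)
}
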