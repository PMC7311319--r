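#' In-node stay probability of a diffusing virion
#'
#' Probability that a virion performing Brownian motion remains within its
#' current grid node during one walk step. Obtained by integrating the
#' radial Gaussian step kernel over a disc (sphere) of area (volume) equal
#' to a grid node, which yields `erf(1 / sqrt(2 * a * pi))` with dimension
#' constant `a = 1` in two dimensions and `a = 4` in three. Evaluates to
#' 0.42 (2D) and 0.22 (3D) to two decimals. The complement is split
#' uniformly over the `2 * dim` axis directions.
#'
#' @param a dimension constant, 1 (2D) or 4 (3D).
#' @return Stay probability in (0, 1).
#' @examples
#' round(stay_probability(1), 2)  # 0.42
#' round(stay_probability(4), 2)  # 0.22
#' @export
stay_probability <- function(a) {
  if (!a %in% c(1, 4)) stop("dimension constant a must be 1 (2D) or 4 (3D)", call. = FALSE)
  erf(1 / sqrt(2 * a * pi))
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Number of potential walk steps in one iteration
#'
#' `n = round(D_P * dt / (2 * dl^2))`: the number of lattice steps a virion
#' with diffusivity `D_P` can take during one simulation interval.
#'
#' @param D_P_um2_s phage diffusivity (um^2 s^-1).
#' @param dt_s iteration duration (s).
#' @param dl_um node edge length (um).
#' @return Non-negative integer step budget.
#' @examples
#' steps_per_iteration(38.2, 450, 3)  # 955
#' @export
steps_per_iteration <- function(D_P_um2_s, dt_s, dl_um) {
  if (dl_um <= 0) stop("dl_um must be positive", call. = FALSE)
  as.integer(round(D_P_um2_s * dt_s / (2 * dl_um^2)))
}

#' Duration of one walk step
#'
#' `dtp = 2 * dl^2 / D_P` seconds; `n * dtp` recovers the iteration
#' duration up to rounding of `n`.
#'
#' @inheritParams steps_per_iteration
#' @return Step time in seconds.
#' @export
step_time <- function(D_P_um2_s, dl_um) {
  if (D_P_um2_s <= 0) stop("step time undefined for D_P = 0 (no walk)", call. = FALSE)
  2 * dl_um^2 / D_P_um2_s
}

#' Residual infection time after a walk
#'
#' When a virion ceases motion after `s` of its `n` potential steps, the
#' time used for the subsequent infection hazard is `dtr = dt * s / n`
#' (the printed convention). The alternative reading `dt * (n - s) / n`
#' is available as the "complement" convention.
#'
#' @param dt_h iteration duration (h).
#' @param s steps consumed, `0 <= s <= n`.
#' @param n step budget.
#' @param complement use `dt * (n - s) / n` instead.
#' @return Time in hours; 0 when `n = 0`.
#' @export
remaining_time <- function(dt_h, s, n, complement = FALSE) {
  if (n == 0) return(0)
  stopifnot(all(s >= 0), all(s <= n))
  if (complement) dt_h * (n - s) / n else dt_h * s / n
}

#' Advective removal probability for an off-biofilm virion
#'
#' Virions in the liquid phase are removed by flow with per-step probability
#' `1 - exp(-dtp * d^2 * delta_P)`, increasing with the squared distance
#' `d` from the biofilm (shear increases away from the surface).
#'
#' @param d_um distance to the nearest biomass-containing node (um).
#' @param delta_P removal rate ((um^2 h)^-1).
#' @param dtp_h step duration (h).
#' @export
removal_probability <- function(d_um, delta_P, dtp_h) {
  if (delta_P == 0 || dtp_h == 0) return(rep(0, length(d_um)))
  -expm1(-dtp_h * d_um^2 * delta_P)
}

#' Biomass interaction probability for one walk step
#'
#' Probability that a virion attempting to diffuse from a source node with
#' aggregate interaction rate `I_s` into a target node with rate `I_t`
#' interacts with biomass (and ceases motion): `1 - exp(-dtp * (I_s + I_t))`.
#'
#' @param I_s,I_t node interaction rates (s^-1), see [node_interaction_rate()].
#' @param dtp_s step duration (s).
#' @export
interaction_probability <- function(I_s, I_t, dtp_s) {
  -expm1(-dtp_s * (I_s + I_t))
}

#' Infection probability given residual time
#'
#' `1 - exp(-gamma * dtr)` with `gamma` the infection rate per contact time.
#'
#' @param gamma_h infection rate (h^-1).
#' @param dtr_h residual time (h), see [remaining_time()].
#' @export
infection_probability <- function(gamma_h, dtr_h) {
  -expm1(-gamma_h * dtr_h)
}

#' Aggregate phage-biomass interaction rate of a node
#'
#' `I_x = sum_i m_i * I_i` over the bacteria in a node: the product of each
#' individual's biomass (in units of the reference cell mass `m_s`, matching
#' the interaction-rate parameter units `(m_s um^3)^-1 s^-1`) and its
#' strain's rate parameter. Additive in individuals; the result is in s^-1
#' so that `dtp * I_x` is a dimensionless per-step hazard.
#'
#' Two normalizations of the printed parameter units are supported:
#' `"per_node_volume"` (the default) divides the summed per-cell rates by
#' the node volume, `I_x = sum (m_i/m_s) * I_i / dV`, giving virions a
#' root-mean-square adsorption reach of roughly 17 um through dense
#' biomass; `"per_cell"` reads `I_i` as the rate contributed by one
#' reference-mass cell, `I_x = sum (m_i/m_s) * I_i`, 27x stronger,
#' stopping virions within a node or two of contact. The methods vignette
#' discusses how the choice shapes epidemic spread and phage
#' sequestration.
#'
#' @param masses_g cell masses (g).
#' @param I_per per-strain interaction rates, recycled against `masses_g`.
#' @param m_s reference cell mass (g).
#' @param dV_um3 node volume (um^3).
#' @param normalization `"per_node_volume"` or `"per_cell"`.
#' @export
node_interaction_rate <- function(masses_g, I_per, m_s, dV_um3,
                                  normalization = c("per_node_volume",
                                                    "per_cell")) {
  normalization <- match.arg(normalization)
  if (length(masses_g) == 0) return(0)
  ix <- sum((masses_g / m_s) * I_per)
  if (normalization == "per_node_volume") ix <- ix / dV_um3
  ix
}

#' Biomass capacity of one grid node
#'
#' @param S_max_g_per_l maximum active biomass density (g litre^-1).
#' @param dV_um3 node volume (um^3).
#' @return Capacity in grams (1 um^3 = 1e-15 litre).
#' @export
node_capacity <- function(S_max_g_per_l, dV_um3) {
  S_max_g_per_l * 1e-15 * dV_um3
}

# --- engine-internal phage stages -------------------------------------------

# Build per-node aggregate interaction-rate matrix (s^-1) on the extended
# grid (rows above the domain are zero).
interaction_rate_matrix <- function(state) {
  p <- state$p
  m <- matrix(0, p$nx, state$ny_ext)
  if (length(state$b_node) > 0) {
    contrib <- (state$b_mass / p$m_s) * p$strains$I[state$b_strain]
    if (!p$ix_per_cell) contrib <- contrib / p$dV
    agg <- rowsum(contrib, state$b_node)
    m[as.integer(rownames(agg))] <- agg
  }
  m
}

# Walk all free phages for one iteration (cycle stage 5). Virions that
# interacted with biomass in an earlier iteration stay adsorbed where they
# stopped (motion ceases permanently on contact; only surface-modification
# hosts release them, see stage_phage_infection) and are not walked again.
# Precomputes the occupancy, interaction and removal fields, then delegates
# the stepping to the compiled kernel. Removed virions leave the system.
stage_phage_movement <- function(state) {
  np <- length(state$ph_x)
  state$counters[["phage_advected"]] <- 0L
  if (np == 0) return(invisible(state))
  free <- which(!state$ph_stopped)
  state$ph_s[free] <- 0L
  if (length(free) == 0) return(invisible(state))
  p <- state$p
  occ_ext <- occupancy_extended(state)
  Ix <- interaction_rate_matrix(state)
  efac <- exp(-p$dtp_s * Ix)
  if (p$delta_P > 0) {
    d2 <- distance2_field(state, occ_ext)
    prem <- -expm1(-p$dtp_h * d2 * p$delta_P)
    prem[occ_ext] <- 0
    prem[!is.finite(prem)] <- 1   # no biomass anywhere: advection dominates
  } else {
    prem <- matrix(0, p$nx, state$ny_ext)
  }
  res <- walk_phages_cpp(state$ph_x[free], state$ph_y[free], state$ph_z[free],
                         p$nx, state$ny_ext, p$nz, p$dim, p$n_steps,
                         p$p_stay, as.numeric(efac), as.logical(occ_ext),
                         as.numeric(prem))
  state$ph_x[free] <- res$x
  state$ph_y[free] <- res$y
  state$ph_z[free] <- res$z
  state$ph_stopped[free] <- res$stopped
  state$ph_s[free] <- res$steps
  removed <- free[res$removed]
  state$counters[["phage_advected"]] <- length(removed)
  if (length(removed) > 0) remove_phages(state, removed)
  invisible(state)
}

# Infection attempts for adsorbed virions (stage 7): both those that ceased
# motion during this iteration's walk (residual time dtr from their stop
# step) and those adsorbed in earlier iterations (full dt under the
# complement convention, since they take no steps). Each adsorbed phage
# draws one host in its node weighted by m_i * I_i; the contact "fires"
# with probability 1 - exp(-gamma * dtr). Outcome depends on the host
# strain's resistance mode; a drawn surface-modification host cannot bind
# the virion and releases it to resume walking next iteration.
stage_phage_infection <- function(state) {
  p <- state$p
  # A virion gets its infection attempt at adsorption (residual time from
  # its stop step); under the default one-shot policy an unsuccessful
  # virion then stays bound as an inert sorbed particle until its node
  # loses its biomass (sorptive scavenging). Under the per-iteration
  # policy adsorbed virions retry every cycle (with the full iteration
  # time under the complement convention, never under the printed one,
  # whose residual time is zero when no steps are taken).
  state$counters[["infections"]] <- 0L
  state$counters[["superinfections"]] <- 0L
  state$counters[["aborted"]] <- 0L
  state$counters[["aborted_mass"]] <- 0
  state$counters[["neutralized"]] <- 0L
  state$counters[["halted"]] <- 0L
  fresh <- state$ph_stopped & state$ph_s > 0L
  stopped <- if (p$attempt_once) {
    which(fresh)
  } else {
    which(state$ph_stopped & (fresh | p$dtr_complement))
  }
  if (length(stopped) == 0) return(invisible(state))
  node_of <- function(i) state$ph_x[i] + p$nx * state$ph_y[i] + 1L  # 2D linear
  ncells <- length(state$b_node)
  cell_alive <- rep(TRUE, ncells)
  w <- if (ncells > 0) (state$b_mass / p$m_s) * p$strains$I[state$b_strain] else numeric(0)
  by_node <- if (ncells > 0) split(seq_len(ncells), state$b_node) else list()
  phage_consumed <- rep(FALSE, length(state$ph_x))
  n_inf <- n_super <- n_abort <- n_neut <- n_halt <- 0L
  aborted_mass <- 0
  killed <- integer(0)

  for (j in stopped) {
    nd <- node_of(j)
    cand <- by_node[[as.character(nd)]]
    cand <- cand[cell_alive[cand]]
    if (length(cand) == 0) next
    dtr <- remaining_time(p$dt_h, state$ph_s[j], p$n_steps,
                          complement = p$dtr_complement)
    if (runif(1) >= infection_probability(p$gamma_h, dtr)) next
    wc <- w[cand]
    if (all(wc <= 0)) next
    host <- if (length(cand) == 1) cand else sample(cand, 1, prob = wc)
    mode <- p$strains$mode[state$b_strain[host]]
    if (mode == "SUSCEPTIBLE") {
      if (!state$b_inf[host]) {
        state$b_inf[host] <- TRUE
        state$b_tinf[host] <- state$time_h + p$dt_h
        n_inf <- n_inf + 1L
        phage_consumed[j] <- TRUE
      } else {
        # drawn particle already infected: only susceptible (uninfected)
        # particles can be entered, so nothing happens to either party
        n_super <- n_super + 1L
      }
    } else if (mode == "ABORTIVE") {
      cell_alive[host] <- FALSE
      killed <- c(killed, host)
      aborted_mass <- aborted_mass + state$b_mass[host]
      n_abort <- n_abort + 1L
      phage_consumed[j] <- TRUE
    } else if (mode == "PHAGE_NEUTRALIZING") {
      n_neut <- n_neut + 1L
      phage_consumed[j] <- TRUE
    } else {  # SURFACE: pass-through, both unharmed; phage released
      state$ph_stopped[j] <- FALSE
      if (p$strains$halt[state$b_strain[host]] && !state$b_halt[host]) {
        state$b_halt[host] <- TRUE
        n_halt <- n_halt + 1L
      }
    }
  }
  # phages still adsorbed retry next iteration with no steps taken
  state$ph_s[state$ph_stopped] <- 0L
  if (length(killed) > 0) remove_cells(state, killed)
  if (any(phage_consumed)) remove_phages(state, which(phage_consumed))
  state$counters[["infections"]] <- n_inf
  state$counters[["superinfections"]] <- n_super
  state$counters[["aborted"]] <- n_abort
  state$counters[["aborted_mass"]] <- aborted_mass
  state$counters[["neutralized"]] <- n_neut
  state$counters[["halted"]] <- n_halt
  invisible(state)
}

# Lysis of infected cells past the latent period (stage 3): the cell is
# removed and beta progeny virions are placed in its node.
stage_lysis <- function(state) {
  p <- state$p
  due <- which(state$b_inf & (state$time_h - state$b_tinf >= p$tau_h - 1e-9))
  state$counters[["bursts"]] <- length(due)
  if (length(due) == 0) return(invisible(state))
  state$counters[["lysed_mass"]] <- sum(state$b_mass[due])
  nodes <- state$b_node[due]
  x <- (nodes - 1L) %% p$nx
  y <- (nodes - 1L) %/% p$nx
  nb <- length(due) * p$beta
  state$ph_x <- c(state$ph_x, rep(x, each = p$beta))
  state$ph_y <- c(state$ph_y, rep(y, each = p$beta))
  state$ph_z <- c(state$ph_z, rep(0L, nb))
  state$ph_stopped <- c(state$ph_stopped, rep(FALSE, nb))
  state$ph_s <- c(state$ph_s, rep(0L, nb))
  remove_cells(state, due)
  invisible(state)
}

# End-of-iteration advective sweep (stage 9): any virion in a node holding
# no live bacterial biomass is removed from the system.
stage_phage_sweep <- function(state) {
  np <- length(state$ph_x)
  if (np == 0) {
    state$counters[["phage_swept"]] <- 0L
    return(invisible(state))
  }
  p <- state$p
  occ <- occupancy_matrix(state)
  inside <- state$ph_y < p$ny
  keep <- inside
  if (any(inside)) {
    idx <- state$ph_x[inside] + p$nx * state$ph_y[inside] + 1L
    keep[inside] <- occ[idx]
  }
  state$counters[["phage_swept"]] <- sum(!keep)
  if (any(!keep)) remove_phages(state, which(!keep))
  invisible(state)
}
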