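#' Per-cell erosion probability
#'
#' The biofilm front erodes at a speed proportional to the squared height
#' above the substratum, `v(y) = delta_E * y^2` (with `delta_E` in
#' `(m h)^-1` this gives `v` in m/h). A front cell at height `y` is removed
#' during one iteration with probability `min(1, v(y) * dt / dl)`, the
#' front-speed converted to a per-node removal hazard.
#'
#' @param y_um height above the substratum (um).
#' @param delta_E_per_m_h erosion constant ((m h)^-1).
#' @param dt_h iteration duration (h).
#' @param dl_um node edge length (um).
#' @export
erosion_probability <- function(y_um, delta_E_per_m_h, dt_h, dl_um) {
  speed_um_h <- delta_E_per_m_h * 1e-6 * y_um^2   # (m h)^-1 * m^2 -> um/h
  pmin(1, speed_um_h * dt_h / dl_um)
}

# Growth and division (cycle stage 2). Uninfected, non-halted cells gain
# dm = (1 - c) * mu_s * N/(K + N) * m * dt and consume dm / Y substrate;
# cells at or above 2 * m_s split symmetrically (mass conserved exactly).
stage_growth <- function(state) {
  p <- state$p
  state$counters[["growth_mass"]] <- 0
  state$counters[["divisions"]] <- 0L
  if (length(state$b_node) == 0) return(invisible(state))
  act <- which(!state$b_inf & !state$b_halt)
  if (length(act) > 0) {
    Nloc <- state$N[state$b_node[act]]
    mu <- (1 - p$strains$cost[state$b_strain[act]]) *
      local_growth_rate(p$mu_s_h, Nloc, p$K_N)
    dm <- mu * state$b_mass[act] * p$dt_h
    state$b_mass[act] <- state$b_mass[act] + dm
    state$counters[["growth_mass"]] <- sum(dm)
    state$substrate_consumed <- state$substrate_consumed + sum(dm) / p$Y
  }
  div <- which(state$b_mass >= 2 * p$m_s)
  if (length(div) > 0) {
    state$b_mass[div] <- state$b_mass[div] / 2
    state$b_node <- c(state$b_node, state$b_node[div])
    state$b_strain <- c(state$b_strain, state$b_strain[div])
    state$b_mass <- c(state$b_mass, state$b_mass[div])
    state$b_inf <- c(state$b_inf, rep(FALSE, length(div)))
    state$b_tinf <- c(state$b_tinf, rep(NA_real_, length(div)))
    state$b_halt <- c(state$b_halt, rep(FALSE, length(div)))
    state$counters[["divisions"]] <- length(div)
  }
  invisible(state)
}

# Height-dependent front erosion (cycle stage 4). Front nodes are occupied
# nodes with at least one empty neighbour toward the liquid (above or
# lateral); every cell in a front node is removed independently.
stage_erosion <- function(state) {
  p <- state$p
  state$counters[["eroded"]] <- 0L
  state$counters[["eroded_mass"]] <- 0
  if (length(state$b_node) == 0) return(invisible(state))
  occ <- occupancy_matrix(state)
  empty_above <- cbind(!occ[, -1, drop = FALSE], TRUE)           # top row faces liquid
  empty_left <- !occ[c(p$nx, seq_len(p$nx - 1L)), , drop = FALSE]
  empty_right <- !occ[c(seq.int(2L, length.out = p$nx - 1L), 1L), , drop = FALSE]
  front <- occ & (empty_above | empty_left | empty_right)
  if (!any(front)) return(invisible(state))
  in_front <- front[state$b_node]
  cand <- which(in_front)
  y_um <- (((state$b_node[cand] - 1L) %/% p$nx) + 0.5) * p$dl  # node-centre height
  prob <- erosion_probability(y_um, p$delta_E_per_m_h_raw, p$dt_h, p$dl)
  gone <- cand[runif(length(cand)) < prob]
  if (length(gone) > 0) {
    state$counters[["eroded"]] <- length(gone)
    state$counters[["eroded_mass"]] <- sum(state$b_mass[gone])
    remove_cells(state, gone)
  }
  invisible(state)
}

# Detachment of biomass disconnected from the substratum (cycle stage 6):
# connected components of occupied nodes (von Neumann adjacency, periodic
# laterally) not touching the bottom row are removed entirely. Reachability
# is computed by iterated dilation from the substratum row.
stage_detachment <- function(state) {
  p <- state$p
  state$counters[["detached"]] <- 0L
  state$counters[["detached_mass"]] <- 0
  if (length(state$b_node) == 0) return(invisible(state))
  occ <- occupancy_matrix(state)
  reach <- matrix(FALSE, p$nx, p$ny)
  reach[, 1] <- occ[, 1]
  repeat {
    grown <- reach
    grown <- grown |
      cbind(FALSE, reach[, -p$ny, drop = FALSE]) |
      cbind(reach[, -1, drop = FALSE], FALSE) |
      reach[c(p$nx, seq_len(p$nx - 1L)), , drop = FALSE] |
      reach[c(seq.int(2L, length.out = p$nx - 1L), 1L), , drop = FALSE]
    grown <- grown & occ
    if (identical(grown, reach)) break
    reach <- grown
  }
  loose <- which(!reach[state$b_node])
  if (length(loose) > 0) {
    state$counters[["detached"]] <- length(loose)
    state$counters[["detached_mass"]] <- sum(state$b_mass[loose])
    remove_cells(state, loose)
  }
  invisible(state)
}

# Shoving relaxation (cycle stage 8): while any node's total mass exceeds
# the capacity S_max * dV, move one randomly chosen whole cell from each
# over-capacity node to its least-full lattice neighbour (ties broken
# uniformly at random; the substratum and the domain top are forbidden).
# Deep inside a slab of nodes all at capacity the least-full neighbour is
# always the hole the excess just left, so a pure neighbour rule ping-pongs;
# when no neighbour has room for the cell, it is instead relocated along a
# breadth-first chain of shoves to the nearest node with spare capacity,
# which strictly reduces the total excess and so guarantees termination.
# Conserves cell count and mass exactly.
stage_shoving <- function(state) {
  p <- state$p
  if (length(state$b_node) == 0) return(invisible(state))
  nnodes <- p$nx * p$ny
  node_mass <- numeric(nnodes)
  agg <- rowsum(state$b_mass, state$b_node)
  node_mass[as.integer(rownames(agg))] <- agg
  cap <- p$cap_node * (1 + 1e-12)
  guard <- 0L
  guard_max <- 20L * length(state$b_node) + 1000L
  stuck <- logical(nnodes)  # single-cell nodes over capacity: nothing to move
  repeat {
    over <- which(node_mass > cap & !stuck)
    if (length(over) == 0) break
    for (nd in over) {
      if (node_mass[nd] <= cap) next
      cells <- which(state$b_node == nd)
      if (length(cells) <= 1) {
        stuck[nd] <- TRUE
        next
      }
      mover <- sample(cells, 1)
      m <- state$b_mass[mover]
      nbrs <- node_neighbors_2d(nd, p$nx, p$ny)
      nm <- node_mass[nbrs]
      best <- nbrs[nm == min(nm)]
      target <- if (length(best) == 1) best else sample(best, 1)
      if (node_mass[target] + m <= cap) {
        state$b_node[mover] <- target
        node_mass[nd] <- node_mass[nd] - m
        node_mass[target] <- node_mass[target] + m
        guard <- guard + 1L
      } else {
        # displacement chain: push one cell per hop along the shortest path
        # to the nearest node with room, so every cell moves at most one
        # node and lineage sectors stay spatially coherent
        # probe with the maximum cell mass so the receiving node can absorb
        # whichever cell the chain delivers (strict progress, no ping-pong)
        path <- bfs_room_path(nd, node_mass, 2 * p$m_s, cap, p$nx, p$ny)
        if (is.null(path)) {
          stuck[nd] <- TRUE  # grid saturated: nothing can absorb a cell
          next
        }
        for (h in seq_len(length(path) - 1L)) {
          a <- path[h]; b <- path[h + 1L]
          cells_a <- which(state$b_node == a)
          mv <- if (length(cells_a) == 1) cells_a else sample(cells_a, 1)
          mm <- state$b_mass[mv]
          state$b_node[mv] <- b
          node_mass[a] <- node_mass[a] - mm
          node_mass[b] <- node_mass[b] + mm
          guard <- guard + 1L
        }
      }
      if (guard > guard_max) {
        stop("shoving relaxation did not terminate (", guard, " moves)",
             call. = FALSE)
      }
    }
  }
  invisible(state)
}

# Breadth-first search from `nd` for the nearest node that can absorb one
# reference-mass cell while staying within capacity; returns the shortest
# path from `nd` to it (ties at equal depth broken uniformly at random), or
# NULL when the whole reachable grid is saturated.
bfs_room_path <- function(nd, node_mass, m, cap, nx, ny) {
  parent <- integer(length(node_mass))
  visited <- logical(length(node_mass))
  visited[nd] <- TRUE
  frontier <- nd
  repeat {
    nxt <- integer(0)
    for (f in frontier) {
      for (nb in node_neighbors_2d(f, nx, ny)) {
        if (!visited[nb]) {
          visited[nb] <- TRUE
          parent[nb] <- f
          nxt <- c(nxt, nb)
        }
      }
    }
    if (length(nxt) == 0) return(NULL)
    room <- nxt[node_mass[nxt] + m <= cap]
    if (length(room) > 0) {
      end <- if (length(room) == 1) room else sample(room, 1)
      path <- end
      while (path[1] != nd) path <- c(parent[path[1]], path)
      return(path)
    }
    frontier <- nxt
  }
}

# In-grid von Neumann neighbours of a 1-based linear node index (periodic x,
# closed bottom and top).
node_neighbors_2d <- function(nd, nx, ny) {
  x <- (nd - 1L) %% nx
  y <- (nd - 1L) %/% nx
  nb <- c(((x + 1L) %% nx) + nx * y + 1L,
          ((x - 1L + nx) %% nx) + nx * y + 1L)
  if (y + 1L < ny) nb <- c(nb, x + nx * (y + 1L) + 1L)
  if (y - 1L >= 0L) nb <- c(nb, x + nx * (y - 1L) + 1L)
  nb
}

remove_cells <- function(state, idx) {
  keep <- rep(TRUE, length(state$b_node))
  keep[idx] <- FALSE
  state$b_node <- state$b_node[keep]
  state$b_strain <- state$b_strain[keep]
  state$b_mass <- state$b_mass[keep]
  state$b_inf <- state$b_inf[keep]
  state$b_tinf <- state$b_tinf[keep]
  state$b_halt <- state$b_halt[keep]
  invisible(state)
}

remove_phages <- function(state, idx) {
  keep <- rep(TRUE, length(state$ph_x))
  keep[idx] <- FALSE
  state$ph_x <- state$ph_x[keep]
  state$ph_y <- state$ph_y[keep]
  state$ph_z <- state$ph_z[keep]
  state$ph_stopped <- state$ph_stopped[keep]
  state$ph_s <- state$ph_s[keep]
  invisible(state)
}
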