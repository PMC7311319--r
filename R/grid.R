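#' Build the lattice geometry
#'
#' Constructs the simulation lattice from a space configuration: nodes of
#' edge length `dl` tile a domain that is laterally periodic, bounded below
#' by a solid substratum (y = 0) and open at the top. Node coordinates are
#' 0-based; physical node centers are at `(i + 1/2) * dl`.
#'
#' @param space list with `x_max_um`, `y_max_um`, optional `z_max_um`, and
#'   `dl_um`, or a full `phagefilm_config`.
#' @return Object of class `biofilm_grid`: `nx`, `ny`, `nz`, `dim`, `dl`,
#'   dimension constant `a` (1 in 2D, 4 in 3D) and node count `n_nodes`.
#' @examples
#' g <- build_grid(list(x_max_um = 900, y_max_um = 150, dl_um = 3))
#' g$n_nodes  # 300 x 50 nodes
#' @export
build_grid <- function(space) {
  if (inherits(space, "phagefilm_config")) space <- space$space
  dl <- space$dl_um
  if (is.null(dl) || dl <= 0) stop("space.dl_um must be positive", call. = FALSE)
  check_divisible(space$x_max_um, dl, "space.x_max_um")
  check_divisible(space$y_max_um, dl, "space.y_max_um")
  three_d <- !is.null(space$z_max_um)
  if (three_d) check_divisible(space$z_max_um, dl, "space.z_max_um")
  nx <- as.integer(round(space$x_max_um / dl))
  ny <- as.integer(round(space$y_max_um / dl))
  nz <- if (three_d) as.integer(round(space$z_max_um / dl)) else 1L
  g <- list(nx = nx, ny = ny, nz = nz, dim = if (three_d) 3L else 2L,
            dl = dl, a = if (three_d) 4 else 1,
            n_nodes = nx * ny * nz)
  class(g) <- "biofilm_grid"
  g
}

#' Neighbouring node in a given axis direction
#'
#' Lateral (`x`, and `z` in 3D) moves wrap periodically; a move below the
#' substratum returns status `"blocked"`; a move above the top row returns
#' coordinates in the off-top liquid zone with status `"off_top"`.
#'
#' @param grid a `biofilm_grid`.
#' @param index integer node coordinates (0-based), length `grid$dim`.
#' @param direction one of `"+x"`, `"-x"`, `"+y"`, `"-y"` (and `"+z"`,
#'   `"-z"` in 3D).
#' @return List with `index` (integer coords) and `status` (`"inside"`,
#'   `"blocked"` or `"off_top"`).
#' @export
neighbor_index <- function(grid, index, direction) {
  dirs <- c("+x", "-x", "+y", "-y", if (grid$dim == 3L) c("+z", "-z"))
  if (!direction %in% dirs) {
    stop("invalid direction '", direction, "'; must be one of ",
         paste(dirs, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(index) == grid$dim)
  if (index[1] < 0 || index[1] >= grid$nx || index[2] < 0 || index[2] >= grid$ny) {
    stop("index out of grid", call. = FALSE)
  }
  out <- as.integer(index)
  status <- "inside"
  switch(direction,
    "+x" = { out[1] <- (index[1] + 1L) %% grid$nx },
    "-x" = { out[1] <- (index[1] - 1L + grid$nx) %% grid$nx },
    "+y" = {
      out[2] <- index[2] + 1L
      if (out[2] >= grid$ny) status <- "off_top"
    },
    "-y" = {
      out[2] <- index[2] - 1L
      if (out[2] < 0L) return(list(index = NULL, status = "blocked"))
    },
    "+z" = { out[3] <- (index[3] + 1L) %% grid$nz },
    "-z" = { out[3] <- (index[3] - 1L + grid$nz) %% grid$nz }
  )
  list(index = out, status = status)
}

# Logical occupancy (live biomass per node) as an nx x ny matrix.
occupancy_matrix <- function(state) {
  occ <- matrix(FALSE, state$p$nx, state$p$ny)
  if (length(state$b_node) > 0) occ[unique(state$b_node)] <- TRUE
  occ
}

# Occupancy on the extended grid (virtual off-top rows are empty liquid).
occupancy_extended <- function(state) {
  occ <- matrix(FALSE, state$p$nx, state$ny_ext)
  if (length(state$b_node) > 0) {
    sub <- arrayInd(unique(state$b_node), c(state$p$nx, state$p$ny))
    occ[cbind(sub[, 1], sub[, 2])] <- TRUE
  }
  occ
}

#' Biofilm front height
#'
#' Per-column height of the biofilm front: `(1 + highest occupied y-index)
#' * dl`, 0 for columns with no live biomass, and the global maximum over
#' columns. Infected cells count as live biomass until they lyse.
#'
#' @param state a simulation state from [new_sim_state()].
#' @return List with `heights` (numeric, per column, um) and `max` (um).
#' @export
front_height <- function(state) {
  occ <- occupancy_matrix(state)
  rows <- front_rows(occ)
  heights <- rows * state$p$dl
  list(heights = heights, max = max(heights, 0))
}

# Highest occupied row index (1-based; 0 = empty column) per column.
front_rows <- function(occ) {
  ny <- ncol(occ)
  hit <- occ %*% (2^(seq_len(ny) - 1))  # cheap but overflow-prone for big ny
  if (ny <= 50) {
    floor(log2(pmax(hit, 0.5))) + 1 -> r
    r[hit == 0] <- 0
    as.numeric(r)
  } else {
    apply(occ, 1, function(col) {
      w <- which(col)
      if (length(w) == 0) 0 else max(w)
    })
  }
}

# Squared vertical node-index distance to biomass within each column of the
# extended grid (Inf for empty columns): two cummin passes.
vertical_dist2 <- function(occ_ext) {
  nx <- nrow(occ_ext); ny <- ncol(occ_ext)
  d <- matrix(Inf, nx, ny)
  d[occ_ext] <- 0
  for (y in 2:ny) d[, y] <- pmin(d[, y], d[, y - 1] + 1)
  for (y in (ny - 1):1) d[, y] <- pmin(d[, y], d[, y + 1] + 1)
  d^2
}

# Full squared Euclidean distance field (um^2) to nearest biomass node,
# periodic in x, on the extended grid.
distance2_field <- function(state, occ_ext = occupancy_extended(state)) {
  p <- state$p
  if (is.null(state$dx2)) {
    i <- seq_len(p$nx) - 1
    dx <- abs(outer(i, i, "-"))
    dx <- pmin(dx, p$nx - dx) * p$dl
    state$dx2 <- dx^2
  }
  h2 <- vertical_dist2(occ_ext) * p$dl^2
  if (all(!occ_ext)) return(matrix(Inf, p$nx, ncol(occ_ext)))
  dist2_field_cpp(h2, state$dx2)
}

#' Distance from a node to the biofilm
#'
#' Euclidean node-center distance (periodic in x) from a node to the nearest
#' node containing live bacterial biomass; 0 if the node itself holds
#' biomass; `Inf` if the grid holds no biomass.
#'
#' @param state a simulation state.
#' @param index 0-based node coordinates `c(x, y)` (y may reach into the
#'   off-top zone).
#' @return Distance in micrometres.
#' @export
distance_to_biofilm <- function(state, index) {
  d2 <- distance2_field(state)
  sqrt(d2[index[1] + 1L, index[2] + 1L])
}
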