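# Small configurations and states used across tests. All fixtures are built
# in code; grids are kept tiny so every test runs in well under a second
# unless it is explicitly a simulation test.

tiny_config <- function(...) {
  overrides <- list(...)
  base <- list(
    space = list(x_max_um = 30, y_max_um = 30),
    sim = list(max_days = 0.5, seed = 42),
    pulse = list(enabled = FALSE)
  )
  for (nm in names(overrides)) {
    base[[nm]] <- utils::modifyList(base[[nm]] %||% list(), overrides[[nm]])
  }
  do.call(sim_config, base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A state with cells placed at given 0-based (x, y) coords, strain ids and
# masses; bypasses inoculation so geometry is exact.
state_with_cells <- function(config, x, y, strain = 1L, mass = NULL) {
  st <- new_sim_state(config)
  p <- st$p
  n <- length(x)
  strain <- rep_len(strain, n)
  mass <- if (is.null(mass)) rep(p$m_s, n) else rep_len(mass, n)
  st$b_node <- as.integer(x + p$nx * y + 1L)
  st$b_strain <- as.integer(strain)
  st$b_mass <- mass
  st$b_inf <- rep(FALSE, n)
  st$b_tinf <- rep(NA_real_, n)
  st$b_halt <- rep(FALSE, n)
  st
}

add_phages <- function(st, x, y) {
  n <- length(x)
  st$ph_x <- c(st$ph_x, as.integer(x))
  st$ph_y <- c(st$ph_y, as.integer(y))
  st$ph_z <- c(st$ph_z, rep(0L, n))
  st$ph_stopped <- c(st$ph_stopped, rep(FALSE, n))
  st$ph_s <- c(st$ph_s, rep(0L, n))
  st
}
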