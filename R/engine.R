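#' Create an empty simulation state
#'
#' Builds the lattice and all agent containers for a run. The state is an
#' environment (reference semantics: the stage functions mutate it in
#' place). Nodes start empty of agents with the nutrient field uniform at
#' `N_max`; call [inoculate()] to place founder cells.
#'
#' @param config a `phagefilm_config` from [sim_config()], or a prebuilt
#'   `sim_params`.
#' @return An environment of class `sim_state`.
#' @export
new_sim_state <- function(config) {
  p <- if (inherits(config, "sim_params")) config else build_params(config)
  if (p$dim == 3L) {
    stop("the dynamic engine is 2D; 3D geometry is supported for grid and ",
         "walk primitives only (drop space.z_max_um)", call. = FALSE)
  }
  state <- new.env(parent = emptyenv())
  state$p <- p
  state$ny_ext <- p$ny + p$n_virtual_rows
  state$b_node <- integer(0)
  state$b_strain <- integer(0)
  state$b_mass <- numeric(0)
  state$b_inf <- logical(0)
  state$b_tinf <- numeric(0)
  state$b_halt <- logical(0)
  state$ph_x <- integer(0)
  state$ph_y <- integer(0)
  state$ph_z <- integer(0)
  state$ph_stopped <- logical(0)
  state$ph_s <- integer(0)
  state$N <- matrix(p$N_max, p$nx, p$ny)
  state$dx2 <- NULL
  state$time_h <- 0
  state$iter <- 0L
  state$infection_time <- NA_real_
  state$f_before <- NA_real_
  state$f_inoculum <- NA_real_
  state$pulse_iters_done <- 0L
  state$peak_phage <- 0L
  state$substrate_consumed <- 0
  state$pending_pulsed <- 0L
  state$counters <- list()
  state$tallies <- list()
  class(state) <- c("sim_state", "environment")
  state
}

#' Inoculate founder cells on the substratum
#'
#' Places `founders_per_node` cells of mass `m_s` in every bottom-row node;
#' each founder is independently assigned to the resistant strain with
#' probability `resistant_fraction` (strains with any non-susceptible
#' resistance mode), otherwise to the susceptible strain.
#'
#' @param state a `sim_state`.
#' @param resistant_fraction probability a founder is resistant, in `[0, 1]`;
#'   defaults to the configured `sim$resistant_fraction`.
#' @param founders_per_node founders per substratum node; a fractional
#'   density scatters `round(nx * founders_per_node)` founders over
#'   uniformly sampled columns.
#' @return The state, invisibly.
#' @export
inoculate <- function(state, resistant_fraction = NULL, founders_per_node = NULL) {
  p <- state$p
  f <- resistant_fraction %||% p$sim$resistant_fraction
  k <- founders_per_node %||% p$sim$founders_per_node
  stopifnot(f >= 0, f <= 1, k > 0)
  s_id <- which(!p$strains$resistant)[1]
  r_id <- which(p$strains$resistant)[1]
  if (f > 0 && is.na(r_id)) stop("no resistant strain configured", call. = FALSE)
  if (f < 1 && is.na(s_id)) stop("no susceptible strain configured", call. = FALSE)
  if (k == round(k)) {
    n <- p$nx * as.integer(k)
    nodes <- rep(seq_len(p$nx), k)   # bottom row: linear index = x
  } else {
    n <- max(1L, as.integer(round(p$nx * k)))
    nodes <- if (k < 1) sample.int(p$nx, n) else
      sample.int(p$nx, n, replace = TRUE)
  }
  if (identical(p$sim$inoculum_assignment, "ratio")) {
    # fix the inoculum composition at the requested ratio: exactly
    # round(n * f) resistant founders in random positions
    n_res <- as.integer(round(n * f))
    if (f > 0 && n_res == 0L) n_res <- 1L
    resistant <- rep(FALSE, n)
    if (n_res > 0L) resistant[sample.int(n, n_res)] <- TRUE
  } else {
    resistant <- runif(n) < f
  }
  state$b_node <- c(state$b_node, as.integer(nodes))
  state$b_strain <- c(state$b_strain, ifelse(resistant, r_id, s_id))
  state$b_mass <- c(state$b_mass, rep(p$m_s, n))
  state$b_inf <- c(state$b_inf, rep(FALSE, n))
  state$b_tinf <- c(state$b_tinf, rep(NA_real_, n))
  state$b_halt <- c(state$b_halt, rep(FALSE, n))
  state$f_inoculum <- resistant_frequency(state)
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resistant-strain frequency
#'
#' Live resistant cells over all live cells (infected cells count as live
#' members of their strain until lysis). `NA` when the population is empty.
#'
#' @param state a `sim_state`.
#' @export
resistant_frequency <- function(state) {
  n <- length(state$b_node)
  if (n == 0) return(NA_real_)
  sum(state$p$strains$resistant[state$b_strain]) / n
}

#' Trigger a phage pulse when the biofilm is tall enough
#'
#' Fires once the global front height reaches the configured threshold
#' (and keeps firing on consecutive iterations for
#' `pulse$duration_iterations`, which may be `Inf` for continuous
#' exposure). `POINT` mode releases `pulse$count` virions in the single
#' highest node containing susceptible biomass (an individual host cell
#' bursting); if no susceptible biomass exists anywhere the highest
#' biomass node is used. `SPRAY` mode scatters `pulse$count` virions over
#' uniformly random columns, each 9 um above that column's front. The time
#' of the first pulse is recorded as the infection time, together with the
#' resistant frequency at that moment.
#'
#' @param state a `sim_state`.
#' @return Number of virions added this call, invisibly.
#' @export
maybe_trigger_pulse <- function(state) {
  p <- state$p
  pu <- p$pulse
  if (!isTRUE(pu$enabled)) return(invisible(0L))
  started <- !is.na(state$infection_time)
  if (!started) {
    fr <- front_height(state)
    if (fr$max < pu$height_threshold_um) return(invisible(0L))
    state$infection_time <- state$time_h
    state$f_before <- resistant_frequency(state)
  } else if (state$pulse_iters_done >= pu$duration_iterations) {
    return(invisible(0L))
  }
  state$pulse_iters_done <- state$pulse_iters_done + 1L

  if (pu$mode == "POINT") {
    sus <- !p$strains$resistant[state$b_strain]
    nodes <- state$b_node[sus]
    if (length(nodes) == 0) nodes <- state$b_node  # fallback: highest biomass
    if (length(nodes) == 0) return(invisible(0L))
    ys <- (nodes - 1L) %/% p$nx
    top <- nodes[ys == max(ys)]
    nd <- if (length(top) == 1) top else sample(top, 1)
    x0 <- (nd - 1L) %% p$nx
    y0 <- (nd - 1L) %/% p$nx
    xs <- rep(as.integer(x0), pu$count)
    ys_new <- rep(as.integer(y0), pu$count)
  } else {  # SPRAY: 9 um above each chosen column's local front
    rows_above <- as.integer(round(9 / p$dl))
    fr_rows <- front_rows(occupancy_matrix(state))
    xs <- sample.int(p$nx, pu$count, replace = TRUE) - 1L
    ys_new <- as.integer(pmin(fr_rows[xs + 1L] + rows_above, state$ny_ext - 1L))
  }
  state$ph_x <- c(state$ph_x, xs)
  state$ph_y <- c(state$ph_y, ys_new)
  state$ph_z <- c(state$ph_z, rep(0L, pu$count))
  state$ph_stopped <- c(state$ph_stopped, rep(FALSE, pu$count))
  state$ph_s <- c(state$ph_s, rep(0L, pu$count))
  state$pending_pulsed <- state$pending_pulsed + as.integer(pu$count)
  invisible(as.integer(pu$count))
}

zero_counters <- function() {
  list(growth_mass = 0, divisions = 0L, bursts = 0L, lysed_mass = 0,
       eroded = 0L, eroded_mass = 0, detached = 0L, detached_mass = 0,
       infections = 0L, superinfections = 0L, aborted = 0L, aborted_mass = 0,
       neutralized = 0L, halted = 0L, phage_advected = 0L, phage_swept = 0L,
       pulsed = 0L)
}

#' Advance the simulation by one iteration
#'
#' Executes the nine-stage cycle in its fixed order: (1) nutrient
#' diffusion, (2) biomass growth and division, (3) lysis of infected
#' bacteria and phage burst, (4) erosion of biomass, (5) phage movement,
#' (6) detachment of biomass, (7) phage infection, (8) biofilm relaxation
#' (shoving), (9) detachment of bacteriophage. Advances time by `dt` and
#' appends a tally row auditing every source of population change.
#'
#' @param state a `sim_state`.
#' @param stage_hook optional `function(stage_name)` called before each
#'   stage, in order (used for instrumentation).
#' @return The state, invisibly.
#' @export
iterate <- function(state, stage_hook = NULL) {
  state$counters <- zero_counters()
  # phage pulses are events fired between iterations; their additions are
  # booked here against the pre-pulse baseline
  state$counters[["pulsed"]] <- state$pending_pulsed
  state$pending_pulsed <- 0L
  mass0 <- sum(state$b_mass)
  ncell0 <- length(state$b_node)
  nph0 <- length(state$ph_x) - state$counters[["pulsed"]]
  stages <- list(
    nutrient_diffusion = stage_nutrients,
    growth_division = stage_growth,
    lysis_burst = stage_lysis,
    erosion = stage_erosion,
    phage_movement = stage_phage_movement,
    biomass_detachment = stage_detachment,
    phage_infection = stage_phage_infection,
    shoving = stage_shoving,
    phage_detachment = stage_phage_sweep
  )
  for (nm in names(stages)) {
    if (!is.null(stage_hook)) stage_hook(nm)
    stages[[nm]](state)
  }
  state$iter <- state$iter + 1L
  state$time_h <- state$time_h + state$p$dt_h
  state$peak_phage <- max(state$peak_phage, length(state$ph_x))
  record_tally(state, mass0, ncell0, nph0)
  invisible(state)
}

record_tally <- function(state, mass0, ncell0, nph0) {
  p <- state$p
  cc <- state$counters
  res <- p$strains$resistant[state$b_strain]
  row <- c(
    iter = state$iter, time_h = state$time_h,
    n_susceptible = sum(!res & !state$b_inf),
    n_infected = sum(state$b_inf),
    n_resistant = sum(res),
    n_phage = length(state$ph_x),
    front_um = front_height(state)$max,
    biomass_g = sum(state$b_mass),
    mass_prev_g = mass0, n_cells_prev = ncell0, n_phage_prev = nph0,
    unlist(cc[names(zero_counters())])
  )
  state$tallies[[length(state$tallies) + 1L]] <- row
  invisible(state)
}

#' Exit-condition check
#'
#' Fixation: one strain's live count is zero while the other's is
#' positive. Timeout: the infection time is set and the clock has reached
#' infection time + the configured endpoint. `EXTINCT` flags the (rare)
#' loss of the whole population.
#'
#' @param state a `sim_state`.
#' @return One of `"CONTINUE"`, `"FIXATION_SUSCEPTIBLE"`,
#'   `"FIXATION_RESISTANT"`, `"TIMEOUT"`, `"EXTINCT"`.
#' @export
check_exit <- function(state) {
  p <- state$p
  res <- p$strains$resistant[state$b_strain]
  n_r <- sum(res)
  n_s <- length(res) - n_r
  if (n_r == 0L && n_s == 0L) return("EXTINCT")
  if (n_r == 0L) return("FIXATION_SUSCEPTIBLE")
  if (n_s == 0L) return("FIXATION_RESISTANT")
  if (!is.na(state$infection_time) &&
      state$time_h >= state$infection_time +
        p$sim$endpoint_days_after_infection * 24 - 1e-9) {
    return("TIMEOUT")
  }
  "CONTINUE"
}

#' Run one replicate simulation
#'
#' Seeds the RNG, inoculates the substratum, then loops the nine-stage
#' cycle with pulse triggering and exit checks until fixation, the
#' post-infection endpoint, or the hard cap `sim$max_days` (exit status
#' `MAX_TIME`; this is how no-phage control runs end). Fully reproducible
#' from `sim$seed`.
#'
#' @param config a `phagefilm_config`; see [sim_config()].
#' @param stage_hook optional instrumentation hook passed to [iterate()].
#' @return An object of class `biofilm_sim` with elements `timeseries`
#'   (tibble, one row per iteration), `record` (one-row tibble of
#'   replicate-level outcomes), `config`, and `final` (the end state).
#' @examples
#' \donttest{
#' cfg <- sim_config(space = list(x_max_um = 90, y_max_um = 45),
#'                   sim = list(max_days = 0.25),
#'                   pulse = list(enabled = FALSE))
#' sim <- run_simulation(cfg)
#' glance(sim)
#' }
#' @export
run_simulation <- function(config, stage_hook = NULL) {
  p <- build_params(config)
  set.seed(p$sim$seed)
  state <- new_sim_state(p)
  inoculate(state)
  iter_cap <- ceiling(p$sim$max_days * 24 / p$dt_h)
  status <- "CONTINUE"
  while (TRUE) {
    maybe_trigger_pulse(state)
    iterate(state, stage_hook = stage_hook)
    status <- check_exit(state)
    if (status != "CONTINUE") break
    if (state$iter >= iter_cap) {
      status <- "MAX_TIME"
      break
    }
  }
  ts <- tibble::as_tibble(do.call(rbind, state$tallies))
  record <- tibble::tibble(
    seed = p$sim$seed,
    f_inoculum = state$f_inoculum,
    f_before = state$f_before,
    f_after = resistant_frequency(state),
    peak_phage = state$peak_phage,
    exit_status = status,
    infection_time_h = state$infection_time,
    t_end_h = state$time_h,
    n_iterations = state$iter
  )
  structure(list(timeseries = ts, record = record, config = config,
                 final = state),
            class = "biofilm_sim")
}

#' @export
print.biofilm_sim <- function(x, ...) {
  r <- x$record
  cat("<biofilm_sim> ", r$n_iterations, " iterations (",
      signif(r$t_end_h / 24, 3), " d), exit: ", r$exit_status, "\n", sep = "")
  cat("  resistant frequency: ", signif(r$f_inoculum, 3), " (inoculum) -> ",
      signif(r$f_after, 3), " (end); peak phage count ", r$peak_phage,
      "\n", sep = "")
  invisible(x)
}

#' Per-node snapshot of a simulation state
#'
#' Tabulates the current contents of every occupied or phage-holding node:
#' per-strain cell counts, infected count, phage count and the local
#' nutrient concentration.
#'
#' @param x a `sim_state` or a finished `biofilm_sim` (its end state).
#' @return Tibble with columns `x_idx`, `y_idx` (0-based node coordinates),
#'   one `n_<strain>` column per strain, `n_infected`, `n_phage` and
#'   `nutrient_mg_l`.
#' @export
sim_snapshot <- function(x) {
  state <- if (inherits(x, "biofilm_sim")) x$final else x
  p <- state$p
  nodes <- sort(unique(c(
    state$b_node,
    state$ph_x[state$ph_y < p$ny] + p$nx * state$ph_y[state$ph_y < p$ny] + 1L
  )))
  if (length(nodes) == 0) {
    return(tibble::tibble(x_idx = integer(0), y_idx = integer(0)))
  }
  out <- tibble::tibble(
    x_idx = (nodes - 1L) %% p$nx,
    y_idx = (nodes - 1L) %/% p$nx
  )
  for (s in seq_len(nrow(p$strains))) {
    sel <- state$b_strain == s & !state$b_inf
    cnt <- integer(length(nodes))
    if (any(sel)) {
      agg <- rowsum(rep(1L, sum(sel)), state$b_node[sel])
      cnt[match(as.integer(rownames(agg)), nodes)] <- agg
    }
    out[[paste0("n_", p$strains$id[s])]] <- cnt
  }
  inf_cnt <- integer(length(nodes))
  if (any(state$b_inf)) {
    agg <- rowsum(rep(1L, sum(state$b_inf)), state$b_node[state$b_inf])
    inf_cnt[match(as.integer(rownames(agg)), nodes)] <- agg
  }
  out$n_infected <- inf_cnt
  ph_cnt <- integer(length(nodes))
  inside <- state$ph_y < p$ny
  if (any(inside)) {
    pn <- state$ph_x[inside] + p$nx * state$ph_y[inside] + 1L
    agg <- rowsum(rep(1L, length(pn)), pn)
    ph_cnt[match(as.integer(rownames(agg)), nodes)] <- agg
  }
  out$n_phage <- ph_cnt
  out$nutrient_mg_l <- state$N[nodes]
  out
}
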