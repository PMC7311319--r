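#' Simulation configuration
#'
#' Builds the full configuration for a phage-biofilm simulation as a nested
#' list. Defaults correspond to experimentally constrained values for
#' *E. coli* and lytic phage T7 growing as a 2D biofilm cross-section;
#' any subset of keys may be overridden by passing nested lists for the
#' sections `space`, `nutrient`, `bacteria`, `phage`, `strains`, `sim` and
#' `pulse`. Unknown sections or keys are errors.
#'
#' Key units (suffix-encoded): lengths in micrometres (`_um`), diffusivities
#' in cm^2 s^-1, concentrations in mg litre^-1, masses in grams, rates per
#' hour/day as named. `bacteria$mu_s_per_day = NULL` derives the maximum
#' specific growth rate from the uptake rate and yield as
#' `q_max * Y` (g substrate per g biomass per day times yield).
#'
#' The two default strains are a phage-susceptible wild type and an
#' abortive-infection resistant mutant (phage adsorbs, both host and phage
#' are neutralized) carrying a 5% growth-rate cost. Resistance modes:
#' `"SUSCEPTIBLE"`, `"ABORTIVE"`, `"SURFACE"` (adsorption-deficient;
#' phage and host both unharmed by contact) and `"PHAGE_NEUTRALIZING"`
#' (phage consumed, host unharmed).
#'
#' Three phage-section switches select between defensible readings of the
#' infection bookkeeping (see the methods vignette): `dtr_convention`
#' (`"printed"`: residual time `dt*s/n`; `"complement"`: `dt*(n-s)/n`),
#' `infection_attempts` (`"once"` at adsorption, or `"per_iteration"`
#' retries), and `interaction_normalization` (`"per_node_volume"` or
#' `"per_cell"`). The sim section's `inoculum_assignment` chooses between
#' `"binomial"` founder strain assignment and an exact `"ratio"`
#' composition; `founders_per_node` may be fractional (sparse scattered
#' founders).
#'
#' @param space,nutrient,bacteria,phage,strains,sim,pulse named lists of
#'   overrides for the corresponding section.
#' @return A nested list of class `phagefilm_config`.
#' @examples
#' cfg <- sim_config(nutrient = list(N_max_mg_per_l = 4))
#' cfg$nutrient$N_max_mg_per_l
#' @export
sim_config <- function(space = list(), nutrient = list(), bacteria = list(),
                       phage = list(), strains = NULL, sim = list(),
                       pulse = list()) {
  cfg <- default_config()
  over <- list(space = space, nutrient = nutrient, bacteria = bacteria,
               phage = phage, sim = sim, pulse = pulse)
  for (sec in names(over)) {
    cfg[[sec]] <- merge_section(cfg[[sec]], over[[sec]], sec)
  }
  if (!is.null(strains)) {
    cfg$strains <- lapply(strains, function(s) {
      merge_section(default_strain(), s, "strains")
    })
    if (is.null(names(cfg$strains)) || any(names(cfg$strains) == "")) {
      stop("every strain must be named", call. = FALSE)
    }
  }
  class(cfg) <- "phagefilm_config"
  cfg
}

default_strain <- function() {
  list(resistance_mode = "SUSCEPTIBLE", cost_c = 0,
       interaction_rate_I = 0.09, halt_on_contact = FALSE)
}

default_config <- function() {
  list(
    space = list(x_max_um = 900, y_max_um = 150, z_max_um = NULL, dl_um = 3),
    nutrient = list(N_max_mg_per_l = 4, D_N_cm2_per_s = 2.3e-6, h_um = 15,
                    K_N_mg_per_l = 1.18, Y = 0.495, q_max_g_per_g_day = 28.5),
    bacteria = list(m_s_g = 1e-12, mu_s_per_day = NULL, S_max_g_per_l = 200,
                    delta_E_per_m_h = 20),
    phage = list(D_P_cm2_per_s = 3.82e-7, delta_P_per_um2_h = 0.1,
                 gamma_per_h = 2.92, tau_min = 28.8, beta = 120,
                 dtr_convention = "printed",
                 infection_attempts = "once",
                 interaction_normalization = "per_node_volume"),
    strains = list(
      susceptible = list(resistance_mode = "SUSCEPTIBLE", cost_c = 0,
                         interaction_rate_I = 0.09, halt_on_contact = FALSE),
      resistant = list(resistance_mode = "ABORTIVE", cost_c = 0.05,
                       interaction_rate_I = 0.09, halt_on_contact = FALSE)
    ),
    sim = list(dt_min = 7.5, seed = 1, endpoint_days_after_infection = 10,
               max_days = 30, founders_per_node = 1, resistant_fraction = 0.5,
               inoculum_assignment = "binomial"),
    pulse = list(enabled = TRUE, mode = "POINT", count = 120,
                 height_threshold_um = 30, duration_iterations = 1)
  )
}

merge_section <- function(base, over, section) {
  if (length(over) == 0) return(base)
  if (is.null(names(over)) || any(names(over) == "")) {
    stop("all entries in section '", section, "' must be named", call. = FALSE)
  }
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in '", section, "': ",
         paste0(section, ".", unknown, collapse = ", "), call. = FALSE)
  }
  base[names(over)] <- over
  base
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds the same nested sections as [sim_config()]; missing keys
#' take their defaults, unknown keys are errors.
#'
#' @param path path to a YAML configuration file.
#' @return A `phagefilm_config` list.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("space", "nutrient", "bacteria", "phage", "strains", "sim", "pulse")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw[intersect(names(raw), known)])
}

resistance_modes <- c("SUSCEPTIBLE", "ABORTIVE", "SURFACE", "PHAGE_NEUTRALIZING")

#' Normalize a configuration into simulation parameters
#'
#' Validates the configuration and converts every quantity to the internal
#' unit system (micrometres, hours, grams, mg litre^-1). Enforces the model
#' consistency constraint that the maximum growth rate equals the product of
#' the maximum substrate uptake rate and the yield, mu_s = q_max * Y
#' (within 0.05 day^-1 when mu_s is given explicitly), and that the domain
#' dimensions are integer multiples of the node edge length.
#'
#' @param config a `phagefilm_config` list from [sim_config()].
#' @return An object of class `sim_params`: a flat list of normalized
#'   parameters (see Details in the package vignette).
#' @examples
#' p <- build_params(sim_config())
#' p$n_steps    # potential walk steps per iteration
#' p$p_stay     # in-node stay probability per step
#' @export
build_params <- function(config) {
  stopifnot(inherits(config, "phagefilm_config") || is.list(config))
  sp <- config$space; nu <- config$nutrient; ba <- config$bacteria
  ph <- config$phage; si <- config$sim; pu <- config$pulse

  dl <- sp$dl_um
  if (!is.numeric(dl) || dl <= 0) stop("space.dl_um must be positive", call. = FALSE)
  for (fld in c("x_max_um", "y_max_um")) {
    check_divisible(sp[[fld]], dl, paste0("space.", fld))
  }
  three_d <- !is.null(sp$z_max_um)
  if (three_d) check_divisible(sp$z_max_um, dl, "space.z_max_um")
  nx <- as.integer(round(sp$x_max_um / dl))
  ny <- as.integer(round(sp$y_max_um / dl))
  nz <- if (three_d) as.integer(round(sp$z_max_um / dl)) else 1L
  dim <- if (three_d) 3L else 2L
  a <- if (three_d) 4 else 1

  # nutrient block
  for (fld in names(nu)) {
    if (!is.numeric(nu[[fld]]) || nu[[fld]] <= 0) {
      stop("nutrient.", fld, " must be positive", call. = FALSE)
    }
  }
  q_day <- nu$q_max_g_per_g_day
  mu_day <- ba$mu_s_per_day
  if (is.null(mu_day)) {
    mu_day <- q_day * nu$Y
  } else if (abs(q_day * nu$Y - mu_day) > 0.05) {
    stop("inconsistent growth parameters: q_max * Y = ",
         signif(q_day * nu$Y, 6), " day^-1 but bacteria.mu_s_per_day = ",
         mu_day, " (must agree, mu = q * Y)", call. = FALSE)
  }

  strains <- config$strains
  modes <- vapply(strains, function(s) s$resistance_mode, character(1))
  if (!all(modes %in% resistance_modes)) {
    stop("unknown resistance_mode: ",
         paste(setdiff(modes, resistance_modes), collapse = ", "), call. = FALSE)
  }
  costs <- vapply(strains, function(s) s$cost_c, numeric(1))
  if (any(costs < 0 | costs >= 1)) stop("strain cost_c must be in [0, 1)", call. = FALSE)
  Is <- vapply(strains, function(s) s$interaction_rate_I, numeric(1))
  if (any(Is < 0)) stop("strain interaction_rate_I must be >= 0", call. = FALSE)
  strain_tab <- data.frame(
    id = names(strains), mode = unname(modes), cost = unname(costs),
    I = unname(Is),
    halt = vapply(strains, function(s) isTRUE(s$halt_on_contact), logical(1)),
    stringsAsFactors = FALSE
  )
  strain_tab$resistant <- strain_tab$mode != "SUSCEPTIBLE"

  if (ph$beta < 1 || ph$beta != round(ph$beta)) {
    stop("phage.beta must be a positive integer", call. = FALSE)
  }
  if (!ph$dtr_convention %in% c("printed", "complement")) {
    stop("phage.dtr_convention must be 'printed' or 'complement'", call. = FALSE)
  }
  if (!ph$interaction_normalization %in% c("per_cell", "per_node_volume")) {
    stop("phage.interaction_normalization must be 'per_cell' or 'per_node_volume'",
         call. = FALSE)
  }
  if (!ph$infection_attempts %in% c("once", "per_iteration")) {
    stop("phage.infection_attempts must be 'once' or 'per_iteration'",
         call. = FALSE)
  }
  if (si$dt_min <= 0) stop("sim.dt_min must be positive", call. = FALSE)
  if (pu$count < 1) stop("pulse.count must be positive", call. = FALSE)
  if (pu$height_threshold_um <= 0) stop("pulse.height_threshold_um must be positive", call. = FALSE)
  if (!pu$mode %in% c("POINT", "SPRAY")) stop("pulse.mode must be POINT or SPRAY", call. = FALSE)

  dt_h <- si$dt_min / 60
  dt_s <- si$dt_min * 60
  D_P_um2_s <- ph$D_P_cm2_per_s * 1e8             # cm^2/s -> um^2/s
  n_steps <- steps_per_iteration(D_P_um2_s, dt_s, dl)
  dtp_s <- if (D_P_um2_s > 0) step_time(D_P_um2_s, dl) else 0

  p <- list(
    # geometry
    dl = dl, nx = nx, ny = ny, nz = nz, dim = dim, a = a, dV = dl^3,
    n_virtual_rows = as.integer(ceiling(30 / dl)),
    # time
    dt_h = dt_h, dt_s = dt_s,
    # nutrients (um, h, mg/L)
    N_max = nu$N_max_mg_per_l, K_N = nu$K_N_mg_per_l, Y = nu$Y,
    D_N_um2_h = nu$D_N_cm2_per_s * 1e8 * 3600, h_um = nu$h_um,
    q_max_h = q_day / 24,
    # bacteria
    m_s = ba$m_s_g, mu_s_h = mu_day / 24,
    cap_node = ba$S_max_g_per_l * 1e-15 * dl^3,   # g per node
    delta_E_per_m_h_raw = ba$delta_E_per_m_h,
    delta_E_um = ba$delta_E_per_m_h * 1e-6,       # speed (um/h) = this * y_um^2
    # phage
    D_P_um2_s = D_P_um2_s, n_steps = n_steps, dtp_s = dtp_s,
    dtp_h = dtp_s / 3600, p_stay = stay_probability(a),
    delta_P = ph$delta_P_per_um2_h, gamma_h = ph$gamma_per_h,
    tau_h = ph$tau_min / 60, beta = as.integer(ph$beta),
    dtr_complement = identical(ph$dtr_convention, "complement"),
    attempt_once = identical(ph$infection_attempts, "once"),
    ix_per_cell = identical(ph$interaction_normalization, "per_cell"),
    # strains / events
    strains = strain_tab,
    pulse = pu,
    sim = si
  )
  class(p) <- "sim_params"
  p
}

check_divisible <- function(value, dl, field) {
  if (is.null(value) || !is.numeric(value) || value <= 0) {
    stop(field, " must be a positive length", call. = FALSE)
  }
  k <- value / dl
  if (abs(k - round(k)) > 1e-9 || round(k) < 1) {
    stop(field, " (", value, ") is not a positive integer multiple of dl_um (",
         dl, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> ", x$nx, "x", x$ny,
      if (x$dim == 3L) paste0("x", x$nz), " nodes (dl = ", x$dl, " um, ",
      x$dim, "D)\n", sep = "")
  cat("  dt = ", x$dt_h * 60, " min; walk: n = ", x$n_steps,
      " steps of ", signif(x$dtp_s, 4), " s, p_stay = ",
      signif(x$p_stay, 3), "\n", sep = "")
  cat("  strains: ", paste0(x$strains$id, " (", x$strains$mode, ", c=",
                            x$strains$cost, ")", collapse = ", "), "\n", sep = "")
  invisible(x)
}
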