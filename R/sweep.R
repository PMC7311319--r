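#' Define a parameter sweep
#'
#' Factorial sweep over bulk nutrient concentration, initial resistant
#' frequency, resistance cost, phage-biomass interaction rate and phage
#' removal rate, with `replicates` seeded runs per cell. The full
#' published-scale experiment is 21 nutrient values (1.1-8 mg/L) crossed
#' with 21 initial frequencies (1%-99%) at ~100 replicates; the default
#' here is a desk-scale 5 x 5 x 10 sweep.
#'
#' @param nutrient_values bulk substrate concentrations (mg litre^-1).
#' @param initial_frequencies initial resistant fractions, in (0, 1).
#' @param cost_levels resistance fitness costs (fraction of max growth rate).
#' @param interaction_levels phage-biomass interaction rates
#'   ((m_s um^3)^-1 s^-1).
#' @param removal_levels phage removal rates ((um^2 h)^-1).
#' @param replicates replicate runs per parameter combination.
#' @param base_seed base RNG seed; replicate seeds are derived injectively.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(nutrient_values = seq(1.1, 8, length.out = 5),
                       initial_frequencies = seq(0.05, 0.95, length.out = 5),
                       cost_levels = 0.05,
                       interaction_levels = 0.09,
                       removal_levels = 0.1,
                       replicates = 10,
                       base_seed = 1L) {
  stopifnot(length(nutrient_values) > 0, length(initial_frequencies) > 0,
            length(cost_levels) > 0, length(interaction_levels) > 0,
            length(removal_levels) > 0, replicates >= 1,
            all(initial_frequencies > 0), all(initial_frequencies < 1))
  structure(list(nutrient_values = nutrient_values,
                 initial_frequencies = initial_frequencies,
                 cost_levels = cost_levels,
                 interaction_levels = interaction_levels,
                 removal_levels = removal_levels,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "sweep_spec")
}

#' Replicate retention rule
#'
#' A replicate is retained only if its peak phage count exceeded 150,
#' i.e. the 120-virion pulse amplified at least once; runs in which the
#' pulse caused zero infections are trimmed from heatmap means (a peak of
#' exactly 150 is trimmed: strict inequality).
#'
#' @param record one-row replicate record (needs column `peak_phage`), or a
#'   `biofilm_sim`.
#' @param threshold phage-count threshold (default 150).
#' @return `TRUE` to keep the replicate.
#' @export
trim_replicate <- function(record, threshold = 150) {
  if (inherits(record, "biofilm_sim")) record <- record$record
  record$peak_phage > threshold
}

#' Change in resistant frequency across phage exposure
#'
#' `delta_f = f_after - f_before`, where frequencies are resistant live
#' cells over all live cells. The baseline is the moment of the first
#' phage pulse (`"pulse"`, the default, isolating the effect of exposure
#' from pre-pulse drift) or inoculation (`"inoculum"`).
#'
#' @param record one-row replicate record or a `biofilm_sim`.
#' @param baseline `"pulse"` or `"inoculum"`.
#' @return Numeric `delta_f` in `[-1, 1]`; `NA` if either frequency is
#'   undefined (empty population).
#' @export
frequency_change <- function(record, baseline = c("pulse", "inoculum")) {
  baseline <- match.arg(baseline)
  if (inherits(record, "biofilm_sim")) record <- record$record
  f0 <- if (baseline == "pulse") record$f_before else record$f_inoculum
  record$f_after - f0
}

#' Run a parameter sweep
#'
#' Executes `run_simulation()` for every sweep cell and replicate
#' (sequentially, deterministic given `base_seed`: replicate `r` of cell
#' `k` uses seed `base_seed + (k - 1) * replicates + (r - 1)`, which is
#' injective over the sweep). Per-cell means of the frequency change are
#' aggregated over retained replicates only.
#'
#' @param spec a [sweep_spec()].
#' @param base_config configuration whose non-swept entries are shared by
#'   all runs.
#' @return Object of class `biofilm_sweep`: `replicates` (tibble, one row
#'   per run) and `heatmap` (tibble, one row per cell with `mean_df` and
#'   `n_retained`).
#' @export
run_sweep <- function(spec, base_config = sim_config()) {
  stopifnot(inherits(spec, "sweep_spec"))
  cells <- tidyr::expand_grid(
    nutrient = spec$nutrient_values,
    f0 = spec$initial_frequencies,
    cost = spec$cost_levels,
    interaction = spec$interaction_levels,
    removal = spec$removal_levels
  )
  reps <- spec$replicates
  rows <- purrr::pmap(
    dplyr::mutate(cells, .cell = dplyr::row_number()),
    function(nutrient, f0, cost, interaction, removal, .cell) {
      purrr::map(seq_len(reps), function(r) {
        seed <- spec$base_seed + (.cell - 1L) * reps + (r - 1L)
        cfg <- sweep_cell_config(base_config, nutrient, f0, cost,
                                 interaction, removal, seed)
        sim <- tryCatch(run_simulation(cfg), error = function(e) e)
        if (inherits(sim, "error")) {
          warning("replicate failed (cell ", .cell, ", seed ", seed, "): ",
                  conditionMessage(sim), call. = FALSE)
          return(NULL)
        }
        dplyr::bind_cols(
          tibble::tibble(nutrient = nutrient, f0 = f0, cost = cost,
                         interaction = interaction, removal = removal,
                         replicate = r),
          sim$record
        )
      })
    }
  )
  replicates <- dplyr::bind_rows(purrr::flatten(rows))
  replicates <- dplyr::mutate(
    replicates,
    delta_f = .data$f_after - .data$f_before,
    delta_f_inoculum = .data$f_after - .data$f_inoculum,
    retained = .data$peak_phage > 150
  )
  heatmap <- replicates |>
    dplyr::group_by(.data$nutrient, .data$f0, .data$cost, .data$interaction,
                    .data$removal) |>
    dplyr::summarise(
      mean_df = mean(.data$delta_f[.data$retained], na.rm = TRUE),
      n_retained = sum(.data$retained & !is.na(.data$delta_f)),
      .groups = "drop"
    )
  structure(list(replicates = replicates, heatmap = heatmap, spec = spec),
            class = "biofilm_sweep")
}

sweep_cell_config <- function(base, nutrient, f0, cost, interaction, removal,
                              seed) {
  strains <- base$strains
  for (id in names(strains)) {
    strains[[id]]$interaction_rate_I <- interaction
    if (strains[[id]]$resistance_mode != "SUSCEPTIBLE") {
      strains[[id]]$cost_c <- cost
    }
  }
  sim_config(
    space = base$space,
    nutrient = utils::modifyList(base$nutrient,
                                 list(N_max_mg_per_l = nutrient)),
    bacteria = base$bacteria,
    phage = utils::modifyList(base$phage,
                              list(delta_P_per_um2_h = removal)),
    strains = strains,
    sim = utils::modifyList(base$sim,
                            list(seed = as.integer(seed),
                                 resistant_fraction = f0)),
    pulse = base$pulse
  )
}

#' Classify per-cell selection on resistance
#'
#' Labels each heatmap cell by the sign of the mean frequency change with
#' a neutrality band: `POSITIVE` if `mean_df > epsilon`, `NEGATIVE` if
#' `mean_df < -epsilon`, else `NEUTRAL`. Resistant cells increasing when
#' rare but decreasing when common across cells is the signature of
#' negative frequency-dependent selection (coexistence).
#'
#' @param heatmap heatmap tibble from [run_sweep()], or a `biofilm_sweep`.
#' @param epsilon half-width of the neutrality band.
#' @return The heatmap with an added `selection` column.
#' @export
classify_selection <- function(heatmap, epsilon = 0.02) {
  if (inherits(heatmap, "biofilm_sweep")) heatmap <- heatmap$heatmap
  dplyr::mutate(
    heatmap,
    selection = dplyr::case_when(
      is.nan(.data$mean_df) | is.na(.data$mean_df) ~ NA_character_,
      .data$mean_df > epsilon ~ "POSITIVE",
      .data$mean_df < -epsilon ~ "NEGATIVE",
      TRUE ~ "NEUTRAL"
    )
  )
}

#' @export
print.biofilm_sweep <- function(x, ...) {
  cat("<biofilm_sweep> ", nrow(x$heatmap), " cells x ", x$spec$replicates,
      " replicates (", nrow(x$replicates), " runs, ",
      sum(x$replicates$retained), " retained)\n", sep = "")
  invisible(x)
}
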