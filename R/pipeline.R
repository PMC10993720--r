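# End-to-end orchestration: synthetic generation -> g_min estimation ->
# temperature-response fitting -> trait correlations -> canopy transpiration
# scenarios, with every table written to a run directory alongside seed and
# config provenance.

#' Default pipeline configuration
#'
#' @param out_dir Run directory to create (tables, logs, metadata).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param n_trees,n_leaves Trees per species and leaves per tree to
#'   simulate in the drydown stage.
#' @param balance_sd Balance noise, g.
#' @param rwc_window RWC window for plateau estimation.
#' @param chamber_pressure Growth-chamber pressure, kPa.
#' @param site_pressure Site pressure for canopy simulation, kPa.
#' @param t_min,t_max Diurnal temperature range of the simulated day.
#' @param rh_at_tmax Daily minimum relative humidity, percent.
#' @param temp_b Exponential temperature-response rate (per degree C) used
#'   to generate synthetic temperature observations.
#' @param sweep_step,sweep_cap Elevation sweep increment and maximum
#'   temperature, degrees C.
#' @param report_temps Scenario maximum temperatures picked out for the
#'   wide report table.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("leafgmin-run-"),
                       seed = 1L,
                       n_trees = 2, n_leaves = 2,
                       balance_sd = 2e-4,
                       rwc_window = c(0.50, 0.80),
                       chamber_pressure = 98.0,
                       site_pressure = 94.9,
                       t_min = 18, t_max = 32.2, rh_at_tmax = 29.4,
                       temp_b = 0.05,
                       sweep_step = 0.1, sweep_cap = 50,
                       report_temps = c(32.2, 35, 40)) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates drydown experiments for each reference species (true g_min
#' taken from the site species table), recovers g_min per leaf and
#' aggregates leaf -> tree -> species -> functional group; generates and
#' fits per-species temperature responses; generates a trait table and its
#' correlations; simulates the hot-day climate and runs the
#' temperature-elevation sweep per species. All stage outputs are written
#' as CSV into `config$out_dir`, plus `metadata.json` (seed, package
#' version, config hash) and `log.txt` with per-stage timing. Identical
#' config and seed give byte-identical numeric tables.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "log.txt")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    logf("stage %s done (%.1fs)", name, proc.time()[["elapsed"]] - t0)
    res
  }
  species <- sccii_species_table()
  emin_ref <- sccii_emin_table()

  # --- drydown simulation + estimation -------------------------------------
  drydown <- stage("drydown", {
    rows <- list()
    est <- list()
    k <- 0L
    for (i in seq_len(nrow(species))) {
      for (tr in seq_len(cfg$n_trees)) {
        for (lf in seq_len(cfg$n_leaves)) {
          k <- k + 1L
          # leaf water pool scaled with conductance so every species
          # traverses the same RWC range over the 30 h drydown
          p <- drydown_sim_params(
            true_gmin = species$gmin[i],
            w_sat = 0.10 + 0.09 * species$gmin[i],
            balance_sd = cfg$balance_sd,
            chamber = air_state(20, 69, cfg$chamber_pressure),
            seed = cfg$seed * 10000L + k)
          rec <- simulate_drydown(p)
          rec$species <- species$species[i]
          rec$tree_id <- sprintf("%s-t%d", species$species[i], tr)
          rec$sample_id <- sprintf("%s-t%d-l%d", species$species[i], tr, lf)
          e <- estimate_gmin(conductance_curve(rec), window = cfg$rwc_window)
          fg_i <- species$functional_group[i]
          true_i <- species$gmin[i]
          rows[[k]] <- tibble::tibble(
            sample_id = rec$sample_id, species = rec$species,
            tree_id = rec$tree_id, functional_group = fg_i,
            true_gmin = true_i, gmin = e$gmin,
            n_intervals = e$n_intervals_used,
            plateau_slope = e$plateau_slope)
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  utils::write.csv(drydown, file.path(cfg$out_dir, "gmin_estimates.csv"),
                   row.names = FALSE)

  agg <- stage("aggregate", aggregate_gmin(drydown))
  utils::write.csv(agg$by_species,
                   file.path(cfg$out_dir, "gmin_by_species.csv"),
                   row.names = FALSE)
  utils::write.csv(agg$by_group,
                   file.path(cfg$out_dir, "gmin_by_group.csv"),
                   row.names = FALSE)

  # --- temperature response -------------------------------------------------
  temp_fits <- stage("temp_response", {
    fits <- lapply(seq_len(nrow(species)), function(i) {
      # synthetic observations anchored so the fit passes through the
      # species' measured g_min at 25 degC
      a_i <- species$gmin[i] / exp(cfg$temp_b * 25)
      restore <- .Random.seed_exists()
      set.seed(cfg$seed * 100L + i)
      temps <- rep(c(25, 30, 35, 40, 45, 50), each = 3)
      gm <- a_i * exp(cfg$temp_b * temps) *
        exp(stats::rnorm(length(temps), 0, 0.08))
      restore()
      obs <- tibble::tibble(species = species$species[i],
                            temperature = temps, gmin = gm)
      fit_exponential(obs)
    })
    names(fits) <- species$species
    fits
  })
  fit_tab <- dplyr::bind_rows(lapply(temp_fits, function(f) {
    tibble::tibble(species = f$species, a = f$a, b = f$b,
                   r_squared = f$r_squared, n = f$n)
  }))
  utils::write.csv(fit_tab, file.path(cfg$out_dir, "temp_response_fits.csv"),
                   row.names = FALSE)

  # --- traits ---------------------------------------------------------------
  traits <- stage("traits", {
    tab <- simulate_trait_table(trait_sim_params(seed = cfg$seed))
    list(table = tab, correlations = correlate_traits(tab))
  })
  utils::write.csv(traits$table, file.path(cfg$out_dir, "trait_table.csv"),
                   row.names = FALSE)
  utils::write.csv(traits$correlations,
                   file.path(cfg$out_dir, "trait_correlations.csv"),
                   row.names = FALSE)

  # --- canopy transpiration -------------------------------------------------
  emin <- stage("emin", {
    day <- simulate_diurnal_climate(climate_sim_params(
      t_min = cfg$t_min, t_max = cfg$t_max, rh_at_tmax = cfg$rh_at_tmax,
      pressure = cfg$site_pressure, seed = cfg$seed))
    sweeps <- lapply(seq_len(nrow(species)), function(i) {
      sp <- species$species[i]
      rr <- emin_ref$r_leaf_basal[match(sp, emin_ref$species)]
      scenario_sweep(temp_fits[[sp]], day,
                     canopy_spec(sp, rr),
                     step = cfg$sweep_step, t_cap = cfg$sweep_cap)
    })
    dplyr::bind_rows(sweeps)
  })
  utils::write.csv(emin, file.path(cfg$out_dir, "emin_sweep.csv"),
                   row.names = FALSE)

  # --- report tables --------------------------------------------------------
  report <- stage("report", make_report_tables(
    agg, emin, report_temps = cfg$report_temps))
  utils::write.csv(report$conductance,
                   file.path(cfg$out_dir, "report_conductance.csv"),
                   row.names = FALSE)
  utils::write.csv(report$emin, file.path(cfg$out_dir, "report_emin.csv"),
                   row.names = FALSE)

  # --- provenance -----------------------------------------------------------
  cfg_yaml <- file.path(cfg$out_dir, "config.yml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")], cfg_yaml)
  meta <- list(
    package = "leafgmin",
    version = as.character(utils::packageVersion("leafgmin")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_yaml)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(meta, file.path(cfg$out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("pipeline complete: %s", cfg$out_dir)
  invisible(list(out_dir = cfg$out_dir, gmin = drydown, aggregate = agg,
                 temp_fits = temp_fits, traits = traits, emin = emin,
                 report = report))
}

#' Format summary tables for reporting
#'
#' Builds two species-by-statistic grids rounded to one decimal place: a
#' conductance table (species means with SE, plus Angiosperm/Gymnosperm
#' group rows) and a wide canopy-transpiration table with one column per
#' requested scenario maximum temperature.
#'
#' @param aggregate Output of [aggregate_gmin()] (list with `by_species`
#'   and `by_group`), or NULL to skip the conductance table.
#' @param emin_sweep A long tibble of [scenario_sweep()] rows across
#'   species, or NULL to skip the transpiration table.
#' @param report_temps Scenario maximum temperatures (degrees C) to pick
#'   out of the sweep (nearest scenario is used).
#' @param digits Rounding for the report (default 1 decimal place).
#' @return A list with tibbles `conductance` and `emin` (either may be an
#'   empty tibble with headers when its input is NULL or empty).
#' @export
make_report_tables <- function(aggregate = NULL, emin_sweep = NULL,
                               report_temps = c(32.2, 35, 40), digits = 1) {
  fmt <- function(x) round(x, digits)
  cond <- tibble::tibble(species = character(), gmin = numeric(),
                         gmin_se = numeric(), n = integer())
  if (!is.null(aggregate) && nrow(aggregate$by_species) > 0) {
    sp <- aggregate$by_species |>
      dplyr::transmute(species = .data$species, gmin = fmt(.data$mean),
                       gmin_se = fmt(.data$se), n = as.integer(.data$n))
    gr <- aggregate$by_group |>
      dplyr::transmute(species = .data$functional_group,
                       gmin = fmt(.data$mean), gmin_se = fmt(.data$se),
                       n = as.integer(.data$n))
    cond <- dplyr::bind_rows(sp, gr)
  }
  emin_wide <- tibble::tibble(species = character())
  if (!is.null(emin_sweep) && nrow(emin_sweep) > 0) {
    picks <- lapply(report_temps, function(tt) {
      emin_sweep |>
        dplyr::group_by(.data$species) |>
        dplyr::slice_min(abs(.data$t_max - tt), n = 1, with_ties = FALSE) |>
        dplyr::ungroup() |>
        dplyr::transmute(.data$species,
                         scenario = sprintf("e_std_%g", tt),
                         value = fmt(.data$e_std))
    })
    emin_wide <- dplyr::bind_rows(picks) |>
      tidyr::pivot_wider(names_from = "scenario", values_from = "value")
  }
  list(conductance = cond, emin = emin_wide)
}
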