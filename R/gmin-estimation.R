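# From weighed drydown mass series to minimum conductance. One record is one
# detached leaf (or twig/fascicle) dried in a climate chamber; conductance is
# computed per weighing interval from the mass loss, referenced to the mean
# relative water content of the interval, and g_min is read off the
# cuticular plateau between 80 and 50% RWC.

#' Construct a drydown record
#'
#' @param sample_id Identifier of the measured leaf/twig.
#' @param species Species label.
#' @param tree_id Individual-tree label.
#' @param leaf_age_class One of `"current-year"`, `"one-year-old"`, `"n/a"`.
#' @param times Seconds since the first weighing, strictly increasing.
#' @param masses Fresh mass at each weighing, g.
#' @param w_sat Saturated fresh mass, g.
#' @param w_dry Oven-dry mass, g.
#' @param area_two_sided Total two-sided leaf area, m2. Can be computed via
#'   [leaf_area_from_sla()] when only SLA and dry mass are known.
#' @param chamber An [air_state()] with the chamber conditions.
#' @param noise_tol Tolerance (g) by which a weighing may exceed `w_sat`
#'   before validation fails; balance noise makes small excursions normal.
#' @return A list of class `drydown_record`.
#' @export
drydown_record <- function(sample_id, species, tree_id,
                           leaf_age_class = c("n/a", "current-year",
                                              "one-year-old"),
                           times, masses, w_sat, w_dry, area_two_sided,
                           chamber, noise_tol = 0.005) {
  leaf_age_class <- match.arg(leaf_age_class)
  stopifnot(length(times) == length(masses), length(times) >= 2)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (w_sat <= w_dry) stop("w_sat must exceed w_dry", call. = FALSE)
  if (max(masses) > w_sat + noise_tol) {
    stop("a weighing exceeds w_sat beyond noise tolerance", call. = FALSE)
  }
  if (min(masses) < w_dry) {
    stop("a weighing lies below the dry mass", call. = FALSE)
  }
  if (area_two_sided <= 0) stop("area_two_sided must be > 0", call. = FALSE)
  stopifnot(inherits(chamber, "air_state"))
  structure(list(sample_id = sample_id, species = species, tree_id = tree_id,
                 leaf_age_class = leaf_age_class,
                 times = as.numeric(times), masses = as.numeric(masses),
                 w_sat = w_sat, w_dry = w_dry,
                 area_two_sided = area_two_sided, chamber = chamber),
            class = "drydown_record")
}

#' Relative water content
#'
#' `RWC = (W_fre - W_dry) / (W_sat - W_dry)`, the fraction of the leaf's
#' saturating water amount still present. Values falling outside \[0, 1\]
#' (balance noise, imperfect saturation) are clamped and flagged.
#'
#' @param w_fre Fresh mass, g (vectorized).
#' @param w_sat Saturated mass, g.
#' @param w_dry Dry mass, g.
#' @return A tibble with columns `rwc` (clamped to \[0, 1\]) and `clamped`.
#' @examples
#' compute_rwc(8.5, 10, 4)  # 0.75
#' @export
compute_rwc <- function(w_fre, w_sat, w_dry) {
  if (w_sat <= w_dry) stop("w_sat must exceed w_dry", call. = FALSE)
  raw <- (w_fre - w_dry) / (w_sat - w_dry)
  tibble::tibble(rwc = pmin(pmax(raw, 0), 1), clamped = raw < 0 | raw > 1)
}

#' Leaf area from specific leaf area and dry mass
#'
#' SLA is measured on a projected (one-sided) basis; conductance is expressed
#' per total two-sided area, so a sidedness factor converts between the two.
#' For flat broadleaves the factor is exactly 2. For conifer needles the
#' projected-to-total conversion depends on needle geometry; the factor is a
#' configurable knob (common literature values ~2.4-2.8 for cylindrical
#' needles) and defaults to 2, a documented source of bias for conifers.
#'
#' @param sla Specific leaf area, m2 per kg dry mass (projected basis).
#' @param dry_mass Dry mass, kg.
#' @param sidedness_factor Projected-to-total multiplier (default 2).
#' @return Leaf area, m2 on the chosen basis.
#' @examples
#' leaf_area_from_sla(15, 0.4e-3)  # 0.012 m2 two-sided
#' @export
leaf_area_from_sla <- function(sla, dry_mass, sidedness_factor = 2) {
  stopifnot(sla > 0, dry_mass > 0, sidedness_factor > 0)
  sidedness_factor * sla * dry_mass
}

#' Interval conductances from a drydown record
#'
#' For each pair of consecutive weighings the water loss is converted to an
#' amount (molar mass 18.015 g mol-1) and divided by elapsed time, leaf area
#' and chamber VPD, then multiplied by the chamber pressure:
#' `J = W_loss / (dt * A * VPD) * P`, in mmol m-2 s-1. Each interval is
#' referenced to the mean of its endpoint RWCs. Intervals with apparent mass
#' gain beyond `noise_tol` are flagged and excluded from later estimation.
#'
#' @param record A [drydown_record()].
#' @param noise_tol Mass-gain tolerance, g (default 3x a 0.2 mg balance).
#' @return A tibble of class `conductance_curve`: `t_mid` (s), `w_loss` (g),
#'   `rwc_mid`, `j` (mmol m-2 s-1), `excluded` (logical).
#' @examples
#' rec <- simulate_drydown(drydown_sim_params(seed = 3))
#' head(conductance_curve(rec))
#' @export
conductance_curve <- function(record, noise_tol = 6e-4) {
  stopifnot(inherits(record, "drydown_record"))
  vpd_kpa <- vpd(record$chamber)
  if (vpd_kpa <= 0) stop("chamber VPD must be positive", call. = FALSE)
  m <- record$masses
  t <- record$times
  n <- length(m) - 1L
  w_loss <- m[-length(m)] - m[-1]
  dt <- diff(t)
  rwc <- compute_rwc(m, record$w_sat, record$w_dry)$rwc
  rwc_mid <- (rwc[-length(rwc)] + rwc[-1]) / 2
  j <- (w_loss / MOLAR_MASS_WATER * 1e3) /     # g -> mmol
    (dt * record$area_two_sided * vpd_kpa) * record$chamber$pressure
  excluded <- w_loss < -noise_tol
  j[j < 0 & !excluded] <- 0   # small negative noise excursions floor at 0
  out <- tibble::tibble(
    t_mid = (t[-length(t)] + t[-1]) / 2,
    w_loss = w_loss, rwc_mid = rwc_mid, j = j, excluded = excluded
  )
  structure(out, sample_id = record$sample_id, species = record$species,
            tree_id = record$tree_id,
            leaf_age_class = record$leaf_age_class,
            class = c("conductance_curve", class(out)))
}

#' Estimate minimum conductance from the drydown plateau
#'
#' Leaves close their stomata early in a drydown; below ~80% RWC the curve of
#' interval conductance against RWC flattens onto the cuticular plateau, and
#' below ~50% RWC shrinkage artifacts (cuticle cracks, stomata pulled open)
#' make values unreliable. g_min is the mean interval conductance inside the
#' closed RWC window (default \[0.50, 0.80\]). The within-window OLS slope of
#' J against RWC is reported as a plateau-flatness diagnostic; a steep slope
#' flags (but does not reject) the estimate.
#'
#' @param curve A [conductance_curve()].
#' @param window Closed RWC window `c(low, high)` (default `c(0.50, 0.80)`).
#' @param min_intervals Minimum number of usable intervals inside the window
#'   (default 3).
#' @param slope_threshold |OLS slope| (mmol m-2 s-1 per unit RWC) above which
#'   the plateau is flagged as non-horizontal.
#' @return A list of class `gmin_estimate`: `gmin`, `n_intervals_used`,
#'   `rwc_window`, `plateau_slope`, `qc_flags` (character), plus the sample
#'   labels carried from the curve.
#' @examples
#' rec <- simulate_drydown(drydown_sim_params(true_gmin = 2, seed = 1))
#' estimate_gmin(conductance_curve(rec))$gmin  # ~2
#' @export
estimate_gmin <- function(curve, window = c(0.50, 0.80),
                          min_intervals = 3, slope_threshold = 10) {
  stopifnot(inherits(curve, "conductance_curve"), length(window) == 2)
  window <- sort(window)
  use <- !curve$excluded & curve$rwc_mid >= window[1] &
    curve$rwc_mid <= window[2]
  n_used <- sum(use)
  if (n_used < min_intervals) {
    stop(sprintf(
      "only %d usable interval(s) inside RWC window [%.2f, %.2f]; need >= %d",
      n_used, window[1], window[2], min_intervals), call. = FALSE)
  }
  jw <- curve$j[use]
  rw <- curve$rwc_mid[use]
  gmin <- mean(jw)
  slope <- if (stats::sd(rw) > 0) {
    unname(stats::coef(stats::lm(jw ~ rw))[2])
  } else NA_real_
  qc <- character(0)
  if (!is.na(slope) && abs(slope) > slope_threshold) {
    qc <- c(qc, "plateau_not_horizontal")
  }
  if (any(curve$excluded)) qc <- c(qc, "intervals_excluded")
  structure(list(gmin = gmin, n_intervals_used = n_used,
                 rwc_window = window, plateau_slope = slope, qc_flags = qc,
                 sample_id = attr(curve, "sample_id"),
                 species = attr(curve, "species"),
                 tree_id = attr(curve, "tree_id"),
                 leaf_age_class = attr(curve, "leaf_age_class")),
            class = "gmin_estimate")
}

#' @export
print.gmin_estimate <- function(x, ...) {
  cat(sprintf(
    "<gmin_estimate> %s: g_min = %.3f mmol m-2 s-1 (%d intervals, RWC %.2f-%.2f)\n",
    x$sample_id %||% "?", x$gmin, x$n_intervals_used,
    x$rwc_window[1], x$rwc_window[2]))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate leaf-level estimates hierarchically
#'
#' Leaves are averaged within tree, trees within species, species within
#' functional group, with the standard error at each level computed from the
#' entities one level below (so the species SE reflects tree-to-tree spread,
#' and the group SE species-to-species spread). Equal weight is given to each
#' tree within a species regardless of its leaf count. Groups or species with
#' a single member report `NA` SE.
#'
#' @param estimates A data frame with columns `gmin`, `tree_id`, `species`
#'   and optionally `functional_group`; a list of [estimate_gmin()] results
#'   is also accepted (it must then carry a `functional_group` via
#'   `group_map`).
#' @param group_map Optional named character vector mapping species to
#'   functional group (used when `estimates` lacks the column).
#' @return A list of tibbles `by_tree`, `by_species`, `by_group`, each with
#'   `mean`, `se`, `n`.
#' @examples
#' df <- data.frame(
#'   species = rep(c("A", "B"), each = 4),
#'   tree_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
#'   functional_group = "angiosperm",
#'   gmin = c(2, 2.2, 2.4, 2.6, 1, 1.2, 1.4, 1.6))
#' aggregate_gmin(df)$by_species
#' @export
aggregate_gmin <- function(estimates, group_map = NULL) {
  if (!is.data.frame(estimates)) {
    estimates <- dplyr::bind_rows(lapply(estimates, function(e) {
      tibble::tibble(sample_id = e$sample_id %||% NA_character_,
                     species = e$species %||% NA_character_,
                     tree_id = e$tree_id %||% NA_character_,
                     gmin = e$gmin)
    }))
  }
  estimates <- tibble::as_tibble(estimates)
  if (!"functional_group" %in% names(estimates)) {
    if (is.null(group_map)) {
      estimates$functional_group <- NA_character_
    } else {
      estimates$functional_group <- unname(group_map[estimates$species])
    }
  }
  se_of <- function(x) {
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  by_tree <- estimates |>
    dplyr::group_by(.data$functional_group, .data$species, .data$tree_id) |>
    dplyr::summarise(mean = mean(.data$gmin), se = se_of(.data$gmin),
                     n = dplyr::n(), .groups = "drop")
  # se is computed before mean so the summarised `mean` column does not
  # mask the tree-level means mid-summarise
  roll_up <- function(tab, ...) {
    tab |>
      dplyr::group_by(...) |>
      dplyr::summarise(se = se_of(.data$mean), n = dplyr::n(),
                       mean = mean(.data$mean), .groups = "drop") |>
      dplyr::relocate("mean", .before = "se")
  }
  by_species <- roll_up(by_tree, .data$functional_group, .data$species)
  by_group <- roll_up(by_species, .data$functional_group)
  list(by_tree = by_tree, by_species = by_species, by_group = by_group)
}

#' Read drydown experiments from CSV
#'
#' Expects a long weighings table (one row per weighing: `sample_id`,
#' `species`, `tree_id`, `age_class`, `time_s`, `mass_g`) and a companion
#' per-sample table (`sample_id`, `w_sat_g`, `w_dry_g`, `area_m2` or
#' `sla_m2_per_kg`, `chamber_t_c`, `chamber_rh_pct`, `pressure_kpa`).
#'
#' @param weighings_csv Path to the weighings CSV.
#' @param samples_csv Path to the per-sample metadata CSV.
#' @param sidedness_factor Passed to [leaf_area_from_sla()] when area is
#'   derived from SLA.
#' @return A list of [drydown_record()] objects, named by `sample_id`.
#' @export
read_drydown_csv <- function(weighings_csv, samples_csv,
                             sidedness_factor = 2) {
  w <- utils::read.csv(weighings_csv, stringsAsFactors = FALSE)
  s <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  needed_w <- c("sample_id", "species", "tree_id", "time_s", "mass_g")
  if (!all(needed_w %in% names(w))) {
    stop("weighings CSV must have columns: ",
         paste(needed_w, collapse = ", "), call. = FALSE)
  }
  recs <- lapply(split(w, w$sample_id), function(wi) {
    si <- s[s$sample_id == wi$sample_id[1], , drop = FALSE]
    if (nrow(si) != 1) {
      stop("no unique sample metadata for ", wi$sample_id[1], call. = FALSE)
    }
    area <- if (!is.null(si$area_m2) && !is.na(si$area_m2)) si$area_m2 else {
      leaf_area_from_sla(si$sla_m2_per_kg, si$w_dry_g * 1e-3,
                         sidedness_factor)
    }
    wi <- wi[order(wi$time_s), ]
    drydown_record(
      sample_id = wi$sample_id[1], species = wi$species[1],
      tree_id = wi$tree_id[1],
      leaf_age_class = if ("age_class" %in% names(wi))
        wi$age_class[1] else "n/a",
      times = wi$time_s, masses = wi$mass_g,
      w_sat = si$w_sat_g, w_dry = si$w_dry_g, area_two_sided = area,
      chamber = air_state(si$chamber_t_c, si$chamber_rh_pct,
                          si$pressure_kpa %||% 98.0)
    )
  })
  recs
}
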