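# Stomatal and cuticular trait metrics and their cross-species Pearson
# correlations with minimum conductance.

#' Stomatal size
#'
#' Guard cell length multiplied by the width of the guard-cell pair, um2.
#'
#' @param length_um Guard cell length L, um.
#' @param width_um Width W of the guard-cell pair, um.
#' @return Stomatal size, um2.
#' @examples
#' stomatal_size(30, 20)  # 600
#' @export
stomatal_size <- function(length_um, width_um) {
  stopifnot(all(length_um >= 0), all(width_um >= 0))
  length_um * width_um
}

#' Fraction of leaf epidermis allocated to stomata
#'
#' `f_gc = (pi/2) * W * L * SD`, treating each guard-cell pair as an ellipse
#' with axes L and W. Lengths are supplied in micrometres and converted to
#' millimetres internally so the result is dimensionless against a stomatal
#' density in mm-2.
#'
#' @param length_um Guard cell length L, um.
#' @param width_um Width W of the guard-cell pair, um.
#' @param density_mm2 Stomatal density SD, stomata per mm2.
#' @return Fraction of epidermis (0-1). Values above 1 are returned as
#'   computed but raise a unit-inconsistency warning.
#' @examples
#' guard_cell_fraction(30, 20, 200)  # ~0.188
#' @export
guard_cell_fraction <- function(length_um, width_um, density_mm2) {
  stopifnot(all(length_um >= 0), all(width_um >= 0), all(density_mm2 >= 0))
  f <- (pi / 2) * (width_um / 1000) * (length_um / 1000) * density_mm2
  if (any(f > 1)) {
    warning("f_gc exceeds 1; check trait units (um vs mm, per-mm2 density)",
            call. = FALSE)
  }
  f
}

#' Combine adaxial and abaxial cuticle thickness
#'
#' @param ct_adaxial Upper-surface cuticle thickness, um.
#' @param ct_abaxial Lower-surface cuticle thickness, um.
#' @return Mean of the two, um.
#' @export
cuticle_total <- function(ct_adaxial, ct_abaxial) {
  (ct_adaxial + ct_abaxial) / 2
}

#' Cross-species correlations between g_min and leaf traits
#'
#' Pearson correlations of (possibly log10-transformed) species mean traits
#' against species mean minimum conductance, pairwise-complete over species.
#' The transform policy mirrors common practice for right-skewed
#' morphometric traits: log10 for stomatal density, stomatal size and g_max,
#' identity for the rest; g_min itself is log10-transformed by default. No
#' multiple-testing correction is applied by default (the six trait tests
#' are reported as raw Pearson p-values); set `p_adjust_method` to change
#' that.
#'
#' @param table Data frame with one row per species, a `gmin_25c` column and
#'   any subset of trait columns (`stomatal_density`, `stomatal_size`,
#'   `f_gc`, `g_max`, `ct_total`, `ct_adaxial`, `ct_abaxial`, `sla`).
#' @param traits Character vector of trait columns to test (default: those
#'   present from the list above).
#' @param log10_traits Traits to log10-transform; default
#'   `c("stomatal_density", "stomatal_size", "g_max")`.
#' @param log10_gmin Log10-transform g_min (default TRUE).
#' @param p_adjust_method Passed to [stats::p.adjust()]; default `"none"`.
#' @return A tibble with one row per trait: `trait`, `r`, `p`, `n`,
#'   `transform`, `note` (set when a correlation is undefined, e.g. a
#'   zero-variance trait).
#' @examples
#' tr <- simulate_trait_table(trait_sim_params(noise_sd = 0, seed = 1))
#' correlate_traits(tr)
#' @export
correlate_traits <- function(table,
                             traits = NULL,
                             log10_traits = c("stomatal_density",
                                              "stomatal_size", "g_max"),
                             log10_gmin = TRUE,
                             p_adjust_method = "none") {
  tab <- tibble::as_tibble(table)
  stopifnot("gmin_25c" %in% names(tab))
  known <- c("stomatal_density", "stomatal_size", "f_gc", "g_max",
             "ct_total", "ct_adaxial", "ct_abaxial", "sla")
  if (is.null(traits)) traits <- intersect(known, names(tab))
  g <- tab$gmin_25c
  if (log10_gmin) g <- log10(g)

  rows <- lapply(traits, function(tr) {
    v <- tab[[tr]]
    logged <- tr %in% log10_traits
    if (logged) v <- log10(v)
    ok <- stats::complete.cases(g, v)
    n <- sum(ok)
    if (n < 3) {
      return(tibble::tibble(trait = tr, r = NA_real_, p = NA_real_, n = n,
                            transform = if (logged) "log10" else "identity",
                            note = "fewer than 3 complete species"))
    }
    if (stats::sd(v[ok]) == 0 || stats::sd(g[ok]) == 0) {
      return(tibble::tibble(trait = tr, r = NA_real_, p = NA_real_, n = n,
                            transform = if (logged) "log10" else "identity",
                            note = "zero variance: correlation undefined"))
    }
    ct <- stats::cor.test(g[ok], v[ok], method = "pearson")
    tibble::tibble(trait = tr, r = unname(ct$estimate), p = ct$p.value,
                   n = n, transform = if (logged) "log10" else "identity",
                   note = NA_character_)
  })
  out <- dplyr::bind_rows(rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust_method)
  out
}
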