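# Published per-species reference values for the nine-species temperate
# forest at the Swiss Canopy Crane II (SCCII) site near Hoelstein: seasonal
# mean minimum and maximum conductance per species, and the canopy
# leaf-area-to-basal-area ratio R together with daily residual canopy
# transpiration under three maximum-temperature scenarios. Used as worked
# inputs for aggregation, reporting and cross-species comparisons.

#' Species conductance reference table (SCCII site)
#'
#' Seasonal mean minimum conductance (`gmin`, mmol m-2 s-1, measured at
#' 20 degrees C) and maximum stomatal conductance (`gmax`) with standard
#' errors and tree replicate counts for nine temperate European tree
#' species (six angiosperms, three gymnosperm conifers). Single SE values
#' are missing where only two trees were available.
#'
#' @return A tibble with columns `species`, `functional_group`, `gmin`,
#'   `gmin_se`, `gmin_n_trees`, `gmax`, `gmax_se`, `gmax_n_trees`.
#' @export
sccii_species_table <- function() {
  path <- system.file("extdata", "sccii_species_conductance.csv",
                      package = "leafgmin", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Residual canopy transpiration reference table (SCCII site)
#'
#' Per-species canopy scaling ratio `r_leaf_basal` (projected canopy leaf
#' area per stem basal area, m2 m-2) and daily residual canopy transpiration
#' at full stomatal closure: standardized by basal area (`e_std_*`, L m-2)
#' and absolute for single site trees (`e_tree_*`, L), under diurnal
#' scenarios whose maximum temperatures are 32.2 (the measured hot drought
#' day), 35 and 40 degrees C.
#'
#' @return A tibble, one row per species.
#' @export
sccii_emin_table <- function() {
  path <- system.file("extdata", "sccii_emin_reference.csv",
                      package = "leafgmin", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}
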