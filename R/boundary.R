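#' Extract boundary cells of a species range
#'
#' For every longitudinal band (grid column) containing presence, returns the
#' single most-poleward or most-equatorward occupied cell.  The cold range
#' boundary of a northern-hemisphere species is its poleward (northern) edge;
#' for a southern-hemisphere species it is the southern edge.
#'
#' @param mask A [range_mask()].
#' @param edge `"poleward"` or `"equatorward"`.
#' @param hemisphere `"N"` or `"S"`; which pole "poleward" refers to.
#' @return A `boundary_profile`: list with `edge`, `hemisphere`, `cells`
#'   (data frame of `col`, `row`, `lon`, `lat`, one row per occupied
#'   longitude band) and `lat_median`.
#' @export
extract_boundary_cells <- function(mask,
                                   edge = c("poleward", "equatorward"),
                                   hemisphere = c("N", "S")) {
  edge <- match.arg(edge)
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(mask, "range_mask"))
  pres <- mask$presence
  cols <- which(colSums(pres) > 0)
  # north-up grid: row 1 is northernmost, so the northern extreme of a
  # column is its minimum occupied row index
  northward <- (edge == "poleward") == (hemisphere == "N")
  rows <- vapply(cols, function(j) {
    occ <- which(pres[, j])
    if (northward) min(occ) else max(occ)
  }, integer(1))
  cells <- data.frame(col = cols, row = rows,
                      lon = mask$lon[cols], lat = mask$lat[rows])
  structure(list(edge = edge, hemisphere = hemisphere, cells = cells,
                 lat_median = stats::median(cells$lat),
                 species_id = mask$species_id),
            class = "boundary_profile")
}

#' @export
print.boundary_profile <- function(x, ...) {
  cat(sprintf("boundary_profile (%s edge, %s hemisphere): %d cells, median lat %.3f\n",
              x$edge, x$hemisphere, nrow(x$cells), x$lat_median))
  invisible(x)
}

#' Cold-boundary profiles under the hemisphere rule
#'
#' The cold boundary is the poleward edge in the hemisphere containing the
#' range centroid.  A range spanning the equator gets two cold boundaries
#' (one per hemisphere, each computed from the presence cells in that
#' hemisphere) and raises a warning, since such species are analysed
#' per-hemisphere.
#'
#' @param mask A [range_mask()].
#' @return List of one or two `boundary_profile` objects.
#' @export
cold_boundaries <- function(mask) {
  pres <- mask$presence
  occ_lat <- mask$lat[row(pres)[pres]]
  hemis <- if (all(occ_lat >= 0)) "N" else if (all(occ_lat <= 0)) "S" else {
    warning("range of '", mask$species_id,
            "' spans the equator; returning one cold boundary per hemisphere")
    c("N", "S")
  }
  lapply(hemis, function(h) {
    keep <- if (h == "N") mask$lat >= 0 else mask$lat <= 0
    sub <- pres
    sub[!keep, ] <- FALSE
    m <- range_mask(sub, mask$lat, mask$lon, mask$species_id)
    extract_boundary_cells(m, edge = "poleward", hemisphere = h)
  })
}

#' Summarise boundary-cell temperatures
#'
#' Looks up the climate value under every boundary cell and returns the
#' median (the per-species boundary temperature used downstream), standard
#' deviation, and median absolute deviation.  The degree to which a range
#' boundary tracks a thermal isocline is read off `t_sd` / `t_mad`.
#'
#' @param profile A `boundary_profile` from [extract_boundary_cells()].
#' @param grid A [climate_grid()] on the same template as the mask the
#'   profile came from.
#' @param mad_constant Consistency scaling for the mad (default 1.4826, the
#'   normal-consistent value; set 1.0 for the raw median absolute
#'   deviation).
#' @return List with `temps`, `t_median`, `t_sd`, `t_mad`, `n`.
#' @export
boundary_temperature_summary <- function(profile, grid, mad_constant = 1.4826) {
  stopifnot(inherits(profile, "boundary_profile"), inherits(grid, "climate_grid"))
  idx <- cbind(profile$cells$row, profile$cells$col)
  temps <- grid$values[idx]
  temps <- temps[!is.na(temps)]
  if (!length(temps))
    stop("boundary_temperature_summary(): all boundary cells are climate-masked")
  list(temps = temps,
       t_median = stats::median(temps),
       t_sd = if (length(temps) > 1) stats::sd(temps) else 0,
       t_mad = stats::mad(temps, constant = mad_constant),
       n = length(temps))
}

#' Metabolic sensitivity to boundary-temperature spread
#'
#' Converts the spread of temperatures along a range boundary into the
#' relative change of the boundary metabolic rate it implies:
#' `100 * t_sd * C / MR_CRB` (percent).
#'
#' @param t_sd Standard deviation of boundary temperatures (degC).
#' @param conductance Thermal conductance (ml O2 h^-1 degC^-1).
#' @param mr_crb Boundary metabolic rate (ml O2 h^-1), > 0.
#' @return Percent change in MR_CRB per one-SD temperature excursion.
#' @export
mr_sensitivity <- function(t_sd, conductance, mr_crb) {
  if (any(mr_crb <= 0, na.rm = TRUE))
    stop("mr_sensitivity(): 'mr_crb' must be > 0")
  100 * t_sd * conductance / mr_crb
}

#' Apply the species-level exclusion filters
#'
#' Drops species whose cold-boundary temperature is not below their lower
#' critical temperature (within the thermal neutral zone at the boundary),
#' species flagged as island-restricted, species whose latitudinal limits
#' are set by continental edges, and (when a `resident` column is present)
#' non-residents.  Every exclusion is logged with a reason code.
#'
#' @param phys Physiology table with `species_id`, `t_lc`, and optionally
#'   `exclude_island`, `exclude_continental_limit`, `resident` columns
#'   (values `"yes"`/`"no"`/`"unknown"`; only `"yes"` excludes,
#'   `"no"` is required to count as resident).
#' @param boundary Data frame with `species_id` and `t_min` (median
#'   cold-boundary temperature, degC).
#' @return List with `kept` (merged table of retained species) and
#'   `excluded` (data frame `species_id`, `reason`).
#' @export
apply_species_filters <- function(phys, boundary) {
  stopifnot("species_id" %in% names(phys), "t_lc" %in% names(phys),
            all(c("species_id", "t_min") %in% names(boundary)))
  tab <- merge(phys, boundary, by = "species_id")
  reasons <- list()
  note <- function(ids, why) {
    if (length(ids))
      reasons[[length(reasons) + 1L]] <<- data.frame(
        species_id = ids, reason = why, stringsAsFactors = FALSE)
  }
  drop <- rep(FALSE, nrow(tab))
  tnz <- tab$t_min >= tab$t_lc
  note(tab$species_id[tnz], "within_TNZ")
  drop <- drop | tnz
  yes <- function(col) if (col %in% names(tab))
    !is.na(tab[[col]]) & tab[[col]] == "yes" else rep(FALSE, nrow(tab))
  isl <- yes("exclude_island")
  note(tab$species_id[isl], "island")
  drop <- drop | isl
  cont <- yes("exclude_continental_limit")
  note(tab$species_id[cont], "continental_limit")
  drop <- drop | cont
  if ("resident" %in% names(tab)) {
    nonres <- is.na(tab$resident) | tab$resident != "yes"
    note(tab$species_id[nonres], "nonresident")
    drop <- drop | nonres
  }
  excluded <- if (length(reasons)) do.call(rbind, reasons)
  else data.frame(species_id = character(), reason = character(),
                  stringsAsFactors = FALSE)
  list(kept = tab[!drop, , drop = FALSE], excluded = excluded)
}
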