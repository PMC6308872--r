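#' Thermally habitable cells for a species
#'
#' A cell is habitable when it has climate data and its minimum temperature
#' is strictly warmer than the species' predicted lower thermal limit.
#'
#' @param grid A [climate_grid()] of minimum temperatures.
#' @param t_limit Predicted lower thermal limit (degC), from
#'   [thermal_limit()].
#' @return Logical matrix on the grid template, with attribute `"empty"`
#'   set when no cell qualifies.
#' @export
habitable_mask <- function(grid, t_limit) {
  stopifnot(inherits(grid, "climate_grid"), is.finite(t_limit))
  m <- !is.na(grid$values) & grid$values > t_limit
  attr(m, "empty") <- !any(m)
  m
}

#' Label connected clumps of a boolean grid
#'
#' Connected-component labelling with queen (8-neighbour, default) or rook
#' (4-neighbour) connectivity, optionally wrapping across the east-west
#' seam.  Labels are dense from 1 in order of first (row-major) appearance.
#' Implemented by iterated minimum-label propagation, which converges to
#' the exact component partition.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 (queen) or 4 (rook).
#' @param wrap Wrap the first and last columns (antimeridian) into
#'   adjacency? Default `FALSE`.
#' @return Integer matrix of labels (0 = background), with attribute
#'   `"n_clumps"`.
#' @export
label_clumps <- function(mask, connectivity = 8, wrap = FALSE) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  mask <- !is.na(mask) & mask
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  npres <- sum(mask)
  if (npres == 0L) {
    attr(lab, "n_clumps") <- 0L
    return(lab)
  }
  vid <- matrix(0L, nr, nc)        # vertex id per presence cell
  vid[mask] <- seq_len(npres)

  # adjacency edges from half the neighbourhood (right, down, diagonals)
  edges <- list()
  add_pairs <- function(a_rows, a_cols, b_rows, b_cols) {
    ok <- mask[cbind(a_rows, a_cols)] & mask[cbind(b_rows, b_cols)]
    if (any(ok))
      edges[[length(edges) + 1L]] <<- cbind(vid[cbind(a_rows, a_cols)][ok],
                                            vid[cbind(b_rows, b_cols)][ok])
  }
  grid_pairs <- function(dr, dc, wrap_cols = FALSE) {
    rs <- seq_len(nr - dr)
    if (wrap_cols) {
      a <- expand.grid(r = rs, c = nc)
      add_pairs(a$r, a$c, a$r + dr, rep(1L, nrow(a)))
      if (dr > 0 && dc < 0) {  # down-left across the seam
        a <- expand.grid(r = rs, c = 1L)
        add_pairs(a$r, a$c, a$r + dr, rep(nc, nrow(a)))
      }
    } else {
      cs <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
      a <- expand.grid(r = rs, c = cs)
      add_pairs(a$r, a$c, a$r + dr, a$c + dc)
    }
  }
  grid_pairs(0L, 1L)                          # right
  grid_pairs(1L, 0L)                          # down
  if (connectivity == 8) {
    grid_pairs(1L, 1L)                        # down-right
    grid_pairs(1L, -1L)                       # down-left
  }
  if (wrap && nc > 1) {
    grid_pairs(0L, 1L, wrap_cols = TRUE)
    if (connectivity == 8) {
      grid_pairs(1L, 1L, wrap_cols = TRUE)
      grid_pairs(1L, -1L, wrap_cols = TRUE)
    }
  }
  el <- if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, npres - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # dense relabel in row-major order of first appearance
  memb_rowmajor <- memb[t(vid)[t(mask)]]
  first_seen <- unique(memb_rowmajor)
  lab[mask] <- match(memb[vid[mask]], first_seen)
  attr(lab, "n_clumps") <- length(first_seen)
  lab
}

#' Drop clumps smaller than 5% of the largest
#'
#' Clump area defaults to the raw cell count, mirroring raster clump
#' workflows; a cosine-latitude weighted area is available (non-canonical)
#' for geodetically honest areas.  Clumps with area strictly less than
#' `frac` of the largest clump's area are dropped; ties at exactly the
#' threshold are kept.
#'
#' @param labels Integer label matrix from [label_clumps()].
#' @param frac Area fraction threshold (default 0.05).
#' @param lat Cell-centre latitudes (needed for `area = "coslat"`).
#' @param area `"cells"` (count) or `"coslat"` (cos-latitude weighted).
#' @return List with `mask` (logical matrix of kept cells) and `census`
#'   (data frame `id`, `area`, `kept`).
#' @export
filter_clumps <- function(labels, frac = 0.05, lat = NULL,
                          area = c("cells", "coslat")) {
  area <- match.arg(area)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) {
    out <- list(mask = labels > 0,
                census = data.frame(id = integer(), area = numeric(),
                                    kept = logical()))
    attr(out$mask, "empty") <- TRUE
    return(out)
  }
  if (area == "coslat") {
    if (is.null(lat)) stop("filter_clumps(): 'lat' required for coslat areas")
    w <- matrix(cos(lat * pi / 180), nrow(labels), ncol(labels))
    sizes <- vapply(ids, function(i) sum(w[labels == i]), numeric(1))
  } else {
    sizes <- vapply(ids, function(i) sum(labels == i), numeric(1))
  }
  thr <- frac * max(sizes)
  kept <- sizes >= thr
  mask <- matrix(labels %in% ids[kept], nrow(labels), ncol(labels))
  list(mask = mask,
       census = data.frame(id = ids, area = sizes, kept = kept))
}

#' Restrict a projection to the observed range envelope
#'
#' Keeps only clumps whose latitudinal span intersects the observed
#' latitudinal extent of the species (closed-interval intersection), then
#' crops the result to the observed west-east longitudinal extent.  This
#' focuses the projection on the core of the distribution, whose poleward
#' edge is the quantity of interest.
#'
#' @param labels Label matrix of the clumps under consideration (use
#'   [label_clumps()] on the mask surviving [filter_clumps()]).
#' @param lat,lon Grid cell-centre coordinates.
#' @param lat_range Observed `c(min, max)` latitude of the species range.
#' @param lon_range Observed `c(min, max)` longitude.
#' @return Logical matrix; attribute `"no_overlap"` is `TRUE` when no clump
#'   intersects the observed latitudinal extent.
#' @export
restrict_to_observed <- function(labels, lat, lon, lat_range, lon_range) {
  ids <- sort(unique(labels[labels > 0]))
  keep_ids <- integer(0)
  for (i in ids) {
    rows <- which(rowSums(labels == i) > 0)
    span <- range(lat[rows])
    if (span[1] <= max(lat_range) && span[2] >= min(lat_range))
      keep_ids <- c(keep_ids, i)
  }
  mask <- matrix(labels %in% keep_ids, nrow(labels), ncol(labels))
  mask[, lon < min(lon_range) | lon > max(lon_range)] <- FALSE
  attr(mask, "no_overlap") <- length(keep_ids) == 0 || !any(mask)
  mask
}

#' Median latitude of the projected cold range boundary
#'
#' Extracts the poleward boundary cell of every occupied longitude band of
#' the final habitable mask and returns the median of their latitudes.
#'
#' @param mask Logical matrix (final projected occupancy).
#' @param lat,lon Grid cell-centre coordinates.
#' @param hemisphere `"N"` or `"S"`.
#' @return Median boundary latitude in degrees, or `NA` (flagged via
#'   attribute `"empty"`) for an empty mask.
#' @export
project_crb <- function(mask, lat, lon, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  if (!any(mask)) {
    out <- NA_real_
    attr(out, "empty") <- TRUE
    return(out)
  }
  rm_ <- range_mask(mask, lat, lon)
  prof <- extract_boundary_cells(rm_, edge = "poleward", hemisphere = hemisphere)
  out <- prof$lat_median
  attr(out, "empty") <- FALSE
  out
}

#' Project a species' cold range boundary under one climate
#'
#' Chains the projection steps: habitability masking at the species'
#' thermal limit, clump labelling, the 5%-of-largest clump filter, the
#' restriction to the observed range envelope, and extraction of the median
#' cold-edge latitude.
#'
#' @param t_limit Species thermal limit (degC).
#' @param grid [climate_grid()] of minimum temperatures for the scenario.
#' @param observed [range_mask()] of the observed range (supplies the
#'   latitudinal/longitudinal envelope).
#' @param hemisphere `"N"` or `"S"`.
#' @param connectivity,wrap Passed to [label_clumps()].
#' @param clump_frac Passed to [filter_clumps()].
#' @param area Clump area mode, see [filter_clumps()].
#' @return List of class `projection_result`: `mask`, `census`, `crb_lat`,
#'   `flags` (character vector of any of `"empty_habitable"`,
#'   `"no_overlap"`, `"empty_projection"`).
#' @export
project_range <- function(t_limit, grid, observed,
                          hemisphere = c("N", "S"),
                          connectivity = 8, wrap = FALSE,
                          clump_frac = 0.05, area = "cells") {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(grid, "climate_grid"), inherits(observed, "range_mask"),
            same_template(grid, observed))
  flags <- character(0)
  hab <- habitable_mask(grid, t_limit)
  if (attr(hab, "empty")) {
    return(structure(list(mask = hab, census = NULL, crb_lat = NA_real_,
                          flags = "empty_habitable"),
                     class = "projection_result"))
  }
  labs <- label_clumps(hab, connectivity = connectivity, wrap = wrap)
  fc <- filter_clumps(labs, frac = clump_frac, lat = grid$lat, area = area)
  # dropping whole clumps never merges or splits the survivors, so the
  # original labels remain a valid partition of the filtered mask
  labs2 <- labs
  labs2[!fc$mask] <- 0L
  occ_lat <- observed$lat[rowSums(observed$presence) > 0]
  occ_lon <- observed$lon[colSums(observed$presence) > 0]
  fin <- restrict_to_observed(labs2, grid$lat, grid$lon,
                              range(occ_lat), range(occ_lon))
  if (attr(fin, "no_overlap")) flags <- c(flags, "no_overlap")
  crb <- project_crb(fin, grid$lat, grid$lon, hemisphere)
  if (isTRUE(attr(crb, "empty"))) flags <- c(flags, "empty_projection")
  structure(list(mask = fin, census = fc$census,
                 crb_lat = as.numeric(crb), flags = flags),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection_result: crb_lat = %.3f, %d cells kept%s\n",
              x$crb_lat, sum(x$mask),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Poleward shift of the cold range boundary
#'
#' Signed so that poleward movement is positive in both hemispheres:
#' `future - current` in the north, `current - future` in the south.
#'
#' @param current,future `projection_result` objects (or boundary
#'   latitudes).
#' @param hemisphere `"N"` or `"S"`.
#' @return Shift in degrees latitude, `NA` (flagged) if either projection
#'   is empty.
#' @export
shift_deg <- function(current, future, hemisphere = c("N", "S")) {
  hemisphere <- match.arg(hemisphere)
  cur <- if (inherits(current, "projection_result")) current$crb_lat else current
  fut <- if (inherits(future, "projection_result")) future$crb_lat else future
  if (is.na(cur) || is.na(fut)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (hemisphere == "N") fut - cur else cur - fut
}
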