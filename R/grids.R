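#' Regular latitude/longitude temperature grid
#'
#' A `climate_grid` is a regular lat/lon raster stored north-up: row 1 is the
#' northernmost row, columns run west to east, and coordinates refer to cell
#' centres.  Missing cells (ocean, no data) are `NA`.
#'
#' @param values Numeric matrix of temperatures (degC), north-up.
#' @param lat Vector of cell-centre latitudes, strictly decreasing, one per
#'   row.
#' @param lon Vector of cell-centre longitudes in `[-180, 180)`, strictly
#'   increasing, one per column.
#' @return An object of class `climate_grid` with elements `values`, `lat`,
#'   `lon`, `res`.
#' @export
climate_grid <- function(values, lat, lon) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(lat), ncol(values) == length(lon))
  if (length(lat) > 1 && any(diff(lat) >= 0))
    stop("climate_grid(): 'lat' must be strictly decreasing (north-up)")
  if (length(lon) > 1 && any(diff(lon) <= 0))
    stop("climate_grid(): 'lon' must be strictly increasing")
  res <- if (length(lat) > 1) -diff(lat)[1] else if (length(lon) > 1) diff(lon)[1] else 1
  steps <- c(if (length(lat) > 1) -diff(lat), if (length(lon) > 1) diff(lon))
  if (any(abs(steps - res) > 1e-6 * res))
    stop("climate_grid(): grid must be regular with square cells")
  structure(list(values = values, lat = as.numeric(lat),
                 lon = as.numeric(lon), res = res),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid: %d rows x %d cols at %g deg, lat [%g, %g], lon [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$res,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  values: %g to %g degC, %d missing cells\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

#' Boolean presence grid aligned to a climate grid template
#'
#' @param presence Logical matrix on the same template as its climate grid
#'   (north-up).  Must contain at least one `TRUE` cell.
#' @param lat,lon Cell-centre coordinates as in [climate_grid()].
#' @param species_id Identifier carried through the pipeline.
#' @return An object of class `range_mask`.
#' @export
range_mask <- function(presence, lat, lon, species_id = NA_character_) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  presence[is.na(presence)] <- FALSE
  stopifnot(nrow(presence) == length(lat), ncol(presence) == length(lon))
  if (!any(presence))
    stop("range_mask(): empty range (no presence cells)")
  structure(list(presence = presence, lat = as.numeric(lat),
                 lon = as.numeric(lon), species_id = species_id),
            class = "range_mask")
}

#' @export
print.range_mask <- function(x, ...) {
  cat(sprintf("range_mask '%s': %d presence cells on %d x %d template\n",
              x$species_id, sum(x$presence), nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

same_template <- function(a, b, tol = 1e-6) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    all(abs(a$lat - b$lat) < tol) && all(abs(a$lon - b$lon) < tol)
}

#' Read an ESRI ASCII grid
#'
#' Reads a single-band ESRI ASCII (`.asc`) raster into a [climate_grid()].
#' Integer rasters stored scaled (a common climate-data dialect, e.g.
#' temperatures in tenths of a degree) are rescaled via `scale`.
#'
#' @param path Path to the `.asc` file.
#' @param scale Multiplier applied to stored values (default 1; use 0.1 for
#'   tenth-degree integer grids).
#' @return A [climate_grid()].
#' @export
read_ascii_grid <- function(path, scale = 1) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("read_ascii_grid(): not an ESRI ASCII grid: ", path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("read_ascii_grid(): header missing ", paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- hdr$ncols; nr <- hdr$nrows
  if (length(vals) != nr * nc)
    stop("read_ascii_grid(): expected ", nr * nc, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # file rows run N -> S
  m[m == nodata] <- NA
  m <- m * scale
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  lon <- xll + cs / 2 + cs * (0:(nc - 1))
  lat <- yll + cs / 2 + cs * ((nr - 1):0)
  climate_grid(m, lat = lat, lon = lon)
}

#' Write an ESRI ASCII grid
#'
#' @param grid A [climate_grid()] or [range_mask()] (presence written as
#'   0/1).
#' @param path Output path.
#' @param nodata No-data sentinel written for `NA` cells.
#' @param digits Significant digits for formatting; the default 17 makes
#'   write/read round-trips bit-exact for doubles.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 17) {
  if (inherits(grid, "range_mask")) {
    m <- grid$presence * 1L; lat <- grid$lat; lon <- grid$lon
  } else {
    m <- grid$values; lat <- grid$lat; lon <- grid$lon
  }
  cs <- if (length(lat) > 1) lat[1] - lat[2] else if (length(lon) > 1) lon[2] - lon[1] else 1
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", min(lon) - cs / 2),
           sprintf("yllcorner %.10g", min(lat) - cs / 2),
           sprintf("cellsize %.10g", cs),
           sprintf("NODATA_value %g", nodata))
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(format(r, digits = digits, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Parse polygons from a GeoJSON file
#'
#' Extracts Polygon and MultiPolygon geometries (outer rings and holes) from
#' a GeoJSON `FeatureCollection`, `Feature`, or bare geometry.  Rings are
#' returned per feature as two-column (lon, lat) matrices with `NA` rows
#' separating rings, the form consumed by [rasterize_range()].
#'
#' @param path Path to a GeoJSON file.
#' @param id_field Feature property holding the species identifier
#'   (default `"species_id"`).
#' @return Named list of ring matrices, one per feature.
#' @export
read_geojson_polygons <- function(path, id_field = "species_id") {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(gj$type %||% "",
    FeatureCollection = gj$features,
    Feature = list(gj),
    list(list(type = "Feature", geometry = gj, properties = list())))
  ring_mat <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  out <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    geom <- f$geometry
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon")) next
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
    rings <- list()
    for (p in polys) for (r in p) rings[[length(rings) + 1L]] <- ring_mat(r)
    sep <- matrix(NA_real_, 1, 2)
    bnd <- do.call(rbind, lapply(seq_along(rings), function(j)
      if (j == 1) rings[[j]] else rbind(sep, rings[[j]])))
    id <- f$properties[[id_field]] %||% paste0("feature_", k)
    out[[as.character(id)]] <- bnd
  }
  if (!length(out)) stop("read_geojson_polygons(): no polygon features in ", path)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize range polygons onto a grid template
#'
#' A cell is marked present when its centre falls inside the polygon
#' (cell-centre containment, the convention of typical 5-arc-minute
#' workflows).  Point-in-polygon uses the even-odd rule, so holes encoded as
#' additional rings are respected.
#'
#' @param polygons Two-column (lon, lat) matrix of ring vertices, with `NA`
#'   rows separating multiple rings, or a list of such matrices (pooled).
#' @param grid_template A [climate_grid()] supplying the cell layout.
#' @param species_id Identifier for the resulting mask.
#' @return A [range_mask()].
#' @export
rasterize_range <- function(polygons, grid_template, species_id = NA_character_) {
  if (is.list(polygons) && !is.matrix(polygons)) {
    sep <- matrix(NA_real_, 1, 2)
    polygons <- do.call(rbind, lapply(seq_along(polygons), function(j)
      if (j == 1) polygons[[j]] else rbind(sep, polygons[[j]])))
  }
  polygons <- as.matrix(polygons)
  if (ncol(polygons) != 2) stop("rasterize_range(): polygons must have 2 columns (lon, lat)")
  fin <- polygons[stats::complete.cases(polygons), , drop = FALSE]
  if (nrow(fin) < 3 || diff(range(fin[, 1])) == 0 || diff(range(fin[, 2])) == 0)
    stop("rasterize_range(): degenerate polygon (zero area)")
  centres <- cbind(rep(grid_template$lon, each = length(grid_template$lat)),
                   rep(grid_template$lat, times = length(grid_template$lon)))
  inside <- mgcv::in.out(polygons, centres)
  pres <- matrix(inside, nrow = length(grid_template$lat),
                 ncol = length(grid_template$lon))
  if (!any(pres))
    stop("rasterize_range(): polygon does not cover any cell centre of the template")
  range_mask(pres, grid_template$lat, grid_template$lon, species_id)
}
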