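# small shared builders for unit tests

# regular north-up grid whose temperature is a pure function of latitude:
# T = a - b * lat
gradient_grid <- function(nr = 20, nc = 10, res = 1, lat_top = 60,
                          lon_left = 0, a = 25, b = 0.5) {
  lat <- lat_top - res / 2 - res * (0:(nr - 1))
  lon <- lon_left + res / 2 + res * (0:(nc - 1))
  climate_grid(outer(a - b * lat, rep(1, nc)), lat, lon)
}

# rectangular presence block on a grid template (row/col index ranges)
block_mask <- function(grid, rows, cols, species_id = "blk") {
  m <- matrix(FALSE, length(grid$lat), length(grid$lon))
  m[rows, cols] <- TRUE
  range_mask(m, grid$lat, grid$lon, species_id)
}

# flood-fill connected-component oracle (breadth-first, explicit queue)
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r <- cell[1] + offs[k, 1]; c <- cell[2] + offs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# physiology data frame in internal names
toy_phys <- function(n = 10, seed = 1) {
  set.seed(seed)
  t_b <- rnorm(n, 38, 1)
  t_lc <- t_b - runif(n, 5, 15)
  data.frame(
    species_id = sprintf("s%02d", seq_len(n)),
    taxon_class = sample(c("mammal", "bird"), n, replace = TRUE),
    mass_g = 10^runif(n, 1, 3),
    bmr = runif(n, 50, 500),
    t_b = t_b, t_lc = t_lc,
    conductance = NA_real_,
    stringsAsFactors = FALSE)
}
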