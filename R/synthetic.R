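#' Specification of a synthetic world
#'
#' Bundles every knob of the seeded synthetic generator: a single-hemisphere
#' latitudinal temperature gradient with local noise, a cohort of species
#' whose poleward range edges track the thermal isocline implied by a known
#' true metabolic expansibility, physiology draws with realistic
#' body-temperature/critical-temperature/BMR allometry, and trait tables
#' with a built-in positive torpor effect and negative log-mass effect on
#' expansibility.
#'
#' The default world is a 180 x 360 grid at 0.5 degrees (a 90-degree
#' latitude window of the northern hemisphere, 180 degrees of longitude)
#' with 100 species; a full pipeline run on it takes seconds while still
#' exercising every stage.
#'
#' @param n_lat,n_lon Grid dimensions (default 180 x 360).
#' @param res Cell size in degrees (default 0.5).
#' @param lat_max Northern edge of the window (default 90).
#' @param lon_min Western edge (default -90).
#' @param t_intercept Sea-level/equator intercept `a` of the gradient
#'   `T_min(lat) = a - b * |lat|` (default 25 degC).
#' @param lapse Latitudinal gradient `b` in degC per degree latitude
#'   (default 0.5).
#' @param sigma_clim SD of cell-level climate noise (default 0.5 degC).
#' @param warming Uniform future warming in degC (default +2).
#' @param n_species Cohort size (default 100).
#' @param me_meanlog,me_sdlog Parameters of the shifted-lognormal true
#'   expansibility, `ME = 1 + LogNormal(meanlog, sdlog)` (defaults 1.0 and
#'   0.4, giving a right-skewed distribution with mean near 4).
#' @param delta_torpor Additive true ME effect of torpor/hibernation use
#'   (default +1.5).
#' @param beta_mass True ME slope per log10 gram of body mass (default
#'   -0.5).
#' @param p_torpor,p_nocturnal Trait prevalences (defaults 0.3, 0.5).
#' @param sigma_edge SD of the per-longitude range-edge jitter, in cells
#'   (default 1).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams (climate, physiology, edges).
#' @return List of class `synthetic_world_spec`.
#' @export
synthetic_world_spec <- function(n_lat = 180, n_lon = 360, res = 0.5,
                                 lat_max = 90, lon_min = -90,
                                 t_intercept = 25, lapse = 0.5,
                                 sigma_clim = 0.5, warming = 2,
                                 n_species = 100,
                                 me_meanlog = 1.0, me_sdlog = 0.4,
                                 delta_torpor = 1.5, beta_mass = -0.5,
                                 p_torpor = 0.3, p_nocturnal = 0.5,
                                 sigma_edge = 1, seed = 1) {
  stopifnot(lapse > 0, sigma_clim >= 0, sigma_edge >= 0, n_species >= 1)
  structure(as.list(environment()), class = "synthetic_world_spec")
}

# independent substream seeds derived from the master seed (kept in 32-bit
# integer range)
substream_seed <- function(seed, stream) {
  offs <- c(climate = 101L, physiology = 211L, edges = 307L, msum = 401L)
  (as.integer(seed) %% 1000003L) * 1009L + offs[[stream]]
}

#' Generate current and future climate grids
#'
#' `T_min(lat) = a - b * |lat| + eps` with cell-level Gaussian noise; the
#' future grid adds the warming pattern to the *same* realization, so the
#' two scenarios differ exactly by the prescribed warming.
#'
#' @param spec A [synthetic_world_spec()].
#' @return List with `current` and `future` [climate_grid()]s.
#' @export
make_climate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  lat <- spec$lat_max - spec$res / 2 - spec$res * (0:(spec$n_lat - 1))
  lon <- spec$lon_min + spec$res / 2 + spec$res * (0:(spec$n_lon - 1))
  base <- outer(spec$t_intercept - spec$lapse * abs(lat),
                rep(1, spec$n_lon))
  noise <- with_preserved_rng(substream_seed(spec$seed, "climate"), {
    matrix(stats::rnorm(spec$n_lat * spec$n_lon, 0, spec$sigma_clim),
           spec$n_lat, spec$n_lon)
  })
  cur <- climate_grid(base + noise, lat, lon)
  fut <- climate_grid(cur$values + spec$warming, lat, lon)
  list(current = cur, future = fut)
}

#' Generate a species cohort with known ground truth
#'
#' Draws physiology (body temperature ~ N(38, 1); lower critical
#' temperature ~ N(28, 3) truncated at least 2 degC below body temperature;
#' mass log-uniform on 5 g - 5 kg; BMR = 3.5 mass^0.72 e^eta allometry with
#' lognormal scatter), traits, and a true expansibility
#' `ME = 1 + LogNormal(me_meanlog, me_sdlog) + delta_torpor * torpor +
#' beta_mass * (log10 mass - centre)`.  Each species' true thermal limit is
#' `t_lc - (ME - 1)(t_b - t_lc)`; its range occupies a random longitudinal
#' window and all rows equatorward of the thermal-limit isocline of the
#' noise-free gradient, with per-column edge jitter of SD `sigma_edge`
#' cells.  Draws whose isocline would leave the grid (or whose true ME
#' falls below 1.05) are redrawn, with a bounded retry budget.
#'
#' @param spec A [synthetic_world_spec()].
#' @param climate Output of [make_climate()] (used for the grid template).
#' @return List with `physiology` (data frame in the [read_physiology()]
#'   schema), `traits`, `masks` (named list of [range_mask()]), and
#'   `truth` (data frame with `me_true`, `t_limit`, `edge_lat` etc.).
#' @export
make_species_cohort <- function(spec, climate) {
  stopifnot(inherits(spec, "synthetic_world_spec"))
  grid <- climate$current
  lat <- grid$lat; lon <- grid$lon
  n <- spec$n_species
  centre_logmass <- mean(log10(c(5, 5000)))
  lat_lo <- min(lat) + 2 * spec$res
  lat_hi <- max(lat) - 2 * spec$res

  draw <- with_preserved_rng(substream_seed(spec$seed, "physiology"), {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        t_b <- stats::rnorm(1, 38, 1)
        t_lc <- stats::rnorm(1, 28, 3)
        if (t_lc > t_b - 2) t_lc <- t_b - 2 - abs(t_lc - (t_b - 2))
        mass <- 10^stats::runif(1, log10(5), log10(5000))
        bmr <- 3.5 * mass^0.72 * exp(stats::rnorm(1, 0, 0.15))
        torpor <- stats::rbinom(1, 1, spec$p_torpor)
        nocturnal <- stats::rbinom(1, 1, spec$p_nocturnal)
        diet <- sample(c("granivore", "herbivore", "invertivore",
                         "carnivore", "omnivore"), 1)
        me_true <- 1 + stats::rlnorm(1, spec$me_meanlog, spec$me_sdlog) +
          spec$delta_torpor * torpor +
          spec$beta_mass * (log10(mass) - centre_logmass)
        t_limit <- t_lc - (me_true - 1) * (t_b - t_lc)
        edge_lat <- (spec$t_intercept - t_limit) / spec$lapse
        if (me_true >= 1.05 && edge_lat > lat_lo + 10 && edge_lat < lat_hi)
          break
        if (try == 200)
          stop("make_species_cohort(): could not place species ", i,
               " inside the grid; widen the grid or adjust the ME range")
      }
      out[[i]] <- list(t_b = t_b, t_lc = t_lc, mass = mass, bmr = bmr,
                       torpor = torpor, nocturnal = nocturnal, diet = diet,
                       me_true = me_true, t_limit = t_limit,
                       edge_lat = edge_lat,
                       taxon = sample(c("mammal", "bird"), 1, prob = c(0.7, 0.3)),
                       has_msum = stats::runif(1) < 0.25,
                       msum_factor = 5 * exp(stats::rnorm(1, 0, 0.2)))
    }
    out
  })

  masks <- with_preserved_rng(substream_seed(spec$seed, "edges"), {
    ms <- vector("list", n)
    for (i in seq_len(n)) {
      d <- draw[[i]]
      width <- sample(40:160, 1)
      start <- sample(seq_len(length(lon) - width + 1), 1)
      cols <- start:(start + width - 1)
      span <- stats::runif(1, 15, 40)
      edge_row <- which.min(abs(lat - d$edge_lat))  # row of the cold edge
      s_row <- which.min(abs(lat - max(min(lat), d$edge_lat - span)))
      pres <- matrix(FALSE, length(lat), length(lon))
      jit <- round(stats::rnorm(width, 0, spec$sigma_edge))
      for (k in seq_along(cols)) {
        top <- min(max(edge_row + jit[k], 2L), s_row)
        pres[top:s_row, cols[k]] <- TRUE
      }
      ms[[i]] <- range_mask(pres, lat, lon,
                            species_id = sprintf("sp%03d", i))
    }
    names(ms) <- sprintf("sp%03d", seq_len(n))
    ms
  })

  ids <- sprintf("sp%03d", seq_len(n))
  g <- function(f) vapply(draw, function(d) f(d), numeric(1))
  gc_ <- function(f) vapply(draw, function(d) f(d), character(1))
  physiology <- data.frame(
    species_id = ids,
    class = gc_(function(d) d$taxon),
    mass_g = g(function(d) d$mass),
    bmr_mlO2_h = g(function(d) d$bmr),
    tb_C = g(function(d) d$t_b),
    tlc_C = g(function(d) d$t_lc),
    tuc_C = NA_real_,
    msum_mlO2_h = g(function(d) if (d$has_msum) d$bmr * d$msum_factor else NA_real_),
    conductance_mlO2_h_C = NA_real_,
    resting_phase = "yes", postabsorptive = "yes", wild_caught = "yes",
    collection_lat = NA_real_, collection_lon = NA_real_,
    exclude_island = "no", exclude_continental_limit = "no",
    stringsAsFactors = FALSE)
  traits <- data.frame(
    species_id = ids,
    diet = gc_(function(d) d$diet),
    nocturnal = g(function(d) d$nocturnal),
    torpor = g(function(d) d$torpor),
    mass_g = g(function(d) d$mass),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    species_id = ids,
    me_true = g(function(d) d$me_true),
    t_limit = g(function(d) d$t_limit),
    edge_lat = g(function(d) d$edge_lat),
    t_b = g(function(d) d$t_b),
    t_lc = g(function(d) d$t_lc),
    bmr = g(function(d) d$bmr),
    mass_g = g(function(d) d$mass),
    torpor = g(function(d) d$torpor),
    stringsAsFactors = FALSE)
  list(physiology = physiology, traits = traits, masks = masks, truth = truth)
}

#' Generate a full synthetic world
#'
#' Convenience wrapper: climate plus cohort.
#'
#' @param spec A [synthetic_world_spec()].
#' @return List with `spec`, `climate` (current/future grids), and the
#'   cohort components of [make_species_cohort()].
#' @export
make_world <- function(spec = synthetic_world_spec()) {
  climate <- make_climate(spec)
  cohort <- make_species_cohort(spec, climate)
  c(list(spec = spec, climate = climate), cohort)
}

#' Write a synthetic world to disk in the pipeline's input formats
#'
#' Emits `physiology.csv`, `traits.csv`, `climate_current.asc`,
#' `climate_future.asc`, and one presence grid `ranges/<species_id>.asc`
#' per species, i.e. exactly the files [run_pipeline()] consumes.
#'
#' @param world Output of [make_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "ranges"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(world$physiology, file.path(dir, "physiology.csv"),
                   row.names = FALSE)
  utils::write.csv(world$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE)
  write_ascii_grid(world$climate$current, file.path(dir, "climate_current.asc"))
  write_ascii_grid(world$climate$future, file.path(dir, "climate_future.asc"))
  for (id in names(world$masks))
    write_ascii_grid(world$masks[[id]], file.path(dir, "ranges", paste0(id, ".asc")))
  invisible(dir)
}

#' Small deterministic fixtures used throughout the unit tests
#'
#' Hand-written grids and tables exercising the boundary-extraction,
#' clump-filtering and physiology rules: a 5 x 5 block mask, a staircase
#' mask whose per-column northern extremes are known, a clump raster with
#' component sizes 100, 4 and 6 (so the 5% rule keeps 100 and 6), and a
#' two-species physiology table.
#'
#' @return Named list of fixtures; element names are stable.
#' @export
make_fixtures <- function() {
  lat5 <- seq(44.5, 40.5, by = -1)  # north-up
  lon5 <- seq(0.5, 4.5, by = 1)
  block <- matrix(FALSE, 5, 5)
  block[2:4, ] <- TRUE              # presence rows 2-4 in all columns

  stair <- matrix(FALSE, 5, 5)
  stair[2:5, 1] <- TRUE             # column extremes at rows 2, 3, 4
  stair[3:5, 2] <- TRUE
  stair[4:5, 3] <- TRUE

  # clump raster: 10x10 block (100 cells), 2x3 block (6), 2x2 block (4),
  # mutually separated by > 1 cell so they stay distinct under queen
  # connectivity
  cl <- matrix(FALSE, 16, 20)
  cl[1:10, 1:10] <- TRUE
  cl[1:2, 13:15] <- TRUE
  cl[13:14, 13:14] <- TRUE

  phys <- data.frame(
    species_id = c("toy_warm", "toy_cold"),
    taxon_class = c("bird", "mammal"),
    mass_g = c(25, 300),
    bmr = c(100, 400),
    t_b = c(40, 37),
    t_lc = c(30, 27),
    t_uc = c(36, NA),
    m_sum = c(500, NA),
    stringsAsFactors = FALSE)

  list(
    block_mask = range_mask(block, lat5, lon5, "toy_block"),
    stair_mask = range_mask(stair, lat5, lon5, "toy_stair"),
    stair_extreme_rows = c(2L, 3L, 4L),
    clump_grid = cl,
    clump_sizes = c(100L, 6L, 4L),
    physiology = phys)
}
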