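#' Read and validate a physiology table
#'
#' Reads the documented physiology CSV schema and normalises it to the
#' package's internal representation.  Mandatory columns: `species_id`,
#' `class` (`bird`/`mammal`), `mass_g`, `bmr_mlO2_h`, `tb_C`, `tlc_C`.
#' Optional: `tuc_C`, `msum_mlO2_h`, `conductance_mlO2_h_C`, `bmr_unit`
#' and `msum_unit` (`mlO2_h` or `W`; rates reported in watts are converted
#' once at read time with the 179 ml O2 h^-1 W^-1 lipid-metabolism factor
#' and the original unit retained), data-quality flags (`resting_phase`,
#' `postabsorptive`, `wild_caught`), collection coordinates, and the
#' exclusion flags `exclude_island` / `exclude_continental_limit`.
#'
#' Rows violating the record invariants (e.g. `tlc_C >= tb_C`) are
#' quarantined with a reason rather than aborting the read; only an
#' unparseable or schema-less file is an error.
#'
#' @param path CSV path.
#' @return List with `data` (clean records, internal column names:
#'   `species_id`, `taxon_class`, `mass_g`, `bmr`, `t_b`, `t_lc`, `t_uc`,
#'   `m_sum`, `conductance`, flags, `bmr_unit_original`) and `quarantined`
#'   (data frame `species_id`, `problem`).
#' @export
read_physiology <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "class", "mass_g", "bmr_mlO2_h", "tb_C", "tlc_C")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("read_physiology(): missing mandatory columns: ",
         paste(miss, collapse = ", "))
  num <- function(col) if (col %in% names(raw)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    v
  } else rep(NA_real_, nrow(raw))
  chr <- function(col, default = "unknown") if (col %in% names(raw))
    as.character(raw[[col]]) else rep(default, nrow(raw))
  for (col in c("mass_g", "bmr_mlO2_h", "tb_C", "tlc_C"))
    if (all(is.na(num(col))) && nrow(raw) > 0)
      stop("read_physiology(): column '", col, "' is not numeric")

  bmr_unit <- chr("bmr_unit", "mlO2_h")
  bmr <- num("bmr_mlO2_h")
  bmr[bmr_unit == "W"] <- watts_to_mlO2_per_h(bmr[bmr_unit == "W"])
  msum_unit <- chr("msum_unit", "mlO2_h")
  m_sum <- num("msum_mlO2_h")
  conv <- msum_unit == "W" & !is.na(m_sum)
  m_sum[conv] <- watts_to_mlO2_per_h(m_sum[conv])

  d <- data.frame(
    species_id = as.character(raw$species_id),
    taxon_class = as.character(raw$class),
    mass_g = num("mass_g"),
    bmr = bmr,
    t_b = num("tb_C"),
    t_lc = num("tlc_C"),
    t_uc = num("tuc_C"),
    m_sum = m_sum,
    conductance = num("conductance_mlO2_h_C"),
    resting_phase = chr("resting_phase"),
    postabsorptive = chr("postabsorptive"),
    wild_caught = chr("wild_caught"),
    collection_lat = num("collection_lat"),
    collection_lon = num("collection_lon"),
    exclude_island = chr("exclude_island", "no"),
    exclude_continental_limit = chr("exclude_continental_limit", "no"),
    bmr_unit_original = bmr_unit,
    stringsAsFactors = FALSE)

  incomplete <- is.na(d$bmr) | is.na(d$mass_g) | is.na(d$t_b) | is.na(d$t_lc)
  quarantined <- if (any(incomplete))
    data.frame(species_id = d$species_id[incomplete],
               problem = "missing_required_value", stringsAsFactors = FALSE)
  else data.frame(species_id = character(), problem = character(),
                  stringsAsFactors = FALSE)
  d2 <- d[!incomplete, , drop = FALSE]
  report <- validate_physiology(d2)
  quarantined <- rbind(quarantined, report)
  list(data = d2[!d2$species_id %in% report$species_id, , drop = FALSE],
       quarantined = quarantined)
}

#' Normalise a physiology table from the CSV schema to internal names
#'
#' Maps the documented interchange columns (`class`, `bmr_mlO2_h`, `tb_C`,
#' `tlc_C`, `tuc_C`, `msum_mlO2_h`, `conductance_mlO2_h_C`) to the internal
#' names used by [analyze_cohort()] (`taxon_class`, `bmr`, `t_b`, `t_lc`,
#' `t_uc`, `m_sum`, `conductance`).  Useful when a cohort is built in
#' memory (e.g. by [make_world()]) rather than read from disk.
#'
#' @param df Data frame in the CSV schema.
#' @return The same data frame with internal column names.
#' @export
normalize_physiology <- function(df) {
  map <- c(class = "taxon_class", bmr_mlO2_h = "bmr", tb_C = "t_b",
           tlc_C = "t_lc", tuc_C = "t_uc", msum_mlO2_h = "m_sum",
           conductance_mlO2_h_C = "conductance")
  hit <- names(df) %in% names(map)
  names(df)[hit] <- unname(map[names(df)[hit]])
  df
}

#' Read a species trait table
#'
#' Schema: `species_id`, `diet`, `nocturnal` (0/1), `torpor` (0/1; 1 when
#' the species uses torpor or hibernation), `mass_g`.  Diet guilds outside
#' the controlled vocabulary (granivore, herbivore, invertivore, carnivore,
#' omnivore) can be collapsed via `diet_map`, a named character vector from
#' source guild to vocabulary entry.
#'
#' @param path CSV path.
#' @param diet_map Optional named character vector remapping diet labels.
#' @return Data frame with a `log10_mass` column added.
#' @export
read_traits <- function(path, diet_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "diet", "nocturnal", "torpor", "mass_g")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_traits(): missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(diet_map)) {
    hit <- d$diet %in% names(diet_map)
    d$diet[hit] <- unname(diet_map[d$diet[hit]])
  }
  vocab <- c("granivore", "herbivore", "invertivore", "carnivore", "omnivore")
  bad <- setdiff(unique(d$diet), vocab)
  if (length(bad))
    stop("read_traits(): diet categories outside the vocabulary: ",
         paste(bad, collapse = ", "), "; supply 'diet_map'")
  if (!all(d$torpor %in% c(0, 1)) || !all(d$nocturnal %in% c(0, 1)))
    stop("read_traits(): 'torpor' and 'nocturnal' must be 0/1")
  d$log10_mass <- log10(d$mass_g)
  d
}

#' Pipeline configuration
#'
#' Collects paths and analysis options.  Paths are validated at
#' construction so a misconfigured run fails before any computation.
#'
#' @param physiology,traits Paths to the input CSVs.
#' @param ranges_dir Directory of per-species presence grids
#'   (`<species_id>.asc`).
#' @param climate_current,climate_future Paths to minimum-temperature
#'   grids (ESRI ASCII).
#' @param out_dir Output directory (created at run time).
#' @param raster_scale Multiplier applied to stored raster values (use 0.1
#'   for integer tenth-degree grids).
#' @param mad_constant,connectivity,wrap,clump_frac,area,subpeak_tol
#'   Analysis options, see the stage functions.
#' @param n_reps Randomization-null replicates (default 1000).
#' @param dip_reps Dip-test null replicates (default 2000).
#' @param seed Seed for all stochastic stages.
#' @param scenario_label Tag for the future scenario in outputs.
#' @param write_rasters Write projected masks as ASCII grids? Default
#'   `FALSE`.
#' @return List of class `coldrange_config`.
#' @export
pipeline_config <- function(physiology, traits, ranges_dir,
                            climate_current, climate_future,
                            out_dir = "coldrange_out",
                            raster_scale = 1,
                            mad_constant = 1.4826, connectivity = 8,
                            wrap = FALSE, clump_frac = 0.05,
                            area = "cells", subpeak_tol = 0.05,
                            n_reps = 1000, dip_reps = 2000, seed = 1,
                            scenario_label = "future",
                            write_rasters = FALSE) {
  for (p in c(physiology, traits, ranges_dir, climate_current, climate_future))
    if (!file.exists(p))
      stop("pipeline_config(): path does not exist: ", p)
  stopifnot(connectivity %in% c(4, 8), clump_frac >= 0, clump_frac <= 1,
            subpeak_tol >= 0, subpeak_tol < 1, n_reps >= 1, dip_reps >= 1)
  structure(as.list(environment()), class = "coldrange_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the file's directory.
#'
#' @param path YAML file.
#' @return A validated `coldrange_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p))
    file.path(base, p) else p
  for (k in c("physiology", "traits", "ranges_dir", "climate_current",
              "climate_future"))
    y[[k]] <- fix(y[[k]])
  do.call(pipeline_config, y)
}

#' Analyse a cohort held in memory
#'
#' The computational core of [run_pipeline()], operating on already-loaded
#' objects: boundary extraction and temperature summaries, species
#' filters, metabolic expansibility, distribution statistics and
#' randomization nulls per taxon class, trait model selection, and
#' current/future cold-boundary projection.
#'
#' @param phys Physiology data frame (internal names, see
#'   [read_physiology()]).
#' @param traits Trait data frame (see [read_traits()]); may be `NULL` to
#'   skip trait models.
#' @param masks Named list of [range_mask()], one per species.
#' @param clim_current,clim_future [climate_grid()]s; `clim_future` may be
#'   `NULL` to skip projection.
#' @param mad_constant,connectivity,wrap,clump_frac,area,subpeak_tol,n_reps,dip_reps,seed
#'   Options as in [pipeline_config()].
#' @param quiet Suppress stage messages?
#' @return Results bundle: list with `species` (per-species table),
#'   `exclusions`, `class_summaries`, `nulls`, `trait_models`,
#'   `projections`, `options`.
#' @export
analyze_cohort <- function(phys, traits, masks, clim_current,
                           clim_future = NULL,
                           mad_constant = 1.4826, connectivity = 8,
                           wrap = FALSE, clump_frac = 0.05, area = "cells",
                           subpeak_tol = 0.05, n_reps = 1000,
                           dip_reps = 2000, seed = 1, quiet = FALSE) {
  say <- function(...) if (!quiet) message("coldrange: ", ...)

  say("extracting range boundaries for ", length(masks), " species")
  brows <- lapply(names(masks), function(id) {
    prof <- cold_boundaries(masks[[id]])[[1]]
    bs <- boundary_temperature_summary(prof, clim_current,
                                       mad_constant = mad_constant)
    data.frame(species_id = id, hemisphere = prof$hemisphere,
               t_min = bs$t_median, t_sd = bs$t_sd, t_mad = bs$t_mad,
               boundary_lat = prof$lat_median, n_boundary_cells = bs$n,
               stringsAsFactors = FALSE)
  })
  boundary <- do.call(rbind, brows)

  say("applying species filters")
  flt <- apply_species_filters(phys, boundary)
  tab <- flt$kept
  if (nrow(tab) == 0) stop("analyze_cohort(): no species survive the filters")

  say("computing metabolic expansibility for ", nrow(tab), " species")
  cond <- ifelse(!is.na(tab$conductance), tab$conductance,
                 estimate_conductance(tab$bmr, tab$t_b, tab$t_lc))
  tab$conductance_used <- cond
  mr <- mr_at_cold_boundary(tab$t_min, tab$t_lc, cond, tab$bmr)
  tab$mr_crb <- as.numeric(mr)
  tab$me_crb <- metabolic_expansibility(tab$mr_crb, tab$bmr)
  tab$t_limit <- thermal_limit(tab$me_crb, tab$t_lc, tab$bmr, cond)
  tab$msum_ratio <- ifelse(!is.na(tab$m_sum) & tab$m_sum > 0,
                           msum_ratio(tab$mr_crb, pmax(tab$m_sum, 1e-12)),
                           NA_real_)
  tab$mr_sensitivity_pct <- mr_sensitivity(tab$t_sd, cond, tab$mr_crb)

  say("distribution statistics per taxon class")
  class_summaries <- list(); nulls <- list()
  for (cl in unique(tab$taxon_class)) {
    sub <- tab[tab$taxon_class == cl, ]
    if (nrow(sub) >= 8) {
      class_summaries[[cl]] <- me_distribution_summary(
        sub$me_crb, subpeak_tol = subpeak_tol, dip_reps = dip_reps,
        seed = seed + 7)
      nulls[[cl]] <- list(
        median = randomization_null(sub, sub$t_min, "median",
                                    n_reps = n_reps, seed = seed + 11),
        mean = randomization_null(sub, sub$t_min, "mean",
                                  n_reps = n_reps, seed = seed + 13))
    } else say("  skipping class '", cl, "' (n = ", nrow(sub), " < 8)")
  }

  trait_models <- NULL
  if (!is.null(traits)) {
    say("trait model selection")
    td <- merge(tab[, c("species_id", "me_crb")], traits, by = "species_id")
    terms <- c("log10_mass", "diet", "nocturnal", "torpor")
    terms <- terms[vapply(terms, function(t)
      length(unique(td[[t]])) > 1, logical(1))]
    if (nrow(td) > length(terms) + 3 && length(terms)) {
      trait_models <- list(
        full = fit_trait_model(td, predictors = terms),
        dredge = dredge_and_average(td, terms))
    } else say("  too few species or no varying traits; skipping")
  }

  projections <- NULL
  if (!is.null(clim_future)) {
    say("projecting cold range boundaries")
    prows <- lapply(seq_len(nrow(tab)), function(i) {
      id <- tab$species_id[i]
      hemi <- tab$hemisphere[i]
      cur <- project_range(tab$t_limit[i], clim_current, masks[[id]],
                           hemisphere = hemi, connectivity = connectivity,
                           wrap = wrap, clump_frac = clump_frac, area = area)
      fut <- project_range(tab$t_limit[i], clim_future, masks[[id]],
                           hemisphere = hemi, connectivity = connectivity,
                           wrap = wrap, clump_frac = clump_frac, area = area)
      data.frame(species_id = id,
                 crb_lat_current = cur$crb_lat,
                 crb_lat_future = fut$crb_lat,
                 shift_deg = as.numeric(shift_deg(cur, fut, hemi)),
                 flags = paste(unique(c(cur$flags, fut$flags)), collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    projections <- do.call(rbind, prows)
  }

  list(species = tab, exclusions = flt$excluded,
       class_summaries = class_summaries, nulls = nulls,
       trait_models = trait_models, projections = projections,
       options = list(mad_constant = mad_constant,
                      connectivity = connectivity, wrap = wrap,
                      clump_frac = clump_frac, area = area,
                      subpeak_tol = subpeak_tol, n_reps = n_reps,
                      dip_reps = dip_reps, seed = seed))
}

#' Run the full pipeline from a configuration
#'
#' Reads the configured inputs, runs [analyze_cohort()], and writes the
#' results bundle: `species.csv` (per-species ME table),
#' `exclusions.csv`, `summary.json` (distribution statistics, null
#' intervals, averaged trait coefficients), `projections.csv`, per-class
#' density curves `density_<class>.csv`, optional projected-mask rasters,
#' and `manifest.yaml` recording the seed, options, and MD5 checksums of
#' every input so a run can be reproduced exactly.
#'
#' @param config A `coldrange_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param quiet Suppress stage messages?
#' @return The results bundle of [analyze_cohort()], invisibly, with
#'   `out_dir` attached.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "coldrange_config"))
  say <- function(...) if (!quiet) message("coldrange: ", ...)

  say("reading inputs")
  ph <- read_physiology(config$physiology)
  tr <- read_traits(config$traits)
  cur <- read_ascii_grid(config$climate_current, scale = config$raster_scale)
  fut <- read_ascii_grid(config$climate_future, scale = config$raster_scale)
  files <- list.files(config$ranges_dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(files))
    stop("run_pipeline(): no presence grids (*.asc) in ", config$ranges_dir)
  masks <- lapply(files, function(f) {
    g <- read_ascii_grid(f)
    range_mask(g$values > 0, g$lat, g$lon,
               species_id = sub("\\.asc$", "", basename(f)))
  })
  names(masks) <- vapply(masks, function(m) m$species_id, character(1))
  masks <- masks[names(masks) %in% ph$data$species_id]

  res <- analyze_cohort(ph$data, tr, masks, cur, fut,
                        mad_constant = config$mad_constant,
                        connectivity = config$connectivity,
                        wrap = config$wrap, clump_frac = config$clump_frac,
                        area = config$area,
                        subpeak_tol = config$subpeak_tol,
                        n_reps = config$n_reps, dip_reps = config$dip_reps,
                        seed = config$seed, quiet = quiet)
  res$quarantined <- ph$quarantined

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say("writing results to ", out)
  utils::write.csv(res$species, file.path(out, "species.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(res$exclusions,
                         stats::setNames(ph$quarantined,
                                         names(res$exclusions))),
                   file.path(out, "exclusions.csv"), row.names = FALSE)
  if (!is.null(res$projections))
    utils::write.csv(res$projections, file.path(out, "projections.csv"),
                     row.names = FALSE)

  summary_json <- list(
    classes = lapply(res$class_summaries, function(s) unclass(s)),
    nulls = lapply(res$nulls, function(nl) list(
      median = nl$median[c("lower", "upper", "observed")],
      mean = nl$mean[c("lower", "upper", "observed")])),
    trait_coefficients = if (!is.null(res$trait_models))
      as.list(res$trait_models$dredge$coefficients),
    n_species = nrow(res$species),
    n_excluded = nrow(res$exclusions))
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (cl in names(res$class_summaries)) {
    pk <- kde_peak(res$species$me_crb[res$species$taxon_class == cl],
                   subpeak_tol = config$subpeak_tol)
    utils::write.csv(pk$density,
                     file.path(out, paste0("density_", cl, ".csv")),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "coldrange",
    version = as.character(utils::packageVersion("coldrange")),
    seed = config$seed,
    scenario_label = config$scenario_label,
    options = res$options,
    inputs = lapply(
      stats::setNames(nm = c("physiology", "traits", "climate_current",
                             "climate_future")),
      function(k) list(path = config[[k]],
                       md5 = unname(tools::md5sum(config[[k]])))))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  attr(res, "out_dir") <- out
  invisible(res)
}
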