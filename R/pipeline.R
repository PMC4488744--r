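# End-to-end orchestration: class maps -> MSPA -> indices -> transition
# chains -> change statistics, from a config list or YAML file, plus a
# seeded demo dataset emulating the published 1985-2010 farmland
# trajectory of South Jiangsu Province.

#' Published South Jiangsu farmland areas, 1985-2010
#'
#' Total and farmland areas (km2) of South Jiangsu Province at the six
#' census dates of the 1985-2010 record, as published from the classified
#' Landsat maps. The farmland share falls from 64.56% to 49.10% over the
#' period.
#'
#' @return An [area_time_series()] with 6 rows.
#' @export
south_jiangsu_areas <- function() {
  area_time_series(
    year = c(1985, 1995, 2000, 2005, 2008, 2010),
    total_area_km2 = c(27749.26, 27749.26, 27749.78, 27749.77,
                       27778.31, 27778.27),
    farmland_area_km2 = c(17915.52, 16959.94, 16397.31, 15194.71,
                          14024.83, 13638.64)
  )
}

#' Published per-date map accuracy and landscape descriptors, 1985-2010
#'
#' Total classification accuracy, kappa coefficient, contagion index and
#' farmland proportion of the six classified maps behind
#' [south_jiangsu_areas()]; useful as calibration targets for the
#' synthetic generator (F 0.49-0.65, contagion about 47-50).
#'
#' @return data.frame with columns `year`, `tca`, `kappa`, `contagion`,
#'   `proportion_pct`.
#' @export
south_jiangsu_accuracy <- function() {
  data.frame(
    year = c(1985, 1995, 2000, 2005, 2008, 2010),
    tca = c(0.85, 0.87, 0.86, 0.87, 0.88, 0.87),
    kappa = c(0.70, 0.73, 0.71, 0.74, 0.75, 0.73),
    contagion = c(49.579, 48.702, 47.088, 47.246, 47.547, 47.463),
    proportion_pct = c(64.56, 61.12, 59.09, 54.76, 50.49, 49.10)
  )
}

# Remove foreground with small punches + edge erosion until the foreground
# proportion reaches the target (deterministic under the caller's RNG
# state). Loss only; never adds cells.
reduce_to_f <- function(fg, target_f) {
  n <- length(fg)
  guard <- 0L
  while (mean(fg) > target_f && guard < 200000L) {
    guard <- guard + 1L
    if (stats::runif(1) < 0.7) {
      r <- sample.int(nrow(fg), 1); c <- sample.int(ncol(fg), 1)
      if (!fg[r, c]) next
      rr <- max(1, r - 2):min(nrow(fg), r + 2)
      cc <- max(1, c - 2):min(ncol(fg), c + 2)
      fg[rr, cc] <- FALSE
    } else {
      boundary <- which(fg & mask_dilate(!fg, 8))
      if (length(boundary) == 0L) break
      take <- boundary[stats::runif(length(boundary)) < 0.02]
      excess <- sum(fg) - ceiling(target_f * n)
      if (length(take) > excess) take <- take[seq_len(max(0, excess))]
      fg[take] <- FALSE
    }
  }
  fg
}

#' Seeded three-date fragmentation scenario
#'
#' Generates a clustered base landscape and degrades it by loss edits to
#' emulate the published farmland trajectory: foreground proportions
#' 0.6456 (1985), 0.5909 (2000) and 0.4910 (2010). Core farmland shrinks
#' and islet farmland grows along the sequence, the qualitative signature
#' of fragmentation-by-loss.
#'
#' @param n_rows,n_cols Grid size (default 192; the base map is generated
#'   with a coarse factor of 4, giving block-contiguous farmland whose
#'   realized proportion is normally within 0.02 of target).
#' @param seed Integer seed.
#' @param cluster_p Clustering of the base map.
#' @param coarse_factor Block replication factor of the base map.
#' @return List with `years`, `targets` and `landscapes` (list of three
#'   [binary_landscape()]).
#' @export
demo_scenario <- function(n_rows = 192, n_cols = 192, seed = 1,
                          cluster_p = 0.5, coarse_factor = 4) {
  props <- south_jiangsu_areas()
  prop <- props$farmland_area_km2 / props$total_area_km2
  targets <- prop[match(c(1985, 2000, 2010), props$year)]
  base <- generate_mrc(n_rows, n_cols, target_f = targets[1],
                       cluster_p = cluster_p, seed = seed,
                       coarse_factor = coarse_factor)
  with_seed(seed + 1L, {
    g2 <- reduce_to_f(base$grid, targets[2])
    g3 <- reduce_to_f(g2, targets[3])
    list(years = c(1985, 2000, 2010), targets = targets,
         landscapes = list(base,
                           binary_landscape(g2, base$cell_size),
                           binary_landscape(g3, base$cell_size)))
  })
}

#' Write the demo dataset to disk
#'
#' Writes the three scenario rasters (ESRI ASCII grids), the published
#' area table (`areas.csv`), and a synthetic driver table
#' (`factors_synthetic.csv`: smooth exponential interpolations anchored at
#' the published 1985/2010 GDP, agricultural-production and share values —
#' synthetic stand-ins, not observed yearly data). Rerunning with the same
#' seed reproduces every file byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_rows,n_cols Raster size.
#' @return Invisible list of file paths.
#' @export
demo_dataset <- function(out_dir, seed = 1, n_rows = 192, n_cols = 192) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- demo_scenario(n_rows, n_cols, seed = seed)
  paths <- character(0)
  for (i in seq_along(sc$years)) {
    p <- file.path(out_dir, sprintf("farmland_%d.asc", sc$years[i]))
    write_asc(sc$landscapes[[i]]$grid * 1L, p,
              cell_size = sc$landscapes[[i]]$cell_size)
    paths <- c(paths, p)
  }
  areas <- south_jiangsu_areas()
  ap <- file.path(out_dir, "areas.csv")
  utils::write.csv(areas, ap, row.names = FALSE)
  yrs <- areas$year
  interp <- function(v0, v1) v0 * (v1 / v0)^((yrs - 1985) / 25)
  fac <- data.frame(
    year = yrs,
    GDP = interp(43.3, 2506.74),
    GAP = interp(6.24, 58.43),
    PGAP = interp(14.43, 2.33)
  )
  fp <- file.path(out_dir, "factors_synthetic.csv")
  utils::write.csv(fac, fp, row.names = FALSE)
  invisible(list(rasters = paths, areas = ap, factors = fp))
}

#' Run the full fragmentation analysis pipeline
#'
#' Sequences the analysis stages over a set of dated class rasters:
#' binarization, MSPA segmentation, class proportions, landscape indices,
#' per-pair transition chains with convergence-rate and entropy
#' diagnostics, and (when an area table is given) change statistics.
#' Writes per-year class maps, CSV reports, and a JSON manifest with the
#' parameters and input hashes needed to reproduce the run.
#'
#' @param config A list or path to a YAML file with fields: `maps` (named
#'   list year -> raster path), `foreground_codes` (default 1),
#'   `edge_width` (default 4), `connectivity` (default 8), `cell_size`
#'   (default from raster), `transitions` (list of 2-vectors of years),
#'   `areas_csv` (optional), `out_dir`, `seed` (default 1).
#' @return Invisible list with per-year results, per-pair chain summaries
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  defaults <- list(foreground_codes = 1L, edge_width = 4, connectivity = 8,
                   cell_size = NULL, transitions = list(), areas_csv = NULL,
                   out_dir = ".", seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$maps) || length(cfg$maps) < 1L) stop("config needs >= 1 map")
  if (cfg$edge_width <= 0) stop("edge_width must be positive")
  years <- names(cfg$maps)
  for (tr in cfg$transitions) {
    if (!all(as.character(tr) %in% years)) {
      stop("transition pair references unlisted year: ",
           paste(tr, collapse = " -> "))
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  rasters <- lapply(years, function(y)
    read_landcover(cfg$maps[[y]], cell_size = cfg$cell_size))
  names(rasters) <- years
  shapes <- vapply(rasters, function(r) paste(dim(r$grid), collapse = "x"), "")
  if (length(unique(shapes)) > 1L) {
    stop("rasters are not aligned: shapes ",
         paste(unique(shapes), collapse = ", "))
  }

  maps <- list()
  for (y in years) {
    ls <- binarize(rasters[[y]], foreground_codes = cfg$foreground_codes)
    m <- mspa_segment(ls, edge_width = cfg$edge_width,
                      connectivity = cfg$connectivity)
    props <- class_proportions(m, per = "foreground")
    metrics <- landscape_metrics(ls, connectivity = cfg$connectivity)
    write_class_map(m, file.path(cfg$out_dir, paste0("classes_", y, ".asc")))
    rep <- m$class_areas
    rep$pct_of_foreground <- c(NA, round_report(100 * props))
    utils::write.csv(rep, file.path(cfg$out_dir, paste0("classes_", y, ".csv")),
                     row.names = FALSE)
    utils::write.csv(metrics,
                     file.path(cfg$out_dir, paste0("metrics_", y, ".csv")),
                     row.names = FALSE)
    maps[[y]] <- list(landscape = ls, mspa = m, proportions = props,
                      metrics = metrics)
  }

  chains <- list()
  for (tr in cfg$transitions) {
    y1 <- as.character(tr[1]); y2 <- as.character(tr[2])
    model <- estimate_transitions(maps[[y1]]$mspa, maps[[y2]]$mspa)
    sm <- chain_summary(model)
    key <- paste0(y1, "_", y2)
    utils::write.csv(model$P,
                     file.path(cfg$out_dir, paste0("transitions_", key, ".csv")))
    jsonlite::write_json(
      list(rho = sm$rho, entropy = sm$entropy, lambda2 = sm$lambda2,
           stationary = as.list(sm$stationary)),
      file.path(cfg$out_dir, paste0("chain_", key, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    chains[[key]] <- list(model = model, summary = sm)
  }

  change <- NULL
  if (!is.null(cfg$areas_csv)) {
    change <- change_statistics(read_area_series(cfg$areas_csv),
                                rounded = TRUE)
    utils::write.csv(change, file.path(cfg$out_dir, "change_stats.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "fragscape",
    version = as.character(utils::packageVersion("fragscape")),
    parameters = cfg[c("foreground_codes", "edge_width", "connectivity",
                       "seed")],
    maps = lapply(cfg$maps, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    transitions = cfg$transitions
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(years = maps, chains = chains, change = change,
                 out_dir = cfg$out_dir))
}
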