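# End-to-end orchestration: one config drives data generation (or loading),
# home ranges, route networks, landscape and resource metrics, and the
# mixed-model battery, writing a deterministic directory of CSV/GeoJSON/JSON
# artifacts.

#' Pipeline run configuration
#'
#' Thresholds default to the analysis constants the pipeline is built
#' around: 10 m matching buffer, 15 m minimum overlap, 45 degree bearing
#' tolerance, habitual = 2 weeks, high-use = 4 weeks, 35 m visual range,
#' 10 m quadrats, 25 m gap buffer, 10,000 CSR simulations.
#'
#' @param synthetic use the synthetic generator (default TRUE); otherwise
#'   `input_dir` must hold `tracks.csv`, `trees.csv`, `gaps.geojson`,
#'   `dem.asc`.
#' @param synth a [synthetic_config()] for synthetic mode.
#' @param input_dir directory of input files for real-data mode.
#' @param seed master seed.
#' @param buffer_m,min_overlap_m,max_dev_deg route-matching parameters.
#' @param habitual_weeks,highuse_weeks route-presence thresholds.
#' @param visual_range_m visual detection distance (m).
#' @param grid_cell_m quadrat size (m).
#' @param gap_radius_m gap-coverage buffer radius (m).
#' @param n_sims CSR simulations.
#' @param csr_radii network buffer radii (m).
#' @param D_grid autocorrelation kernel grid (m).
#' @param model3_random_slopes `"full"` (uncorrelated slopes for every term)
#'   or `"intercept"` (random intercept only; advisable when only a couple of
#'   groups are available).
#' @param exclude_groups group ids excluded from models 1-2.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(synthetic = TRUE, synth = synthetic_config(),
                       input_dir = NULL, seed = synth$seed %||% 1,
                       buffer_m = 10, min_overlap_m = 15, max_dev_deg = 45,
                       habitual_weeks = 2, highuse_weeks = 4,
                       visual_range_m = 35, grid_cell_m = 10,
                       gap_radius_m = 25, n_sims = 10000,
                       csr_radii = c(5, 10, 15, 20), D_grid = 1:30,
                       model3_random_slopes = c("full", "intercept"),
                       exclude_groups = character(0)) {
  model3_random_slopes <- match.arg(model3_random_slopes)
  thr <- list(buffer_m = buffer_m, min_overlap_m = min_overlap_m,
              max_dev_deg = max_dev_deg, habitual_weeks = habitual_weeks,
              highuse_weeks = highuse_weeks, visual_range_m = visual_range_m,
              grid_cell_m = grid_cell_m, gap_radius_m = gap_radius_m,
              n_sims = n_sims)
  if (any(unlist(thr) <= 0)) stop("all thresholds must be positive")
  structure(c(list(synthetic = synthetic, synth = synth,
                   input_dir = input_dir, seed = seed,
                   csr_radii = csr_radii, D_grid = D_grid,
                   model3_random_slopes = model3_random_slopes,
                   exclude_groups = exclude_groups), thr),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' A small, fast pipeline profile
#'
#' Two groups, six sampling weeks, 200 CSR simulations, a coarse
#' autocorrelation grid and intercept-only model-3 random effects: a
#' complete end-to-end run in a couple of minutes, used for smoke testing.
#'
#' @param seed master seed.
#' @return A [run_config()].
#' @export
smoke_config <- function(seed = 1) {
  run_config(
    synthetic = TRUE,
    synth = synthetic_config(seed = seed, n_groups = 2,
                             hr_area_ha = c(8, 10), n_trees = c(140, 180),
                             n_weeks = 6, bouts_per_day = 4,
                             route_nodes = 12),
    seed = seed, n_sims = 200, D_grid = seq(2, 14, by = 3),
    model3_random_slopes = "intercept")
}

#' Load a run configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; the `synth` key holds
#' [synthetic_config()] arguments.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sargs <- y$synth %||% list()
  if (!is.null(sargs$extent)) sargs$extent <- unlist(sargs$extent)
  synth <- do.call(synthetic_config, sargs)
  y$synth <- NULL
  y$model3_random_slopes <- y$model3_random_slopes %||% "full"
  do.call(run_config, c(list(synth = synth), y))
}

.read_inputs <- function(config) {
  dir <- config$input_dir
  need <- c("tracks.csv", "trees.csv", "gaps.geojson", "dem.asc")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s) in ", dir, ": ", paste(missing, collapse = ", "))
  gj <- read_geojson(file.path(dir, "gaps.geojson"))
  gaps <- lapply(gj$geometries, function(g) if (is.list(g)) g[[1]] else g)
  list(tracks = utils::read.csv(file.path(dir, "tracks.csv")),
       trees = utils::read.csv(file.path(dir, "trees.csv")),
       gaps = gaps,
       dem = read_esri_ascii(file.path(dir, "dem.asc")))
}

#' Run the full pipeline
#'
#' Generates (or loads) the data, estimates home ranges, builds the route
#' networks, assembles quadrat covariates and resource metrics, fits the
#' models, and writes all artifacts under `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @param quiet suppress progress messages.
#' @return List of class `"pipeline_result"` with every intermediate product.
#' @export
run_all <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  ## stage: data
  if (config$synthetic) {
    say("stage synth: generating synthetic study (seed %d)", config$seed)
    config$synth$seed <- config$seed
    study <- synth_study(config$synth)
    tracks <- study$tracks; trees <- study$trees
    gaps <- study$gaps; dem <- study$dem
  } else {
    say("stage load: reading inputs from %s", config$input_dir)
    inp <- .read_inputs(config)
    tracks <- inp$tracks; trees <- inp$trees; gaps <- inp$gaps; dem <- inp$dem
    study <- NULL
  }
  gids <- sort(unique(as.character(tracks$group_id)))

  ## stage: home ranges
  say("stage homerange: KDE for %d groups", length(gids))
  hrs <- lapply(gids, function(g) {
    sc <- tracks[tracks$group_id == g & tracks$rec_type == "scan", ]
    kde_home_range(cbind(sc$x, sc$y), group_id = g)
  })
  names(hrs) <- gids
  hr_tab <- hr_summary(hrs)
  hr95 <- lapply(hrs, hr_isopleth, q = 0.95)
  core50 <- lapply(hrs, hr_isopleth, q = 0.5)

  ## stage: route networks
  say("stage network: matching paths (buffer %g m, overlap %g m, %g deg)",
      config$buffer_m, config$min_overlap_m, config$max_dev_deg)
  nets <- lapply(gids, function(g) {
    build_group_network(tracks[tracks$group_id == g, ],
                        buffer_m = config$buffer_m,
                        min_overlap_m = config$min_overlap_m,
                        max_dev_deg = config$max_dev_deg,
                        habitual_threshold = config$habitual_weeks)
  })
  names(nets) <- gids
  net_tab <- do.call(rbind, lapply(nets, network_summary))
  cov <- vapply(gids, function(g) {
    bb <- tracks_to_bouts(tracks[tracks$group_id == g, ])
    as.numeric(network_coverage(bb$lines, nets[[g]]))
  }, 0)
  net_tab$bout_coverage <- cov

  ## stage: trees per group (assigned by home-range membership)
  group_trees <- lapply(gids, function(g) {
    inside <- hr_contains(hrs[[g]], cbind(trees$x, trees$y), 0.95)
    tr <- trees[inside, ]
    if (nrow(tr) == 0 && "group_id" %in% names(trees))
      tr <- trees[trees$group_id == g, ]
    tr
  })
  names(group_trees) <- gids

  ## stage: resource metrics
  say("stage metrics: CSR null (%d sims) and segment rates", config$n_sims)
  buffer_counts <- do.call(rbind, lapply(gids, function(g) {
    csr_null(group_trees[[g]], hr95[[g]], gaps, nets[[g]],
             radii = config$csr_radii, n_sims = config$n_sims,
             seed = module_seed(config$seed, "csr") + match(g, gids))
  }))
  seg_rates <- do.call(rbind, lapply(gids, function(g)
    segment_rates(nets[[g]], group_trees[[g]], radii = config$csr_radii)))

  ## stage: quadrats
  say("stage quadrats: %g m grid with landscape covariates", config$grid_cell_m)
  quads <- lapply(gids, function(g)
    quadrat_table(g, hr95[[g]], dem, gaps, group_trees[[g]], nets[[g]],
                  core = core50[[g]], cell_m = config$grid_cell_m,
                  gap_radius_m = config$gap_radius_m,
                  visual_radii = seq(5, config$visual_range_m, by = 5),
                  habitual_weeks = config$habitual_weeks,
                  highuse_weeks = config$highuse_weeks))
  names(quads) <- gids
  quads <- flag_overlap(quads, hr95)
  quadrats <- do.call(rbind, quads)

  ## stage: models
  say("stage models: mixed-model battery")
  models <- if (config$model3_random_slopes == "full") tryCatch(
    run_route_models(buffer_counts, seg_rates, quadrats,
                     exclude_groups = config$exclude_groups,
                     D_grid = config$D_grid,
                     fixed_effects_check = TRUE),
    error = function(e) {
      say("  model battery failed (%s); retrying with intercept-only random effects",
          conditionMessage(e))
      NULL
    }) else NULL
  if (is.null(models)) {
    models <- .run_models_intercept(buffer_counts, seg_rates, quadrats,
                                    config)
  }

  res <- list(config = config, study = study, tracks = tracks, trees = trees,
              gaps = gaps, dem = dem, home_ranges = hrs, hr_summary = hr_tab,
              networks = nets, network_summary = net_tab,
              buffer_counts = buffer_counts, segment_rates = seg_rates,
              quadrats = quadrats, models = models,
              elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir, quiet = quiet)
  res
}

# model battery with intercept-only random effects (small-cluster profile)
.run_models_intercept <- function(buffer_counts, seg_rates, quadrats, config) {
  out <- list()
  bc <- buffer_counts[!buffer_counts$group_id %in% config$exclude_groups, ]
  m1dat <- rbind(
    data.frame(group_id = bc$group_id, buffer_m = as.numeric(bc$buffer_m),
               n_fts = bc$observed_count, loc_type = "observed"),
    data.frame(group_id = bc$group_id, buffer_m = as.numeric(bc$buffer_m),
               n_fts = bc$sim_mean, loc_type = "simulated"))
  m1dat$loc_type <- factor(m1dat$loc_type, levels = c("simulated", "observed"))
  spec1 <- model_spec("n_fts", c("loc_type", "buffer_m"), "group_id",
                      "gaussian", random_slopes = character(0))
  m1f <- fit_mixed(spec1, m1dat)
  m1n <- fit_mixed(spec1, m1dat, drop_terms = "loc_type")
  out$model1 <- list(fit = m1f, null = m1n, lrt = lrt(m1f, m1n), data = m1dat)

  sr <- seg_rates[!seg_rates$group_id %in% config$exclude_groups, ]
  minpos <- min(sr$trees_per_m[sr$trees_per_m > 0])
  sr$log_rate <- log(sr$trees_per_m + minpos / 2)
  sr$weeks_used <- as.numeric(sr$weeks_used)
  sr$buffer_m <- as.numeric(sr$buffer_m)
  spec2 <- model_spec("log_rate", c("weeks_used", "buffer_m"), "group_id",
                      "gaussian", random_slopes = character(0))
  m2f <- fit_mixed(spec2, sr)
  m2n <- fit_mixed(spec2, sr, drop_terms = "weeks_used")
  out$model2 <- list(fit = m2f, null = m2n, lrt = lrt(m2f, m2n), data = sr)

  q <- quadrats
  q$sqrt_slope <- sqrt(q$slope_deg)
  q$gap_presence <- as.numeric(q$gap_pct > 0)
  q <- standardize_covariates(q, c("sqrt_slope", "rel_elevation", "ft_density"))
  fixed3 <- c("sqrt_slope", "gap_presence", "rel_elevation", "ft_density",
              "rel_elevation:ft_density", "overlap_flag", "core_flag")
  controls <- c("overlap_flag", "core_flag")
  for (resp in c("route_ge2", "route_ge4")) {
    spec3 <- model_spec(resp, fixed3, "group_id", "binomial",
                        random_slopes = character(0))
    opt <- optimize_D(spec3, q, D_grid = config$D_grid,
                      coords = cbind(q$cx, q$cy), random_slope_term = FALSE)
    qd <- q; qd$ac_term <- opt$term
    spec3n <- spec3; spec3n$fixed <- c(controls, "ac_term")
    fnull <- fit_mixed(spec3n, qd)
    spec3f <- spec3; spec3f$fixed <- c(fixed3, "ac_term")
    d1 <- tryCatch(drop1_tests(spec3f, qd, keep = c(controls, "ac_term")),
                   error = function(e) NULL)
    out[[paste0("model3_", sub("route_", "", resp))]] <-
      list(fit = opt$fit, D = opt$D, profile = opt$profile, null = fnull,
           lrt = tryCatch(lrt(opt$fit, fnull), error = function(e) NULL),
           drop1 = d1, fe_check = NULL, data = qd)
  }
  out$report <- .models_report(out)
  class(out) <- "route_models"
  out
}

#' Write pipeline artifacts to a directory
#'
#' Emits `tracks.csv`, `trees.csv`, `gaps.geojson`, `dem.asc`,
#' `homeranges.geojson`, `hr_summary.csv`, `network.geojson`,
#' `network_summary.csv`, `buffer_counts.csv`, `segment_rates.csv`,
#' `quadrats.csv`, `models_report.csv`, `models_report.json` and
#' `run_log.json` (seed, config, versions).
#'
#' @param res a `"pipeline_result"`.
#' @param out_dir target directory.
#' @param quiet suppress messages.
#' @export
write_pipeline_outputs <- function(res, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(res$tracks, "tracks.csv")
  wcsv(res$trees, "trees.csv")
  if (length(res$gaps))
    write_polygons_geojson(res$gaps, file.path(out_dir, "gaps.geojson"),
                           properties = data.frame(gap_id = seq_along(res$gaps)))
  write_esri_ascii(res$dem, file.path(out_dir, "dem.asc"))
  polys <- list(); props <- list()
  for (g in names(res$home_ranges)) for (q in c(0.5, 0.95)) {
    rings <- hr_isopleth(res$home_ranges[[g]], q)
    for (r in rings) {
      polys[[length(polys) + 1]] <- r
      props[[length(props) + 1]] <-
        data.frame(group_id = g, isopleth = q,
                   area_ha = res$home_ranges[[g]]$isopleths[[sprintf("%g", q)]]$area_ha)
    }
  }
  if (length(polys))
    write_polygons_geojson(polys, file.path(out_dir, "homeranges.geojson"),
                           properties = do.call(rbind, props))
  wcsv(res$hr_summary, "hr_summary.csv")
  lines <- list(); lprops <- list()
  for (g in names(res$networks)) {
    tab <- network_segments(res$networks[[g]])
    for (i in seq_len(nrow(tab))) {
      lines[[length(lines) + 1]] <- res$networks[[g]]$segments[[i]]$xy
      lprops[[length(lprops) + 1]] <-
        data.frame(group_id = g, weeks_used = tab$weeks_used[i],
                   length_m = tab$length_m[i])
    }
  }
  if (length(lines))
    write_lines_geojson(lines, file.path(out_dir, "network.geojson"),
                        properties = do.call(rbind, lprops))
  wcsv(res$network_summary, "network_summary.csv")
  wcsv(res$buffer_counts, "buffer_counts.csv")
  wcsv(res$segment_rates, "segment_rates.csv")
  wcsv(res$quadrats, "quadrats.csv")
  if (!is.null(res$models)) {
    wcsv(res$models$report, "models_report.csv")
    mj <- list()
    for (id in c("model1", "model2", "model3_ge2", "model3_ge4")) {
      m <- res$models[[id]]
      if (is.null(m)) next
      mj[[id]] <- list(
        coefficients = m$fit$coefficients,
        loglik = m$fit$loglik, n_obs = m$fit$n_obs,
        converged = m$fit$converged, singular = m$fit$singular,
        full_null_lrt = m$lrt, D = m$D %||% NULL,
        drop1 = m$drop1 %||% NULL)
    }
    jsonlite::write_json(mj, file.path(out_dir, "models_report.json"),
                         auto_unbox = TRUE, digits = 10, null = "null")
  }
  cfg <- res$config
  cfg$synth <- unclass(cfg$synth)
  log <- list(seed = res$config$seed,
              config = unclass(cfg),
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("routescape")),
              elapsed_s = res$elapsed_s,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  if (!quiet) message("wrote pipeline outputs to ", out_dir)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d groups, %.1f s\n",
              length(x$networks), x$elapsed_s))
  print(x$network_summary, row.names = FALSE)
  invisible(x)
}
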