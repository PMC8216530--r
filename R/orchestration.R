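# End-to-end pipeline: simulate (or load) -> label -> trips -> UDs/overlap
# -> predictors -> repeatability -> niche -> diet, producing one report
# directory with a run manifest. Coordinates are decimal degrees WGS84
# (lon before lat in files); timestamps ISO 8601 UTC.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] (synthetic mode) or NULL for real-data mode.
#' @param fixes_csv,isotopes_csv,prey_csv input paths for real-data mode.
#' @param ud_level isopleth levels computed for the overlap test.
#' @param n_perm randomizations for the overlap test.
#' @param n_boot bootstrap resamples for repeatability.
#' @param mcmc list with `chains` and `iter` for the mixing model.
#' @param env_months monthly layers simulated in synthetic mode.
#' @param seed master seed (overrides `sim$seed` when given).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), fixes_csv = NULL,
                            isotopes_csv = NULL, prey_csv = NULL,
                            ud_level = c(0.50, 0.95), n_perm = 200,
                            n_boot = 500, mcmc = list(chains = 4, iter = 4000),
                            env_months = 12, seed = NULL) {
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, fixes_csv = fixes_csv,
                 isotopes_csv = isotopes_csv, prey_csv = prey_csv,
                 ud_level = ud_level, n_perm = n_perm, n_boot = n_boot,
                 mcmc = mcmc, env_months = env_months,
                 seed = if (is.null(seed)) sim$seed else as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Deterministic given the seed. Emits per-stage CSV/ASCII-grid outputs and
#' a JSON manifest (seed, config hash, package version, stage log). Any
#' stage failure writes a `FAILED` marker naming the stage and rethrows;
#' outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir report directory (created if needed).
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "FAILED"))
  log <- list()
  results <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(paste("stage:", name), conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log[[name]] <<- list(
      rows = if (is.data.frame(res)) nrow(res) else NA,
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    message(sprintf("[%s] done (%.1fs)", name, log[[name]]$seconds))
    res
  }
  if (is.null(config$sim))
    stop("a `sim` block is required (it carries the colony position and module parameters)")
  synthetic <- is.null(config$fixes_csv)
  colony <- config$sim$colony_lonlat

  # --- tracks -------------------------------------------------------------
  fixes <- stage("tracks", {
    if (synthetic) simulate_tracks(config$sim)$fixes
    else read_fixes(config$fixes_csv)
  })
  if (is.null(fixes$group)) fixes$group <- "all"
  write_csv_file(fixes, file.path(out_dir, "fixes.csv"))

  # --- trips and behaviour ------------------------------------------------
  trips <- stage("trips", split_trips(fixes, colony,
                                      radius_km = config$sim$colony_radius_km))
  steps <- stage("steps", {
    do.call(rbind, lapply(unique(trips$trip_id), function(id)
      step_features(trips[trips$trip_id == id, , drop = FALSE])))
  })
  model <- stage("behaviour_fit", fit_embc(steps, seed = config$seed))
  labels <- stage("behaviour_label", label_fixes(trips, model))
  trips$label <- labels
  write_csv_file(trips, file.path(out_dir, "labelled_fixes.csv"))

  metrics <- stage("trip_metrics", trip_metrics_table(trips, labels, colony))
  metrics <- merge(metrics, unique(fixes[, c("bird_id", "group")]), by = "bird_id")
  write_csv_file(metrics, file.path(out_dir, "trip_metrics.csv"))

  # --- space use ----------------------------------------------------------
  forage <- trips[!is.na(trips$label) & trips$label == "LH", , drop = FALSE]
  overlap <- stage("overlap", {
    grid <- ud_grid(forage)
    h <- as.numeric(lscv_bandwidth(forage[, c("lon", "lat")]))
    groups <- unique(forage$group)
    for (g in groups) {
      u <- fit_kernel_ud(forage[forage$group == g, ], grid, h)
      write_ascii_grid(ud_as_raster(u),
                       file.path(out_dir, sprintf("ud_%s.asc", g)))
    }
    if (length(groups) == 2) {
      res <- do.call(rbind, lapply(config$ud_level, function(lv) {
        r <- ud_permutation_test(forage, level = lv, h = h, grid = grid,
                                 n_perm = config$n_perm, seed = config$seed)
        data.frame(group_A = groups[1], group_B = groups[2], level = lv,
                   observed = r$observed_BA, perm_mean = mean(r$permuted_BA),
                   perm_sd = sd(r$permuted_BA), p = r$p_value,
                   n_perm = r$n_perm, seed = r$seed, h = h)
      }))
      write_csv_file(res, file.path(out_dir, "overlap.csv"))
      res
    } else {
      message("overlap test needs exactly 2 groups; skipped")
      NULL
    }
  })

  # --- environmental predictors -------------------------------------------
  covars <- stage("predictors", {
    stack <- simulate_environment(months = config$env_months, config = config$sim)
    grads <- lapply(stack, gradient_pc)
    names(grads) <- paste0("G", names(stack))
    full <- c(stack, grads)
    tab <- extract_at(trips, full)
    write_csv_file(tab, file.path(out_dir, "predictor_table.csv"))
    tab
  })
  vif <- stage("vif", {
    num <- covars[, setdiff(names(covars), c("bird_id", "group", "trip_id",
                                             "timestamp", "lon", "lat", "label")),
                  drop = FALSE]
    v <- vif_screen(num, threshold = 3)
    write_csv_file(data.frame(variable = names(v$vif), vif = as.numeric(v$vif)),
                   file.path(out_dir, "vif_retained.csv"))
    v
  })

  # --- repeatability ------------------------------------------------------
  rpt <- stage("repeatability", {
    traits <- c("duration_h", "max_dist_colony_km", "prop_travel",
                "prop_forage", "prop_rest")
    tab <- repeatability_table(metrics, traits, n_boot = config$n_boot,
                               seed = config$seed)
    write_csv_file(tab, file.path(out_dir, "repeatability.csv"))
    tab
  })

  # --- trophic stages (skipped when no isotope input) ---------------------
  iso <- NULL
  if (synthetic) {
    iso <- simulate_isotopes(config$sim)
  } else if (!is.null(config$isotopes_csv) && file.exists(config$isotopes_csv %||% "")) {
    iso <- list(consumers = read_isotopes(config$isotopes_csv),
                prey = if (is.null(config$prey_csv)) NULL else
                  read_isotopes(config$prey_csv))
  }
  if (is.null(iso)) {
    message("no isotope inputs: trophic stages skipped")
  } else {
    niche <- stage("niche", {
      tab <- niche_metrics_table(iso$consumers, seed = config$seed)
      write_csv_file(tab, file.path(out_dir, "niche_metrics.csv"))
      tab
    })
    diet <- stage("diet", {
      tabs <- do.call(rbind, lapply(unique(iso$consumers$group), function(g) {
        post <- fit_mixing(iso$consumers[iso$consumers$group == g, ],
                           config$sim$source_groups, config$sim$tef,
                           chains = config$mcmc$chains, iter = config$mcmc$iter,
                           seed = module_seed(config$seed, match(g, unique(iso$consumers$group))))
        cbind(group = g, summarize_posterior(post))
      }))
      write_csv_file(tabs, file.path(out_dir, "diet_summary.csv"))
      tabs
    })
    results$niche <- niche
    results$diet <- diet
  }

  manifest <- list(
    package = "seaforage",
    version = as.character(utils::packageVersion("seaforage")),
    seed = config$seed,
    config_hash = config_hash(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stages = log,
    files = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results <- c(list(fixes = fixes, trips = trips, model = model,
                    metrics = metrics, overlap = overlap, vif = vif,
                    repeatability = rpt, manifest = manifest), results)
  invisible(results)
}

# Stable hash of the configuration: serialize deterministically to JSON,
# md5 the bytes.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), function(x)
    if (is.function(x)) deparse(x) else x, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Validate pipeline input files
#'
#' Schema and sanity checks for fix tables, isotope tables and raster
#' grids. Never throws: returns a report listing failures.
#'
#' @param fixes_csv,isotopes_csv optional CSV paths.
#' @param rasters optional named list of [env_raster] layers expected to
#'   share one grid.
#' @return data.frame: check, status ("ok"/"fail"), detail.
#' @export
validate_inputs <- function(fixes_csv = NULL, isotopes_csv = NULL,
                            rasters = NULL) {
  rep <- list()
  add <- function(check, ok, detail = "") {
    rep[[length(rep) + 1L]] <<- data.frame(check = check,
                                           status = if (ok) "ok" else "fail",
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  if (!is.null(fixes_csv)) {
    if (!file.exists(fixes_csv)) {
      add("fixes_exists", FALSE, fixes_csv)
    } else {
      add("fixes_exists", TRUE)
      fx <- tryCatch(read_fixes(fixes_csv), error = function(e) e)
      if (inherits(fx, "error")) {
        add("fixes_schema", FALSE, conditionMessage(fx))
      } else {
        add("fixes_schema", TRUE, sprintf("%d rows", nrow(fx)))
        add("fixes_coords", all(abs(fx$lat) <= 90 & abs(fx$lon) <= 180),
            "lat in [-90,90], lon in [-180,180]")
        ordered <- all(vapply(split(fx$timestamp, fx$bird_id),
                              function(t) !is.unsorted(t, strictly = TRUE),
                              logical(1)))
        add("fixes_time_ordered", ordered, "strictly increasing per bird")
      }
    }
  }
  if (!is.null(isotopes_csv)) {
    if (!file.exists(isotopes_csv)) {
      add("isotopes_exists", FALSE, isotopes_csv)
    } else {
      add("isotopes_exists", TRUE)
      iso <- tryCatch(read_isotopes(isotopes_csv), error = function(e) e)
      if (inherits(iso, "error")) add("isotopes_schema", FALSE, conditionMessage(iso))
      else add("isotopes_schema", TRUE, sprintf("%d rows", nrow(iso)))
    }
  }
  if (!is.null(rasters) && length(rasters) > 1) {
    ref <- rasters[[1]]
    for (i in seq_along(rasters)[-1]) {
      same <- isTRUE(all.equal(ref$lon, rasters[[i]]$lon)) &&
        isTRUE(all.equal(ref$lat, rasters[[i]]$lat))
      add(sprintf("raster_grid_%s", names(rasters)[i] %||% i), same,
          if (same) "" else sprintf(
            "grid of '%s' (%dx%d) does not match grid of '%s' (%dx%d)",
            names(rasters)[i] %||% i, length(rasters[[i]]$lat),
            length(rasters[[i]]$lon), names(rasters)[1] %||% 1,
            length(ref$lat), length(ref$lon)))
    }
  }
  do.call(rbind, rep)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Read a fix table CSV
#'
#' Header-keyed (column order free): bird_id, timestamp (ISO 8601 UTC),
#' lon, lat; trip_id and group pass through when present.
#'
#' @param path CSV path.
#' @return data.frame with POSIXct timestamps, sorted by bird and time.
#' @export
read_fixes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fix table missing columns: ", paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(df$timestamp))) stop("unparseable timestamps in ", path)
  df[order(df$bird_id, df$timestamp), , drop = FALSE]
}

#' Read an isotope table CSV
#'
#' @param path CSV with at least group, d13C, d15N (individual optional).
#' @return data.frame.
#' @export
read_isotopes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "d13C", "d15N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("isotope table missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$d13C)) || any(!is.finite(df$d15N)))
    stop("non-finite isotope values in ", path)
  df
}

# CSV writer with ISO 8601 UTC timestamps.
write_csv_file <- function(df, path) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct"))
      df[[nm]] <- format(df[[nm]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
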