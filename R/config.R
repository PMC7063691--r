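## Configuration, pipeline driver and fixtures ----------------------------

#' Load a run configuration
#'
#' Reads a YAML run configuration and validates it. Recognised keys (all
#' optional except `sites`): `sites` (list of preset names or paths to
#' site YAML files), `years` (default 100), `n_starts` (default 25),
#' `n_candidates` (default 16), `patience` (default 20), `max_gen`
#' (default 200), `seed` (default 1), `out_dir` (default `"wheatgap-out"`),
#' `reduced` (logical; scales to 10 years / 3 starts / 50 generations),
#' `cultivar` (path to a cultivar YAML, else the reference cultivar), and
#' `trait_ranges` (mapping trait name to `[lower, upper]`).
#'
#' @param path Path to a YAML file.
#' @return A validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  cfg <- list(sites = raw$sites,
              years = raw$years %||% 100L,
              n_starts = raw$n_starts %||% 25L,
              n_candidates = raw$n_candidates %||% 16L,
              patience = raw$patience %||% 20L,
              max_gen = raw$max_gen %||% 200L,
              seed = raw$seed %||% 1L,
              out_dir = raw$out_dir %||% "wheatgap-out",
              reduced = isTRUE(raw$reduced))
  if (is.null(cfg$sites) || length(cfg$sites) == 0L) {
    stop(sprintf("%s: 'sites' must name at least one site preset or file",
                 path), call. = FALSE)
  }
  if (cfg$years < 2L) {
    stop(sprintf(
      "%s: 'years' must be >= 2 (the yield CV filter needs at least 2 years)",
      path), call. = FALSE)
  }
  if (cfg$n_candidates < 1L) {
    stop(sprintf("%s: 'n_candidates' must be >= 1", path), call. = FALSE)
  }
  if (cfg$n_starts < 1L) {
    stop(sprintf("%s: 'n_starts' must be >= 1", path), call. = FALSE)
  }
  cfg$cultivar <- if (!is.null(raw$cultivar)) {
    if (!file.exists(raw$cultivar)) {
      stop(sprintf("%s: cultivar file not found: %s", path, raw$cultivar),
           call. = FALSE)
    }
    read_cultivar_yaml(raw$cultivar)
  } else {
    default_cultivar()
  }
  cfg$trait_ranges <- if (!is.null(raw$trait_ranges)) {
    bad <- setdiff(names(raw$trait_ranges), TRAIT_NAMES)
    if (length(bad)) {
      stop(sprintf("%s: unknown trait name(s) %s in trait_ranges; legal: %s",
                   path, paste(bad, collapse = ", "),
                   paste(TRAIT_NAMES, collapse = ", ")), call. = FALSE)
    }
    do.call(default_trait_ranges, raw$trait_ranges)
  } else {
    default_trait_ranges()
  }
  cfg$sites <- lapply(cfg$sites, function(s) {
    if (s %in% names(WEATHER_PRESETS)) {
      site_preset(s)
    } else if (file.exists(s)) {
      read_site_yaml(s)
    } else {
      stop(sprintf(
        "%s: site '%s' is neither a preset (%s) nor an existing file",
        path, s, paste(names(WEATHER_PRESETS), collapse = ", ")),
        call. = FALSE)
    }
  })
  if (cfg$reduced) {
    cfg$years <- min(cfg$years, 10L)
    cfg$n_starts <- min(cfg$n_starts, 3L)
    cfg$max_gen <- min(cfg$max_gen, 50L)
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write cultivar and site parameter YAML files
#'
#' Cultivar files hold blocks `traits:`, `stress:` and optional scalar
#' physiology keys (`rue`, `k_ext`, `t_base`, `grains_per_g`,
#' `max_grain_wt`, `labile_frac`, `lue_multiplier`). Site files hold the
#' fields of [site_climate()]. Units as documented in the constructors.
#'
#' @param path File path.
#' @param cv,site Objects to write.
#' @return The read object, or (for writers) `path` invisibly.
#' @export
read_cultivar_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$traits)) {
    stop(sprintf("%s: cultivar file must have a 'traits' block", path),
         call. = FALSE)
  }
  args <- list(traits = unlist(raw$traits),
               stress = if (!is.null(raw$stress)) unlist(raw$stress)
                        else stress_params("iS"))
  for (k in c("rue", "k_ext", "t_base", "grains_per_g", "max_grain_wt",
              "labile_frac", "lue_multiplier")) {
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  }
  do.call(cultivar_params, args)
}

#' @rdname read_cultivar_yaml
#' @export
write_cultivar_yaml <- function(cv, path) {
  stopifnot(inherits(cv, "cultivar_params"))
  yaml::write_yaml(list(
    traits = as.list(cv$traits), stress = as.list(cv$stress),
    rue = cv$rue, k_ext = cv$k_ext, t_base = cv$t_base,
    grains_per_g = cv$grains_per_g, max_grain_wt = cv$max_grain_wt,
    labile_frac = cv$labile_frac, lue_multiplier = cv$lue_multiplier),
    path)
  invisible(path)
}

#' @rdname read_cultivar_yaml
#' @export
read_site_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(site_climate, raw)
}

#' @rdname read_cultivar_yaml
#' @export
write_site_yaml <- function(site, path) {
  stopifnot(inherits(site, "site_climate"))
  yaml::write_yaml(unclass(site), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' For every configured site: generate weather, simulate the local
#' cultivar baseline, design the iS and iT ideotypes, and compute the gap
#' report. Writes per-site weather CSVs, optimization traces, optimized
#' ideotype cultivar files, a per-site gap report
#' (`gap_report.csv`: `site,mode,y_w,y_iw,y_ig_abs,y_ig_pct`) and a
#' cross-site summary (`gap_summary.csv`) into the configured output
#' directory. Each stage is logged with its seed so every number can be
#' re-derived.
#'
#' @param config A `run_config` from [load_run_config()], or a path to one.
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list with `report` and `summary` data frames and
#'   the output directory.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  rows <- list()
  for (site in config$sites) {
    t0 <- Sys.time()
    log_msg("[%s] weather: %d years (seed %d)", site$site_id, config$years,
            split_seed(config$seed, site$site_id, "weather"))
    res <- run_site_analysis(
      site, base = config$cultivar, seed = config$seed,
      years = config$years, n_starts = config$n_starts,
      n_candidates = config$n_candidates, patience = config$patience,
      max_gen = config$max_gen, ranges = config$trait_ranges)
    write_weather_csv(res$series,
                      file.path(config$out_dir,
                                paste0("weather_", site$site_id, ".csv")))
    utils::write.csv(
      format_csv_num(as.data.frame(res$baseline)),
      file.path(config$out_dir,
                paste0("seasons_", site$site_id, "_cv.csv")),
      row.names = FALSE, quote = FALSE)
    for (mode in c("iS", "iT")) {
      opt <- attr(res[[mode]], "optim")
      write_trace_csv(opt, file.path(
        config$out_dir, paste0("trace_", site$site_id, "_", mode, ".csv")))
      ideo <- set_traits(config$cultivar, opt$best$genome)
      ideo$stress <- stress_params(mode)
      ideo$lue_multiplier <- 1.10
      write_cultivar_yaml(ideo, file.path(
        config$out_dir, paste0("ideotype_", site$site_id, "_", mode, ".yaml")))
      rows[[length(rows) + 1L]] <- as.data.frame(res[[mode]])
      log_msg("[%s] %s: Y_W %.2f  Y_iW %.2f  gap %.2f t/ha (%.1f%%)",
              site$site_id, mode, res[[mode]]$y_w, res[[mode]]$y_iw,
              res[[mode]]$y_ig_abs, res[[mode]]$y_ig_pct)
    }
    log_msg("[%s] done in %.1f s", site$site_id,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  report <- do.call(rbind, rows)
  summ <- aggregate_gaps(report)
  utils::write.csv(format_csv_num(report),
                   file.path(config$out_dir, "gap_report.csv"),
                   row.names = FALSE, quote = FALSE)
  summ_df <- summ$by_mode
  utils::write.csv(format_csv_num(summ_df),
                   file.path(config$out_dir, "gap_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(list(report = report, summary = summ, out_dir = config$out_dir))
}

# Fixed-format numeric columns so report files are byte-stable.
format_csv_num <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  df
}

#' Generate the small deterministic fixtures used by the test suite
#'
#' Writes a 5-year mini weather series for the temperate archetype, the
#' reference cultivar, and a reduced run configuration into `dir`. All
#' outputs are plain text and byte-identical for a given seed.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Named character vector of the files written.
#' @export
make_fixtures <- function(dir = tempfile("wheatgap-fixtures"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  site <- site_preset("temperate_CW")
  w <- generate_weather(site, years = 5, seed = split_seed(seed, "fixture"))
  weather_path <- file.path(dir, "weather_mini.csv")
  # fixed formatting so regeneration is byte-identical
  wdf <- w[, c("day", "tmin", "tmax", "precip", "rad")]
  wdf$tmin <- sprintf("%.4f", wdf$tmin)
  wdf$tmax <- sprintf("%.4f", wdf$tmax)
  wdf$precip <- sprintf("%.4f", wdf$precip)
  wdf$rad <- sprintf("%.4f", wdf$rad)
  utils::write.csv(wdf, weather_path, row.names = FALSE, quote = FALSE)
  cultivar_path <- file.path(dir, "cultivar_reference.yaml")
  write_cultivar_yaml(default_cultivar(), cultivar_path)
  site_path <- file.path(dir, "site_temperate_CW.yaml")
  write_site_yaml(site, site_path)
  config_path <- file.path(dir, "config_reduced.yaml")
  yaml::write_yaml(list(sites = list("temperate_CW"), years = 6L,
                        n_starts = 2L, max_gen = 5L, patience = 3L,
                        seed = as.integer(seed), reduced = FALSE,
                        out_dir = file.path(dir, "out")),
                   config_path)
  c(weather = weather_path, cultivar = cultivar_path, site = site_path,
    config = config_path)
}
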