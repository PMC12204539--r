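#' Read a haul table from CSV
#'
#' Expects columns `survey,year,x_km,y_km,density_per_km2` (header required).
#' Alternatively, `lon,lat` may replace `x_km,y_km`; they are projected to
#' planar km with a single equirectangular approximation about the data
#' centroid (adequate at regional scale; not a cartographic contract).
#' Malformed rows — negative densities, unknown survey labels, missing
#' values — are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @param allowed_surveys Permitted survey labels; `NULL` accepts any.
#' @return Haul tibble with columns `survey`, `year`, `x_km`, `y_km`,
#'   `density_per_km2`.
#' @export
read_hauls <- function(path, allowed_surveys = c("CTS", "IBTS", "UWTV")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0) stop("no haul records in ", path, call. = FALSE)
  if (all(c("lon", "lat") %in% names(df)) &&
      !all(c("x_km", "y_km") %in% names(df))) {
    km <- lonlat_to_km(df$lon, df$lat)
    df$x_km <- km$x_km
    df$y_km <- km$y_km
  }
  needed <- c("survey", "year", "x_km", "y_km", "density_per_km2")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  bad_na <- which(!stats::complete.cases(df[needed]))
  if (length(bad_na)) {
    problems <- c(problems, paste0("row ", bad_na, ": missing value"))
  }
  bad_neg <- which(df$density_per_km2 < 0)
  if (length(bad_neg)) {
    problems <- c(problems, paste0("row ", bad_neg, ": negative density (",
                                   df$density_per_km2[bad_neg], ")"))
  }
  if (!is.null(allowed_surveys)) {
    bad_sv <- which(!df$survey %in% allowed_surveys)
    if (length(bad_sv)) {
      problems <- c(problems, paste0("row ", bad_sv, ": unknown survey '",
                                     df$survey[bad_sv], "'"))
    }
  }
  if (length(problems)) {
    stop("invalid haul records:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  tibble::as_tibble(df[needed])
}

#' Write a haul table to CSV
#'
#' @param hauls Haul tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hauls <- function(hauls, path) {
  readr::write_csv(
    hauls[c("survey", "year", "x_km", "y_km", "density_per_km2")], path
  )
  invisible(path)
}

#' Project longitude/latitude to planar kilometres
#'
#' Single equirectangular approximation about a reference point (default the
#' data centroid): `x = (lon - lon0) * 111.32 * cos(lat0)`,
#' `y = (lat - lat0) * 111.32`, in km. Good to a few parts per thousand over
#' a regional survey domain.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param lon0,lat0 Reference point (defaults to the centroids).
#' @return Tibble `x_km`, `y_km`.
#' @export
lonlat_to_km <- function(lon, lat, lon0 = mean(lon), lat0 = mean(lat)) {
  tibble::tibble(
    x_km = (lon - lon0) * 111.32 * cos(lat0 * pi / 180),
    y_km = (lat - lat0) * 111.32
  )
}

#' Run the survey-evaluation pipeline
#'
#' Threads the package's stages into one reproducible run: `synth` generates
#' haul data from a truth configuration, `simulate` runs the grid
#' detection-power experiment, `detect` computes the zero-detection bounds,
#' `fit` estimates the delta GLMM, and `index` extracts annual indices and
#' the CV-weighted trend. Outputs of earlier stages feed later ones (e.g.
#' `fit` consumes the `synth` hauls). Every run emits a manifest (stage list,
#' configuration snapshot, seed, package version, timestamps and, when
#' `out_dir` is given, file digests) sufficient to reproduce it.
#'
#' @param stages Character vector, subset of
#'   `c("synth", "simulate", "detect", "fit", "index")`, run in this order.
#' @param truth [truth_config()] for `synth` (its seed governs generation).
#' @param sim [sim_config()] for `simulate`.
#' @param detect_n,detect_level Transect count and level for `detect`.
#' @param spec [delta_spec()] for `fit`.
#' @param hauls Haul table for `fit` when `synth` is not among the stages.
#' @param out_dir Optional directory; artifacts and `manifest.json` are
#'   written there as CSV/JSON.
#' @return Named list of stage artifacts plus `manifest`.
#' @export
run_litter_pipeline <- function(stages = c("synth", "fit", "index"),
                                truth = truth_config(),
                                sim = sim_config(),
                                detect_n = 87L, detect_level = 0.95,
                                spec = delta_spec(),
                                hauls = NULL,
                                out_dir = NULL) {
  stages <- match.arg(stages, c("synth", "simulate", "detect", "fit", "index"),
                      several.ok = TRUE)
  art <- list()
  times <- list()
  for (stage in stages) {
    t0 <- Sys.time()
    art[[stage]] <- switch(
      stage,
      synth = gen_hauls(truth),
      simulate = run_experiment(sim, keep_replicates = FALSE),
      detect = detection_report(detect_n, level = detect_level),
      fit = {
        dat <- art$synth %||% hauls
        if (is.null(dat)) {
          stop("stage 'fit' needs hauls (run 'synth' first or pass hauls)",
               call. = FALSE)
        }
        fit_delta_glmm(dat, spec)
      },
      index = {
        if (is.null(art$fit)) stop("stage 'index' needs stage 'fit'",
                                   call. = FALSE)
        idx <- annual_index(art$fit)
        list(indices = idx, trend = weighted_trend(idx))
      }
    )
    times[[stage]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("stage %-8s done in %.1f s", stage, times[[stage]]))
  }

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(art$synth)) {
      files <- c(files, write_hauls(art$synth, file.path(out_dir, "hauls.csv")))
    }
    if (!is.null(art$simulate)) {
      readr::write_csv(art$simulate, f <- file.path(out_dir, "scenarios.csv"))
      files <- c(files, f)
    }
    if (!is.null(art$detect)) {
      jsonlite::write_json(art$detect, f <- file.path(out_dir, "detect.json"),
                           auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
    }
    if (!is.null(art$index)) {
      readr::write_csv(art$index$indices, f <- file.path(out_dir, "indices.csv"))
      files <- c(files, f)
    }
  }

  manifest <- list(
    stages = stages,
    seeds = list(truth = truth$seed, sim = sim$seed,
                 knots = spec$knot_seed),
    config = list(truth_years = range(truth$years),
                  sim_densities = sim$densities_per_km2,
                  sim_sample_sizes = sim$sample_sizes,
                  model = list(binomial = spec$binomial, gamma = spec$gamma,
                               anisotropy = spec$anisotropy)),
    package_version = as.character(utils::packageVersion("litterindex")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    stage_seconds = times,
    file_digests = if (length(files)) as.list(tools::md5sum(files))
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  art$manifest <- manifest
  invisible(art)
}
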