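#' Scenario configuration for the transect-sampling experiment
#'
#' Bundles the full factorial design of the detection-power experiment:
#' litter-density scenarios crossed with sample-size scenarios, each run for
#' `n_replicates` replicates.
#'
#' @param densities_per_km2 Density scenarios (items per km^2).
#' @param sample_sizes Numbers of transects per replicate.
#' @param n_replicates Replicates per scenario cell.
#' @param transect_length_cells Transect length (1 m^2 cells).
#' @param width_m,height_m Grid dimensions in metres.
#' @param regenerate_field_per_replicate If `TRUE` (default) a fresh litter
#'   field is placed for every replicate; if `FALSE` one field is shared by
#'   all replicates of a scenario.
#' @param seed Integer seed; all experiment randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(densities_per_km2 = c(10, 50, 100, 500, 1000, 5000),
                       sample_sizes = c(50, 100, 200, 500, 1000),
                       n_replicates = 1000L,
                       transect_length_cells = 148L,
                       width_m = 1000L, height_m = 1000L,
                       regenerate_field_per_replicate = TRUE,
                       seed = 1L) {
  stopifnot(all(densities_per_km2 >= 0), all(sample_sizes >= 1),
            n_replicates >= 1)
  structure(
    list(densities_per_km2 = densities_per_km2,
         sample_sizes = as.integer(sample_sizes),
         n_replicates = as.integer(n_replicates),
         transect_length_cells = as.integer(transect_length_cells),
         width_m = as.integer(width_m), height_m = as.integer(height_m),
         regenerate_field_per_replicate = isTRUE(regenerate_field_per_replicate),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Pooled swept-area density estimate
#'
#' Converts per-transect item counts to a density in items per km^2 by
#' pooling: total items divided by total area swept
#' (`n_transects * length_cells * 1e-6` km^2). With equal-length transects
#' this equals the mean of per-transect densities.
#'
#' @param counts Integer vector of per-transect item counts.
#' @param length_cells Transect length in cells (1 cell = 1 m^2).
#' @return Density in items per km^2.
#' @examples
#' estimate_density(1, 148) # one item in a single transect: ~6757 items/km2
#' @export
estimate_density <- function(counts, length_cells = 148L) {
  if (length(counts) == 0) stop("no transect counts supplied", call. = FALSE)
  sum(counts) / (length(counts) * length_cells * 1e-6)
}

#' Run one replicate of a density/sample-size scenario
#'
#' Places a fresh litter field and drags `n_transects` independent random
#' transects across it.
#'
#' @inheritParams estimate_density
#' @param density_per_km2 True litter density for the replicate.
#' @param n_transects Number of transects.
#' @param width_m,height_m,length_cells Grid and transect geometry.
#' @param field Optionally, a pre-placed `litter_field` to reuse (shared-field
#'   mode); default `NULL` places a new one.
#' @return Integer vector of per-transect counts.
#' @export
run_replicate <- function(density_per_km2, n_transects,
                          width_m = 1000L, height_m = 1000L,
                          length_cells = 148L, field = NULL) {
  if (is.null(field)) {
    field <- place_litter(density_per_km2, width_m, height_m)
  }
  tr <- draw_transect(n_transects, width_m, height_m, length_cells)
  count_transects_fast(field, tr)
}

# Vectorized counting: one linear-index gather over all covered cells of all
# transects at once (cell (r, c) has column-major index (c-1)*H + r).
count_transects_fast <- function(field, transects) {
  n <- nrow(transects)
  if (length(field$occupied) == 0) return(integer(n))
  H <- field$height_m
  v <- logical(H * field$width_m)
  v[field$occupied] <- TRUE
  L <- transects$length_cells[1]
  horiz <- transects$orientation == "horizontal"
  counts <- integer(n)
  if (any(horiz)) {
    base <- transects$row[horiz] + (transects$col[horiz] - 1) * H
    lin <- rep(base, each = L) + H * rep.int(0:(L - 1), length(base))
    counts[horiz] <- colSums(matrix(v[lin], L))
  }
  if (any(!horiz)) {
    base <- transects$row[!horiz] + (transects$col[!horiz] - 1) * H
    lin <- rep(base, each = L) + rep.int(0:(L - 1), length(base))
    counts[!horiz] <- colSums(matrix(v[lin], L))
  }
  counts
}

# Deterministic per-scenario seed derived from the experiment seed, so a
# scenario's replicate stream does not depend on the position of other
# scenarios in the factorial grid.
scenario_seed <- function(seed, density, n_transects) {
  (as.double(seed) + 7919 * round(density) + 104729 * n_transects) %% 2147483647
}

#' Run the full transect-sampling detection experiment
#'
#' For every combination of litter density and sample size in the
#' configuration, runs `n_replicates` replicates of the grid experiment and
#' summarises (i) the proportion of replicates in which no litter item was
#' captured and (ii) the mean and spread of the replicate density estimates.
#'
#' @param config A [sim_config()].
#' @param keep_replicates Keep per-replicate density estimates as a list
#'   column (`TRUE`, default) or drop them to save memory.
#' @return A tibble of class `scenario_result` with one row per scenario:
#'   `density_per_km2`, `n_transects`, `n_replicates`, `prop_zero_replicates`,
#'   `mean_density`, `sd_density`, and (optionally) `replicate_densities`.
#' @examples
#' \donttest{
#' res <- run_experiment(sim_config(densities_per_km2 = c(10, 100),
#'                                  sample_sizes = c(50, 100),
#'                                  n_replicates = 200, seed = 7))
#' res
#' }
#' @export
run_experiment <- function(config = sim_config(), keep_replicates = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  grid <- tidyr::expand_grid(density_per_km2 = config$densities_per_km2,
                             n_transects = config$sample_sizes)
  res <- purrr::pmap(grid, function(density_per_km2, n_transects) {
    set.seed(scenario_seed(config$seed, density_per_km2, n_transects))
    shared_field <- if (!config$regenerate_field_per_replicate) {
      place_litter(density_per_km2, config$width_m, config$height_m)
    }
    dens <- numeric(config$n_replicates)
    n_zero <- 0L
    for (r in seq_len(config$n_replicates)) {
      counts <- run_replicate(density_per_km2, n_transects,
                              config$width_m, config$height_m,
                              config$transect_length_cells,
                              field = shared_field)
      tot <- sum(counts)
      if (tot == 0L) n_zero <- n_zero + 1L
      dens[r] <- tot / (n_transects * config$transect_length_cells * 1e-6)
    }
    tibble::tibble(prop_zero_replicates = n_zero / config$n_replicates,
                   mean_density = mean(dens),
                   sd_density = stats::sd(dens),
                   replicate_densities = list(dens))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  out$n_replicates <- config$n_replicates
  out <- dplyr::relocate(out, "n_replicates", .after = "n_transects")
  if (!keep_replicates) out$replicate_densities <- NULL
  attr(out, "seed") <- config$seed
  class(out) <- c("scenario_result", class(out))
  out
}
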