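#' Place litter items uniformly on a 1 m^2 grid
#'
#' Builds the simulation world: a `width_m` x `height_m` grid of 1 m^2 cells
#' over which `round(density_per_km2 * area_km2)` litter items are scattered
#' uniformly at random, at most one item per cell. The default grid is
#' 1000 x 1000 m, i.e. exactly 1 km^2, so the item count equals the density
#' rounded to an integer.
#'
#' @param density_per_km2 Non-negative true litter density (items per km^2).
#' @param width_m,height_m Grid dimensions in metres (= cells per side).
#' @return An object of class `litter_field`: a list with the grid dimensions,
#'   the true density, and `occupied`, an integer vector of occupied cell
#'   indices (column-major, 1-based).
#' @examples
#' f <- place_litter(100)
#' length(f$occupied) # 100
#' @export
place_litter <- function(density_per_km2, width_m = 1000L, height_m = 1000L) {
  stopifnot(density_per_km2 >= 0, width_m >= 1, height_m >= 1)
  n_cells <- as.double(width_m) * as.double(height_m)
  area_km2 <- n_cells * 1e-6
  n_items <- round(density_per_km2 * area_km2)
  if (n_items > n_cells) {
    stop("density ", density_per_km2, " items/km2 requires ", n_items,
         " items but the grid has only ", n_cells,
         " cells (one item per m2 allowed)", call. = FALSE)
  }
  occupied <- if (n_items > 0) sample.int(n_cells, n_items) else integer(0)
  structure(
    list(width_m = as.integer(width_m), height_m = as.integer(height_m),
         true_density_per_km2 = density_per_km2, occupied = occupied),
    class = "litter_field"
  )
}

#' @export
print.litter_field <- function(x, ...) {
  cat("<litter_field> ", x$width_m, " x ", x$height_m, " m, ",
      length(x$occupied), " items (true density ",
      x$true_density_per_km2, " / km2)\n", sep = "")
  invisible(x)
}

# Dense logical matrix view of a field (rows = height, cols = width).
# Used for fast transect counting; rebuilt on demand.
field_matrix <- function(field) {
  m <- matrix(FALSE, nrow = field$height_m, ncol = field$width_m)
  m[field$occupied] <- TRUE
  m
}

#' Draw random UWTV transects over the grid
#'
#' Each transect is a run of `length_cells` consecutive 1 m^2 cells, laid out
#' horizontally or vertically with probability 1/2 each, with the start cell
#' uniform over all positions that keep the transect fully inside the grid.
#' Transects drawn together are independent and may overlap.
#'
#' @param n Number of transects to draw.
#' @param width_m,height_m Grid dimensions in metres.
#' @param length_cells Transect length in cells (default 148, the average
#'   swept area of a 10-minute UWTV tow in m^2).
#' @return A tibble with one row per transect: `orientation`
#'   (`"horizontal"`/`"vertical"`), `row`, `col` (1-based start cell) and
#'   `length_cells`.
#' @export
draw_transect <- function(n = 1L, width_m = 1000L, height_m = 1000L,
                          length_cells = 148L) {
  stopifnot(n >= 1, length_cells >= 1)
  if (length_cells > width_m || length_cells > height_m) {
    stop("transect of ", length_cells,
         " cells does not fit inside a ", width_m, " x ", height_m, " grid",
         call. = FALSE)
  }
  horizontal <- sample(c(TRUE, FALSE), n, replace = TRUE)
  row <- integer(n); col <- integer(n)
  nh <- sum(horizontal)
  # horizontal: any row, start col in 1..(width - L + 1); vertical mirrored
  row[horizontal] <- sample.int(height_m, nh, replace = TRUE)
  col[horizontal] <- sample.int(width_m - length_cells + 1L, nh, replace = TRUE)
  row[!horizontal] <- sample.int(height_m - length_cells + 1L, n - nh, replace = TRUE)
  col[!horizontal] <- sample.int(width_m, n - nh, replace = TRUE)
  tibble::tibble(
    orientation = ifelse(horizontal, "horizontal", "vertical"),
    row = row, col = col, length_cells = as.integer(length_cells)
  )
}

#' Count litter items covered by transects
#'
#' @param field A `litter_field`.
#' @param transects A tibble as returned by [draw_transect()].
#' @return Integer vector of item counts, one per transect, each in
#'   `[0, length_cells]`.
#' @export
count_on_transect <- function(field, transects) {
  stopifnot(inherits(field, "litter_field"))
  L <- transects$length_cells
  if (any(transects$col + ifelse(transects$orientation == "horizontal", L - 1L, 0L) > field$width_m) ||
      any(transects$row + ifelse(transects$orientation == "vertical", L - 1L, 0L) > field$height_m)) {
    stop("transect extends outside the grid", call. = FALSE)
  }
  if (length(field$occupied) == 0) return(integer(nrow(transects)))
  m <- field_matrix(field)
  counts <- integer(nrow(transects))
  horiz <- transects$orientation == "horizontal"
  for (i in seq_len(nrow(transects))) {
    counts[i] <- if (horiz[i]) {
      sum(m[transects$row[i], transects$col[i]:(transects$col[i] + L[i] - 1L)])
    } else {
      sum(m[transects$row[i]:(transects$row[i] + L[i] - 1L), transects$col[i]])
    }
  }
  counts
}
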