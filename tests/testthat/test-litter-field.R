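# Construct a field with items at chosen (row, col) cells.
field_at <- function(cells, width = 1000L, height = 1000L) {
  structure(
    list(width_m = width, height_m = height,
         true_density_per_km2 = nrow(cells) / (width * height * 1e-6),
         occupied = (cells[, 2] - 1L) * height + cells[, 1]),
    class = "litter_field"
  )
}

test_that("litter placement puts exactly round(density * area) items, one per cell", {
  set.seed(1)
  expect_length(place_litter(0)$occupied, 0)
  f <- place_litter(10)
  expect_length(f$occupied, 10)
  expect_false(anyDuplicated(f$occupied) > 0)
  expect_true(all(f$occupied >= 1 & f$occupied <= 1e6))
  # fractional densities round
  expect_length(place_litter(10.4)$occupied, 10)
  # more items than cells is impossible
  expect_error(place_litter(2e6), "one item per m2")
})

test_that("litter placement is uniform over cells", {
  # 20 x 20 m grid (400 cells), 5 items per draw; occupancy frequencies
  # should be indistinguishable from uniform
  set.seed(42)
  tally <- integer(400)
  for (i in 1:4000) {
    occ <- place_litter(12500, 20L, 20L)$occupied
    tally[occ] <- tally[occ] + 1L
  }
  expect_gt(stats::chisq.test(tally)$p.value, 0.01)
})

test_that("transects stay inside the grid and balance orientations", {
  set.seed(2)
  tr <- draw_transect(5000)
  horiz <- tr$orientation == "horizontal"
  expect_true(all(tr$col[horiz] >= 1 & tr$col[horiz] <= 1000 - 148 + 1))
  expect_true(all(tr$row[horiz] >= 1 & tr$row[horiz] <= 1000))
  expect_true(all(tr$row[!horiz] <= 1000 - 148 + 1))
  # orientation is a fair coin: 3 binomial SE at n = 5000 is ~0.021
  expect_lt(abs(mean(horiz) - 0.5), 3 * sqrt(0.25 / 5000))
  # boundary: transect as long as the grid has a single start position
  tight <- draw_transect(50, width_m = 148L, height_m = 148L)
  expect_true(all(tight$col[tight$orientation == "horizontal"] == 1))
  expect_true(all(tight$row[tight$orientation == "vertical"] == 1))
  expect_error(draw_transect(1, width_m = 100L), "does not fit")
})

test_that("transect counts equal the number of covered occupied cells", {
  tr_h <- tibble::tibble(orientation = "horizontal", row = 10L, col = 20L,
                         length_cells = 148L)
  empty <- place_litter(0)
  expect_identical(count_on_transect(empty, tr_h), 0L)

  full <- place_litter(1e6) # every cell occupied
  expect_identical(count_on_transect(full, tr_h), 148L)

  # one item on a covered cell, one just outside the transect
  f <- field_at(rbind(c(10L, 167L), c(10L, 168L), c(11L, 20L)))
  expect_identical(count_on_transect(f, tr_h), 1L)
  tr_v <- tibble::tibble(orientation = "vertical", row = 5L, col = 167L,
                         length_cells = 148L)
  expect_identical(count_on_transect(f, tr_v), 1L)
  # out-of-grid transect rejected
  bad <- tibble::tibble(orientation = "horizontal", row = 1L, col = 900L,
                        length_cells = 148L)
  expect_error(count_on_transect(f, bad), "outside the grid")
})
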