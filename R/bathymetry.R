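#' Generate a synthetic coastal depth grid
#'
#' Builds a shore-parallel bathymetry on a regular grid: depth increases
#' with offshore distance at a mean rate of `slope` metres per row, modulated
#' by smooth alongshore "bay" undulations and optional small-scale roughness.
#' Row 1 is the shoreline; depth is positive downward. Cells with
#' `0 < depth <= 12` m form the modelled domain (the in-scope mask), the
#' depth range over which eelgrass occurrence is modelled.
#'
#' @param n_rows,n_cols Grid dimensions (rows run shore to offshore).
#' @param cell_size Cell edge length in metres (default 100 m).
#' @param slope Mean depth increase per row, m (must be > 0).
#' @param bay_amplitude Relative amplitude of alongshore depth undulation
#'   (0 disables bays). The undulation multiplies the mean depth ramp.
#' @param bay_wavelength Alongshore wavelength of the undulation, in cells.
#' @param roughness Standard deviation of multiplicative small-scale depth
#'   noise (0 disables).
#' @param max_depth_in_scope Deepest depth (m) retained in the modelled
#'   domain; cells deeper than this are out of scope.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#'
#' @return A `depth_grid`: a tibble with one row per cell and columns
#'   `row`, `col`, `depth` (m) and `in_scope` (logical), carrying attributes
#'   `n_rows`, `n_cols`, `cell_size` and `max_depth_in_scope`.
#' @examples
#' grid <- make_bathymetry(n_rows = 20, n_cols = 10, slope = 0.6, seed = 1)
#' dplyr::count(grid, in_scope)
#' @export
make_bathymetry <- function(n_rows = 100, n_cols = 80, cell_size = 100,
                            slope = 0.125, bay_amplitude = 0.12,
                            bay_wavelength = 25, roughness = 0.01,
                            max_depth_in_scope = 12, seed = 1L) {
  if (n_rows < 1 || n_cols < 1) {
    abort("`n_rows` and `n_cols` must be positive integers.")
  }
  if (slope <= 0) abort("`slope` must be > 0.")
  if (cell_size <= 0) abort("`cell_size` must be > 0.")

  grid <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  ramp <- slope * grid$row

  modulation <- rep(1, nrow(grid))
  if (bay_amplitude > 0) {
    phases <- with_seed(seed, runif(2L, 0, 2 * pi))
    along <- grid$col / bay_wavelength
    modulation <- 1 + bay_amplitude * (
      0.7 * sin(2 * pi * along + phases[1L]) +
        0.3 * sin(4 * pi * along + phases[2L])
    )
  }
  noise <- if (roughness > 0) {
    with_seed(seed + 1L, rnorm(nrow(grid), 0, roughness))
  } else {
    0
  }

  depth <- ramp * modulation * (1 + noise)
  new_depth_grid(
    tibble::tibble(
      row = grid$row, col = grid$col, depth = depth,
      in_scope = depth > 0 & depth <= max_depth_in_scope
    ),
    n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
    max_depth_in_scope = max_depth_in_scope
  )
}

new_depth_grid <- function(df, n_rows, n_cols, cell_size,
                           max_depth_in_scope = 12) {
  structure(
    df,
    n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
    max_depth_in_scope = max_depth_in_scope,
    class = c("depth_grid", class(tibble::tibble()))
  )
}

#' Construct a depth grid from a depth matrix or cell table
#'
#' Real-data entry point: wraps an existing bathymetry (matrix with rows
#' running shore to offshore, or a data frame with `row`, `col`, `depth`
#' columns) in the `depth_grid` container used throughout the package.
#' The in-scope mask is derived as `0 < depth <= max_depth_in_scope`.
#'
#' @param x A numeric matrix of depths (m, positive down; values `<= 0`
#'   are land) or a data frame with columns `row`, `col`, `depth`.
#' @inheritParams make_bathymetry
#' @return A `depth_grid` tibble.
#' @export
as_depth_grid <- function(x, cell_size = 100, max_depth_in_scope = 12) {
  if (is.matrix(x)) {
    df <- tibble::tibble(
      row = as.integer(base::row(x)[seq_along(x)]),
      col = as.integer(base::col(x)[seq_along(x)]),
      depth = as.numeric(x)
    )
    df <- dplyr::arrange(df, .data$row, .data$col)
    n_rows <- nrow(x)
    n_cols <- ncol(x)
  } else if (is.data.frame(x)) {
    stopifnot(all(c("row", "col", "depth") %in% names(x)))
    df <- tibble::as_tibble(x[c("row", "col", "depth")])
    n_rows <- max(df$row)
    n_cols <- max(df$col)
  } else {
    abort("`x` must be a depth matrix or a data frame with row/col/depth.")
  }
  df$in_scope <- !is.na(df$depth) & df$depth > 0 &
    df$depth <= max_depth_in_scope
  new_depth_grid(df, n_rows, n_cols, cell_size, max_depth_in_scope)
}

#' Total in-scope area of a depth grid
#'
#' @param grid A `depth_grid`.
#' @return Area in km^2 (number of in-scope cells times cell area).
#' @export
domain_area <- function(grid) {
  cell <- attr(grid, "cell_size")
  sum(grid$in_scope) * cell^2 / 1e6
}

#' Convert a depth grid to a matrix
#'
#' @param x A `depth_grid`.
#' @param value Column to spread into the matrix (default `"depth"`).
#' @param ... Unused.
#' @return A `n_rows` by `n_cols` numeric matrix.
#' @export
as.matrix.depth_grid <- function(x, value = "depth", ...) {
  m <- matrix(NA_real_, attr(x, "n_rows"), attr(x, "n_cols"))
  m[cbind(x$row, x$col)] <- x[[value]]
  m
}

# Runs code with a local RNG state so generators are pure in (config, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
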