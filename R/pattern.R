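#' Point patterns of RyR cluster centroids
#'
#' A point pattern is a tibble with columns `x`, `y`, `z` holding cluster
#' centroid coordinates in micrometres. All package functions that consume
#' patterns accept any data frame with these columns; the `ryr_pattern` class
#' only adds printing and plotting sugar.
#'
#' @param x,y,z numeric coordinate vectors (um), or `x` may be a matrix /
#'   data frame with three columns.
#' @return A tibble of class `ryr_pattern` with columns `x`, `y`, `z`.
#' @examples
#' p <- ryr_pattern(c(0, 1), c(0, 0), c(0, 0))
#' nn_distances(p)
#' @export
ryr_pattern <- function(x, y = NULL, z = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 3)
    y <- m[, 2]
    z <- m[, 3]
    x <- m[, 1]
  }
  if (is.null(z)) z <- rep(0, length(x))
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    abort("point coordinates must be finite")
  out <- tibble(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  class(out) <- c("ryr_pattern", class(out))
  out
}

#' @export
as_ryr_pattern <- function(x) {
  if (inherits(x, "ryr_pattern")) return(x)
  ryr_pattern(x[["x"]], x[["y"]], x[["z"]])
}

#' Number of points in a pattern
#' @param pattern a point pattern.
#' @export
n_points <- function(pattern) nrow(pattern)

#' Nearest-neighbour distances of a point pattern
#'
#' All-pairs Euclidean nearest-neighbour distances. Ties are broken by point
#' index order (the first minimising index is reported by
#' [nn_indices()]).
#'
#' @param pattern a point pattern (>= 2 points).
#' @return numeric vector, one distance per point (um).
#' @export
nn_distances <- function(pattern) {
  if (nrow(pattern) < 2) abort("need at least 2 points")
  d <- as.matrix(dist(as.matrix(pattern[, c("x", "y", "z")])))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' @rdname nn_distances
#' @export
nn_indices <- function(pattern) {
  if (nrow(pattern) < 2) abort("need at least 2 points")
  d <- as.matrix(dist(as.matrix(pattern[, c("x", "y", "z")])))
  diag(d) <- Inf
  unname(apply(d, 1, which.min))
}

#' Intensity of a pattern over an admissible window
#'
#' Points per unit admissible volume (um^-3).
#'
#' @param pattern a point pattern.
#' @param window an `ryr_window` (see [build_window()], [box_window()]).
#' @export
pattern_intensity <- function(pattern, window) {
  v <- window_volume(window)
  if (v <= 0) abort("window has degenerate volume")
  nrow(pattern) / v
}

# effective dimensionality: 2 when the pattern is confined to one axial plane
pattern_dim <- function(pattern, axial_axis = 3L, tol = 1e-9) {
  ax <- as.matrix(pattern[, c("x", "y", "z")])[, axial_axis]
  if (length(ax) == 0 || diff(range(ax)) <= tol) 2L else 3L
}

#' Read / write point patterns as CSV
#'
#' CSV files use the header `x_um,y_um,z_um`.
#'
#' @param path file path.
#' @export
read_pattern <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(df)))
  ryr_pattern(df$x_um, df$y_um, df$z_um)
}

#' @rdname read_pattern
#' @param pattern a point pattern.
#' @export
write_pattern <- function(pattern, path) {
  df <- data.frame(x_um = pattern$x, y_um = pattern$y, z_um = pattern$z)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ryr_pattern <- function(x, ...) {
  cat(sprintf("<ryr_pattern: %d points>\n", nrow(x)))
  NextMethod()
}
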