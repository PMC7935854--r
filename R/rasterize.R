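#' Grid geometry for pseudo-color rasterization
#'
#' The circular display area is inscribed in a `G x G` pixel grid: pixel
#' (0,0) is the top-left corner, x runs rightward and y downward in pixel
#' space, and the degree-space origin is the display center. `pixel_scale`
#' is degrees per pixel.
#'
#' @param grid_size Grid side length in pixels (the analysis standard is 401;
#'   coarser grids are proportionally equivalent).
#' @param display_radius Display radius in degrees.
#' @return List with `grid_size`, `pixel_scale`, logical `mask` (inscribed
#'   circle over pixel centers), pixel-center coordinate matrices `px`, `py`
#'   (degrees, y upward), and 0-based column-major `mask_idx`.
#' @export
map_grid <- function(grid_size = 401L, display_radius = 5.3) {
  G <- as.integer(grid_size)
  ps <- 2 * display_radius / G
  half <- display_radius
  cols <- matrix(rep(0:(G - 1), each = G), G, G)   # column index per cell
  rows <- matrix(rep(0:(G - 1), times = G), G, G)  # row index per cell
  px <- (cols + 0.5) * ps - half
  py <- half - (rows + 0.5) * ps
  mask <- px^2 + py^2 <= display_radius^2
  list(grid_size = G, pixel_scale = ps, display_radius = display_radius,
       mask = mask, px = px, py = py, mask_idx = which(mask) - 1L)
}

# default smoothing support: 20 px on the 401 grid, scaled proportionally
# and forced odd so the kernel is centered
default_kernel_width <- function(grid_size) {
  w <- max(3L, as.integer(round(20 * grid_size / 401)))
  if (w %% 2L == 0L) w + 1L else w
}

#' Centered Gaussian smoothing kernel
#'
#' One-dimensional Gaussian taps with `sigma = width / 4` (a 20-pixel support
#' therefore gets sigma 5 px), truncated to the stated support and normalized
#' to unit sum; the 2-D kernel is its separable outer product.
#'
#' @param width Support width in pixels (forced odd).
#' @return Numeric vector of kernel taps summing to 1.
#' @export
gaussian_kernel <- function(width) {
  w <- as.integer(width)
  if (w %% 2L == 0L) w <- w + 1L
  if (w < 1L) stop("kernel width must be positive")
  sigma <- width / 4
  t <- seq(-(w %/% 2L), w %/% 2L)
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

#' Rasterize one dot display into a signed pseudo-color map
#'
#' Each dot paints its signed color (+1 blue, -1 red) over the pixels its
#' disc covers; the image is then smoothed with a unit-sum separable Gaussian
#' kernel. Values outside the inscribed display circle are set to `NA`.
#'
#' @param dots Tibble with `x`, `y` (degrees) and `color` (+1/-1); e.g. one
#'   display of [simulate_session()] dots.
#' @param grid_size Pixels per side.
#' @param kernel_width Smoothing support in pixels; default scales the
#'   20-pixel standard proportionally to `grid_size`. Use 1 for no smoothing.
#' @param geometry A [display_geometry()].
#' @param mask_circle If `FALSE`, keep values outside the display circle
#'   (smoothing always precedes masking).
#' @return A `grid_size` x `grid_size` matrix of class `wm_pseudocolor`, with
#'   attributes `pixel_scale` and `mask`.
#' @export
pseudocolor_map <- function(dots, grid_size = 401L, kernel_width = NULL,
                            geometry = display_geometry(),
                            mask_circle = TRUE) {
  grid <- map_grid(grid_size, geometry$display_radius)
  if (nrow(dots) > 0 &&
      any(sqrt(dots$x^2 + dots$y^2) >
          geometry$display_radius - geometry$dot_diameter / 2 + 1e-9))
    stop("corrupt input: dot center outside the display support circle")
  kw <- if (is.null(kernel_width)) default_kernel_width(grid$grid_size)
        else as.integer(kernel_width)
  if (kw >= grid$grid_size) stop("kernel width must be below the grid size")
  kern <- if (kw <= 1L) 1 else gaussian_kernel(kw)
  m <- cpp_rasterize(as.numeric(dots$x), as.numeric(dots$y),
                     as.numeric(dots$color), grid$grid_size,
                     grid$pixel_scale, geometry$dot_diameter / 2, kern)
  if (mask_circle) m[!grid$mask] <- NA_real_
  structure(m, pixel_scale = grid$pixel_scale, mask = grid$mask,
            kernel_width = kw, class = c("wm_pseudocolor", "matrix", "array"))
}

# Build the (n_trials x 6 x n_maskpixels) design cube of smoothed pseudo-color
# values. `rotation` is an optional per-trial angle in degrees
# (counterclockwise) applied to dot coordinates before painting.
build_design_cube <- function(trials, dots, grid, kernel_width,
                              geometry = display_geometry(),
                              rotation = NULL) {
  stopifnot(all(c("trial_id", "display", "x", "y", "color") %in% names(dots)))
  id_pos <- match(dots$trial_id, trials$trial_id)
  if (anyNA(id_pos)) stop("dots reference trial_ids absent from `trials`")
  o <- order(id_pos, dots$display)
  dots <- dots[o, ]
  id_pos <- id_pos[o]
  rot <- if (is.null(rotation)) rep(0, nrow(trials)) else {
    stopifnot(length(rotation) == nrow(trials))
    rotation * pi / 180
  }
  kern <- if (kernel_width <= 1L) 1 else gaussian_kernel(kernel_width)
  cpp_build_design(as.numeric(dots$x), as.numeric(dots$y),
                   as.numeric(dots$color), as.integer(id_pos - 1L),
                   as.integer(dots$display - 1L), nrow(trials), 6L,
                   grid$grid_size, grid$pixel_scale,
                   geometry$dot_diameter / 2, kern, grid$mask_idx, rot)
}
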