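#' Generate a jittered object grid layout
#'
#' Places twelve object centers on a 4 x 3 grid spanning the screen, applies an
#' independent Gaussian offset (`grid_jitter_deg`) to every center, and samples
#' a target object uniformly. Objects are guaranteed non-overlapping: the
#' minimum pairwise center distance exceeds twice the object radius, otherwise
#' an error is raised.
#'
#' @param config An [sim_config()] object.
#' @param seed Optional integer seed; defaults to `config$seed`.
#' @return An object of class `frp_layout`: a list with `centers` (tibble of
#'   `object`, `cx_px`, `cy_px`), `target_index` (1-based), `object_radius_deg`
#'   and `px_per_deg`.
#' @export
#' @examples
#' lay <- generate_layout(sim_config(seed = 7))
#' lay$centers
generate_layout <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "frp_sim_config"))
  set.seed(seed)
  w <- config$screen_px[1]
  h <- config$screen_px[2]
  radius_px <- config$object_radius_deg * config$px_per_deg
  jitter_px <- config$grid_jitter_deg * config$px_per_deg

  n_col <- 4L
  n_row <- 3L
  margin_x <- w / 7
  margin_y <- h / 7
  gx <- seq(margin_x, w - margin_x, length.out = n_col)
  gy <- seq(margin_y, h - margin_y, length.out = n_row)
  base <- expand.grid(cx_px = gx, cy_px = gy)

  spacing <- min(diff(gx), diff(gy))
  if (spacing - 6 * jitter_px <= 2 * radius_px) {
    abort("layout geometry infeasible: grid spacing cannot keep objects non-overlapping")
  }

  for (attempt in 1:100) {
    cx <- base$cx_px + rnorm(12, 0, jitter_px)
    cy <- base$cy_px + rnorm(12, 0, jitter_px)
    if (min(stats::dist(cbind(cx, cy))) > 2 * radius_px) break
    if (attempt == 100) {
      abort("layout geometry infeasible: objects overlap after jitter")
    }
  }

  structure(
    list(
      centers = tibble::tibble(object = 1:12, cx_px = cx, cy_px = cy),
      target_index = sample.int(12, 1),
      object_radius_deg = config$object_radius_deg,
      px_per_deg = config$px_per_deg
    ),
    class = "frp_layout"
  )
}

#' @export
print.frp_layout <- function(x, ...) {
  cat(sprintf(
    "<frp_layout> 12 objects, target #%d, radius %g deg (%g px/deg)\n",
    x$target_index, x$object_radius_deg, x$px_per_deg
  ))
  invisible(x)
}
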