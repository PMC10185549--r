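#' Imaging layout of the phantom frame
#'
#' Geometry of the acrylic frame used to scan up to 20 cylindrical phantoms
#' at once: a 185 mm frame holding 31.5 mm diameter holes, imaged on a
#' square matrix. Disk centres sit on a centre hole plus two concentric
#' rings (6 at 33.5 mm, 13 at 69.5 mm), which keeps every pair of disks
#' disjoint with better than 1 mm margin and all disks inside the frame
#' circle.
#'
#' @param n_phantoms Number of holes used (max 20).
#' @param grid Matrix size in pixels (square).
#' @param fov_mm Field of view in mm.
#' @param frame_diameter_mm,phantom_diameter_mm Frame and hole diameters.
#' @param n_slices Number of imaged slices.
#' @return An object of class `phantom_layout`: list with `grid`, `n_slices`,
#'   `pixel_mm`, `radius_px`, `centers` (tibble `position`, `row`, `col`) and
#'   `assignment` (integer matrix; 0 = background, k = disk of position k).
#' @examples
#' layout <- phantom_layout(20)
#' layout$radius_px
#' @export
phantom_layout <- function(n_phantoms = 20, grid = 320L, fov_mm = 200,
                           frame_diameter_mm = 185, phantom_diameter_mm = 31.5,
                           n_slices = 3L) {
  stopifnot(n_phantoms >= 1, n_phantoms <= 20, grid >= 32)
  pixel_mm <- fov_mm / grid
  radius_mm <- phantom_diameter_mm / 2
  radius_px <- radius_mm / pixel_mm

  ring <- function(n, r_mm, offset = 0) {
    th <- offset + 2 * pi * (seq_len(n) - 1) / n
    ring_scale <- frame_diameter_mm / 185   # shrink geometry with the frame
    tibble::tibble(x_mm = r_mm * ring_scale * cos(th),
                   y_mm = r_mm * ring_scale * sin(th))
  }
  pos <- dplyr::bind_rows(tibble::tibble(x_mm = 0, y_mm = 0),
                          ring(6, 33.5), ring(13, 69.5, offset = pi / 13))
  pos <- pos[seq_len(n_phantoms), ]

  centre_px <- (grid + 1) / 2
  centers <- dplyr::mutate(pos,
    position = dplyr::row_number(),
    row = round(centre_px + .data$y_mm / pixel_mm),
    col = round(centre_px + .data$x_mm / pixel_mm)
  ) |>
    dplyr::select("position", "row", "col")

  # disjointness and containment checks
  if (n_phantoms > 1) {
    dd <- as.matrix(stats::dist(centers[, c("row", "col")]))
    diag(dd) <- Inf
    stopifnot(min(dd) > 2 * radius_px)
  }
  r_frame_px <- frame_diameter_mm / 2 / pixel_mm
  stopifnot(all(sqrt((centers$row - centre_px)^2 + (centers$col - centre_px)^2) +
                  radius_px <= r_frame_px + 1e-9))

  rowg <- matrix(seq_len(grid), grid, grid)
  colg <- t(rowg)
  assignment <- matrix(0L, grid, grid)
  for (k in seq_len(n_phantoms)) {
    inside <- (rowg - centers$row[k])^2 + (colg - centers$col[k])^2 <= radius_px^2
    assignment[inside] <- k
  }

  structure(list(grid = as.integer(grid), n_slices = as.integer(n_slices),
                 pixel_mm = pixel_mm, radius_px = radius_px,
                 frame_diameter_mm = frame_diameter_mm,
                 phantom_diameter_mm = phantom_diameter_mm,
                 centers = centers, assignment = assignment),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat("<phantom_layout> ", nrow(x$centers), " disks, grid ", x$grid, "x", x$grid,
      ", ", x$n_slices, " slices, ", format(x$pixel_mm, digits = 4),
      " mm/px, disk radius ", format(x$radius_px, digits = 4), " px\n", sep = "")
  invisible(x)
}

#' Simulate a multi-TI inversion-recovery image stack
#'
#' Forward-simulates the signed (real-valued) IR signal
#' \eqn{S = a(1 - b e^{-TI/T1})} for every pixel of every disk at each
#' inversion time, adds white Gaussian noise everywhere (background included)
#' and returns the stack. A magnitude mode (`magnitude = TRUE`) stores
#' \eqn{|S|} instead, emulating a reconstruction without polarity.
#'
#' @param truth Tibble with one row per imaged phantom: `id`, `a`, `b`,
#'   `T1_ms` (e.g. rows of [synthesize_cohort()]`$truth`). Rows are assigned
#'   to layout positions in order.
#' @param layout [phantom_layout()] with at least `nrow(truth)` holes.
#' @param noise_sd Gaussian noise SD in signal units (amplitude is 1).
#'   The default corresponds to the very high SNR of long-TR phantom
#'   imaging; see the methods vignette for its calibration.
#' @param seed Integer seed.
#' @param ti_list_ms Inversion times (ms).
#' @param tr_ms Repetition time (ms), metadata only (TR >> T1).
#' @param magnitude Store magnitude images instead of signed ones.
#' @param t1_jitter_sd Relative SD of optional per-pixel T1 jitter.
#' @return Object of class `ir_stack`: list with `images` (array
#'   `grid x grid x n_TI x n_slices`), `ti_list_ms`, `tr_ms`, `layout`,
#'   `phantom_ids`, `magnitude`, `noise_sd`.
#' @export
simulate_ir_stack <- function(truth, layout, noise_sd = 0.002, seed = 1L,
                              ti_list_ms = c(200, 500, 700, 1000, 2000, 3000, 4000),
                              tr_ms = 12000, magnitude = FALSE,
                              t1_jitter_sd = 0) {
  stopifnot(inherits(layout, "phantom_layout"),
            all(c("id", "a", "b", "T1_ms") %in% names(truth)))
  n_ph <- nrow(truth)
  if (n_ph > nrow(layout$centers)) {
    stop("more recipes (", n_ph, ") than layout holes (", nrow(layout$centers), ")")
  }
  grid <- layout$grid
  n_ti <- length(ti_list_ms)
  set.seed(seed)

  asg <- layout$assignment
  asg[asg > n_ph] <- 0L
  idx <- which(asg > 0L)
  ph <- asg[idx]

  a <- truth$a[ph]
  b <- truth$b[ph]
  t1 <- truth$T1_ms[ph]
  if (t1_jitter_sd > 0) t1 <- t1 * exp(rnorm(length(t1), 0, t1_jitter_sd))

  images <- array(0, dim = c(grid, grid, n_ti, layout$n_slices))
  for (s in seq_len(layout$n_slices)) {
    for (j in seq_len(n_ti)) {
      img <- matrix(0, grid, grid)
      img[idx] <- a * (1 - b * exp(-ti_list_ms[j] / t1))
      if (noise_sd > 0) img <- img + rnorm(grid * grid, 0, noise_sd)
      if (magnitude) img <- abs(img)
      images[, , j, s] <- img
    }
  }

  structure(list(images = images, ti_list_ms = ti_list_ms, tr_ms = tr_ms,
                 layout = layout, phantom_ids = truth$id[seq_len(n_ph)],
                 magnitude = magnitude, noise_sd = noise_sd),
            class = "ir_stack")
}

#' @export
print.ir_stack <- function(x, ...) {
  d <- dim(x$images)
  cat("<ir_stack> ", d[1], "x", d[2], " px, ", d[3], " TIs, ", d[4],
      " slice(s), ", length(x$phantom_ids), " phantoms",
      if (x$magnitude) ", magnitude" else ", signed", "\n", sep = "")
  invisible(x)
}
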