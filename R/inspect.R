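#' Render On-Off activation maps of a frame pair to an image
#'
#' Writes a colour-coded inspection image for one channel of a frame pair:
#' red marks pixels whose vertical (bipolar) response fired, yellow marks
#' interior centres with at least one non-centre horizontal match, white
#' marks neither. Border centres (no full 3x3 field) are grey.
#'
#' @param pair An `avs_frame_pair`.
#' @param path Output PNG path.
#' @param channel Channel index 1..3.
#' @param eps_vertical,eps_horizontal On-Off thresholds.
#' @return The path, invisibly.
#' @export
render_onoff_image <- function(pair, path, channel = 1L,
                               eps_vertical = 0, eps_horizontal = 1) {
  oo <- onoff_maps(pair$frame_t, pair$frame_t1, eps_vertical, eps_horizontal)
  d <- dim(oo$vertical)
  img <- array(1, dim = c(d[1L], d[2L], 3L))          # white
  hz <- oo$horizontal[, , -5L, channel]
  hz_any <- apply(hz, c(1L, 2L), function(v) any(v == 1, na.rm = TRUE))
  border <- is.na(oo$horizontal[, , 1L, channel])
  img[, , 3L][hz_any] <- 0                              # yellow = (1,1,0)
  vert <- oo$vertical[, , channel] == 1
  img[, , 2L][vert] <- 0; img[, , 3L][vert] <- 0        # red = (1,0,0)
  for (ch in 1:3) img[, , ch][border] <- 0.8            # grey border
  png::writePNG(img, path)
  invisible(path)
}

#' Render the LGN activation heatmaps of a direction field
#'
#' Writes one grey-scale PNG per direction, scaled to [0, 1] over the whole
#' field, for visual inspection of where each direction's LGN neurons fire.
#'
#' @param field An [avs_forward()] result.
#' @param directory Output directory (created if missing).
#' @return The file paths, invisibly.
#' @export
render_direction_heatmaps <- function(field, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  rng <- range(field$M)
  paths <- character(dim(field$M)[3L])
  for (m in seq_len(dim(field$M)[3L])) {
    img <- (field$M[, , m] - rng[1L]) / max(rng[2L] - rng[1L], 1e-12)
    paths[m] <- file.path(directory, sprintf("direction%d.png", m))
    png::writePNG(img, paths[m])
  }
  invisible(paths)
}
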