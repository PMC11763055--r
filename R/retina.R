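#' Split an RGB frame into cone-cell channels
#'
#' Mimics the S/M/L cone cells scanning a frame: returns the three intensity
#' planes of an h x w x 3 array as a list of h x w matrices. Lossless.
#'
#' @param frame An h x w x 3 array of 8-bit intensities.
#' @return A list of three h x w matrices named R, G, B.
#' @export
split_channels <- function(frame) {
  d <- dim(frame)
  if (length(d) != 3L || d[3L] != 3L)
    stop("frame must be an h x w x 3 array")
  list(R = frame[, , 1L], G = frame[, , 2L], B = frame[, , 3L])
}

#' Vertical On-Off response (bipolar cells)
#'
#' A bipolar cell fires when the intensity of its pixel changes between the
#' two frames: the response at (a, b) in channel c is 1 iff
#' |x(t) - x(t+1)| > eps_vertical. Equality with the threshold is assigned to
#' the off branch.
#'
#' @param frame_t,frame_t1 Same-shaped h x w x 3 intensity arrays.
#' @param eps_vertical Non-negative intensity threshold (default 0: any
#'   integer change fires).
#' @return An h x w x 3 array with entries in {0, 1}.
#' @export
vertical_onoff <- function(frame_t, frame_t1, eps_vertical = 0) {
  if (!identical(dim(frame_t), dim(frame_t1)))
    stop("frames must have identical dimensions")
  if (eps_vertical < 0) stop("eps_vertical must be >= 0")
  (abs(frame_t - frame_t1) > eps_vertical) + 0L
}

#' Horizontal On-Off response (horizontal cells)
#'
#' A horizontal cell compares the centre pixel at time t with the i-th cell of
#' its 3x3 receptive field at time t+1: slot i at centre (a, b) is 1 iff
#' |x_centre(t) - x'_i(t+1)| < eps_horizontal. Slots are indexed 1..9 in
#' reading order (slot 5 = the centre itself). Centres whose 3x3 field leaves
#' the grid carry NA: no intensities are fabricated beyond the border.
#'
#' @inheritParams vertical_onoff
#' @param eps_horizontal Positive intensity threshold (default 1: exact match
#'   on integer intensities).
#' @return An h x w x 9 x 3 array with entries in {0, 1} (NA at border
#'   centres), slots in dimension 3, channels in dimension 4.
#' @export
horizontal_onoff <- function(frame_t, frame_t1, eps_horizontal = 1) {
  d <- dim(frame_t)
  if (!identical(d, dim(frame_t1)))
    stop("frames must have identical dimensions")
  if (eps_horizontal <= 0) stop("eps_horizontal must be > 0")
  h <- d[1L]; w <- d[2L]
  H <- array(NA_real_, dim = c(h, w, 9L, 3L))
  rows <- 2:(h - 1L); cols <- 2:(w - 1L)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, -1L), c(0L, 0L), c(0L, 1L),
                c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (ch in 1:3) {
    centre <- frame_t[rows, cols, ch]
    for (i in 1:9) {
      nb <- frame_t1[rows + offs[i, 1L], cols + offs[i, 2L], ch]
      H[rows, cols, i, ch] <- (abs(centre - nb) < eps_horizontal) + 0
    }
  }
  H
}

#' Compute both On-Off maps of a frame pair
#'
#' Convenience wrapper bundling [vertical_onoff()] and [horizontal_onoff()]
#' with their thresholds.
#'
#' @inheritParams vertical_onoff
#' @inheritParams horizontal_onoff
#' @return An object of class `avs_onoff`: list with `vertical`
#'   (h x w x 3), `horizontal` (h x w x 9 x 3), `eps_vertical`,
#'   `eps_horizontal`.
#' @export
onoff_maps <- function(frame_t, frame_t1, eps_vertical = 0, eps_horizontal = 1) {
  structure(
    list(vertical = vertical_onoff(frame_t, frame_t1, eps_vertical),
         horizontal = horizontal_onoff(frame_t, frame_t1, eps_horizontal),
         eps_vertical = eps_vertical, eps_horizontal = eps_horizontal),
    class = "avs_onoff"
  )
}

#' Assemble the 9-slot receptive-field input of one centre pixel
#'
#' The dendritic neuron's input vector takes slot 5 from the vertical
#' (bipolar) map and slots i != 5 from the horizontal (horizontal-cell) maps.
#'
#' @param onoff An [onoff_maps()] result.
#' @param center Length-2 integer (row, col), 1-based; must be an interior
#'   pixel with a full 3x3 neighbourhood.
#' @param channel Channel index 1..3.
#' @return A binary 9-vector.
#' @export
assemble_rf_inputs <- function(onoff, center, channel) {
  d <- dim(onoff$vertical)
  r <- center[1L]; c <- center[2L]
  if (r < 2L || r > d[1L] - 1L || c < 2L || c > d[2L] - 1L)
    stop("centre (", r, ", ", c, ") has no full 3x3 neighbourhood in-grid")
  x <- onoff$horizontal[r, c, , channel]
  x[5L] <- onoff$vertical[r, c, channel]
  as.numeric(x)
}
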