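# Shared fixtures, all built in code.

# A white object of `size` pixels on a black background, moving in
# `direction`; the high-contrast regime of the worked LGN example.
white_on_black_pair <- function(size, h, w, direction, seed = 1L) {
  set.seed(seed)
  mask <- grow_object_mask(size, h, w)
  render_motion_pair(mask, matrix(255L, size, 3L), array(0L, c(h, w, 3L)),
                     direction, config = "LD", object_size = size)
}

# A small random-colour pair (object and background both random).
random_pair <- function(h = 8L, w = 8L, size = 4L, direction = 5L, seed = 1L) {
  set.seed(seed)
  mask <- grow_object_mask(size, h, w)
  render_motion_pair(mask, sample_region_colors("random", size),
                     array(sample_region_colors("random", h * w),
                           dim = c(h, w, 3L)),
                     direction, config = "RR", object_size = size)
}

# Flood fill over the 4-neighbour graph; reference for connectivity checks.
flood_fill_count <- function(mask) {
  key <- paste(mask[, 1L], mask[, 2L])
  seen <- rep(FALSE, nrow(mask))
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    nb <- cbind(mask[cur, 1L] + c(-1L, 1L, 0L, 0L),
                mask[cur, 2L] + c(0L, 0L, -1L, 1L))
    hit <- match(paste(nb[, 1L], nb[, 2L]), key)
    hit <- hit[!is.na(hit)]
    hit <- hit[!seen[hit]]
    seen[hit] <- TRUE
    queue <- c(queue, hit)
  }
  sum(seen)
}

# Direction slot correspondence used by idealised parameters and tests.
slot_of_direction <- c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)

# Reference On-Off maps computed by literal double loops over pixels,
# independent of the vectorised implementation.
onoff_loops <- function(frame_t, frame_t1, eps_v, eps_h) {
  d <- dim(frame_t)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, -1L), c(0L, 0L), c(0L, 1L),
                c(1L, -1L), c(1L, 0L), c(1L, 1L))
  V <- array(NA_real_, d)
  H <- array(NA_real_, c(d[1L], d[2L], 9L, 3L))
  for (ch in 1:3) for (a in seq_len(d[1L])) for (b in seq_len(d[2L])) {
    V[a, b, ch] <- as.numeric(abs(frame_t[a, b, ch] - frame_t1[a, b, ch]) > eps_v)
    if (a > 1L && a < d[1L] && b > 1L && b < d[2L]) {
      for (i in 1:9) {
        na <- a + offs[i, 1L]; nb <- b + offs[i, 2L]
        H[a, b, i, ch] <-
          as.numeric(abs(frame_t[a, b, ch] - frame_t1[na, nb, ch]) < eps_h)
      }
    }
  }
  list(vertical = V, horizontal = H)
}
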