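#' Encode a frame pair as grouped receptive-field patterns
#'
#' Every interior pixel of a frame pair feeds the dendritic neurons a binary
#' 9-vector per channel (27 bits in total), assembled from the On-Off maps.
#' Because the network applies identical parameters at every pixel, pixels
#' sharing a pattern produce identical activations; this encoder deduplicates
#' the patterns and keeps multiplicities, which is an exact, loss-free
#' regrouping of the per-pixel computation.
#'
#' @param pair An `avs_frame_pair`.
#' @param eps_vertical,eps_horizontal On-Off thresholds (see [onoff_maps()]).
#' @return A list with `X` (U x 27 binary matrix of unique patterns; columns
#'   are channel-major: channel c slot i at column (c-1)*9 + i), `n`
#'   (multiplicity of each pattern), `label` (direction), `n_pixels` (number
#'   of interior centres).
#' @export
encode_pair <- function(pair, eps_vertical = 0, eps_horizontal = 1) {
  oo <- onoff_maps(pair$frame_t, pair$frame_t1, eps_vertical, eps_horizontal)
  d <- dim(oo$vertical)
  rows <- 2:(d[1L] - 1L); cols <- 2:(d[2L] - 1L)
  p <- length(rows) * length(cols)
  X <- matrix(0, p, 27L)
  for (ch in 1:3) {
    for (i in 1:9) {
      X[, (ch - 1L) * 9L + i] <-
        if (i == 5L) as.numeric(oo$vertical[rows, cols, ch])
        else as.numeric(oo$horizontal[rows, cols, i, ch])
    }
  }
  key <- as.vector(X %*% 2^(0:26))
  ukey <- sort(unique(key))
  idx <- match(key, ukey)
  n <- tabulate(idx, nbins = length(ukey))
  Xu <- X[match(ukey, key), , drop = FALSE]
  list(X = Xu, n = n, label = pair$direction, n_pixels = p)
}

#' Encode a whole dataset
#'
#' Applies [encode_pair()] to every pair; the result is the input format of
#' [train_model()] and [evaluate_accuracy()].
#'
#' @param dataset An `avs_dataset`, or a plain list of `avs_frame_pair`s.
#' @inheritParams encode_pair
#' @return An object of class `avs_encoded`: list with `samples` (list of
#'   encodings), `labels`, `config`, `object_size`, `eps_vertical`,
#'   `eps_horizontal`.
#' @export
encode_dataset <- function(dataset, eps_vertical = 0, eps_horizontal = 1) {
  pairs <- if (inherits(dataset, "avs_dataset")) dataset$pairs else dataset
  if (length(pairs) == 0L) stop("dataset is empty")
  samples <- lapply(pairs, encode_pair, eps_vertical = eps_vertical,
                    eps_horizontal = eps_horizontal)
  structure(
    list(samples = samples,
         labels = vapply(samples, `[[`, integer(1L), "label"),
         config = vapply(pairs, `[[`, character(1L), "config"),
         object_size = vapply(pairs, `[[`, integer(1L), "object_size"),
         eps_vertical = eps_vertical, eps_horizontal = eps_horizontal),
    class = "avs_encoded"
  )
}

#' @export
print.avs_encoded <- function(x, ...) {
  cat("avs_encoded:", length(x$samples), "frame pairs,",
      "mean unique patterns/pair =",
      round(mean(vapply(x$samples, function(s) length(s$n), numeric(1L))), 1L),
      "\n")
  invisible(x)
}

# Stack a subset of encoded samples into one block for vectorised
# forward/backward passes: X (R x 27), n (R), group (R, sample index within
# the subset), labels.
.stack_encoded <- function(enc, idx) {
  ss <- enc$samples[idx]
  nr <- vapply(ss, function(s) nrow(s$X), integer(1L))
  list(X = do.call(rbind, lapply(ss, `[[`, "X")),
       n = unlist(lapply(ss, `[[`, "n"), use.names = FALSE),
       group = rep(seq_along(ss), nr),
       labels = enc$labels[idx],
       n_samples = length(ss))
}
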