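#' LGN integration of the three channel responses
#'
#' The lateral geniculate nucleus stage requires joint activation of all
#' three colour channels: M = sigmoid(lambda (O_R O_G O_B - theta)). Its
#' synapses are fixed; nothing here is learned.
#'
#' @param O Numeric vector of the three per-channel soma outputs at one
#'   pixel and direction.
#' @param lambda Positive slope.
#' @param theta Threshold.
#' @return The LGN activation in (0, 1).
#' @export
lgn_integrate <- function(O, lambda = 5, theta = 0.5) {
  if (length(O) != 3L) stop("LGN integration expects exactly 3 channel outputs")
  if (lambda <= 0) stop("LGN slope lambda must be > 0")
  .sigmoid(lambda * (prod(O) - theta))
}

#' Global direction sums
#'
#' Sums the LGN activation field of each direction over all (interior)
#' pixels: D_m = sum_{a,b} M_m(a, b).
#'
#' @param M A rows x cols x directions array of LGN activations.
#' @return A numeric vector of length `dim(M)[3]`.
#' @export
direction_sums <- function(M) {
  apply(M, 3L, sum)
}

#' Normalise the direction sums
#'
#' Default mode `"simplex"` divides by the total, so the result is a
#' probability vector (a well-posed input for a cross-entropy). Mode
#' `"area"` divides by the pixel count A*B instead — the normalisation under
#' which the shortcut backward rule's constant Jacobian 1/(A*B) is exact —
#' but the result does not sum to one. The two modes coincide up to a scale
#' factor that the argmax readout ignores.
#'
#' @param D Non-negative direction sums.
#' @param mode `"simplex"` or `"area"`.
#' @param area Pixel count A*B (required for mode `"area"`).
#' @return Normalised vector `D_norm`.
#' @export
normalize_outputs <- function(D, mode = c("simplex", "area"), area = NULL) {
  mode <- match.arg(mode)
  if (any(D < 0)) stop("direction sums must be non-negative")
  if (mode == "simplex") {
    tot <- sum(D)
    if (tot == 0) stop("degenerate field: all direction sums are zero")
    D / tot
  } else {
    if (is.null(area)) stop("mode 'area' needs the pixel count `area`")
    D / area
  }
}

#' Predicted motion direction
#'
#' The argmax over the direction sums; exact ties break toward the smallest
#' direction index (deterministic).
#'
#' @param D Direction sums (length M).
#' @return Integer direction index.
#' @export
predict_direction <- function(D) {
  which.max(D)
}

# ---------------------------------------------------------------------------
# Vectorised forward pass over a block of grouped patterns.
#
# Because inputs are binary, a synapse takes only two values,
# S1 = sigmoid((w - q)/d) at x = 1 and S0 = sigmoid(-q/d) at x = 0, and a
# branch's log-output is a linear form in the pattern bits:
#   log b_j = Xc %*% log S1 + (1 - Xc) %*% log S0.
# This evaluates every layer for all rows of the block at once.
#
# block: list(X [R x 27], n [R], group [R], labels, n_samples)
# Returns per-row intermediates needed by the backward pass.
.forward_block <- function(block, params) {
  R <- nrow(block$X)
  I <- params$I; J <- params$J; M <- params$M; C <- params$C
  Xc <- lapply(seq_len(C), function(ch)
    block$X[, (ch - 1L) * I + seq_len(I), drop = FALSE])
  X0c <- lapply(Xc, function(x) 1 - x)
  lS1 <- stats::plogis((params$w - params$q) / params$d, log.p = TRUE)
  lS0 <- stats::plogis(-params$q / params$d, log.p = TRUE)
  lb <- array(NA_real_, dim = c(R, J, M, C))
  O <- array(NA_real_, dim = c(R, M, C))
  for (ch in seq_len(C)) {
    for (m in seq_len(M)) {
      u <- numeric(R)
      for (j in seq_len(J)) {
        lbj <- Xc[[ch]] %*% lS1[, j, m, ch] + X0c[[ch]] %*% lS0[, j, m, ch]
        lb[, j, m, ch] <- lbj
        u <- u + params$v[j, m, ch] * exp(lbj)
      }
      O[, m, ch] <- .sigmoid(params$lambda_soma * (u - params$theta_soma))
    }
  }
  prodO <- matrix(1, R, M)
  for (ch in seq_len(C)) prodO <- prodO * matrix(O[, , ch], R, M)
  Mv <- .sigmoid(params$lambda_lgn * (prodO - params$theta_lgn))
  D <- rowsum(Mv * block$n, block$group, reorder = TRUE)
  list(Xc = Xc, X0c = X0c, lS1 = lS1, lS0 = lS0, lb = lb, O = O,
       prodO = prodO, Mv = Mv, D = D)
}

#' Full network forward pass on one frame pair
#'
#' Runs retina, ganglion and LGN stages over every interior pixel and
#' aggregates the global direction readout.
#'
#' @param pair An `avs_frame_pair`.
#' @param params An `avs_params` object.
#' @param eps_vertical,eps_horizontal On-Off thresholds.
#' @param normalize Normalisation mode, see [normalize_outputs()].
#' @return An object of class `avs_direction_field`: list with `M`
#'   (rows x cols x directions LGN activation field over interior pixels),
#'   `D` (direction sums), `D_norm`, `prediction`.
#' @export
avs_forward <- function(pair, params, eps_vertical = 0, eps_horizontal = 1,
                        normalize = "simplex") {
  s <- encode_pair(pair, eps_vertical, eps_horizontal)
  # forward over unique patterns, then scatter back to the pixel grid
  block <- list(X = s$X, n = s$n, group = rep(1L, nrow(s$X)),
                labels = s$label, n_samples = 1L)
  fw <- .forward_block(block, params)
  d <- dim(pair$frame_t)
  h <- d[1L] - 2L; w <- d[2L] - 2L
  # recompute the per-pixel pattern index to expand the grouped rows
  pp <- .pair_pattern_index(pair, eps_vertical, eps_horizontal, s$X)
  Mfield <- array(fw$Mv[pp, ], dim = c(h, w, params$M))
  D <- direction_sums(Mfield)
  structure(
    list(M = Mfield, D = D,
         D_norm = normalize_outputs(D, normalize, area = d[1L] * d[2L]),
         prediction = predict_direction(D)),
    class = "avs_direction_field"
  )
}

# Index of each interior pixel's pattern among the unique rows Xu.
.pair_pattern_index <- function(pair, eps_vertical, eps_horizontal, Xu) {
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
  match(as.vector(X %*% 2^(0:26)), as.vector(Xu %*% 2^(0:26)))
}

#' @export
print.avs_direction_field <- function(x, ...) {
  cat("avs_direction_field: prediction =", x$prediction, "\n")
  cat("  D      =", paste(sprintf("%.3f", x$D), collapse = " "), "\n")
  cat("  D_norm =", paste(sprintf("%.4f", x$D_norm), collapse = " "), "\n")
  invisible(x)
}
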