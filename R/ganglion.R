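.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Create (and randomly initialise) ganglion-neuron parameters
#'
#' One dendritic neuron exists per motion direction m and colour channel c.
#' Each has I sigmoid synapses on each of J branches; branch outputs are the
#' product of their synapse outputs, the membrane sums branches with fixed
#' weights v, and the soma applies a final sigmoid with slope `lambda_soma`
#' and threshold `theta_soma`. Only the synaptic weights `w` and biases `q`
#' are learnable; with the defaults (I = 9, J = 1, M = 8, C = 3) that is
#' 9 x 2 x 8 x 3 = 432 parameters.
#'
#' Initialisation (`init`), drawn from the current RNG state (seed via
#' [set.seed()]):
#' \describe{
#'   \item{`"change_gated"` (default)}{Surround synapses start permissive
#'     (near constant-1: `w ~ U(-0.25, 0.25)`, `q ~ U(-0.7, -0.5)`) and the
#'     centre (bipolar) synapse starts excitatory (`w = 1.5`, `q = 0.75`).
#'     The centre slot carries temporal change, which every direction needs,
#'     so this gates all neurons on motion without biasing any direction; it
#'     concentrates the learning signal on the patterns that actually
#'     discriminate directions. Because a branch multiplies its synapse
#'     outputs, this is also the regime where gradients flow: products of
#'     randomly saturated sigmoids vanish.}
#'   \item{`"uniform"`}{`w`, `q ~ U(-1, 1)` independently; kept for
#'     comparison. Most draws give branch products near zero and barely
#'     trainable neurons.}
#' }
#'
#' @param I Synapses per branch (9 = the 3x3 receptive field).
#' @param J Branches per neuron.
#' @param M Number of motion directions.
#' @param C Number of colour channels.
#' @param d Distance hyperparameter of the synaptic sigmoid (slope 1/d).
#' @param v Fixed branch weight (scalar, replicated to a J x M x C array).
#' @param lambda_soma,theta_soma Soma sigmoid slope and threshold.
#' @param lambda_lgn,theta_lgn LGN sigmoid slope and threshold (carried here
#'   so one object parameterises the whole network; the LGN stage is
#'   non-learnable).
#' @return An object of class `avs_params`.
#' @export
avs_params <- function(I = 9L, J = 1L, M = 8L, C = 3L, d = 0.2, v = 1,
                       lambda_soma = 5, theta_soma = 0.5,
                       lambda_lgn = 5, theta_lgn = 0.5,
                       init = c("change_gated", "uniform")) {
  if (d <= 0) stop("distance parameter d must be > 0")
  if (lambda_soma <= 0 || lambda_lgn <= 0) stop("sigmoid slopes must be > 0")
  init <- match.arg(init)
  n <- I * J * M * C
  if (init == "uniform") {
    w <- array(stats::runif(n, -1, 1), dim = c(I, J, M, C))
    q <- array(stats::runif(n, -1, 1), dim = c(I, J, M, C))
  } else {
    w <- array(stats::runif(n, -0.25, 0.25), dim = c(I, J, M, C))
    q <- array(stats::runif(n, -0.7, -0.5), dim = c(I, J, M, C))
    centre <- (I + 1L) %/% 2L
    w[centre, , , ] <- 1.5
    q[centre, , , ] <- 0.75
  }
  structure(
    list(w = w, q = q,
         d = d,
         v = array(v, dim = c(J, M, C)),
         lambda_soma = lambda_soma, theta_soma = theta_soma,
         lambda_lgn = lambda_lgn, theta_lgn = theta_lgn,
         I = as.integer(I), J = as.integer(J),
         M = as.integer(M), C = as.integer(C)),
    class = "avs_params"
  )
}

#' @export
print.avs_params <- function(x, ...) {
  cat("avs_params: I =", x$I, "synapses, J =", x$J, "branches, M =", x$M,
      "directions, C =", x$C, "channels\n")
  cat("  learnable parameters:", count_learnable(x),
      " (w, q); d =", x$d, ", soma lambda/theta =", x$lambda_soma, "/",
      x$theta_soma, ", LGN lambda/theta =", x$lambda_lgn, "/", x$theta_lgn,
      "\n")
  invisible(x)
}

#' Number of learnable parameters
#'
#' Counts the learnable synaptic weights and biases: I x J x M x C x 2. At
#' the defaults this is 432.
#'
#' @param params An `avs_params` object.
#' @return Integer count.
#' @export
count_learnable <- function(params) {
  length(params$w) + length(params$q)
}

#' Synaptic sigmoid activation
#'
#' S(x) = sigmoid((w x - q) / d): the output of one synapse given its binary
#' input, weight, bias and distance hyperparameter.
#'
#' @param x Binary input (0 or 1); vectorised.
#' @param w,q Weight and bias.
#' @param d Positive distance parameter.
#' @return Value(s) in (0, 1).
#' @export
synapse_activation <- function(x, w, q, d = 0.2) {
  if (any(d <= 0)) stop("distance parameter d must be > 0")
  .sigmoid((w * x - q) / d)
}

#' Classify a synapse's connection state
#'
#' A synapse is classified by its outputs at x = 0 and x = 1, thresholded at
#' 0.5: (low, high) = excitatory, (high, low) = inhibitory, (high, high) =
#' constant-1, (low, low) = constant-0.
#'
#' @inheritParams synapse_activation
#' @return Character vector with values in `c("excitatory", "inhibitory",
#'   "constant-1", "constant-0")`.
#' @export
connection_state <- function(w, q, d = 0.2) {
  s0 <- synapse_activation(0, w, q, d) > 0.5
  s1 <- synapse_activation(1, w, q, d) > 0.5
  out <- character(length(s0))
  out[!s0 & s1] <- "excitatory"
  out[s0 & !s1] <- "inhibitory"
  out[s0 & s1] <- "constant-1"
  out[!s0 & !s1] <- "constant-0"
  out
}

#' Branch output: product of synapse outputs
#'
#' @param S Vector of synapse outputs in (0, 1).
#' @return Their product.
#' @export
branch_output <- function(S) prod(S)

#' Membrane potential: weighted sum of branch outputs
#'
#' @param b Vector of branch outputs.
#' @param v Vector of branch weights.
#' @return The dot product sum_j v_j b_j.
#' @export
membrane_potential <- function(b, v) {
  if (length(b) != length(v)) stop("branch and weight vectors must agree")
  sum(v * b)
}

#' Soma output
#'
#' O = sigmoid(lambda (u - theta)).
#'
#' @param u Membrane potential.
#' @param lambda Positive slope.
#' @param theta Threshold.
#' @return Value in (0, 1).
#' @export
soma_output <- function(u, lambda = 5, theta = 0.5) {
  if (any(lambda <= 0)) stop("soma slope lambda must be > 0")
  .sigmoid(lambda * (u - theta))
}

#' Full forward pass of one ganglion neuron
#'
#' Composes synapse, branch, membrane and soma layers for direction `m` and
#' channel `c`, recording all intermediates (needed by the backward pass and
#' by tests).
#'
#' @param x Binary input 9-vector (see [assemble_rf_inputs()]).
#' @param params An `avs_params` object.
#' @param m Direction index 1..M.
#' @param c Channel index 1..C.
#' @return A list with `S` (I x J), `b` (J), `u`, `O`.
#' @export
ganglion_forward <- function(x, params, m, c) {
  if (length(x) != params$I) stop("input must have length I = ", params$I)
  S <- matrix(NA_real_, params$I, params$J)
  for (j in seq_len(params$J))
    S[, j] <- synapse_activation(x, params$w[, j, m, c], params$q[, j, m, c],
                                 params$d)
  b <- apply(S, 2L, branch_output)
  u <- membrane_potential(b, params$v[, m, c])
  O <- soma_output(u, params$lambda_soma, params$theta_soma)
  list(S = S, b = b, u = u, O = O)
}

#' Hand-constructed direction-selective parameters
#'
#' Builds the idealised parameter set that the trained network is expected to
#' approach on high-contrast data: for each direction m, the synapse at the
#' centre slot (vertical change) and the synapse at the slot the object moves
#' into (horizontal match) are excitatory; all other synapses are constant-1.
#' Useful as an oracle: it classifies high-contrast motion perfectly without
#' training.
#'
#' @param d,lambda_soma,theta_soma,lambda_lgn,theta_lgn Hyperparameters
#'   passed through to [avs_params()].
#' @return An `avs_params` object (J = 1).
#' @export
ideal_params <- function(d = 0.2, lambda_soma = 5, theta_soma = 0.5,
                         lambda_lgn = 5, theta_lgn = 0.5) {
  p <- avs_params(d = d, lambda_soma = lambda_soma, theta_soma = theta_soma,
                  lambda_lgn = lambda_lgn, theta_lgn = theta_lgn)
  # constant-1 everywhere: S(0) = S(1) = sigmoid(1/d) ~ 1
  p$w[] <- 0
  p$q[] <- -1
  for (m in 1:8) {
    for (ch in 1:3) {
      for (slot in c(5L, .slot_of_direction[m])) {
        p$w[slot, 1L, m, ch] <- 2   # excitatory: S(0) = sigmoid(-5),
        p$q[slot, 1L, m, ch] <- 1   #             S(1) = sigmoid(5)
      }
    }
  }
  p
}

#' Save / load parameters as a versioned text checkpoint
#'
#' Serialises an `avs_params` object to JSON with full floating-point
#' precision (17 significant digits), which round-trips binary64 values
#' exactly and is portable across platforms.
#'
#' @param params An `avs_params` object.
#' @param path File path.
#' @return `write_checkpoint()` the path, invisibly; `read_checkpoint()` an
#'   `avs_params` object.
#' @export
write_checkpoint <- function(params, path) {
  stopifnot(inherits(params, "avs_params"))
  # doubles are serialised as %.17g strings: 17 significant digits
  # round-trip IEEE binary64 exactly, which JSON number emitters do not
  # always guarantee
  num <- function(x) sprintf("%.17g", as.numeric(x))
  obj <- list(format = "avsmotion-checkpoint", version = 1L,
              I = params$I, J = params$J, M = params$M, C = params$C,
              d = num(params$d),
              v = num(params$v),
              w = num(params$w), q = num(params$q),
              lambda_soma = num(params$lambda_soma),
              theta_soma = num(params$theta_soma),
              lambda_lgn = num(params$lambda_lgn),
              theta_lgn = num(params$theta_lgn))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "avsmotion-checkpoint"))
    stop(path, " is not an avsmotion checkpoint")
  num <- function(x) as.numeric(x)
  p <- avs_params(I = obj$I, J = obj$J, M = obj$M, C = obj$C,
                  d = num(obj$d),
                  lambda_soma = num(obj$lambda_soma),
                  theta_soma = num(obj$theta_soma),
                  lambda_lgn = num(obj$lambda_lgn),
                  theta_lgn = num(obj$theta_lgn))
  p$w <- array(num(obj$w), dim = c(obj$I, obj$J, obj$M, obj$C))
  p$q <- array(num(obj$q), dim = c(obj$I, obj$J, obj$M, obj$C))
  p$v <- array(num(obj$v), dim = c(obj$J, obj$M, obj$C))
  p
}
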