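#' Training configuration
#'
#' Bundles the optimizer and preprocessing settings of [train_model()].
#' Defaults: learning rate 0.05, 100 epochs, mini-batches of 32, exact
#' gradients, early stop after 10 epochs without loss improvement.
#'
#' @param learning_rate Positive step size eta of gradient descent.
#' @param epochs Maximum number of passes over the training set.
#' @param batch_size Mini-batch size (1 = online learning).
#' @param seed Integer seed controlling initialisation and shuffling.
#' @param eps_vertical,eps_horizontal On-Off thresholds used when encoding.
#' @param gradient_mode `"exact"` (true chain rule, default) or
#'   `"simplified"` (a shortcut backward rule that drops the normalisation
#'   Jacobian and evaluates layer derivatives at set-points; see the methods
#'   vignette).
#' @param early_stop_patience Epochs without improvement before stopping.
#' @return An object of class `avs_train_config`.
#' @export
train_config <- function(learning_rate = 0.05, epochs = 100L, batch_size = 32L,
                         seed = 1L, eps_vertical = 0, eps_horizontal = 1,
                         gradient_mode = c("exact", "simplified"),
                         early_stop_patience = 10L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         eps_vertical = eps_vertical, eps_horizontal = eps_horizontal,
         gradient_mode = match.arg(gradient_mode),
         early_stop_patience = as.integer(early_stop_patience)),
    class = "avs_train_config"
  )
}

#' Cross-entropy loss of a normalised direction readout
#'
#' E = -sum_m T_m log(D_norm_m) with a one-hot teacher T: the negative log
#' of the true direction's normalised output. Probabilities below 1e-12 are
#' clamped (with a warning) so the loss stays finite.
#'
#' @param D_norm Normalised direction outputs (probability vector).
#' @param label True direction index, or a one-hot vector.
#' @return The scalar loss.
#' @export
cross_entropy_loss <- function(D_norm, label) {
  if (length(label) > 1L) label <- which.max(label)
  p <- D_norm[label]
  if (p < 1e-12) {
    warning("true-direction probability below 1e-12; clamped")
    p <- 1e-12
  }
  -log(p)
}

# Backward pass over a forward block. Returns the mean-over-samples gradient
# of the cross-entropy loss w.r.t. w and q, plus the batch loss and
# per-sample predictions.
.backward_block <- function(block, fw, params, mode = "exact") {
  S <- block$n_samples
  I <- params$I; J <- params$J; M <- params$M; C <- params$C
  R <- nrow(block$X)
  D <- fw$D
  truth <- cbind(seq_len(S), block$labels)
  preds <- max.col(D, ties.method = "first")

  # dE/dD per sample (S x M), scaled by 1/S for the batch mean
  if (mode == "exact") {
    # softmax normalisation of the direction sums; shift-invariant, so the
    # direction-independent background response drops out of the gradient
    P <- exp(D - apply(D, 1L, max))
    P <- P / rowSums(P)
    loss <- mean(-log(pmax(P[truth], 1e-12)))
    dEdD <- P / S
    dEdD[truth] <- dEdD[truth] - 1 / S
  } else {
    # shortcut rule: the normalisation Jacobian collapses to 1, so only the
    # true direction receives gradient, -T_m / D_norm_m, with D_norm the
    # per-area normalisation that collapse implies
    area <- rowsum(block$n, block$group)[, 1L]
    p_true <- D[truth] / area
    loss <- mean(-log(pmax(p_true, 1e-12)))
    dEdD <- matrix(0, S, M)
    dEdD[truth] <- -1 / (S * pmax(p_true, 1e-12))
  }
  # expand to pattern rows with multiplicities
  dEdM <- dEdD[block$group, , drop = FALSE] * block$n

  Mv <- fw$Mv
  if (mode == "exact") {
    tM <- dEdM * params$lambda_lgn * Mv * (1 - Mv)
  } else {
    # shortcut rule: the LGN sigmoid derivative is evaluated per channel at
    # (O^c - theta_m) instead of at the channel product; applied below
    tM <- dEdM
  }

  gw <- array(0, dim = c(I, J, M, C))
  gq <- array(0, dim = c(I, J, M, C))
  S1 <- exp(fw$lS1); S0 <- exp(fw$lS0)
  s1p <- S1 * (1 - S1); s0p <- S0 * (1 - S0)
  for (ch in seq_len(C)) {
    Xc <- fw$Xc[[ch]]; X0c <- fw$X0c[[ch]]
    Och <- matrix(fw$O[, , ch], R, M)
    if (mode == "exact") {
      oth <- matrix(1, R, M)
      for (c2 in seq_len(C)) if (c2 != ch)
        oth <- oth * matrix(fw$O[, , c2], R, M)
      dEdO <- tM * oth
    } else {
      sig <- .sigmoid(params$lambda_lgn * (Och - params$theta_lgn))
      dEdO <- tM * params$lambda_lgn * sig * (1 - sig)
    }
    for (m in seq_len(M)) {
      if (mode == "exact") {
        dEdu <- dEdO[, m] * params$lambda_soma * Och[, m] * (1 - Och[, m])
      }
      for (j in seq_len(J)) {
        if (mode == "exact") {
          dEdb <- dEdu * params$v[j, m, ch]
        } else {
          # shortcut rule: soma derivative at the set-point (v - theta)
          sv <- .sigmoid(params$lambda_soma *
                           (params$v[j, m, ch] - params$theta_soma))
          dEdb <- dEdO[, m] * params$v[j, m, ch] * params$lambda_soma *
            sv * (1 - sv)
        }
        # leave-one-out branch products via log space
        lSrow <- Xc * matrix(fw$lS1[, j, m, ch], R, I, byrow = TRUE) +
          X0c * matrix(fw$lS0[, j, m, ch], R, I, byrow = TRUE)
        loo <- exp(as.vector(fw$lb[, j, m, ch]) - lSrow)
        dEdS <- dEdb * loo
        aw <- colSums(dEdS * Xc)
        a0 <- colSums(dEdS * X0c)
        gw[, j, m, ch] <- (1 / params$d) * s1p[, j, m, ch] * aw
        gq[, j, m, ch] <- -(1 / params$d) *
          (s1p[, j, m, ch] * aw + s0p[, j, m, ch] * a0)
      }
    }
  }
  list(gw = gw, gq = gq, loss = loss, predictions = preds)
}

#' Analytic gradients of the loss over a batch
#'
#' Runs the forward pass on the selected samples of an encoded dataset and
#' returns the mean analytic gradient of the cross-entropy loss with respect
#' to every synaptic weight and bias. Mode `"exact"` differentiates the
#' forward equations as implemented (including the LGN product over channels
#' and the softmax normalisation of the training objective); mode
#' `"simplified"` applies shortcut factors instead (normalisation
#' Jacobian = 1, LGN derivative evaluated per channel at O^c, soma
#' derivative evaluated at the set-point v).
#'
#' @param encoded An [encode_dataset()] result.
#' @param params An `avs_params` object.
#' @param mode `"exact"` or `"simplified"`.
#' @param idx Indices of the samples forming the batch (default: all).
#' @return A list with `gw`, `gq` (arrays shaped like `params$w`), `loss`,
#'   `predictions`.
#' @export
backward_gradients <- function(encoded, params, mode = c("exact", "simplified"),
                               idx = NULL) {
  mode <- match.arg(mode)
  if (is.null(idx)) idx <- seq_along(encoded$samples)
  block <- .stack_encoded(encoded, idx)
  fw <- .forward_block(block, params)
  .backward_block(block, fw, params, mode)
}

#' Batch loss without gradients
#'
#' Mean cross-entropy of the selected samples under the current parameters;
#' the scalar objective that [numeric_gradient_oracle()] differentiates.
#'
#' @inheritParams backward_gradients
#' @return The mean loss.
#' @export
batch_loss <- function(encoded, params, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(encoded$samples)
  block <- .stack_encoded(encoded, idx)
  fw <- .forward_block(block, params)
  P <- exp(fw$D - apply(fw$D, 1L, max))
  P <- P / rowSums(P)
  truth <- cbind(seq_len(block$n_samples), block$labels)
  mean(-log(pmax(P[truth], 1e-12)))
}

#' Central finite-difference gradient (reference oracle)
#'
#' Estimates the gradient of `loss_fn(params)` with respect to every entry of
#' `params$w` and `params$q` by central differences. A test-time reference,
#' independent of the analytic backward pass.
#'
#' @param loss_fn Function taking an `avs_params` and returning a scalar.
#' @param params An `avs_params` object.
#' @param step Positive finite-difference step.
#' @param richardson If `TRUE`, combine central differences at `step` and
#'   `step/2` by Richardson extrapolation, cancelling the O(step^2)
#'   truncation term. Use a larger step (e.g. 1e-3) in this mode so
#'   cancellation noise stays small.
#' @return A list with `gw` and `gq`.
#' @export
numeric_gradient_oracle <- function(loss_fn, params, step = 1e-5,
                                    richardson = FALSE) {
  if (step <= 0) stop("step must be > 0")
  central <- function(field, k, h) {
    up <- params; up[[field]][k] <- up[[field]][k] + h
    dn <- params; dn[[field]][k] <- dn[[field]][k] - h
    (loss_fn(up) - loss_fn(dn)) / (2 * h)
  }
  grad_of <- function(field) {
    g <- array(0, dim = dim(params[[field]]))
    for (k in seq_along(g)) {
      g[k] <- if (richardson)
        (4 * central(field, k, step / 2) - central(field, k, step)) / 3
      else central(field, k, step)
    }
    g
  }
  list(gw = grad_of("w"), gq = grad_of("q"))
}

#' One gradient-descent update
#'
#' w <- w - eta * dE/dw and q <- q - eta * dE/dq; nothing else changes.
#'
#' @param params An `avs_params` object.
#' @param gradients List with `gw`, `gq` (as from [backward_gradients()]).
#' @param learning_rate Step size eta.
#' @return The updated `avs_params`.
#' @export
sgd_step <- function(params, gradients, learning_rate) {
  for (field in c("gw", "gq")) {
    bad <- which(!is.finite(gradients[[field]]))
    if (length(bad) > 0L)
      stop("non-finite gradient in ", substr(field, 2L, 2L),
           " at coordinate ", bad[1L])
  }
  params$w <- params$w - learning_rate * gradients$gw
  params$q <- params$q - learning_rate * gradients$gq
  params
}

#' Train the network by mini-batch gradient descent
#'
#' Initialises parameters (see [avs_params()]) and runs seeded mini-batch
#' gradient descent on the cross-entropy loss, logging per-epoch mean loss
#' and running training accuracy. Training stops early when the running
#' training accuracy has not improved for `early_stop_patience` epochs, and
#' the parameters of the best epoch (highest accuracy, then lowest loss) are
#' returned: once the readout is confidently correct the cross-entropy can
#' drift upward on a few hard samples while accuracy keeps improving, so
#' accuracy is the quantity worth stopping on. Deterministic given
#' `config$seed`.
#'
#' @param encoded An [encode_dataset()] result (the training set).
#' @param config An [train_config()] object.
#' @param params Optional starting `avs_params` (default: fresh random
#'   initialisation from `config$seed`).
#' @param quiet Suppress the per-epoch progress line on standard error.
#' @return An object of class `avs_fit`: list with `params`, `history`
#'   (data.frame epoch / train_loss / train_acc), `config`.
#' @export
train_model <- function(encoded, config = train_config(), params = NULL,
                        quiet = TRUE) {
  if (length(encoded$samples) == 0L) stop("training set is empty")
  set.seed(config$seed)
  if (is.null(params)) params <- avs_params()
  n <- length(encoded$samples)
  best_acc <- -1
  best_loss <- Inf
  best_params <- params
  since_best <- 0L
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_acc <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0; ep_correct <- 0L
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      block <- .stack_encoded(encoded, idx)
      fw <- .forward_block(block, params)
      bw <- .backward_block(block, fw, params, config$gradient_mode)
      params <- sgd_step(params, bw, config$learning_rate)
      ep_loss <- ep_loss + bw$loss * length(idx)
      ep_correct <- ep_correct + sum(bw$predictions == block$labels)
    }
    ep_loss <- ep_loss / n
    ep_acc <- ep_correct / n
    hist_epoch <- c(hist_epoch, epoch)
    hist_loss <- c(hist_loss, ep_loss)
    hist_acc <- c(hist_acc, ep_acc)
    if (!quiet)
      message(sprintf("epoch %3d  loss %.5f  train acc %.4f",
                      epoch, ep_loss, ep_acc))
    if (ep_acc > best_acc ||
        (ep_acc == best_acc && ep_loss < best_loss - 1e-9)) {
      improved <- ep_acc > best_acc
      best_acc <- ep_acc
      best_loss <- min(best_loss, ep_loss)
      best_params <- params
      since_best <- if (improved) 0L else since_best + 1L
    } else {
      since_best <- since_best + 1L
    }
    if (since_best >= config$early_stop_patience) break
  }
  structure(
    list(params = best_params,
         history = data.frame(epoch = hist_epoch, train_loss = hist_loss,
                              train_acc = hist_acc),
         config = config),
    class = "avs_fit"
  )
}

#' @export
print.avs_fit <- function(x, ...) {
  last <- nrow(x$history)
  cat("avs_fit:", last, "epochs; final train loss",
      sprintf("%.5f", x$history$train_loss[last]), "acc",
      sprintf("%.4f", x$history$train_acc[last]), "\n")
  invisible(x)
}

#' Classification accuracy on a labelled dataset
#'
#' Fraction of pairs whose argmax direction readout equals the ground-truth
#' label.
#'
#' @param params An `avs_params` object.
#' @param encoded An [encode_dataset()] result.
#' @param chunk_size Samples per vectorised forward chunk.
#' @return Fraction correct in [0, 1].
#' @export
evaluate_accuracy <- function(params, encoded, chunk_size = 1000L) {
  n <- length(encoded$samples)
  correct <- 0L
  for (s in seq(1L, n, by = chunk_size)) {
    idx <- s:min(s + chunk_size - 1L, n)
    block <- .stack_encoded(encoded, idx)
    fw <- .forward_block(block, params)
    preds <- max.col(fw$D, ties.method = "first")
    correct <- correct + sum(preds == block$labels)
  }
  correct / n
}
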