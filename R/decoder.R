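# Sequence decoder from population instantaneous rates to toroidal position:
# a two-layer LSTM (256 hidden features) reading 20 bins of 20 ms and
# predicting cos/sin of the two torus angles, trained with Adam on a mean
# squared error loss for one epoch. The network (forward pass, backprop
# through time and Adam) is implemented in compiled code; all randomness
# (weight initialization, batch order) is drawn from R's RNG so runs are
# reproducible given a seed.

#' Decoder hyperparameters
#'
#' @param window input window length in bins (20 bins of 20 ms = 400 ms).
#' @param bin rate bin width (s).
#' @param rate_smooth_sd rate smoothing kernel sd (s).
#' @param hidden hidden features per LSTM layer.
#' @param lr Adam learning rate.
#' @param batch batch size.
#' @param epochs training epochs (1 in the standard analysis).
#' @param output_smooth_sd smoothing sd (s) applied to the four decoded
#'   outputs before the arctangent.
#' @param seed RNG seed for initialization and batch order.
#' @return list of class `decoder_spec`.
#' @export
decoder_spec <- function(window = 20, bin = 0.02, rate_smooth_sd = 0.02,
                         hidden = 256, lr = 0.001, batch = 64, epochs = 1,
                         output_smooth_sd = 0.1, seed = 1) {
  structure(list(window = window, bin = bin,
                 rate_smooth_sd = rate_smooth_sd, hidden = hidden, lr = lr,
                 batch = batch, epochs = epochs,
                 output_smooth_sd = output_smooth_sd, seed = seed),
            class = "decoder_spec")
}

#' Population rate matrix
#'
#' Instantaneous rate of every cell on a common binning.
#'
#' @param spikes named list of spike-time vectors.
#' @param t_start,t_end time span (s).
#' @param bin bin width (s).
#' @param smooth_sd smoothing sd (s).
#' @return list: `t` (bin centers), `rates` (bins x cells matrix).
#' @export
rate_matrix <- function(spikes, t_start, t_end, bin = 0.02,
                        smooth_sd = 0.02) {
  series <- lapply(spikes, instantaneous_rate, t_start = t_start,
                   t_end = t_end, bin = bin, smooth_sd = smooth_sd)
  list(t = series[[1]]$t,
       rates = do.call(cbind, lapply(series, `[[`, "rate")))
}

#' Build the sequence dataset
#'
#' Window-end indices for every sample whose full window lies inside one
#' contiguous segment, plus the 4-column cos/sin target at the window end.
#'
#' @param v matrix (bins x 2) of torus angles aligned to the rate bins.
#' @param window window length in bins.
#' @param segments optional 2-column matrix of segment (start, end) bin
#'   indices; default one segment covering everything.
#' @return list: `idx` (window-end bin indices), `Y` (targets), and
#'   `n_dropped` (segments shorter than the window).
#' @export
build_dataset <- function(v, window, segments = NULL) {
  n <- nrow(v)
  if (is.null(segments)) segments <- cbind(1, n)
  dropped <- 0
  idx <- integer(0)
  for (s in seq_len(nrow(segments))) {
    a <- segments[s, 1]; b <- segments[s, 2]
    if (b - a + 1 < window) {
      dropped <- dropped + 1
      next
    }
    idx <- c(idx, (a + window - 1):b)
  }
  Y <- cbind(cos(v[idx, 1]), sin(v[idx, 1]), cos(v[idx, 2]), sin(v[idx, 2]))
  list(idx = idx, Y = Y, n_dropped = dropped)
}

# PyTorch-style uniform init U(-1/sqrt(H), 1/sqrt(H)) for all parameters
init_lstm_params <- function(n_in, hidden) {
  k <- 1 / sqrt(hidden)
  ru <- function(nr, nc) matrix(runif(nr * nc, -k, k), nr, nc)
  list(l1_W = ru(4 * hidden, n_in), l1_U = ru(4 * hidden, hidden),
       l1_b = matrix(runif(4 * hidden, -k, k), ncol = 1),
       l2_W = ru(4 * hidden, hidden), l2_U = ru(4 * hidden, hidden),
       l2_b = matrix(runif(4 * hidden, -k, k), ncol = 1),
       out_W = ru(4, hidden), out_b = matrix(runif(4, -k, k), ncol = 1))
}

zero_like <- function(par) lapply(par, function(p) p * 0)

#' Train the toroidal decoder
#'
#' Trains the LSTM on the supplied rate matrix and torus labels
#' (chronological batches after a seeded shuffle, one epoch by default).
#'
#' @param rates bins x cells rate matrix (Hz).
#' @param v bins x 2 matrix of torus angles (labels).
#' @param spec a [decoder_spec()].
#' @param segments optional contiguous-segment index matrix for
#'   [build_dataset()].
#' @return decoder model: list of class `torus_decoder` with the trained
#'   parameters, spec, number of cells and training losses.
#' @export
train_decoder <- function(rates, v, spec = decoder_spec(), segments = NULL) {
  stopifnot(nrow(rates) == nrow(v))
  set.seed(spec$seed)
  ds <- build_dataset(v, spec$window, segments)
  par <- init_lstm_params(ncol(rates), spec$hidden)
  state <- list(m = zero_like(par), v = zero_like(par), step = 0L)
  losses <- c()
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(length(ds$idx))
    fit <- cpp_lstm_train_epoch(rates, ds$idx, ds$Y, spec$window, par, state,
                                ord, spec$batch, spec$lr)
    par <- fit$par; state <- fit$state
    losses <- c(losses, fit$losses)
  }
  structure(list(par = par, spec = spec, n_cells = ncol(rates),
                 losses = losses),
            class = "torus_decoder")
}

#' Decode toroidal position from population rates
#'
#' Runs the trained decoder over every bin with a full preceding window,
#' smooths the four cos/sin outputs with a Gaussian kernel, and converts
#' them to wrapped angles with the two-argument arctangent.
#'
#' @param model a `torus_decoder` from [train_decoder()].
#' @param rates bins x cells rate matrix (same cell order as training).
#' @param t optional bin-center times to attach.
#' @return data.frame of class `torus_path`: `bin` (window-end bin index),
#'   optional `t`, `v0`, `v1` in `[0, 2pi)`.
#' @export
decode_torus <- function(model, rates, t = NULL) {
  if (ncol(rates) != model$n_cells) {
    stop("cell count differs from the training data")
  }
  w <- model$spec$window
  idx <- w:nrow(rates)
  pred <- matrix(NA_real_, length(idx), 4)
  # predict in chunks to bound the batch workspace
  chunk <- 2048L
  for (s in seq(1, length(idx), by = chunk)) {
    e <- min(s + chunk - 1, length(idx))
    pred[s:e, ] <- cpp_lstm_predict(rates, idx[s:e], w, model$par)
  }
  sdb <- model$spec$output_smooth_sd / model$spec$bin
  for (j in 1:4) pred[, j] <- gauss_smooth_1d(pred[, j], sdb)
  out <- data.frame(bin = idx,
                    v0 = wrap_angle(atan2(pred[, 2], pred[, 1])),
                    v1 = wrap_angle(atan2(pred[, 4], pred[, 3])))
  if (!is.null(t)) out$t <- t[idx]
  class(out) <- c("torus_path", "data.frame")
  out
}
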