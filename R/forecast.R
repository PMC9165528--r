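# Annual-series projection with a minimal LSTM recurrent cell.
#
# A single univariate LSTM layer with a linear output head, trained by
# full-batch gradient descent with analytic backpropagation through time.
# The recurrence is the standard gated one: input, forget and output gates
# through the logistic function, a tanh candidate state,
# C_t = f . C_{t-1} + i . g, and h_t = o_t . tanh(C_t). Inputs are min-max
# scaled to [0, 1] on the training span; projections are recursive,
# feeding predictions back as inputs.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM forecaster hyperparameters
#'
#' @param hidden_size Hidden units (default 8).
#' @param window Lag length: each prediction sees this many previous
#'   values (default 5).
#' @param epochs Full-batch gradient descent epochs (default 200).
#' @param learning_rate Initial step size (default 0.2). The step is
#'   halved within an epoch when it would increase the loss, so the
#'   monitored training loss is non-increasing.
#' @param seed Integer seed for weight initialization; required, there is
#'   no silent default randomness.
#' @return An object of class `nf_lstm_params`.
#' @export
lstm_params <- function(hidden_size = 8L, window = 5L, epochs = 200L,
                        learning_rate = 0.2, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("an integer seed is required", call. = FALSE)
  }
  stopifnot(hidden_size >= 1, window >= 1, epochs >= 1, learning_rate > 0)
  structure(
    list(hidden_size = as.integer(hidden_size), window = as.integer(window),
      epochs = as.integer(epochs), learning_rate = learning_rate,
      seed = as.integer(seed)),
    class = "nf_lstm_params"
  )
}

init_lstm_weights <- function(hidden_size, seed) {
  set.seed(seed)
  h <- hidden_size
  m <- 1L + h  # input width 1 plus recurrent state
  list(
    W = matrix(runif(4 * h * m, -0.2, 0.2), nrow = 4 * h, ncol = m),
    b = c(rep(0, h), rep(1, h), rep(0, 2 * h)),  # forget-gate bias 1
    wy = runif(h, -0.2, 0.2),
    by = 0
  )
}

gate_rows <- function(h) {
  list(i = 1:h, f = (h + 1):(2 * h), o = (2 * h + 1):(3 * h),
    g = (3 * h + 1):(4 * h))
}

#' One step of the LSTM recurrence
#'
#' Applies the gated update to a single scaled input: input, forget and
#' output gates through the logistic function, candidate through tanh,
#' `C_t = f * c_prev + i * g`, `h_t = o_t * tanh(C_t)`. Every component of
#' `h_t` lies strictly inside (-1, 1).
#'
#' @param x_t Scalar scaled input.
#' @param h_prev,c_prev Numeric vectors of length `hidden_size`.
#' @param weights List with gate weight matrix `W` (rows stacked input /
#'   forget / output / candidate), bias `b`, as built during fitting.
#' @return List with `h`, `c` (and the gate activations `i`, `f`, `o`,
#'   `g`, used by backpropagation).
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, weights) {
  h <- length(h_prev)
  if (length(c_prev) != h || nrow(weights$W) != 4 * h ||
      ncol(weights$W) != 1 + h) {
    stop("dimension mismatch between states and weights", call. = FALSE)
  }
  rows <- gate_rows(h)
  z <- c(x_t, h_prev)
  a <- drop(weights$W %*% z) + weights$b
  i <- sigmoid(a[rows$i])
  f <- sigmoid(a[rows$f])
  o <- sigmoid(a[rows$o])
  g <- tanh(a[rows$g])
  c_t <- f * c_prev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, i = i, f = f, o = o, g = g, z = z)
}

# Forward pass over one window; returns prediction and per-step caches.
lstm_forward <- function(x, weights, hidden_size) {
  h_t <- numeric(hidden_size)
  c_t <- numeric(hidden_size)
  steps <- vector("list", length(x))
  for (t in seq_along(x)) {
    st <- lstm_cell_step(x[t], h_t, c_t, weights)
    st$c_prev <- c_t
    steps[[t]] <- st
    h_t <- st$h
    c_t <- st$c
  }
  list(pred = sum(weights$wy * h_t) + weights$by, steps = steps, h_T = h_t)
}

# Full-batch loss and analytic BPTT gradients over all windows.
lstm_loss_grad <- function(X, y, weights, hidden_size) {
  hs <- hidden_size
  rows <- gate_rows(hs)
  n <- nrow(X)
  gW <- matrix(0, nrow(weights$W), ncol(weights$W))
  gb <- numeric(length(weights$b))
  gwy <- numeric(hs)
  gby <- 0
  loss <- 0
  for (s in seq_len(n)) {
    fw <- lstm_forward(X[s, ], weights, hs)
    e <- fw$pred - y[s]
    loss <- loss + e^2
    dh <- (2 * e / n) * weights$wy
    gwy <- gwy + (2 * e / n) * fw$h_T
    gby <- gby + 2 * e / n
    dc <- numeric(hs)
    for (t in rev(seq_along(fw$steps))) {
      st <- fw$steps[[t]]
      tc <- tanh(st$c)
      do <- dh * tc
      dc <- dc + dh * st$o * (1 - tc^2)
      di <- dc * st$g
      dg <- dc * st$i
      df <- dc * st$c_prev
      dc_prev <- dc * st$f
      da <- numeric(4 * hs)
      da[rows$i] <- di * st$i * (1 - st$i)
      da[rows$f] <- df * st$f * (1 - st$f)
      da[rows$o] <- do * st$o * (1 - st$o)
      da[rows$g] <- dg * (1 - st$g^2)
      gW <- gW + tcrossprod(da, st$z)
      gb <- gb + da
      dz <- drop(crossprod(weights$W, da))
      dh <- dz[-1]
      dc <- dc_prev
    }
  }
  list(loss = loss / n, gW = gW, gb = gb, gwy = gwy, gby = gby)
}

scale_series <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi > lo) {
    list(lo = lo, hi = hi, scaled = (x - lo) / (hi - lo))
  } else {
    # zero-variance series: map to the midpoint; the inverse transform
    # collapses any prediction back to the constant
    list(lo = lo, hi = lo, scaled = rep(0.5, length(x)))
  }
}

inverse_scale <- function(s, scaling) {
  if (scaling$hi > scaling$lo) {
    scaling$lo + s * (scaling$hi - scaling$lo)
  } else {
    rep(scaling$lo, length(s))
  }
}

#' Fit the LSTM forecaster to an annual series
#'
#' Min-max scales the series (fitted on the training span only), forms all
#' one-step windows, and trains by full-batch gradient descent with
#' backpropagation through time. The step is backtracked (halved, up to 30
#' times) whenever it would increase the loss, so the recorded training
#' loss is non-increasing. Deterministic given the seed.
#'
#' @param series Numeric vector of annual values (length > window + 1).
#' @param params An [lstm_params()].
#' @return An object of class `nf_lstm`: weights, scaling, the training
#'   loss trace, and in-sample one-step `rmse` on the original scale.
#' @export
fit_forecaster <- function(series, params) {
  stopifnot(inherits(params, "nf_lstm_params"))
  if (any(!is.finite(series))) {
    stop("series contains non-finite values", call. = FALSE)
  }
  w <- params$window
  if (length(series) <= w + 1) {
    stop("series too short: need more than window + 1 points", call. = FALSE)
  }
  scaling <- scale_series(series)
  s <- scaling$scaled
  n_win <- length(s) - w
  X <- t(vapply(seq_len(n_win), function(i) s[i:(i + w - 1)], numeric(w)))
  y <- s[(w + 1):length(s)]

  weights <- init_lstm_weights(params$hidden_size, params$seed)
  lr <- params$learning_rate
  trace <- numeric(params$epochs + 1)
  cur <- lstm_loss_grad(X, y, weights, params$hidden_size)
  trace[1] <- cur$loss
  for (ep in seq_len(params$epochs)) {
    step_lr <- lr
    for (try in 1:30) {
      cand <- list(
        W = weights$W - step_lr * cur$gW,
        b = weights$b - step_lr * cur$gb,
        wy = weights$wy - step_lr * cur$gwy,
        by = weights$by - step_lr * cur$gby
      )
      nxt <- lstm_loss_grad(X, y, cand, params$hidden_size)
      if (nxt$loss <= cur$loss + 1e-15) break
      step_lr <- step_lr / 2
    }
    if (nxt$loss <= cur$loss + 1e-15) {
      weights <- cand
      cur <- nxt
    }
    trace[ep + 1] <- cur$loss
  }

  preds <- vapply(seq_len(n_win), function(i) {
    lstm_forward(X[i, ], weights, params$hidden_size)$pred
  }, numeric(1))
  fit_rmse <- rmse(inverse_scale(preds, scaling), inverse_scale(y, scaling))

  structure(
    list(params = params, weights = weights, scaling = scaling,
      loss_trace = trace, rmse = fit_rmse),
    class = "nf_lstm"
  )
}

#' @export
print.nf_lstm <- function(x, ...) {
  cat("<nf_lstm> hidden", x$params$hidden_size, "window", x$params$window,
    "epochs", x$params$epochs, "\n")
  cat("  in-sample one-step RMSE:", signif(x$rmse, 4), "\n")
  invisible(x)
}

#' Project an annual series beyond its last observed year
#'
#' Recursive multi-step forecasting: each one-step prediction is appended
#' to the window and fed back as an input. Outputs are inverse-scaled to
#' the original units.
#'
#' @param series The observed annual values the model was fitted to (or a
#'   series to continue; the fitted scaling is reused).
#' @param trained An `nf_lstm` from [fit_forecaster()].
#' @param last_year Year of the final observation.
#' @param horizon Final projected year; must exceed `last_year`.
#' @return Tibble with `year` and `value` for `last_year + 1 ... horizon`.
#' @export
project_series <- function(series, trained, last_year, horizon) {
  stopifnot(inherits(trained, "nf_lstm"))
  if (horizon <= last_year) {
    stop("horizon must lie beyond the last observed year", call. = FALSE)
  }
  w <- trained$params$window
  scaling <- trained$scaling
  s <- if (scaling$hi > scaling$lo) {
    (series - scaling$lo) / (scaling$hi - scaling$lo)
  } else {
    rep(0.5, length(series))
  }
  buf <- tail(s, w)
  n_ahead <- horizon - last_year
  preds <- numeric(n_ahead)
  for (k in seq_len(n_ahead)) {
    p <- lstm_forward(buf, trained$weights, trained$params$hidden_size)$pred
    preds[k] <- p
    buf <- c(buf[-1], p)
  }
  tibble::tibble(
    year = seq(last_year + 1L, as.integer(horizon)),
    value = inverse_scale(preds, scaling)
  )
}

#' Root mean square error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Square root of the mean squared difference.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0) {
    stop("predicted and observed must have equal positive length",
      call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Damped-linear-trend fallback forecaster
#'
#' A deterministic alternative to the LSTM: continues the series with its
#' least-squares linear slope, geometrically damped, for settings where
#' stochastic training is undesirable.
#'
#' @param series Numeric vector of annual values.
#' @param last_year Year of the final observation.
#' @param horizon Final projected year.
#' @param damping Per-step slope damping factor in (0, 1\].
#' @return Tibble with `year` and `value`.
#' @export
project_trend <- function(series, last_year, horizon, damping = 0.9) {
  if (horizon <= last_year) {
    stop("horizon must lie beyond the last observed year", call. = FALSE)
  }
  stopifnot(damping > 0, damping <= 1, length(series) >= 2)
  t <- seq_along(series)
  slope <- stats::coef(stats::lm(series ~ t))[["t"]]
  n_ahead <- horizon - last_year
  incr <- slope * damping^(seq_len(n_ahead))
  tibble::tibble(
    year = seq(last_year + 1L, as.integer(horizon)),
    value = tail(series, 1) + cumsum(incr)
  )
}

#' Fit and project an annual footprint series
#'
#' Convenience wrapper: fits the chosen forecaster to a (year, value)
#' series and projects it to the horizon, reporting the in-sample one-step
#' RMSE alongside the projection.
#'
#' @param series Tibble with `year` and `value` columns (annual, sorted).
#' @param horizon Final projected year.
#' @param params An [lstm_params()] (ignored for the trend method).
#' @param method `"lstm"` (default) or `"trend"`.
#' @return List with `projection` (tibble `year`, `value`), `rmse`
#'   (in-sample one-step, `NA` for the trend method), `method`, `seed`.
#' @export
forecast_footprint <- function(series, horizon, params = NULL,
                               method = c("lstm", "trend")) {
  method <- match.arg(method)
  stopifnot(all(c("year", "value") %in% names(series)))
  series <- dplyr::arrange(series, .data$year)
  last_year <- max(series$year)
  if (method == "trend") {
    proj <- project_trend(series$value, last_year, horizon)
    return(list(projection = proj, rmse = NA_real_, method = method,
      seed = NA_integer_))
  }
  if (is.null(params)) {
    stop("lstm_params (with a seed) are required for method = 'lstm'",
      call. = FALSE)
  }
  fit <- fit_forecaster(series$value, params)
  proj <- project_series(series$value, fit, last_year, horizon)
  list(projection = proj, rmse = fit$rmse, method = method,
    seed = params$seed, fit = fit)
}
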