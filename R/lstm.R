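# A compact LSTM regressor written in base R matrix algebra: one recurrent
# layer, two dense layers with a linear output, mean-squared-error loss and
# the Adam optimiser, trained full-batch with backpropagation through time.
# Used as the sleep-history model of the forecaster (inputs are n x 7 x 7
# arrays: 7 prior days x 7 sleep features).

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initialisation
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

lstm_init <- function(input_dim, units, dense_units) {
  list(
    W = glorot(input_dim, 4 * units),   # input -> gates [i, f, o, g]
    U = glorot(units, 4 * units),       # recurrent -> gates
    b = {b <- numeric(4 * units); b[(units + 1):(2 * units)] <- 1; b}, # forget bias 1
    Wd1 = glorot(units, dense_units), bd1 = numeric(dense_units),
    Wd2 = glorot(dense_units, 1), bd2 = 0
  )
}

# Forward pass. X: n x T x F. Returns predictions and, when cache = TRUE,
# every intermediate needed for backpropagation.
lstm_forward <- function(p, X, cache = FALSE) {
  n <- dim(X)[1]; Tt <- dim(X)[2]
  H <- ncol(p$U)/4
  h <- matrix(0, n, H); cs <- matrix(0, n, H)
  st <- if (cache) vector("list", Tt) else NULL
  for (t in seq_len(Tt)) {
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(n, dim(X)[3])
    z <- xt %*% p$W + h %*% p$U + matrix(p$b, n, 4 * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cs + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (cache) st[[t]] <- list(x = xt, h_prev = h, c_prev = cs,
                               i = i, f = f, o = o, g = g, c = c_new, tc = tc)
    h <- h_new; cs <- c_new
  }
  a1 <- h %*% p$Wd1 + matrix(p$bd1, n, length(p$bd1), byrow = TRUE)
  r1 <- pmax(a1, 0)
  out <- as.numeric(r1 %*% p$Wd2 + p$bd2)
  if (!cache) return(out)
  list(out = out, h = h, r1 = r1, a1 = a1, states = st)
}

# Analytic gradients of the MSE loss wrt every parameter (BPTT).
lstm_grad <- function(p, X, y) {
  n <- dim(X)[1]; Tt <- dim(X)[2]
  H <- ncol(p$U)/4
  fw <- lstm_forward(p, X, cache = TRUE)
  err <- fw$out - y
  loss <- mean(err^2)
  dout <- matrix(2 * err / n, n, 1)
  gWd2 <- t(fw$r1) %*% dout
  gbd2 <- sum(dout)
  dr1 <- dout %*% t(p$Wd2)
  da1 <- dr1 * (fw$a1 > 0)
  gWd1 <- t(fw$h) %*% da1
  gbd1 <- colSums(da1)
  dh <- da1 %*% t(p$Wd1)
  dc <- matrix(0, n, H)
  gW <- matrix(0, nrow(p$W), ncol(p$W))
  gU <- matrix(0, nrow(p$U), ncol(p$U))
  gb <- numeric(4 * H)
  for (t in rev(seq_len(Tt))) {
    s <- fw$states[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                do * s$o * (1 - s$o),
                dg * (1 - s$g^2))
    gW <- gW + t(s$x) %*% dz
    gU <- gU + t(s$h_prev) %*% dz
    gb <- gb + colSums(dz)
    dh <- dz %*% t(p$U)
    dc <- dc * s$f
  }
  list(loss = loss,
       grads = list(W = gW, U = gU, b = gb, Wd1 = gWd1, bd1 = gbd1,
                    Wd2 = gWd2, bd2 = gbd2))
}

# Full-batch Adam on the MSE loss.
lstm_train_core <- function(X, y, units, dense_units, epochs, lr, seed) {
  with_seed(seed, {
    p <- lstm_init(dim(X)[3], units, dense_units)
    mns <- lapply(p, function(w) w * 0)
    vs <- lapply(p, function(w) w * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (ep in seq_len(epochs)) {
      gr <- lstm_grad(p, X, y)
      for (k in names(p)) {
        mns[[k]] <- b1 * mns[[k]] + (1 - b1) * gr$grads[[k]]
        vs[[k]] <- b2 * vs[[k]] + (1 - b2) * gr$grads[[k]]^2
        mhat <- mns[[k]] / (1 - b1^ep)
        vhat <- vs[[k]] / (1 - b2^ep)
        p[[k]] <- p[[k]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    p
  })
}

#' Train the sleep-history model
#'
#' Fits the recurrent sleep model on per-day sleep-history tensors (one row
#' per daily forecast: `sleep_days` prior days by 7 sleep features, oldest
#' day first) against binary seizure-day labels, with mean-squared-error
#' loss and Adam. Features are z-scored with training statistics stored in
#' the model. Degenerate all-one-class labels yield a constant model at the
#' class rate.
#'
#' @param tensor numeric array n x days x 7 (see [build_sleep_tensor()]).
#' @param labels 0/1 seizure-day labels, length n.
#' @param units recurrent units (default 64).
#' @param dense_units width of the first dense layer.
#' @param epochs training epochs (default 100).
#' @param lr Adam learning rate.
#' @param seed RNG seed for weight initialisation.
#' @return object of class `sleep_model`; `predict()` returns likelihoods
#'   clipped to `[0, 1]`.
#' @export
train_sleep_model <- function(tensor, labels, units = 64, dense_units = 32,
                              epochs = 100, lr = 0.005, seed = 1L) {
  stopifnot(length(dim(tensor)) == 3, dim(tensor)[3] == 7,
            dim(tensor)[1] == length(labels))
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) {
    mod <- structure(list(constant = mean(y), dims = dim(tensor)[2:3]),
                     class = "sleep_model")
    return(mod)
  }
  n <- dim(tensor)[1]
  flat <- matrix(tensor, nrow = n)
  mu <- colMeans(flat)
  sdv <- apply(flat, 2, stats::sd)
  sdv[sdv < 1e-8] <- 1
  Xs <- array(sweep(sweep(flat, 2, mu), 2, sdv, "/"), dim = dim(tensor))
  params <- lstm_train_core(Xs, y, units, dense_units, epochs, lr, seed)
  structure(list(params = params, mu = mu, sd = sdv, dims = dim(tensor)[2:3]),
            class = "sleep_model")
}

#' @rdname train_sleep_model
#' @param object a `sleep_model`.
#' @param tensor_new new n x days x 7 array.
#' @param ... unused.
#' @export
predict.sleep_model <- function(object, tensor_new, ...) {
  n <- dim(tensor_new)[1]
  if (!is.null(object$constant)) return(rep(object$constant, n))
  flat <- matrix(tensor_new, nrow = n)
  Xs <- array(sweep(sweep(flat, 2, object$mu), 2, object$sd, "/"),
              dim = dim(tensor_new))
  clamp01(lstm_forward(object$params, Xs))
}

#' Assemble sleep-history tensors for daily forecasts
#'
#' For each daily forecast (indexed by its wake event) collects the sleep
#' feature vectors of the `days` preceding nights, oldest first. Nights
#' absent from the record are forward-filled from the most recent available
#' night with the two deviation features zeroed; rows before any history use
#' the first observed night the same way.
#'
#' @param sleep_features per-night features from [compute_sleep_features()].
#' @param at_wake_min wake times (minutes) of the forecasts to build rows
#'   for; defaults to every wake event present.
#' @param days history length in days (default 7).
#' @return numeric array `length(at_wake_min)` x `days` x 7.
#' @export
build_sleep_tensor <- function(sleep_features, at_wake_min = NULL, days = 7) {
  sf <- sleep_features[order(sleep_features$wake_min), , drop = FALSE]
  at <- at_wake_min %||% sf$wake_min
  n <- length(at)
  out <- array(0, dim = c(n, days, 7))
  feats <- as.matrix(sf[, SLEEP_FEATURE_NAMES, drop = FALSE])
  ffill_row <- function(j) { # most recent night with wake <= some time
    v <- feats[j, ]
    v[6:7] <- 0 # zero the deviation features when carried forward
    v
  }
  for (i in seq_len(n)) {
    for (d in seq_len(days)) {
      # day slot d is (days - d) days before the forecast day
      target <- at[i] - (days - d + 1) * MIN_PER_DAY
      j <- findInterval(target + MIN_PER_DAY / 2, sf$wake_min)
      if (j >= 1 && abs(sf$wake_min[j] - target) <= MIN_PER_DAY / 2) {
        out[i, d, ] <- feats[j, ]
      } else {
        jj <- max(1L, j)
        out[i, d, ] <- ffill_row(jj)
      }
    }
  }
  out
}
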