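# CNN + peephole-LSTM sleep stage classifier.
# Four same-padded convolutional units with LReLU (kernels 6x6, 5x5, 5x5,
# 2x2), max pooling after the first three, a collapse of the map into a
# time sequence (width axis = time), one peephole LSTM layer, a fully
# connected layer, and a 5-way softmax.

#' Leaky rectified linear activation
#'
#' Identity for non-negative input; negative input is scaled by `slope`.
#'
#' @param x Numeric vector/matrix.
#' @param slope Negative-side slope (default 0.1).
#' @return Same shape as `x`.
#' @export
lrelu <- function(x, slope = 0.1) {
  pmax(x, 0) + slope * pmin(x, 0)
}

lrelu_grad <- function(x, slope = 0.1) {
  slope + (1 - slope) * (x >= 0)
}

#' Classifier configuration
#'
#' Kernel sizes, LReLU slope, LSTM width and class count follow the staging
#' architecture; filter counts, pooling, and the optimizer are tunable and
#' default to values sized for CPU training.
#'
#' @param conv_kernels List of four `c(kh, kw)` kernel sizes.
#' @param conv_filters Integer vector of four per-unit filter counts.
#' @param conv_strides List of four `c(sh, sw)` convolution strides; the
#'   default strides the first unit to shrink the map early.
#' @param pool List of four pooling sizes `c(ph, pw)` (or `NULL` for no
#'   pooling after that unit).
#' @param lrelu_slope Negative slope of the LReLU activations.
#' @param lstm_units LSTM layer width.
#' @param n_classes Number of output classes (5 stages).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience on validation accuracy.
#' @param seed Seed controlling initialization and shuffling.
#' @return Object of class `model_config`.
#' @export
model_config <- function(conv_kernels = list(c(6, 6), c(5, 5), c(5, 5), c(2, 2)),
                         conv_filters = c(8, 8, 8, 16),
                         conv_strides = list(c(2, 3), c(1, 1), c(1, 1), c(1, 1)),
                         pool = list(NULL, c(2, 2), c(2, 2), NULL),
                         lrelu_slope = 0.1,
                         lstm_units = 128,
                         n_classes = 5,
                         batch_size = 128,
                         learning_rate = 1e-3,
                         max_epochs = 14,
                         patience = 4,
                         seed = 1) {
  stopifnot(length(conv_kernels) == 4, length(conv_filters) == 4,
            length(conv_strides) == 4, length(pool) == 4,
            lstm_units >= 1, n_classes == 5,
            batch_size >= 1, learning_rate >= 0, max_epochs >= 1)
  structure(list(conv_kernels = conv_kernels, conv_filters = conv_filters,
                 conv_strides = conv_strides,
                 pool = pool, lrelu_slope = lrelu_slope,
                 lstm_units = lstm_units, n_classes = n_classes,
                 batch_size = batch_size, learning_rate = learning_rate,
                 max_epochs = max_epochs, patience = patience, seed = seed),
            class = "model_config")
}

# Trace the shape of a (H, W) map through the conv/pool stack.
model_shapes <- function(cfg, input_shape) {
  H <- input_shape[1]; W <- input_shape[2]; C <- 1
  shapes <- list()
  for (l in 1:4) {
    st <- cfg$conv_strides[[l]]
    H <- (H + st[1] - 1) %/% st[1]   # same-padded strided conv: ceil(H/sh)
    W <- (W + st[2] - 1) %/% st[2]
    C <- cfg$conv_filters[l]
    shapes[[paste0("conv", l)]] <- c(H, W, C)
    if (!is.null(cfg$pool[[l]])) {
      H <- H %/% cfg$pool[[l]][1]
      W <- W %/% cfg$pool[[l]][2]
      if (H < 1 || W < 1) {
        stop("input ", input_shape[1], "x", input_shape[2],
             " collapses to nothing at pool", l, call. = FALSE)
      }
      shapes[[paste0("pool", l)]] <- c(H, W, C)
    }
  }
  shapes$sequence <- c(H * C, W)   # D features per step, T = W steps
  shapes
}

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

#' Build an initialized model
#'
#' Lays out the parameter set for the conv stack, LSTM and output layer,
#' initialized reproducibly from `cfg$seed` (two builds with the same seed
#' are identical). Forget-gate biases start at 1, the usual LSTM warm start.
#'
#' @param cfg A [model_config()].
#' @param input_shape `c(height, width)` of the input feature streams.
#' @return Object of class `sleep_model`: parameters, config, layer shapes
#'   and `n_params`.
#' @export
build_model <- function(cfg = model_config(), input_shape) {
  stopifnot(inherits(cfg, "model_config"), length(input_shape) >= 2)
  shapes <- model_shapes(cfg, input_shape)
  rng <- local_rng(cfg$seed)
  on.exit(rng(), add = TRUE)
  params <- list()
  Cin <- 1
  for (l in 1:4) {
    k <- cfg$conv_kernels[[l]]
    Fn <- cfg$conv_filters[l]
    params[[paste0("convW", l)]] <- glorot(k[1] * k[2] * Cin, Fn)
    params[[paste0("convb", l)]] <- rep(0, Fn)
    Cin <- Fn
  }
  D <- shapes$sequence[1]; Hn <- cfg$lstm_units
  params$lstmWx <- glorot(4 * Hn, D)
  params$lstmWh <- glorot(4 * Hn, Hn)
  b <- rep(0, 4 * Hn); b[(Hn + 1):(2 * Hn)] <- 1
  params$lstmb <- b
  params$lstmpi <- rep(0, Hn)
  params$lstmpf <- rep(0, Hn)
  params$lstmpo <- rep(0, Hn)
  params$fcW <- glorot(Hn, cfg$n_classes)
  params$fcb <- rep(0, cfg$n_classes)
  structure(list(params = params, config = cfg,
                 input_shape = input_shape[1:2], shapes = shapes,
                 n_params = sum(vapply(params, length, numeric(1))),
                 trained = FALSE),
            class = "sleep_model")
}

#' @export
print.sleep_model <- function(x, ...) {
  cat("<sleep_model>", paste(x$input_shape, collapse = "x"), "input,",
      x$n_params, "parameters,",
      if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

# Forward pass on a batch. X: matrix (H*W) x B. Returns probs (K x B) and,
# if keep_cache, everything backward needs.
model_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  H <- model$input_shape[1]; W <- model$input_shape[2]
  B <- ncol(X)
  cache <- list()
  A <- X; Cin <- 1; curH <- H; curW <- W
  for (l in 1:4) {
    k <- cfg$conv_kernels[[l]]
    st <- cfg$conv_strides[[l]]
    Z <- nn_conv_fw(A, curH, curW, Cin, p[[paste0("convW", l)]],
                    p[[paste0("convb", l)]], k[1], k[2], st[1], st[2])
    Act <- lrelu(Z, cfg$lrelu_slope)
    if (keep_cache) {
      cache[[paste0("in", l)]] <- A
      cache[[paste0("pre", l)]] <- Z
      cache[[paste0("dims", l)]] <- c(curH, curW, Cin)
    }
    curH <- (curH + st[1] - 1) %/% st[1]
    curW <- (curW + st[2] - 1) %/% st[2]
    Cin <- cfg$conv_filters[l]
    if (!is.null(cfg$pool[[l]])) {
      pl <- nn_pool_fw(Act, curH, curW, Cin, cfg$pool[[l]][1], cfg$pool[[l]][2])
      if (keep_cache) {
        cache[[paste0("poolidx", l)]] <- pl$idx
        cache[[paste0("poolinlen", l)]] <- nrow(Act)
      }
      A <- pl$Y
      curH <- curH %/% cfg$pool[[l]][1]
      curW <- curW %/% cfg$pool[[l]][2]
    } else {
      A <- Act
    }
  }
  # collapse: width becomes the LSTM time axis, height x filters the feature
  H4 <- curH; W4 <- curW; F4 <- Cin
  arr <- array(A, dim = c(H4, W4, F4, B))
  seqarr <- array(aperm(arr, c(1, 3, 4, 2)), dim = c(H4 * F4, B, W4))
  lf <- nn_lstm_fw(seqarr, p$lstmWx, p$lstmWh, p$lstmb,
                   p$lstmpi, p$lstmpf, p$lstmpo)
  logits <- t(p$fcW) %*% lf$h_last + p$fcb      # K x B
  m <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, m))
  probs <- sweep(ex, 2, colSums(ex), `/`)
  if (keep_cache) {
    cache$seq <- seqarr; cache$lstm <- lf
    cache$collapse <- c(H4, W4, F4, B)
    cache$probs <- probs
  }
  list(probs = probs, cache = if (keep_cache) cache else NULL)
}

# Backward pass for mean cross-entropy; y is an integer class vector 1..K.
model_backward <- function(model, cache, y) {
  cfg <- model$config; p <- model$params
  B <- length(y)
  K <- cfg$n_classes
  dlogits <- cache$probs
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  dlogits <- dlogits / B
  hT <- cache$lstm$h_last
  grads <- list(fcW = hT %*% t(dlogits), fcb = rowSums(dlogits))
  dhT <- p$fcW %*% dlogits
  lb <- nn_lstm_bw(cache$seq, cache$lstm$gates, cache$lstm$cells,
                   cache$lstm$hidden, p$lstmWx, p$lstmWh,
                   p$lstmpi, p$lstmpf, p$lstmpo, dhT)
  grads$lstmWx <- lb$dWx; grads$lstmWh <- lb$dWh; grads$lstmb <- drop(lb$db)
  grads$lstmpi <- drop(lb$dpi); grads$lstmpf <- drop(lb$dpf)
  grads$lstmpo <- drop(lb$dpo)
  cl <- cache$collapse; H4 <- cl[1]; W4 <- cl[2]; F4 <- cl[3]
  dseq <- array(lb$dX, dim = c(H4, F4, B, W4))
  dA <- matrix(aperm(dseq, c(1, 4, 2, 3)), nrow = H4 * W4 * F4, ncol = B)
  for (l in 4:1) {
    if (!is.null(cfg$pool[[l]])) {
      dA <- nn_pool_bw(dA, cache[[paste0("poolidx", l)]],
                       cache[[paste0("poolinlen", l)]])
    }
    dZ <- dA * lrelu_grad(cache[[paste0("pre", l)]], cfg$lrelu_slope)
    d <- cache[[paste0("dims", l)]]
    k <- cfg$conv_kernels[[l]]
    st <- cfg$conv_strides[[l]]
    cb <- nn_conv_bw(cache[[paste0("in", l)]], dZ, d[1], d[2], d[3],
                     p[[paste0("convW", l)]], k[1], k[2], st[1], st[2])
    grads[[paste0("convW", l)]] <- cb$dW
    grads[[paste0("convb", l)]] <- drop(cb$db)
    dA <- cb$dX
  }
  grads
}

streams_to_batch <- function(streams) {
  stopifnot(length(streams) > 0)
  d <- dim(streams[[1]]$tensor)
  X <- vapply(streams, function(s) {
    if (!identical(dim(s$tensor), d)) {
      stop("stream tensor shape ", paste(dim(s$tensor), collapse = "x"),
           " differs from ", paste(d, collapse = "x"), call. = FALSE)
    }
    as.vector(s$tensor)
  }, numeric(prod(d)))
  y <- match(vapply(streams, `[[`, character(1), "label"), stages())
  list(X = matrix(X, ncol = length(streams)), y = y, shape = d)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

batch_eval <- function(model, X, y, chunk = 256) {
  n <- ncol(X)
  loss <- 0; correct <- 0
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    pr <- model_forward(model, X[, s:e, drop = FALSE])$probs
    idx <- cbind(y[s:e], seq_len(e - s + 1))
    loss <- loss + sum(-log(pmax(pr[idx], 1e-12)))
    correct <- correct + sum(apply(pr, 2, which.max) == y[s:e])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the classifier
#'
#' Mini-batch Adam on unweighted cross-entropy. After every epoch the model
#' is scored on the validation streams; the parameters with the best
#' validation accuracy are retained, and training stops early when that
#' accuracy has not improved for `patience` epochs. Fully seeded: the same
#' config and data reproduce the same history.
#'
#' @param model A [build_model()] result.
#' @param train_streams,val_streams Non-empty lists of feature streams;
#'   training labels must cover at least two classes.
#' @return The model with trained parameters and a `history` data frame
#'   (epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_model <- function(model, train_streams, val_streams) {
  stopifnot(inherits(model, "sleep_model"))
  cfg <- model$config
  tr <- streams_to_batch(train_streams)
  va <- streams_to_batch(val_streams)
  if (length(unique(tr$y)) < 2) {
    stop("training labels cover a single class (",
         stages()[unique(tr$y)], "); nothing to discriminate", call. = FALSE)
  }
  if (!identical(tr$shape[1:2], as.integer(model$input_shape)) &&
      !identical(as.numeric(tr$shape[1:2]), as.numeric(model$input_shape))) {
    stop("stream shape ", paste(tr$shape, collapse = "x"),
         " does not match model input ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  }
  rng <- local_rng(cfg$seed + 1L)
  on.exit(rng(), add = TRUE)
  state <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params, epoch = 0)
  hist <- list()
  n <- ncol(tr$X)
  for (ep in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      fw <- model_forward(model, tr$X[, idx, drop = FALSE], keep_cache = TRUE)
      pick <- cbind(tr$y[idx], seq_along(idx))
      ep_loss <- ep_loss + sum(-log(pmax(fw$probs[pick], 1e-12)))
      ep_correct <- ep_correct + sum(apply(fw$probs, 2, which.max) == tr$y[idx])
      grads <- model_backward(model, fw$cache, tr$y[idx])
      upd <- adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    vl <- batch_eval(model, va$X, va$y)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n,
                             train_acc = ep_correct / n,
                             val_loss = vl["loss"], val_acc = vl["acc"])
    if (vl["acc"] > best$acc + 1e-12) {
      best <- list(acc = vl["acc"], params = model$params, epoch = ep)
    } else if (ep - best$epoch >= cfg$patience) {
      break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  rownames(model$history) <- NULL
  model
}

#' Predict stages for feature streams
#'
#' Deterministic given fixed parameters; batch order does not affect any
#' output.
#'
#' @param model A (typically trained) [build_model()] result.
#' @param streams List of feature streams.
#' @return List with `probs` (n x 5 matrix, rows on the simplex, columns in
#'   stage order) and `labels` (character vector of argmax stages).
#' @export
predict_stages <- function(model, streams) {
  stopifnot(inherits(model, "sleep_model"))
  b <- streams_to_batch(streams)
  if (!identical(as.numeric(b$shape[1:2]), as.numeric(model$input_shape))) {
    stop("stream shape ", paste(b$shape, collapse = "x"),
         " does not match model input ",
         paste(model$input_shape, collapse = "x"), call. = FALSE)
  }
  n <- ncol(b$X)
  probs <- matrix(NA_real_, n, model$config$n_classes,
                  dimnames = list(NULL, stages()))
  for (s in seq(1, n, by = 256)) {
    e <- min(s + 255, n)
    probs[s:e, ] <- t(model_forward(model, b$X[, s:e, drop = FALSE])$probs)
  }
  list(probs = probs, labels = stages()[max.col(probs, ties.method = "first")])
}

#' One peephole LSTM cell step (reference implementation)
#'
#' Gate equations with peephole connections: the input and forget gates see
#' the previous cell state, the output gate the current one; all peepholes
#' act diagonally (one scalar weight per unit). The hidden output is
#' `o * tanh(C_t)` with `C_t = f * C_prev + i * c_cand`.
#'
#' @param x Input vector.
#' @param h_prev,C_prev Previous hidden and cell state vectors.
#' @param wts List with matrices `Wxi, Wxf, Wxo, Wxc` (units x input),
#'   `Whi, Whf, Who, Whc` (units x units), peephole vectors
#'   `wci, wcf, wco`, and biases `bi, bf, bo, bc`.
#' @return List with `h` and `C`.
#' @export
lstm_cell_step <- function(x, h_prev, C_prev, wts) {
  sig <- function(a) 1 / (1 + exp(-a))
  i <- sig(wts$Wxi %*% x + wts$Whi %*% h_prev + wts$wci * C_prev + wts$bi)
  f <- sig(wts$Wxf %*% x + wts$Whf %*% h_prev + wts$wcf * C_prev + wts$bf)
  cc <- tanh(wts$Wxc %*% x + wts$Whc %*% h_prev + wts$bc)
  C <- f * C_prev + i * cc
  o <- sig(wts$Wxo %*% x + wts$Who %*% h_prev + wts$wco * C + wts$bo)
  list(h = drop(o * tanh(C)), C = drop(C))
}

#' Save / load a model checkpoint
#'
#' @param model A `sleep_model`.
#' @param path Checkpoint file path (RDS).
#' @return `path` invisibly; `load_checkpoint` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sleep_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "sleep_model"))
  model
}
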