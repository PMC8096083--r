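#' Edge classifier configuration
#'
#' A feed-forward network with two densely connected hidden layers of size
#' 256, rectifier activations, a 2-way softmax output and cross-entropy loss,
#' trained for at most 2000 epochs with early stopping once the validation
#' loss has not reached a new minimum for 10 consecutive epochs (the
#' parameters from the best validation epoch are kept). Optimizer settings
#' (Adam, learning rate 1e-3) are conventional defaults. The default
#' minibatch of 64 keeps several gradient updates per epoch even on small
#' edge sets; with a batch larger than the training split an "epoch" is a
#' single update and patience-based early stopping degenerates.
#'
#' @param hidden hidden layer width
#' @param max_epochs maximum training epochs
#' @param patience early-stopping patience in epochs
#' @param batch_size minibatch size
#' @param lr Adam learning rate
#' @param seed integer seed (weight init + shuffling)
#' @return a `classifier_config` list
#' @export
classifier_config <- function(hidden = 256L, max_epochs = 2000L,
                              patience = 10L, batch_size = 64L, lr = 1e-3,
                              seed = 1L) {
  stopifnot(hidden >= 1, max_epochs >= 1, patience >= 1, batch_size >= 1,
            lr > 0)
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Edge representation by the average operator
#'
#' Represents the unordered pair `(u, v)` as the component-wise mean of the
#' endpoint embeddings, `(f(u) + f(v)) / 2`; symmetric in its arguments.
#'
#' @param table an [embedding_table()]
#' @param u,v character vectors of term tokens (recycled to equal length)
#' @return matrix with one row per pair
#' @export
edge_embedding <- function(table, u, v) {
  (embedding_vectors(table, u) + embedding_vectors(table, v)) / 2
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- exp(z - apply(z, 1L, max))
  z / rowSums(z)
}

mlp_forward <- function(par, x) {
  h1 <- relu(x %*% par$W1 + rep(par$b1, each = nrow(x)))
  h2 <- relu(h1 %*% par$W2 + rep(par$b2, each = nrow(h1)))
  logits <- h2 %*% par$W3 + rep(par$b3, each = nrow(h2))
  list(h1 = h1, h2 = h2, p = softmax_rows(logits))
}

cross_entropy <- function(p, y) {
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], 1e-12)))
}

#' Train the edge classifier
#'
#' @param x_train,x_valid numeric feature matrices (edge representations)
#' @param y_train,y_valid 0/1 labels; both splits must contain both classes
#' @param cfg a [classifier_config()]
#' @return an `edge_classifier` with the best-validation-loss parameters, the
#'   per-epoch validation-loss trajectory, and the stopping epoch
#' @export
train_edge_classifier <- function(x_train, y_train, x_valid, y_valid,
                                  cfg = classifier_config()) {
  stopifnot(is.matrix(x_train), is.matrix(x_valid),
            nrow(x_train) == length(y_train), nrow(x_valid) == length(y_valid))
  y_train <- as.integer(y_train); y_valid <- as.integer(y_valid)
  if (length(unique(y_train)) < 2L || length(unique(y_valid)) < 2L) {
    stop("train and validation splits must both contain both classes")
  }
  d <- ncol(x_train); h <- cfg$hidden
  with_rng_seed(cfg$seed, {
    par <- list(
      W1 = matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h), b1 = numeric(h),
      W2 = matrix(stats::rnorm(h * h, sd = sqrt(2 / h)), h, h), b2 = numeric(h),
      W3 = matrix(stats::rnorm(h * 2L, sd = sqrt(2 / h)), h, 2L), b3 = numeric(2L)
    )
    mom <- lapply(par, function(w) w * 0)
    vel <- lapply(par, function(w) w * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L

    n <- nrow(x_train)
    best <- list(loss = Inf, par = par, epoch = 0L)
    wait <- 0L
    val_losses <- numeric(0)

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + cfg$batch_size - 1L, n)]
        xb <- x_train[idx, , drop = FALSE]
        yb <- y_train[idx]
        fw <- mlp_forward(par, xb)
        nb <- length(idx)
        # softmax + CE gradient
        dlogits <- fw$p
        dlogits[cbind(seq_len(nb), yb + 1L)] <-
          dlogits[cbind(seq_len(nb), yb + 1L)] - 1
        dlogits <- dlogits / nb
        g <- list()
        g$W3 <- crossprod(fw$h2, dlogits); g$b3 <- colSums(dlogits)
        dh2 <- (dlogits %*% t(par$W3)) * (fw$h2 > 0)
        g$W2 <- crossprod(fw$h1, dh2); g$b2 <- colSums(dh2)
        dh1 <- (dh2 %*% t(par$W2)) * (fw$h1 > 0)
        g$W1 <- crossprod(xb, dh1); g$b1 <- colSums(dh1)
        step <- step + 1L
        for (nm in names(par)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * g[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * g[[nm]]^2
          mh <- mom[[nm]] / (1 - beta1^step)
          vh <- vel[[nm]] / (1 - beta2^step)
          par[[nm]] <- par[[nm]] - cfg$lr * mh / (sqrt(vh) + eps)
        }
      }
      vl <- cross_entropy(mlp_forward(par, x_valid)$p, y_valid)
      val_losses <- c(val_losses, vl)
      if (vl < best$loss) {
        best <- list(loss = vl, par = par, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  structure(list(par = best$par, best_epoch = best$epoch,
                 best_val_loss = best$loss, val_losses = val_losses,
                 epochs_run = length(val_losses), config = cfg),
            class = "edge_classifier")
}

#' @export
print.edge_classifier <- function(x, ...) {
  cat(sprintf("edge_classifier: stopped after %d epochs (best epoch %d, val loss %.4f)\n",
              x$epochs_run, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict with an edge classifier
#'
#' @param object an [train_edge_classifier()] result
#' @param x feature matrix
#' @param type `"prob"` for the positive-class probability, `"class"` for the
#'   0/1 argmax decision
#' @param ... unused
#' @return numeric vector of probabilities or integer labels
#' @export
predict.edge_classifier <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- mlp_forward(object$par, x)$p
  if (type == "prob") p[, 2L] else as.integer(p[, 2L] >= p[, 1L])
}
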