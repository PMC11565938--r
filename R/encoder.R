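#' Configuration of the permutation-invariant set encoder
#'
#' The encoder is a DeepSets composite `Enc(X) = g(mean_i h(x_i))`: an
#' element network `h` applied to every (hash, count) element of a sketch,
#' mean pooling over the set, and a head network `g` producing the
#' embedding. Both subnets are fully connected; every layer except the
#' last of each subnet uses batch normalization followed by a ReLU.
#'
#' @param h_layers Widths of `h`, input first (default
#'   `c(2, 128, 128, 128, 128)`).
#' @param g_layers Widths of `g` (default `c(128, 256, 256, 256, 64)`);
#'   the first width must equal the last width of `h`, and the final width
#'   is the embedding dimension.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(h_layers = c(2, 128, 128, 128, 128),
                           g_layers = c(128, 256, 256, 256, 64)) {
  if (tail1(h_layers) != g_layers[1]) {
    abort("h output width must equal g input width")
  }
  if (h_layers[1] != 2) {
    warn("element inputs are 2-dimensional (hash, count); unusual h input width")
  }
  structure(list(h_layers = h_layers, g_layers = g_layers),
            class = "encoder_config")
}

tail1 <- function(x) x[length(x)]

#' Training configuration for the encoder
#'
#' @param batch_size Samples per minibatch (default 128).
#' @param epochs Training epochs (default 400).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Seed for initialization and batch shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 128, epochs = 400,
                         learning_rate = 1e-3, seed = 1) {
  stopifnot(batch_size >= 2, epochs >= 1, learning_rate > 0)
  structure(list(batch_size = batch_size, epochs = epochs,
                 learning_rate = learning_rate, seed = seed),
            class = "train_config")
}

# --- network internals -----------------------------------------------------

init_subnet <- function(dims) {
  n_layers <- length(dims) - 1
  map(seq_len(n_layers), function(l) {
    fan_in <- dims[l]
    layer <- list(
      W = matrix(rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = rep(0, dims[l + 1]),
      bn = l < n_layers
    )
    if (layer$bn) {
      layer$gamma <- rep(1, dims[l + 1])
      layer$beta <- rep(0, dims[l + 1])
      layer$run_mean <- rep(0, dims[l + 1])
      layer$run_var <- rep(1, dims[l + 1])
    }
    layer
  })
}

#' Initialize an untrained encoder
#'
#' @param config An [encoder_config()].
#' @param seed Seed for weight initialization.
#' @return A list of class `set_encoder` holding both subnets.
#' @export
init_encoder <- function(config = encoder_config(), seed = 1) {
  state <- with_seed(seed, {
    list(h = init_subnet(config$h_layers), g = init_subnet(config$g_layers))
  })
  state$config <- config
  class(state) <- "set_encoder"
  state
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

subnet_forward <- function(layers, M, training = FALSE) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    layer <- layers[[l]]
    input <- M
    A <- sweep(input %*% layer$W, 2, layer$b, "+")
    cache <- list(input = input, A = A)
    if (layer$bn) {
      if (training) {
        mu <- colMeans(A)
        v <- colMeans(sweep(A, 2, mu)^2)
        layers[[l]]$run_mean <- (1 - BN_MOMENTUM) * layer$run_mean +
          BN_MOMENTUM * mu
        n <- nrow(A)
        unbiased <- if (n > 1) v * n / (n - 1) else v
        layers[[l]]$run_var <- (1 - BN_MOMENTUM) * layer$run_var +
          BN_MOMENTUM * unbiased
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      inv_sd <- 1 / sqrt(v + BN_EPS)
      xhat <- sweep(sweep(A, 2, mu), 2, inv_sd, "*")
      P <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
      M <- pmax(P, 0)
      cache <- c(cache, list(xhat = xhat, inv_sd = inv_sd, P = P))
    } else {
      M <- A
    }
    caches[[l]] <- cache
  }
  list(out = M, caches = caches, layers = layers)
}

subnet_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    layer <- layers[[l]]
    cache <- caches[[l]]
    if (layer$bn) {
      dP <- dOut * (cache$P > 0)
      dgamma <- colSums(dP * cache$xhat)
      dbeta <- colSums(dP)
      dxhat <- sweep(dP, 2, layer$gamma, "*")
      n <- nrow(dP)
      sum_dxhat <- colSums(dxhat)
      sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
      dA <- sweep(
        dxhat * n - matrix(sum_dxhat, n, length(sum_dxhat), byrow = TRUE) -
          sweep(cache$xhat, 2, sum_dxhat_xhat, "*"),
        2, cache$inv_sd / n, "*"
      )
      grads[[l]] <- list(W = crossprod(cache$input, dA), b = colSums(dA),
                         gamma = dgamma, beta = dbeta)
    } else {
      dA <- dOut
      grads[[l]] <- list(W = crossprod(cache$input, dA), b = colSums(dA))
    }
    dOut <- tcrossprod(dA, layer$W)
  }
  grads
}

pool_sets <- function(H, set_index, n_sets) {
  sizes <- tabulate(set_index, nbins = n_sets)
  P <- rowsum(H, set_index, reorder = TRUE)
  P / sizes
}

#' Embed one or more sketch sets
#'
#' Runs the encoder in evaluation mode (batch normalization uses running
#' statistics), so the output is deterministic and exactly permutation
#' invariant in the set elements.
#'
#' @param x A single n-by-2 matrix of normalized (hash, count) elements, or
#'   a list of such matrices.
#' @param encoder A `set_encoder`.
#' @return A matrix with one embedding row per input set.
#' @export
encode <- function(x, encoder) {
  stopifnot(inherits(encoder, "set_encoder"))
  if (is.matrix(x)) x <- list(x)
  if (any(map_dbl(x, nrow) == 0)) abort("cannot encode an empty set")
  # canonicalize element order so the pooled sum is bitwise identical for
  # any permutation of the input set
  x <- map(x, function(m) m[order(m[, 1], m[, 2]), , drop = FALSE])
  E <- do.call(rbind, x)
  set_index <- rep(seq_along(x), map_dbl(x, nrow))
  H <- subnet_forward(encoder$h, E, training = FALSE)$out
  P <- pool_sets(H, set_index, length(x))
  subnet_forward(encoder$g, P, training = FALSE)$out
}

#' Cosine-MSE contrastive loss
#'
#' Mean squared error between all pairwise cosine similarities of a batch
#' of embeddings (diagonal included) and the corresponding entries of the
#' label similarity matrix:
#' `(1/N^2) * sum_ij (cos(z_i, z_j) - S_ij)^2`. Nonnegative, and zero iff
#' every pairwise cosine equals its label.
#'
#' @param Z Matrix of embeddings, one row per sample.
#' @param S Label similarity matrix for this batch.
#' @return A scalar.
#' @export
contrastive_loss <- function(Z, S) {
  Z <- as.matrix(Z)
  S <- as.matrix(S)
  r <- sqrt(rowSums(Z^2))
  if (any(r < 1e-12)) abort("zero-norm embedding in contrastive loss")
  Zhat <- Z / r
  C <- tcrossprod(Zhat)
  mean((C - S)^2)
}

loss_and_grad_Z <- function(Z, S) {
  n <- nrow(Z)
  r <- sqrt(rowSums(Z^2))
  if (any(r < 1e-12)) abort("zero-norm embedding in contrastive loss")
  Zhat <- Z / r
  C <- tcrossprod(Zhat)
  G <- 2 * (C - S) / n^2
  dZhat <- (G + t(G)) %*% Zhat
  proj <- rowSums(dZhat * Zhat)
  dZ <- (dZhat - Zhat * proj) / r
  list(loss = mean((C - S)^2), dZ = dZ)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = c("matrix", "numeric"))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk_names <- c("W", "b", "gamma", "beta")
  for (net in c("h", "g")) {
    for (l in seq_along(params[[net]])) {
      for (nm in walk_names) {
        g <- grads[[net]][[l]][[nm]]
        if (is.null(g)) next
        st <- state[[net]][[l]][[nm]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        params[[net]][[l]][[nm]] <- params[[net]][[l]][[nm]] -
          lr * mhat / (sqrt(vhat) + eps)
        state[[net]][[l]][[nm]] <- st
      }
    }
  }
  list(params = params, state = state)
}

#' Train the set encoder by contrastive regression
#'
#' Minimizes the cosine-MSE loss of [contrastive_loss()] over minibatches
#' drawn without replacement each epoch, using Adam. Batch normalization
#' uses minibatch statistics during training (pooled over all set elements
#' in the batch for `h`, over samples for `g`) and tracks running
#' statistics for inference.
#'
#' @param inputs List of n-by-2 matrices of normalized sketch elements
#'   (parents and augmented variants alike).
#' @param labels Similarity matrix aligned with `inputs` (use
#'   [extend_labels()] to propagate parent similarities to augmented
#'   variants).
#' @param config An [encoder_config()].
#' @param train An [train_config()].
#' @param encoder Optional warm-start `set_encoder`.
#' @return A trained `set_encoder` with a `loss_history` attribute (mean
#'   batch loss per epoch).
#' @export
train_encoder <- function(inputs, labels,
                          config = encoder_config(),
                          train = train_config(),
                          encoder = NULL) {
  n <- length(inputs)
  labels <- as.matrix(labels)
  if (nrow(labels) != n || ncol(labels) != n) {
    abort("label matrix must be n x n for n inputs")
  }
  if (is.null(encoder)) encoder <- init_encoder(config, seed = train$seed)
  params <- list(h = encoder$h, g = encoder$g)
  adam <- adam_init(params)
  nb <- min(train$batch_size, n)
  tot_batch <- max(1, floor(n / nb))
  history <- numeric(train$epochs)
  t_step <- 0

  with_seed(train$seed + 1, {
    for (epoch in seq_len(train$epochs)) {
      perm <- sample(n)
      epoch_losses <- numeric(tot_batch)
      for (b in seq_len(tot_batch)) {
        idx <- perm[((b - 1) * nb + 1):(b * nb)]
        x <- inputs[idx]
        E <- do.call(rbind, x)
        set_index <- rep(seq_along(x), map_dbl(x, nrow))

        fh <- subnet_forward(params$h, E, training = TRUE)
        params$h <- fh$layers     # running-stat updates
        sizes <- tabulate(set_index, nbins = nb)
        P <- pool_sets(fh$out, set_index, nb)
        fg <- subnet_forward(params$g, P, training = TRUE)
        params$g <- fg$layers
        lg <- loss_and_grad_Z(fg$out, labels[idx, idx, drop = FALSE])

        grads_g <- subnet_backward(params$g, fg$caches, lg$dZ)
        dP <- backprop_input(params$g, fg$caches, lg$dZ)
        dH <- dP[set_index, , drop = FALSE] / sizes[set_index]
        grads_h <- subnet_backward(params$h, fh$caches, dH)

        t_step <- t_step + 1
        upd <- adam_update(params, list(h = grads_h, g = grads_g), adam,
                           train$learning_rate, t_step)
        params <- upd$params
        adam <- upd$state
        epoch_losses[b] <- lg$loss
      }
      history[epoch] <- mean(epoch_losses)
    }
  })
  out <- list(h = params$h, g = params$g, config = encoder$config)
  class(out) <- "set_encoder"
  attr(out, "loss_history") <- history
  out
}

# gradient of a subnet's output w.r.t. its input matrix
backprop_input <- function(layers, caches, dOut) {
  for (l in rev(seq_along(layers))) {
    layer <- layers[[l]]
    cache <- caches[[l]]
    if (layer$bn) {
      dP <- dOut * (cache$P > 0)
      dxhat <- sweep(dP, 2, layer$gamma, "*")
      n <- nrow(dP)
      sum_dxhat <- colSums(dxhat)
      sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
      dA <- sweep(
        dxhat * n - matrix(sum_dxhat, n, length(sum_dxhat), byrow = TRUE) -
          sweep(cache$xhat, 2, sum_dxhat_xhat, "*"),
        2, cache$inv_sd / n, "*"
      )
    } else {
      dA <- dOut
    }
    dOut <- tcrossprod(dA, layer$W)
  }
  dOut
}

#' @export
print.set_encoder <- function(x, ...) {
  cat("<set_encoder> h:", paste(x$config$h_layers, collapse = "-"),
      " g:", paste(x$config$g_layers, collapse = "-"), "\n")
  invisible(x)
}

#' @export
glance.set_encoder <- function(x, ...) {
  hist <- attr(x, "loss_history")
  tibble(
    embedding_dim = tail1(x$config$g_layers),
    n_parameters = sum(rapply(list(x$h, x$g), length, how = "unlist")),
    epochs_trained = length(hist) %||% 0L,
    final_loss = if (length(hist)) tail1(hist) else NA_real_
  )
}

#' Read-subsampling data augmentation
#'
#' Creates one subsampled variant of a read set per sampling ratio, with
#' per-read Bernoulli retention at the given probability (seeded). At the
#' default ratios this yields seven variants per sample, multiplying the
#' training corpus eightfold with no additional BO computation: a
#' subsample of a sample is expected to share its optimal parameter
#' vector, so variants inherit their parents' similarity labels.
#'
#' @param reads Character vector of read sequences.
#' @param ratios Sampling ratios (default `c(0.65, 0.7, 0.75, 0.8, 0.85,
#'   0.9, 0.95)`).
#' @param seed Seed for the Bernoulli draws.
#' @return A tibble with columns `ratio` and `reads` (list column).
#' @export
augment_reads <- function(reads, ratios = c(0.65, 0.7, 0.75, 0.8, 0.85,
                                            0.9, 0.95),
                          seed = 1) {
  if (length(reads) == 0) abort("cannot augment an empty read set")
  variants <- with_seed(seed, {
    map(ratios, function(r) {
      if (r >= 1) return(reads)
      keep <- runif(length(reads)) < r
      reads[keep]
    })
  })
  tibble(ratio = ratios, reads = variants)
}

#' Propagate parent similarities to augmented variants
#'
#' Given the m-by-m similarity matrix of the parent samples and a family
#' index mapping every training input (parents and variants) to its parent,
#' returns the extended label matrix: a pair from different families gets
#' its parents' similarity; a pair from the same family (a parent and its
#' subsamples, which proxy the same objective) gets label 1.
#'
#' @param S Parent similarity matrix.
#' @param family Integer vector, one entry per training input, with values
#'   in `1..nrow(S)`.
#' @return The extended label matrix.
#' @export
extend_labels <- function(S, family) {
  S <- as.matrix(S)
  if (any(family < 1 | family > nrow(S))) abort("family index out of range")
  L <- S[family, family, drop = FALSE]
  same <- outer(family, family, "==")
  L[same] <- 1
  L
}

# Evaluate an expression with a private, seeded RNG stream, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
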