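test_that("encoding is exactly permutation invariant at inference", {
  enc <- init_encoder(small_encoder_config(), seed = 2)
  x <- withr::with_seed(1, matrix(rnorm(40), 20, 2))
  z1 <- encode(x, enc)
  z2 <- encode(x[sample(1:20), , drop = FALSE], enc)
  expect_identical(z1, z2)
  # single-element set: z = g(h(x))
  single <- x[1, , drop = FALSE]
  expect_equal(dim(encode(single, enc)), c(1L, 8L))
  expect_error(encode(matrix(numeric(0), 0, 2), enc), "empty")
})

test_that("default architecture embeds into 64 dimensions", {
  cfg <- encoder_config()
  expect_equal(cfg$h_layers, c(2, 128, 128, 128, 128))
  expect_equal(cfg$g_layers, c(128, 256, 256, 256, 64))
  enc <- init_encoder(cfg, seed = 1)
  x <- withr::with_seed(2, matrix(rnorm(20), 10, 2))
  expect_equal(ncol(encode(x, enc)), 64L)
  expect_error(encoder_config(c(2, 16), c(8, 4)), "width")
})

test_that("contrastive loss matches hand arithmetic", {
  # exact fit: cosines equal labels -> 0
  Z <- diag(2)
  expect_equal(contrastive_loss(Z, diag(2)), 0)
  # two embeddings at 60 degrees, labels 0.9 off-diagonal:
  # (1/4) * 2 * (0.5 - 0.9)^2 = 0.08
  Z2 <- rbind(c(1, 0), c(0.5, sqrt(3) / 2))
  S2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(contrastive_loss(Z2, S2), 0.08)
  # nonnegative, zero only at exact fit
  withr::with_seed(3, {
    Zr <- matrix(rnorm(12), 4, 3)
    Sr <- matrix(runif(16, -1, 1), 4); Sr <- (Sr + t(Sr)) / 2; diag(Sr) <- 1
    expect_gte(contrastive_loss(Zr, Sr), 0)
  })
  expect_error(contrastive_loss(rbind(c(0, 0), c(1, 0)), diag(2)),
               "zero-norm")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- encoder_config(c(2, 5, 4), c(4, 6, 3))
  enc <- init_encoder(cfg, seed = 7)
  inputs <- withr::with_seed(8, lapply(1:4, function(i) matrix(rnorm(12), 6, 2)))
  S <- matrix(c(1, .8, -.2, 0,
                .8, 1, .1, -.5,
                -.2, .1, 1, .3,
                0, -.5, .3, 1), 4, 4)
  params <- list(h = enc$h, g = enc$g)
  forward_loss <- function(params) {
    E <- do.call(rbind, inputs)
    idx <- rep(1:4, each = 6)
    fh <- asmtune:::subnet_forward(params$h, E, training = TRUE)
    P <- asmtune:::pool_sets(fh$out, idx, 4)
    fg <- asmtune:::subnet_forward(params$g, P, training = TRUE)
    asmtune:::contrastive_loss(fg$out, S)
  }
  # analytic gradients
  E <- do.call(rbind, inputs)
  idx <- rep(1:4, each = 6)
  fh <- asmtune:::subnet_forward(params$h, E, training = TRUE)
  P <- asmtune:::pool_sets(fh$out, idx, 4)
  fg <- asmtune:::subnet_forward(params$g, P, training = TRUE)
  lg <- asmtune:::loss_and_grad_Z(fg$out, S)
  grads_g <- asmtune:::subnet_backward(params$g, fg$caches, lg$dZ)
  dP <- asmtune:::backprop_input(params$g, fg$caches, lg$dZ)
  dH <- dP[idx, , drop = FALSE] / 6
  grads_h <- asmtune:::subnet_backward(params$h, fh$caches, dH)

  eps <- 1e-5
  check <- function(net, l, nm, grad, n_checks = 4) {
    p <- params[[net]][[l]][[nm]]
    picks <- withr::with_seed(l * 100 + nchar(nm),
                              sample(length(p), min(n_checks, length(p))))
    for (ix in picks) {
      pp <- params; pm <- params
      pp[[net]][[l]][[nm]][ix] <- p[ix] + eps
      pm[[net]][[l]][[nm]][ix] <- p[ix] - eps
      fd <- (forward_loss(pp) - forward_loss(pm)) / (2 * eps)
      expect_equal(grad[ix], fd, tolerance = 1e-4,
                   label = paste(net, l, nm, ix))
    }
  }
  for (l in seq_along(params$h)) {
    check("h", l, "W", grads_h[[l]]$W); check("h", l, "b", grads_h[[l]]$b)
    if (!is.null(grads_h[[l]]$gamma)) {
      check("h", l, "gamma", grads_h[[l]]$gamma)
    }
  }
  for (l in seq_along(params$g)) {
    check("g", l, "W", grads_g[[l]]$W)
    if (!is.null(grads_g[[l]]$beta)) check("g", l, "beta", grads_g[[l]]$beta)
  }
})

test_that("augmentation yields one variant per ratio with inherited labels", {
  reads <- random_reads(200, 30, seed = 5)
  aug <- augment_reads(reads, seed = 2)
  expect_equal(nrow(aug), 7L)
  expect_equal(aug$ratio, c(0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95))
  # subsample sizes track the ratios
  sizes <- vapply(aug$reads, length, 0L)
  expect_true(all(abs(sizes / 200 - aug$ratio) < 0.15))
  # every retained read is one of the parent's
  expect_true(all(unlist(aug$reads) %in% reads))
  # diagnostic ratio 1 reproduces the parent read set
  expect_identical(augment_reads(reads, ratios = 1, seed = 2)$reads[[1]],
                   reads)
  # identical seeds reproduce the draw
  expect_identical(aug$reads, augment_reads(reads, seed = 2)$reads)

  # label propagation: any two members of families i != j inherit S[i, j],
  # same-family pairs get 1
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  family <- c(1, 2, 1, 1, 2)
  L <- extend_labels(S, family)
  expect_equal(L[1, 2], 0.4)
  expect_equal(L[3, 5], 0.4)
  expect_equal(L[1, 3], 1)
  expect_equal(L[1, 4], 1)
  expect_equal(diag(L), rep(1, 5))
})

test_that("training reduces the loss and separates planted groups", {
  # 20 samples in 2 groups; group controls the element distribution
  n_per <- 10
  inputs <- withr::with_seed(11, {
    c(
      lapply(seq_len(n_per), function(i) {
        cbind(rnorm(15, mean = -1, sd = 0.3), rnorm(15, mean = 1, sd = 0.3))
      }),
      lapply(seq_len(n_per), function(i) {
        cbind(rnorm(15, mean = 1, sd = 0.3), rnorm(15, mean = -1, sd = 0.3))
      })
    )
  })
  grp <- rep(1:2, each = n_per)
  S <- ifelse(outer(grp, grp, "=="), 0.9, -0.5)
  diag(S) <- 1
  enc <- train_encoder(inputs, S, config = small_encoder_config(),
                       train = train_config(batch_size = 10, epochs = 50,
                                            seed = 4))
  hist <- attr(enc, "loss_history")
  expect_lt(hist[length(hist)], hist[1])

  Z <- encode(inputs, enc)
  C <- tcrossprod(Z / sqrt(rowSums(Z^2)))
  within <- C[outer(grp, grp, "==") & upper.tri(C)]
  between <- C[outer(grp, grp, "!=") & upper.tri(C)]
  # within-group cosines dominate between-group cosines for >= 95% of pairs
  frac <- mean(outer(within, between, ">"))
  expect_gte(frac, 0.95)

  # fixed seed reproduces the final loss
  enc2 <- train_encoder(inputs, S, config = small_encoder_config(),
                        train = train_config(batch_size = 10, epochs = 5,
                                             seed = 4))
  enc3 <- train_encoder(inputs, S, config = small_encoder_config(),
                        train = train_config(batch_size = 10, epochs = 5,
                                             seed = 4))
  expect_identical(attr(enc2, "loss_history"), attr(enc3, "loss_history"))

  expect_error(train_encoder(inputs, S[1:5, 1:5]), "n x n")
})

test_that("encoder weights persist as JSON bit-for-bit", {
  enc <- init_encoder(small_encoder_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_encoder(enc, path)
  back <- read_encoder(path)
  x <- withr::with_seed(5, matrix(rnorm(16), 8, 2))
  expect_identical(encode(x, enc), encode(x, back))
})
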