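#' Gaussian-process surrogate over a mixed parameter space
#'
#' Fits a GP regression to the (parameter vector, loss) pairs of a BO
#' trace. Continuous and integer coordinates are min-max scaled to `[0, 1]`
#' using the search domain and enter a Matern-5/2 kernel with a shared
#' length scale; binary coordinates enter a categorical-overlap (Hamming)
#' kernel; the full kernel is the product of the two, scaled by a signal
#' variance, plus observation noise. Losses are standardized to zero mean
#' and unit variance before fitting; posterior means are reported on the
#' original scale. Hyperparameters are chosen by maximizing the log
#' marginal likelihood from a small fixed set of starts.
#'
#' @param trace A [bo_trace()] with at least two records.
#' @param domain The `search_domain` used for coordinate scaling.
#' @param space The [param_space()] (defines coordinate kinds). Defaults to
#'   the space attached to the trace.
#' @param noise Fixed observation-noise variance on the standardized scale,
#'   or `NULL` (the default) to estimate it by marginal likelihood.
#' @param optimize_hyperparams If `FALSE`, keep the supplied (or default)
#'   hyperparameters (used when refitting frequently inside the BO loop).
#' @param par Optional fixed hyperparameter vector (as produced by a
#'   previous fit); implies no re-optimization unless
#'   `optimize_hyperparams` is `TRUE`.
#' @return An object of class `gp_surrogate`.
#' @export
fit_surrogate <- function(trace, domain, space = attr(trace, "space"),
                          noise = NULL, optimize_hyperparams = TRUE,
                          par = NULL) {
  stopifnot(inherits(trace, "bo_trace"))
  if (nrow(trace) < 2) abort("need at least two records to fit a surrogate")
  if (is.null(space)) abort("trace carries no space; pass `space`")
  X <- theta_matrix(trace, space)
  # collapse repeated query points (warmup revisits), averaging their losses,
  # so the noise-free kernel matrix stays well conditioned
  key <- apply(X, 1, paste, collapse = ",")
  if (anyDuplicated(key)) {
    y_agg <- tapply(trace$y, key, mean)
    first <- !duplicated(key)
    X <- X[first, , drop = FALSE]
    y <- as.numeric(y_agg[key[first]])
  } else {
    y <- trace$y
  }
  if (nrow(X) < 2) {
    abort("degenerate trace: all parameter vectors identical")
  }
  Z <- encode_points(X, space, domain)
  y_mean <- mean(y)
  y_sd <- sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  cont <- space$kind != "binary"
  has_cat <- any(!cont)
  # log(lengthscale), log(signal sd), log(noise sd), log(hamming rate)
  nll <- function(par) {
    K <- kernel_matrix(Z, Z, cont, par)
    diag(K) <- diag(K) + noise_var(par, noise)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(L))) +
                 0.5 * length(ys) * log(2 * pi))
  }
  par0 <- par %||% c(log(0.3), log(1),
                     if (is.null(noise)) log(0.05) else NULL,
                     if (has_cat) log(1) else NULL)
  par <- par0
  if (optimize_hyperparams) {
    starts <- list(par0,
                   par0 + c(log(3), 0, rep(0, length(par0) - 2)),
                   par0 + c(log(0.2), 0, rep(0, length(par0) - 2)))
    fits <- map(starts, function(p0) {
      tryCatch(
        optim(p0, nll, method = "L-BFGS-B",
              lower = rep(log(1e-4), length(p0)),
              upper = rep(log(1e3), length(p0)),
              control = list(maxit = 60)),
        error = function(e) list(par = p0, value = nll(p0))
      )
    })
    par <- fits[[which.min(map_dbl(fits, "value"))]]$par
  }
  K <- kernel_matrix(Z, Z, cont, par)
  diag(K) <- diag(K) + noise_var(par, noise)
  L <- chol(K + diag(1e-8, nrow(K)))
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(
    list(Z = Z, y_mean = y_mean, y_sd = y_sd, par = par, noise = noise,
         cont = cont, L = L, alpha = alpha, space = space, domain = domain),
    class = "gp_surrogate"
  )
}

noise_var <- function(par, noise) {
  if (is.null(noise)) exp(2 * par[3]) + 1e-8 else noise + 1e-10
}

encode_points <- function(X, space, domain) {
  Z <- X
  nb <- space$kind != "binary"
  rng <- pmax(domain$hi - domain$lo, 1e-12)
  for (j in which(nb)) Z[, j] <- (X[, j] - domain$lo[j]) / rng[j]
  Z
}

kernel_matrix <- function(Z1, Z2, cont, par) {
  ell <- exp(par[1])
  sf2 <- exp(2 * par[2])
  n1 <- nrow(Z1); n2 <- nrow(Z2)
  K <- matrix(1, n1, n2)
  if (any(cont)) {
    A <- Z1[, cont, drop = FALSE]
    B <- Z2[, cont, drop = FALSE]
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    r <- sqrt(pmax(d2, 0)) / ell
    K <- K * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  }
  if (any(!cont)) {
    gamma <- exp(par[length(par)])
    A <- Z1[, !cont, drop = FALSE]
    B <- Z2[, !cont, drop = FALSE]
    mism <- matrix(0, n1, n2)
    for (j in seq_len(ncol(A))) {
      mism <- mism + outer(A[, j], B[, j], function(a, b) as.numeric(a != b))
    }
    K <- K * exp(-gamma * mism / ncol(A))
  }
  sf2 * K
}

#' Posterior mean (and variance) of a surrogate
#'
#' @param object A fitted surrogate.
#' @param theta A named parameter vector, a list of them, or a matrix with
#'   one row per vector.
#' @param ... Unused.
#' @return For `posterior_mean`, a numeric vector of posterior means on the
#'   loss scale; `gp_posterior` additionally returns standard deviations.
#' @export
posterior_mean <- function(object, theta, ...) UseMethod("posterior_mean")

#' @export
posterior_mean.gp_surrogate <- function(object, theta, ...) {
  gp_posterior(object, theta)$mean
}

#' @rdname posterior_mean
#' @export
gp_posterior <- function(object, theta) {
  stopifnot(inherits(object, "gp_surrogate"))
  X <- as_theta_matrix(theta, object$space$name)
  Zs <- encode_points(X, object$space, object$domain)
  Ks <- kernel_matrix(Zs, object$Z, object$cont, object$par)
  mu <- as.numeric(Ks %*% object$alpha) * object$y_sd + object$y_mean
  v <- forwardsolve(t(object$L), t(Ks))
  kss <- kernel_matrix(Zs, Zs, object$cont, object$par)
  var_std <- pmax(diag(kss) - colSums(v^2), 0)
  tibble(mean = mu, sd = sqrt(var_std) * object$y_sd)
}

as_theta_matrix <- function(theta, names) {
  if (is.matrix(theta)) {
    colnames(theta) <- colnames(theta) %||% names
    return(theta[, names, drop = FALSE])
  }
  if (is.numeric(theta)) theta <- list(theta)
  do.call(rbind, map(theta, function(t) conform_theta(t, names)))
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat("<gp_surrogate>", nrow(x$Z), "training points,",
      sum(x$cont), "continuous +", sum(!x$cont), "binary coordinates\n")
  invisible(x)
}
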