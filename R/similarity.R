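#' normrank: trace-based dissimilarity between two samples
#'
#' For samples `i` and `j` with BO traces and fitted surrogates, normrank
#' is the fraction of parameter vectors queried for sample `i` whose
#' posterior-mean loss under sample `i`'s surrogate is strictly below the
#' posterior mean at sample `j`'s best parameter vector. If the two loss
#' landscapes are alike, `j`'s optimum is near-optimal for `i` and few
#' queried points beat it, so normrank is small. The strict inequality
#' means exact ties do not count, and evaluating `j = i` at the trace's
#' posterior-mean argmin gives 0.
#'
#' @param trace_i Sample `i`'s [bo_trace()].
#' @param surrogate_i A surrogate fitted on `trace_i` (anything with a
#'   [posterior_mean()] method).
#' @param theta_hat_j Sample `j`'s best parameter vector. Coordinates are
#'   clipped into `clip_domain` (if given) before the posterior is
#'   evaluated, to bound GP extrapolation outside `i`'s search region.
#' @param clip_domain Optional `search_domain` for clipping.
#' @return A scalar in `[0, 1]`.
#' @export
normrank <- function(trace_i, surrogate_i, theta_hat_j, clip_domain = NULL) {
  stopifnot(inherits(trace_i, "bo_trace"))
  if (nrow(trace_i) == 0) abort("empty trace")
  if (!is.null(clip_domain)) {
    theta_hat_j <- pmin(pmax(conform_theta(theta_hat_j, clip_domain$name),
                             clip_domain$lo), clip_domain$hi)
  }
  mu_trace <- posterior_mean(surrogate_i, trace_i$theta)
  mu_hat <- posterior_mean(surrogate_i, theta_hat_j)
  sum(mu_trace < mu_hat) / nrow(trace_i)
}

#' Symmetrize a normrank matrix
#'
#' @param nr Square matrix of pairwise normrank values.
#' @return The elementwise average of the matrix and its transpose.
#' @export
symmetrize <- function(nr) {
  nr <- as.matrix(nr)
  if (nrow(nr) != ncol(nr)) abort("matrix must be square")
  (nr + t(nr)) / 2
}

#' All-pairs shortest-path repair of a dissimilarity matrix
#'
#' Treats the symmetric matrix as edge weights of a complete graph and
#' replaces every entry by the shortest-path distance (Floyd-Warshall).
#' The result is elementwise no larger than the input, satisfies the
#' triangle inequality, and the operation is idempotent.
#'
#' @param d Symmetric nonnegative matrix with zero diagonal.
#' @return The repaired distance matrix.
#' @export
shortest_path_repair <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("matrix must be square")
  if (any(d < 0)) abort("entries must be nonnegative")
  if (max(abs(d - t(d))) > 1e-12) abort("matrix must be symmetric")
  diag(d) <- 0
  m <- nrow(d)
  for (k in seq_len(m)) {
    via <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, via)
  }
  d
}

#' Similarity from a repaired distance matrix
#'
#' Maps distances in `[0, 1]` to similarities in `[-1, 1]` via
#' `S = 1 - 2 * D`, matching the range of cosine similarity used by the
#' encoder.
#'
#' @param dhat Distance matrix with entries in `[0, 1]`.
#' @return A similarity matrix of class `sim_matrix`.
#' @export
similarity_from_distance <- function(dhat) {
  dhat <- as.matrix(dhat)
  if (any(dhat < -1e-12 | dhat > 1 + 1e-12)) {
    abort("distances must lie in [0, 1]")
  }
  s <- 1 - 2 * dhat
  class(s) <- c("sim_matrix", class(s))
  s
}

#' Build the training similarity matrix from BO traces
#'
#' Runs the full pipeline: refit a GP surrogate on each complete trace
#' (reusing the BO-phase configuration), compute all pairwise normrank
#' values, symmetrize, force the diagonal to zero, repair to a metric by
#' shortest paths, and convert to similarities.
#'
#' @param traces List of [bo_trace()] objects.
#' @param domains List of `search_domain`s (one per trace) used for GP
#'   coordinate scaling and for clipping foreign optima; a single domain is
#'   recycled.
#' @param space The shared [param_space()].
#' @param surrogates Optional list of pre-fitted surrogates (one per
#'   trace), e.g. the lookup surrogates of [make_trace()]; skips refitting.
#' @return A `sim_matrix` with attributes `normrank` (the raw asymmetric
#'   matrix) and `distance` (the repaired metric) for audit, and sample
#'   ids as dimnames.
#' @export
build_similarity <- function(traces, domains = NULL,
                             space = attr(traces[[1]], "space"),
                             surrogates = NULL) {
  m <- length(traces)
  if (m < 1) abort("need at least one trace")
  if (is.null(domains)) {
    domains <- rep(list(initial_domain(space)), m)
  } else if (inherits(domains, "search_domain")) {
    domains <- rep(list(domains), m)
  }
  if (is.null(surrogates)) {
    surrogates <- map2(traces, domains, function(tr, dom) {
      fit_surrogate(tr, dom, space)
    })
  }
  theta_hats <- map(traces, function(tr) trace_best(tr)$theta)
  nr <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      nr[i, j] <- normrank(traces[[i]], surrogates[[i]], theta_hats[[j]],
                           clip_domain = domains[[i]])
    }
  }
  d <- symmetrize(nr)
  diag(d) <- 0
  dhat <- shortest_path_repair(d)
  s <- similarity_from_distance(dhat)
  ids <- map(traces, function(tr) attr(tr, "sample_id") %||% NA_character_)
  dimnames(s) <- list(unlist(ids), unlist(ids))
  attr(s, "normrank") <- nr
  attr(s, "distance") <- dhat
  s
}

#' @export
tidy.sim_matrix <- function(x, ...) {
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  expand_grid_ids(ids) |>
    mutate(similarity = as.vector(unclass(x)))
}

expand_grid_ids <- function(ids) {
  tibble(
    sample_i = rep(ids, times = length(ids)),
    sample_j = rep(ids, each = length(ids))
  )
}

#' @export
autoplot.sim_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_j, y = .data$sample_i,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Persist / load a similarity (or distance) matrix as TSV
#'
#' Dense tab-separated values with a sample-id header row and column.
#'
#' @param s A matrix with dimnames.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(s, path) {
  df <- data.frame(sample_id = rownames(s), unclass(s), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
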