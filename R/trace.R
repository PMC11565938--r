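#' Build a BO evaluation trace
#'
#' A trace is the ordered record of every objective evaluation made while
#' tuning one sample: the queried parameter vector and its loss, tagged by
#' the phase (coordinate-ascent warmup or GP-BO) that produced it.
#'
#' @param thetas List of named parameter vectors (or a matrix with one row
#'   per vector).
#' @param y Numeric losses, one per vector.
#' @param phase Character vector (recycled) tagging each evaluation.
#' @param sample_id Sample label.
#' @param space The [param_space()] the vectors live in.
#' @return A tibble of class `bo_trace` with columns `eval`, `phase`,
#'   `theta` (list column) and `y`.
#' @export
bo_trace <- function(thetas, y, phase = "bo", sample_id = "sample",
                     space = NULL) {
  if (is.matrix(thetas)) {
    thetas <- map(seq_len(nrow(thetas)), function(i) thetas[i, ])
  }
  if (length(thetas) != length(y)) abort("thetas and y lengths differ")
  if (any(!is.finite(y))) abort("losses must be finite")
  out <- tibble(
    eval = seq_along(y),
    phase = rep_len(phase, length(y)),
    theta = thetas,
    y = as.numeric(y)
  )
  attr(out, "sample_id") <- sample_id
  attr(out, "space") <- space
  class(out) <- c("bo_trace", class(out))
  out
}

theta_matrix <- function(trace, space = attr(trace, "space")) {
  nm <- if (!is.null(space)) space$name else names(trace$theta[[1]])
  do.call(rbind, map(trace$theta, function(t) conform_theta(t, nm)))
}

#' Best record of a trace
#'
#' @param trace A [bo_trace()].
#' @return A list with `theta`, `y` and `eval` of the earliest minimum.
#' @export
trace_best <- function(trace) {
  stopifnot(inherits(trace, "bo_trace"), nrow(trace) > 0)
  i <- which.min(trace$y)   # which.min returns the earliest tie
  list(theta = trace$theta[[i]], y = trace$y[i], eval = trace$eval[i])
}

#' Persist / load traces as tab-separated text
#'
#' One evaluation per line: sample id, evaluation index, phase, one column
#' per parameter, and the loss.
#'
#' @param trace A [bo_trace()].
#' @param path Output file.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   [bo_trace()].
#' @export
write_trace <- function(trace, path) {
  X <- theta_matrix(trace)
  df <- data.frame(
    sample_id = attr(trace, "sample_id") %||% "sample",
    eval = trace$eval, phase = trace$phase, X, y = trace$y,
    check.names = FALSE
  )
  write_tsv_full(df, path)
  invisible(path)
}

# write a TSV preserving doubles to full (17 significant digit) precision
write_tsv_full <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param space Optional [param_space()] to attach on read.
#' @export
read_trace <- function(path, space = NULL) {
  df <- read.delim(path, check.names = FALSE)
  fixed <- c("sample_id", "eval", "phase", "y")
  pnames <- setdiff(names(df), fixed)
  thetas <- map(seq_len(nrow(df)), function(i) {
    setNames(as.numeric(df[i, pnames]), pnames)
  })
  bo_trace(thetas, df$y, phase = df$phase,
           sample_id = df$sample_id[1], space = space)
}

#' @export
tidy.bo_trace <- function(x, ...) {
  X <- theta_matrix(x)
  bind_cols(
    tibble(eval = x$eval, phase = x$phase, y = x$y,
           best_so_far = cummin(x$y)),
    as_tibble(as.data.frame(X))
  )
}

#' @export
glance.bo_trace <- function(x, ...) {
  best <- trace_best(x)
  tibble(
    sample_id = attr(x, "sample_id") %||% NA_character_,
    n_evals = nrow(x),
    n_warmup = sum(x$phase == "warmup"),
    best_y = best$y,
    best_eval = best$eval
  )
}

#' @export
autoplot.bo_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eval)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y, colour = .data$phase),
                        alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far)) +
    ggplot2::labs(x = "objective evaluation", y = "loss (-AUC)",
                  colour = "phase")
}
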