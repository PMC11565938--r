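#' Build the representative-sample index
#'
#' The index caches, for every representative sample, its embedding, its
#' best parameter vector found by BO and the corresponding loss. Advising
#' a new sample is then a cosine nearest-neighbor scan over the cached
#' embeddings.
#'
#' @param sample_ids Character vector of representative ids.
#' @param embeddings Matrix with one embedding row per representative.
#' @param theta_hats List of best parameter vectors (one per
#'   representative).
#' @param best_losses Numeric vector of the corresponding losses.
#' @param space The [param_space()].
#' @param norm_stats z-normalization statistics (from [znorm_corpus()])
#'   needed to sketch-normalize new samples.
#' @param encoder The trained `set_encoder`.
#' @param sketch_params List with `k`, `s`, `min_count`, `seed` used for
#'   sketching.
#' @return A list of class `advisor_index`.
#' @export
advisor_index <- function(sample_ids, embeddings, theta_hats, best_losses,
                          space, norm_stats = NULL, encoder = NULL,
                          sketch_params = NULL) {
  m <- length(sample_ids)
  stopifnot(nrow(embeddings) == m, length(theta_hats) == m,
            length(best_losses) == m)
  structure(
    list(sample_ids = sample_ids, embeddings = embeddings,
         theta_hats = theta_hats, best_losses = best_losses, space = space,
         norm_stats = norm_stats, encoder = encoder,
         sketch_params = sketch_params),
    class = "advisor_index"
  )
}

#' Cosine nearest neighbors in the embedding space
#'
#' @param z_new Embedding of the query sample (numeric vector or one-row
#'   matrix).
#' @param index An [advisor_index()].
#' @param p Number of neighbors (most similar first; ties broken by stable
#'   index order). If `p` exceeds the index size, all members are returned
#'   with a warning.
#' @return A tibble with `rank`, `sample_id`, `cosine`.
#' @export
nearest_neighbors <- function(z_new, index, p = 5) {
  stopifnot(inherits(index, "advisor_index"), p >= 1)
  z_new <- as.numeric(z_new)
  m <- length(index$sample_ids)
  if (p > m) {
    warn(paste0("p = ", p, " exceeds index size ", m, "; returning all"))
    p <- m
  }
  E <- index$embeddings
  cos <- unname(as.numeric(E %*% z_new) /
                  (sqrt(unname(rowSums(E^2))) * sqrt(sum(z_new^2))))
  ord <- order(-cos, seq_len(m))
  picked <- ord[seq_len(p)]
  tibble(rank = seq_len(p), sample_id = index$sample_ids[picked],
         cosine = cos[picked])
}

#' Advisor set for a new sample
#'
#' Sketches the sample (unless a sketch or embedding is supplied),
#' z-normalizes with the training statistics, embeds it with the trained
#' encoder, finds the `p` most similar representatives by cosine, and
#' collects their best parameter vectors (most similar neighbor first;
#' duplicate vectors are kept, since distinct neighbors may share an
#' optimum).
#'
#' @param x A character vector of reads, a `sketch_set`, or a numeric
#'   embedding.
#' @param index An [advisor_index()] holding the encoder and normalization
#'   statistics.
#' @param p Advisor-set size.
#' @return A tibble of class `advisor_set` with `rank`, `sample_id`,
#'   `cosine` and `theta` (list column of parameter vectors).
#' @export
advisor_set <- function(x, index, p = 5) {
  stopifnot(inherits(index, "advisor_index"))
  z <- query_embedding(x, index)
  nn <- nearest_neighbors(z, index, p)
  nn$theta <- index$theta_hats[match(nn$sample_id, index$sample_ids)]
  class(nn) <- c("advisor_set", class(nn))
  nn
}

query_embedding <- function(x, index) {
  if (is.numeric(x) && !inherits(x, "sketch_set")) return(as.numeric(x))
  if (is.character(x)) {
    sp <- index$sketch_params %||%
      list(k = 21, s = 1000, min_count = 2, seed = 42)
    x <- minhash_sketch(x, k = sp$k, s = sp$s, min_count = sp$min_count,
                        seed = sp$seed)
  }
  if (inherits(x, "sketch_set")) {
    if (is.null(index$norm_stats) || is.null(index$encoder)) {
      abort("index has no encoder/normalization stats; pass an embedding")
    }
    if (nrow(x) == 0) abort("cannot normalize an empty sketch")
    return(as.numeric(encode(apply_znorm(x, index$norm_stats),
                             index$encoder)))
  }
  abort("unsupported query type")
}

#' Evaluate an advisor set and pick the best candidate
#'
#' Runs the sample's objective on every candidate parameter vector and
#' returns the argmin (earliest on ties), i.e. the advising oracle.
#'
#' @param advisor An [advisor_set()] (or any tibble with a `theta` list
#'   column).
#' @param objective An `asm_objective` for the sample being advised.
#' @return A list with `theta_best`, `loss_best` and `evaluations` (the
#'   advisor tibble with a `loss` column).
#' @export
oracle_pick <- function(advisor, objective) {
  if (nrow(advisor) == 0) abort("empty advisor set")
  losses <- map_dbl(advisor$theta, objective)
  advisor$loss <- losses
  i <- which.min(losses)
  list(theta_best = advisor$theta[[i]], loss_best = losses[i],
       evaluations = advisor)
}

#' Persist / load an advisor index as a directory of text files
#'
#' Writes the embeddings and best-parameter tables as TSV, the sketch and
#' normalization metadata as JSON, and the encoder weights as JSON.
#'
#' @param index An [advisor_index()].
#' @param dir Output directory (created if needed).
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- data.frame(sample_id = index$sample_ids, index$embeddings)
  write_tsv_full(emb, file.path(dir, "embeddings.tsv"))
  th <- data.frame(sample_id = index$sample_ids,
                   do.call(rbind, index$theta_hats),
                   best_loss = index$best_losses, check.names = FALSE)
  write_tsv_full(th, file.path(dir, "theta_hats.tsv"))
  meta <- list(
    assembler = attr(index$space, "assembler"),
    space = as.data.frame(index$space[, c("name", "kind", "default",
                                          "warmup_step")]),
    sketch_params = index$sketch_params,
    norm_stats = if (!is.null(index$norm_stats)) {
      as.data.frame(if (inherits(index$norm_stats, "znorm_corpus")) {
        index$norm_stats$stats
      } else index$norm_stats)
    }
  )
  jsonlite::write_json(meta, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = I(17))
  if (!is.null(index$encoder)) {
    write_encoder(index$encoder, file.path(dir, "encoder.json"))
  }
  invisible(dir)
}

#' @rdname write_index
#' @export
read_index <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "index.json"),
                              simplifyVector = TRUE)
  space <- param_space(meta$space, assembler = meta$assembler %||% "custom")
  emb <- read.delim(file.path(dir, "embeddings.tsv"), check.names = FALSE)
  th <- read.delim(file.path(dir, "theta_hats.tsv"), check.names = FALSE)
  pnames <- space$name
  theta_hats <- map(seq_len(nrow(th)), function(i) {
    setNames(as.numeric(th[i, pnames]), pnames)
  })
  enc_path <- file.path(dir, "encoder.json")
  advisor_index(
    sample_ids = as.character(emb$sample_id),
    embeddings = as.matrix(emb[, -1, drop = FALSE]),
    theta_hats = theta_hats,
    best_losses = th$best_loss,
    space = space,
    norm_stats = if (!is.null(meta$norm_stats)) as_tibble(meta$norm_stats),
    encoder = if (file.exists(enc_path)) read_encoder(enc_path),
    sketch_params = meta$sketch_params
  )
}

#' Persist / load encoder weights as JSON
#'
#' @param encoder A `set_encoder`.
#' @param path Output file.
#' @export
write_encoder <- function(encoder, path) {
  ser_subnet <- function(layers) {
    map(layers, function(l) {
      out <- list(W = l$W, b = l$b, bn = l$bn)
      if (l$bn) {
        out <- c(out, l[c("gamma", "beta", "run_mean", "run_var")])
      }
      out
    })
  }
  obj <- list(h_layers = encoder$config$h_layers,
              g_layers = encoder$config$g_layers,
              h = ser_subnet(encoder$h), g = ser_subnet(encoder$g))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  deser_subnet <- function(layers) {
    map(layers, function(l) {
      out <- list(W = as.matrix(l$W), b = as.numeric(l$b),
                  bn = isTRUE(l$bn))
      if (out$bn) {
        out$gamma <- as.numeric(l$gamma)
        out$beta <- as.numeric(l$beta)
        out$run_mean <- as.numeric(l$run_mean)
        out$run_var <- as.numeric(l$run_var)
      }
      out
    })
  }
  state <- list(
    h = deser_subnet(obj$h), g = deser_subnet(obj$g),
    config = encoder_config(as.numeric(obj$h_layers),
                            as.numeric(obj$g_layers))
  )
  class(state) <- "set_encoder"
  state
}
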