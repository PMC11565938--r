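#' Train an advisor: BO on representatives, similarity, encoder, index
#'
#' Runs the full training workflow over a set of representative samples:
#' (i) CAWarm-BO on every representative's objective, recording the trace
#' and the best parameter vector; (ii) removal of representatives whose
#' best AUC is below `min_auc` (degenerate samples carry no usable
#' parameter signal); (iii) the trace-based similarity pipeline
#' ([build_similarity()]); (iv) MinHash sketching of every representative
#' plus read-subsampling augmentation, corpus z-normalization and
#' contrastive training of the set encoder; and (v) assembly of the
#' [advisor_index()] used to advise new samples.
#'
#' @param samples A tibble with columns `sample_id`, `reads` (list of
#'   character vectors) and `objective` (list of `asm_objective`s), e.g.
#'   `make_universe(...)$samples` or a subset of it.
#' @param space The shared [param_space()].
#' @param bo A [bo_config()].
#' @param sketch_params List with `k`, `s`, `min_count`, `seed`.
#' @param encoder An [encoder_config()].
#' @param train A [train_config()].
#' @param ratios Augmentation sampling ratios (`NULL` disables
#'   augmentation).
#' @param min_auc Representative filter threshold on the best AUC found by
#'   BO (default 3e-4).
#' @param out_dir Optional directory; when given, traces, the similarity
#'   matrix, the encoder and the index are persisted there as text files.
#' @param verbose Print per-stage progress.
#' @return A list of class `asm_advisor` with elements `index`, `traces`,
#'   `similarity`, `encoder`, `fits` (per-sample BO summaries) and
#'   `dropped` (ids removed by the AUC filter).
#' @export
train_advisor <- function(samples, space,
                          bo = bo_config(),
                          sketch_params = list(k = 21, s = 1000,
                                               min_count = 2, seed = 42),
                          encoder = encoder_config(),
                          train = train_config(),
                          ratios = c(0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95),
                          min_auc = 3e-4,
                          out_dir = NULL,
                          verbose = FALSE) {
  stopifnot(all(c("sample_id", "reads", "objective") %in% names(samples)))
  say <- function(...) if (verbose) message(...)

  say("stage 1/4: CAWarm-BO on ", nrow(samples), " representatives")
  fits <- map(seq_len(nrow(samples)), function(i) {
    cfg <- bo
    cfg$seed <- bo$seed + i
    cawarm_bo(samples$objective[[i]], space, cfg)
  })
  best_auc <- -map_dbl(fits, "y_hat")
  keep <- best_auc >= min_auc
  dropped <- samples$sample_id[!keep]
  if (all(!keep)) abort("all representatives fell below the AUC filter")
  samples <- samples[keep, ]
  fits <- fits[keep]

  say("stage 2/4: similarity over ", nrow(samples), " retained traces")
  traces <- map(fits, "trace")
  domains <- map(fits, "domain")
  similarity <- build_similarity(traces, domains, space)

  say("stage 3/4: sketching, augmentation, contrastive training")
  sp <- sketch_params
  parent_sketches <- map(samples$reads, function(r) {
    minhash_sketch(r, k = sp$k, s = sp$s, min_count = sp$min_count,
                   seed = sp$seed)
  })
  m <- nrow(samples)
  if (!is.null(ratios) && length(ratios) > 0) {
    aug_sketches <- map(seq_len(m), function(i) {
      aug <- augment_reads(samples$reads[[i]], ratios,
                           seed = train$seed * 10000 + i)
      map(aug$reads, function(r) {
        minhash_sketch(r, k = sp$k, s = sp$s, min_count = sp$min_count,
                       seed = sp$seed)
      })
    })
    sketches <- c(parent_sketches, unlist(aug_sketches, recursive = FALSE))
    family <- c(seq_len(m), rep(seq_len(m), each = length(ratios)))
  } else {
    sketches <- parent_sketches
    family <- seq_len(m)
  }
  corpus <- znorm_corpus(sketches)
  labels <- extend_labels(similarity, family)
  enc <- train_encoder(corpus$inputs, labels, encoder, train)

  say("stage 4/4: building the index")
  parent_inputs <- map(parent_sketches, apply_znorm, stats = corpus$stats)
  embeddings <- encode(parent_inputs, enc)
  index <- advisor_index(
    sample_ids = samples$sample_id,
    embeddings = embeddings,
    theta_hats = map(fits, "theta_hat"),
    best_losses = map_dbl(fits, "y_hat"),
    space = space,
    norm_stats = corpus$stats,
    encoder = enc,
    sketch_params = sp
  )
  out <- structure(
    list(index = index, traces = traces, similarity = similarity,
         encoder = enc, dropped = dropped,
         fits = tibble(sample_id = samples$sample_id,
                       best_loss = map_dbl(fits, "y_hat"),
                       n_evals = map_dbl(traces, nrow))),
    class = "asm_advisor"
  )
  if (!is.null(out_dir)) persist_advisor(out, out_dir)
  out
}

persist_advisor <- function(advisor, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trace_dir <- file.path(out_dir, "traces")
  dir.create(trace_dir, showWarnings = FALSE)
  for (tr in advisor$traces) {
    write_trace(tr, file.path(trace_dir,
                              paste0(attr(tr, "sample_id"), ".tsv")))
  }
  write_matrix_tsv(advisor$similarity, file.path(out_dir, "similarity.tsv"))
  write_index(advisor$index, file.path(out_dir, "index"))
  invisible(out_dir)
}

#' Advise a new sample
#'
#' Sketch-normalize-embed the query, retrieve the `p` most similar
#' representatives, and report their best parameter vectors; when the
#' sample's objective is supplied, each candidate is evaluated and the
#' argmin (the advising oracle) is flagged.
#'
#' @param x Reads (character vector), a `sketch_set`, or an embedding.
#' @param index An [advisor_index()] or an `asm_advisor`.
#' @param p Advisor-set size (the reported sets in the field are 1, 5 and
#'   30).
#' @param objective Optional `asm_objective` for oracle evaluation.
#' @return A tibble with one row per candidate (`rank`, `sample_id`,
#'   `cosine`, `theta`, and with an objective also `loss` and `picked`).
#' @export
advise <- function(x, index, p = 5, objective = NULL) {
  if (inherits(index, "asm_advisor")) index <- index$index
  adv <- advisor_set(x, index, p)
  if (!is.null(objective)) {
    pick <- oracle_pick(adv, objective)
    adv <- pick$evaluations
    adv$picked <- seq_len(nrow(adv)) == which.min(adv$loss)
  }
  adv
}

#' @export
print.asm_advisor <- function(x, ...) {
  cat("<asm_advisor>", length(x$index$sample_ids), "representatives",
      if (length(x$dropped)) paste0("(", length(x$dropped),
                                    " dropped by AUC filter)") else "",
      "\n")
  invisible(x)
}

#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sensitivity,
                                       y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "sensitivity", y = "precision")
}
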