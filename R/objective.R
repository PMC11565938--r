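#' Wrap a loss function as an evaluation objective
#'
#' An objective is a callable mapping a named parameter vector to a scalar
#' loss (negative AUC for real assemblies, so lower is better). The wrapper
#' carries metadata used by traces and the advisor.
#'
#' @param fn Function taking a named numeric parameter vector, returning a
#'   finite scalar loss.
#' @param sample_id Label of the sample this objective evaluates.
#' @param space The [param_space()] the objective is defined over.
#' @return A function of class `asm_objective`.
#' @export
new_objective <- function(fn, sample_id = "sample", space = NULL) {
  stopifnot(is.function(fn))
  obj <- function(theta) {
    y <- fn(theta)
    if (!is.numeric(y) || length(y) != 1 || !is.finite(y)) {
      abort(paste0("objective for sample \"", sample_id,
                   "\" returned a non-finite loss"))
    }
    y
  }
  attr(obj, "sample_id") <- sample_id
  attr(obj, "space") <- space
  class(obj) <- c("asm_objective", "function")
  obj
}

#' Deterministic synthetic assembly objective with a planted optimum
#'
#' Builds a smooth, mildly multimodal stand-in for the assembler loss
#' `f_R(theta) = -AUC`, with a known global minimizer. Each coordinate
#' contributes a heavy-tailed (Cauchy-shaped) bump centered on the planted
#' optimum — so the loss keeps a usable gradient signal across the whole
#' search domain — plus a small secondary bump three length-scales away,
#' which creates shallow local optima. The loss is a weighted mix of the
#' mean and the product of the per-coordinate scores, so it is separable
#' enough for coordinate ascent to make progress but not exactly
#' separable. The range is contained in `[-1, 0]` and the global minimum
#' value is exactly `-1`, attained only at `planted_opt`.
#'
#' @param planted_opt Named parameter vector; the global minimizer. Integer
#'   coordinates must be integral.
#' @param space The [param_space()].
#' @param width_scale Multiplier on the per-coordinate length scales
#'   (`max(default, 1) / 2` before scaling). Larger values flatten the
#'   landscape.
#' @param seed Seed controlling small per-sample jitter of the length
#'   scales; the returned function itself is deterministic.
#' @param sample_id Label for the objective.
#' @return An `asm_objective` with attributes `planted_opt` and `widths`.
#' @examples
#' sp <- builtin_space("stringtie2")
#' f <- synthetic_objective(default_vector(sp), sp, seed = 1)
#' f(default_vector(sp))
#' @export
synthetic_objective <- function(planted_opt, space, width_scale = 1,
                                seed = 1, sample_id = "synthetic") {
  stopifnot(inherits(space, "param_space"))
  planted_opt <- conform_theta(planted_opt, space$name)
  if (!validate_vector(space, planted_opt,
                       domain = adjust_domain(initial_domain(space),
                                              planted_opt))) {
    abort("planted_opt is not a valid vector for this space")
  }
  base_width <- ifelse(space$kind == "binary", 0.5,
                       pmax(space$default, 1) / 2)
  rng <- local_rng(seed)
  jitter <- exp(rng(length(base_width), min = -0.2, max = 0.2))
  widths <- base_width * jitter * width_scale
  g0 <- 1 + 0.15 / 82
  fn <- function(theta) {
    theta <- conform_theta(theta, space$name)
    d <- (theta - planted_opt) / widths
    u <- d^2
    score <- (1 / (1 + u) + 0.15 / (1 + (u - 9)^2)) / g0
    -(0.9 * mean(score) + 0.1 * prod(score))
  }
  obj <- new_objective(fn, sample_id = sample_id, space = space)
  attr(obj, "planted_opt") <- planted_opt
  attr(obj, "widths") <- widths
  obj
}

# Draw uniform variates from a private RNG stream without touching the
# global .Random.seed.
local_rng <- function(seed) {
  state <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  state$seed <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  function(n, min = 0, max = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state$seed, envir = globalenv())
    out <- runif(n, min, max)
    state$seed <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
}

#' Objective that drives an external transcript assembler
#'
#' Builds an objective that, for each queried parameter vector, writes the
#' parameters as command-line flags, runs the assembler on an aligned
#' sample, parses the emitted GTF and returns the negative
#' precision-sensitivity AUC against a reference annotation. Evaluations
#' are cached by parameter vector, so repeated queries are free and
#' identical.
#'
#' @param sample_path Aligned reads (SAM/BAM), passed through to the
#'   assembler untouched.
#' @param assembler `"scallop"` or `"stringtie2"` (selects the flag
#'   convention), or a function `(theta, sample_path, out_gtf)` returning
#'   the full command-line character vector.
#' @param annotation Reference annotation GTF/GFF path (parsed once).
#' @param min_coverage Abundance cutoff for evaluation.
#' @param executable Path to the assembler binary; defaults to the
#'   assembler name.
#' @param workdir Directory for per-evaluation GTF output.
#' @param sample_id Label for the objective.
#' @return An `asm_objective`.
#' @export
external_assembler_objective <- function(sample_path, assembler, annotation,
                                         min_coverage = 0,
                                         executable = NULL,
                                         workdir = tempfile("asmtune-"),
                                         sample_id = basename(sample_path)) {
  refs <- read_gtf(annotation, role = "reference")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  cache <- new.env(parent = emptyenv())
  build_cmd <- if (is.function(assembler)) {
    assembler
  } else {
    exe <- executable %||% assembler
    switch(tolower(assembler),
      scallop = function(theta, sample_path, out_gtf) {
        c(exe, "-i", sample_path, "-o", out_gtf,
          as.vector(rbind(paste0("--", names(theta)),
                          format_flag_value(theta))))
      },
      stringtie2 = function(theta, sample_path, out_gtf) {
        flags <- character(0)
        for (nm in names(theta)) {
          if (nm %in% c("t", "u")) {
            if (theta[[nm]] == 1) flags <- c(flags, paste0("-", nm))
          } else {
            flags <- c(flags, paste0("-", nm), format_flag_value(theta[nm]))
          }
        }
        c(exe, sample_path, "-o", out_gtf, flags)
      },
      abort(paste0("no flag convention for assembler \"", assembler, "\""))
    )
  }
  fn <- function(theta) {
    key <- paste(format(theta, digits = 15), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    out_gtf <- file.path(workdir, paste0("eval-", length(ls(cache)) + 1, ".gtf"))
    cmd <- build_cmd(theta, sample_path, out_gtf)
    log <- suppressWarnings(
      system2(cmd[1], cmd[-1], stdout = TRUE, stderr = TRUE)
    )
    status <- attr(log, "status") %||% 0L
    if (status != 0 || !file.exists(out_gtf)) {
      abort(paste0("assembler run failed (exit ", status, "):\n",
                   paste(utils::tail(log, 20), collapse = "\n")))
    }
    preds <- read_gtf(out_gtf, role = "predicted")
    y <- assembly_loss(preds, refs, min_coverage = min_coverage)
    cache[[key]] <- y
    y
  }
  new_objective(fn, sample_id = sample_id)
}

format_flag_value <- function(x) {
  format(unname(x), trim = TRUE, scientific = FALSE, digits = 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
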