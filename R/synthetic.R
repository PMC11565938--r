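#' Generate a grouped synthetic sample universe
#'
#' Builds a desk-scale stand-in for a universe of RNA-seq samples with the
#' structure the advising pipeline exploits: samples fall into groups, all
#' samples of a group share one planted optimal parameter vector (their
#' synthetic objectives are minimized exactly there, with per-sample
#' jitter of the loss landscape's length scales), and the reads of
#' same-group samples are drawn from the same group reference sequence
#' (with per-sample mutations), so their k-mer content is correlated
#' within the group and essentially unrelated across groups. Everything is
#' a pure function of the seed.
#'
#' @param n_groups,samples_per_group Universe size.
#' @param space The [param_space()] the objectives are defined over.
#' @param read_params List with `ref_length` (group reference length in
#'   bases), `read_length`, `coverage` (mean per-base read coverage) and
#'   `mutation_rate` (per-base substitution rate per sample).
#' @param seed Master seed.
#' @return A list of class `synthetic_universe` with `samples` (a tibble
#'   with `sample_id`, `group`, `reads` list column and `objective` list
#'   column), `groups` (a tibble with `group`, `opt` list column,
#'   `reference`), plus `space` and `seed`.
#' @export
make_universe <- function(n_groups = 4, samples_per_group = 6, space,
                          read_params = list(ref_length = 2000,
                                             read_length = 100,
                                             coverage = 4,
                                             mutation_rate = 0.01),
                          seed = 1) {
  stopifnot(n_groups >= 1, samples_per_group >= 1,
            inherits(space, "param_space"))
  rp <- modifyList(list(ref_length = 2000, read_length = 100, coverage = 4,
                        mutation_rate = 0.01), read_params)
  with_seed(seed, {
    domain <- initial_domain(space)
    groups <- map(seq_len(n_groups), function(g) {
      opt <- random_lattice_point(space, domain)
      reference <- paste(sample(c("A", "C", "G", "T"), rp$ref_length,
                                replace = TRUE), collapse = "")
      list(group = g, opt = opt, reference = reference)
    })
    samples <- map(seq_len(n_groups * samples_per_group), function(i) {
      g <- ((i - 1) %/% samples_per_group) + 1
      sample_id <- sprintf("g%02d_s%02d", g,
                           ((i - 1) %% samples_per_group) + 1)
      mutated <- mutate_sequence(groups[[g]]$reference, rp$mutation_rate)
      reads <- simulate_reads(mutated, rp$read_length, rp$coverage)
      objective <- synthetic_objective(groups[[g]]$opt, space,
                                       seed = seed * 1000 + i,
                                       sample_id = sample_id)
      list(sample_id = sample_id, group = g, reads = reads,
           objective = objective)
    })
    structure(
      list(
        samples = tibble(
          sample_id = map_chr(samples, "sample_id"),
          group = map_dbl(samples, "group"),
          reads = map(samples, "reads"),
          objective = map(samples, "objective")
        ),
        groups = tibble(
          group = map_dbl(groups, "group"),
          opt = map(groups, "opt"),
          reference = map_chr(groups, "reference")
        ),
        space = space, seed = seed, read_params = rp
      ),
      class = "synthetic_universe"
    )
  })
}

random_lattice_point <- function(space, domain) {
  theta <- map2_dbl(seq_len(nrow(space)), space$kind, function(i, kind) {
    switch(kind,
      binary = sample(c(0, 1), 1),
      integer = sample(seq(ceiling(domain$lo[i]), floor(domain$hi[i])), 1),
      runif(1, domain$lo[i], domain$hi[i])
    )
  })
  setNames(theta, space$name)
}

mutate_sequence <- function(reference, rate) {
  if (rate <= 0) return(reference)
  bases <- strsplit(reference, "")[[1]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
  }
  paste(bases, collapse = "")
}

simulate_reads <- function(reference, read_length, coverage) {
  L <- nchar(reference)
  read_length <- min(read_length, L)
  n_reads <- max(1, round(coverage * L / read_length))
  starts <- sample(seq_len(L - read_length + 1), n_reads, replace = TRUE)
  substring(reference, starts, starts + read_length - 1)
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat("<synthetic_universe>", nrow(x$groups), "groups x",
      nrow(x$samples) / nrow(x$groups), "samples, seed", x$seed, "\n")
  invisible(x)
}

#' Hand-constructed toy transcript sets
#'
#' Small predicted/reference GTF pairs covering the evaluation rules:
#' `"perfect"` (predictions identical to the annotation),
#' `"shifted_terminal"` (intron chains match but terminal exon ends
#' differ), `"boundary80"` (two single-exon predictions, one exactly at
#' and one just under the 80% overlap threshold), `"tie"` (equal
#' abundances, exercising cutoff tie handling) and `"mixed"` (three
#' predictions with abundances 5, 3, 1 of which the first and last are
#' correct, against two references).
#'
#' @param case_name One of the cases above.
#' @return A list with `pred` and `ref` transcript sets.
#' @export
make_toy_gtf <- function(case_name) {
  two_exon <- function(id, chrom, s1, e1, s2, e2, ab = NA, strand = "+") {
    tibble(transcript_id = id, chrom = chrom, strand = strand,
           start = c(s1, s2), end = c(e1, e2), abundance = ab)
  }
  one_exon <- function(id, chrom, s, e, ab = NA, strand = "+") {
    tibble(transcript_id = id, chrom = chrom, strand = strand,
           start = s, end = e, abundance = ab)
  }
  case <- switch(case_name,
    perfect = list(
      pred = bind_rows(two_exon("p1", "chr1", 0, 100, 200, 300, 5),
                       two_exon("p2", "chr1", 400, 500, 600, 700, 3)),
      ref = bind_rows(two_exon("r1", "chr1", 0, 100, 200, 300),
                      two_exon("r2", "chr1", 400, 500, 600, 700))
    ),
    shifted_terminal = list(
      pred = two_exon("p1", "chr1", 10, 100, 200, 290, 4),
      ref = two_exon("r1", "chr1", 0, 100, 200, 300)
    ),
    boundary80 = list(
      pred = bind_rows(one_exon("p1", "chr1", 0, 80, 2),
                       one_exon("p2", "chr1", 200, 279, 2)),
      ref = bind_rows(one_exon("r1", "chr1", 0, 100),
                      one_exon("r2", "chr1", 200, 300))
    ),
    tie = list(
      pred = bind_rows(two_exon("p1", "chr1", 0, 100, 200, 300, 2),
                       two_exon("p2", "chr1", 0, 90, 210, 300, 2),
                       two_exon("p3", "chr1", 400, 500, 600, 700, 2)),
      ref = bind_rows(two_exon("r1", "chr1", 0, 100, 200, 300),
                      two_exon("r2", "chr1", 400, 500, 600, 700))
    ),
    mixed = list(
      pred = bind_rows(two_exon("p1", "chr1", 0, 100, 200, 300, 5),
                       two_exon("p2", "chr1", 0, 100, 210, 300, 3),
                       two_exon("p3", "chr1", 400, 500, 600, 700, 1)),
      ref = bind_rows(two_exon("r1", "chr1", 0, 100, 200, 300),
                      two_exon("r2", "chr1", 400, 500, 600, 700))
    ),
    abort(paste0("unknown toy case \"", case_name, "\""))
  )
  list(pred = transcript_set(case$pred, role = "predicted"),
       ref = transcript_set(case$ref, role = "reference"))
}

#' Canned trace with a lookup-table surrogate
#'
#' Builds a [bo_trace()] from explicit (parameter vector, value) pairs
#' together with a surrogate whose posterior mean at those points is
#' forced to the given values — a fixture for exercising the normrank
#' pipeline without fitting a GP.
#'
#' @param mu_values Posterior-mean values to plant (also used as the trace
#'   losses).
#' @param thetas List of named parameter vectors (equal length).
#' @param sample_id Trace label.
#' @param space Optional [param_space()].
#' @return A list with `trace` and `surrogate` (class
#'   `lookup_surrogate`).
#' @export
make_trace <- function(mu_values, thetas, sample_id = "fixture",
                       space = NULL) {
  if (length(mu_values) != length(thetas)) abort("length mismatch")
  trace <- bo_trace(thetas, mu_values, phase = "fixture",
                    sample_id = sample_id, space = space)
  keys <- map_chr(thetas, theta_key)
  surrogate <- structure(
    list(table = setNames(as.numeric(mu_values), keys)),
    class = "lookup_surrogate"
  )
  list(trace = trace, surrogate = surrogate)
}

theta_key <- function(theta) {
  paste(format(as.numeric(theta), digits = 15, trim = TRUE), collapse = ",")
}

#' @export
posterior_mean.lookup_surrogate <- function(object, theta, ...) {
  if (is.numeric(theta) && !is.matrix(theta)) theta <- list(theta)
  if (is.matrix(theta)) {
    theta <- map(seq_len(nrow(theta)), function(i) theta[i, ])
  }
  keys <- map_chr(theta, theta_key)
  if (any(!keys %in% names(object$table))) {
    abort("lookup surrogate queried at an unknown point")
  }
  unname(object$table[keys])
}
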