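#' Canonical k-mer counts of a read set
#'
#' Decomposes every read into its length-`k` windows, canonicalizes each
#' (lexicographic minimum of the k-mer and its reverse complement, so the
#' result is strand-neutral) and counts multiplicities. Windows containing
#' non-ACGT symbols are skipped; reads shorter than `k` contribute
#' nothing.
#'
#' @param reads Character vector of read sequences.
#' @param k k-mer length (default 21).
#' @return A tibble with columns `kmer` and `count`.
#' @export
kmerize <- function(reads, k = 21) {
  if (k < 1) abort("k must be >= 1")
  df <- .count_canonical_kmers(as.character(reads), as.integer(k))
  arrange(as_tibble(df), .data$kmer)
}

#' Hash k-mers
#'
#' Deterministic 64-bit MurmurHash3-style hash of the k-mer bytes,
#' truncated to 53 bits so values are exact in doubles.
#'
#' @param kmers Character vector.
#' @param seed Integer hash seed.
#' @return Numeric vector of hash values.
#' @export
hash_kmers <- function(kmers, seed = 42) {
  .hash_kmers(as.character(kmers), as.numeric(seed))
}

#' MinHash sketch of an RNA-seq sample
#'
#' Counts canonical k-mers, drops those occurring fewer than `min_count`
#' times, hashes the survivors, and keeps the `s` smallest distinct hash
#' values together with the multiplicity of their k-mers. The sketch is
#' the sample's set representation: each element is the pair
#' (hash value, k-mer count).
#'
#' @param reads Character vector of read sequences.
#' @param k k-mer length (default 21, the Mash default).
#' @param s Sketch size (default 1000).
#' @param min_count Minimum k-mer multiplicity (default 2).
#' @param seed Hash seed; sketches are only comparable at equal `k` and
#'   seed.
#' @return A tibble of class `sketch_set` with columns `hash` (ascending)
#'   and `count`, and attributes `k`, `s`, `min_count`, `seed` and
#'   `n_eligible` (number of distinct k-mers that passed the count
#'   filter).
#' @export
minhash_sketch <- function(reads, k = 21, s = 1000, min_count = 2,
                           seed = 42) {
  stopifnot(k >= 1, s >= 1, min_count >= 1)
  tab <- kmerize(reads, k)
  tab <- tab[tab$count >= min_count, ]
  tab$hash <- hash_kmers(tab$kmer, seed)
  tab <- arrange(tab, .data$hash)
  keep <- head(seq_len(nrow(tab)), s)
  out <- tibble(hash = tab$hash[keep], count = tab$count[keep])
  attr(out, "k") <- k
  attr(out, "s") <- s
  attr(out, "min_count") <- min_count
  attr(out, "seed") <- seed
  attr(out, "n_eligible") <- nrow(tab)
  class(out) <- c("sketch_set", class(out))
  out
}

#' Mash distance between two sketches
#'
#' Estimates the Jaccard index of the two samples' k-mer sets from the
#' bottom-`s` sketch of their union (the standard Mash estimator) and
#' converts it to a k-mer mutation distance
#' `-(1/k) * log(2 j / (1 + j))`. A zero Jaccard estimate (disjoint
#' sketches) is reported as the saturated distance 1.
#'
#' @param a,b `sketch_set` objects built with the same `k` and hash seed.
#' @return A scalar distance in `[0, 1]`.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "sketch_set"), inherits(b, "sketch_set"))
  if (attr(a, "k") != attr(b, "k") || attr(a, "seed") != attr(b, "seed")) {
    abort("sketches use different k or hash seed and are not comparable")
  }
  s <- min(attr(a, "s"), attr(b, "s"))
  merged <- sort(unique(c(a$hash, b$hash)))
  merged <- head(merged, s)
  shared <- sum(merged %in% a$hash & merged %in% b$hash)
  j <- shared / length(merged)
  if (j == 0) return(1)
  min(-log(2 * j / (1 + j)) / attr(a, "k"), 1)
}

#' z-score normalization of a sketch corpus
#'
#' Computes per-dimension (hash value, k-mer count) means and standard
#' deviations pooled over every element of every sketch in the training
#' corpus, and maps each element to its z-scores. The statistics are
#' returned so new samples can be normalized identically at advising
#' time.
#'
#' @param sketches List of `sketch_set` objects.
#' @return A list of class `znorm_corpus` with `inputs` (list of n-by-2
#'   matrices of normalized (hash, count) rows) and `stats` (a tibble with
#'   `dim`, `mean`, `sd`).
#' @export
znorm_corpus <- function(sketches) {
  if (length(sketches) == 0) abort("empty sketch corpus")
  all_h <- unlist(map(sketches, "hash"))
  all_c <- unlist(map(sketches, "count"))
  stats <- tibble(
    dim = c("hash", "count"),
    mean = c(mean(all_h), mean(all_c)),
    sd = c(sd(all_h), sd(all_c))
  )
  if (any(!is.finite(stats$sd) | stats$sd < 1e-12)) {
    abort("zero-variance dimension in sketch corpus; cannot z-normalize")
  }
  inputs <- map(sketches, apply_znorm, stats = stats)
  structure(list(inputs = inputs, stats = stats), class = "znorm_corpus")
}

#' @rdname znorm_corpus
#' @param sketch A single `sketch_set`.
#' @param stats The `stats` tibble from a previous [znorm_corpus()] call.
#' @export
apply_znorm <- function(sketch, stats) {
  if (inherits(stats, "znorm_corpus")) stats <- stats$stats
  cbind(
    hash = (sketch$hash - stats$mean[stats$dim == "hash"]) /
      stats$sd[stats$dim == "hash"],
    count = (sketch$count - stats$mean[stats$dim == "count"]) /
      stats$sd[stats$dim == "count"]
  )
}

#' Read sequences from FASTA/FASTQ
#'
#' @param path File path; `.fastq`/`.fq` (optionally gzipped) is read as
#'   FASTQ, anything else as FASTA.
#' @return Character vector of sequences.
#' @export
read_reads <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA/FASTQ requires the Biostrings package")
  }
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Persist / load a sketch as JSON
#'
#' @param sketch A `sketch_set`.
#' @param path Output file.
#' @export
write_sketch <- function(sketch, path) {
  obj <- list(
    k = attr(sketch, "k"), s = attr(sketch, "s"),
    min_count = attr(sketch, "min_count"), seed = attr(sketch, "seed"),
    n_eligible = attr(sketch, "n_eligible"),
    hash = sketch$hash, count = sketch$count
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- tibble(hash = as.numeric(obj$hash), count = as.numeric(obj$count))
  attr(out, "k") <- obj$k
  attr(out, "s") <- obj$s
  attr(out, "min_count") <- obj$min_count
  attr(out, "seed") <- obj$seed
  attr(out, "n_eligible") <- obj$n_eligible
  class(out) <- c("sketch_set", class(out))
  out
}
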