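#' Build a transcript set
#'
#' A transcript set is a tibble with one row per transcript and columns
#' `transcript_id`, `chrom`, `strand` (`"+"`, `"-"` or `"."`), `exons`
#' (a list column of two-column matrices of 0-based half-open intervals,
#' sorted and non-overlapping) and `abundance` (expression/coverage;
#' `NA` allowed for reference sets).
#'
#' @param transcripts A data frame with the columns above, or a flat exon
#'   table with columns `transcript_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open) and optionally `abundance`, which is nested into
#'   one row per transcript.
#' @param role `"predicted"` or `"reference"`.
#' @return A tibble of class `transcript_set`.
#' @examples
#' transcript_set(data.frame(
#'   transcript_id = c("t1", "t1"), chrom = "chr1", strand = "+",
#'   start = c(0, 200), end = c(100, 300), abundance = 5
#' ), role = "predicted")
#' @export
transcript_set <- function(transcripts, role = c("predicted", "reference")) {
  role <- match.arg(role)
  tx <- as_tibble(transcripts)
  if ("start" %in% names(tx) && !"exons" %in% names(tx)) {
    tx <- nest_exons(tx)
  }
  required <- c("transcript_id", "chrom", "strand", "exons")
  missing_cols <- setdiff(required, names(tx))
  if (length(missing_cols) > 0) {
    abort(paste0("transcript table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"abundance" %in% names(tx)) tx$abundance <- NA_real_
  if (!all(tx$strand %in% c("+", "-", "."))) {
    abort("strand must be one of \"+\", \"-\", \".\"")
  }
  tx$exons <- map(tx$exons, check_exons)
  if (role == "predicted" && any(!is.na(tx$abundance) & tx$abundance < 0)) {
    abort("abundances must be nonnegative")
  }
  out <- tx[, c("transcript_id", "chrom", "strand", "exons", "abundance")]
  attr(out, "role") <- role
  class(out) <- c("transcript_set", class(out))
  out
}

nest_exons <- function(tx) {
  tx <- arrange(tx, .data$transcript_id, .data$start)
  grouped <- group_by(tx, .data$transcript_id)
  out <- summarise(
    grouped,
    chrom = .data$chrom[1],
    strand = .data$strand[1],
    exons = list(cbind(start = .data$start, end = .data$end)),
    abundance = if ("abundance" %in% names(tx)) .data$abundance[1] else NA_real_,
    .groups = "drop"
  )
  out
}

check_exons <- function(m) {
  m <- matrix(as.numeric(m), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (nrow(m) < 1) abort("a transcript needs at least one exon")
  if (any(m[, 2] <= m[, 1])) abort("exon end must exceed exon start")
  if (nrow(m) > 1) {
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] < m[-nrow(m), 2])) abort("exons must be non-overlapping")
  }
  m
}

n_exons <- function(set) map_dbl(set$exons, nrow)

intron_chain <- function(exons) {
  n <- nrow(exons)
  if (n < 2) return(matrix(numeric(0), ncol = 2))
  cbind(start = exons[-n, 2], end = exons[-1, 1])
}

chain_key <- function(chrom, exons) {
  ic <- intron_chain(exons)
  paste0(chrom, "|", paste(ic[, 1], ic[, 2], sep = "-", collapse = ";"))
}

strand_compatible <- function(a, b) a == "." | b == "." | a == b

#' Read transcripts from a GTF/GFF file
#'
#' Imports exon features with `rtracklayer`, converting the 1-based
#' inclusive file coordinates to the internal 0-based half-open convention.
#' Abundance is taken from the first of the given attributes present
#' (assembler GTFs usually write `cov`, `FPKM` or `TPM`).
#'
#' @param path GTF or GFF file.
#' @param role Passed to [transcript_set()].
#' @param abundance_attr Attribute names to try, in order, for abundance.
#' @return A `transcript_set`.
#' @export
read_gtf <- function(path, role = c("predicted", "reference"),
                     abundance_attr = c("cov", "FPKM", "TPM")) {
  role <- match.arg(role)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) abort(paste0("no exon features found in ", path))
  md <- as.data.frame(gr)
  ab <- rep(NA_real_, nrow(md))
  for (attr_name in abundance_attr) {
    if (attr_name %in% names(md)) {
      vals <- suppressWarnings(as.numeric(md[[attr_name]]))
      ab[is.na(ab)] <- vals[is.na(ab)]
    }
  }
  tx <- tibble(
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(md$seqnames),
    strand = ifelse(as.character(md$strand) == "*", ".",
                    as.character(md$strand)),
    start = md$start - 1,
    end = md$end,
    abundance = ab
  )
  transcript_set(tx, role = role)
}

#' Write a transcript set to GTF
#'
#' @param set A `transcript_set`.
#' @param path Output file.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(set, path, source = "asmtune") {
  stopifnot(inherits(set, "transcript_set"))
  flat <- unnest_exons(set)
  attrs <- paste0(
    "gene_id \"", flat$transcript_id, "\"; transcript_id \"",
    flat$transcript_id, "\";",
    ifelse(is.na(flat$abundance), "",
           paste0(" cov \"", format(flat$abundance, trim = TRUE), "\";"))
  )
  lines <- paste(flat$chrom, source, "exon", flat$start + 1, flat$end, ".",
                 ifelse(flat$strand == ".", ".", flat$strand), ".", attrs,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Flatten a transcript set to one row per exon
#'
#' @param set A `transcript_set`.
#' @return A tibble with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open) and `abundance`.
#' @export
unnest_exons <- function(set) {
  rows <- map(seq_len(nrow(set)), function(i) {
    ex <- set$exons[[i]]
    tibble(
      transcript_id = set$transcript_id[i],
      chrom = set$chrom[i],
      strand = set$strand[i],
      start = ex[, 1],
      end = ex[, 2],
      abundance = set$abundance[i]
    )
  })
  bind_rows(rows)
}
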