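#' Transcript-level correctness calls against a reference annotation
#'
#' Implements the gffcompare-style matching rules used to score transcript
#' assemblies: a predicted multi-exon transcript is correct iff its ordered
#' intron chain exactly equals that of a multi-exon reference transcript on
#' the same chromosome and a compatible strand (terminal exon ends are
#' ignored); a predicted single-exon transcript is correct iff it overlaps
#' at least `single_exon_frac` of the length of some single-exon reference
#' transcript. Matching is one-to-one: each reference transcript validates
#' at most one prediction, so surplus duplicates count as incorrect.
#' Predictions claim references greedily in order of decreasing abundance
#' (ties by input order), which makes the calls consistent across every
#' abundance cutoff of the precision-sensitivity sweep.
#'
#' @param preds,refs `transcript_set` objects (reference nonempty).
#' @param single_exon_frac Minimum fraction of the reference length that a
#'   single-exon prediction must overlap (default 0.8; the comparison is
#'   `overlap >= frac * ref_length`, so the boundary counts).
#' @return `preds` with a logical `correct` column appended.
#' @export
match_transcripts <- function(preds, refs, single_exon_frac = 0.8) {
  stopifnot(inherits(preds, "transcript_set"), inherits(refs, "transcript_set"))
  if (nrow(refs) == 0) abort("reference transcript set is empty")
  np <- nrow(preds)
  correct <- logical(np)
  if (np == 0) {
    out <- preds
    out$correct <- logical(0)
    return(out)
  }

  ref_nex <- n_exons(refs)
  ref_used <- logical(nrow(refs))
  ref_keys <- vapply(seq_len(nrow(refs)), function(j) {
    if (ref_nex[j] >= 2) chain_key(refs$chrom[j], refs$exons[[j]]) else NA_character_
  }, character(1))

  ab <- ifelse(is.na(preds$abundance), 0, preds$abundance)
  ord <- order(-ab, seq_len(np))
  pred_nex <- n_exons(preds)

  for (i in ord) {
    if (pred_nex[i] >= 2) {
      key <- chain_key(preds$chrom[i], preds$exons[[i]])
      cand <- which(!ref_used & !is.na(ref_keys) & ref_keys == key &
                      strand_compatible(preds$strand[i], refs$strand))
      if (length(cand) > 0) {
        ref_used[cand[1]] <- TRUE
        correct[i] <- TRUE
      }
    } else {
      ex <- preds$exons[[i]]
      cand <- which(!ref_used & ref_nex == 1 & refs$chrom == preds$chrom[i] &
                      strand_compatible(preds$strand[i], refs$strand))
      if (length(cand) > 0) {
        ref_len <- map_dbl(refs$exons[cand], function(m) m[1, 2] - m[1, 1])
        ov <- map_dbl(refs$exons[cand], function(m) {
          max(0, min(ex[1, 2], m[1, 2]) - max(ex[1, 1], m[1, 1]))
        })
        ok <- ov >= single_exon_frac * ref_len
        if (any(ok)) {
          best <- cand[ok][which.max(ov[ok] / ref_len[ok])]
          ref_used[best] <- TRUE
          correct[i] <- TRUE
        }
      }
    }
  }
  out <- preds
  out$correct <- correct
  out
}

#' Does a multi-exon prediction match some reference intron chain?
#'
#' @param pred A one-row `transcript_set` (or a row index into `preds`)
#'   with at least two exons.
#' @param refs Reference `transcript_set`.
#' @return `TRUE`/`FALSE`.
#' @export
match_multi_exon <- function(pred, refs) {
  stopifnot(nrow(pred) == 1)
  if (n_exons(pred) < 2) abort("match_multi_exon needs a multi-exon prediction")
  key <- chain_key(pred$chrom[1], pred$exons[[1]])
  hits <- vapply(seq_len(nrow(refs)), function(j) {
    nrow(refs$exons[[j]]) >= 2 &&
      strand_compatible(pred$strand[1], refs$strand[j]) &&
      chain_key(refs$chrom[j], refs$exons[[j]]) == key
  }, logical(1))
  any(hits)
}

#' Does a single-exon prediction overlap a reference sufficiently?
#'
#' @inheritParams match_multi_exon
#' @inheritParams match_transcripts
#' @export
match_single_exon <- function(pred, refs, single_exon_frac = 0.8) {
  stopifnot(nrow(pred) == 1)
  if (n_exons(pred) != 1) abort("match_single_exon needs a single-exon prediction")
  ex <- pred$exons[[1]]
  hits <- vapply(seq_len(nrow(refs)), function(j) {
    m <- refs$exons[[j]]
    nrow(m) == 1 && refs$chrom[j] == pred$chrom[1] &&
      strand_compatible(pred$strand[1], refs$strand[j]) &&
      max(0, min(ex[1, 2], m[1, 2]) - max(ex[1, 1], m[1, 1])) >=
        single_exon_frac * (m[1, 2] - m[1, 1])
  }, logical(1))
  any(hits)
}

#' Sensitivity and precision of a predicted transcript set
#'
#' Sensitivity is the number of correct predictions divided by the number of
#' reference transcripts; precision is correct predictions over total
#' predictions (0 when there are no predictions).
#'
#' @inheritParams match_transcripts
#' @return A one-row tibble with `n_pred`, `n_ref`, `correct`,
#'   `sensitivity`, `precision`.
#' @export
precision_sensitivity <- function(preds, refs, single_exon_frac = 0.8) {
  matched <- match_transcripts(preds, refs, single_exon_frac)
  n_correct <- sum(matched$correct)
  tibble(
    n_pred = nrow(preds),
    n_ref = nrow(refs),
    correct = n_correct,
    sensitivity = n_correct / nrow(refs),
    precision = if (nrow(preds) == 0) 0 else n_correct / nrow(preds)
  )
}

#' Abundance-ranked precision-sensitivity curve
#'
#' Predictions with abundance below `min_coverage` are dropped, then the
#' remaining distinct abundances are swept as cutoffs from highest to
#' lowest; at each cutoff the predictions with abundance at or above it are
#' scored against the reference. Equal-abundance predictions enter and
#' leave the curve together.
#'
#' @inheritParams match_transcripts
#' @param min_coverage Abundance cutoff applied before the sweep
#'   (assembler defaults are 1.01 for Scallop and 1.0 for StringTie2;
#'   evaluation default here is 0).
#' @return A tibble of class `pr_curve` with columns `threshold`, `n_pred`,
#'   `correct`, `sensitivity`, `precision`, ordered by decreasing threshold.
#' @export
pr_curve <- function(preds, refs, min_coverage = 0, single_exon_frac = 0.8) {
  stopifnot(inherits(preds, "transcript_set"))
  if (nrow(refs) == 0) abort("reference transcript set is empty")
  ab <- ifelse(is.na(preds$abundance), 0, preds$abundance)
  keep <- ab >= min_coverage
  preds <- preds[keep, ]
  ab <- ab[keep]
  if (nrow(preds) == 0) {
    out <- tibble(threshold = numeric(0), n_pred = integer(0),
                  correct = integer(0), sensitivity = numeric(0),
                  precision = numeric(0))
    class(out) <- c("pr_curve", class(out))
    return(out)
  }
  matched <- match_transcripts(preds, refs, single_exon_frac)
  cuts <- sort(unique(ab), decreasing = TRUE)
  rows <- map(cuts, function(ct) {
    at <- ab >= ct
    nc <- sum(matched$correct[at])
    tibble(threshold = ct, n_pred = sum(at), correct = nc,
           sensitivity = nc / nrow(refs), precision = nc / sum(at))
  })
  out <- bind_rows(rows)
  class(out) <- c("pr_curve", class(out))
  out
}

#' Area under the precision-sensitivity curve
#'
#' Curve points are ordered by increasing sensitivity (ties by sweep order,
#' i.e. decreasing threshold); the area is the rectangle from sensitivity 0
#' to the first point at that point's precision, plus trapezoids between
#' consecutive points (`anchor = "first"`). With `anchor = "none"` the
#' leading rectangle is omitted.
#'
#' @inheritParams pr_curve
#' @param anchor How to close the curve at sensitivity 0.
#' @return A scalar in `[0, 1]`.
#' @export
auc <- function(preds, refs, min_coverage = 0, single_exon_frac = 0.8,
                anchor = c("first", "none")) {
  curve <- pr_curve(preds, refs, min_coverage, single_exon_frac)
  auc_from_curve(curve, anchor = anchor)
}

#' @rdname auc
#' @param curve A `pr_curve` tibble.
#' @export
auc_from_curve <- function(curve, anchor = c("first", "none")) {
  anchor <- match.arg(anchor)
  if (nrow(curve) == 0) return(0)
  ord <- order(curve$sensitivity, -curve$threshold)
  s <- curve$sensitivity[ord]
  p <- curve$precision[ord]
  area <- if (anchor == "first") s[1] * p[1] else 0
  if (length(s) > 1) {
    area <- area + sum(diff(s) * (head(p, -1) + p[-1]) / 2)
  }
  min(max(area, 0), 1)
}

#' Assembly loss: negative precision-sensitivity AUC
#'
#' @inheritParams auc
#' @return A scalar in `[-1, 0]`.
#' @export
assembly_loss <- function(preds, refs, min_coverage = 0,
                          single_exon_frac = 0.8) {
  -auc(preds, refs, min_coverage, single_exon_frac)
}
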