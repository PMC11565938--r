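# Shared fixtures and independent oracles.

toy_space2 <- function() {
  param_space(
    data.frame(name = c("a", "b"), kind = "integer", default = c(5, 5)),
    assembler = "toy2"
  )
}

toy_space3 <- function() {
  param_space(
    data.frame(name = c("a", "b", "c"),
               kind = c("integer", "integer", "float"),
               default = c(10, 20, 2)),
    assembler = "toy3"
  )
}

toy_space_mixed <- function() {
  param_space(
    data.frame(name = c("flag", "n", "x"),
               kind = c("binary", "integer", "float"),
               default = c(0, 10, 1.5)),
    assembler = "toymix"
  )
}

# flat exon-table constructor for transcripts
tx_rows <- function(id, chrom, exons, ab = NA, strand = "+") {
  tibble::tibble(
    transcript_id = id, chrom = chrom, strand = strand,
    start = vapply(exons, `[`, numeric(1), 1),
    end = vapply(exons, `[`, numeric(1), 2),
    abundance = ab
  )
}

# --- independent oracles ---------------------------------------------------

# Brute-force transcript correctness: for each cutoff recompute a maximal
# one-to-one matching by exhaustive assignment (feasible at toy sizes).
oracle_correct_count <- function(preds, refs, frac = 0.8) {
  np <- nrow(preds); nr <- nrow(refs)
  if (np == 0) return(0)
  compat <- matrix(FALSE, np, nr)
  for (i in seq_len(np)) {
    pe <- preds$exons[[i]]
    for (j in seq_len(nr)) {
      re <- refs$exons[[j]]
      if (!(preds$strand[i] == "." || refs$strand[j] == "." ||
            preds$strand[i] == refs$strand[j])) next
      if (preds$chrom[i] != refs$chrom[j]) next
      if (nrow(pe) >= 2 && nrow(re) >= 2) {
        pi_ <- cbind(pe[-nrow(pe), 2], pe[-1, 1])
        ri_ <- cbind(re[-nrow(re), 2], re[-1, 1])
        compat[i, j] <- nrow(pi_) == nrow(ri_) && all(pi_ == ri_)
      } else if (nrow(pe) == 1 && nrow(re) == 1) {
        ov <- max(0, min(pe[1, 2], re[1, 2]) - max(pe[1, 1], re[1, 1]))
        compat[i, j] <- ov >= frac * (re[1, 2] - re[1, 1])
      }
    }
  }
  # maximum bipartite matching by exhaustive recursion (tiny instances)
  best <- 0
  recurse <- function(i, used) {
    if (i > np) {
      return(0)
    }
    skip <- recurse(i + 1, used)
    take <- 0
    for (j in which(compat[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      take <- max(take, 1 + recurse(i + 1, used2))
    }
    max(skip, take)
  }
  recurse(1, rep(FALSE, nr))
}

# Independent PR/AUC sweep: enumerate every distinct abundance cutoff,
# recompute correctness from scratch, integrate with the documented rule.
oracle_auc <- function(preds, refs, min_coverage = 0, frac = 0.8) {
  ab <- ifelse(is.na(preds$abundance), 0, preds$abundance)
  preds <- preds[ab >= min_coverage, ]
  ab <- ab[ab >= min_coverage]
  if (nrow(preds) == 0) return(0)
  cuts <- sort(unique(ab), decreasing = TRUE)
  pts <- t(vapply(cuts, function(ct) {
    sub <- preds[ab >= ct, ]
    nc <- oracle_correct_count(sub, refs, frac)
    c(sens = nc / nrow(refs), prec = nc / nrow(sub), cut = ct)
  }, c(sens = 0, prec = 0, cut = 0)))
  ord <- order(pts[, "sens"], -pts[, "cut"])
  s <- unname(pts[ord, "sens"]); p <- unname(pts[ord, "prec"])
  area <- s[1] * p[1]
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      area <- area + (s[i] - s[i - 1]) * (p[i] + p[i - 1]) / 2
    }
  }
  area
}

# Brute-force canonical k-mer multiset of a read set.
oracle_kmers <- function(reads, k) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  out <- character(0)
  for (r in reads) {
    r <- toupper(r)
    if (nchar(r) < k) next
    for (i in 1:(nchar(r) - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- revcomp(km)
      out <- c(out, if (rc < km) rc else km)
    }
  }
  out
}

# random read sets with guaranteed duplicate coverage (counts >= 2)
random_reads <- function(n, len, seed, alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
  })
}

small_encoder_config <- function() {
  encoder_config(h_layers = c(2, 16, 16), g_layers = c(16, 16, 8))
}

expect_theta_equal <- function(theta, expected, tol = 1e-8) {
  expect_equal(unname(theta[names(expected)]), unname(expected),
               tolerance = tol)
}
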