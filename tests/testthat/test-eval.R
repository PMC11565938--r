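test_that("multi-exon matching compares intron chains only", {
  ref <- transcript_set(tx_rows("r1", "chr1", list(c(0, 100), c(200, 300))),
                        role = "reference")
  same <- transcript_set(tx_rows("p", "chr1", list(c(0, 100), c(200, 300)),
                                 ab = 1), role = "predicted")
  shifted <- transcript_set(tx_rows("p", "chr1", list(c(10, 100), c(200, 290)),
                                    ab = 1), role = "predicted")
  off <- transcript_set(tx_rows("p", "chr1", list(c(0, 100), c(201, 300)),
                                ab = 1), role = "predicted")
  expect_true(match_multi_exon(same, ref))
  expect_true(match_multi_exon(shifted, ref))   # terminal ends differ, chain equal
  expect_false(match_multi_exon(off, ref))
  # strand and chromosome must be compatible
  minus <- transcript_set(tx_rows("p", "chr1", list(c(0, 100), c(200, 300)),
                                  ab = 1, strand = "-"), role = "predicted")
  expect_false(match_multi_exon(minus, ref))
  dot <- transcript_set(tx_rows("p", "chr1", list(c(0, 100), c(200, 300)),
                                ab = 1, strand = "."), role = "predicted")
  expect_true(match_multi_exon(dot, ref))
})

test_that("single-exon matching flips exactly at 80% of reference length", {
  ref <- transcript_set(tx_rows("r1", "chr1", list(c(0, 100))),
                        role = "reference")
  at <- transcript_set(tx_rows("p", "chr1", list(c(0, 80)), ab = 1),
                       role = "predicted")
  under <- transcript_set(tx_rows("p", "chr1", list(c(0, 79)), ab = 1),
                          role = "predicted")
  full <- transcript_set(tx_rows("p", "chr1", list(c(0, 100)), ab = 1),
                         role = "predicted")
  expect_true(match_single_exon(full, ref))
  expect_true(match_single_exon(at, ref))      # boundary inclusive
  expect_false(match_single_exon(under, ref))

  # sweep overlap fractions: smallest correct fraction is 0.80
  fracs <- seq(0.70, 0.90, by = 0.01)
  hits <- vapply(fracs, function(f) {
    pred <- transcript_set(tx_rows("p", "chr1",
                                   list(c(0, round(100 * f))), ab = 1),
                           role = "predicted")
    match_single_exon(pred, ref)
  }, logical(1))
  expect_equal(min(fracs[hits]), 0.80)
})

test_that("precision and sensitivity count one-to-one matches", {
  # 3 predictions, 4 references, exactly 2 predictions correct
  refs <- transcript_set(dplyr::bind_rows(
    tx_rows("r1", "chr1", list(c(0, 100), c(200, 300))),
    tx_rows("r2", "chr1", list(c(400, 500), c(600, 700))),
    tx_rows("r3", "chr1", list(c(800, 900), c(1000, 1100))),
    tx_rows("r4", "chr2", list(c(0, 100)))
  ), role = "reference")
  preds <- transcript_set(dplyr::bind_rows(
    tx_rows("p1", "chr1", list(c(0, 100), c(200, 300)), ab = 5),
    tx_rows("p2", "chr1", list(c(0, 100), c(210, 300)), ab = 3),
    tx_rows("p3", "chr1", list(c(400, 500), c(600, 700)), ab = 1)
  ), role = "predicted")
  ps <- precision_sensitivity(preds, refs)
  expect_equal(ps$sensitivity, 0.5)
  expect_equal(ps$precision, 2 / 3, tolerance = 1e-12)

  # perfect assembly
  toy <- make_toy_gtf("perfect")
  ps2 <- precision_sensitivity(toy$pred, toy$ref)
  expect_equal(c(ps2$sensitivity, ps2$precision), c(1, 1))

  # empty predictions
  empty <- transcript_set(
    tibble::tibble(transcript_id = character(0), chrom = character(0),
                   strand = character(0), exons = list(),
                   abundance = numeric(0)),
    role = "predicted"
  )
  ps3 <- precision_sensitivity(empty, refs)
  expect_equal(c(ps3$sensitivity, ps3$precision), c(0, 0))
  expect_error(precision_sensitivity(preds, empty), "empty")

  # duplicates: a reference validates at most one prediction
  dup <- transcript_set(dplyr::bind_rows(
    tx_rows("p1", "chr1", list(c(0, 100), c(200, 300)), ab = 5),
    tx_rows("p2", "chr1", list(c(5, 100), c(200, 295)), ab = 4)
  ), role = "predicted")
  psd <- precision_sensitivity(dup, refs)
  expect_equal(psd$correct, 1L)
})

test_that("AUC equals the independent brute-force sweep oracle", {
  for (case in c("perfect", "shifted_terminal", "boundary80", "tie",
                 "mixed")) {
    toy <- make_toy_gtf(case)
    expect_equal(auc(toy$pred, toy$ref), oracle_auc(toy$pred, toy$ref),
                 tolerance = 1e-12, label = paste("case", case))
  }
  toy <- make_toy_gtf("mixed")
  # frozen oracle value: cutoffs {5,3,1} give PR points (.5,1), (.5,.5),
  # (1,2/3); rectangle .5*1 plus trapezoid .5*(.5+2/3)/2
  expect_equal(auc(toy$pred, toy$ref), 0.5 + 0.5 * (0.5 + 2 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(assembly_loss(toy$pred, toy$ref),
               -auc(toy$pred, toy$ref))

  # randomized toy instances against the oracle
  withr::with_seed(21, {
    for (rep in 1:8) {
      n_ref <- sample(2:4, 1)
      refs <- transcript_set(dplyr::bind_rows(lapply(seq_len(n_ref),
        function(j) {
          s <- j * 1000
          tx_rows(paste0("r", j), "chr1",
                  list(c(s, s + 100), c(s + 200, s + 300)))
        })), role = "reference")
      n_pred <- sample(2:5, 1)
      preds <- transcript_set(dplyr::bind_rows(lapply(seq_len(n_pred),
        function(i) {
          j <- sample(n_ref, 1)
          s <- j * 1000
          shift <- sample(c(0, 0, 7), 1)   # sometimes a wrong chain
          tx_rows(paste0("p", i), "chr1",
                  list(c(s, s + 100), c(s + 200 + shift, s + 300)),
                  ab = sample(1:4, 1))
        })), role = "predicted")
      expect_equal(auc(preds, refs), oracle_auc(preds, refs),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC bounds, order invariance, and min_coverage monotonicity", {
  toy <- make_toy_gtf("tie")
  a1 <- auc(toy$pred, toy$ref)
  shuffled <- transcript_set(toy$pred[c(3, 1, 2), ], role = "predicted")
  expect_equal(auc(shuffled, toy$ref), a1, tolerance = 1e-12)
  expect_gte(a1, 0); expect_lte(a1, 1)

  # all-incorrect predictions
  wrong <- transcript_set(tx_rows("p", "chr9", list(c(0, 50), c(60, 90)),
                                  ab = 2), role = "predicted")
  expect_equal(auc(wrong, toy$ref), 0)
  expect_equal(assembly_loss(wrong, toy$ref), 0)

  # raising min_coverage only removes predictions
  toy2 <- make_toy_gtf("mixed")
  s_all <- pr_curve(toy2$pred, toy2$ref, min_coverage = 0)
  s_cut <- pr_curve(toy2$pred, toy2$ref, min_coverage = 2)
  expect_lte(max(s_cut$sensitivity), max(s_all$sensitivity))
  expect_lte(nrow(s_cut), nrow(s_all))
})

test_that("abundance ties enter and leave the curve together", {
  toy <- make_toy_gtf("tie")
  curve <- pr_curve(toy$pred, toy$ref)
  expect_equal(nrow(curve), 1L)        # single distinct abundance
  expect_equal(curve$n_pred, 3L)
})

test_that("synthetic objective is deterministic with a planted minimum", {
  sp <- toy_space2()
  opt <- c(a = 3, b = 7)
  f <- synthetic_objective(opt, sp, seed = 5)
  expect_equal(f(opt), -1)
  expect_identical(f(c(a = 4, b = 9)),
                   synthetic_objective(opt, sp, seed = 5)(c(a = 4, b = 9)))
  # exhaustive grid on the integer lattice: argmin at the planted optimum
  dom <- initial_domain(sp)
  grid <- expand.grid(a = 0:50, b = 0:50)
  vals <- apply(grid, 1, function(r) f(c(a = unname(r[1]), b = unname(r[2]))))
  expect_equal(unlist(grid[which.min(vals), ]), opt)
  expect_true(all(vals >= -1 & vals <= 0))
})

test_that("external assembler objective surfaces subprocess failures", {
  skip_if_not_installed("rtracklayer")
  dir <- withr::local_tempdir()
  toy <- make_toy_gtf("perfect")
  ann <- file.path(dir, "ann.gtf")
  write_gtf(toy$ref, ann)
  obj <- external_assembler_objective(
    sample_path = file.path(dir, "missing.bam"),
    assembler = function(theta, sample_path, out_gtf) {
      c("false")   # a command that always fails
    },
    annotation = ann
  )
  expect_error(obj(c(x = 1)), "failed")
})
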