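test_that("profile scores match the closed form and a hand-built oracle", {
  # single row, vanishing pseudocount: consensus path scores log2(1/background)
  bg <- aa_background()
  m1 <- build_profile(msa("r1", "ACD"), pseudocount_weight = 1e-9)
  expect_equal(m1$match["A", 1], log2(1 / bg["A"]), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(m1$match["C", 2], log2(1 / bg["C"]), ignore_attr = TRUE,
               tolerance = 1e-6)

  # 3-row toy with w = 1, scores recomputed by direct arithmetic
  seed <- msa(c("r1", "r2", "r3"), c("AC", "AC", "AD"))
  m3 <- build_profile(seed, pseudocount_weight = 1)
  for (a in aa_alphabet()) {
    cnt1 <- sum(c("A", "A", "A") == a)
    expect_equal(m3$match[a, 1],
                 log2(((cnt1 + bg[a]) / 4) / bg[a]), ignore_attr = TRUE)
    cnt2 <- sum(c("C", "C", "D") == a)
    expect_equal(m3$match[a, 2],
                 log2(((cnt2 + bg[a]) / 4) / bg[a]), ignore_attr = TRUE)
  }
  # expected per-column score under background is never positive
  expect_true(all(colSums(m3$match[1:20, , drop = FALSE] * bg) <= 1e-12))
})

test_that("gap-dominated seed columns are dropped from the model", {
  seed <- msa(sprintf("r%d", 1:5), c("AAC", "AAC", "A-C", "A-C", "A-C"))
  m <- build_profile(seed)
  expect_equal(m$n_cols, 2L)         # middle column is 60% gaps
  expect_identical(m$kept_columns, c(1L, 3L))
  expect_error(build_profile(msa("r1", "---")), "gap")
})

test_that("local profile scoring equals brute-force enumeration on tiny cases", {
  set.seed(77)
  for (case in 1:20) {
    width <- sample(3:6, 1)
    cons <- paraldiv:::sample_residues(width)
    seed <- noisy_family(cons, 2, rate = 0.1)
    model <- build_profile(seed)
    L <- sample(6:12, 1)
    seq <- paraldiv:::sample_residues(L)
    if (runif(1) < 0.5) {
      # embed part of the consensus so positive scores exist
      at <- sample(L - width + 1, 1)
      seq <- paste0(substr(seq, 1, at - 1), cons,
                    substr(seq, at + width, L))
    }
    a <- match(strsplit(seq, "")[[1]], rownames(model$match))
    dp <- paraldiv:::affine_local_dp(model$match[a, , drop = FALSE],
                                     model$gap_open, model$gap_extend,
                                     traceback = FALSE)
    bf <- brute_force_local_score(model$match, a, model$gap_open,
                                  model$gap_extend)
    dp_score <- if (is.null(dp)) 0 else dp$score
    if (bf > 0) expect_equal(dp_score, bf, tolerance = 1e-9)
  }
})

test_that("Gumbel fitting recovers known parameters", {
  set.seed(3)
  x <- 5 - log(-log(runif(2000))) / 0.7
  f <- fit_gumbel(x)
  expect_lt(abs(f$mu - 5), 0.2)
  expect_lt(abs(f$lambda - 0.7), 0.1)
})

test_that("E-values are monotone non-increasing in score and need calibration", {
  cm <- calibrated_model(seed = 2)
  s <- seq(5, 40, by = 5)
  e <- vapply(s, function(S) paraldiv:::profile_evalue(cm$model, S, 1e4),
              numeric(1))
  expect_true(all(diff(e) <= 0))
  raw <- build_profile(noisy_family(paraldiv:::sample_residues(30), 3))
  expect_error(scan_protein(raw, list(id = "x", locus_id = "x",
                                      residues = paraldiv:::sample_residues(100))),
               "calibrat")
})

test_that("calibration rejects a degenerate null", {
  seed <- msa(c("r1", "r2"), c("AAAAAAAAAA", "AAAAAAAAAA"))
  m <- build_profile(seed)
  # a model whose scores cannot vary enough will stop; force degeneracy by
  # zeroing the score matrix
  m$match[] <- 0
  expect_error(calibrate_evalue(m, n_shuffled = 100, seed = 1), "degenerate")
  expect_error(calibrate_evalue(build_profile(seed), n_shuffled = 50, seed = 1),
               "at least 100")
})

test_that("a planted exact consensus is found at its interval with high coverage", {
  cm <- calibrated_model(seed = 4)
  set.seed(8)
  flank1 <- paraldiv:::sample_residues(80)
  flank2 <- paraldiv:::sample_residues(70)
  prot <- list(id = "p1", locus_id = "p1",
               residues = paste0(flank1, cm$consensus, flank2))
  hits <- scan_protein(cm$model, prot, max_evalue = 0.01)
  expect_equal(nrow(hits), 1L)
  expect_lte(abs(hits$start - 81), 2)
  expect_lte(abs(hits$end - 130), 2)
  expect_gte(hits$model_coverage, 0.95)
  expect_true(hits$complete)

  # scanning is invariant to description text
  expect_equal(nrow(scan_protein(cm$model,
                                 list(id = "p1", locus_id = "p1",
                                      description = "other text",
                                      residues = prot$residues),
                                 max_evalue = 0.01)), 1L)
})

test_that("background proteins rarely reach E <= 0.01 and tiny proteins never hit", {
  cm <- calibrated_model(seed = 6)
  set.seed(9)
  n_hit <- 0L
  for (t in 1:100) {
    prot <- list(id = "bg", locus_id = "bg",
                 residues = paraldiv:::sample_residues(200))
    n_hit <- n_hit + (nrow(scan_protein(cm$model, prot, max_evalue = 0.01)) > 0L)
  }
  expect_lte(n_hit, 5L)
  expect_equal(nrow(scan_protein(cm$model, list(id = "s", locus_id = "s",
                                                residues = "ACD"))), 0L)
})

test_that("survey recovers planted domains and classifies truncations partial", {
  cm <- calibrated_model(seed = 10)
  gen <- generate_proteome(30, 10, cm$consensus, truncation_fraction = 0.2,
                           seed = 12)
  hits <- survey_proteome(cm$model, gen$proteins, evalue_cutoff = 0.01)
  truth <- gen$truth$planted_domains
  recovered <- vapply(seq_len(nrow(truth)), function(k) {
    h <- hits[hits$protein_id == truth$protein_id[k], , drop = FALSE]
    nrow(h) > 0 && any(pmin(h$end, truth$end[k]) >= pmax(h$start, truth$start[k]))
  }, logical(1))
  expect_gte(sum(recovered), 9L)
  expect_lte(sum(!(hits$protein_id %in% truth$protein_id)), 1L)
  trunc_ids <- truth$protein_id[truth$truncated]
  expect_true(all(!hits$complete[hits$protein_id %in% trunc_ids]))
  expect_true(all(classify_completeness(hits[hits$model_coverage >= 0.8, ])))
  expect_equal(nrow(survey_proteome(cm$model, gen$proteins[0, ])), 0L)
})

test_that("locus dedup prefers complete domains, then longer proteins", {
  proteome <- protein_set(
    c("L1_T01", "L1_T02", "L2_T01", "L2_T02", "L3_T01"),
    c(strrep("A", 300), strrep("A", 250), strrep("C", 320), strrep("C", 280),
      strrep("D", 100)))
  hits <- data.frame(
    protein_id = c("L1_T01", "L1_T02", "L2_T01", "L2_T02", "L3_T01"),
    locus_id = c("L1", "L1", "L2", "L2", "L3"),
    start = 1L, end = 10L,
    score = c(30, 40, 50, 45, 20), evalue = 1e-5,
    model_coverage = c(1, 1, 0.5, 1, 1),
    complete = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  kept <- dedupe_loci(hits, proteome)
  expect_equal(nrow(kept), 3L)
  # both complete: longer protein wins
  expect_true("L1_T01" %in% kept$protein_id)
  # complete-280 beats partial-320
  expect_true("L2_T02" %in% kept$protein_id)
  # idempotent; singleton loci pass through
  expect_identical(dedupe_loci(kept, proteome)$protein_id, kept$protein_id)
  shuffled <- hits[c(5, 3, 1, 4, 2), ]
  expect_identical(sort(dedupe_loci(shuffled, proteome)$protein_id),
                   sort(kept$protein_id))
})
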