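test_that("local alignment matches hand-computed and limiting cases", {
  r <- local_align("AAAA", "AAAA")
  expect_equal(r$score, 16L)  # 4 matches x BLOSUM62 A/A = +4
  expect_equal(r$identity, 1.0)
  expect_equal(r$q_span, c(1L, 4L))
  # all-negative substitution pairs floor at the empty alignment
  r2 <- local_align("KKKK", "DDDD")
  expect_equal(r2$score, 0L)
  expect_null(r2$q_span)
  expect_equal(r2$n_columns, 0L)
})

test_that("self-alignment recovers the diagonal substitution sum", {
  mat <- blosum62_matrix()
  for (seed in 1:5) {
    s <- withr::with_seed(seed, random_peptide(sample(5:40, 1),
                                               aa_alphabet()))
    r <- local_align(s, s)
    expect_equal(r$identity, 1.0)
    chars <- strsplit(s, "")[[1]]
    expect_equal(r$score, sum(mat[cbind(chars, chars)]))
  }
})

test_that("score is symmetric under a symmetric substitution matrix", {
  for (seed in 1:10) {
    pair <- withr::with_seed(seed, list(random_peptide(sample(4:20, 1)),
                                        random_peptide(sample(4:20, 1))))
    expect_equal(local_align(pair[[1]], pair[[2]])$score,
                 local_align(pair[[2]], pair[[1]])$score)
  }
})

test_that("optimal score equals literal path enumeration on tiny pairs", {
  mat <- blosum62_matrix()
  for (seed in 1:20) {
    pair <- withr::with_seed(seed, list(random_peptide(sample(2:4, 1)),
                                        random_peptide(sample(2:4, 1))))
    expect_equal(local_align(pair[[1]], pair[[2]])$score,
                 oracle_sw_enum(pair[[1]], pair[[2]], mat),
                 info = paste(pair[[1]], pair[[2]]))
  }
})

test_that("compiled aligner agrees with an independent R Gotoh DP", {
  mat <- blosum62_matrix()
  for (seed in 1:50) {
    pair <- withr::with_seed(seed, list(random_peptide(sample(2:8, 1)),
                                        random_peptide(sample(2:8, 1))))
    expect_equal(local_align(pair[[1]], pair[[2]])$score,
                 oracle_sw_dp(pair[[1]], pair[[2]], mat),
                 info = paste(pair[[1]], pair[[2]]))
  }
})

test_that("scores agree with Biostrings pairwiseAlignment", {
  skip_if_not_installed("Biostrings")
  mat <- blosum62_matrix()
  for (seed in 1:15) {
    pair <- withr::with_seed(seed,
                             list(random_peptide(sample(10:60, 1),
                                                 aa_alphabet()),
                                  random_peptide(sample(10:60, 1),
                                                 aa_alphabet())))
    ours <- local_align(pair[[1]], pair[[2]])$score
    # Biostrings charges gapOpening + g * gapExtension for a gap of
    # length g, so open 10 / extend 1 matches our 11 + (g - 1) * 1
    theirs <- Biostrings::pairwiseAlignment(
      pair[[1]], pair[[2]], type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, as.numeric(theirs), info = seed)
  }
})

test_that("'X' is scored neutrally and unknown residues are rejected", {
  r <- local_align("AAXAA", "AAXAA")
  expect_equal(r$score, 16L)
  expect_error(local_align("AB1", "AAA"), "not present")
})

test_that("E-values follow the Karlin-Altschul closed form", {
  model <- evalue_model("canonical")
  # pivot: lambda * score = ln(K m n) gives E = 1
  m <- 161; n <- 161
  s0 <- log(model$K * m * n) / model$lambda
  expect_equal(evalue(s0, m, n, model), 1.0)
  expect_equal(evalue(30, m, 2 * n, model), 2 * evalue(30, m, n, model))
  expect_true(evalue(40, m, n, model) < evalue(30, m, n, model))
  expect_error(evalue(30, m, n, list(lambda = 1)), "evalue_model")
})

test_that("shuffle calibration predicts the empirical score tail", {
  q <- sample_sequence(background_composition(), 120, seed = 21)
  subj <- sample_sequence(background_composition(), 120, seed = 22)
  model <- evalue_model("shuffle", query = q, subject = subj,
                        n_shuffles = 200, seed = 23)
  expect_gt(model$lambda, 0)
  expect_gt(model$K, 0)
  # fresh shuffles: P(score >= s) should approximate 1 - exp(-E(s))
  sv <- strsplit(subj, "")[[1]]
  scores <- withr::with_seed(24, vapply(1:200, function(i) {
    local_align(q, paste(sample(sv), collapse = ""))$score
  }, numeric(1)))
  s0 <- as.numeric(stats::quantile(scores, 0.9))
  p_emp <- mean(scores >= s0)
  p_pred <- 1 - exp(-evalue(s0, 120, 120, model))
  expect_gt(p_pred, p_emp / 4)
  expect_lt(p_pred, p_emp * 4)
})

test_that("the homology gate passes self and rejects background", {
  ref <- consensus <- sample_sequence(background_composition(), 161,
                                      seed = 31)
  regions <- data.frame(protein_id = "self", seq = ref,
                        stringsAsFactors = FALSE)
  g <- select_candidates(regions, ref)
  expect_true(g$pass)
  bg <- data.frame(
    protein_id = sprintf("bg%03d", 1:100),
    seq = vapply(1:100, function(i) {
      sample_sequence(background_composition(), 161, seed = 4000 + i)
    }, ""),
    stringsAsFactors = FALSE)
  gb <- select_candidates(bg, ref, threshold = 1e-10)
  expect_equal(sum(gb$pass), 0L)
  # vacuous gate and empty input
  expect_true(all(select_candidates(bg, ref, threshold = Inf)$pass))
  expect_equal(nrow(select_candidates(bg[0, ], ref)), 0L)
})

test_that("the gate is monotone in its threshold", {
  fam <- cached_family(seed = 1L, n = 4L)
  vwa <- fam$hits[fam$hits$domain_class == "VWA", ][1:10, ]
  regions <- data.frame(
    protein_id = vwa$protein_id,
    seq = substr(fam$proteins$seq[match(vwa$protein_id,
                                        fam$proteins$id)],
                 vwa$start, vwa$end),
    stringsAsFactors = FALSE)
  ref <- fam$reference$vwa
  for (pair in list(c(1e-20, 1e-10), c(1e-10, 1e-2))) {
    p1 <- select_candidates(regions, ref, threshold = pair[1])$pass
    p2 <- select_candidates(regions, ref, threshold = pair[2])$pass
    expect_true(all(p2[p1]))
  }
})
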