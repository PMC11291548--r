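test_that("PSSM scores follow the pseudocount log-odds formula", {
  unif <- setNames(rep(0.05, 20), aa_alphabet())
  # identical sequences, vanishing pseudocount: consensus ~ log2(20)
  p <- build_pssm(rep("ACDE", 3), background = unif,
                  pseudocount = 1e-9)
  expect_equal(unname(p$scores["A", 1]), log2(20), tolerance = 1e-4)
  expect_equal(p$consensus, "ACDE")
  # columns at background frequency carry no information
  seqs <- vapply(1:20, function(i) strrep(aa_alphabet()[i], 4), "")
  p0 <- build_pssm(seqs, background = unif, pseudocount = 1e-9)
  expect_true(all(abs(p0$scores) < 1e-4))
  # two-sequence hand example, checked against the formula directly
  bg <- background_composition()
  ph <- build_pssm(c("ADKG", "ADWG"), background = bg, pseudocount = 2)
  expect_equal(unname(ph$scores["A", 1]),
               log2(((2 + 2 * bg[["A"]]) / 4) / bg[["A"]]))
  expect_equal(unname(ph$scores["K", 3]),
               log2(((1 + 2 * bg[["K"]]) / 4) / bg[["K"]]))
  expect_equal(unname(ph$scores["C", 2]),
               log2(((0 + 2 * bg[["C"]]) / 4) / bg[["C"]]))
})

test_that("PSSM construction enforces its preconditions", {
  expect_error(build_pssm("ACDE"), ">= 2")
  expect_error(build_pssm(c("ACDE", "ACD")), "equal length")
  expect_error(build_pssm(c("ACD", "ACD")), ">= 4")
  expect_error(build_pssm(c("AXDE", "AXDE")), "only 'X'")
})

test_that("scanning finds planted profile copies and not background", {
  seed_aln <- withr::with_seed(51, {
    cons <- random_peptide(20, aa_alphabet())
    c(cons, cons, cons)
  })
  pssm <- build_pssm(seed_aln, pseudocount = 0.5, name = "toy")
  cons <- seed_aln[1]
  bg <- function(n, s) sample_sequence(background_composition(), n, s)
  prot <- list(id = "p1", seq = paste0(bg(49, 61), cons, bg(60, 62)))
  hits <- scan_pssm(pssm, prot, n_null = 150, seed = 1)
  expect_equal(hits$start[which.min(hits$ievalue)], 50L)
  # two planted copies, well separated
  prot2 <- list(id = "p2",
                seq = paste0(bg(30, 63), cons, bg(50, 64), cons,
                             bg(30, 65)))
  hits2 <- scan_pssm(pssm, prot2, n_null = 150, seed = 1,
                     max_evalue = 0.01)
  expect_equal(hits2$start, c(31L, 101L))
  # background-only proteins yield no confident hit
  fp <- vapply(1:10, function(i) {
    h <- scan_pssm(pssm, list(id = "b", seq = bg(200, 700 + i)),
                   n_null = 150, seed = i)
    any(h$ievalue < 1e-5)
  }, logical(1))
  expect_equal(sum(fp), 0L)
  expect_error(scan_pssm(pssm, prot, n_null = 50), ">= 100")
})

test_that("tier assignment partitions the E-value axis", {
  expect_identical(assign_tier(c(1e-6, 0.5, 5000, 20000)),
                   c("CBM_14", "CBM_14L1", "CBM_14L2", "none"))
  # lower-inclusive boundaries
  expect_identical(assign_tier(c(1e-5, 1.0, 1e4)),
                   c("CBM_14L1", "CBM_14L2", "none"))
  expect_identical(assign_tier(0), "CBM_14")
  expect_error(assign_tier(-1), "non-negative")
  ev <- withr::with_seed(52, 10^runif(1000, -12, 6))
  tiers <- assign_tier(ev)
  expect_true(all(tiers %in% c("CBM_14", "CBM_14L1", "CBM_14L2",
                               "none")))
  expect_identical(tiers == "CBM_14", ev < 1e-5)
  expect_identical(tiers == "CBM_14L2", ev >= 1 & ev < 1e4)
})

test_that("architecture assembly resolves overlaps by E-value", {
  prot <- list(id = "p", seq = strrep("A", 200))
  hits <- data.frame(
    protein_id = "p", domain_class = "VWA",
    start = c(10L, 50L), end = c(100L, 140L), score = c(50, 40),
    ievalue = c(1e-30, 1e-6), stringsAsFactors = FALSE)
  arch <- assemble_architecture(prot, hits)
  expect_equal(nrow(arch$elements), 1L)
  expect_equal(arch$elements$start, 10L)
  # ties on ievalue: longer span, then smaller start
  hits2 <- data.frame(
    protein_id = "p", domain_class = "VWA",
    start = c(10L, 5L), end = c(100L, 140L), score = c(50, 50),
    ievalue = c(1e-10, 1e-10), stringsAsFactors = FALSE)
  arch2 <- assemble_architecture(prot, hits2)
  expect_equal(arch2$elements$start, 5L)
})

test_that("assembled architectures carry the planted flags", {
  fam <- cached_family(seed = 1L, n = 4L)
  tr <- fam$truth
  for (id in fam$proteins$id) {
    p <- fam$proteins[fam$proteins$id == id, ]
    tp <- tr[tr$protein_id == id, ]
    anch <- list(
      n = unlist(tp[tp$kind == "anchor_n", c("start", "end")]),
      c = unlist(tp[tp$kind == "anchor_c", c("start", "end")]))
    arch <- assemble_architecture(
      p, fam$hits[fam$hits$protein_id == id, ], anchors = anch)
    expect_equal(arch$n_vwa,
                 sum(tp$kind == "domain" & tp$class == "VWA"))
    expect_true(arch$has_cb)
    expect_equal(arch$lg_status, tp$class[tp$kind == "lg_status"])
    # element list sorted and non-overlapping
    e <- arch$elements
    if (nrow(e) > 1) {
      expect_true(all(diff(e$start) > 0))
      expect_true(all(e$start[-1] > e$end[-nrow(e)]))
    }
  }
})

test_that("degenerate architectures are handled", {
  prot <- list(id = "p", seq = strrep("A", 100))
  empty <- assemble_architecture(
    prot, data.frame(protein_id = character(0),
                     domain_class = character(0), start = integer(0),
                     end = integer(0), score = numeric(0),
                     ievalue = numeric(0)))
  expect_equal(empty$n_vwa, 0L)
  expect_false(empty$has_cb)
  expect_equal(empty$lg_status, "absent")
  hits <- data.frame(protein_id = "p", domain_class = "VWA",
                     start = 5L, end = 60L, score = 40,
                     ievalue = 1e-20, stringsAsFactors = FALSE)
  expect_warning(
    assemble_architecture(prot, hits, signal_span = c(1L, 18L)),
    "signal")
  expect_error(
    assemble_architecture(prot, transform(hits, protein_id = "q")),
    "other than p")
})
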