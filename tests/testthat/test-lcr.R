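test_that("window entropy matches closed forms", {
  expect_equal(window_entropy("AAAAAAAAAAAA"), 0.0)
  expect_equal(window_entropy("ADADADADADAD"), 1.0)
  expect_equal(window_entropy("ACDEFGHIKLMN"), log2(12))
  expect_equal(window_entropy("AAXAA"), 0.0)  # 'X' excluded
  expect_error(window_entropy("XXXX"), "only 'X'")
})

test_that("sliding entropies equal per-window recomputation", {
  s <- sample_sequence(background_composition(), 120, seed = 81)
  s <- paste0(substr(s, 1, 50), "XXX", substr(s, 54, 120))
  chars <- strsplit(s, "")[[1]]
  slid <- pifarch:::.all_window_entropies(chars, 12L)
  direct <- vapply(seq_len(nchar(s) - 11L), function(p) {
    window_entropy(substr(s, p, p + 11L))
  }, numeric(1))
  expect_equal(slid, direct)
})

test_that("planted low-complexity tracts are detected and covered", {
  for (seed in 1:25) {
    prot <- withr::with_seed(seed, {
      res <- sample(c("D", "S", "K", "T"), 1)
      list(id = "p",
           seq = paste0(sample_sequence(background_composition(), 60,
                                        seed = 9000 + seed),
                        strrep(res, 30),
                        sample_sequence(background_composition(), 60,
                                        seed = 9500 + seed)))
    })
    segs <- detect_lcrs(prot)
    expect_gte(nrow(segs), 1L)
    # some detected segment covers the tract interior (61..90 +/- W)
    expect_true(any(segs$start <= 66 & segs$end >= 85))
  }
})

test_that("separated tracts give separate segments, merged when close", {
  bg <- function(n, s) sample_sequence(background_composition(), n, s)
  two <- list(id = "p", seq = paste0(bg(40, 91), strrep("K", 24),
                                     bg(50, 92), strrep("D", 24),
                                     bg(40, 93)))
  segs <- detect_lcrs(two)
  expect_equal(nrow(segs), 2L)
  expect_true(all(diff(segs$start) > 0))
  expect_true(all(segs$start[-1] > segs$end[-nrow(segs)] + 1L))
})

test_that("detected segments respect the extension entropy ceiling", {
  fam <- cached_family(seed = 1L, n = 4L)
  params <- lcr_params()
  for (i in 1:6) {
    p <- fam$proteins[i, ]
    segs <- detect_lcrs(p, params)
    if (nrow(segs) == 0) next
    expect_true(all(segs$mean_entropy <= params$extend))
    expect_true(all(segs$end - segs$start + 1L >= params$min_len))
  }
})

test_that("a lower trigger never covers more residues", {
  covered <- function(segs) {
    if (nrow(segs) == 0) 0L else sum(segs$end - segs$start + 1L)
  }
  fam <- cached_family(seed = 2L, n = 4L)
  for (i in c(1, 5, 9)) {
    p <- fam$proteins[i, ]
    cov <- vapply(c(2.4, 2.2, 2.0, 1.5), function(kt) {
      covered(detect_lcrs(p, lcr_params(trigger = kt)))
    }, integer(1))
    expect_true(all(diff(cov) <= 0))
  }
})

test_that("zone intervals follow the architecture geometry", {
  prot <- list(id = "p", seq = strrep("A", 1200))
  hits <- data.frame(
    protein_id = "p",
    domain_class = c(rep("VWA", 4), "CBM_14"),
    start = c(51L, 261L, 471L, 681L, 901L),
    end = c(230L, 440L, 650L, 860L, 955L),
    score = 50, ievalue = 1e-20, stringsAsFactors = FALSE)
  arch <- assemble_architecture(prot, hits, signal_span = c(1L, 18L),
                                anchors = list(n = c(960L, 991L),
                                               c = c(1100L, 1158L)))
  z <- zone_intervals(arch)
  expect_equal(z$zone1, data.frame(start = 19L, end = 50L))
  expect_equal(nrow(z$zone2), 3L)  # gaps between 4 tandem VWAs
  expect_equal(z$zone2$start, c(231L, 441L, 651L))
  expect_equal(z$zone3, data.frame(start = 861L, end = 900L))
  expect_equal(z$zone4, data.frame(start = 992L, end = 1099L))
  # zones are pairwise disjoint
  all_iv <- do.call(rbind, z)
  all_iv <- all_iv[order(all_iv$start), ]
  expect_true(all(all_iv$start[-1] > all_iv$end[-nrow(all_iv)]))
})

test_that("missing domains simply omit zones", {
  prot <- list(id = "p", seq = strrep("A", 400))
  one_vwa <- data.frame(protein_id = "p", domain_class = "VWA",
                        start = 1L, end = 180L, score = 50,
                        ievalue = 1e-20, stringsAsFactors = FALSE)
  z <- zone_intervals(assemble_architecture(prot, one_vwa))
  expect_null(z$zone1)  # VWA starts at residue 1
  expect_null(z$zone2)
  expect_null(z$zone3)  # no CB domain
  expect_null(z$zone4)  # no anchors
})

test_that("LCRs are assigned by midpoint and numbered within zones", {
  zones <- list(zone1 = data.frame(start = 1L, end = 100L),
                zone2 = data.frame(start = 101L, end = 300L),
                zone4 = data.frame(start = 400L, end = 1000L))
  lcrs <- data.frame(
    protein_id = "p",
    start = c(150L, 90L, 500L, 700L, 900L, 350L),
    end = c(170L, 115L, 520L, 720L, 920L, 370L),
    mean_entropy = 1, zone = NA_character_, ordinal = NA_integer_,
    stringsAsFactors = FALSE)
  out <- assign_zones(lcrs, zones)
  # straddling segment (90-115, midpoint 102) goes to zone2
  expect_identical(out$zone[out$start == 90L], "zone2")
  expect_identical(out$zone[out$start == 350L], "outside")
  z4 <- out[out$zone == "zone4", ]
  expect_equal(z4$ordinal, 1:3)
  expect_equal(z4$start, c(500L, 700L, 900L))
})

test_that("planted zone labels are recovered through the full chain", {
  fam <- cached_family(seed = 1L, n = 4L)
  tr <- fam$truth
  for (id in fam$proteins$id) {
    p <- fam$proteins[fam$proteins$id == id, ]
    tp <- tr[tr$protein_id == id, ]
    sig <- unlist(tp[tp$kind == "signal", c("start", "end")])
    anch <- list(
      n = unlist(tp[tp$kind == "anchor_n", c("start", "end")]),
      c = unlist(tp[tp$kind == "anchor_c", c("start", "end")]))
    if (length(anch$n) == 0) anch$n <- NULL
    if (length(anch$c) == 0) anch$c <- NULL
    arch <- assemble_architecture(
      p, fam$hits[fam$hits$protein_id == id, ],
      signal_span = if (length(sig)) sig else NULL, anchors = anch)
    segs <- assign_zones(detect_lcrs(p), zone_intervals(arch))
    planted <- tp[tp$kind == "lcr", ]
    for (r in seq_len(nrow(planted))) {
      hit <- segs[segs$start <= planted$start[r] &
                    segs$end >= planted$end[r] - 1L, ]
      expect_gte(nrow(hit), 1L)
      expect_identical(hit$zone[1], planted$zone[r],
                       info = paste(id, r))
    }
  }
})
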