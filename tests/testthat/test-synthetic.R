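test_that("sample_sequence is reproducible and follows its composition", {
  degenerate <- setNames(c(0, 0, 1, rep(0, 17)), aa_alphabet())
  expect_identical(sample_sequence(degenerate, 5, seed = 1), "DDDDD")
  expect_identical(sample_sequence(background_composition(), 50, seed = 9),
                   sample_sequence(background_composition(), 50, seed = 9))
  expect_error(sample_sequence(background_composition(), 0, seed = 1),
               ">= 1")
  # law of large numbers: uniform composition, frequencies near 0.05
  unif <- setNames(rep(0.05, 20), aa_alphabet())
  s <- sample_sequence(unif, 10000, seed = 3)
  freq <- table(factor(strsplit(s, "")[[1]], levels = aa_alphabet())) / 10000
  expect_true(all(abs(freq - 0.05) < 0.01))
})

test_that("seeded generation does not disturb the global RNG stream", {
  set.seed(77)
  a <- runif(3)
  set.seed(77)
  invisible(sample_sequence(background_composition(), 100, seed = 5))
  invisible(plant_family(synthetic_spec(n_per_subfamily = 2L, seed = 2)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("planted architectures follow their templates", {
  fam <- cached_family(seed = 1L, n = 4L)
  tr <- fam$truth
  # BMSP-like: four VWA spans strictly increasing, all before any CB
  for (id in unique(tr$protein_id[tr$subfamily == "bmsplike"])) {
    tp <- tr[tr$protein_id == id & tr$kind == "domain", ]
    vwa <- tp[tp$class == "VWA", ]
    cb <- tp[tp$class == "CBM_14", ]
    expect_equal(nrow(vwa), 4L)
    expect_true(all(diff(vwa$start) > 0))
    expect_true(all(vwa$end < min(cb$start)))
  }
  # CCP-like: Sushi repeats strictly between last VWA end and first CB
  for (id in unique(tr$protein_id[tr$subfamily == "ccplike"])) {
    tp <- tr[tr$protein_id == id & tr$kind == "domain", ]
    sushi <- tp[tp$class == "Sushi", ]
    expect_equal(nrow(sushi), 3L)
    expect_true(all(sushi$start > max(tp$start[tp$class == "VWA"])))
    expect_true(all(sushi$end < min(tp$start[tp$class == "CBM_14"])))
  }
})

test_that("every planted element is recoverable at its recorded span", {
  fam <- cached_family(seed = 1L, n = 4L)
  tr <- fam$truth[!is.na(fam$truth$start), ]
  seqs <- setNames(fam$proteins$seq, fam$proteins$id)
  got <- substr(seqs[tr$protein_id], tr$start, tr$end)
  expect_identical(unname(got), tr$seq)
  # spans non-overlapping within a protein for physical elements
  phys <- tr[tr$kind %in% c("signal", "domain", "anchor_n", "anchor_c"), ]
  for (id in unique(phys$protein_id)) {
    sp <- phys[phys$protein_id == id, ]
    sp <- sp[order(sp$start), ]
    if (nrow(sp) > 1) expect_true(all(sp$start[-1] > sp$end[-nrow(sp)]))
  }
})

test_that("planted hit E-values sit strictly inside their tier windows", {
  fam <- cached_family(seed = 1L, n = 4L)
  tiers <- assign_tier(fam$hits$ievalue)
  cb <- fam$hits$domain_class == "CBM_14"
  tr_cb <- fam$truth[fam$truth$kind == "domain" &
                       fam$truth$class == "CBM_14", ]
  expect_identical(sort(tiers[cb]), sort(tr_cb$tier))
  expect_true(all(fam$hits$ievalue[!cb] < 1e-5))
})

test_that("insert composition profiles realise the planted contrast", {
  fam <- cached_family(seed = 2L, n = 6L)
  tr <- fam$truth[fam$truth$kind == "insert", ]
  comp <- t(vapply(tr$seq, composition_vector, numeric(20)))
  dkr <- rowSums(comp[, c("D", "K", "R")])
  ds <- rowSums(comp[, c("D", "S")])
  pinc <- tr$profile == "pinctada_like"
  # Asp/Lys/Arg dominate pinctada-like, Ser dominates unionida-like
  expect_gt(mean(dkr[pinc]), mean(dkr[!pinc]) + 10)
  expect_gt(min(comp[!pinc, "S"]), max(comp[pinc, "S"]))
  expect_true(all(comp[pinc, "D"] > 18))
  expect_true(all(ds[!pinc] > 30))
})

test_that("a template with zero elements yields pure background", {
  tpl <- list(architecture_template("bare", n_vwa = 0L,
                                    cb_tiers = character(0),
                                    signal = FALSE, lg = FALSE,
                                    lcr_plan = c()),
              architecture_template("plain", n_vwa = 1L,
                                    cb_tiers = character(0), lg = FALSE,
                                    lcr_plan = c()))
  fam <- plant_family(synthetic_spec(n_per_subfamily = 2L,
                                     templates = tpl, seed = 3))
  bare <- fam$truth[fam$truth$subfamily == "bare", ]
  expect_true(all(bare$kind == "lg_status"))
  expect_false(any(fam$hits$protein_id %in% bare$protein_id))
})

test_that("planted support tree separates family, subfamilies, outgroup", {
  spec <- synthetic_spec(n_per_subfamily = 4L, seed = 5)
  tre <- plant_support_tree(spec)
  expect_false(any(tre$outgroup %in% tre$truth$leaf))
  fc <- find_family_clade(tre$tree, tre$reference)
  expect_setequal(fc$tips, tre$truth$leaf)
  part <- partition_subfamilies(tre$tree, fc)
  expect_equal(nrow(part$subfamilies), 3L)
  for (sf in unique(tre$truth$subfamily)) {
    leaves <- sort(tre$truth$leaf[tre$truth$subfamily == sf])
    expect_true(paste(leaves, collapse = ",") %in%
                  part$subfamilies$leaves)
  }
  # determinism
  expect_identical(tre$newick, plant_support_tree(spec)$newick)
})

test_that("all-weak subfamily branches leave every leaf unassigned", {
  tpl <- lapply(default_templates(), function(t) {
    t$support_class <- "weak"
    t
  })
  tre <- plant_support_tree(synthetic_spec(n_per_subfamily = 3L,
                                           templates = tpl, seed = 8))
  fc <- find_family_clade(tre$tree, tre$reference)
  part <- partition_subfamilies(tre$tree, fc)
  expect_equal(nrow(part$subfamilies), 0L)
  expect_setequal(part$unassigned, tre$truth$leaf)
})

test_that("fixture emission is byte-deterministic and seed-sensitive", {
  spec <- synthetic_spec(n_per_subfamily = 2L, seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- emit_fixtures(spec, d1)
  p2 <- emit_fixtures(spec, d2)
  expect_setequal(basename(unname(p1)),
                  c("proteins.fasta", "hits.tsv", "tree.nwk",
                    "truth.tsv", "spec.yaml"))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     info = k)
  }
  d3 <- withr::local_tempdir()
  p3 <- emit_fixtures(synthetic_spec(n_per_subfamily = 2L, seed = 5), d3)
  expect_false(identical(readLines(p1[["proteins"]]),
                         readLines(p3[["proteins"]])))
})
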