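# Shared synthetic fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_family <- function(seed = 1L, n = 4L) {
  key <- paste0("fam_", seed, "_", n)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      plant_family(synthetic_spec(n_per_subfamily = n, seed = seed))
  }
  .fixture_cache[[key]]
}

# two well-separated composition profiles matching the family's
# characteristic insert chemistries
planted_composition_matrix <- function(n1 = 6L, n2 = 28L, seed = 1L) {
  pr <- insert_profiles()
  withr::with_seed(seed, {
    lens <- sample(138:1438, n1 + n2, replace = TRUE)
    seqs <- vapply(seq_len(n1 + n2), function(j) {
      p <- if (j <= n1) pr$pinctada_like else pr$unionida_like
      sample_sequence(p, lens[j], seed = sample.int(2^30, 1))
    }, "")
    names(seqs) <- sprintf("r%02d", seq_along(seqs))
    list(mat = composition_matrix(seqs),
         truth = rep(1:2, c(n1, n2)))
  })
}

# label agreement up to cluster relabelling (2 clusters)
label_agreement2 <- function(labels, truth) {
  max(mean(labels == truth), mean((3L - labels) == truth))
}
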