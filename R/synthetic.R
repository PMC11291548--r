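# Synthetic Pif/BMSP-like families with a machine-readable truth table.
#
# The generator plants, per protein: an optional signal peptide, 1-4
# tandem VWA-like domains, optional Sushi repeats, 0-3 chitin-binding
# domains at controlled E-value tiers, the two conserved LG anchor
# peptides flanking an insert of controlled length and composition,
# and low-complexity tracts in the four architecture zones. Sequences
# and the support-labelled tree are generated independently (no
# substitution model along the tree).

# nominal element lengths (residues)
.element_lengths <- c(VWA = 180L, CBM_14 = 55L, Sushi = 60L,
                      Laminin_G_3 = 170L, signal = 18L)

#' Insert composition profiles
#'
#' Named 20-vectors emulating the two contrasting insert chemistries of
#' the family: a `pinctada_like` profile enriched in Asp/Lys/Arg (the
#' polar, acidic-basic inserts of pearl-oyster Pif) and a
#' `unionida_like` profile enriched in Ser/Asp (freshwater-mussel Pif).
#'
#' @return Named list of probability 20-vectors.
#' @export
insert_profiles <- function() {
  list(
    pinctada_like = profile_with(c(D = 0.25, K = 0.12, R = 0.10)),
    unionida_like = profile_with(c(S = 0.22, D = 0.20))
  )
}

#' Build a composition profile by overriding background frequencies
#'
#' Fixes the given residue probabilities and rescales the remaining
#' residues proportionally to the background so the vector sums to 1.
#'
#' @param overrides Named numeric vector of probabilities (sum < 1).
#' @param background Base composition (default
#'   [background_composition()]).
#' @return Probability 20-vector.
#' @export
profile_with <- function(overrides, background = background_composition()) {
  stopifnot(all(names(overrides) %in% aa_alphabet()), sum(overrides) < 1)
  p <- background
  rest <- setdiff(aa_alphabet(), names(overrides))
  p[names(overrides)] <- overrides
  p[rest] <- background[rest] / sum(background[rest]) *
    (1 - sum(overrides))
  check_composition(p, "profile")
}

#' Sample an i.i.d. amino-acid sequence
#'
#' @param composition Probability 20-vector.
#' @param length Positive sequence length.
#' @param seed Integer seed; identical seeds give identical sequences
#'   and the global RNG state is untouched.
#' @return Amino-acid string.
#' @export
sample_sequence <- function(composition, length, seed) {
  composition <- check_composition(composition)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  withr::with_seed(seed, {
    paste(sample(aa_alphabet(), length, replace = TRUE,
                 prob = composition), collapse = "")
  })
}

# Internal: substitute positions of seq down to the given identity
# (substitutions only, no indels). Runs under the caller's RNG.
.mutate_seq <- function(seq, identity) {
  if (identity >= 1) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_mut <- round((1 - identity) * length(chars))
  if (n_mut == 0L) return(seq)
  pos <- sample(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(aa_alphabet(), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Internal: deterministic per-class consensus sequence.
consensus_sequence <- function(class, length = .element_lengths[[class]]) {
  key <- paste0(class, "_", length)
  if (is.null(.pkg_cache$consensus)) .pkg_cache$consensus <- list()
  if (is.null(.pkg_cache$consensus[[key]])) {
    seed <- sum(utf8ToInt(class) * seq_along(utf8ToInt(class))) + length
    .pkg_cache$consensus[[key]] <-
      sample_sequence(background_composition(), length, seed)
  }
  .pkg_cache$consensus[[key]]
}

# E-value tier windows sampled log-uniformly strictly inside the tier
# (never on a boundary, so planted tiers are unambiguous).
.tier_windows <- list(
  confident = c(-15, -6),
  CBM_14 = c(-15, -6),
  CBM_14L1 = c(-4.5, -0.5),
  CBM_14L2 = c(0.5, 3.5)
)

.sample_ievalue <- function(tier) {
  w <- .tier_windows[[tier]]
  if (is.null(w)) stop("unknown tier ", tier, call. = FALSE)
  10^runif(1L, w[1], w[2])
}

#' Define a subfamily architecture template
#'
#' @param name Subfamily tag (used in protein ids and tree leaves).
#' @param n_vwa Number of tandem VWA domains (1-4).
#' @param n_sushi Number of Sushi repeats between VWA and CB (0-5).
#' @param cb_tiers Character vector of planted chitin-binding tiers,
#'   each of `"CBM_14"`, `"CBM_14L1"`, `"CBM_14L2"` (0-3 entries).
#' @param signal Plant a signal peptide?
#' @param lg Plant the LG anchor pair with an insert?
#' @param insert_profile Name of an [insert_profiles()] entry.
#' @param insert_len_range Inclusive insert length range (default
#'   138-1438, the observed span of insert lengths in the family).
#' @param lcr_plan Named counts of planted low-complexity tracts per
#'   zone (`zone1`, `zone2`, `zone3`, `zone4`).
#' @param support_class Planted support class of the subfamily's
#'   ancestor branch (`"strong"`, `"medium"`, `"weak"`).
#' @param anchor_identity Identity at which anchors are planted
#'   (substitutions only; default 1 = exact).
#' @return An `architecture_template` list.
#' @export
architecture_template <- function(name, n_vwa = 1L, n_sushi = 0L,
                                  cb_tiers = "CBM_14", signal = TRUE,
                                  lg = TRUE,
                                  insert_profile = "pinctada_like",
                                  insert_len_range = c(138L, 1438L),
                                  lcr_plan = c(zone1 = 0L, zone2 = 0L,
                                               zone3 = 0L, zone4 = 0L),
                                  support_class = "strong",
                                  anchor_identity = 1.0) {
  if (n_vwa < 0L || n_vwa > 4L) stop("n_vwa must be 0-4", call. = FALSE)
  if (length(cb_tiers) > 3L) stop("at most 3 CB domains", call. = FALSE)
  if (!all(cb_tiers %in% c("CBM_14", "CBM_14L1", "CBM_14L2"))) {
    stop("invalid cb tier", call. = FALSE)
  }
  plan <- c(zone1 = 0L, zone2 = 0L, zone3 = 0L, zone4 = 0L)
  plan[names(lcr_plan)] <- as.integer(lcr_plan)
  if (plan["zone1"] > 0 && n_vwa < 1L) {
    stop("zone1 tracts require a VWA domain", call. = FALSE)
  }
  if (plan["zone2"] > 0 && n_vwa < 2L) {
    stop("zone2 tracts require >= 2 VWA domains", call. = FALSE)
  }
  if (plan["zone3"] > 0 && length(cb_tiers) == 0L) {
    stop("zone3 tracts require a CB domain", call. = FALSE)
  }
  if (plan["zone4"] > 0 && !lg) {
    stop("zone4 tracts require LG anchors", call. = FALSE)
  }
  if (anchor_identity < 0.7 || anchor_identity > 1) {
    stop("anchor_identity must be in [0.7, 1]", call. = FALSE)
  }
  structure(list(name = name, n_vwa = as.integer(n_vwa),
                 n_sushi = as.integer(n_sushi), cb_tiers = cb_tiers,
                 signal = signal, lg = lg,
                 insert_profile = insert_profile,
                 insert_len_range = as.integer(insert_len_range),
                 lcr_plan = plan, support_class = support_class,
                 anchor_identity = anchor_identity),
            class = "architecture_template")
}

#' Default subfamily templates
#'
#' Three templates spanning the family's characteristic layouts: a
#' Pif-like subfamily (one VWA, two confident CB domains, Asp/Lys/Arg
#' insert), a BMSP-like subfamily (four tandem VWA domains) and a
#' PifCCP-like subfamily (Sushi repeats between VWA and CB, degenerate
#' CB tier).
#'
#' @return List of [architecture_template()]s.
#' @export
default_templates <- function() {
  list(
    architecture_template("piflike", n_vwa = 1L,
                          cb_tiers = c("CBM_14", "CBM_14"),
                          insert_profile = "pinctada_like",
                          lcr_plan = c(zone3 = 1L, zone4 = 2L),
                          support_class = "strong"),
    architecture_template("bmsplike", n_vwa = 4L, cb_tiers = "CBM_14",
                          insert_profile = "unionida_like",
                          lcr_plan = c(zone1 = 1L, zone2 = 1L,
                                       zone4 = 1L),
                          support_class = "strong"),
    architecture_template("ccplike", n_vwa = 1L, n_sushi = 3L,
                          cb_tiers = "CBM_14L1",
                          insert_profile = "unionida_like",
                          lcr_plan = c(zone1 = 1L),
                          support_class = "medium")
  )
}

#' Specification of a synthetic family
#'
#' @param n_per_subfamily Proteins per subfamily template (single value
#'   or one per template).
#' @param templates List of [architecture_template()]s (>= 2 for tree
#'   planting).
#' @param seed Master seed; every random choice derives from it.
#' @param domain_identity Identity of planted domain instances to their
#'   class consensus.
#' @param n_outgroup Outgroup leaves attached outside the family clade.
#' @param lcr_tract_len Length of planted low-complexity tracts
#'   (default 24).
#' @param background Linker composition.
#' @param profiles Named insert composition profiles.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_subfamily = 8L,
                           templates = default_templates(), seed = 1L,
                           domain_identity = 0.85, n_outgroup = 3L,
                           lcr_tract_len = 24L,
                           background = background_composition(),
                           profiles = insert_profiles()) {
  background <- check_composition(background, "background")
  for (nm in names(profiles)) {
    profiles[[nm]] <- check_composition(profiles[[nm]], nm)
  }
  n <- rep_len(as.integer(n_per_subfamily), length(templates))
  for (t in templates) {
    if (t$lg && !(t$insert_profile %in% names(profiles))) {
      stop("unknown insert profile ", t$insert_profile, call. = FALSE)
    }
  }
  structure(list(n_per_subfamily = n, templates = templates,
                 seed = as.integer(seed),
                 domain_identity = domain_identity,
                 n_outgroup = as.integer(n_outgroup),
                 lcr_tract_len = as.integer(lcr_tract_len),
                 background = background, profiles = profiles),
            class = "synthetic_spec")
}

# Internal: a linker segment with planted low-complexity tracts.
# Returns list(seq, tracts = data.frame(start, end, seq) relative).
.zone_segment <- function(n_tracts, tract_len, tract_residues,
                          background, pad_range = c(20L, 40L)) {
  if (n_tracts == 0L) {
    len <- sample(25:45, 1L)
    return(list(seq = paste(sample(aa_alphabet(), len, replace = TRUE,
                                   prob = background), collapse = ""),
                tracts = data.frame(start = integer(0), end = integer(0),
                                    seq = character(0))))
  }
  parts <- character(0)
  tracts <- data.frame(start = integer(0), end = integer(0),
                       seq = character(0), stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_len(n_tracts)) {
    pad <- sample(pad_range[1]:pad_range[2], 1L)
    parts <- c(parts, paste(sample(aa_alphabet(), pad, replace = TRUE,
                                   prob = background), collapse = ""))
    pos <- pos + pad
    res <- sample(tract_residues, 1L)
    tract <- strrep(res, tract_len)
    parts <- c(parts, tract)
    tracts <- rbind(tracts, data.frame(start = pos + 1L,
                                       end = pos + tract_len,
                                       seq = tract,
                                       stringsAsFactors = FALSE))
    pos <- pos + tract_len
  }
  pad <- sample(pad_range[1]:pad_range[2], 1L)
  parts <- c(parts, paste(sample(aa_alphabet(), pad, replace = TRUE,
                                 prob = background), collapse = ""))
  list(seq = paste(parts, collapse = ""), tracts = tracts)
}

#' Generate a synthetic protein family with truth table
#'
#' Builds every protein of the specification by concatenating
#' background linkers and planted elements, emits the corresponding
#' domain-hit rows (E-values drawn log-uniformly strictly inside the
#' intended tier window) and a complete truth table.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `proteins` (record `data.frame`), `hits`
#'   (domain-hit `data.frame`), `truth` (`data.frame` of planted
#'   elements: `protein_id`, `subfamily`, `kind`, `class`, `tier`,
#'   `start`, `end`, `zone`, `profile`, `seq`), and `reference`
#'   (list: `id` of the reference protein, `vwa` reference sequence).
#' @export
plant_family <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  proteins <- list()
  hits <- list()
  truth <- list()
  counter <- 0L
  lcr_residues <- c("D", "S", "K", "T", "G", "Q", "P", "N")
  for (ti in seq_along(spec$templates)) {
    tpl <- spec$templates[[ti]]
    for (pi in seq_len(spec$n_per_subfamily[ti])) {
      counter <- counter + 1L
      id <- sprintf("%s_%02d", tpl$name, pi)
      pseed <- derive_seed(spec$seed, counter)
      built <- withr::with_seed(pseed, {
        .build_protein(id, tpl, spec, lcr_residues)
      })
      proteins[[counter]] <- data.frame(id = id, taxon = tpl$name,
                                        seq = built$seq,
                                        stringsAsFactors = FALSE)
      hits[counter] <- list(built$hits)  # may be NULL (no elements)
      truth[[counter]] <- built$truth
    }
  }
  ref_id <- sprintf("%s_01", spec$templates[[1]]$name)
  list(proteins = do.call(rbind, proteins),
       hits = do.call(rbind, hits),
       truth = do.call(rbind, truth),
       reference = list(id = ref_id, vwa = consensus_sequence("VWA")))
}

# Internal: build one protein under the caller's seeded RNG.
.build_protein <- function(id, tpl, spec, lcr_residues) {
  parts <- character(0)
  pos <- 0L
  truth <- list()
  hits <- list()
  add_part <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    span <- c(pos + 1L, pos + nchar(s))
    pos <<- pos + nchar(s)
    span
  }
  add_truth <- function(kind, class = NA, tier = NA, span = c(NA, NA),
                        zone = NA, profile = NA, seq = NA) {
    truth[[length(truth) + 1L]] <<- data.frame(
      protein_id = id, subfamily = tpl$name, kind = kind,
      class = class, tier = tier, start = span[1], end = span[2],
      zone = zone, profile = profile, seq = seq,
      stringsAsFactors = FALSE)
  }
  add_hit <- function(class, span, tier) {
    hits[[length(hits) + 1L]] <<- data.frame(
      protein_id = id, domain_class = class, start = span[1],
      end = span[2], score = round(runif(1L, 25, 90), 1),
      ievalue = .sample_ievalue(tier), stringsAsFactors = FALSE)
  }
  add_zone_seg <- function(zone, n_tracts) {
    seg <- .zone_segment(n_tracts, spec$lcr_tract_len, lcr_residues,
                         spec$background)
    span <- add_part(seg$seq)
    if (nrow(seg$tracts)) {
      for (r in seq_len(nrow(seg$tracts))) {
        add_truth("lcr", span = span[1] - 1L +
                    c(seg$tracts$start[r], seg$tracts$end[r]),
                  zone = zone, seq = seg$tracts$seq[r])
      }
    }
  }
  bg_linker <- function(lo, hi) {
    paste(sample(aa_alphabet(), sample(lo:hi, 1L), replace = TRUE,
                 prob = spec$background), collapse = "")
  }
  plan <- tpl$lcr_plan

  if (tpl$signal) {
    sp <- paste0("M", paste(sample(aa_alphabet(),
                                   .element_lengths[["signal"]] - 1L,
                                   replace = TRUE,
                                   prob = spec$background),
                            collapse = ""))
    span <- add_part(sp)
    add_truth("signal", class = "signal", span = span, seq = sp)
  }
  add_zone_seg("zone1", plan[["zone1"]])
  # tandem VWA block, zone2 tracts distributed round-robin over gaps
  gap_counts <- integer(max(0L, tpl$n_vwa - 1L))
  if (length(gap_counts) && plan[["zone2"]] > 0) {
    gi <- rep_len(seq_along(gap_counts), plan[["zone2"]])
    for (g in gi) gap_counts[g] <- gap_counts[g] + 1L
  }
  for (v in seq_len(tpl$n_vwa)) {
    dom <- .mutate_seq(consensus_sequence("VWA"), spec$domain_identity)
    span <- add_part(dom)
    add_truth("domain", class = "VWA", tier = "confident", span = span,
              seq = dom)
    add_hit("VWA", span, "confident")
    if (v < tpl$n_vwa) add_zone_seg("zone2", gap_counts[v])
  }
  has_cb <- length(tpl$cb_tiers) > 0L
  if (has_cb) {
    add_zone_seg("zone3", plan[["zone3"]])
    for (s in seq_len(tpl$n_sushi)) {
      dom <- .mutate_seq(consensus_sequence("Sushi"),
                         spec$domain_identity)
      span <- add_part(dom)
      add_truth("domain", class = "Sushi", tier = "confident",
                span = span, seq = dom)
      add_hit("Sushi", span, "confident")
      add_part(bg_linker(12L, 25L))
    }
    for (tier in tpl$cb_tiers) {
      dom <- .mutate_seq(consensus_sequence("CBM_14"),
                         spec$domain_identity)
      span <- add_part(dom)
      add_truth("domain", class = "CBM_14", tier = tier, span = span,
                seq = dom)
      add_hit("CBM_14", span, tier)
      add_part(bg_linker(10L, 25L))
    }
  }
  if (tpl$lg) {
    anchors <- lg_anchors()
    n_seq <- .mutate_seq(anchors$n, tpl$anchor_identity)
    span_n <- add_part(n_seq)
    add_truth("anchor_n", span = span_n, seq = n_seq)
    ins_len <- sample(tpl$insert_len_range[1]:tpl$insert_len_range[2], 1L)
    profile <- spec$profiles[[tpl$insert_profile]]
    n_tr <- plan[["zone4"]]
    tract_res <- names(profile)[which.max(profile)]
    tract_total <- n_tr * spec$lcr_tract_len
    if (ins_len < tract_total + (n_tr + 1L) * 20L) {
      ins_len <- tract_total + (n_tr + 1L) * 20L
    }
    free <- ins_len - tract_total
    cuts <- if (n_tr > 0) {
      base <- rep(free %/% (n_tr + 1L), n_tr + 1L)
      base[1] <- base[1] + free %% (n_tr + 1L)
      base
    } else free
    ins_parts <- character(0)
    tract_rel <- data.frame(start = integer(0), end = integer(0))
    rel <- 0L
    for (k in seq_len(n_tr + 1L)) {
      chunk <- paste(sample(aa_alphabet(), cuts[k], replace = TRUE,
                            prob = profile), collapse = "")
      ins_parts <- c(ins_parts, chunk)
      rel <- rel + cuts[k]
      if (k <= n_tr) {
        ins_parts <- c(ins_parts, strrep(tract_res, spec$lcr_tract_len))
        tract_rel <- rbind(tract_rel,
                           data.frame(start = rel + 1L,
                                      end = rel + spec$lcr_tract_len))
        rel <- rel + spec$lcr_tract_len
      }
    }
    ins_seq <- paste(ins_parts, collapse = "")
    span_i <- add_part(ins_seq)
    add_truth("insert", span = span_i, profile = tpl$insert_profile,
              seq = ins_seq)
    if (n_tr > 0) {
      for (r in seq_len(nrow(tract_rel))) {
        add_truth("lcr", span = span_i[1] - 1L +
                    c(tract_rel$start[r], tract_rel$end[r]),
                  zone = "zone4",
                  seq = strrep(tract_res, spec$lcr_tract_len))
      }
    }
    c_seq <- .mutate_seq(anchors$c, tpl$anchor_identity)
    span_c <- add_part(c_seq)
    add_truth("anchor_c", span = span_c, seq = c_seq)
    lg_status <- if (span_c[1] - span_n[2] - 1L <= 250L) {
      "complete"
    } else "partial"
    add_truth("lg_status", class = lg_status)
  } else {
    add_truth("lg_status", class = "absent")
  }
  add_part(bg_linker(15L, 30L))
  list(seq = paste(parts, collapse = ""),
       hits = if (length(hits)) do.call(rbind, hits) else NULL,
       truth = do.call(rbind, truth))
}

#' Plant a support-labelled family tree
#'
#' Builds a rooted binary tree whose leaves are the specification's
#' protein ids: random subtrees per subfamily, subfamily ancestor
#' branches labelled with supports drawn from the planted class's
#' range (strong: UFBoot 95-100 / SH-aLRT 85-100; medium: 75-94 /
#' 65-100; weak below both), a strongly supported family ancestor, a
#' weak spine joining subfamilies, and outgroup leaves attached outside
#' the family clade. The first protein of the first template is the
#' designated reference leaf.
#'
#' @param spec A [synthetic_spec()] (needs >= 2 subfamilies of >= 2
#'   leaves each).
#' @return List with `tree` ([parse_support_tree()] object), `newick`
#'   (string), `truth` (`data.frame`: `leaf`, `subfamily`,
#'   `support_class`), `reference`, `outgroup`.
#' @export
plant_support_tree <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$templates) < 2L || any(spec$n_per_subfamily < 2L)) {
    stop("need >= 2 subfamilies with >= 2 leaves each", call. = FALSE)
  }
  withr::with_seed(derive_seed(spec$seed, 999983L), {
    bl <- function() sprintf("%.4f", runif(1L, 0.02, 0.3))
    lab <- function(class) {
      r <- switch(class,
                  strong = c(sample(85:100, 1L), sample(95:100, 1L)),
                  medium = c(sample(65:100, 1L), sample(75:94, 1L)),
                  weak = c(sample(0:64, 1L), sample(0:74, 1L)),
                  stop("unknown support class ", class, call. = FALSE))
      paste0(r[1], "/", r[2])
    }
    subtree <- function(leaves, class) {
      if (length(leaves) == 1L) return(paste0(leaves, ":", bl()))
      k <- if (length(leaves) == 2L) 1L else sample(length(leaves) - 1L, 1L)
      sh <- sample(leaves)
      paste0("(", subtree(sh[1:k], class), ",",
             subtree(sh[-(1:k)], class), ")", lab(class), ":", bl())
    }
    clades <- character(0)
    truth <- list()
    for (ti in seq_along(spec$templates)) {
      tpl <- spec$templates[[ti]]
      leaves <- sprintf("%s_%02d", tpl$name,
                        seq_len(spec$n_per_subfamily[ti]))
      k <- if (length(leaves) == 2L) 1L else sample(length(leaves) - 1L, 1L)
      sh <- sample(leaves)
      # nested nodes inherit the subfamily's class so the planted
      # ancestor is always the maximal supported clade
      cl <- paste0("(", subtree(sh[1:k], tpl$support_class), ",",
                   subtree(sh[-(1:k)], tpl$support_class), ")",
                   lab(tpl$support_class), ":", bl())
      clades <- c(clades, cl)
      truth[[ti]] <- data.frame(leaf = leaves, subfamily = tpl$name,
                                support_class = tpl$support_class,
                                stringsAsFactors = FALSE)
    }
    # weak spine joining subfamilies; the top join is the family node
    spine <- clades[1]
    if (length(clades) > 2L) {
      for (i in 2:(length(clades) - 1L)) {
        spine <- paste0("(", spine, ",", clades[i], ")", lab("weak"),
                        ":", bl())
      }
    }
    family <- if (length(clades) >= 2L) {
      paste0("(", spine, ",", clades[length(clades)], ")",
             lab("strong"), ":", bl())
    } else {
      spine
    }
    og <- sprintf("outgroup_%02d", seq_len(max(1L, spec$n_outgroup)))
    og_sub <- if (length(og) == 1L) {
      paste0(og, ":", bl())
    } else {
      subtree(og, "weak")
    }
    newick <- paste0("(", family, ",", og_sub, ");")
    list(tree = parse_support_tree(newick), newick = newick,
         truth = do.call(rbind, truth),
         reference = sprintf("%s_01", spec$templates[[1]]$name),
         outgroup = og)
  })
}

#' Write the complete fixture set for a specification
#'
#' Emits `proteins.fasta`, `hits.tsv`, `tree.nwk`, `truth.tsv` and
#' `spec.yaml` into `dir`. Re-running with the same specification
#' reproduces byte-identical files.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
emit_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  fam <- plant_family(spec)
  tre <- plant_support_tree(spec)
  paths <- c(proteins = file.path(dir, "proteins.fasta"),
             hits = file.path(dir, "hits.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.tsv"),
             spec = file.path(dir, "spec.yaml"))
  write_fasta(fam$proteins, paths[["proteins"]])
  write_hit_table(fam$hits, paths[["hits"]])
  writeLines(tre$newick, paths[["tree"]])
  truth <- fam$truth
  extra <- data.frame(
    protein_id = c(tre$reference, tre$outgroup),
    subfamily = NA_character_,
    kind = c("reference", rep("outgroup", length(tre$outgroup))),
    class = NA_character_, tier = NA_character_,
    start = NA_integer_, end = NA_integer_,
    zone = NA_character_, profile = NA_character_, seq = NA_character_,
    stringsAsFactors = FALSE)
  truth <- rbind(truth, extra)
  write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  spec_out <- spec
  spec_out$templates <- lapply(spec$templates, function(t) {
    t$lcr_plan <- as.list(t$lcr_plan)
    unclass(t)
  })
  spec_out$background <- as.list(round(spec$background, 10))
  spec_out$profiles <- lapply(spec$profiles,
                              function(p) as.list(round(p, 10)))
  yaml::write_yaml(unclass(spec_out), paths[["spec"]])
  invisible(paths)
}
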