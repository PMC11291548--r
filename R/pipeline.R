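#' Pipeline run configuration
#'
#' Strict configuration for [run_pipeline()]: unknown keys are fatal
#' (the method is threshold-heavy and a silent typo would change the
#' science). All thresholds must be positive.
#'
#' @param fasta Path to the protein FASTA.
#' @param hits Path to the domain-hit table.
#' @param tree Path to the dual-support Newick tree.
#' @param outdir Output directory.
#' @param references Character vector of reference leaf names
#'   (PfuPif-like anchors of the family clade).
#' @param outgroup Optional outgroup leaf names; when given the tree is
#'   re-rooted on their MRCA edge before clade extraction.
#' @param signal_tsv Optional TSV of signal-peptide annotation
#'   (`protein_id`, `start`, `end`); prediction is not performed.
#' @param homology_threshold E-value gate for VWA homology to the
#'   reference (default `1e-10`).
#' @param confident_ceiling Confident-domain E-value ceiling (default
#'   `1e-5`).
#' @param family_min_class,subfamily_min_class Support classes for
#'   family/subfamily extraction (defaults `"strong"` / `"medium"`).
#' @param medium_ufboot_only Use the UFBoot-only medium convention.
#' @param anchor_min_identity,anchor_min_coverage LG-anchor acceptance.
#' @param max_complete_gap Largest inter-anchor gap still counted as a
#'   complete LG domain (default 250).
#' @param lcr LCR parameters ([lcr_params()]).
#' @param reference_vwa Optional explicit reference VWA sequence; by
#'   default the first confident VWA region of the first reference
#'   protein is used.
#' @param zscore Standardize compositions before clustering.
#' @param seed Integer seed for any stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta, hits, tree, outdir,
                       references, outgroup = character(0),
                       signal_tsv = NULL,
                       homology_threshold = 1e-10,
                       confident_ceiling = 1e-5,
                       family_min_class = "strong",
                       subfamily_min_class = "medium",
                       medium_ufboot_only = FALSE,
                       anchor_min_identity = 0.5,
                       anchor_min_coverage = 0.8,
                       max_complete_gap = 250L,
                       lcr = lcr_params(),
                       reference_vwa = NULL,
                       zscore = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (any(c(homology_threshold, confident_ceiling, anchor_min_identity,
            anchor_min_coverage, max_complete_gap) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML mapping whose keys are the [run_config()] arguments.
#' Unknown keys are a hard error naming the key.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown config key: ", bad[1], call. = FALSE)
  }
  if (!is.null(y$lcr)) y$lcr <- do.call(lcr_params, y$lcr)
  do.call(run_config, y)
}

#' Run the full family-delimitation pipeline
#'
#' Executes, in dependency order: input parsing, VWA homology gating
#' against the reference, per-protein architecture assembly, LG anchor
#' location and insert extraction, low-complexity detection with zone
#' assignment, composition clustering of inserts and of LCRs, and
#' family/subfamily extraction from the support tree. Per-protein
#' failures are logged and skipped without aborting the run; the skip
#' count is reported. Results are written to `config$outdir` and the
#' run is byte-for-byte reproducible from the same inputs, config and
#' seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage messages.
#' @return A `run_report`: list with `summary` (per-protein
#'   `data.frame`), `gate`, `partition`, `insert_clusters`,
#'   `lcr_clusters`, `lcrs`, `inserts`, `n_failed`, `config`, `seed`,
#'   `version`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[pifarch] ", ...)

  proteins <- read_fasta(config$fasta)
  lens <- setNames(nchar(proteins$seq), proteins$id)
  hits <- read_domain_hit_table(config$hits, config$confident_ceiling,
                                lengths = lens)
  stree <- parse_support_tree(config$tree)
  missing_ref <- setdiff(config$references, stree$phylo$tip.label)
  if (length(missing_ref) > 0) {
    stop("reference leaf missing from tree: ", missing_ref[1],
         call. = FALSE)
  }
  if (length(config$outgroup) > 0) {
    phy <- ape::root(stree$phylo, outgroup = config$outgroup,
                     resolve.root = TRUE, edgelabel = TRUE)
    stree <- parse_support_tree(ape::write.tree(phy))
  }
  signals <- NULL
  if (!is.null(config$signal_tsv)) {
    signals <- read.delim(config$signal_tsv, stringsAsFactors = FALSE)
    stopifnot(all(c("protein_id", "start", "end") %in% names(signals)))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say(nrow(proteins), " proteins, ", nrow(hits), " hits, ",
      length(stree$phylo$tip.label), " tree leaves")

  # --- homology gate on confident VWA regions -------------------------
  vwa_hits <- hits[hits$domain_class == "VWA" & !hits$relaxed, ,
                   drop = FALSE]
  regions <- data.frame(
    protein_id = vwa_hits$protein_id,
    seq = substr(proteins$seq[match(vwa_hits$protein_id, proteins$id)],
                 vwa_hits$start, vwa_hits$end),
    stringsAsFactors = FALSE)
  ref_vwa <- config$reference_vwa
  if (is.null(ref_vwa)) {
    ref_rows <- which(vwa_hits$protein_id == config$references[1])
    if (length(ref_rows) == 0) {
      stop("no confident VWA hit on reference protein ",
           config$references[1], call. = FALSE)
    }
    ref_vwa <- regions$seq[ref_rows[1]]
  }
  gate <- select_candidates(regions, ref_vwa,
                            threshold = config$homology_threshold)
  gate$start <- vwa_hits$start
  gate$end <- vwa_hits$end
  say("gate: ", sum(gate$pass), "/", nrow(gate), " VWA regions pass")

  # --- per-protein characterization ----------------------------------
  n_failed <- 0L
  per <- vector("list", nrow(proteins))
  inserts <- list()
  lcr_all <- list()
  for (i in seq_len(nrow(proteins))) {
    p <- proteins[i, ]
    res <- tryCatch({
      ph <- hits[hits$protein_id == p$id, , drop = FALSE]
      sig <- NULL
      if (!is.null(signals)) {
        sr <- signals[signals$protein_id == p$id, , drop = FALSE]
        if (nrow(sr) > 0) sig <- c(sr$start[1], sr$end[1])
      }
      lg <- find_lg_region(p, min_identity = config$anchor_min_identity,
                           min_coverage = config$anchor_min_coverage)
      anch <- list()
      if (!is.null(lg$n)) anch$n <- lg$n$span
      if (!is.null(lg$c)) anch$c <- lg$c$span
      arch <- assemble_architecture(
        p, ph, signal_span = sig, anchors = anch,
        confident_ceiling = config$confident_ceiling,
        max_complete_gap = config$max_complete_gap)
      zones <- zone_intervals(arch)
      lcrs <- assign_zones(detect_lcrs(p, config$lcr), zones)
      if (!is.null(lg$insert) && lg$insert$length > 0) {
        inserts[[p$id]] <- lg$insert
      }
      if (nrow(lcrs) > 0) lcr_all[[p$id]] <- lcrs
      tiers <- sort(arch$elements$tier[arch$elements$class == "CBM_14"])
      zc <- table(factor(lcrs$zone, levels = c(paste0("zone", 1:4),
                                               "outside")))
      data.frame(
        protein_id = p$id, length = arch$length, n_vwa = arch$n_vwa,
        cb_tiers = paste(tiers, collapse = ","),
        has_cb = arch$has_cb, lg_status = arch$lg_status,
        insert_length = if (!is.null(lg$insert)) lg$insert$length
                        else NA_integer_,
        lcr_zone1 = as.integer(zc[["zone1"]]),
        lcr_zone2 = as.integer(zc[["zone2"]]),
        lcr_zone3 = as.integer(zc[["zone3"]]),
        lcr_zone4 = as.integer(zc[["zone4"]]),
        lcr_outside = as.integer(zc[["outside"]]),
        stringsAsFactors = FALSE)
    }, error = function(e) {
      say("protein ", p$id, " failed: ", conditionMessage(e))
      n_failed <<- n_failed + 1L
      NULL
    })
    per[[i]] <- res
  }
  summary <- do.call(rbind, per)
  say(nrow(summary), " proteins characterized, ", n_failed, " skipped")

  # --- clade / subfamily extraction ----------------------------------
  family <- find_family_clade(stree, config$references,
                              min_class = config$family_min_class,
                              medium_ufboot_only = config$medium_ufboot_only)
  partition <- partition_subfamilies(
    stree, family, min_class = config$subfamily_min_class,
    medium_ufboot_only = config$medium_ufboot_only)
  summary$subfamily <- unname(
    partition$membership[summary$protein_id])
  say("family clade: ", length(family$tips), " leaves, ",
      nrow(partition$subfamilies), " subfamilies")

  # --- composition clustering ----------------------------------------
  insert_clusters <- NULL
  if (length(inserts) >= 3L) {
    iseqs <- vapply(inserts, `[[`, "", "seq")
    imat <- composition_matrix(iseqs)
    insert_clusters <- choose_k(imat, standardize = config$zscore)
    write_matrix_tsv(imat, file.path(config$outdir, "insert_comp.tsv"))
  }
  summary$insert_cluster <- if (!is.null(insert_clusters)) {
    unname(insert_clusters$labels[summary$protein_id])
  } else NA_integer_
  lcr_clusters <- NULL
  lcr_df <- if (length(lcr_all)) do.call(rbind, lcr_all) else NULL
  if (!is.null(lcr_df) && nrow(lcr_df) >= 3L) {
    ids <- sprintf("%s|%s|%d", lcr_df$protein_id, lcr_df$zone,
                   lcr_df$ordinal)
    seqs <- substr(proteins$seq[match(lcr_df$protein_id, proteins$id)],
                   lcr_df$start, lcr_df$end)
    lmat <- composition_matrix(setNames(seqs, ids))
    lcr_clusters <- choose_k(lmat, standardize = config$zscore)
    write_matrix_tsv(lmat, file.path(config$outdir, "lcr_comp.tsv"))
  }

  # --- report ---------------------------------------------------------
  rownames(summary) <- NULL
  report <- structure(
    list(summary = summary, gate = gate, family = family,
         partition = partition, insert_clusters = insert_clusters,
         lcr_clusters = lcr_clusters, lcrs = lcr_df, inserts = inserts,
         n_failed = n_failed, config = config, seed = config$seed,
         version = as.character(utils::packageVersion("pifarch"))),
    class = "run_report")
  write_run_report(report, config$outdir)
  report
}

#' Write the run report files
#'
#' Writes `report.tsv` (per-protein summary), `gate.tsv`,
#' `subfamilies.tsv`, `lcrs.tsv` and `run.yaml` (config echo, seed,
#' version) into `dir`. Deterministic: no timestamps.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$summary, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  gate_out <- report$gate
  gate_out$evalue <- sprintf("%.6e", gate_out$evalue)
  write.table(gate_out, file.path(dir, "gate.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$partition$subfamilies,
              file.path(dir, "subfamilies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$lcrs)) {
    lcr_out <- report$lcrs
    lcr_out$mean_entropy <- sprintf("%.4f", lcr_out$mean_entropy)
    write.table(lcr_out, file.path(dir, "lcrs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  cfg <- report$config
  cfg$lcr <- unclass(cfg$lcr)
  meta <- list(version = report$version, seed = report$seed,
               config = unclass(cfg),
               n_failed = report$n_failed)
  yaml::write_yaml(meta, file.path(dir, "run.yaml"))
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("pifarch run_report:", nrow(x$summary), "proteins (",
      x$n_failed, "failed ),",
      nrow(x$partition$subfamilies), "subfamilies\n")
  if (!is.null(x$insert_clusters)) {
    cat("  insert clusters: k =", x$insert_clusters$chosen_k, "\n")
  }
  invisible(x)
}
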