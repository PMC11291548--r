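#' Known domain class labels
#'
#' Domain classes recognised by the architecture machinery. Anything
#' else read from a hit table is mapped to `"other"` with a warning.
#' @return Character vector.
#' @export
domain_classes <- function() {
  c("VWA", "CBM_14", "Laminin_G_3", "Sushi", "Sulfotransfer_1", "other")
}

#' Read a domain-hit table
#'
#' Reads per-domain hits in either the package's simplified 6-column
#' tab-separated dialect (header `protein_id, domain_class, start, end,
#' score, ievalue`) or, with `dialect = "domtblout"`, a strict HMMER
#' `--domtblout` file whose columns are mapped as target name ->
#' `protein_id`, query name -> `domain_class`, ali from/to ->
#' `start`/`end`, i-Evalue -> `ievalue`. Coordinates are 1-based
#' inclusive alignment coordinates throughout.
#'
#' Hits with independent E-value below `evalue_ceiling` are confident;
#' rows at or above the ceiling are retained but flagged `relaxed = TRUE`
#' so that degenerate chitin-binding-like matches remain available for
#' tier classification.
#'
#' @param path Path to the hit table.
#' @param evalue_ceiling Positive confidence ceiling on the independent
#'   E-value (default `1e-5`, the conventional profile-search cutoff).
#' @param dialect `"tsv"` (default) or `"domtblout"`.
#' @param lengths Optional named integer vector of protein lengths; when
#'   supplied, spans exceeding a protein's length are hard errors.
#' @return `data.frame` with columns `protein_id`, `domain_class`,
#'   `start`, `end`, `score`, `ievalue`, `relaxed`.
#' @export
read_domain_hit_table <- function(path, evalue_ceiling = 1e-5,
                                  dialect = c("tsv", "domtblout"),
                                  lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  if (!is.numeric(evalue_ceiling) || evalue_ceiling <= 0) {
    stop("evalue_ceiling must be > 0", call. = FALSE)
  }
  if (dialect == "tsv") {
    d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("protein_id", "domain_class", "start", "end", "score", "ievalue")
    if (!all(need %in% names(d))) {
      stop("hit table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    d <- d[, need]
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "[ \t]+")
    bad <- which(vapply(f, length, 1L) < 23L)
    if (length(bad) > 0) {
      stop("malformed domtblout row(s) at line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    d <- data.frame(
      protein_id = vapply(f, `[[`, "", 1L),
      domain_class = vapply(f, `[[`, "", 4L),
      start = as.integer(vapply(f, `[[`, "", 18L)),
      end = as.integer(vapply(f, `[[`, "", 19L)),
      score = as.numeric(vapply(f, `[[`, "", 14L)),
      ievalue = as.numeric(vapply(f, `[[`, "", 13L)),
      stringsAsFactors = FALSE
    )
  }
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  d$score <- as.numeric(d$score)
  d$ievalue <- as.numeric(d$ievalue)
  malformed <- !is.finite(d$start) | !is.finite(d$end) |
    !is.finite(d$ievalue) | d$ievalue < 0 | d$start < 1L
  if (any(malformed)) {
    stop("malformed hit row(s) at line(s) ",
         paste(utils::head(which(malformed) + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(d$start > d$end)) {
    i <- which(d$start > d$end)[1]
    stop("hit with start > end (", d$start[i], " > ", d$end[i],
         ") for protein ", d$protein_id[i], call. = FALSE)
  }
  unknown <- !(d$domain_class %in% domain_classes())
  if (any(unknown)) {
    warning("unknown domain class(es) mapped to 'other': ",
            paste(unique(d$domain_class[unknown]), collapse = ", "),
            call. = FALSE)
    d$domain_class[unknown] <- "other"
  }
  if (!is.null(lengths)) {
    known <- d$protein_id %in% names(lengths)
    over <- known & d$end > lengths[d$protein_id]
    if (any(over)) {
      i <- which(over)[1]
      stop("hit end ", d$end[i], " exceeds length of protein ",
           d$protein_id[i], call. = FALSE)
    }
  }
  d$relaxed <- d$ievalue >= evalue_ceiling
  rownames(d) <- NULL
  d
}

#' Write a domain-hit table in the package dialect
#'
#' @param hits `data.frame` as returned by [read_domain_hit_table()]
#'   (the `relaxed` column, if present, is dropped on write).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  need <- c("protein_id", "domain_class", "start", "end", "score", "ievalue")
  stopifnot(all(need %in% names(hits)))
  out <- hits[, need]
  out$score <- sprintf("%.1f", out$score)
  out$ievalue <- sprintf("%.6e", out$ievalue)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labelled numeric matrix as TSV
#'
#' Writes a row-and-column-labelled real matrix so that a round-trip
#' through [read_matrix_tsv()] reproduces the values to 1e-9. UTF-8,
#' `'.'` decimal separator, non-finite entries are hard errors.
#'
#' @param mat Numeric matrix with unique row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix must have row and column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("row and column labels must be unique", call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    stop("non-finite values cannot be written", call. = FALSE)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r) {
    paste(format(r, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = "\t")
  })
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a labelled numeric matrix written by [write_matrix_tsv()]
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, row.names = 1L, check.names = FALSE,
                  fileEncoding = "UTF-8")
  as.matrix(d)
}
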