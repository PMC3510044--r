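#' @name array_io
#' @title File formats used by the pipeline
#' @description
#' The pipeline touches four plain-text formats: a GPR-dialect TSV for
#' spot-level array data, GMT for gene-set catalogs, generic TSV for score
#' and hit tables, and JSON for run summaries and simulation ground truth.
#' Only the columns the analysis consumes are required from the GPR dialect:
#' `Name`, `Block`, `F635 Median`, `F532 Median`, `Flags`. `Name` encodes
#' the probe as `<gene_id>|<feature>` with feature one of exon / intron /
#' junction; second-intron probes carry a `_2` suffix on the gene id. Which
#' channel holds the mutant sample is a property of the array (its dye
#' orientation), not of the file, and lives in the sample metadata.
NULL

SPOT_COLUMNS <- c("Name", "Block", "F635 Median", "F532 Median", "Flags")
FEATURES <- c("exon", "intron", "junction")

#' Write a spot table in GPR-dialect TSV
#'
#' @param spots Data.frame with columns `gene_id`, `feature`, `block`,
#'   `i_ch1`, `i_ch2`, `flag` (channel 1 = ~635 nm scan, channel 2 =
#'   ~532 nm).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  stopifnot(all(c("gene_id", "feature", "block", "i_ch1", "i_ch2", "flag")
                %in% names(spots)))
  out <- data.frame(
    Name = paste0(spots$gene_id, "|", spots$feature),
    Block = as.integer(spots$block),
    `F635 Median` = formatC(spots$i_ch1, digits = 6, format = "g"),
    `F532 Median` = formatC(spots$i_ch2, digits = 6, format = "g"),
    Flags = as.integer(spots$flag),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GPR-dialect spot table
#'
#' Tolerates and ignores extra GenePix columns; requires `Name`, `Block`,
#' `F635 Median`, `F532 Median`, `Flags`. Rows with unparseable intensities
#' are dropped with a warning naming the row; negative intensities are an
#' error. The count of flagged rows is reported via `message()`.
#'
#' @param path File to read.
#' @param sample_meta Optional list of array metadata (`sample_id`,
#'   `genotype`, `reference`, `temperature`, `bio_rep`,
#'   `orientation` in `"forward"`/`"flipped"`), attached as the
#'   `"sample"` attribute of the result.
#' @return Data.frame of spot records (`gene_id`, `feature`, `block`,
#'   `i_ch1`, `i_ch2`, `flag`).
#' @export
read_spot_table <- function(path, sample_meta = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           colClasses = "character",
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(SPOT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("spot table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  name_parts <- strsplit(raw$Name, "|", fixed = TRUE)
  bad_name <- lengths(name_parts) != 2L |
    !vapply(name_parts, function(p) p[length(p)] %in% FEATURES, logical(1))
  i1 <- suppressWarnings(as.numeric(raw$`F635 Median`))
  i2 <- suppressWarnings(as.numeric(raw$`F532 Median`))
  neg <- which(!is.na(i1) & i1 < 0 | !is.na(i2) & i2 < 0)
  if (length(neg)) {
    stop(sprintf("negative intensity at data row %d", neg[1]), call. = FALSE)
  }
  unparseable <- which(is.na(i1) | is.na(i2) | bad_name)
  keep <- setdiff(seq_len(nrow(raw)), unparseable)
  if (length(unparseable)) {
    warning(sprintf(
      "dropped %d unparseable spot row(s) (rows: %s)",
      length(unparseable),
      paste(utils::head(unparseable, 5L), collapse = ", ")), call. = FALSE)
  }
  spots <- data.frame(
    gene_id = vapply(name_parts[keep], `[`, character(1), 1L),
    feature = vapply(name_parts[keep], `[`, character(1), 2L),
    block = as.integer(raw$Block[keep]),
    i_ch1 = i1[keep],
    i_ch2 = i2[keep],
    flag = as.integer(raw$Flags[keep]),
    stringsAsFactors = FALSE
  )
  n_flagged <- sum(spots$flag < 0)
  message(sprintf("%s: %d spots read, %d flagged for exclusion",
                  basename(path), nrow(spots), n_flagged))
  if (!is.null(sample_meta)) attr(spots, "sample") <- sample_meta
  spots
}

#' Read a GMT gene-set file into a catalog
#'
#' Each line is `set_id<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a line are deduplicated with a warning. The
#' universe defaults to the union of all members unless supplied.
#'
#' @param path GMT file.
#' @param universe Optional character vector declaring the gene universe.
#' @return A [gene_catalog()] (zero-set catalog for an empty file).
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(list(sets = list(), descriptions = character(0),
                          universe = unique(as.character(universe %||% character(0)))),
                     class = "gene_catalog"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]),
         call. = FALSE)
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  desc <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1)))
  if (ndup > 0) {
    warning(sprintf("%d duplicate member(s) within GMT lines deduplicated",
                    ndup), call. = FALSE)
    members <- lapply(members, unique)
  }
  names(members) <- ids
  if (is.null(universe)) universe <- unique(unlist(members, use.names = FALSE))
  gene_catalog(members, universe, descriptions = desc)
}

#' Write a catalog as GMT
#'
#' @param catalog A [gene_catalog()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  lines <- vapply(names(catalog$sets), function(sid) {
    paste(c(sid, catalog$descriptions[[sid]], catalog$sets[[sid]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene score table (e.g. E-MAP genetic-interaction scores)
#'
#' @param path TSV with a header row.
#' @param score_column Name of the numeric score column.
#' @param gene_column Name of the gene-id column (default `"gene"`).
#' @return Named numeric vector gene -> score. Duplicate genes keep the most
#'   negative score (the strongest negative interaction) with a warning;
#'   `NA` scores are skipped with a warning.
#' @export
read_scores_table <- function(path, score_column = "score",
                              gene_column = "gene") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, quote = "",
                           colClasses = "character",
                           fileEncoding = "UTF-8")
  for (col in c(gene_column, score_column)) {
    if (!col %in% names(tab)) {
      stop("scores table is missing column: ", col, call. = FALSE)
    }
  }
  raw <- tab[[score_column]]
  is_na <- is.na(raw) | raw %in% c("NA", "")
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!is_na & is.na(val))
  if (length(bad)) {
    stop(sprintf("non-numeric score %s at data row %d",
                 dQuote(raw[bad[1]]), bad[1]), call. = FALSE)
  }
  if (any(is_na)) {
    warning(sprintf("skipped %d row(s) with missing scores", sum(is_na)),
            call. = FALSE)
  }
  genes <- tab[[gene_column]][!is_na]
  val <- val[!is_na]
  if (anyDuplicated(genes)) {
    warning("duplicate gene(s) in score table; keeping most negative score",
            call. = FALSE)
    o <- order(genes, val)   # most negative first within gene
    genes <- genes[o]; val <- val[o]
    keep <- !duplicated(genes)
    genes <- genes[keep]; val <- val[keep]
  }
  stats::setNames(val, genes)
}

#' Write a simple named-vector or data.frame TSV
#'
#' Floats are serialized with 6 significant digits; files are UTF-8 with a
#' header row.
#'
#' @param x Data.frame to write.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 6, format = "g"))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth Ground-truth list from the generators.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  # named atomic vectors must become JSON objects, not bare arrays
  namedify <- function(x) {
    if (is.list(x)) lapply(x, namedify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namedify(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
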