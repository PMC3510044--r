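#' Pipeline configuration for spot-to-profile processing
#'
#' @param min_spots Minimum surviving technical-replicate spots per
#'   (gene, feature) on one array; below it the feature value is missing.
#' @param iai_cutoff Intron Accumulation Index above which (strictly) a gene
#'   is called splicing-defective. Log2 units.
#' @param severity_bins Increasing breakpoints for the severity histogram of
#'   defective genes; with the default `c(0.3, 0.6, 1.0)` the bins are
#'   (0.3, 0.6], (0.6, 1.0], (1.0, Inf).
#' @param normalization `"median_center"` (subtract the array-wide median
#'   log ratio from every spot, removing global dye bias) or `"none"`.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_spots = 3L, iai_cutoff = 0.3,
                            severity_bins = c(0.3, 0.6, 1.0),
                            normalization = c("median_center", "none")) {
  normalization <- match.arg(normalization)
  if (iai_cutoff <= 0) stop("`iai_cutoff` must be positive", call. = FALSE)
  if (is.unsorted(severity_bins, strictly = TRUE)) {
    stop("`severity_bins` must be strictly increasing", call. = FALSE)
  }
  if (min_spots < 1L) stop("`min_spots` must be >= 1", call. = FALSE)
  structure(list(min_spots = as.integer(min_spots), iai_cutoff = iai_cutoff,
                 severity_bins = severity_bins, normalization = normalization),
            class = "pipeline_config")
}

#' Per-spot log2 mutant/reference ratio
#'
#' The ratio of the two channel median intensities, oriented so the value is
#' always mutant over wild-type reference: on a forward array the mutant is
#' in channel 1, on a dye-flipped array in channel 2. Spots with a
#' non-positive intensity in either channel yield `NA`.
#'
#' @param i_ch1,i_ch2 Channel median intensities (vectors).
#' @param orientation `"forward"` or `"flipped"`.
#' @return Numeric vector of log2 ratios (NA where degenerate).
#' @export
spot_log_ratio <- function(i_ch1, i_ch2, orientation) {
  orientation <- match.arg(orientation, c("forward", "flipped"))
  lr <- ifelse(i_ch1 > 0 & i_ch2 > 0, log2(i_ch1 / i_ch2), NA_real_)
  if (orientation == "flipped") lr <- -lr
  lr
}

#' Combine technical replicates on one array into feature log ratios
#'
#' Computes spot log ratios (dropping flagged and degenerate spots),
#' median-centers all surviving ratios on the array when
#' `normalization = "median_center"`, then takes the median over surviving
#' technical replicates per (gene, feature). Features with fewer than
#' `min_spots` survivors come back with `log2_ratio = NA`.
#'
#' @param spots Spot data.frame (`gene_id`, `feature`, `i_ch1`, `i_ch2`,
#'   `flag`).
#' @param orientation Dye orientation of the array (`"forward"`/
#'   `"flipped"`); defaults to the `orientation` field of the `"sample"`
#'   attribute when present.
#' @param cfg A [pipeline_config()].
#' @return Data.frame `gene_id`, `feature`, `log2_ratio`, `n_spots_used`.
#' @export
combine_replicates <- function(spots, orientation = NULL,
                               cfg = pipeline_config()) {
  if (is.null(orientation)) {
    orientation <- attr(spots, "sample")$orientation
  }
  if (is.null(orientation)) {
    stop("array dye orientation unknown: pass `orientation`", call. = FALSE)
  }
  lr <- spot_log_ratio(spots$i_ch1, spots$i_ch2, orientation)
  usable <- spots$flag >= 0 & !is.na(lr)
  n_dropped <- sum(!usable)
  if (!any(usable)) {
    warning("array has zero usable spots", call. = FALSE)
    return(data.frame(gene_id = character(0), feature = character(0),
                      log2_ratio = numeric(0), n_spots_used = integer(0),
                      stringsAsFactors = FALSE))
  }
  lr_use <- lr[usable]
  if (cfg$normalization == "median_center") {
    lr_use <- lr_use - stats::median(lr_use)
  }
  key <- paste(spots$gene_id[usable], spots$feature[usable], sep = "\r")
  med <- tapply(lr_use, key, stats::median)
  n <- tapply(lr_use, key, length)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1L),
    feature = vapply(parts, `[`, character(1), 2L),
    log2_ratio = as.numeric(med),
    n_spots_used = as.integer(n),
    stringsAsFactors = FALSE
  )
  out$log2_ratio[out$n_spots_used < cfg$min_spots] <- NA_real_
  out[order(out$gene_id, out$feature), , drop = FALSE]
}

#' Average per-array feature tables over biological replicates
#'
#' Unweighted mean per (gene, feature) over the arrays where the value is
#' non-missing; forward and dye-flipped arrays enter on equal footing since
#' their ratios are already expressed mutant-over-reference.
#'
#' @param tables List of data.frames from [combine_replicates()].
#' @return Data.frame `gene_id`, `feature`, `log2_ratio`, `n_arrays_used`.
#' @export
average_biological <- function(tables) {
  stopifnot(length(tables) >= 1L)
  if (length(tables) == 1L) {
    warning("single replicate: no biological averaging possible",
            call. = FALSE)
  }
  all_tab <- do.call(rbind, tables)
  ok <- !is.na(all_tab$log2_ratio)
  key_all <- paste(all_tab$gene_id, all_tab$feature, sep = "\r")
  keys <- unique(key_all)
  mean_lr <- rep(NA_real_, length(keys))
  n_used <- integer(length(keys))
  if (any(ok)) {
    m <- tapply(all_tab$log2_ratio[ok], key_all[ok], mean)
    n <- tapply(all_tab$log2_ratio[ok], key_all[ok], length)
    idx <- match(names(m), keys)
    mean_lr[idx] <- as.numeric(m)
    n_used[idx] <- as.integer(n)
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene_id = vapply(parts, `[`, character(1), 1L),
    feature = vapply(parts, `[`, character(1), 2L),
    log2_ratio = mean_lr,
    n_arrays_used = n_used,
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id, out$feature), , drop = FALSE]
}

#' Intron Accumulation Index
#'
#' `IAI = intron_lr - exon_lr` in log2 units: the intron (pre-mRNA) change
#' normalized for the exon (total transcript) change, so a pure
#' transcription shift common to both features cancels. Missing inputs give
#' a missing IAI.
#'
#' @param exon_lr,intron_lr Log2 mutant/WT ratios (vectors).
#' @return Numeric vector of IAI values.
#' @export
compute_iai <- function(exon_lr, intron_lr) {
  intron_lr - exon_lr
}

#' Assemble per-gene splicing profiles from an averaged feature table
#'
#' Pivots the long (gene, feature) table to one row per gene id (second
#' introns keep their `_2`-suffixed ids) with exon, intron and junction log
#' ratios and the IAI. Exon values for `_2` rows are inherited from the
#' parent gene, which carries the single exon probe set.
#'
#' @param feature_table Data.frame from [average_biological()] (or
#'   [combine_replicates()] for a single array).
#' @return Data.frame `gene_id`, `exon_lr`, `intron_lr`, `junction_lr`,
#'   `iai`.
#' @export
splicing_profiles <- function(feature_table) {
  ids <- unique(feature_table$gene_id)
  get <- function(id, feat) {
    v <- feature_table$log2_ratio[feature_table$gene_id == id &
                                    feature_table$feature == feat]
    if (length(v)) v[1] else NA_real_
  }
  exon <- vapply(ids, function(id) {
    v <- get(id, "exon")
    if (is.na(v) && grepl("_2$", id)) v <- get(sub("_2$", "", id), "exon")
    v
  }, numeric(1))
  intron <- vapply(ids, get, numeric(1), feat = "intron")
  junction <- vapply(ids, get, numeric(1), feat = "junction")
  keep <- !(is.na(intron) & is.na(junction))  # rows that carry an intron
  out <- data.frame(
    gene_id = ids, exon_lr = unname(exon), intron_lr = unname(intron),
    junction_lr = unname(junction),
    iai = compute_iai(unname(exon), unname(intron)),
    stringsAsFactors = FALSE
  )
  out <- out[keep | !grepl("_2$", out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Call splicing defects and bin their severity
#'
#' A gene (pooling its `_2`-suffixed second-intron rows with the parent) is
#' defective iff any of its introns has IAI strictly greater than
#' `iai_cutoff`. The severity histogram bins defective genes by their
#' maximal IAI using `severity_bins` breakpoints; genes with no defined IAI
#' are reported separately and excluded from the histogram.
#'
#' @param profiles Data.frame from [splicing_profiles()].
#' @param cfg A [pipeline_config()].
#' @return List with `calls` (data.frame `gene`, `max_iai`, `defect_class`
#'   in none/defective/missing), `histogram` (named integer vector of
#'   severity-bin counts over defective genes), `n_defective`, `n_missing`.
#' @export
classify_defects <- function(profiles, cfg = pipeline_config()) {
  parent <- sub("_2$", "", profiles$gene_id)
  genes <- unique(parent)
  max_iai <- vapply(genes, function(g) {
    v <- profiles$iai[parent == g]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  defect_class <- ifelse(is.na(max_iai), "missing",
                         ifelse(max_iai > cfg$iai_cutoff, "defective", "none"))
  calls <- data.frame(gene = genes, max_iai = unname(max_iai),
                      defect_class = unname(defect_class),
                      stringsAsFactors = FALSE)
  breaks <- c(cfg$severity_bins, Inf)
  labels <- c(
    sprintf("(%g,%g]", utils::head(cfg$severity_bins, -1L),
            cfg$severity_bins[-1L]),
    sprintf(">%g", cfg$severity_bins[length(cfg$severity_bins)])
  )
  def <- calls$max_iai[calls$defect_class == "defective"]
  histogram <- table(cut(def, breaks = breaks, labels = labels,
                         right = TRUE))
  histogram <- stats::setNames(as.integer(histogram), labels)
  list(calls = calls, histogram = histogram,
       n_defective = sum(defect_class == "defective"),
       n_missing = sum(defect_class == "missing"))
}

#' Uncentered Pearson correlation
#'
#' The cosine-like similarity `sum(x*y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))`
#' used by classic expression-clustering software; unlike centered Pearson
#' it treats the zero log ratio (no change) as the reference point. Missing
#' entries are excluded pairwise. An all-zero vector has undefined
#' similarity, returned as 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Similarity in [-1, 1].
#' @export
uncentered_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    warning("all-zero vector: uncentered correlation undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  sum(x * y) / (nx * ny)
}

#' Uncentered-Pearson distance matrix (1 - similarity)
#'
#' @param mat Numeric matrix, rows = genes.
#' @return A `dist` object over the rows.
#' @export
uncentered_pearson_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d[i, j] <- d[j, i] <-
          1 - suppressWarnings(uncentered_pearson(mat[i, ], mat[j, ]))
      }
    }
  }
  rownames(d) <- colnames(d) <- rownames(mat)
  stats::as.dist(d)
}

#' Cluster splicing profiles
#'
#' Agglomerative hierarchical clustering of the per-gene profile matrix with
#' average linkage on the 1 - uncentered-Pearson distance, the combination
#' used by Cluster 3.0-style expression analysis. Deterministic given the
#' input row order.
#'
#' @param mat Numeric matrix (rows = genes, columns = features/conditions).
#' @return List with `order` (leaf order, integer row indices), `labels`,
#'   `merge` and `height` (as in [stats::hclust()]). For fewer than 2 rows,
#'   the identity ordering with empty merge tree.
#' @export
cluster_profiles <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2L) {
    return(list(order = seq_len(n), labels = rownames(mat),
                merge = matrix(integer(0), 0, 2), height = numeric(0)))
  }
  hc <- stats::hclust(uncentered_pearson_dist(mat), method = "average")
  list(order = hc$order, labels = rownames(mat),
       merge = hc$merge, height = hc$height)
}

#' Run the full array-processing pipeline on one experiment
#'
#' Convenience driver: combines technical replicates per array, averages
#' biological replicates, assembles profiles, and calls defects.
#'
#' @param experiment List as returned by [generate_array_experiment()]
#'   (elements `arrays`, each with `sample` and `spots`), or any list of
#'   such arrays under `$arrays`.
#' @param cfg A [pipeline_config()].
#' @return List with `features` (averaged feature table), `profiles`,
#'   `defects` (from [classify_defects()]).
#' @export
process_experiment <- function(experiment, cfg = pipeline_config()) {
  tables <- lapply(experiment$arrays, function(a) {
    combine_replicates(a$spots, orientation = a$sample$orientation, cfg = cfg)
  })
  features <- average_biological(tables)
  profiles <- splicing_profiles(features)
  list(features = features, profiles = profiles,
       defects = classify_defects(profiles, cfg))
}
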