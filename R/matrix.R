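#' Barcode-by-sample UMI count matrix
#'
#' Container for the central pipeline object: a matrix of UMI counts with
#' barcodes as rows and samples as columns, sample metadata, and per-barcode
#' annotations.
#'
#' @param counts Integer matrix, rownames = barcode sequences, colnames =
#'   sample ids.
#' @param samples Data frame of sample metadata with a `sample_id` column
#'   matching `colnames(counts)`; typically also `mouse`, `compartment`,
#'   `timepoint`, `replicate`, `sorted_cells`, `gfp_fraction`.
#' @param annotations Optional data frame keyed by a `barcode` column.
#' @return An object of class `barcode_matrix`.
#' @export
barcode_matrix <- function(counts, samples, annotations = NULL) {
  stopifnot(is.matrix(counts),
            nrow(counts) == 0L || !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(colnames(counts) == samples$sample_id))
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, samples = samples,
                 annotations = annotations),
            class = "barcode_matrix")
}

#' @export
print.barcode_matrix <- function(x, ...) {
  cat(sprintf("barcode_matrix: %d barcodes x %d samples (%d UMIs)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.barcode_matrix <- function(x) dim(x$counts)

#' Build the UMI count matrix from per-UMI barcode calls
#'
#' Entry (b, s) is the number of distinct accepted UMIs in sample s whose
#' consensus called barcode b.
#'
#' @param calls Data frame with columns `sample_id`, `umi`, `barcode` (one
#'   row per accepted UMI, e.g. `call_reads()$calls`).
#' @param samples Sample metadata data frame (`sample_id` column; samples
#'   without calls get zero columns).
#' @param annotations Optional per-barcode annotation data frame.
#' @return A `barcode_matrix`.
#' @export
build_matrix <- function(calls, samples, annotations = NULL) {
  sample_ids <- samples$sample_id
  barcodes <- sort(unique(calls$barcode))
  counts <- matrix(0L, length(barcodes), length(sample_ids),
                   dimnames = list(barcodes, sample_ids))
  if (nrow(calls)) {
    tb <- table(factor(calls$barcode, levels = barcodes),
                factor(calls$sample_id, levels = sample_ids))
    counts[] <- as.integer(tb)
  }
  barcode_matrix(counts, samples, annotations)
}

## biological-sample grouping key of replicate-level samples
.bio_key <- function(samples) {
  paste(samples$mouse, samples$compartment, samples$timepoint, sep = "|")
}

#' Filter the count matrix on replicate-consistent detection
#'
#' Technical (PCR duplicate) replicates of the same biological sample are
#' compared: a (barcode, biological sample) detection is kept only if the
#' barcode reaches `min_umis` UMIs in every replicate (when
#' `require_both_replicates`) or in the replicate-summed counts otherwise.
#' Replicate counts are then summed into one column per biological sample.
#'
#' @param mat A replicate-level `barcode_matrix` (samples must carry
#'   `mouse`, `compartment`, `timepoint`, `replicate`).
#' @param min_umis Minimum UMIs per replicate for a detection.
#' @param require_both_replicates Require the threshold in every replicate
#'   (and presence in all of them).
#' @return A `barcode_matrix` with one column per biological sample (rows
#'   with no remaining detections dropped) and a `qc` attribute listing
#'   entry/barcode retention tallies.
#' @export
filter_matrix <- function(mat, min_umis = 3L, require_both_replicates = TRUE) {
  stopifnot(inherits(mat, "barcode_matrix"))
  key <- .bio_key(mat$samples)
  groups <- split(seq_len(ncol(mat$counts)), key)
  bio_ids <- names(groups)
  out <- matrix(0L, nrow(mat$counts), length(bio_ids),
                dimnames = list(rownames(mat$counts), bio_ids))
  dropped <- 0L; retained <- 0L
  for (g in seq_along(groups)) {
    cols <- groups[[g]]
    sub <- mat$counts[, cols, drop = FALSE]
    keep <- if (require_both_replicates) {
      rowSums(sub >= min_umis) == length(cols)
    } else {
      rowSums(sub) >= min_umis
    }
    detected <- rowSums(sub) > 0
    dropped <- dropped + sum(detected & !keep)
    retained <- retained + sum(keep)
    out[, g] <- ifelse(keep, rowSums(sub), 0L)
  }
  nonzero <- rowSums(out) > 0
  out <- out[nonzero, , drop = FALSE]
  meta_rows <- vapply(groups, `[`, integer(1), 1L)
  samples <- mat$samples[meta_rows, , drop = FALSE]
  samples$sample_id <- bio_ids
  samples$replicate <- NULL
  rownames(samples) <- NULL
  ann <- mat$annotations
  if (!is.null(ann)) ann <- ann[ann$barcode %in% rownames(out), , drop = FALSE]
  res <- barcode_matrix(out, samples, ann)
  attr(res, "qc") <- c(entries_retained = retained, entries_dropped = dropped,
                       barcodes_retained = sum(nonzero),
                       barcodes_dropped = nrow(mat$counts) - sum(nonzero))
  res
}

#' Per-sample fractions and arcsinh-transformed abundances
#'
#' Fractions are counts over the per-sample total (summing to 1 across
#' retained barcodes); transformed values are `asinh(fraction / cofactor)`,
#' the variance-stabilizing transform used for abundance heatmaps and
#' replicate correlations.
#'
#' @param mat A `barcode_matrix`.
#' @param cofactor Arcsinh cofactor.
#' @return `mat` with `fractions` and `transformed` matrices added.
#' @export
normalize_and_transform <- function(mat, cofactor = 1) {
  stopifnot(inherits(mat, "barcode_matrix"))
  totals <- colSums(mat$counts)
  if (any(totals == 0))
    stop("sample(s) with zero counts: ",
         paste(colnames(mat$counts)[totals == 0], collapse = ", "))
  mat$fractions <- sweep(mat$counts, 2L, totals, "/")
  mat$transformed <- asinh(mat$fractions / cofactor)
  mat
}

#' Concordance between technical replicates
#'
#' For every biological sample with two replicates: the Jaccard overlap of
#' detected barcode sets, and the Pearson correlation of
#' arcsinh-transformed fractions over the union of detected barcodes
#' (absences as zeros).
#'
#' @param mat A replicate-level `barcode_matrix`.
#' @param cofactor Arcsinh cofactor for the correlation scale.
#' @return Data frame: mouse, compartment, timepoint, overlap, correlation.
#' @export
replicate_concordance <- function(mat, cofactor = 1) {
  stopifnot(inherits(mat, "barcode_matrix"))
  key <- .bio_key(mat$samples)
  groups <- split(seq_len(ncol(mat$counts)), key)
  rows <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (length(cols) != 2L) {
      warning("biological sample ", g, " does not have 2 replicates; skipped")
      next
    }
    x <- mat$counts[, cols[1L]]
    y <- mat$counts[, cols[2L]]
    union <- x > 0 | y > 0
    overlap <- if (!any(union)) NA_real_ else
      sum(x > 0 & y > 0) / sum(union)
    fx <- if (sum(x) > 0) x / sum(x) else x
    fy <- if (sum(y) > 0) y / sum(y) else y
    tx <- asinh(fx / cofactor)[union]
    ty <- asinh(fy / cofactor)[union]
    correlation <- if (sum(union) >= 3L && stats::sd(tx) > 0 && stats::sd(ty) > 0)
      stats::cor(tx, ty) else NA_real_
    meta <- mat$samples[cols[1L], ]
    rows[[g]] <- data.frame(mouse = meta$mouse, compartment = meta$compartment,
                            timepoint = meta$timepoint, overlap = overlap,
                            correlation = correlation,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write count matrices and sample sheets as TSV
#'
#' @param mat A `barcode_matrix`.
#' @param dir Output directory; writes `matrix.tsv`, `samples.tsv` and (if
#'   present) `annotations.tsv`.
#' @return `write_matrix_tsv` returns `dir` invisibly; `read_sample_sheet`
#'   returns a data frame.
#' @export
write_matrix_tsv <- function(mat, dir) {
  stopifnot(inherits(mat, "barcode_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- data.frame(barcode = rownames(mat$counts), mat$counts,
                       check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(mat$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(mat$annotations))
    utils::write.table(mat$annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_matrix_tsv
#' @param path Sample sheet TSV path (columns sample_id, mouse, compartment,
#'   timepoint, replicate, ...).
#' @export
read_sample_sheet <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
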