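#' Annotate barcodes with generation probabilities
#'
#' Computes `Pgen` once per distinct barcode (cached) and stores it in the
#' matrix annotations. Barcodes no scenario can produce get `Pgen = 0` and
#' are flagged.
#'
#' @param mat A `barcode_matrix`.
#' @param model A `drag_model`.
#' @param reference A `cassette_reference`.
#' @return `mat` with `pgen` (and `pgen_zero` flag) columns added to its
#'   annotations.
#' @export
annotate_pgen <- function(mat, model, reference) {
  stopifnot(inherits(mat, "barcode_matrix"))
  barcodes <- rownames(mat$counts)
  pg <- compute_pgen(model, reference, barcodes)
  ann <- mat$annotations
  if (is.null(ann)) ann <- data.frame(barcode = barcodes,
                                      stringsAsFactors = FALSE)
  ann$pgen <- pg[match(ann$barcode, barcodes)]
  extra <- setdiff(barcodes, ann$barcode)
  if (length(extra)) {
    add <- data.frame(barcode = extra, stringsAsFactors = FALSE)
    for (nm in setdiff(names(ann), c("barcode", "pgen"))) add[[nm]] <- NA
    add$pgen <- pg[match(extra, barcodes)]
    ann <- rbind(ann, add[, names(ann), drop = FALSE])
  }
  ann$pgen_zero <- ann$pgen == 0
  mat$annotations <- ann
  mat
}

#' Filter out high-generation-probability (recurrent) barcodes
#'
#' Barcodes whose generation probability is at or above the threshold are
#' likely to arise independently in multiple cells or mice and are removed
#' before clonal analysis; strictly `pgen < threshold` is retained. The
#' default cutoff is `1e-4`.
#'
#' @param mat A `barcode_matrix` annotated by [annotate_pgen()].
#' @param threshold Retention threshold on `Pgen`.
#' @return A list with `matrix` (retained rows) and `report`, a
#'   `pgen_report` containing threshold, n_input, n_retained,
#'   fraction_retained and (when several mice are present)
#'   fraction_mouse_unique among retained barcodes.
#' @export
filter_by_pgen <- function(mat, threshold = 1e-4) {
  stopifnot(inherits(mat, "barcode_matrix"))
  ann <- mat$annotations
  if (is.null(ann) || is.null(ann$pgen))
    stop("matrix has no pgen annotation; run annotate_pgen() first")
  pg <- ann$pgen[match(rownames(mat$counts), ann$barcode)]
  keep <- pg < threshold
  out <- mat
  out$counts <- mat$counts[keep, , drop = FALSE]
  out$annotations <- ann[ann$barcode %in% rownames(out$counts), , drop = FALSE]
  if (!is.null(mat$fractions)) {
    out$fractions <- NULL
    out$transformed <- NULL
  }
  report <- list(threshold = threshold,
                 n_input = nrow(mat$counts),
                 n_retained = sum(keep),
                 fraction_retained = if (nrow(mat$counts)) mean(keep) else NA_real_,
                 fraction_mouse_unique = cross_mouse_uniqueness(out))
  class(report) <- "pgen_report"
  list(matrix = out, report = report)
}

#' @export
print.pgen_report <- function(x, ...) {
  cat(sprintf("pgen_report: threshold %.3g, retained %d / %d (%.1f%%)\n",
              x$threshold, x$n_retained, x$n_input,
              100 * x$fraction_retained))
  if (!is.na(x$fraction_mouse_unique))
    cat(sprintf("  mouse-unique among retained: %.1f%%\n",
                100 * x$fraction_mouse_unique))
  invisible(x)
}

#' Probability that a barcode arises independently at least twice
#'
#' Binomial tail at two or more successes among `n_events` independent
#' recombination events, each producing this barcode with probability
#' `pgen`: `1 - (1-p)^n - n p (1-p)^(n-1)`.
#'
#' @param pgen Generation probability (vectorized).
#' @param n_events Number of independent recombination events.
#' @return Probability of at least two independent occurrences.
#' @export
recurrence_probability <- function(pgen, n_events) {
  stopifnot(all(pgen >= 0 & pgen <= 1), all(n_events >= 0))
  out <- stats::pbinom(1, n_events, pgen, lower.tail = FALSE)
  out[n_events < 2] <- 0
  out
}

#' Fraction of barcodes private to a single mouse
#'
#' Over the union of barcodes detected in the matrix (or a list of per-mouse
#' matrices), the fraction present in exactly one mouse.
#'
#' @param mats A `barcode_matrix` whose samples carry a `mouse` column, or a
#'   list of per-mouse `barcode_matrix` objects.
#' @return Fraction in `[0, 1]`; `NA` if no barcodes.
#' @export
cross_mouse_uniqueness <- function(mats) {
  per_mouse <- if (inherits(mats, "barcode_matrix")) {
    mice <- unique(mats$samples$mouse)
    lapply(mice, function(m) {
      cols <- mats$samples$mouse == m
      rownames(mats$counts)[rowSums(mats$counts[, cols, drop = FALSE]) > 0]
    })
  } else {
    lapply(mats, function(m) rownames(m$counts)[rowSums(m$counts) > 0])
  }
  all_bc <- unique(unlist(per_mouse))
  if (!length(all_bc)) return(NA_real_)
  pres <- vapply(per_mouse, function(b) all_bc %in% b,
                 logical(length(all_bc)))
  if (!is.matrix(pres)) pres <- matrix(pres, nrow = length(all_bc))
  mean(rowSums(pres) == 1L)
}
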