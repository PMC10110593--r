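#' Simulate a barcoded clone population with compartment fate classes
#'
#' Generates the ground truth for pipeline benchmarking: clones carrying
#' unique recombination barcodes, assigned to one of the seven nonempty
#' subsets of the developmental compartments `{HSPC, MP, M}` (hematopoietic
#' stem/progenitor cells, myeloid progenitors, mature myeloid cells), with
#' heavy-tailed per-compartment cell counts. A clone has nonzero cells
#' exactly in the compartments of its fate class.
#'
#' Default fate-class proportions put 13.7\% of clones in the multi-outcome
#' HSPC-MP-M class (the observed fraction of barcodes shared across all
#' three compartments) and essentially no mass on the biologically
#' unsupported HSPC-M class. Per-compartment clone sizes are log-normal;
#' the myeloid (M) defaults (median 1000 cells, sigma = 0.5 log10 units)
#' span roughly 100 to 10,000 cells.
#'
#' @param n_clones Number of clones.
#' @param class_proportions Named probability vector over the seven fate
#'   classes (names like `"HSPC"`, `"MP-M"`, `"HSPC-MP-M"`); must sum to 1.
#' @param size_median,size_sigma_log10 Named numeric vectors (names `HSPC`,
#'   `MP`, `M`) giving the log-normal median cell count and log10-scale sd
#'   per compartment.
#' @param labeling_efficiency Fraction of clones carrying an activated
#'   (GFP+) recombined cassette, in (0, 1].
#' @param model,reference Generative model and cassette used to draw
#'   barcodes (exact duplicate barcodes are redrawn unless
#'   `allow_collisions`).
#' @param allow_collisions Keep exact barcode collisions between clones.
#' @return An object of class `clone_population`: list with `clones` (data
#'   frame: clone_id, barcode, fate_class, cells_HSPC, cells_MP, cells_M,
#'   gfp_labeled, plus the true scenario fields) and `labeling_efficiency`.
#' @export
simulate_clone_population <- function(
    n_clones,
    class_proportions = default_class_proportions(),
    size_median = c(HSPC = 100, MP = 300, M = 1000),
    size_sigma_log10 = c(HSPC = 0.5, MP = 0.5, M = 0.5),
    labeling_efficiency = 0.1,
    model = default_model(reference),
    reference = default_reference(),
    allow_collisions = FALSE) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-9,
            labeling_efficiency > 0, labeling_efficiency <= 1)
  classes <- names(class_proportions)
  if (is.null(classes)) stop("class_proportions must be named by fate class")
  empty <- data.frame(clone_id = character(), barcode = character(),
                      fate_class = character(), cells_HSPC = numeric(),
                      cells_MP = numeric(), cells_M = numeric(),
                      gfp_labeled = logical(), stringsAsFactors = FALSE)
  if (n_clones == 0L)
    return(structure(list(clones = empty,
                          labeling_efficiency = labeling_efficiency),
                     class = "clone_population"))
  samp <- sample_recombination(model, reference, n_clones)
  bc <- samp$sequences
  sc <- samp$scenarios
  if (!allow_collisions) {
    for (tries in 1:50) {
      dup <- which(duplicated(bc))
      if (!length(dup)) break
      rs <- sample_recombination(model, reference, length(dup))
      bc[dup] <- rs$sequences
      sc[dup, ] <- rs$scenarios
    }
    if (anyDuplicated(bc))
      warning("exact barcode collisions remain after redrawing")
  }
  fate <- sample(classes, n_clones, replace = TRUE, prob = class_proportions)
  cells <- matrix(0, n_clones, 3, dimnames = list(NULL, c("HSPC", "MP", "M")))
  for (comp in c("HSPC", "MP", "M")) {
    inc <- vapply(strsplit(fate, "-"), function(x) comp %in% x, logical(1))
    n <- sum(inc)
    if (n)
      cells[inc, comp] <- round(stats::rlnorm(
        n, meanlog = log(size_median[[comp]]),
        sdlog = size_sigma_log10[[comp]] * log(10)))
    cells[inc, comp] <- pmax(cells[inc, comp], 1)
  }
  clones <- data.frame(
    clone_id = sprintf("clone%05d", seq_len(n_clones)),
    barcode = bc, fate_class = fate,
    cells_HSPC = cells[, "HSPC"], cells_MP = cells[, "MP"],
    cells_M = cells[, "M"],
    gfp_labeled = stats::runif(n_clones) < labeling_efficiency,
    stringsAsFactors = FALSE)
  clones <- cbind(clones, sc)
  structure(list(clones = clones, labeling_efficiency = labeling_efficiency),
            class = "clone_population")
}

#' Default fate-class proportions
#'
#' Proportions of barcodes per fate class: 13.7\% in the HSPC-MP-M
#' multi-outcome class, no HSPC-M class (barcodes in HSPC and myeloid cells
#' but absent from progenitors are not observed), and the remainder spread
#' over the single- and two-compartment classes.
#'
#' @return Named probability vector over the seven nonempty subsets of
#'   `{HSPC, MP, M}`.
#' @export
default_class_proportions <- function() {
  c("HSPC" = 0.25, "MP" = 0.08, "M" = 0.27,
    "HSPC-MP" = 0.10, "HSPC-M" = 0.0, "MP-M" = 0.163,
    "HSPC-MP-M" = 0.137)
}

#' @export
print.clone_population <- function(x, ...) {
  cat("clone_population:", nrow(x$clones), "clones,",
      sum(x$clones$gfp_labeled), "GFP-labeled",
      sprintf("(labeling efficiency %.3f)\n", x$labeling_efficiency))
  if (nrow(x$clones))
    print(round(100 * table(x$clones$fate_class) / nrow(x$clones), 1))
  invisible(x)
}
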