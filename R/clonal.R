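#' Classify barcode fates across developmental compartments
#'
#' Each barcode's fate class is the subset of compartments (HSPC, MP, M) in
#' which it is detected after filtering. Summaries report (i) the percentage
#' of barcodes per class and (ii) each class's contribution to every
#' compartment: the percentage of the compartment's total normalized
#' abundance carried by barcodes of that class (contributions per
#' compartment sum to 100).
#'
#' @param mat A filtered, replicate-collapsed `barcode_matrix` restricted to
#'   one mouse, with columns covering compartments HSPC, MP and M.
#' @param compartments Compartment labels expected in
#'   `mat$samples$compartment`.
#' @return A list with `classes` (data frame: barcode, fate_class),
#'   `class_fractions` (percentage of barcodes per class) and
#'   `contributions` (class x compartment percentage matrix).
#' @export
classify_fates <- function(mat, compartments = c("HSPC", "MP", "M")) {
  stopifnot(inherits(mat, "barcode_matrix"))
  if (length(unique(mat$samples$mouse)) > 1L)
    stop("classify_fates expects a single mouse; subset the matrix first")
  missing <- setdiff(compartments, mat$samples$compartment)
  if (length(missing))
    stop("compartment column(s) missing: ", paste(missing, collapse = ", "))
  comp_counts <- vapply(compartments, function(cp) {
    cols <- mat$samples$compartment == cp
    rowSums(mat$counts[, cols, drop = FALSE])
  }, numeric(nrow(mat$counts)))
  if (!is.matrix(comp_counts))
    comp_counts <- matrix(comp_counts, nrow = nrow(mat$counts),
                          dimnames = list(rownames(mat$counts), compartments))
  present <- comp_counts > 0
  detected <- rowSums(present) > 0
  comp_counts <- comp_counts[detected, , drop = FALSE]
  present <- present[detected, , drop = FALSE]
  fate <- apply(present, 1L, function(p)
    paste(compartments[p], collapse = "-"))
  all_classes <- unlist(lapply(seq_along(compartments), function(k)
    utils::combn(compartments, k, paste, collapse = "-", simplify = TRUE)))
  class_fractions <- 100 * table(factor(fate, levels = all_classes)) /
    max(1L, length(fate))
  fracs <- sweep(comp_counts, 2L, pmax(colSums(comp_counts), 1e-300), "/")
  contributions <- do.call(rbind, lapply(all_classes, function(cl) {
    100 * colSums(fracs[fate == cl, , drop = FALSE])
  }))
  rownames(contributions) <- all_classes
  list(classes = data.frame(barcode = rownames(comp_counts),
                            fate_class = unname(fate),
                            stringsAsFactors = FALSE),
       class_fractions = class_fractions,
       contributions = contributions)
}

#' Clone sizes in cells from normalized barcode abundances
#'
#' The number of cells a clone contributes to a sorted sample is its
#' normalized UMI fraction times the sorted cell count. Optionally scales to
#' the whole (labeled + unlabeled) population by dividing by the GFP+
#' labeling fraction.
#'
#' @param mat A `barcode_matrix` whose samples carry `sorted_cells` (and
#'   `gfp_fraction` when `scale_to_population`).
#' @param scale_to_population Divide sizes by the per-sample labeling
#'   fraction.
#' @return Matrix of cells per (barcode, sample).
#' @export
clone_sizes <- function(mat, scale_to_population = FALSE) {
  stopifnot(inherits(mat, "barcode_matrix"))
  sc <- mat$samples$sorted_cells
  if (is.null(sc) || any(is.na(sc)) || any(sc <= 0))
    stop("samples must carry positive sorted_cells counts")
  totals <- colSums(mat$counts)
  if (any(totals == 0)) stop("sample(s) with zero counts")
  sizes <- sweep(sweep(mat$counts, 2L, totals, "/"), 2L, sc, "*")
  if (scale_to_population) {
    gf <- mat$samples$gfp_fraction
    if (is.null(gf) || any(is.na(gf)) || any(gf <= 0) || any(gf > 1))
      stop("samples must carry gfp_fraction in (0, 1] for population scaling")
    sizes <- sweep(sizes, 2L, gf, "/")
  }
  sizes
}

#' Incidence-based richness estimation (chao2)
#'
#' Estimates total barcode richness from detection/non-detection across `m`
#' sampling units (by default the PCR duplicates) using singleton (`Q1`) and
#' doubleton (`Q2`) incidence counts. The classic estimator is
#' `S_obs + ((m-1)/m) * Q1^2 / (2 Q2)`; when `Q2 = 0` (or on request) the
#' bias-corrected form `S_obs + ((m-1)/m) * Q1 (Q1 - 1) / (2 (Q2 + 1))` is
#' used. The estimate is scaled to the whole clone population by dividing by
#' the labeling efficiency (labeled clones are a Bernoulli thinning of all
#' clones under neutral labeling).
#'
#' @param incidence Logical or 0/1 matrix, barcodes x sampling units
#'   (`m = ncol >= 2`).
#' @param labeling_fraction GFP+ labeling efficiency used for the corrected
#'   total; 1 leaves the estimate on the labeled-clone scale.
#' @param form `"auto"` (classic when `Q2 > 0`, else bias-corrected),
#'   `"classic"` or `"bias_corrected"`.
#' @return List: S_obs, Q1, Q2, m, form, estimate, corrected_total.
#' @export
chao2 <- function(incidence, labeling_fraction = 1,
                  form = c("auto", "classic", "bias_corrected")) {
  form <- match.arg(form)
  incidence <- incidence > 0
  m <- ncol(incidence)
  if (is.null(m) || m < 2L) stop("chao2 needs at least 2 sampling units")
  stopifnot(labeling_fraction > 0, labeling_fraction <= 1)
  det <- rowSums(incidence)
  chao2_stats(sum(det > 0), sum(det == 1L), sum(det == 2L), m,
              labeling_fraction = labeling_fraction, form = form)
}

#' @rdname chao2
#' @param S_obs,Q1,Q2 Observed richness and singleton/doubleton incidence
#'   counts.
#' @param m Number of sampling units.
#' @export
chao2_stats <- function(S_obs, Q1, Q2, m, labeling_fraction = 1,
                        form = c("auto", "classic", "bias_corrected")) {
  form <- match.arg(form)
  stopifnot(m >= 2L, S_obs >= 0, Q1 >= 0, Q2 >= 0,
            labeling_fraction > 0, labeling_fraction <= 1)
  used <- if (form == "auto") {
    if (Q2 > 0) "classic" else "bias_corrected"
  } else form
  est <- if (used == "classic") {
    if (Q2 == 0 && Q1 > 0)
      stop("classic chao2 undefined with Q2 = 0; use the bias-corrected form")
    S_obs + if (Q1 == 0) 0 else (m - 1) / m * Q1^2 / (2 * Q2)
  } else {
    S_obs + (m - 1) / m * Q1 * (Q1 - 1) / (2 * (Q2 + 1))
  }
  list(S_obs = S_obs, Q1 = Q1, Q2 = Q2, m = m, form = used,
       estimate = est, corrected_total = est / labeling_fraction)
}

#' Renyi entropy and Simpson diversity profile
#'
#' For a relative-abundance vector p: `H_q = log(sum(p^q)) / (1 - q)` for
#' `q != 1`, the Shannon entropy at `q = 1`; Simpson concentration
#' `lambda = sum(p^2)`, Gini-Simpson `1 - lambda` and inverse Simpson
#' `1 / lambda = exp(H_2)`.
#'
#' @param p Nonnegative abundances; normalized (with a warning) if they do
#'   not sum to 1.
#' @param q Renyi orders.
#' @return List with `renyi` (data frame: q, H) and `simpson` (named vector:
#'   concentration, gini_simpson, inverse_simpson).
#' @export
diversity_profile <- function(p, q = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf)) {
  stopifnot(all(p >= 0), any(p > 0))
  if (abs(sum(p) - 1) > 1e-9) {
    warning("abundances do not sum to 1; normalizing")
  }
  p <- p / sum(p)
  p <- p[p > 0]
  H <- vapply(q, function(qq) {
    if (qq == 1) -sum(p * log(p))
    else if (is.infinite(qq)) -log(max(p))
    else log(sum(p^qq)) / (1 - qq)
  }, numeric(1))
  lambda <- sum(p^2)
  list(renyi = data.frame(q = q, H = H),
       simpson = c(concentration = lambda, gini_simpson = 1 - lambda,
                   inverse_simpson = 1 / lambda))
}
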