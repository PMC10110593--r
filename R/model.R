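#' Generative model of cassette recombination
#'
#' A recombination event is parameterized by independent categorical
#' distributions for the number of bases trimmed at each of the four trimming
#' sites (V 3' end, D 5' and 3' ends after orientation, J 5' end), the lengths
#' of the two untemplated (N) insertions, the nucleotide composition of
#' inserted bases (i.i.d. per base, reflecting TdT addition), and a Bernoulli
#' probability that the D segment is incorporated in inverted
#' (reverse-complement) orientation.
#'
#' @param p_del_v,p_del_d5,p_del_d3,p_del_j Numeric probability vectors over
#'   trim counts `0..K` (element `k+1` is the probability of trimming `k`
#'   bases). Each must be nonnegative and sum to 1 within 1e-9.
#' @param p_ins_vd,p_ins_dj Probability vectors over insertion lengths `0..I`.
#' @param p_nt Probability vector of length 4, named `A`, `C`, `G`, `T`.
#' @param p_inv Probability of D-segment inversion, in \[0, 1\].
#' @return An object of class `drag_model`.
#' @seealso [default_model()], [sample_recombination()], [compute_pgen()]
#' @export
generative_model <- function(p_del_v, p_del_d5, p_del_d3, p_del_j,
                             p_ins_vd, p_ins_dj, p_nt, p_inv) {
  cats <- list(p_del_v = p_del_v, p_del_d5 = p_del_d5, p_del_d3 = p_del_d3,
               p_del_j = p_del_j, p_ins_vd = p_ins_vd, p_ins_dj = p_ins_dj,
               p_nt = p_nt)
  for (nm in names(cats)) {
    p <- cats[[nm]]
    if (any(p < 0)) stop(nm, " has negative entries")
    if (abs(sum(p) - 1) > 1e-9) stop(nm, " does not sum to 1 (got ", sum(p), ")")
  }
  if (length(p_nt) != 4L) stop("p_nt must have length 4")
  names(cats$p_nt) <- c("A", "C", "G", "T")
  if (p_inv < 0 || p_inv > 1) stop("p_inv must lie in [0, 1]")
  for (nm in setdiff(names(cats), "p_nt"))
    names(cats[[nm]]) <- as.character(seq_along(cats[[nm]]) - 1L)
  structure(c(cats, list(p_inv = p_inv)), class = "drag_model")
}

## truncated geometric over 0..kmax with decay rate r
trunc_geom <- function(kmax, r) {
  p <- r^(0:kmax)
  p / sum(p)
}

#' Default generative model
#'
#' Default supports cover the observed extremes of the barcoding system: up
#' to 32 deletions per trimming site (capped at the segment length) and up to
#' 15 untemplated insertions per junction. Within the supports, trim and
#' insertion length distributions are truncated-geometric with most mass at
#' small counts, the inserted-base composition is mildly G/C-biased (TdT
#' preference), and the D-inversion probability is 0.12, the observed
#' inversion rate. All parameters are re-estimable from data with
#' [fit_model()].
#'
#' @param reference A `cassette_reference`; supports are capped at the
#'   segment lengths.
#' @param max_del,max_ins Upper bounds of the trim and insertion supports.
#' @param p_inv D-inversion probability.
#' @return A `drag_model`.
#' @export
default_model <- function(reference = default_reference(),
                          max_del = 32L, max_ins = 15L, p_inv = 0.12) {
  nv <- nchar(reference$v_seq); nd <- nchar(reference$d_seq)
  nj <- nchar(reference$j_seq)
  generative_model(
    p_del_v  = trunc_geom(min(max_del, nv), 0.80),
    p_del_d5 = trunc_geom(min(max_del, nd), 0.80),
    p_del_d3 = trunc_geom(min(max_del, nd), 0.80),
    p_del_j  = trunc_geom(min(max_del, nj), 0.80),
    p_ins_vd = trunc_geom(max_ins, 0.65),
    p_ins_dj = trunc_geom(max_ins, 0.65),
    p_nt = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2),
    p_inv = p_inv)
}

#' @export
print.drag_model <- function(x, ...) {
  cat("drag_model\n")
  cat(sprintf("  trim supports: V 0..%d, D5 0..%d, D3 0..%d, J 0..%d\n",
              length(x$p_del_v) - 1L, length(x$p_del_d5) - 1L,
              length(x$p_del_d3) - 1L, length(x$p_del_j) - 1L))
  cat(sprintf("  insertion supports: VD 0..%d, DJ 0..%d\n",
              length(x$p_ins_vd) - 1L, length(x$p_ins_dj) - 1L))
  cat(sprintf("  p_nt: A=%.3f C=%.3f G=%.3f T=%.3f   p_inv=%.3f\n",
              x$p_nt[1], x$p_nt[2], x$p_nt[3], x$p_nt[4], x$p_inv))
  invisible(x)
}

## support bounds implied by a model's categorical lengths
model_bounds <- function(model) {
  list(del_v = length(model$p_del_v) - 1L,
       del_d5 = length(model$p_del_d5) - 1L,
       del_d3 = length(model$p_del_d3) - 1L,
       del_j = length(model$p_del_j) - 1L,
       ins_vd = length(model$p_ins_vd) - 1L,
       ins_dj = length(model$p_ins_dj) - 1L)
}

#' Construct recombination scenarios
#'
#' A scenario fully specifies one recombination event: the D orientation, the
#' four trim counts and the two inserted nucleotide strings. Scenarios are
#' stored as rows of a data frame so that all scenario-level operations are
#' vectorized.
#'
#' @param inverted Logical; D segment in reverse-complement orientation.
#' @param del_v,del_d5,del_d3,del_j Nonnegative integer trim counts (D trims
#'   are counted in the post-orientation frame).
#' @param ins_vd,ins_dj Inserted nucleotide strings (possibly `""`).
#' @return A data frame with one row per scenario.
#' @export
recombination_scenario <- function(inverted = FALSE, del_v = 0L, del_d5 = 0L,
                                   del_d3 = 0L, del_j = 0L,
                                   ins_vd = "", ins_dj = "") {
  df <- data.frame(inverted = as.logical(inverted),
                   del_v = as.integer(del_v), del_d5 = as.integer(del_d5),
                   del_d3 = as.integer(del_d3), del_j = as.integer(del_j),
                   ins_vd = as.character(ins_vd), ins_dj = as.character(ins_dj),
                   stringsAsFactors = FALSE)
  if (any(df$del_v < 0 | df$del_d5 < 0 | df$del_d3 < 0 | df$del_j < 0))
    stop("trim counts must be nonnegative")
  if (any(grepl("[^ACGT]", df$ins_vd)) || any(grepl("[^ACGT]", df$ins_dj)))
    stop("insertion strings must be over {A,C,G,T}")
  df
}

#' Realize the barcode sequence of a recombination scenario
#'
#' Pure deterministic map from (reference, scenario) to the recombined
#' sequence: the V segment trimmed at its 3' end, the first N insertion, the
#' (optionally inverted, then trimmed) D segment, the second N insertion and
#' the J segment trimmed at its 5' end.
#'
#' @param reference A `cassette_reference`.
#' @param scenarios A scenario data frame (see [recombination_scenario()]);
#'   vectorized over rows.
#' @return Character vector of recombined sequences.
#' @export
realize_scenario <- function(reference, scenarios) {
  stopifnot(inherits(reference, "cassette_reference"))
  nv <- nchar(reference$v_seq); nd <- nchar(reference$d_seq)
  nj <- nchar(reference$j_seq)
  if (any(scenarios$del_v > nv) || any(scenarios$del_j > nj) ||
      any(scenarios$del_d5 + scenarios$del_d3 > nd))
    stop("scenario trims exceed segment lengths")
  d_fwd <- reference$d_seq
  d_rev <- revcomp(reference$d_seq)
  d_or <- ifelse(scenarios$inverted, d_rev, d_fwd)
  paste0(substring(reference$v_seq, 1L, nv - scenarios$del_v),
         scenarios$ins_vd,
         substring(d_or, scenarios$del_d5 + 1L, nd - scenarios$del_d3),
         scenarios$ins_dj,
         substring(reference$j_seq, scenarios$del_j + 1L, nj))
}

## per-row A/C/G/T counts of a character vector (insertions)
nt_counts <- function(x) {
  out <- matrix(0L, nrow = length(x), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (b in c("A", "C", "G", "T"))
    out[, b] <- nchar(x) - nchar(gsub(b, "", x, fixed = TRUE))
  out
}

#' Probability of a recombination scenario under a generative model
#'
#' The scenario probability factorizes over the independent model components:
#' orientation, the four trim counts, the two insertion lengths and the
#' composition of every inserted base. Scenarios outside the model supports
#' have probability 0.
#'
#' @inheritParams realize_scenario
#' @param model A `drag_model`.
#' @param log Return log-probabilities (`-Inf` outside support).
#' @return Numeric vector of probabilities, one per scenario row.
#' @export
scenario_probability <- function(model, scenarios, log = FALSE) {
  stopifnot(inherits(model, "drag_model"))
  lk <- function(p, k) {
    out <- rep(-Inf, length(k))
    ok <- k >= 0 & k < length(p)
    out[ok] <- base::log(p[k[ok] + 1L])
    out
  }
  cnt <- nt_counts(scenarios$ins_vd) + nt_counts(scenarios$ins_dj)
  lp <- ifelse(scenarios$inverted, base::log(model$p_inv),
               base::log(1 - model$p_inv)) +
    lk(model$p_del_v, scenarios$del_v) +
    lk(model$p_del_d5, scenarios$del_d5) +
    lk(model$p_del_d3, scenarios$del_d3) +
    lk(model$p_del_j, scenarios$del_j) +
    lk(model$p_ins_vd, nchar(scenarios$ins_vd)) +
    lk(model$p_ins_dj, nchar(scenarios$ins_dj)) +
    as.vector(cnt %*% base::log(model$p_nt))
  if (log) lp else exp(lp)
}

## sample n random insertion strings with lengths len from p_nt
sample_ins_strings <- function(len, p_nt) {
  total <- sum(len)
  out <- character(length(len))
  if (total == 0L) return(out)
  bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE, prob = p_nt)
  idx <- rep.int(seq_along(len), len)
  nz <- len > 0L
  out[nz] <- vapply(split(bases, factor(idx, levels = which(nz))),
                    paste, character(1), collapse = "")
  out
}

#' Sample recombination events from a generative model
#'
#' Forward sampler: draws each scenario component independently from its
#' categorical (and the inversion Bernoulli), then realizes the recombined
#' sequence. Infeasible D trim pairs (`del_d5 + del_d3 > |D|`) are resampled;
#' with default supports this is a no-op because D-site supports are capped
#' at the D length. Randomness comes from R's global RNG; call `set.seed()`
#' for reproducibility.
#'
#' @inheritParams scenario_probability
#' @param reference A `cassette_reference`.
#' @param n Number of events to sample.
#' @return A list with `scenarios` (data frame, `n` rows) and `sequences`
#'   (character vector of realized barcodes).
#' @export
sample_recombination <- function(model, reference, n = 1L) {
  stopifnot(inherits(model, "drag_model"), inherits(reference, "cassette_reference"))
  nd <- nchar(reference$d_seq)
  draw <- function(p, n) sample.int(length(p), n, replace = TRUE, prob = p) - 1L
  del_d5 <- draw(model$p_del_d5, n)
  del_d3 <- draw(model$p_del_d3, n)
  bad <- which(del_d5 + del_d3 > nd)
  while (length(bad)) {
    del_d5[bad] <- draw(model$p_del_d5, length(bad))
    del_d3[bad] <- draw(model$p_del_d3, length(bad))
    bad <- bad[del_d5[bad] + del_d3[bad] > nd]
  }
  sc <- data.frame(
    inverted = stats::runif(n) < model$p_inv,
    del_v = draw(model$p_del_v, n),
    del_d5 = del_d5, del_d3 = del_d3,
    del_j = draw(model$p_del_j, n),
    ins_vd = sample_ins_strings(draw(model$p_ins_vd, n), model$p_nt),
    ins_dj = sample_ins_strings(draw(model$p_ins_dj, n), model$p_nt),
    stringsAsFactors = FALSE)
  list(scenarios = sc, sequences = realize_scenario(reference, sc))
}

#' Serialize / deserialize a generative model as JSON
#'
#' @param model A `drag_model`.
#' @param path File path.
#' @return `read_model` returns a `drag_model`; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "drag_model"))
  obj <- lapply(unclass(model), unname)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  generative_model(obj$p_del_v, obj$p_del_d5, obj$p_del_d3, obj$p_del_j,
                   obj$p_ins_vd, obj$p_ins_dj, obj$p_nt, obj$p_inv)
}
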