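## Scenario enumeration and exact generation-probability computation.
##
## A recombined sequence s is explained by scenarios
##   s = V[1..nv-del_v] + ins_vd + core + ins_dj + J[del_j+1..nj]
## where core is the (optionally inverted) D segment trimmed by del_d5/del_d3.
## Junctions are ambiguous (inserted bases may coincide with germline ends),
## so many scenarios can produce the same sequence; Pgen sums over all of
## them. Enumeration is organized around three independent blocks:
##   left  (start):  choices of del_v and ins_vd consistent with a core (or
##                   split point) beginning at position `start` of s;
##   core  (start,end): D-core placements, found as common substrings of s
##                   and the oriented D segment (plus the empty core);
##   right (end):    choices of del_j and ins_dj.
## The blocks interact only through (start, end), which keeps both explicit
## enumeration and the exact factorized Pgen sum cheap.

## default enumeration bounds for a reference
default_bounds <- function(reference, max_del = 32L, max_ins = 15L) {
  list(del_v = min(max_del, nchar(reference$v_seq)),
       del_d5 = min(max_del, nchar(reference$d_seq)),
       del_d3 = min(max_del, nchar(reference$d_seq)),
       del_j = min(max_del, nchar(reference$j_seq)),
       ins_vd = max_ins, ins_dj = max_ins)
}

## forward common-substring runs between raw vectors sv and dch: returns
## (i0, j0, run) with s[i0..i0+k-1] == d[j0..j0+k-1] for k = 1..run.
## Computed without an R-level loop: the match matrix is unrolled
## diagonal-major with FALSE separators, and remaining-run lengths come from
## a single rle() pass.
## cache of index geometry per (L, nd): row/col indices and diagonal-major
## permutation, reused across sequences of the same length
.mr_cache <- new.env(parent = emptyenv())

.mr_geom <- function(L, nd) {
  key <- paste0(L, "_", nd)
  g <- .mr_cache[[key]]
  if (is.null(g)) {
    t <- seq_len(L * nd) - 1L
    i <- t %% L + 1L
    j <- t %/% L + 1L
    o <- order(i - j, i)
    g <- list(i = i, j = j, o = o, diag = (i - j)[o] + nd)
    .mr_cache[[key]] <- g
  }
  g
}

.match_runs <- function(sv, dch) {
  L <- length(sv); nd <- length(dch)
  if (L == 0L || nd == 0L) return(NULL)
  M <- matrix(sv, L, nd) == matrix(dch, L, nd, byrow = TRUE)
  if (!any(M)) return(NULL)
  g <- .mr_geom(L, nd)
  i <- g$i; j <- g$j; o <- g$o
  z <- M[o]
  ## label TRUE cells by diagonal id so rle runs never span diagonals
  val <- g$diag * z
  r <- rle(val)
  pos_end <- cumsum(r$lengths)
  truerun <- r$values > 0L
  len <- r$lengths[truerun]
  if (!length(len)) return(NULL)
  dpos <- sequence(len, from = pos_end[truerun] - len + 1L)
  cell <- o[dpos]
  list(i0 = i[cell], j0 = j[cell],
       run = sequence(len, from = len, by = -1L))
}

## shared per-sequence geometry: prefix/suffix germline matches and the
## resulting valid trim ranges
.seq_frame <- function(s, reference, bounds) {
  sv <- charToRaw(s)
  v <- charToRaw(reference$v_seq); jj <- charToRaw(reference$j_seq)
  L <- length(sv); nv <- length(v); nj <- length(jj)
  n1 <- min(L, nv)
  mm <- if (n1) which(sv[seq_len(n1)] != v[seq_len(n1)]) else integer()
  lcp <- if (length(mm)) mm[1L] - 1L else n1
  n2 <- min(L, nj)
  mm <- if (n2) which(rev(sv)[seq_len(n2)] != rev(jj)[seq_len(n2)]) else integer()
  lcs <- if (length(mm)) mm[1L] - 1L else n2
  list(sv = sv, L = L, nv = nv, nj = nj, nd = nchar(reference$d_seq),
       dv_min = max(0L, nv - lcp), dv_max = min(bounds$del_v, nv),
       dj_min = max(0L, nj - lcs), dj_max = min(bounds$del_j, nj))
}

## valid (start, del_v, ins_vd-length) combinations for each core start
## position; returns integer columns start, dv, a
.left_block <- function(fr, bounds, cap = Inf, min_right = 0) {
  starts <- seq_len(fr$L + 1L)
  dv_lo <- pmax(fr$dv_min, fr$nv - starts + 1L)
  dv_hi <- pmin(fr$dv_max, fr$nv - starts + 1L + bounds$ins_vd)
  if (is.finite(cap)) {
    ## edits dv + a = 2*dv - (nv - start + 1) increase with dv
    dv_hi <- pmin(dv_hi, (cap - min_right + fr$nv - starts + 1L) %/% 2L)
  }
  n <- pmax(0L, dv_hi - dv_lo + 1L)
  keep <- which(n > 0L)
  if (!length(keep)) return(NULL)
  k <- rep.int(keep, n[keep])
  dv <- sequence(n[keep], from = dv_lo[keep])
  list(start = k, dv = dv, a = dv - (fr$nv - k + 1L))
}

## valid (end, del_j, ins_dj-length) combinations; end ranges over 0..L
.right_block <- function(fr, bounds, cap = Inf, min_left = 0) {
  ends <- 0:fr$L
  dj_lo <- pmax(fr$dj_min, fr$nj - fr$L + ends)
  dj_hi <- pmin(fr$dj_max, fr$nj - fr$L + ends + bounds$ins_dj)
  if (is.finite(cap))
    dj_hi <- pmin(dj_hi, (cap - min_left + fr$nj - fr$L + ends) %/% 2L)
  n <- pmax(0L, dj_hi - dj_lo + 1L)
  keep <- which(n > 0L)
  if (!length(keep)) return(NULL)
  k <- rep.int(keep, n[keep])
  dj <- sequence(n[keep], from = dj_lo[keep])
  list(end = ends[k], dj = dj, b = dj - (fr$nj - fr$L + ends[k]))
}

## D-core placements per orientation: vectors start, end, d5, d3, inverted
.core_entries <- function(fr, reference, bounds) {
  acc <- list(start = integer(), end = integer(), d5 = integer(),
              d3 = integer(), inverted = logical())
  d_fwd <- charToRaw(reference$d_seq)
  d_rev <- rev(charToRaw(chartr("ACGT", "TGCA", reference$d_seq)))
  for (inv in c(FALSE, TRUE)) {
    dch <- if (inv) d_rev else d_fwd
    tr <- .match_runs(fr$sv, dch)
    if (is.null(tr)) next
    i0 <- rep.int(tr$i0, tr$run)
    j0 <- rep.int(tr$j0, tr$run)
    lc <- sequence(tr$run)
    d5 <- j0 - 1L
    d3 <- fr$nd - d5 - lc
    ok <- d5 <= bounds$del_d5 & d3 <= bounds$del_d3
    if (!any(ok)) next
    acc$start <- c(acc$start, i0[ok])
    acc$end <- c(acc$end, i0[ok] + lc[ok] - 1L)
    acc$d5 <- c(acc$d5, d5[ok])
    acc$d3 <- c(acc$d3, d3[ok])
    acc$inverted <- c(acc$inverted, rep.int(inv, sum(ok)))
  }
  if (!length(acc$start)) NULL else acc
}

## full-deletion d5 split range (d5 + d3 = nd)
.empty_core_d5 <- function(fr, bounds) {
  lo <- max(0L, fr$nd - bounds$del_d3)
  hi <- min(bounds$del_d5, fr$nd)
  if (lo > hi) integer() else lo:hi
}

#' Enumerate all recombination scenarios producing a sequence
#'
#' Returns exactly the scenarios within the given supports whose realization
#' equals `sequence`, in deterministic lexicographic order. Because inserted
#' bases may coincide with germline segment ends, a sequence typically admits
#' many scenarios; generation probabilities sum over all of them.
#'
#' @param reference A `cassette_reference`.
#' @param sequence A single nucleotide string over `{A,C,G,T}`.
#' @param bounds Support bounds, a list with elements `del_v`, `del_d5`,
#'   `del_d3`, `del_j`, `ins_vd`, `ins_dj` (see [default_bounds()]).
#' @param max_total_edits Optional cap on `del_v + del_d5 + del_d3 + del_j +
#'   |ins_vd| + |ins_dj|`; scenarios above the cap are omitted. The default
#'   (`Inf`) enumerates the complete set.
#' @return A scenario data frame (possibly 0-row) with an added integer
#'   column `total_edits`.
#' @export
enumerate_scenarios <- function(reference, sequence, bounds = NULL,
                                max_total_edits = Inf) {
  stopifnot(inherits(reference, "cassette_reference"), length(sequence) == 1L)
  if (grepl("[^ACGT]", sequence)) stop("sequence must be over {A,C,G,T}")
  if (is.null(bounds)) bounds <- default_bounds(reference)
  fr <- .seq_frame(sequence, reference, bounds)
  empty <- recombination_scenario()[0, ]
  empty$total_edits <- integer()
  if (fr$dv_min > fr$dv_max || fr$dj_min > fr$dj_max) return(empty)

  lb <- .left_block(fr, bounds, max_total_edits, min_right = 0)
  rb <- .right_block(fr, bounds, max_total_edits, min_left = 0)
  if (is.null(lb) || is.null(rb)) return(empty)
  ## per-position minimal left/right edit costs, for cap pruning
  minL <- rep(Inf, fr$L + 1L); minR <- rep(Inf, fr$L + 1L)
  le <- lb$dv + lb$a; re <- rb$dj + rb$b
  minL[unique(lb$start)] <- tapply(le, lb$start, min)[as.character(unique(lb$start))]
  minR[unique(rb$end) + 1L] <- tapply(re, rb$end, min)[as.character(unique(rb$end))]

  rows <- list()
  ## scenarios with a nonempty D core
  ce <- .core_entries(fr, reference, bounds)
  if (!is.null(ce)) {
    ok <- minL[ce$start] + minR[ce$end + 1L] + ce$d5 + ce$d3 <= max_total_edits
    ce <- lapply(ce, `[`, ok)
    if (length(ce$start)) {
      li <- split(seq_along(lb$start), lb$start)
      ri <- split(seq_along(rb$end), rb$end)
      for (r in seq_along(ce$start)) {
        il <- li[[as.character(ce$start[r])]]
        ir <- ri[[as.character(ce$end[r])]]
        if (is.null(il) || is.null(ir)) next
        g <- expand.grid(il = il, ir = ir)
        tot <- lb$dv[g$il] + lb$a[g$il] + ce$d5[r] + ce$d3[r] +
          rb$dj[g$ir] + rb$b[g$ir]
        g <- g[tot <= max_total_edits, , drop = FALSE]
        if (!nrow(g)) next
        rows[[length(rows) + 1L]] <- data.frame(
          inverted = ce$inverted[r],
          del_v = lb$dv[g$il], del_d5 = ce$d5[r], del_d3 = ce$d3[r],
          del_j = rb$dj[g$ir], a = lb$a[g$il], b = rb$b[g$ir],
          start = ce$start[r], end = ce$end[r])
      }
    }
  }
  ## scenarios with the D segment fully deleted (core empty): the middle
  ## region is split between the two insertions at a boundary g, and every
  ## (del_d5, del_d3) partition of |D| and both orientations are distinct
  ## scenarios producing the same sequence
  d5s <- .empty_core_d5(fr, bounds)
  if (length(d5s)) {
    for (g in 0:fr$L) {
      il <- which(lb$start == g + 1L)
      ir <- which(rb$end == g)
      if (!length(il) || !length(ir)) next
      gg <- expand.grid(il = il, ir = ir)
      tot <- lb$dv[gg$il] + lb$a[gg$il] + fr$nd + rb$dj[gg$ir] + rb$b[gg$ir]
      gg <- gg[tot <= max_total_edits, , drop = FALSE]
      if (!nrow(gg)) next
      n <- nrow(gg)
      for (d5 in d5s) for (inv in c(FALSE, TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          inverted = inv,
          del_v = lb$dv[gg$il], del_d5 = d5, del_d3 = fr$nd - d5,
          del_j = rb$dj[gg$ir], a = lb$a[gg$il], b = rb$b[gg$ir],
          start = g + 1L, end = g)
      }
    }
  }
  if (!length(rows)) return(empty)
  sc <- do.call(rbind, rows)
  P <- fr$nv - sc$del_v
  Q <- fr$L - (fr$nj - sc$del_j)
  out <- data.frame(
    inverted = sc$inverted,
    del_v = sc$del_v, del_d5 = sc$del_d5, del_d3 = sc$del_d3, del_j = sc$del_j,
    ins_vd = substr(rep(sequence, nrow(sc)), P + 1L, P + sc$a),
    ins_dj = substr(rep(sequence, nrow(sc)), sc$end + 1L, Q),
    stringsAsFactors = FALSE)
  out$total_edits <- sc$del_v + sc$del_d5 + sc$del_d3 + sc$del_j + sc$a + sc$b
  out <- out[order(out$inverted, out$del_v, out$del_d5, out$del_d3, out$del_j,
                   out$ins_vd, out$ins_dj), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generation probability of barcode sequences
#'
#' Computes `Pgen(s)`, the probability that one recombination event drawn
#' from the generative model realizes exactly the sequence `s`, by an exact
#' sum over all consistent scenarios. The sum is evaluated in factorized form
#' (left junction x D-core placement x right junction), which is exact and
#' fast even though the explicit scenario set can be combinatorially large.
#'
#' @param model A `drag_model`.
#' @param reference A `cassette_reference`.
#' @param sequences Character vector of sequences; vectorized.
#' @return Numeric vector of probabilities in `[0, 1]`; 0 for sequences no
#'   scenario can produce.
#' @export
compute_pgen <- function(model, reference, sequences) {
  stopifnot(inherits(model, "drag_model"), inherits(reference, "cassette_reference"))
  bounds <- model_bounds(model)
  vapply(sequences, .pgen_one, numeric(1),
         model = model, reference = reference, bounds = bounds,
         USE.NAMES = FALSE)
}

.pgen_one <- function(s, model, reference, bounds) {
  if (grepl("[^ACGT]", s)) return(0)
  fr <- .seq_frame(s, reference, bounds)
  if (fr$dv_min > fr$dv_max || fr$dj_min > fr$dj_max) return(0)
  lb <- .left_block(fr, bounds)
  rb <- .right_block(fr, bounds)
  if (is.null(lb) || is.null(rb)) return(0)
  ## cumulative log-composition of s under p_nt
  base_idx <- match(as.integer(fr$sv), as.integer(charToRaw("ACGT")))
  clc <- c(0, cumsum(log(model$p_nt)[base_idx]))
  ## left sums over start = 1..L+1 and right sums over end = 0..L
  P <- fr$nv - lb$dv
  lterm <- model$p_del_v[lb$dv + 1L] * model$p_ins_vd[lb$a + 1L] *
    exp(clc[lb$start] - clc[P + 1L])
  Ls <- numeric(fr$L + 1L)
  agg <- rowsum(lterm, lb$start)
  Ls[as.integer(rownames(agg))] <- agg[, 1L]
  Q <- fr$L - (fr$nj - rb$dj)
  rterm <- model$p_del_j[rb$dj + 1L] * model$p_ins_dj[rb$b + 1L] *
    exp(clc[Q + 1L] - clc[rb$end + 1L])
  Rs <- numeric(fr$L + 1L)
  agg <- rowsum(rterm, rb$end)
  Rs[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  ## nonempty D cores
  ce <- .core_entries(fr, reference, bounds)
  core_sum <- 0
  if (!is.null(ce)) {
    kterm <- ifelse(ce$inverted, model$p_inv, 1 - model$p_inv) *
      model$p_del_d5[ce$d5 + 1L] * model$p_del_d3[ce$d3 + 1L]
    core_sum <- sum(kterm * Ls[ce$start] * Rs[ce$end + 1L])
  }
  ## empty core: orientation marginalizes to 1, d5 splits sum analytically
  d5s <- .empty_core_d5(fr, bounds)
  empty_sum <- 0
  if (length(d5s)) {
    k0 <- sum(model$p_del_d5[d5s + 1L] * model$p_del_d3[fr$nd - d5s + 1L])
    empty_sum <- k0 * sum(Ls * Rs)
  }
  min(core_sum + empty_sum, 1)
}
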