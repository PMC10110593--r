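## Expectation-maximization fitting of the generative model.
##
## The E-step needs, for every observed sequence, the posterior weight of
## every scenario that can produce it. The complete scenario set of a
## sequence under wide supports is combinatorially large but almost all of
## its probability mass sits close to the most parsimonious explanations
## (every extra reattributed base costs a trim-probability and an
## insertion-probability factor). fit_model therefore enumerates, per
## sequence, all scenarios whose total edit count is within `slack` edits of
## the sequence's parsimony minimum, and runs exact EM on that fixed
## truncated scenario space. The truncation is data-independent across
## iterations, so the (truncated, penalized) likelihood is non-decreasing.

.datatable.aware <- TRUE

## integer scenario table for one sequence: columns
## inv, dv, d5, d3, dj, a, b, nA, nC, nG, nT (insertion base counts)
.enumerate_table <- function(s, reference, bounds, slack = 8L) {
  fr <- .seq_frame(s, reference, bounds)
  if (fr$dv_min > fr$dv_max || fr$dj_min > fr$dj_max) return(NULL)
  lb <- .left_block(fr, bounds)
  rb <- .right_block(fr, bounds)
  if (is.null(lb) || is.null(rb)) return(NULL)
  L <- fr$L
  le <- lb$dv + lb$a
  re <- rb$dj + rb$b
  ## blocks are ordered by (start, dv) and (end, dj); edits increase with
  ## dv/dj within a group, so the group's first element is its minimum
  minL <- rep.int(NA_integer_, L + 1L)
  f <- !duplicated(lb$start)
  minL[lb$start[f]] <- le[f]
  minR <- rep.int(NA_integer_, L + 1L)
  f <- !duplicated(rb$end)
  minR[rb$end[f] + 1L] <- re[f]

  ce <- .core_entries(fr, reference, bounds)
  d5s <- .empty_core_d5(fr, bounds)
  ## parsimony minimum total edits
  pars <- Inf
  if (!is.null(ce))
    pars <- min(pars, suppressWarnings(
      min(minL[ce$start] + ce$d5 + ce$d3 + minR[ce$end + 1L], na.rm = TRUE)))
  if (length(d5s))
    pars <- min(pars, suppressWarnings(
      min(minL + fr$nd + minR, na.rm = TRUE)))
  if (!is.finite(pars)) return(NULL)
  cap <- pars + slack

  ## candidate (start, end, d5, d3, inv) entries; empty-core rows are marked
  ## d5 = -1 and expanded over splits/orientations afterwards
  ent_start <- integer(); ent_end <- integer(); ent_d5 <- integer()
  ent_d3 <- integer(); ent_inv <- integer(); ent_core <- integer()
  if (!is.null(ce)) {
    ent_start <- ce$start; ent_end <- ce$end; ent_d5 <- ce$d5; ent_d3 <- ce$d3
    ent_inv <- as.integer(ce$inverted); ent_core <- ce$d5 + ce$d3
  }
  if (length(d5s)) {
    g <- which(!is.na(minL) & !is.na(minR)) - 1L  # boundary g has Ls at g+1, Rs at g
    g <- g[!is.na(minL[g + 1L])]
    if (length(g)) {
      ent_start <- c(ent_start, g + 1L); ent_end <- c(ent_end, g)
      ent_d5 <- c(ent_d5, rep.int(-1L, length(g)))
      ent_d3 <- c(ent_d3, rep.int(-1L, length(g)))
      ent_inv <- c(ent_inv, rep.int(-1L, length(g)))
      ent_core <- c(ent_core, rep.int(fr$nd, length(g)))
    }
  }
  if (!length(ent_start)) return(NULL)
  ok <- !is.na(minL[ent_start]) & !is.na(minR[ent_end + 1L]) &
    minL[ent_start] + ent_core + minR[ent_end + 1L] <= cap
  if (!any(ok)) return(NULL)
  ent_start <- ent_start[ok]; ent_end <- ent_end[ok]; ent_d5 <- ent_d5[ok]
  ent_d3 <- ent_d3[ok]; ent_inv <- ent_inv[ok]; ent_core <- ent_core[ok]

  ## offset indexing into the (already grouped) left/right blocks
  cntL <- tabulate(lb$start, L + 1L)
  offL <- c(0L, cumsum(cntL))
  cntR <- tabulate(rb$end + 1L, L + 1L)
  offR <- c(0L, cumsum(cntR))

  ## expand entries x right block x left block, fully vectorized
  nR <- cntR[ent_end + 1L]
  e1 <- rep.int(seq_along(ent_start), nR)
  ir <- sequence(nR) + offR[ent_end[e1] + 1L]
  nL <- cntL[ent_start[e1]]
  r2 <- rep.int(seq_along(e1), nL)
  il <- sequence(nL) + offL[ent_start[e1][r2]]
  e2 <- e1[r2]; ir2 <- ir[r2]
  tot <- le[il] + ent_core[e2] + re[ir2]
  keep <- tot <= cap
  if (!any(keep)) return(NULL)
  e2 <- e2[keep]; il <- il[keep]; ir2 <- ir2[keep]

  ## expand empty-core rows over (d5 split) x (orientation)
  is_empty <- ent_d5[e2] < 0L
  n_split <- ifelse(is_empty, 2L * length(d5s), 1L)
  r3 <- rep.int(seq_along(e2), n_split)
  pos <- sequence(n_split)
  e3 <- e2[r3]; il3 <- il[r3]; ir3 <- ir2[r3]
  d5_out <- ent_d5[e3]; d3_out <- ent_d3[e3]; inv_out <- ent_inv[e3]
  emp <- d5_out < 0L
  if (any(emp)) {
    k <- pos[emp]
    d5_out[emp] <- d5s[(k - 1L) %/% 2L + 1L]
    d3_out[emp] <- fr$nd - d5_out[emp]
    inv_out[emp] <- (k - 1L) %% 2L
  }

  ## insertion base counts via cumulative composition of s
  bi <- match(as.integer(fr$sv), as.integer(charToRaw("ACGT")))
  cc <- matrix(0L, 4L, L + 1L)
  if (L > 0L) for (b in 1:4) cc[b, ] <- c(0L, cumsum(bi == b))
  P <- fr$nv - lb$dv[il3]
  Q <- L - (fr$nj - rb$dj[ir3])
  st <- ent_start[e3]; en <- ent_end[e3]
  cnt <- (cc[, st, drop = FALSE] - cc[, P + 1L, drop = FALSE]) +
    (cc[, Q + 1L, drop = FALSE] - cc[, en + 1L, drop = FALSE])
  cbind(inv = inv_out, dv = lb$dv[il3], d5 = d5_out, d3 = d3_out,
        dj = rb$dj[ir3], a = lb$a[il3], b = rb$b[ir3],
        nA = cnt[1L, ], nC = cnt[2L, ], nG = cnt[3L, ], nT = cnt[4L, ])
}

## uniform initialization over the bound supports
uniform_model <- function(bounds) {
  u <- function(k) rep(1 / (k + 1), k + 1)
  generative_model(u(bounds$del_v), u(bounds$del_d5), u(bounds$del_d3),
                   u(bounds$del_j), u(bounds$ins_vd), u(bounds$ins_dj),
                   rep(0.25, 4), 0.5)
}

#' Fit the generative model by expectation-maximization
#'
#' E-step: each scenario consistent with each sequence is weighted by its
#' normalized probability under the current model. M-step: every categorical
#' is set to the (pseudo-count regularized) expected-count distribution.
#' Iteration stops when the largest absolute parameter change drops below
#' `tol` or after `max_iter` iterations.
#'
#' Scenario sets are enumerated once, truncated per sequence at
#' `slack` total edits above the parsimony minimum (see package vignette);
#' the truncation is fixed across iterations, so the monitored data
#' log-likelihood is non-decreasing.
#'
#' @param sequences Character vector of observed barcode sequences
#'   (duplicates allowed; they are pooled with multiplicity).
#' @param reference A `cassette_reference`.
#' @param bounds Support bounds (default [default_bounds()]).
#' @param init Initial `drag_model` (default: uniform categoricals,
#'   `p_inv = 0.5`).
#' @param max_iter,tol EM stopping rule.
#' @param pseudo Pseudo-count added per category in the M-step.
#' @param slack Per-sequence scenario truncation: total edits retained up to
#'   parsimony + `slack`.
#' @return A fitted `drag_model` with attributes `logLik` (per-iteration
#'   data log-likelihood), `n_excluded` (sequences with no consistent
#'   scenario), `n_iter` and `converged`.
#' @export
fit_model <- function(sequences, reference, bounds = NULL, init = NULL,
                      max_iter = 200L, tol = 1e-6, pseudo = 0.5, slack = 6L) {
  stopifnot(inherits(reference, "cassette_reference"), length(sequences) >= 1L)
  if (is.null(bounds)) bounds <- default_bounds(reference)
  if (is.null(init)) init <- uniform_model(bounds)
  tab <- table(sequences)
  useq <- names(tab)
  mult <- as.numeric(tab)

  tabs <- lapply(useq, .enumerate_table, reference = reference,
                 bounds = bounds, slack = slack)
  bad <- vapply(tabs, is.null, logical(1))
  n_excluded <- sum(mult[bad])
  if (all(bad)) stop("no sequence admits a recombination scenario within bounds")
  if (n_excluded > 0L)
    warning(n_excluded, " sequence(s) admit no scenario within bounds; excluded")
  tabs <- tabs[!bad]
  mult <- mult[!bad]
  nsc <- vapply(tabs, nrow, integer(1))
  dt <- data.table::as.data.table(do.call(rbind, tabs))
  dt[, `:=`(seq = rep.int(seq_along(nsc), nsc),
            m = rep.int(mult, nsc))]

  model <- init
  ll_trace <- numeric(0)
  converged <- FALSE
  par_vec <- function(m) c(m$p_del_v, m$p_del_d5, m$p_del_d3, m$p_del_j,
                           m$p_ins_vd, m$p_ins_dj, m$p_nt, m$p_inv)
  norm1 <- function(x) x / sum(x)
  for (it in seq_len(max_iter)) {
    lpv <- log(model$p_del_v); lp5 <- log(model$p_del_d5)
    lp3 <- log(model$p_del_d3); lpj <- log(model$p_del_j)
    li1 <- log(model$p_ins_vd); li2 <- log(model$p_ins_dj)
    lnt <- log(model$p_nt)
    linv <- c(log(1 - model$p_inv), log(model$p_inv))
    dt[, lp := lpv[dv + 1L] + lp5[d5 + 1L] + lp3[d3 + 1L] + lpj[dj + 1L] +
         li1[a + 1L] + li2[b + 1L] + linv[inv + 1L] +
         nA * lnt[1L] + nC * lnt[2L] + nG * lnt[3L] + nT * lnt[4L]]
    dt[, w := {mx <- max(lp); e <- exp(lp - mx); e / sum(e)}, by = seq]
    ll <- dt[, .(l = {mx <- max(lp); (mx + log(sum(exp(lp - mx)))) * m[1L]}),
             by = seq][, sum(l)]
    ll_trace <- c(ll_trace, ll)
    dt[, wm := w * m]
    ecount <- function(col, k) {
      s <- dt[, .(v = sum(wm)), by = col]
      out <- rep(pseudo, k + 1L)
      out[s[[col]] + 1L] <- out[s[[col]] + 1L] + s$v
      out
    }
    new <- model
    new$p_del_v <- stats::setNames(norm1(ecount("dv", bounds$del_v)),
                                   names(model$p_del_v))
    new$p_del_d5 <- stats::setNames(norm1(ecount("d5", bounds$del_d5)),
                                    names(model$p_del_d5))
    new$p_del_d3 <- stats::setNames(norm1(ecount("d3", bounds$del_d3)),
                                    names(model$p_del_d3))
    new$p_del_j <- stats::setNames(norm1(ecount("dj", bounds$del_j)),
                                   names(model$p_del_j))
    new$p_ins_vd <- stats::setNames(norm1(ecount("a", bounds$ins_vd)),
                                    names(model$p_ins_vd))
    new$p_ins_dj <- stats::setNames(norm1(ecount("b", bounds$ins_dj)),
                                    names(model$p_ins_dj))
    ntc <- dt[, .(A = sum(wm * nA), C = sum(wm * nC),
                  G = sum(wm * nG), T = sum(wm * nT))]
    new$p_nt <- stats::setNames(norm1(unlist(ntc) + pseudo),
                                c("A", "C", "G", "T"))
    ninv <- dt[, sum(wm * inv)]
    new$p_inv <- (ninv + pseudo) / (sum(mult) + 2 * pseudo)
    delta <- max(abs(par_vec(new) - par_vec(model)))
    model <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(model, "logLik") <- ll_trace
  attr(model, "n_excluded") <- n_excluded
  attr(model, "n_iter") <- length(ll_trace)
  attr(model, "converged") <- converged
  model
}
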