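#' Dynamics of clonal diversity over time with a breakpoint
#'
#' Parameters of the programmed diversity trajectory: on the log scale the
#' expected diversity of mouse `i` at time `t` (months post-induction) is
#' `beta0 + u_i + beta1 * t + beta2 * max(0, t - breakpoint)` with
#' `u_i ~ Normal(0, sigma_u^2)`; realized diversity is Gamma-distributed
#' around that mean with the given shape. The defaults encode the motif of
#' the barcoding study: diversity declines up to month 7 and rises again
#' afterwards.
#'
#' @param baseline_log Intercept `beta0` (log diversity at t = 0).
#' @param slope_before Log-scale slope `beta1` per month before the
#'   breakpoint.
#' @param slope_change Change in slope `beta2` at the breakpoint (slope
#'   after = `beta1 + beta2`).
#' @param breakpoint Breakpoint time in months.
#' @param sigma_u Between-mouse random-intercept standard deviation.
#' @param shape Gamma shape of the realized diversity around its mean; `Inf`
#'   for noiseless dynamics.
#' @return A list of class `diversity_dynamics`.
#' @export
diversity_dynamics <- function(baseline_log = log(300), slope_before = -0.15,
                               slope_change = 0.30, breakpoint = 7,
                               sigma_u = 0.25, shape = 20) {
  stopifnot(shape > 0, sigma_u >= 0)
  structure(list(baseline_log = baseline_log, slope_before = slope_before,
                 slope_change = slope_change, breakpoint = breakpoint,
                 sigma_u = sigma_u, shape = shape),
            class = "diversity_dynamics")
}

## expected log-diversity of the fixed-effect trajectory
.dyn_eta <- function(dyn, t, u = 0) {
  dyn$baseline_log + u + dyn$slope_before * t +
    dyn$slope_change * pmax(0, t - dyn$breakpoint)
}

#' Simulate longitudinal diversity observations from the breakpoint model
#'
#' Draws per-sample diversity values directly from the segmented gamma mixed
#' model (mouse random intercepts, gamma noise around the piecewise
#' log-linear mean). This is the generating process the breakpoint GLMM of
#' [fit_breakpoint_glmm()] assumes; use it for parameter-recovery studies.
#'
#' @param dynamics A `diversity_dynamics`.
#' @param mice Number of mice (or character vector of ids).
#' @param timepoints Numeric vector of sampling times (months).
#' @param replicates Technical replicates per (mouse, time).
#' @return Data frame: mouse, t, replicate, y.
#' @export
simulate_diversity_observations <- function(dynamics = diversity_dynamics(),
                                            mice = 4L,
                                            timepoints = 4:12,
                                            replicates = 2L) {
  stopifnot(inherits(dynamics, "diversity_dynamics"))
  ids <- if (is.character(mice)) mice else sprintf("m%d", seq_len(mice))
  u <- stats::rnorm(length(ids), 0, dynamics$sigma_u)
  names(u) <- ids
  g <- expand.grid(replicate = seq_len(replicates), t = timepoints,
                   mouse = ids, stringsAsFactors = FALSE)
  mu <- exp(.dyn_eta(dynamics, g$t, u[g$mouse]))
  y <- if (is.finite(dynamics$shape)) {
    stats::rgamma(nrow(g), shape = dynamics$shape,
                  rate = dynamics$shape / mu)
  } else mu
  data.frame(mouse = g$mouse, t = g$t, replicate = g$replicate, y = y,
             stringsAsFactors = FALSE)
}

#' Simulate a longitudinal blood-sampling timecourse at the clone level
#'
#' Realizes the programmed diversity trajectory through the number of clones
#' actively contributing at each timepoint: each mouse carries a pool of
#' barcoded clones with log-normal abundance weights; at time `t` a
#' Gamma-distributed number of clones around the trajectory mean is active,
#' and each blood replicate captures each active clone independently with
#' probability `capture` (low capture emulates the small blood volume).
#' Captured clones receive UMI counts proportional to their abundance.
#'
#' @param dynamics A `diversity_dynamics`; its `baseline_log` should stay
#'   below `log(pool_size)`.
#' @param mice Number of mice.
#' @param timepoints Months sampled.
#' @param replicates Blood PCR replicates per timepoint.
#' @param capture Per-replicate probability that an active clone is
#'   detected (1 = every active clone observed).
#' @param pool_size Clones in each mouse's pool.
#' @param mean_umis Mean UMI count scale for captured clones.
#' @param reference,model Cassette and generative model for barcode drawing.
#' @return A list with `observations` (long data frame: mouse, t, replicate,
#'   barcode, umis), `truth` (per mouse x t: active-clone count K) and
#'   `clones` (per-mouse barcode pools).
#' @export
simulate_timecourse <- function(dynamics = diversity_dynamics(),
                                mice = 4L, timepoints = 4:12,
                                replicates = 2L, capture = 0.05,
                                pool_size = 1500L, mean_umis = 20,
                                reference = default_reference(),
                                model = default_model(reference)) {
  stopifnot(inherits(dynamics, "diversity_dynamics"),
            capture > 0, capture <= 1)
  ids <- sprintf("m%d", seq_len(mice))
  u <- stats::rnorm(mice, 0, dynamics$sigma_u)
  clones <- lapply(ids, function(id) {
    bc <- sample_recombination(model, reference, pool_size)$sequences
    dup <- which(duplicated(bc))
    if (length(dup))
      bc[dup] <- paste0(bc[dup], seq_along(dup)) # disambiguate rare collisions
    data.frame(mouse = id, barcode = bc,
               weight = stats::rlnorm(pool_size, 0, 1),
               stringsAsFactors = FALSE)
  })
  names(clones) <- ids
  obs <- list(); truth <- list()
  for (i in seq_along(ids)) {
    for (t in timepoints) {
      mu <- exp(.dyn_eta(dynamics, t, u[i]))
      K_raw <- if (is.finite(dynamics$shape)) {
        stats::rgamma(1, shape = dynamics$shape, rate = dynamics$shape / mu)
      } else mu
      K <- max(1L, min(pool_size, as.integer(round(K_raw))))
      active <- sample.int(pool_size, K)
      truth[[length(truth) + 1L]] <- data.frame(
        mouse = ids[i], t = t, K_true = K, stringsAsFactors = FALSE)
      for (r in seq_len(replicates)) {
        cap <- if (capture >= 1) active else
          active[stats::runif(K) < capture]
        if (!length(cap)) next
        w <- clones[[i]]$weight[cap]
        umis <- 1L + stats::rpois(length(cap), mean_umis * w / mean(w))
        obs[[length(obs) + 1L]] <- data.frame(
          mouse = ids[i], t = t, replicate = r,
          barcode = clones[[i]]$barcode[cap], umis = umis,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(observations = do.call(rbind, obs),
       truth = do.call(rbind, truth),
       clones = do.call(rbind, clones))
}

#' Per-sample diversity of a simulated timecourse
#'
#' Collapses the clone-level observations of [simulate_timecourse()] into
#' per-(mouse, time, replicate) diversity values suitable for
#' [fit_breakpoint_glmm()].
#'
#' @param timecourse Result of [simulate_timecourse()].
#' @param index `"richness"` (number of distinct barcodes) or
#'   `"inverse_simpson"`.
#' @return Data frame: mouse, t, replicate, y.
#' @export
timecourse_diversity <- function(timecourse, index = c("richness",
                                                       "inverse_simpson")) {
  index <- match.arg(index)
  ob <- timecourse$observations
  key <- interaction(ob$mouse, ob$t, ob$replicate, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(ob)), key), function(ix) {
    y <- if (index == "richness") length(unique(ob$barcode[ix])) else {
      p <- ob$umis[ix] / sum(ob$umis[ix])
      1 / sum(p^2)
    }
    data.frame(mouse = ob$mouse[ix[1]], t = ob$t[ix[1]],
               replicate = ob$replicate[ix[1]], y = y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mouse, out$t, out$replicate), ]
}
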