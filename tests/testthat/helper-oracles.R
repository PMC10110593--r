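## Shared fixtures and independent oracles.

## micro cassette: segments small enough for exhaustive scenario-space
## enumeration; D length >= del_d5 + del_d3 supports so the joint D-trim
## support is feasible and the model normalizes exactly
micro_reference <- function() {
  cassette_reference("ACGTA", "TACGT", "GGATC", "ACGT", "TGCA")
}

micro_bounds <- function() {
  list(del_v = 2L, del_d5 = 2L, del_d3 = 2L, del_j = 2L,
       ins_vd = 2L, ins_dj = 2L)
}

micro_model <- function(p_inv = 0.3) {
  generative_model(
    p_del_v = c(0.5, 0.3, 0.2), p_del_d5 = c(0.6, 0.25, 0.15),
    p_del_d3 = c(0.7, 0.2, 0.1), p_del_j = c(0.4, 0.4, 0.2),
    p_ins_vd = c(0.5, 0.3, 0.2), p_ins_dj = c(0.6, 0.3, 0.1),
    p_nt = c(A = 0.25, C = 0.25, G = 0.3, T = 0.2), p_inv = p_inv)
}

## point-mass model: no trims, no insertions, no inversion
point_mass_model <- function() {
  generative_model(1, 1, 1, 1, 1, 1, c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                   p_inv = 0)
}

## all insertion strings up to length imax (including "")
ins_space <- function(imax) {
  out <- ""
  for (l in seq_len(imax)) {
    g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), l))
    out <- c(out, apply(g, 1, paste, collapse = ""))
  }
  out
}

## exhaustive scenario grid within bounds (the brute-force oracle space)
brute_scenarios <- function(reference, bounds) {
  nd <- nchar(reference$d_seq)
  g <- expand.grid(inverted = c(FALSE, TRUE),
                   del_v = 0:bounds$del_v, del_d5 = 0:bounds$del_d5,
                   del_d3 = 0:bounds$del_d3, del_j = 0:bounds$del_j,
                   ins_vd = ins_space(bounds$ins_vd),
                   ins_dj = ins_space(bounds$ins_dj),
                   stringsAsFactors = FALSE)
  g[g$del_d5 + g$del_d3 <= nd, , drop = FALSE]
}

## brute-force enumeration oracle: realize everything and filter
brute_enumerate <- function(reference, sequence, bounds) {
  g <- brute_scenarios(reference, bounds)
  g[realize_scenario(reference, g) == sequence, , drop = FALSE]
}

scenario_key <- function(df) {
  sort(paste(df$inverted, df$del_v, df$del_d5, df$del_d3, df$del_j,
             df$ins_vd, df$ins_dj))
}

## total-variation distance between two categorical distributions
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
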