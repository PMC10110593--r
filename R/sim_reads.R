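#' Read layout of a UMI-tagged barcode amplicon
#'
#' Reads start with a random unique molecular identifier (UMI) of
#' `umi_length` bases, followed by a constant anchor and then the recombined
#' barcode region, which runs to the end of the read.
#'
#' @param umi_length UMI length in nt.
#' @param anchor Constant anchor sequence following the UMI.
#' @param anchor_max_mismatch Maximum tolerated anchor mismatches during UMI
#'   extraction.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(umi_length = 8L,
                        anchor = default_reference()$left_const,
                        anchor_max_mismatch = 1L) {
  stopifnot(umi_length >= 1L, nchar(anchor) >= 1L, anchor_max_mismatch >= 0L)
  structure(list(umi_length = as.integer(umi_length), anchor = anchor,
                 anchor_max_mismatch = as.integer(anchor_max_mismatch)),
            class = "read_layout")
}

#' Specification of one sequenced biological sample
#'
#' @param mouse,compartment,timepoint Sample identity (compartment one of
#'   `HSPC`, `MP`, `M`, `blood-M`; timepoint in months post-induction).
#' @param cells_sampled Number of GFP+ cells drawn from the compartment.
#' @param pcr_replicates Number of technical (PCR duplicate) replicates the
#'   sampled material is split into before amplification.
#' @param umis_per_cell Mean extra UMIs per sampled cell; each cell yields
#'   `1 + Poisson(umis_per_cell)` tagged molecules.
#' @param reads_per_umi Mean extra reads per UMI; each UMI yields
#'   `1 + Poisson(reads_per_umi)` reads.
#' @param seq_error_rate Per-base substitution error probability.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(mouse = "m1", compartment = "M", timepoint = 0,
                        cells_sampled = 1000L, pcr_replicates = 2L,
                        umis_per_cell = 0.3, reads_per_umi = 2,
                        seq_error_rate = 1e-3) {
  stopifnot(cells_sampled >= 0L, pcr_replicates >= 1L,
            seq_error_rate >= 0, seq_error_rate <= 1,
            umis_per_cell >= 0, reads_per_umi >= 0)
  structure(list(mouse = mouse, compartment = compartment,
                 timepoint = timepoint,
                 cells_sampled = as.integer(cells_sampled),
                 pcr_replicates = as.integer(pcr_replicates),
                 umis_per_cell = umis_per_cell, reads_per_umi = reads_per_umi,
                 seq_error_rate = seq_error_rate),
            class = "sample_spec")
}

## multivariate hypergeometric draw: sample k cells without replacement from
## clones with sizes `sizes`
rmvhyper <- function(sizes, k) {
  out <- integer(length(sizes))
  rest <- sum(sizes)
  for (i in seq_along(sizes)) {
    if (k <= 0L) break
    rest <- rest - sizes[i]
    out[i] <- stats::rhyper(1L, sizes[i], rest, k)
    k <- k - out[i]
  }
  out
}

## random fixed-length oligos
random_oligos <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), n, len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## inject substitution errors at per-base rate; vectorized over reads
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), nerr[i])
    for (p in pos)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate UMI-tagged sequencing reads from a clone population
#'
#' GFP+ cells of the requested compartment are sampled without replacement
#' proportional to clone sizes, split across PCR replicates, tagged with
#' random UMIs (`1 + Poisson` per cell), amplified into `1 + Poisson` reads
#' per UMI, and sequenced with independent per-base substitution errors.
#' Each read is `UMI + anchor + barcode`; reads span the full recombined
#' region, so read length varies with the barcode.
#'
#' @param population A `clone_population`.
#' @param spec A `sample_spec`.
#' @param layout A `read_layout`.
#' @return A list with
#'   \describe{
#'     \item{reads}{data frame: read_id, sample_id, replicate, sequence.}
#'     \item{truth}{data frame per (clone, replicate): true sampled cells,
#'       true UMI count, emitted read count.}
#'     \item{samples}{data frame of per-replicate sample metadata.}
#'   }
#' @export
simulate_reads <- function(population, spec, layout = read_layout()) {
  stopifnot(inherits(population, "clone_population"),
            inherits(spec, "sample_spec"), inherits(layout, "read_layout"))
  cl <- population$clones
  comp_col <- paste0("cells_", sub("^blood-", "", spec$compartment))
  if (!comp_col %in% names(cl)) stop("unknown compartment: ", spec$compartment)
  pool <- ifelse(cl$gfp_labeled, cl[[comp_col]], 0)
  if (spec$cells_sampled > sum(pool))
    stop("cells_sampled exceeds the GFP+ compartment size (",
         sum(pool), " cells)")
  n_cells <- rmvhyper(pool, spec$cells_sampled)
  R <- spec$pcr_replicates
  sample_ids <- sprintf("%s_%s_t%g_r%d", spec$mouse, spec$compartment,
                        spec$timepoint, seq_len(R))

  reads_acc <- vector("list", R)
  truth_acc <- vector("list", R)
  for (r in seq_len(R)) {
    ## split each clone's sampled cells across the remaining replicates
    if (r < R) {
      keep <- stats::rbinom(length(n_cells), n_cells, 1 / (R - r + 1))
    } else keep <- n_cells
    n_cells <- n_cells - keep
    cells_rep <- keep
    active <- which(cells_rep > 0L)
    n_umi_per_clone <- integer(length(cells_rep))
    reads_list <- list()
    if (length(active)) {
      cell_clone <- rep.int(active, cells_rep[active])
      n_umi_cell <- 1L + stats::rpois(length(cell_clone), spec$umis_per_cell)
      umi_clone <- rep.int(cell_clone, n_umi_cell)
      n_umi <- length(umi_clone)
      umis <- random_oligos(n_umi, layout$umi_length)
      n_reads_umi <- 1L + stats::rpois(n_umi, spec$reads_per_umi)
      read_umi_idx <- rep.int(seq_len(n_umi), n_reads_umi)
      seqs <- paste0(umis[read_umi_idx], layout$anchor,
                     cl$barcode[umi_clone[read_umi_idx]])
      seqs <- inject_errors(seqs, spec$seq_error_rate)
      n_umi_per_clone <- tabulate(umi_clone, length(cells_rep))
      reads_list <- data.frame(
        read_id = sprintf("%s_read%06d", sample_ids[r], seq_along(seqs)),
        sample_id = sample_ids[r],
        replicate = r,
        clone_id = cl$clone_id[umi_clone[read_umi_idx]],
        umi = umis[read_umi_idx],
        sequence = seqs, stringsAsFactors = FALSE)
      n_reads_per_clone <- tabulate(umi_clone[read_umi_idx], length(cells_rep))
    } else {
      n_reads_per_clone <- integer(length(cells_rep))
      reads_list <- data.frame(read_id = character(), sample_id = character(),
                               replicate = integer(), clone_id = character(),
                               umi = character(), sequence = character(),
                               stringsAsFactors = FALSE)
    }
    reads_acc[[r]] <- reads_list
    truth_acc[[r]] <- data.frame(
      sample_id = sample_ids[r], replicate = r, clone_id = cl$clone_id,
      barcode = cl$barcode, cells = cells_rep, umis = n_umi_per_clone,
      reads = n_reads_per_clone, stringsAsFactors = FALSE)
  }
  samples <- data.frame(
    sample_id = sample_ids, mouse = spec$mouse,
    compartment = spec$compartment, timepoint = spec$timepoint,
    replicate = seq_len(R), stringsAsFactors = FALSE)
  list(reads = do.call(rbind, reads_acc),
       truth = do.call(rbind, truth_acc),
       samples = samples)
}

#' Write simulated reads as FASTQ / read them back
#'
#' @param reads Read data frame from [simulate_reads()].
#' @param path Output FASTQ path (`.gz` for compressed output).
#' @return `write_fastq` returns `path` invisibly; `read_fastq` returns a
#'   data frame with read_id and sequence.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  qual <- Biostrings::BStringSet(vapply(nchar(reads$sequence), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(ss), sequence = as.character(ss),
             stringsAsFactors = FALSE)
}
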