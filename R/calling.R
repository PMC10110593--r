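#' Extract UMIs and barcode inserts from raw reads
#'
#' The first `umi_length` bases are the UMI; the following bases must match
#' the constant anchor within `anchor_max_mismatch` substitutions; the
#' remainder of the read is the barcode insert. Reads failing either check
#' are rejected with a reason code.
#'
#' @param sequences Character vector of read sequences.
#' @param layout A `read_layout`.
#' @return Data frame: umi, insert, accept (logical), reason (`""`,
#'   `"too_short"` or `"anchor_mismatch"`).
#' @export
extract_umi <- function(sequences, layout = read_layout()) {
  stopifnot(inherits(layout, "read_layout"))
  na <- nchar(layout$anchor)
  ext <- layout$umi_length + na
  n <- length(sequences)
  len <- nchar(sequences)
  reason <- character(n)
  reason[len < ext + 1L] <- "too_short"
  umi <- substr(sequences, 1L, layout$umi_length)
  obs_anchor <- substr(sequences, layout$umi_length + 1L, ext)
  mism <- integer(n)
  anchor_ch <- strsplit(layout$anchor, "")[[1]]
  for (p in seq_len(na))
    mism <- mism + (substr(obs_anchor, p, p) != anchor_ch[p])
  bad_anchor <- reason == "" & mism > layout$anchor_max_mismatch
  reason[bad_anchor] <- "anchor_mismatch"
  accept <- reason == ""
  data.frame(umi = ifelse(len >= layout$umi_length, umi, NA_character_),
             insert = ifelse(accept, substr(sequences, ext + 1L, len), NA),
             accept = accept, reason = reason, stringsAsFactors = FALSE)
}

## per-position majority vote across equal-length strings; NULL on any tie
.majority_vote <- function(seqs) {
  ch <- do.call(rbind, strsplit(seqs, ""))
  cons <- character(ncol(ch))
  for (p in seq_len(ncol(ch))) {
    tb <- sort(table(ch[, p]), decreasing = TRUE)
    if (length(tb) > 1L && tb[1L] == tb[2L]) return(NULL)
    cons[p] <- names(tb)[1L]
  }
  paste(cons, collapse = "")
}

#' Collapse reads to per-UMI consensus sequences
#'
#' Reads are grouped by (sample, UMI); each group is collapsed to a
#' per-position majority-vote consensus over the reads of the modal insert
#' length. Groups with fewer than `min_reads` reads, with a tie for the
#' modal length, or with a tied vote at any position are discarded (barcode
#' identity must be exact, so ties are dropped rather than ambiguity-coded).
#'
#' @param calls Data frame with columns `sample_id`, `umi`, `insert`
#'   (accepted rows of [extract_umi()] joined to their sample).
#' @param min_reads Minimum reads per UMI group.
#' @return Data frame: sample_id, umi, consensus, support (reads in group).
#' @export
consensus_by_umi <- function(calls, min_reads = 2L) {
  stopifnot(all(c("sample_id", "umi", "insert") %in% names(calls)))
  if (!nrow(calls))
    return(data.frame(sample_id = character(), umi = character(),
                      consensus = character(), support = integer(),
                      stringsAsFactors = FALSE))
  dt <- data.table::data.table(sample_id = calls$sample_id, umi = calls$umi,
                               insert = calls$insert)
  res <- dt[, {
    support <- .N
    if (support < min_reads) {
      list(consensus = NA_character_, support = support)
    } else if (data.table::uniqueN(insert) == 1L) {
      list(consensus = insert[1L], support = support)
    } else {
      lens <- nchar(insert)
      tb <- sort(table(lens), decreasing = TRUE)
      if (length(tb) > 1L && tb[1L] == tb[2L]) {
        list(consensus = NA_character_, support = support)
      } else {
        use <- insert[lens == as.integer(names(tb)[1L])]
        cons <- .majority_vote(use)
        list(consensus = if (is.null(cons)) NA_character_ else cons,
             support = support)
      }
    }
  }, by = .(sample_id, umi)]
  out <- as.data.frame(res[!is.na(consensus)])
  out
}

#' Annotate a consensus sequence against the cassette
#'
#' Finds the most parsimonious recombination scenario explaining the
#' sequence: among all consistent scenarios, the one with maximal total
#' germline retention (equivalently, minimal total edits — the two orders
#' coincide because sequence length fixes insertions given deletions), with
#' lexicographic tie-breaking. Sequences whose germline V-prefix / J-suffix
#' match is shorter than the minimum anchor length, that contain `N`, or
#' that admit no scenario within bounds are rejected.
#'
#' @param sequences Character vector of consensus sequences.
#' @param reference A `cassette_reference`.
#' @param bounds Enumeration bounds (default [default_bounds()]).
#' @param min_v_match,min_j_match Minimum germline match lengths at the V
#'   and J ends.
#' @return Data frame with one row per input: barcode (the sequence),
#'   accept, reason, and scenario annotation columns (del_v, del_d5, del_d3,
#'   del_j, ins_vd, ins_dj, n_ins_vd, n_ins_dj, inverted, total_edits).
#' @export
call_barcode <- function(sequences, reference, bounds = NULL,
                         min_v_match = 10L, min_j_match = 10L) {
  stopifnot(inherits(reference, "cassette_reference"))
  if (is.null(bounds)) bounds <- default_bounds(reference)
  one <- function(s) {
    rej <- function(reason) data.frame(
      barcode = s, accept = FALSE, reason = reason, inverted = NA,
      del_v = NA_integer_, del_d5 = NA_integer_, del_d3 = NA_integer_,
      del_j = NA_integer_, ins_vd = NA_character_, ins_dj = NA_character_,
      n_ins_vd = NA_integer_, n_ins_dj = NA_integer_,
      total_edits = NA_integer_, stringsAsFactors = FALSE)
    if (grepl("[^ACGT]", s)) return(rej("ambiguous_base"))
    fr <- .seq_frame(s, reference, bounds)
    if (fr$nv - fr$dv_min < min_v_match) return(rej("v_anchor_too_short"))
    if (fr$nj - fr$dj_min < min_j_match) return(rej("j_anchor_too_short"))
    tb <- .enumerate_table(s, reference, bounds, slack = 0L)
    if (is.null(tb)) return(rej("unannotatable"))
    pars <- min(tb[, "dv"] + tb[, "d5"] + tb[, "d3"] + tb[, "dj"] +
                  tb[, "a"] + tb[, "b"])
    sc <- enumerate_scenarios(reference, s, bounds, max_total_edits = pars)
    best <- sc[1L, ]
    data.frame(barcode = s, accept = TRUE, reason = "",
               inverted = best$inverted, del_v = best$del_v,
               del_d5 = best$del_d5, del_d3 = best$del_d3,
               del_j = best$del_j, ins_vd = best$ins_vd,
               ins_dj = best$ins_dj, n_ins_vd = nchar(best$ins_vd),
               n_ins_dj = nchar(best$ins_dj), total_edits = best$total_edits,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(sequences, one))
  rownames(out) <- NULL
  out
}

#' Full calling pipeline: reads to per-UMI barcode calls
#'
#' Runs [extract_umi()], [consensus_by_umi()] and [call_barcode()]
#' (annotating each distinct consensus once) over a read table.
#'
#' @param reads Data frame with columns `sample_id` and `sequence` (e.g.
#'   from [simulate_reads()] or [read_fastq()] joined to a sample sheet).
#' @param reference A `cassette_reference`.
#' @param layout A `read_layout`.
#' @param min_reads Minimum reads per UMI.
#' @param bounds Annotation bounds.
#' @param ... Passed to [call_barcode()].
#' @return A list with `calls` (data frame: sample_id, umi, barcode, one row
#'   per accepted UMI), `annotations` (one row per distinct accepted
#'   barcode) and `qc` (named counts of rejection reasons).
#' @export
call_reads <- function(reads, reference, layout = read_layout(),
                       min_reads = 2L, bounds = NULL, ...) {
  ex <- extract_umi(reads$sequence, layout)
  qc <- c(reads_total = nrow(reads),
          reads_rejected_umi = sum(!ex$accept))
  keep <- data.frame(sample_id = reads$sample_id[ex$accept],
                     umi = ex$umi[ex$accept], insert = ex$insert[ex$accept],
                     stringsAsFactors = FALSE)
  cons <- consensus_by_umi(keep, min_reads = min_reads)
  qc["umi_groups_kept"] <- nrow(cons)
  uniq <- unique(cons$consensus)
  ann <- call_barcode(uniq, reference, bounds = bounds, ...)
  qc["barcodes_unannotatable"] <- sum(!ann$accept)
  ok <- ann$accept[match(cons$consensus, ann$barcode)]
  calls <- data.frame(sample_id = cons$sample_id[ok], umi = cons$umi[ok],
                      barcode = cons$consensus[ok], stringsAsFactors = FALSE)
  list(calls = calls, annotations = ann[ann$accept, , drop = FALSE], qc = qc)
}
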