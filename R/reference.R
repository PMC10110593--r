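#' Cassette reference for a VDJ-recombination barcoding locus
#'
#' Bundles the germline V, D and J segment sequences of a recombination
#' cassette together with the constant flanks upstream and downstream of the
#' recombined region. All downstream operations (scenario realization,
#' enumeration, Pgen) are defined relative to such a reference.
#'
#' @param v_seq,d_seq,j_seq Germline segment sequences (uppercase A/C/G/T).
#'   The V segment is trimmed at its 3' end, the J segment at its 5' end and
#'   the D segment at both ends (after optional inversion).
#' @param left_const,right_const Constant anchor sequences flanking the
#'   recombined region (used by the read simulator and UMI extraction).
#' @return An object of class `cassette_reference`.
#' @examples
#' ref <- cassette_reference("ACGT", "TT", "GCAA")
#' @export
cassette_reference <- function(v_seq, d_seq, j_seq,
                               left_const = "ACGTACGTACGT",
                               right_const = "TGCATGCATGCA") {
  seqs <- c(V = v_seq, D = d_seq, J = j_seq,
            LCONST = left_const, RCONST = right_const)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    if (!is.character(s) || length(s) != 1L || is.na(s) || nchar(s) == 0L)
      stop("reference sequence '", nm, "' must be a nonempty string")
    if (grepl("[^ACGT]", s))
      stop("reference sequence '", nm, "' contains characters outside {A,C,G,T}")
  }
  structure(list(v_seq = v_seq, d_seq = d_seq, j_seq = j_seq,
                 left_const = left_const, right_const = right_const),
            class = "cassette_reference")
}

#' Default synthetic cassette reference
#'
#' A fixed synthetic reference with a 60-nt V segment, a 17-nt D segment
#' (DSP2.4-like length, start codon mutated to ATC) and a 40-nt J segment,
#' long enough to support trims of up to 32 nt at the V and J sites. The
#' sequences are synthetic stand-ins, not the genomic cassette; real segment
#' sequences can be supplied via [cassette_reference()] or [read_reference()].
#'
#' @return A `cassette_reference`.
#' @export
default_reference <- function() {
  cassette_reference(
    v_seq = "AGTCCCCAGGCTAAACCGTCTGAATACCGTATGTAACCAGTATCACCGAGACTTATGCGC",
    d_seq = "TCTACTATCGTTACGAC",
    j_seq = "AGCAATCTTGCATCATTGTTATCGAACGGAGCCGGTATGA",
    left_const = "AGTACAGGACGT",
    right_const = "TGGGCAAGATAC")
}

#' @export
print.cassette_reference <- function(x, ...) {
  cat("cassette_reference\n")
  cat(sprintf("  V: %d nt  D: %d nt  J: %d nt  (flanks %d/%d nt)\n",
              nchar(x$v_seq), nchar(x$d_seq), nchar(x$j_seq),
              nchar(x$left_const), nchar(x$right_const)))
  invisible(x)
}

#' Read / write a cassette reference as FASTA
#'
#' The FASTA file must contain records named `V`, `D`, `J`, `LCONST` and
#' `RCONST`.
#'
#' @param path Path to a FASTA file.
#' @return `read_reference` returns a `cassette_reference`; `write_reference`
#'   returns `path` invisibly.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  need <- c("V", "D", "J", "LCONST", "RCONST")
  if (!all(need %in% names(ss)))
    stop("reference FASTA must contain records named ", paste(need, collapse = ", "))
  s <- as.character(ss)
  cassette_reference(s[["V"]], s[["D"]], s[["J"]], s[["LCONST"]], s[["RCONST"]])
}

#' @rdname read_reference
#' @param reference A `cassette_reference`.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "cassette_reference"))
  ss <- Biostrings::DNAStringSet(c(V = reference$v_seq, D = reference$d_seq,
                                   J = reference$j_seq,
                                   LCONST = reference$left_const,
                                   RCONST = reference$right_const))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## reverse complement, vectorized over character
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
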