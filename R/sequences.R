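#' Sequence records
#'
#' A `sequence_record` holds a one-letter amino-acid string together with the
#' offset that maps residue 1 of the string onto mature-protein numbering.
#' All sequence coordinates in this package are 1-based mature numbering.
#'
#' @param name sequence identifier.
#' @param residues one-letter amino-acid string (20 standard letters plus
#'   `"X"` for unknown).
#' @param numbering_offset mature-sequence position of the first residue of
#'   `residues` (default 1).
#' @return An object of class `sequence_record`.
#' @export
sequence_record <- function(name, residues, numbering_offset = 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (nchar(residues) == 0L) stop("empty sequence for '", name, "'")
  bad <- gsub("[ACDEFGHIKLMNPQRSTVWYX]", "", residues)
  if (nchar(bad) > 0L)
    stop("sequence '", name, "' contains non-amino-acid letters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  structure(list(name = name, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s: %d aa (numbering starts at %d)\n",
              x$name, nchar(x$residues), x$numbering_offset))
  invisible(x)
}

#' @export
length.sequence_record <- function(x) nchar(x$residues)

#' Built-in mature sequences of the CCR9-CCL25 system
#'
#' Mature one-letter sequences of human CCR9 (isoform A), CCL25 (full length,
#' 127 residues; residue 1 is the glutamine-derived pyroglutamate, written
#' here as its proline-like one-letter stand-in "P" as conventionally printed
#' for the mature chemokine), and the N-terminally engineered analog
#' \[1P6\]CCL25 in which residues 1-4 (pGlu-Gly-Val-Phe) are replaced by
#' Tyr-Gln-Ala-Ser.
#'
#' @param which one of `"CCR9"`, `"CCL25"`, `"1P6-CCL25"`.
#' @return A [sequence_record].
#' @examples
#' find_subsequence(builtin_sequence("CCL25"), "QEVSGSCNLPA")  # 29
#' n_terminal_region(builtin_sequence("CCL25"))                # 6
#' @export
builtin_sequence <- function(which = c("CCL25", "CCR9", "1P6-CCL25")) {
  which <- match.arg(which)
  seqs <- list(
    "CCR9" = paste0(
      "MTPTDFTSPIPNMADDYGSESTSSMEDYVNFNFTDFYCEKNNVRQFASHFLPPLYWLVFI",
      "VGALGNSLVILVYWYCTRVKTMTDMFLLNLAIADLLFLVTLPFWAIAAADQWKFQTFMCK",
      "VVNSMYKMNFYSCVLLIMCISVDRYIAIAQAMRAHTWREKRLLYSKMVCFTIWVLAAALC",
      "IPEILYSQIKEESGIAICTMVYPSDESTKLKSAVLTLKVILGFFLPFVVMACCYTIIIHT",
      "LIQAKKSSKHKALKVTITVLTVFVLSQFPYNCILLVQTIDAYAMFISNCAVSTNIDICFQ",
      "VTQTIAFFHSCLNPVLYVFVGERFRRDLVKTLKNLGCISQAQWVSFTRREGSLKLSSMLL",
      "ETTSGALSL"),
    "CCL25" = paste0(
      "PGVFEDCCLAYHYPIGWAVLRRAWTYRIQEVSGSCNLPAAIFYLPKRHRKVCGNPKSREV",
      "QRAMKLLDARNKVFAKLHHNTQTFQAGPHAVKKLSSGNSKLSSSKFSNPISSSKRNVSLL",
      "ISANSGL"),
    "1P6-CCL25" = paste0(
      "YQASEDCCLAYHYPIGWAVLRRAWTYRIQEVSGSCNLPAAIFYLPKRHRKVCGNPKSREV",
      "QRAMKLLDARNKVFAKLHHNTQTFQAGPHAVKKLSSGNSKLSSSKFSNPISSSKRNVSLL",
      "ISANSGL"))
  sequence_record(which, seqs[[which]])
}

#' Locate a motif within a sequence
#'
#' Returns the 1-based mature-numbering start position of the first occurrence
#' of `motif` in `seq`. Used e.g. to locate the CCL25 30s loop
#' (`"QEVSGSCNLPA"`, positions 29-39).
#'
#' @param seq a [sequence_record].
#' @param motif non-empty amino-acid string.
#' @return Integer start position (mature numbering).
#' @export
find_subsequence <- function(seq, motif) {
  stopifnot(inherits(seq, "sequence_record"))
  motif <- toupper(gsub("[[:space:]]", "", motif))
  if (nchar(motif) == 0L) stop("motif is empty")
  hits <- gregexpr(motif, seq$residues, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("motif '", motif, "' not found in sequence '", seq$name, "'")
  if (length(hits) > 1L)
    warning("motif '", motif, "' occurs ", length(hits),
            " times; returning first occurrence")
  as.integer(hits[1]) + seq$numbering_offset - 1L
}

#' Length of the N-terminal region before the first cysteine
#'
#' Chemokine N-terminal regions are conventionally delimited by the first
#' conserved cysteine; for CCL25 this region is six residues long.
#'
#' @param seq a [sequence_record] containing at least one `C`.
#' @return Integer count of residues strictly before the first cysteine.
#' @export
n_terminal_region <- function(seq) {
  stopifnot(inherits(seq, "sequence_record"))
  pos <- regexpr("C", seq$residues, fixed = TRUE)
  if (pos == -1L) stop("sequence '", seq$name, "' has no cysteine")
  as.integer(pos) - 1L
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param numbering_offset offset applied to all records (default 1).
#' @return A list of [sequence_record]s.
#' @export
read_fasta_sequences <- function(path, numbering_offset = 1L) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  lapply(names(recs),
         function(nm) sequence_record(nm, as.character(recs[[nm]]),
                                      numbering_offset))
}
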