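#' E-box / IUPAC motif query
#'
#' @param pattern IUPAC nucleotide pattern; the default `"CANNTG"` is the
#'   canonical E-box bound by basic helix-loop-helix factors.
#' @param both_strands Scan the reverse strand too (default `TRUE`)?
#' @return A `motif_query` list.
#' @export
motif_query <- function(pattern = "CANNTG", both_strands = TRUE) {
  pattern <- toupper(as.character(pattern))
  if (length(pattern) != 1L || nchar(pattern) == 0) {
    abort("pattern must be a single non-empty string")
  }
  chars <- strsplit(pattern, "")[[1]]
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  bad <- which(!chars %in% iupac)
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC code '%s' at offset %d", chars[bad[1]],
                  bad[1] - 1L))
  }
  structure(list(pattern = pattern, both_strands = isTRUE(both_strands)),
            class = "motif_query")
}

#' Scan a sequence for an IUPAC motif
#'
#' Reports every position where the pattern matches the forward strand and,
#' when `both_strands`, every reverse-strand match reported at its forward
#' coordinate. Matching uses IUPAC set intersection on both pattern and
#' subject (so an `N` in the sequence is compatible with any pattern
#' position). Hits are 0-based and sorted by position, `+` before `-` at the
#' same position; overlapping hits are all reported.
#'
#' @param seq A single nucleotide string over `A/C/G/T/N` (case-insensitive).
#' @param query A [motif_query()], or a pattern string.
#' @return Tibble with columns `position` (0-based start), `strand`,
#'   `matched` (the pattern-length sequence as read on the reported strand).
#' @examples
#' scan_motif("ACAGCTGT", "CANNTG")
#' @export
scan_motif <- function(seq, query = motif_query()) {
  if (is.character(query)) query <- motif_query(query)
  stopifnot(inherits(query, "motif_query"))
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1L)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    abort(sprintf("invalid nucleotide '%s' at offset %d", chars[bad[1]],
                  bad[1] - 1L))
  }
  m <- nchar(query$pattern)
  subject <- Biostrings::DNAString(seq)
  hits <- tibble(position = integer(0), strand = character(0),
                 matched = character(0))
  if (nchar(seq) >= m) {
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(query$pattern),
                                    subject, fixed = FALSE)
    if (length(fwd) > 0) {
      hits <- bind_rows(hits, tibble(
        position = Biostrings::start(fwd) - 1L, strand = "+",
        matched = as.character(fwd)))
    }
    if (query$both_strands) {
      rcpat <- Biostrings::reverseComplement(Biostrings::DNAString(query$pattern))
      rev <- Biostrings::matchPattern(rcpat, subject, fixed = FALSE)
      if (length(rev) > 0) {
        matched <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(rev)))
        hits <- bind_rows(hits, tibble(
          position = Biostrings::start(rev) - 1L, strand = "-",
          matched = unname(matched)))
      }
    }
  }
  arrange(hits, .data$position, .data$strand)
}

#' Motif presence per species
#'
#' Scans one enhancer sequence per species and calls the motif present when
#' at least one hit is found. Rows follow the declared species order of the
#' input.
#'
#' @param seqs Named character vector (or `Biostrings::DNAStringSet`) of one
#'   sequence per species.
#' @param query A [motif_query()] or pattern string.
#' @return Tibble with columns `species`, `present`, `n_hits`, and a
#'   `positions` list-column of 0-based hit starts.
#' @export
species_motif_presence <- function(seqs, query = motif_query()) {
  if (methods::is(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (length(seqs) == 0) abort("at least one species is required")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("sequences must be named by species")
  }
  empty <- which(is.na(seqs) | !nzchar(seqs))
  if (length(empty) > 0) {
    abort(sprintf("empty sequence for species %s", names(seqs)[empty[1]]))
  }
  res <- purrr::imap(seqs, function(s, sp) {
    h <- scan_motif(s, query)
    tibble(species = sp, present = nrow(h) > 0, n_hits = nrow(h),
           positions = list(h$position))
  })
  bind_rows(res)
}

#' Read enhancer sequences from FASTA
#'
#' @param path Path to an (uncompressed) FASTA file; record names are taken
#'   as species labels.
#' @return Named character vector of sequences.
#' @export
read_enhancer_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
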