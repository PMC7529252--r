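# Separase cleavage-consensus and docking-motif scanning.
#
# The cleavage consensus is [E/D]XXR (X = any residue); separase cuts after
# the arginine. The docking motif is [L/V/I/M]PE. An X in a query sequence
# matches only the "any residue" positions of a motif, never the anchors.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

motif_defs <- list(
  cleavage_ExxR = list(
    len = 4L,
    # lookahead => all overlapping matches are reported
    regex = "(?=[ED]..R)"
  ),
  docking_LVIMPE = list(
    len = 3L,
    regex = "(?=[LVIM]PE)"
  )
)

#' Scan protein sequences for separase-related motifs
#'
#' Reports all (overlapping) matches of the separase cleavage consensus
#' `[E/D]XXR` (`motif = "cleavage_ExxR"`) or of the separase docking motif
#' `[L/V/I/M]PE` (`motif = "docking_LVIMPE"`), left to right, in 1-based
#' residue coordinates. `X` in a sequence matches only the unconstrained
#' motif positions, never the anchor residues.
#'
#' @param sequences Named character vector of unaligned amino-acid
#'   sequences, a single unnamed string, or a [Biostrings::AAStringSet].
#' @param motif Which motif to scan for.
#' @return Data.frame with one row per hit: `id`, `motif`, `start`,
#'   `matched_text`, and `cleavage_position` (position after the arginine of
#'   a cleavage hit — the scissile bond; `NA` for docking hits).
#' @section Errors: residues outside the 20-letter alphabet plus `X` are a
#'   validation error; an empty sequence simply yields no hits.
#' @examples
#' scan_motif(c(uno_like = "MAEQGRT"))             # cleavage hit at 3
#' scan_motif(c(s = "KLPEK"), motif = "docking_LVIMPE")
#' @export
scan_motif <- function(sequences, motif = c("cleavage_ExxR", "docking_LVIMPE")) {
  motif <- match.arg(motif)
  sequences <- as_aa_character(sequences, allow_gaps = FALSE)
  def <- motif_defs[[motif]]
  hits <- lapply(seq_along(sequences), function(i) {
    s <- sequences[i]
    if (nchar(s) == 0L) return(NULL)
    m <- gregexpr(def$regex, s, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    starts <- as.integer(m)
    starts <- starts[starts + def$len - 1L <= nchar(s)]
    if (length(starts) == 0L) return(NULL)
    data.frame(
      id = names(sequences)[i],
      motif = motif,
      start = starts,
      matched_text = substring(s, starts, starts + def$len - 1L),
      cleavage_position = if (motif == "cleavage_ExxR") starts + 4L
                          else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(id = character(0), motif = character(0),
                      start = integer(0), matched_text = character(0),
                      cleavage_position = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Apply a non-cleavable mutation to a cleavage-consensus hit
#'
#' Replaces both anchor residues of a `cleavage_ExxR` hit — the acidic
#' residue at `start` and the arginine at `start + 3` — by alanine, the
#' in-silico equivalent of the E-to-A/R-to-A double mutation used to render
#' a substrate non-cleavable (E130A/R133A in UNO). Re-scanning the mutated
#' sequence yields no cleavage hit at that position; applying the mutation
#' to an already-mutated (`A..A`) site is a no-op, so the operation is
#' idempotent.
#'
#' @param sequence A single amino-acid string (or length-1 named vector).
#' @param start 1-based start of a cleavage hit in `sequence`, e.g. from
#'   [scan_motif()].
#' @return The mutated sequence (same names).
#' @examples
#' apply_site_mutation("MAEQGRT", 3)  # "MAAQGAT"
#' @export
apply_site_mutation <- function(sequence, start) {
  seqs <- as_aa_character(sequence, allow_gaps = FALSE)
  if (length(seqs) != 1L) {
    stop_meioconj("`sequence` must be a single sequence", "meioconj_invalid_input")
  }
  s <- seqs[[1]]
  if (!is_count(start) || start + 3L > nchar(s)) {
    stop_meioconj("`start` is out of range for a 4-residue cleavage motif",
                  "meioconj_invalid_input")
  }
  window <- substring(s, start, start + 3L)
  if (grepl("^A..A$", window)) {
    return(stats::setNames(s, names(seqs)))  # already mutated: idempotent
  }
  if (!grepl("^[ED]..R$", window)) {
    stop_meioconj(
      sprintf("residues %d-%d ('%s') do not match the [E/D]XXR cleavage consensus",
              start, start + 3L, window),
      "meioconj_invalid_input"
    )
  }
  substr(s, start, start) <- "A"
  substr(s, start + 3L, start + 3L) <- "A"
  names(s) <- names(seqs)
  s
}

#' Per-column conservation of a motif across an alignment
#'
#' Maps a motif hit found in the ungapped reference sequence through the
#' reference's gaps to alignment columns, then reports for each motif column
#' the fraction of non-gap rows whose residue is identical to the
#' reference's.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (gaps `-`), or an [Biostrings::AAStringSet] of aligned sequences.
#' @param reference_id Name of the reference row (the sequence in which the
#'   hit was found).
#' @param start 1-based ungapped position of the hit in the reference.
#' @param motif_len Motif length (4 for cleavage, 3 for docking).
#' @return Numeric vector of length `motif_len`: identity fraction per motif
#'   column (the reference row counts among the non-gap rows).
#' @examples
#' aln <- c(a = "MAEQGRT", b = "MAEQGRT", c = "MAEAGRT", d = "M-EQGRT")
#' column_conservation(aln, "a", start = 3, motif_len = 4)
#' @export
column_conservation <- function(alignment, reference_id, start, motif_len = 4L) {
  alignment <- as_aa_character(alignment, allow_gaps = TRUE)
  if (!reference_id %in% names(alignment)) {
    stop_meioconj(sprintf("reference '%s' not present in the alignment", reference_id),
                  "meioconj_invalid_input")
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop_meioconj("alignment rows must have equal length", "meioconj_invalid_input")
  }
  ref <- strsplit(alignment[[reference_id]], "")[[1]]
  ungapped <- cumsum(ref != "-")
  cols <- vapply(seq.int(start, start + motif_len - 1L), function(p) {
    i <- which(ungapped == p & ref != "-")
    if (length(i) != 1L) {
      stop_meioconj("hit position maps outside the ungapped reference",
                    "meioconj_invalid_input")
    }
    i
  }, integer(1))
  rows <- do.call(rbind, strsplit(alignment, ""))
  vapply(seq_along(cols), function(k) {
    col <- rows[, cols[k]]
    nongap <- col != "-"
    sum(col[nongap] == ref[cols[k]]) / sum(nongap)
  }, numeric(1))
}

#' Read and write protein FASTA files
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] and
#' [Biostrings::writeXStringSet()] returning/accepting named character
#' vectors, the representation the scanning functions use. Aligned FASTA
#' (rows of equal length with `-` gaps) is read the same way.
#'
#' @param path File path.
#' @return `read_protein_fasta()`: named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_protein_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_protein_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  ss <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

as_aa_character <- function(x, allow_gaps = FALSE) {
  if (inherits(x, "AAStringSet")) x <- as.character(x)
  if (!is.character(x)) {
    stop_meioconj("sequences must be a character vector or AAStringSet",
                  "meioconj_invalid_input")
  }
  if (is.null(names(x))) {
    names(x) <- if (length(x) == 1L) "seq1" else paste0("seq", seq_along(x))
  }
  alphabet <- c(AA_ALPHABET, if (allow_gaps) "-")
  bad <- !vapply(strsplit(toupper(x), ""), function(ch) all(ch %in% alphabet),
                 logical(1))
  if (any(bad)) {
    stop_meioconj(
      sprintf("invalid residues in sequence(s): %s",
              paste(names(x)[bad], collapse = ", ")),
      "meioconj_invalid_input"
    )
  }
  toupper_named <- toupper(x)
  names(toupper_named) <- names(x)
  toupper_named
}
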