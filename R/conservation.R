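#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal files; rows must be equal length and
#' use the 20 amino-acid letters plus `-` for gaps.
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return A `multiple_alignment`: list with `ids` and `seqs` (uppercase
#'   character vector, equal lengths).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  new_alignment(names(Biostrings::unmasked(aln)),
                as.character(Biostrings::unmasked(aln)))
}

.aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

#' @rdname read_alignment
#' @param ids Sequence identifiers.
#' @param seqs Aligned sequences (strings of equal length).
#' @export
new_alignment <- function(ids, seqs) {
  seqs <- toupper(seqs)
  if (length(ids) != length(seqs)) stop_config("ids/seqs lengths differ")
  if (length(seqs) < 2) stop_config("an alignment needs >= 2 sequences")
  len <- nchar(seqs)
  if (length(unique(len)) != 1)
    stop_config("ragged alignment: sequence '%s' has length %d, expected %d",
                ids[which(len != len[1])[1]], len[len != len[1]][1], len[1])
  bad <- !grepl(sprintf("^[%s-]*$", paste(setdiff(.aa_alphabet, "-"),
                                          collapse = "")), seqs)
  if (any(bad))
    stop_config("sequence '%s' contains non amino-acid symbols", ids[bad][1])
  structure(list(ids = ids, seqs = seqs), class = "multiple_alignment")
}

#' Alignment as a character matrix (sequences x columns)
#' @param aln A `multiple_alignment`.
#' @export
alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Entropy-based conservation score of an alignment column
#'
#' AL2CO-style unweighted entropy measure: `1 - H / log(21)` with Shannon
#' entropy `H` (natural log) over the 20 amino acids plus gap as a 21st
#' symbol. 1 means an invariant, gap-free column; 0 means all 21 symbols
#' equally frequent. Gaps therefore penalize a column rather than being
#' ignored.
#'
#' @param column Character vector of one-letter symbols (one per sequence).
#' @return Score in `[0, 1]`.
#' @export
conservation_score <- function(column) {
  if (!length(column)) stop_config("empty column")
  p <- table(factor(column, levels = .aa_alphabet)) / length(column)
  p <- p[p > 0]
  H <- -sum(p * log(p))
  1 - H / log(21)
}

#' Column-wise conservation of a whole alignment
#' @param aln A `multiple_alignment`.
#' @return Numeric vector of per-column scores.
#' @export
conservation_profile <- function(aln) {
  m <- alignment_matrix(aln)
  apply(m, 2, conservation_score)
}

#' Map a residue number of one sequence to its alignment column
#'
#' @param aln A `multiple_alignment`.
#' @param seq_id Sequence identifier.
#' @param residue_number 1-based position in the ungapped sequence.
#' @return 1-based alignment column index.
#' @export
map_residue <- function(aln, seq_id, residue_number) {
  i <- match(seq_id, aln$ids)
  if (is.na(i)) stop_config("sequence '%s' not in alignment", seq_id)
  chars <- strsplit(aln$seqs[i], "")[[1]]
  ungapped <- cumsum(chars != "-")
  col <- match(residue_number, ungapped)
  if (is.na(col) || residue_number < 1)
    stop_config("residue %d out of range for '%s' (ungapped length %d)",
                residue_number, seq_id, max(ungapped))
  col
}

#' Conservation report for contact residues
#'
#' For each contact residue of the reference sequence: its alignment
#' column, the symbol shown by every sequence, whether the column is
#' identical in all sequences, its conservation score, and the mean score
#' over a flanking window (+/- `flank` columns, i.e. patches of about
#' 15 residues by default).
#'
#' @param aln A `multiple_alignment`.
#' @param reference_id Id of the reference sequence (the pump whose
#'   numbering the contact residues use).
#' @param contact_residues Integer residue numbers in the reference
#'   sequence.
#' @param ref_offset Number to subtract from `contact_residues` before
#'   mapping, for alignments that cover only a window of the reference
#'   (residue `n` maps to ungapped position `n - ref_offset`).
#' @param flank Flanking half-window in columns (default 7).
#' @return Data frame with one row per contact residue.
#' @export
site_report <- function(aln, reference_id, contact_residues,
                        ref_offset = 0, flank = 7) {
  m <- alignment_matrix(aln)
  scores <- apply(m, 2, conservation_score)
  rows <- lapply(contact_residues, function(res) {
    col <- map_residue(aln, reference_id, res - ref_offset)
    symbols <- m[, col]
    non_gap <- symbols[symbols != "-"]
    win <- max(1, col - flank):min(ncol(m), col + flank)
    data.frame(residue = res,
               column = col,
               ref_symbol = symbols[match(reference_id, aln$ids)],
               symbols = paste(symbols, collapse = ""),
               identical_in_all = length(unique(symbols)) == 1 &&
                 !any(symbols == "-"),
               score = scores[col],
               flank_score = mean(scores[win]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default contact residues of the reference proton pump
#'
#' Residue numbers (reference pump numbering) of the lipid contact sites
#' identified in the membrane analysis: sites A1/A2 (K238, K705, L706,
#' K707, R842), B (K57, K60), C (Q266, R267, R268, Y270, R271) and D/E
#' (K692, D693, R694, K696).
#'
#' @return Named integer vector.
#' @export
default_contact_residues <- function() {
  c(K57 = 57L, K60 = 60L, K238 = 238L, Q266 = 266L, R267 = 267L,
    R268 = 268L, Y270 = 270L, R271 = 271L, K692 = 692L, D693 = 693L,
    R694 = 694L, K696 = 696L, K705 = 705L, L706 = 706L, K707 = 707L,
    R842 = 842L)
}

#' Write an alignment as aligned FASTA
#' @param aln A `multiple_alignment`.
#' @param path Output path.
#' @export
write_alignment <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$ids), aln$seqs)), path)
  invisible(path)
}
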