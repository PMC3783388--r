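# Six-frame conceptual translation with invertible coordinate maps.
#
# Every peptide position maps back to a unique 3-nt genomic interval on the
# forward coordinate system, so domain hits found in translations become
# exact genomic features. Stops are retained as '*' (decayed elements carry
# in-frame stops); codons containing N translate to 'X'.

#' Translate a genome record in all six frames
#'
#' Standard genetic code (translation table 1). Frames +1..+3 read the
#' forward strand with offsets 0..2; frames -1..-3 read the reverse
#' complement with offsets 0..2. Stops are emitted as `*` and retained;
#' any codon containing N becomes `X`.
#'
#' @param record a `genome_record`.
#' @return a list of six `frame_translation` objects (frames +1,+2,+3,-1,-2,-3),
#'   each with fields `seq_id`, `frame`, `peptide`, `offset` and `seq_length`.
#'   Records shorter than 3 nt yield empty peptides with a warning.
#' @export
translate_six_frames <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  if (record$length < 3L)
    warning("record '", record$id, "' is shorter than 3 nt; ",
            "translations are empty")
  fwd <- record$residues
  rev <- revcomp(fwd)
  frames <- list()
  for (f in 1:3) {
    frames[[length(frames) + 1L]] <-
      new_frame_translation(record$id, f, translate_frame(fwd, f - 1L),
                            f - 1L, record$length)
  }
  for (f in 1:3) {
    frames[[length(frames) + 1L]] <-
      new_frame_translation(record$id, -f, translate_frame(rev, f - 1L),
                            f - 1L, record$length)
  }
  names(frames) <- vapply(frames, function(t) frame_label(t$frame), "")
  frames
}

frame_label <- function(frame) sprintf("%+d", frame)

new_frame_translation <- function(seq_id, frame, peptide, offset, seq_length) {
  structure(list(seq_id = seq_id, frame = as.integer(frame),
                 peptide = peptide, offset = as.integer(offset),
                 seq_length = as.integer(seq_length)),
            class = "frame_translation")
}

# translate one reading frame of a (possibly reverse-complemented) sequence
translate_frame <- function(seq, offset) {
  L <- nchar(seq)
  n_codon <- (L - offset) %/% 3L
  if (n_codon <= 0L) return("")
  starts <- offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Map a peptide window back to its genomic interval
#'
#' @param t a `frame_translation`.
#' @param pep_start,pep_end 0-based half-open peptide coordinates.
#' @return a `yr_interval` of length `3 * (pep_end - pep_start)` on the
#'   forward coordinate system, with strand matching the frame sign.
#' @export
map_to_genome <- function(t, pep_start, pep_end) {
  stopifnot(inherits(t, "frame_translation"))
  np <- nchar(t$peptide)
  pep_start <- as.integer(pep_start); pep_end <- as.integer(pep_end)
  if (pep_start < 0L || pep_end <= pep_start || pep_end > np)
    stop("peptide coordinates [", pep_start, ",", pep_end,
         ") out of range for peptide of length ", np)
  if (t$frame > 0L) {
    g_start <- t$offset + 3L * pep_start
    g_end <- t$offset + 3L * pep_end
    yr_interval(t$seq_id, g_start, g_end, "+")
  } else {
    # positions on the reverse complement map back through L - r
    g_end <- t$seq_length - (t$offset + 3L * pep_start)
    g_start <- t$seq_length - (t$offset + 3L * pep_end)
    yr_interval(t$seq_id, g_start, g_end, "-")
  }
}

# inverse map: genomic interval (codon-aligned for this frame) -> peptide window
map_to_peptide <- function(t, g_start, g_end) {
  if (t$frame > 0L) {
    p1 <- (g_start - t$offset) / 3
    p2 <- (g_end - t$offset) / 3
  } else {
    p1 <- (t$seq_length - g_end - t$offset) / 3
    p2 <- (t$seq_length - g_start - t$offset) / 3
  }
  if (p1 != floor(p1) || p2 != floor(p2))
    stop("interval is not codon-aligned in frame ", frame_label(t$frame))
  c(as.integer(p1), as.integer(p2))
}
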