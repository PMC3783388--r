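# Sequence and annotation I/O plus the canonical coordinate model.
#
# All coordinates are held 0-based, half-open internally; every file written
# for the outside world (GFF3, TSV reports) is 1-based, inclusive.

#' Construct a genome record
#'
#' A named nucleotide sequence with normalised residues. Lowercase
#' (soft-masked) input is uppercased and the soft-masked fraction recorded;
#' IUPAC ambiguity codes other than A/C/G/T/N are collapsed to N and counted.
#'
#' @param id sequence identifier.
#' @param residues nucleotide string.
#' @return an object of class `genome_record` with fields `id`, `residues`,
#'   `length`, `softmask_frac` and `n_ambiguous`.
#' @export
genome_record <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty character scalar")
  if (!is.character(residues) || length(residues) != 1L)
    stop("'residues' must be a character scalar")
  cc <- chars(residues)
  soft <- mean(cc %in% letters)
  if (is.nan(soft)) soft <- 0
  up <- toupper(residues)
  cc <- chars(up)
  iupac <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "U")
  bad <- !(cc %in% iupac)
  if (any(bad))
    stop("illegal characters in sequence '", id, "': ",
         paste(unique(cc[bad]), collapse = ", "))
  amb <- !(cc %in% c("A", "C", "G", "T", "N"))
  if (any(amb)) cc[amb] <- "N"
  structure(
    list(id = id, residues = paste(cc, collapse = ""), length = length(cc),
         softmask_frac = soft, n_ambiguous = sum(amb)),
    class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d nt (soft-masked %.1f%%, %d ambiguous)\n",
              x$id, x$length, 100 * x$softmask_frac, x$n_ambiguous))
  invisible(x)
}

#' Construct a genomic interval
#'
#' 0-based, half-open, stranded. File output converts to 1-based inclusive.
#'
#' @param seq_id reference sequence identifier.
#' @param start,end integer bounds with `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `yr_interval`.
#' @export
yr_interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("invalid interval: need 0 <= start < end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "yr_interval")
}

interval_len <- function(iv) iv$end - iv$start

#' Read a nucleotide FASTA file
#'
#' Headers are split at the first whitespace for the identifier; duplicate
#' identifiers are an error, as are empty records. Residues are normalised
#' as in [genome_record()].
#'
#' @param path path to a FASTA file (multi-record, wrapped or single-line).
#' @return a list of `genome_record` objects in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(set) == 0L))
    stop("empty sequence record in ", path)
  recs <- lapply(seq_along(set), function(i)
    genome_record(ids[i], as.character(set[[i]])))
  names(recs) <- ids
  recs
}

#' Write genome records as FASTA
#'
#' @param records a list of `genome_record` objects.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "residues"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(NULL)
}

#' Read an aligned (gapped) amino-acid FASTA file
#'
#' @param path path to aligned FASTA; all rows must have equal length.
#' @return a named character vector of gapped rows.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  w <- Biostrings::width(set)
  if (length(unique(w)) > 1L)
    stop("ragged alignment rows in ", path, ": widths ",
         paste(unique(w), collapse = ", "))
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write an alignment as aligned FASTA
#' @param rows named character vector of equal-length gapped rows.
#' @param path output path.
#' @export
write_aligned_fasta <- function(rows, path) {
  stopifnot(length(unique(nchar(rows))) <= 1L)
  set <- Biostrings::AAStringSet(rows)
  Biostrings::writeXStringSet(set, path)
  invisible(NULL)
}

#' Write annotated elements as GFF3
#'
#' One `mobile_genetic_element` feature per element, with
#' `polypeptide_domain` children for domain hits and `repeat_region` children
#' for terminal-repeat copies. Internal 0-based half-open coordinates are
#' converted to the 1-based inclusive GFF3 convention.
#'
#' @param elements a list of `element_model` objects (see [classify_element()]).
#' @param path output path.
#' @param seq_lengths optional named integer vector for `##sequence-region`
#'   directives.
#' @export
write_gff3 <- function(elements, path, seq_lengths = NULL) {
  feats <- element_features(elements)
  if (nrow(feats) == 0L) {
    con <- file(path, "w")
    writeLines("##gff-version 3", con)
    close(con)
    return(invisible(NULL))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = feats$seq_id,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand)
  S4Vectors::mcols(gr)$source <- "yrscan"
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$ID
  S4Vectors::mcols(gr)$Parent <- feats$Parent
  for (col in setdiff(colnames(feats),
                      c("seq_id", "start", "end", "strand", "type", "ID",
                        "Parent")))
    S4Vectors::mcols(gr)[[col]] <- feats[[col]]
  if (!is.null(seq_lengths)) {
    GenomeInfoDb::seqlengths(gr) <-
      seq_lengths[GenomeInfoDb::seqlevels(gr)]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(NULL)
}

# flatten element models into a feature table for GFF3 / TSV output
element_features <- function(elements) {
  rows <- list()
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    eid <- el$id %||% sprintf("YR%04d", i)
    iv <- el$outer_interval
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = iv$seq_id, start = iv$start, end = iv$end, strand = iv$strand,
      type = "mobile_genetic_element", ID = eid, Parent = NA_character_,
      superfamily = el$superfamily, completeness = el$completeness,
      clade = el$clade, family_id = el$family_id %||% NA_character_,
      domain_class = NA_character_, profile = NA_character_,
      dscore = NA_real_, identity = NA_real_, repeat_role = NA_character_,
      stringsAsFactors = FALSE)
    hits <- el$core$hits
    for (k in seq_along(hits)) {
      h <- hits[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = h$interval$seq_id, start = h$interval$start,
        end = h$interval$end, strand = h$interval$strand,
        type = "polypeptide_domain", ID = sprintf("%s.d%d", eid, k),
        Parent = eid, superfamily = NA_character_,
        completeness = NA_character_, clade = NA_character_,
        family_id = NA_character_, domain_class = h$domain_class,
        profile = h$profile_name, dscore = h$score, identity = NA_real_,
        repeat_role = NA_character_, stringsAsFactors = FALSE)
    }
    rp <- el$repeats
    if (!is.null(rp) && rp$kind != "none") {
      roles <- if (rp$kind == "ITR") c("ITR_left", "ITR_right")
               else c("A1", "B1", "A2", "B2")
      ids <- c(rp$copies, if (!is.null(rp$icr)) list(rp$icr))
      roles <- c(roles, if (!is.null(rp$icr)) "ICR")
      idents <- if (rp$kind == "ITR") rep(rp$identity_A, 2)
                else c(rp$identity_A, rp$identity_B, rp$identity_A,
                       rp$identity_B)
      idents <- c(idents, if (!is.null(rp$icr)) NA_real_)
      for (k in seq_along(ids)) {
        cp <- ids[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = cp$interval$seq_id, start = cp$interval$start,
          end = cp$interval$end, strand = cp$interval$strand,
          type = "repeat_region", ID = sprintf("%s.r%d", eid, k),
          Parent = eid, superfamily = NA_character_,
          completeness = NA_character_, clade = NA_character_,
          family_id = NA_character_, domain_class = NA_character_,
          profile = NA_character_, dscore = NA_real_,
          identity = idents[k], repeat_role = roles[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      type = character(), ID = character(),
                      Parent = character()))
  do.call(rbind, rows)
}

#' Write a tree in Newick format
#'
#' Branch lengths are rounded to 6 decimal places before serialisation.
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, 6)
  ape::write.tree(tree, file = path)
  invisible(NULL)
}

#' Read a Newick tree
#' @param path path to a Newick file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path) ape::read.tree(path)
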