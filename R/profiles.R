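# Domain profiles: position score matrices for the four diagnostic domains
# (RT, RH, YR, MT), built from seed alignments, read from HMMER3 ASCII files,
# and serialised in a plain-text PSSM format.
#
# Scores are natural-log odds against a background distribution (uniform 1/20
# by default) with a +1 pseudocount per residue:
#   s_a = log( ((c_a + 1) / (N + 20)) / bg_a )
# so a column observed N times in agreement scores positively for the
# consensus residue and (mildly) negatively for everything else.

STOP_PENALTY <- -8  # fixed score for '*' aligned to any profile column

#' Construct a domain profile
#'
#' @param name profile name.
#' @param domain_class one of `"RT"`, `"RH"`, `"YR"`, `"MT"`.
#' @param scores a 20-row numeric matrix (rows in `ACDEFGHIKLMNPQRSTVWY`
#'   order), one column per profile position.
#' @param affinity superfamily affinity tag: `"DIRS-specific"`,
#'   `"Ngaro-like"` or `"generic"`.
#' @param gap_open,gap_extend negative affine gap penalties.
#' @param score_threshold minimal reported alignment score.
#' @return an object of class `domain_profile`.
#' @export
domain_profile <- function(name, domain_class, scores,
                           affinity = "generic",
                           gap_open = -10, gap_extend = -2,
                           score_threshold = NULL) {
  stopifnot(is.matrix(scores), nrow(scores) == 20L, ncol(scores) >= 1L,
            all(is.finite(scores)))
  if (!domain_class %in% c("RT", "RH", "YR", "MT"))
    stop("unknown domain_class: ", domain_class)
  if (!affinity %in% c("DIRS-specific", "Ngaro-like", "generic"))
    stop("unknown affinity: ", affinity)
  if (gap_open >= 0 || gap_extend >= 0)
    stop("gap penalties must be negative")
  rownames(scores) <- AA_ALPHABET
  max_self <- sum(apply(scores, 2, max))
  if (is.null(score_threshold)) score_threshold <- 0.3 * max_self
  structure(list(name = name, domain_class = domain_class,
                 affinity = affinity, scores = scores,
                 gap_open = gap_open, gap_extend = gap_extend,
                 score_threshold = score_threshold,
                 max_self_score = max_self),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf(
    "<domain_profile> %s [%s, %s]: %d columns, threshold %.1f (max self %.1f)\n",
    x$name, x$domain_class, x$affinity, ncol(x$scores), x$score_threshold,
    x$max_self_score))
  invisible(x)
}

#' Consensus peptide of a profile (best-scoring residue per column)
#' @param profile a `domain_profile`.
#' @return a character scalar.
#' @export
profile_consensus <- function(profile) {
  paste(AA_ALPHABET[apply(profile$scores, 2, which.max)], collapse = "")
}

#' Build a profile from member peptides
#'
#' Members may be pre-aligned (equal-length, gapped with `-`) or unaligned,
#' in which case the progressive aligner is applied first. Columns with gap
#' fraction above `max_gap_fraction` are dropped; remaining counts are turned
#' into log-odds with a +1 pseudocount against the background.
#'
#' @param members character vector of at least 5 member peptides.
#' @param domain_class one of `"RT"`, `"RH"`, `"YR"`, `"MT"`.
#' @param name profile name.
#' @param affinity superfamily affinity tag.
#' @param background per-residue background frequencies (default uniform 1/20).
#' @param max_gap_fraction columns gappier than this are dropped.
#' @param ... passed to [domain_profile()].
#' @return a `domain_profile`.
#' @export
build_profile_from_members <- function(members, domain_class,
                                       name = "custom",
                                       affinity = "generic",
                                       background = rep(1 / 20, 20),
                                       max_gap_fraction = 0.5, ...) {
  if (length(members) < 5L)
    stop("at least 5 member sequences are required (got ", length(members), ")")
  widths <- nchar(members)
  aligned <- if (length(unique(widths)) == 1L) members
             else progressive_align(members)$rows
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  mat <- mat[, gap_frac <= max_gap_fraction, drop = FALSE]
  if (ncol(mat) == 0L) stop("all columns dropped by the gap-fraction rule")
  n <- nrow(mat)
  counts <- apply(mat, 2, function(col) {
    tabulate(match(col, AA_ALPHABET), nbins = 20L)
  })
  scores <- log(((counts + 1) / (n + 20)) / background)
  domain_profile(name, domain_class, scores, affinity = affinity, ...)
}

#' Write a profile in the packaged PSSM text format
#'
#' @param profile a `domain_profile`.
#' @param path output path.
#' @export
write_pssm <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# yrscan PSSM v1",
               paste("NAME", profile$name),
               paste("CLASS", profile$domain_class),
               paste("AFFINITY", profile$affinity),
               sprintf("GAP_OPEN %.6f", profile$gap_open),
               sprintf("GAP_EXTEND %.6f", profile$gap_extend),
               sprintf("THRESHOLD %.6f", profile$score_threshold),
               paste("NCOL", ncol(profile$scores)),
               paste("ALPHA", paste(AA_ALPHABET, collapse = ""))), con)
  for (j in seq_len(ncol(profile$scores)))
    writeLines(paste(j, paste(sprintf("%.6f", profile$scores[, j]),
                              collapse = " ")), con)
  invisible(NULL)
}

#' Read a profile from the packaged PSSM text format
#' @param path path to a PSSM file written by [write_pssm()].
#' @return a `domain_profile`.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  kv <- list()
  body <- character()
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] %in% c("NAME", "CLASS", "AFFINITY", "GAP_OPEN", "GAP_EXTEND",
                      "THRESHOLD", "NCOL", "ALPHA")) {
      kv[[tok[1]]] <- tok[2]
    } else body <- c(body, ln)
  }
  ncol <- as.integer(kv$NCOL)
  scores <- matrix(NA_real_, 20, ncol)
  for (ln in body) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    j <- as.integer(tok[1])
    scores[, j] <- as.numeric(tok[-1])
  }
  domain_profile(kv$NAME, kv$CLASS, scores, affinity = kv$AFFINITY,
                 gap_open = as.numeric(kv$GAP_OPEN),
                 gap_extend = as.numeric(kv$GAP_EXTEND),
                 score_threshold = as.numeric(kv$THRESHOLD))
}

#' Read a HMMER3 ASCII profile
#'
#' Match-state emission log-probabilities are converted to log-odds against a
#' uniform background; insert states are not modelled (gaps use the
#' profile-level affine penalties). The profile name is mapped to a domain
#' class and affinity through the packaged Pfam/CDD-style name map.
#'
#' @param path path to a `HMMER3/f` ASCII profile (amino alphabet).
#' @param gap_open,gap_extend affine gap penalties for the returned profile.
#' @return a `domain_profile`.
#' @export
read_hmmer3_profile <- function(path, gap_open = -10, gap_extend = -2) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^HMMER3/f", lines[1]))
    stop("unsupported profile leader (expected HMMER3/f): ",
         substr(lines[1] %||% "", 1, 30))
  name <- NA_character_; leng <- NA_integer_; alph <- NA_character_
  i <- 2L
  while (i <= length(lines) && !grepl("^HMM\\s", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (tok[1] == "NAME") name <- tok[2]
    if (tok[1] == "LENG") leng <- as.integer(tok[2])
    if (tok[1] == "ALPH") alph <- tolower(tok[2])
    i <- i + 1L
  }
  if (is.na(alph) || alph != "amino")
    stop("profile alphabet is '", alph, "'; only amino profiles are supported")
  # the HMM header line carries the emission alphabet order
  hmm_alpha <- strsplit(trimws(sub("^HMM\\s+", "", lines[i])), "\\s+")[[1]]
  scores <- matrix(NA_real_, 20, leng)
  j <- 0L
  i <- i + 2L  # skip the transition-name line
  while (i <= length(lines) && !grepl("^//", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (suppressWarnings(!is.na(as.integer(tok[1]))) &&
        as.integer(tok[1]) == j + 1L) {
      j <- j + 1L
      em <- suppressWarnings(as.numeric(tok[2:21]))
      # emissions are negative natural-log probabilities
      sc <- -em + log(20)
      scores[match(hmm_alpha, AA_ALPHABET), j] <- sc
      i <- i + 3L  # skip insert-emission and transition lines
    } else i <- i + 1L
  }
  if (j != leng) stop("profile truncated: expected ", leng,
                      " match states, found ", j)
  map <- PROFILE_CLASS_MAP[PROFILE_CLASS_MAP$name == name, ]
  dc <- if (nrow(map) == 1L) map$domain_class else "RT"
  af <- if (nrow(map) == 1L) map$affinity else "generic"
  if (nrow(map) == 0L)
    warning("profile name '", name, "' not in the packaged class map; ",
            "assuming RT/generic")
  domain_profile(name, dc, scores, affinity = af, gap_open = gap_open,
                 gap_extend = gap_extend)
}

# ---- packaged profile sets -------------------------------------------------

pkg_extdata <- function(...) {
  system.file("extdata", ..., package = "yrscan", mustWork = TRUE)
}

.profile_cache <- new.env(parent = emptyenv())

#' Load the packaged scanning profiles
#'
#' The package ships small seed alignments (synthetic stand-ins, internally
#' consistent with the synthetic-genome generator) for DIRS-specific,
#' Ngaro-like and generic variants of the four diagnostic domains. Profiles
#' are built from the seed alignments on first use and cached.
#'
#' @return a named list of `domain_profile` objects.
#' @export
packaged_profiles <- function() {
  if (!is.null(.profile_cache$profiles)) return(.profile_cache$profiles)
  map <- read.table(pkg_extdata("profiles", "profile_set.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  profs <- lapply(seq_len(nrow(map)), function(i) {
    rows <- read_aligned_fasta(pkg_extdata("profiles", map$seed_file[i]))
    build_profile_from_members(rows, map$domain_class[i], name = map$name[i],
                               affinity = map$affinity[i])
  })
  names(profs) <- map$name
  for (p in profs) stopifnot(ncol(p$scores) >= 10L)
  .profile_cache$profiles <- profs
  profs
}

#' Load the packaged clade/lineage motif profile sets
#'
#' Short motif profiles (one per domain) for the four Ngaro clades and the
#' two DIRS lineages, reconstructed as synthetic stand-ins for the
#' clade-diagnostic motifs. Used by the clade and lineage assignment rules.
#'
#' @return a named list (`Ngaro1`..`Ngaro4`, `DIRS_A`, `DIRS_B`), each a list
#'   of `domain_profile` objects keyed by domain class.
#' @export
packaged_clade_motifs <- function() {
  if (!is.null(.profile_cache$motifs)) return(.profile_cache$motifs)
  map <- read.table(pkg_extdata("motifs", "motif_set.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  groups <- unique(map$group)
  out <- lapply(groups, function(g) {
    sub <- map[map$group == g, ]
    ms <- lapply(seq_len(nrow(sub)), function(i) {
      rows <- read_aligned_fasta(pkg_extdata("motifs", sub$seed_file[i]))
      build_profile_from_members(
        rows, sub$domain_class[i],
        name = paste0(g, "_", sub$domain_class[i], "_motif"))
    })
    names(ms) <- sub$domain_class
    ms
  })
  names(out) <- groups
  .profile_cache$motifs <- out
  out
}

#' Load the packaged per-group domain consensus peptides
#'
#' Synthetic consensus peptides for each superfamily/clade and domain class;
#' the synthetic-genome generator plants these, and the packaged scanning
#' profiles are built from seed alignments around them.
#'
#' @return a data frame with columns `group`, `domain_class`, `peptide`.
#' @export
packaged_consensus <- function() {
  if (!is.null(.profile_cache$consensus)) return(.profile_cache$consensus)
  set <- Biostrings::readAAStringSet(pkg_extdata("profiles", "consensus.faa"))
  rows <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  parts <- strsplit(names(rows), "|", fixed = TRUE)
  out <- data.frame(group = vapply(parts, `[`, "", 1),
                    domain_class = vapply(parts, `[`, "", 2),
                    peptide = unname(rows), stringsAsFactors = FALSE)
  .profile_cache$consensus <- out
  out
}
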