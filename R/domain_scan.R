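# Locating RT / RH / YR / MT domain matches in six-frame translations and
# merging frame-split, strand-consistent hits into element cores.
#
# Scanning is local profile-sequence alignment with affine gaps (stops score
# a fixed penalty, X scores 0). Long translations are scanned in overlapping
# chunks so the dynamic programming stays in bounded memory; results are
# identical to a single-pass scan because no reportable hit can span more
# than the chunk overlap.

#' Scan one frame translation with a domain profile
#'
#' Reports all non-overlapping local optima with score at or above the
#' profile threshold, greedily from the best score with aligned-region
#' masking. Genomic coordinates come from [map_to_genome()].
#'
#' @param t a `frame_translation`.
#' @param profile a `domain_profile`.
#' @param threshold score threshold (defaults to the profile's).
#' @param chunk_size,chunk_overlap chunking of long translations (amino
#'   acids); the overlap must exceed any reportable alignment length.
#' @return a list of `domain_hit` objects, best score first. Each hit has
#'   fields `interval`, `frame`, `domain_class`, `profile_name`, `score`,
#'   `empirical_p` (NA until [empirical_pvalue()] is applied),
#'   `profile_coverage`, `pep_start`, `pep_end` and `peptide`.
#' @export
scan_profile <- function(t, profile, threshold = profile$score_threshold,
                         chunk_size = 5000L, chunk_overlap = 400L) {
  stopifnot(inherits(t, "frame_translation"), inherits(profile, "domain_profile"))
  np <- nchar(t$peptide)
  if (np == 0L) return(list())
  code <- pep_encode(t$peptide)
  starts <- if (np <= chunk_size) 0L else
    seq(0L, max(0L, np - chunk_overlap - 1L), by = chunk_size - chunk_overlap)
  raw <- list()
  for (s0 in starts) {
    s1 <- min(np, s0 + chunk_size)
    m <- cpp_pssm_scan(code[(s0 + 1L):s1], profile$scores, profile$gap_open,
                       profile$gap_extend, STOP_PENALTY, threshold)
    if (nrow(m) > 0L) {
      m[, "pep_start"] <- m[, "pep_start"] + s0
      m[, "pep_end"] <- m[, "pep_end"] + s0
      raw[[length(raw) + 1L]] <- m
    }
    if (s1 >= np) break
  }
  if (length(raw) == 0L) return(list())
  m <- do.call(rbind, raw)
  # greedy overlap resolution across chunk seams: best score wins, ties by
  # longer alignment then leftmost start
  ord <- order(-m[, "score"], -(m[, "pep_end"] - m[, "pep_start"]),
               m[, "pep_start"])
  m <- m[ord, , drop = FALSE]
  kept <- logical(0)
  keep_rows <- integer(0)
  for (r in seq_len(nrow(m))) {
    ov <- FALSE
    for (k in keep_rows) {
      inter <- min(m[r, "pep_end"], m[k, "pep_end"]) -
        max(m[r, "pep_start"], m[k, "pep_start"])
      if (inter > 0) { ov <- TRUE; break }
    }
    if (!ov) keep_rows <- c(keep_rows, r)
  }
  m <- m[keep_rows, , drop = FALSE]
  lapply(seq_len(nrow(m)), function(r) {
    ps <- as.integer(m[r, "pep_start"]); pe <- as.integer(m[r, "pep_end"])
    structure(list(
      interval = map_to_genome(t, ps, pe),
      frame = t$frame,
      domain_class = profile$domain_class,
      profile_name = profile$name,
      score = unname(m[r, "score"]),
      empirical_p = NA_real_,
      profile_coverage = unname(m[r, "aligned_cols"]) / ncol(profile$scores),
      pep_start = ps, pep_end = pe,
      peptide = substr(t$peptide, ps + 1L, pe)),
      class = "domain_hit")
  })
}

#' Empirical shuffle p-value for a hit score
#'
#' The null is the best local alignment score of residue-shuffled copies of
#' the scored peptide: `p = (1 + #[shuffled >= hit]) / (n_shuffles + 1)`.
#'
#' @param hit_score observed alignment score.
#' @param peptide the peptide that was scored (a string, or a
#'   `frame_translation` whose peptide is used).
#' @param profile the `domain_profile` that produced the score.
#' @param n_shuffles number of shuffles (at least 19).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return the empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(hit_score, peptide, profile, n_shuffles = 199L,
                             seed = 1L) {
  if (n_shuffles < 19L) stop("n_shuffles must be at least 19")
  if (inherits(peptide, "frame_translation")) peptide <- peptide$peptide
  code <- pep_encode(peptide)
  ge <- 0L
  with_seed(seed, {
    for (i in seq_len(n_shuffles)) {
      sc <- cpp_pssm_best_score(sample(code), profile$scores,
                                profile$gap_open, profile$gap_extend,
                                STOP_PENALTY)
      if (sc >= hit_score) ge <- ge + 1L
    }
  })
  (1 + ge) / (n_shuffles + 1)
}

#' Scan a genome record with a set of profiles on both strands
#'
#' Translates the record in six frames, scans every frame with every profile,
#' and attaches empirical shuffle p-values computed on the matched peptide
#' stretch plus flanking context. Hits with `p > p_max` are dropped.
#'
#' @param record a `genome_record`.
#' @param profiles list of `domain_profile`s (default: packaged set).
#' @param p_max empirical p-value cutoff (default 0.01).
#' @param n_shuffles shuffles per hit for the null.
#' @param seed RNG seed.
#' @param context extra residues of context on each side of a hit used for
#'   the shuffle null.
#' @return a list of `domain_hit`s sorted by genomic start.
#' @export
scan_genome <- function(record, profiles = packaged_profiles(),
                        p_max = 0.01, n_shuffles = 199L, seed = 1L,
                        context = 30L) {
  frames <- translate_six_frames(record)
  hits <- list()
  for (t in frames) {
    for (p in profiles) {
      hs <- scan_profile(t, p)
      for (h in hs) {
        a <- max(0L, h$pep_start - context)
        b <- min(nchar(t$peptide), h$pep_end + context)
        pep_ctx <- substr(t$peptide, a + 1L, b)
        h$empirical_p <- empirical_pvalue(
          h$score, pep_ctx, p, n_shuffles = n_shuffles,
          seed = derive_seed(seed, paste(record$id, t$frame, h$pep_start)))
        if (h$empirical_p <= p_max) hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (length(hits) == 0L) return(hits)
  hits[order(vapply(hits, function(h) h$interval$start, 0L))]
}

#' Merge domain hits into element cores
#'
#' Same-class hits overlapping by more than half of the shorter hit are
#' deduplicated (best score wins, ties broken by longer alignment then
#' leftmost start); surviving hits on the same sequence and strand are
#' chained by single linkage whenever their intervals are within
#' `max_gap_nt`.
#'
#' @param hits a list of `domain_hit`s.
#' @param max_gap_nt maximum nucleotide gap joining two hits (default 3000).
#' @return a list of `element_core` objects with fields `interval`, `strand`,
#'   `hits` and `has_frameshift`.
#' @export
merge_hits <- function(hits, max_gap_nt = 3000L) {
  if (length(hits) == 0L) return(list())
  key <- vapply(hits, function(h) paste(h$interval$seq_id, h$interval$strand),
                "")
  cores <- list()
  for (grp in split(hits, key)) {
    grp <- grp[order(vapply(grp, function(h) h$interval$start, 0L))]
    grp <- dedup_hits(grp)
    starts <- vapply(grp, function(h) h$interval$start, 0L)
    ends <- vapply(grp, function(h) h$interval$end, 0L)
    cluster <- integer(length(grp))
    cur <- 1L; cluster[1] <- 1L
    if (length(grp) > 1L) {
      max_end <- ends[1]
      for (i in 2:length(grp)) {
        if (starts[i] - max_end > max_gap_nt) cur <- cur + 1L
        cluster[i] <- cur
        max_end <- max(max_end, ends[i])
      }
    }
    for (cl in split(seq_along(grp), cluster)) {
      sub <- grp[cl]
      iv0 <- sub[[1]]$interval
      env <- yr_interval(iv0$seq_id, min(starts[cl]), max(ends[cl]),
                         iv0$strand)
      frames <- unique(vapply(sub, function(h) h$frame, 0L))
      cores[[length(cores) + 1L]] <- structure(
        list(interval = env, strand = iv0$strand, hits = sub,
             has_frameshift = length(frames) > 1L),
        class = "element_core")
    }
  }
  cores[order(vapply(cores, function(cc) cc$interval$seq_id, ""),
              vapply(cores, function(cc) cc$interval$start, 0L))]
}

# same-domain-class overlap resolution (>50% of the shorter hit)
dedup_hits <- function(grp) {
  ord <- order(-vapply(grp, function(h) h$score, 0),
               -vapply(grp, function(h) interval_len(h$interval), 0L),
               vapply(grp, function(h) h$interval$start, 0L))
  kept <- list()
  for (h in grp[ord]) {
    drop <- FALSE
    for (k in kept) {
      if (k$domain_class != h$domain_class) next
      inter <- min(h$interval$end, k$interval$end) -
        max(h$interval$start, k$interval$start)
      if (inter > 0.5 * min(interval_len(h$interval),
                            interval_len(k$interval))) { drop <- TRUE; break }
    }
    if (!drop) kept[[length(kept) + 1L]] <- h
  }
  kept[order(vapply(kept, function(h) h$interval$start, 0L))]
}

#' RT/RH parity quality-control report
#'
#' RT and RH are co-occurring domains in intact elements, so their counts
#' should match; a surplus of RH-only cores flags profile insensitivity on
#' the RT side. The report never removes elements.
#'
#' @param cores a list of `element_core`s.
#' @return a list with counts of RT- and RH-bearing cores, the RH:RT parity
#'   ratio, and the indices of RH-without-RT cores.
#' @export
qc_rt_rh_parity <- function(cores) {
  has <- function(core, cls)
    any(vapply(core$hits, function(h) h$domain_class, "") == cls)
  rt <- vapply(cores, has, TRUE, "RT")
  rh <- vapply(cores, has, TRUE, "RH")
  list(n_rt = sum(rt), n_rh = sum(rh),
       parity_ratio = if (sum(rt) > 0) sum(rh) / sum(rt) else NA_real_,
       flagged = which(rh & !rt),
       n_flagged = sum(rh & !rt))
}
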