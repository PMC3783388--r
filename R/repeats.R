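# Terminal-repeat architecture detection around element cores.
#
# DIRS elements carry inverted terminal repeats (left terminus = reverse
# complement of the right terminus, plus an optional internal complementary
# region); Ngaro elements carry split direct repeats in A1-core-B1-A2-B2
# order. Both detectors share one ungapped matcher: candidate diagonals come
# from exact k-mer seeds (or exhaustive diagonal enumeration when the search
# windows are small enough that seeding buys nothing), and the candidate on
# each diagonal is the maximum-scoring segment under +1/-2 match/mismatch
# scoring, which keeps reported boundaries tight. Structures are ranked by
# length x identity. N never matches anything.

# window pair below which every diagonal is enumerated instead of seeded
EXHAUSTIVE_AREA <- 600L * 600L

#' Find the best ungapped direct matches between two sequence windows
#'
#' Internal workhorse for the repeat detectors; exported because the
#' brute-force test oracles exercise it directly.
#'
#' @param s1,s2 nucleotide strings (windows, not whole genomes).
#' @param k seed word length.
#' @param min_len minimal candidate length.
#' @param min_identity minimal candidate identity.
#' @param self_pair set TRUE when `s1` and `s2` are the same window; only
#'   positive diagonals are searched and candidates whose two copies overlap
#'   are discarded.
#' @return a data frame of candidates (0-based half-open window coordinates):
#'   `i_start`, `i_end`, `j_start`, `j_end`, `len`, `identity`, `score`
#'   (+1/-2 segment score) and `rank` (= len * identity), sorted best first
#'   (rank desc, then score desc, then len desc, then leftmost `i_start`,
#'   then leftmost `j_start`).
#' @export
ungapped_matches <- function(s1, s2, k = 11L, min_len = 20L,
                             min_identity = 0.80, self_pair = FALSE) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  empty <- data.frame(i_start = integer(), i_end = integer(),
                      j_start = integer(), j_end = integer(),
                      len = integer(), identity = numeric(),
                      score = numeric(), rank = numeric())
  if (n1 < min_len || n2 < min_len) return(empty)
  c1 <- chars(s1); c2 <- chars(s2)

  diags <- if (as.double(n1) * n2 <= EXHAUSTIVE_AREA) {
    (-(n1 - min_len)):(n2 - min_len)
  } else seed_diagonals(s1, s2, k)
  if (self_pair) diags <- diags[diags >= min_len]
  if (length(diags) == 0L) return(empty)

  rows <- vector("list", length(diags))
  nr <- 0L
  for (d in diags) {
    # diagonal d pairs s1 position i with s2 position i + d (0-based)
    i0 <- max(0L, -d)             # first s1 index on this diagonal
    m <- min(n1 - i0, n2 - (i0 + d))
    if (m < min_len) next
    ii <- i0 + seq_len(m)         # 1-based s1 indices
    jj <- ii + d
    v <- ifelse(c1[ii] == c2[jj] & c1[ii] != "N" & c2[jj] != "N", 1, -2)
    w <- kadane_window(v)
    if (is.null(w)) next
    len <- w[2] - w[1] + 1L
    if (len < min_len) next
    ident <- sum(v[w[1]:w[2]] == 1) / len
    if (ident < min_identity) next
    is <- i0 + w[1] - 1L          # 0-based window start in s1
    js <- is + d
    if (self_pair && js < is + len) next  # copies must not overlap
    nr <- nr + 1L
    rows[[nr]] <- c(is, is + len, js, js + len, len, ident, w[3], len * ident)
  }
  if (nr == 0L) return(empty)
  m <- do.call(rbind, rows[seq_len(nr)])
  out <- data.frame(i_start = as.integer(m[, 1]), i_end = as.integer(m[, 2]),
                    j_start = as.integer(m[, 3]), j_end = as.integer(m[, 4]),
                    len = as.integer(m[, 5]), identity = m[, 6],
                    score = m[, 7], rank = m[, 8])
  out[order(-out$rank, -out$score, -out$len, out$i_start, out$j_start), ,
      drop = FALSE]
}

# maximum-sum segment of v (Kadane). Ties on the score prefer the SHORTEST
# window, then the leftmost start: zero-net fringes of chance matches are
# trimmed, keeping reported repeat boundaries tight. Returns
# c(start, end, score) in 1-based indices or NULL if no positive segment
# exists.
kadane_window <- function(v) {
  S <- cumsum(v)
  P <- c(0, S[-length(S)])
  cm <- cummin(P)
  val <- S - cm
  best <- max(val)
  if (best <= 0) return(NULL)
  ends <- which(val == best)
  t_start <- t_end <- NA_integer_; t_len <- Inf
  for (t in ends) {
    u <- max(which(P[seq_len(t)] == cm[t]))   # shortest window for this end
    len <- t - u + 1L
    if (len < t_len || (len == t_len && u < t_start)) {
      t_start <- u; t_end <- t; t_len <- len
    }
  }
  c(t_start, t_end, best)
}

# candidate diagonals from shared exact k-mers (k-mers containing N excluded)
seed_diagonals <- function(s1, s2, k) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < k || n2 < k) return(integer())
  k1 <- substring(s1, 1:(n1 - k + 1), k:n1)
  k2 <- substring(s2, 1:(n2 - k + 1), k:n2)
  ok1 <- !grepl("N", k1, fixed = TRUE)
  ok2 <- !grepl("N", k2, fixed = TRUE)
  pos1 <- split(which(ok1), k1[ok1])
  pos2 <- split(which(ok2), k2[ok2])
  shared <- intersect(names(pos1), names(pos2))
  if (length(shared) == 0L) return(integer())
  ds <- unlist(lapply(shared, function(w) {
    as.vector(outer(pos2[[w]], pos1[[w]], `-`))
  }), use.names = FALSE)
  sort(unique(ds))
}

new_repeat_copy <- function(seq_id, start, end, strand, sequence) {
  structure(list(interval = yr_interval(seq_id, start, end, strand),
                 sequence = sequence), class = "repeat_copy")
}

new_repeat_structure <- function(kind, copies, identity_A = NA_real_,
                                 identity_B = NA_real_, icr = NULL) {
  structure(list(kind = kind, copies = copies, identity_A = identity_A,
                 identity_B = identity_B, icr = icr),
            class = "repeat_structure")
}

#' An explicit "no repeat structure found" value
#' @return a `repeat_structure` of kind `"none"`.
#' @export
repeat_none <- function() new_repeat_structure("none", list())

# clip helper: [a, b) intersected with [0, L)
clip <- function(a, b, L) c(max(0L, a), min(L, b))

# how far a repeat copy may reach into the domain-hit envelope
CORE_OVERLAP_TOL <- 30L

#' Find inverted terminal repeats flanking an element core
#'
#' Searches the flank upstream of the core against the reverse complement of
#' the downstream flank. Copies may overlap the core envelope by at most 30
#' nt. Both copies are reported on the forward strand.
#'
#' @param record a `genome_record`.
#' @param core a `yr_interval` (the domain-hit envelope).
#' @param flank_nt flank width searched on each side (default 2000).
#' @param k seed word length (default 11).
#' @param min_len minimal repeat length (default 20).
#' @param min_identity minimal repeat identity (default 0.80).
#' @return a `repeat_structure` of kind `"ITR"` (copies: left, right;
#'   `identity_A` carries the identity) or of kind `"none"`.
#' @export
find_itr <- function(record, core, flank_nt = 2000L, k = 11L,
                     min_len = 20L, min_identity = 0.80) {
  L <- record$length
  lw <- clip(core$start - flank_nt, core$start + CORE_OVERLAP_TOL, L)
  rw <- clip(core$end - CORE_OVERLAP_TOL, core$end + flank_nt, L)
  if (diff(lw) < min_len || diff(rw) < min_len) return(repeat_none())
  left_seq <- substr(record$residues, lw[1] + 1L, lw[2])
  right_seq <- substr(record$residues, rw[1] + 1L, rw[2])
  cand <- ungapped_matches(left_seq, revcomp(right_seq), k = k,
                           min_len = min_len, min_identity = min_identity)
  if (nrow(cand) == 0L) return(repeat_none())
  b <- cand[1, ]
  l_start <- lw[1] + b$i_start; l_end <- lw[1] + b$i_end
  # positions in the reverse complement map back through the window length
  nr <- diff(rw)
  r_start <- rw[1] + nr - b$j_end; r_end <- rw[1] + nr - b$j_start
  left_cp <- new_repeat_copy(record$id, l_start, l_end, "+",
                             substr(record$residues, l_start + 1L, l_end))
  right_cp <- new_repeat_copy(record$id, r_start, r_end, "+",
                              substr(record$residues, r_start + 1L, r_end))
  new_repeat_structure("ITR", list(left = left_cp, right = right_cp),
                       identity_A = b$identity)
}

#' Find the Ngaro split direct-repeat layout A1-core-B1-A2-B2
#'
#' A-pair candidates have one copy in the upstream flank and one downstream
#' of the core; B-pair candidates have both copies downstream (searched in a
#' window of twice the flank width, which must hold B1, A2 and B2). Every
#' (A, B) combination satisfying the ordering `start(B1) < start(A2) <
#' start(B2)` with all of B1/A2/B2 after the core is scored by
#' `lenA * idA + lenB * idB`; the outer element boundary is
#' `start(A1)..end(B2)`.
#'
#' @inheritParams find_itr
#' @return a `repeat_structure` of kind `"SPLIT_DIRECT"` (copies: A1, B1,
#'   A2, B2, element-oriented; coordinates on the forward strand) or of kind
#'   `"none"`.
#' @export
find_split_direct <- function(record, core, flank_nt = 2000L, k = 11L,
                              min_len = 20L, min_identity = 0.80) {
  if (core$strand == "-") {
    # the split layout is element-oriented: analyse the reverse complement
    # of a window around the core and map the copies back
    L <- record$length
    w0 <- max(0L, core$start - 2L * flank_nt - 50L)
    w1 <- min(L, core$end + 2L * flank_nt + 50L)
    local_seq <- revcomp(substr(record$residues, w0 + 1L, w1))
    pseudo <- structure(list(id = record$id, residues = local_seq,
                             length = nchar(local_seq)),
                        class = "genome_record")
    pcore <- yr_interval(record$id, w1 - core$end, w1 - core$start, "+")
    res <- find_split_direct(pseudo, pcore, flank_nt, k, min_len,
                             min_identity)
    if (res$kind == "none") return(res)
    res$copies <- lapply(res$copies, function(cp) {
      s <- w1 - cp$interval$end; e <- w1 - cp$interval$start
      new_repeat_copy(record$id, s, e, "+",
                      substr(record$residues, s + 1L, e))
    })
    return(res)
  }
  L <- record$length
  lw <- clip(core$start - flank_nt, core$start + CORE_OVERLAP_TOL, L)
  dw <- clip(core$end - CORE_OVERLAP_TOL, core$end + 2L * flank_nt, L)
  if (diff(lw) < min_len || diff(dw) < 3L * min_len) return(repeat_none())
  up <- substr(record$residues, lw[1] + 1L, lw[2])
  down <- substr(record$residues, dw[1] + 1L, dw[2])
  a_cand <- ungapped_matches(up, down, k = k, min_len = min_len,
                             min_identity = min_identity)
  b_cand <- ungapped_matches(down, down, k = k, min_len = min_len,
                             min_identity = min_identity, self_pair = TRUE)
  if (nrow(a_cand) == 0L || nrow(b_cand) == 0L) return(repeat_none())
  # genomic coordinates
  a_cand$a1s <- lw[1] + a_cand$i_start; a_cand$a1e <- lw[1] + a_cand$i_end
  a_cand$a2s <- dw[1] + a_cand$j_start; a_cand$a2e <- dw[1] + a_cand$j_end
  b_cand$b1s <- dw[1] + b_cand$i_start; b_cand$b1e <- dw[1] + b_cand$i_end
  b_cand$b2s <- dw[1] + b_cand$j_start; b_cand$b2e <- dw[1] + b_cand$j_end
  best <- NULL; best_key <- NULL
  for (ai in seq_len(nrow(a_cand))) {
    a <- a_cand[ai, ]
    if (a$a1s >= core$start) next             # A1 must start before the core
    if (a$a2s < core$end - CORE_OVERLAP_TOL) next
    for (bi in seq_len(nrow(b_cand))) {
      b <- b_cand[bi, ]
      if (b$b1s < core$end - CORE_OVERLAP_TOL) next
      # ordering: B1 < A2 < B2, copies pairwise disjoint
      if (!(b$b1s < a$a2s && a$a2s < b$b2s)) next
      if (b$b1e > a$a2s || a$a2e > b$b2s) next
      score <- a$rank + b$rank
      key <- c(score, a$len + b$len, -a$a1s)
      if (is.null(best_key) ||
          key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2]) ||
          (key[1] == best_key[1] && key[2] == best_key[2] &&
           key[3] > best_key[3])) {
        best <- list(a = a, b = b); best_key <- key
      }
    }
  }
  if (is.null(best)) return(repeat_none())
  a <- best$a; b <- best$b
  res <- record$residues
  cp <- function(s, e) new_repeat_copy(record$id, s, e, "+",
                                       substr(res, s + 1L, e))
  new_repeat_structure(
    "SPLIT_DIRECT",
    list(A1 = cp(a$a1s, a$a1e), B1 = cp(b$b1s, b$b1e),
         A2 = cp(a$a2s, a$a2e), B2 = cp(b$b2s, b$b2e)),
    identity_A = a$identity, identity_B = b$identity)
}

#' Find an internal complementary region supporting an ITR call
#'
#' Searches the element interior for a segment matching the reverse
#' complement of the left ITR copy. Supporting evidence only; never required
#' for classification.
#'
#' @param record a `genome_record`.
#' @param element a `yr_interval` covering the whole element.
#' @param itr a `repeat_structure` of kind `"ITR"`.
#' @param min_len minimal ICR length (default 15).
#' @param min_identity minimal identity (default 0.80).
#' @return a `repeat_copy` or `NULL`.
#' @export
find_icr <- function(record, element, itr, min_len = 15L,
                     min_identity = 0.80) {
  stopifnot(itr$kind == "ITR")
  left <- itr$copies$left
  int_start <- left$interval$end
  int_end <- itr$copies$right$interval$start
  if (int_end - int_start < min_len) return(NULL)
  interior <- substr(record$residues, int_start + 1L, int_end)
  cand <- ungapped_matches(revcomp(left$sequence), interior,
                           k = 11L, min_len = min_len,
                           min_identity = min_identity)
  if (nrow(cand) == 0L) return(NULL)
  b <- cand[1, ]
  s <- int_start + b$j_start; e <- int_start + b$j_end
  new_repeat_copy(record$id, s, e, "+", substr(record$residues, s + 1L, e))
}

#' Detect the repeat structure around a core, preferring the better-scoring
#' architecture
#'
#' Runs both detectors; if both find a structure the higher `length x
#' identity` total wins. An ICR is attached to ITR results when present.
#'
#' @inheritParams find_itr
#' @return a `repeat_structure` (possibly of kind `"none"`).
#' @export
find_repeat_structure <- function(record, core, flank_nt = 2000L, k = 11L,
                                  min_len = 20L, min_identity = 0.80) {
  itr <- find_itr(record, core, flank_nt, k, min_len, min_identity)
  spl <- find_split_direct(record, core, flank_nt, k, min_len, min_identity)
  itr_rank <- if (itr$kind == "ITR")
    2 * interval_len(itr$copies$left$interval) * itr$identity_A else -Inf
  spl_rank <- if (spl$kind == "SPLIT_DIRECT")
    2 * (interval_len(spl$copies$A1$interval) * spl$identity_A +
         interval_len(spl$copies$B1$interval) * spl$identity_B) else -Inf
  if (is.infinite(itr_rank) && is.infinite(spl_rank)) return(repeat_none())
  if (itr_rank >= spl_rank) {
    el <- yr_interval(record$id, itr$copies$left$interval$start,
                      itr$copies$right$interval$end, core$strand)
    itr$icr <- find_icr(record, el, itr)
    itr
  } else spl
}
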