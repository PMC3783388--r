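# Independent brute-force oracles and small construction helpers shared by
# the test files. Oracles are deliberately written as plain, slow R with no
# calls into the package's optimised code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_pep <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
mutate_pep <- function(p, rate) {
  cc <- strsplit(p, "")[[1]]
  k <- round(rate * length(cc))
  if (k > 0) {
    at <- sample(seq_along(cc), k)
    cc[at] <- vapply(cc[at], function(a) sample(setdiff(AA20, a), 1), "")
  }
  paste(cc, collapse = "")
}
mutate_dna <- function(s, rate) {
  cc <- strsplit(s, "")[[1]]
  k <- round(rate * length(cc))
  if (k > 0) {
    at <- sample(seq_along(cc), k)
    cc[at] <- vapply(cc[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  }
  paste(cc, collapse = "")
}
revcomp_chr <- function(x)
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1]])), collapse = "")

# wrap a bare peptide as a frame_translation for scanner tests
fake_translation <- function(pep, frame = 1L, offset = 0L, seq_id = "t") {
  structure(list(seq_id = seq_id, frame = as.integer(frame), peptide = pep,
                 offset = as.integer(offset),
                 seq_length = as.integer(offset + 3L * nchar(pep) +
                                           (3L - offset) %% 3L)),
            class = "frame_translation")
}

# a synthetic domain hit for merge/classify tests
fake_hit <- function(start, end, frame = 1L, domain_class = "RT",
                     profile_name = "RVT_1", score = 50, coverage = 0.9,
                     seq_id = "g", strand = "+", peptide = NULL) {
  if (is.null(peptide)) peptide <- rand_pep((end - start) %/% 3L)
  structure(list(interval = yr_interval(seq_id, start, end, strand),
                 frame = as.integer(frame), domain_class = domain_class,
                 profile_name = profile_name, score = score,
                 empirical_p = 0.005, profile_coverage = coverage,
                 pep_start = start %/% 3L, pep_end = end %/% 3L,
                 peptide = peptide),
            class = "domain_hit")
}

fake_core <- function(hits) {
  starts <- vapply(hits, function(h) h$interval$start, 0L)
  ends <- vapply(hits, function(h) h$interval$end, 0L)
  iv <- hits[[1]]$interval
  structure(list(interval = yr_interval(iv$seq_id, min(starts), max(ends),
                                        iv$strand),
                 strand = iv$strand, hits = hits,
                 has_frameshift = length(unique(vapply(hits, `[[`, 0L,
                                                       "frame"))) > 1L),
            class = "element_core")
}

# ---- exhaustive local profile-alignment oracle -----------------------------
# Full-matrix affine-gap Smith-Waterman against a PSSM with greedy masking,
# written independently of the C++ kernel.
oracle_pssm_scan <- function(pep, profile, threshold = profile$score_threshold) {
  cc <- strsplit(pep, "")[[1]]
  n <- length(cc); m <- ncol(profile$scores)
  go <- profile$gap_open; ge <- profile$gap_extend
  emit <- function(ch, j) {
    if (ch == "*") return(-8)
    k <- match(ch, AA20)
    if (is.na(k)) return(0)
    profile$scores[k, j]
  }
  masked <- rep(FALSE, n)
  hits <- list()
  repeat {
    H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
    F <- matrix(-Inf, n + 1, m + 1)
    for (i in 1:n) for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + go + ge, E[i + 1, j] + ge)
      F[i + 1, j + 1] <- if (masked[i]) -Inf else
        max(H[i, j + 1] + go + ge, F[i, j + 1] + ge)
      s <- if (masked[i]) -Inf else H[i, j] + emit(cc[i], j)
      H[i + 1, j + 1] <- max(0, s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
    best <- max(H)
    if (best < threshold) break
    idx <- which(H == best, arr.ind = TRUE)[1, ]
    # trace the peptide extent of the best alignment
    i <- as.integer(idx[1]) - 1L; j <- as.integer(idx[2]) - 1L; state <- "H"
    pep_end <- i
    while (TRUE) {
      if (state == "H") {
        if (H[i + 1, j + 1] == 0) break
        s <- if (masked[i]) -Inf else H[i, j] + emit(cc[i], j)
        if (H[i + 1, j + 1] == s) { i <- i - 1; j <- j - 1 }
        else if (H[i + 1, j + 1] == E[i + 1, j + 1]) state <- "E"
        else state <- "F"
      } else if (state == "E") {
        if (E[i + 1, j + 1] == H[i + 1, j] + go + ge) { j <- j - 1; state <- "H" }
        else j <- j - 1
      } else {
        if (F[i + 1, j + 1] == H[i, j + 1] + go + ge) { i <- i - 1; state <- "H" }
        else i <- i - 1
      }
    }
    hits[[length(hits) + 1L]] <- list(score = best, pep_start = i,
                                      pep_end = pep_end)
    if (pep_end <= i) break
    masked[(i + 1):pep_end] <- TRUE
  }
  hits
}

# ---- exhaustive ungapped repeat-pair oracle --------------------------------
# Enumerates every pairing offset between s1 and s2 and, on each offset,
# every window, scoring +1/-2; keeps the maximal-scoring window per offset,
# filters by length and identity, ranks by len*identity with the package's
# tie-breaks. Quadratic per offset - pure brute force.
oracle_best_pair <- function(s1, s2, min_len = 20L, min_identity = 0.80,
                             self_pair = FALSE) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  n1 <- length(c1); n2 <- length(c2)
  cands <- list()
  for (d in (-(n1 - min_len)):(n2 - min_len)) {
    if (self_pair && d < min_len) next
    i0 <- max(0L, -d)
    m <- min(n1 - i0, n2 - (i0 + d))
    if (m < min_len) next
    ii <- i0 + seq_len(m); jj <- ii + d
    v <- ifelse(c1[ii] == c2[jj] & c1[ii] != "N" & c2[jj] != "N", 1, -2)
    # all windows, brute force; ties on score prefer the shortest window,
    # then the leftmost start (which.max gives the shortest window for a
    # fixed start, since the score first reaches its maximum there)
    best <- NULL
    for (a in seq_len(m)) {
      run <- cumsum(v[a:m])
      b_rel <- which.max(run)
      sc <- run[b_rel]
      if (is.null(best) || sc > best$sc ||
          (sc == best$sc && b_rel < best$len) ||
          (sc == best$sc && b_rel == best$len && a < best$a))
        best <- list(a = a, b = a + b_rel - 1L, sc = sc, len = b_rel)
    }
    if (best$sc <= 0) next
    len <- best$b - best$a + 1L
    if (len < min_len) next
    ident <- sum(v[best$a:best$b] == 1) / len
    if (ident < min_identity) next
    is <- i0 + best$a - 1L; js <- is + d
    if (self_pair && js < is + len) next
    cands[[length(cands) + 1L]] <- data.frame(
      i_start = is, i_end = is + len, j_start = js, j_end = js + len,
      len = len, identity = ident, score = best$sc, rank = len * ident)
  }
  if (length(cands) == 0L) return(NULL)
  all <- do.call(rbind, cands)
  all[order(-all$rank, -all$score, -all$len, all$i_start, all$j_start), ][1, ]
}

# ---- identity-clustering oracle --------------------------------------------
# Pairwise global-alignment identity through Biostrings under the same
# scoring (match +2, mismatch -1, gap of length g costs 2 + g), plus the
# same greedy order, with no word prefilter.
oracle_identity <- function(a, b) {
  sub <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sub) <- 2
  al <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sub,
                                      gapOpening = 2, gapExtension = 1,
                                      type = "global")
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

oracle_greedy_cluster <- function(seqs, threshold) {
  seqs <- seqs[order(-nchar(seqs), names(seqs))]
  reps <- character(); members <- list()
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (oracle_identity(seqs[[i]], seqs[[reps[r]]]) >= threshold) {
        members[[r]] <- c(members[[r]], names(seqs)[i]); placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, names(seqs)[i])
      members[[length(reps)]] <- names(seqs)[i]
    }
  }
  setNames(members, reps)
}

# ---- union-find components oracle ------------------------------------------
oracle_components <- function(nodes, edges_i, edges_j) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(edges_i)) {
    ri <- find(edges_i[k]); rj <- find(edges_j[k])
    if (ri != rj) parent[[ri]] <- rj
  }
  roots <- vapply(nodes, find, "")
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, "", 1))])
}
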