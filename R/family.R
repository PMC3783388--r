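# Family assignment: greedy identity clustering of concatenated domain
# peptides (CD-HIT style), plus an all-vs-all similarity graph with
# Gumbel-calibrated shuffle p-values and connected components.

#' Concatenate the best domain peptides of annotated elements
#'
#' Best-scoring hit peptides are concatenated in fixed RT, RH, YR, MT order
#' (absent domains skipped).
#'
#' @param elements a list of `element_model`s (or `element_core`s).
#' @return a data frame with `element_id`, `peptide` and `parts` (a
#'   `class:start-end` offset summary; 0-based half-open).
#' @export
concat_domains <- function(elements) {
  rows <- lapply(seq_along(elements), function(i) {
    el <- elements[[i]]
    core <- if (inherits(el, "element_model")) el$core else el
    eid <- (if (inherits(el, "element_model")) el$id else NULL) %||%
      sprintf("el%04d", i)
    hits <- best_hits_by_class(core)
    pep <- ""
    parts <- character()
    for (cls in c("RT", "RH", "YR", "MT")) {
      h <- hits[[cls]]
      if (is.null(h)) next
      parts <- c(parts, sprintf("%s:%d-%d", cls, nchar(pep),
                                nchar(pep) + nchar(h$peptide)))
      pep <- paste0(pep, h$peptide)
    }
    if (!nzchar(pep)) return(NULL)
    data.frame(element_id = eid, peptide = pep,
               parts = paste(parts, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(element_id = character(), peptide = character(),
                      parts = character()))
  do.call(rbind, rows)
}

#' Global-alignment identity between two peptides
#'
#' Identity is the number of identical aligned residues in the optimal
#' global alignment (match +2, mismatch -1, affine gaps -2/-1) divided by
#' the shorter sequence length (the CD-HIT convention for the denominator).
#' The mismatch and gap penalties keep spurious gapped re-alignment of
#' unrelated regions from inflating the identity.
#'
#' @param a,b peptide strings.
#' @return identity in `[0, 1]`.
#' @export
pair_identity <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  eq <- outer(ca, cb, `==`)
  S <- matrix(-1, length(ca), length(cb))
  S[eq] <- 2
  al <- cpp_align_matrix(S, -2, -1, 0L)
  ops <- al$ops
  ri <- cumsum(ops != 2L); cj <- cumsum(ops != 1L)
  d <- ops == 0L
  matches <- sum(eq[cbind(ri[d], cj[d])])
  matches / min(length(ca), length(cb))
}

#' Greedy incremental identity clustering
#'
#' Sequences are sorted by length descending (ties broken by identifier);
#' each sequence joins the first existing representative it matches at
#' `threshold` identity (after a shared-word count prefilter), otherwise it
#' founds a new cluster. Deterministic.
#'
#' @param seqs a named character vector of peptides, or the data frame from
#'   [concat_domains()].
#' @param threshold identity threshold in (0, 1] (default 0.60).
#' @param word_len word length of the prefilter (default 4).
#' @return a list of clusters, each with `representative_id`, `member_ids`
#'   and `threshold`; the list carries the per-sequence assignment in
#'   attribute `"membership"`.
#' @export
greedy_identity_cluster <- function(seqs, threshold = 0.60, word_len = 4L) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$peptide, seqs$element_id)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  if (word_len < 2L) stop("word_len must be >= 2")
  if (length(seqs) == 0L) return(structure(list(), membership = character()))
  orig_names <- names(seqs)
  seqs <- seqs[order(-nchar(seqs), names(seqs))]
  reps <- character()        # representative ids in founding order
  members <- list()
  words_of <- function(s) {
    n <- nchar(s)
    if (n < word_len) return(character())
    substring(s, 1:(n - word_len + 1), word_len:n)
  }
  rep_words <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]; s <- seqs[[i]]
    w <- words_of(s)
    placed <- FALSE
    for (r in seq_along(reps)) {
      rid <- reps[r]
      ls <- min(nchar(s), nchar(seqs[[rid]]))
      need <- max(0, ls - word_len + 1 - word_len * floor((1 - threshold) * ls))
      if (need > 0) {
        tw <- table(w); trw <- table(rep_words[[r]])
        common <- intersect(names(tw), names(trw))
        shared <- sum(pmin(as.integer(tw[common]), as.integer(trw[common])))
        if (shared < need) next
      }
      if (pair_identity(s, seqs[[rid]]) >= threshold) {
        members[[r]] <- c(members[[r]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
      rep_words[[length(reps)]] <- w
    }
  }
  clusters <- lapply(seq_along(reps), function(r)
    list(representative_id = reps[r], member_ids = members[[r]],
         threshold = threshold))
  membership <- setNames(rep(reps, lengths(members)), unlist(members))
  structure(clusters, membership = membership[orig_names])
}

# BLOSUM62 substitution scores for a pair of peptides
blosum62_matrix <- function(a, b) {
  bl <- get_blosum62()
  ca <- chars(a); cb <- chars(b)
  ca[!ca %in% rownames(bl)] <- "X"
  cb[!cb %in% rownames(bl)] <- "X"
  bl[ca, cb, drop = FALSE]
}

.blosum_cache <- new.env(parent = emptyenv())
get_blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62
  }
  .blosum_cache$m
}

# local BLOSUM62 score with the graph module's gap penalties
local_sw_score <- function(a, b, gap_open = -11, gap_extend = -1) {
  cpp_align_score(blosum62_matrix(a, b), gap_open, gap_extend, 1L)
}

#' Build an all-vs-all similarity graph
#'
#' Pairwise local-alignment scores (BLOSUM62, affine gaps) are converted to
#' p-values by fitting a Gumbel distribution (location/scale by the method
#' of moments) to each pair's shuffled-score null; edges are kept at
#' `p <= p_threshold`. Deterministic given the seed.
#'
#' @param seqs named character vector of peptides (or [concat_domains()]
#'   output); at least 2 sequences.
#' @param p_threshold edge p-value cutoff (default 1e-06).
#' @param n_shuffles shuffles of the shorter sequence per pair (>= 50).
#' @param seed RNG seed.
#' @return an object of class `similarity_graph` with `nodes`, `edges`
#'   (data frame `i`, `j`, `score`, `p`) and `p_threshold`.
#' @export
build_similarity_graph <- function(seqs, p_threshold = 1e-06,
                                   n_shuffles = 50L, seed = 1L) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$peptide, seqs$element_id)
  if (length(seqs) < 2L) stop("at least 2 sequences are required")
  if (n_shuffles < 50L) stop("n_shuffles must be >= 50")
  ids <- names(seqs)
  edges <- list()
  for (i in seq_len(length(seqs) - 1L)) {
    for (j in (i + 1L):length(seqs)) {
      sc <- local_sw_score(seqs[[i]], seqs[[j]])
      shorter <- if (nchar(seqs[[i]]) <= nchar(seqs[[j]])) seqs[[i]] else seqs[[j]]
      longer <- if (nchar(seqs[[i]]) <= nchar(seqs[[j]])) seqs[[j]] else seqs[[i]]
      cs <- chars(shorter)
      null <- numeric(n_shuffles)
      with_seed(derive_seed(seed, paste(ids[i], ids[j])), {
        for (s in seq_len(n_shuffles))
          null[s] <- local_sw_score(paste(sample(cs), collapse = ""), longer)
      })
      p <- gumbel_upper_p(sc, null)
      if (p <= p_threshold)
        edges[[length(edges) + 1L]] <- data.frame(
          i = ids[i], j = ids[j], score = sc, p = p,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(i = character(), j = character(), score = numeric(),
               p = numeric())
  structure(list(nodes = ids, edges = edges, p_threshold = p_threshold),
            class = "similarity_graph")
}

# upper-tail Gumbel p-value with method-of-moments location/scale
gumbel_upper_p <- function(x, null) {
  m <- mean(null); s <- stats::sd(null)
  if (!is.finite(s) || s == 0) return(if (x > m) 1e-300 else 1)
  beta <- s * sqrt(6) / pi
  mu <- m - 0.5772156649 * beta
  z <- (x - mu) / beta
  p <- if (z > 30) exp(-z) else -expm1(-exp(-z))
  max(p, 1e-300)
}

#' Connected components of a similarity graph
#'
#' @param g a `similarity_graph`.
#' @return a list of components (character vectors of node ids), ordered by
#'   their smallest member id, members sorted within each component.
#' @export
connected_components <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("i", "j"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = g$nodes))
  memb <- igraph::components(ig)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, "", 1))]
}

#' Seeded force-directed 2D layout of a similarity graph
#'
#' Edge attraction is proportional to `-log10(p)`; all node pairs repel;
#' the step size decays linearly. Visualisation only: no classification
#' decision reads these coordinates.
#'
#' @param g a `similarity_graph`.
#' @param iterations number of iterations (default 200).
#' @param seed RNG seed for the initial placement.
#' @return a matrix of node coordinates (rownames = node ids).
#' @export
layout_2d <- function(g, iterations = 200L, seed = 1L) {
  n <- length(g$nodes)
  stopifnot(n >= 1L)
  if (n == 1L)
    return(matrix(0, 1, 2, dimnames = list(g$nodes, c("x", "y"))))
  area <- n
  pos <- with_seed(seed, matrix(runif(2 * n, -sqrt(area), sqrt(area)), n, 2))
  rownames(pos) <- g$nodes
  kk <- sqrt(area / n)
  ei <- match(g$edges$i, g$nodes); ej <- match(g$edges$j, g$nodes)
  w <- -log10(pmax(g$edges$p, 1e-300))
  w <- w / max(w, 1)
  step0 <- sqrt(area) / 10
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    # all-pairs repulsion
    dx <- outer(pos[, 1], pos[, 1], `-`); dy <- outer(pos[, 2], pos[, 2], `-`)
    d2 <- dx^2 + dy^2; d2[d2 < 1e-08] <- 1e-08
    f <- kk^2 / d2; diag(f) <- 0
    disp[, 1] <- rowSums(f * dx); disp[, 2] <- rowSums(f * dy)
    # edge attraction weighted by -log10(p)
    if (length(ei)) {
      ex <- pos[ej, 1] - pos[ei, 1]; ey <- pos[ej, 2] - pos[ei, 2]
      ed <- sqrt(ex^2 + ey^2); ed[ed < 1e-08] <- 1e-08
      fa <- w * ed / kk
      for (e in seq_along(ei)) {
        ux <- ex[e] / ed[e] * fa[e]; uy <- ey[e] / ed[e] * fa[e]
        disp[ei[e], ] <- disp[ei[e], ] + c(ux, uy)
        disp[ej[e], ] <- disp[ej[e], ] - c(ux, uy)
      }
    }
    step <- step0 * (1 - (it - 1) / iterations)
    len <- sqrt(rowSums(disp^2)); len[len < 1e-08] <- 1e-08
    pos <- pos + disp / len * pmin(len, step)
  }
  colnames(pos) <- c("x", "y")
  pos
}
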