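# Representative-element trees: per-domain progressive alignment, column
# trimming, partition concatenation, protein distances, neighbor joining and
# outgroup rooting. Distance-based NJ deliberately stands in for
# maximum-likelihood inference: the claims this stage supports (group
# separation among representatives) are testable at the distance level.

#' Construct an alignment object
#' @param rows named character vector of equal-length gapped rows.
#' @param partitions optional named list of 0-based half-open column ranges.
#' @return an object of class `yr_alignment`.
#' @export
yr_alignment <- function(rows, partitions = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L,
            length(unique(nchar(rows))) == 1L)
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("rows must have unique names")
  structure(list(rows = rows, width = nchar(rows[[1]]),
                 partitions = partitions), class = "yr_alignment")
}

#' @export
print.yr_alignment <- function(x, ...) {
  cat(sprintf("<yr_alignment> %d rows x %d columns", length(x$rows), x$width))
  if (!is.null(x$partitions))
    cat(" [", paste(names(x$partitions), collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

# 20 x L matrix of per-column residue frequencies (gap mass dropped)
profile_freqs <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(mat)
  f <- matrix(0, 20, L)
  for (j in seq_len(L)) {
    cnt <- tabulate(match(mat[, j], AA_ALPHABET), nbins = 20L)
    f[, j] <- cnt / nrow(mat)
  }
  f
}

# BLOSUM62 restricted to the package alphabet order
blosum20 <- function() {
  bl <- get_blosum62()
  bl[AA_ALPHABET, AA_ALPHABET]
}

# merge two gapped profiles with a global affine-gap alignment on
# expected-substitution column scores
merge_profiles <- function(rows1, rows2, gap_open = -11, gap_extend = -1) {
  F1 <- profile_freqs(rows1); F2 <- profile_freqs(rows2)
  S <- t(F1) %*% blosum20() %*% F2
  al <- cpp_align_matrix(S, gap_open, gap_extend, 0L)
  ops <- al$ops
  out1 <- character(length(rows1)); out2 <- character(length(rows2))
  c1 <- strsplit(rows1, "", fixed = TRUE)
  c2 <- strsplit(rows2, "", fixed = TRUE)
  i <- 0L; j <- 0L
  col1 <- integer(length(ops)); col2 <- integer(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) { i <- i + 1L; j <- j + 1L; col1[k] <- i; col2[k] <- j }
    else if (ops[k] == 1L) { i <- i + 1L; col1[k] <- i; col2[k] <- 0L }
    else { j <- j + 1L; col1[k] <- 0L; col2[k] <- j }
  }
  take <- function(cc, cols) {
    v <- character(length(cols))
    v[cols == 0L] <- "-"
    v[cols != 0L] <- cc[cols[cols != 0L]]
    paste(v, collapse = "")
  }
  c(vapply(c1, take, "", cols = col1), vapply(c2, take, "", cols = col2))
}

# k-mer distance between two peptides for the guide tree
kmer_distance <- function(a, b, k = 3L) {
  wa <- if (nchar(a) >= k) substring(a, 1:(nchar(a) - k + 1), k:nchar(a)) else character()
  wb <- if (nchar(b) >= k) substring(b, 1:(nchar(b) - k + 1), k:nchar(b)) else character()
  if (!length(wa) || !length(wb)) return(1)
  ta <- table(wa); tb <- table(wb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
  1 - shared / min(length(wa), length(wb))
}

#' Progressive multiple alignment of peptides
#'
#' A guide tree is built from pairwise k-mer distances (UPGMA supplies the
#' rooted merge order); profiles are merged bottom-up with global
#' affine-gap alignments on BLOSUM62 expected-substitution column scores.
#' Deterministic.
#'
#' @param peptides named character vector (>= 2 sequences); unnamed input
#'   gets `s1..sn` names.
#' @param gap_open,gap_extend affine gap penalties.
#' @return a `yr_alignment` with rows in input order.
#' @export
progressive_align <- function(peptides, gap_open = -11, gap_extend = -1) {
  if (length(peptides) < 2L) stop("at least 2 sequences are required")
  if (is.null(names(peptides)))
    names(peptides) <- sprintf("s%d", seq_along(peptides))
  n <- length(peptides)
  if (n == 2L) {
    rows <- merge_profiles(peptides[1], peptides[2], gap_open, gap_extend)
    names(rows) <- names(peptides)
    return(yr_alignment(rows))
  }
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- kmer_distance(peptides[[i]], peptides[[j]])
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  groups <- lapply(seq_len(n), function(i) setNames(peptides[i], names(peptides)[i]))
  for (s in seq_len(nrow(hc$merge))) {
    a <- hc$merge[s, 1]; b <- hc$merge[s, 2]
    ga <- if (a < 0) groups[[-a]] else groups[[n + a]]
    gb <- if (b < 0) groups[[-b]] else groups[[n + b]]
    merged <- merge_profiles(ga, gb, gap_open, gap_extend)
    names(merged) <- c(names(ga), names(gb))
    groups[[n + s]] <- merged
  }
  rows <- groups[[n + nrow(hc$merge)]][names(peptides)]
  yr_alignment(rows)
}

#' Remove gappy alignment columns
#'
#' Columns with gap fraction above `max_gap_fraction` are dropped and
#' partition ranges recomputed.
#'
#' @param a a `yr_alignment`.
#' @param max_gap_fraction maximum tolerated gap fraction (default 0.05).
#' @return a trimmed `yr_alignment` with attribute `"n_removed"`.
#' @export
trim_columns <- function(a, max_gap_fraction = 0.05) {
  stopifnot(inherits(a, "yr_alignment"))
  mat <- do.call(rbind, strsplit(a$rows, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) stop("all columns removed at gap fraction ",
                       max_gap_fraction)
  rows <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(rows) <- names(a$rows)
  parts <- NULL
  if (!is.null(a$partitions)) {
    kept_cum <- cumsum(keep)
    parts <- list()
    for (nm in names(a$partitions)) {
      rg <- a$partitions[[nm]]
      lo <- if (rg[1] == 0L) 0L else kept_cum[rg[1]]
      hi <- kept_cum[rg[2]]
      if (hi > lo) parts[[nm]] <- c(lo, hi)
    }
  }
  out <- yr_alignment(rows, parts)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Concatenate per-domain alignments into a partitioned supermatrix
#'
#' Row-id sets may differ; an element missing a domain is padded with
#' all-gap rows for that partition. Entirely disjoint row-id sets are an
#' error.
#'
#' @param alignments named list of `yr_alignment`s (e.g. RT, RH, YR).
#' @return a `yr_alignment` whose partitions map each input alignment to
#'   its column range.
#' @export
concat_partitions <- function(alignments) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  idsets <- lapply(alignments, function(a) names(a$rows))
  ids <- unique(unlist(idsets))
  if (length(alignments) > 1L &&
      length(Reduce(intersect, idsets)) == 0L)
    stop("disjoint row ids across partitions")
  rows <- setNames(rep("", length(ids)), ids)
  parts <- list()
  offset <- 0L
  for (nm in names(alignments)) {
    a <- alignments[[nm]]
    w <- a$width
    pad <- paste(rep("-", w), collapse = "")
    for (id in ids)
      rows[id] <- paste0(rows[id],
                         if (id %in% names(a$rows)) a$rows[[id]] else pad)
    parts[[nm]] <- c(offset, offset + w)
    offset <- offset + w
  }
  yr_alignment(rows, parts)
}

#' Pairwise protein distances from an alignment
#'
#' Distances are computed over columns where both rows are ungapped:
#' p-distance is the mismatch fraction; the Poisson distance is
#' `-ln(1 - p)`.
#'
#' @param a a `yr_alignment` with at least 2 rows.
#' @param model `"p-distance"` or `"poisson"`.
#' @return a symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(a, model = c("p-distance", "poisson")) {
  model <- match.arg(model)
  stopifnot(inherits(a, "yr_alignment"), length(a$rows) >= 2L)
  mat <- do.call(rbind, strsplit(a$rows, "", fixed = TRUE))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(a$rows), names(a$rows)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok))
      stop("rows '", names(a$rows)[i], "' and '", names(a$rows)[j],
           "' share no ungapped columns")
    p <- mean(mat[i, ok] != mat[j, ok])
    d <- if (model == "p-distance") p else {
      if (p >= 1) stop("Poisson distance undefined at p = 1 for rows '",
                       names(a$rows)[i], "' and '", names(a$rows)[j], "'")
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion; negative branch
#' lengths are clamped to zero with a warning.
#'
#' @param d a symmetric numeric matrix with zero diagonal and at least 3
#'   taxa (rownames used as labels).
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance input must be a square matrix")
  if (max(abs(d - t(d))) > 1e-08) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")
  if (nrow(d) < 3L) stop("at least 3 taxa are required")
  tr <- ape::nj(d)
  if (any(tr$edge.length < 0)) {
    warning("negative branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Root a tree with an outgroup
#'
#' The root is placed at the midpoint of the branch separating a
#' monophyletic outgroup from the ingroup.
#'
#' @param tree an [ape::phylo] tree.
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup tips not in tree: ", paste(missing, collapse = ", "))
  if (!ape::is.monophyletic(tree, outgroup))
    stop("outgroup is not monophyletic: ", paste(outgroup, collapse = ", "),
         " do not form a clade")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  # split the basal branch evenly across the two root children
  root_node <- ape::Ntip(rooted) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  if (length(kids) == 2L && !is.null(rooted$edge.length)) {
    tot <- sum(rooted$edge.length[kids])
    rooted$edge.length[kids] <- tot / 2
  }
  rooted
}
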