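# Progressive alignment, trimming, concatenation, distances, NJ, rooting.

test_that("progressive alignment handles identity and single-gap cases", {
  a <- progressive_align(c(x = "ACDEFGHIKL", y = "ACDEFGHIKL"))
  expect_equal(unname(a$rows), c("ACDEFGHIKL", "ACDEFGHIKL"))
  # deletion of D forces exactly one gap column opposite the D
  a2 <- progressive_align(c(x = "ACDEFG", y = "ACEFG"))
  expect_equal(a2$width, 6L)
  expect_equal(unname(a2$rows["x"]), "ACDEFG")
  expect_equal(unname(a2$rows["y"]), "AC-EFG")
  expect_error(progressive_align(c(x = "ACDEF")), "at least 2")
})

test_that("pairwise projections from a 5-sequence alignment track the
           optimal pairwise alignments", {
  set.seed(1)
  seedp <- rand_pep(60)
  peps <- setNames(vapply(1:5, function(i) mutate_pep(seedp, 0.08), ""),
                   paste0("s", 1:5))
  # drop a few residues from two sequences so gaps are required
  peps[2] <- paste0(substr(peps[2], 1, 20), substr(peps[2], 24, 60))
  peps[4] <- substr(peps[4], 3, 60)
  a <- progressive_align(peps)
  expect_equal(length(unique(nchar(a$rows))), 1L)
  bl <- yrscan:::get_blosum62()
  proj_score <- function(r1, r2) {
    c1 <- strsplit(r1, "")[[1]]; c2 <- strsplit(r2, "")[[1]]
    s <- 0; in_gap <- FALSE
    for (k in seq_along(c1)) {
      if (c1[k] == "-" && c2[k] == "-") next
      if (c1[k] == "-" || c2[k] == "-") {
        s <- s + (if (in_gap) -1 else -12); in_gap <- TRUE
      } else { s <- s + bl[c1[k], c2[k]]; in_gap <- FALSE }
    }
    s
  }
  for (i in 1:4) for (j in (i + 1):5) {
    sub <- matrix(bl[AA20, AA20], 20, 20, dimnames = list(AA20, AA20))
    opt <- Biostrings::pairwiseAlignment(peps[i], peps[j],
                                         substitutionMatrix = sub,
                                         gapOpening = 11, gapExtension = 1,
                                         type = "global")
    ps <- proj_score(a$rows[i], a$rows[j])
    expect_lte(ps, Biostrings::score(opt) + 1e-9)   # optimality bound
    expect_gte(ps, 0.9 * Biostrings::score(opt))    # near-optimal projection
  }
})

test_that("column trimming drops gappy columns and recomputes partitions", {
  a <- yr_alignment(c(x = "ACDEF", y = "ACDEF"))
  expect_equal(trim_columns(a)$rows, a$rows)
  a2 <- yr_alignment(c(x = "AC-EF", y = "ACDEF"))      # col 3: 50% gaps
  t2 <- trim_columns(a2, 0.05)
  expect_equal(unname(t2$rows), c("ACEF", "ACEF"))
  expect_equal(attr(t2, "n_removed"), 1L)
  expect_equal(trim_columns(a2, 1.0)$rows, a2$rows)    # boundary: identity
  a3 <- yr_alignment(c(x = "--", y = "A-"))
  expect_error(trim_columns(a3, 0.05), "all columns removed")
  # partition ranges are recomputed
  a4 <- yr_alignment(c(x = "AC-EFG", y = "ACDE-G"),
                     partitions = list(RT = c(0L, 3L), RH = c(3L, 6L)))
  t4 <- trim_columns(a4, 0.05)
  expect_equal(t4$partitions, list(RT = c(0L, 2L), RH = c(2L, 4L)))
})

test_that("partition concatenation pads missing rows with gaps", {
  rt <- yr_alignment(c(a = "ACD", b = "ACD", c = "ACD"))
  rh <- yr_alignment(c(a = "EFGH", b = "EFGH", c = "EFGH"))
  yr <- yr_alignment(c(a = "IKLMN", b = "IKLMN"))
  cc <- concat_partitions(list(RT = rt, RH = rh, YR = yr))
  expect_equal(cc$width, 12L)
  expect_equal(cc$partitions,
               list(RT = c(0L, 3L), RH = c(3L, 7L), YR = c(7L, 12L)))
  expect_equal(unname(cc$rows["c"]), "ACDEFGH-----")
  expect_equal(concat_partitions(list(RT = rt))$rows, rt$rows)
  other <- yr_alignment(c(z = "AAA"))
  expect_error(concat_partitions(list(RT = rt, RH = other)), "disjoint")
})

test_that("distances follow the p and Poisson formulas over shared
           ungapped columns", {
  a <- yr_alignment(c(x = "AAAAAAAAAA", y = "AAAAAAAAAA"))
  expect_equal(unname(distance_matrix(a)["x", "y"]), 0)
  cc <- paste(c(rep("A", 8), "C", "C"), collapse = "")
  a2 <- yr_alignment(c(x = "AAAAAAAAAA", y = cc))
  expect_equal(unname(distance_matrix(a2, "p-distance")["x", "y"]), 0.2)
  expect_equal(unname(distance_matrix(a2, "poisson")["x", "y"]), -log(0.8),
               tolerance = 1e-12)
  # saturated pair: poisson undefined at p = 1
  a3 <- yr_alignment(c(x = "AAAA", y = "CCCC"))
  expect_error(distance_matrix(a3, "poisson"), "p = 1")
  # gap-only overlap is an error
  a4 <- yr_alignment(c(x = "AA--", y = "--CC"))
  expect_error(distance_matrix(a4), "no ungapped")
})

test_that("neighbor joining recovers additive trees exactly", {
  # ((A:1,B:2):1,(C:3,D:4)) as an additive distance matrix
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  expect_equal(c(as.dist(cophenetic(tr))), c(as.dist(D)), tolerance = 1e-09)
  # AB|CD is the single internal split
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))

  # ultrametric 3-taxon case solves the three-point formulas
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(D3)
  lens <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])],
                   tr3$tip.label)
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  expect_error(neighbor_joining(matrix(1:6, 2, 3)), "square")
  Dx <- D; Dx[1, 2] <- 99
  expect_error(neighbor_joining(Dx), "symmetric")
  Dd <- D; diag(Dd)[2] <- 0.5
  expect_error(neighbor_joining(Dd), "diagonal")
})

test_that("random 10-leaf additive matrices are recovered with exact
           topology and branch lengths", {
  set.seed(2)
  for (case in 1:20) {
    tr0 <- ape::rtree(10)
    D <- cophenetic(tr0)
    tr <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr0), tr)[1], 0,
                 ignore_attr = TRUE)
    expect_equal(c(as.dist(cophenetic(tr)[rownames(D), rownames(D)])),
                 c(as.dist(D)), tolerance = 1e-08)
  }
})

test_that("outgroup rooting places the root mid-branch and demands
           monophyly", {
  D <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  rooted <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  expect_true(ape::is.monophyletic(rooted, c("A", "B", "C")))
  # rooting then unrooting returns the original topology
  expect_equal(ape::dist.topo(ape::unroot(rooted), tr)[1], 0,
               ignore_attr = TRUE)
  # path lengths are preserved by mid-branch rooting
  expect_equal(c(as.dist(cophenetic(rooted)[rownames(D), rownames(D)])),
               c(as.dist(D)), tolerance = 1e-09)
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")

  set.seed(3)
  tr2 <- ape::rtree(8)
  # two tips that are not sisters cannot be an outgroup
  pick <- c(tr2$tip.label[1],
            tr2$tip.label[which(cophenetic(tr2)[1, ] ==
                                  max(cophenetic(tr2)[1, ]))[1]])
  if (!ape::is.monophyletic(tr2, pick))
    expect_error(root_with_outgroup(tr2, pick), "not monophyletic")
})

test_that("trimming never increases columns; distances stay symmetric,
           non-negative, zero-diagonal", {
  set.seed(4)
  for (i in 1:10) {
    seedp <- rand_pep(40)
    peps <- setNames(vapply(1:4, function(k) mutate_pep(seedp, 0.2), ""),
                     paste0("s", 1:4))
    peps[2] <- substr(peps[2], 1, 35)
    a <- progressive_align(peps)
    t <- trim_columns(a, 0.3)
    expect_lte(t$width, a$width)
    D <- distance_matrix(t)
    expect_equal(D, t(D))
    expect_true(all(D >= 0))
    expect_true(all(diag(D) == 0))
  }
})
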