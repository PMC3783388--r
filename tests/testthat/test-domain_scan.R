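# Profile construction, scanning, shuffle p-values, hit merging and QC.

test_that("profile building follows the pseudocount log-odds closed form", {
  members <- rep(paste(rep(c("A", "C", "D"), 10), collapse = ""), 5)
  p <- build_profile_from_members(members, "RT", name = "ident5")
  expect_equal(ncol(p$scores), 30L)
  # 5 identical members: consensus residue scores log(((5+1)/(5+20))/(1/20))
  expect_equal(p$max_self_score, 30 * log(6 / (25 * 0.05)), tolerance = 1e-12)
  # never-observed residues score log(((0+1)/25)/0.05) < 0
  expect_equal(unname(p$scores["Y", 1]), log((1 / 25) / 0.05),
               tolerance = 1e-12)
  expect_error(build_profile_from_members(members[1:4], "RT"), "at least 5")
})

test_that("gappy alignment columns are dropped from built profiles", {
  rows <- c("ACDEF", "AC-EF", "AC-EF", "AC-EF", "ACDEF")
  p <- build_profile_from_members(rows, "RH")   # col 3 is 60% gaps
  expect_equal(ncol(p$scores), 4L)
  rows2 <- c("A-DEF", "AC-EF", "ACD-F", "ACDE-", "-CDEF")  # 20% gaps each
  expect_equal(ncol(build_profile_from_members(rows2, "RH")$scores), 5L)
})

test_that("a consensus peptide self-matches with full coverage and the
           maximal score", {
  p <- packaged_profiles()[["RVT_1"]]
  cons <- profile_consensus(p)
  hits <- scan_profile(fake_translation(cons), p)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$score, p$max_self_score, tolerance = 1e-09)
  expect_equal(hits[[1]]$profile_coverage, 1.0)
  expect_equal(c(hits[[1]]$pep_start, hits[[1]]$pep_end), c(0L, nchar(cons)))
})

test_that("shuffled consensus peptides do not hit at the default threshold", {
  p <- packaged_profiles()[["RVT_1"]]
  cons <- strsplit(profile_consensus(p), "")[[1]]
  set.seed(17)
  n_hit <- 0L
  for (i in 1:100) {
    sh <- paste(sample(cons), collapse = "")
    if (length(scan_profile(fake_translation(sh), p)) > 0) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 1L)   # no hit in at least 99/100 shuffles
})

test_that("an in-frame stop inside a domain reduces but does not destroy
           the hit (remnant tolerance)", {
  p <- packaged_profiles()[["RVT_1"]]
  cons <- profile_consensus(p)
  broken <- paste0(substr(cons, 1, 30), "*", substr(cons, 31, nchar(cons)))
  hits <- scan_profile(fake_translation(broken), p)
  expect_length(hits, 1)
  expect_lt(hits[[1]]$score, p$max_self_score)
  expect_gt(hits[[1]]$score, p$score_threshold)
})

test_that("empirical shuffle p-values follow the add-one formula", {
  # a flat profile scores every peptide identically, so ties are exact
  flat <- domain_profile("flat", "RT", matrix(0, 20, 12),
                         score_threshold = 1)
  pep <- rand_pep(40)
  # every shuffle ties (>=): p = (1 + n) / (n + 1) = 1
  expect_equal(empirical_pvalue(0, pep, flat, n_shuffles = 99, seed = 1), 1)
  # hit score above every shuffled score: p = 1 / (n + 1)
  expect_equal(empirical_pvalue(5, pep, flat, n_shuffles = 99, seed = 1),
               0.01)
  expect_equal(empirical_pvalue(5, pep, flat, n_shuffles = 19, seed = 1),
               0.05)
  expect_error(empirical_pvalue(5, pep, flat, n_shuffles = 10), "at least 19")
  # deterministic given the seed
  p <- packaged_profiles()[["Rnase_H"]]
  v1 <- empirical_pvalue(20, rand_pep(80), p, seed = 7)
  v2 <- empirical_pvalue(20, rand_pep(80), p, seed = 7)
  expect_true(v1 > 0 && v1 <= 1)
})

test_that("hit merging chains frame-split hits and respects the gap limit", {
  hits <- list(fake_hit(100, 400, frame = 1, domain_class = "RT"),
               fake_hit(450, 700, frame = 1, domain_class = "RH"),
               fake_hit(900, 1200, frame = 2, domain_class = "YR"))
  cores <- merge_hits(hits, max_gap_nt = 3000)
  expect_length(cores, 1)
  expect_true(cores[[1]]$has_frameshift)
  expect_equal(c(cores[[1]]$interval$start, cores[[1]]$interval$end),
               c(100L, 1200L))

  far <- list(fake_hit(100, 400, domain_class = "YR"),
              fake_hit(10400, 10700, domain_class = "YR"))
  expect_length(merge_hits(far, max_gap_nt = 3000), 2)

  # dedup: two same-class hits overlapping 90% keep the better score
  dup <- list(fake_hit(100, 400, domain_class = "RT", score = 50),
              fake_hit(130, 400, domain_class = "RT", score = 80))
  core <- merge_hits(dup, max_gap_nt = 3000)
  expect_length(core, 1)
  expect_length(core[[1]]$hits, 1)
  expect_equal(core[[1]]$hits[[1]]$score, 80)

  # opposite strands never merge
  two <- list(fake_hit(100, 400), fake_hit(500, 800, strand = "-"))
  expect_length(merge_hits(two), 2)
  expect_length(merge_hits(list()), 0)
})

test_that("raising thresholds is monotone for hits and cores", {
  set.seed(23)
  p <- packaged_profiles()[["Phage_integrase"]]
  cons <- profile_consensus(p)
  pep <- paste0(rand_pep(60), mutate_pep(cons, 0.2), rand_pep(40),
                mutate_pep(cons, 0.35), rand_pep(60))
  t <- fake_translation(pep)
  thresholds <- c(5, 15, 30, 60, 90)
  counts <- vapply(thresholds, function(th)
    length(scan_profile(t, p, threshold = th)), 0L)
  expect_true(all(diff(counts) <= 0))

  hits <- list(fake_hit(0, 300, domain_class = "RT"),
               fake_hit(1300, 1600, domain_class = "RH"),
               fake_hit(4000, 4300, domain_class = "YR"))
  n_cores <- vapply(c(500, 1000, 2500, 5000), function(g)
    length(merge_hits(hits, max_gap_nt = g)), 0L)
  expect_true(all(diff(n_cores) <= 0))
})

test_that("scan scores and extents equal the exhaustive DP oracle on short
           peptides", {
  set.seed(31)
  for (case in 1:40) {
    members <- replicate(5, mutate_pep(rand_pep(sample(12:25, 1)), 0.08))
    prof <- build_profile_from_members(members, "RT", name = "oracle")
    cons <- profile_consensus(prof)
    pep <- paste0(rand_pep(sample(10:60, 1)),
                  mutate_pep(cons, runif(1, 0, 0.3)),
                  rand_pep(sample(10:60, 1)))
    got <- scan_profile(fake_translation(pep), prof)
    want <- oracle_pssm_scan(pep, prof)
    expect_equal(length(got), length(want))
    if (length(got) == length(want) && length(got) > 0) {
      for (k in seq_along(got)) {
        expect_equal(got[[k]]$score, want[[k]]$score, tolerance = 1e-09)
        expect_equal(got[[k]]$pep_start, want[[k]]$pep_start)
        expect_equal(got[[k]]$pep_end, want[[k]]$pep_end)
      }
    }
  }
})

test_that("chunked scanning of long translations equals single-chunk
           scanning", {
  set.seed(37)
  p <- packaged_profiles()[["RVT_1"]]
  cons <- profile_consensus(p)
  pep <- paste0(rand_pep(3000), cons, rand_pep(2500), mutate_pep(cons, 0.15),
                rand_pep(3000))
  t <- fake_translation(pep)
  a <- scan_profile(t, p, chunk_size = 2000L, chunk_overlap = 300L)
  b <- scan_profile(t, p, chunk_size = 100000L)
  expect_equal(length(a), length(b))
  expect_equal(vapply(a, `[[`, 0, "score"), vapply(b, `[[`, 0, "score"))
  expect_equal(vapply(a, `[[`, 0L, "pep_start"),
               vapply(b, `[[`, 0L, "pep_start"))
})

test_that("planted domains are recovered with exact boundaries when intact
           and >= 90% when decayed", {
  p <- packaged_profiles()[["RVT_1"]]
  cons <- profile_consensus(p)
  set.seed(41)
  exact <- 0L; recovered <- 0L
  n <- 100L
  for (i in seq_len(n)) {
    left <- sample(20:150, 1)
    pep0 <- paste0(rand_pep(left), cons, rand_pep(sample(20:150, 1)))
    hits0 <- scan_profile(fake_translation(pep0), p)
    if (length(hits0) >= 1 && hits0[[1]]$pep_start == left &&
        hits0[[1]]$pep_end == left + nchar(cons)) exact <- exact + 1L
    pep1 <- paste0(rand_pep(left), mutate_pep(cons, 0.10),
                   rand_pep(sample(20:150, 1)))
    h1 <- scan_profile(fake_translation(pep1), p)
    if (length(h1) >= 1 && h1[[1]]$pep_start < left + nchar(cons) &&
        h1[[1]]$pep_end > left) recovered <- recovered + 1L
  }
  expect_equal(exact, n)
  expect_gte(recovered, 0.9 * n)
})

test_that("RT/RH parity QC counts and flags without deleting anything", {
  both <- lapply(1:10, function(i)
    fake_core(list(fake_hit(0, 300, domain_class = "RT"),
                   fake_hit(400, 700, domain_class = "RH"))))
  r <- qc_rt_rh_parity(both)
  expect_equal(r$parity_ratio, 1.0)
  expect_equal(r$n_flagged, 0L)

  rh_only <- lapply(1:6, function(i)
    fake_core(list(fake_hit(0, 300, domain_class = "RH"))))
  r2 <- qc_rt_rh_parity(c(rh_only, both[1:6]))
  expect_equal(r2$parity_ratio, 2.0)     # 12 RH-bearing vs 6 RT-bearing
  expect_equal(r2$n_flagged, 6L)
  expect_equal(r2$flagged, 1:6)

  r3 <- qc_rt_rh_parity(list())
  expect_equal(r3$n_rt + r3$n_rh, 0L)
})

test_that("built profiles detect their own members after a write/read
           round-trip", {
  set.seed(43)
  seedpep <- rand_pep(40)
  members <- replicate(8, mutate_pep(seedpep, 0.1))
  p <- build_profile_from_members(members, "YR", name = "fam")
  f <- withr::local_tempfile()
  write_pssm(p, f)
  q <- read_pssm(f)
  hits <- scan_profile(fake_translation(members[1]), q)
  expect_length(hits, 1)
})
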