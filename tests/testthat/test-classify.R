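# Superfamily / completeness / clade assignment rules.

# repeat structures built directly for rule tests
fake_itr <- function(seq_id = "g", s1 = 100, e1 = 150, s2 = 1200, e2 = 1250) {
  yrscan:::new_repeat_structure(
    "ITR",
    list(left = yrscan:::new_repeat_copy(seq_id, s1, e1, "+", rand_dna(e1 - s1)),
         right = yrscan:::new_repeat_copy(seq_id, s2, e2, "+", rand_dna(e2 - s2))),
    identity_A = 0.95)
}
fake_split <- function(seq_id = "g") {
  cp <- function(s, e) yrscan:::new_repeat_copy(seq_id, s, e, "+",
                                                rand_dna(e - s))
  yrscan:::new_repeat_structure(
    "SPLIT_DIRECT",
    list(A1 = cp(100, 140), B1 = cp(1200, 1240), A2 = cp(1300, 1340),
         B2 = cp(1400, 1440)),
    identity_A = 0.95, identity_B = 0.95)
}

core_of <- function(classes, profiles = NULL, coverage = 0.9,
                    start = 200, width = 200) {
  if (is.null(profiles))
    profiles <- c(RT = "RVT_1", RH = "Rnase_H", YR = "Phage_integrase",
                  MT = "Dam")[classes]
  hits <- lapply(seq_along(classes), function(i)
    fake_hit(start + (i - 1) * (width + 50), start + i * width + (i - 1) * 50,
             domain_class = classes[i], profile_name = profiles[i],
             coverage = coverage))
  fake_core(hits)
}

test_that("the classification truth table follows domain composition and
           repeat order", {
  set.seed(1)
  # MT (and ITR) => DIRS
  r <- classify_superfamily(core_of(c("RT", "RH", "MT", "YR")), fake_itr())
  expect_equal(r$superfamily, "DIRS")
  # RT,RH,YR with split direct repeats => Ngaro
  r2 <- classify_superfamily(core_of(c("RT", "RH", "YR")), fake_split())
  expect_equal(r2$superfamily, "Ngaro")
  # single generic RH, no repeats => undetermined
  r3 <- classify_superfamily(core_of("RH"), repeat_none())
  expect_equal(r3$superfamily, "undetermined")
  # MT with split direct repeats is a recorded conflict
  r4 <- classify_superfamily(core_of(c("RT", "MT")), fake_split())
  expect_equal(r4$superfamily, "undetermined")
  expect_true(any(grepl("conflict", r4$evidence)))
  # MT alone implies DIRS even without repeats
  r5 <- classify_superfamily(core_of("MT"), repeat_none())
  expect_equal(r5$superfamily, "DIRS")
})

test_that("profile affinity voting decides when no MT and no repeats are
           present", {
  set.seed(2)
  dirs_core <- core_of(c("RT", "RH"),
                       profiles = c("RT_DIRS1", "RNase_HI_RT_DIRS1"))
  expect_equal(classify_superfamily(dirs_core, repeat_none())$superfamily,
               "DIRS")
  ngaro_core <- core_of(c("RT", "RH"), profiles = c("RT_Ngaro", "RH_Ngaro"))
  expect_equal(classify_superfamily(ngaro_core, repeat_none())$superfamily,
               "Ngaro")
  # one vote each way is a tie
  tie_core <- core_of(c("RT", "RH"), profiles = c("RT_DIRS1", "RH_Ngaro"))
  expect_equal(classify_superfamily(tie_core, repeat_none())$superfamily,
               "undetermined")
})

test_that("completeness distinguishes complete, truncated and remnant", {
  set.seed(3)
  full <- core_of(c("RT", "RH", "MT", "YR"), coverage = 0.95)
  expect_equal(call_completeness(full, fake_itr(), "DIRS"), "complete")
  # full Ngaro domain set but no repeats -> truncated
  ng <- core_of(c("RT", "RH", "YR"), coverage = 0.9)
  expect_equal(call_completeness(ng, repeat_none(), "Ngaro"), "truncated")
  # a single low-coverage fragment -> remnant
  frag <- core_of("YR", coverage = 0.3)
  expect_equal(call_completeness(frag, repeat_none(), "undetermined"),
               "remnant")
  # full set but one low-coverage hit -> truncated, not complete
  mixed <- core_of(c("RT", "RH", "MT", "YR"), coverage = 0.95)
  mixed$hits[[2]]$profile_coverage <- 0.6
  expect_equal(call_completeness(mixed, fake_itr(), "DIRS"), "truncated")
})

test_that("clade assignment recovers the planted clade with a clear margin", {
  cons <- packaged_consensus()
  for (clade in c("Ngaro2", "Ngaro3")) {
    hits <- lapply(c("RT", "RH", "YR"), function(cls)
      fake_hit(200, 400, domain_class = cls,
               peptide = cons$peptide[cons$group == clade &
                                      cons$domain_class == cls]))
    core <- fake_core(hits)
    a <- assign_ngaro_clade(core)
    expect_equal(a$group, clade)
    expect_gt(a$margin, 0.05)
  }
})

test_that("equal clade scores give unassigned", {
  cons <- packaged_consensus()
  hits <- lapply(c("RT", "RH", "YR"), function(cls)
    fake_hit(200, 400, domain_class = cls,
             peptide = cons$peptide[cons$group == "Ngaro1" &
                                    cons$domain_class == cls]))
  core <- fake_core(hits)
  motifs <- packaged_clade_motifs()
  # duplicating one clade's motif set forces an exact tie
  tied <- list(Ngaro1 = motifs$Ngaro1, Ngaro4 = motifs$Ngaro1)
  a <- assign_ngaro_clade(core, clade_motifs = tied)
  expect_equal(a$group, "unassigned")
  expect_equal(a$margin, 0)
})

test_that("a single-domain remnant is scored on its one available domain,
           matching a brute-force motif score", {
  cons <- packaged_consensus()
  pep <- cons$peptide[cons$group == "Ngaro3" & cons$domain_class == "RH"]
  core <- fake_core(list(fake_hit(200, 350, domain_class = "RH",
                                  peptide = pep)))
  a <- assign_ngaro_clade(core)
  expect_equal(a$group, "Ngaro3")
  # brute-force oracle: score each clade via the independent R DP
  motifs <- packaged_clade_motifs()
  oracle <- vapply(paste0("Ngaro", 1:4), function(g) {
    m <- motifs[[g]]$RH
    o <- oracle_pssm_scan(pep, m, threshold = 1e-9)
    if (length(o)) o[[1]]$score else 0
  }, 0)
  expect_equal(unname(a$scores[names(oracle)]), unname(oracle),
               tolerance = 1e-09)
})

test_that("DIRS lineages are assigned by the same motif scheme", {
  cons <- packaged_consensus()
  for (lin in c("DIRS_A", "DIRS_B")) {
    hits <- lapply(c("RT", "RH", "YR"), function(cls)
      fake_hit(200, 400, domain_class = cls,
               peptide = cons$peptide[cons$group == lin &
                                      cons$domain_class == cls]))
    a <- assign_dirs_lineage(fake_core(hits))
    expect_equal(a$group, lin)
  }
  # tie -> unassigned
  hits <- lapply("RT", function(cls)
    fake_hit(200, 400, domain_class = cls,
             peptide = cons$peptide[cons$group == "DIRS_A" &
                                    cons$domain_class == cls]))
  motifs <- packaged_clade_motifs()
  a2 <- assign_dirs_lineage(fake_core(hits),
                            lineage_motifs = list(DIRS_A = motifs$DIRS_A,
                                                  DIRS_B = motifs$DIRS_A))
  expect_equal(a2$group, "unassigned")
})

test_that("element models carry repeat-extended boundaries and a full
           evidence trail, deterministically", {
  set.seed(4)
  core <- core_of(c("RT", "RH", "MT", "YR"))
  itr <- fake_itr()
  el1 <- classify_element(core, itr, id = "e1")
  el2 <- classify_element(core, itr, id = "e1")
  expect_equal(el1, el2)
  expect_equal(el1$outer_interval$start, 100L)
  expect_equal(el1$outer_interval$end, 1250L)
  expect_gt(length(el1$evidence), 0)
  # without repeats the outer interval is the core envelope
  el3 <- classify_element(core, repeat_none())
  expect_equal(el3$outer_interval$start, el3$core$interval$start)
})
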