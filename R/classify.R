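# Superfamily, completeness and clade assignment.
#
# The decision ladder follows domain composition first (the MT
# methyltransferase occurs only in DIRS), then repeat architecture (ITR =
# DIRS, split direct repeats = Ngaro), then profile-affinity voting;
# contradictory evidence yields "undetermined" with both evidences recorded.

DIRS_DOMAINS <- c("RT", "RH", "MT", "YR")
NGARO_DOMAINS <- c("RT", "RH", "YR")

core_classes <- function(core)
  unique(vapply(core$hits, function(h) h$domain_class, ""))

# best-scoring hit of each domain class
best_hits_by_class <- function(core) {
  out <- list()
  for (h in core$hits) {
    cur <- out[[h$domain_class]]
    if (is.null(cur) || h$score > cur$score) out[[h$domain_class]] <- h
  }
  out
}

#' Assign the superfamily of an element core
#'
#' Decision ladder: (1) an MT hit implies DIRS; (2) inverted terminal
#' repeats imply DIRS; (3) split direct repeats imply Ngaro; (4) otherwise
#' the best hit of each domain class votes through its profile affinity tag
#' (generic profiles abstain); (5) ties or all-generic evidence give
#' "undetermined". Contradictions between rules 1-3 (an MT hit together with
#' split direct repeats) give "undetermined" with both evidences recorded.
#'
#' @param core an `element_core`.
#' @param repeats a `repeat_structure`.
#' @return a list with `superfamily` and an `evidence` character vector
#'   (the audit trail of rules fired).
#' @export
classify_superfamily <- function(core, repeats) {
  stopifnot(length(core$hits) >= 1L)
  classes <- core_classes(core)
  has_mt <- "MT" %in% classes
  kind <- if (is.null(repeats)) "none" else repeats$kind
  evidence <- character()
  if (has_mt) evidence <- c(evidence, "MT domain present (DIRS-diagnostic)")
  if (kind == "ITR") evidence <- c(evidence, "inverted terminal repeats (DIRS)")
  if (kind == "SPLIT_DIRECT")
    evidence <- c(evidence, "split direct repeats A1-core-B1-A2-B2 (Ngaro)")
  if (has_mt && kind == "SPLIT_DIRECT") {
    return(list(superfamily = "undetermined",
                evidence = c(evidence, "conflict: MT with split direct repeats")))
  }
  if (has_mt || kind == "ITR")
    return(list(superfamily = "DIRS", evidence = evidence))
  if (kind == "SPLIT_DIRECT")
    return(list(superfamily = "Ngaro", evidence = evidence))
  # affinity vote over the best hit per domain class
  votes <- vapply(best_hits_by_class(core), function(h) {
    prof <- packaged_profiles()[[h$profile_name]]
    aff <- if (!is.null(prof)) prof$affinity else
      PROFILE_CLASS_MAP$affinity[match(h$profile_name, PROFILE_CLASS_MAP$name)]
    aff %||% "generic"
  }, "")
  n_dirs <- sum(votes == "DIRS-specific", na.rm = TRUE)
  n_ngaro <- sum(votes == "Ngaro-like", na.rm = TRUE)
  evidence <- c(evidence, sprintf("affinity vote: %d DIRS-specific, %d Ngaro-like",
                                  n_dirs, n_ngaro))
  if (n_dirs > n_ngaro) list(superfamily = "DIRS", evidence = evidence)
  else if (n_ngaro > n_dirs) list(superfamily = "Ngaro", evidence = evidence)
  else list(superfamily = "undetermined",
            evidence = c(evidence, "vote tied or all-generic"))
}

#' Call element completeness
#'
#' `complete`: the full expected domain set for the superfamily (DIRS:
#' RT, RH, MT, YR; Ngaro: RT, RH, YR), every hit covering at least 80% of
#' its profile, and a full repeat structure. `remnant`: every hit covers
#' less than half of its profile, or only one domain class is present.
#' Everything else is `truncated`.
#'
#' @param core an `element_core`.
#' @param repeats a `repeat_structure`.
#' @param superfamily the assigned superfamily.
#' @return one of `"complete"`, `"truncated"`, `"remnant"`.
#' @export
call_completeness <- function(core, repeats, superfamily) {
  classes <- core_classes(core)
  cov <- vapply(core$hits, function(h) h$profile_coverage, 0)
  expected <- switch(superfamily, DIRS = DIRS_DOMAINS, Ngaro = NGARO_DOMAINS,
                     DIRS_DOMAINS)
  kind <- if (is.null(repeats)) "none" else repeats$kind
  full_repeats <- (superfamily == "DIRS" && kind == "ITR") ||
    (superfamily == "Ngaro" && kind == "SPLIT_DIRECT")
  if (setequal(intersect(expected, classes), expected) &&
      all(cov >= 0.8) && full_repeats) return("complete")
  if (all(cov < 0.5) || length(classes) == 1L) return("remnant")
  "truncated"
}

# sum of best motif-profile local-alignment scores over available domains
motif_group_score <- function(peps, motifs) {
  s <- 0
  for (cls in names(peps)) {
    m <- motifs[[cls]]
    if (is.null(m)) next
    s <- s + cpp_pssm_best_score(pep_encode(peps[[cls]]), m$scores,
                                 m$gap_open, m$gap_extend, STOP_PENALTY)
  }
  s
}

assign_group_by_motifs <- function(core, motif_sets, domains, margin_min) {
  hits <- best_hits_by_class(core)
  peps <- lapply(hits[intersect(names(hits), domains)],
                 function(h) h$peptide)
  if (length(peps) == 0L)
    return(list(group = "unassigned", margin = NA_real_, scores = NULL))
  scores <- vapply(motif_sets, motif_group_score, 0, peps = peps)
  ord <- order(-scores)
  best <- scores[ord[1]]; second <- scores[ord[2]]
  if (best <= 0)
    return(list(group = "unassigned", margin = NA_real_, scores = scores))
  margin <- unname((best - second) / abs(best))
  group <- if (margin < margin_min) "unassigned" else names(scores)[ord[1]]
  list(group = group, margin = margin, scores = scores)
}

#' Assign a Ngaro element to one of the four clades
#'
#' Each clade's score is the sum over available RT/RH/YR hit peptides of the
#' best local-alignment score against that clade's motif profiles. The
#' winner is reported with `margin = (best - second) / |best|`; margins
#' below `margin_min` give `"unassigned"` (Ngaro clades 1 and 4 share
#' motifs, so near-ties are genuinely ambiguous).
#'
#' @param core an `element_core` of a Ngaro element.
#' @param clade_motifs per-clade motif profile sets (default: packaged
#'   `Ngaro1`..`Ngaro4`).
#' @param margin_min minimal relative margin (default 0.05).
#' @return a list with `group`, `margin` and the per-clade `scores`.
#' @export
assign_ngaro_clade <- function(core, clade_motifs = NULL, margin_min = 0.05) {
  if (is.null(clade_motifs)) {
    all <- packaged_clade_motifs()
    clade_motifs <- all[grepl("^Ngaro", names(all))]
  }
  assign_group_by_motifs(core, clade_motifs, NGARO_DOMAINS, margin_min)
}

#' Assign a DIRS element to one of the two lineages
#'
#' Same scoring scheme as [assign_ngaro_clade()] with the two packaged
#' DIRS lineage motif sets.
#'
#' @param core an `element_core` of a DIRS element.
#' @param lineage_motifs lineage motif sets (default: packaged `DIRS_A`,
#'   `DIRS_B`).
#' @param margin_min minimal relative margin (default 0.05).
#' @return a list with `group`, `margin` and per-lineage `scores`.
#' @export
assign_dirs_lineage <- function(core, lineage_motifs = NULL,
                                margin_min = 0.05) {
  if (is.null(lineage_motifs)) {
    all <- packaged_clade_motifs()
    lineage_motifs <- all[grepl("^DIRS_", names(all))]
  }
  assign_group_by_motifs(core, lineage_motifs, DIRS_DOMAINS, margin_min)
}

#' Build the full element model from a core and its repeat structure
#'
#' Combines superfamily, completeness and clade assignment, and sets the
#' outer interval to the repeat-extended boundaries when repeats were found
#' (otherwise the core envelope).
#'
#' @param core an `element_core`.
#' @param repeats a `repeat_structure` (defaults to none).
#' @param id optional element identifier.
#' @return an object of class `element_model`.
#' @export
classify_element <- function(core, repeats = repeat_none(), id = NULL) {
  stopifnot(length(core$hits) >= 1L)
  sf <- classify_superfamily(core, repeats)
  completeness <- call_completeness(core, repeats, sf$superfamily)
  clade <- "unassigned"; margin <- NA_real_
  if (sf$superfamily == "Ngaro") {
    a <- assign_ngaro_clade(core)
    clade <- a$group; margin <- a$margin
  } else if (sf$superfamily == "DIRS") {
    a <- assign_dirs_lineage(core)
    clade <- a$group; margin <- a$margin
  }
  outer <- if (repeats$kind %in% c("ITR", "SPLIT_DIRECT")) {
    # repeat-extended element boundary (A1..B2 or left ITR..right ITR,
    # expressed on the forward coordinate system)
    starts <- vapply(repeats$copies, function(cp) cp$interval$start, 0L)
    ends <- vapply(repeats$copies, function(cp) cp$interval$end, 0L)
    yr_interval(core$interval$seq_id,
                min(starts, core$interval$start),
                max(ends, core$interval$end), core$strand)
  } else core$interval
  structure(list(id = id, core = core, repeats = repeats,
                 outer_interval = outer, superfamily = sf$superfamily,
                 completeness = completeness, clade = clade,
                 clade_margin = margin, evidence = sf$evidence,
                 family_id = NA_character_),
            class = "element_model")
}

#' @export
print.element_model <- function(x, ...) {
  iv <- x$outer_interval
  cat(sprintf("<element_model> %s:%d-%d(%s) %s/%s/%s, %d domain hit(s)%s\n",
              iv$seq_id, iv$start + 1L, iv$end, iv$strand, x$superfamily,
              x$completeness, x$clade, length(x$core$hits),
              if (isTRUE(x$core$has_frameshift)) ", frameshifted" else ""))
  invisible(x)
}
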