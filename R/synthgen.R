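# Synthetic genomes with planted DIRS and Ngaro elements and full truth
# annotations, so detection, boundary resolution, classification, clustering
# and the tree stage are all testable offline against known ground truth.
#
# Planted domain peptides are the packaged per-group consensus peptides
# (synthetic stand-ins, internally consistent with the packaged scanning
# profiles). Architectures follow the two diagnostic layouts:
#   DIRS:  ITR - gag stuffer - RT - RH - MT - YR - ICR - revcomp(ITR)
#   Ngaro: A1 - gag stuffer - RT - RH - [optional +1 frameshift] - YR
#          - B1 - A2 - B2
# Decay is applied last, in a fixed order: substitutions, then truncation
# from a uniformly chosen end, then deletion of listed domains.

DEFAULT_ITR_LEN <- 150L
DEFAULT_AB_LEN <- 100L

#' Specify one synthetic element
#'
#' @param superfamily `"DIRS"` or `"Ngaro"`.
#' @param clade clade/lineage label (`Ngaro1`..`Ngaro4` or `DIRS_A`/`DIRS_B`);
#'   default picks the first group of the superfamily.
#' @param frameshift plant the YR ORF in a +1 frame relative to RT/RH
#'   (Ngaro only).
#' @param mu substitution rate in `[0, 1)` applied uniformly over the element.
#' @param truncation fraction in `[0, 1)` removed from a uniformly chosen end.
#' @param domain_loss character vector of domain classes deleted outright.
#' @param repeat_len terminal repeat copy length (nt).
#' @param include_icr plant an internal complementary region (DIRS only).
#' @param seed RNG seed for this element.
#' @return an object of class `element_spec`.
#' @export
element_spec <- function(superfamily = c("DIRS", "Ngaro"), clade = NULL,
                         frameshift = FALSE, mu = 0, truncation = 0,
                         domain_loss = character(), repeat_len = NULL,
                         include_icr = TRUE, seed = 1L) {
  superfamily <- match.arg(superfamily)
  if (is.null(clade))
    clade <- if (superfamily == "DIRS") "DIRS_A" else "Ngaro1"
  ok <- if (superfamily == "DIRS") c("DIRS_A", "DIRS_B")
        else paste0("Ngaro", 1:4)
  if (!clade %in% ok)
    stop("clade '", clade, "' is invalid for superfamily ", superfamily)
  if (superfamily == "DIRS" && frameshift)
    stop("the frameshift option models the Ngaro YR ORF")
  if (superfamily == "Ngaro" && "MT" %in% domain_loss)
    stop("Ngaro specs have no MT domain to lose")
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  if (truncation < 0 || truncation >= 1) stop("truncation must be in [0, 1)")
  if (is.null(repeat_len))
    repeat_len <- if (superfamily == "DIRS") DEFAULT_ITR_LEN else DEFAULT_AB_LEN
  structure(list(superfamily = superfamily, clade = clade,
                 frameshift = frameshift, mu = mu, truncation = truncation,
                 domain_loss = domain_loss, repeat_len = as.integer(repeat_len),
                 include_icr = include_icr, seed = as.integer(seed)),
            class = "element_spec")
}

# seeded random DNA at a given GC content
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# reverse-translate a peptide with seeded codon choice
reverse_translate <- function(pep) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), code)
  paste(vapply(chars(pep), function(a) {
    cs <- by_aa[[a]]
    if (is.null(cs)) stop("cannot reverse-translate residue '", a, "'")
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, ""), collapse = "")
}

group_peptide <- function(group, domain_class) {
  cons <- packaged_consensus()
  p <- cons$peptide[cons$group == group & cons$domain_class == domain_class]
  if (length(p) != 1L)
    stop("no packaged consensus for ", group, "/", domain_class)
  p
}

#' Synthesise one element from a spec
#'
#' Builds the nucleotide sequence of a single element (element-local
#' coordinates, forward strand) together with its truth record, then applies
#' decay. Deterministic given the spec's seed.
#'
#' @param spec an `element_spec`.
#' @return a list with `sequence` (nucleotide string) and `truth`: a list
#'   holding `superfamily`, `clade`, `frameshift`, `completeness`, `domains`
#'   (data frame: class, start, end — 0-based half-open, local), and
#'   `repeats` (data frame: role, start, end).
#' @export
synthesize_element <- function(spec) {
  stopifnot(inherits(spec, "element_spec"))
  with_seed(spec$seed, synthesize_element_impl(spec))
}

synthesize_element_impl <- function(spec) {
  linker_pep <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                 collapse = "")
  dom_classes <- if (spec$superfamily == "DIRS") c("RT", "RH", "MT", "YR")
                 else c("RT", "RH", "YR")
  peps <- setNames(lapply(dom_classes, group_peptide, group = spec$clade),
                   dom_classes)

  seqs <- character(); doms <- list(); reps <- list(); pos <- 0L
  add <- function(nt) { seqs <<- c(seqs, nt); pos <<- pos + nchar(nt); invisible(NULL) }
  mark_rep <- function(role, nt) {
    reps[[length(reps) + 1L]] <<- data.frame(role = role, start = pos,
                                             end = pos + nchar(nt))
    add(nt)
  }
  mark_dom <- function(cls, pep) {
    nt <- reverse_translate(pep)
    doms[[length(doms) + 1L]] <<- data.frame(class = cls, start = pos,
                                             end = pos + nchar(nt))
    add(nt)
  }

  if (spec$superfamily == "DIRS") {
    itr <- random_dna(spec$repeat_len)
    mark_rep("ITR_left", itr)
    add(reverse_translate(linker_pep(150L)))            # gag stuffer
    mark_dom("RT", peps$RT); add(reverse_translate(linker_pep(8L)))
    mark_dom("RH", peps$RH); add(reverse_translate(linker_pep(8L)))
    mark_dom("MT", peps$MT); add(reverse_translate(linker_pep(8L)))
    mark_dom("YR", peps$YR)
    if (spec$include_icr) {
      add(random_dna(40L))
      icr <- revcomp(substr(itr, 1L, 40L))
      mark_rep("ICR", icr)
      add(random_dna(40L))
    } else add(random_dna(80L))
    mark_rep("ITR_right", revcomp(itr))
  } else {
    a_rep <- random_dna(spec$repeat_len)
    b_rep <- random_dna(spec$repeat_len)
    mark_rep("A1", a_rep)
    add(reverse_translate(linker_pep(150L)))            # gag stuffer
    mark_dom("RT", peps$RT); add(reverse_translate(linker_pep(8L)))
    mark_dom("RH", peps$RH)
    if (spec$frameshift) add(substr(random_dna(3L), 1L, 1L))  # +1 shift
    else add(reverse_translate(linker_pep(4L)))
    mark_dom("YR", peps$YR)
    add(random_dna(60L))
    mark_rep("B1", b_rep)
    add(random_dna(80L))
    mark_rep("A2", a_rep)
    add(random_dna(80L))
    mark_rep("B2", b_rep)
  }
  seq <- paste(seqs, collapse = "")
  doms <- do.call(rbind, doms)
  reps <- do.call(rbind, reps)

  # --- decay: substitutions, truncation, domain deletion -------------------
  L <- nchar(seq)
  if (spec$mu > 0) {
    n_sub <- round(spec$mu * L)
    if (n_sub > 0) {
      at <- sample.int(L, n_sub)
      cc <- chars(seq)
      cc[at] <- vapply(cc[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      seq <- paste(cc, collapse = "")
    }
  }
  if (spec$truncation > 0) {
    cut <- round(spec$truncation * L)
    from_right <- sample(c(TRUE, FALSE), 1L)
    if (from_right) {
      keep_end <- L - cut
      seq <- substr(seq, 1L, keep_end)
      clipper <- function(df) {
        df <- df[df$start < keep_end, , drop = FALSE]
        df$end <- pmin(df$end, keep_end); df
      }
    } else {
      seq <- substr(seq, cut + 1L, L)
      clipper <- function(df) {
        df <- df[df$end > cut, , drop = FALSE]
        df$start <- pmax(df$start, cut) - cut
        df$end <- df$end - cut; df
      }
    }
    doms <- clipper(doms)
    reps <- clipper(reps)
  }
  if (length(spec$domain_loss) > 0 && nrow(doms) > 0) {
    for (cls in spec$domain_loss) {
      k <- which(doms$class == cls)
      if (length(k) == 0L) next
      s <- doms$start[k[1]]; e <- doms$end[k[1]]
      w <- e - s
      seq <- paste0(substr(seq, 1L, s), substr(seq, e + 1L, nchar(seq)))
      shift <- function(df) {
        df <- df[!(df$start >= s & df$end <= e), , drop = FALSE]
        df$start <- ifelse(df$start >= e, df$start - w, df$start)
        df$end <- ifelse(df$end > s, pmax(df$end - w, df$start + 1L), df$end)
        df
      }
      doms <- doms[-k[1], , drop = FALSE]
      doms <- shift(doms)
      reps <- shift(reps)
    }
  }

  term_roles <- if (spec$superfamily == "DIRS") c("ITR_left", "ITR_right")
                else c("A1", "B1", "A2", "B2")
  full_reps <- all(term_roles %in% reps$role)
  full_doms <- setequal(
    doms$class, if (spec$superfamily == "DIRS") c("RT", "RH", "MT", "YR")
                else c("RT", "RH", "YR"))
  completeness <- if (full_doms && full_reps && spec$mu == 0 &&
                      spec$truncation == 0) "complete"
                  else if (nrow(doms) <= 1L) "remnant" else "truncated"
  list(sequence = seq,
       truth = list(superfamily = spec$superfamily, clade = spec$clade,
                    frameshift = spec$frameshift, completeness = completeness,
                    domains = doms, repeats = reps))
}

#' Draw a set of element specs emulating a decayed element population
#'
#' @param n number of elements.
#' @param prop_dirs proportion of DIRS elements (default 0.5).
#' @param mu substitution rate for every element.
#' @param trunc_prob probability that an element is truncated; truncated
#'   elements lose a uniform fraction in `[0.1, 0.5]` from a random end.
#' @param frameshift_prob probability that a Ngaro element has a
#'   frameshifted YR (default 0.5).
#' @param seed RNG seed.
#' @return a list of `element_spec`s.
#' @export
sample_element_specs <- function(n, prop_dirs = 0.5, mu = 0,
                                 trunc_prob = 0, frameshift_prob = 0.5,
                                 seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      dirs <- runif(1) < prop_dirs
      element_spec(
        superfamily = if (dirs) "DIRS" else "Ngaro",
        clade = if (dirs) sample(c("DIRS_A", "DIRS_B"), 1L)
                else sample(paste0("Ngaro", 1:4), 1L),
        frameshift = !dirs && runif(1) < frameshift_prob,
        mu = mu,
        truncation = if (runif(1) < trunc_prob) runif(1, 0.1, 0.5) else 0,
        seed = derive_seed(seed, i))
    })
  })
}

#' Synthesise a genome with planted elements and truth annotations
#'
#' Elements are placed on an i.i.d. background at the stated GC content,
#' in random order and orientation, separated by at least `min_spacing`
#' nucleotides (so neighbouring elements can never be chained into one
#' core), or nested inside an earlier element with probability
#' `nesting_prob`.
#'
#' @param specs list of `element_spec`s (one element planted per spec).
#' @param background_length background length in nt before insertion.
#' @param gc background GC content (default 0.5).
#' @param nesting_prob probability that an element nests inside an earlier
#'   element instead of occupying background (default 0).
#' @param min_spacing minimal background gap between top-level elements.
#' @param seq_id identifier of the emitted sequence.
#' @param seed RNG seed.
#' @return a list with `record` (a `genome_record`), `truth` (a data frame:
#'   element_id, start, end, strand, superfamily, clade, completeness,
#'   n_domains, nested) and `details` (per-element truth with genomic
#'   domain/repeat coordinates).
#' @export
synthesize_genome <- function(specs, background_length = 200000L, gc = 0.5,
                              nesting_prob = 0, min_spacing = 5000L,
                              seq_id = "synth1", seed = 1L) {
  n <- length(specs)
  elems <- lapply(specs, synthesize_element)
  with_seed(derive_seed(seed, "genome"), {
    lens <- vapply(elems, function(e) nchar(e$sequence), 0L)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    nested <- c(FALSE, runif(max(0L, n - 1L)) < nesting_prob)
    n_top <- sum(!nested)
    need <- (n_top + 1L) * min_spacing
    if (background_length < need)
      stop("background too short: need at least ", need,
           " nt for ", n_top, " elements at min_spacing ", min_spacing)
    # gap lengths: min_spacing plus a random split of the surplus
    surplus <- background_length - need
    cuts <- sort(sample.int(surplus + 1L, n_top, replace = TRUE) - 1L)
    gaps <- diff(c(0L, cuts, surplus)) + min_spacing

    pieces <- character(); truth_rows <- list(); details <- list()
    pos <- 0L; ti <- 0L
    host_ids <- integer()   # indices (in `details`) of placed top-level hosts
    for (i in seq_len(n)) {
      el <- elems[[i]]
      seq_i <- el$sequence
      if (strands[i] == "-") seq_i <- revcomp(seq_i)
      flip <- function(df, L) {
        if (is.null(df) || nrow(df) == 0L) return(df)
        new_start <- L - df$end; df$end <- L - df$start; df$start <- new_start
        df[order(df$start), , drop = FALSE]
      }
      doms <- el$truth$domains; reps <- el$truth$repeats
      if (strands[i] == "-") {
        L <- nchar(el$sequence)
        doms <- flip(doms, L); reps <- flip(reps, L)
      }
      if (!nested[i] || length(host_ids) == 0L) {
        ti <- ti + 1L
        pieces <- c(pieces, random_dna(gaps[ti], gc), seq_i)
        pos <- pos + gaps[ti]
        start <- pos
        pos <- pos + nchar(seq_i)
        details[[i]] <- list(start = start, end = pos, strand = strands[i],
                             truth = el$truth, domains = doms, reps = reps,
                             nested = FALSE)
        host_ids <- c(host_ids, i)
      } else {
        # insert into a previous top-level element's interior, avoiding its
        # domains and repeat copies
        h <- details[[sample(host_ids, 1L)]]
        avoid <- rbind(h$domains[, c("start", "end")],
                       h$reps[, c("start", "end")])
        ok_local <- setdiff(seq(50L, (h$end - h$start) - 50L),
                            unlist(apply(avoid, 1, function(r)
                              seq(r[1], r[2]), simplify = FALSE)))
        if (length(ok_local) == 0L) ok_local <- (h$end - h$start) %/% 2L
        at <- h$start + sample(ok_local, 1L)   # genomic insertion point
        details[[i]] <- list(start = at, end = at + nchar(seq_i),
                             strand = strands[i], truth = el$truth,
                             domains = doms, reps = reps, nested = TRUE,
                             pending_seq = seq_i)
      }
    }
    pieces <- c(pieces, random_dna(gaps[n_top + 1L], gc))
    genome <- paste(pieces, collapse = "")

    # splice nested elements in, updating earlier coordinates
    nested_idx <- which(vapply(details, function(d) isTRUE(d$nested), TRUE))
    nested_idx <- nested_idx[order(vapply(details[nested_idx], `[[`, 0,
                                          "start"), decreasing = TRUE)]
    for (i in nested_idx) {
      d <- details[[i]]
      at <- d$start; w <- nchar(d$pending_seq)
      genome <- paste0(substr(genome, 1L, at), d$pending_seq,
                       substr(genome, at + 1L, nchar(genome)))
      for (k in seq_along(details)) {
        if (k == i) next
        dk <- details[[k]]
        if (dk$start >= at) {
          dk$start <- dk$start + w; dk$end <- dk$end + w
        } else if (dk$end > at) {
          # insertion lands inside element k: its span grows and local
          # features downstream of the insertion point shift right
          local_at <- at - dk$start
          dk$end <- dk$end + w
          shift_df <- function(df) {
            if (is.null(df) || nrow(df) == 0L) return(df)
            df$start <- ifelse(df$start >= local_at, df$start + w, df$start)
            df$end <- ifelse(df$end > local_at, df$end + w, df$end)
            df
          }
          dk$domains <- shift_df(dk$domains)
          dk$reps <- shift_df(dk$reps)
        }
        details[[k]] <- dk
      }
      details[[i]]$pending_seq <- NULL
    }

    genome <- apply_terminus_collars(genome, details)

    for (i in seq_along(details)) {
      d <- details[[i]]
      truth_rows[[i]] <- data.frame(
        element_id = sprintf("truth%03d", i), start = d$start, end = d$end,
        strand = d$strand, superfamily = d$truth$superfamily,
        clade = d$truth$clade, completeness = d$truth$completeness,
        n_domains = nrow(d$domains), nested = isTRUE(d$nested),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth_rows)
    rec <- genome_record(seq_id, genome)
    list(record = rec, truth = truth, details = details)
  })
}

# Make planted outer repeat termini unambiguous: background immediately
# flanking an element can chance-match a repeat's ungapped extension partner,
# in which case the genome truly contains a longer repeat than the recorded
# truth and the planted boundary is not identifiable. A 2-nt collar of
# forced mismatches outside each top-level element pins the truth boundary.
# Only background bases are touched; element sequence and truth coordinates
# are unchanged.
apply_terminus_collars <- function(genome, details) {
  cc <- strsplit(genome, "", fixed = TRUE)[[1]]
  L <- length(cc)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bump <- function(i, clash) {
    # 1-based index i; pick a base different from both current pairing
    # partner value `clash` and N
    if (i < 1L || i > L) return(invisible(NULL))
    if (cc[i] != clash) return(invisible(NULL))
    cc[i] <<- sample(setdiff(c("A", "C", "G", "T"), clash), 1L)
    invisible(NULL)
  }
  at <- function(i) if (i >= 1L && i <= L) cc[i] else "N"
  for (d in details) {
    if (isTRUE(d$nested)) next
    roles <- d$reps$role
    rint <- function(role, field)
      d$start + d$reps[[field]][d$reps$role == role]
    s <- d$start; e <- d$end
    if (all(c("ITR_left", "ITR_right") %in% roles)) {
      for (k in 1:2) bump(s - k + 1L, comp[[at(e + k)]])
    } else if (all(c("A1", "B1", "A2", "B2") %in% roles)) {
      if (d$strand == "+") {
        a2s <- rint("A2", "start"); b1e <- rint("B1", "end")
        for (k in 1:2) {
          bump(s - k + 1L, at(a2s - k + 1L))
          bump(e + k, at(b1e + k))
        }
      } else {
        a2e <- rint("A2", "end"); b1s <- rint("B1", "start")
        for (k in 1:2) {
          bump(e + k, at(a2e + k))
          bump(s - k + 1L, at(b1s - k + 1L))
        }
      }
    }
  }
  paste(cc, collapse = "")
}

#' Write a synthetic truth table as GFF3
#'
#' @param truth the truth data frame from [synthesize_genome()].
#' @param seq_id the genome sequence identifier.
#' @param path output path.
#' @export
write_truth_gff3 <- function(truth, seq_id, path) {
  if (nrow(truth) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(NULL))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seq_id,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr)$source <- "yrscan_synth"
  S4Vectors::mcols(gr)$type <- "mobile_genetic_element"
  S4Vectors::mcols(gr)$ID <- truth$element_id
  S4Vectors::mcols(gr)$superfamily <- truth$superfamily
  S4Vectors::mcols(gr)$clade <- truth$clade
  S4Vectors::mcols(gr)$completeness <- truth$completeness
  rtracklayer::export(gr, path, format = "gff3")
  invisible(NULL)
}
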