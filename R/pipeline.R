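# Run configuration and the end-to-end pipeline driver:
# scan -> merge -> repeats -> classify -> families -> graph -> tree.

CONFIG_DEFAULTS <- list(
  domain_p = 0.01,            # empirical p-value cutoff for domain hits
  n_shuffles = 199L,          # shuffles behind each domain hit p-value
  max_gap_nt = 3000L,         # single-linkage merge distance for hits
  flank_nt = 2000L,           # repeat search flank width
  repeat_k = 11L,             # repeat seed word length
  min_repeat_len = 20L,       # minimal repeat copy length
  min_repeat_identity = 0.80, # minimal repeat identity
  identity_threshold = 0.60,  # family clustering identity
  word_len = 4L,              # family clustering word length
  graph_p = 1e-06,            # similarity graph edge cutoff
  graph_shuffles = 50L,       # shuffles behind each graph p-value
  trim_gap_fraction = 0.05,   # alignment column trimming
  clade_margin = 0.05,        # minimal clade-assignment margin
  distance_model = "p-distance",
  layout_iterations = 200L,
  seed = 1L)

#' Build a validated run configuration
#'
#' Defaults mirror the pipeline's standard operating point (family identity
#' 0.60 with word length 4, graph edges at p <= 1e-06, domain hits at
#' empirical p <= 0.01, repeat search flanks of 2000 nt at identity >= 0.80,
#' hit merging within 3000 nt, trimming at 5% gaps). Unknown keys are an
#' error. Every run writes its fully resolved configuration next to its
#' outputs.
#'
#' @param ... overrides of the defaults (see `yrscan:::CONFIG_DEFAULTS`).
#' @return a named list of class `yr_config`.
#' @export
yr_config <- function(...) {
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(names(over) == "")))
    stop("configuration overrides must be named")
  unknown <- setdiff(names(over), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, over)
  stopifnot(cfg$domain_p > 0, cfg$domain_p <= 1,
            cfg$identity_threshold > 0, cfg$identity_threshold <= 1,
            cfg$min_repeat_identity > 0, cfg$min_repeat_identity <= 1,
            cfg$graph_p > 0, cfg$max_gap_nt >= 0, cfg$flank_nt > 0)
  structure(cfg, class = "yr_config")
}

#' Annotate one genome record
#'
#' Scans six-frame translations with the profile set, merges hits into
#' cores, resolves repeat structures and classifies each core.
#'
#' @param record a `genome_record`.
#' @param config a `yr_config`.
#' @param profiles list of `domain_profile`s (default: packaged set).
#' @param verbose emit per-stage messages.
#' @return a list of `element_model`s.
#' @export
annotate_genome <- function(record, config = yr_config(),
                            profiles = packaged_profiles(), verbose = FALSE) {
  hits <- scan_genome(record, profiles, p_max = config$domain_p,
                      n_shuffles = config$n_shuffles, seed = config$seed)
  if (verbose) message(sprintf("[scan] %s: %d domain hits", record$id,
                               length(hits)))
  cores <- merge_hits(hits, max_gap_nt = config$max_gap_nt)
  elements <- lapply(seq_along(cores), function(i) {
    core <- cores[[i]]
    rp <- find_repeat_structure(record, core$interval,
                                flank_nt = config$flank_nt,
                                k = config$repeat_k,
                                min_len = config$min_repeat_len,
                                min_identity = config$min_repeat_identity)
    classify_element(core, rp)
  })
  if (verbose) {
    if (length(elements) == 0L) message(sprintf("[classify] %s: 0 elements",
                                                record$id))
    else {
      tab <- table(vapply(elements, `[[`, "", "superfamily"))
      message(sprintf("[classify] %s: %d elements (%s)", record$id,
                      length(elements),
                      paste(names(tab), tab, sep = "=", collapse = ", ")))
    }
  }
  elements
}

#' Run the full annotation pipeline
#'
#' Chains scanning, repeat resolution, classification, family clustering,
#' the representative similarity graph and the representative tree, and
#' optionally writes all stage outputs to a directory.
#'
#' @param genomes a `genome_record`, a list of them, or a FASTA path.
#' @param config a `yr_config`.
#' @param profiles list of `domain_profile`s (default: packaged set).
#' @param out_dir optional output directory (created if needed): writes
#'   `elements.gff3`, `report.tsv`, `families.tsv`, `graph_edges.tsv`,
#'   `layout.tsv`, `representatives.nwk` and `config.yaml`.
#' @param verbose emit per-stage messages.
#' @return an object of class `yr_annotation`.
#' @export
yr_pipeline <- function(genomes, config = yr_config(),
                        profiles = packaged_profiles(), out_dir = NULL,
                        verbose = TRUE) {
  if (is.character(genomes)) genomes <- read_fasta(genomes)
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)

  elements <- list()
  for (rec in genomes)
    elements <- c(elements, annotate_genome(rec, config, profiles,
                                            verbose = verbose))
  for (i in seq_along(elements)) elements[[i]]$id <- sprintf("YR%04d", i)

  qc <- qc_rt_rh_parity(lapply(elements, `[[`, "core"))

  families <- NULL; graph <- NULL; comps <- NULL; layout <- NULL; tree <- NULL
  concat <- concat_domains(elements)
  if (nrow(concat) >= 1L) {
    families <- greedy_identity_cluster(concat,
                                        threshold = config$identity_threshold,
                                        word_len = config$word_len)
    memb <- attr(families, "membership")
    for (i in seq_along(elements))
      elements[[i]]$family_id <- unname(memb[elements[[i]]$id])
    if (verbose) message(sprintf("[cluster] %d elements in %d families",
                                 nrow(concat), length(families)))
    reps <- vapply(families, `[[`, "", "representative_id")
    rep_seqs <- setNames(concat$peptide[match(reps, concat$element_id)], reps)
    if (length(reps) >= 2L) {
      graph <- build_similarity_graph(rep_seqs, p_threshold = config$graph_p,
                                      n_shuffles = config$graph_shuffles,
                                      seed = config$seed)
      comps <- connected_components(graph)
      layout <- layout_2d(graph, iterations = config$layout_iterations,
                          seed = config$seed)
      if (verbose) message(sprintf(
        "[graph] %d nodes, %d edges, %d component(s)", length(graph$nodes),
        nrow(graph$edges), length(comps)))
    }
    if (length(reps) >= 3L)
      tree <- representative_tree(elements, reps, config)
  } else if (verbose) message("[cluster] 0 elements")

  res <- structure(list(elements = elements, families = families,
                        graph = graph, components = comps, layout = layout,
                        tree = tree, qc = qc, config = config,
                        report = report_table(elements)),
                   class = "yr_annotation")
  if (!is.null(out_dir)) write_outputs(res, out_dir, genomes)
  res
}

#' Build the representative-element tree
#'
#' Per-domain progressive alignments of the representatives' RT, RH and YR
#' peptides (MT is DIRS-only and excluded), trimmed, concatenated and turned
#' into a neighbor-joining tree.
#'
#' @param elements list of `element_model`s.
#' @param rep_ids ids of the representative elements (>= 3).
#' @param config a `yr_config`.
#' @return an [ape::phylo] tree, or `NULL` when fewer than 3 representatives
#'   carry alignable domains.
#' @export
representative_tree <- function(elements, rep_ids, config = yr_config()) {
  ids <- vapply(elements, `[[`, "", "id")
  reps <- elements[match(rep_ids, ids)]
  aligns <- list()
  for (cls in c("RT", "RH", "YR")) {
    peps <- list()
    for (el in reps) {
      h <- best_hits_by_class(el$core)[[cls]]
      if (!is.null(h)) peps[[el$id]] <- h$peptide
    }
    if (length(peps) >= 2L) {
      a <- progressive_align(unlist(peps))
      aligns[[cls]] <- tryCatch(
        trim_columns(a, config$trim_gap_fraction),
        error = function(e) a)  # keep untrimmed if trimming empties it
    }
  }
  if (length(aligns) == 0L) return(NULL)
  conc <- concat_partitions(aligns)
  if (length(conc$rows) < 3L) return(NULL)
  D <- distance_matrix(conc, model = config$distance_model)
  neighbor_joining(D)
}

#' Per-element report table
#'
#' One row per element with 1-based inclusive output coordinates.
#'
#' @param elements list of `element_model`s.
#' @return a data frame.
#' @export
report_table <- function(elements) {
  if (length(elements) == 0L)
    return(data.frame(element_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      superfamily = character(), completeness = character(),
                      clade = character(), family_id = character(),
                      domains = character(), frameshift = logical(),
                      repeat_kind = character(), repeat_identity = numeric()))
  do.call(rbind, lapply(elements, function(el) {
    iv <- el$outer_interval
    data.frame(
      element_id = el$id %||% NA_character_, seq_id = iv$seq_id,
      start = iv$start + 1L, end = iv$end, strand = iv$strand,
      superfamily = el$superfamily, completeness = el$completeness,
      clade = el$clade, family_id = el$family_id %||% NA_character_,
      domains = paste(sort(core_classes(el$core)), collapse = "+"),
      frameshift = isTRUE(el$core$has_frameshift),
      repeat_kind = el$repeats$kind,
      repeat_identity = el$repeats$identity_A %||% NA_real_,
      stringsAsFactors = FALSE)
  }))
}

write_outputs <- function(res, out_dir, genomes) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seq_lengths <- setNames(vapply(genomes, `[[`, 0L, "length"),
                          vapply(genomes, `[[`, "", "id"))
  write_gff3(res$elements, file.path(out_dir, "elements.gff3"), seq_lengths)
  write.table(res$report, file.path(out_dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$families)) {
    fam <- do.call(rbind, lapply(res$families, function(cl)
      data.frame(element_id = cl$member_ids,
                 family_id = cl$representative_id,
                 representative = cl$member_ids == cl$representative_id)))
    write.table(fam, file.path(out_dir, "families.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$graph))
    write.table(res$graph$edges, file.path(out_dir, "graph_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$layout))
    write.table(data.frame(id = rownames(res$layout), res$layout),
                file.path(out_dir, "layout.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(res$tree))
    write_newick(res$tree, file.path(out_dir, "representatives.nwk"))
  yaml::write_yaml(unclass(res$config), file.path(out_dir, "config.yaml"))
  invisible(NULL)
}

#' @export
print.yr_annotation <- function(x, ...) {
  cat("<yr_annotation>\n")
  cat(sprintf("  elements: %d\n", length(x$elements)))
  if (length(x$elements) > 0L) {
    sf <- table(vapply(x$elements, `[[`, "", "superfamily"))
    cat("  superfamilies:",
        paste(names(sf), sf, sep = "=", collapse = ", "), "\n")
    cm <- table(vapply(x$elements, `[[`, "", "completeness"))
    cat("  completeness:",
        paste(names(cm), cm, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$families))
    cat(sprintf("  families: %d\n", length(x$families)))
  if (!is.null(x$components))
    cat(sprintf("  graph components: %d\n", length(x$components)))
  if (!is.null(x$tree))
    cat(sprintf("  representative tree: %d tips\n", length(x$tree$tip.label)))
  invisible(x)
}

#' @method summary yr_annotation
#' @export
summary.yr_annotation <- function(object, ...) {
  print(object)
  if (length(object$elements) > 0L) {
    cl <- table(vapply(object$elements, `[[`, "", "clade"))
    cat("  clades:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
    cat(sprintf("  RT/RH parity: %d RT-bearing, %d RH-bearing (%d flagged)\n",
                object$qc$n_rt, object$qc$n_rh, object$qc$n_flagged))
  }
  invisible(object)
}
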