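# End-to-end pipeline driver and configuration. Defaults are the
# analysis protocol's printed parameters: 50 bp minimum repeat length,
# exact repeats, 3,000 bp junction flanks, 1,800 bp dual-flank overlap,
# 95% full-length threshold, 70% organelle query coverage.

#' Pipeline configuration
#'
#' @param min_repeat_len minimum dispersed-repeat length, bp.
#' @param min_identity repeat identity threshold (1 = exact).
#' @param flank_len junction flank length, bp.
#' @param min_flank_overlap dual-flank overlap rule, bp.
#' @param full_length_threshold full-length linear alignment fraction.
#' @param organelle_query_coverage mitochondrial read retention bar.
#' @param max_events recombination events per enumerated form.
#' @param k,stride aligner anchor parameters.
#' @param seed master seed for simulation stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_repeat_len = 50L, min_identity = 1.0,
                            flank_len = 3000L, min_flank_overlap = 1800L,
                            full_length_threshold = 0.95,
                            organelle_query_coverage = 0.70,
                            max_events = 2L, k = 15L, stride = 5L,
                            seed = 1L) {
  stopifnot(min_flank_overlap <= flank_len,
            full_length_threshold > 0, full_length_threshold <= 1,
            organelle_query_coverage > 0, organelle_query_coverage <= 1)
  structure(list(min_repeat_len = as.integer(min_repeat_len),
                 min_identity = min_identity,
                 flank_len = as.integer(flank_len),
                 min_flank_overlap = as.integer(min_flank_overlap),
                 full_length_threshold = full_length_threshold,
                 organelle_query_coverage = organelle_query_coverage,
                 max_events = as.integer(max_events),
                 k = as.integer(k), stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# flat key-value run manifest
.write_manifest <- function(path, config, extra = character()) {
  kv <- c(sprintf("package=circrecomb"),
          sprintf("version=%s",
                  tryCatch(as.character(utils::packageVersion("circrecomb")),
                           error = function(e) "dev")),
          sprintf("%s=%s", names(unclass(config)),
                  vapply(unclass(config), format, character(1))),
          extra)
  writeLines(kv, path)
  invisible(path)
}

#' Run the full repeat-rearrangement pipeline on a simulation scenario
#'
#' Generates (or accepts) a planted genome, detects its dispersed
#' repeats, enumerates the isomeric forms reachable through the large
#' repeat pairs, simulates an isomer-mixture long-read set, classifies
#' junction-spanning reads for every unshadowed repeat pair, and runs
#' the full-length read accounting against the master circle and the
#' doubly-rearranged alternative. All reports are written under
#' `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param genome optional [circular_sequence()]; default: the
#'   [preset_genome()] preset generated from `config$seed`.
#' @param mixture named form-proportion vector for the read simulation;
#'   the default emulates roughly equimolar flip-flop at the large IR
#'   and a strongly rearranged large DR.
#' @param n_reads reads to simulate.
#' @param sim_args extra arguments to [read_sim_spec()] (error rates,
#'   length distribution).
#' @return (invisibly) list with `catalog`, `forms`, `support`,
#'   `full_length`, `paths`.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         genome = NULL,
                         mixture = c(MC1 = 0.11, MC2 = 0.11,
                                     `MC1^2` = 0.40, `MC2^2` = 0.38),
                         n_reads = 1000L, sim_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  if (is.null(genome)) {
    genome <- preset_genome(seed = config$seed)$genome
  }
  write_fasta(list(genome), p("genome.fasta"))

  catalog <- find_dispersed_repeats(genome, min_len = config$min_repeat_len,
                                    min_identity = config$min_identity)
  write_catalog_tsv(catalog, p("repeat_catalog.tsv"), p("repeat_nesting.tsv"))

  pairs <- catalog_pairs(catalog)
  shadowed <- pairs[pairs$shadowed, , drop = FALSE]
  for (nm in shadowed$pair_name) {
    message("skipping shadowed pair ", nm,
            " (junction evidence indistinguishable from the outer family)")
  }
  active <- pairs[!pairs$shadowed, , drop = FALSE]

  # forms via the two largest-pair events (flip-flop + fission)
  big <- active[active$family_id %in% c(1L, 2L), , drop = FALSE]
  forms <- enumerate_forms(genome, catalog, active_pairs = big,
                           max_events = config$max_events)
  write_forms(forms, p("forms.fasta"), p("forms_manifest.tsv"))
  form_names <- vapply(forms, `[[`, character(1), "name")

  mixture <- mixture[names(mixture) %in% form_names]
  mixture <- mixture / sum(mixture)
  sim <- do.call(read_sim_spec,
                 c(list(n_reads = n_reads, seed = config$seed + 1L),
                   sim_args))
  simd <- simulate_reads(forms, mixture, sim)
  write_fastq(simd$reads, p("reads.fastq.gz"))
  write_tsv_report(simd$truth, p("reads_truth.tsv"))

  labels <- list()
  for (i in seq_len(nrow(active))) {
    pr <- .resolve_pair(catalog, active[i, , drop = FALSE])
    jset <- build_junctions(genome, pr, flank_len = config$flank_len)
    write_junctions_fasta(jset, p(sprintf("junctions_%s.fasta",
                                          gsub("[^A-Za-z0-9_-]", "_",
                                               pr$name))))
    cls <- classify_reads(simd$reads, jset,
                          min_flank_overlap = config$min_flank_overlap,
                          k = config$k, stride = config$stride)
    labels[[pr$name]] <- cls$label
  }
  support <- support_rates(labels,
                           pair_meta = data.frame(pair_name = active$pair_name,
                                                  pair_class = active$pair_class,
                                                  length = active$length))
  write_support_tsv(support, p("support_table.tsv"))

  alt_i <- match("MC2^2", form_names)
  alt <- if (is.na(alt_i)) forms[[length(forms)]] else forms[[alt_i]]
  flr <- full_length_accounting(simd$reads, genome, alt,
                                threshold = config$full_length_threshold,
                                k = config$k, stride = config$stride)
  write_full_length_tsv(flr, p("full_length_report.tsv"))

  .write_manifest(p("run_manifest.txt"), config,
                  extra = c(sprintf("n_reads=%d", n_reads),
                            sprintf("mixture=%s",
                                    paste(names(mixture), mixture, sep = ":",
                                          collapse = ","))))
  invisible(list(catalog = catalog, forms = forms, support = support,
                 full_length = flr,
                 paths = list(out_dir = out_dir)))
}
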