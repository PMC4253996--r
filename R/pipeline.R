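# End-to-end orchestration: identification -> classification ->
# characterization -> expression/specificity -> mimicry & mutants, with
# per-stage TSV outputs and one summary table.

#' Assemble and validate a pipeline configuration
#'
#' Collects input paths, thresholds and seeds. All thresholds must be
#' positive and the tissue groups must partition the expression matrix
#' samples (validated when the pipeline runs).
#'
#' @param paths named list of input paths: `assembled`, `annotation`,
#'   `genome`, `fpkm`, and optionally `repeats`, `srna_loci`,
#'   `conservation`, `mirnas`, `fsts`.
#' @param tissue_groups named list of sample ids.
#' @param min_len,multi_min,single_min,window,min_orf_codons cascade
#'   thresholds (see [run_identification()]).
#' @param js_floor specificity floor for categorization.
#' @param min_identity,upstream_len FST mapping parameters.
#' @param decoy_rules mimicry rule constants from [decoy_rules()].
#' @param n_shuffles,seed neighbor-correlation controls.
#' @return validated config list.
#' @export
pipeline_config <- function(paths, tissue_groups,
                            min_len = 200, multi_min = 0.5, single_min = 2,
                            window = 500, min_orf_codons = 100,
                            js_floor = 0.5, min_identity = 90,
                            upstream_len = 1000,
                            decoy_rules = ricelnc::decoy_rules(),
                            # (namespace-qualified: 'decoy_rules' is also the
                            # argument name)
                            n_shuffles = 1000, seed = 1) {
  need <- c("assembled", "annotation", "genome", "fpkm")
  missing <- setdiff(need, names(paths))
  if (length(missing))
    stop("config lacks required paths: ", paste(missing, collapse = ", "))
  thr <- c(min_len, multi_min, single_min, window, min_orf_codons, js_floor,
           min_identity, upstream_len)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  list(paths = paths, tissue_groups = tissue_groups, min_len = min_len,
       multi_min = multi_min, single_min = single_min, window = window,
       min_orf_codons = min_orf_codons, js_floor = js_floor,
       min_identity = min_identity, upstream_len = upstream_len,
       decoy_rules = decoy_rules, n_shuffles = n_shuffles, seed = seed)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full lncRNA pipeline
#'
#' Reads every input named in the config, runs identification,
#' classification, characterization, tissue-specificity categorization and,
#' when miRNA / FST inputs are present, decoy prediction and mutant mapping.
#' Writes one TSV per stage plus a run summary into `out_dir`. Any stage
#' failure aborts with the stage name and cause. Deterministic for a fixed
#' config (all randomness is seeded from `config$seed`).
#'
#' @param config from [pipeline_config()].
#' @param out_dir output directory.
#' @return list of per-stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  for (p in unlist(config$paths))
    if (!file.exists(p)) stop("input file missing: ", p)

  inp <- stage("read_inputs", {
    genome <- read_fasta(config$paths$genome)
    list(candidates = read_gtf(config$paths$assembled),
         annotation = read_gtf(config$paths$annotation),
         genome = genome,
         fpkm = read_expression(config$paths$fpkm),
         repeats = if (!is.null(config$paths$repeats))
           read_bed(config$paths$repeats),
         srna_loci = if (!is.null(config$paths$srna_loci))
           read_bed(config$paths$srna_loci),
         track = if (!is.null(config$paths$conservation))
           read_bedgraph(config$paths$conservation,
                         stats::setNames(lengths(genome), names(genome))),
         mirnas = if (!is.null(config$paths$mirnas))
           Biostrings::readRNAStringSet(config$paths$mirnas),
         fsts = if (!is.null(config$paths$fsts))
           read_fsts(config$paths$fsts))
  })

  ident <- stage("identification",
    run_identification(inp$candidates, inp$annotation, inp$genome, inp$fpkm,
                       min_len = config$min_len, multi_min = config$multi_min,
                       single_min = config$single_min, window = config$window,
                       min_orf_codons = config$min_orf_codons))
  write_tsv(ident$report, file.path(out_dir, "filter_report.tsv"))

  mrna <- inp$annotation[S4Vectors::mcols(inp$annotation)$biotype ==
                           "known_mRNA"]
  calls <- stage("classification", classify_lnc(ident$lncrna, mrna))
  linc_ids <- calls$id[calls$lnc_class == "lincRNA"]
  linc <- ident$lncrna[linc_ids]
  neigh <- stage("classification",
                 if (length(linc)) neighbor_orientation(linc, mrna) else NULL)
  if (!is.null(neigh))
    calls <- merge(calls, neigh, by = "id", all.x = TRUE, sort = TRUE)
  write_tsv(calls, file.path(out_dir, "classification.tsv"))
  if (length(ident$lncrna)) write_gtf(ident$lncrna,
                                      file.path(out_dir, "lncrna.gtf"))

  sets <- list(lincRNA = ident$lncrna[linc_ids],
               lncNAT = ident$lncrna[setdiff(names(ident$lncrna), linc_ids)],
               mRNA = mrna,
               TE_mRNA = inp$annotation[S4Vectors::mcols(inp$annotation)$biotype
                                        == "TE_mRNA"])
  sets <- sets[lengths(sets) > 0]
  charac <- stage("characterization", {
    rows <- lapply(sets, characterize_set, genome = inp$genome,
                   repeats = inp$repeats, srna_loci = inp$srna_loci,
                   track = inp$track)
    cbind(set = names(rows), do.call(rbind, rows))
  })
  write_tsv(charac, file.path(out_dir, "characterization.tsv"))

  lnc_ids <- names(ident$lncrna)
  spec <- stage("specificity", {
    spec <- js_specificity(inp$fpkm[lnc_ids, , drop = FALSE])
    cats <- categorize(lnc_ids, inp$fpkm, config$tissue_groups,
                       js_floor = config$js_floor)
    merge(spec, cats[, c("id", "category")], by = "id", sort = TRUE)
  })
  write_tsv(spec, file.path(out_dir, "specificity.tsv"))

  decoys <- NULL
  if (!is.null(inp$mirnas) && length(ident$lncrna)) {
    decoys <- stage("mimicry", predict_decoy_sites(
      as.character(spliced_seqs(ident$lncrna, inp$genome)),
      stats::setNames(as.character(inp$mirnas), names(inp$mirnas)),
      rules = config$decoy_rules))
    write_tsv(decoys, file.path(out_dir, "decoy_sites.tsv"))
  }

  mutants <- NULL
  if (!is.null(inp$fsts) && length(linc)) {
    hits <- stage("mutants", map_fst(inp$fsts, linc, inp$genome,
                                     upstream_len = config$upstream_len,
                                     min_identity = config$min_identity))
    mutants <- list(hits = hits, table = tabulate_mutants(hits))
    write_tsv(hits, file.path(out_dir, "mutant_hits.tsv"))
    write_tsv(mutants$table, file.path(out_dir, "mutant_table.tsv"))
  }

  summary <- stage("summary", {
    n_lnc <- length(ident$lncrna)
    med <- expression_summary(lapply(sets, names), inp$fpkm)$medians
    med <- round(med[c("lincRNA", "lncNAT", "mRNA", "TE_mRNA")], 2)
    data.frame(
      quantity = c("candidates", "lncRNAs", "lincRNAs", "lncNATs",
                   "lincRNA_pct", "reproductive", "vegetative", "other",
                   paste0("median_fpkm_", c("lincRNA", "lncNAT", "mRNA",
                                            "TE_mRNA")),
                   "decoy_sites", "decoy_lincRNAs", "mutant_hits"),
      value = c(length(inp$candidates), n_lnc, sum(calls$lnc_class == "lincRNA"),
                sum(calls$lnc_class == "lncNAT"),
                if (n_lnc) percent_of(sum(calls$lnc_class == "lincRNA"),
                                      n_lnc) else NA,
                sum(spec$category == "reproductive"),
                sum(spec$category == "vegetative"),
                sum(spec$category == "other"),
                unname(med),
                if (is.null(decoys)) NA else nrow(decoys),
                if (is.null(decoys)) NA else
                  length(unique(decoys$lncrna_id[decoys$lncrna_id %in%
                                                   linc_ids])),
                if (is.null(mutants)) NA else nrow(mutants$hits)),
      stringsAsFactors = FALSE)
  })
  write_tsv(summary, file.path(out_dir, "summary.tsv"))

  invisible(list(identification = ident, classification = calls,
                 characterization = charac, specificity = spec,
                 decoys = decoys, mutants = mutants, summary = summary))
}
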