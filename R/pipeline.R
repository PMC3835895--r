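#' Default end-to-end run configuration
#'
#' Assembles a complete, validated pipeline configuration. Thresholds
#' default to the standard analysis values: DEG calling at FDR <= 0.001
#' with |log2 ratio| >= 1, GO-style enrichment at corrected P <= 0.05
#' (Bonferroni), KEGG-style at Q <= 0.05 (Benjamini-Hochberg), curation at
#' minimum length 400 bp and minimum ORF 100 aa. Every stochastic stage
#' derives its seed from the single `seed`.
#'
#' @param seed Master seed (required).
#' @param out_dir Output directory.
#' @param sim Named list of overrides for [sim_config()] (all but `seed`).
#' @param annotations Overrides for [generate_annotations()] parameters.
#' @param thresholds Overrides for the analysis thresholds.
#' @param overlap Fraction of the first treatment's spiked genes re-used by
#'   the second treatment (models two exposures hitting an overlapping
#'   response set).
#' @param tpm_denominator `"clean"` or `"unambiguous"`.
#' @param strand_mode Reference strand mode, see [build_tag_index()].
#' @param run_id Label embedded in the summary.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed, out_dir = "tagdge_run",
                       sim = list(), annotations = list(),
                       thresholds = list(), overlap = 0.5,
                       tpm_denominator = "clean",
                       strand_mode = "sense_only",
                       run_id = "run") {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(
        as.integer(seed)))) {
    stop_input("run configuration requires an integer seed")
  }
  sim_defaults <- list(n_genes = 2000L, length_range = c(300L, 2000L),
                       catg_free_fraction = 0.05, library_size = 1e6,
                       error_rate = 0.01, n_contaminant_reads = 1000L,
                       n_up = 100L, n_down = 100L, fold_change = 8,
                       abundance_sdlog = 1)
  ann_defaults <- list(n_terms = 20L, enriched_rate = 0.6,
                       background_rate = 0.05)
  thr_defaults <- list(fdr_max = 0.001, min_abs_log2 = 1,
                       go_alpha = 0.05, kegg_alpha = 0.05,
                       min_len = 400L, min_orf_aa = 100L,
                       min_identity = 0.95, min_coverage = 0.8)
  cfg <- list(run_id = run_id, seed = as.integer(seed), out_dir = out_dir,
              sim = modifyList(sim_defaults, sim),
              annotations = modifyList(ann_defaults, annotations),
              thresholds = modifyList(thr_defaults, thresholds),
              overlap = overlap,
              tpm_denominator = match.arg(tpm_denominator,
                                          c("clean", "unambiguous")),
              strand_mode = match.arg(strand_mode,
                                      c("sense_only", "both")))
  # fail fast on simulator parameters too
  do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  structure(cfg, class = "run_config")
}

## second-treatment truth: re-spike sharing `overlap` of the first
## treatment's up/down sets, remainder drawn from nulls
respike_truth <- function(truth, fold, overlap, seed) {
  truth <- copy(as.data.table(truth))
  up_a <- which(truth$de_label == "up")
  dn_a <- which(truth$de_label == "down")
  nulls <- which(truth$de_label == "null" & !truth$catg_free)
  withr::with_seed(as.integer(seed), {
    keep_up <- sample(up_a, round(overlap * length(up_a)))
    keep_dn <- sample(dn_a, round(overlap * length(dn_a)))
    pool <- sample(nulls)
    new_up <- head(pool, length(up_a) - length(keep_up))
    new_dn <- head(setdiff(pool, new_up), length(dn_a) - length(keep_dn))
    truth[, `:=`(fold_change = 1, de_label = "null")]
    truth[c(keep_up, new_up), `:=`(fold_change = ..fold,
                                   de_label = "up")]
    truth[c(keep_dn, new_dn), `:=`(fold_change = 1 / ..fold,
                                   de_label = "down")]
  })
  truth[]
}

## expression table + accounting sidecar, in plain text
write_expression_bundle <- function(table, prefix) {
  write_tsv(table$expr, paste0(prefix, ".tsv"))
  meta <- c(list(library = table$library,
                 denominator = table$denominator), table$totals)
  jsonlite::write_json(meta, paste0(prefix, ".accounting.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

read_expression_bundle <- function(prefix) {
  expr <- read_tsv(paste0(prefix, ".tsv"))
  meta <- jsonlite::read_json(paste0(prefix, ".accounting.json"),
                              simplifyVector = TRUE)
  totals <- meta[c("clean", "mapped", "unambiguous", "ambiguous",
                   "unmapped", "invalid_length")]
  structure(list(expr = as.data.table(expr), totals = totals,
                 library = meta$library,
                 denominator = meta$denominator %||% NA_character_),
            class = "expression_table")
}

quantify_library <- function(lib, index, denominator) {
  tpm_normalize(map_tags(clean_tags(lib), index), denominator)
}

#' Run the full tag-DGE pipeline on synthetic data
#'
#' Executes simulate -> build-ref -> quant -> de -> intersect -> enrich ->
#' curate with a single configuration, mirroring a three-library design
#' (control plus two exposures with partially overlapping response gene
#' sets). All stage outputs are written as plain text under
#' `config$out_dir` along with `summary.json`; identical configurations
#' produce byte-identical summaries.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"),
              "config must come from run_config()")
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", label,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds

  sim_cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  sim <- stage("simulate", generate_unigenes(sim_cfg))
  truth_b <- respike_truth(sim$truth, sim_cfg$fold_change, config$overlap,
                           config$seed + 10L)
  libs <- stage("simulate", list(
    control = simulate_tag_library(sim, treated = FALSE, config = sim_cfg,
                                   library_seed = config$seed + 1L,
                                   name = "control"),
    treat_a = simulate_tag_library(sim, treated = TRUE, config = sim_cfg,
                                   library_seed = config$seed + 2L,
                                   name = "treat_a"),
    treat_b = simulate_tag_library(sim, truth = truth_b, treated = TRUE,
                                   config = sim_cfg,
                                   library_seed = config$seed + 3L,
                                   name = "treat_b")))
  write_fasta(sim$sequences, file.path(out, "unigenes.fasta"))
  write_tsv(sim$truth, file.path(out, "truth_a.tsv"))
  write_tsv(truth_b, file.path(out, "truth_b.tsv"))
  for (nm in names(libs)) {
    write_tag_library(libs[[nm]], file.path(out, sprintf("tags_%s.tsv", nm)))
  }

  index <- stage("build-ref", build_tag_index(sim, config$strand_mode))
  write_tag_index(index, file.path(out, "reference_tags.tsv"))

  tabs <- stage("quant", lapply(libs, quantify_library, index = index,
                                denominator = config$tpm_denominator))
  for (nm in names(tabs)) {
    write_expression_bundle(tabs[[nm]], file.path(out, paste0("expr_", nm)))
  }

  de <- stage("de", list(
    a = diff_expression(tabs$control, tabs$treat_a, thr$fdr_max,
                        thr$min_abs_log2),
    b = diff_expression(tabs$control, tabs$treat_b, thr$fdr_max,
                        thr$min_abs_log2)))
  write_tsv(de$a, file.path(out, "de_control_vs_a.tsv"))
  write_tsv(de$b, file.path(out, "de_control_vs_b.tsv"))
  common <- stage("intersect", common_degs(de$a, de$b))
  write_tsv(data.table(gene_id = common$common_up, direction = "up"),
            file.path(out, "common_up.tsv"))
  write_tsv(data.table(gene_id = common$common_down, direction = "down"),
            file.path(out, "common_down.tsv"))

  ann <- stage("enrich", do.call(generate_annotations, c(
    list(truth = sim$truth), config$annotations,
    list(seed = config$seed + 4L))))
  write_tsv(ann, file.path(out, "annotations.tsv"))
  enr <- stage("enrich", lapply(de, function(d) {
    degs <- d$gene_id[d$call != "ns"]
    list(go = enrich_terms(ann, degs, correction = "bonferroni",
                           alpha = thr$go_alpha),
         kegg = enrich_terms(ann, degs, correction = "bh",
                             alpha = thr$kegg_alpha))
  }))
  write_tsv(enr$a$go, file.path(out, "enrichment_go_a.tsv"))
  write_tsv(enr$b$go, file.path(out, "enrichment_go_b.tsv"))

  fixtures <- generate_family_fixtures(config$seed + 5L)
  cur <- stage("curate", curate_families(
    fixtures, min_len = thr$min_len, min_orf_aa = thr$min_orf_aa,
    min_identity = thr$min_identity, min_coverage = thr$min_coverage))
  write_tsv(cur, file.path(out, "curation.tsv"))

  deg_counts <- lapply(de, function(d)
    list(up = sum(d$call == "up"), down = sum(d$call == "down")))
  summary <- list(
    run_id = config$run_id,
    config = unclass(config),
    libraries = lapply(tabs, function(tb) tb$totals),
    degs = deg_counts,
    common = list(up = length(common$common_up),
                  down = length(common$common_down)),
    enrichment = lapply(enr, function(e)
      list(go_significant = sum(e$go$significant),
           kegg_significant = sum(e$kegg$significant),
           top_term = e$go$term[1L])),
    curation = as.list(table(cur$disposition)))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}
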