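# Workflow orchestration: generate -> featurize -> evaluate, with
# content-hash caching and a provenance record per run. A thin Rscript
# front-end over these functions ships at inst/cli/ppidstk.R.

write_provenance <- function(dir, command, params, inputs = character(0)) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  prov <- list(command = command, params = params,
               input_md5 = hashes,
               package_version = as.character(utils::packageVersion("ppidstk")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, paste0(command, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Generate a synthetic corpus on disk
#'
#' Writes `corpus.xml`, `trees.txt`, `truth.csv` and a provenance record
#' into `outdir`. Deterministic under `seed`.
#'
#' @param outdir Output directory.
#' @param n Number of sentences.
#' @param pos_fraction,label_noise,distractor_prob,multiword_prob,seed
#'   Passed to [synth_config()].
#' @return Invisibly, the written file paths.
#' @export
cmd_synth <- function(outdir, n = 250L, pos_fraction = 0.4,
                      label_noise = 0, distractor_prob = 0.15,
                      multiword_prob = 0.15, seed = 1L) {
  cfg <- synth_config(n_sentences = n, pos_fraction = pos_fraction,
                      label_noise = label_noise,
                      distractor_prob = distractor_prob,
                      multiword_prob = multiword_prob, seed = seed)
  gen <- generate_corpus(cfg, dir = outdir)
  viol <- validate_corpus(gen$corpus)
  if (nrow(viol) > 0) {
    stop("generator self-check failed: ", nrow(viol), " violations")
  }
  write_provenance(outdir, "synth", unclass(cfg))
  message("wrote ", length(gen$paths), " files to ", outdir)
  invisible(gen$paths)
}

load_corpus_with_trees <- function(corpus_xml, trees_path) {
  corpus <- read_ppi_xml(corpus_xml)
  trees <- read_ptb_trees(trees_path)
  attach_parses(corpus, trees)
}

featurize_cache_key <- function(corpus_xml, trees_path, config) {
  paste0(tools::md5sum(corpus_xml), "-", tools::md5sum(trees_path), "-",
         str_hash(paste(config$lambda, config$d, config$k, config$seed,
                        config$oov, sep = "|")))
}

#' Extract features and DST matrices for a corpus on disk
#'
#' Runs preprocessing, feature extraction, lexicalization and the
#' distributed-tree construction; writes the sparse feature file, the
#' embedding table and a prepared-instance cache keyed by the content
#' hash of the inputs and the kernel parameters. A rerun with unchanged
#' inputs is a cache hit and recomputes nothing.
#'
#' @param corpus_xml Unified PPI XML path.
#' @param trees_path Bracketed parse file path.
#' @param outdir Output directory.
#' @param config A `kernel_config`.
#' @return Invisibly, the path of the prepared-instance cache.
#' @export
cmd_featurize <- function(corpus_xml, trees_path, outdir,
                          config = kernel_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  key <- featurize_cache_key(corpus_xml, trees_path, config)
  cache <- file.path(outdir, paste0("prep-", key, ".rds"))
  if (file.exists(cache)) {
    message("cache hit: ", cache, " (no recompute)")
    return(invisible(cache))
  }
  corpus <- load_corpus_with_trees(corpus_xml, trees_path)
  prep <- prepare_instances(corpus, config)
  ids <- vapply(prep$instances, function(x)
    paste0(x$sentence_id, ":", x$e1, "-", x$e2), character(1))
  write_feature_file(stats::setNames(prep$features, ids),
                     file.path(outdir, "features.tsv"))
  write_embeddings(prep$embeddings, file.path(outdir, "embeddings.txt"))
  saveRDS(prep, cache)
  write_provenance(outdir, "featurize",
                   c(unclass(config), cache_key = key),
                   inputs = c(corpus_xml, trees_path))
  message("featurized ", length(prep$instances), " instances")
  invisible(cache)
}

#' Cross-validate the three kernels on a corpus on disk
#'
#' Runs [cross_validate()] for the requested kernel tags and writes
#' `results.csv`, `results.json`, `roc.csv` and a provenance record.
#'
#' @param corpus_xml Unified PPI XML path.
#' @param trees_path Bracketed parse file path.
#' @param outdir Output directory.
#' @param config A `kernel_config`.
#' @param folds Number of CV folds.
#' @param kernels Kernel tags (`"all"` expands to fea, dstk, ckl).
#' @param seed Fold seed.
#' @param corpus_name Corpus label in the report.
#' @return Invisibly, the reports from [cross_validate()].
#' @export
cmd_evaluate <- function(corpus_xml, trees_path, outdir,
                         config = kernel_config(), folds = 10L,
                         kernels = "all", seed = 1L,
                         corpus_name = "corpus") {
  if (identical(kernels, "all")) kernels <- c("fea", "dstk", "ckl")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  corpus <- load_corpus_with_trees(corpus_xml, trees_path)
  prep <- prepare_instances(corpus, config,
                            need_trees = any(kernels != "fea"))
  reports <- cross_validate(prep, config, folds = folds, seed = seed,
                            kernels = kernels)
  write_results(reports, outdir, corpus_name)
  write_provenance(outdir, "evaluate",
                   c(unclass(config), folds = folds, cv_seed = seed,
                     kernels = list(kernels)),
                   inputs = c(corpus_xml, trees_path))
  for (tag in names(reports)) print(reports[[tag]])
  invisible(reports)
}
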