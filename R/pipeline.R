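## pipeline: end-to-end orchestration with a config file, per-stage caching,
## and a JSON run manifest (written even on partial failure).

default_run_params <- function() {
  list(det_fc = 2, det_q = 0.05, dep_p = 0.01,
       up_fc = 1.2, down_fc = 0.83, sig_rule = "q", sig_cut = 0.05,
       min_count = 7L, q_max = 0.05, aag_threshold = 0.08,
       group_feature = "codon:AAG",
       max_terms = 21L, degree = 1L, max_knots = 50L,
       seed = 1L, id_attribute = "ID",
       min_observed = 3L, protein_replicates = 4L)
}

#' Read and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list.  Required keys: `fasta`, `gff3`,
#' `transcripts`, `proteins`, `control`, `treatments`, `out_dir`; optional:
#' `annotation` (gene/term TSV) and `params` overriding the defaults (DET
#' fold change 2 with BH q < 0.05; DEP t-test p < 0.01; group cutoffs
#' 1.2/0.83 at q < 0.05; enrichment min count 7 at q < 0.05; AAG threshold
#' 0.08).  Unknown keys (top-level or in `params`) are rejected.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated config list with a fully populated `params`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  required <- c("fasta", "gff3", "transcripts", "proteins", "control",
                "treatments", "out_dir")
  allowed <- c(required, "annotation", "params")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stopf("missing config keys: %s", paste(missing, collapse = ", "))
  params <- default_run_params()
  extra <- setdiff(names(config$params %||% list()), names(params))
  if (length(extra))
    stopf("unknown params keys: %s", paste(extra, collapse = ", "))
  config$params <- modifyList(params, config$params %||% list())
  for (f in c("fasta", "gff3", "transcripts", "proteins",
              if (!is.null(config$annotation)) "annotation"))
    if (!file.exists(config[[f]]))
      stopf("input file for '%s' not found: %s", f, config[[f]])
  config$treatments <- as.character(config$treatments)
  config
}

stage_key <- function(input_files, params) {
  md5 <- unname(tools::md5sum(input_files))
  paste(c(md5, as.character(jsonlite::toJSON(params, auto_unbox = TRUE,
                                             digits = NA))),
        collapse = "|")
}

#' Run the full analysis pipeline
#'
#' Executes fold-change derivation, feature extraction, association
#' (correlation + MARS contribution + OLS/elastic-net verification), group
#' statistics and (when an annotation map is supplied) enrichment, for each
#' treatment against the control, writing stage outputs beneath `out_dir`
#' and a `manifest.json` recording the config, per-stage input checksums,
#' wall-clock seconds and warnings.  Re-runs skip stages whose inputs and
#' parameters are unchanged and whose outputs still exist; `force = TRUE`
#' disables the cache.  On stage failure the manifest is still written, with
#' the failing stage identified, and earlier outputs retained.
#'
#' @param config Config path or list, see [read_run_config()].
#' @param force Recompute every stage.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, force = FALSE) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- NULL
  if (file.exists(manifest_path) && !force)
    prev <- tryCatch(jsonlite::read_json(manifest_path), error = function(e) NULL)
  manifest <- list(
    tool = "codoncontrib",
    version = as.character(packageVersion("codoncontrib")),
    config = cfg, stages = list(), status = "running")
  state <- new.env(parent = emptyenv())

  get_catalog <- function() {
    if (is.null(state$catalog))
      state$catalog <- load_catalog(cfg$fasta, cfg$gff3,
                                    id_attribute = cfg$params$id_attribute)
    state$catalog
  }

  run_stage <- function(name, input_files, params, outputs, fun) {
    key <- stage_key(input_files, params)
    cached <- FALSE
    if (!force && !is.null(prev$stages[[name]]$key) &&
        identical(prev$stages[[name]]$key, key) &&
        all(file.exists(outputs))) {
      cached <- TRUE
    }
    t0 <- proc.time()[["elapsed"]]
    warnings <- character(0)
    if (!cached) {
      withCallingHandlers(
        tryCatch(fun(), error = function(e)
          stopf("stage '%s' failed: %s", name, conditionMessage(e))),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    manifest$stages[[name]] <<- list(
      key = key, inputs = as.list(input_files), outputs = as.list(outputs),
      cached = cached, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      warnings = warnings)
    invisible(NULL)
  }

  finish <- function(status, error = NULL) {
    manifest$status <<- status
    if (!is.null(error)) manifest$error <<- error
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  p <- cfg$params
  result <- tryCatch({
    for (trt in cfg$treatments) {
      fc_path <- file.path(out_dir, sprintf("fc_%s.tsv", trt))
      run_stage(paste0("foldchange_", trt),
                c(cfg$transcripts, cfg$proteins),
                c(p[c("det_fc", "det_q", "dep_p", "min_observed",
                      "protein_replicates")],
                  list(control = cfg$control, treatment = trt)),
                fc_path, function() {
        tr <- read_expression(cfg$transcripts)
        pr <- filter_and_impute_protein(read_expression(cfg$proteins),
                                        min_observed = p$min_observed,
                                        replicates = p$protein_replicates)
        fc <- build_fc_table(tr, pr, cfg$control, trt,
                             det_fc = p$det_fc, det_q = p$det_q,
                             dep_p = p$dep_p)
        message(sprintf("[%s] %d genes quantified, %d DET, %d DEP",
                        trt, nrow(fc), sum(fc$det), sum(fc$dep)))
        write_tsv(fc, fc_path)
      })

      feat_path <- file.path(out_dir, sprintf("features_%s.tsv", trt))
      reg_path <- file.path(out_dir, "registry.tsv")
      run_stage(paste0("features_", trt),
                c(cfg$fasta, cfg$gff3, fc_path),
                p["id_attribute"], c(feat_path, reg_path), function() {
        fc <- read_fc_table(fc_path)
        fm <- build_feature_matrix(get_catalog(),
                                   setNames(fc$transcript_fc, fc$gene_id))
        message(sprintf("[%s] feature matrix: %d genes x %d features",
                        trt, nrow(fm$values), ncol(fm$values)))
        write_features(fm, feat_path, reg_path)
      })

      assoc_files <- file.path(out_dir, sprintf(
        c("correlation_%s.tsv", "contribution_%s.tsv",
          "contribution_categories_%s.tsv", "importance_%s.tsv",
          "model_%s.json", "verification_%s.tsv"), trt))
      run_stage(paste0("associate_", trt), c(feat_path, fc_path),
                p[c("max_terms", "degree", "max_knots", "seed")],
                assoc_files, function() {
        fm <- read_features(feat_path, reg_path)
        fc <- read_fc_table(fc_path)
        res <- associate(fm, fc, max_terms = p$max_terms, degree = p$degree,
                         max_knots = p$max_knots, seed = p$seed)
        write_tsv(res$correlation, assoc_files[1])
        write_tsv(res$contribution$features, assoc_files[2])
        cats <- rbind(res$contribution$categories,
                      data.frame(category = "unexplained",
                                 contribution_pct = res$contribution$unexplained_pct))
        write_tsv(cats, assoc_files[3])
        write_tsv(res$importance, assoc_files[4])
        write_mars_json(res$model, assoc_files[5])
        write_tsv(res$verification, assoc_files[6])
        message(sprintf("[%s] explained %.1f%%", trt,
                        res$contribution$total_explained_pct))
      })

      group_files <- file.path(out_dir, sprintf(
        c("groups_%s.tsv", "group_test_%s.tsv"), trt))
      run_stage(paste0("groups_", trt), c(feat_path, fc_path),
                p[c("up_fc", "down_fc", "sig_rule", "sig_cut",
                    "group_feature")],
                group_files, function() {
        fm <- read_features(feat_path, reg_path)
        fc <- read_fc_table(fc_path)
        gs <- assign_groups(fc, up_fc = p$up_fc, down_fc = p$down_fc,
                            sig_rule = p$sig_rule, sig_cut = p$sig_cut,
                            whole_genome = catalog_genes(get_catalog()))
        gc <- group_summary(gs, fm, feature_name = p$group_feature,
                            seed = p$seed)
        write_tsv(gc$summary, group_files[1])
        tst <- gc$test
        write_tsv(data.frame(feature = p$group_feature, H = tst$H,
                             df = tst$df, tie_correction = tst$tie_correction,
                             p = tst$p, method = tst$method),
                  group_files[2])
      })

      if (!is.null(cfg$annotation)) {
        enr_files <- file.path(out_dir, sprintf(
          c("enrich_aag_%s.tsv", "enrich_dep_up_%s.tsv"), trt))
        run_stage(paste0("enrich_", trt),
                  c(cfg$annotation, feat_path, fc_path),
                  p[c("min_count", "q_max", "aag_threshold", "up_fc",
                      "sig_rule", "sig_cut")],
                  enr_files, function() {
          annot <- read_annotation_map(cfg$annotation)
          fm <- read_features(feat_path, reg_path)
          fc <- read_fc_table(fc_path)
          universe <- intersect(rownames(fm$values),
                                unique(unlist(annot$terms)))
          aag <- intersect(aag_rich_set(fm, p$aag_threshold), universe)
          e1 <- if (length(aag)) enrich(aag, universe, annot,
                                        min_count = p$min_count,
                                        q_max = p$q_max)
                else data.frame()
          write_tsv(e1, enr_files[1])
          gs <- assign_groups(fc, up_fc = p$up_fc, down_fc = p$down_fc,
                              sig_rule = p$sig_rule, sig_cut = p$sig_cut)
          up <- intersect(gs$groups$up, universe)
          e2 <- if (length(up)) enrich(up, universe, annot,
                                       min_count = p$min_count,
                                       q_max = p$q_max)
                else data.frame()
          write_tsv(e2, enr_files[2])
        })
      }
    }

    ## combined cross-treatment contribution comparison
    cmp_path <- file.path(out_dir, "comparison.tsv")
    contrib_paths <- file.path(out_dir,
                               sprintf("contribution_%s.tsv", cfg$treatments))
    run_stage("comparison", contrib_paths, list(), cmp_path, function() {
      tabs <- lapply(seq_along(cfg$treatments), function(i) {
        df <- read_tsv(contrib_paths[i])
        names(df)[names(df) == "contribution_pct"] <-
          paste0("contribution_pct_", cfg$treatments[i])
        df
      })
      cmp <- Reduce(function(a, b) merge(a, b, by = c("feature", "category"),
                                         all = TRUE), tabs)
      write_tsv(cmp[order(-cmp[[3]]), ], cmp_path)
    })
    finish("ok")
    manifest
  }, error = function(e) {
    finish("failed", conditionMessage(e))
    stop(e)
  })
  invisible(result)
}

#' Read a fold-change table written by the pipeline
#'
#' @param path TSV from [build_fc_table()] output.
#' @return data.frame.
#' @export
read_fc_table <- function(path) {
  df <- tryCatch(read_tsv(path), error = function(e)
    stopf("failed to read fold-change table '%s': %s", path,
          conditionMessage(e)))
  need <- c("gene_id", "transcript_fc", "protein_fc")
  if (!all(need %in% names(df)))
    stopf("'%s' is not a valid fold-change table (missing %s)", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  df
}
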