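#' Run the complete study replica
#'
#' Executes all stages in order on a synthetic cohort: simulate plates, fit
#' standard curves, quantify to copies/mL, exclude hemolysed samples, apply
#' the 500 copies/mL expression filter (computed on the Discovery cohort),
#' normalize by the global geometric mean, test differential expression on
#' Discovery, run the focused and unbiased panel searches over the requested
#' panel sizes, pick the optimal panel by Validation AUC (ties prefer the
#' smaller panel, then the unbiased strategy), and evaluate the frozen
#' optimal model: Discovery/Validation AUC, AUC with normal-mammogram
#' controls added, both operating points, and score trends across tumour
#' size, stage and nodal classes.
#'
#' Normal-mammogram samples are never used for training or panel selection —
#' they enter evaluation only.
#'
#' @param config A [cohort_config()].
#' @param k_range Panel sizes to sweep (default 2:8).
#' @param rounds Cross-validation rounds per search (default 200).
#' @param seed Master seed (defaults to `config$seed`).
#' @param strategies Subset of `c("focused", "unbiased")`.
#' @param min_copies Expression-filter threshold (copies/mL).
#' @param de_alpha FDR level for the focused candidate set.
#' @param n_perm_trend Permutations for the trend tests.
#' @param out_dir Optional directory; when given, all result tables, the
#'   optimal model and a run manifest are written there.
#' @param verbose Print stage progress.
#' @return A list of class `mirna_study` with elements `config`, `curves`,
#'   `expression`, `qc`, `retained`, `normalized`, `de`, `searches`
#'   (per strategy/size), `panel_summary`, `optimal`, `evaluation`, `trends`,
#'   `manifest`.
#' @export
run_study <- function(config, k_range = 2:8, rounds = 200L,
                      seed = config$seed,
                      strategies = c("focused", "unbiased"),
                      min_copies = 500, de_alpha = 0.05,
                      n_perm_trend = 10000L,
                      out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  strategies <- match.arg(strategies, several.ok = TRUE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    timings[stage] <<- el
    if (verbose) message(sprintf("[%s] done in %.1fs", stage, el))
    res
  }

  standards <- tick("simulate-standards", generate_standard_curve_plate(config))
  cohort <- tick("simulate-cohort", generate_cohort(config))
  curves <- tick("fit-curves", fit_standard_curves(standards$ct))
  expr <- tick("quantify",
               quantify(cohort$ct, curves, floor_ct = config$ct_ceiling))
  qc <- tick("qc-hemolysis", flag_hemolysis(expr))

  ann <- cohort$annotations
  excluded <- qc$sample_id[!is.na(qc$hemolysed_call) & qc$hemolysed_call]
  clean <- setdiff(rownames(expr$values), excluded)
  ann <- ann[match(clean, ann$sample_id), , drop = FALSE]
  ids <- function(cohort_name) ann$sample_id[ann$cohort %in% cohort_name]
  disc <- ids("discovery"); val <- ids("validation"); nrm <- ids("normal")

  retained <- tick("expression-filter",
                   expression_filter(expr$values[disc, , drop = FALSE],
                                     min_copies = min_copies))
  norm <- tick("normalize",
               global_geomean_normalize(expr$values[clean, , drop = FALSE],
                                        retained = retained))
  lab <- stats::setNames(ann$diagnosis == "malignant", ann$sample_id)
  de <- tick("differential-expression",
             differential_expression(norm[disc, , drop = FALSE], lab[disc],
                                     alpha = de_alpha))

  cand <- list()
  if ("focused" %in% strategies)
    cand$focused <- tryCatch(focused_candidates(de, alpha = de_alpha),
                             error = function(e) {
                               if (verbose) message("focused strategy skipped: ",
                                                    conditionMessage(e))
                               NULL
                             })
  if ("unbiased" %in% strategies) cand$unbiased <- unbiased_candidates(retained)

  searches <- list()
  summary_rows <- list()
  for (strat in names(cand)) {
    cd <- cand[[strat]]
    if (is.null(cd)) next
    for (k in k_range) {
      if (k > length(cd)) {
        if (verbose) message(sprintf("%s k=%d skipped (only %d candidates)",
                                     strat, k, length(cd)))
        next
      }
      key <- sprintf("%s-k%d", strat, k)
      res <- tick(paste0("search-", key),
                  cv_panel_search(norm[disc, , drop = FALSE], lab[disc],
                                  cd, k = k, rounds = rounds,
                                  seed = child_seed(seed, key)))
      res$strategy <- strat
      val_auc <- auc_rank(score_panel(res$model, norm[val, , drop = FALSE]),
                          lab[val])
      searches[[key]] <- res
      summary_rows[[key]] <- data.frame(
        strategy = strat, k = k,
        median_cv_auc = res$median_auc,
        resubstitution_auc = res$resubstitution_auc,
        validation_auc = val_auc,
        panel = paste(res$model$mirnas, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(searches)) stop("no panel search completed")
  panel_summary <- do.call(rbind, summary_rows)
  rownames(panel_summary) <- NULL

  # optimal panel: maximise Validation AUC; ties (within 1e-6) prefer the
  # smaller panel, then the unbiased strategy
  ps <- panel_summary
  ps$strat_pref <- ifelse(ps$strategy == "unbiased", 0L, 1L)
  ord <- order(-round(ps$validation_auc / 1e-6), ps$k, ps$strat_pref)
  best <- ps[ord[1], ]
  optimal <- searches[[sprintf("%s-k%d", best$strategy, best$k)]]

  model <- optimal$model
  eval_disc <- evaluate_frozen(model, norm[disc, , drop = FALSE], lab[disc])
  eval_val <- evaluate_frozen(model, norm[val, , drop = FALSE], lab[val])
  vn <- c(val, nrm)
  eval_val_norm <- evaluate_frozen(model, norm[vn, , drop = FALSE], lab[vn])
  pooled_mal <- ann$sample_id[ann$diagnosis == "malignant"]
  pooled_scores <- score_panel(model, norm[pooled_mal, , drop = FALSE])
  trend_of <- function(col, levels_order) {
    v <- ann[[col]][match(pooled_mal, ann$sample_id)]
    g <- factor(v, levels = levels_order, ordered = TRUE)
    tryCatch(trend_by_group(pooled_scores, g, n_perm = n_perm_trend,
                            seed = child_seed(seed, paste0("trend-", col))),
             error = function(e) list(error = conditionMessage(e)))
  }
  trends <- tick("trends", list(
    size_class = trend_of("size_class", c("<=10mm", "11-20mm", ">20mm")),
    stage = trend_of("stage", c("0", "1", "2", "3")),
    node_class = trend_of("node_class", c("0", "1-3", ">3"))))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mirpanel")),
    seed = seed,
    config = unclass(config),
    n_samples = c(discovery = length(disc), validation = length(val),
                  normal = length(nrm), excluded_hemolysis = length(excluded)),
    n_retained = length(retained),
    rounds = rounds, k_range = k_range,
    optimal = list(strategy = best$strategy, k = best$k,
                   panel = model$mirnas),
    timings = timings)

  bundle <- structure(list(
    config = config, curves = curves, expression = expr, qc = qc,
    annotations = ann, retained = retained, normalized = norm,
    labels = lab, sample_sets = list(discovery = disc, validation = val,
                                     normal = nrm, excluded = excluded),
    de = de, candidates = cand, searches = searches,
    panel_summary = panel_summary, optimal = optimal,
    evaluation = list(discovery = eval_disc, validation = eval_val,
                      validation_plus_normals = eval_val_norm),
    trends = trends, manifest = manifest), class = "mirna_study")

  if (!is.null(out_dir)) write_study(bundle, out_dir)
  bundle
}

#' Write a study bundle's result tables to a directory
#'
#' Emits CSV tables (annotations, QC report, standard curves, expression,
#' differential expression, panel summary, per-round CV logs), the optimal
#' panel model as flat JSON, and a JSON run manifest including MD5 digests of
#' every written file.
#'
#' @param bundle A `mirna_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mirna_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_annotations(bundle$annotations, fp("annotations.csv"))
  utils::write.csv(bundle$qc, fp("qc_report.csv"), row.names = FALSE)
  write_standard_curves(bundle$curves, fp("standard_curves.csv"))
  write_expression_matrix(bundle$expression, fp("expression_copies_per_ml.csv"))
  write_expression_matrix(bundle$normalized, fp("expression_normalized_log2.csv"))
  utils::write.csv(bundle$de, fp("differential_expression.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$panel_summary, fp("panel_summary.csv"),
                   row.names = FALSE)
  rounds <- do.call(rbind, lapply(names(bundle$searches), function(key) {
    d <- bundle$searches[[key]]$rounds
    d$strategy <- bundle$searches[[key]]$strategy
    d$k <- bundle$searches[[key]]$k
    d
  }))
  utils::write.csv(rounds, fp("cv_rounds.csv"), row.names = FALSE)
  write_panel_model(bundle$optimal$model, fp("optimal_panel.json"))
  ev <- bundle$evaluation
  eval_rows <- do.call(rbind, lapply(names(ev), function(nm) {
    data.frame(evaluation_set = nm, auc = ev[[nm]]$auc,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(eval_rows, fp("evaluation_auc.csv"), row.names = FALSE)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- bundle$manifest
  manifest$file_digests <- as.list(tools::md5sum(sort(files)))
  names(manifest$file_digests) <- basename(names(manifest$file_digests))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(fp("manifest.json"))
}

#' @export
print.mirna_study <- function(x, ...) {
  cat("miRNA biomarker study replica\n")
  cat(sprintf("  retained miRNAs: %d; excluded (hemolysis): %d\n",
              length(x$retained), length(x$sample_sets$excluded)))
  cat(sprintf("  optimal panel: %s k=%d (%s)\n",
              x$optimal$strategy, x$optimal$k,
              paste(x$optimal$model$mirnas, collapse = ", ")))
  cat(sprintf("  AUC discovery %.3f | validation %.3f | validation+normals %.3f\n",
              x$evaluation$discovery$auc, x$evaluation$validation$auc,
              x$evaluation$validation_plus_normals$auc))
  invisible(x)
}
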