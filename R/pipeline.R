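#' Assemble a pipeline configuration
#'
#' Collects file paths and every stage parameter, with defaults, into a
#' validated list consumed by [run_pipeline()]. A second (validation)
#' cohort and a GMT collection are optional; the corresponding stages are
#' skipped when they are absent.
#'
#' @param matrix_path Path to the discovery intensity matrix.
#' @param annotation_path Path to its sample annotation TSV.
#' @param out_dir Output directory (created if needed).
#' @param format `"tsv"` ([read_intensity_tsv()]) or `"maxquant"`
#'   ([read_protein_groups()]).
#' @param gmt_path Optional GMT collection for the ORA and GSEA stages.
#' @param validation_matrix_path,validation_annotation_path Optional
#'   independent cohort scored with the discovery signature.
#' @param alpha,min_detect,pseudocount,test Differential-stage parameters
#'   (see [differential_table()]).
#' @param include_exclusive Passed to [define_signature()].
#' @param min_coverage Passed to [mean_signature_score()].
#' @param metric,n_perm,perm_type GSEA-stage parameters.
#' @param seed Integer master seed; stage seeds are derived by fixed
#'   offsets so each stage reproduces independently of execution order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path, annotation_path, out_dir,
                            format = c("tsv", "maxquant"),
                            gmt_path = NULL,
                            validation_matrix_path = NULL,
                            validation_annotation_path = NULL,
                            alpha = 0.05, min_detect = 1L, pseudocount = 1e-8,
                            test = "welch_t", include_exclusive = FALSE,
                            min_coverage = 0.5, metric = "signal_to_noise",
                            n_perm = 1000L, perm_type = "gene_set",
                            seed = 1L) {
  structure(list(matrix_path = matrix_path, annotation_path = annotation_path,
                 out_dir = out_dir, format = match.arg(format),
                 gmt_path = gmt_path,
                 validation_matrix_path = validation_matrix_path,
                 validation_annotation_path = validation_annotation_path,
                 alpha = alpha, min_detect = min_detect,
                 pseudocount = pseudocount, test = test,
                 include_exclusive = include_exclusive,
                 min_coverage = min_coverage, metric = metric,
                 n_perm = as.integer(n_perm), perm_type = perm_type,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes quantify -> differential -> (validation, if a second cohort
#' is configured) -> ORA -> GSEA (both only if a GMT is configured),
#' writing `diff.tsv`, `sig.txt`, `validation.json`, `ora.tsv`,
#' `gsea.tsv`, and `run_log.txt` under `config$out_dir`. Any stage error
#' is re-raised with the stage name; outputs of completed stages are
#' retained. The ORA query is the up-signature against the detected
#' proteome as background; GSEA ranks the validation cohort when one is
#' configured (mirroring signature-activity checks on independent data)
#' and the discovery cohort otherwise.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(sprintf("vitreomics %s",
                         as.character(utils::packageVersion("vitreomics"))),
                 "effective config:",
                 vapply(names(unclass(config)), function(k) {
                   sprintf("  %s = %s", k,
                           paste(format(config[[k]] %||% "NULL"), collapse = ","))
                 }, character(1)))
  writeLines(log_lines, log_path)

  ifot <- NULL; ann <- NULL
  stage_run("quantify", {
    mat <- if (config$format == "maxquant") {
      read_protein_groups(config$matrix_path)
    } else {
      read_intensity_tsv(config$matrix_path)
    }
    ann <- read_sample_annotation(config$annotation_path)
    ifot <- ifot_normalize(mat)
  })

  diff_tbl <- NULL; sig <- NULL
  stage_run("diff", {
    diff_tbl <- differential_table(ifot, ann, alpha = config$alpha,
                                    min_detect = config$min_detect,
                                    pseudocount = config$pseudocount,
                                    method = config$test)
    sig <- define_signature(diff_tbl, alpha = config$alpha,
                             include_exclusive = config$include_exclusive)
    readr::write_tsv(dplyr::select(diff_tbl, -dplyr::any_of("statistic")),
                     file.path(config$out_dir, "diff.tsv"), progress = FALSE)
    writeLines(sig$up, file.path(config$out_dir, "sig.txt"))
  })

  validation <- NULL
  val_log <- NULL; val_ann <- NULL
  if (!is.null(config$validation_matrix_path)) {
    stage_run("validate", {
      vmat <- read_intensity_tsv(config$validation_matrix_path)
      val_ann <- read_sample_annotation(config$validation_annotation_path)
      vifot <- ifot_normalize(vmat)
      val_log <- log_transform(vifot, config$pseudocount)
      z <- zscore_by_protein(val_log)
      scores <- mean_signature_score(z, sig, config$min_coverage)
      joined <- dplyr::inner_join(scores, val_ann, by = "sample")
      mw <- mann_whitney_u(joined$score[joined$group == "case"],
                           joined$score[joined$group == "control"],
                           alternative = "greater")
      roc <- roc_auc(joined)
      validation <- list(scores = scores, coverage = attr(scores, "coverage"),
                          mwu = mw, roc = roc)
      jsonlite::write_json(
        list(coverage = attr(scores, "coverage"),
             scores = joined,
             u = mw$u, p_value = mw$p_value, auc = roc$auc,
             roc_points = roc$points),
        file.path(config$out_dir, "validation.json"),
        auto_unbox = TRUE, digits = NA)
    })
  }

  ora <- NULL; gsea <- NULL
  if (!is.null(config$gmt_path)) {
    collection <- NULL
    stage_run("ora", {
      if (!file.exists(config$gmt_path)) {
        abort(sprintf("GMT file not found: %s", config$gmt_path))
      }
      collection <- read_gmt(config$gmt_path)
      part <- attr(diff_tbl, "partition")
      background <- c(part$only_case, part$only_control, part$shared)
      ora <- fisher_enrich(sig$up, collection, background)
      readr::write_tsv(dplyr::mutate(ora, overlap_genes =
                                       purrr::map_chr(.data$overlap_genes,
                                                      paste, collapse = ";")),
                       file.path(config$out_dir, "ora.tsv"), progress = FALSE)
    })
    stage_run("gsea", {
      if (is.null(val_log)) {
        ranked <- rank_genes(log_transform(ifot, config$pseudocount), ann,
                             metric = config$metric)
      } else {
        ranked <- rank_genes(val_log, val_ann, metric = config$metric)
      }
      gsea <- run_gsea_collection(ranked, collection, n_perm = config$n_perm,
                                   seed = config$seed + 101L,
                                   perm_type = config$perm_type)
      readr::write_tsv(dplyr::mutate(gsea, leading_edge =
                                       purrr::map_chr(.data$leading_edge,
                                                      paste, collapse = ";")),
                       file.path(config$out_dir, "gsea.tsv"), progress = FALSE)
    })
  }

  cat(sprintf("completed: %s\n",
              paste(c("quantify", "diff",
                      if (!is.null(validation)) "validate",
                      if (!is.null(ora)) "ora",
                      if (!is.null(gsea)) "gsea"), collapse = ", ")),
      file = log_path, append = TRUE)
  invisible(list(ifot = ifot, differential = diff_tbl, signature = sig,
                 validation = validation, ora = ora, gsea = gsea,
                 out_dir = config$out_dir))
}
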