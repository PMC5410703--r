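# serialise an R list of plain values exactly (hex floats) so a run's
# configuration round-trips byte-for-byte
deparse_exact <- function(x) {
  paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames",
                               "showAttributes", "hexNumeric")),
        collapse = " ")
}

#' Write / read a pipeline run configuration
#'
#' Key-value text serialisation of a [run_config()]; numeric values are
#' stored in hex notation so the restored configuration reproduces the
#' run exactly.
#'
#' @param config a run configuration list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", deparse_exact(config[[k]])), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  config <- list()
  for (ln in lines) {
    k <- sub(" = .*$", "", ln)
    v <- sub("^[^=]+ = ", "", ln)
    config[[k]] <- eval(parse(text = v), envir = baseenv())
  }
  config
}

#' Assemble a pipeline run configuration
#'
#' @param sim_config a [simulation_config()] describing the synthetic
#'   methylome (or `NULL` when `allc`/`genes` paths are given).
#' @param allc,genes optional paths to an existing call table and
#'   annotation, used instead of simulation.
#' @param flank_bp metaplot flank width.
#' @param alpha,min_cg_sites,unit,strict_noncg,fdr_scope classifier
#'   settings (see [classify_genes()]).
#' @param background optional named numeric background override.
#' @param resample_k,resample_reps resampled-metaplot control settings
#'   (0 reps disables it).
#' @param downsample_target optional mean coverage to thin to, for the
#'   deep-vs-shallow comparison (NULL disables).
#' @param seed master seed; stage seeds (simulate / thin / resample) are
#'   derived from it.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sim_config = simulation_config(),
                       allc = NULL, genes = NULL,
                       flank_bp = 1000L, alpha = 0.05,
                       min_cg_sites = 10L, unit = "reads",
                       strict_noncg = FALSE, fdr_scope = "context",
                       background = NULL,
                       resample_k = 100L, resample_reps = 100L,
                       downsample_target = NULL, seed = 1L) {
  cfg <- list(allc = allc, genes = genes, flank_bp = as.integer(flank_bp),
              alpha = alpha, min_cg_sites = as.integer(min_cg_sites),
              unit = unit, strict_noncg = strict_noncg,
              fdr_scope = fdr_scope, background = background,
              resample_k = as.integer(resample_k),
              resample_reps = as.integer(resample_reps),
              downsample_target = downsample_target,
              seed = as.integer(seed))
  if (!is.null(sim_config)) cfg$sim <- unclass(validate_config(sim_config))
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(master, stage) {
  # distinct, reproducible, < 2^31
  (as.integer(master) + stage * 1000003L) %% 2147483629L
}

#' Run the full gene-body methylation pipeline
#'
#' Orchestrates simulate (or load) -> per-gene summaries -> background ->
#' classification -> metaplots (+ resampling control) -> optional read
#' thinning with re-classification, writing every table and a
#' human-readable report into `outdir`. Deterministic given the seeds in
#' the configuration; the serialised configuration written alongside the
#' outputs reproduces the run exactly.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return (invisibly) a report list: per-context genome-wide levels,
#'   label counts, the classification/metaplot tables, and — when ground
#'   truth is available — gbM sensitivity and false-positive rates.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configuration"
  report <- list()
  tryCatch({
    truth <- NULL
    if (!is.null(config$sim)) {
      stage <- "simulate"
      sim_cfg <- config$sim
      class(sim_cfg) <- "simulation_config"
      sim <- simulate_methylome(sim_cfg)
      records <- sim$records; genes <- sim$genes; truth <- sim$truth
      write_fixture(sim, outdir)
    } else {
      stage <- "load"
      if (is.null(config$allc) || is.null(config$genes))
        stop("need either a simulation config or allc + genes paths")
      records <- read_allc(config$allc)
      genes <- read_genes(config$genes)
    }

    stage <- "summarize"
    summaries <- summarize_genes(records, genes)
    fwrite(summaries, file.path(outdir, "gene_summaries.tsv"), sep = "\t")

    stage <- "background"
    bg <- if (is.null(config$background))
      estimate_background(records, genes, unit = config$unit)
    else config$background
    bg_tab <- if (inherits(bg, "background_levels")) as.data.table(bg)
              else data.table(context = names(bg), p0 = unname(bg))
    fwrite(bg_tab, file.path(outdir, "background.tsv"), sep = "\t")

    stage <- "classify"
    cls <- classify_genes(summaries, bg, alpha = config$alpha,
                          min_cg_sites = config$min_cg_sites,
                          unit = config$unit,
                          strict_noncg = config$strict_noncg,
                          fdr_scope = config$fdr_scope)
    fwrite(cls, file.path(outdir, "classification.tsv"), sep = "\t")

    stage <- "metaplot"
    prof <- metaplot(records, genes, flank_bp = config$flank_bp)
    fwrite(prof, file.path(outdir, "metaplot.tsv"), sep = "\t")

    gbm_ids <- cls$gene_id[cls$label == "gbM"]
    resamp <- NULL
    if (config$resample_reps > 0L &&
        length(gbm_ids) >= config$resample_k) {
      stage <- "resample"
      resamp <- resampled_metaplot(
        records, genes[genes$gene_id %in% gbm_ids, ],
        k = config$resample_k, reps = config$resample_reps,
        seed = stage_seed(config$seed, 2L), flank_bp = config$flank_bp)
      fwrite(resamp, file.path(outdir, "resampled_metaplot.tsv"),
             sep = "\t")
    }

    shallow <- NULL
    if (!is.null(config$downsample_target)) {
      stage <- "downsample"
      thin <- downsample_records(records, config$downsample_target,
                                 seed = stage_seed(config$seed, 1L))
      thin_sum <- summarize_genes(thin, genes)
      thin_bg <- estimate_background(thin, genes, unit = config$unit)
      thin_cls <- classify_genes(thin_sum, thin_bg, alpha = config$alpha,
                                 min_cg_sites = config$min_cg_sites,
                                 unit = config$unit,
                                 strict_noncg = config$strict_noncg,
                                 fdr_scope = config$fdr_scope)
      fwrite(thin_cls, file.path(outdir, "classification_downsampled.tsv"),
             sep = "\t")
      shallow <- list(classification = thin_cls,
                      genome_levels = vapply(
                        CONTEXTS, function(ctx)
                          weighted_methylation(thin, context = ctx),
                        numeric(1L)))
    }

    stage <- "report"
    genome_levels <- vapply(CONTEXTS, function(ctx)
      weighted_methylation(records, context = ctx), numeric(1L))
    label_counts <- table(cls$label)
    report <- list(config = config,
                   n_genes = nrow(genes),
                   n_records = nrow(records),
                   genome_levels = genome_levels,
                   background = bg_tab,
                   label_counts = label_counts,
                   classification = cls,
                   metaplot = prof,
                   resampled_metaplot = resamp,
                   shallow = shallow)
    if (!is.null(truth)) {
      m <- merge(cls[, c("gene_id", "label")], truth, by = "gene_id")
      report$recovery <- list(
        gbM_sensitivity =
          mean(m$label[m$true_class == "gbM"] == "gbM"),
        TE_like_called_gbM =
          sum(m$label[m$true_class == "TE_like"] == "gbM"),
        unmethylated_gbM_rate =
          mean(m$label[m$true_class == "unmethylated"] == "gbM"),
        unclassified = sum(m$label == "unclassified"))
    }
    write_run_config(unclass(config), file.path(outdir, "run_config.txt"))
    writeLines(format_report(report), file.path(outdir, "report.txt"))
    invisible(report)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

format_report <- function(report) {
  lines <- c("gene-body methylation pipeline report",
             sprintf("genes: %d   cytosine records: %d",
                     report$n_genes, report$n_records),
             "genome-wide weighted methylation:",
             sprintf("  %s: %s", CONTEXTS,
                     formatC(report$genome_levels, digits = 4L,
                             format = "f")),
             "background (coding-sequence) levels:",
             sprintf("  %s: %.6f", report$background$context,
                     report$background$p0),
             "gene labels:",
             sprintf("  %s: %d", names(report$label_counts),
                     as.integer(report$label_counts)))
  if (!is.null(report$recovery)) {
    r <- report$recovery
    lines <- c(lines, "recovery against simulated ground truth:",
               sprintf("  gbM sensitivity: %.4f", r$gbM_sensitivity),
               sprintf("  TE-like genes called gbM: %d",
                       r$TE_like_called_gbM),
               sprintf("  unmethylated genes called gbM: %.4f",
                       r$unmethylated_gbM_rate),
               sprintf("  unclassified genes: %d", r$unclassified))
  }
  if (!is.null(report$shallow)) {
    lines <- c(lines,
               sprintf("after thinning: %d unclassified genes",
                       sum(report$shallow$classification$label ==
                             "unclassified")))
  }
  lines
}
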