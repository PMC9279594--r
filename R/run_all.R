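#' Assemble a pipeline run configuration
#'
#' Collects the seed, thresholds and input paths that define one reproducible
#' end-to-end run. Any field may also be supplied through a YAML file via
#' [read_run_config()]; identical configurations and seeds produce
#' byte-identical outputs.
#'
#' @param seed Integer RNG seed, recorded in every output artifact.
#' @param out_dir Output directory (created if needed).
#' @param matrix Path to a wide expression TSV, or `NULL` to simulate one
#'   with [gen_fpkm_dataset()] using `sim` below.
#' @param sim An [fpkm_sim_config()] used when `matrix` is `NULL` (its seed
#'   is overridden by `seed`).
#' @param housekeeping_id Housekeeping feature id.
#' @param sum_threshold,initial_threshold,min_step,fold_limit,alpha Pipeline
#'   thresholds (see [run_fpkm_pipeline()] and [enrich_table()]).
#' @param gmt Optional path to a GMT annotation collection for enrichment of
#'   the consensus up-/down-regulated gene lists.
#' @param background Optional path to a background gene list; default is the
#'   set of features that survive filtering.
#' @param fish_signal,fish_rois Optional paths to a Q-FISH signal TIFF and
#'   its ROI JSON for per-cell RTL quantification.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = "senesceq_run", matrix = NULL,
                       sim = fpkm_sim_config(), housekeeping_id = "GAPDH",
                       sum_threshold = 5, initial_threshold = 1,
                       min_step = 0, fold_limit = 3, alpha = 0.05,
                       gmt = NULL, background = NULL,
                       fish_signal = NULL, fish_rois = NULL) {
  structure(list(seed = assert_count(seed, "seed"), out_dir = out_dir,
                 matrix = matrix, sim = sim,
                 housekeeping_id = housekeeping_id,
                 sum_threshold = sum_threshold,
                 initial_threshold = initial_threshold,
                 min_step = min_step, fold_limit = fold_limit,
                 alpha = alpha, gmt = gmt, background = background,
                 fish_signal = fish_signal, fish_rois = fish_rois),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with `run_config` fields (unknown fields rejected).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort_input("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(y$sim)) y$sim <- do.call(fpkm_sim_config, y$sim)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0("[stage: ", name, "] ", conditionMessage(e)),
                        class = c("senesceq_stage_error", "error")))
  })
}

#' Run the full pipeline end to end
#'
#' Executes, in order: input acquisition (read or simulate the expression
#' matrix), the FPKM trend pipeline, per-candidate slope tests with BH FDR,
#' enrichment of the consensus up/down gene lists (when annotations are
#' given), and Q-FISH quantification (when image inputs are given). Every
#' table is written to `out_dir` together with a `manifest.json` recording
#' the configuration, seed, and counts at every stage. The manifest carries
#' no timestamps, so reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config A [run_config()] (or a path to a YAML file for it).
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    abort_input("config must be a run_config or a YAML path")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)

  truth <- NULL
  mat <- stage("input", {
    if (!is.null(config$matrix)) {
      read_expression_tsv(config$matrix)
    } else {
      sim <- config$sim
      sim$seed <- config$seed
      ds <- gen_fpkm_dataset(sim)
      truth <<- ds$truth
      write_expression_tsv(ds$matrix, outp("expression_matrix.tsv"))
      ds$matrix
    }
  })

  if (!(config$housekeeping_id %in% mat$feature_id)) {
    stop(errorCondition(
      paste0("[stage: config] housekeeping feature '",
             config$housekeeping_id, "' absent from the expression matrix"),
      class = c("senesceq_stage_error", "error")))
  }

  pipe <- stage("fpkm_pipeline", {
    run_fpkm_pipeline(mat, housekeeping_id = config$housekeeping_id,
                      sum_threshold = config$sum_threshold,
                      initial_threshold = config$initial_threshold,
                      min_step = config$min_step,
                      fold_limit = config$fold_limit)
  })
  utils::write.table(pipe$trends, outp("trend_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pipe$report[c("n_input", "n_removed_fail",
                                     "n_removed_low", "n_kept")],
                       outp("filter_report.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  utils::write.table(pipe$cv, outp("cv.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # slope-test surrogate for significance: per consensus candidate, OLS of
  # the log2 evolution on time pooled across cultures, BH-adjusted
  slope_tab <- stage("trend_stats", {
    cand <- pipe$trends$feature_id[pipe$trends$consensus != "none"]
    if (length(cand) == 0L) {
      data.frame(feature_id = character(0), slope = numeric(0),
                 p = numeric(0), q = numeric(0), stringsAsFactors = FALSE)
    } else {
      norm <- pipe$normalized
      tp_index <- as.integer(sub("^t", "", norm$timepoint))
      rows <- lapply(cand, function(fid) {
        sel <- norm$feature_id == fid & !is.na(norm$log2_evolution)
        fit <- fit_linear(tp_index[sel], norm$log2_evolution[sel])
        data.frame(feature_id = fid, slope = fit$slope, p = fit$p_value,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      tab$q <- bh_fdr(tab$p)
      tab[order(tab$q, tab$feature_id), , drop = FALSE]
    }
  })
  utils::write.table(slope_tab, outp("slope_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  up <- pipe$trends$feature_id[pipe$trends$consensus == "up"]
  down <- pipe$trends$feature_id[pipe$trends$consensus == "down"]
  write_gene_list(sort(up), outp("up_genes.txt"))
  write_gene_list(sort(down), outp("down_genes.txt"))

  enr <- NULL
  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", {
      sets <- read_gmt(config$gmt)
      bg <- if (!is.null(config$background)) {
        read_gene_list(config$background)
      } else {
        unique(pipe$trends$feature_id)
      }
      lapply(list(up = up, down = down), function(q) {
        if (length(q) == 0L) return(NULL)
        enrich_table(q, sets, background = unique(c(bg, q)),
                     alpha = config$alpha)
      })
    })
    for (dirn in names(enr)) {
      if (!is.null(enr[[dirn]])) {
        utils::write.table(enr[[dirn]],
                           outp(paste0("enrichment_", dirn, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  fish <- NULL
  if (!is.null(config$fish_signal)) {
    fish <- stage("image_quant", {
      img <- read_tiff16(config$fish_signal)
      rois <- read_roi_json(config$fish_rois)
      quantify_fish_image(img, rois)
    })
    utils::write.table(fish$cells, outp("cell_rtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fish$spots, outp("spot_measures.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    schema = "senesceq-manifest/1",
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    sim = if (is.null(config$matrix)) unclass(config$sim) else NULL,
    counts = list(
      features_input = pipe$report$n_input,
      removed_fail = pipe$report$n_removed_fail,
      removed_low = pipe$report$n_removed_low,
      features_kept = pipe$report$n_kept,
      consensus_up = length(up),
      consensus_down = length(down),
      slope_tested = nrow(slope_tab),
      anomalous_hk_timepoints = nrow(pipe$anomalies),
      cells_quantified = if (is.null(fish)) 0L else nrow(fish$cells)))
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, pipeline = pipe,
                 slope_tests = slope_tab, enrichment = enr, fish = fish,
                 truth = truth))
}
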