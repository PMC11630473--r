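# End-to-end orchestration: simulate -> detect -> activity, with a run
# report, plus dataset-level realm summaries.

#' Pipeline configuration
#'
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param stages Character vector of stages to run, in dependency order;
#'   any subset of `c("simulate", "detect", "activity")`.
#' @param simulation A [simulation_config()]; required when `"simulate"` is
#'   enabled.
#' @param depth_file Depth TSV to read when `"simulate"` is disabled but
#'   `"detect"` is enabled.
#' @param detection A [detection_params()].
#' @param ... Unknown keys are rejected.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir = NULL,
                            stages = c("simulate", "detect", "activity"),
                            simulation = NULL, depth_file = NULL,
                            detection = detection_params(), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  stopifnot(all(stages %in% c("simulate", "detect", "activity")))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = stages, simulation = simulation,
                 depth_file = depth_file, detection = detection),
            class = "pipeline_config")
}

#' Run the induction-detection pipeline
#'
#' Runs the enabled stages in dependency order: `simulate` generates a
#' seeded depth profile with planted elements, `detect` calls
#' elevated-coverage elements, `activity` computes the phage-to-host ratio
#' and activity class of every detected element against its segment
#' background. Identical config (including seed) gives identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with `report` (per-stage counts, parameters, seed),
#'   `truth` (when simulated), `elements` and `activity` tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, stages = config$stages,
                 params = unclass(config$detection), counts = list(),
                 warnings = character(0))
  out <- list(report = report)
  depth <- NULL
  truth <- NULL
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if ("simulate" %in% config$stages) {
    if (is.null(config$simulation))
      stop("stage 'simulate' enabled but no simulation config given")
    sim <- simulate_depth_profile(config$simulation)
    depth <- sim$depth
    truth <- sim$truth
    out$truth <- truth
    out$report$counts$n_planted <- nrow(truth$elements)
    if (!is.null(config$out_dir)) {
      write_depth_tsv(depth, file.path(config$out_dir, "depth.tsv"),
                      seed = config$seed)
      jsonlite::write_json(
        truth$elements, file.path(config$out_dir, "truth.json"),
        dataframe = "rows")
    }
  }

  if ("detect" %in% config$stages) {
    if (is.null(depth)) {
      if (is.null(config$depth_file))
        stop("stage 'detect' needs a depth profile: enable 'simulate' or ",
             "set depth_file")
      if (!file.exists(config$depth_file))
        stop("depth file not found: ", config$depth_file)
      depth <- read_depth_tsv(config$depth_file)
    }
    det <- detect_induced_elements(depth, config$detection)
    out$elements <- det$elements
    out$detection <- det
    out$report$counts$n_detected <- nrow(det$elements)
    out$report$counts <- utils::modifyList(out$report$counts, det$report)
    if (!is.null(config$out_dir))
      write_elements_bed(det$elements,
                         file.path(config$out_dir, "elements.bed"))
  }

  if ("activity" %in% config$stages) {
    if (is.null(out$detection))
      stop("stage 'activity' needs detection results; enable 'detect'")
    det <- out$detection
    rows <- list()
    for (i in seq_len(nrow(det$elements))) {
      el <- det$elements[i, ]
      segkeys <- names(det$stats)[startsWith(names(det$stats),
                                             paste0(el$contig, ":"))]
      if (!length(segkeys)) {
        # plasmid contig: compare against the whole-genome median
        pc <- correct_plasmid_ptoh(el$mean_coverage, det$genome_median, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          element_id = el$element_id, ptoh = pc$raw,
          ptoh_corrected = pc$corrected, category = NA_character_)
        next
      }
      # segment containing the element midpoint
      mid <- (el$start + el$end) / 2
      bounds <- do.call(rbind, lapply(strsplit(sub(".*:", "", segkeys), "-"),
                                      as.numeric))
      k <- which(mid >= bounds[, 1] & mid < bounds[, 2])[1]
      st <- det$stats[[segkeys[k]]]
      rows[[length(rows) + 1L]] <- data.frame(
        element_id = el$element_id,
        ptoh = el$mean_coverage / st$median,
        ptoh_corrected = el$mean_coverage / st$median,
        category = classify_activity(el$mean_coverage, st))
    }
    out$activity <- if (length(rows)) do.call(rbind, rows) else
      data.frame(element_id = character(), ptoh = numeric(),
                 ptoh_corrected = numeric(), category = character())
    if (!is.null(config$out_dir))
      data.table::fwrite(out$activity,
                         file.path(config$out_dir, "activity.tsv"),
                         sep = "\t")
  }

  if (!is.null(config$out_dir))
    jsonlite::write_json(out$report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, force = TRUE)
  out
}

#' Per-realm counts and percentages of a prophage set
#'
#' @param realms Character vector of realm assignments (one per prophage).
#' @return `data.frame` with columns `realm`, `count`, `percent` (one
#'   decimal); all-zero with a warning for an empty input.
#' @export
summarize_realms <- function(realms) {
  lv <- c("tailless", "filamentous", "tailed", "other")
  if (!length(realms)) {
    warning("empty prophage set")
    return(data.frame(realm = lv, count = 0L, percent = 0))
  }
  stopifnot(all(realms %in% lv))
  tab <- table(factor(realms, levels = lv))
  data.frame(realm = lv, count = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(realms), 1))
}
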