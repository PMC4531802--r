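# Batch orchestration: dataset discovery, per-field analysis with fault
# quarantine, event calling, condition summaries and comparisons.

log_msg <- function(con, level, ...) {
  line <- paste0(...)
  if (!is.null(con)) writeLines(line, con)
  if (identical(level, "info")) message(line)
  invisible(line)
}

#' Discover the fields of a dataset condition directory
#'
#' A field is identified by the presence of `<base>_DAPI.tif`; the remaining
#' channels are expected alongside as `<base>_<Channel>.tif`.
#'
#' @param dir Condition directory.
#' @return Character vector of field base names.
#' @export
discover_fields <- function(dir) {
  dapi <- list.files(dir, pattern = "_DAPI\\.tif$")
  sort(sub("_DAPI\\.tif$", "", dapi))
}

#' Run the full analysis pipeline over a dataset
#'
#' Walks every condition directory under `config$input_dir` (any
#' subdirectory containing `*_DAPI.tif` files), analyzes each field
#' (projection, segmentation, spot detection), concatenates the per-field
#' tables, calls breakage/translocation events, and writes per-condition
#' result tables plus cross-condition summaries, pairwise Fisher
#' comparisons, spot-count histograms and a run log. Failing fields are
#' quarantined and logged; the run fails only if every field of every
#' condition fails.
#'
#' @param config A [run_config()] or the path of a YAML/JSON file readable
#'   by [read_run_config()].
#' @return Invisibly, a list with `summaries`, `comparisons`, `conditions`
#'   (per-condition event tables), `quarantined` (data frame of failed
#'   fields and messages) and `status` (0 = clean, 3 = partial failure with
#'   quarantined fields).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$output_dir, "run.log"), open = "wt")
  on.exit(close(logcon))
  lv <- config$log_level
  log_msg(logcon, lv, "bafish ",
          as.character(utils::packageVersion("bafish")),
          " | R ", R.version.string)
  log_msg(logcon, lv, "seed: ", config$seed)
  log_msg(logcon, lv, "parameters: ",
          gsub("\n", " | ", yaml::as.yaml(strip_class(
            config[c("imaging", "segmentation", "spots", "thresholds")]))))

  cond_dirs <- list.dirs(config$input_dir, recursive = FALSE)
  cond_dirs <- cond_dirs[vapply(cond_dirs,
                                function(d) length(discover_fields(d)) > 0,
                                logical(1))]
  if (!length(cond_dirs)) {
    stop("no condition directories with *_DAPI.tif fields under ",
         config$input_dir, call. = FALSE)
  }

  quarantined <- list()
  conditions <- list()
  summaries <- list()
  for (cdir in cond_dirs) {
    label <- basename(cdir)
    meta <- tryCatch(parse_metadata(label), bafish_parse_error = function(e) {
      log_msg(logcon, lv, "non-conforming condition name '", label, "': ",
              conditionMessage(e))
      NULL
    })
    fields <- discover_fields(cdir)
    nuc_acc <- list(); spot_acc <- list()
    for (base in fields) {
      res <- tryCatch({
        fi <- read_field_image(cdir, base, config$imaging, field_id = base)
        analyze_field(fi, config$segmentation, config$spots)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        log_msg(logcon, lv, "QUARANTINED ", label, "/", base, ": ",
                conditionMessage(res))
        quarantined[[length(quarantined) + 1L]] <- data.frame(
          condition = label, field = base,
          message = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      nuc_acc[[base]] <- res$nuclei
      spot_acc[[base]] <- res$spots
    }
    if (!length(nuc_acc)) {
      log_msg(logcon, lv, "condition ", label, ": no analyzable fields")
      next
    }
    nuclei <- do.call(rbind, nuc_acc)
    spots <- do.call(rbind, spot_acc)
    ev <- call_events(nuclei, spots, config$thresholds)
    meta_chr <- if (is.null(meta)) c(condition = label) else
      c(condition = label, unlist(meta))
    write_ba_table(nuclei, file.path(config$output_dir,
                                     paste0(label, "_nuclei.tsv")),
                   meta = meta_chr)
    write_ba_table(spots, file.path(config$output_dir,
                                    paste0(label, "_spots.tsv")),
                   meta = meta_chr)
    write_ba_table(ev$alleles, file.path(config$output_dir,
                                         paste0(label, "_distances.tsv")),
                   meta = meta_chr)
    write_ba_table(ev$nuclei, file.path(config$output_dir,
                                        paste0(label, "_events.tsv")),
                   meta = meta_chr)
    hist_rows <- list()
    for (ch in c("Green", "Red", "FarRed")) {
      h <- spot_count_histogram(nuclei, spots, ch)
      if (nrow(h)) hist_rows[[ch]] <- cbind(channel = ch, h)
    }
    if (length(hist_rows)) {
      write_ba_table(do.call(rbind, hist_rows),
                     file.path(config$output_dir,
                               paste0(label, "_spot_counts.tsv")),
                     meta = meta_chr)
    }
    conditions[[label]] <- ev
    for (ecl in c("breakage", "translocation")) {
      ok <- any(ev$nuclei$qc_pass)
      if (ok) {
        summaries[[paste(label, ecl)]] <-
          summarize_condition(ev$nuclei, label, ecl)
      }
    }
  }
  if (!length(conditions)) {
    stop("all fields of all conditions failed analysis", call. = FALSE)
  }
  summary_df <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(condition = character(0), event_class = character(0),
               n_nuclei_analyzed = integer(0), n_positive = integer(0),
               proportion = numeric(0), percent = character(0),
               ci_low = numeric(0), ci_high = numeric(0))
  rownames(summary_df) <- NULL
  write_ba_table(summary_df,
                 file.path(config$output_dir, "condition_summaries.tsv"))

  comp_rows <- list()
  labs <- names(conditions)
  if (length(labs) >= 2L) {
    for (i in seq_len(length(labs) - 1L)) {
      for (j in (i + 1L):length(labs)) {
        for (ecl in c("breakage", "translocation")) {
          sa <- summary_df[summary_df$condition == labs[i] &
                             summary_df$event_class == ecl, ]
          sb <- summary_df[summary_df$condition == labs[j] &
                             summary_df$event_class == ecl, ]
          if (!nrow(sa) || !nrow(sb)) next
          cmp <- fisher_exact_comparison(
            sa$n_positive, sa$n_nuclei_analyzed - sa$n_positive,
            sb$n_positive, sb$n_nuclei_analyzed - sb$n_positive)
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            condition_a = labs[i], condition_b = labs[j],
            event_class = ecl, p_value = cmp$p_value,
            fold_change = cmp$fold_change, stringsAsFactors = FALSE)
        }
      }
    }
  }
  comparisons <- if (length(comp_rows)) do.call(rbind, comp_rows) else
    data.frame(condition_a = character(0), condition_b = character(0),
               event_class = character(0), p_value = numeric(0),
               fold_change = numeric(0))
  write_ba_table(comparisons,
                 file.path(config$output_dir, "comparisons.tsv"))

  quarantined <- if (length(quarantined)) do.call(rbind, quarantined) else
    data.frame(condition = character(0), field = character(0),
               message = character(0))
  status <- if (nrow(quarantined)) 3L else 0L
  log_msg(logcon, lv, "done: ", length(conditions), " conditions, ",
          nrow(quarantined), " quarantined fields, status ", status)
  invisible(list(summaries = summary_df, comparisons = comparisons,
                 conditions = conditions, quarantined = quarantined,
                 status = status))
}
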