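# Per-nucleus QC, per-Red-signal minimum distances, and breakage /
# translocation event calling.

#' Per-nucleus quality-control filter
#'
#' A nucleus is admitted to event calling only if it contains (a) at least
#' two signals in each of the Green, Red and FarRed channels and (b) an equal
#' number of Green and Red signals. The filter guards against missed or
#' spurious spot detections: a break-apart locus contributes one Green and
#' one Red signal whether or not it is broken, so unequal counts indicate a
#' detection artifact.
#'
#' @param n_green,n_red,n_farred Integer spot counts (vectorized).
#' @return Data frame with `qc_pass` and `qc_reason` (empty string when
#'   passing; otherwise the first failed clause among `green_lt_2`,
#'   `red_lt_2`, `farred_lt_2`, `unequal_red_green`).
#' @export
#' @examples
#' qc_filter(3, 3, 2)   # modal intact configuration: pass
#' qc_filter(3, 2, 2)   # unequal Red/Green: fail
qc_filter <- function(n_green, n_red, n_farred) {
  n <- max(length(n_green), length(n_red), length(n_farred))
  n_green <- rep_len(n_green, n)
  n_red <- rep_len(n_red, n)
  n_farred <- rep_len(n_farred, n)
  reason <- character(n)
  reason[n_farred < 2] <- "farred_lt_2"
  reason[n_red < 2] <- "red_lt_2"
  reason[n_green < 2] <- "green_lt_2"
  need_b <- !nzchar(reason) & n_green != n_red
  reason[need_b] <- "unequal_red_green"
  data.frame(qc_pass = !nzchar(reason), qc_reason = reason,
             stringsAsFactors = FALSE)
}

#' Per-Red-signal minimum distances
#'
#' For every Red spot in a nucleus, computes center-to-center Euclidean 2D
#' distances to every Green and every FarRed spot in the same nucleus, and
#' records the per-Red minima (R-G_min and R-FR_min).
#'
#' @param red,green,farred Data frames with columns `x`, `y` (and optionally
#'   `spot_id`) for one nucleus, in pixel units.
#' @return Data frame with one row per Red spot: `red_spot_id`, `rg_min`,
#'   `rfr_min`, plus list-columns `rg_dists` and `rfr_dists` holding the full
#'   distance vectors.
#' @export
#' @examples
#' pairwise_distances(data.frame(x = 0, y = 0),
#'                    data.frame(x = 3, y = 4),
#'                    data.frame(x = 0, y = 2))
pairwise_distances <- function(red, green, farred) {
  if (nrow(green) == 0L || nrow(farred) == 0L) {
    stop("pairwise_distances called with empty Green or FarRed spot list; ",
         "nuclei must pass QC first", call. = FALSE)
  }
  ids <- if ("spot_id" %in% names(red)) red$spot_id else seq_len(nrow(red))
  dg <- sqrt(outer(red$x, green$x, "-")^2 + outer(red$y, green$y, "-")^2)
  df <- sqrt(outer(red$x, farred$x, "-")^2 + outer(red$y, farred$y, "-")^2)
  out <- data.frame(red_spot_id = ids,
                    rg_min = apply(dg, 1, min),
                    rfr_min = apply(df, 1, min))
  out$rg_dists <- lapply(seq_len(nrow(dg)), function(i) dg[i, ])
  out$rfr_dists <- lapply(seq_len(nrow(df)), function(i) df[i, ])
  out
}

#' Classify a Red signal as intact, breakage, or translocation
#'
#' A breakage event is a Red signal whose minimum Red/Green distance exceeds
#' the proximity threshold. A translocation event is a Red signal that
#' simultaneously has a minimum Red/Green distance above the threshold and a
#' minimum Red/FarRed distance at or below it. Signals separated by the
#' threshold distance or less are proximal, so a Red/Green minimum exactly at
#' the threshold is intact.
#'
#' @param rg_min,rfr_min Per-Red minimum distances (px, vectorized).
#' @param thresholds A [ba_thresholds()].
#' @return Character vector in `{"intact", "breakage", "translocation"}`.
#' @export
#' @examples
#' classify_red_signal(c(5, 5, 4), c(3, 6, 0.5), ba_thresholds(4))
classify_red_signal <- function(rg_min, rfr_min,
                                thresholds = ba_thresholds()) {
  t <- thresholds$proximity_px
  ifelse(rg_min > t,
         ifelse(rfr_min <= t, "translocation", "breakage"),
         "intact")
}

#' Summarize event calls for one nucleus
#'
#' Counts breakage and translocation events over the nucleus' Red signals
#' and sets the per-nucleus positivity flags. A translocation-classified Red
#' signal satisfies the breakage condition and is counted in the breakage
#' tally as well. Nuclei failing QC report zero events.
#'
#' @param records Data frame from [pairwise_distances()] with an
#'   `event_class` column (see [classify_red_signal()]), all rows from one
#'   nucleus.
#' @param qc One row of [qc_filter()] output.
#' @return One-row data frame: `qc_pass`, `qc_reason`, `n_red_signals`,
#'   `n_breakage_events`, `n_translocation_events`, `breakage_positive`,
#'   `translocation_positive`.
#' @export
summarize_nucleus <- function(records, qc) {
  if (!is.null(records) && "nucleus_id" %in% names(records) &&
      length(unique(records$nucleus_id)) > 1L) {
    stop("records from more than one nucleus passed to summarize_nucleus",
         call. = FALSE)
  }
  if (!qc$qc_pass) {
    return(data.frame(qc_pass = FALSE, qc_reason = qc$qc_reason,
                      n_red_signals = 0L, n_breakage_events = 0L,
                      n_translocation_events = 0L,
                      breakage_positive = FALSE,
                      translocation_positive = FALSE))
  }
  cls <- records$event_class
  n_tr <- sum(cls == "translocation")
  n_br <- sum(cls %in% c("breakage", "translocation"))
  data.frame(qc_pass = TRUE, qc_reason = "",
             n_red_signals = nrow(records),
             n_breakage_events = n_br,
             n_translocation_events = n_tr,
             breakage_positive = n_br > 0L,
             translocation_positive = n_tr > 0L)
}

#' Call breakage and translocation events over a dataset of nuclei
#'
#' Applies the QC filter to every non-excluded nucleus, computes per-Red
#' minimum distances, classifies each Red signal, and summarizes events per
#' nucleus. Accepts the tables produced by [analyze_field()] (possibly
#' concatenated over fields) or user-supplied tables in the same dialect,
#' which lets coordinate data enter the pipeline mid-way.
#'
#' @param nuclei Nucleus table with `nucleus_id`, optional `field_id`, and
#'   (if produced by segmentation) `excluded`.
#' @param spots Spot table with `nucleus_id`, optional `field_id`, `channel`
#'   (`Green`/`Red`/`FarRed`), `x`, `y`.
#' @param thresholds A [ba_thresholds()].
#' @param coord_units `"px"` (default) or `"um"`; micrometer coordinates are
#'   converted to pixels using `thresholds$pixel_size_um` before
#'   thresholding.
#' @return A list with `alleles` (one row per Red signal of each QC-passing
#'   nucleus: keys, `rg_min`, `rfr_min`, `rg_min_um`, `rfr_min_um`,
#'   `event_class`) and `nuclei` (one row per non-excluded nucleus: keys,
#'   spot counts, QC verdict, event counts and positivity flags).
#' @export
call_events <- function(nuclei, spots, thresholds = ba_thresholds(),
                        coord_units = c("px", "um")) {
  coord_units <- match.arg(coord_units)
  if (!"field_id" %in% names(nuclei)) nuclei$field_id <- "f001"
  if (!"field_id" %in% names(spots)) spots$field_id <- "f001"
  if (coord_units == "um") {
    spots$x <- spots$x / thresholds$pixel_size_um
    spots$y <- spots$y / thresholds$pixel_size_um
  }
  if ("excluded" %in% names(nuclei)) {
    nuclei <- nuclei[!nuclei$excluded, , drop = FALSE]
  }
  if (!nrow(nuclei)) {
    return(list(alleles = data.frame(), nuclei = data.frame()))
  }
  key <- function(f, n) paste(f, n, sep = "\r")
  spots$.key <- key(spots$field_id, spots$nucleus_id)
  sp_split <- split(spots, spots$.key)
  allele_rows <- list()
  nuc_rows <- vector("list", nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    k <- key(nuclei$field_id[i], nuclei$nucleus_id[i])
    sp <- sp_split[[k]]
    ng <- if (is.null(sp)) 0L else sum(sp$channel == "Green")
    nr <- if (is.null(sp)) 0L else sum(sp$channel == "Red")
    nf <- if (is.null(sp)) 0L else sum(sp$channel == "FarRed")
    qc <- qc_filter(ng, nr, nf)
    if (qc$qc_pass) {
      rec <- pairwise_distances(sp[sp$channel == "Red", , drop = FALSE],
                                sp[sp$channel == "Green", , drop = FALSE],
                                sp[sp$channel == "FarRed", , drop = FALSE])
      rec$event_class <- classify_red_signal(rec$rg_min, rec$rfr_min,
                                             thresholds)
      summ <- summarize_nucleus(rec, qc)
      allele_rows[[length(allele_rows) + 1L]] <- data.frame(
        field_id = nuclei$field_id[i],
        nucleus_id = nuclei$nucleus_id[i],
        red_spot_id = rec$red_spot_id,
        rg_min = rec$rg_min, rfr_min = rec$rfr_min,
        rg_min_um = rec$rg_min * thresholds$pixel_size_um,
        rfr_min_um = rec$rfr_min * thresholds$pixel_size_um,
        event_class = rec$event_class,
        stringsAsFactors = FALSE)
    } else {
      summ <- summarize_nucleus(NULL, qc)
    }
    nuc_rows[[i]] <- cbind(
      data.frame(field_id = nuclei$field_id[i],
                 nucleus_id = nuclei$nucleus_id[i],
                 n_green = ng, n_red = nr, n_farred = nf,
                 stringsAsFactors = FALSE),
      summ)
  }
  alleles <- if (length(allele_rows)) do.call(rbind, allele_rows) else
    data.frame(field_id = character(0), nucleus_id = integer(0),
               red_spot_id = integer(0), rg_min = numeric(0),
               rfr_min = numeric(0), rg_min_um = numeric(0),
               rfr_min_um = numeric(0), event_class = character(0))
  nuc <- do.call(rbind, nuc_rows)
  rownames(alleles) <- NULL
  rownames(nuc) <- NULL
  # event hierarchy holds by construction; assert it on every run
  stopifnot(all(nuc$n_translocation_events <= nuc$n_breakage_events),
            all(nuc$n_breakage_events <= nuc$n_red_signals),
            all(!nuc$translocation_positive | nuc$breakage_positive))
  list(alleles = alleles, nuclei = nuc)
}
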