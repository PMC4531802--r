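# From raw z-stacks to per-nucleus spot tables: maximum projection, DAPI
# nucleus segmentation with morphology filters, ROI-constrained spot
# detection. All coordinates 0-based pixels, x = column, y = row.

#' Maximum intensity projection
#'
#' Per-pixel maximum over the z dimension of a `[row, col, z]` stack.
#'
#' @param stack A 3D numeric array (or a 2D matrix, returned unchanged).
#' @return A matrix with the stack's lateral shape.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    stop("`stack` must be a [row, col, z] array with at least one plane",
         call. = FALSE)
  }
  out <- stack[, , 1L]
  for (k in seq_len(dim(stack)[3])[-1L]) {
    out <- pmax(out, stack[, , k])
  }
  out
}

roundness_of <- function(area, perimeter) {
  pmin(1, 4 * pi * area / pmax(perimeter, 1e-9)^2)
}

#' Segment nuclei from a DAPI projection
#'
#' Gaussian smoothing followed by global Otsu thresholding, hole filling,
#' connected-component labelling and (optionally) watershed splitting of
#' touching nuclei. Each object is measured (area, perimeter, roundness =
#' `4*pi*A/P^2`, centroid) and flagged excluded if it touches the image
#' border, falls outside the admissible area range, or is rougher than the
#' roundness minimum. Excluded nuclei are retained with a reason for audit;
#' they take no further part in analysis.
#'
#' @param dapi 2D nonnegative image (maximum projection of the DAPI stack).
#' @param params A [seg_params()].
#' @return A list with `labels` (integer label matrix) and `nuclei`, a data
#'   frame with columns `nucleus_id`, `x`, `y` (centroid, 0-based px),
#'   `area_px`, `perimeter_px`, `roundness`, `touches_border`, `excluded`,
#'   `exclude_reason`.
#' @export
segment_nuclei <- function(dapi, params = seg_params()) {
  stopifnot(is.matrix(dapi), all(dapi >= 0))
  empty <- list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                nuclei = data.frame(
                  nucleus_id = integer(0), x = numeric(0), y = numeric(0),
                  area_px = numeric(0), perimeter_px = numeric(0),
                  roundness = numeric(0), touches_border = logical(0),
                  excluded = logical(0), exclude_reason = character(0),
                  stringsAsFactors = FALSE))
  if (max(dapi) <= 0) return(empty)
  sm <- EBImage::gblur(dapi, sigma = params$blur_sigma)
  sm[sm < 0] <- 0
  rng <- range(sm)
  if (diff(rng) <= 0) return(empty)
  norm <- (sm - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > th
  mask <- EBImage::fillHull(mask)
  labels <- if (isTRUE(params$watershed)) {
    EBImage::watershed(EBImage::distmap(mask))
  } else {
    EBImage::bwlabel(mask)
  }
  labels <- matrix(as.integer(labels), nrow(dapi), ncol(dapi))
  n <- max(labels)
  if (n == 0L) return(empty)
  shp <- EBImage::computeFeatures.shape(labels)
  H <- nrow(labels); W <- ncol(labels)
  border_ids <- unique(c(labels[1, ], labels[H, ], labels[, 1], labels[, W]))
  rows <- vector("list", n)
  idx <- which(labels > 0)
  lab_v <- labels[idx]
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  for (i in seq_len(n)) {
    sel <- lab_v == i
    area <- shp[i, "s.area"]
    perim <- shp[i, "s.perimeter"]
    rd <- roundness_of(area, perim)
    tb <- i %in% border_ids
    reason <- if (tb) {
      "touches_border"
    } else if (area < params$area_range[1] || area > params$area_range[2]) {
      "area_out_of_range"
    } else if (rd < params$min_roundness) {
      "low_roundness"
    } else ""
    rows[[i]] <- data.frame(
      nucleus_id = i,
      x = mean(cc[sel]) - 1, y = mean(rr[sel]) - 1,
      area_px = area, perimeter_px = perim, roundness = rd,
      touches_border = tb, excluded = nzchar(reason),
      exclude_reason = reason, stringsAsFactors = FALSE)
  }
  list(labels = labels, nuclei = do.call(rbind, rows))
}

# Difference-of-Gaussians band-pass at the spot scale.
dog_filter <- function(img, s1, s2) {
  EBImage::gblur(img, sigma = s1) - EBImage::gblur(img, sigma = s2)
}

#' Detect FISH spots within one nucleus
#'
#' Band-pass filters the channel image (difference of Gaussians at the spot
#' scale), finds local maxima restricted to the nucleus mask, thresholds at
#' `median + k_mad * MAD` of the band-passed signal inside the nucleus,
#' enforces a minimum inter-spot separation (keeping the brighter peak), and
#' refines each detection to a sub-pixel centroid by intensity weighting in a
#' small window. Zero detections is a valid result.
#'
#' @param channel_image 2D image (maximum projection of a FISH channel).
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param nucleus_id Label of the (non-excluded) nucleus to search.
#' @param params A [spot_params()].
#' @return Data frame with `spot_id`, `x`, `y` (0-based px, sub-pixel),
#'   `peak_intensity`, `integrated_intensity`.
#' @export
detect_spots <- function(channel_image, labels, nucleus_id,
                         params = spot_params()) {
  stopifnot(is.matrix(channel_image),
            identical(dim(channel_image), dim(labels)))
  empty <- data.frame(spot_id = integer(0), x = numeric(0), y = numeric(0),
                      peak_intensity = numeric(0),
                      integrated_intensity = numeric(0))
  idx <- which(labels == nucleus_id)
  if (!length(idx)) return(empty)
  H <- nrow(labels)
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  pad <- 8L
  r0 <- max(1L, min(rr) - pad); r1 <- min(H, max(rr) + pad)
  c0 <- max(1L, min(cc) - pad); c1 <- min(ncol(labels), max(cc) + pad)
  crop <- channel_image[r0:r1, c0:c1, drop = FALSE]
  mcrop <- labels[r0:r1, c0:c1, drop = FALSE] == nucleus_id
  dog <- dog_filter(crop, params$dog_sigma1, params$dog_sigma2)
  inside <- dog[mcrop]
  thr <- stats::median(inside) + params$k_mad * stats::mad(inside)
  # floor against numerical residue on noise-free, structure-free input
  thr <- max(thr, 1e-6 * max(crop))
  up <- params$upsample
  dogu <- if (up > 1L) {
    EBImage::resize(dog, w = nrow(dog) * up, h = ncol(dog) * up)
  } else dog
  dil <- EBImage::dilate(dogu, EBImage::makeBrush(3, "box"))
  cand <- which(dogu >= dil & dogu > thr)
  if (!length(cand)) return(empty)
  hu <- nrow(dogu)
  pru <- (cand - 1L) %% hu + 1L
  pcu <- (cand - 1L) %/% hu + 1L
  # map upsampled indices back to original (1-based) pixel coordinates
  pr_f <- (pru - 0.5) / up + 0.5
  pc_f <- (pcu - 0.5) / up + 0.5
  pr <- pmin(pmax(round(pr_f), 1L), nrow(crop))
  pc <- pmin(pmax(round(pc_f), 1L), ncol(crop))
  in_mask <- mcrop[cbind(pr, pc)]
  pr_f <- pr_f[in_mask]; pc_f <- pc_f[in_mask]
  pr <- pr[in_mask]; pc <- pc[in_mask]
  val <- dogu[cand][in_mask]
  if (!length(val)) return(empty)
  ord <- order(val, decreasing = TRUE)
  pr_f <- pr_f[ord]; pc_f <- pc_f[ord]
  pr <- pr[ord]; pc <- pc[ord]; val <- val[ord]
  keep <- rep(TRUE, length(val))
  if (params$min_separation_px > 0 && length(val) > 1L) {
    for (i in seq_along(val)[-1L]) {
      prev <- which(keep[seq_len(i - 1L)])
      if (length(prev) &&
          any((pr_f[i] - pr_f[prev])^2 + (pc_f[i] - pc_f[prev])^2 <
              params$min_separation_px^2)) {
        keep[i] <- FALSE
      }
    }
  }
  pr <- pr[keep]; pc <- pc[keep]
  # distinct sub-pixel maxima can round to one pixel; centroiding would
  # return duplicates, so drop exact duplicates here
  dup <- duplicated(cbind(pr, pc))
  pr <- pr[!dup]; pc <- pc[!dup]
  w <- params$centroid_halfwin
  bg <- stats::median(crop[mcrop])
  out <- vector("list", length(pr))
  for (i in seq_along(pr)) {
    rows <- max(1L, pr[i] - w):min(nrow(crop), pr[i] + w)
    cols <- max(1L, pc[i] - w):min(ncol(crop), pc[i] + w)
    # centroid weights from the band-passed image: a close neighbour's
    # broad tail cancels in the DoG, so paired spots stay separable
    win <- pmax(dog[rows, cols, drop = FALSE], 0)
    s <- sum(win)
    if (s <= 0) {
      cx <- pc[i]; cy <- pr[i]
    } else {
      cx <- sum(colSums(win) * cols) / s
      cy <- sum(rowSums(win) * rows) / s
    }
    out[[i]] <- data.frame(
      spot_id = i,
      x = cx - 1 + (c0 - 1L), y = cy - 1 + (r0 - 1L),
      peak_intensity = crop[pr[i], pc[i]],
      integrated_intensity = sum(pmax(crop[rows, cols] - bg, 0)))
  }
  res <- do.call(rbind, out)
  # a symmetric spot sampled into equal pixels yields a flat plateau whose
  # corners all pass the grid maximum test; their refined centroids
  # coincide, so suppress centroid-level duplicates (brightest first)
  if (nrow(res) > 1L && params$min_separation_px > 0) {
    keep2 <- rep(TRUE, nrow(res))
    for (i in seq_len(nrow(res))[-1L]) {
      prev <- which(keep2[seq_len(i - 1L)])
      if (length(prev) &&
          any((res$x[i] - res$x[prev])^2 + (res$y[i] - res$y[prev])^2 <
              params$min_separation_px^2)) {
        keep2[i] <- FALSE
      }
    }
    res <- res[keep2, , drop = FALSE]
  }
  # sub-pixel refinement must stay inside the parent mask
  ri <- pmin(pmax(round(res$y) + 1L, 1L), H)
  ci <- pmin(pmax(round(res$x) + 1L, 1L), ncol(labels))
  res <- res[labels[cbind(ri, ci)] == nucleus_id, , drop = FALSE]
  res$spot_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Analyze one multi-channel field
#'
#' Maximum-projects every channel, segments nuclei on the DAPI projection,
#' and detects FISH spots per channel within every non-excluded nucleus.
#' Excluded nuclei are kept in the output (flagged, spot-free) for audit.
#'
#' @param field A `field_image` as produced by [simulate_field()] or
#'   [read_field_image()]: a list with `field_id`, `stacks` (named list of
#'   `[row, col, z]` arrays covering DAPI, Green, Red, FarRed) and `imaging`.
#' @param segmentation A [seg_params()].
#' @param spots A [spot_params()].
#' @return A list with `nuclei` (the [segment_nuclei()] table plus
#'   `field_id`) and `spots` (data frame `field_id`, `nucleus_id`, `channel`,
#'   `spot_id`, `x`, `y`, `peak_intensity`, `integrated_intensity`).
#' @export
analyze_field <- function(field,
                          segmentation = seg_params(),
                          spots = spot_params()) {
  need <- c("DAPI", "Green", "Red", "FarRed")
  if (is.null(field$stacks) || !all(need %in% names(field$stacks))) {
    stop("field must provide DAPI, Green, Red and FarRed stacks",
         call. = FALSE)
  }
  proj <- lapply(field$stacks, max_project)
  seg <- segment_nuclei(proj$DAPI, segmentation)
  nuc <- seg$nuclei
  fid <- if (is.null(field$field_id)) "f001" else field$field_id
  spot_rows <- list()
  if (nrow(nuc)) {
    for (i in which(!nuc$excluded)) {
      nid <- nuc$nucleus_id[i]
      for (ch in c("Green", "Red", "FarRed")) {
        det <- detect_spots(proj[[ch]], seg$labels, nid, spots)
        if (nrow(det)) {
          det$field_id <- fid
          det$nucleus_id <- nid
          det$channel <- ch
          spot_rows[[length(spot_rows) + 1L]] <-
            det[, c("field_id", "nucleus_id", "channel", "spot_id",
                    "x", "y", "peak_intensity", "integrated_intensity")]
        }
      }
    }
  }
  spots_df <- if (length(spot_rows)) {
    do.call(rbind, spot_rows)
  } else {
    data.frame(field_id = character(0), nucleus_id = integer(0),
               channel = character(0), spot_id = integer(0),
               x = numeric(0), y = numeric(0),
               peak_intensity = numeric(0),
               integrated_intensity = numeric(0))
  }
  nuc <- if (nrow(nuc)) cbind(field_id = fid, nuc) else
    cbind(nuc, field_id = character(0))[, c("field_id", names(seg$nuclei))]
  rownames(nuc) <- NULL
  rownames(spots_df) <- NULL
  list(nuclei = nuc, spots = spots_df)
}
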