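# Synthetic three-color break-apart FISH imaging with exact ground truth.
#
# Coordinates are 0-based pixel units, origin top-left, x = column, y = row.
# Image stacks are numeric arrays [row, col, z] holding photon counts.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Rayleigh deviates parameterized by the distribution mean.
rrayleigh_mean <- function(n, mean) {
  sigma <- mean / sqrt(pi / 2)
  sigma * sqrt(-2 * log(runif(n)))
}

# Is point (x, y) inside the `scale`-shrunk ellipse?
in_ellipse <- function(x, y, ell, scale = 1) {
  ct <- cos(ell$theta); st <- sin(ell$theta)
  u <- ((x - ell$x) * ct + (y - ell$y) * st) / (ell$a * scale)
  v <- (-(x - ell$x) * st + (y - ell$y) * ct) / (ell$b * scale)
  u * u + v * v <= 1
}

# Uniform point in the `scale`-shrunk ellipse.
runif_ellipse <- function(ell, scale = 0.8) {
  r <- sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
  u <- r * cos(phi) * ell$a * scale
  v <- r * sin(phi) * ell$b * scale
  ct <- cos(ell$theta); st <- sin(ell$theta)
  c(x = ell$x + u * ct - v * st, y = ell$y + u * st + v * ct)
}

# Place a point at distance `dist` from `origin` in a uniform direction,
# constrained to the nucleus; after bounded retries the distance is shrunk
# toward the origin until the point fits.
offset_in_nucleus <- function(origin, dist, ell, scale = 0.95,
                              max_tries = 40L) {
  for (i in seq_len(max_tries)) {
    phi <- runif(1, 0, 2 * pi)
    p <- origin + dist * c(cos(phi), sin(phi))
    if (in_ellipse(p[1], p[2], ell, scale)) return(p)
  }
  phi <- runif(1, 0, 2 * pi)
  d <- dist
  repeat {
    d <- d * 0.8
    p <- origin + d * c(cos(phi), sin(phi))
    if (in_ellipse(p[1], p[2], ell, scale) || d < 1e-3) return(p)
  }
}

# Rejection placement of non-overlapping elliptical nuclei fully inside the
# field (2 px border margin). A minimum gap keeps adjacent nuclei separable
# by the segmentation stage, emulating sparse plating.
place_nuclei <- function(n_cells, field_shape_px, axes_px_range,
                         margin_px = 2, gap_px = 6, max_tries = 400L) {
  H <- field_shape_px[1]; W <- field_shape_px[2]
  out <- vector("list", n_cells)
  placed <- 0L
  tries <- 0L
  while (placed < n_cells) {
    tries <- tries + 1L
    if (tries > max_tries * max(1L, n_cells)) {
      stop("could not place ", n_cells, " non-overlapping nuclei in a ",
           H, "x", W, " field: field too dense", call. = FALSE)
    }
    a <- runif(1, axes_px_range[1], axes_px_range[2])
    b <- runif(1, axes_px_range[1], axes_px_range[2])
    rmax <- max(a, b)
    lo <- rmax + margin_px
    if (W - 1 - lo <= lo || H - 1 - lo <= lo) {
      stop("field too small for the configured nucleus size", call. = FALSE)
    }
    x <- runif(1, lo, W - 1 - lo)
    y <- runif(1, lo, H - 1 - lo)
    ok <- TRUE
    if (placed > 0L) {
      for (j in seq_len(placed)) {
        o <- out[[j]]
        if ((x - o$x)^2 + (y - o$y)^2 <
            (rmax + max(o$a, o$b) + gap_px)^2) { ok <- FALSE; break }
      }
    }
    if (ok) {
      placed <- placed + 1L
      out[[placed]] <- list(x = x, y = y, a = a, b = b,
                            theta = runif(1, 0, pi))
    }
  }
  out
}

# Uniform loci within the nucleus subject to a minimum pairwise spacing
# (distinct alleles of one gene occupy distinct chromosome territories).
sample_spaced_loci <- function(n, ell, min_dist_px, scale = 0.8,
                               max_tries = 60L) {
  loci <- matrix(NA_real_, n, 2)
  for (j in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      p <- runif_ellipse(ell, scale)
      if (j == 1L || all((loci[seq_len(j - 1L), 1] - p[1])^2 +
                           (loci[seq_len(j - 1L), 2] - p[2])^2 >=
                           min_dist_px^2)) break
    }
    loci[j, ] <- p
  }
  loci
}

# Draw allele states and true spot positions for one cell.
sample_cell_truth <- function(ell, cell_model, imaging) {
  px <- imaging$pixel_size_um
  z_max <- (imaging$z_planes - 1) * imaging$z_spacing_um
  z_mid <- z_max / 2
  nA <- cell_model$n_alleles_A
  nB <- cell_model$n_alleles_B
  spacing_px <- cell_model$territory_spacing_um / px

  spot_z <- function(n) pmin(pmax(rnorm(n, z_mid, 1.0), 0), z_max)

  loci_A <- sample_spaced_loci(nA, ell, spacing_px)
  loci_B <- sample_spaced_loci(nB, ell, spacing_px)
  states <- character(nA)
  ch <- character(0); aid <- character(0)
  sx <- numeric(0); sy <- numeric(0)
  red_pos <- matrix(NA_real_, nA, 2)
  for (j in seq_len(nA)) {
    locus <- loci_A[j, ]
    broken <- runif(1) < cell_model$p_break
    states[j] <- if (broken) "broken" else "intact"
    off_um <- if (broken) cell_model$broken_offset_um else
      cell_model$intact_offset_um
    off_px <- rrayleigh_mean(1, off_um) / px
    red <- offset_in_nucleus(locus, off_px, ell)
    red_pos[j, ] <- red
    ch <- c(ch, "Green", "Red")
    aid <- c(aid, sprintf("A%d", j), sprintf("A%d", j))
    sx <- c(sx, locus[[1]], red[[1]])
    sy <- c(sy, locus[[2]], red[[2]])
  }

  # translocations: a broken allele captures a distinct FarRed partner locus
  broken_idx <- which(states == "broken")
  tr <- broken_idx[runif(length(broken_idx)) <
                     cell_model$p_transloc_given_break]
  if (length(tr) > nB) tr <- sort(sample(tr, nB))
  states[tr] <- "translocated"
  partner_of <- rep(NA_integer_, nB)
  if (length(tr) > 0L && nB > 0L) {
    part <- if (nB == 1L) 1L else sample(nB, length(tr))
    partner_of[part] <- tr
  }
  for (k in seq_len(nB)) {
    if (!is.na(partner_of[k])) {
      j <- partner_of[k]
      d_px <- rrayleigh_mean(1, cell_model$proximity_offset_um) / px
      p <- offset_in_nucleus(red_pos[j, ], d_px, ell)
      a <- sprintf("A%d", j)
    } else {
      p <- loci_B[k, ]
      a <- sprintf("B%d", k)
    }
    ch <- c(ch, "FarRed"); aid <- c(aid, a)
    sx <- c(sx, p[[1]]); sy <- c(sy, p[[2]])
  }

  list(states = states, channel = ch, allele_id = aid,
       x = sx, y = sy, z_um = spot_z(length(ch)))
}

# Render all nuclei and spots of one field. All additions happen on arrays
# local to this function, so subassignment stays in place.
render_field_stacks <- function(ells, truth_spots, imaging) {
  H <- imaging$field_shape_px[1]; W <- imaging$field_shape_px[2]
  Z <- imaging$z_planes
  stacks <- lapply(stats::setNames(nm = imaging$channels),
                   function(ch) array(0, dim = c(H, W, Z)))
  z_pos <- (seq_len(Z) - 1) * imaging$z_spacing_um
  z_mid <- max(z_pos, 0) / 2

  dapi <- stacks$DAPI
  zf_dapi <- exp(-(z_pos - z_mid)^2 / (2 * imaging$dapi_sigma_z_um^2))
  for (ell in ells) {
    rmax <- max(ell$a, ell$b) + 3
    rows <- max(1L, floor(ell$y - rmax) + 1L):
      min(H, ceiling(ell$y + rmax) + 1L)
    cols <- max(1L, floor(ell$x - rmax) + 1L):
      min(W, ceiling(ell$x + rmax) + 1L)
    ct <- cos(ell$theta); st <- sin(ell$theta)
    dx <- outer(rep(1, length(rows)), (cols - 1) - ell$x)
    dy <- outer((rows - 1) - ell$y, rep(1, length(cols)))
    u <- (dx * ct + dy * st) / ell$a
    v <- (-dx * st + dy * ct) / ell$b
    base <- imaging$dapi_amplitude *
      stats::plogis((1 - sqrt(u * u + v * v)) / 0.05)
    for (k in seq_len(Z)) {
      dapi[rows, cols, k] <- dapi[rows, cols, k] + base * zf_dapi[k]
    }
  }
  stacks$DAPI <- dapi

  s <- imaging$psf_sigma_px
  r <- max(3L, ceiling(4 * s))
  for (ch in c("Green", "Red", "FarRed")) {
    sel <- truth_spots$channel == ch
    if (!any(sel)) next
    st_ch <- stacks[[ch]]
    xs <- truth_spots$x[sel]; ys <- truth_spots$y[sel]
    zs <- truth_spots$z_um[sel]
    for (i in seq_along(xs)) {
      rows <- max(1L, floor(ys[i] - r) + 1L):
        min(H, ceiling(ys[i] + r) + 1L)
      cols <- max(1L, floor(xs[i] - r) + 1L):
        min(W, ceiling(xs[i] + r) + 1L)
      gx <- exp(-((cols - 1) - xs[i])^2 / (2 * s^2))
      gy <- exp(-((rows - 1) - ys[i])^2 / (2 * s^2))
      patch <- imaging$spot_amplitude * outer(gy, gx)
      zf <- exp(-(z_pos - zs[i])^2 / (2 * imaging$psf_sigma_z_um^2))
      for (k in seq_len(Z)) {
        if (zf[k] > 1e-4) {
          st_ch[rows, cols, k] <- st_ch[rows, cols, k] + zf[k] * patch
        }
      }
    }
    stacks[[ch]] <- st_ch
  }
  stacks
}

apply_noise <- function(stack, noise) {
  lambda <- stack + noise$background
  if (noise$poisson) {
    stack <- array(stats::rpois(length(lambda), lambda), dim = dim(lambda))
  } else {
    stack <- lambda
  }
  if (noise$read_sd > 0) {
    stack <- stack + array(stats::rnorm(length(stack), 0, noise$read_sd),
                           dim = dim(stack))
    stack[stack < 0] <- 0
  }
  stack
}

#' Simulate one imaging field with ground truth
#'
#' Places non-overlapping elliptical nuclei in a field, draws per-allele
#' breakage/translocation states and true spot positions from the cell
#' model, renders a DAPI z-stack plus three FISH channel z-stacks (each spot
#' a 3D Gaussian), and applies the configured noise. Returns both the images
#' and the exact ground truth, so that downstream stages can be validated
#' spot by spot.
#'
#' @param cell_model A [cell_model()].
#' @param n_cells Number of nuclei to place (may be 0).
#' @param imaging An [imaging_config()].
#' @param noise A [noise_spec()], a list of its fields, or `"none"`.
#' @param seed Integer seed; identical seeds and arguments give bit-identical
#'   output. `NULL` uses the current RNG state.
#' @param field_id Label stored in the ground-truth tables.
#' @param render If `FALSE`, skip image rendering and return ground truth
#'   with empty stacks (fast path for distribution-level studies).
#'
#' @return A list of class `sim_field` with elements `field` (a
#'   `field_image`: list of per-channel `[row, col, z]` stacks plus the
#'   imaging config) and `truth` (a `ground_truth`: data frames `cells`,
#'   `alleles`, `spots`; coordinates in 0-based pixels).
#' @export
#' @examples
#' sf <- simulate_field(cell_model(p_break = 0.5), n_cells = 4,
#'                      imaging = imaging_config(field_shape_px = c(128, 128)),
#'                      seed = 1)
#' table(sf$truth$alleles$state)
simulate_field <- function(cell_model, n_cells,
                           imaging = imaging_config(),
                           noise = noise_spec(),
                           seed = NULL,
                           field_id = "f001",
                           render = TRUE) {
  stopifnot(inherits(cell_model, "cell_model"),
            inherits(imaging, "imaging_config"),
            n_cells >= 0)
  noise <- as_noise_spec(noise)
  with_local_seed(seed, {
    axes_px <- cell_model$nucleus_axes_um / imaging$pixel_size_um
    ells <- place_nuclei(n_cells, imaging$field_shape_px, axes_px)

    cid_all <- sprintf("c%03d", seq_along(ells))
    tr_all <- vector("list", length(ells))
    for (i in seq_along(ells)) {
      tr_all[[i]] <- sample_cell_truth(ells[[i]], cell_model, imaging)
    }
    nspots <- vapply(tr_all, function(t) length(t$channel), integer(1))
    cells <- data.frame(
      field_id = rep(field_id, length(ells)),
      cell_id = cid_all,
      x = vapply(ells, `[[`, numeric(1), "x"),
      y = vapply(ells, `[[`, numeric(1), "y"),
      a_px = vapply(ells, `[[`, numeric(1), "a"),
      b_px = vapply(ells, `[[`, numeric(1), "b"),
      theta = vapply(ells, `[[`, numeric(1), "theta"),
      stringsAsFactors = FALSE)
    nA <- cell_model$n_alleles_A
    alleles <- data.frame(
      field_id = rep(field_id, nA * length(ells)),
      cell_id = rep(cid_all, each = nA),
      allele_id = rep(sprintf("A%d", seq_len(nA)), times = length(ells)),
      state = as.character(unlist(lapply(tr_all, `[[`, "states"))),
      stringsAsFactors = FALSE)
    spots <- data.frame(
      field_id = rep(field_id, sum(nspots)),
      cell_id = rep(cid_all, times = nspots),
      channel = as.character(unlist(lapply(tr_all, `[[`, "channel"))),
      allele_id = as.character(unlist(lapply(tr_all, `[[`, "allele_id"))),
      x = as.numeric(unlist(lapply(tr_all, `[[`, "x"))),
      y = as.numeric(unlist(lapply(tr_all, `[[`, "y"))),
      z_um = as.numeric(unlist(lapply(tr_all, `[[`, "z_um"))),
      stringsAsFactors = FALSE)
    truth <- structure(list(cells = cells, alleles = alleles, spots = spots),
                       class = "ground_truth")

    stacks <- NULL
    if (render) {
      stacks <- render_field_stacks(ells, truth$spots, imaging)
      stacks <- lapply(stacks, apply_noise, noise = noise)
    }
    structure(list(
      field = structure(list(field_id = field_id, stacks = stacks,
                             imaging = imaging), class = "field_image"),
      truth = truth
    ), class = "sim_field")
  })
}

# Deterministic per-field seed stream derived from one master seed: seeds are
# (master + 7919 * counter) mod (2^31 - 1), counter running over fields in
# generation order.
field_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) + 7919 * counter) %% 2147483647)
}

#' Simulate a multi-condition imaging experiment on disk
#'
#' Generates one directory per condition, each containing per-field,
#' per-channel multi-page TIFF z-stacks plus tab-delimited ground-truth
#' tables, laid out so the dataset can be fed directly to [run_pipeline()].
#' Condition labels double as directory names and are intended to follow the
#' underscore-delimited metadata convention parsed by [parse_metadata()]
#' (`<experiment(2 tokens)>_<cellline>_<construct>_<probeset>_<treatment>`).
#'
#' @param conditions A list; each element a list with `label` (unique string),
#'   `cell_model` (a [cell_model()]) and `n_cells` (total cells to simulate).
#' @param out_dir Output directory (created; see `overwrite`).
#' @param imaging An [imaging_config()].
#' @param noise A [noise_spec()] applied to every field.
#' @param seed Master integer seed; per-field seeds are derived from it by a
#'   fixed counter scheme so each field is independently reproducible.
#' @param cells_per_field Nuclei per simulated field.
#' @param overwrite Refuse to write into an existing `out_dir` unless `TRUE`.
#'
#' @return Invisibly, a manifest list with per-condition field file paths and
#'   ground-truth tables.
#' @export
simulate_experiment <- function(conditions, out_dir,
                                imaging = imaging_config(),
                                noise = noise_spec(),
                                seed = 1L,
                                cells_per_field = 10L,
                                overwrite = FALSE) {
  labels <- vapply(conditions, function(co) co$label, character(1))
  if (anyDuplicated(labels)) {
    stop("condition labels must be unique", call. = FALSE)
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output path ", out_dir,
         " exists and is not empty; pass overwrite = TRUE to replace it",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counter <- 0L
  manifest <- list()
  for (co in conditions) {
    cdir <- file.path(out_dir, co$label)
    dir.create(cdir, showWarnings = FALSE)
    n_fields <- ceiling(co$n_cells / cells_per_field)
    remaining <- co$n_cells
    truth_acc <- list()
    files <- character(0)
    for (f in seq_len(n_fields)) {
      counter <- counter + 1L
      fid <- sprintf("f%03d", f)
      n_here <- min(cells_per_field, remaining)
      remaining <- remaining - n_here
      sim <- simulate_field(co$cell_model, n_here, imaging, noise,
                            seed = field_seed(seed, counter),
                            field_id = fid)
      for (ch in imaging$channels) {
        p <- file.path(cdir, sprintf("%s_%s_%s.tif", co$label, fid, ch))
        write_stack(sim$field$stacks[[ch]], p)
        files <- c(files, p)
      }
      truth_acc[[f]] <- sim$truth
    }
    truth <- list(
      cells = do.call(rbind, lapply(truth_acc, `[[`, "cells")),
      alleles = do.call(rbind, lapply(truth_acc, `[[`, "alleles")),
      spots = do.call(rbind, lapply(truth_acc, `[[`, "spots"))
    )
    meta <- c(condition = co$label, cell_model = co$cell_model$name,
              n_cells = co$n_cells, seed = seed)
    for (nm in names(truth)) {
      if (is.null(truth[[nm]])) next
      write_ba_table(truth[[nm]],
                     file.path(cdir, sprintf("ground_truth_%s.tsv", nm)),
                     meta = meta)
    }
    manifest[[co$label]] <- list(dir = cdir, files = files, truth = truth)
  }
  invisible(manifest)
}

#' Spot detection accuracy against ground truth
#'
#' Greedily matches detected spot centroids to ground-truth positions within
#' a radius (closest pairs first, one-to-one) and reports the fraction of
#' ground-truth spots recovered, per channel.
#'
#' @param truth_spots Ground-truth spot table (`channel`, `x`, `y`, plus
#'   optional `field_id`).
#' @param detected_spots Detected spot table in the dialect produced by
#'   [analyze_field()] (`channel`, `x`, `y`, optional `field_id`).
#' @param radius_px Maximum match distance in pixels.
#' @return A data frame with one row per channel: `channel`, `n_truth`,
#'   `n_matched`, `accuracy` (fraction).
#' @export
detection_accuracy <- function(truth_spots, detected_spots, radius_px = 2) {
  if (!"field_id" %in% names(truth_spots)) truth_spots$field_id <- "f"
  if (!"field_id" %in% names(detected_spots)) detected_spots$field_id <- "f"
  channels <- sort(unique(truth_spots$channel))
  res <- lapply(channels, function(ch) {
    tt <- truth_spots[truth_spots$channel == ch, ]
    dd <- detected_spots[detected_spots$channel == ch, ]
    matched <- 0L
    for (fid in unique(tt$field_id)) {
      t1 <- tt[tt$field_id == fid, c("x", "y")]
      d1 <- dd[dd$field_id == fid, c("x", "y")]
      if (nrow(t1) == 0L || nrow(d1) == 0L) next
      dm <- sqrt(outer(t1$x, d1$x, "-")^2 + outer(t1$y, d1$y, "-")^2)
      while (TRUE) {
        m <- which.min(dm)
        if (!length(m) || dm[m] > radius_px) break
        ij <- arrayInd(m, dim(dm))
        matched <- matched + 1L
        dm[ij[1], ] <- Inf
        dm[, ij[2]] <- Inf
        if (all(is.infinite(dm))) break
      }
    }
    data.frame(channel = ch, n_truth = nrow(tt), n_matched = matched,
               accuracy = if (nrow(tt)) matched / nrow(tt) else NA_real_)
  })
  do.call(rbind, res)
}
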