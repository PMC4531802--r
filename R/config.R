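#' Imaging configuration
#'
#' Acquisition geometry shared by the synthetic-imaging simulator and the
#' analysis pipeline: lateral pixel size, z sampling, field dimensions, the
#' role of each acquired channel, and the optical/photon parameters used when
#' rendering synthetic images.
#'
#' Defaults mirror a 40x high-throughput confocal acquisition with camera
#' binning of 2: a pixel size of 0.32 um and seven z-planes spaced 1.5 um
#' apart, with DAPI plus three FISH channels (Green/Red/FarRed) acquired
#' sequentially.
#'
#' @param pixel_size_um Lateral size of one pixel in micrometers.
#' @param z_planes Number of z-planes per stack.
#' @param z_spacing_um Axial distance between consecutive z-planes (um).
#' @param field_shape_px Integer vector `c(height, width)` of the field in
#'   pixels.
#' @param channels Character vector of channel roles, each of
#'   `"DAPI"`, `"Green"`, `"Red"`, `"FarRed"` exactly once, in acquisition
#'   order.
#' @param psf_sigma_px Lateral standard deviation of the Gaussian point
#'   spread function used to render FISH spots, in pixels. The default 0.45
#'   px corresponds to a diffraction-limited spot of roughly one pixel full
#'   width at half maximum at this pixel size.
#' @param psf_sigma_z_um Axial standard deviation of the spot PSF (um).
#' @param spot_amplitude Expected photon count in the brightest pixel of an
#'   in-focus FISH spot.
#' @param dapi_amplitude Expected photon count of the DAPI signal inside a
#'   nucleus at the central z-plane.
#' @param dapi_sigma_z_um Axial extent (Gaussian sd, um) of the rendered
#'   nuclear DAPI signal.
#'
#' @return An object of class `imaging_config`.
#' @export
#' @examples
#' cfg <- imaging_config(field_shape_px = c(128, 128))
#' cfg$pixel_size_um
imaging_config <- function(pixel_size_um = 0.32,
                           z_planes = 7,
                           z_spacing_um = 1.5,
                           field_shape_px = c(192L, 192L),
                           channels = c("DAPI", "Green", "Red", "FarRed"),
                           psf_sigma_px = 0.45,
                           psf_sigma_z_um = 0.75,
                           spot_amplitude = 400,
                           dapi_amplitude = 150,
                           dapi_sigma_z_um = 2.0) {
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            pixel_size_um > 0)
  z_planes <- as.integer(z_planes)
  stopifnot(z_planes >= 1L, z_spacing_um > 0)
  field_shape_px <- as.integer(field_shape_px)
  stopifnot(length(field_shape_px) == 2L, all(field_shape_px >= 8L))
  if (!setequal(channels, c("DAPI", "Green", "Red", "FarRed")) ||
      length(channels) != 4L) {
    stop("`channels` must contain DAPI, Green, Red and FarRed exactly once",
         call. = FALSE)
  }
  stopifnot(psf_sigma_px > 0, psf_sigma_z_um > 0,
            spot_amplitude > 0, dapi_amplitude > 0, dapi_sigma_z_um > 0)
  structure(list(
    pixel_size_um = pixel_size_um,
    z_planes = z_planes,
    z_spacing_um = z_spacing_um,
    field_shape_px = field_shape_px,
    channels = channels,
    psf_sigma_px = psf_sigma_px,
    psf_sigma_z_um = psf_sigma_z_um,
    spot_amplitude = spot_amplitude,
    dapi_amplitude = dapi_amplitude,
    dapi_sigma_z_um = dapi_sigma_z_um
  ), class = "imaging_config")
}

#' Cell allele model for the simulator
#'
#' Describes a cell population for synthetic imaging: how many break-apart
#' probe loci (gene A, labelled by paired Red/Green probes) and how many
#' third-color partner loci (gene B, FarRed) each cell carries, the per-allele
#' probability of a breakage event, the conditional probability that a broken
#' allele is joined to a gene-B partner (translocation), and the spatial
#' offsets that separate the probe signals in each state.
#'
#' The default allele counts describe a cell line with three gene-A and two
#' gene-B alleles, the modal configuration observed for the
#' translocation-negative line used to calibrate the assay.
#'
#' @param name Label for the model (e.g. a cell-line name).
#' @param n_alleles_A Number of break-apart (Red/Green) loci per cell.
#' @param n_alleles_B Number of partner (FarRed) loci per cell.
#' @param p_break Per-allele probability that a gene-A allele is broken.
#' @param p_transloc_given_break Conditional probability that a broken allele
#'   is translocated, i.e. joined to a gene-B partner.
#' @param intact_offset_um Mean Red/Green separation at an intact allele (um).
#'   Drawn from a Rayleigh distribution with this mean; the default of
#'   0.32 um equals one pixel, matching a median observed Red/Green distance
#'   of one pixel at intact loci.
#' @param broken_offset_um Mean Red/Green separation at a broken allele (um).
#' @param proximity_offset_um Mean Red/FarRed separation at a translocated
#'   allele (um).
#' @param nucleus_axes_um Length-2 range (um) from which each nuclear
#'   semi-axis is drawn uniformly.
#' @param territory_spacing_um Minimum distance between two loci of the same
#'   gene (um). Distinct alleles reside in distinct chromosome territories
#'   and are practically never found within a micrometer of each other;
#'   loci of different genes remain unconstrained, preserving the random
#'   cross-channel proximity background.
#'
#' @return An object of class `cell_model`.
#' @export
#' @examples
#' mac2a_like <- cell_model("M2A", p_break = 0)
#' k299_like <- cell_model("K299", n_alleles_A = 4, n_alleles_B = 4,
#'                         p_break = 0.5, p_transloc_given_break = 1)
cell_model <- function(name = "cell",
                       n_alleles_A = 3L,
                       n_alleles_B = 2L,
                       p_break = 0,
                       p_transloc_given_break = 0,
                       intact_offset_um = 0.32,
                       broken_offset_um = 3.2,
                       proximity_offset_um = 0.32,
                       nucleus_axes_um = c(4.5, 6.0),
                       territory_spacing_um = 2.0) {
  n_alleles_A <- as.integer(n_alleles_A)
  n_alleles_B <- as.integer(n_alleles_B)
  stopifnot(n_alleles_A >= 0L, n_alleles_B >= 0L,
            p_break >= 0, p_break <= 1,
            p_transloc_given_break >= 0, p_transloc_given_break <= 1,
            intact_offset_um > 0, proximity_offset_um > 0,
            length(nucleus_axes_um) == 2L, all(nucleus_axes_um > 0),
            nucleus_axes_um[1] <= nucleus_axes_um[2],
            territory_spacing_um >= 0)
  if (broken_offset_um <= intact_offset_um) {
    stop("`broken_offset_um` must exceed `intact_offset_um`", call. = FALSE)
  }
  structure(list(
    name = as.character(name),
    n_alleles_A = n_alleles_A,
    n_alleles_B = n_alleles_B,
    p_break = p_break,
    p_transloc_given_break = p_transloc_given_break,
    intact_offset_um = intact_offset_um,
    broken_offset_um = broken_offset_um,
    proximity_offset_um = proximity_offset_um,
    nucleus_axes_um = nucleus_axes_um,
    territory_spacing_um = territory_spacing_um
  ), class = "cell_model")
}

#' Noise specification for synthetic imaging
#'
#' @param background Mean background photon count added to every pixel before
#'   shot noise.
#' @param poisson Apply Poisson (shot) noise to the photon image?
#' @param read_sd Standard deviation of additive Gaussian camera read noise
#'   (photon-equivalent counts).
#'
#' @return An object of class `noise_spec`. `noise_spec("none")` disables all
#'   noise sources.
#' @export
#' @examples
#' noise_spec()          # default: shot noise over background 20, read sd 3
#' noise_spec("none")    # noiseless rendering
noise_spec <- function(background = 20, poisson = TRUE, read_sd = 3) {
  if (identical(background, "none")) {
    background <- 0; poisson <- FALSE; read_sd <- 0
  }
  stopifnot(is.numeric(background), length(background) == 1L,
            background >= 0,
            is.logical(poisson), length(poisson) == 1L, !is.na(poisson),
            is.numeric(read_sd), length(read_sd) == 1L, read_sd >= 0)
  structure(list(background = background, poisson = poisson,
                 read_sd = read_sd), class = "noise_spec")
}

as_noise_spec <- function(noise) {
  if (inherits(noise, "noise_spec")) return(noise)
  if (is.null(noise) || identical(noise, "none")) return(noise_spec("none"))
  if (is.list(noise)) return(do.call(noise_spec, noise))
  stop("invalid noise specification", call. = FALSE)
}

#' Nucleus segmentation parameters
#'
#' @param blur_sigma Gaussian smoothing sd (px) applied to the DAPI
#'   projection before Otsu thresholding.
#' @param area_range Admissible nuclear area range `c(min, max)` in px^2;
#'   nuclei outside it are flagged excluded.
#' @param min_roundness Minimum roundness `4*pi*A/P^2`; rougher objects are
#'   flagged excluded.
#' @param watershed Split touching nuclei by watershed on the distance map?
#'   Off by default.
#'
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(blur_sigma = 2,
                       area_range = c(500, 15000),
                       min_roundness = 0.5,
                       watershed = FALSE) {
  stopifnot(blur_sigma > 0, length(area_range) == 2L,
            area_range[1] > 0, area_range[1] < area_range[2],
            min_roundness > 0, min_roundness <= 1,
            is.logical(watershed))
  structure(list(blur_sigma = blur_sigma, area_range = area_range,
                 min_roundness = min_roundness, watershed = watershed),
            class = "seg_params")
}

#' Spot detection parameters
#'
#' Spots are detected by band-pass filtering (difference of Gaussians at the
#' spot scale), local-maximum search inside the nuclear mask, a robust
#' intensity threshold at `median + k_mad * MAD` of the band-passed signal
#' within the nucleus, and intensity-weighted sub-pixel centroid refinement.
#'
#' @param dog_sigma1 Narrow Gaussian sd (px) of the band-pass filter; match
#'   to the spot scale.
#' @param dog_sigma2 Wide Gaussian sd (px) of the band-pass filter.
#' @param k_mad Threshold multiplier on the within-nucleus MAD.
#' @param min_separation_px Minimum allowed distance between detected spots;
#'   the brighter of two closer peaks is kept.
#' @param centroid_halfwin Half-width of the square window (px) used for the
#'   intensity-weighted sub-pixel centroid.
#' @param upsample Integer magnification applied (bilinear) to the
#'   band-passed image before the local-maximum search. On the original
#'   pixel grid two spots little more than a pixel apart fall into each
#'   other's 3x3 neighbourhoods and cannot yield two maxima; searching on a
#'   finer grid resolves pairs down to near the band-pass bimodality limit.
#'
#' @return An object of class `spot_params`.
#' @export
spot_params <- function(dog_sigma1 = 0.45,
                        dog_sigma2 = 2.0,
                        k_mad = 7,
                        min_separation_px = 0.9,
                        centroid_halfwin = 1L,
                        upsample = 3L) {
  stopifnot(dog_sigma1 > 0, dog_sigma2 > dog_sigma1, k_mad > 0,
            min_separation_px >= 0, centroid_halfwin >= 1L,
            upsample >= 1L)
  structure(list(dog_sigma1 = dog_sigma1, dog_sigma2 = dog_sigma2,
                 k_mad = k_mad, min_separation_px = min_separation_px,
                 centroid_halfwin = as.integer(centroid_halfwin),
                 upsample = as.integer(upsample)),
            class = "spot_params")
}

#' Event-calling distance thresholds
#'
#' A Red signal whose minimum Red/Green distance exceeds `proximity_px` is a
#' breakage event; if its minimum Red/FarRed distance is simultaneously at or
#' below `proximity_px` it is a translocation event. Signals separated by
#' `proximity_px` or fewer pixels are considered proximal (part of the same
#' or a joined locus).
#'
#' @param proximity_px Distance threshold in pixels (default 4, i.e. 1.28 um
#'   at a 0.32 um pixel).
#' @param pixel_size_um Pixel size used when reporting distances in
#'   micrometers, and for converting micrometer-coordinates on input.
#'
#' @return An object of class `ba_thresholds`.
#' @export
#' @examples
#' thresholds()               # 4 px = 1.28 um
ba_thresholds <- function(proximity_px = 4, pixel_size_um = 0.32) {
  stopifnot(is.numeric(proximity_px), length(proximity_px) == 1L,
            proximity_px > 0,
            is.numeric(pixel_size_um), pixel_size_um > 0)
  structure(list(proximity_px = proximity_px,
                 pixel_size_um = pixel_size_um),
            class = "ba_thresholds")
}

#' @rdname ba_thresholds
#' @export
thresholds <- ba_thresholds

#' Read or write a run configuration
#'
#' A run configuration gathers the imaging geometry, segmentation, spot and
#' threshold parameters plus input/output paths and a seed. It round-trips
#' through YAML or JSON unchanged.
#'
#' @param path File to read/write; format chosen by extension (`.yaml`,
#'   `.yml` or `.json`).
#' @param config For [write_run_config()], a list as returned by
#'   [run_config()].
#' @name run_config_io
NULL

#' Assemble a run configuration
#'
#' @param input_dir,output_dir Dataset and result directories.
#' @param imaging An [imaging_config()].
#' @param segmentation A [seg_params()].
#' @param spots A [spot_params()].
#' @param thresholds A [ba_thresholds()].
#' @param seed Integer seed recorded for provenance.
#' @param log_level One of `"info"`, `"quiet"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       imaging = imaging_config(),
                       segmentation = seg_params(),
                       spots = spot_params(),
                       thresholds = ba_thresholds(),
                       seed = 1L,
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 imaging = imaging, segmentation = segmentation,
                 spots = spots, thresholds = thresholds,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_class)
  }
  attributes(x) <- attributes(x)["names"]
  x
}

#' @rdname run_config_io
#' @export
write_run_config <- function(config, path) {
  plain <- strip_class(unclass(config))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported config format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname run_config_io
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  plain <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext, call. = FALSE)
  }
  run_config(
    input_dir = plain$input_dir,
    output_dir = plain$output_dir,
    imaging = do.call(imaging_config, plain$imaging),
    segmentation = do.call(seg_params, plain$segmentation),
    spots = do.call(spot_params, plain$spots),
    thresholds = do.call(ba_thresholds, plain$thresholds),
    seed = plain$seed,
    log_level = plain$log_level
  )
}
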