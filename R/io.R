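# Reading and writing image stacks, delimited result tables with provenance
# preambles, and filename-encoded experimental metadata.

#' Write / read a z-stack as a multi-page TIFF
#'
#' Stacks are stored as 16-bit multi-page TIFFs, one page per z-plane, with
#' photon counts mapped linearly onto the 16-bit range (counts are clipped at
#' 65535). [read_stack()] inverts the mapping, returning counts.
#'
#' @param stack `[row, col, z]` numeric array of photon counts.
#' @param path File path (`.tif`).
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a `[row, col, z]` array.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  planes <- lapply(seq_len(dim(stack)[3]), function(k) {
    m <- stack[, , k]
    m[m < 0] <- 0
    m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(planes)) planes <- list(planes)
  arr <- array(0, dim = c(dim(planes[[1]]), length(planes)))
  for (k in seq_along(planes)) arr[, , k] <- planes[[k]] * 65535
  arr
}

#' Write / read a whole field as one multi-channel TIFF
#'
#' The single-file dialect stores all channels of a field in one multi-page
#' TIFF, channel-major (all z-planes of the first channel, then all z-planes
#' of the second, ...), in the channel order of the imaging configuration.
#' The per-channel-file dialect written by [simulate_experiment()] is read
#' back with [read_field_image()].
#'
#' @param field A `field_image` (see [analyze_field()] for the layout).
#' @param path Output `.tif` path.
#' @param imaging An [imaging_config()] describing the stored geometry.
#' @param field_id Field label to attach on reading.
#' @return The written path, invisibly / a `field_image`.
#' @export
write_field_tiff <- function(field, path) {
  chans <- field$imaging$channels
  planes <- list()
  for (ch in chans) {
    st <- field$stacks[[ch]]
    for (k in seq_len(dim(st)[3])) {
      m <- st[, , k]
      m[m < 0] <- 0; m[m > 65535] <- 65535
      planes[[length(planes) + 1L]] <- m / 65535
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path, imaging = imaging_config(),
                            field_id = "f001") {
  planes <- tiff::readTIFF(path, all = TRUE)
  nz <- imaging$z_planes
  if (length(planes) != nz * length(imaging$channels)) {
    stop("page count does not match the imaging configuration (",
         length(planes), " pages, expected ",
         nz * length(imaging$channels), ")", call. = FALSE)
  }
  stacks <- list()
  for (i in seq_along(imaging$channels)) {
    arr <- array(0, dim = c(dim(planes[[1]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- planes[[(i - 1L) * nz + k]] * 65535
    stacks[[imaging$channels[i]]] <- arr
  }
  structure(list(field_id = field_id, stacks = stacks, imaging = imaging),
            class = "field_image")
}

#' Read one field from per-channel stack files
#'
#' @param dir Directory holding the files.
#' @param base File-name prefix; channel `ch` is read from
#'   `<base>_<ch>.tif`.
#' @param imaging An [imaging_config()].
#' @param field_id Field label.
#' @return A `field_image`.
#' @export
read_field_image <- function(dir, base, imaging = imaging_config(),
                             field_id = base) {
  stacks <- list()
  for (ch in imaging$channels) {
    p <- file.path(dir, sprintf("%s_%s.tif", base, ch))
    if (!file.exists(p)) {
      stop("missing channel file: ", p, call. = FALSE)
    }
    stacks[[ch]] <- read_stack(p)
  }
  structure(list(field_id = field_id, stacks = stacks, imaging = imaging),
            class = "field_image")
}

#' Write / read a result table with a provenance preamble
#'
#' Tables are UTF-8, tab-delimited, one header line, preceded by
#' `#`-prefixed key/value provenance lines (package version, timestamp-free
#' parameters, etc.). [read_ba_table()] skips the preamble.
#'
#' @param df Data frame (list-columns are dropped with a warning).
#' @param path Output path.
#' @param meta Named character vector written as `# key: value` lines.
#' @return The path, invisibly / the data frame.
#' @export
write_ba_table <- function(df, path, meta = character(0)) {
  is_list <- vapply(df, is.list, logical(1))
  if (any(is_list)) {
    warning("dropping list-columns: ",
            paste(names(df)[is_list], collapse = ", "))
    df <- df[!is_list]
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# bafish %s",
                     as.character(utils::packageVersion("bafish"))), con)
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ba_table
#' @export
read_ba_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Parse experimental metadata from a file or directory name
#'
#' Names follow the underscore-delimited convention
#' `<experiment(2 tokens)>_<cellline>_<construct>_<probeset>_<treatment>`,
#' e.g. `BC_140713_K299_K299_ALK_UN`: the first two tokens form the
#' experiment name, followed by cell line, transfected construct, FISH probe
#' set and treatment. Non-conforming names raise an error of class
#' `bafish_parse_error` so callers can report rather than silently skip
#' them.
#'
#' @param name Path-like string; directory components and a `.tif`/`.tsv`
#'   extension are stripped.
#' @return List with `experiment`, `cell_line`, `construct`, `probe_set`,
#'   `treatment` (all non-empty).
#' @export
#' @examples
#' parse_metadata("BC_140815_M2A_GFP_ALK_IR")
parse_metadata <- function(name) {
  base <- tools::file_path_sans_ext(basename(name))
  tok <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(tok) != 6L || any(!nzchar(tok))) {
    stop(structure(class = c("bafish_parse_error", "error", "condition"),
                   list(message = paste0(
                     "cannot parse metadata from '", base,
                     "': expected 6 underscore-delimited tokens ",
                     "(experiment x2, cell line, construct, probe set, ",
                     "treatment), got ", length(tok)),
                     call = NULL)))
  }
  list(experiment = paste(tok[1], tok[2], sep = "_"),
       cell_line = tok[3], construct = tok[4],
       probe_set = tok[5], treatment = tok[6])
}
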