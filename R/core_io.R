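#' @importFrom stats median mad sd quantile qt rnorm rpois runif rbinom setNames
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

CHANNEL_ROLES <- c("dna", "tubulin", "total_tau", "p_tau")

WELL_IDS_96 <- as.vector(outer(LETTERS[1:8], 1:12, paste0))

#' Construct a field image
#'
#' A field image bundles the four co-registered channel grids acquired from
#' one microscope field of a well: DNA stain (Hoechst), beta-III-tubulin,
#' total tau (pan-tau antibody) and phospho-tau. Intensities are arbitrary
#' detector units, stored as plain numeric matrices and never rescaled.
#'
#' @param channels named list of numeric matrices; names must be exactly
#'   `dna`, `tubulin`, `total_tau`, `p_tau`, all of identical dimension with
#'   finite, non-negative entries.
#' @param well_id plate coordinate such as `"B7"` (96-well grid A1--H12).
#' @param field_index integer in 0..24; position of the field within the
#'   well's acquisition layout.
#' @param pixel_size optional physical pixel size in micrometres.
#' @return an object of class `field_image`.
#' @export
field_image <- function(channels, well_id = "A1", field_index = 0L,
                        pixel_size = NULL) {
  if (!is.list(channels) || !setequal(names(channels), CHANNEL_ROLES))
    stop("incomplete field: channels must be named ",
         paste(CHANNEL_ROLES, collapse = ", "))
  channels <- channels[CHANNEL_ROLES]
  dims <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m), logical(1))))
    stop("channel grids must be matrices")
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("channel geometry mismatch")
  for (ch in CHANNEL_ROLES) {
    v <- channels[[ch]]
    if (any(!is.finite(v)) || any(v < 0))
      stop("channel '", ch, "' has non-finite or negative intensities")
  }
  structure(list(channels = channels,
                 well_id = as.character(well_id),
                 field_index = as.integer(field_index),
                 pixel_size = pixel_size),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$channels$dna)
  cat(sprintf("field_image %s/%02d  %d x %d px, 4 channels\n",
              x$well_id, x$field_index, d[1], d[2]))
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$channels$dna)

#' Read a multi-plane TIFF into a field image
#'
#' Planes are mapped to channel roles through an explicit `channel_map`;
#' channel identity is never inferred from plane order. Integer (8/16 bit)
#' and floating-point TIFFs are accepted and values are passed through
#' without rescaling.
#'
#' @param path a multi-plane TIFF file.
#' @param channel_map named integer vector mapping role -> plane index,
#'   e.g. `c(dna = 1, tubulin = 2, total_tau = 3, p_tau = 4)`.
#' @inheritParams field_image
#' @return a [field_image()].
#' @export
read_field <- function(path, channel_map = c(dna = 1, tubulin = 2,
                                             total_tau = 3, p_tau = 4),
                       well_id = "A1", field_index = 0L) {
  if (!setequal(names(channel_map), CHANNEL_ROLES))
    stop("incomplete field: channel_map must cover ",
         paste(CHANNEL_ROLES, collapse = ", "))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (max(channel_map) > length(planes))
    stop("incomplete field: TIFF has ", length(planes),
         " plane(s), channel_map needs plane ", max(channel_map))
  channels <- lapply(CHANNEL_ROLES, function(ch) {
    m <- planes[[channel_map[[ch]]]]
    if (length(dim(m)) == 3L) m <- m[, , 1]  # collapse spurious colour axis
    storage.mode(m) <- "double"
    m
  })
  names(channels) <- CHANNEL_ROLES
  field_image(channels, well_id = well_id, field_index = field_index)
}

#' Write a field image as a multi-plane 16-bit TIFF
#'
#' Intensities are rounded to integers and clipped to `[0, 65535]`; within
#' that range the write/read round trip is bit exact.
#'
#' @param field a [field_image()].
#' @param path output file path.
#' @export
write_field <- function(field, path) {
  planes <- lapply(field$channels, function(m) {
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Construct and validate a plate layout
#'
#' @param wells data.frame with columns `well_id`, `kind`
#'   (`dmso`, `positive_control`, `compound`, `empty`), `compound_id`
#'   (NA except for compounds) and `dose` (micromolar, NA except compounds
#'   and optionally positive controls).
#' @param plate_id plate identifier.
#' @param fields_per_well number of imaged fields per well (default 25).
#' @return an object of class `plate_layout`.
#' @export
plate_layout <- function(wells, plate_id = "plate1", fields_per_well = 25L) {
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  need <- c("well_id", "kind")
  if (!all(need %in% names(wells)))
    stop("layout needs columns: ", paste(need, collapse = ", "))
  if (is.null(wells$compound_id)) wells$compound_id <- NA_character_
  if (is.null(wells$dose)) wells$dose <- NA_real_
  wells$well_id <- toupper(trimws(as.character(wells$well_id)))
  wells$kind <- tolower(trimws(as.character(wells$kind)))
  kinds <- c("dmso", "positive_control", "compound", "empty")
  alias <- c(vehicle = "dmso", negative = "dmso", neg = "dmso",
             pos = "positive_control", control = "positive_control")
  hit <- wells$kind %in% names(alias)
  wells$kind[hit] <- alias[wells$kind[hit]]
  if (!all(wells$kind %in% kinds))
    stop("unknown treatment kind: ",
         paste(setdiff(wells$kind, kinds), collapse = ", "))
  bad <- !wells$well_id %in% WELL_IDS_96
  if (any(bad))
    stop("well id outside 96-well grid A1-H12: ",
         paste(wells$well_id[bad], collapse = ", "))
  if (anyDuplicated(wells$well_id))
    stop("duplicate well: ",
         paste(unique(wells$well_id[duplicated(wells$well_id)]), collapse = ", "))
  if (!any(wells$kind == "dmso"))
    stop("no negative control: at least one DMSO well is required")
  cmp <- wells$kind == "compound"
  if (any(cmp & (is.na(wells$dose) | !is.finite(wells$dose))))
    stop("every compound well needs a dose")
  wells$dose <- as.numeric(wells$dose)
  structure(list(plate_id = as.character(plate_id),
                 wells = wells[c("well_id", "kind", "compound_id", "dose")],
                 fields_per_well = as.integer(fields_per_well)),
            class = "plate_layout")
}

#' Read a plate layout from CSV or YAML
#'
#' CSV must carry columns `well_id,kind,compound_id,dose`; YAML mirrors the
#' same fields under a top-level `wells:` list plus optional `plate_id` and
#' `fields_per_well`.
#'
#' @param path file path ending in `.csv`, `.yml` or `.yaml`.
#' @return a [plate_layout()].
#' @export
read_plate_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    plate_layout(df)
  } else if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    wells <- do.call(rbind, lapply(y$wells, function(w)
      data.frame(well_id = w$well_id, kind = w$kind,
                 compound_id = w$compound_id %||% NA_character_,
                 dose = w$dose %||% NA_real_)))
    plate_layout(wells,
                 plate_id = y$plate_id %||% "plate1",
                 fields_per_well = y$fields_per_well %||% 25L)
  } else stop("unsupported layout format: .", ext)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write segmentation masks as 16-bit label TIFFs
#'
#' One single-plane file per mask role (`<prefix>_<role>.tif`); background
#' is 0 and labels are preserved exactly, so reading back reproduces the
#' label grid pixel for pixel.
#'
#' @param masks a `segmentation_masks` object (see [finalize_masks()]) or a
#'   named list of integer/logical matrices.
#' @param path output prefix; directory components are created.
#' @return invisibly, the vector of files written.
#' @export
write_masks <- function(masks, path) {
  grids <- Filter(function(x) is.matrix(x), unclass(masks))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (role in names(grids)) {
    m <- grids[[role]]
    storage.mode(m) <- "double"
    if (max(m) > 65535) stop("label overflow in mask '", role, "'")
    f <- paste0(path, "_", role, ".tif")
    tiff::writeTIFF(m / 65535, f, bits.per.sample = 16L, compression = "none")
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a label mask written by [write_masks()]
#' @param path a 16-bit label TIFF.
#' @return integer matrix of labels (background 0).
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Write a metrics table to CSV at full precision
#'
#' @param table data.frame of per-field or per-well metrics.
#' @param path output CSV path.
#' @export
write_metrics <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, formatC(x, digits = 17, format = "g"))
  })
  write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics()]
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metrics <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Default pipeline configuration
#'
#' One nested list holding the parameters of every stage (simulator,
#' segmentation, quantification, screen statistics) so that a run can log
#' the fully resolved parameter set. [read_config()] merges a user YAML
#' over these defaults.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(synth = unclass(synth_field_config()),
       segmentation = unclass(seg_params()),
       quantify = list(background_subtract = FALSE),
       screen = unclass(qc_thresholds()))
}

#' Read a YAML configuration, merged over package defaults
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested named list as [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  cfg
}
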