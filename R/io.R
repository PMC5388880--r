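#' Write a bolus cohort to disk as CSV manifest plus per-trace files
#'
#' One manifest row per (vessel, condition) pointing at a two-column CSV
#' (`time_s`, `fluorescence`), together with the ground-truth table.
#'
#' @param cohort a `bolus_cohort` with rendered traces.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_bolus_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bolus_cohort"))
  if (is.null(cohort$traces)) stop("cohort has no rendered traces")
  dir.create(file.path(dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- list()
  for (id in names(cohort$traces)) {
    for (cond in c("normocapnia", "hypercapnia")) {
      tr <- cohort$traces[[id]][[cond]]
      fn <- file.path("traces", paste0(id, "_", substr(cond, 1, 5), ".csv"))
      utils::write.csv(data.frame(time_s = tr$time,
                                  fluorescence = tr$fluorescence),
                       file.path(dir, fn), row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        vessel_id = id, vessel_type = attr(tr, "vessel_type"),
        condition = cond, trace_file = fn, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a bolus cohort written by [write_bolus_cohort()]
#'
#' @param dir directory holding `manifest.csv` and `traces/`.
#' @return named list of trace pairs usable by [fit_bolus_cohort()].
#' @export
read_bolus_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  ids <- unique(manifest$vessel_id)
  out <- lapply(ids, function(id) {
    rows <- manifest[manifest$vessel_id == id, ]
    pair <- lapply(stats::setNames(rows$trace_file, rows$condition),
                   function(fn) {
                     d <- utils::read.csv(file.path(dir, fn))
                     bolus_trace(d$time_s, d$fluorescence, vessel_id = id,
                                 vessel_type = rows$vessel_type[1])
                   })
    pair
  })
  names(out) <- ids
  out
}

#' Write / read an LFP recording as columnar text
#'
#' Two-column CSV (`sample_index`, `voltage`) with the sampling rate and
#' metadata in a JSON sidecar (`<file>.json`).
#'
#' @param rec an [lfp_recording()].
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_lfp_csv <- function(rec, file) {
  stopifnot(inherits(rec, "lfp_recording"))
  utils::write.csv(data.frame(sample_index = seq_along(rec$samples),
                              voltage = rec$samples),
                   file, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = rec$sampling_rate,
                            channel_id = rec$channel_id,
                            animal_id = rec$animal_id,
                            genotype = rec$genotype),
                       paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(file) {
  d <- utils::read.csv(file)
  meta <- jsonlite::read_json(paste0(file, ".json"))
  lfp_recording(d$voltage, meta$sampling_rate,
                channel_id = meta$channel_id %||% NA_character_,
                animal_id = meta$animal_id %||% NA_character_,
                genotype = meta$genotype %||% NA_character_)
}

#' Write / read a labeled mask as single-channel TIFF with JSON sidecar
#'
#' Integer labels are stored in a 16-bit grayscale TIFF; the physical
#' pixel size (micrometers per pixel) goes in `<file>.json`.
#'
#' @param mask integer matrix (0 background).
#' @param file TIFF path.
#' @param pixel_size micrometers per pixel.
#' @return `file`, invisibly.
#' @export
write_mask_tiff <- function(mask, file, pixel_size = 1) {
  m <- matrix(as.numeric(mask) / 65535, nrow(mask), ncol(mask))
  tiff::writeTIFF(m, file, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size = pixel_size,
                            max_label = max(mask)),
                       paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(file) {
  m <- tiff::readTIFF(file)
  meta <- jsonlite::read_json(paste0(file, ".json"))
  lab <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  attr(lab, "pixel_size") <- meta$pixel_size
  lab
}

#' Serialize an analysis report to JSON
#'
#' Deterministic JSON (no timestamps): identical inputs and seeds give
#' byte-identical files.
#'
#' @param report a report list (e.g. from [run_vascular_experiment()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report_json <- function(report, file) {
  clean <- .jsonable(report)
  jsonlite::write_json(clean, file, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(file)
}

# strip classes/attributes jsonlite cannot round-trip deterministically
.jsonable <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(unclass(x), .jsonable)
  } else if (is.data.frame(x)) {
    attr(x, "electrode_values") <- NULL
    attr(x, "statistic") <- NULL
  } else if (is.matrix(x)) {
    x <- apply(x, 1, identity, simplify = FALSE)
  }
  attributes(x)[setdiff(names(attributes(x)),
                        c("names", "row.names", "class"))] <- NULL
  x
}
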