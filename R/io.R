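# Readers and writers: dense spectra (RDS containers), peak lists (CSV/JSON),
# dataset manifests (JSON lines), vocabularies (JSON) and model checkpoints.

#' Write a spectrum or peak list to disk
#'
#' Dense spectra (`spectrum_1d`, `spectrum_hsqc`) are stored as self-describing
#' compressed RDS containers holding grid metadata and the intensity array at
#' full floating precision. Peak lists are stored as CSV
#' (`shift_ppm,intensity` for 1D, `h_ppm,c_ppm,intensity` for HSQC) or JSON
#' with the same field names, chosen by file extension.
#'
#' @param record a `spectrum_1d`, `spectrum_hsqc`, `peaklist_1d` or
#'   `peaklist_hsqc`.
#' @param path output path; extension `.rds`, `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(record, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(record, "spectrum_1d") || inherits(record, "spectrum_hsqc")) {
    if (ext != "rds") stop("dense spectra are written as .rds containers")
    saveRDS(record, path)
    return(invisible(path))
  }
  if (inherits(record, "peaklist_1d")) {
    df <- data.frame(shift_ppm = record$shift_ppm, intensity = record$intensity)
    if (ext == "csv") {
      con <- file(path, "w")
      writeLines(sprintf("# nucleus=%s", record$nucleus), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    } else if (ext == "json") {
      jsonlite::write_json(list(nucleus = record$nucleus,
                                shift_ppm = record$shift_ppm,
                                intensity = record$intensity),
                           path, digits = NA, auto_unbox = TRUE)
    } else stop("peak lists are written as .csv or .json")
    return(invisible(path))
  }
  if (inherits(record, "peaklist_hsqc")) {
    df <- data.frame(h_ppm = record$h_ppm, c_ppm = record$c_ppm,
                     intensity = record$intensity)
    if (ext == "csv") {
      utils::write.csv(df, path, row.names = FALSE)
    } else if (ext == "json") {
      jsonlite::write_json(list(h_ppm = record$h_ppm, c_ppm = record$c_ppm,
                                intensity = record$intensity),
                           path, digits = NA, auto_unbox = TRUE)
    } else stop("peak lists are written as .csv or .json")
    return(invisible(path))
  }
  stop("unsupported record type: ", paste(class(record), collapse = "/"))
}

.check_peak_fields <- function(df, fields, path) {
  for (f in fields) {
    if (!f %in% names(df))
      stop(sprintf("%s: missing field '%s'", path, f))
    if (!is.numeric(df[[f]]) || any(!is.finite(df[[f]])))
      stop(sprintf("%s: field '%s' must be finite numeric", path, f))
  }
  if (any(df$intensity < 0))
    stop(sprintf("%s: field 'intensity' contains negative values", path))
  df
}

#' Read a spectrum or peak list from disk
#'
#' Inverse of [write_spectrum()]; the record type is recovered from the file
#' content. Round-trips are lossless. Malformed files raise an error naming
#' the offending field.
#'
#' @param path file written by [write_spectrum()].
#' @return a `spectrum_1d`, `spectrum_hsqc`, `peaklist_1d` or `peaklist_hsqc`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "rds") {
    rec <- readRDS(path)
    if (!(inherits(rec, "spectrum_1d") || inherits(rec, "spectrum_hsqc")))
      stop(path, ": not a spectrum container")
    return(rec)
  }
  if (ext == "csv") {
    first <- readLines(path, n = 1L)
    if (startsWith(first, "# nucleus=")) {
      nucleus <- sub("# nucleus=", "", first)
      df <- utils::read.csv(path, comment.char = "#")
      df <- .check_peak_fields(df, c("shift_ppm", "intensity"), path)
      return(peaklist_1d(nucleus, df$shift_ppm, df$intensity))
    }
    df <- utils::read.csv(path)
    if (all(c("h_ppm", "c_ppm", "intensity") %in% names(df))) {
      df <- .check_peak_fields(df, c("h_ppm", "c_ppm", "intensity"), path)
      return(peaklist_hsqc(df$h_ppm, df$c_ppm, df$intensity))
    }
    if (all(c("shift_ppm", "intensity") %in% names(df)))
      stop(path, ": 1D peak-list CSV is missing its '# nucleus=' header line")
    stop(path, ": unrecognized peak-list CSV header")
  }
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(obj$nucleus)) {
      df <- .check_peak_fields(as.data.frame(obj[c("shift_ppm", "intensity")]),
                               c("shift_ppm", "intensity"), path)
      return(peaklist_1d(obj$nucleus, df$shift_ppm, df$intensity))
    }
    df <- .check_peak_fields(as.data.frame(obj[c("h_ppm", "c_ppm", "intensity")]),
                             c("h_ppm", "c_ppm", "intensity"), path)
    return(peaklist_hsqc(df$h_ppm, df$c_ppm, df$intensity))
  }
  stop("unsupported extension: .", ext)
}

#' Write a dataset manifest (JSON lines)
#'
#' One JSON object per record with fields `smiles`, `formula`, `heavy_atoms`,
#' `files` (path per modality), `split` and `seed`.
#'
#' @param manifest a `dataset_manifest` (see [build_dataset()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  lines <- vapply(manifest$records, function(r) {
    jsonlite::toJSON(list(smiles = r$smiles, formula = r$formula,
                          heavy_atoms = r$heavy_atoms, files = r$files,
                          split = manifest$split, seed = manifest$seed),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dataset manifest written by [write_manifest()]
#' @param path JSONL manifest path.
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  recs <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    list(smiles = o$smiles, formula = o$formula,
         heavy_atoms = as.integer(o$heavy_atoms),
         files = as.list(o$files))
  })
  o1 <- jsonlite::fromJSON(lines[[1]])
  structure(list(split = o1$split, seed = as.integer(o1$seed), records = recs),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest '%s': %d records, seed %d>\n",
              x$split, length(x$records), x$seed))
  invisible(x)
}

#' Write a vocabulary to JSON
#' @param vocab a `vocabulary` (see [build_vocab()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  jsonlite::write_json(list(version = 1L, token_to_id = as.list(vocab$token_to_id)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary written by [write_vocab()]
#' @param path JSON vocabulary path.
#' @return a `vocabulary`.
#' @export
read_vocab <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- unlist(obj$token_to_id)
  .new_vocab(ids)
}

#' Save a fitted model to a checkpoint file
#'
#' The checkpoint is a single self-describing RDS container holding the
#' parameters, the model configuration, the vocabulary and a hash of the
#' vocabulary for compatibility checks.
#'
#' @param object a fitted `nmr2mol` model.
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "nmr2mol"))
  saveRDS(object, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return a fitted `nmr2mol` model.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "nmr2mol")) stop(path, ": not an nmr2mol checkpoint")
  obj
}
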