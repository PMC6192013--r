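#' @include classes-dataset.R
NULL

## Canonical on-disk formats: wide CSV for spectra (header `time_s,<wl>,...`),
## long CSV for references (`sample_time_s,lod_percent[,excluded]`), and a
## YAML manifest tying a campaign together.

#' Read a batch of spectra from a wide CSV file
#'
#' The header row holds the wavelength grid in nm (first column `time_s`);
#' each subsequent row is one spectrum in lg(1/R) units. Rows are re-sorted
#' by time if needed.
#'
#' @param path path to a CSV file.
#' @param batchId batch label; defaults to the file name without extension.
#' @return a [SpectraBatch-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, batchId = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop("file not found: ", path)
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
    if (length(header) < 2L || header[1] != "time_s")
        stop("malformed spectra header in ", path,
             ": expected 'time_s,<wl_1>,...'")
    wl <- suppressWarnings(as.numeric(header[-1]))
    if (anyNA(wl))
        stop("non-numeric wavelength in header column ",
             which(is.na(wl))[1] + 1L, " of ", path)
    if (length(wl) > 1L && any(diff(wl) <= 0))
        stop("wavelength axis not strictly increasing in ", path)
    body <- utils::read.csv(path, header = TRUE, colClasses = "numeric",
                            check.names = FALSE)
    if (anyNA(body)) {
        bad <- which(apply(body, 1L, anyNA))[1]
        stop("non-numeric or missing cell in data row ", bad, " of ", path)
    }
    SpectraBatch(batchId, times = body[[1]], wavelengths = wl,
                 intensities = as.matrix(body[, -1, drop = FALSE]))
}

#' Write a batch of spectra to a wide CSV file
#'
#' Inverse of [readSpectra()]; the numeric round-trip is exact to full
#' double precision (values are written with 17 significant digits).
#'
#' @param batch a [SpectraBatch-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(batch, path) {
    stopifnot(is(batch, "SpectraBatch"))
    df <- data.frame(time_s = batch@times,
                     format(batch@intensities, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     check.names = FALSE)
    names(df)[-1] <- format(batch@wavelengths, digits = 17, trim = TRUE)
    ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
              silent = TRUE)
    if (inherits(ok, "try-error"))
        stop("cannot write spectra to ", path)
    invisible(path)
}

#' Read reference moisture samples from CSV
#'
#' Expected columns: `sample_time_s`, `lod_percent` and optionally
#' `excluded` (0/1). Negative LOD values are rejected.
#'
#' @param path path to a CSV file.
#' @param batchId batch label; defaults to the file name without extension.
#' @return a [ReferenceSet-class]; `excluded` defaults to `FALSE`.
#' @export
readReferences <- function(path,
                           batchId = sub("\\.[^.]*$", "", basename(path))) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.csv(path, header = TRUE)
    need <- c("sample_time_s", "lod_percent")
    if (!all(need %in% names(df)))
        stop("reference CSV ", path, " must have columns ",
             paste(need, collapse = ", "))
    if (any(df$lod_percent < 0))
        stop("negative LOD value in row ", which(df$lod_percent < 0)[1],
             " of ", path)
    exc <- if ("excluded" %in% names(df)) df$excluded != 0
           else rep(FALSE, nrow(df))
    ReferenceSet(batchId, df$sample_time_s, df$lod_percent, exc)
}

#' Write reference moisture samples to CSV
#'
#' @param refs a [ReferenceSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReferences <- function(refs, path) {
    stopifnot(is(refs, "ReferenceSet"))
    df <- data.frame(sample_time_s = format(refs@sampleTimes, digits = 17,
                                            trim = TRUE),
                     lod_percent = format(refs@lodValues, digits = 17,
                                          trim = TRUE),
                     excluded = as.integer(refs@excluded))
    ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
              silent = TRUE)
    if (inherits(ok, "try-error"))
        stop("cannot write references to ", path)
    invisible(path)
}

#' Read a campaign manifest
#'
#' The manifest is a YAML file listing one entry per batch:
#' ```yaml
#' batches:
#'   - id: B01
#'     spectra: B01_spectra.csv
#'     references: B01_refs.csv
#'     role: calibration
#' ```
#' Paths are resolved relative to the manifest location.
#'
#' @param path path to a manifest YAML file.
#' @return a [ProcessDataset-class].
#' @seealso [writeCampaign()]
#' @export
readCampaign <- function(path) {
    if (!file.exists(path))
        stop("manifest not found: ", path)
    man <- yaml::read_yaml(path)
    if (is.null(man$batches) || !length(man$batches))
        stop("manifest ", path, " lists no batches")
    dir <- dirname(path)
    batches <- list(); references <- list(); roles <- character()
    for (b in man$batches) {
        if (is.null(b$id) || is.null(b$spectra))
            stop("manifest entry lacks 'id' or 'spectra'")
        batches[[b$id]] <- readSpectra(file.path(dir, b$spectra),
                                       batchId = b$id)
        if (!is.null(b$references))
            references[[b$id]] <- readReferences(file.path(dir, b$references),
                                                 batchId = b$id)
        if (!is.null(b$role))
            roles[b$id] <- b$role
    }
    ProcessDataset(batches, references, roles)
}

#' Write a campaign to a directory with a manifest
#'
#' Writes one spectra CSV and one reference CSV per batch plus
#' `manifest.yaml` into `dir`.
#'
#' @param dataset a [ProcessDataset-class].
#' @param dir output directory, created if missing.
#' @return path of the manifest, invisibly.
#' @export
writeCampaign <- function(dataset, dir) {
    stopifnot(is(dataset, "ProcessDataset"))
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    entries <- list()
    for (id in batchIds(dataset)) {
        sf <- paste0(id, "_spectra.csv")
        writeSpectra(getBatch(dataset, id), file.path(dir, sf))
        entry <- list(id = id, spectra = sf)
        if (id %in% names(dataset@references)) {
            rf <- paste0(id, "_refs.csv")
            writeReferences(dataset@references[[id]], file.path(dir, rf))
            entry$references <- rf
        }
        if (id %in% names(dataset@roles))
            entry$role <- unname(dataset@roles[id])
        entries[[length(entries) + 1L]] <- entry
    }
    manifest <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(list(batches = entries), manifest)
    invisible(manifest)
}
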