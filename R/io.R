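#' @include AllClasses.R
NULL

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

.read_sidecar <- function(path, required = character()) {
  sp <- .sidecar_path(path)
  meta <- if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
          else list()
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0)
    stop("sidecar ", sp, " is missing required field(s): ",
         paste(missing, collapse = ", "))
  meta
}

.ext_of <- function(path) {
  if (grepl("\\.nii\\.gz$", path)) return("nii")
  tolower(tools::file_ext(path))
}

#' Write a planar image to disk
#'
#' NIfTI (`.nii` / `.nii.gz`) stores float pixels losslessly with spacing in
#' the header; TIFF (`.tif` / `.tiff`) stores 16-bit integer counts
#' (values must be whole numbers in 0..65535). Both get a JSON sidecar
#' (`<path>.json`) carrying spacing, view and identifiers.
#'
#' @param img a [PlanarImage-class].
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writePlanar <- function(img, path) {
  stopifnot(is(img, "PlanarImage"))
  px <- pixels(img)
  meta <- list(spacing_mm = img@spacingMm, view = img@view,
               patient_id = img@patientId, acquisition_id = img@acquisitionId)
  ext <- .ext_of(path)
  if (ext == "nii") {
    im <- RNifti::asNifti(px)
    im <- RNifti::`pixdim<-`(im, img@spacingMm)
    RNifti::writeNifti(im, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (any(px < 0) || any(px > 65535) || any(abs(px - round(px)) > 1e-6))
      stop("TIFF output stores 16-bit integer counts in 0..65535; ",
           "use NIfTI for float images")
    tiff::writeTIFF(round(px) / 65535, path, bits.per.sample = 16L)
    meta$intensity_scale <- 65535
  } else {
    stop("unsupported output format '", ext, "'; use .nii, .nii.gz or .tiff")
  }
  .write_sidecar(path, meta)
  invisible(path)
}

#' Read a planar image from disk
#'
#' Accepts NIfTI (2D, or 3D with a singleton third axis), 16-bit TIFF and
#' 16-bit PNG. Raster formats require a JSON sidecar with `spacing_mm`;
#' NIfTI takes spacing from the header and the sidecar (if present)
#' supplies view and identifiers. Negative pixels are rejected.
#'
#' @param path file path.
#' @return a [PlanarImage-class].
#' @export
readPlanar <- function(path) {
  ext <- .ext_of(path)
  if (ext == "nii") {
    im <- RNifti::readNifti(path)
    arr <- as.array(im)
    d <- dim(arr)
    if (length(d) == 3L && d[3] == 1L) {
      arr <- arr[, , 1]
      d <- dim(arr)
    }
    if (length(d) != 2L) stop("NIfTI image is not 2D (or squeezable 3D)")
    meta <- .read_sidecar(path)
    sp <- meta$spacing_mm %||% RNifti::pixdim(im)[1:2]
    px <- arr
  } else if (ext %in% c("tif", "tiff")) {
    meta <- .read_sidecar(path, required = "spacing_mm")
    v <- tiff::readTIFF(path)
    px <- round(v * (meta$intensity_scale %||% 65535))
    sp <- meta$spacing_mm
  } else if (ext == "png") {
    meta <- .read_sidecar(path, required = "spacing_mm")
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    px <- round(v * (meta$intensity_scale %||% 65535))
    sp <- meta$spacing_mm
  } else {
    stop("unsupported input format '", ext, "'")
  }
  if (any(px < 0)) stop("negative pixels in ", path)
  PlanarImage(matrix(as.numeric(px), nrow(px)), as.numeric(sp),
              meta$view %||% "pseudo", meta$patient_id %||% "",
              meta$acquisition_id %||% "")
}

#' Write / read a 3D activity volume (NIfTI)
#'
#' @param vol an [ActivityVolume-class].
#' @param path `.nii` / `.nii.gz` destination.
#' @return `path` (write) or an [ActivityVolume-class] (read).
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "ActivityVolume"))
  im <- RNifti::asNifti(vol@voxels)
  im <- RNifti::`pixdim<-`(im, vol@spacingMm)
  RNifti::writeNifti(im, path)
  .write_sidecar(path, list(spacing_mm = vol@spacingMm,
                            ap_axis = vol@apAxis))
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  im <- RNifti::readNifti(path)
  meta <- .read_sidecar(path)
  ActivityVolume(array(as.numeric(im), dim(im)),
                 as.numeric(meta$spacing_mm %||% RNifti::pixdim(im)[1:3]),
                 as.integer(meta$ap_axis %||% 3L))
}

#' Write a labelled cohort to disk
#'
#' One NIfTI per view per case plus a `labels.csv` with columns
#' `patient_id`, `acquisition_id`, `view`, `grade`, `uptake_fraction`,
#' `seed`. Ground-truth masks (when present) go to `masks/` as NIfTI.
#'
#' @param cases list of [LabeledCase-class].
#' @param dir output directory (created if needed).
#' @param seed cohort seed recorded in the label table.
#' @return the label table, invisibly.
#' @export
writeCohort <- function(cases, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cs in cases) {
    for (v in names(caseImages(cs))) {
      img <- caseImages(cs)[[v]]
      fn <- sprintf("%s_%s_%s.nii.gz", patientId(cs), acquisitionId(cs), v)
      writePlanar(img, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patientId(cs), acquisition_id = acquisitionId(cs),
        view = v, grade = caseGrade(cs),
        uptake_fraction = uptakeFraction(cs), seed = seed)
    }
    if (length(caseMasks(cs)) > 0) {
      mdir <- file.path(dir, "masks")
      dir.create(mdir, showWarnings = FALSE)
      for (s in names(caseMasks(cs))) {
        m <- caseMasks(cs)[[s]]
        fn <- sprintf("%s_%s_%s.nii.gz", patientId(cs), acquisitionId(cs), s)
        writePlanar(PlanarImage(m@data, m@spacingMm, "pseudo",
                                patientId(cs), acquisitionId(cs)),
                    file.path(mdir, fn))
      }
    }
  }
  tab <- do.call(rbind, rows)
  write.csv(tab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(tab)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir cohort directory containing `labels.csv`.
#' @return list of [LabeledCase-class].
#' @export
readCohort <- function(dir) {
  tab <- read.csv(file.path(dir, "labels.csv"),
                  colClasses = c(patient_id = "character",
                                 acquisition_id = "character"))
  out <- list()
  for (key in unique(paste(tab$patient_id, tab$acquisition_id))) {
    sub <- tab[paste(tab$patient_id, tab$acquisition_id) == key, ]
    imgs <- list()
    for (i in seq_len(nrow(sub))) {
      fn <- sprintf("%s_%s_%s.nii.gz", sub$patient_id[i],
                    sub$acquisition_id[i], sub$view[i])
      imgs[[sub$view[i]]] <- readPlanar(file.path(dir, fn))
    }
    masks <- list()
    mdir <- file.path(dir, "masks")
    if (dir.exists(mdir)) {
      for (s in .STRUCTURES) {
        fn <- file.path(mdir, sprintf("%s_%s_%s.nii.gz", sub$patient_id[1],
                                      sub$acquisition_id[1], s))
        if (file.exists(fn)) {
          mi <- readPlanar(fn)
          masks[[s]] <- LabelMask(pixels(mi), s, spacingMm(mi))
        }
      }
    }
    out[[length(out) + 1L]] <- LabeledCase(
      sub$patient_id[1], sub$acquisition_id[1], sub$grade[1], imgs,
      uptakeFraction = sub$uptake_fraction[1], masks = masks)
  }
  out
}
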