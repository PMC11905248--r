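# Case-directory layout: image/dose/masks as NIfTI plus a JSON manifest.
#
#   case_dir/
#     manifest.json                    names, prescription, fractions, grid
#     image.nii.gz  dose.nii.gz
#     masks/<structure>.nii.gz
#     daily_<k>/image.nii.gz  dose.nii.gz  truth_field.nii.gz  masks/...

#' Write a planning case to a directory
#'
#' @param case a [CaseBundle-class].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCase <- function(case, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  writeVolume(case@image, file.path(dir, "image.nii.gz"))
  writeVolume(case@planDose, file.path(dir, "dose.nii.gz"))
  for (nm in structureNames(case@structures))
    writeVolume(getMask(case@structures, nm) + 0,
                file.path(dir, "masks", paste0(nm, ".nii.gz")),
                grid = case@structures@grid)
  g <- case@image@grid
  manifest <- list(
    schema = "doseAccum-case-1",
    structures = as.list(structureNames(case@structures)),
    prescription_gy = case@prescriptionGy,
    n_fractions = case@nFractions,
    spacing_mm = g@spacing, origin_mm = g@origin, shape = g@shape,
    axes = c("RL", "AP", "SI")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a daily case under a planning case directory
#'
#' @param daily a [DailyCase-class].
#' @param dir the planning case directory.
#' @return the fraction subdirectory, invisibly.
#' @export
writeDailyCase <- function(daily, dir) {
  sub <- file.path(dir, sprintf("daily_%d", daily@fractionIndex))
  dir.create(file.path(sub, "masks"), recursive = TRUE, showWarnings = FALSE)
  writeVolume(daily@image, file.path(sub, "image.nii.gz"))
  writeVolume(daily@deliveredFractionDose, file.path(sub, "dose.nii.gz"))
  writeField(daily@truthField, file.path(sub, "truth_field.nii.gz"))
  for (nm in structureNames(daily@structures))
    writeVolume(getMask(daily@structures, nm) + 0,
                file.path(sub, "masks", paste0(nm, ".nii.gz")),
                grid = daily@structures@grid)
  invisible(sub)
}

#' @noRd
.readMasks <- function(dir, names, grid) {
  masks <- lapply(names, function(nm) {
    v <- readVolume(file.path(dir, paste0(nm, ".nii.gz")))
    array(v@voxels >= 0.5, dim(v@voxels))
  })
  structureSet(stats::setNames(masks, names), grid)
}

#' Read a planning case directory
#'
#' @param dir a directory written by [writeCase()].
#' @return a [CaseBundle-class].
#' @export
readCase <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  image <- readVolume(file.path(dir, "image.nii.gz"))
  dose <- readVolume(file.path(dir, "dose.nii.gz"))
  structures <- .readMasks(file.path(dir, "masks"),
                           manifest$structures, image@grid)
  new("CaseBundle", image = image, structures = structures, planDose = dose,
      nFractions = as.integer(manifest$n_fractions),
      prescriptionGy = as.numeric(manifest$prescription_gy))
}

#' Read a daily case subdirectory
#'
#' @param dir the planning case directory.
#' @param fraction fraction index k (subdirectory `daily_<k>`).
#' @param structures structure names; defaults to the planning manifest's.
#' @return a [DailyCase-class].
#' @export
readDailyCase <- function(dir, fraction, structures = NULL) {
  if (is.null(structures)) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    structures <- manifest$structures
  }
  sub <- file.path(dir, sprintf("daily_%d", fraction))
  if (!dir.exists(sub)) stop("missing fraction directory: ", sub)
  image <- readVolume(file.path(sub, "image.nii.gz"))
  dose <- readVolume(file.path(sub, "dose.nii.gz"))
  field <- readField(file.path(sub, "truth_field.nii.gz"))
  ss <- .readMasks(file.path(sub, "masks"), structures, image@grid)
  new("DailyCase", image = image, structures = ss,
      deliveredFractionDose = dose, truthField = field,
      fractionIndex = as.integer(fraction))
}
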