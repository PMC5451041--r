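# NIfTI-1 I/O through RNifti; voxel spacing goes in the header, variant
# and configuration metadata in JSON sidecars.

.writeNii <- function(vol, path, spacing) {
  img <- RNifti::asNifti(unclass(vol))
  # trailing singleton dimensions may be dropped by the NIfTI container
  RNifti::pixdim(img) <- rep(spacing, length(RNifti::pixdim(img)))
  RNifti::writeNifti(img, path)
  path
}

#' Write a phantom to NIfTI volumes with a JSON sidecar
#'
#' Writes `hu.nii.gz`, `activity.nii.gz`, `label.nii.gz` and
#' `config.json` into `dir`.
#'
#' @param phantom a [DigitalPhantom].
#' @param dir output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom@spacing
  paths <- c(
    hu = .writeNii(phantom@huVolume, file.path(dir, "hu.nii.gz"), sp),
    activity = .writeNii(phantom@activityVolume,
                         file.path(dir, "activity.nii.gz"), sp),
    label = .writeNii(phantom@labelVolume + 0,
                      file.path(dir, "label.nii.gz"), sp),
    config = file.path(dir, "config.json"))
  cfg <- phantom@config
  jsonlite::write_json(
    lapply(stats::setNames(methods::slotNames("PhantomConfig"),
                           methods::slotNames("PhantomConfig")),
           function(s) methods::slot(cfg, s)),
    paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return List with `volume` (array) and `spacing` (mm).
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vol)) == 2) dim(vol) <- c(dim(vol), 1)
  list(volume = vol, spacing = RNifti::pixdim(img)[1])
}

#' Write an attenuation map as NIfTI with a variant sidecar
#'
#' @param mumap a [MuMap].
#' @param path output path (`.nii.gz`); the sidecar is written next to
#'   it as `<path>.json`.
#' @return Invisibly, the paths.
#' @export
writeMuMap <- function(mumap, path) {
  .writeNii(mumap@lac, path, mumap@spacing)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(variant = mumap@variant, units = "cm^-1",
                            spacing_mm = mumap@spacing),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(volume = path, sidecar = side))
}

#' Read an attenuation map written by [writeMuMap()]
#'
#' @param path NIfTI file path with an adjacent `<path>.json` sidecar.
#' @return A [MuMap].
#' @export
readMuMap <- function(path) {
  v <- readVolumeNifti(path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing variant sidecar: ", side)
  meta <- jsonlite::read_json(side)
  new("MuMap", lac = .as3d(v$volume), spacing = v$spacing,
      variant = meta$variant)
}
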