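#' Read an epochs dataset from its HDF5 container
#'
#' The container layout is: root attributes `sampling_rate` (float, Hz),
#' `times` (float vector, ms) and `sensor_names` (string vector); one HDF5
#' group per subject named by identifier; within it one dataset per condition
#' named by label with shape (trials, sensors, timepoints), float values in
#' microvolts.
#'
#' @param path path to the `.h5` file.
#' @param format container format; only `"hdf5"` is supported.
#' @return a validated [eeg_epochs()] object.
#' @export
load_epochs <- function(path, format = "hdf5") {
  format <- match.arg(format, "hdf5")
  if (!file.exists(path)) stopf("epochs file not found: %s", path)
  att <- rhdf5::h5readAttributes(path, "/")
  for (f in c("sampling_rate", "times", "sensor_names"))
    if (is.null(att[[f]]))
      stopf("epochs file %s is missing root attribute '%s'", path, f)
  ls <- rhdf5::h5ls(path)
  subjects <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  if (length(subjects) == 0L) stopf("epochs file %s holds no subject groups", path)
  data <- lapply(subjects, function(s) {
    conds <- ls$name[ls$group == paste0("/", s) & ls$otype == "H5I_DATASET"]
    # stored C-order shape is (trials, sensors, timepoints); rhdf5 presents
    # the axes reversed, so permute back
    blocks <- lapply(conds, function(cn)
      aperm(rhdf5::h5read(path, paste0("/", s, "/", cn)), 3:1))
    names(blocks) <- conds
    blocks
  })
  names(data) <- subjects
  eeg_epochs(data, as.character(att$sensor_names), as.numeric(att$times),
             as.numeric(att$sampling_rate))
}

#' Write an epochs dataset to an HDF5 container
#'
#' Inverse of [load_epochs()]; see there for the container layout.
#'
#' @param x an [eeg_epochs()] object.
#' @param path output path; overwritten if present.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(x, path) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5writeAttribute(x$sampling_rate, fid, "sampling_rate")
  rhdf5::h5writeAttribute(x$times, fid, "times")
  rhdf5::h5writeAttribute(x$sensor_names, fid, "sensor_names")
  for (s in x$subjects) {
    rhdf5::h5createGroup(fid, s)
    for (cn in x$conditions)
      rhdf5::h5write(aperm(x$data[[s]][[cn]], 3:1), fid, paste0(s, "/", cn))
  }
  invisible(path)
}
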