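#' Device orientation on the thigh
#'
#' Declares how the device axes map onto the canonical anatomical frame
#' (longitudinal toward the knee, anterior, lateral). Two named placements
#' are shipped: `"preschool"`, where the device y axis points toward the
#' knee and x is lateral (narrow-belt mounting), and `"school"`, where the
#' device x axis points toward the knee and y is lateral (tape mounting).
#' Any other placement is declared with `preset = "custom"` and a signed
#' axis-permutation matrix.
#'
#' The mapping is always one of the 24 proper signed axis permutations:
#' each row and column of the matrix holds a single +1 or -1 entry and the
#' determinant is +1, so per-sample vector norms are preserved exactly.
#'
#' @param preset `"preschool"`, `"school"` or `"custom"`.
#' @param custom_map 3 x 3 signed permutation matrix mapping device to
#'   canonical coordinates (`canonical = custom_map %*% device`); required
#'   when `preset = "custom"`, ignored otherwise.
#' @return An object of class `device_orientation` with elements `preset`
#'   and `map`.
#' @examples
#' device_orientation("school")
#' @export
device_orientation <- function(preset = c("school", "preschool", "custom"),
                               custom_map = NULL) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e) stop("unknown orientation preset: ",
                                              preset[1L]))
  map <- switch(preset,
    # canonical (long, ant, lat) from device (x, y, z); det +1 in each case
    preschool = rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
    school    = rbind(c(1, 0, 0), c(0, 0, -1), c(0, 1, 0)),
    custom    = {
      if (is.null(custom_map)) stop("preset 'custom' requires `custom_map`")
      m <- as.matrix(custom_map)
      check_signed_permutation(m)
      m
    })
  structure(list(preset = preset, map = map), class = "device_orientation")
}

check_signed_permutation <- function(m) {
  ok <- identical(dim(m), c(3L, 3L)) &&
    all(m %in% c(-1, 0, 1)) &&
    all(rowSums(abs(m)) == 1) && all(colSums(abs(m)) == 1) &&
    abs(det(m) - 1) < 1e-12
  if (!ok) {
    stop("`custom_map` must be a 3x3 signed axis permutation with det +1")
  }
  invisible(TRUE)
}

#' @export
print.device_orientation <- function(x, ...) {
  cat("<device_orientation>", x$preset, "\n")
  print(x$map)
  invisible(x)
}

#' Inverse of a device orientation
#'
#' @param orientation a [device_orientation()].
#' @return A `device_orientation` whose map undoes `orientation` (the
#'   transpose, since signed permutations are orthogonal).
#' @export
orientation_inverse <- function(orientation) {
  stopifnot(inherits(orientation, "device_orientation"))
  device_orientation("custom", custom_map = t(orientation$map))
}

#' Rotate a raw recording into the canonical anatomical frame
#'
#' Applies the signed axis permutation of `orientation` so that axis 1 is
#' longitudinal (positive toward the knee; quiet upright standing reads
#' about +1 g), axis 2 anterior, axis 3 lateral. Sample count and sampling
#' frequency are unchanged and per-sample Euclidean norms are preserved.
#'
#' @param rec a [triaxial_recording()] in the `"raw_device"` frame.
#' @param orientation a [device_orientation()].
#' @return The recording in the `"canonical"` frame.
#' @export
remap_to_canonical <- function(rec, orientation) {
  stopifnot(inherits(rec, "triaxial_recording"),
            inherits(orientation, "device_orientation"))
  if (rec$frame != "raw_device") {
    stop("recording is already in the '", rec$frame, "' frame")
  }
  out <- rec$samples %*% t(orientation$map)
  triaxial_recording(out, fs = rec$fs, frame = "canonical",
                     start_time = rec$start_time)
}

#' Express a canonical recording in a device frame
#'
#' Inverse of [remap_to_canonical()]: rewrites a canonical-frame recording
#' as the raw signal a device mounted with `orientation` would have
#' reported. Used by the simulator so synthetic recordings round-trip
#' through the same orientation handling as field data.
#'
#' @param rec a [triaxial_recording()] in the `"canonical"` frame.
#' @param orientation a [device_orientation()].
#' @return The recording in the `"raw_device"` frame.
#' @export
remap_to_device <- function(rec, orientation) {
  stopifnot(inherits(rec, "triaxial_recording"),
            inherits(orientation, "device_orientation"))
  if (rec$frame != "canonical") {
    stop("recording must be in the canonical frame")
  }
  triaxial_recording(rec$samples %*% orientation$map, fs = rec$fs,
                     frame = "raw_device", start_time = rec$start_time)
}
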