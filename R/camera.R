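#' Pinhole camera model
#'
#' A stationary, axis-aligned pinhole camera: the optical axis points along
#' +z, u grows with +x and v grows downward (with -y). Only the extrinsic
#' position is ever estimated by the pipeline; focal length and principal
#' point come from device metadata.
#'
#' @param focal Focal length in pixels (> 0).
#' @param principal_point Numeric length-2, `(u0, v0)` pixels.
#' @param position Numeric length-3, camera center `(x, y, z)` in meters in
#'   the world frame of the 3D skeletons.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(focal, principal_point = c(540, 960),
                         position = c(0, 0, 0)) {
  if (!is.numeric(focal) || length(focal) != 1L || focal <= 0)
    stop("focal must be a single positive number of pixels")
  stopifnot(length(principal_point) == 2L, length(position) == 3L,
            all(is.finite(principal_point)), all(is.finite(position)))
  structure(list(focal = focal,
                 principal_point = as.numeric(principal_point),
                 position = as.numeric(position)),
            class = "camera_model")
}

#' Project a 3D pose frame to pixel space
#'
#' Pinhole projection `u = u0 + f * x_c / z_c`, `v = v0 - f * y_c / z_c`,
#' where `(x_c, y_c, z_c)` are camera-relative coordinates (v grows downward,
#' image convention). A point on the optical axis projects to the principal
#' point at any depth.
#'
#' @param camera A [camera_model()].
#' @param frame A `21 x 3` matrix (one `frames3d` slice), rownames = joints;
#'   `NA` rows pass through as `NA`.
#' @param min_depth Joints closer than this along the optical axis (or behind
#'   the camera) raise an error naming the joint. Default 0.1 m.
#' @return A `21 x 2` matrix of `(u, v)` pixels with the same rownames.
#' @export
project_frame <- function(camera, frame, min_depth = 0.1) {
  stopifnot(inherits(camera, "camera_model"), is.matrix(frame), ncol(frame) == 3L)
  rel <- sweep(frame, 2, camera$position)
  z <- rel[, 3]
  present <- apply(is.finite(frame), 1, all)
  bad <- present & z <= min_depth
  if (any(bad))
    stop("joint behind camera (depth <= ", min_depth, " m): ",
         paste(rownames(frame)[bad], collapse = ", "))
  u <- camera$principal_point[1] + camera$focal * rel[, 1] / z
  v <- camera$principal_point[2] - camera$focal * rel[, 2] / z
  out <- cbind(u = u, v = v)
  rownames(out) <- rownames(frame)
  out[!present, ] <- NA_real_
  out
}

# Project a whole frames3d array (n x j x 3) -> n x j x 2; vectorized.
project_array <- function(camera, a3, min_depth = 0.1) {
  X <- a3[, , 1] - camera$position[1]
  Y <- a3[, , 2] - camera$position[2]
  Z <- a3[, , 3] - camera$position[3]
  pres <- is.finite(X) & is.finite(Y) & is.finite(Z)
  if (any(pres & Z <= min_depth)) {
    idx <- which(pres & Z <= min_depth, arr.ind = TRUE)
    stop("joint behind camera at frame ", idx[1, 1] - 1L, ": ",
         dimnames(a3)[[2]][idx[1, 2]])
  }
  u <- camera$principal_point[1] + camera$focal * X / Z
  v <- camera$principal_point[2] - camera$focal * Y / Z
  out <- array(NA_real_, c(dim(a3)[1], dim(a3)[2], 2),
               dimnames = list(NULL, dimnames(a3)[[2]], c("u", "v")))
  out[, , 1] <- u
  out[, , 2] <- v
  out
}

# Back-lift pixel coordinates to 3D at given camera-relative depths.
# u,v,zc: matrices n x j (zc = depth along optical axis, > 0).
lift_array <- function(camera, u, v, zc) {
  a <- (u - camera$principal_point[1]) / camera$focal
  b <- (camera$principal_point[2] - v) / camera$focal
  list(x = camera$position[1] + a * zc,
       y = camera$position[2] + b * zc,
       z = camera$position[3] + zc,
       a = a, b = b)
}
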