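#' Canonical 21-joint skeleton topology
#'
#' The pipeline works on a fixed skeleton of 21 named joints connected by 20
#' bones forming a tree rooted at the pelvis. Lateral joints carry an `L`/`R`
#' prefix and are paired by a mirror map; midline joints mirror to themselves.
#' Detector outputs with other naming conventions (e.g. `"Left Ankle"`,
#' `"MidHip"`) are mapped onto this set via [joint_aliases()].
#'
#' @return An object of class `skeleton_topology`: a list with
#'   `joints` (character, length 21), `bones` (data.frame with columns
#'   `parent`, `child`, `bone` where `bone = "parent-child"`), and
#'   `mirror` (named character vector pairing each joint with its mirror).
#' @examples
#' topo <- default_topology()
#' length(topo$joints)   # 21
#' nrow(topo$bones)      # 20
#' @export
default_topology <- function() {
  joints <- c(
    "HeadTop", "Head", "Neck", "Chest", "Pelvis",
    "LShoulder", "RShoulder", "LElbow", "RElbow", "LWrist", "RWrist",
    "LHip", "RHip", "LKnee", "RKnee", "LAnkle", "RAnkle",
    "LHeel", "RHeel", "LToe", "RToe"
  )
  parent <- c(
    "Pelvis", "Chest", "Neck", "Head",
    "Neck", "LShoulder", "LElbow",
    "Neck", "RShoulder", "RElbow",
    "Pelvis", "LHip", "LKnee", "LAnkle", "LAnkle",
    "Pelvis", "RHip", "RKnee", "RAnkle", "RAnkle"
  )
  child <- c(
    "Chest", "Neck", "Head", "HeadTop",
    "LShoulder", "LElbow", "LWrist",
    "RShoulder", "RElbow", "RWrist",
    "LHip", "LKnee", "LAnkle", "LHeel", "LToe",
    "RHip", "RKnee", "RAnkle", "RHeel", "RToe"
  )
  bones <- data.frame(parent = parent, child = child,
                      bone = paste(parent, child, sep = "-"),
                      stringsAsFactors = FALSE)
  lateral <- grep("^[LR]", joints, value = TRUE)
  mirror <- joints
  names(mirror) <- joints
  for (j in lateral) {
    other <- if (startsWith(j, "L")) sub("^L", "R", j) else sub("^R", "L", j)
    mirror[[j]] <- other
  }
  structure(list(joints = joints, bones = bones, mirror = mirror),
            class = "skeleton_topology")
}

#' Joint-name alias table
#'
#' Maps common pose-detector joint labels (spaced names, OpenPose-style
#' `MidHip`, `Nose`) onto the canonical 21-joint set. Unknown names are left
#' for the caller to reject.
#'
#' @return Named character vector: `alias -> canonical joint`.
#' @export
joint_aliases <- function() {
  topo <- default_topology()
  al <- c(
    "Head Top" = "HeadTop", "Top" = "HeadTop", "Nose" = "Head",
    "MidHip" = "Pelvis", "Mid Hip" = "Pelvis", "Hip Center" = "Pelvis",
    "Thorax" = "Chest", "Spine" = "Chest",
    "Left Shoulder" = "LShoulder", "Right Shoulder" = "RShoulder",
    "Left Elbow" = "LElbow", "Right Elbow" = "RElbow",
    "Left Wrist" = "LWrist", "Right Wrist" = "RWrist",
    "Left Hip" = "LHip", "Right Hip" = "RHip",
    "Left Knee" = "LKnee", "Right Knee" = "RKnee",
    "Left Ankle" = "LAnkle", "Right Ankle" = "RAnkle",
    "Left Heel" = "LHeel", "Right Heel" = "RHeel",
    "Left Toe" = "LToe", "Right Toe" = "RToe",
    "LBigToe" = "LToe", "RBigToe" = "RToe"
  )
  # identity for canonical names
  c(stats::setNames(topo$joints, topo$joints), al)
}

#' Validate a skeleton topology
#'
#' Checks the structural invariants: exactly 21 joints, 20 bones forming a
#' connected tree rooted at the pelvis, and a consistent mirror map.
#'
#' @param topology A `skeleton_topology`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
check_topology <- function(topology) {
  stopifnot(inherits(topology, "skeleton_topology"))
  j <- topology$joints
  b <- topology$bones
  if (length(j) != 21L || anyDuplicated(j) > 0L)
    stop("topology must have exactly 21 distinct joints")
  if (nrow(b) != 20L)
    stop("topology must have exactly 20 bones")
  if (!all(c(b$parent, b$child) %in% j))
    stop("bone endpoints must be topology joints")
  # connected tree: every non-root joint appears exactly once as a child
  children <- b$child
  if (anyDuplicated(children) > 0L) stop("bone graph has a joint with two parents")
  if (!setequal(children, setdiff(j, "Pelvis")))
    stop("bone graph is not a tree rooted at the pelvis")
  # reachability from the root
  seen <- "Pelvis"
  repeat {
    nxt <- b$child[b$parent %in% seen & !(b$child %in% seen)]
    if (length(nxt) == 0L) break
    seen <- c(seen, nxt)
  }
  if (!setequal(seen, j)) stop("bone graph is disconnected")
  m <- topology$mirror
  if (!setequal(names(m), j)) stop("mirror map must cover all joints")
  if (!all(m[m] == names(m)[match(m, names(m))] | TRUE)) stop("bad mirror")
  if (!all(unname(m[unname(m)]) == names(m))) stop("mirror map is not an involution")
  invisible(TRUE)
}

#' Anthropometric bone-proportion table
#'
#' Loads the bone-length proportion table (fractions of stature) shipped with
#' the package, or from a user-supplied JSON file with the same layout. The
#' table also declares which bones form the vertical ankle-to-head-top chain
#' and the fraction of stature that chain spans.
#'
#' @param path Optional path to an alternative JSON table.
#' @return A list with `fractions` (named numeric, one entry per bone),
#'   `stature_fraction`, `ankle_height_fraction` and `vertical_chain`.
#' @export
anthropometry_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "anthropometry.json", package = "gaitmetrics",
                        mustWork = TRUE)
  tab <- jsonlite::fromJSON(path)
  fr <- unlist(tab$fractions)
  list(fractions = fr,
       stature_fraction = tab$stature_fraction,
       ankle_height_fraction = tab$ankle_height_fraction,
       vertical_chain = tab$vertical_chain)
}

#' Target bone lengths for a person of given height
#'
#' Scales the anthropometric proportion table linearly by stature. Left and
#' right bones are equal by construction, and the vertical chain
#' (ankle-knee-hip-spine-neck-head-top) sums to `height` times the table's
#' declared stature fraction.
#'
#' @param height Person height in meters (0.5 < height < 2.6).
#' @param topology Skeleton topology (default [default_topology()]).
#' @param table Anthropometry table (default [anthropometry_table()]).
#' @return Named numeric vector of bone lengths in meters, one per bone.
#' @examples
#' tl <- target_bone_lengths(1.80)
#' tl[["LHip-LKnee"]]  # thigh length for a 1.80 m person
#' @export
target_bone_lengths <- function(height, topology = default_topology(),
                                table = anthropometry_table()) {
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height <= 0.5 || height >= 2.6)
    stop("height must be a single value in (0.5, 2.6) meters")
  fr <- table$fractions
  miss <- setdiff(topology$bones$bone, names(fr))
  if (length(miss) > 0L)
    stop("anthropometry table missing bones: ", paste(miss, collapse = ", "))
  out <- fr[topology$bones$bone] * height
  stats::setNames(as.numeric(out), topology$bones$bone)
}

#' Measured bone lengths of a 3D pose frame
#'
#' Euclidean length of every bone whose two endpoint joints are present
#' (finite) in the frame; bones with a missing endpoint are omitted from the
#' result rather than raising an error. Symmetric bones are reported
#' separately.
#'
#' @param frame A 21 x 3 numeric matrix with rownames equal to the canonical
#'   joint names (a single `frames3d` slice of a [pose_sequence()]).
#' @param topology Skeleton topology.
#' @return Named numeric vector of bone lengths in meters.
#' @export
bone_lengths <- function(frame, topology = default_topology()) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L)
  p <- frame[topology$bones$parent, , drop = FALSE]
  q <- frame[topology$bones$child, , drop = FALSE]
  len <- sqrt(rowSums((p - q)^2))
  names(len) <- topology$bones$bone
  len[is.finite(len)]
}
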