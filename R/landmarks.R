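## Landmark containers and CSV I/O.

# The nine named landmarks every specimen must carry. Order matters only
# for printing; lookups are by name.
LANDMARK_NAMES <- c(
  "jaw_joint",             # center of the articular surface (fulcrum)
  "coronoid_tip",          # tip of coronoid process (adductor in-lever end)
  "anterior_tip",          # anteriormost point of the mandible
  "posterior_tip",         # posteriormost point (retroarticular end)
  "triturating_posterior", # posterior end of the triturating surface
  "width_left",            # lateral margin of left ectocondylar flange
  "width_right",           # lateral margin of right ectocondylar flange
  "trit_width_left",       # span of maximum triturating-surface width
  "trit_width_right"
)

#' Landmark set for one mandible
#'
#' Bundles the named 3D points that define all lever arms and width spans
#' of one specimen's mandible.
#'
#' @param specimen_id single character id.
#' @param coords numeric matrix with one row per landmark (rownames from
#'   [landmark_names()]) and columns x, y, z; or a named list of length-3
#'   numeric vectors.
#' @param length_unit unit of the coordinates (metadata only).
#' @return Object of class `landmark_set`.
#' @examples
#' sim <- make_jaw_landmarks("generic", n = 1, noise_sd = 0)
#' sim$landmarks[[1]]
#' @export
landmark_set <- function(specimen_id, coords, length_unit = "mm") {
  if (!is.character(specimen_id) || length(specimen_id) != 1L) {
    stop("`specimen_id` must be a single string", call. = FALSE)
  }
  if (is.list(coords) && !is.data.frame(coords)) {
    coords <- do.call(rbind, coords)
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  missing_lm <- setdiff(LANDMARK_NAMES, rownames(coords))
  if (length(missing_lm)) {
    stop("missing landmark(s): ", paste(missing_lm, collapse = ", "),
         call. = FALSE)
  }
  coords <- coords[LANDMARK_NAMES, , drop = FALSE]
  colnames(coords) <- c("x", "y", "z")
  if (!all(is.finite(coords))) {
    bad <- rownames(coords)[!apply(is.finite(coords), 1, all)]
    stop("non-finite coordinates for landmark(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (identical(coords["jaw_joint", ], coords["anterior_tip", ])) {
    stop("degenerate geometry: jaw_joint coincides with anterior_tip",
         call. = FALSE)
  }
  if (identical(coords["width_left", ], coords["width_right", ])) {
    stop("degenerate geometry: width_left coincides with width_right",
         call. = FALSE)
  }
  structure(
    list(specimen_id = specimen_id, coords = coords,
         length_unit = length_unit),
    class = "landmark_set"
  )
}

#' Names of the required mandibular landmarks
#' @return Character vector of the nine landmark names.
#' @export
landmark_names <- function() LANDMARK_NAMES

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", x$specimen_id, " (", x$length_unit, ")\n", sep = "")
  print(round(x$coords, 4))
  invisible(x)
}

lm_point <- function(lm, name) lm$coords[name, ]

#' Cross-section ellipse of the dentary ramus
#'
#' Ellipse axis lengths fitted to the jaw-ramus cross-section at the
#' midpoint of the dentary ramus. `a` is the axis perpendicular to the
#' applied (bite) force, i.e. the mediolateral width; `b` is the axis
#' parallel to the force, i.e. the dorsoventral height. Where along the
#' ramus the section was taken is a data-collection concern and is kept as
#' metadata only.
#'
#' @param a,b positive axis lengths.
#' @param position optional free-text note on the section location.
#' @return Object of class `cross_section`.
#' @export
cross_section <- function(a, b, position = "dentary ramus midpoint") {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("cross-section axes `a` and `b` must be finite and > 0",
         call. = FALSE)
  }
  structure(list(a = a, b = b, position = position), class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat("<cross_section> a =", x$a, " b =", x$b, "\n")
  invisible(x)
}

#' Read landmark sets and cross-sections from CSV
#'
#' One row per specimen; columns `specimen_id`, `<landmark>_x`,
#' `<landmark>_y`, `<landmark>_z` for each of [landmark_names()], plus
#' `cs_a`, `cs_b` and an optional `unit` column.
#'
#' @param path path to a CSV file.
#' @return A list with components `landmarks` (list of [landmark_set()])
#'   and `cross_sections` (list of [cross_section()]), both named by
#'   specimen id.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("specimen_id",
              as.vector(t(outer(LANDMARK_NAMES, c("_x", "_y", "_z"), paste0))),
              "cs_a", "cs_b")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("landmark CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  unit <- if ("unit" %in% names(df)) as.character(df$unit) else
    rep("mm", nrow(df))
  landmarks <- vector("list", nrow(df))
  sections <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    coords <- matrix(NA_real_, nrow = length(LANDMARK_NAMES), ncol = 3,
                     dimnames = list(LANDMARK_NAMES, c("x", "y", "z")))
    for (nm in LANDMARK_NAMES) {
      coords[nm, ] <- as.numeric(df[i, paste0(nm, c("_x", "_y", "_z"))])
    }
    landmarks[[i]] <- landmark_set(as.character(df$specimen_id[i]), coords,
                                   length_unit = unit[i])
    sections[[i]] <- cross_section(df$cs_a[i], df$cs_b[i])
  }
  names(landmarks) <- names(sections) <- as.character(df$specimen_id)
  list(landmarks = landmarks, cross_sections = sections)
}

#' Write landmark sets and cross-sections to CSV
#'
#' Inverse of [read_landmarks()].
#'
#' @param landmarks list of [landmark_set()].
#' @param cross_sections list of [cross_section()], same length and order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, cross_sections, path) {
  stopifnot(length(landmarks) == length(cross_sections))
  rows <- lapply(seq_along(landmarks), function(i) {
    lm <- landmarks[[i]]
    cs <- cross_sections[[i]]
    vals <- as.vector(t(lm$coords))
    names(vals) <- as.vector(t(outer(LANDMARK_NAMES, c("_x", "_y", "_z"),
                                     paste0)))
    c(list(specimen_id = lm$specimen_id), as.list(vals),
      list(cs_a = cs$a, cs_b = cs$b, unit = lm$length_unit))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  write_numeric_csv(df, path)
  invisible(path)
}
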