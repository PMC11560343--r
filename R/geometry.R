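#' Sagittal plane configuration
#'
#' Lever-arm distances are measured as straight lines within the sagittal
#' plane of the mandible. The specimen coordinate frame is not fixed by
#' convention, so the pair of axes spanning that plane is configurable. The
#' default takes `x` as the anteroposterior axis and `z` as the dorsoventral
#' axis; the mediolateral component (`y`) is discarded when projecting.
#'
#' @param axes character vector of length 2 naming the two in-plane axes,
#'   a subset of `c("x", "y", "z")`. Default `c("x", "z")`.
#' @return An object of class `sagittal_config`.
#' @examples
#' cfg <- sagittal_config()
#' project_sagittal(c(1, 5, 2), cfg)
#' @export
sagittal_config <- function(axes = c("x", "z")) {
  axes <- as.character(axes)
  if (length(axes) != 2L || anyNA(axes) || axes[1] == axes[2] ||
      !all(axes %in% c("x", "y", "z"))) {
    stop("`axes` must be two distinct names among 'x', 'y', 'z'",
         call. = FALSE)
  }
  structure(list(axes = axes), class = "sagittal_config")
}

#' @export
print.sagittal_config <- function(x, ...) {
  cat("Sagittal plane: (", x$axes[1], ", ", x$axes[2], ")\n", sep = "")
  invisible(x)
}

#' Project a 3D point onto the sagittal plane
#'
#' Orthogonal projection: the coordinate along the discarded (mediolateral)
#' axis is dropped, so distances between points already lying in the plane
#' are preserved exactly.
#'
#' @param p numeric vector of length 3 (named or in x, y, z order), or a
#'   matrix with 3 columns (one point per row).
#' @param cfg a [sagittal_config()].
#' @return A numeric vector of length 2 (or a 2-column matrix).
#' @export
project_sagittal <- function(p, cfg = sagittal_config()) {
  stopifnot(inherits(cfg, "sagittal_config"))
  idx <- match(cfg$axes, c("x", "y", "z"))
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    if (!all(is.finite(p))) stop("non-finite coordinates", call. = FALSE)
    return(p[, idx, drop = FALSE])
  }
  if (length(p) != 3L || !all(is.finite(p))) {
    stop("a 3D point must be 3 finite coordinates", call. = FALSE)
  }
  unname(p[idx])
}

## Euclidean distance between two points (any dimension).
point_dist <- function(p, q) {
  sqrt(sum((p - q)^2))
}

## Sagittal-projected distance between two 3D points.
sagittal_dist <- function(p, q, cfg = sagittal_config()) {
  point_dist(project_sagittal(p, cfg), project_sagittal(q, cfg))
}
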