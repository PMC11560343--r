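## The six biomechanical measurements, computed from a landmark_set and a
## cross_section. The mandible is treated as a lever rotating about the
## jaw joint: closing mechanical advantages divide the adductor in-lever
## (joint to coronoid tip) by an out-lever ending at the anterior jaw tip
## (AMA) or at the posterior end of the triturating surface (PMA); opening
## mechanical advantage is a first-order lever whose in-lever is the
## retroarticular process behind the joint. Lever distances are straight
## lines in the sagittal plane; width spans are transverse by construction
## and use full 3D distances.

in_lever_closing <- function(lm, cfg) {
  sagittal_dist(lm_point(lm, "jaw_joint"), lm_point(lm, "coronoid_tip"), cfg)
}

mandible_length <- function(lm, cfg) {
  sagittal_dist(lm_point(lm, "anterior_tip"), lm_point(lm, "posterior_tip"),
                cfg)
}

#' Anterior mechanical advantage (AMA)
#'
#' In-lever (jaw joint to coronoid tip) divided by the out-lever ending at
#' the anteriormost tip of the jaw. A proxy for force transmission of an
#' anterior bite; invariant to rigid motion and uniform scaling.
#'
#' @param lm a [landmark_set()].
#' @param cfg a [sagittal_config()].
#' @return Dimensionless ratio > 0.
#' @export
anterior_mechanical_advantage <- function(lm, cfg = sagittal_config()) {
  stopifnot(inherits(lm, "landmark_set"))
  out <- sagittal_dist(lm_point(lm, "jaw_joint"), lm_point(lm, "anterior_tip"),
                       cfg)
  if (out == 0) {
    stop("degenerate geometry: zero AMA out-lever (jaw_joint == anterior_tip ",
         "in the sagittal plane)", call. = FALSE)
  }
  in_lever_closing(lm, cfg) / out
}

#' Posterior mechanical advantage (PMA)
#'
#' In-lever (jaw joint to coronoid tip) divided by the out-lever ending at
#' the posterior end of the triturating surface. When that point lies
#' closer to the joint than the coronoid tip the jaw acts as a
#' second-order lever and PMA exceeds 1; such values are meaningful
#' (greater force transmission, slower closing) and are never clamped.
#'
#' @inheritParams anterior_mechanical_advantage
#' @return Dimensionless ratio > 0 (may exceed 1).
#' @export
posterior_mechanical_advantage <- function(lm, cfg = sagittal_config()) {
  stopifnot(inherits(lm, "landmark_set"))
  out <- sagittal_dist(lm_point(lm, "jaw_joint"),
                       lm_point(lm, "triturating_posterior"), cfg)
  if (out == 0) {
    stop("degenerate geometry: zero PMA out-lever", call. = FALSE)
  }
  in_lever_closing(lm, cfg) / out
}

#' Opening mechanical advantage (OMA)
#'
#' First-order lever: the depressor in-lever (jaw joint to posteriormost
#' point of the retroarticular process) divided by the out-lever (jaw
#' joint to anterior tip — the same out-lever as AMA). Zero is allowed:
#' a jaw with no retroarticular process has OMA 0.
#'
#' @inheritParams anterior_mechanical_advantage
#' @return Dimensionless ratio >= 0.
#' @export
opening_mechanical_advantage <- function(lm, cfg = sagittal_config()) {
  stopifnot(inherits(lm, "landmark_set"))
  out <- sagittal_dist(lm_point(lm, "jaw_joint"), lm_point(lm, "anterior_tip"),
                       cfg)
  if (out == 0) {
    stop("degenerate geometry: zero OMA out-lever", call. = FALSE)
  }
  sagittal_dist(lm_point(lm, "jaw_joint"), lm_point(lm, "posterior_tip"),
                cfg) / out
}

#' Standardized second moment of area (SMOI)
#'
#' Area moment of inertia of the cross-section ellipse, I_na = pi*a*b^3/4,
#' divided by that of a circle of equal area (radius sqrt(ab)),
#' I_c = pi*(ab)^2/4. The quotient simplifies algebraically to `b/a`:
#' values above 1 indicate a ramus that is dorsoventrally taller than it
#' is mediolaterally wide (stiffer against vertical bending), values below
#' 1 a ramus transversely wider than tall.
#'
#' @param cs a [cross_section()].
#' @return Dimensionless ratio > 0.
#' @export
second_moment_ratio <- function(cs) {
  stopifnot(inherits(cs, "cross_section"))
  cs$b / cs$a
}

#' Mandibular length-width ratio (LWR)
#'
#' Sagittal length of the mandible (anterior tip to posterior tip) divided
#' by its maximum width (3D distance between the lateral margins of the
#' left and right ectocondylar flanges). Standardizes jaw length by width
#' in lieu of an absolute size measure.
#'
#' @inheritParams anterior_mechanical_advantage
#' @return Dimensionless ratio > 0.
#' @export
length_width_ratio <- function(lm, cfg = sagittal_config()) {
  stopifnot(inherits(lm, "landmark_set"))
  width <- point_dist(lm_point(lm, "width_left"), lm_point(lm, "width_right"))
  if (width == 0) {
    stop("degenerate geometry: zero mandibular width", call. = FALSE)
  }
  mandible_length(lm, cfg) / width
}

#' Relative triturating-surface width (RTW)
#'
#' Maximum width of the triturating surface in dorsal view (3D distance
#' between the two width-span landmarks) divided by the mandibular length
#' (same definition as in [length_width_ratio()]). A value of 0 (no
#' triturating surface) is allowed with a warning.
#'
#' @inheritParams anterior_mechanical_advantage
#' @return Dimensionless ratio >= 0; a warning is issued if >= 1.
#' @export
relative_triturating_width <- function(lm, cfg = sagittal_config()) {
  stopifnot(inherits(lm, "landmark_set"))
  len <- mandible_length(lm, cfg)
  if (len == 0) {
    stop("degenerate geometry: zero mandibular length", call. = FALSE)
  }
  tw <- point_dist(lm_point(lm, "trit_width_left"),
                   lm_point(lm, "trit_width_right"))
  rtw <- tw / len
  if (tw == 0) {
    warning("triturating-surface width is zero for ", lm$specimen_id,
            call. = FALSE)
  } else if (rtw >= 1) {
    warning("relative triturating width >= 1 for ", lm$specimen_id,
            " -- implausible jaw proportions", call. = FALSE)
  }
  rtw
}

#' Functional profile of one specimen
#'
#' Computes all six biomechanical measurements. Deterministic; a missing
#' or degenerate landmark raises an error naming the offender rather than
#' propagating NaN.
#'
#' @param lm a [landmark_set()].
#' @param cs a [cross_section()].
#' @param cfg a [sagittal_config()].
#' @return Object of class `functional_profile`: a named list with
#'   `species_id` and the measurements `ama`, `pma`, `oma`, `smoi`,
#'   `lwr`, `rtw`.
#' @export
profile_species <- function(lm, cs, cfg = sagittal_config()) {
  stopifnot(inherits(lm, "landmark_set"), inherits(cs, "cross_section"))
  structure(
    list(
      species_id = lm$specimen_id,
      ama = anterior_mechanical_advantage(lm, cfg),
      pma = posterior_mechanical_advantage(lm, cfg),
      oma = opening_mechanical_advantage(lm, cfg),
      smoi = second_moment_ratio(cs),
      lwr = length_width_ratio(lm, cfg),
      rtw = relative_triturating_width(lm, cfg)
    ),
    class = "functional_profile"
  )
}

#' @export
print.functional_profile <- function(x, ...) {
  cat("<functional_profile>", x$species_id, "\n")
  v <- unlist(x[c("ama", "pma", "oma", "smoi", "lwr", "rtw")])
  print(round(v, 4))
  invisible(x)
}

#' Profile a sample of specimens
#'
#' Applies [profile_species()] to parallel lists of landmark sets and
#' cross-sections and returns a data frame, including the raw lever
#' components needed by [classify_jaw_type()].
#'
#' @param landmarks list of [landmark_set()].
#' @param cross_sections list of [cross_section()], same length/order.
#' @param cfg a [sagittal_config()].
#' @return Data frame with columns `species_id`, `ama`, `pma`, `oma`,
#'   `smoi`, `lwr`, `rtw`, plus `oma_in_lever` (joint to posterior tip)
#'   and `jaw_length` (anterior to posterior tip), both sagittal.
#' @export
profile_sample <- function(landmarks, cross_sections,
                           cfg = sagittal_config()) {
  stopifnot(length(landmarks) == length(cross_sections))
  rows <- lapply(seq_along(landmarks), function(i) {
    lm <- landmarks[[i]]
    p <- profile_species(lm, cross_sections[[i]], cfg)
    data.frame(
      species_id = p$species_id, ama = p$ama, pma = p$pma, oma = p$oma,
      smoi = p$smoi, lwr = p$lwr, rtw = p$rtw,
      oma_in_lever = sagittal_dist(lm_point(lm, "jaw_joint"),
                                   lm_point(lm, "posterior_tip"), cfg),
      jaw_length = mandible_length(lm, cfg),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Classify specimens into lever-proportion jaw types
#'
#' A heuristic, sample-relative classifier for the three jaw archetypes
#' defined by extreme lever proportions:
#' \describe{
#'   \item{trionychid}{extremely elongated retroarticular process: the
#'     opening in-lever relative to jaw length exceeds the sample's 75th
#'     percentile while AMA does not exceed the sample median;}
#'   \item{pelomedusoid}{short pre-coronoid region: both AMA and OMA
#'     exceed their 75th percentiles;}
#'   \item{chelid}{elongated postcoronoid region without a hypertrophied
#'     retroarticular process: AMA exceeds its 75th percentile while OMA
#'     lies within the interquartile range.}
#' }
#' Rules are applied in that order and the first match wins; specimens
#' matching none are labelled `"none"`. Percentile cutoffs are only
#' meaningful for reasonably sized samples: with fewer than 8 specimens
#' every label is `"none"`.
#'
#' Ties at a cutoff count as not exceeding it; for the trionychid AMA
#' condition, values equal to the median are accepted (a relative, not
#' strict, "low AMA").
#'
#' @param profiles data frame from [profile_sample()] (needs columns
#'   `ama`, `oma`, `oma_in_lever`, `jaw_length`).
#' @return Character vector of labels, one per row of `profiles`, in
#'   `c("trionychid", "pelomedusoid", "chelid", "none")`.
#' @export
classify_jaw_type <- function(profiles) {
  needed <- c("ama", "oma", "oma_in_lever", "jaw_length")
  missing_cols <- setdiff(needed, names(profiles))
  if (length(missing_cols)) {
    stop("`profiles` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(profiles)
  if (n < 2L) stop("jaw-type classification needs at least 2 specimens",
                   call. = FALSE)
  if (n < 8L) return(rep("none", n))
  rel_retro <- profiles$oma_in_lever / profiles$jaw_length
  ama <- profiles$ama
  oma <- profiles$oma
  q_retro <- stats::quantile(rel_retro, 0.75, names = FALSE)
  med_ama <- stats::median(ama)
  q_ama <- stats::quantile(ama, 0.75, names = FALSE)
  q_oma <- stats::quantile(oma, c(0.25, 0.75), names = FALSE)
  labels <- rep("none", n)
  for (i in seq_len(n)) {
    if (rel_retro[i] > q_retro && ama[i] <= med_ama) {
      labels[i] <- "trionychid"
    } else if (ama[i] > q_ama && oma[i] > q_oma[2]) {
      labels[i] <- "pelomedusoid"
    } else if (ama[i] > q_ama && oma[i] >= q_oma[1] && oma[i] <= q_oma[2]) {
      labels[i] <- "chelid"
    }
  }
  labels
}
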