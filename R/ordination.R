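## Ordination: Z-transformation and PCA for continuous trait tables, and
## principal coordinate analysis (classical metric MDS) for distance
## matrices. Both return a common `ordination` container.

new_ordination <- function(scores, eigenvalues, proportion, loadings = NULL,
                           method = "pca") {
  structure(
    list(scores = scores,
         eigenvalues = eigenvalues,
         sdevs = sqrt(eigenvalues),
         proportion = proportion,
         loadings = loadings,
         method = method),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", toupper(x$method), ": ", nrow(x$scores), " objects, ",
      ncol(x$scores), " axes\n", sep = "")
  cat("variance explained (%):",
      paste(sprintf("%.1f", 100 * x$proportion), collapse = " "), "\n")
  invisible(x)
}

#' Z-transform a trait table
#'
#' Centers each trait to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator), so every measurement receives equal weight in a
#' subsequent PCA.
#'
#' @param t numeric matrix or data frame, species in rows, traits in
#'   columns; no missing values.
#' @return A numeric matrix of the same shape.
#' @export
z_transform <- function(t) {
  m <- as.matrix(t)
  if (!is.numeric(m) || anyNA(m) || !all(is.finite(m))) {
    stop("trait table must be numeric with no missing values", call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant trait(s) cannot be Z-transformed: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis of a trait table
#'
#' Column-centers the input and decomposes it by SVD; eigenvalue k is the
#' k-th squared singular value divided by (n - 1), so eigenvalues are
#' per-axis score variances and sum to the total trait variance. Axis
#' signs are fixed deterministically: the largest-magnitude loading of
#' each axis is made positive. The caller is expected to [z_transform()]
#' first when traits are on different scales (the pipeline default does).
#'
#' @param t numeric matrix or data frame, species in rows (>= 2), traits
#'   in columns.
#' @return An `ordination` with scores, eigenvalues, per-axis standard
#'   deviations, variance proportions, and orthonormal loadings.
#' @export
pca <- function(t) {
  m <- as.matrix(t)
  if (nrow(m) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  if (!is.numeric(m) || anyNA(m)) {
    stop("trait table must be numeric with no missing values", call. = FALSE)
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  k <- min(nrow(m) - 1L, ncol(m))
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading of each axis positive
  for (a in seq_len(k)) {
    top <- which.max(abs(v[, a]))
    if (v[top, a] < 0) {
      v[, a] <- -v[, a]
      u[, a] <- -u[, a]
    }
  }
  eig <- d^2 / (nrow(m) - 1L)
  scores <- u %*% diag(d, k, k)
  axis_names <- paste0("PC", seq_len(k))
  dimnames(scores) <- list(rownames(m), axis_names)
  dimnames(v) <- list(colnames(m), axis_names)
  names(eig) <- axis_names
  new_ordination(scores, eig, eig / sum(eig), loadings = v, method = "pca")
}

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric multidimensional scaling: squared distances are
#' double-centered (B = -1/2 J D^2 J), B is eigendecomposed, and scores
#' are eigenvectors scaled by the square roots of their eigenvalues. Axes
#' with eigenvalues below `tol` times the largest are dropped. Negative
#' eigenvalues — expected when Gower distances computed under missing
#' data are not Euclidean — are dropped, and variance proportions are
#' computed over the positive eigenvalues only; no Lingoes/Cailliez
#' correction is applied by default.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#'   (a `dist`, a [gower_distance()] result, or a plain square matrix).
#' @param tol relative eigenvalue threshold for axis retention
#'   (default `1e-8`).
#' @param correction `"none"` (default) or `"cailliez"` (adds the
#'   smallest constant to off-diagonal distances making the configuration
#'   Euclidean).
#' @return An `ordination` with scores (sign convention: first nonzero
#'   score element of each axis positive), eigenvalues, and variance
#'   proportions; `loadings` is `NULL`.
#' @export
pcoa <- function(d, tol = 1e-8, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(d < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  if (correction == "cailliez" && n > 2L) {
    d <- cailliez_constant(d)
  }
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * centering %*% (d^2) %*% centering
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  pos <- e$values > 0
  keep <- e$values > tol * max(e$values)
  if (!any(keep)) stop("no positive eigenvalues: degenerate configuration",
                       call. = FALSE)
  eig <- e$values[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  scores <- vec %*% diag(sqrt(eig), length(eig), length(eig))
  for (a in seq_len(ncol(scores))) {
    nz <- which(abs(scores[, a]) > 1e-12)
    if (length(nz) && scores[nz[1], a] < 0) scores[, a] <- -scores[, a]
  }
  axis_names <- paste0("PCo", seq_len(ncol(scores)))
  dimnames(scores) <- list(rownames(d), axis_names)
  names(eig) <- axis_names
  new_ordination(scores, eig, eig / sum(e$values[pos]), loadings = NULL,
                 method = "pcoa")
}

## Cailliez (1983) additive constant: smallest c so that d + c applied to
## off-diagonal entries yields a Euclidean configuration.
cailliez_constant <- function(d) {
  n <- nrow(d)
  centering <- diag(n) - matrix(1 / n, n, n)
  delta1 <- -0.5 * centering %*% (d^2) %*% centering
  delta2 <- -0.5 * centering %*% d %*% centering
  zero <- matrix(0, n, n)
  big <- rbind(cbind(zero, 2 * delta1), cbind(-diag(n), -4 * delta2))
  cc <- max(Re(eigen(big, only.values = TRUE)$values))
  off <- row(d) != col(d)
  d[off] <- d[off] + cc
  d
}

#' Export ordination tables as CSV
#'
#' Writes scores, a per-axis variance table (eigenvalue, standard
#' deviation, proportion), and — for PCA — loadings.
#'
#' @param ord an `ordination`.
#' @param dir output directory (created if absent).
#' @param prefix filename prefix (default the ordination method).
#' @return Character vector of the paths written, invisibly.
#' @export
write_ordination <- function(ord, dir, prefix = ord$method) {
  stopifnot(inherits(ord, "ordination"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  sc <- data.frame(species_id = rownames(ord$scores),
                   as.data.frame(ord$scores), check.names = FALSE)
  p <- file.path(dir, paste0(prefix, "_scores.csv"))
  write_numeric_csv(sc, p)
  paths <- c(paths, p)
  vt <- data.frame(axis = names(ord$eigenvalues),
                   eigenvalue = ord$eigenvalues,
                   sdev = ord$sdevs,
                   proportion = ord$proportion)
  p <- file.path(dir, paste0(prefix, "_variance.csv"))
  write_numeric_csv(vt, p)
  paths <- c(paths, p)
  if (!is.null(ord$loadings)) {
    ld <- data.frame(trait = rownames(ord$loadings),
                     as.data.frame(ord$loadings), check.names = FALSE)
    p <- file.path(dir, paste0(prefix, "_loadings.csv"))
    write_numeric_csv(ld, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
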