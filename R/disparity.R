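## Disparity: per-group sum of variances over ordination axes, bootstrap
## distributions, and the hypothesis-test battery (two-sided pairwise
## Mann-Whitney on bootstrap distributions with Bonferroni correction;
## pairwise t-tests on raw measurements for group-mean comparisons).

#' Sum of variances of a score subset
#'
#' The disparity metric: the sum over all ordination axes of the sample
#' variance (n - 1 denominator) of the subset's scores. Characterizes the
#' volume a group occupies in morphospace and is relatively insensitive
#' to sample size. Over the full sample it equals the sum of the
#' ordination's eigenvalues (trace conservation), and it is invariant
#' under orthogonal rotation of the scores.
#'
#' @param scores numeric matrix, species in rows (rownames are ids),
#'   axes in columns; or an `ordination` (its scores are used).
#' @param subset character vector of row ids, or `NULL` for all rows.
#' @return Non-negative scalar. Subsets of fewer than 2 rows return 0
#'   with a warning.
#' @export
sum_of_variances <- function(scores, subset = NULL) {
  scores <- scores_matrix(scores)
  if (!is.null(subset)) {
    absent <- setdiff(subset, rownames(scores))
    if (length(absent)) {
      stop("species absent from scores: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    scores <- scores[subset, , drop = FALSE]
  }
  if (nrow(scores) < 2L) {
    warning("fewer than 2 members; sum of variances is 0", call. = FALSE)
    return(0)
  }
  sum(apply(scores, 2, stats::var))
}

scores_matrix <- function(scores) {
  if (inherits(scores, "ordination")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) {
    rownames(scores) <- as.character(seq_len(nrow(scores)))
  }
  scores
}

#' Bootstrap a group's disparity
#'
#' Resamples the subset's rows with replacement at constant n and
#' recomputes [sum_of_variances()] for each replicate. No rarefaction is
#' applied. Reproducible for a fixed seed; the global RNG state is left
#' untouched.
#'
#' @inheritParams sum_of_variances
#' @param n_boot number of replicates (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of length `n_boot`.
#' @export
bootstrap_disparity <- function(scores, subset = NULL, n_boot = 100,
                                seed = NULL) {
  if (!is.numeric(n_boot) || length(n_boot) != 1L || is.na(n_boot) ||
      n_boot < 1) {
    stop("`n_boot` must be a positive integer", call. = FALSE)
  }
  n_boot <- as.integer(n_boot)
  scores <- scores_matrix(scores)
  if (is.null(subset)) subset <- rownames(scores)
  absent <- setdiff(subset, rownames(scores))
  if (length(absent)) {
    stop("species absent from scores: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sub <- scores[subset, , drop = FALSE]
  n <- nrow(sub)
  if (n < 2L) stop("bootstrap needs a subset of >= 2 members", call. = FALSE)
  with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      resampled <- sub[idx, , drop = FALSE]
      sum(apply(resampled, 2, stats::var))
    }, numeric(1))
  })
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Returns the U statistic for `x` and a two-sided p-value: exact by full
#' enumeration of all group labelings when `length(x) + length(y) <= 12`
#' and there are no ties, otherwise a normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max combined size up to which the exact enumeration is
#'   used (default 12).
#' @return List with `W` (the U statistic for `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  combined <- c(x, y)
  r <- rank(combined)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(combined) > 0L
  if (n <= exact_max && !has_ties) {
    # full enumeration: U distribution over all C(n, nx) labelings
    subsets <- utils::combn(n, nx)
    ranks <- rank(combined)  # tie-free: a permutation of 1..n
    u_all <- colSums(matrix(ranks[subsets], nrow = nx)) - nx * (nx + 1) / 2
    p_lower <- mean(u_all <= u_obs)
    p_upper <- mean(u_all >= u_obs)
    p <- min(1, 2 * min(p_lower, p_upper))
    return(list(W = u_obs, p = p, method = "exact"))
  }
  mu <- nx * ny / 2
  ties <- table(combined)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(W = u_obs, p = 1, method = "normal"))
  z <- u_obs - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(W = u_obs, p = p, method = "normal")
}

#' Bonferroni correction
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param m number of comparisons (defaults to `length(pvals)`; must be
#'   at least that).
#' @return `pmin(1, pvals * m)`.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (m < length(pvals)) {
    stop("`m` must be >= the number of p-values", call. = FALSE)
  }
  pmin(1, pvals * m)
}

#' Compare group disparities
#'
#' For every group in a grouping scheme: the point-estimate sum of
#' variances, a bootstrap distribution of the metric, and — for each pair
#' of testable groups — a two-sided Mann-Whitney test comparing the two
#' replicate vectors, Bonferroni-corrected over the number of pairs.
#' Because replicates of a bootstrap distribution are not independent
#' observations, the p-values are to be read as a conventional disparity
#' comparison, not as literal error probabilities.
#'
#' @inheritParams bootstrap_disparity
#' @param groups named character vector or factor mapping species ids
#'   (names) to group labels, an unnamed vector aligned with the score
#'   rows, or a named list of member-id vectors (which permits the same
#'   species in several groups). Two groups with identical membership
#'   receive identical bootstrap replicates (per-group seeds derive from
#'   the membership), so a group compared against itself yields p = 1.
#' @param min_group minimum group size admitted to testing (default 3);
#'   smaller groups are reported but excluded from tests, with a warning.
#' @return Object of class `disparity_result`: list with `groups` (data
#'   frame: group, n, sum_of_variances, boot_lower, boot_upper, tested),
#'   `boot` (named list of replicate vectors), `tests` (data frame:
#'   group1, group2, W, p, p_adj, degenerate), `n_boot`, `seed`.
#' @export
compare_disparities <- function(scores, groups, n_boot = 100, seed = NULL,
                                min_group = 3L) {
  scores <- scores_matrix(scores)
  if (is.list(groups)) {
    if (is.null(names(groups))) {
      stop("a list of groups must be named", call. = FALSE)
    }
    split_ids <- lapply(groups, as.character)
  } else {
    if (is.null(names(groups))) {
      if (length(groups) != nrow(scores)) {
        stop("unnamed `groups` must align with the score rows", call. = FALSE)
      }
      names(groups) <- rownames(scores)
    }
    groups <- groups[!is.na(groups)]
    split_ids <- split(names(groups), as.character(groups))
  }
  absent <- setdiff(unique(unlist(split_ids)), rownames(scores))
  if (length(absent)) {
    stop("species absent from scores: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sizes <- lengths(split_ids)
  small <- names(sizes)[sizes < min_group]
  if (length(small)) {
    warning("group(s) below minimum size ", min_group, " excluded from ",
            "tests: ", paste(small, collapse = ", "), call. = FALSE)
  }
  testable <- names(sizes)[sizes >= max(2L, min_group)]
  if (length(testable) < 2L) {
    stop("need >= 2 groups of size >= ", max(2L, min_group),
         " for disparity comparison", call. = FALSE)
  }
  point <- vapply(split_ids, function(ids) {
    if (length(ids) < 2L) 0 else sum_of_variances(scores, ids)
  }, numeric(1))
  boot <- vector("list", length(testable))
  names(boot) <- testable
  for (i in seq_along(testable)) {
    g <- testable[i]
    # seed from the membership, not the group index: identical member
    # sets resample identically, so self-comparisons are exact ties
    gseed <- if (is.null(seed)) NULL else
      derive_seed(seed, membership_hash(split_ids[[g]]))
    boot[[g]] <- bootstrap_disparity(scores, split_ids[[g]], n_boot, gseed)
  }
  pairs <- utils::combn(sort(testable), 2)
  tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      W = NA_real_, p = NA_real_, p_adj = NA_real_,
                      degenerate = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    b1 <- boot[[pairs[1, k]]]
    b2 <- boot[[pairs[2, k]]]
    res <- mann_whitney_u(b1, b2)
    tests$W[k] <- res$W
    tests$p[k] <- res$p
    tests$degenerate[k] <- stats::sd(c(b1, b2)) == 0
  }
  tests$p_adj <- bonferroni_adjust(tests$p, ncol(pairs))
  q <- t(vapply(names(split_ids), function(g) {
    if (g %in% names(boot)) {
      stats::quantile(boot[[g]], c(0.025, 0.975), names = FALSE)
    } else c(NA_real_, NA_real_)
  }, numeric(2)))
  structure(
    list(groups = data.frame(group = names(split_ids), n = as.integer(sizes),
                             sum_of_variances = point,
                             boot_lower = q[, 1], boot_upper = q[, 2],
                             tested = names(split_ids) %in% testable,
                             row.names = NULL, stringsAsFactors = FALSE),
         boot = boot, tests = tests, n_boot = as.integer(n_boot),
         seed = seed),
    class = "disparity_result"
  )
}

#' @export
print.disparity_result <- function(x, ...) {
  cat("<disparity_result> ", nrow(x$groups), " groups, n_boot = ",
      x$n_boot, "\n", sep = "")
  print(x$groups, digits = 4)
  cat("pairwise two-sided Mann-Whitney (Bonferroni-adjusted):\n")
  print(x$tests, digits = 4)
  invisible(x)
}

#' Pairwise group-mean t-tests
#'
#' Two-sample t statistics for every pair of groups with the pooled
#' standard deviation estimated across all groups (df = N - k), matching
#' the conventional pairwise procedure; a Welch variant (per-pair
#' variances, Welch df) is available. P-values are Bonferroni-corrected
#' over the number of pairs. Groups with fewer than 2 members are
#' excluded with a warning.
#'
#' @param values numeric vector of a single measurement.
#' @param groups group labels aligned with `values`.
#' @param method `"pooled"` (default) or `"welch"`.
#' @return Data frame: group1, group2, t, df, p, p_adj.
#' @export
pairwise_group_means <- function(values, groups,
                                 method = c("pooled", "welch")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  split_v <- split(values, groups)
  sizes <- lengths(split_v)
  if (any(sizes < 2L)) {
    warning("group(s) with n < 2 excluded: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
    split_v <- split_v[sizes >= 2L]
  }
  if (length(split_v) < 2L) {
    stop("need >= 2 groups with n >= 2", call. = FALSE)
  }
  k <- length(split_v)
  ns <- lengths(split_v)
  vars <- vapply(split_v, stats::var, numeric(1))
  means <- vapply(split_v, mean, numeric(1))
  pooled_df <- sum(ns) - k
  pooled_sd <- sqrt(sum((ns - 1) * vars) / pooled_df)
  pairs <- utils::combn(sort(names(split_v)), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    if (method == "pooled") {
      se <- pooled_sd * sqrt(1 / ns[g1] + 1 / ns[g2])
      tt <- if (se == 0) 0 else (means[g1] - means[g2]) / se
      df <- pooled_df
    } else {
      se2 <- vars[g1] / ns[g1] + vars[g2] / ns[g2]
      tt <- if (se2 == 0) 0 else (means[g1] - means[g2]) / sqrt(se2)
      df <- if (se2 == 0) ns[g1] + ns[g2] - 2 else
        se2^2 / ((vars[g1] / ns[g1])^2 / (ns[g1] - 1) +
                 (vars[g2] / ns[g2])^2 / (ns[g2] - 1))
    }
    out$t[i] <- tt
    out$df[i] <- df
    out$p[i] <- if (tt == 0 && se_zero(method, pooled_sd, vars, g1, g2)) 1
      else 2 * stats::pt(-abs(tt), df)
  }
  out$p_adj <- bonferroni_adjust(out$p, ncol(pairs))
  out
}

se_zero <- function(method, pooled_sd, vars, g1, g2) {
  if (method == "pooled") pooled_sd == 0 else vars[g1] + vars[g2] == 0
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with
#'   nonzero variance.
#' @return List with `R` (sample Pearson correlation), `p` (two-sided,
#'   from t = R * sqrt((n - 2) / (1 - R^2)) with n - 2 df), and `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("correlation needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input has no defined correlation", call. = FALSE)
  }
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(R = r, p = p, n = n)
}
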