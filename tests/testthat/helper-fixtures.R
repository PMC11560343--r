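# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Build a landmark_set from sagittal (x, z) lever points; y = 0 for all
# lever landmarks, width spans placed transversely.
make_test_lm <- function(joint = c(0, 0), coronoid = c(2, 1),
                         anterior = c(5, 0), posterior = c(-1, 0),
                         trit_post = c(3, 0), width = 4, trit_width = 1,
                         id = "test") {
  xz <- function(p) c(p[1], 0, p[2])
  coords <- rbind(
    jaw_joint = xz(joint),
    coronoid_tip = xz(coronoid),
    anterior_tip = xz(anterior),
    posterior_tip = xz(posterior),
    triturating_posterior = xz(trit_post),
    width_left = c(1, -width / 2, 0),
    width_right = c(1, width / 2, 0),
    trit_width_left = c(2, -trit_width / 2, 0),
    trit_width_right = c(2, trit_width / 2, 0)
  )
  landmark_set(id, coords)
}

# Apply a rigid motion plus uniform scaling to a landmark_set, restricted
# to a rotation within the sagittal (x, z) plane so sagittal-projected
# distances are preserved alongside 3D ones.
transform_lm <- function(lm, angle = 0.7, scale = 2.5,
                         shift = c(3, -1, 4)) {
  rot <- rbind(c(cos(angle), 0, -sin(angle)),
               c(0, 1, 0),
               c(sin(angle), 0, cos(angle)))
  coords <- scale * lm$coords %*% t(rot)
  coords <- sweep(coords, 2, shift, "+")
  rownames(coords) <- rownames(lm$coords)
  landmark_set(lm$specimen_id, coords)
}

# Brute-force Gower oracle: per-pair mean mismatch over characters
# scored in both taxa. Cells: single states as character, NA missing.
gower_oracle <- function(cells) {
  n <- nrow(cells)
  d <- matrix(0, n, n, dimnames = list(rownames(cells), rownames(cells)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0L
      den <- 0L
      for (c in seq_len(ncol(cells))) {
        if (!is.na(cells[i, c]) && !is.na(cells[j, c])) {
          den <- den + 1L
          if (cells[i, c] != cells[j, c]) num <- num + 1L
        }
      }
      d[i, j] <- if (den == 0L) NA_real_ else num / den
    }
  }
  d
}

# Random character cell matrix with controllable missingness.
random_cells <- function(n_taxa, n_chars, n_states = 3, p_missing = 0.2) {
  cells <- matrix(as.character(sample.int(n_states, n_taxa * n_chars,
                                          replace = TRUE) - 1L),
                  n_taxa, n_chars,
                  dimnames = list(paste0("t", seq_len(n_taxa)),
                                  paste0("c", seq_len(n_chars))))
  cells[runif(length(cells)) < p_missing] <- NA_character_
  cells
}

# Exact Mann-Whitney oracle: enumerate all labelings via stats::wilcox.test
# (independent code path from the package's own enumeration).
wilcox_oracle <- function(x, y) {
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                             correct = TRUE))
  list(W = unname(res$statistic), p = res$p.value)
}
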