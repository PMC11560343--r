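# Character matrix parsing, polymorphism resolution, Gower, PCoA.

write_toy_nexus <- function(path, rows,
                            header = "  FORMAT SYMBOLS=\"012\" MISSING=? GAP=-;") {
  writeLines(c("#NEXUS", "BEGIN CHARACTERS;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(rows),
                       nchar(gsub("\\{[^}]*\\}|\\([^)]*\\)", "X",
                                  sub("^\\S+\\s+", "", rows[1])))),
               header, "  MATRIX", paste0("    ", rows), "  ;", "END;"),
             path)
}

test_that("NEXUS reader handles missing, gaps, polymorphisms and taxon order", {
  path <- withr::local_tempfile(fileext = ".nex")
  write_toy_nexus(path, c("tax_b  01?", "tax_a  0{01}1", "tax_c  1-0"))
  m <- read_characters(path)
  expect_s3_class(m, "character_matrix")
  expect_equal(rownames(m$cells), c("tax_b", "tax_a", "tax_c"))
  expect_true(is.na(m$cells["tax_b", 3]))
  expect_true(is.na(m$cells["tax_c", 2]))  # gap parsed as missing
  expect_equal(m$cells["tax_a", 2], "0/1")
  # quoted taxon names and parenthesis polymorphisms
  path2 <- withr::local_tempfile(fileext = ".nex")
  write_toy_nexus(path2, c("'Genus species'  0(01)1", "t2  000"))
  m2 <- read_characters(path2)
  expect_equal(rownames(m2$cells)[1], "Genus species")
  expect_equal(m2$cells[1, 2], "0/1")
})

test_that("NEXUS reader reports ragged rows and unknown tokens with position", {
  path <- withr::local_tempfile(fileext = ".nex")
  write_toy_nexus(path, c("t1  010", "t2  01"))
  expect_error(read_characters(path), "ragged")
  path2 <- withr::local_tempfile(fileext = ".nex")
  write_toy_nexus(path2, c("t1  0A0", "t2  010"))
  expect_error(read_characters(path2), "line 6")
  expect_error(read_characters(withr::local_tempfile(fileext = ".nex")),
               "not found")
})

test_that("CSV reader parses states, missing and slash polymorphisms", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("taxon,c1,c2,c3", "t1,0,?,1", "t2,{01},2,0", "t3,1,0/1,-"),
             path)
  m <- read_characters(path, format = "csv")
  expect_true(is.na(m$cells["t1", "c2"]))
  expect_equal(m$cells["t2", "c1"], "0/1")
  expect_equal(m$cells["t3", "c2"], "0/1")
  expect_true(is.na(m$cells["t3", "c3"]))
})

test_that("polymorphism resolution follows the majority rule with ties to missing", {
  cells <- rbind(t1 = c("0/0/1", "0/1", "2"),
                 t2 = c("0", "1", "1/1/2"))
  m <- character_matrix(cells)
  maj <- resolve_polymorphisms(m, "majority")
  expect_equal(maj$cells["t1", 1], "0")      # multiset {0,0,1} -> 0
  expect_true(is.na(maj$cells["t1", 2]))     # tie {0,1} -> missing
  expect_equal(maj$cells["t2", 3], "1")
  mis <- resolve_polymorphisms(m, "missing")
  expect_true(all(is.na(mis$cells[c(1, 3, 6)])))
  # monomorphic matrix unchanged under every mode
  mono <- character_matrix(rbind(a = c("0", "1"), b = c("1", "1")))
  for (mode in c("majority", "missing", "keep")) {
    expect_equal(resolve_polymorphisms(mono, mode)$cells, mono$cells)
  }
})

test_that("gower_distance matches hand-computed cases", {
  m <- character_matrix(rbind(t1 = c("0", "1", "0", "1"),
                              t2 = c("0", "1", "0", "1"),
                              t3 = c("1", "0", "1", "0")))
  d <- gower_distance(m)
  expect_equal(d["t1", "t2"], 0)
  expect_equal(d["t1", "t3"], 1.0)
  # rows (0,1,?,0) vs (0,0,1,?): comparable chars {c1,c2}, one mismatch
  m2 <- character_matrix(rbind(t1 = c("0", "1", NA, "0"),
                               t2 = c("0", "0", "1", NA)))
  expect_equal(gower_distance(m2)["t1", "t2"], 0.5)
  # disjoint scorings
  m3 <- character_matrix(rbind(t1 = c("0", NA), t2 = c(NA, "1")))
  expect_error(gower_distance(m3), "no comparable")
  # polymorphic cells must be resolved first
  m4 <- character_matrix(rbind(t1 = c("0/1", "0"), t2 = c("0", "1")))
  expect_error(gower_distance(m4), "resolve_polymorphisms")
})

test_that("gower_distance equals the brute-force oracle and daisy on random matrices", {
  set.seed(11)
  for (rep in 1:30) {
    n_taxa <- sample(2:5, 1)
    n_chars <- sample(1:5, 1)
    cells <- random_cells(n_taxa, n_chars)
    oracle <- gower_oracle(cells)
    if (anyNA(oracle)) next  # incomparable pair: error path tested above
    d <- gower_distance(character_matrix(cells))
    expect_equal(unclass(d), oracle, tolerance = 1e-12)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unclass(d), t(unclass(d)))
    # daisy (factor Gower) as a second, independent reference
    df <- as.data.frame(lapply(as.data.frame(cells), factor))
    # all-NA columns make daisy warn about empty factor ranges; harmless
    daisy_d <- suppressWarnings(as.matrix(cluster::daisy(df,
                                                         metric = "gower")))
    dimnames(daisy_d) <- dimnames(oracle)
    expect_equal(unclass(d), daisy_d, tolerance = 1e-12)
  }
})

test_that("gower handles exhaustive missing patterns on a 2x3 matrix", {
  base <- rbind(t1 = c("0", "1", "2"), t2 = c("0", "0", "2"))
  for (mask in 0:62) {  # 63 = all-missing leaves no comparable characters
    cells <- base
    cells[which(bitwAnd(mask, 2^(0:5)) > 0)] <- NA_character_
    oracle <- gower_oracle(cells)
    if (anyNA(oracle)) {
      expect_error(gower_distance(character_matrix(cells)), "no comparable")
    } else {
      expect_equal(unclass(gower_distance(character_matrix(cells))), oracle)
    }
  }
})

test_that("pcoa reproduces collinear and duplicated-taxon geometry", {
  # 1D points {0, 1, 3}: exactly one positive axis carrying all variance
  d <- as.matrix(dist(c(0, 1, 3)))
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  co <- pcoa(d)
  expect_equal(ncol(co$scores), 1L)
  expect_equal(co$proportion, c(PCo1 = 1))
  # duplicated taxa coincide on every axis
  x <- rbind(p = c(0, 0), q = c(1, 2), q2 = c(1, 2), r = c(4, 1))
  co2 <- pcoa(as.matrix(dist(x)))
  expect_equal(co2$scores["q", ], co2$scores["q2", ], tolerance = 1e-9)
  # input validation
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
  expect_error(pcoa(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})

test_that("pcoa on Euclidean distances recovers the PCA configuration", {
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(30), 10, 3)
    rownames(x) <- paste0("s", 1:10)
    co <- pcoa(as.matrix(dist(x)))
    pc <- pca(x)
    k <- min(ncol(co$scores), ncol(pc$scores))
    expect_equal(co$proportion[1:k], pc$proportion[1:k],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(as.matrix(dist(co$scores)), as.matrix(dist(x)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_lte(ncol(co$scores), nrow(x) - 1L)
  }
})

test_that("pcoa agrees with the ape reference on Gower input and drops negative eigenvalues", {
  set.seed(23)
  cells <- random_cells(8, 12, p_missing = 0.3)
  d <- gower_distance(character_matrix(cells))
  co <- pcoa(d)
  ref <- ape::pcoa(stats::as.dist(unclass(d)))
  k <- ncol(co$scores)
  expect_equal(unname(co$eigenvalues),
               ref$values$Eigenvalues[1:k], tolerance = 1e-9)
  # proportions over positive eigenvalues only (ape's Relative_eig uses
  # the full trace including negatives, so renormalize its eigenvalues)
  pos <- ref$values$Eigenvalues[ref$values$Eigenvalues > 0]
  expect_equal(unname(co$proportion),
               ref$values$Eigenvalues[1:k] / sum(pos), tolerance = 1e-9)
  expect_true(all(co$eigenvalues > 0))
})

test_that("NEXUS writer round-trips through the reader", {
  sim <- make_character_matrix(n_groups = 2, group_sizes = 4, n_chars = 10,
                               missing_prob = 0.1, poly_prob = 0.1, seed = 3)
  path <- withr::local_tempfile(fileext = ".nex")
  write_characters_nexus(sim$matrix, path)
  back <- read_characters(path)
  expect_equal(rownames(back$cells), rownames(sim$matrix$cells))
  # polymorphic multisets collapse to their distinct states on write
  norm <- function(cells) {
    apply(cells, c(1, 2), function(cell) {
      if (is.na(cell)) return(NA_character_)
      paste(sort(unique(strsplit(cell, "/", fixed = TRUE)[[1]])),
            collapse = "/")
    })
  }
  expect_equal(unname(norm(back$cells)), unname(norm(sim$matrix$cells)))
})
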