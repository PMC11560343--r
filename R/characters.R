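## Discrete character matrices: species x characters tables of nominal
## states with missing and polymorphic cells.
##
## Internal representation: a character matrix whose cells are either a
## single non-negative integer state ("0"), NA (missing), or a
## slash-joined multiset of >= 2 states ("0/1", "0/0/1"). Slash cells may
## repeat states so that a specimen-level majority rule has a defined
## answer.

#' Construct a discrete character matrix
#'
#' @param cells character matrix (taxa in rows, characters in columns)
#'   with rownames (taxon ids) and colnames (character ids). Cells are
#'   single states (`"0"`), `NA` for missing, or slash-joined multisets
#'   (`"0/1"`, `"0/0/1"`) for polymorphisms.
#' @return Object of class `character_matrix`.
#' @export
character_matrix <- function(cells) {
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (is.null(rownames(cells))) {
    rownames(cells) <- paste0("t", seq_len(nrow(cells)))
  }
  if (is.null(colnames(cells))) {
    colnames(cells) <- paste0("c", seq_len(ncol(cells)))
  }
  ok <- is.na(cells) | grepl("^[0-9]+(/[0-9]+)*$", cells)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("invalid cell at (", rownames(cells)[bad[1]], ", ",
         colnames(cells)[bad[2]], "): '", cells[bad[1], bad[2]], "'",
         call. = FALSE)
  }
  poly <- grepl("/", cells) & !is.na(cells)
  if (any(poly)) {
    distinct <- vapply(strsplit(cells[poly], "/", fixed = TRUE),
                       function(s) length(unique(s)), integer(1))
    if (any(distinct < 2L)) {
      stop("polymorphic cells must contain >= 2 distinct states",
           call. = FALSE)
    }
  }
  structure(list(cells = cells), class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cells <- x$cells
  cat("<character_matrix> ", nrow(cells), " taxa x ", ncol(cells),
      " characters; ", sum(is.na(cells)), " missing, ",
      sum(grepl("/", cells), na.rm = TRUE), " polymorphic\n", sep = "")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

## Parse one matrix token into the internal cell encoding.
parse_cell <- function(token, missing_chars = c("?", "-"), where = "") {
  token <- trimws(token)
  if (token %in% missing_chars) return(NA_character_)
  if (grepl("^[0-9]+$", token)) return(token)
  if (grepl("^[{(][0-9 ,]+[})]$", token)) {
    states <- regmatches(token, gregexpr("[0-9]", token))[[1]]
    if (length(unique(states)) < 2L) {
      stop("polymorphic token '", token, "'", where,
           " has fewer than 2 distinct states", call. = FALSE)
    }
    return(paste(states, collapse = "/"))
  }
  if (grepl("^[0-9]+(/[0-9]+)+$", token)) return(token)
  stop("unknown character-state token '", token, "'", where, call. = FALSE)
}

#' Read a discrete character matrix
#'
#' Reads a taxa-by-characters matrix of nominal states from NEXUS (a
#' CHARACTERS or DATA block) or CSV. `"?"` and `"-"` (or the symbols
#' declared in the NEXUS FORMAT line) are parsed as missing; `"{01}"`,
#' `"(01)"` and `"0/1"` as polymorphic state sets. Taxon order is
#' preserved.
#'
#' @param path file path.
#' @param format `"nexus"` or `"csv"`; the default guesses from the file
#'   extension (`.nex`/`.nexus` vs anything else).
#' @return A [character_matrix()].
#' @export
read_characters <- function(path, format = c("auto", "nexus", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("character file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus"
              else "csv"
  }
  if (format == "nexus") read_characters_nexus(path) else
    read_characters_csv(path)
}

read_characters_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character())
  if (ncol(df) < 2L) {
    stop("character CSV needs a taxon column plus >= 1 character column",
         call. = FALSE)
  }
  taxa <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  out <- matrix(NA_character_, nrow(cells), ncol(cells),
                dimnames = list(taxa, colnames(cells)))
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(ncol(cells))) {
      tok <- cells[i, j]
      if (is.na(tok) || tok == "") {
        stop("empty cell at line ", i + 1L, ", column ", j + 1L,
             call. = FALSE)
      }
      out[i, j] <- parse_cell(tok, where = paste0(" at line ", i + 1L))
    }
  }
  character_matrix(out)
}

read_characters_nexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#NEXUS", toupper(trimws(lines[1])))) {
    stop("not a NEXUS file (missing #NEXUS header): ", path, call. = FALSE)
  }
  upper <- toupper(lines)
  missing_sym <- "?"
  gap_sym <- "-"
  fmt_line <- grep("\\bFORMAT\\b", upper)
  if (length(fmt_line)) {
    fmt <- lines[fmt_line[1]]
    m <- regmatches(fmt, regexec("MISSING\\s*=\\s*(\\S)", fmt,
                                 ignore.case = TRUE))[[1]]
    if (length(m) == 2L) missing_sym <- m[2]
    g <- regmatches(fmt, regexec("GAP\\s*=\\s*(\\S)", fmt,
                                 ignore.case = TRUE))[[1]]
    if (length(g) == 2L) gap_sym <- g[2]
  }
  start <- grep("^\\s*MATRIX\\s*$", upper)
  if (!length(start)) stop("no MATRIX command found in ", path, call. = FALSE)
  start <- start[1]
  taxa <- character()
  rows <- list()
  i <- start + 1L
  done <- FALSE
  while (i <= length(lines) && !done) {
    line <- trimws(lines[i])
    if (grepl(";\\s*$", line)) {
      done <- TRUE
      line <- trimws(sub(";\\s*$", "", line))
    }
    if (nzchar(line) && !grepl("^\\[", line)) {
      # taxon name: quoted or first whitespace-delimited token
      if (grepl("^'", line)) {
        m <- regexec("^'([^']*)'\\s*(.*)$", line)
        parts <- regmatches(line, m)[[1]]
        if (length(parts) != 3L) {
          stop("malformed quoted taxon name at line ", i, call. = FALSE)
        }
        name <- parts[2]
        states_str <- parts[3]
      } else {
        m <- regexec("^(\\S+)\\s+(.*)$", line)
        parts <- regmatches(line, m)[[1]]
        if (length(parts) != 3L) {
          stop("malformed matrix row at line ", i, call. = FALSE)
        }
        name <- parts[2]
        states_str <- parts[3]
      }
      toks <- tokenize_states(states_str, i)
      cells <- vapply(toks, parse_cell,
                      missing_chars = c(missing_sym, gap_sym),
                      where = paste0(" at line ", i), FUN.VALUE = character(1))
      taxa <- c(taxa, name)
      rows[[length(rows) + 1L]] <- unname(cells)
    }
    i <- i + 1L
  }
  if (!done) stop("unterminated MATRIX (no ';') in ", path, call. = FALSE)
  if (!length(rows)) stop("empty MATRIX in ", path, call. = FALSE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop("ragged matrix: taxon '", taxa[bad], "' has ", lens[bad],
         " characters, expected ", lens[1], call. = FALSE)
  }
  cells <- do.call(rbind, rows)
  dimnames(cells) <- list(taxa, paste0("c", seq_len(ncol(cells))))
  character_matrix(cells)
}

## Split a NEXUS state string into tokens: single symbols, or {..}/(..)
## groups kept whole.
tokenize_states <- function(s, lineno) {
  chars <- strsplit(gsub("\\s", "", s), "")[[1]]
  toks <- character()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars)) {
        stop("unbalanced '", ch, "' at line ", lineno, call. = FALSE)
      }
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

#' Resolve polymorphic cells
#'
#' Three policies for set-valued cells:
#' \describe{
#'   \item{majority}{replace each polymorphic multiset by its most
#'     frequent state; ties become missing;}
#'   \item{missing}{replace every polymorphic cell by missing;}
#'   \item{keep}{pass the matrix through unchanged.}
#' }
#'
#' @param m a [character_matrix()].
#' @param mode `"majority"`, `"missing"` or `"keep"`.
#' @return A [character_matrix()] with no polymorphic cells (unless
#'   `mode = "keep"`).
#' @export
resolve_polymorphisms <- function(m, mode = c("majority", "missing", "keep")) {
  stopifnot(inherits(m, "character_matrix"))
  mode <- match.arg(mode)
  if (mode == "keep") return(m)
  cells <- m$cells
  poly <- which(grepl("/", cells) & !is.na(cells))
  for (idx in poly) {
    if (mode == "missing") {
      cells[idx] <- NA_character_
    } else {
      states <- strsplit(cells[idx], "/", fixed = TRUE)[[1]]
      tab <- table(states)
      top <- names(tab)[tab == max(tab)]
      cells[idx] <- if (length(top) == 1L) top else NA_character_
    }
  }
  character_matrix(cells)
}

#' Gower dissimilarity for nominal characters
#'
#' For each pair of taxa, the proportion of mismatching states over the
#' characters scored (non-missing) in both, all characters unordered
#' nominal with equal weight (pairwise-complete renormalization). Output
#' is bounded in \[0, 1\]; with missing data it need not satisfy the
#' triangle inequality.
#'
#' @param m a [character_matrix()] with no polymorphic cells (apply
#'   [resolve_polymorphisms()] first).
#' @return A symmetric `dist`-like square matrix of class
#'   `distance_matrix` with zero diagonal and taxon labels.
#' @export
gower_distance <- function(m) {
  stopifnot(inherits(m, "character_matrix"))
  cells <- m$cells
  if (any(grepl("/", cells) & !is.na(cells))) {
    stop("matrix still contains polymorphic cells; run ",
         "resolve_polymorphisms() first", call. = FALSE)
  }
  n <- nrow(cells)
  d <- matrix(0, n, n, dimnames = list(rownames(cells), rownames(cells)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      comp <- !is.na(cells[i, ]) & !is.na(cells[j, ])
      if (!any(comp)) {
        stop("no comparable characters between '", rownames(cells)[i],
             "' and '", rownames(cells)[j], "'", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(cells[i, comp] != cells[j, comp])
    }
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

#' Write a distance matrix as square CSV
#' @param d square distance matrix with labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(taxon = rownames(d), as.data.frame(unclass(d)),
                   check.names = FALSE)
  write_numeric_csv(df, path)
  invisible(path)
}
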