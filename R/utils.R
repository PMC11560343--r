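## Shared helpers: seeded evaluation that does not disturb the caller's
## RNG stream, deterministic sub-seed derivation, and a CSV writer that
## prints floating-point columns with 12 significant digits so numeric
## artifacts are byte-stable across runs.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a parent seed and an index, kept within
## 32-bit integer range and never zero.
derive_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) + 99991 * as.double(i)
  as.integer(s %% 2147483646) + 1L
}

## Polynomial rolling hash of a string, kept within 32-bit integer range.
string_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  h
}

## Hash of a set of ids (order-insensitive via sorting), reduced for seed
## derivation.
membership_hash <- function(ids) {
  string_hash(paste(sort(ids), collapse = ";")) %% 1048573
}

## Write a data frame as CSV with numeric columns formatted to 12
## significant digits.
write_numeric_csv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = 12, format = "g")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
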