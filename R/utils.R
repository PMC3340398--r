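#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Reverse complement of plain character DNA (ACGTN); vectorised.
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## Encode a DNA string as integer codes 1..4 (A,C,G,T); N and anything
## else becomes NA.  Scanning works on this encoding.
encode_dna <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- match(ch, DNA_BASES)
  m
}

check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside %s: %s",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_hexamer <- function(x, what = "hexamer") {
  if (any(nchar(x) != 6L)) {
    stop(sprintf("%s must be exactly 6 bases long (got: %s)", what,
                 paste(utils::head(x[nchar(x) != 6L], 3), collapse = ", ")),
         call. = FALSE)
  }
  check_dna(toupper(x), allow_n = FALSE, what = what)
}

## Run code with a seeded, isolated RNG stream; the caller's RNG state
## is left untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is required", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
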