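#' TRE architecture definitions
#'
#' The three element geometries scanned for: direct repeat with 4-bp
#' spacer (DR4), inverted repeat with no spacer (IR0) and everted repeat
#' with 6-bp spacer (ER6). Element length is 12 + spacer.
#'
#' @param name One of "DR4", "IR0", "ER6".
#' @return A list with \code{name}, \code{spacer}, \code{geometry},
#'   \code{length}.
#' @export
tre_architecture <- function(name) {
  defs <- list(
    DR4 = list(name = "DR4", spacer = 4L, geometry = "direct"),
    IR0 = list(name = "IR0", spacer = 0L, geometry = "inverted"),
    ER6 = list(name = "ER6", spacer = 6L, geometry = "everted"))
  if (!name %in% names(defs)) {
    stop("unknown architecture: ", name, " (expected DR4, IR0 or ER6)",
         call. = FALSE)
  }
  a <- defs[[name]]
  a$length <- 12L + a$spacer
  a
}

ARCHITECTURES <- c("DR4", "IR0", "ER6")

#' Scan thresholds
#'
#' The dual-threshold rule: one half-site must score at least
#' \code{high_bits} and the other at least \code{low_bits}, regardless of
#' half-site order.
#'
#' @param low_bits Lower cut-off in bits (default 3.76).
#' @param high_bits Higher cut-off in bits (default 6).
#' @export
scan_thresholds <- function(low_bits = 3.76, high_bits = 6.0) {
  if (low_bits > high_bits) stop("low_bits must be <= high_bits", call. = FALSE)
  list(low_bits = low_bits, high_bits = high_bits)
}

#' Scan configuration
#'
#' @param thresholds A \code{\link{scan_thresholds}} list.
#' @param architectures Subset of DR4, IR0, ER6 to scan.
#' @param both_strands Also scan the reverse complement of each promoter?
#'   Default FALSE (sense strand only).
#' @export
scan_config <- function(thresholds = scan_thresholds(),
                        architectures = ARCHITECTURES,
                        both_strands = FALSE) {
  architectures <- match.arg(architectures, ARCHITECTURES, several.ok = TRUE)
  if (length(architectures) < 1L) {
    stop("at least one architecture must be enabled", call. = FALSE)
  }
  list(thresholds = thresholds, architectures = architectures,
       both_strands = both_strands)
}

#' A TSS-anchored promoter sequence
#'
#' @param gene Gene identifier.
#' @param species One of "mouse", "rat", "human".
#' @param seq DNA string over ACGTN (N never matches; lower case is
#'   upper-cased).
#' @param window_start Offset of the first base relative to the TSS
#'   (negative = upstream; default -8000).
#' @param window_end One past the last base, TSS-relative. Defaults to
#'   \code{window_start + nchar(seq)} and must equal it.
#' @return A list of class \code{promoter}.
#' @export
promoter <- function(gene, species, seq, window_start = -8000L,
                     window_end = window_start + nchar(seq)) {
  seq <- toupper(seq)
  check_dna(seq, allow_n = TRUE, what = sprintf("promoter %s/%s", gene, species))
  species <- match.arg(species, c("mouse", "rat", "human"))
  if (nchar(seq) != window_end - window_start) {
    stop(sprintf("promoter %s/%s: sequence length %d != window %d..%d",
                 gene, species, nchar(seq), window_start, window_end),
         call. = FALSE)
  }
  structure(list(gene = gene, species = species, seq = seq,
                 window_start = as.integer(window_start),
                 window_end = as.integer(window_end)),
            class = "promoter")
}

#' Map a sequence offset to a TSS-relative position
#'
#' @param offset_in_seq 0-based offset of a base within the window.
#' @param window_start TSS-relative position of the window's first base.
#' @return \code{window_start + offset_in_seq}; 0 is the TSS, negative is
#'   upstream.
#' @export
tss_position <- function(offset_in_seq, window_start) {
  if (any(offset_in_seq < 0)) {
    stop("offset_in_seq must be non-negative", call. = FALSE)
  }
  as.integer(window_start + offset_in_seq)
}

#' Extract the two half-sites of an element window
#'
#' Realises the repeat geometry: for a direct repeat both hexamers are
#' read as written; for an inverted repeat the downstream hexamer is
#' reverse-complemented; for an everted repeat the upstream hexamer is
#' reverse-complemented. The returned hexamers are "as read for scoring",
#' i.e. in the AGGTCA-like orientation the matrix was trained on.
#'
#' @param window DNA string of length 12 + spacer.
#' @param arch An architecture name or \code{\link{tre_architecture}}.
#' @return Character vector \code{c(halfsite1, halfsite2)}.
#' @export
extract_halfsites <- function(window, arch) {
  if (is.character(arch)) arch <- tre_architecture(arch)
  n <- nchar(window)
  if (n != arch$length) {
    stop(sprintf("internal error: %s window must be %d bases, got %d",
                 arch$name, arch$length, n), call. = FALSE)
  }
  h1 <- substr(window, 1, 6)
  h2 <- substr(window, n - 5, n)
  switch(arch$name,
         DR4 = c(h1, h2),
         IR0 = c(h1, revcomp(h2)),
         ER6 = c(revcomp(h1), h2))
}

## Per-offset half-site scores over an encoded sequence.
## fwd[j]: score of the hexamer starting at j read as written;
## rc[j]:  score of its reverse complement. NA where the hexamer runs
## over an N or the window end.
halfsite_score_tracks <- function(code, bits) {
  L <- length(code)
  if (L < 6L) return(list(fwd = numeric(0), rc = numeric(0)))
  n <- L - 5L
  fwd <- numeric(n)
  rc <- numeric(n)
  for (k in 1:6) {
    fwd <- fwd + bits[k, ][code[k:(n + k - 1L)]]
    # position k of the revcomp hexamer is the complement of base j+6-k
    rc <- rc + bits[k, 5L - code[(7L - k):(L + 1L - k)]]
  }
  list(fwd = fwd, rc = rc)
}

## complement in code space: A<->T (1<->4), C<->G (2<->3) => 5 - code
## bits must be indexable by column integer; reorder columns accordingly.

#' Scan a promoter for candidate TREs
#'
#' Evaluates every start offset and enabled architecture; a hit is
#' emitted iff one extracted half-site scores at least \code{high_bits}
#' and the other at least \code{low_bits} (in either order). Windows
#' containing N are skipped. Hits are sorted by position, then
#' architecture.
#'
#' @param p A \code{\link{promoter}}.
#' @param pwm A \code{\link{build_pwm}} fit.
#' @param cfg A \code{\link{scan_config}}.
#' @return A data frame of class \code{tre_hits} with columns
#'   \code{gene, species, architecture, pos, strand, halfsite1,
#'   spacer_seq, halfsite2, bits1, bits2, element}. \code{pos} is the
#'   TSS-relative coordinate of the element's 5'-most base; \code{element}
#'   is the genomic element string as written on the scanned strand.
#' @export
scan_promoter <- function(p, pwm, cfg = scan_config()) {
  stopifnot(inherits(p, "promoter"), inherits(pwm, "halfsite_pwm"))
  if (nchar(p$seq) == 0L) {
    stop(sprintf("promoter %s/%s has an empty sequence", p$gene, p$species),
         call. = FALSE)
  }
  if (length(cfg$architectures) < 1L) {
    stop("no architectures enabled", call. = FALSE)
  }
  hits <- scan_strand(p$seq, p, pwm, cfg, strand = "+")
  if (isTRUE(cfg$both_strands)) {
    hits <- rbind(hits, scan_strand(revcomp(p$seq), p, pwm, cfg, strand = "-"))
  }
  hits <- hits[order(hits$pos, hits$architecture), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("tre_hits", "data.frame")
  hits
}

scan_strand <- function(seq, p, pwm, cfg, strand) {
  code <- encode_dna(seq)
  L <- length(code)
  ## reorder bits columns to code order A,C,G,T (already) as matrix rows x 4;
  ## pad a 5th NA column so N (NA code) propagates via indexing below
  bits <- pwm$bits
  tracks <- halfsite_score_tracks(code, bits)
  low <- cfg$thresholds$low_bits
  high <- cfg$thresholds$high_bits
  hasN <- cumsum(c(0L, is.na(code)))  # hasN[j+1]-hasN[i] = N count in i..j
  out <- list()
  for (aname in cfg$architectures) {
    arch <- tre_architecture(aname)
    elen <- arch$length
    if (L < elen) next
    starts <- seq_len(L - elen + 1L)
    b1 <- switch(aname,
                 DR4 = tracks$fwd[starts],
                 IR0 = tracks$fwd[starts],
                 ER6 = tracks$rc[starts])
    b2 <- switch(aname,
                 DR4 = tracks$fwd[starts + 10L],
                 IR0 = tracks$rc[starts + 6L],
                 ER6 = tracks$fwd[starts + 12L])
    nfree <- (hasN[starts + elen] - hasN[starts]) == 0L
    keep <- nfree & !is.na(b1) & !is.na(b2) &
      pmin(b1, b2) >= low & pmax(b1, b2) >= high
    keep[is.na(keep)] <- FALSE
    idx <- starts[keep]
    if (length(idx) == 0L) next
    windows <- substring(seq, idx, idx + elen - 1L)
    hs <- vapply(windows, extract_halfsites, character(2), arch = arch,
                 USE.NAMES = FALSE)
    pos <- if (strand == "+") tss_position(idx - 1L, p$window_start)
           else tss_position(L - idx - elen + 1L, p$window_start)
    out[[aname]] <- data.frame(
      gene = p$gene, species = p$species, architecture = aname,
      pos = pos, strand = strand,
      halfsite1 = hs[1, ], spacer_seq = substr(windows, 7, 6 + arch$spacer),
      halfsite2 = hs[2, ], bits1 = b1[keep], bits2 = b2[keep],
      element = windows, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(gene = character(), species = character(),
                      architecture = character(), pos = integer(),
                      strand = character(), halfsite1 = character(),
                      spacer_seq = character(), halfsite2 = character(),
                      bits1 = numeric(), bits2 = numeric(),
                      element = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Scan a set of promoters
#'
#' @param promoters A list of \code{\link{promoter}} objects (a
#'   \code{promoter_set}).
#' @inheritParams scan_promoter
#' @return A combined \code{tre_hits} data frame.
#' @export
scan_promoters <- function(promoters, pwm, cfg = scan_config()) {
  res <- lapply(promoters, scan_promoter, pwm = pwm, cfg = cfg)
  out <- do.call(rbind, res)
  if (is.null(out)) out <- scan_promoter(promoter("x", "mouse", "ACGTAC", 0L),
                                         pwm, cfg)[0, ]
  rownames(out) <- NULL
  class(out) <- c("tre_hits", "data.frame")
  out
}

#' @export
print.tre_hits <- function(x, ...) {
  cat(sprintf("%d candidate TRE hit(s) in %d gene(s)\n",
              nrow(x), length(unique(x$gene))))
  NextMethod()
}
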