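#' Read TSS-anchored promoter FASTA
#'
#' Headers are either \code{gene|species|window_start|window_end} or a
#' bare gene id accompanied by a sidecar TSV with columns \code{gene,
#' species, window_start}. Lowercase bases are upper-cased on read (and
#' noted via a message).
#'
#' @param path FASTA path.
#' @param sidecar Optional sidecar TSV path.
#' @return A \code{promoter_set}: list of \code{\link{promoter}}s.
#' @export
read_promoter_fasta <- function(path, sidecar = NULL) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- unname(as.character(ss))
  if (any(grepl("[acgtn]", seqs))) {
    message("read_promoter_fasta: lowercase bases upper-cased in ", path)
    seqs <- toupper(seqs)
  }
  headers <- names(ss)
  side <- NULL
  if (!is.null(sidecar)) {
    side <- utils::read.delim(sidecar, comment.char = "#",
                              stringsAsFactors = FALSE)
    if (!all(c("gene", "species", "window_start") %in% names(side))) {
      stop("sidecar TSV needs columns gene, species, window_start",
           call. = FALSE)
    }
  }
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (!is.null(side)) {
      gene <- headers[i]
      row <- side[side$gene == gene, ]
      if (nrow(row) != 1L) {
        stop(sprintf("sidecar has %d rows for gene %s (record %d)",
                     nrow(row), gene, i), call. = FALSE)
      }
      ws <- as.integer(row$window_start)
      sp <- row$species
    } else {
      parts <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
      if (length(parts) != 4L) {
        stop(sprintf("record %d: header '%s' is not gene|species|window_start|window_end",
                     i, headers[i]), call. = FALSE)
      }
      gene <- parts[1]; sp <- parts[2]; ws <- as.integer(parts[3])
      we <- as.integer(parts[4])
      if (nchar(seqs[i]) != we - ws) {
        stop(sprintf("record %d (%s): sequence length %d != declared window %d..%d",
                     i, gene, nchar(seqs[i]), ws, we), call. = FALSE)
      }
    }
    out[[i]] <- promoter(gene, sp, seqs[i], ws)
  }
  structure(out, class = c("promoter_set", "list"))
}

#' Write a promoter set as FASTA
#'
#' Headers follow \code{gene|species|window_start|window_end}.
#'
#' @param promoters A \code{promoter_set}.
#' @param path Output FASTA path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(vapply(promoters, `[[`, character(1), "seq"))
  names(seqs) <- vapply(promoters, function(p)
    sprintf("%s|%s|%d|%d", p$gene, p$species, p$window_start, p$window_end),
    character(1))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write / read TRE hit tables
#'
#' TSV with a header comment declaring the coordinate convention
#' (pos = TSS-relative coordinate of the element's 5'-most base, TSS = 0,
#' negative upstream).
#'
#' @param hits A \code{tre_hits} data frame.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pos: TSS-relative coordinate of the element's 5'-most base; TSS = 0, negative = upstream", con)
  utils::write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("tre_hits", "data.frame")
  df
}

#' Export hits as 6-column BED
#'
#' Coordinates are 0-based half-open offsets within each gene's promoter
#' window (chrom = gene); name is \code{gene:architecture} and score is
#' \code{min(bits1, bits2)} rescaled linearly from [0, 12] to [0, 1000]
#' and clamped.
#'
#' @param hits A \code{tre_hits} data frame.
#' @param window_start TSS-relative start of the scanned windows (used to
#'   shift positions to window offsets).
#' @param path Output BED path.
#' @export
write_hits_bed <- function(hits, path, window_start = -8000L) {
  if (nrow(hits) == 0L) {
    writeLines("# BED coordinates: 0-based half-open offsets within the promoter window",
               path)
    return(invisible(path))
  }
  elen <- vapply(hits$architecture, function(a) tre_architecture(a)$length,
                 integer(1))
  start <- hits$pos - window_start
  score <- pmin(1000L, pmax(0L,
                            as.integer(round(pmin(hits$bits1, hits$bits2) /
                                               12 * 1000))))
  bed <- data.frame(chrom = hits$gene, start = start, end = start + elen,
                    name = paste0(hits$gene, ":", hits$architecture),
                    score = score, strand = hits$strand)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED coordinates: 0-based half-open offsets within the promoter window", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a conserved-TRE table
#'
#' One row per (mouse element x rat match x human match) combination,
#' with TSS-relative positions and half-site mismatch counts per species.
#'
#' @param conserved A \code{conserved_tres} object.
#' @param path Output path.
#' @export
write_conserved_tsv <- function(conserved, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are TSS-relative (TSS = 0, negative = upstream); mm = half-site mismatches vs mouse", con)
  utils::write.table(conserved$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the conservation funnel report as JSON
#'
#' @param conserved A \code{conserved_tres} object.
#' @param path Output path.
#' @export
write_funnel_json <- function(conserved, path) {
  f <- conserved$funnel
  jsonlite::write_json(list(
    n_initial = f$n_initial, n_after_rat = f$n_after_rat,
    n_after_human = f$n_after_human,
    genes_initial = f$genes_initial,
    genes_after_rat = f$genes_after_rat,
    genes_after_human = f$genes_after_human,
    skipped_no_ortholog = f$skipped_no_ortholog),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' The packaged published conserved-element table
#'
#' Long-format table of published conserved thyroid response elements:
#' one row per mouse element x ortholog (rat/human) comparison, with
#' TSS-relative positions, element strings and published half-site
#' mismatch counts. \code{hamming_consistent} marks the rows whose
#' published count a plain half-site Hamming distance reproduces (all but
#' one, which reflects a shifted alignment in the original analysis).
#'
#' @return A data frame.
#' @export
published_tre_elements <- function() {
  utils::read.delim(system.file("extdata", "published_tre_elements.tsv",
                                package = "trescan", mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}
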