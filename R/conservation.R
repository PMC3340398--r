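#' Substitution matrix for ortholog alignment ranking
#'
#' An ungapped sliding-window alignment ranks candidate ortholog offsets
#' by this matrix. It favours conservation of the guanines at positions
#' two and three of each hexamer half-site, which are strongly retained in
#' receptor-bound elements: a mismatch against a mouse G at those
#' positions is penalised below an ordinary mismatch. The matrix only
#' ranks offsets; the conservation filter itself uses the plain half-site
#' mismatch count.
#'
#' @param match_score Score per identical base (default 1).
#' @param mismatch_score Score per ordinary mismatch (default 0).
#' @param g_conservation_penalty Score when the mouse base at half-site
#'   position 2 or 3 is G and the aligned base differs (default -1).
#' @export
substitution_matrix <- function(match_score = 1, mismatch_score = 0,
                                g_conservation_penalty = -1) {
  if (!(match_score > mismatch_score &&
        mismatch_score >= g_conservation_penalty)) {
    stop("require match_score > mismatch_score >= g_conservation_penalty",
         call. = FALSE)
  }
  list(match_score = match_score, mismatch_score = mismatch_score,
       g_conservation_penalty = g_conservation_penalty)
}

#' Conservation filter configuration
#'
#' @param max_mismatches Maximum half-site mismatches allowed per species
#'   comparison (default 2).
#' @param max_distance_bp Maximum TSS-relative distance between the mouse
#'   element and its ortholog match, inclusive (default 2000).
#' @param min_pwm_bits Minimum bit score required of the better ortholog
#'   half-site (default 3.76, the scan's low threshold). Set to
#'   \code{-Inf} to disable.
#' @export
conservation_config <- function(max_mismatches = 2L, max_distance_bp = 2000L,
                                min_pwm_bits = 3.76) {
  if (max_mismatches < 0 || max_distance_bp < 0) {
    stop("max_mismatches and max_distance_bp must be non-negative",
         call. = FALSE)
  }
  list(max_mismatches = as.integer(max_mismatches),
       max_distance_bp = as.integer(max_distance_bp),
       min_pwm_bits = min_pwm_bits)
}

## 1-based element positions belonging to the two half-sites
halfsite_positions <- function(elen) c(1:6, (elen - 5L):elen)

#' Count half-site mismatches between a mouse element and an ortholog
#'
#' The Hamming distance restricted to the 12 half-site positions (the
#' first and last six bases of the element, as written in genomic
#' orientation); spacer bases never count.
#'
#' @param mouse_tre,ortholog_tre Element strings of equal length.
#' @param architecture "DR4", "IR0" or "ER6"; used to validate the
#'   element length (12 + spacer).
#' @return Integer mismatch count (0-12).
#' @export
count_halfsite_mismatches <- function(mouse_tre, ortholog_tre, architecture) {
  arch <- tre_architecture(architecture)
  if (nchar(mouse_tre) != nchar(ortholog_tre)) {
    stop("mouse and ortholog elements must have equal length", call. = FALSE)
  }
  if (nchar(mouse_tre) != arch$length) {
    stop(sprintf("%s elements must be %d bases, got %d", arch$name,
                 arch$length, nchar(mouse_tre)), call. = FALSE)
  }
  a <- strsplit(toupper(mouse_tre), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(ortholog_tre), "", fixed = TRUE)[[1]]
  idx <- halfsite_positions(arch$length)
  sum(a[idx] != b[idx])
}

## substitution-matrix score of an ungapped pairing (character vectors)
sub_score <- function(mouse_ch, orth_ch, sub, elen) {
  eq <- mouse_ch == orth_ch
  hp <- halfsite_positions(elen)
  g23 <- intersect(hp[c(2, 3, 8, 9)], seq_along(mouse_ch))
  s <- ifelse(eq, sub$match_score, sub$mismatch_score)
  pen <- !eq & seq_along(mouse_ch) %in% g23 & mouse_ch == "G"
  s[pen] <- sub$g_conservation_penalty
  sum(s)
}

#' Align a mouse TRE to an ortholog promoter
#'
#' Slides the full element (ungapped) across every offset of the ortholog
#' promoter whose TSS-relative position lies within
#' \code{max_distance_bp} of the mouse element's position. Candidate
#' offsets are ranked by the substitution-matrix score; every offset
#' whose half-site mismatch count is at most \code{max_mismatches} (and,
#' when a matrix is supplied, whose better half-site scores at least
#' \code{min_pwm_bits}) is returned, best score first; ties are all
#' retained. Windows containing N are skipped. An ortholog window
#' disjoint from the distance band yields an empty result, not an error.
#'
#' @param mouse_hit One row of a \code{tre_hits} data frame (or a list
#'   with \code{gene, architecture, pos, element}).
#' @param ortholog A \code{\link{promoter}} for the same gene in rat or
#'   human.
#' @param sub A \code{\link{substitution_matrix}}.
#' @param cfg A \code{\link{conservation_config}}.
#' @param pwm Optional \code{halfsite_pwm} enforcing \code{min_pwm_bits}.
#' @return Data frame with columns \code{species, pos, matched_seq,
#'   halfsite_mismatches, distance, score}.
#' @export
align_tre_to_ortholog <- function(mouse_hit, ortholog, sub = substitution_matrix(),
                                  cfg = conservation_config(), pwm = NULL) {
  if (is.data.frame(mouse_hit)) mouse_hit <- as.list(mouse_hit[1, ])
  arch <- tre_architecture(mouse_hit$architecture)
  elen <- arch$length
  el <- toupper(mouse_hit$element)
  stopifnot(nchar(el) == elen)
  mouse_ch <- strsplit(el, "", fixed = TRUE)[[1]]
  ws <- ortholog$window_start
  L <- nchar(ortholog$seq)
  ## admissible 1-based start offsets: element fits and |pos - pos_mouse| <= D
  pos_lo <- mouse_hit$pos - cfg$max_distance_bp
  pos_hi <- mouse_hit$pos + cfg$max_distance_bp
  j_lo <- max(1L, pos_lo - ws + 1L)
  j_hi <- min(L - elen + 1L, pos_hi - ws + 1L)
  empty <- data.frame(species = character(), pos = integer(),
                      matched_seq = character(),
                      halfsite_mismatches = integer(), distance = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (j_hi < j_lo) return(empty)
  orth_ch <- strsplit(toupper(ortholog$seq), "", fixed = TRUE)[[1]]
  hp <- halfsite_positions(elen)
  res <- lapply(j_lo:j_hi, function(j) {
    w <- orth_ch[j:(j + elen - 1L)]
    if (anyNA(match(w, DNA_BASES))) return(NULL)
    mm <- sum(mouse_ch[hp] != w[hp])
    if (mm > cfg$max_mismatches) return(NULL)
    list(j = j, mm = mm, score = sub_score(mouse_ch, w, sub, elen),
         seq = paste(w, collapse = ""))
  })
  res <- Filter(Negate(is.null), res)
  if (length(res) == 0L) return(empty)
  out <- data.frame(
    species = ortholog$species,
    pos = vapply(res, function(r) tss_position(r$j - 1L, ws), integer(1)),
    matched_seq = vapply(res, `[[`, character(1), "seq"),
    halfsite_mismatches = vapply(res, `[[`, integer(1), "mm"),
    score = vapply(res, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  out$distance <- abs(out$pos - mouse_hit$pos)
  if (!is.null(pwm) && is.finite(cfg$min_pwm_bits)) {
    best <- vapply(out$matched_seq, function(s) {
      hs <- extract_halfsites(s, arch)
      max(score_halfsite(pwm, hs))
    }, numeric(1), USE.NAMES = FALSE)
    out <- out[best >= cfg$min_pwm_bits, , drop = FALSE]
  }
  out <- out[order(-out$score, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("species", "pos", "matched_seq", "halfsite_mismatches",
          "distance", "score")]
}

#' Filter mouse TRE hits by rat and human conservation
#'
#' Applies the two-stage conservation funnel: each mouse hit is first
#' aligned to the rat ortholog promoter; survivors are then aligned to
#' the human ortholog promoter. An element survives a stage if at least
#' one ortholog offset satisfies the mismatch, distance and minimum-score
#' criteria. Hits for genes lacking an ortholog promoter are skipped with
#' a logged message, never silently.
#'
#' @param mouse_hits A \code{tre_hits} data frame.
#' @param rat_promoters,human_promoters Lists of \code{\link{promoter}}s
#'   (or \code{promoter_set}s) keyed by gene.
#' @param pwm The \code{halfsite_pwm} used for the minimum-score filter.
#' @param sub A \code{\link{substitution_matrix}}.
#' @param cfg A \code{\link{conservation_config}}.
#' @return An object of class \code{conserved_tres}: a list with
#'   \code{elements} (per surviving hit: the mouse hit plus rat and human
#'   match tables), \code{table} (one row per element x rat-match x
#'   human-match combination, mirroring a conserved-element report) and
#'   \code{funnel} (stage counts and per-stage gene lists).
#' @export
filter_conserved <- function(mouse_hits, rat_promoters, human_promoters,
                             pwm, sub = substitution_matrix(),
                             cfg = conservation_config()) {
  find_prom <- function(set, gene) {
    for (p in set) if (p$gene == gene) return(p)
    NULL
  }
  n0 <- nrow(mouse_hits)
  genes0 <- unique(mouse_hits$gene)
  skipped <- character(0)
  stage <- function(hits, promoters, species) {
    keep <- vector("list", nrow(hits))
    for (i in seq_len(nrow(hits))) {
      g <- hits$gene[i]
      p <- find_prom(promoters, g)
      if (is.null(p)) {
        message(sprintf("filter_conserved: no %s ortholog promoter for %s; hit dropped",
                        species, g))
        skipped <<- union(skipped, paste0(g, ":", species))
        next
      }
      m <- align_tre_to_ortholog(hits[i, ], p, sub, cfg, pwm)
      if (nrow(m) > 0L) keep[[i]] <- m
    }
    keep
  }
  rat_matches <- stage(mouse_hits, rat_promoters, "rat")
  pass_rat <- !vapply(rat_matches, is.null, logical(1))
  hits_rat <- mouse_hits[pass_rat, , drop = FALSE]
  human_matches <- stage(hits_rat, human_promoters, "human")
  pass_human <- !vapply(human_matches, is.null, logical(1))

  elements <- list()
  rows <- list()
  ridx <- which(pass_rat)
  for (k in seq_len(nrow(hits_rat))) {
    if (!pass_human[k]) next
    h <- hits_rat[k, ]
    rm <- rat_matches[[ridx[k]]]
    hm <- human_matches[[k]]
    elements[[length(elements) + 1L]] <-
      list(mouse_hit = h, rat = rm, human = hm)
    comb <- expand.grid(r = seq_len(nrow(rm)), h = seq_len(nrow(hm)))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = h$gene, type = h$architecture, mouse_pos = h$pos,
      mouse_tre = h$element,
      rat_pos = rm$pos[comb$r], rat_tre = rm$matched_seq[comb$r],
      rat_mm = rm$halfsite_mismatches[comb$r],
      human_pos = hm$pos[comb$h], human_tre = hm$matched_seq[comb$h],
      human_mm = hm$halfsite_mismatches[comb$h],
      stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), type = character(), mouse_pos = integer(),
               mouse_tre = character(), rat_pos = integer(),
               rat_tre = character(), rat_mm = integer(),
               human_pos = integer(), human_tre = character(),
               human_mm = integer(), stringsAsFactors = FALSE)
  rownames(table) <- NULL
  funnel <- list(
    n_initial = n0,
    n_after_rat = sum(pass_rat),
    n_after_human = sum(pass_human),
    genes_initial = genes0,
    genes_after_rat = unique(hits_rat$gene),
    genes_after_human = unique(hits_rat$gene[pass_human]),
    skipped_no_ortholog = skipped)
  structure(list(elements = elements, table = table, funnel = funnel),
            class = "conserved_tres")
}

#' @export
print.conserved_tres <- function(x, ...) {
  f <- x$funnel
  cat(sprintf("Conservation funnel: %d hits in %d genes -> rat: %d in %d -> human: %d in %d\n",
              f$n_initial, length(f$genes_initial),
              f$n_after_rat, length(f$genes_after_rat),
              f$n_after_human, length(f$genes_after_human)))
  if (length(f$skipped_no_ortholog)) {
    cat("Skipped (no ortholog promoter):",
        paste(f$skipped_no_ortholog, collapse = ", "), "\n")
  }
  invisible(x)
}
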