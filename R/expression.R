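#' Expression classifier configuration
#'
#' @param alpha FDR significance threshold for a cell to count as a
#'   significant response (default 0.05).
#' @export
expression_config <- function(alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  list(alpha = alpha)
}

EXPR_GROUPS <- c("hypo", "hyper", "hypo_plus")
EXPR_SEXES <- c("male", "female")

#' Read / write per-gene expression tables
#'
#' TSV with columns \code{gene, accession, sex, group, fold_change,
#' fdr_p}. A gene-sex-group cell that is absent from the table means "not
#' significant" (as a blank cell in a published table would), never zero.
#' Fold changes are signed ratios: negative means down-regulated, and
#' magnitudes are at least 1.
#'
#' @param path File path.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "accession", "sex", "group", "fold_change", "fdr_p")
  if (!all(need %in% names(df))) {
    stop("expression TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  validate_expression(df)
  df
}

#' @param records Expression record data frame.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fold_change: signed ratio, negative = down-regulated; absent cells = not significant", con)
  utils::write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(df) {
  bad <- !df$sex %in% EXPR_SEXES
  if (any(bad)) stop("unknown sex value: ", df$sex[bad][1], call. = FALSE)
  bad <- !df$group %in% EXPR_GROUPS
  if (any(bad)) stop("unknown group value: ", df$group[bad][1], call. = FALSE)
  if (any(abs(df$fold_change) < 1, na.rm = TRUE)) {
    stop("fold changes are ratio-style: |fold_change| must be >= 1",
         call. = FALSE)
  }
  if (any(is.na(df$fold_change) != is.na(df$fdr_p))) {
    stop("fdr_p must be present exactly when fold_change is present",
         call. = FALSE)
  }
  key <- paste(df$gene, df$sex, df$group)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("conflicting duplicate records for ", d, call. = FALSE)
  }
  invisible(df)
}

## classify one gene within one sex; returns list(positive, veto, codes,
## pattern) where veto flags a contradiction of the hypo-direction or
## hypo/hypo+ agreement rules
classify_sex <- function(cells, alpha) {
  sig <- function(g) {
    r <- cells[cells$group == g, ]
    if (nrow(r) == 0L || is.na(r$fdr_p[1]) || r$fdr_p[1] >= alpha) return(NA_real_)
    r$fold_change[1]
  }
  fc <- c(hypo = sig("hypo"), hyper = sig("hyper"), hypo_plus = sig("hypo_plus"))
  codes <- character(0)
  induced_sign <- NA_real_
  a <- !is.na(fc["hyper"]) || !is.na(fc["hypo_plus"])
  if (!a) codes <- c(codes, "no_sig_hyper_or_hypoplus")
  b <- TRUE
  if (!is.na(fc["hyper"]) && !is.na(fc["hypo_plus"])) {
    b <- sign(fc["hyper"]) == sign(fc["hypo_plus"])
    if (!b) codes <- c(codes, "hyper_hypoplus_sign_conflict")
  }
  if (a && b) induced_sign <- sign(c(fc["hyper"], fc["hypo_plus"]))[
    which(!is.na(fc[c("hyper", "hypo_plus")]))[1]]
  cc <- TRUE
  if (!is.na(fc["hypo"]) && !is.na(induced_sign)) {
    cc <- sign(fc["hypo"]) == -induced_sign
    if (!cc) codes <- c(codes, "hypo_same_direction")
  }
  d <- TRUE
  if (!is.na(fc["hypo"]) && !is.na(fc["hypo_plus"])) {
    d <- sign(fc["hypo"]) != sign(fc["hypo_plus"])
    if (!d) codes <- c(codes, "hypo_hypoplus_same_sign")
  }
  pat <- paste(vapply(names(fc), function(g) {
    if (is.na(fc[g])) sprintf("%s.", sub("_plus", "+", g))
    else sprintf("%s%s", sub("_plus", "+", g), if (fc[g] > 0) "+" else "-")
  }, character(1)), collapse = "/")
  list(positive = a && b && cc && d, veto = !cc || !d,
       codes = if (length(codes)) codes else "pattern_ok", pattern = pat)
}

#' Classify genes as candidate direct thyroid-hormone targets
#'
#' A gene is called directly regulated when, within at least one sex, its
#' significant responses follow the direct-regulation pattern: the
#' hyperthyroid and hormone-replacement (hypo+) groups respond in the
#' same direction, the hypothyroid group (if significant) responds in the
#' opposite direction, and the hypothyroid and hypo+ responses are never
#' in the same direction — with at least one of hyper/hypo+ significant.
#' A sex whose data contradict the hypo-direction or hypo/hypo+
#' agreement rules vetoes the call even if the other sex fits.
#'
#' @param records Expression record data frame (see
#'   \code{\link{read_expression_tsv}}).
#' @param cfg An \code{\link{expression_config}}.
#' @return Data frame of class \code{direct_regulation_calls} with
#'   columns \code{gene, verdict, evidence, reasons}; \code{evidence} is
#'   the observed per-sex sign pattern (\code{.} = not significant) and
#'   \code{reasons} the per-sex rule codes.
#' @export
classify_direct_regulation <- function(records, cfg = expression_config()) {
  validate_expression(records)
  genes <- unique(records$gene)
  out <- lapply(genes, function(g) {
    sub <- records[records$gene == g, ]
    per_sex <- lapply(EXPR_SEXES, function(s)
      classify_sex(sub[sub$sex == s, ], cfg$alpha))
    names(per_sex) <- EXPR_SEXES
    positive <- vapply(per_sex, `[[`, logical(1), "positive")
    veto <- vapply(per_sex, `[[`, logical(1), "veto")
    verdict <- if (any(positive) && !any(veto)) "direct" else "not_direct"
    data.frame(
      gene = g, verdict = verdict,
      evidence = paste(sprintf("%s: %s", c("M", "F"),
                               vapply(per_sex, `[[`, character(1), "pattern")),
                       collapse = "; "),
      reasons = paste(sprintf("%s:%s", c("M", "F"),
                              vapply(per_sex, function(x)
                                paste(x$codes, collapse = ","), character(1))),
                      collapse = "; "),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(), verdict = character(),
                      evidence = character(), reasons = character(),
                      stringsAsFactors = FALSE)
  }
  class(res) <- c("direct_regulation_calls", "data.frame")
  res
}

#' Genes selected for promoter scanning
#'
#' @param calls Output of \code{\link{classify_direct_regulation}}.
#' @return Character vector of genes with verdict \code{direct},
#'   deduplicated, in stable (input) order.
#' @export
select_scan_candidates <- function(calls) {
  unique(calls$gene[calls$verdict == "direct"])
}

#' Write direct-regulation calls as TSV
#'
#' @param calls A \code{direct_regulation_calls} data frame.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# evidence: per-sex hypo/hyper/hypo+ sign pattern ('.' = not significant)", con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged direct-target expression fixture
#'
#' A 28-gene fold-change table encoding the published direct-target
#' candidate list (significant cells carry their printed fold changes;
#' blank cells are absent). Useful as a worked example and as the input
#' gene list for promoter scanning.
#'
#' @return Expression record data frame.
#' @export
direct_target_table <- function() {
  read_expression_tsv(system.file("extdata", "direct_targets_expression.tsv",
                                  package = "trescan", mustWork = TRUE))
}
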