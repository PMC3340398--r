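#' Run the full TRE discovery pipeline
#'
#' Executes the three stages in order: (1) classify genes as candidate
#' direct targets from the expression table; (2) scan the mouse promoter
#' windows of the candidates for DR4/IR0/ER6 elements under the dual
#' bit-score thresholds; (3) filter hits by rat-then-human ortholog
#' conservation. Writes the candidate gene list, hit TSV and BED,
#' conserved-TRE TSV, funnel report and a run manifest into \code{out};
#' an identical manifest implies identical outputs.
#'
#' @param training Path to the half-site training TSV, or a
#'   \code{halfsite_training} object.
#' @param promoters_mouse,promoters_rat,promoters_human Promoter FASTA
#'   paths or \code{promoter_set}s.
#' @param expression Expression TSV path or record data frame.
#' @param out Output directory (created if needed).
#' @param low_bits,high_bits Scan thresholds (defaults 3.76 and 6).
#' @param architectures Architectures to scan (default all three).
#' @param max_mm Maximum half-site mismatches per species (default 2).
#' @param max_dist Maximum TSS-relative distance in bp (default 2000).
#' @param alpha FDR significance threshold (default 0.05).
#' @param pseudocount PWM pseudocount (default 0.25).
#' @param both_strands Scan the reverse strand too? Default FALSE.
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents any upstream simulation).
#' @return Invisibly, a list with \code{candidates}, \code{hits},
#'   \code{conserved}, \code{pwm} and the manifest.
#' @export
run_full_pipeline <- function(training, promoters_mouse, promoters_rat,
                              promoters_human, expression, out,
                              low_bits = 3.76, high_bits = 6.0,
                              architectures = ARCHITECTURES,
                              max_mm = 2L, max_dist = 2000L, alpha = 0.05,
                              pseudocount = 0.25, both_strands = FALSE,
                              seed = NA_integer_) {
  as_training <- function(x)
    if (is.character(x) && length(x) == 1L && file.exists(x))
      read_training_tsv(x) else x
  as_promoters <- function(x)
    if (is.character(x) && length(x) == 1L) read_promoter_fasta(x) else x
  as_expression <- function(x)
    if (is.character(x) && length(x) == 1L) read_expression_tsv(x) else x

  training <- as_training(training)
  pm <- as_promoters(promoters_mouse)
  pr <- as_promoters(promoters_rat)
  ph <- as_promoters(promoters_human)
  records <- as_expression(expression)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  message("stage classify: ", length(unique(records$gene)), " genes in")
  calls <- classify_direct_regulation(records, expression_config(alpha))
  candidates <- select_scan_candidates(calls)
  message("stage classify: ", length(candidates), " candidate direct targets")
  write_calls_tsv(calls, file.path(out, "direct_regulation_calls.tsv"))
  writeLines(candidates, file.path(out, "candidate_genes.txt"))

  pwm <- build_pwm(training, pseudocount = pseudocount)
  write_pwm_tsv(pwm, file.path(out, "halfsite_pwm.tsv"))
  cfg <- scan_config(scan_thresholds(low_bits, high_bits), architectures,
                     both_strands)
  scan_set <- Filter(function(p) p$gene %in% candidates, pm)
  hits <- scan_promoters(scan_set, pwm, cfg)
  message("stage scan: ", nrow(hits), " hits in ",
          length(unique(hits$gene)), " genes")
  write_hits_tsv(hits, file.path(out, "tre_hits.tsv"))
  ws <- if (length(scan_set)) scan_set[[1]]$window_start else -8000L
  write_hits_bed(hits, file.path(out, "tre_hits.bed"), window_start = ws)

  ccfg <- conservation_config(max_mm, max_dist, min_pwm_bits = low_bits)
  conserved <- filter_conserved(hits, pr, ph, pwm,
                                substitution_matrix(), ccfg)
  f <- conserved$funnel
  message(sprintf("stage conserve: %d -> %d (rat) -> %d (human) elements; genes %d -> %d -> %d",
                  f$n_initial, f$n_after_rat, f$n_after_human,
                  length(f$genes_initial), length(f$genes_after_rat),
                  length(f$genes_after_human)))
  write_conserved_tsv(conserved, file.path(out, "conserved_tres.tsv"))
  write_funnel_json(conserved, file.path(out, "funnel.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("trescan")),
    seed = seed,
    parameters = list(low_bits = low_bits, high_bits = high_bits,
                      architectures = architectures, max_mm = max_mm,
                      max_dist = max_dist, alpha = alpha,
                      pseudocount = pseudocount,
                      both_strands = both_strands),
    n_training_halfsites = nrow(training),
    n_genes_expression = length(unique(records$gene)),
    n_candidates = length(candidates),
    funnel = list(n_initial = f$n_initial, n_after_rat = f$n_after_rat,
                  n_after_human = f$n_after_human))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(calls = calls, candidates = candidates, hits = hits,
                 conserved = conserved, pwm = pwm, manifest = manifest))
}
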