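#' Synthetic-data generator configuration
#'
#' Configures the generator that emulates the study inputs: TSS-anchored
#' promoter windows for mouse/rat/human ortholog triplets with elements
#' planted at known positions, and fold-change tables with known
#' regulation classes. All randomness flows from \code{seed}; a seed is
#' mandatory so no output is silently nondeterministic.
#'
#' Random draws are made unconditionally and then thresholded by the
#' rates, so runs that share a seed but differ in a rate are coupled: the
#' substitutions present at a lower rate are a subset of those at a
#' higher rate. This makes recovery-versus-divergence curves monotone by
#' construction rather than only in expectation.
#'
#' @param n_genes Number of genes (default 30).
#' @param window_start,window_end Promoter window, TSS-relative (defaults
#'   -8000 and +2000, the scan's promoter definition).
#' @param background Per-base background probabilities (default uniform).
#' @param substitution_rate Per-site substitution probability applied to
#'   each planted half-site base, independently in rat and human
#'   (default 0.1, roughly the half-site divergence seen between mouse
#'   and human elements).
#' @param spacer_mutation_rate Per-site substitution probability for
#'   spacer bases, independent of the half-site rate (default 0.1).
#' @param jitter_bp Maximum absolute TSS-relative positional shift of the
#'   planted element in rat/human (default 500).
#' @param architecture_mix Named probabilities over DR4/IR0/ER6 (default
#'   equal).
#' @param halfsite_pool Hexamers planted as half-sites, in scoring
#'   orientation (default strong consensus variants).
#' @param class_mix Named probabilities over regulation classes
#'   \code{direct_up, direct_down, indirect, unresponsive} (default equal).
#' @param fc_range Fold-change magnitude range for significant cells
#'   (default c(1.2, 2.0), centred near the ~1.6 average response).
#' @param alpha Significance level the table should be read at (default
#'   0.05).
#' @param seed Integer seed (required).
#' @export
generator_config <- function(n_genes = 30L, window_start = -8000L,
                             window_end = 2000L,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             substitution_rate = 0.1,
                             spacer_mutation_rate = 0.1,
                             jitter_bp = 500L,
                             architecture_mix = c(DR4 = 1/3, IR0 = 1/3,
                                                  ER6 = 1/3),
                             halfsite_pool = c("AGGTCA", "GGGTCA",
                                               "AGGACA", "AGGTGA"),
                             class_mix = c(direct_up = 0.25,
                                           direct_down = 0.25,
                                           indirect = 0.25,
                                           unresponsive = 0.25),
                             fc_range = c(1.2, 2.0), alpha = 0.05,
                             seed) {
  if (missing(seed)) stop("generator_config: seed is required", call. = FALSE)
  rates <- c(substitution_rate, spacer_mutation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0,1]", call. = FALSE)
  if (jitter_bp < 0) stop("jitter_bp must be >= 0", call. = FALSE)
  check_hexamer(halfsite_pool, "halfsite_pool entry")
  structure(list(n_genes = as.integer(n_genes),
                 window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 background = background[DNA_BASES],
                 substitution_rate = substitution_rate,
                 spacer_mutation_rate = spacer_mutation_rate,
                 jitter_bp = as.integer(jitter_bp),
                 architecture_mix = architecture_mix,
                 halfsite_pool = halfsite_pool,
                 class_mix = class_mix, fc_range = fc_range, alpha = alpha,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## assemble the genomic element string from scoring-orientation half-sites
assemble_element <- function(h1, h2, spacer_seq, arch) {
  switch(arch,
         DR4 = paste0(h1, spacer_seq, h2),
         IR0 = paste0(h1, revcomp(h2)),
         ER6 = paste0(revcomp(h1), spacer_seq, h2))
}

## apply pre-drawn substitutions: positions where u < rate take the
## pre-drawn alternative base (always != original)
apply_substitutions <- function(chars, u, alt, rate) {
  hit <- which(u < rate)
  subs <- data.frame(position = integer(0), from = character(0),
                     to = character(0), stringsAsFactors = FALSE)
  if (length(hit)) {
    subs <- data.frame(position = hit, from = chars[hit], to = alt[hit],
                       stringsAsFactors = FALSE)
    chars[hit] <- alt[hit]
  }
  list(chars = chars, subs = subs)
}

#' Generate ortholog promoter triplets with planted elements
#'
#' For each gene, generates mouse, rat and human promoter windows of
#' identical TSS-relative coordinates with i.i.d. background composition,
#' and plants one element (architecture drawn from the configured mix,
#' half-sites from the configured pool). The mouse window carries the
#' element verbatim; rat and human carry copies independently mutated at
#' the configured half-site and spacer rates and shifted by at most
#' \code{jitter_bp}. Identical config and seed give byte-identical
#' output.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return List with \code{promoters} (named list of mouse/rat/human
#'   \code{promoter_set}s) and \code{truth} (the planting ledger: one row
#'   per gene x species with position, architecture, half-sites, spacer,
#'   element string and an encoded substitution list).
#' @export
generate_promoter_triplets <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    L <- cfg$window_end - cfg$window_start
    genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
    species <- c("mouse", "rat", "human")
    proms <- list(mouse = list(), rat = list(), human = list())
    truth <- list()
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      arch <- sample(names(cfg$architecture_mix), 1,
                     prob = cfg$architecture_mix)
      ad <- tre_architecture(arch)
      elen <- ad$length
      margin <- cfg$jitter_bp + 1L
      lo <- margin + 1L
      hi <- L - elen - margin
      if (hi < lo) {
        stop(sprintf("generate_promoter_triplets: window too small to plant a %s element for %s",
                     arch, g), call. = FALSE)
      }
      offset <- lo + floor(runif(1) * (hi - lo + 1L))  # 1-based mouse offset
      h1 <- sample(cfg$halfsite_pool, 1)
      h2 <- sample(cfg$halfsite_pool, 1)
      spacer_seq <- paste(sample(DNA_BASES, ad$spacer, replace = TRUE,
                                 prob = cfg$background), collapse = "")
      element <- assemble_element(h1, h2, spacer_seq, arch)
      el_chars <- strsplit(element, "", fixed = TRUE)[[1]]
      hp <- halfsite_positions(elen)
      for (sp in species) {
        bg <- sample(DNA_BASES, L, replace = TRUE, prob = cfg$background)
        ## draws are unconditional so different rates share them (coupling)
        jit_u <- runif(1)
        u <- runif(elen)
        alt <- vapply(el_chars, function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1), USE.NAMES = FALSE)
        if (sp == "mouse") {
          chars <- el_chars
          subs <- data.frame(position = integer(0), from = character(0),
                             to = character(0))
          off <- offset
        } else {
          rate <- ifelse(seq_len(elen) %in% hp, cfg$substitution_rate,
                         cfg$spacer_mutation_rate)
          res <- apply_substitutions(el_chars, u, alt, rate)
          chars <- res$chars
          subs <- res$subs
          off <- offset + as.integer(round((2 * jit_u - 1) * cfg$jitter_bp))
        }
        bg[off:(off + elen - 1L)] <- chars
        proms[[sp]][[gi]] <- promoter(g, sp, paste(bg, collapse = ""),
                                      cfg$window_start, cfg$window_end)
        truth[[length(truth) + 1L]] <- data.frame(
          gene = g, species = sp, architecture = arch,
          pos = tss_position(off - 1L, cfg$window_start),
          halfsite1 = h1, halfsite2 = h2, spacer_seq = spacer_seq,
          element = paste(chars, collapse = ""),
          n_halfsite_subs = sum(subs$position %in% hp),
          n_spacer_subs = sum(!subs$position %in% hp),
          substitutions = paste(sprintf("%d:%s>%s", subs$position,
                                        subs$from, subs$to), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    class(truth) <- c("synthetic_truth", "data.frame")
    for (sp in species) class(proms[[sp]]) <- c("promoter_set", "list")
    list(promoters = proms, truth = truth)
  })
}

#' Generate a synthetic fold-change table with known regulation classes
#'
#' Assigns each gene a regulation class and emits per-sex, per-group
#' records consistent with it: direct targets respond in the same
#' direction in the hyper and hypo+ groups and oppositely in hypo;
#' indirect genes respond in the same direction in hypo and hypo+;
#' unresponsive genes get only non-significant rows. Fold-change
#' magnitudes for significant cells are drawn from \code{fc_range}.
#'
#' @param cfg A \code{\link{generator_config}}.
#' @return List with \code{records} (expression record data frame) and
#'   \code{truth} (data frame gene, class).
#' @export
generate_expression_table <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 1L, {
    genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
    ## deterministic class counts (largest-remainder), shuffled over genes,
    ## so the planted composition is exactly the configured mix
    p <- cfg$class_mix / sum(cfg$class_mix)
    n_per <- floor(p * cfg$n_genes)
    rem <- cfg$n_genes - sum(n_per)
    if (rem > 0) {
      extra <- order(p * cfg$n_genes - n_per, decreasing = TRUE)[seq_len(rem)]
      n_per[extra] <- n_per[extra] + 1L
    }
    classes <- sample(rep(names(cfg$class_mix), n_per))
    mag <- function() runif(1, cfg$fc_range[1], cfg$fc_range[2])
    sigp <- function() runif(1, 1e-4, cfg$alpha * 0.9)
    nsp <- function() runif(1, min(1, cfg$alpha * 4), 0.9)
    rows <- list()
    emit <- function(g, s, grp, fc, p) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = g, accession = paste0("SYN_", g), sex = s, group = grp,
        fold_change = round(fc, 2), fdr_p = signif(p, 3),
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(genes)) {
      g <- genes[i]
      dir_sign <- if (classes[i] == "direct_down") -1 else 1
      ind_sign <- sample(c(-1, 1), 1)
      for (s in EXPR_SEXES) {
        switch(classes[i],
          direct_up = , direct_down = {
            emit(g, s, "hypo", -dir_sign * mag(), sigp())
            emit(g, s, "hyper", dir_sign * mag(), sigp())
            emit(g, s, "hypo_plus", dir_sign * mag(), sigp())
          },
          indirect = {
            emit(g, s, "hypo", ind_sign * mag(), sigp())
            emit(g, s, "hypo_plus", ind_sign * mag(), sigp())
          },
          unresponsive = {
            emit(g, s, "hyper", sample(c(-1, 1), 1) * runif(1, 1.0, 1.15),
                 nsp())
          })
      }
    }
    records <- do.call(rbind, rows)
    truth <- data.frame(gene = genes, class = classes,
                        stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Write / read the planting ledger as JSON
#'
#' @param truth A \code{synthetic_truth} data frame.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(as.data.frame(truth), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  class(df) <- c("synthetic_truth", "data.frame")
  df
}
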