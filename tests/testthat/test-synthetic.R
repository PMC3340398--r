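test_that("identical config and seed give byte-identical output", {
  cfg <- generator_config(n_genes = 6, window_start = -1500,
                          window_end = 500, seed = 99)
  a <- generate_promoter_triplets(cfg)
  b <- generate_promoter_triplets(cfg)
  expect_identical(a$truth, b$truth)
  for (sp in c("mouse", "rat", "human")) {
    expect_identical(vapply(a$promoters[[sp]], `[[`, character(1), "seq"),
                     vapply(b$promoters[[sp]], `[[`, character(1), "seq"))
  }
  ea <- generate_expression_table(cfg)
  eb <- generate_expression_table(cfg)
  expect_identical(ea$records, eb$records)
  expect_error(generator_config(n_genes = 5), "seed")
})

test_that("zero substitution and jitter give identical triplets", {
  cfg <- generator_config(n_genes = 8, window_start = -1500,
                          window_end = 500, substitution_rate = 0,
                          spacer_mutation_rate = 0, jitter_bp = 0, seed = 13)
  g <- generate_promoter_triplets(cfg)
  tr <- g$truth
  for (gene in unique(tr$gene)) {
    rows <- tr[tr$gene == gene, ]
    expect_equal(length(unique(rows$element)), 1L, info = gene)
    expect_equal(length(unique(rows$pos)), 1L, info = gene)
    m <- rows[rows$species == "mouse", ]
    for (sp in c("rat", "human")) {
      o <- rows[rows$species == sp, ]
      expect_identical(count_halfsite_mismatches(m$element, o$element,
                                                 m$architecture), 0L)
    }
  }
})

test_that("spacer-only mutation leaves mismatch counts at zero", {
  cfg <- generator_config(n_genes = 12, window_start = -1500,
                          window_end = 500, substitution_rate = 0,
                          spacer_mutation_rate = 1, jitter_bp = 0, seed = 14,
                          architecture_mix = c(DR4 = 0.5, IR0 = 0, ER6 = 0.5))
  g <- generate_promoter_triplets(cfg)
  tr <- g$truth
  spacers_differ <- FALSE
  for (gene in unique(tr$gene)) {
    rows <- tr[tr$gene == gene, ]
    m <- rows[rows$species == "mouse", ]
    for (sp in c("rat", "human")) {
      o <- rows[rows$species == sp, ]
      expect_identical(count_halfsite_mismatches(m$element, o$element,
                                                 m$architecture), 0L)
      if (o$element != m$element) spacers_differ <- TRUE
      expect_equal(o$n_halfsite_subs, 0L)
    }
  }
  expect_true(spacers_differ)
})

test_that("the recorded substitutions reproduce the emitted elements", {
  cfg <- generator_config(n_genes = 10, window_start = -1500,
                          window_end = 500, substitution_rate = 0.3,
                          spacer_mutation_rate = 0.3, seed = 15)
  g <- generate_promoter_triplets(cfg)
  tr <- g$truth
  for (i in which(tr$species != "mouse")) {
    row <- tr[i, ]
    m <- tr[tr$gene == row$gene & tr$species == "mouse", ]
    rebuilt <- m$element
    if (nzchar(row$substitutions)) {
      for (s in strsplit(row$substitutions, ";", fixed = TRUE)[[1]]) {
        p <- as.integer(sub(":.*", "", s))
        to <- sub(".*>", "", s)
        substr(rebuilt, p, p) <- to
      }
    }
    expect_identical(rebuilt, row$element)
    # planted elements sit where the ledger says
    pr <- g$promoters[[row$species]][[match(row$gene, unique(tr$gene))]]
    off <- row$pos - pr$window_start + 1
    expect_identical(substr(pr$seq, off, off + nchar(row$element) - 1),
                     row$element)
  }
})

test_that("conservation survival matches the closed-form binomial rate", {
  # expected 3 half-site substitutions per ortholog: rate 0.25 over 12 sites
  rate <- 0.25
  cfg <- generator_config(n_genes = 400, window_start = -900,
                          window_end = 300, substitution_rate = rate,
                          spacer_mutation_rate = 0, jitter_bp = 20, seed = 16)
  g <- generate_promoter_triplets(cfg)
  hits <- hits_from_truth(g$truth)
  class(hits) <- c("tre_hits", "data.frame")
  pwm <- build_pwm(default_training_set())
  ccfg <- conservation_config(max_mismatches = 2, max_distance_bp = 60,
                              min_pwm_bits = -Inf)
  res <- filter_conserved(hits, g$promoters$rat, g$promoters$human, pwm,
                          cfg = ccfg)
  observed <- res$funnel$n_after_human / res$funnel$n_initial
  p_one <- pbinom(2, 12, rate)
  expected <- p_one^2
  mc_sd <- sqrt(expected * (1 - expected) / cfg$n_genes)
  expect_lt(abs(observed - expected), 4 * mc_sd + 0.01)
})

test_that("expression truth classes drive the expected record patterns", {
  cfg <- generator_config(n_genes = 40, seed = 17, alpha = 0.05)
  gen <- generate_expression_table(cfg)
  recs <- gen$records
  for (i in seq_len(nrow(gen$truth))) {
    g <- gen$truth$gene[i]
    cl <- gen$truth$class[i]
    r <- recs[recs$gene == g & recs$sex == "male", ]
    sig <- r[r$fdr_p < cfg$alpha, ]
    if (cl == "direct_up") {
      expect_true(sig$fold_change[sig$group == "hypo"] < 0)
      expect_true(all(sig$fold_change[sig$group != "hypo"] > 0))
    } else if (cl == "direct_down") {
      expect_true(sig$fold_change[sig$group == "hypo"] > 0)
      expect_true(all(sig$fold_change[sig$group != "hypo"] < 0))
    } else if (cl == "indirect") {
      expect_equal(sign(sig$fold_change[sig$group == "hypo"]),
                   sign(sig$fold_change[sig$group == "hypo_plus"]))
    } else {
      expect_equal(nrow(sig), 0L)
    }
  }
  # class counts follow the mix exactly
  expect_equal(unname(table(gen$truth$class)[c("direct_up", "direct_down",
                                               "indirect", "unresponsive")]),
               rep(10L, 4), ignore_attr = TRUE)
})

test_that("an all-unresponsive table yields zero direct calls", {
  cfg <- generator_config(n_genes = 20, seed = 18,
                          class_mix = c(direct_up = 0, direct_down = 0,
                                        indirect = 0, unresponsive = 1))
  gen <- generate_expression_table(cfg)
  calls <- classify_direct_regulation(gen$records)
  expect_equal(select_scan_candidates(calls), character(0))
})

test_that("elements that would overflow the window are refused", {
  expect_error(
    generate_promoter_triplets(generator_config(n_genes = 2,
                                                window_start = -10,
                                                window_end = 10, seed = 1)),
    "window too small")
})
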