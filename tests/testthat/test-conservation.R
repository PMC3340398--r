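pool_pwm <- build_pwm(default_training_set())

# plant `el` into a fresh random background at 1-based offset `at`
plant <- function(gene, species, el, at, L = 2000, ws = -1000) {
  seq <- random_dna(L)
  substr(seq, at, at + nchar(el) - 1) <- el
  promoter(gene, species, seq, ws)
}

mouse_hit <- function(gene, arch, pos, element) {
  data.frame(gene = gene, species = "mouse", architecture = arch, pos = pos,
             strand = "+", halfsite1 = NA, spacer_seq = NA, halfsite2 = NA,
             bits1 = NA_real_, bits2 = NA_real_, element = element,
             stringsAsFactors = FALSE)
}

test_that("half-site mismatch counts reproduce the published table", {
  # worked examples
  expect_equal(count_halfsite_mismatches("AGGTGGAATGAGGACA",
                                         "AGGTGGAATGAGGACA", "DR4"), 0)
  expect_equal(count_halfsite_mismatches("AGGACAAGTCCC",
                                         "AGGACATGTCCC", "IR0"), 1)
  expect_equal(count_halfsite_mismatches("AGGTGAAGTGAGGTCA",
                                         "AGATTGTCTGAGGTTA", "DR4"), 4)
  # spacer exclusion: published everted element whose spacers differ, MM 0
  expect_equal(count_halfsite_mismatches("TGACCTTTATGCAAGTCA",
                                         "TGACCTTTATTCAAGTCA", "ER6"), 0)
  # full fixture: every comparison a plain Hamming count can explain
  tab <- published_tre_elements()
  cons <- tab[tab$hamming_consistent == 1, ]
  expect_gte(nrow(cons), 50)
  got <- mapply(count_halfsite_mismatches, cons$mouse_tre, cons$tre,
                cons$type)
  expect_equal(unname(got), cons$printed_mm)
  # exactly one published count needs a non-Hamming explanation
  expect_equal(sum(tab$hamming_consistent == 0), 1L)
})

test_that("mismatch metric is symmetric, zero iff identical, triangular", {
  set.seed(21)
  for (i in 1:25) {
    arch <- sample(c("DR4", "IR0", "ER6"), 1)
    elen <- tre_architecture(arch)$length
    a <- random_dna(elen); b <- random_dna(elen); c <- random_dna(elen)
    ab <- count_halfsite_mismatches(a, b, arch)
    expect_identical(ab, count_halfsite_mismatches(b, a, arch))
    expect_identical(count_halfsite_mismatches(a, a, arch), 0L)
    expect_lte(ab, count_halfsite_mismatches(a, c, arch) +
                   count_halfsite_mismatches(c, b, arch))
  }
  expect_error(count_halfsite_mismatches("AGGTCA", "AGGTCAT", "IR0"),
               "equal length")
})

test_that("mutating only spacer bases never changes the mismatch count", {
  set.seed(22)
  for (i in 1:20) {
    arch <- sample(c("DR4", "ER6"), 1)
    elen <- tre_architecture(arch)$length
    a <- random_dna(elen)
    b <- a
    for (j in 7:(elen - 6)) substr(b, j, j) <- sample(c("A","C","G","T"), 1)
    expect_identical(count_halfsite_mismatches(a, b, arch), 0L)
  }
})

test_that("an exact ortholog copy aligns as the single top match", {
  set.seed(31)
  el <- "AGGTCAGGTAAGGACA"
  hit <- mouse_hit("g1", "DR4", pos = -400, element = el)
  orth <- plant("g1", "rat", el, at = 701, L = 2000, ws = -1000)  # pos -300
  m <- align_tre_to_ortholog(hit, orth, cfg = conservation_config(
    max_mismatches = 0, max_distance_bp = 500))
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, -300)
  expect_equal(m$halfsite_mismatches, 0L)
  expect_equal(m$distance, 100L)
  expect_equal(m$matched_seq, el)
})

test_that("three half-site substitutions exceed the default mismatch cap", {
  set.seed(32)
  el <- "AGGTCAGGTAAGGACA"
  mut <- el
  for (j in c(1, 3, 12)) substr(mut, j, j) <- c(A = "C", C = "G", G = "T",
                                                T = "A")[substr(mut, j, j)]
  expect_equal(count_halfsite_mismatches(el, mut, "DR4"), 3L)
  hit <- mouse_hit("g1", "DR4", pos = -400, element = el)
  orth <- plant("g1", "rat", mut, at = 601, L = 2000, ws = -1000)
  m <- align_tre_to_ortholog(hit, orth, cfg = conservation_config(
    max_mismatches = 2, max_distance_bp = 150))
  expect_equal(nrow(m), 0L)
})

test_that("two equally mutated copies inside the band are both returned", {
  set.seed(33)
  el <- "AGGTCAGGTAAGGACA"
  mut <- el
  substr(mut, 2, 2) <- "A"
  seq <- random_dna(2000)
  substr(seq, 501, 516) <- mut
  substr(seq, 1001, 1016) <- mut
  orth <- promoter("g1", "human", seq, -1000)
  hit <- mouse_hit("g1", "DR4", pos = -300, element = el)
  m <- align_tre_to_ortholog(hit, orth, cfg = conservation_config(
    max_mismatches = 2, max_distance_bp = 600))
  expect_equal(sort(m$pos), c(-500L, 0L))
  expect_equal(m$halfsite_mismatches, c(1L, 1L))
  # equal substitution scores: both retained, ranked by position
  expect_equal(m$score[1], m$score[2])
})

test_that("the substitution matrix penalises G loss at half-site positions 2 and 3", {
  el <- "AGGTCAGGTAAGGTCA"
  hit <- mouse_hit("g1", "DR4", pos = 0, element = el)
  mk <- function(mut) {
    promoter("g1", "rat", paste0(paste(rep("C", 50), collapse = ""), mut,
                                 paste(rep("C", 50), collapse = "")), -50)
  }
  cfg <- conservation_config(max_mismatches = 2, max_distance_bp = 10,
                             min_pwm_bits = -Inf)
  g_loss <- el; substr(g_loss, 2, 2) <- "T"     # mouse G at half-site pos 2
  plain <- el; substr(plain, 5, 5) <- "T"       # ordinary mismatch
  s_g <- align_tre_to_ortholog(hit, mk(g_loss), cfg = cfg)$score
  s_p <- align_tre_to_ortholog(hit, mk(plain), cfg = cfg)$score
  expect_lt(max(s_g), max(s_p))
  expect_error(substitution_matrix(match_score = 0, mismatch_score = 0),
               "match_score")
})

test_that("the distance band is inclusive at the boundary", {
  el <- "AGGTCAGGTAAGGACA"
  L <- 6000
  base <- paste(rep("C", L), collapse = "")
  cfg <- conservation_config(max_mismatches = 2, max_distance_bp = 2000,
                             min_pwm_bits = -Inf)
  hit <- mouse_hit("g1", "DR4", pos = -1000, element = el)
  for (delta in c(2000L, 2001L)) {
    seq <- base
    at <- (-1000 + delta) - (-3000) + 1  # plant at pos -1000 + delta
    substr(seq, at, at + 15) <- el
    orth <- promoter("g1", "rat", seq, -3000)
    m <- align_tre_to_ortholog(hit, orth, cfg = cfg)
    if (delta == 2000L) {
      expect_equal(m$distance, 2000L)
    } else {
      expect_equal(nrow(m), 0L)
    }
  }
})

test_that("a window disjoint from the distance band yields an empty result", {
  hit <- mouse_hit("g1", "DR4", pos = -7000, element = "AGGTCAGGTAAGGACA")
  orth <- promoter("g1", "rat", random_dna(1000), 0)  # covers 0..1000
  m <- align_tre_to_ortholog(hit, orth, cfg = conservation_config())
  expect_equal(nrow(m), 0L)
})

test_that("the two-stage funnel matches a planting ledger exactly", {
  set.seed(41)
  el <- "AGGTCAGGTAAGGACA"
  heavy <- function(x) {  # 5 half-site substitutions: never conserved
    for (j in c(1, 2, 5, 11, 16))
      substr(x, j, j) <- c(A = "C", C = "G", G = "T", T = "A")[substr(x, j, j)]
    x
  }
  n <- 10; both <- 1:4; rat_only <- 5:10
  hits <- do.call(rbind, lapply(1:n, function(i)
    mouse_hit(sprintf("g%02d", i), "DR4", pos = -200, element = el)))
  class(hits) <- c("tre_hits", "data.frame")
  rats <- lapply(1:n, function(i)
    plant(sprintf("g%02d", i), "rat", el, at = 801, L = 2000, ws = -1000))
  humans <- lapply(1:n, function(i)
    plant(sprintf("g%02d", i), "human",
          if (i %in% both) el else heavy(el), at = 801, L = 2000, ws = -1000))
  cfg <- conservation_config(max_mismatches = 2, max_distance_bp = 100)
  res <- filter_conserved(hits, rats, humans, pool_pwm, cfg = cfg)
  expect_equal(res$funnel$n_initial, 10L)
  expect_equal(res$funnel$n_after_rat, 10L)
  expect_equal(res$funnel$n_after_human, 4L)
  expect_setequal(res$funnel$genes_after_human, sprintf("g%02d", both))
  # funnel monotonicity
  f <- res$funnel
  expect_true(f$n_after_human <= f$n_after_rat &&
              f$n_after_rat <= f$n_initial)
})

test_that("zero hits give an empty, well-formed funnel", {
  hits <- mouse_hit("g", "DR4", 0, "AGGTCAGGTAAGGACA")[0, ]
  class(hits) <- c("tre_hits", "data.frame")
  res <- filter_conserved(hits, list(), list(), pool_pwm)
  expect_equal(res$funnel$n_initial, 0L)
  expect_equal(res$funnel$n_after_rat, 0L)
  expect_equal(res$funnel$n_after_human, 0L)
  expect_equal(nrow(res$table), 0L)
})

test_that("a missing ortholog promoter is skipped with a logged reason", {
  hits <- mouse_hit("lonely", "DR4", -200, "AGGTCAGGTAAGGACA")
  class(hits) <- c("tre_hits", "data.frame")
  expect_message(
    res <- filter_conserved(hits, list(), list(), pool_pwm),
    "no rat ortholog promoter")
  expect_equal(res$funnel$n_after_rat, 0L)
  expect_true("lonely:rat" %in% res$funnel$skipped_no_ortholog)
})
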