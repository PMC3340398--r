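# Independent oracles: straight-line reimplementations used only to
# check the package's faster paths. They share nothing with the
# implementation beyond the fitted bit matrix itself.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# column-by-column PWM arithmetic from first principles
oracle_pwm_score <- function(hexamers, query, pseudocount = 0.25,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  n <- length(hexamers)
  total <- 0
  for (i in 1:6) {
    col <- substr(hexamers, i, i)
    b <- substr(query, i, i)
    f <- (sum(col == b) + pseudocount) / (n + 4 * pseudocount)
    total <- total + log2(f / background[[b]])
  }
  total
}

# exhaustive re-scorer: every offset, every architecture, plain substr
oracle_scan <- function(seq, pwm, low, high,
                        archs = c("DR4", "IR0", "ER6")) {
  bits <- coef(pwm)
  score6 <- function(h) {
    ch <- strsplit(h, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
    s <- 0
    for (i in 1:6) s <- s + bits[i, ch[i]]
    s
  }
  spacers <- c(DR4 = 4L, IR0 = 0L, ER6 = 6L)
  out <- list()
  L <- nchar(seq)
  for (a in archs) {
    elen <- 12L + spacers[[a]]
    if (L < elen) next
    for (j in 1:(L - elen + 1L)) {
      w <- substr(seq, j, j + elen - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      first6 <- substr(w, 1, 6)
      last6 <- substr(w, elen - 5L, elen)
      hs <- switch(a,
                   DR4 = c(first6, last6),
                   IR0 = c(first6, oracle_revcomp(last6)),
                   ER6 = c(oracle_revcomp(first6), last6))
      b1 <- score6(hs[1]); b2 <- score6(hs[2])
      if (is.na(b1) || is.na(b2)) next
      if (min(b1, b2) >= low && max(b1, b2) >= high) {
        out[[length(out) + 1L]] <- data.frame(
          architecture = a, offset = j, halfsite1 = hs[1],
          halfsite2 = hs[2], bits1 = b1, bits2 = b2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(architecture = character(), offset = integer(),
                      halfsite1 = character(), halfsite2 = character(),
                      bits1 = numeric(), bits2 = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$offset, res$architecture), , drop = FALSE]
}

random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# a tre_hits-shaped data frame built directly from a truth ledger's
# mouse rows (bypasses the scanner; used to isolate the conservation stage)
hits_from_truth <- function(truth) {
  m <- truth[truth$species == "mouse", ]
  data.frame(gene = m$gene, species = "mouse", architecture = m$architecture,
             pos = m$pos, strand = "+", halfsite1 = m$halfsite1,
             spacer_seq = m$spacer_seq, halfsite2 = m$halfsite2,
             bits1 = NA_real_, bits2 = NA_real_, element = m$element,
             stringsAsFactors = FALSE)
}
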