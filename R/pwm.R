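#' Read a half-site training set
#'
#' Reads a TSV of validated hexamer half-sites with columns \code{id},
#' \code{hexamer} and \code{source}. Lines starting with \code{#} are
#' comments. Hexamers are upper-cased on read and must be exactly six
#' bases over ACGT.
#'
#' @param path Path to the training TSV.
#' @return A data frame of class \code{halfsite_training} with columns
#'   \code{id}, \code{hexamer}, \code{source}.
#' @export
read_training_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "hexamer", "source")
  if (!all(need %in% names(df))) {
    stop("training TSV must have columns id, hexamer, source", call. = FALSE)
  }
  halfsite_training(df$hexamer, id = df$id, source = df$source)
}

#' Construct a half-site training set
#'
#' @param hexamer Character vector of 6-base half-sites (ACGT).
#' @param id Optional identifiers (defaults to \code{hs1, hs2, ...}).
#' @param source Optional free-text provenance per entry.
#' @return A \code{halfsite_training} data frame.
#' @export
halfsite_training <- function(hexamer, id = NULL, source = NULL) {
  hexamer <- toupper(hexamer)
  for (i in seq_along(hexamer)) {
    if (nchar(hexamer[i]) != 6L || grepl("[^ACGT]", hexamer[i])) {
      stop(sprintf("training entry %s ('%s') is not a 6-base ACGT hexamer",
                   if (is.null(id)) i else id[i], hexamer[i]), call. = FALSE)
    }
  }
  if (is.null(id)) id <- paste0("hs", seq_along(hexamer))
  if (is.null(source)) source <- rep("", length(hexamer))
  structure(data.frame(id = as.character(id), hexamer = hexamer,
                       source = as.character(source),
                       stringsAsFactors = FALSE),
            class = c("halfsite_training", "data.frame"))
}

#' Fit a hexamer half-site position weight matrix
#'
#' Builds a 6-position x 4-base bit-score matrix from a training set of
#' validated half-sites. The score of base \eqn{b} at position \eqn{i} is
#' the log-odds in bits of its smoothed training frequency against the
#' background: \deqn{bits_{i}(b) = \log_2 \frac{(n_i(b) + c) / (N + 4c)}{q(b)}}
#' where \eqn{n_i(b)} counts base \eqn{b} at position \eqn{i} among the
#' \eqn{N} training hexamers, \eqn{c} is the pseudocount and \eqn{q} the
#' background composition. A hexamer's score is the sum of its six
#' per-position entries, so a perfectly conserved training set scores its
#' consensus at 12 bits under a uniform background.
#'
#' @param training A \code{halfsite_training} set (or character vector of
#'   hexamers, which is coerced).
#' @param pseudocount Non-negative smoothing count added per base and
#'   position; default 0.25 (a quarter count per base). With 0 the matrix
#'   may contain \code{-Inf} for bases unseen in training.
#' @param background Named per-base probabilities summing to 1; default
#'   uniform.
#' @return An object of class \code{halfsite_pwm} with components
#'   \code{bits} (6 x 4 matrix), \code{pseudocount}, \code{background},
#'   \code{n_train} and \code{training}.
#' @examples
#' pwm <- build_pwm(halfsite_training(rep("AGGTCA", 4)), pseudocount = 0)
#' score_halfsite(pwm, "AGGTCA")  # 12 bits
#' @export
build_pwm <- function(training, pseudocount = 0.25,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (is.character(training)) training <- halfsite_training(training)
  if (!inherits(training, "halfsite_training")) {
    stop("training must be a halfsite_training set", call. = FALSE)
  }
  n <- nrow(training)
  if (n < 2L) {
    stop("at least 2 training hexamers are required to build a matrix",
         call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number", call. = FALSE)
  }
  background <- background[DNA_BASES]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-8) {
    stop("background must be named probabilities for A,C,G,T summing to 1",
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(training$hexamer, "", fixed = TRUE))
  counts <- vapply(seq_len(6), function(i) {
    tabulate(match(chars[, i], DNA_BASES), nbins = 4L)
  }, numeric(4))
  counts <- t(counts)  # 6 x 4
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  bits <- log2(sweep(freq, 2, background, "/"))
  dimnames(bits) <- list(position = as.character(1:6), base = DNA_BASES)
  structure(list(bits = bits, pseudocount = pseudocount,
                 background = background, n_train = n, training = training),
            class = "halfsite_pwm")
}

#' Score hexamer half-sites against a fitted matrix
#'
#' Returns the additive bit score \eqn{\sum_i bits_i(h_i)} of each query
#' hexamer. A base with zero smoothed frequency (only possible with
#' pseudocount 0) yields \code{-Inf}, which fails every threshold.
#'
#' @param pwm A \code{halfsite_pwm}.
#' @param hexamer Character vector of 6-base ACGT queries.
#' @return Numeric vector of bit scores.
#' @export
score_halfsite <- function(pwm, hexamer) {
  stopifnot(inherits(pwm, "halfsite_pwm"))
  hexamer <- toupper(hexamer)
  check_hexamer(hexamer, "query hexamer")
  vapply(hexamer, function(h) {
    idx <- match(strsplit(h, "", fixed = TRUE)[[1]], DNA_BASES)
    sum(pwm$bits[cbind(1:6, idx)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Leave-one-out half-site scores
#'
#' Scores each training half-site against a matrix rebuilt from all the
#' other entries — the cross-validation used to calibrate scan
#' thresholds. Genome scanning itself always uses the full matrix.
#'
#' @inheritParams build_pwm
#' @return Data frame with columns \code{id}, \code{hexamer}, \code{bits},
#'   in training order.
#' @export
leave_one_out_scores <- function(training, pseudocount = 0.25,
                                 background = c(A = 0.25, C = 0.25,
                                                G = 0.25, T = 0.25)) {
  if (is.character(training)) training <- halfsite_training(training)
  if (nrow(training) < 3L) {
    stop("leave-one-out scoring requires at least 3 training entries",
         call. = FALSE)
  }
  bits <- vapply(seq_len(nrow(training)), function(k) {
    m <- build_pwm(training[-k, , drop = FALSE], pseudocount, background)
    score_halfsite(m, training$hexamer[k])
  }, numeric(1))
  data.frame(id = training$id, hexamer = training$hexamer, bits = bits,
             stringsAsFactors = FALSE)
}

#' @export
print.halfsite_pwm <- function(x, ...) {
  cat(sprintf("Half-site PWM (bits) fit on %d hexamers, pseudocount %g\n",
              x$n_train, x$pseudocount))
  print(round(x$bits, 3))
  invisible(x)
}

#' @export
coef.halfsite_pwm <- function(object, ...) object$bits

#' @export
summary.halfsite_pwm <- function(object, ...) {
  consensus <- paste(DNA_BASES[apply(object$bits, 1, which.max)],
                     collapse = "")
  # expected score under the column frequencies = information content
  freq <- 2^object$bits * matrix(object$background, 6, 4, byrow = TRUE)
  ic <- rowSums(ifelse(freq > 0, freq * object$bits, 0))
  out <- list(consensus = consensus,
              consensus_bits = score_halfsite(object, consensus),
              information_content = ic, n_train = object$n_train,
              pseudocount = object$pseudocount)
  class(out) <- "summary.halfsite_pwm"
  out
}

#' @export
print.summary.halfsite_pwm <- function(x, ...) {
  cat(sprintf("Consensus %s (%.2f bits); trained on %d half-sites\n",
              x$consensus, x$consensus_bits, x$n_train))
  cat("Per-position information content (bits):\n")
  print(round(x$information_content, 3))
  invisible(x)
}

#' Predict bit scores for new hexamers
#'
#' @param object A \code{halfsite_pwm}.
#' @param newdata Character vector of hexamers; defaults to the training
#'   half-sites.
#' @param ... Unused.
#' @export
predict.halfsite_pwm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$training$hexamer
  score_halfsite(object, newdata)
}

#' Simulate hexamers from the fitted position frequencies
#'
#' @param object A \code{halfsite_pwm}.
#' @param nsim Number of hexamers to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @export
simulate.halfsite_pwm <- function(object, nsim = 1, seed = NULL, ...) {
  freq <- 2^object$bits * matrix(object$background, 6, 4, byrow = TRUE)
  freq <- freq / rowSums(freq)
  draw <- function() paste(vapply(1:6, function(i)
    sample(DNA_BASES, 1, prob = freq[i, ]), character(1)), collapse = "")
  if (is.null(seed)) vapply(seq_len(nsim), function(i) draw(), character(1))
  else with_seed(seed, vapply(seq_len(nsim), function(i) draw(), character(1)))
}

#' @export
plot.halfsite_pwm <- function(x, ...) {
  freq <- 2^x$bits * matrix(x$background, 6, 4, byrow = TRUE)
  ic <- rowSums(ifelse(freq > 0, freq * x$bits, 0))
  heights <- t(freq * ic)  # stacked contribution per base
  graphics::barplot(heights, names.arg = 1:6, col = c("#33a02c", "#1f78b4",
                    "#ff7f00", "#e31a1c"), xlab = "half-site position",
                    ylab = "information content (bits)", ylim = c(0, 2), ...)
  graphics::legend("topright", legend = DNA_BASES, bty = "n",
                   fill = c("#33a02c", "#1f78b4", "#ff7f00", "#e31a1c"))
  invisible(x)
}

#' Write / read a PWM as TSV
#'
#' Six rows (positions 1-6), columns \code{position, A, C, G, T}, bits to
#' six decimals, header row required.
#'
#' @param pwm A \code{halfsite_pwm}.
#' @param path Output path.
#' @export
write_pwm_tsv <- function(pwm, path) {
  df <- data.frame(position = 1:6, round(pwm$bits, 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# half-site PWM, bits = log2(freq/background)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @export
read_pwm_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  bits <- as.matrix(df[, DNA_BASES])
  dimnames(bits) <- list(position = as.character(1:6), base = DNA_BASES)
  structure(list(bits = bits, pseudocount = NA_real_,
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 n_train = NA_integer_, training = NULL),
            class = "halfsite_pwm")
}

#' The packaged default half-site training set
#'
#' A curated synthetic stand-in for a literature-derived list of validated
#' thyroid response element half-sites: the canonical nuclear-receptor
#' hexamer AGGTCA, close variants observed in characterised elements
#' (e.g. the Klf9 and Mbp promoter elements), and common degenerate forms.
#' Absolute bit scores from any particular validated list will differ; the
#' training file is a required, logged input so runs are reproducible.
#'
#' @return A \code{halfsite_training} data frame (14 entries).
#' @export
default_training_set <- function() {
  read_training_tsv(system.file("extdata", "halfsite_training_synthetic.tsv",
                                package = "trescan", mustWork = TRUE))
}
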