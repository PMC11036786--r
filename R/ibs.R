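#' Tally a word distribution over the 64 pattern codes
#'
#' Counts occurrences of each pattern word (code 0..63), converts to
#' occurrence probabilities, and assigns probability ranks 1..|support| in
#' descending probability. Ties in probability are broken by ascending word
#' index, so ranks are integral and reproducible. Words with zero
#' probability carry no rank.
#'
#' @param codes integer vector of pattern codes in \code{[0, 63]}; NAs
#'   (undefined voxels) are dropped. A \code{pattern_map} may be passed
#'   directly.
#' @param n_words alphabet size (64 for the structural pattern alphabet).
#' @return A \code{word_distribution}: list with \code{word} (0..n_words-1),
#'   \code{count}, \code{prob}, \code{rank} (NA outside the support) and
#'   \code{n}, the number of tallied voxels.
#' @examples
#' d <- tally_distribution(c(0, 0, 0, 5, 5, 9))
#' d$prob[d$word %in% c(0, 5, 9)]  # 0.5, 1/3, 1/6
#' @export
tally_distribution <- function(codes, n_words = 64L) {
  if (inherits(codes, "pattern_map")) codes <- unclass(codes)
  codes <- as.vector(codes)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L)
    stop("no codes to tally (empty collection)", call. = FALSE)
  codes <- as.integer(codes)
  if (any(codes < 0L | codes >= n_words))
    stop(sprintf("codes must lie in [0, %d]", n_words - 1L), call. = FALSE)
  counts <- tabulate(codes + 1L, nbins = n_words)
  new_word_distribution(counts / sum(counts), counts = counts,
                        n = sum(counts))
}

#' Build a word distribution from a probability vector
#'
#' Used for group-average distributions, where probabilities are means of
#' per-subject probability vectors rather than raw counts. Ranks are
#' recomputed from the given probabilities with the same descending-order,
#' ascending-word tie rule as \code{\link{tally_distribution}}.
#'
#' @param prob numeric vector of length \code{n_words}, non-negative,
#'   summing to 1.
#' @param n number of observations behind the probabilities (NA if unknown).
#' @return A \code{word_distribution}.
#' @export
word_distribution_from_prob <- function(prob, n = NA_integer_) {
  n_words <- length(prob)
  if (any(!is.finite(prob)) || any(prob < 0))
    stop("probabilities must be finite and non-negative", call. = FALSE)
  if (abs(sum(prob) - 1) > 1e-9)
    stop("probabilities must sum to 1", call. = FALSE)
  new_word_distribution(prob, counts = rep(NA_integer_, n_words), n = n)
}

new_word_distribution <- function(prob, counts, n) {
  n_words <- length(prob)
  word <- seq_len(n_words) - 1L
  support <- which(prob > 0)
  ord <- support[order(-prob[support], word[support])]
  rank <- rep(NA_integer_, n_words)
  rank[ord] <- seq_along(ord)
  structure(list(word = word, count = counts, prob = prob, rank = rank,
                 n = n),
            class = "word_distribution")
}

#' @export
print.word_distribution <- function(x, ...) {
  sup <- which(!is.na(x$rank))
  cat("<word_distribution> ", length(sup), " / ", length(x$word),
      " words in support", sep = "")
  if (!is.na(x$n)) cat(", n = ", x$n, sep = "")
  cat("\n")
  top <- sup[order(x$rank[sup])]
  top <- head(top, 5L)
  for (i in top)
    cat(sprintf("  rank %2d: word %2d  p = %.4f\n",
                x$rank[i], x$word[i], x$prob[i]))
  if (length(sup) > 5L) cat("  ...\n")
  invisible(x)
}

# Fast numeric IBS distance from two prob/rank vectors (no validation).
# D = (1/N12) * sum over shared words of |R1 - R2| * F,  F normalised to 1.
ibs_value <- function(p1, r1, p2, r2) {
  shared <- which(p1 > 0 & p2 > 0)
  n12 <- length(shared)
  if (n12 == 0L) return(c(value = 1, n12 = 0))
  f <- -p1[shared] * log(p1[shared]) - p2[shared] * log(p2[shared])
  z <- sum(f)
  if (z == 0) {
    # every shared word has p = 1 in both: a single shared word, both rank 1
    return(c(value = 0, n12 = n12))
  }
  d <- sum(abs(r1[shared] - r2[shared]) * f / z) / n12
  c(value = d, n12 = n12)
}

#' Information-based similarity distance between two word distributions
#'
#' The entropy-weighted rank distance
#' \deqn{D = (1/N_{12}) \sum_k |R_1(w_k) - R_2(w_k)| F(w_k)}
#' summed over the N12 shared words (probability > 0 in both
#' distributions). The weight \eqn{F(w_k) \propto -p_1\log p_1 - p_2\log
#' p_2} is normalised so the weights sum to 1; ranks are each
#' distribution's probability ranks over its own full support. D is
#' symmetric and zero for identical distributions; small D means similar
#' pattern organisation.
#'
#' @param a,b \code{word_distribution} objects over the same alphabet.
#' @param warn_disjoint warn when the supports are disjoint (the distance
#'   is then defined as 1 with zero shared words).
#' @return An \code{ibs_distance}: list with \code{value} and
#'   \code{shared_words} (N12).
#' @examples
#' a <- word_distribution_from_prob(c(0.6, 0.4, rep(0, 62)))
#' b <- word_distribution_from_prob(c(0.4, 0.6, rep(0, 62)))
#' ibs_distance(a, b)$value  # 0.5
#' @export
ibs_distance <- function(a, b, warn_disjoint = TRUE) {
  stopifnot(inherits(a, "word_distribution"),
            inherits(b, "word_distribution"))
  if (length(a$prob) != length(b$prob))
    stop("distributions use different alphabet sizes", call. = FALSE)
  res <- ibs_value(a$prob, a$rank, b$prob, b$rank)
  if (res[["n12"]] == 0L && warn_disjoint)
    warning("distributions share no words; distance set to 1",
            call. = FALSE)
  structure(list(value = unname(res[["value"]]),
                 shared_words = as.integer(res[["n12"]])),
            class = "ibs_distance")
}

#' @export
print.ibs_distance <- function(x, ...) {
  cat(sprintf("IBS distance D = %.6f  (shared words N12 = %d)\n",
              x$value, x$shared_words))
  invisible(x)
}

#' @export
as.double.ibs_distance <- function(x, ...) x$value

#' Write or read a word distribution as delimited text
#'
#' One row per word: word, count, probability, rank. Round-trips exactly
#' for tallied distributions.
#'
#' @param x a \code{word_distribution}.
#' @param path file path.
#' @return \code{read_word_distribution} returns a \code{word_distribution}.
#' @export
write_word_distribution <- function(x, path) {
  stopifnot(inherits(x, "word_distribution"))
  df <- data.frame(word = x$word, count = x$count,
                   probability = x$prob, rank = x$rank)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_word_distribution
#' @export
read_word_distribution <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  need <- c("word", "count", "probability", "rank")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed distribution file '%s': need columns %s",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  d <- new_word_distribution(df$probability,
                             counts = as.integer(df$count),
                             n = if (all(is.na(df$count))) NA_integer_
                                 else sum(df$count, na.rm = TRUE))
  d
}
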