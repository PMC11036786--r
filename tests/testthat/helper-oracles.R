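# Independent reference implementations used as oracles. These are literal,
# slow transcriptions kept deliberately separate from the package internals.

# Brute-force voxel-by-voxel pattern encoder: explicit neighbour lookup in a
# zero-padded copy, out-of-mask neighbours valued 0.
brute_pattern_map <- function(v, mask) {
  d <- dim(v)
  w <- v
  w[!mask] <- 0
  get <- function(i, j, k) {
    if (i < 1 || i > d[1] || j < 1 || j > d[2] || k < 1 || k > d[3]) 0
    else w[i, j, k]
  }
  out <- array(NA_integer_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    ctr <- w[i, j, k]
    nb <- c(get(i + 1, j, k), get(i - 1, j, k),   # right, left
            get(i, j + 1, k), get(i, j - 1, k),   # anterior, posterior
            get(i, j, k + 1), get(i, j, k - 1))   # superior, inferior
    bits <- as.integer(ctr >= nb)
    out[i, j, k] <- sum(bits * c(32L, 16L, 8L, 4L, 2L, 1L))
  }
  out
}

# Literal transcription of the IBS definition: probabilities ranked in
# descending order (ties by ascending word), entropy weight normalised over
# shared words, mean absolute rank difference with the 1/N12 prefactor.
brute_ibs <- function(p1, p2, base = exp(1)) {
  n_words <- length(p1)
  rank_of <- function(p) {
    r <- rep(NA_real_, n_words)
    sup <- which(p > 0)
    remaining <- sup
    nxt <- 1
    while (length(remaining) > 0) {
      best <- remaining[1]
      for (w in remaining) {
        if (p[w] > p[best]) best <- w
        # equal probability: keep the lower word index (already first)
      }
      r[best] <- nxt
      nxt <- nxt + 1
      remaining <- setdiff(remaining, best)
    }
    r
  }
  r1 <- rank_of(p1)
  r2 <- rank_of(p2)
  shared <- which(p1 > 0 & p2 > 0)
  n12 <- length(shared)
  if (n12 == 0) return(1)
  z <- 0
  for (w in shared)
    z <- z + (-p1[w] * log(p1[w], base) - p2[w] * log(p2[w], base))
  if (z == 0) return(0)
  total <- 0
  for (w in shared) {
    f <- (-p1[w] * log(p1[w], base) - p2[w] * log(p2[w], base)) / z
    total <- total + abs(r1[w] - r2[w]) * f
  }
  total / n12
}

# Random sparse probability vector over n_words with k-word support.
random_distribution <- function(n_words = 64, k = sample(2:8, 1)) {
  p <- numeric(n_words)
  sup <- sample.int(n_words, k)
  w <- runif(k)
  p[sup] <- w / sum(w)
  p
}

# Theoretical code law under i.i.d. continuous intensities.
code_law <- function() {
  k <- rowSums(ibsmorph::decode_pattern(0:63))
  factorial(k) * factorial(6 - k) / factorial(7)
}
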