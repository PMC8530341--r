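# Independent metric oracles implemented directly from the definitions.

brute_force_weighted_kappa <- function(true, predicted, levels,
                                       quadratic = FALSE) {
  k <- length(levels)
  n <- length(true)
  wo <- we <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- abs(i - j) / (k - 1)
      if (quadratic) w <- w^2
      o_ij <- sum(true == levels[i] & predicted == levels[j])
      e_ij <- sum(true == levels[i]) * sum(predicted == levels[j]) / n
      wo <- wo + w * o_ij
      we <- we + w * e_ij
    }
  }
  1 - wo / we
}

brute_force_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos)
    for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

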