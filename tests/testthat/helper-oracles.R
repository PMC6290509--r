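# Independent brute-force oracles for the ranking metrics. These loop over
# ranks / pairs / arrangements explicitly and share no code with the package.

# AP of one fully-ordered arrangement: explicit loop over ranks.
ap_of_arrangement <- function(labels_in_rank_order) {
  hits <- 0; total <- 0
  for (i in seq_along(labels_in_rank_order)) {
    if (labels_in_rank_order[i] == 1) {
      hits <- hits + 1
      total <- total + hits / i
    }
  }
  total / sum(labels_in_rank_order)
}

# Expected AP over uniformly random orderings of tied blocks. The precision
# contributed by a block depends only on the arrangement inside that block
# (everything above it is fixed by the block composition), so by linearity of
# expectation each block can be enumerated exhaustively on its own: for every
# placement of the block's positives over its slots, sum precision at each
# positive's global rank, then average. Blocks must stay small; the generator
# below keeps them <= 4.
brute_force_ap <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  block_id <- match(s, unique(s))
  total <- 0
  p0 <- 0; s0 <- 0
  for (bi in unique(block_id)) {
    idx <- which(block_id == bi)
    b <- length(idx)
    k <- sum(l[idx] == 1)
    if (k > 0) {
      placements <- combn(b, k, simplify = FALSE)
      contribs <- vapply(placements, function(pos) {
        contrib <- 0
        seen <- 0
        for (t in seq_len(b)) {
          if (t %in% pos) {
            seen <- seen + 1
            contrib <- contrib + (p0 + seen) / (s0 + t)
          }
        }
        contrib
      }, 0)
      total <- total + mean(contribs)
    }
    p0 <- p0 + k
    s0 <- s0 + b
  }
  total / sum(l == 1)
}

# AUROC by explicit loop over all positive-negative pairs, half credit on ties.
brute_force_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# random score/label sets with genuine ties but small tied blocks (<= 4),
# so exhaustive AP enumeration stays cheap
random_tied_set <- function(n) {
  base <- round(runif(ceiling(n / 2)), 2)
  scores <- sample(base, n, replace = TRUE)
  # cap block sizes at 4 by jittering overfull blocks
  repeat {
    tab <- table(scores)
    big <- names(tab[tab > 4])
    if (length(big) == 0) break
    idx <- which(scores %in% as.numeric(big))
    scores[idx] <- scores[idx] + runif(length(idx), -0.002, 0.002)
  }
  labels <- rbinom(n, 1, 0.4)
  if (sum(labels) == 0) labels[sample(n, 1)] <- 1
  if (sum(labels) == n) labels[sample(n, 1)] <- 0
  list(scores = scores, labels = labels)
}
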