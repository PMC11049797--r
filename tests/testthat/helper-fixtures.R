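# Fixture builders and independent brute-force oracles used across tests.

# bee_image from a normalized gray matrix (R = G = B), values in [0,1].
gray_image <- function(values, bit_depth = 8L, image_id = "fixture") {
  maxval <- 2^bit_depth - 1
  q <- as.integer(round(values * maxval))
  pixels <- array(q, dim = c(nrow(values), ncol(values), 3L))
  beecolor:::new_bee_image(pixels, bit_depth, image_id)
}

# bee_image with explicit integer R, G, B matrices.
rgb_image <- function(r, g, b, bit_depth = 8L, image_id = "fixture") {
  pixels <- array(c(r, g, b), dim = c(nrow(r), ncol(r), 3L))
  beecolor:::new_bee_image(array(as.integer(pixels), dim = dim(pixels)),
                           bit_depth, image_id)
}

# Sort-and-pick median, independent of stats::median.
brute_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0) return(NA_real_)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Hand-summed trapezoid with unit spacing.
brute_trapz <- function(v) {
  s <- 0
  for (i in seq_len(length(v) - 1)) s <- s + (v[i] + v[i + 1]) / 2
  s
}

# Pairwise-comparison AUC: concordant pairs / total, ties count 1/2.
brute_auc <- function(scores, truth, positive) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
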