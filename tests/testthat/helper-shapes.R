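# Geometric fixtures built in code.

digital_disk <- function(n, r, center = (n + 1) / 2) {
  rr <- sqrt(outer(seq_len(n) - center, seq_len(n) - center,
                   function(a, b) a^2 + b^2))
  m <- (rr <= r) * 1L
  dim(m) <- c(n, n)
  m
}

two_level_disk_image <- function(n = 96, r = 20, lo = 50, hi = 200) {
  d <- digital_disk(n, r)
  img <- ifelse(d == 1, lo, hi)
  dim(img) <- c(n, n)
  list(image = img, truth = d)
}

# brute-force confusion recount used as the metrics oracle
brute_confusion <- function(y, p) {
  c(TP = sum(y == 1 & p == 1), FP = sum(y == 0 & p == 1),
    FN = sum(y == 1 & p == 0), TN = sum(y == 0 & p == 0))
}

# brute-force pair-counting AUC oracle
brute_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
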