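# Independent oracles and small generators shared across the test files.
# These deliberately avoid the package's own code paths: the natural-vector
# oracle enumerates k-mers as substrings, the reverse complement works on
# the character level.

random_seq <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(alphabet, n, replace = TRUE, prob = p[seq_along(alphabet)] /
                 sum(p[seq_along(alphabet)])), collapse = "")
}

revcomp_string <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(seq)), "")[[1]]),
        collapse = "")
}

# brute-force k-mer natural vector: substring enumeration, split/tapply
# aggregation, positions indexed over the full k-mer sequence (invalid
# k-mers skipped but still advancing the index).
oracle_nv <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  m <- n - k + 1L
  km <- substring(seq, 1:m, k:n)
  valid <- !grepl("[^ACGT]", km)
  pos <- which(valid)
  sp <- split(pos, km[valid])            # names sorted alphabetically
  counts <- vapply(sp, length, numeric(1))
  means <- vapply(sp, mean, numeric(1))
  ssq <- mapply(function(p, mu) sum((p - mu)^2), sp, means)
  list(kmer = names(sp), count = unname(counts), mean = unname(means),
       moment = unname(ssq / (counts * m)), m = m)
}

expect_nv_equals_oracle <- function(v, orc, tolerance = 1e-9) {
  df <- as.data.frame(v)
  expect_identical(df$kmer, orc$kmer)
  expect_equal(df$count, orc$count, tolerance = tolerance)
  expect_equal(df$mean, orc$mean, tolerance = tolerance)
  expect_equal(df$moment, orc$moment, tolerance = tolerance)
  expect_equal(v$m, orc$m)
}

# flattened dense representation for cosine cross-checks
dense_nv <- function(v) {
  k <- v$k
  idx <- v$kmers + 1
  out <- numeric(3 * 4^k)
  out[idx] <- v$count
  out[4^k + idx] <- v$mean
  out[2 * 4^k + idx] <- v$moment
  out
}

nv_equal <- function(a, b, tolerance = 1e-9) {
  isTRUE(all.equal(a, b, tolerance = tolerance))
}
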