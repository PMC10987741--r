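# The k-mer natural vector embedding and its concatenation /
# reverse-complement algebra.

test_that("natural vector statistics match hand-computed values", {
  df <- as.data.frame(kmer_natural_vector("ACGT", 1))
  expect_identical(df$kmer, c("A", "C", "G", "T"))
  expect_equal(df$count, rep(1, 4))
  expect_equal(df$mean, 1:4, ignore_attr = TRUE)
  expect_equal(df$moment, rep(0, 4))

  # absent letters follow the zero convention (no entry == all-zero stats)
  v <- kmer_natural_vector("AAAA", 1)
  df <- as.data.frame(v)
  expect_identical(df$kmer, "A")
  expect_equal(dense_nv(v)[c(2, 6, 10)], c(0, 0, 0))  # C count/mean/moment

  df <- as.data.frame(kmer_natural_vector("AA", 1))
  expect_equal(df$count, 2)
  expect_equal(df$mean, 1.5)
  expect_equal(df$moment, ((1 - 1.5)^2 + (2 - 1.5)^2) / (2 * 2))

  v <- kmer_natural_vector("ACGT", 2)
  df <- as.data.frame(v)
  expect_identical(df$kmer, c("AC", "CG", "GT"))
  expect_equal(df$count, rep(1, 3))
  expect_equal(df$mean, 1:3, ignore_attr = TRUE)
  expect_equal(v$m, 3)
})

test_that("vector computation agrees with the substring-enumeration oracle", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    s <- random_seq(n, gc = runif(1, 0.3, 0.7))
    if (rep %% 3 == 0) {  # inject ambiguity runs
      at <- sample(n - 10, 1)
      substring(s, at, at + sample(3:8, 1)) <- strrep("N", 9)
    }
    for (k in c(1, 2, 3)) {
      expect_nv_equals_oracle(kmer_natural_vector(s, k), oracle_nv(s, k))
    }
  }
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(kmer_natural_vector("ACGT", 0), "positive integer")
  expect_error(kmer_natural_vector(sequence_record("tiny", "AC"), 5),
               "'tiny'.*shorter than k = 5")
  expect_error(kmer_natural_vector("NNNNN", 2), "no valid k-mer")
  expect_error(nv_concat(kmer_natural_vector("ACGT", 1),
                         kmer_natural_vector("ACGT", 2)),
               "word sizes differ")
})

test_that("concatenation algebra is exact at k = 1", {
  expect_true(nv_equal(
    nv_concat(kmer_natural_vector("A", 1), kmer_natural_vector("A", 1)),
    kmer_natural_vector("AA", 1), tolerance = 1e-12))
  set.seed(17)
  for (rep in 1:10) {
    s1 <- random_seq(500)
    s2 <- random_seq(500)
    alg <- nv_concat(kmer_natural_vector(s1, 1), kmer_natural_vector(s2, 1))
    direct <- kmer_natural_vector(paste0(s1, s2), 1)
    expect_true(nv_equal(direct, alg, tolerance = 1e-12))
  }
})

test_that("the empty vector is the identity of the concatenation algebra", {
  v <- kmer_natural_vector("ACGTTGCA", 3)
  expect_true(nv_equal(v, nv_concat(v, nv_empty(3))))
  expect_true(nv_equal(v, nv_concat(nv_empty(3), v)))
})

test_that("concatenation conserves counts and lengths", {
  set.seed(3)
  s1 <- random_seq(321); s2 <- random_seq(257)
  for (k in c(1, 2, 4)) {
    a <- kmer_natural_vector(s1, k); b <- kmer_natural_vector(s2, k)
    ab <- nv_concat(a, b)
    expect_equal(sum(ab$count), sum(a$count) + sum(b$count))
    expect_equal(ab$seq_length, a$seq_length + b$seq_length)
    expect_equal(ab$m, a$m + b$m)
    expect_true(all(ab$count > 0) && all(ab$moment >= -1e-15))
    expect_true(all(ab$mean >= 1 - 1e-9 & ab$mean <= ab$m + 1e-9))
  }
})

test_that("k > 1 concatenation misses exactly the boundary k-mers", {
  set.seed(29)
  for (k in c(2, 3, 5)) {
    s1 <- random_seq(800); s2 <- random_seq(700)
    alg <- nv_concat(kmer_natural_vector(s1, k), kmer_natural_vector(s2, k))
    direct <- kmer_natural_vector(paste0(s1, s2), k)
    da <- dense_nv(alg)[1:(4^k)]
    dd <- dense_nv(direct)[1:(4^k)]
    expect_true(all(dd - da >= 0))          # direct only ever has more
    expect_equal(sum(dd - da), k - 1)       # the junction-spanning k-mers
  }
})

test_that("reverse-complement transform matches the string oracle and is an involution", {
  v <- nv_reverse_complement(kmer_natural_vector("ACG", 1))
  expect_true(nv_equal(kmer_natural_vector("CGT", 1), v, tolerance = 1e-12))
  set.seed(53)
  for (rep in 1:10) {
    s <- random_seq(sample(30:300, 1))
    for (k in c(1, 2, 3)) {
      nv <- kmer_natural_vector(s, k)
      rc <- nv_reverse_complement(nv)
      expect_true(nv_equal(kmer_natural_vector(revcomp_string(s), k), rc))
      expect_true(nv_equal(nv, nv_reverse_complement(rc), tolerance = 1e-12))
      expect_equal(sort(rc$count), sort(nv$count))
      expect_equal(rc$m, nv$m)
      expect_equal(rc$seq_length, nv$seq_length)
    }
  }
})

test_that("a reverse-complement palindrome is a fixed point of the transform", {
  v <- kmer_natural_vector("ACGT", 1)   # revcomp("ACGT") == "ACGT"
  expect_true(nv_equal(v, nv_reverse_complement(v), tolerance = 1e-12))
})

test_that("two segments yield exactly eight fusion representations, closed under reverse complement", {
  set.seed(11)
  a <- kmer_natural_vector(random_seq(150), 2)
  b <- kmer_natural_vector(random_seq(90), 2)
  reps <- fusion_representations(a, b)
  expect_length(reps$variants, 8)
  expect_length(unique(reps$labels), 8)
  expect_equal(reps$fused_length, a$seq_length + b$seq_length)
  expect_true(all(vapply(reps$variants, function(v) v$m == a$m + b$m,
                         logical(1))))
  # closure: the reverse complement of every variant is itself a variant
  for (v in reps$variants) {
    rcv <- nv_reverse_complement(v)
    expect_true(any(vapply(reps$variants, nv_equal, logical(1), b = rcv)))
  }
})

test_that("each fusion representation at k = 1 equals the vector of its orientation string", {
  set.seed(19)
  s1 <- random_seq(120); s2 <- random_seq(80)
  reps <- fusion_representations(kmer_natural_vector(s1, 1),
                                 kmer_natural_vector(s2, 1))
  r1 <- revcomp_string(s1); r2 <- revcomp_string(s2)
  strings <- c(paste0(s1, s2), paste0(s1, r2), paste0(r1, s2), paste0(r1, r2),
               paste0(s2, s1), paste0(s2, r1), paste0(r2, s1), paste0(r2, r1))
  for (i in 1:8) {
    expect_true(nv_equal(kmer_natural_vector(strings[i], 1),
                         reps$variants[[i]], tolerance = 1e-12),
                label = sprintf("orientation %s", reps$labels[i]))
  }
})

test_that("representation count follows s! * 2^s", {
  expect_equal(representation_count(2), 8)
  expect_equal(representation_count(1), 2)
  expect_equal(representation_count(3), 48)
  expect_error(representation_count(0), "positive integer")
})

test_that("cosine similarity is bounded and exact for identical vectors", {
  set.seed(2)
  a <- kmer_natural_vector(random_seq(400), 3)
  b <- kmer_natural_vector(random_seq(350), 3)
  expect_equal(nv_cosine(a, a), 1)
  cs <- nv_cosine(a, b)
  expect_true(cs >= 0 && cs <= 1)
  # cross-check against dense dot product
  da <- dense_nv(a); db <- dense_nv(b)
  expect_equal(cs, sum(da * db) / sqrt(sum(da^2) * sum(db^2)),
               tolerance = 1e-12)
})
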