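# Distances, pairing loss and fusion-scenario detection.

make_set <- function(seqs, k, label = "set") {
  names(seqs) <- sprintf("%s_%02d", label, seq_along(seqs))
  chromosome_set(seqs, k, label = label)
}

test_that("cosine dissimilarity is zero for identical and one for disjoint vectors", {
  set.seed(31)
  v <- kmer_natural_vector(random_seq(300), 2)
  d <- d1_distance(v, list(nv_reverse_complement(v), v))
  expect_equal(as.numeric(d), 0)
  expect_equal(attr(d, "which"), 2L)
  # disjoint k-mer support: orthogonal embeddings
  a <- kmer_natural_vector("AAAAAA", 2)
  b <- kmer_natural_vector("CCCCCC", 2)
  expect_equal(as.numeric(d1_distance(a, list(b))), 1)
  # the max over variants is order-free
  w <- kmer_natural_vector(random_seq(200), 2)
  expect_equal(as.numeric(d1_distance(v, list(w, nv_reverse_complement(w)))),
               as.numeric(d1_distance(v, list(nv_reverse_complement(w), w))))
})

test_that("length distance is the absolute difference and fused lengths add", {
  expect_equal(d2_distance(100, 100), 0)
  expect_equal(d2_distance(100, 250), 150)
  set.seed(8)
  s1 <- random_seq(60); s2 <- random_seq(40)
  reps <- fusion_representations(kmer_natural_vector(s1, 1),
                                 kmer_natural_vector(s2, 1))
  expect_equal(d2_distance(100, reps$fused_length), 0)
})

test_that("min-max normalization maps its pool onto [0, 1] with a zero degenerate case", {
  pool <- c(3, 9, 5)
  expect_equal(normalize_minmax(3, pool), 0)
  expect_equal(normalize_minmax(9, pool), 1)
  expect_equal(normalize_minmax(5, pool), 1 / 3)
  expect_equal(normalize_minmax(4, c(4, 4, 4)), 0)
  expect_error(normalize_minmax(1, numeric(0)), "non-empty")
})

test_that("pairing loss vanishes on identical sets and single rows", {
  set.seed(23)
  seqs <- replicate(4, random_seq(1000))
  sa <- make_set(seqs, 3, "a")
  sb <- make_set(seqs, 3, "b")
  pl <- pairing_loss(sa, sb)
  expect_equal(pl$loss, 0)
  expect_equal(pl$pairs$b_id, sprintf("b_%02d", 1:4))  # matched copies
  one <- pairing_loss(make_set(seqs[1], 3, "x"), make_set(seqs[2], 3, "y"))
  expect_equal(one$loss, 0)  # degenerate single-candidate pools
})

test_that("pairing loss equals the exhaustive-permutation optimum of its own matrix", {
  set.seed(67)
  sa <- make_set(replicate(5, random_seq(sample(800:1500, 1))), 3, "a")
  sb <- make_set(replicate(5, random_seq(sample(800:1500, 1))), 3, "b")
  pl <- pairing_loss(sa, sb)
  oracle <- brute_force_assignment(unclass(pl$cost_matrix))
  expect_equal(pl$loss, oracle$total_cost, tolerance = 1e-10)
  expect_true(pl$loss >= 0 && pl$loss <= 2 * 5)
})

test_that("scenario enumeration counts all unordered pairs", {
  expect_equal(nrow(enumerate_fusion_scenarios(23)), 253)
  expect_equal(nrow(enumerate_fusion_scenarios(2)), 1)
  expect_equal(nrow(enumerate_fusion_scenarios(24)), 276)
  expect_error(enumerate_fusion_scenarios(1), ">= 2")
})

test_that("an exact planted fusion is identified with strictly minimal loss", {
  set.seed(101)
  seqs_b <- replicate(6, random_seq(sample(3000:6000, 1)))
  fused <- paste0(seqs_b[2], seqs_b[5])
  seqs_a <- c(fused, seqs_b[-c(2, 5)])
  sa <- make_set(seqs_a, 4, "A")
  sb <- make_set(seqs_b, 4, "B")
  rep <- detect_fusion(sa, sb)
  expect_equal(sort(rep$best$pair), c(2, 5))
  expect_true(rep$gap > 0)
  expect_true(all(rep$ranked$loss[-1] > rep$ranked$loss[1]))
  expect_equal(rep$best$fused_a_id, "A_01")
})

test_that("n = 1 detection has exactly one (trivially best) scenario", {
  set.seed(103)
  s1 <- random_seq(2000); s2 <- random_seq(1500)
  sa <- make_set(paste0(s1, s2), 3, "A")
  sb <- make_set(c(s1, s2), 3, "B")
  rep <- detect_fusion(sa, sb)
  expect_equal(nrow(rep$ranked), 1)
  expect_equal(rep$best$pair, c(1, 2))
  expect_true(is.na(rep$gap))
})

test_that("losses are invariant to strand flips and record order", {
  set.seed(107)
  sim <- make_fusion_dataset(simulation_config(
    n_chromosomes = 5, length_range = c(4000L, 8000L), seed = 11))
  k <- 4
  sa <- chromosome_set(sim$set_a, k, "A")
  sb <- chromosome_set(sim$set_b, k, "B")
  base <- detect_fusion(sa, sb)

  # reverse-complement one member of B: every scenario keeps its loss
  flipped <- sim$set_b
  flipped[[3]] <- sequence_record(flipped[[3]]$id,
                                  revcomp_string(flipped[[3]]$seq))
  rep_f <- detect_fusion(sa, chromosome_set(flipped, k, "Bf"))
  key <- function(r) paste(r$ranked$j1_id, r$ranked$j2_id)
  expect_equal(rep_f$ranked$loss[order(key(rep_f))],
               base$ranked$loss[order(key(base))], tolerance = 1e-9)

  # shuffling record order relabels but does not change the detection
  perm_a <- c(3, 1, 4, 2); perm_b <- c(5, 2, 1, 4, 3)
  rep_s <- detect_fusion(chromosome_set(sim$set_a[perm_a], k, "As"),
                         chromosome_set(sim$set_b[perm_b], k, "Bs"))
  expect_equal(sort(c(rep_s$best$j1_id, rep_s$best$j2_id)),
               sort(c(base$best$j1_id, base$best$j2_id)))
  expect_equal(rep_s$best$loss, base$best$loss, tolerance = 1e-9)
  expect_equal(sort(rep_s$ranked$loss), sort(base$ranked$loss),
               tolerance = 1e-9)
})

test_that("recognition degrades monotonically with substitution noise", {
  rates <- c(0, 0.01, 0.05)
  mean_rank <- vapply(rates, function(rate) {
    ranks <- vapply(1:20, function(seed) {
      sim <- make_fusion_dataset(simulation_config(
        n_chromosomes = 7, length_range = c(5000L, 10000L),
        substitution_rate = rate, insertion_rate = 0, deletion_rate = 0,
        seed = 1000 + seed))
      rep <- detect_fusion(chromosome_set(sim$set_a, 4, "A"),
                           chromosome_set(sim$set_b, 4, "B"))
      score_against_truth(rep, sim$truth)$true_rank
    }, numeric(1))
    mean(ranks)
  }, numeric(1))
  expect_equal(mean_rank[1], 1)                  # zero noise: always rank 1
  expect_true(all(diff(mean_rank) >= 0))
})

test_that("complexity terms scale as documented", {
  g1 <- complexity_guard(12, 1e6, 5)
  g2 <- complexity_guard(24, 1e6, 5)
  expect_equal(unname(g2["vectors"] / g1["vectors"]), 2)
  expect_equal(unname(g2["distances"] / g1["distances"]), 8)
  expect_equal(unname(g2["assignments"] / g1["assignments"]), 32)
  g <- complexity_guard(1, 5e4, 3)
  expect_equal(unname(g["total"]),
               unname(g["vectors"] + g["distances"] + g["assignments"]))
  expect_true(all(is.finite(complexity_guard(24, 1e6, 10, warn_above = Inf))))
  expect_error(complexity_guard(0, 10, 2), "positive")
})

test_that("set-size and word-size mismatches are rejected", {
  set.seed(13)
  sa <- make_set(replicate(3, random_seq(500)), 2, "a")
  sb4 <- make_set(replicate(4, random_seq(500)), 2, "b")
  sb6 <- make_set(replicate(6, random_seq(500)), 2, "c")
  expect_error(detect_fusion(sa, sb6), "one more chromosome")
  sb_k3 <- make_set(replicate(4, random_seq(500)), 3, "d")
  expect_error(detect_fusion(sa, sb_k3), "word sizes")
  expect_error(pairing_loss(sa, sb4), "equal size")
})
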