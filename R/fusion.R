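# Fusion recognition proper. Two sets of chromosomes are given: A with n
# members (one of which is hypothesized to be a fused product) and B with
# n + 1. For every unordered pair (j1, j2) of B the pair is replaced by its
# algebraically fused candidate, giving a set B~ of size n, and the scenario
# is scored by the pairing loss
#   L(A, B~) = min over permutations p of
#              sum_i N(D1(a_i, b~_{p_i})) + N(D2(a_i, b~_{p_i}))
# where D1 is the cosine dissimilarity of k-mer natural vectors maximized
# over strand/orientation representations, D2 the absolute length
# difference, and N a row-wise min-max normalization that puts the two
# distances on a common [0, 1] scale. The minimum-loss scenario names the
# fused pair; its permutation gives the chromosome correspondence.

#' Build a chromosome set from sequence records
#'
#' Computes the k-mer natural vector of every record and bundles ids,
#' lengths and vectors into one object used by the detection functions.
#'
#' @param records List of `sequence_record`s (e.g. from [read_fasta_set]),
#'   or a named character vector of sequences.
#' @param k Word size shared by all members.
#' @param label Optional set label.
#' @param vectors Optional precomputed list of `kmer_nv`s (e.g. from
#'   [load_vectors]), one per record in the same order; checked for matching
#'   `k`.
#' @param workers Number of parallel workers for vector computation
#'   (see [compute_vectors]).
#' @return An object of class `chromosome_set`.
#' @export
chromosome_set <- function(records, k, label = "set", vectors = NULL,
                           workers = 1L) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) stop("a character vector of sequences must be named")
    records <- mapply(sequence_record, ids, records, SIMPLIFY = FALSE)
  }
  ids <- unname(vapply(records, function(r) r$id, character(1)))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record ids in set '%s': %s", label,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (is.null(vectors)) {
    vectors <- compute_vectors(records, k, workers = workers)
  } else {
    if (length(vectors) != length(records))
      stop("'vectors' must have one entry per record")
    kk <- vapply(vectors, function(v) v$k, integer(1))
    if (any(kk != k)) stop("precomputed vectors disagree with 'k'")
  }
  structure(list(ids = ids,
                 lengths = unname(vapply(records, function(r) r$length,
                                         numeric(1))),
                 vectors = vectors,
                 k = .check_k(k),
                 label = label),
            class = "chromosome_set")
}

#' @export
print.chromosome_set <- function(x, ...) {
  cat(sprintf("<chromosome_set> '%s': %d chromosomes, k=%d, %s-%s nt\n",
              x$label, length(x$ids), x$k,
              format(min(x$lengths), big.mark = ","),
              format(max(x$lengths), big.mark = ",")))
  invisible(x)
}

#' @export
length.chromosome_set <- function(x) length(x$ids)

# A candidate is one column of the cost matrix: a chromosome (2 strand
# variants) or a fused product (8 orientation variants). `forward` is the
# representative used when the candidate sits on the row side of a
# directed comparison.
.candidate <- function(id, variants, labels, length) {
  list(id = id, variants = variants, labels = labels, length = length)
}

#' Turn a chromosome set into assignment candidates
#'
#' Each member becomes a candidate carrying its forward and
#' reverse-complement vectors, so that downstream cosine comparisons take
#' the better strand (sequencing submissions do not fix strand orientation
#' between assemblies).
#'
#' @param set A `chromosome_set`.
#' @return An object of class `candidate_set`.
#' @export
as_candidate_set <- function(set) {
  stopifnot(inherits(set, "chromosome_set"))
  cands <- lapply(seq_along(set$ids), function(j) {
    v <- set$vectors[[j]]
    .candidate(set$ids[j], list(v, nv_reverse_complement(v)),
               c("+", "-"), set$lengths[j])
  })
  structure(list(candidates = cands, k = set$k, label = set$label),
            class = "candidate_set")
}

#' Replace a pair of chromosomes by their fused candidate
#'
#' Builds the candidate set B~ for one fusion scenario: members `j1` and
#' `j2` are removed and a single fused candidate (eight orientation
#' variants, summed length, id `"id1+id2"`) is inserted in front of the
#' remaining members (which keep their original order).
#'
#' @param set A `chromosome_set` (the larger set B).
#' @param j1,j2 Indices of the members hypothesized to have fused
#'   (`j1 < j2`).
#' @return A `candidate_set` of size `length(set) - 1`.
#' @export
fused_candidate_set <- function(set, j1, j2) {
  stopifnot(inherits(set, "chromosome_set"))
  n1 <- length(set$ids)
  if (!(j1 >= 1 && j2 <= n1 && j1 < j2))
    stop("need 1 <= j1 < j2 <= number of chromosomes")
  reps <- fusion_representations(set$vectors[[j1]], set$vectors[[j2]])
  fused <- .candidate(paste(set$ids[j1], set$ids[j2], sep = "+"),
                      reps$variants, reps$labels, reps$fused_length)
  rest <- setdiff(seq_len(n1), c(j1, j2))
  cands <- c(list(fused), lapply(as_candidate_set(set)$candidates[rest],
                                 identity))
  structure(list(candidates = cands, k = set$k,
                 label = paste0(set$label, "~[", set$ids[j1], "+",
                                set$ids[j2], "]")),
            class = "candidate_set")
}

#' Cosine dissimilarity against a family of strand/orientation variants
#'
#' `1 - max` cosine similarity between `a` and each variant: two variants
#' for a normal chromosome (forward and reverse strand), eight for a fused
#' candidate (all orientation readings, which already cover both strands —
#' no further reverse complement is applied on top). Non-negative vector
#' components bound the result to \[0, 1\].
#'
#' @param a A `kmer_nv`.
#' @param b_variants List of `kmer_nv` variants (or a
#'   `fusion_representations` object).
#' @return Distance in \[0, 1\]; attribute `"which"` records the index of
#'   the maximizing variant.
#' @export
d1_distance <- function(a, b_variants) {
  if (inherits(b_variants, "fusion_representations"))
    b_variants <- b_variants$variants
  cs <- vapply(b_variants, function(v) nv_cosine(a, v), numeric(1))
  w <- which.max(cs)
  structure(1 - cs[w], which = w)
}

#' Length-difference distance
#'
#' Absolute difference of nucleotide lengths; for a fused candidate the
#' length is the sum of its two segments, so a noiseless fusion has
#' distance zero to its product.
#'
#' @param len_a,len_b Non-negative nucleotide counts.
#' @return `abs(len_a - len_b)`.
#' @export
d2_distance <- function(len_a, len_b) {
  if (any(len_a < 0) || any(len_b < 0)) stop("lengths must be non-negative")
  abs(len_a - len_b)
}

#' Min-max normalization against a pool
#'
#' `(x - min(pool)) / (max(pool) - min(pool))`, mapping the pool onto
#' \[0, 1\] so that cosine dissimilarities (order 1e-6..1e-1) and length
#' differences (order 1e6 nt) can be summed on equal footing. A degenerate
#' pool (all values equal) normalizes to 0: a constant row carries no
#' ranking information and any constant preserves the argmin.
#'
#' @param x Value(s) to normalize (conventionally members of `pool`).
#' @param pool Non-empty numeric pool defining the scale.
#' @return Normalized value(s) in \[0, 1\].
#' @export
normalize_minmax <- function(x, pool = x) {
  if (!length(pool)) stop("'pool' must be non-empty")
  rng <- range(pool)
  if (rng[2] - rng[1] <= 0) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

.row_normalize <- function(mat) {
  t(apply(mat, 1L, function(r) normalize_minmax(r, r)))
}

# directed raw distance matrices: rows of `rows_cs` (their forward variant)
# against all variants of each column candidate.
.raw_distance_matrices <- function(row_vectors, row_lengths, col_cands) {
  nr <- length(row_vectors)
  nc <- length(col_cands)
  D1 <- matrix(0, nr, nc)
  W <- matrix(1L, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d <- d1_distance(row_vectors[[i]], col_cands[[j]]$variants)
      D1[i, j] <- d
      W[i, j] <- attr(d, "which")
    }
  }
  D2 <- outer(row_lengths,
              vapply(col_cands, function(cc) cc$length, numeric(1)),
              d2_distance)
  list(D1 = D1, D2 = D2, which = W)
}

#' Normalized pairing-cost matrix between a set and a candidate set
#'
#' The n x n matrix `c_ij = N(D1(a_i, b~_j) | row i) + N(D2(a_i, b~_j) |
#' row i)`: both distances are min-max normalized within their own row
#' before summation, so each entry lies in \[0, 2\].
#'
#' @param set_a A `chromosome_set` (rows).
#' @param candidates A `candidate_set` or `chromosome_set` (columns; a
#'   `chromosome_set` is converted with [as_candidate_set]).
#' @return Numeric matrix with row/column dimnames; attribute `"which"`
#'   holds the index of the maximizing variant per cell.
#' @export
normalized_cost_matrix <- function(set_a, candidates) {
  if (inherits(candidates, "chromosome_set"))
    candidates <- as_candidate_set(candidates)
  stopifnot(inherits(set_a, "chromosome_set"),
            inherits(candidates, "candidate_set"))
  if (set_a$k != candidates$k) stop("word sizes of the two sets differ")
  raw <- .raw_distance_matrices(set_a$vectors, set_a$lengths,
                                candidates$candidates)
  cost <- .row_normalize(raw$D1) + .row_normalize(raw$D2)
  dimnames(cost) <- list(set_a$ids,
                         vapply(candidates$candidates, function(cc) cc$id,
                                character(1)))
  attr(cost, "which") <- raw$which
  cost
}

#' Pairing loss between two equal-size chromosome sets
#'
#' Builds the row-normalized two-part cost matrix and solves the assignment
#' problem over it, returning the minimal total loss and the optimal
#' correspondence. Loss is bounded by `2 n` (each row contributes two
#' normalized terms in \[0, 1\]); identical sets attain loss 0.
#'
#' @inheritParams normalized_cost_matrix
#' @return List with `loss`, `permutation` (row i matched to column
#'   `permutation[i]`), `pairs` (data.frame of matched ids) and
#'   `cost_matrix`.
#' @export
pairing_loss <- function(set_a, candidates) {
  if (inherits(candidates, "chromosome_set"))
    candidates <- as_candidate_set(candidates)
  if (length(set_a$ids) != length(candidates$candidates))
    stop(sprintf("sets must have equal size (%d vs %d)",
                 length(set_a$ids), length(candidates$candidates)))
  cost <- normalized_cost_matrix(set_a, candidates)
  sol <- solve_assignment(unclass(cost))
  list(loss = sol$total_cost,
       permutation = sol$permutation,
       pairs = data.frame(a_id = rownames(cost),
                          b_id = colnames(cost)[sol$permutation],
                          stringsAsFactors = FALSE),
       cost_matrix = cost)
}

#' Enumerate candidate fusion scenarios
#'
#' All unordered pairs of the larger set: different fusion orders and
#' orientations collapse into the per-scenario orientation maximum, so only
#' `choose(n_plus_1, 2)` hypotheses need scoring (253 for 23 chromosomes).
#'
#' @param n_plus_1 Size of the larger chromosome set (>= 2).
#' @return Two-column integer matrix of pairs `(j1 < j2)`.
#' @export
enumerate_fusion_scenarios <- function(n_plus_1) {
  if (!is.numeric(n_plus_1) || length(n_plus_1) != 1L || is.na(n_plus_1) ||
      n_plus_1 < 2 || n_plus_1 != floor(n_plus_1))
    stop("'n_plus_1' must be an integer >= 2")
  t(utils::combn(as.integer(n_plus_1), 2L))
}

#' Detect the most likely chromosome fusion between two sets
#'
#' For every unordered pair of set B (the set with one more chromosome),
#' the pair is fused algebraically in all eight orientations, the pairing
#' loss of A against the resulting candidate set is computed, and scenarios
#' are ranked by loss. Raw cosine and length distances for all
#' (row, candidate) pairs are computed once up front; each scenario only
#' re-normalizes its own n x n sub-matrix and solves one assignment.
#'
#' @param set_a `chromosome_set` with n members (contains the fused
#'   product).
#' @param set_b `chromosome_set` with n + 1 members (contains the two
#'   pre-fusion chromosomes).
#' @return An object of class `fusion_report`: `ranked` (data.frame of all
#'   scenarios sorted by loss, ties broken by lexicographic pair),
#'   `best` (the minimum-loss scenario with its `pairs` correspondence and
#'   the orientation variant matched for the fused product), `gap`
#'   (sub-optimal minus optimal loss; small or zero gaps are flagged as
#'   unreliable), and `scenarios` (full per-scenario detail).
#' @export
detect_fusion <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "chromosome_set"), inherits(set_b, "chromosome_set"))
  n <- length(set_a$ids)
  n1 <- length(set_b$ids)
  if (n1 != n + 1L)
    stop(sprintf("set B must have exactly one more chromosome than set A (got %d vs %d)",
                 n1, n))
  if (set_a$k != set_b$k) stop("word sizes of the two sets differ")

  # precompute directed distances A rows x B columns (normal candidates)
  bc <- as_candidate_set(set_b)
  raw_n <- .raw_distance_matrices(set_a$vectors, set_a$lengths, bc$candidates)

  pairs <- enumerate_fusion_scenarios(n1)
  scen <- vector("list", nrow(pairs))
  for (s in seq_len(nrow(pairs))) {
    j1 <- pairs[s, 1L]; j2 <- pairs[s, 2L]
    reps <- fusion_representations(set_b$vectors[[j1]], set_b$vectors[[j2]])
    fused_id <- paste(set_b$ids[j1], set_b$ids[j2], sep = "+")
    cosm <- vapply(reps$variants,
                   function(v) vapply(set_a$vectors, nv_cosine, numeric(1), b = v),
                   numeric(n))
    cosm <- matrix(cosm, nrow = n)
    wbest <- max.col(cosm, ties.method = "first")
    d1f <- 1 - cosm[cbind(seq_len(n), wbest)]
    d2f <- d2_distance(set_a$lengths, reps$fused_length)
    rest <- setdiff(seq_len(n1), c(j1, j2))
    D1 <- cbind(d1f, raw_n$D1[, rest, drop = FALSE])
    D2 <- cbind(d2f, raw_n$D2[, rest, drop = FALSE])
    cost <- .row_normalize(D1) + .row_normalize(D2)
    col_ids <- c(fused_id, set_b$ids[rest])
    dimnames(cost) <- list(set_a$ids, col_ids)
    sol <- solve_assignment(cost)
    fused_row <- which(sol$permutation == 1L)
    scen[[s]] <- list(pair = c(j1, j2),
                      j1_id = set_b$ids[j1], j2_id = set_b$ids[j2],
                      loss = sol$total_cost,
                      permutation = sol$permutation,
                      pairs = data.frame(a_id = set_a$ids,
                                         b_id = col_ids[sol$permutation],
                                         stringsAsFactors = FALSE),
                      fused_a_id = set_a$ids[fused_row],
                      best_variant = reps$labels[wbest[fused_row]],
                      best_variant_per_row = reps$labels[wbest],
                      cost_matrix = cost)
  }

  losses <- vapply(scen, function(s) s$loss, numeric(1))
  ord <- order(losses, pairs[, 1L], pairs[, 2L])
  ranked <- data.frame(j1 = pairs[ord, 1L], j2 = pairs[ord, 2L],
                       j1_id = vapply(scen, function(s) s$j1_id, character(1))[ord],
                       j2_id = vapply(scen, function(s) s$j2_id, character(1))[ord],
                       loss = losses[ord],
                       rank = seq_along(ord),
                       stringsAsFactors = FALSE)
  gap <- if (nrow(ranked) >= 2L) ranked$loss[2L] - ranked$loss[1L] else NA_real_
  if (isTRUE(gap == 0))
    warning("optimal and sub-optimal scenarios have identical loss; the detection is unreliable")
  structure(list(ranked = ranked,
                 best = scen[[ord[1L]]],
                 gap = gap,
                 scenarios = scen[ord],
                 k = set_a$k,
                 n = n),
            class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, n_show = 5L, ...) {
  cat(sprintf("Chromosome fusion detection (k = %d, %d scenarios)\n",
              x$k, nrow(x$ranked)))
  cat(sprintf("Best scenario : %s + %s  (loss %.6g)\n",
              x$best$j1_id, x$best$j2_id, x$best$loss))
  cat(sprintf("Fused product : %s  (orientation %s)\n",
              x$best$fused_a_id, x$best$best_variant))
  if (!is.na(x$gap)) {
    cat(sprintf("Loss gap      : %.6g (optimal vs sub-optimal)\n", x$gap))
    others <- x$ranked$loss[-1L]
    if (length(others) >= 2L) {
      spread <- mean(diff(others))
      if (!is.na(spread) && (x$gap <= 0 || (spread > 0 && x$gap < 3 * spread)))
        cat("NOTE: the gap is small relative to the spread of non-optimal losses;\n",
            "      treat this identification as unreliable.\n", sep = "")
    }
  }
  cat("\nTop scenarios:\n")
  print(utils::head(x$ranked, n_show), row.names = FALSE)
  cat("\nCorrespondence under the best scenario:\n")
  print(x$best$pairs, row.names = FALSE)
  invisible(x)
}

#' Estimate the operation count of a detection run
#'
#' The method's cost decomposes into vector computation `O(n l)`, distance
#' evaluation over all pairs and fused candidates `O(n^3 4^k)`, and the
#' assignment solves over all scenarios `O(n^5)`. Useful for warning before
#' launching a large run.
#'
#' @param n Number of chromosomes per set.
#' @param l Typical chromosome length (nt).
#' @param k Word size.
#' @param warn_above Total above which a message is emitted.
#' @return Named numeric vector of the three terms plus their `total`.
#' @export
complexity_guard <- function(n, l, k, warn_above = 1e13) {
  if (any(c(n, l, k) <= 0)) stop("'n', 'l' and 'k' must be positive")
  terms <- c(vectors = n * l, distances = n^3 * 4^k, assignments = n^5)
  out <- c(terms, total = sum(terms))
  if (out["total"] > warn_above)
    message(sprintf(
      "estimated ~%.3g operations (vectors %.3g, distances %.3g, assignments %.3g); this run may be slow",
      out["total"], terms[1], terms[2], terms[3]))
  out
}
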