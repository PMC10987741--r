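# Synthetic chromosome sets with a planted fusion. The generator emulates
# the study design used to stress-test fusion recognition: draw n + 1
# independent random chromosomes (set B), fuse a random pair in a random
# order and strand orientation to produce one member of set A, carry the
# remaining chromosomes over as mutated copies (substitutions and
# single-base indels), optionally reverse-complement each set-A member, and
# record the full ground truth.

.restore_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

.BASES <- c("A", "C", "G", "T")

.codes_to_seq <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes + 1L])
}

.revcomp_seq <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Simulation configuration
#'
#' Bundles the study conditions of a synthetic fusion experiment. Defaults
#' are the desk-scale conditions used throughout the test-suite: 9
#' chromosomes in the larger set (n = 8 after fusion), 20-50 kb lengths,
#' 42% GC (typical mammalian composition), 0.5% substitutions and 0.05%
#' single-base insertions/deletions between the two sets, and a fair-coin
#' strand flip per set-A member.
#'
#' @param n_chromosomes Size of set B (the pre-fusion set), >= 2.
#' @param length_range Min/max chromosome length in nucleotides.
#' @param gc_content Fraction of G+C, in \[0, 1\].
#' @param substitution_rate,insertion_rate,deletion_rate Per-base event
#'   probabilities applied to every set-A member.
#' @param strand_flip_prob Probability that a set-A member is stored as its
#'   reverse complement.
#' @param seed Integer RNG seed; fixed seed gives byte-identical outputs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 9L,
                              length_range = c(20000L, 50000L),
                              gc_content = 0.42,
                              substitution_rate = 0.005,
                              insertion_rate = 0.0005,
                              deletion_rate = 0.0005,
                              strand_flip_prob = 0.5,
                              seed = 1L) {
  if (n_chromosomes < 2) stop("'n_chromosomes' must be at least 2")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2])
    stop("'length_range' must be increasing positive bounds")
  rates <- c(gc_content, substitution_rate, insertion_rate, deletion_rate,
             strand_flip_prob)
  if (any(rates < 0 | rates > 1))
    stop("gc_content, rates and strand_flip_prob must lie in [0, 1]")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 length_range = as.integer(length_range),
                 gc_content = gc_content,
                 substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 strand_flip_prob = strand_flip_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a random chromosome sequence
#'
#' i.i.d. bases with `P(G) = P(C) = gc_content / 2` and
#' `P(A) = P(T) = (1 - gc_content) / 2`. Draws from the current RNG
#' stream; seed at the caller for reproducibility.
#'
#' @param length Sequence length (>= 1).
#' @param gc_content Fraction of G+C in \[0, 1\].
#' @param id Record id.
#' @return A `sequence_record`.
#' @export
generate_chromosome <- function(length, gc_content = 0.42, id = "chr") {
  if (length < 1) stop("'length' must be at least 1")
  if (gc_content < 0 || gc_content > 1) stop("'gc_content' must be in [0, 1]")
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  codes <- sample.int(4L, length, replace = TRUE, prob = p) - 1L
  sequence_record(id, .codes_to_seq(codes))
}

#' Mutate a sequence with substitutions and single-base indels
#'
#' Each base is substituted (to a uniformly chosen different base) with
#' probability `sub_rate`, deleted with probability `del_rate`, and followed
#' by one random inserted base with probability `ins_rate`; events are
#' independent per base. Expected length drift is
#' `length * (ins_rate - del_rate)`.
#'
#' @param record A `sequence_record`.
#' @param sub_rate,ins_rate,del_rate Per-base probabilities in \[0, 1\].
#' @return A mutated `sequence_record` (same id).
#' @export
mutate_sequence <- function(record, sub_rate = 0, ins_rate = 0, del_rate = 0) {
  stopifnot(inherits(record, "sequence_record"))
  if (any(c(sub_rate, ins_rate, del_rate) < 0) ||
      any(c(sub_rate, ins_rate, del_rate) > 1))
    stop("rates must lie in [0, 1]")
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(record)
  codes <- .encode_bases(record$seq)
  n <- length(codes)
  sub <- stats::runif(n) < sub_rate
  if (any(sub))  # shift by 1..3 mod 4: always a different base
    codes[sub] <- (codes[sub] + sample.int(3L, sum(sub), replace = TRUE)) %% 4L
  keep <- stats::runif(n) >= del_rate
  ins <- stats::runif(n) < ins_rate
  emit <- rep.int(seq_len(n), keep + ins)
  first <- !duplicated(emit)
  orig_slot <- first & keep[emit]
  out <- integer(length(emit))
  out[orig_slot] <- codes[emit[orig_slot]]
  n_ins <- sum(!orig_slot)
  if (n_ins) out[!orig_slot] <- sample.int(4L, n_ins, replace = TRUE) - 1L
  if (!length(out)) stop("mutation deleted the whole sequence")
  sequence_record(record$id, .codes_to_seq(out))
}

#' Simulate a chromosome-fusion dataset with planted truth
#'
#' Draws `n + 1` random chromosomes (set B), fuses a random pair in random
#' order and strand orientation into one member of set A, passes every
#' set-A member (fused product included) through the mutation channel, and
#' reverse-complements each with `strand_flip_prob`. Set-A members are
#' shuffled so that the true correspondence is a non-trivial permutation.
#'
#' @param config A [simulation_config].
#' @param out_dir Optional directory; when given, writes `setA.fa`,
#'   `setB.fa` and `truth.json` there.
#' @return List with `set_a`, `set_b` (lists of `sequence_record`s) and
#'   `truth`: `fused_pair` (indices into B, j1 < j2), `fused_a_id`,
#'   `segment_order` (B index read first, 5' side), `segment_strands`,
#'   `correspondence` (data.frame a_id / b_id for non-fused members),
#'   `flip_mask` (named logical over set-A ids), `seed`.
#' @export
make_fusion_dataset <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  restore <- .restore_rng()
  on.exit(restore())
  set.seed(config$seed)

  nb <- config$n_chromosomes
  n <- nb - 1L
  lens <- sample(config$length_range[1]:config$length_range[2], nb,
                 replace = TRUE)
  set_b <- lapply(seq_len(nb), function(j)
    generate_chromosome(lens[j], config$gc_content,
                        id = sprintf("chrB_%02d", j)))

  pair <- sort(sample.int(nb, 2L))
  order_first <- sample(pair, 1L)                 # which segment reads 5'
  order_second <- setdiff(pair, order_first)
  strands <- sample(c("+", "-"), 2L, replace = TRUE)
  seg <- function(j, strand) {
    s <- set_b[[j]]$seq
    if (strand == "-") .revcomp_seq(s) else s
  }
  fused_seq <- paste0(seg(order_first, strands[1]), seg(order_second, strands[2]))

  rest <- setdiff(seq_len(nb), pair)
  a_source <- c(list(sequence_record("fused", fused_seq)),
                set_b[rest])                       # B index per A member:
  a_b_index <- c(NA_integer_, rest)                # NA marks the fused product

  shuffle <- sample.int(n)
  a_source <- a_source[shuffle]
  a_b_index <- a_b_index[shuffle]

  flip <- stats::runif(n) < config$strand_flip_prob
  set_a <- vector("list", n)
  for (i in seq_len(n)) {
    r <- mutate_sequence(a_source[[i]], config$substitution_rate,
                         config$insertion_rate, config$deletion_rate)
    s <- if (flip[i]) .revcomp_seq(r$seq) else r$seq
    set_a[[i]] <- sequence_record(sprintf("chrA_%02d", i), s)
  }
  a_ids <- vapply(set_a, function(r) r$id, character(1))

  non_fused <- which(!is.na(a_b_index))
  truth <- list(fused_pair = pair,
                fused_a_id = a_ids[which(is.na(a_b_index))],
                segment_order = c(order_first, order_second),
                segment_strands = strands,
                correspondence = data.frame(
                  a_id = a_ids[non_fused],
                  b_id = vapply(a_b_index[non_fused],
                                function(j) set_b[[j]]$id, character(1)),
                  stringsAsFactors = FALSE),
                flip_mask = stats::setNames(flip, a_ids),
                seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta_set(set_a, file.path(out_dir, "setA.fa"))
    write_fasta_set(set_b, file.path(out_dir, "setB.fa"))
    jsonlite::write_json(
      list(fused_pair = truth$fused_pair,
           fused_a_id = truth$fused_a_id,
           segment_order = truth$segment_order,
           segment_strands = truth$segment_strands,
           correspondence = truth$correspondence,
           flip_mask = as.list(truth$flip_mask),
           seed = truth$seed),
      file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(set_a = set_a, set_b = set_b, truth = truth)
}

#' Score a detection report against planted truth
#'
#' A dataset counts as recovered when the best scenario names the planted
#' pair; the correspondence additionally requires every non-fused set-A
#' member to be matched to its true set-B counterpart and the fused set-A
#' member to the fused candidate. Fusion orientation is deliberately not
#' scored: it is unidentifiable from the vector representation (all eight
#' readings describe the same molecule).
#'
#' @param report A `fusion_report` from [detect_fusion].
#' @param truth The `truth` component of [make_fusion_dataset]'s result.
#' @return List with logicals `pair_recovered`, `correspondence_recovered`
#'   and `true_rank` (position of the planted scenario in the ranking).
#' @export
score_against_truth <- function(report, truth) {
  stopifnot(inherits(report, "fusion_report"))
  best_pair <- sort(report$best$pair)
  pair_ok <- identical(as.integer(best_pair), as.integer(sort(truth$fused_pair)))
  pairs <- report$best$pairs
  fused_col <- paste(report$best$j1_id, report$best$j2_id, sep = "+")
  fused_ok <- isTRUE(pairs$b_id[pairs$a_id == truth$fused_a_id] == fused_col)
  tr <- truth$correspondence
  match_ok <- all(vapply(seq_len(nrow(tr)), function(i) {
    isTRUE(pairs$b_id[pairs$a_id == tr$a_id[i]] == tr$b_id[i])
  }, logical(1)))
  rk <- report$ranked
  true_rank <- rk$rank[rk$j1 == sort(truth$fused_pair)[1] &
                         rk$j2 == sort(truth$fused_pair)[2]]
  list(pair_recovered = pair_ok,
       correspondence_recovered = pair_ok && fused_ok && match_ok,
       true_rank = true_rank)
}
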