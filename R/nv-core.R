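# k-mer natural vectors: the alignment-free embedding at the heart of the
# fusion-recognition method, plus the concatenation / reverse-complement
# algebra that lets fused-chromosome vectors be derived without ever touching
# the raw fused sequence.
#
# A k-mer natural vector records, for every k-mer l present in a sequence of
# m = n - k + 1 overlapping k-mers:
#   n_l   occurrence count,
#   mu_l  mean 1-based position (in k-mer index units),
#   D2_l  second central moment of positions scaled by 1 / (n_l * m).
# Absent k-mers have n = mu = D2 = 0 by convention; storage is sparse
# (only k-mers with n_l > 0 are kept, sorted by k-mer code).

# base -> code lookup (A=0, C=1, G=2, T=3; everything else NA). A k-mer code
# is the base-4 number with the first base most significant, so sorting by
# code equals sorting k-mer strings alphabetically.
.BASE_LOOKUP <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut
})

.encode_bases <- function(seq) .BASE_LOOKUP[utf8ToInt(seq)]

#' Create a sequence record
#'
#' A minimal container for one chromosome-scale sequence: an identifier and
#' the nucleotide string (IUPAC alphabet; ambiguity codes are tolerated and
#' handled downstream by skipping k-mers that contain them).
#'
#' @param id Non-empty record label, unique within a set.
#' @param seq Nucleotide string; case-insensitive, stored uppercased.
#' @return An object of class `sequence_record` with fields `id`, `seq`,
#'   `length`.
#' @export
sequence_record <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a single non-empty string")
  if (!is.character(seq) || length(seq) != 1L)
    stop("'seq' must be a single string")
  seq <- toupper(seq)
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s: %s nt\n", x$id,
              format(x$length, big.mark = ",")))
  invisible(x)
}

.new_kmer_nv <- function(k, kmers, count, mean, moment, m, seq_length,
                         n_skipped = 0, id = NA_character_) {
  o <- order(kmers)
  structure(list(k = as.integer(k),
                 kmers = kmers[o],
                 count = as.numeric(count[o]),
                 mean = as.numeric(mean[o]),
                 moment = as.numeric(moment[o]),
                 m = as.numeric(m),
                 seq_length = as.numeric(seq_length),
                 n_skipped = as.numeric(n_skipped),
                 id = id),
            class = "kmer_nv")
}

#' Empty k-mer natural vector
#'
#' The identity element of the concatenation algebra: a vector with no k-mer
#' positions at all (`m = 0`, `seq_length = 0`).
#'
#' @param k Word size.
#' @return A `kmer_nv` with no entries.
#' @export
nv_empty <- function(k) {
  .check_k(k)
  .new_kmer_nv(k, numeric(0), numeric(0), numeric(0), numeric(0), 0, 0,
               id = "empty")
}

.check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k))
    stop("'k' must be a single positive integer")
  if (k > 15) stop("word sizes above k = 15 are not supported (4^k overflows)")
  invisible(as.integer(k))
}

#' Compute the k-mer natural vector of a sequence
#'
#' Scans the `m = length - k + 1` overlapping k-mers of a sequence and
#' records, per k-mer, the occurrence count, the mean 1-based position and the
#' scaled second central moment of positions (sum of squared deviations
#' divided by `count * m`). K-mers containing any non-ACGT character are
#' skipped, but position indices still advance over them so that mean
#' positions stay comparable across sequences; the number of skipped k-mer
#' positions is recorded in the result (`$n_skipped`).
#'
#' @param record A `sequence_record`, or a plain nucleotide string.
#' @param k Word size (k = 1 gives the classical natural vector over
#'   A, C, G, T).
#' @return A `kmer_nv` object: sparse, sorted-by-k-mer triplets of
#'   (count, mean, moment) plus `m` (number of k-mer positions),
#'   `seq_length`, and `n_skipped`.
#' @examples
#' v <- kmer_natural_vector("ACGTACGT", k = 2)
#' as.data.frame(v)
#' @export
kmer_natural_vector <- function(record, k) {
  k <- .check_k(k)
  if (is.character(record)) record <- sequence_record("sequence", record)
  if (!inherits(record, "sequence_record"))
    stop("'record' must be a sequence_record or a nucleotide string")
  n <- record$length
  if (n < k)
    stop(sprintf("sequence '%s' (%d nt) is shorter than k = %d",
                 record$id, n, k))
  codes <- .encode_bases(record$seq)
  m <- n - k + 1L
  idd <- numeric(m)
  ok <- rep(TRUE, m)
  for (j in 0:(k - 1L)) {
    seg <- codes[(1L + j):(m + j)]
    bad <- is.na(seg)
    if (any(bad)) {
      ok <- ok & !bad
      seg[bad] <- 0L
    }
    idd <- idd * 4 + seg
  }
  pos <- which(ok)
  if (length(pos) == 0L)
    stop(sprintf("sequence '%s' contains no valid k-mer at k = %d", record$id, k))
  ids <- idd[ok]
  agg <- rowsum(cbind(1, pos), group = ids)           # sorted by k-mer code
  uid <- as.numeric(rownames(agg))
  cnt <- agg[, 1L]
  mu <- agg[, 2L] / cnt
  dev2 <- (pos - mu[match(ids, uid)])^2
  ssq <- rowsum(dev2, group = ids)[, 1L]
  d2 <- ssq / (cnt * m)
  .new_kmer_nv(k, uid, cnt, mu, d2, m, n,
               n_skipped = m - length(pos), id = record$id)
}

#' Concatenate two k-mer natural vectors algebraically
#'
#' Produces the vector of the fused sequence `S1 + S2` from the vectors of
#' its parts: counts add; means combine as the count-weighted mean with the
#' second block's positions offset by the first block's k-mer position count;
#' scaled moments combine through the parallel-axis decomposition of the raw
#' sums of squared deviations. Exact for `k = 1`; for `k > 1` the `k - 1`
#' k-mers spanning the junction are omitted, a negligible approximation for
#' chromosome-scale inputs.
#'
#' @param first,second `kmer_nv` objects with identical `k`.
#' @return A `kmer_nv` for the concatenation; `m` and `seq_length` add.
#' @export
nv_concat <- function(first, second) {
  if (!inherits(first, "kmer_nv") || !inherits(second, "kmer_nv"))
    stop("both arguments must be kmer_nv objects")
  if (first$k != second$k)
    stop(sprintf("word sizes differ (%d vs %d)", first$k, second$k))
  N1 <- first$m; N2 <- second$m
  if (N2 == 0) return(first)
  if (N1 == 0) return(second)
  uid <- sort(unique(c(first$kmers, second$kmers)))
  i1 <- match(uid, first$kmers)
  i2 <- match(uid, second$kmers)
  n1 <- ifelse(is.na(i1), 0, first$count[i1])
  n2 <- ifelse(is.na(i2), 0, second$count[i2])
  mu1 <- ifelse(is.na(i1), 0, first$mean[i1])
  mu2 <- ifelse(is.na(i2), 0, second$mean[i2])
  d1 <- ifelse(is.na(i1), 0, first$moment[i1])
  d2 <- ifelse(is.na(i2), 0, second$moment[i2])
  n3 <- n1 + n2
  mu3 <- (n1 * mu1 + n2 * (mu2 + N1)) / n3
  # raw sums of squared deviations, then re-scale by the fused n * m
  s3 <- n1 * N1 * d1 + n2 * N2 * d2 +
    n1 * (mu1 - mu3)^2 + n2 * (mu2 + N1 - mu3)^2
  d3 <- s3 / (n3 * (N1 + N2))
  id <- if (!is.na(first$id) && !is.na(second$id))
    paste(first$id, second$id, sep = "+") else NA_character_
  .new_kmer_nv(first$k, uid, n3, mu3, d3, N1 + N2,
               first$seq_length + second$seq_length,
               n_skipped = first$n_skipped + second$n_skipped, id = id)
}

# reverse-complement a vector of k-mer codes: complement each base digit
# (d -> 3 - d) and reverse digit order.
.rc_codes <- function(ids, k) {
  r <- numeric(length(ids))
  x <- ids
  for (j in seq_len(k)) {
    d <- x %% 4
    x <- (x - d) / 4
    r <- r * 4 + (3 - d)
  }
  r
}

#' Reverse-complement a k-mer natural vector
#'
#' Maps every k-mer's statistics onto its reverse-complement k-mer and flips
#' mean positions to the opposite strand (`mu' = m + 1 - mu`; the k-mer at
#' position i reads at position m + 1 - i on the reverse strand). Counts and
#' scaled moments carry over unchanged. The transform is an involution. The
#' absent-k-mer convention (mean = moment = 0) is preserved automatically by
#' the sparse storage.
#'
#' @param v A `kmer_nv`.
#' @return The `kmer_nv` of the reverse strand.
#' @export
nv_reverse_complement <- function(v) {
  if (!inherits(v, "kmer_nv")) stop("'v' must be a kmer_nv object")
  if (length(v$kmers) == 0L) return(v)
  .new_kmer_nv(v$k, .rc_codes(v$kmers, v$k), v$count, v$m + 1 - v$mean,
               v$moment, v$m, v$seq_length, n_skipped = v$n_skipped,
               id = if (is.na(v$id)) NA_character_ else paste0("rc(", v$id, ")"))
}

#' All eight vector representations of a two-segment fusion
#'
#' A fusion of two double-stranded segments can read, 5' to 3', as either
#' segment first and with either strand of each segment: 2! orders times 2^2
#' strand choices = 8 representations. All eight are derived algebraically
#' with [nv_concat] and [nv_reverse_complement]; the set is closed under
#' reverse complement (four strand pairs).
#'
#' @param a,b `kmer_nv` objects of the two segments (same `k`).
#' @return An object of class `fusion_representations`: list with `variants`
#'   (8 `kmer_nv`s), `labels` (segment order and strands, e.g. `"a+|b+"`),
#'   and `fused_length` (sum of the two nucleotide lengths).
#' @export
fusion_representations <- function(a, b) {
  if (!inherits(a, "kmer_nv") || !inherits(b, "kmer_nv"))
    stop("both arguments must be kmer_nv objects")
  if (a$k != b$k) stop(sprintf("word sizes differ (%d vs %d)", a$k, b$k))
  ra <- nv_reverse_complement(a)
  rb <- nv_reverse_complement(b)
  variants <- list(nv_concat(a, b), nv_concat(a, rb),
                   nv_concat(ra, b), nv_concat(ra, rb),
                   nv_concat(b, a), nv_concat(b, ra),
                   nv_concat(rb, a), nv_concat(rb, ra))
  # label encodes 5'->3' reading: "x+|y-" means segment x forward then
  # segment y reverse-complemented.
  labels <- c("a+|b+", "a+|b-", "a-|b+", "a-|b-",
              "b+|a+", "b+|a-", "b-|a+", "b-|a-")
  structure(list(variants = variants, labels = labels,
                 fused_length = a$seq_length + b$seq_length),
            class = "fusion_representations")
}

#' Number of fusion representations for a given segment count
#'
#' With `s` double-stranded segments there are `s! * 2^s` distinct readings
#' of the fused product (orderings times per-segment strand choices); two
#' segments give 8, a single segment gives its 2 strands.
#'
#' @param num_segments Positive integer.
#' @return `num_segments! * 2^num_segments`.
#' @export
representation_count <- function(num_segments) {
  if (!is.numeric(num_segments) || length(num_segments) != 1L ||
      is.na(num_segments) || num_segments < 1 ||
      num_segments != floor(num_segments))
    stop("'num_segments' must be a single positive integer")
  factorial(num_segments) * 2^num_segments
}

#' Cosine similarity of two k-mer natural vectors
#'
#' The cosine of the angle between the full 3*4^k-dimensional embeddings
#' (counts, means, moments concatenated); absent k-mers contribute zero by
#' convention. All components are non-negative, so the cosine lies in
#' \[0, 1\].
#'
#' @param a,b `kmer_nv` objects with identical `k`.
#' @return Cosine similarity in \[0, 1\].
#' @export
nv_cosine <- function(a, b) {
  if (a$k != b$k) stop(sprintf("word sizes differ (%d vs %d)", a$k, b$k))
  na2 <- sum(a$count^2) + sum(a$mean^2) + sum(a$moment^2)
  nb2 <- sum(b$count^2) + sum(b$mean^2) + sum(b$moment^2)
  if (na2 == 0 || nb2 == 0)
    stop("cannot take the cosine of a zero-norm natural vector")
  i <- match(a$kmers, b$kmers)
  hit <- !is.na(i)
  j <- i[hit]
  dot <- sum(a$count[hit] * b$count[j]) +
    sum(a$mean[hit] * b$mean[j]) +
    sum(a$moment[hit] * b$moment[j])
  min(1, dot / sqrt(na2 * nb2))
}

# k-mer code -> string, vectorized
.code_to_kmer <- function(ids, k) {
  letters4 <- c("A", "C", "G", "T")
  out <- matrix("", nrow = length(ids), ncol = k)
  x <- ids
  for (j in k:1) {
    d <- x %% 4
    x <- (x - d) / 4
    out[, j] <- letters4[d + 1]
  }
  apply(out, 1L, paste0, collapse = "")
}

.kmer_to_code <- function(kmers) {
  vapply(kmers, function(s) {
    d <- .BASE_LOOKUP[utf8ToInt(s)]
    if (anyNA(d)) stop(sprintf("invalid k-mer string '%s'", s))
    sum(d * 4^(rev(seq_along(d)) - 1))
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
as.data.frame.kmer_nv <- function(x, ...) {
  data.frame(kmer = if (length(x$kmers)) .code_to_kmer(x$kmers, x$k) else character(0),
             count = x$count, mean = x$mean, moment = x$moment,
             stringsAsFactors = FALSE)
}

#' @export
print.kmer_nv <- function(x, ...) {
  cat(sprintf("<kmer_nv> %s  k=%d  %d/%s k-mers populated  m=%s  length=%s nt",
              if (is.na(x$id)) "" else x$id, x$k, length(x$kmers),
              format(4^x$k, big.mark = ","),
              format(x$m, big.mark = ","),
              format(x$seq_length, big.mark = ",")))
  if (x$n_skipped > 0)
    cat(sprintf("  (%.3g%% k-mer positions skipped)", 100 * x$n_skipped / x$m))
  cat("\n")
  invisible(x)
}

#' @method all.equal kmer_nv
#' @export
all.equal.kmer_nv <- function(target, current, tolerance = 1e-9, ...) {
  if (!inherits(current, "kmer_nv")) return("'current' is not a kmer_nv")
  msgs <- character(0)
  if (target$k != current$k) msgs <- c(msgs, "k differs")
  if (!isTRUE(all.equal(target$kmers, current$kmers)))
    msgs <- c(msgs, "k-mer support differs")
  else {
    for (f in c("count", "mean", "moment")) {
      ae <- all.equal(target[[f]], current[[f]], tolerance = tolerance)
      if (!isTRUE(ae)) msgs <- c(msgs, paste0(f, ": ", ae))
    }
  }
  if (!isTRUE(all.equal(target$m, current$m))) msgs <- c(msgs, "m differs")
  if (length(msgs)) msgs else TRUE
}
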