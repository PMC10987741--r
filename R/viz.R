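# Visualisation-support layer: the exported artefacts are numbers (TSV
# matrices and 2-D coordinates), not figures — plots are cosmetic and
# optional. Cross-set pairing-loss grids feed heatmaps; symmetrized
# within-set distances feed a metric multidimensional scaling of
# chromosomes onto the plane.

#' Cross-set pairing-loss grid (heatmap input)
#'
#' The row-normalized two-part cost matrix of set A against a candidate set
#' (typically B~ under the detected fusion): entries in \[0, 2\], each row
#' containing at least one exact 0 at its row minimum.
#'
#' @inheritParams normalized_cost_matrix
#' @return Numeric matrix with id dimnames (attribute `"which"` stripped).
#' @export
cross_set_loss_matrix <- function(set_a, candidates) {
  if (inherits(candidates, "chromosome_set"))
    candidates <- as_candidate_set(candidates)
  if (length(set_a$ids) != length(candidates$candidates))
    stop(sprintf("sets must have equal size (%d vs %d)",
                 length(set_a$ids), length(candidates$candidates)))
  m <- normalized_cost_matrix(set_a, candidates)
  attr(m, "which") <- NULL
  m
}

#' Construct a distance table
#'
#' @param values Symmetric non-negative matrix with zero diagonal.
#' @param labels Row/column labels (defaults to `rownames(values)`).
#' @return Object of class `distance_table` with fields `labels`, `values`.
#' @export
distance_table <- function(values, labels = rownames(values)) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("'values' must be a square matrix")
  if (any(values < 0)) stop("distances must be non-negative")
  if (max(abs(values - t(values))) > 1e-8) stop("'values' must be symmetric")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal must be zero")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values), class = "distance_table")
}

#' Symmetrized within-set chromosome distances
#'
#' Applies the normalized two-part distance with the set playing both roles
#' (rows and candidate columns), then symmetrizes the directed matrix as
#' `(M + t(M)) / 2` and zeroes the diagonal. Row-wise normalization makes
#' the directed matrix asymmetric; the arithmetic mean is the canonical
#' symmetrization and preserves zero self-distance.
#'
#' @param set A non-empty `chromosome_set`.
#' @return A `distance_table`.
#' @export
within_set_distances <- function(set) {
  stopifnot(inherits(set, "chromosome_set"))
  m <- cross_set_loss_matrix(set, as_candidate_set(set))
  sym <- (m + t(m)) / 2
  diag(sym) <- 0
  distance_table(sym, set$ids)
}

#' Combined distance table across two matched sets
#'
#' Stacks within-set distances of A and of the candidate set B~ on the
#' diagonal blocks and the symmetrized cross-set normalized costs on the
#' off-diagonal blocks, giving one table over all chromosomes of both
#' groups suitable for a joint embedding.
#'
#' @param set_a `chromosome_set` (n members).
#' @param set_b_tilde `chromosome_set` of the same size (e.g. built from
#'   the fused candidate sequences), used for the second block.
#' @return A `distance_table` over `2 n` labels.
#' @export
combined_distance_table <- function(set_a, set_b_tilde) {
  stopifnot(inherits(set_a, "chromosome_set"),
            inherits(set_b_tilde, "chromosome_set"))
  wa <- within_set_distances(set_a)$values
  wb <- within_set_distances(set_b_tilde)$values
  mab <- cross_set_loss_matrix(set_a, set_b_tilde)
  mba <- cross_set_loss_matrix(set_b_tilde, set_a)
  cross <- (mab + t(mba)) / 2
  top <- cbind(wa, cross)
  bottom <- cbind(t(cross), wb)
  distance_table(rbind(top, bottom), c(set_a$ids, set_b_tilde$ids))
}

#' Metric multidimensional scaling onto the plane
#'
#' Finds coordinates `x_1..x_n` in 2-D approximately minimizing the raw
#' stress `sum over i != j of (d_ij - |x_i - x_j|)^2` by SMACOF
#' majorization (iterated Guttman transform), whose stress is
#' non-increasing by construction. Several seeded random starts are run
#' and the lowest-stress solution kept; the embedding is arbitrary up to
#' rotation, reflection and translation.
#'
#' @param table A `distance_table` (or a symmetric matrix).
#' @param seed RNG seed for the random starts.
#' @param n_starts Number of random restarts.
#' @param max_iter Iteration cap per start.
#' @param tol Relative stress-change convergence threshold.
#' @return Object of class `embedding2d`: `labels`, `coordinates`
#'   (n x 2 matrix), `stress` (final raw stress), `stress_trace`
#'   (per-iteration stress of the winning start), `n_iter`.
#' @export
mds_embed <- function(table, seed = 1L, n_starts = 4L, max_iter = 1000L,
                      tol = 1e-9) {
  if (is.matrix(table)) table <- distance_table(table)
  stopifnot(inherits(table, "distance_table"))
  d <- table$values
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 items to embed")
  restore <- .restore_rng()
  on.exit(restore())
  set.seed(seed)
  scale0 <- max(d, 1e-12)

  run_start <- function() {
    X <- matrix(stats::runif(n * 2L, -scale0, scale0), n, 2L)
    trace <- numeric(0)
    f_prev <- Inf
    for (it in seq_len(max_iter)) {
      E <- as.matrix(stats::dist(X))
      f <- sum((d - E)^2)
      trace <- c(trace, f)
      if (is.finite(f_prev) && (f_prev - f) <= tol * max(f_prev, 1e-300)) break
      f_prev <- f
      ratio <- ifelse(E > 0, d / E, 0)
      diag(ratio) <- 0
      B <- -ratio
      diag(B) <- rowSums(ratio)
      X <- (B %*% X) / n
    }
    list(X = X, trace = trace)
  }

  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    r <- run_start()
    if (is.null(best) || utils::tail(r$trace, 1) < utils::tail(best$trace, 1))
      best <- r
  }
  coords <- best$X
  dimnames(coords) <- list(table$labels, c("x", "y"))
  structure(list(labels = table$labels,
                 coordinates = coords,
                 stress = utils::tail(best$trace, 1),
                 stress_trace = best$trace,
                 n_iter = length(best$trace)),
            class = "embedding2d")
}

#' @export
print.embedding2d <- function(x, ...) {
  cat(sprintf("<embedding2d> %d points, stress %.6g after %d iterations\n",
              length(x$labels), x$stress, x$n_iter))
  invisible(x)
}

#' Write a labelled matrix as TSV
#'
#' Header row holds column labels; first column holds row labels.
#'
#' @param mat Matrix with dimnames (or a `distance_table`).
#' @param path Output file.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (inherits(mat, "distance_table")) mat <- mat$values
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write 2-D embedding coordinates as TSV
#'
#' @param emb An `embedding2d`.
#' @param path Output file.
#' @export
write_embedding_tsv <- function(emb, path) {
  stopifnot(inherits(emb, "embedding2d"))
  df <- data.frame(id = emb$labels, x = emb$coordinates[, 1],
                   y = emb$coordinates[, 2], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
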