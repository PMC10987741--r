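# Square assignment problem: find the permutation p minimizing
# sum_i m[i, p_i]. Solved with the Kuhn-Munkres (Hungarian) method in its
# O(n^3) shortest-augmenting-path form with dual potentials; an exhaustive
# enumeration oracle is provided for testing. Chromosome sets keep n below
# ~25, so raw speed is irrelevant and correctness plus determinism are the
# whole contract.

.check_cost_matrix <- function(costs) {
  if (!is.matrix(costs) || !is.numeric(costs))
    stop("'costs' must be a numeric matrix")
  if (nrow(costs) != ncol(costs))
    stop(sprintf("cost matrix must be square (got %d x %d)",
                 nrow(costs), ncol(costs)))
  if (nrow(costs) == 0L) stop("cost matrix must be non-empty")
  if (any(!is.finite(costs))) stop("cost matrix entries must all be finite")
  invisible(costs)
}

# core Hungarian solver (Jonker-Volgenant style augmenting paths).
# Index shift: column 0 is the virtual start column, stored at position 1.
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j+1]: row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      free_j <- which(!used[-1L])
      if (length(free_j)) {
        cur <- cost[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
        upd <- cur < minv[free_j + 1L]
        if (any(upd)) {
          minv[free_j[upd] + 1L] <- cur[upd]
          way[free_j[upd] + 1L] <- j0
        }
        best <- which.min(minv[free_j + 1L])
        delta <- minv[free_j[best] + 1L]
        j1 <- free_j[best]
      }
      usedi <- which(used)
      u[p[usedi] + 1L] <- u[p[usedi] + 1L] + delta
      v[usedi] <- v[usedi] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  perm[p[-1L]] <- seq_len(n)
  perm
}

#' Solve the assignment problem exactly
#'
#' Finds a permutation `p` minimizing `sum(costs[cbind(1:n, p)])` with the
#' Kuhn-Munkres (Hungarian) method. Among equally optimal permutations the
#' lexicographically smallest is returned (resolved by re-solving reduced
#' problems row by row), which makes results deterministic and
#' regression-friendly.
#'
#' @param costs Square numeric matrix of finite pairing losses.
#' @param tie_break `"lexicographic"` (default) or `"first"` (whatever
#'   permutation the solver lands on; cheaper, still deterministic for a
#'   given matrix).
#' @return A list with `permutation` (row i is assigned column
#'   `permutation[i]`) and `total_cost`.
#' @examples
#' solve_assignment(matrix(c(1, 3, 2, 1), 2, 2))
#' @export
solve_assignment <- function(costs, tie_break = c("lexicographic", "first")) {
  .check_cost_matrix(costs)
  tie_break <- match.arg(tie_break)
  n <- nrow(costs)
  perm <- .hungarian(costs)
  total <- sum(costs[cbind(seq_len(n), perm)])
  if (tie_break == "lexicographic" && n > 1L) {
    tol <- 1e-9 * (1 + abs(total))
    cols_left <- seq_len(n)
    fixed <- integer(n)
    remaining <- total
    for (i in seq_len(n)) {
      rows_rest <- if (i < n) (i + 1L):n else integer(0)
      for (cc in cols_left) {
        rest_cost <- if (length(rows_rest)) {
          sub <- costs[rows_rest, setdiff(cols_left, cc), drop = FALSE]
          sp <- .hungarian(sub)
          sum(sub[cbind(seq_along(rows_rest), sp)])
        } else 0
        if (costs[i, cc] + rest_cost <= remaining + tol) {
          fixed[i] <- cc
          cols_left <- setdiff(cols_left, cc)
          remaining <- remaining - costs[i, cc]
          break
        }
      }
    }
    perm <- fixed
    total <- sum(costs[cbind(seq_len(n), perm)])
  }
  list(permutation = perm, total_cost = total)
}

#' Exhaustive assignment oracle
#'
#' Enumerates all `n!` permutations in lexicographic order and returns the
#' first one attaining the minimum total cost (hence the lexicographically
#' smallest optimum, matching [solve_assignment]'s tie-break). Guarded to
#' `n <= 9`.
#'
#' @inheritParams solve_assignment
#' @return A list with `permutation` and `total_cost`.
#' @export
brute_force_assignment <- function(costs) {
  .check_cost_matrix(costs)
  n <- nrow(costs)
  if (n > 9L)
    stop(sprintf("refusing exhaustive enumeration for n = %d (limit 9)", n))
  best_cost <- Inf
  best_perm <- integer(n)
  perm <- integer(n)
  used <- rep(FALSE, n)
  rec <- function(i, acc) {
    if (acc > best_cost) return()       # later ties can't beat the first optimum
    if (i > n) {
      if (acc < best_cost) {
        best_cost <<- acc
        best_perm <<- perm
      }
      return()
    }
    for (cc in seq_len(n)) {
      if (!used[cc]) {
        used[cc] <<- TRUE
        perm[i] <<- cc
        rec(i + 1L, acc + costs[i, cc])
        used[cc] <<- FALSE
      }
    }
  }
  rec(1L, 0)
  list(permutation = best_perm, total_cost = best_cost)
}
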