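#' Pairwise cost (distance) matrix
#'
#' Absolute differences between every learner sample and every expert sample:
#' `entry[j, i] = |u[j] - v[i]|`. Rows index the learner (`u`), columns the
#' expert (`v`). Small entries mark sample pairs that agree; a warping path
#' threads the matrix through its cheap cells.
#'
#' @param v expert window (numeric or [magnitude_series()]).
#' @param u learner window, same length.
#' @return A numeric matrix of class `cost_matrix` with dimensions
#'   `length(u) x length(v)`.
#' @export
cost_matrix <- function(v, u) {
  v <- as.numeric(v); u <- as.numeric(u)
  if (length(v) != length(u)) {
    stop("cost_matrix needs equal-length windows", call. = FALSE)
  }
  m <- abs(outer(u, v, "-"))
  class(m) <- c("cost_matrix", class(m))
  m
}

new_warp_path <- function(i, j, method, total_cost) {
  structure(list(points = cbind(i = as.integer(i), j = as.integer(j)),
                 method = method, total_cost = total_cost),
            class = "warp_path")
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf("<warp_path> %s, %d points, total cost %g\n",
              x$method, nrow(x$points), x$total_cost))
  invisible(x)
}

#' Greedy adjacent-side warping path
#'
#' Walks the cost matrix from cell (1, 1) to (n, n). At each step the walker
#' inspects the three forward neighbours — right `(i+1, j)`, diagonal
#' `(i+1, j+1)` and up `(i, j+1)` — and moves to whichever has the smallest
#' local cost; ties prefer the diagonal, then right, then up, and at the
#' matrix border the candidate set shrinks to the feasible moves. This local
#' rule is the pipeline's default path method; it is not guaranteed to be
#' globally optimal (see [dp_path()]).
#'
#' @param cm a square [cost_matrix()].
#' @return A `warp_path`: 1-based `(i, j)` points, `method = "greedy"`, and
#'   the summed cost of the visited cells.
#' @export
greedy_path <- function(cm) {
  n <- ncol(cm)
  stopifnot(nrow(cm) == n, n >= 1L)
  # worst case 2n - 1 steps
  ii <- integer(2L * n); jj <- integer(2L * n)
  i <- 1L; j <- 1L; s <- 1L
  ii[1L] <- 1L; jj[1L] <- 1L
  total <- cm[1L, 1L]
  while (i < n || j < n) {
    # candidates in tie-preference order: diagonal, right, up
    ci <- integer(0); cj <- integer(0)
    if (i < n && j < n) { ci <- c(ci, i + 1L); cj <- c(cj, j + 1L) }
    if (i < n)          { ci <- c(ci, i + 1L); cj <- c(cj, j) }
    if (j < n)          { ci <- c(ci, i);      cj <- c(cj, j + 1L) }
    costs <- cm[cbind(cj, ci)]
    b <- which.min(costs)                 # first minimum = preferred tie
    i <- ci[b]; j <- cj[b]
    s <- s + 1L
    ii[s] <- i; jj[s] <- j
    total <- total + cm[j, i]
  }
  new_warp_path(ii[seq_len(s)], jj[seq_len(s)], "greedy", total)
}

#' Optimal warping path by dynamic programming
#'
#' Classical dynamic-time-warping recurrence over the same step set as the
#' greedy walker (right, up, diagonal; endpoints (1, 1) and (n, n)): the
#' accumulated cost `D[j, i] = cm[j, i] + min(D[j-1, i-1], D[j, i-1],
#' D[j-1, i])` is filled and the path read back, preferring the diagonal on
#' backtracking ties. Its total cost is a lower bound on the greedy path's and
#' serves as the optimality oracle in the test suite; it is also available as
#' an alternative path method.
#'
#' @param cm a square [cost_matrix()].
#' @return A `warp_path` with `method = "dp"` and the globally minimal total
#'   cost.
#' @export
dp_path <- function(cm) {
  n <- ncol(cm)
  stopifnot(nrow(cm) == n, n >= 1L)
  D <- matrix(Inf, n, n)
  D[1L, 1L] <- cm[1L, 1L]
  if (n > 1L) {
    for (i in 2L:n) D[1L, i] <- D[1L, i - 1L] + cm[1L, i]
    for (j in 2L:n) D[j, 1L] <- D[j - 1L, 1L] + cm[j, 1L]
    for (j in 2L:n) {
      Dprev <- D[j - 1L, ]
      row <- numeric(n); row[1L] <- D[j, 1L]
      cmj <- cm[j, ]
      for (i in 2L:n) {
        row[i] <- cmj[i] + min(Dprev[i - 1L], row[i - 1L], Dprev[i])
      }
      D[j, ] <- row
    }
  }
  # backtrack from (n, n); predecessor preference: diagonal, right, up
  i <- n; j <- n
  ri <- integer(2L * n); rj <- integer(2L * n); s <- 1L
  ri[1L] <- n; rj[1L] <- n
  while (i > 1L || j > 1L) {
    if (i > 1L && j > 1L) {
      d <- D[j - 1L, i - 1L]; r <- D[j, i - 1L]; u <- D[j - 1L, i]
      if (d <= r && d <= u)      { i <- i - 1L; j <- j - 1L }
      else if (r <= u)           { i <- i - 1L }
      else                       { j <- j - 1L }
    } else if (i > 1L)           { i <- i - 1L }
    else                         { j <- j - 1L }
    s <- s + 1L
    ri[s] <- i; rj[s] <- j
  }
  idx <- s:1L
  new_warp_path(ri[idx], rj[idx], "dp", D[n, n])
}

#' Extract a warping path with the chosen method
#'
#' @param cm a square [cost_matrix()].
#' @param method `"greedy"` (the pipeline default) or `"dp"`.
#' @return A `warp_path`.
#' @export
warp_path <- function(cm, method = c("greedy", "dp")) {
  method <- match.arg(method)
  if (method == "greedy") greedy_path(cm) else dp_path(cm)
}

#' Write a warping path as a two-column CSV
#'
#' Columns `i` (expert index) and `j` (learner index), 1-based, for plotting
#' or external regression.
#'
#' @param path a `warp_path`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_path_csv <- function(path, file) {
  stopifnot(inherits(path, "warp_path"))
  utils::write.csv(as.data.frame(path$points), file, row.names = FALSE)
  invisible(file)
}
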