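#' Enumerate all k-input Boolean functions of a class
#'
#' Lists, without duplicates, every truth table on exactly `k` effective
#' inputs belonging to the requested class:
#' \describe{
#'   \item{ALL}{every function, including constants and functions with
#'     ineffective inputs.}
#'   \item{EF}{effective functions: every input matters somewhere.}
#'   \item{UF / EUF}{unate (monotone per input) functions; EUF additionally
#'     requires effectiveness in every input.}
#'   \item{CF}{canalyzing (and effective) functions: some input at some value
#'     forces the output.}
#'   \item{NCF}{nested canalyzing functions.}
#'   \item{RoF}{read-once functions: expressible with AND/OR/NOT using each
#'     input exactly once.}
#' }
#' NCFs at `k = 4` and RoFs are generated constructively (layer structures,
#' resp. recursive AND/OR composition over signed literals with memoization
#' over variable subsets); other classes filter the full table space, which
#' bounds `k` at 4.
#'
#' @param k input count (`<= 4`).
#' @param label one of `"ALL"`, `"EF"`, `"UF"`, `"EUF"`, `"CF"`, `"NCF"`,
#'   `"RoF"`.
#' @param labels optional input names applied to every returned table.
#' @return list of [truth_table]s.
#' @examples
#' length(enumerate_class(2, "NCF"))   # 8
#' @export
enumerate_class <- function(k, label = c("ALL", "EF", "UF", "EUF", "CF",
                                         "NCF", "RoF"),
                            labels = NULL) {
  label <- match.arg(label)
  if (k > 4L) stop("enumeration supported for k <= 4; use the class tests ",
                   "(effectiveness, input_signs, is_ncf) above that")
  if (k < 1L) stop("k must be >= 1")
  mat <- switch(label,
                ALL = all_tables_matrix(k),
                EF = ef_matrix(k),
                UF = uf_matrix(k, effective = FALSE),
                EUF = uf_matrix(k, effective = TRUE),
                CF = cf_matrix(k),
                NCF = ncf_matrix(k),
                RoF = rof_matrix(k))
  lapply(seq_len(ncol(mat)), function(i) truth_table(mat[, i], labels))
}

# 2^k x 2^(2^k) matrix; column t is table with encoding integer t-1
# (row 0 = least-significant bit).
all_tables_matrix <- function(k) {
  n <- 2^k
  t <- 0:(2^n - 1)
  vapply(0:(n - 1L), function(r) as.integer((t %/% 2^r) %% 2), integer(2^n)) |>
    t()
}

# logical vector over columns of m: input j effective
col_effective <- function(m, k, j) {
  idx <- bitwXor(0:(2^k - 1L), 2^(k - j)) + 1L
  colSums(m != m[idx, , drop = FALSE]) > 0L
}

ef_matrix <- function(k) {
  m <- all_tables_matrix(k)
  keep <- rep(TRUE, ncol(m))
  for (j in seq_len(k)) keep <- keep & col_effective(m, k, j)
  m[, keep, drop = FALSE]
}

uf_matrix <- function(k, effective) {
  m <- all_tables_matrix(k)
  keep <- rep(TRUE, ncol(m))
  r <- 0:(2^k - 1L)
  for (j in seq_len(k)) {
    b <- 2^(k - j)
    low <- r[bitwAnd(r, b) == 0L] + 1L
    d <- m[low + b, , drop = FALSE] - m[low, , drop = FALSE]
    dual <- (colSums(d > 0L) > 0L) & (colSums(d < 0L) > 0L)
    keep <- keep & !dual
    if (effective) keep <- keep & col_effective(m, k, j)
  }
  m[, keep, drop = FALSE]
}

cf_matrix <- function(k) {
  m <- ef_matrix(k)
  r <- 0:(2^k - 1L)
  can <- rep(FALSE, ncol(m))
  for (j in seq_len(k)) for (a in 0:1) {
    b <- 2^(k - j)
    rows <- r[(r %/% b) %% 2L == a] + 1L
    sub <- m[rows, , drop = FALSE]
    can <- can | (colSums(sub) == 0L) | (colSums(sub) == nrow(sub))
  }
  m[, can, drop = FALSE]
}

# Constructive NCF generation: an ordering sigma of the k inputs, canalyzing
# input values a_1..a_k and canalyzed outputs b_1..b_k define
#   f(x) = b_i for the first i with x[sigma_i] == a_i, else !b_k.
# Every such table is an NCF effective in all k inputs, and every NCF arises
# this way; duplicates are removed by the output column.
ncf_matrix <- function(k) {
  if (k == 1L) return(matrix(c(0L, 1L, 1L, 0L), nrow = 2))
  perms <- permutations_of(k)
  m <- input_matrix(k)
  cols <- list()
  for (p in seq_len(nrow(perms))) {
    sigma <- perms[p, ]
    for (av in 0:(2^k - 1L)) {
      a <- (av %/% 2^((k - 1):0)) %% 2L
      for (bv in 0:(2^k - 1L)) {
        b <- (bv %/% 2^((k - 1):0)) %% 2L
        out <- rep(1L - b[k], 2^k)
        done <- rep(FALSE, 2^k)
        for (i in seq_len(k)) {
          hit <- !done & m[, sigma[i]] == a[i]
          out[hit] <- b[i]
          done <- done | hit
        }
        cols[[length(cols) + 1L]] <- out
      }
    }
  }
  dedupe_columns(do.call(cbind, cols))
}

# Read-once functions over the full k-variable row space, by recursion over
# variable subsets: rof(S) = literals for |S| = 1, else all g AND h / g OR h
# with {vars(g), vars(h)} a binary split of S. Deduplication by output column
# collapses associativity/commutativity duplicates.
rof_matrix <- function(k) {
  m <- input_matrix(k)
  memo <- new.env(parent = emptyenv())
  rof <- function(S) {                 # S: integer vector of input positions
    key <- paste(S, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (length(S) == 1L) {
      cbind(m[, S], 1L - m[, S])
    } else {
      first <- S[1]; rest <- S[-1]
      cols <- list()
      for (msk in 0:(2^length(rest) - 1L)) {
        inA <- as.logical((msk %/% 2^(seq_along(rest) - 1L)) %% 2L)
        A <- c(first, rest[inA]); B <- rest[!inA]
        if (length(B) == 0L) next
        ga <- rof(A); gb <- rof(B)
        for (ia in seq_len(ncol(ga))) for (ib in seq_len(ncol(gb))) {
          cols[[length(cols) + 1L]] <- ga[, ia] * gb[, ib]
          cols[[length(cols) + 1L]] <-
            1L - (1L - ga[, ia]) * (1L - gb[, ib])
        }
      }
      dedupe_columns(do.call(cbind, cols))
    }
    memo[[key]] <- res
    res
  }
  dedupe_columns(rof(seq_len(k)))
}

dedupe_columns <- function(m) {
  keys <- apply(m, 2L, paste, collapse = "")
  m[, !duplicated(keys), drop = FALSE]
}

# All permutations of 1:k as rows (k! x k), lexicographic.
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}
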