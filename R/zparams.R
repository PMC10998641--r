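#' Complement-canalyzing block vector of a truth table
#'
#' Scans the truth table recursively from the full `2^k`-row block down to
#' 2-row blocks. A `2^i`-row block (which fixes inputs `x_1..x_(k-i)` and is
#' split by input `x_(k-i+1)` into a top half, where that input is 0, and a
#' bottom half) is *complement canalyzing* (CC) when its top half is constant
#' at one output value and its bottom half constant at the complement. A
#' CC-`2^i`-block contributes its full `2^i` rows to component
#' `n_(k-i+1)`; the recursion does not descend into a contributing block, so
#' sub-blocks of a contributing block never contribute.
#'
#' @param tt a [truth_table] with `k >= 1`.
#' @return integer vector `n` of length k; `n[j]` is the total contribution
#'   of CC-`2^(k-j+1)`-blocks.
#' @examples
#' f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
#' n_vector(f)   # 0 4 2
#' @export
n_vector <- function(tt) {
  k <- tt$k
  if (k < 1L) stop("n_vector requires k >= 1")
  n <- integer(k)
  scan <- function(lo, size) {        # block = rows lo..lo+size-1 (0-based)
    half <- size %/% 2L
    top <- tt$outputs[(lo + 1L):(lo + half)]
    bot <- tt$outputs[(lo + half + 1L):(lo + size)]
    ut <- unique(top); ub <- unique(bot)
    if (length(ut) == 1L && length(ub) == 1L && ut != ub) {
      j <- k - as.integer(log2(size)) + 1L
      n[j] <<- n[j] + as.integer(size)
    } else if (size > 2L) {
      scan(lo, half)
      scan(lo + half, half)
    }
  }
  scan(0L, as.integer(2^k))
  n
}

#' Wuensche Z_left of a Boolean function under its given input ordering
#'
#' The probability that the next unknown input of a partial pre-image is
#' uniquely determined, computed from the CC-block vector as
#' `Z_left = 2^-k * sum_j n_j * (1/2)^(k-j)`: a CC-`2^i`-block contributes
#' its `2^i` rows with weight `(1/2)^(i-1)`. Constant functions give 0;
#' fully pre-image-deterministic functions (e.g. parity) give 1.
#'
#' @param tt a [truth_table] with `k >= 1`.
#' @return numeric in `[0, 1]`.
#' @export
z_left <- function(tt) {
  k <- tt$k
  n <- n_vector(tt)
  2^(-k) * sum(n * (1 / 2)^(k - seq_len(k)))
}

#' Permutation-based Z-parameter variants of a Boolean function
#'
#' Computes `Z_left` for all `k!` orderings of the inputs and summarizes:
#' `z_max`, `z_min` and `z_ave` are the maximum, minimum and mean over
#' orderings and `z_mid = (z_max + z_min)/2`. The mean is taken over all
#' `k!` orderings; since each distinct permuted table occurs equally often
#' (see [distinct_permutations]), this equals the mean over distinct tables.
#'
#' @param tt a [truth_table] with `1 <= k <= 8` (the `k!` bound).
#' @param keep_per_permutation if `TRUE`, attach the `Z_left` value of every
#'   ordering.
#' @param median if `TRUE`, also report the median of the `Z_left` values
#'   (an optional extra summary, not one of the four variants).
#' @return object of class `z_parameters`: list with `z_max`, `z_min`,
#'   `z_ave`, `z_mid`, optionally `z_median` and `per_permutation` (named
#'   numeric vector, names are comma-separated orderings).
#' @examples
#' f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
#' z_variants(f)   # z_max 0.75, z_min 0.25, z_ave 0.5, z_mid 0.5
#' @export
z_variants <- function(tt, keep_per_permutation = FALSE, median = FALSE) {
  k <- tt$k
  if (k < 1L) stop("z_variants requires k >= 1")
  if (k > 8L) stop("k! permutations enumerable only for k <= 8; ",
                   "see z_variants_sampled")
  perms <- permutations_of(k)
  zs <- vapply(seq_len(nrow(perms)), function(p)
    z_left(tt_permute_inputs(tt, perms[p, ])), numeric(1))
  res <- list(z_max = max(zs), z_min = min(zs), z_ave = mean(zs),
              z_mid = (max(zs) + min(zs)) / 2)
  if (median) res$z_median <- stats::median(zs)
  if (keep_per_permutation) {
    names(zs) <- apply(perms, 1L, paste, collapse = ",")
    res$per_permutation <- zs
  }
  structure(res, class = "z_parameters")
}

#' @export
print.z_parameters <- function(x, ...) {
  cat(sprintf("Z-parameters: Z_max = %.4g, Z_min = %.4g, Z_ave = %.4g, Z_mid = %.4g\n",
              x$z_max, x$z_min, x$z_ave, x$z_mid))
  invisible(x)
}

#' Sampled Z-parameter estimates for large input counts
#'
#' Above the `k <= 8` exhaustive bound, estimates the Z variants from a
#' seeded sample of input orderings. Estimates only: `z_max`/`z_min` are
#' biased toward the interior.
#'
#' @param tt a [truth_table].
#' @param n_orderings number of orderings to sample.
#' @param seed integer seed.
#' @return a `z_parameters` object with an `estimated = TRUE` attribute.
#' @export
z_variants_sampled <- function(tt, n_orderings = 1000L, seed = 1L) {
  k <- tt$k
  zs <- with_seed(seed, vapply(seq_len(n_orderings), function(i)
    z_left(tt_permute_inputs(tt, sample.int(k))), numeric(1)))
  structure(list(z_max = max(zs), z_min = min(zs), z_ave = mean(zs),
                 z_mid = (max(zs) + min(zs)) / 2),
            class = "z_parameters", estimated = TRUE)
}

#' Closed-form Z-parameters of nested canalyzing functions
#'
#' For a k-input NCF with bias P (number of 1-rows; necessarily odd and not
#' `2^(k-1)`):
#' \deqn{Z_{max} = P/2^{k-1} \textrm{ if } P < 2^{k-1}, \; 2 - P/2^{k-1}
#'   \textrm{ otherwise};\quad Z_{min} = 1/2^{k-1};}
#' \deqn{Z_{mid} = (1+P)/2^k \textrm{ if } P < 2^{k-1}, \; 1 - (P-1)/2^k
#'   \textrm{ otherwise.}}
#' `Z_min` depends on k only; `Z_max` and `Z_mid` are linear in P on each
#' side of `2^(k-1)`.
#'
#' @param k input count (`>= 2`).
#' @param P bias, odd, `0 < P < 2^k`.
#' @return named numeric vector `c(z_max, z_min, z_mid)`.
#' @examples
#' ncf_closed_forms(3, 3)   # 0.75 0.25 0.50
#' @export
ncf_closed_forms <- function(k, P) {
  if (k < 2L) stop("closed forms defined for k >= 2")
  if (P <= 0L || P >= 2^k || P %% 2L == 0L)
    stop("bias P = ", P, " is not achievable by a k-input NCF ",
         "(P must be odd with 0 < P < 2^k)")
  z_max <- if (P < 2^(k - 1)) P / 2^(k - 1) else 2 - P / 2^(k - 1)
  z_min <- 1 / 2^(k - 1)
  z_mid <- if (P < 2^(k - 1)) (1 + P) / 2^k else 1 - (P - 1) / 2^k
  c(z_max = z_max, z_min = z_min, z_mid = z_mid)
}

#' Group input orderings by the permuted truth table
#'
#' Applies all `k!` input orderings and groups those yielding identical
#' output columns. The distinct permuted tables all occur with equal
#' multiplicity, and their number m divides `k!`; averaging `Z_left` over
#' the m distinct tables therefore equals the average over all `k!`
#' orderings, which is how `z_ave` can be computed faster in practice.
#'
#' @param tt a [truth_table] with `k <= 8`.
#' @return list with `tables` (list of m truth_tables), `multiplicities`
#'   (integer vector summing to `k!`) and `m`.
#' @export
distinct_permutations <- function(tt) {
  k <- tt$k
  if (k > 8L) stop("k <= 8 required")
  perms <- permutations_of(k)
  tabs <- lapply(seq_len(nrow(perms)), function(p)
    tt_permute_inputs(tt, perms[p, ]))
  keys <- vapply(tabs, function(x) paste(x$outputs, collapse = ""),
                 character(1))
  counts <- table(keys)
  first <- !duplicated(keys)
  list(tables = tabs[first],
       multiplicities = as.integer(counts[keys[first]]),
       m = sum(first))
}

#' Per-function Z-parameter table
#'
#' One row per truth table: integer encoding (for `k <= 5`, else NA), k,
#' bias P, the CC-block vector, the four Z variants and the average
#' sensitivity. Suitable for TSV export via [utils::write.table].
#'
#' @param tts list of [truth_table]s.
#' @return data.frame.
#' @export
zparam_table <- function(tts) {
  rows <- lapply(tts, function(tt) {
    zv <- z_variants(tt)
    data.frame(encoding = if (tt$k <= 5L) encode_integer(tt) else NA_real_,
               k = tt$k, P = bias(tt),
               n = paste(n_vector(tt), collapse = ","),
               z_max = zv$z_max, z_min = zv$z_min,
               z_ave = zv$z_ave, z_mid = zv$z_mid,
               s = average_sensitivity(tt))
  })
  do.call(rbind, rows)
}
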