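#' Construct a truth table
#'
#' A `truth_table` stores a k-input Boolean function as its ordered output
#' column. Row `r` (0-based) holds the value of the function at the input
#' vector whose binary expansion, with the *first* input as the most
#' significant bit, equals `r`. Under this convention flipping input `x_j`
#' toggles bit `2^(k-j)` of the row index, and the `2^i`-row blocks of the
#' table correspond to fixing inputs `x_1, ..., x_(k-i)`.
#'
#' @param outputs vector of 2^k values coercible to 0/1, row 0 first.
#' @param labels optional character vector of k input names; defaults to
#'   `x1, ..., xk`.
#' @return an object of class `truth_table` with fields `k`, `outputs`
#'   (integer 0/1) and `labels`.
#' @examples
#' tt <- truth_table(c(0, 0, 0, 1))          # AND(x1, x2)
#' bias(tt)
#' average_sensitivity(tt)
#' @export
truth_table <- function(outputs, labels = NULL) {
  outputs <- as.integer(outputs)
  if (any(is.na(outputs)) || any(outputs != 0L & outputs != 1L))
    stop("outputs must be 0/1")
  n <- length(outputs)
  k <- as.integer(round(log2(n)))
  if (n < 1L || 2^k != n)
    stop("length of outputs must be a power of two")
  if (is.null(labels)) {
    labels <- if (k > 0L) paste0("x", seq_len(k)) else character(0)
  }
  if (length(labels) != k) stop("need exactly k input labels")
  structure(list(k = k, outputs = outputs, labels = as.character(labels)),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: k = %d, P = %d/%d\n", x$k, bias(x), 2^x$k))
  if (x$k > 0L && x$k <= 6L) {
    m <- input_matrix(x$k)
    colnames(m) <- x$labels
    print(cbind(m, f = x$outputs))
  } else {
    cat("outputs:", paste(x$outputs, collapse = ""), "\n")
  }
  invisible(x)
}

#' @export
format.truth_table <- function(x, ...) tt_serialize(x)

#' @export
`==.truth_table` <- function(e1, e2) {
  e1$k == e2$k && all(e1$outputs == e2$outputs)
}

# 2^k x k 0/1 matrix; row r+1 is the input vector encoded by r (x1 = MSB).
input_matrix <- function(k) {
  r <- 0:(2^k - 1)
  m <- vapply(seq_len(k), function(j) as.integer((r %/% 2^(k - j)) %% 2),
              integer(2^k))
  matrix(m, nrow = 2^k, ncol = k)
}

# Row index (0-based) of an input vector under the MSB-first convention.
row_index <- function(x) {
  k <- length(x)
  if (k == 0L) return(0L)
  as.integer(sum(x * 2^((k - 1):0)))
}

#' Evaluate a truth table at one or more input vectors
#'
#' @param tt a [truth_table].
#' @param x a 0/1 vector of length k, or a matrix with k columns.
#' @return 0/1 output value(s).
#' @export
tt_eval <- function(tt, x) {
  if (is.matrix(x)) {
    idx <- as.integer(x %*% 2^((tt$k - 1):0))
    tt$outputs[idx + 1L]
  } else {
    tt$outputs[row_index(x) + 1L]
  }
}

#' Build a truth table from a Boolean expression
#'
#' Parses an expression over named inputs using `&` (AND), `|` (OR),
#' `!` (NOT), parentheses and the constants `0`/`1`, and evaluates it at
#' all 2^k input vectors.
#'
#' @param expression character scalar, e.g. `"x2 & (!x3 | x1)"`.
#' @param labels ordered input names; the first is the most significant bit
#'   of the row index.
#' @return a [truth_table].
#' @examples
#' truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
#' @export
truth_table_from_expression <- function(expression, labels) {
  labels <- as.character(labels)
  ast <- parse_bool_expr(expression)
  vars <- bool_expr_vars(ast)
  unknown <- setdiff(vars, labels)
  if (length(unknown))
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "))
  k <- length(labels)
  m <- input_matrix(k)
  env <- stats::setNames(lapply(seq_len(k), function(j) m[, j]), labels)
  out <- eval_bool_expr(ast, env, nrow(m))
  truth_table(out, labels)
}

#' Bias of a Boolean function
#'
#' The bias P is the number of input combinations mapped to output 1.
#'
#' @param tt a [truth_table].
#' @return integer in `[0, 2^k]`.
#' @export
bias <- function(tt) sum(tt$outputs)

#' Complement a truth table's output
#' @param tt a [truth_table].
#' @return a [truth_table] computing `!f`.
#' @export
tt_complement <- function(tt) truth_table(1L - tt$outputs, tt$labels)

#' Negate one input of a truth table
#' @param tt a [truth_table].
#' @param j input position to negate (1-based).
#' @return a [truth_table] computing `f` with `x_j` replaced by `!x_j`.
#' @export
tt_negate_input <- function(tt, j) {
  stopifnot(j >= 1L, j <= tt$k)
  b <- 2^(tt$k - j)
  idx <- bitwXor(0:(2^tt$k - 1L), b)
  truth_table(tt$outputs[idx + 1L], tt$labels)
}

#' Permute the inputs of a truth table
#'
#' Returns the truth table of the same function read with its inputs in a
#' new order: input `j` of the result is input `perm[j]` of the original.
#'
#' @param tt a [truth_table].
#' @param perm a permutation of `1:k`.
#' @return a [truth_table] over the permuted input ordering.
#' @export
tt_permute_inputs <- function(tt, perm) {
  k <- tt$k
  stopifnot(length(perm) == k, all(sort(perm) == seq_len(k)))
  m <- input_matrix(k)
  # row r of the new table holds inputs v; original input i takes value
  # v[ which(perm == i) ]
  inv <- order(perm)
  idx <- as.integer(m[, inv, drop = FALSE] %*% 2^((k - 1):0))
  truth_table(tt$outputs[idx + 1L], tt$labels[perm])
}

#' Effectiveness of inputs
#'
#' An input is effective when some input vector exists at which flipping it
#' changes the output; a function is effective when every input is.
#'
#' @param tt a [truth_table].
#' @return list with `per_input` (logical vector of length k) and `effective`
#'   (their conjunction).
#' @export
effectiveness <- function(tt) {
  k <- tt$k
  per <- vapply(seq_len(k), function(j) {
    idx <- bitwXor(0:(2^k - 1L), 2^(k - j))
    any(tt$outputs != tt$outputs[idx + 1L])
  }, logical(1))
  list(per_input = per, effective = all(per) && k > 0L)
}

#' Regulatory sign of each input
#'
#' Classifies each input as `"activating"` (output non-decreasing in that
#' input, with some strict increase), `"inhibiting"` (non-increasing),
#' `"dual"` (both directions occur) or `"ineffective"`. A function is unate
#' iff no input is dual.
#'
#' @param tt a [truth_table].
#' @return list with `signs` (character vector) and `unate` (logical).
#' @export
input_signs <- function(tt) {
  k <- tt$k
  signs <- vapply(seq_len(k), function(j) {
    b <- 2^(k - j)
    r <- 0:(2^k - 1L)
    low <- r[bitwAnd(r, b) == 0L]
    d <- tt$outputs[low + b + 1L] - tt$outputs[low + 1L]
    up <- any(d > 0L); down <- any(d < 0L)
    if (up && down) "dual"
    else if (up) "activating"
    else if (down) "inhibiting"
    else "ineffective"
  }, character(1))
  list(signs = signs, unate = !any(signs == "dual"))
}

# Restrict tt by fixing input j (1-based) to value a; returns table on the
# remaining k-1 inputs in their original order.
tt_restrict <- function(tt, j, a) {
  k <- tt$k
  b <- 2^(k - j)
  r <- 0:(2^k - 1L)
  keep <- r[(r %/% b) %% 2L == a]
  truth_table(tt$outputs[keep + 1L], tt$labels[-j])
}

#' Test for a nested canalyzing function
#'
#' A function is nested canalyzing when its inputs can be ordered so that
#' each successive input, at one of its values, forces ("canalyzes") the
#' output of the residual function obtained by fixing all earlier inputs to
#' their non-canalyzing values. Single-input identity and negation count as
#' (trivially) nested canalyzing; constants do not. The test peels canalyzing
#' variables recursively.
#'
#' @param tt a [truth_table].
#' @return list with `is_ncf` (logical) and, when true, `layers`: a data
#'   frame with columns `input` (label), `canalyzing_value` and
#'   `canalyzed_output`, one row per peeled variable in peel order.
#' @export
is_ncf <- function(tt) {
  res <- ncf_peel(tt)
  if (is.null(res)) list(is_ncf = FALSE, layers = NULL)
  else list(is_ncf = TRUE, layers = res)
}

ncf_peel <- function(tt) {
  k <- tt$k
  out <- tt$outputs
  if (length(unique(out)) == 1L) return(NULL)    # constant
  if (k == 1L) {
    # x or !x: canalyzing trivially in its single input
    return(data.frame(input = tt$labels, canalyzing_value = 0:1,
                      canalyzed_output = out[1:2],
                      stringsAsFactors = FALSE)[1, , drop = FALSE])
  }
  for (j in seq_len(k)) {
    for (a in 0:1) {
      sub <- tt_restrict(tt, j, a)
      if (length(unique(sub$outputs)) == 1L) {
        rest <- ncf_peel(tt_restrict(tt, j, 1L - a))
        if (!is.null(rest)) {
          layer <- data.frame(input = tt$labels[j], canalyzing_value = a,
                              canalyzed_output = sub$outputs[1],
                              stringsAsFactors = FALSE)
          return(rbind(layer, rest))
        }
      }
    }
  }
  NULL
}

#' Average sensitivity of a Boolean function
#'
#' The mean, over all 2^k input vectors, of the number of inputs whose
#' single-bit flip changes the output (not divided by k): s in `[0, k]`.
#'
#' @param tt a [truth_table].
#' @return numeric scalar.
#' @export
average_sensitivity <- function(tt) {
  k <- tt$k
  if (k == 0L) return(0)
  r <- 0:(2^k - 1L)
  s <- 0
  for (j in seq_len(k)) {
    idx <- bitwXor(r, 2^(k - j))
    s <- s + mean(tt$outputs != tt$outputs[idx + 1L])
  }
  s
}

#' Integer encoding of a truth table
#'
#' Encodes the output column as `sum_r outputs[r] * 2^r`: row 0 is the
#' least-significant bit. The encoding convention is confined to this
#' function pair. Exact for `k <= 5` (the value fits a double exactly).
#'
#' @param tt a [truth_table].
#' @return non-negative numeric.
#' @export
encode_integer <- function(tt) {
  if (tt$k > 5L) stop("integer encoding supported for k <= 5")
  sum(tt$outputs * 2^(seq_along(tt$outputs) - 1L))
}

#' @rdname encode_integer
#' @param value non-negative integer `< 2^(2^k)`.
#' @param k input count.
#' @param labels optional input names.
#' @export
decode_integer <- function(value, k, labels = NULL) {
  if (k > 5L) stop("integer encoding supported for k <= 5")
  if (value < 0 || value >= 2^(2^k)) stop("value out of range for k")
  bits <- (value %/% 2^(0:(2^k - 1L))) %% 2
  truth_table(bits, labels)
}

#' One-line text serialization of a truth table
#'
#' Format: `<k> <comma-separated labels> <output bitstring row 0..2^k-1>`.
#'
#' @param tt a [truth_table].
#' @return character scalar.
#' @export
tt_serialize <- function(tt) {
  sprintf("%d %s %s", tt$k, paste(tt$labels, collapse = ","),
          paste(tt$outputs, collapse = ""))
}

#' @rdname tt_serialize
#' @param line a serialized line.
#' @export
tt_deserialize <- function(line) {
  parts <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(parts) != 3L) stop("malformed truth-table line")
  k <- as.integer(parts[1])
  labels <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  outputs <- as.integer(strsplit(parts[3], "")[[1]])
  tt <- truth_table(outputs, labels)
  if (tt$k != k) stop("k does not match output length")
  tt
}
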