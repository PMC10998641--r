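#' Truth-table row constraints induced by required fixed points
#'
#' For each node i and each required fixed point X*, the truth-table row
#' indexed by the regulator values of i in X* must output the node's own
#' value in X*. Constraints from different fixed points hitting the same
#' row are merged; a row required to be both 0 and 1 is a structural
#' impossibility and is reported with the offending node and states.
#'
#' @param structure a `bn_structure` or [boolean_network] (functions
#'   ignored).
#' @param fixed_points list of 0/1 vectors of length N (node order), or a
#'   character vector of bitstrings.
#' @return named list: per node, an integer vector of required outputs named
#'   by 0-based row indices.
#' @export
fixed_point_constraints <- function(structure, fixed_points) {
  nodes <- structure$nodes
  N <- length(nodes)
  fps <- lapply(fixed_points, function(fp) {
    if (is.character(fp)) fp <- as.integer(strsplit(fp, "")[[1]])
    fp <- as.integer(fp)
    if (length(fp) != N || any(fp != 0L & fp != 1L))
      stop("fixed points must be N-bit 0/1 states")
    fp
  })
  out <- stats::setNames(vector("list", N), nodes)
  for (i in seq_len(N)) {
    nd <- nodes[i]
    regs <- match(structure$regulators[[nd]], nodes)
    cons <- integer(0)
    for (fi in seq_along(fps)) {
      fp <- fps[[fi]]
      r <- if (length(regs)) row_index(fp[regs]) else 0L
      key <- as.character(r)
      if (key %in% names(cons) && cons[[key]] != fp[i])
        stop("contradictory fixed-point constraints at node '", nd,
             "': row ", r, " required to be both ", cons[[key]], " and ",
             fp[i], " (fixed point #", fi, ")")
      cons[[key]] <- fp[i]
    }
    out[[nd]] <- cons
  }
  out
}

#' Sample one constrained Boolean function from a class
#'
#' Draws a truth table on `k` effective inputs from the requested class,
#' subject to required output values on given rows:
#' \describe{
#'   \item{EF}{free rows uniform random, rejected until every input is
#'     effective.}
#'   \item{NCF / RoF, `k <= 4`}{the enumerated class is filtered by the
#'     constraints and a member drawn uniformly.}
#'   \item{NCF, `k > 4`}{a random layer structure (input ordering,
#'     canalyzing values, canalyzed outputs) with rejection on constraint
#'     violation.}
#'   \item{RoF, `k > 4`}{a random read-once expression tree (random binary
#'     splits, AND/OR labels, literal signs) with rejection.}
#'   \item{EUF, `k <= 4`}{enumerated unate effective functions, filtered by
#'     constraints (and by `signs` when given), drawn uniformly.}
#'   \item{EUF, `k > 4`}{the color-propagation hypercube sampler
#'     ([sample_euf_colorprop]); input signs are drawn uniformly per attempt
#'     when not supplied.}
#' }
#'
#' @param k input count.
#' @param label `"EF"`, `"EUF"`, `"RoF"` or `"NCF"`.
#' @param constraints integer vector of required outputs named by 0-based
#'   row indices (may be empty/NULL).
#' @param signs optional character vector of length k with entries
#'   `"activating"`/`"inhibiting"` (EUF only).
#' @param labels optional input names for the returned table.
#' @param max_attempts rejection budget before declaring infeasibility.
#' @return a [truth_table].
#' @export
sample_function <- function(k, label = c("EF", "EUF", "RoF", "NCF"),
                            constraints = NULL, signs = NULL, labels = NULL,
                            max_attempts = 10000L) {
  label <- match.arg(label)
  if (k < 1L) stop("k must be >= 1")
  cons_rows <- if (length(constraints))
    as.integer(names(constraints)) else integer(0)
  cons_vals <- as.integer(constraints)
  if (any(cons_rows < 0L | cons_rows >= 2^k))
    stop("constraint row out of range")

  if (label %in% c("NCF", "RoF") && k <= 4L ||
      label == "EUF" && k <= 4L) {
    pool <- class_pool(k, label)
    keep <- rep(TRUE, length(pool))
    if (length(cons_rows)) {
      keep <- vapply(pool, function(tt)
        all(tt$outputs[cons_rows + 1L] == cons_vals), logical(1))
    }
    if (!is.null(signs) && label == "EUF") {
      keep <- keep & vapply(pool, function(tt)
        identical(input_signs(tt)$signs, as.character(signs)), logical(1))
    }
    pool <- pool[keep]
    if (!length(pool))
      stop("no ", label, " with k = ", k, " satisfies the constraints")
    tt <- pool[[sample.int(length(pool), 1L)]]
    return(truth_table(tt$outputs, labels))
  }

  for (attempt in seq_len(max_attempts)) {
    tt <- switch(label,
                 EF = random_constrained_table(k, cons_rows, cons_vals),
                 NCF = random_ncf(k),
                 RoF = random_rof(k),
                 EUF = {
                   sg <- if (is.null(signs))
                     sample(c("activating", "inhibiting"), k, replace = TRUE)
                   else as.character(signs)
                   sample_euf_colorprop(k, cons_rows, cons_vals, sg,
                                        max_attempts = 1L, quiet = TRUE)
                 })
    if (is.null(tt)) next
    if (length(cons_rows) &&
        !all(tt$outputs[cons_rows + 1L] == cons_vals)) next
    if (!effectiveness(tt)$effective) next
    return(truth_table(tt$outputs, labels))
  }
  stop("no ", label, " satisfying the constraints found within ",
       max_attempts, " attempts (node may be infeasible)")
}

# cached enumerations per (k, label)
class_pool_cache <- new.env(parent = emptyenv())
class_pool <- function(k, label) {
  key <- paste0(label, k)
  if (is.null(class_pool_cache[[key]]))
    class_pool_cache[[key]] <- enumerate_class(k, label)
  class_pool_cache[[key]]
}

random_constrained_table <- function(k, cons_rows, cons_vals) {
  out <- sample(0:1, 2^k, replace = TRUE)
  out[cons_rows + 1L] <- cons_vals
  truth_table(out)
}

# random NCF layer structure: ordering sigma, canalyzing values a,
# canalyzed outputs b; f(x) = b_i at the first i with x[sigma_i] = a_i,
# else !b_k
random_ncf <- function(k) {
  sigma <- sample.int(k)
  a <- sample(0:1, k, replace = TRUE)
  b <- sample(0:1, k, replace = TRUE)
  m <- input_matrix(k)
  out <- rep(1L - b[k], 2^k)
  done <- rep(FALSE, 2^k)
  for (i in seq_len(k)) {
    hit <- !done & m[, sigma[i]] == a[i]
    out[hit] <- b[i]
    done <- done | hit
  }
  truth_table(out)
}

# random read-once tree over a random variable split
random_rof <- function(k) {
  m <- input_matrix(k)
  build <- function(vars) {
    if (length(vars) == 1L) {
      col <- m[, vars]
      if (stats::runif(1) < 0.5) col else 1L - col
    } else {
      sz <- sample.int(length(vars) - 1L, 1L)
      left <- sample(vars, sz)
      a <- build(left); b <- build(setdiff(vars, left))
      if (stats::runif(1) < 0.5) a * b else 1L - (1L - a) * (1L - b)
    }
  }
  truth_table(build(seq_len(k)))
}

#' Color-propagation sampler for unate functions
#'
#' Samples an effective unate function with the given input signs by
#' monotone closure on the Boolean hypercube. Inhibiting inputs are mapped
#' to activating coordinates, making the target function monotone
#' non-decreasing; constrained vertices are pre-colored and their monotone
#' closure propagated (any vertex above a 1 is 1, any below a 0 is 0). Then,
#' repeatedly, an uncolored vertex is picked uniformly, assigned a uniform
#' output, and its closure propagated. A run producing a contradiction or an
#' ineffective function is rejected and restarted. The resulting
#' distribution over unate functions is close to, but not exactly, uniform.
#'
#' @param k input count.
#' @param cons_rows integer vector of constrained 0-based row indices.
#' @param cons_vals required outputs on those rows.
#' @param signs character vector of length k, `"activating"` or
#'   `"inhibiting"`.
#' @param max_attempts restart budget.
#' @param quiet return `NULL` instead of erroring when the budget is
#'   exhausted.
#' @return a [truth_table] with the requested signs, or `NULL`.
#' @export
sample_euf_colorprop <- function(k, cons_rows = integer(0),
                                 cons_vals = integer(0), signs = NULL,
                                 max_attempts = 10000L, quiet = FALSE) {
  if (is.null(signs)) signs <- rep("activating", k)
  stopifnot(length(signs) == k, all(signs %in% c("activating", "inhibiting")))
  flip_mask <- sum(2^(k - which(signs == "inhibiting")))
  r <- 0:(2^k - 1L)
  # transform rows so the target is monotone non-decreasing in every input
  t_rows <- bitwXor(cons_rows, flip_mask)
  # above[[v+1]]: vertices >= v, below[[v+1]]: vertices <= v (bitwise)
  above <- lapply(r, function(v) r[bitwAnd(r, v) == v])
  below <- lapply(r, function(v) r[bitwAnd(r, v) == r])
  for (attempt in seq_len(max_attempts)) {
    col <- rep(NA_integer_, 2^k)
    ok <- TRUE
    assign_bit <- function(v, b) {
      affected <- if (b == 1L) above[[v + 1L]] else below[[v + 1L]]
      cur <- col[affected + 1L]
      if (any(!is.na(cur) & cur != b)) return(FALSE)
      col[affected + 1L] <<- b
      TRUE
    }
    for (i in seq_along(t_rows)) {
      if (!assign_bit(t_rows[i], cons_vals[i])) {
        stop("contradictory constraints for a unate function with the ",
             "given signs (monotonicity violation)")
      }
    }
    while (anyNA(col)) {
      cand <- r[is.na(col)]
      v <- if (length(cand) == 1L) cand else sample(cand, 1L)
      if (!assign_bit(v, sample(0:1, 1L))) { ok <- FALSE; break }
    }
    if (!ok) next
    # map back to the signed coordinates
    out <- col[bitwXor(r, flip_mask) + 1L]
    tt <- truth_table(out)
    if (!effectiveness(tt)$effective) next
    if (!identical(input_signs(tt)$signs, signs)) next
    return(tt)
  }
  if (quiet) return(NULL)
  stop("color-propagation sampler exhausted its attempt budget")
}

#' Generate an ensemble of Boolean models
#'
#' Draws `n_models` Boolean networks sharing the given structure (nodes and
#' ordered regulators), whose node functions all belong to the requested
#' class and which all keep the required fixed points fixed. Node functions
#' are sampled independently given the row constraints — the fixed-point
#' property factorizes over nodes, so independence preserves it exactly;
#' each declared fixed point of each model is nevertheless re-verified with
#' [synchronous_step] after sampling.
#'
#' @param structure a `bn_structure` or [boolean_network].
#' @param fixed_points list of 0/1 state vectors or bitstrings (may be
#'   empty).
#' @param label `"EF"`, `"EUF"`, `"RoF"` or `"NCF"`.
#' @param n_models ensemble size.
#' @param seed integer seed.
#' @param signs optional named list mapping node name to a sign vector over
#'   its regulators (EUF sampling).
#' @param max_attempts per-node rejection budget.
#' @return object of class `bn_ensemble`: list with `label`, `structure`,
#'   `fixed_points`, `seed` and `models` (list of [boolean_network]s).
#' @export
generate_ensemble <- function(structure, fixed_points = list(),
                              label = c("EF", "EUF", "RoF", "NCF"),
                              n_models = 100L, seed = 1L, signs = NULL,
                              max_attempts = 10000L) {
  label <- match.arg(label)
  cons <- fixed_point_constraints(structure, fixed_points)
  nodes <- structure$nodes
  models <- with_seed(seed, lapply(seq_len(n_models), function(i) {
    fns <- lapply(nodes, function(nd) {
      regs <- structure$regulators[[nd]]
      sample_function(length(regs), label, constraints = cons[[nd]],
                      signs = if (!is.null(signs)) signs[[nd]] else NULL,
                      labels = regs, max_attempts = max_attempts)
    })
    boolean_network(nodes, structure$regulators,
                    stats::setNames(fns, nodes))
  }))
  ens <- list(label = label,
              structure = boolean_network(nodes, structure$regulators),
              fixed_points = fixed_points, seed = seed, models = models)
  class(ens) <- "bn_ensemble"
  verify_ensemble(ens)
  ens
}

verify_ensemble <- function(ens) {
  fps <- lapply(ens$fixed_points, function(fp) {
    if (is.character(fp)) as.integer(strsplit(fp, "")[[1]]) else as.integer(fp)
  })
  for (m in ens$models) for (fp in fps) {
    if (!all(synchronous_step(m, fp) == fp))
      stop("internal error: sampled model violates a declared fixed point")
  }
  invisible(TRUE)
}

#' @export
print.bn_ensemble <- function(x, ...) {
  cat(sprintf("bn_ensemble: %d %s models on %d nodes / %d edges, %d fixed point(s), seed %d\n",
              length(x$models), x$label, length(x$structure$nodes),
              n_edges(x$structure), length(x$fixed_points), x$seed))
  invisible(x)
}

#' Write an ensemble to a directory of BoolNet files
#'
#' One `model_<i>.bnet` per model plus a `manifest.json` recording the
#' class label, seed and fixed points.
#'
#' @param ens a `bn_ensemble`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ens$models)) {
    write_boolnet(ens$models[[i]],
                  file.path(dir, sprintf("model_%04d.bnet", i)))
  }
  manifest <- list(label = ens$label, seed = ens$seed,
                   n_models = length(ens$models),
                   nodes = ens$structure$nodes,
                   fixed_points = vapply(ens$fixed_points, function(fp)
                     paste(as.integer(if (is.character(fp))
                       strsplit(fp, "")[[1]] else fp), collapse = ""),
                     character(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
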