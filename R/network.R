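#' Construct a Boolean network
#'
#' A `boolean_network` is an ordered set of named nodes, each with an
#' ordered list of regulators and a [truth_table] over them (the table's
#' first input is its first regulator, as the most significant bit of the
#' row index). Self-loops are allowed. With `functions = NULL` the object is
#' a structure-only skeleton of class `bn_structure` (nodes and regulators
#' but no logic), as used for ensemble generation.
#'
#' @param nodes character vector of N node names.
#' @param regulators named list: for each node, its ordered regulator names.
#' @param functions named list of [truth_table]s, or `NULL` for a
#'   structure-only skeleton.
#' @return object of class `boolean_network` (or `bn_structure`).
#' @export
boolean_network <- function(nodes, regulators, functions = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (!setequal(names(regulators), nodes))
    stop("regulators must be named by the nodes")
  regulators <- regulators[nodes]
  for (nd in nodes) {
    bad <- setdiff(regulators[[nd]], nodes)
    if (length(bad))
      stop("node '", nd, "' has undeclared regulator(s): ",
           paste(bad, collapse = ", "))
  }
  if (is.null(functions)) {
    return(structure(list(nodes = nodes, regulators = regulators),
                     class = "bn_structure"))
  }
  if (!setequal(names(functions), nodes))
    stop("functions must be named by the nodes")
  functions <- functions[nodes]
  for (nd in nodes) {
    if (functions[[nd]]$k != length(regulators[[nd]]))
      stop("node '", nd, "': truth table arity does not match regulator count")
  }
  structure(list(nodes = nodes, regulators = regulators,
                 functions = functions),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network: %d nodes, %d edges\n",
              length(x$nodes), n_edges(x)))
  for (nd in x$nodes) {
    cat(sprintf("  %s <- [%s]  (k = %d, P = %d)\n", nd,
                paste(x$regulators[[nd]], collapse = ", "),
                x$functions[[nd]]$k, bias(x$functions[[nd]])))
  }
  invisible(x)
}

#' @export
print.bn_structure <- function(x, ...) {
  cat(sprintf("bn_structure: %d nodes, %d edges (no functions)\n",
              length(x$nodes), n_edges(x)))
  for (nd in x$nodes)
    cat(sprintf("  %s <- [%s]\n", nd,
                paste(x$regulators[[nd]], collapse = ", ")))
  invisible(x)
}

#' Number of directed edges (sum of in-degrees)
#' @param network a `boolean_network` or `bn_structure`.
#' @return integer edge count.
#' @export
n_edges <- function(network) sum(lengths(network$regulators))

#' Parse a BoolNet plain-text model
#'
#' Reads the "targets, factors" format: a header line, then one
#' `name, expression` line per node with `&`, `|`, `!`, parentheses and the
#' constants 0/1; `#` starts a comment. Regulator order is the left-to-right
#' first-appearance order of variables in the expression; a constant
#' expression yields a 0-input truth table (flagged with a warning, since
#' constant nodes are excluded from the effective-function classes).
#'
#' @param text character scalar (whole file) or vector of lines.
#' @return a [boolean_network].
#' @examples
#' net <- parse_boolnet("targets, factors\na, b\nb, !a")
#' @export
parse_boolnet <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BoolNet text")
  if (!grepl("^targets[[:space:]]*,[[:space:]]*factors$", lines[1],
             ignore.case = TRUE))
    stop("missing 'targets, factors' header")
  lines <- lines[-1]
  targets <- character(0); exprs <- character(0)
  for (ln in lines) {
    m <- regexpr(",", ln, fixed = TRUE)
    if (m < 0) stop("malformed line (no comma): ", ln)
    tg <- trimws(substr(ln, 1, m - 1))
    ex <- trimws(substr(ln, m + 1, nchar(ln)))
    if (!nzchar(ex)) stop("empty expression for target: ", tg)
    if (tg %in% targets) stop("duplicate target: ", tg)
    targets <- c(targets, tg); exprs <- c(exprs, ex)
  }
  regulators <- list(); functions <- list()
  for (i in seq_along(targets)) {
    ast <- parse_bool_expr(exprs[i])
    regs <- bool_expr_vars_ordered(ast)
    bad <- setdiff(regs, targets)
    if (length(bad))
      stop("node '", targets[i], "' references undeclared regulator(s): ",
           paste(bad, collapse = ", "))
    regulators[[targets[i]]] <- regs
    functions[[targets[i]]] <-
      if (length(regs)) truth_table_from_expression(exprs[i], regs)
      else truth_table(eval_bool_expr(ast, list(), 1L), character(0))
  }
  if (any(vapply(functions, function(f) f$k == 0L, logical(1))))
    warning("network contains constant node(s)")
  boolean_network(targets, regulators, functions)
}

#' @rdname parse_boolnet
#' @param path file to read.
#' @export
read_boolnet <- function(path) parse_boolnet(readLines(path))

#' Write a Boolean network in BoolNet format
#'
#' Each node's function is rendered as a disjunctive normal form over its
#' regulators (constants as `0`/`1`); `parse_boolnet(write_boolnet(net))`
#' reproduces the truth tables and regulator orders exactly.
#'
#' @param network a [boolean_network].
#' @param path optional file; when `NULL` the text is returned.
#' @return character scalar (invisibly when writing to a file).
#' @export
write_boolnet <- function(network, path = NULL) {
  lines <- c("targets, factors")
  for (nd in network$nodes) {
    tt <- network$functions[[nd]]
    lines <- c(lines, paste0(nd, ", ", tt_to_expression_string(tt)))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(txt)
}

# DNF rendering of a truth table over its own labels. Keeps every regulator
# present in the expression (appending non-contributing regulators would
# change the parsed regulator set, so ineffective inputs are retained via
# explicit minterms; a tautology is rendered through its minterms too).
tt_to_expression_string <- function(tt) {
  if (tt$k == 0L) return(as.character(tt$outputs[1]))
  ones <- which(tt$outputs == 1L) - 1L
  if (length(ones) == 0L)
    return(paste0(tt$labels[1], " & !", tt$labels[1],
                  if (tt$k > 1L)
                    paste0(" & ", paste(tt$labels[-1], collapse = " & "))
                  else ""))
  m <- input_matrix(tt$k)
  terms <- vapply(ones, function(r) {
    lits <- ifelse(m[r + 1L, ] == 1L, tt$labels, paste0("!", tt$labels))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

#' One synchronous update of a network state
#'
#' Every node simultaneously applies its truth table to the regulator values
#' read from the input state.
#'
#' @param network a [boolean_network].
#' @param state 0/1 vector of length N (node order).
#' @return 0/1 integer vector of length N.
#' @export
synchronous_step <- function(network, state) {
  stopifnot(length(state) == length(network$nodes))
  state <- as.integer(state)
  names(state) <- network$nodes
  vapply(network$nodes, function(nd)
    tt_eval(network$functions[[nd]], state[network$regulators[[nd]]]),
    integer(1), USE.NAMES = FALSE)
}

#' Network-level descriptors of local dynamics
#'
#' Unweighted node means of the four Z-parameter variants
#' (`z_bar_max`, `z_bar_min`, `z_bar_ave`, `z_bar_mid`) and of the average
#' sensitivity (`s_bar`). `delta`, the one-step perturbation response read
#' off a Derrida plot at perturbation size 1, is identical to `s_bar` and is
#' reported under both names.
#'
#' @param network a [boolean_network]; every node's in-degree must be within
#'   the `k <= 8` permutation bound.
#' @return object of class `network_descriptors`: list with the five means,
#'   `delta`, and `per_node` (data.frame of per-node k, P, Z variants, s).
#' @export
network_descriptors <- function(network) {
  per <- lapply(network$nodes, function(nd) {
    tt <- network$functions[[nd]]
    if (tt$k == 0L) {
      data.frame(node = nd, k = 0L, P = bias(tt), z_max = 0, z_min = 0,
                 z_ave = 0, z_mid = 0, s = 0)
    } else {
      zv <- z_variants(tt)
      data.frame(node = nd, k = tt$k, P = bias(tt), z_max = zv$z_max,
                 z_min = zv$z_min, z_ave = zv$z_ave, z_mid = zv$z_mid,
                 s = average_sensitivity(tt))
    }
  })
  per <- do.call(rbind, per)
  res <- list(z_bar_max = mean(per$z_max), z_bar_min = mean(per$z_min),
              z_bar_ave = mean(per$z_ave), z_bar_mid = mean(per$z_mid),
              s_bar = mean(per$s))
  res$delta <- res$s_bar
  res$per_node <- per
  structure(res, class = "network_descriptors")
}

#' @export
print.network_descriptors <- function(x, ...) {
  cat(sprintf(paste0("network descriptors: Z_bar_max = %.4g, ",
                     "Z_bar_min = %.4g, Z_bar_ave = %.4g, Z_bar_mid = %.4g, ",
                     "s_bar = delta = %.4g\n"),
              x$z_bar_max, x$z_bar_min, x$z_bar_ave, x$z_bar_mid, x$s_bar))
  invisible(x)
}
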