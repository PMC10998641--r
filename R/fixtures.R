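#' Built-in network fixtures
#'
#' Constructs small networks used throughout examples and tests:
#' \describe{
#'   \item{`mdgrn_structure()`}{the 11-node, 30-edge myeloid differentiation
#'     GRN structure (nodes and ordered regulator lists only — the published
#'     logic is not shipped; functions are supplied by
#'     [generate_ensemble]). `C/EBPa` is spelled `CEBPa` to stay within the
#'     BoolNet identifier grammar.}
#'   \item{`random_structure(N, k_max, seed)`}{a seeded random structure:
#'     each node draws an in-degree uniformly from `1..k_max` and that many
#'     distinct regulators uniformly from all nodes.}
#'   \item{`chain_network(H)`}{a saturating binary down-counter on
#'     `log2(H+1)` nodes whose STG is the linear chain
#'     `H -> H-1 -> ... -> 0` with a fixed point at 0: exactly one
#'     garden-of-Eden state and `lambda_goe = 1/H`. Requires
#'     `H = 2^m - 1`.}
#'   \item{`identity_network(N)`}{every node copies itself: bijective
#'     dynamics, `2^N` fixed points, no garden-of-Eden states.}
#'   \item{`constant_network(N, value)`}{every node is the constant
#'     `value`: all states map to one state in a single step.}
#' }
#'
#' @param N node count.
#' @param k_max maximum in-degree.
#' @param seed integer seed.
#' @param H chain length (`2^m - 1`).
#' @param value constant output bit.
#' @return a `bn_structure` (structure fixtures) or [boolean_network].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
mdgrn_structure <- function() {
  regs <- list(
    GATA_2 = c("GATA_2", "GATA_1", "FOG_1", "PU_1"),
    GATA_1 = c("GATA_2", "GATA_1", "Fli_1", "PU_1"),
    FOG_1 = "GATA_1",
    EKLF = c("GATA_1", "Fli_1"),
    Fli_1 = c("GATA_1", "EKLF"),
    SCL = c("GATA_1", "PU_1"),
    CEBPa = c("GATA_1", "FOG_1", "SCL", "CEBPa"),
    PU_1 = c("GATA_2", "GATA_1", "CEBPa", "PU_1"),
    cJun = c("Gfi_1", "PU_1"),
    EgrNab = c("cJun", "Gfi_1", "PU_1"),
    Gfi_1 = c("EgrNab", "CEBPa"))
  boolean_network(names(regs), regs)
}

#' @rdname fixtures
#' @export
random_structure <- function(N, k_max = 3L, seed = 1L) {
  stopifnot(N >= 1L, k_max >= 1L, k_max <= N)
  nodes <- paste0("g", seq_len(N))
  regs <- with_seed(seed, {
    stats::setNames(lapply(seq_len(N), function(i) {
      k <- sample.int(k_max, 1L)
      nodes[sample.int(N, k)]
    }), nodes)
  })
  boolean_network(nodes, regs)
}

#' @rdname fixtures
#' @export
chain_network <- function(H) {
  m <- log2(H + 1)
  if (m != round(m) || m < 1)
    stop("chain_network requires H = 2^m - 1 (saturating counter)")
  m <- as.integer(m)
  nodes <- paste0("b", seq_len(m))
  # successor of state v is max(v - 1, 0); node i is bit 2^(m-i)
  states <- 0:(2^m - 1L)
  nxt <- pmax(states - 1L, 0L)
  fns <- lapply(seq_len(m), function(i) {
    truth_table((nxt %/% 2^(m - i)) %% 2L, nodes)
  })
  boolean_network(nodes, stats::setNames(rep(list(nodes), m), nodes),
                  stats::setNames(fns, nodes))
}

#' @rdname fixtures
#' @export
identity_network <- function(N) {
  nodes <- paste0("g", seq_len(N))
  fns <- lapply(nodes, function(nd) truth_table(c(0L, 1L), nd))
  boolean_network(nodes, stats::setNames(as.list(nodes), nodes),
                  stats::setNames(fns, nodes))
}

#' @rdname fixtures
#' @export
constant_network <- function(N, value = 0L) {
  nodes <- paste0("g", seq_len(N))
  fns <- lapply(nodes, function(nd) truth_table(as.integer(value)))
  boolean_network(nodes, stats::setNames(rep(list(character(0)), N), nodes),
                  stats::setNames(fns, nodes))
}

#' @rdname fixtures
#' @param which fixture name: `"mdgrn_structure"`, `"random"`, `"chain"`,
#'   `"identity"` or `"constant"`.
#' @param ... passed to the specific fixture constructor.
#' @export
make_fixtures <- function(which = c("mdgrn_structure", "random", "chain",
                                    "identity", "constant"), ...) {
  which <- match.arg(which)
  switch(which,
         mdgrn_structure = mdgrn_structure(),
         random = random_structure(...),
         chain = chain_network(...),
         identity = identity_network(...),
         constant = constant_network(...))
}
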