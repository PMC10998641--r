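#' Build the complete synchronous state transition graph
#'
#' Enumerates all `2^N` network states (encoded as integers `0..2^N-1` with
#' node 1 as the most significant bit, mirroring the truth-table row
#' convention), computes each state's unique successor, the in-degree of
#' every state, the attractors (fixed points and cycles) and every state's
#' transient length — the number of synchronous steps to the first attractor
#' state (0 exactly on attractor states).
#'
#' @param network a [boolean_network].
#' @param max_nodes exhaustive bound on N (default 20, about a million
#'   states); larger networks are refused.
#' @return object of class `stg`: list with `N`, `successor` (integer vector
#'   indexed by state + 1), `in_degree`, `attractors` (list of integer state
#'   sequences in cycle order), `attractor_of` (attractor index per state)
#'   and `transient_length`.
#' @export
build_stg <- function(network, max_nodes = 20L) {
  N <- length(network$nodes)
  if (N > max_nodes)
    stop("N = ", N, " exceeds the exhaustive STG bound (", max_nodes, ")")
  n_states <- 2^N
  states <- 0:(n_states - 1L)
  bits <- input_matrix(N)                     # 2^N x N, node 1 = MSB
  nxt_bits <- matrix(0L, n_states, N)
  for (i in seq_len(N)) {
    nd <- network$nodes[i]
    regs <- match(network$regulators[[nd]], network$nodes)
    tt <- network$functions[[nd]]
    if (tt$k == 0L) {
      nxt_bits[, i] <- tt$outputs[1]
    } else {
      idx <- as.integer(bits[, regs, drop = FALSE] %*% 2^((tt$k - 1):0))
      nxt_bits[, i] <- tt$outputs[idx + 1L]
    }
  }
  successor <- as.integer(nxt_bits %*% 2^((N - 1):0))
  in_degree <- tabulate(successor + 1L, nbins = n_states)

  # states on attractors: peel garden-of-Eden states iteratively
  deg <- in_degree
  frontier <- states[deg == 0L]
  removed <- rep(FALSE, n_states)
  while (length(frontier)) {
    removed[frontier + 1L] <- TRUE
    succ <- successor[frontier + 1L]
    dec <- table(succ)
    idx <- as.integer(names(dec)) + 1L
    deg[idx] <- deg[idx] - as.integer(dec)
    cand <- idx[deg[idx] == 0L] - 1L
    frontier <- cand[!removed[cand + 1L]]
  }
  on_cycle <- !removed

  # group cycle states into attractors, in cycle order
  attractors <- list()
  attractor_of <- integer(n_states)
  seen <- rep(FALSE, n_states)
  for (s in states[on_cycle]) {
    if (seen[s + 1L]) next
    cyc <- s
    cur <- successor[s + 1L]
    while (cur != s) { cyc <- c(cyc, cur); cur <- successor[cur + 1L] }
    seen[cyc + 1L] <- TRUE
    attractors[[length(attractors) + 1L]] <- cyc
    attractor_of[cyc + 1L] <- length(attractors)
  }

  # transient lengths and basin labels by reverse BFS from attractor states
  preds <- split(states, factor(successor, levels = states))
  transient <- rep(NA_integer_, n_states)
  transient[on_cycle] <- 0L
  frontier <- states[on_cycle]
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    prev <- unlist(preds[frontier + 1L], use.names = FALSE)
    prev <- prev[is.na(transient[prev + 1L])]
    transient[prev + 1L] <- d
    attractor_of[prev + 1L] <- attractor_of[successor[prev + 1L] + 1L]
    frontier <- prev
  }

  structure(list(N = N, successor = successor, in_degree = in_degree,
                 attractors = attractors, attractor_of = attractor_of,
                 transient_length = transient),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  g <- goe_and_bushiness(x)
  cyc_len <- lengths(x$attractors)
  cat(sprintf("stg: %d states (N = %d), %d attractor(s) (%d fixed point(s)),\n",
              2^x$N, x$N, length(x$attractors), sum(cyc_len == 1L)))
  cat(sprintf("     %d GoE states (G-density = %.4g), <d_in>_non-GoE = %.4g\n",
              length(g$goe_states), g$g_density, g$mean_indegree_non_goe))
  invisible(x)
}

#' Garden-of-Eden states and bushiness measures
#'
#' A garden-of-Eden (GoE) state has no predecessor. G-density is the GoE
#' fraction of the `2^N` states — the one-step phase-space contraction
#' factor. The mean in-degree of non-GoE states satisfies the identity
#' `<d_in>_non-GoE = 1/(1 - G-density)` exactly.
#'
#' @param stg an [build_stg] result.
#' @return list with `goe_states` (integer vector), `g_density` and
#'   `mean_indegree_non_goe`.
#' @export
goe_and_bushiness <- function(stg) {
  goe <- which(stg$in_degree == 0L) - 1L
  g_density <- length(goe) / 2^stg$N
  non_goe <- stg$in_degree[stg$in_degree > 0L]
  list(goe_states = goe, g_density = g_density,
       mean_indegree_non_goe = mean(non_goe))
}

#' Convergence rates from transient lengths
#'
#' `lambda_goe = 1/T_GoE` where `T_GoE` is the mean transient length over
#' garden-of-Eden states, and `lambda_all = 1/T_all` with the mean over all
#' `2^N` states. Undefined (NA with a flag) when no GoE state exists
#' (bijective dynamics), resp. when every state lies on an attractor.
#'
#' @param stg an [build_stg] result.
#' @return list with `lambda_goe`, `lambda_all`, `t_goe`, `t_all` and
#'   logical flags `lambda_goe_defined`, `lambda_all_defined`.
#' @export
convergence_rates <- function(stg) {
  goe <- which(stg$in_degree == 0L) - 1L
  t_goe <- if (length(goe)) mean(stg$transient_length[goe + 1L]) else NA_real_
  t_all <- mean(stg$transient_length)
  list(lambda_goe = if (length(goe) && t_goe > 0) 1 / t_goe else NA_real_,
       lambda_all = if (t_all > 0) 1 / t_all else NA_real_,
       t_goe = t_goe, t_all = t_all,
       lambda_goe_defined = length(goe) > 0L,
       lambda_all_defined = t_all > 0)
}

#' Sampled convergence rate from random initial states
#'
#' Estimates `lambda_all` without building the STG: samples initial states
#' uniformly with replacement, walks each trajectory under synchronous
#' update until it enters its attractor (detected by first state revisit)
#' counting the steps, and returns the reciprocal of the mean transient
#' length with a bootstrap standard error. With `exhaustive = TRUE` all
#' `2^N` states are used once, reproducing `lambda_all` exactly.
#'
#' @param network a [boolean_network].
#' @param n_samples number of sampled initial states.
#' @param seed integer seed.
#' @param exhaustive use every state exactly once (oracle mode).
#' @param n_boot bootstrap resamples for the standard error.
#' @return list with `lambda_random`, `t_random`, `se` (bootstrap standard
#'   error of `lambda_random`), `n_samples`, `seed`, and `defined` (FALSE
#'   when every sampled transient is 0).
#' @export
lambda_random <- function(network, n_samples = 1000L, seed = 1L,
                          exhaustive = FALSE, n_boot = 200L) {
  N <- length(network$nodes)
  trans <- with_seed(seed, {
    starts <- if (exhaustive) 0:(2^N - 1L)
              else sample.int(2^N, n_samples, replace = TRUE) - 1L
    lens <- vapply(starts, function(s) transient_by_walk(network, s),
                   numeric(1))
    lens
  })
  t_bar <- mean(trans)
  if (t_bar == 0) {
    return(list(lambda_random = NA_real_, t_random = 0, se = NA_real_,
                n_samples = length(trans), seed = seed, defined = FALSE))
  }
  se <- with_seed(seed + 1L, {
    stats::sd(vapply(seq_len(n_boot), function(b) {
      m <- mean(trans[sample.int(length(trans), replace = TRUE)])
      if (m == 0) NA_real_ else 1 / m
    }, numeric(1)), na.rm = TRUE)
  })
  list(lambda_random = 1 / t_bar, t_random = t_bar, se = se,
       n_samples = length(trans), seed = seed, defined = TRUE)
}

# Steps from integer state s to the first state of its attractor, by
# walking successors until a state repeats within the trajectory.
transient_by_walk <- function(network, s) {
  N <- length(network$nodes)
  seen <- new.env(parent = emptyenv(), size = 64L)
  traj_time <- 0L
  cur <- s
  repeat {
    key <- as.character(cur)
    t0 <- seen[[key]]
    if (!is.null(t0)) return(t0)       # cycle entry time = transient length
    seen[[key]] <- traj_time
    bitsv <- (cur %/% 2^((N - 1):0)) %% 2L
    cur <- as.integer(sum(synchronous_step(network, bitsv) * 2^((N - 1):0)))
    traj_time <- traj_time + 1L
  }
}

#' One-step perturbation response (Derrida)
#'
#' The short-term perturbation response `delta` — the slope of the Derrida
#' map at perturbation size 1 — is identical to the network sensitivity
#' `s_bar`. Optionally also returns a sampled Derrida curve: the mean
#' Hamming distance after one synchronous update of two states initially
#' differing in m random bits, for m = 1..N.
#'
#' @param network a [boolean_network].
#' @param curve also sample the Derrida curve.
#' @param n_samples state pairs per perturbation size.
#' @param seed integer seed.
#' @return list with `delta` and, when requested, `curve`
#'   (data.frame of m and mean Hamming distance after one step).
#' @export
derrida_response <- function(network, curve = FALSE, n_samples = 500L,
                             seed = 1L) {
  res <- list(delta = network_descriptors(network)$s_bar)
  if (curve) {
    N <- length(network$nodes)
    res$curve <- with_seed(seed, {
      rows <- lapply(seq_len(N), function(m) {
        h <- vapply(seq_len(n_samples), function(i) {
          x <- sample(0:1, N, replace = TRUE)
          y <- x
          flip <- sample.int(N, m)
          y[flip] <- 1L - y[flip]
          sum(synchronous_step(network, x) != synchronous_step(network, y))
        }, numeric(1))
        data.frame(m = m, mean_hamming = mean(h))
      })
      do.call(rbind, rows)
    })
  }
  res
}

#' Export an STG as an edge list
#'
#' Two columns of state bitstrings (node 1 first), one row per state:
#' `from`, `to`. With `dot = TRUE` returns Graphviz DOT text instead.
#'
#' @param stg an [build_stg] result.
#' @param dot return DOT text.
#' @return data.frame (or character scalar of DOT text).
#' @export
stg_edge_list <- function(stg, dot = FALSE) {
  fmt <- function(s) {
    m <- input_matrix(stg$N)
    apply(m[s + 1L, , drop = FALSE], 1L, paste, collapse = "")
  }
  states <- 0:(2^stg$N - 1L)
  from <- fmt(states); to <- fmt(stg$successor)
  if (dot) {
    return(paste0("digraph stg {\n",
                  paste(sprintf("  \"%s\" -> \"%s\";", from, to),
                        collapse = "\n"),
                  "\n}\n"))
  }
  data.frame(from = from, to = to)
}

#' Global STG measures of one model
#'
#' Convenience wrapper: builds the STG and returns all global measures plus
#' the network-level descriptors in one flat list (the per-model row of an
#' ensemble survey).
#'
#' @param network a [boolean_network].
#' @param n_samples samples for [lambda_random]; 0 skips it.
#' @param seed seed for [lambda_random].
#' @param max_nodes passed to [build_stg].
#' @return named list of measures.
#' @export
global_measures <- function(network, n_samples = 0L, seed = 1L,
                            max_nodes = 20L) {
  stg <- build_stg(network, max_nodes = max_nodes)
  g <- goe_and_bushiness(stg)
  cv <- convergence_rates(stg)
  nd <- network_descriptors(network)
  out <- list(g_density = g$g_density,
              mean_indegree_non_goe = g$mean_indegree_non_goe,
              lambda_goe = cv$lambda_goe, lambda_all = cv$lambda_all,
              z_bar_max = nd$z_bar_max, z_bar_min = nd$z_bar_min,
              z_bar_ave = nd$z_bar_ave, z_bar_mid = nd$z_bar_mid,
              s_bar = nd$s_bar)
  if (n_samples > 0L) {
    lr <- lambda_random(network, n_samples = n_samples, seed = seed)
    out$lambda_random <- lr$lambda_random
  }
  out
}
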