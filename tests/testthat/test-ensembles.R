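test_that("fixed points translate into per-node row constraints", {
  st <- boolean_network(c("a", "b", "c"),
                        list(a = c("b", "c"), b = "a", c = c("a", "c")))
  cons <- fixed_point_constraints(st, list(c(0, 0, 0)))
  expect_equal(cons$a, c("0" = 0L))
  expect_equal(cons$b, c("0" = 0L))
  expect_equal(cons$c, c("0" = 0L))
  # two fixed points with identical regulator rows but different outputs
  st2 <- boolean_network(c("a", "b"), list(a = "b", b = "b"))
  expect_error(fixed_point_constraints(st2, list(c(0, 1), c(1, 1))),
               "contradictory")
  # constraint count bounded by one row per fixed point per node
  md <- mdgrn_structure()
  fps <- list(rep(0L, 11), rep(1L, 11))     # mutually consistent
  cons <- fixed_point_constraints(md, fps)
  expect_lte(sum(lengths(cons)), 2L * 11L)
  expect_equal(sum(lengths(cons)), 22L)     # distinct rows at every node
})

test_that("unconstrained NCF sampling is uniform over the enumerated class", {
  set.seed(71)
  draws <- replicate(8000, encode_integer(sample_function(2, "NCF")))
  support <- vapply(enumerate_class(2, "NCF"), encode_integer, numeric(1))
  expect_setequal(unique(draws), support)
  p <- stats::chisq.test(table(factor(draws, levels = support)))$p.value
  expect_gt(p, 0.01)
})

test_that("constrained EUF sampling restricts to the brute-force support", {
  # signs (+,+), row 3 -> 1 and row 0 -> 0 leave exactly {AND, OR}
  set.seed(73)
  draws <- replicate(200, encode_integer(
    sample_function(2, "EUF", constraints = c("3" = 1L, "0" = 0L),
                    signs = c("activating", "activating"))))
  expect_setequal(unique(draws),
                  c(encode_integer(truth_table(c(0, 0, 0, 1))),   # AND
                    encode_integer(truth_table(c(0, 1, 1, 1)))))  # OR
  # monotonicity violation: row 0 -> 1 with row 3 -> 0 under (+,+)
  expect_error(sample_euf_colorprop(2, cons_rows = c(0L, 3L),
                                    cons_vals = c(1L, 0L),
                                    signs = rep("activating", 2)),
               "monotonicity")
})

test_that("sampled functions pass their class test and the constraints", {
  set.seed(79)
  for (lab in c("EF", "EUF", "RoF", "NCF")) {
    for (i in 1:20) {
      k <- sample(1:4, 1)
      r <- sample(0:(2^k - 1), 1)
      cons <- stats::setNames(sample(0:1, 1), as.character(r))
      tt <- tryCatch(sample_function(k, lab, constraints = cons),
                     error = function(e) NULL)
      if (is.null(tt)) next     # constraint infeasible for this class
      expect_equal(tt$outputs[r + 1L], unname(cons))
      expect_true(effectiveness(tt)$effective)
      if (lab == "NCF") expect_true(is_ncf(tt)$is_ncf)
      if (lab == "EUF") expect_true(input_signs(tt)$unate)
    }
  }
})

test_that("large-k samplers produce valid class members", {
  set.seed(83)
  for (i in 1:5) {
    ncf <- sample_function(5, "NCF")
    expect_true(is_ncf(ncf)$is_ncf)
    rof <- sample_function(5, "RoF")
    expect_true(input_signs(rof)$unate)    # read-once implies unate
    expect_true(effectiveness(rof)$effective)
    euf <- sample_function(5, "EUF")
    expect_true(input_signs(euf)$unate)
  }
})

test_that("the color-propagation sampler is near-uniform at small k", {
  set.seed(89)
  for (k in 2:3) {
    draws <- replicate(10000, {
      sg <- sample(c("activating", "inhibiting"), k, replace = TRUE)
      encode_integer(sample_euf_colorprop(k, signs = sg))
    })
    support <- vapply(enumerate_class(k, "EUF"), encode_integer, numeric(1))
    expect_setequal(unique(draws), support)
    emp <- table(factor(draws, levels = support)) / length(draws)
    tv <- 0.5 * sum(abs(emp - 1 / length(support)))
    expect_lt(tv, 0.1)
  }
})

test_that("ensembles keep the declared fixed points and the structure", {
  st <- identity_network(3)                      # structure reused
  fps <- list(c(0, 0, 0), c(1, 1, 1))
  ens <- generate_ensemble(st, fps, "NCF", n_models = 10, seed = 97)
  expect_length(ens$models, 10L)
  for (m in ens$models) {
    expect_equal(m$nodes, st$nodes)
    expect_equal(m$regulators, st$regulators)
    for (fp in fps) expect_equal(synchronous_step(m, fp), as.integer(fp))
  }
  # n = 0 is a valid empty ensemble
  expect_length(generate_ensemble(st, fps, "NCF", n_models = 0,
                                  seed = 1)$models, 0L)
})

test_that("different seeds give different models under the same invariants", {
  md <- mdgrn_structure()
  set.seed(101)
  fp <- list(sample(0:1, 11, replace = TRUE))
  e1 <- generate_ensemble(md, fp, "EF", n_models = 5, seed = 1)
  e2 <- generate_ensemble(md, fp, "EF", n_models = 5, seed = 2)
  enc <- function(e) unlist(lapply(e$models, function(m)
    lapply(m$functions, `[[`, "outputs")))
  expect_false(identical(enc(e1), enc(e2)))
  e1b <- generate_ensemble(md, fp, "EF", n_models = 5, seed = 1)
  expect_identical(enc(e1), enc(e1b))
})

test_that("class containment: every NCF-ensemble model passes EUF and EF tests", {
  st <- random_structure(5, 3, seed = 103)
  ens <- generate_ensemble(st, list(), "NCF", n_models = 10, seed = 107)
  for (m in ens$models) for (tt in m$functions) {
    expect_true(effectiveness(tt)$effective)
    expect_true(input_signs(tt)$unate)
    expect_true(is_ncf(tt)$is_ncf)
  }
})

test_that("ensembles serialize to BoolNet files with a manifest", {
  st <- random_structure(4, 2, seed = 109)
  ens <- generate_ensemble(st, list(), "RoF", n_models = 3, seed = 113)
  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  files <- list.files(dir)
  expect_length(grep("\\.bnet$", files), 3L)
  expect_true("manifest.json" %in% files)
  back <- read_boolnet(file.path(dir, "model_0001.bnet"))
  expect_equal(back$regulators, ens$models[[1]]$regulators)
})
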