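fig_example <- function() {
  truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
}

test_that("CC-block vector of the worked three-input example is (0, 4, 2)", {
  expect_equal(n_vector(fig_example()), c(0L, 4L, 2L))
  expect_equal(n_vector(truth_table(c(0, 1, 1, 0))), c(0L, 4L))  # parity
  expect_equal(n_vector(truth_table(rep(1, 8))), c(0L, 0L, 0L))
})

test_that("n-vector components are block-size multiples and disjoint", {
  set.seed(5)
  for (i in 1:200) {
    k <- sample(1:5, 1)
    n <- n_vector(random_tt(k))
    expect_true(all(n %% 2^(k - seq_len(k) + 1L) == 0L))
    expect_lte(sum(n), 2^k)
  }
})

test_that("Z_left reproduces the worked example and the limiting cases", {
  expect_equal(z_left(fig_example()), 0.5)
  expect_equal(z_left(truth_table(c(0, 1, 1, 0))), 1)
  expect_equal(z_left(truth_table(rep(0, 8))), 0)
  expect_equal(z_left(truth_table(c(0, 1))), 1)
})

test_that("Z_left stays within [0, 1]", {
  set.seed(6)
  for (i in 1:1000) {
    k <- sample(1:6, 1)
    z <- z_left(random_tt(k))
    expect_gte(z, 0); expect_lte(z, 1)
  }
})

test_that("Z_left is invariant under input negation and complementation", {
  set.seed(13)
  for (i in 1:200) {
    k <- sample(1:5, 1)
    tt <- random_tt(k)
    z <- z_left(tt)
    expect_equal(z_left(tt_negate_input(tt, sample.int(k, 1))), z)
    expect_equal(z_left(tt_complement(tt)), z)
  }
})

test_that("permutation variants match the worked example and symmetry", {
  zv <- z_variants(fig_example(), keep_per_permutation = TRUE)
  expect_equal(zv$z_max, 0.75)
  expect_equal(zv$z_min, 0.25)
  expect_equal(zv$z_ave, 0.5)
  expect_equal(zv$z_mid, 0.5)
  expect_equal(sort(unname(zv$per_permutation)),
               c(0.25, 0.25, 0.5, 0.5, 0.75, 0.75))
  and2 <- z_variants(truth_table(c(0, 0, 0, 1)))
  expect_equal(unlist(and2[c("z_max", "z_min", "z_ave", "z_mid")]),
               c(z_max = 0.5, z_min = 0.5, z_ave = 0.5, z_mid = 0.5))
  # symmetric function: all orderings identical
  maj <- truth_table(c(0, 0, 0, 1, 0, 1, 1, 1))
  zm <- z_variants(maj)
  expect_equal(zm$z_max, zm$z_min)
  expect_equal(zm$z_ave, zm$z_mid)
})

test_that("variant ordering invariants hold on random functions", {
  set.seed(21)
  for (i in 1:100) {
    tt <- random_tt(sample(1:4, 1))
    zv <- z_variants(tt)
    expect_lte(zv$z_min, zv$z_ave + 1e-12)
    expect_lte(zv$z_ave, zv$z_max + 1e-12)
    expect_equal(zv$z_mid, (zv$z_max + zv$z_min) / 2)
  }
})

test_that("NCF closed forms evaluate the printed formulas", {
  expect_equal(unname(ncf_closed_forms(3, 3)), c(0.75, 0.25, 0.5))
  expect_equal(unname(ncf_closed_forms(2, 1)), c(0.5, 0.5, 0.5))
  expect_equal(unname(ncf_closed_forms(3, 5)), c(0.75, 0.25, 0.5))
  expect_error(ncf_closed_forms(3, 4), "not achievable")
  expect_error(ncf_closed_forms(3, 8), "not achievable")
})

test_that("brute-force Z variants equal the NCF closed forms exactly", {
  for (k in 2:4) {
    for (tt in enumerate_class(k, "NCF")) {
      cf <- ncf_closed_forms(k, bias(tt))
      zv <- z_variants(tt)
      expect_identical(zv$z_max, unname(cf["z_max"]))
      expect_identical(zv$z_min, unname(cf["z_min"]))
      expect_identical(zv$z_mid, unname(cf["z_mid"]))
    }
  }
})

test_that("distinct permuted tables occur with equal multiplicity dividing k!", {
  dp <- distinct_permutations(truth_table(c(0, 0, 0, 0, 0, 0, 0, 1)))  # AND3
  expect_equal(dp$m, 1L)
  expect_equal(dp$multiplicities, 6L)
  dp2 <- distinct_permutations(truth_table(c(0, 0, 1, 1)))   # f = x1
  expect_equal(dp2$m, 2L)
  expect_equal(dp2$multiplicities, c(1L, 1L))
  set.seed(31)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    dp <- distinct_permutations(random_tt(k))
    expect_true(all(dp$multiplicities == dp$multiplicities[1]))
    expect_identical(factorial(k) %% dp$m, 0)
    expect_equal(dp$m * dp$multiplicities[1], factorial(k))
  }
})

test_that("z_ave over distinct permutations equals the all-orderings mean", {
  set.seed(41)
  for (i in 1:50) {
    tt <- random_tt(sample(2:4, 1))
    dp <- distinct_permutations(tt)
    expect_equal(mean(vapply(dp$tables, z_left, numeric(1))),
                 z_variants(tt)$z_ave)
  }
})

test_that("zparam_table collects one row per function", {
  tab <- zparam_table(list(fig_example(), truth_table(c(0, 0, 0, 1))))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n[1], "0,4,2")
  expect_equal(tab$z_mid, c(0.5, 0.5))
  expect_equal(tab$s, c(1.25, 1))
})
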