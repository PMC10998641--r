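test_that("expression evaluation fills the table in MSB-first row order", {
  f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
  expect_equal(f$outputs, c(0L, 0L, 1L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(truth_table_from_expression("x1", "x1")$outputs, c(0L, 1L))
  expect_equal(truth_table_from_expression("x1 & !x1", "x1")$outputs,
               c(0L, 0L))
  expect_error(truth_table_from_expression("x1 & y", "x1"), "unknown variable")
  expect_error(truth_table_from_expression("x1 &", "x1"), "unexpected end")
  expect_error(truth_table_from_expression("(x1", "x1"), "parenthesis")
})

test_that("bias counts 1-rows", {
  f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
  expect_identical(bias(f), 3L)
  expect_identical(bias(truth_table(rep(1, 4))), 4L)
  expect_identical(bias(truth_table(c(0, 1, 1, 0))), 2L)
})

test_that("effectiveness detects inputs that matter", {
  f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
  expect_true(effectiveness(f)$effective)
  proj <- truth_table(c(0, 0, 1, 1))        # f(x1,x2) = x1
  eff <- effectiveness(proj)
  expect_equal(eff$per_input, c(TRUE, FALSE))
  expect_false(eff$effective)
  expect_false(effectiveness(truth_table(rep(0, 8)))$effective)
})

test_that("input signs classify monotone directions and unateness", {
  and2 <- truth_table(c(0, 0, 0, 1))
  expect_equal(input_signs(and2)$signs, c("activating", "activating"))
  expect_true(input_signs(and2)$unate)
  xor2 <- truth_table(c(0, 1, 1, 0))
  expect_equal(input_signs(xor2)$signs, c("dual", "dual"))
  expect_false(input_signs(xor2)$unate)
  f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
  expect_equal(input_signs(f)$signs,
               c("activating", "activating", "inhibiting"))
  expect_true(input_signs(f)$unate)
})

test_that("nested canalyzing test peels layers", {
  f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
  res <- is_ncf(f)
  expect_true(res$is_ncf)
  expect_equal(nrow(res$layers), 3L)
  expect_false(is_ncf(truth_table(c(0, 1, 1, 0)))$is_ncf)   # parity
  expect_false(is_ncf(truth_table(rep(1, 8)))$is_ncf)       # constant
  expect_true(is_ncf(truth_table(c(1, 0)))$is_ncf)          # !x at k = 1
})

test_that("class enumeration matches known counts and class tests", {
  expect_length(enumerate_class(2, "NCF"), 8L)
  expect_length(enumerate_class(1, "EF"), 2L)
  # at k = 2 the read-once functions are exactly the NCFs
  enc <- function(tts) sort(vapply(tts, encode_integer, numeric(1)))
  expect_equal(enc(enumerate_class(2, "RoF")), enc(enumerate_class(2, "NCF")))
  # every enumerated member passes its class test, duplicate-free
  for (k in 2:3) {
    for (lab in c("EF", "EUF", "NCF", "RoF")) {
      pool <- enumerate_class(k, lab)
      expect_false(anyDuplicated(vapply(pool, encode_integer,
                                        numeric(1))) > 0)
      expect_true(all(vapply(pool, function(tt)
        effectiveness(tt)$effective, logical(1))))
      if (lab == "EUF")
        expect_true(all(vapply(pool, function(tt) input_signs(tt)$unate,
                               logical(1))))
      if (lab == "NCF")
        expect_true(all(vapply(pool, function(tt) is_ncf(tt)$is_ncf,
                               logical(1))))
    }
  }
  expect_error(enumerate_class(5, "NCF"), "k <= 4")
})

test_that("constructive NCF generation agrees with brute-force filtering", {
  for (k in 2:3) {
    brute <- Filter(function(tt) is_ncf(tt)$is_ncf, enumerate_class(k, "EF"))
    enc <- function(tts) sort(vapply(tts, encode_integer, numeric(1)))
    expect_equal(enc(enumerate_class(k, "NCF")), enc(brute))
  }
})

test_that("NCFs are unate, effective and of odd bias up to k = 4", {
  for (k in 2:4) {
    pool <- enumerate_class(k, "NCF")
    expect_true(all(vapply(pool, function(tt) input_signs(tt)$unate,
                           logical(1))))
    expect_true(all(vapply(pool, function(tt) effectiveness(tt)$effective,
                           logical(1))))
    expect_true(all(vapply(pool, bias, integer(1)) %% 2L == 1L))
  }
})

test_that("read-once functions are unate and effective", {
  for (k in 2:4) {
    pool <- enumerate_class(k, "RoF")
    expect_true(all(vapply(pool, function(tt) input_signs(tt)$unate,
                           logical(1))))
    expect_true(all(vapply(pool, function(tt) effectiveness(tt)$effective,
                           logical(1))))
  }
})

test_that("average sensitivity matches the naive double-loop oracle", {
  expect_equal(average_sensitivity(truth_table(c(0, 1, 1, 0))), 2)
  expect_equal(average_sensitivity(truth_table(rep(0, 16))), 0)
  expect_equal(average_sensitivity(truth_table(c(0, 0, 0, 1))), 1)
  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:5, 1)
    tt <- random_tt(k)
    expect_equal(average_sensitivity(tt), naive_sensitivity(tt))
  }
})

test_that("complementation preserves sensitivity and reflects bias", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(1:4, 1)
    tt <- random_tt(k)
    ct <- tt_complement(tt)
    expect_identical(bias(ct), as.integer(2^k - bias(tt)))
    expect_equal(average_sensitivity(ct), average_sensitivity(tt))
  }
})

test_that("integer encoding round-trips with row 0 as least-significant bit", {
  expect_equal(encode_integer(truth_table(c(0, 0, 0, 1))), 8)
  expect_equal(encode_integer(truth_table(rep(0, 8))), 0)
  set.seed(11)
  for (i in 1:100) {
    k <- sample(1:4, 1)
    tt <- random_tt(k)
    expect_equal(decode_integer(encode_integer(tt), k)$outputs, tt$outputs)
  }
  expect_error(decode_integer(16, 2), "out of range")
})

test_that("text serialization round-trips", {
  f <- truth_table_from_expression("x2 & (!x3 | x1)", c("x1", "x2", "x3"))
  line <- tt_serialize(f)
  expect_match(line, "^3 x1,x2,x3 00100011$")
  g <- tt_deserialize(line)
  expect_equal(g$outputs, f$outputs)
  expect_equal(g$labels, f$labels)
})
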