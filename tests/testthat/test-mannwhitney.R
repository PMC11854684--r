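# independent permutation oracle: U from pairwise comparisons (not ranks),
# p by explicit enumeration over all group assignments
oracle_mw <- function(a, b) {
  u_pairs <- function(x, y)
    sum(outer(x, y, function(i, j) (i > j) + 0.5 * (i == j)))
  ua <- u_pairs(a, b)
  n <- length(a) + length(b)
  pooled <- c(a, b)
  mu <- length(a) * length(b) / 2
  combs <- combn(n, length(a))
  us <- apply(combs, 2, function(idx) u_pairs(pooled[idx], pooled[-idx]))
  list(U = min(ua, length(a) * length(b) - ua),
       p = mean(abs(us - mu) >= abs(ua - mu) - 1e-9))
}

test_that("identical symmetric samples give U = 4.5 and p = 1", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3), mode = "exact")
  expect_equal(r$U, 4.5)
  expect_equal(r$p, 1)
})

test_that("complete separation of 3 vs 3 gives U = 0, exact p = 0.1", {
  r <- mann_whitney(c(1, 1, 1), c(3, 3, 3), mode = "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
})

test_that("exact p matches the permutation oracle on random grade samples", {
  set.seed(21)
  for (k in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- sample(0:3, na, replace = TRUE)
    b <- sample(0:3, nb, replace = TRUE)
    if (max(c(a, b)) == min(c(a, b))) next
    r <- mann_whitney(a, b, mode = "exact")
    o <- oracle_mw(a, b)
    expect_equal(r$U, o$U)
    expect_equal(r$p, o$p, tolerance = 1e-12)
  }
})

test_that("exact p matches wilcox.test when there are no ties", {
  set.seed(22)
  for (k in 1:10) {
    a <- sample(1:1000, 6); b <- sample(2000:3000, 5)
    a[1] <- b[1] + 17   # interleave so p is not always minimal
    r <- mann_whitney(a, b, mode = "exact")
    w <- suppressWarnings(wilcox.test(a, b, exact = TRUE, correct = FALSE))
    expect_equal(r$p, w$p.value, tolerance = 1e-12)
  }
})

test_that("normal mode matches the tie-corrected approximation", {
  a <- c(1, 2, 2, 3, 3, 3, 1, 2); b <- c(2, 3, 3, 3, 1, 2, 3, 3)
  r <- mann_whitney(a, b, mode = "normal")
  w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(r$p, w$p.value, tolerance = 1e-9)
})

test_that("degenerate all-tied input reports p = 1 with a warning", {
  expect_warning(r <- mann_whitney(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(r$p, 1)
})

test_that("empty samples are rejected", {
  expect_error(mann_whitney(numeric(0), c(1, 2)), class = "invalid_input")
})
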