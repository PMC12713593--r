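test_that("spot totals are column sums and zero-total spots are an error", {
  m <- matrix(c(1L, 3L, 2L, 4L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(spot_totals(m), c(s1 = 4, s2 = 6))

  r <- random_counts(50, 200, seed = 11)
  expect_equal(unname(spot_totals(r)),
               vapply(seq_len(ncol(r)), function(j) sum(r[, j]), numeric(1)))

  z <- matrix(0L, 2, 3, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  expect_error(spot_totals(z), "a, b, c")
})

test_that("count validation rejects malformed matrices", {
  m <- matrix(1L, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(validate_counts(m), "duplicate gene IDs")
  m2 <- matrix(c(1, 1.5, 2, 3), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(validate_counts(m2), "non-integer")
  m3 <- matrix(c(1, -1, 2, 3), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(validate_counts(m3), "negative")
})

test_that("deviance is zero for a perfect proportional fit", {
  m <- matrix(c(1L, 9L, 2L, 18L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  # g1 is 10% of both totals (10, 20)
  expect_equal(unname(binomial_deviance(m)[1]), 0, tolerance = 1e-10)
})

test_that("deviance matches the frozen two-spot worked example", {
  m <- matrix(c(3L, 7L, 0L, 10L), 2,
              dimnames = list(c("g1", "rest"), c("s1", "s2")))
  d <- binomial_deviance(m)   # g1: counts (3, 0), totals (10, 10)
  # frozen from a fine-grid likelihood maximization and an independent GLM
  expect_equal(unname(d["g1"]), 4.691077, tolerance = 1e-5)
  expect_equal(unname(d["g1"]),
               glm_deviance(m, spot_totals(m))[1], tolerance = 1e-8)
})

test_that("per-spot stratification saturates the model (deviance zero)", {
  m <- random_counts(20, 15, seed = 3)
  d <- binomial_deviance(m, groups = colnames(m))
  expect_true(all(d < 1e-8))
})

test_that("single-level grouping equals the no-groups fit", {
  m <- random_counts(30, 40, seed = 4)
  expect_equal(binomial_deviance(m, groups = rep("only", ncol(m))),
               binomial_deviance(m))
})

test_that("closed-form deviance matches the binomial GLM oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n_g <- sample(5:30, 1)
    n_s <- sample(20:80, 1)
    m <- random_counts(n_g, n_s)
    tot <- spot_totals(m)
    groups <- sample(letters[1:sample(2:4, 1)], n_s, replace = TRUE)
    expect_equal(unname(binomial_deviance(m)), glm_deviance(m, tot),
                 tolerance = 1e-6)
    expect_equal(unname(binomial_deviance(m, groups = groups)),
                 glm_deviance(m, tot, groups), tolerance = 1e-6)
  }
})

test_that("nestedness: batch model never exceeds the default deviance", {
  set.seed(7)
  m <- random_counts(40, 60)
  groups <- rep(c("a", "b"), each = 30)
  # adversarial rows: all-zero in one batch, and a gene owning a whole stratum
  m[1, 1:30] <- 0L
  m[2, ] <- 0L
  m[2, 31] <- 5L
  sat <- m
  sat[, 31] <- 0L
  sat[2, 31] <- 5L          # gene 2 accounts for every count in spot 31
  for (mm in list(m, sat)) {
    d0 <- binomial_deviance(mm)
    db <- binomial_deviance(mm, groups = groups)
    expect_true(all(db <= d0 + 1e-8 * (1 + d0)))
  }
})

test_that("deviance is invariant to spot and gene permutations", {
  m <- random_counts(25, 50, seed = 9)
  groups <- sample(c("x", "y", "z"), 50, replace = TRUE)
  d <- binomial_deviance(m, groups = groups)
  ps <- sample(ncol(m))
  pg <- sample(nrow(m))
  d_perm <- binomial_deviance(m[pg, ps], groups = groups[ps])
  expect_equal(d_perm, d[pg])
})

test_that("scaling all counts by an integer leaves fitted proportions fixed", {
  m <- random_counts(15, 30, seed = 13)
  pihat <- function(mm) rowSums(mm) / sum(spot_totals(mm))
  expect_equal(pihat(m * 3L), pihat(m))
})

test_that("gene ranks order by decreasing deviance with stable ties", {
  expect_equal(unname(rank_genes(c(5, 1, 3))), c(1L, 3L, 2L))
  expect_equal(unname(rank_genes(c(2, 2))), c(1L, 2L))
  set.seed(21)
  d <- runif(100)
  expect_equal(unname(rank_genes(d)), rank_oracle(d))
  d[4:9] <- d[2]   # heavy ties
  expect_equal(unname(rank_genes(d)), rank_oracle(d))
  expect_error(rank_genes(c(1, NaN)), "finite")
  expect_error(rank_genes(c(1, -2)), "non-negative")
})

test_that("deviance_table fills both models and is permutation invariant", {
  sim <- simulate_svg_counts(tiny_config())
  dt <- deviance_table(sim$counts, sim$annotations, "batch")
  expect_s3_class(dt, "tbl_df")
  expect_equal(nrow(dt), nrow(sim$counts))
  expect_true(all(dt$d_batch <= dt$d_default + 1e-8 * (1 + dt$d_default)))
  expect_setequal(dt$r_default, seq_len(nrow(dt)))
  expect_setequal(dt$r_batch, seq_len(nrow(dt)))

  perm <- sample(ncol(sim$counts))
  dt_perm <- deviance_table(sim$counts[, perm],
                            sim$annotations[perm, ], "batch")
  expect_equal(dt_perm, dt)
})

test_that("single-level batch variable reproduces the default model", {
  sim <- simulate_svg_counts(tiny_config(n_batches = 1L))
  expect_warning(
    dt <- deviance_table(sim$counts, sim$annotations, "batch"),
    "single level")
  expect_equal(dt$d_batch, dt$d_default)
  expect_equal(dt$r_batch, dt$r_default)
})

test_that("unknown batch variables and misaligned annotations error", {
  sim <- simulate_svg_counts(tiny_config())
  expect_error(deviance_table(sim$counts, sim$annotations, "slide"),
               "unknown batch variable")
  expect_error(deviance_table(sim$counts, sim$annotations[-1, ], "batch"),
               "missing from")
})
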