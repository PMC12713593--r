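test_that("RCD follows its defining arithmetic and zero conventions", {
  expect_equal(relative_change_in_deviance(4.2, 4.2), 0)
  expect_equal(relative_change_in_deviance(6, 4), 0.5)
  expect_equal(relative_change_in_deviance(0, 0), 0)
  expect_equal(relative_change_in_deviance(3, 0), Inf)
  expect_error(relative_change_in_deviance(-1, 2), "non-negative")
})

test_that("RD is the rank difference, sums to zero, validates permutations", {
  expect_equal(rank_deviance(1L, 1L), 0L)
  set.seed(5)
  r1 <- sample(500L)
  r2 <- sample(500L)
  rd <- rank_deviance(r1, r2)
  expect_equal(rd, r2 - r1)
  expect_equal(sum(rd), 0L)
  expect_error(rank_deviance(c(1L, 1L), c(1L, 2L)), "permutation")
})

test_that("a gene moving from rank 1 to rank 500 has RD 499", {
  r_default <- 1:500
  r_batch <- c(500L, 2:499, 1L)   # the former top gene drops to the bottom
  expect_equal(rank_deviance(r_default, r_batch)[1], 499L)
})

test_that("nSD standardises to mean 0, sample SD 1", {
  expect_equal(nsd(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  z <- nsd(rnorm(1000, 5, 3))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("degenerate and sentinel nSD inputs behave as documented", {
  expect_warning(z <- nsd(c(5, 5, 5)), "zero")
  expect_equal(z, c(0, 0, 0))
  z2 <- nsd(c(1, 2, 3, Inf))
  expect_equal(z2[4], Inf)
  expect_equal(z2[1:3], c(-1, 0, 1))   # Inf excluded from mean/SD
  expect_error(nsd(1), "at least 2")
})

test_that("detect_bias flags one-sided per mode and respects cutoffs", {
  n <- 40
  d_default <- rep(100, n)
  d_batch <- rep(95, n)
  d_batch[1] <- 10          # strong positive RCD outlier
  d_default[2] <- 60        # gene *gains* importance under batch (negative)
  dev <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:n), batch_var = "sample",
    d_default = d_default, d_batch = d_batch,
    r_default = rank_genes(d_default), r_batch = rank_genes(d_batch))

  b_rcd <- detect_bias(dev, mode = "rcd_only")
  expect_true("g01" %in% b_rcd$flagged$sample)
  expect_false("g02" %in% b_rcd$flagged$sample)  # one-sided: never flagged

  b_int <- detect_bias(dev, mode = "intersection")
  b_uni <- detect_bias(dev, mode = "union")
  expect_true(all(b_int$flagged$sample %in% b_uni$flagged$sample))
})

test_that("no outliers means empty flagged set and unchanged SVG list", {
  dev <- tibble::tibble(
    gene_id = letters[1:10], batch_var = "b",
    d_default = seq(10, 100, by = 10), d_batch = seq(9, 99, by = 10),
    r_default = 10:1, r_batch = 10:1)
  expect_warning(b <- detect_bias(dev), "zero")  # RD degenerate: all equal
  expect_length(b$flagged$b, 0)
  expect_equal(refine_svg_list(letters[1:10], b), letters[1:10])
})

test_that("infinite RCD force-flags regardless of mode", {
  dev <- tibble::tibble(
    gene_id = letters[1:5], batch_var = "b",
    d_default = c(50, 10, 11, 12, 13), d_batch = c(0, 9, 10, 11, 12),
    r_default = c(1L, 5L, 4L, 3L, 2L), r_batch = c(5L, 4L, 3L, 2L, 1L))
  b <- detect_bias(dev, mode = "rd_only")
  expect_true("a" %in% b$flagged$b)
  expect_equal(tidy(b)$nsd_rcd[1], Inf)
})

test_that("single-level batch variable flags nothing", {
  sim <- simulate_svg_counts(tiny_config(n_batches = 1L))
  suppressWarnings({
    dt <- deviance_table(sim$counts, sim$annotations, "batch")
    b <- detect_bias(dt)
  })
  tb <- tidy(b)
  expect_true(all(tb$rcd == 0))
  expect_true(all(tb$rd == 0L))
  expect_length(b$flagged$batch, 0)
})

test_that("injected batch effects outscore null genes on RCD", {
  # effect gene vs null gene across 100 seeded replicates
  wins <- 0L
  for (s in 1:100) {
    sim <- simulate_svg_counts(
      tiny_config(n_genes = 40L, n_spots_per_batch = 30L,
                  n_batch_biased = 1L, n_spatial = 0L, seed = s))
    dt <- deviance_table(sim$counts, sim$annotations, "batch")
    rcd <- relative_change_in_deviance(dt$d_default, dt$d_batch)
    effect <- rcd[dt$gene_id %in% sim$truth$biased_gene_ids]
    null <- rcd[dt$gene_id == "gene00030"]
    if (effect > null) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("flagged sets shrink weakly as cutoffs rise", {
  sim <- simulate_svg_counts(tiny_config())
  dt <- deviance_table(sim$counts, sim$annotations, "batch")
  for (mode in c("union", "intersection", "rcd_only", "rd_only")) {
    prev <- NULL
    for (cut in c(1, 2, 3, 5, 10)) {
      f <- detect_bias(dt, cut, cut, mode = mode)$flagged$batch
      if (!is.null(prev)) expect_true(all(f %in% prev))
      prev <- f
    }
  }
})

test_that("refine_svg_list is an order-preserving set difference", {
  svgs <- sprintf("g%02d", 10:1)
  expect_equal(refine_svg_list(svgs, c("g03", "g07")),
               setdiff(svgs, c("g03", "g07")))
  expect_equal(refine_svg_list(svgs, character()), svgs)
  expect_equal(refine_svg_list(svgs, list(c("g01", "g02"), c("g02", "g03"))),
               sprintf("g%02d", 10:4))
  expect_error(refine_svg_list(svgs, "unknown"), "bookkeeping")
})

test_that("tidy and glance expose the bias results", {
  sim <- simulate_svg_counts(tiny_config())
  b <- detect_bias(deviance_table(sim$counts, sim$annotations, "batch"))
  tb <- tidy(b)
  expect_named(tb, c("gene_id", "batch_var", "d_default", "d_batch",
                     "r_default", "r_batch", "rcd", "rd",
                     "nsd_rcd", "nsd_rd", "flagged"))
  g <- glance(b)
  expect_equal(g$n_genes, nrow(sim$counts))
  expect_equal(g$n_flagged, sum(tb$flagged))
  # cross-table invariants
  expect_equal(sum(tb$rd), 0L)
  fin <- is.finite(tb$nsd_rcd)
  expect_equal(mean(tb$nsd_rcd[fin]), 0, tolerance = 1e-9)
  expect_equal(sd(tb$nsd_rcd[fin]), 1, tolerance = 1e-9)
})
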