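test_that("k-means grouping matches the optimal 1-D partition and orders groups", {
  m <- c(s1 = 90, s2 = 89, s3 = 70, s4 = 69, s5 = 52, s6 = 51)
  p <- kmeans_skill_groups(m, seed = 1)
  expect_equal(unname(p$group_of),
               factor(c("GI", "GI", "GII", "GII", "GIII", "GIII"),
                      levels = c("GI", "GII", "GIII")))
  expect_true(all(diff(p$centroids) < 0))
  p2 <- kmeans_skill_groups(m, seed = 1)
  expect_identical(p$group_of, p2$group_of)
  expect_error(kmeans_skill_groups(rep(50, 6)), "degenerate")
  expect_error(kmeans_skill_groups(c(1, 2)), "fewer subjects")
})

test_that("three accuracy strata are recovered exactly at 10-point separation", {
  skip_if_not_installed("mclust")
  for (seed in 1:5) {
    set.seed(seed)
    truth <- rep(c("GI", "GII", "GIII"), times = c(5, 6, 7))
    m <- c(stats::rnorm(5, 85, 1.5), stats::rnorm(6, 72, 1.5),
           stats::rnorm(7, 58, 1.5))
    names(m) <- paste0("s", seq_along(m))
    p <- kmeans_skill_groups(m, seed = seed)
    expect_equal(mclust::adjustedRandIndex(as.character(p$group_of), truth), 1)
  }
})

test_that("relevance mapping normalizes, merges beta by maximum, and localizes", {
  C <- 16
  pidx <- fc_pair_index(C)
  P <- C * (C - 1) / 2
  # single nonzero coefficient dominates after min-max normalization
  co <- matrix(0, 4 * P, 1); co[10] <- -3
  fake <- structure(list(coefficients = co), class = "lda_model")
  rm1 <- relevance_from_lda(fake, pidx)
  expect_equal(max(rm1$per_band_weights), 1)
  expect_equal(sum(rm1$per_band_weights), 1)
  expect_length(rm1$merged_weights, C * (C - 1))

  # beta blocks merge element-wise by max
  co2 <- matrix(0, 4 * P, 1)
  co2[1 * P + 3] <- 0.2; co2[2 * P + 3] <- 0.9; co2[3 * P + 3] <- 0.4
  rm2 <- relevance_from_lda(structure(list(coefficients = co2),
                                      class = "lda_model"), pidx)
  expect_equal(rm2$merged_weights[P + 3], 1)  # 0.9 is the global max -> 1

  # class signal planted in known feature pairs reaches the top decile
  set.seed(9)
  n <- 120
  x <- matrix(stats::rnorm(n * 4 * P), n)
  y <- rep(0:1, each = n / 2)
  planted <- c(5, 40, 2 * P + 17)
  for (j in planted) x[, j] <- x[, j] + 1.5 * y
  model <- fit_lda(x, y)
  rmap <- relevance_from_lda(model, pidx)
  top <- order(rmap$per_band_weights, decreasing = TRUE)[seq_len(ceiling(0.1 * 4 * P))]
  expect_true(all(planted %in% top))
})

test_that("group relevance reports per-link maxima above the threshold", {
  C <- 8; P <- C * (C - 1) / 2
  pidx <- fc_pair_index(C)
  mk <- function(seed) {
    set.seed(seed)
    co <- matrix(stats::runif(4 * P), ncol = 1)
    relevance_from_lda(structure(list(coefficients = co), class = "lda_model"),
                       pidx)
  }
  maps <- list(a = mk(1), b = mk(2), c = mk(3))
  part <- structure(list(group_of = factor(c(a = "GI", b = "GI", c = "GII"),
                                           levels = c("GI", "GII", "GIII"))),
                    class = "skill_partition")
  gr <- group_relevance(maps, part, "GI", 0.9)
  stacked <- rbind(maps$a$merged_weights, maps$b$merged_weights)
  expect_equal(gr$max_weights, apply(stacked, 2, max))
  expect_equal(nrow(group_relevance(maps, part, "GI", 1.01)$links), 0)
  single <- group_relevance(maps, part, "GII", 0.9)
  expect_equal(single$max_weights, maps$c$merged_weights)
  expect_error(group_relevance(maps, part, "GIII"), "empty group")
})
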