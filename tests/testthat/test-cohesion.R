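test_that("focus distances follow Euclidean geometry in 2D and 3D", {
  expect_equal(foci_distance(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(foci_distance(rbind(c(0, 0, 0), c(1, 2, 2))), 3)
  expect_true(is.na(foci_distance(rbind(c(1, 1)))))
  expect_error(foci_distance(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "condensorheo_ambiguity_error")
})

test_that("split classification uses a strict 1.6 um threshold", {
  mk <- function(d, id) list(cell_id = id,
                             centroids = rbind(c(0, 0), c(0, d)))
  recs <- Map(mk, c(0.5, 2.0, 1.6, 3.1), letters[1:4])
  s <- classify_split(recs, threshold = 1.6)
  expect_equal(s$n_split, 2L)           # 1.6 is not > 1.6
  expect_equal(s$percent_split, 50)
  # single-focus cells are never split
  singles <- lapply(1:5, function(i) list(cell_id = i,
                                          centroids = rbind(c(0, 0))))
  expect_equal(classify_split(singles)$percent_split, 0)
  expect_error(classify_split(list()), class = "condensorheo_param_error")
})

test_that("population split fraction equals the counting oracle exactly", {
  set.seed(33)
  n <- 1000
  # two-component mixture: cohered ~N(0.6, 0.2), split ~N(2.5, 0.5)
  split_true <- runif(n) < 0.3
  d <- ifelse(split_true, rnorm(n, 2.5, 0.5), abs(rnorm(n, 0.6, 0.2)))
  d <- pmax(d, 0.01)
  recs <- lapply(seq_len(n), function(i)
    list(cell_id = i, centroids = rbind(c(0, 0), c(d[i], 0))))
  s <- classify_split(recs, threshold = 1.6)
  expect_equal(s$n_split, sum(d > 1.6))
  expect_equal(s$percent_split, 100 * sum(d > 1.6) / n)
  # order invariance
  expect_equal(classify_split(rev(recs))$percent_split, s$percent_split)
  # rigid transformation invariance (rotation + translation of all cells)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  recs_rot <- lapply(recs, function(r)
    list(cell_id = r$cell_id, centroids = r$centroids %*% rot + 5))
  expect_equal(classify_split(recs_rot)$percent_split, s$percent_split)
  # monotone non-increasing in the threshold
  pct <- vapply(c(0.5, 1.0, 1.6, 2.5, 4.0), function(thr)
    classify_split(recs, thr)$percent_split, 1.0)
  expect_true(all(diff(pct) <= 0))
})

test_that("distance time series track separating foci", {
  recs <- lapply(0:5, function(t)
    list(cell_id = "c1", time_s = 60 * t,
         centroids = rbind(c(0, 0), c(0.5 + 0.4 * t, 0))))
  ts <- distance_timeseries(recs)$c1
  expect_equal(ts$distance, 0.5 + 0.4 * (0:5))
  expect_equal(diff(ts$distance), rep(0.4, 5), tolerance = 1e-12)
  # classification toggles at the strict crossing
  over <- ts$distance > 1.6
  expect_equal(over, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  # static foci give a constant series; single focus gives NA
  stat <- lapply(0:3, function(t)
    list(cell_id = "c2", time_s = t,
         centroids = if (t == 2) rbind(c(0, 0))
                     else rbind(c(0, 0), c(1, 0))))
  ts2 <- distance_timeseries(stat)$c2
  expect_equal(ts2$distance[c(1, 2, 4)], rep(1, 3))
  expect_true(is.na(ts2$distance[3]))
})

test_that("replicate comparison matches the textbook t formulas", {
  set.seed(44)
  a <- rnorm(6, 30, 8); b <- rnorm(6, 45, 8)
  un <- compare_replicates(a, b, paired = FALSE)
  expect_equal(un$statistic, oracle_t_unpaired(a, b), tolerance = 1e-10)
  pa <- compare_replicates(a, b, paired = TRUE)
  expect_equal(pa$statistic, oracle_t_paired(a, b), tolerance = 1e-10)
  # identical groups: t = 0, p = 1 (unpaired; paired is degenerate)
  same <- compare_replicates(c(10, 20, 30), c(10, 20, 30), paired = FALSE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # constant paired differences: degenerate, flagged not thrown
  deg <- compare_replicates(c(10, 20, 30), c(15, 25, 35), paired = TRUE)
  expect_true(deg$degenerate)
  expect_error(compare_replicates(1, c(1, 2)),
               class = "condensorheo_param_error")
})
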