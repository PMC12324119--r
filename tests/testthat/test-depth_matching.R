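test_that("downsample_site degenerate draws are deterministic", {
  set.seed(1)
  expect_equal(downsample_site(rep(5L, 100), rep(5L, 100), 10L),
               rep(5L, 100))                      # full draw
  expect_equal(downsample_site(rep(10L, 100), rep(0L, 100), 4L),
               rep(4L, 100))                      # all-methylated pool
  expect_error(downsample_site(3L, 2L, 10L), "exceeds observed depth")
})

test_that("hypergeometric mean and variance match closed forms", {
  # K = 6 methylated of N = 10 reads, draw n = 5:
  # E[k] = n K / N = 3; Var = n K/N (1-K/N) (N-n)/(N-1)
  set.seed(42)
  reps <- 10000L
  k <- downsample_site(rep(6L, reps), rep(4L, reps), 5L)
  m_exp <- 5 * 6 / 10
  v_exp <- 5 * 0.6 * 0.4 * (10 - 5) / (10 - 1)
  se_mean <- sqrt(v_exp / reps)
  expect_lt(abs(mean(k) - m_exp), 3 * se_mean)
  # variance of the sample variance ~ 2 v^2 / n for a rough 3-sigma band
  expect_lt(abs(var(k) - v_exp), 3 * sqrt(2 * v_exp^2 / reps))
  # also the spec's (6,4,5) mean example at +-0.05
  expect_lt(abs(mean(k) - 3.0), 0.05)
})

test_that("resampled levels are confined to the matched-depth lattice", {
  set.seed(7)
  for (d in 1:10) {
    lattice <- 100 * (0:d) / d
    for (n_meth in c(0L, 3L, 7L, 12L)) {
      n_unmeth <- 12L - pmin(n_meth, 12L) + 2L
      k <- downsample_site(rep(n_meth, 200), rep(n_unmeth, 200), d)
      lv <- 100 * k / d
      expect_true(all(lv %in% lattice),
                  info = sprintf("d=%d n_meth=%d", d, n_meth))
    }
  }
})

shared_pair <- function(n = 400, seed = 2) {
  set.seed(seed)
  pos <- sort(sample(0:99999, n))
  theta <- rbeta(n, 2, 2)
  da <- pmax(4L, rpois(n, 25)); db <- pmax(4L, rpois(n, 8))
  ka <- rbinom(n, da, theta); kb <- rbinom(n, db, theta)
  list(a = callset(data.frame(chrom = "chr1", pos = pos, n_meth = ka,
                              n_unmeth = da - ka), genome_id = "g"),
       b = callset(data.frame(chrom = "chr1", pos = pos, n_meth = kb,
                              n_unmeth = db - kb), genome_id = "g"))
}

test_that("run_depth_matched is reproducible byte-for-byte under a seed", {
  pr <- shared_pair()
  cfg <- downsample_config(n_replicates = 5L, seed = 99L)
  r1 <- run_depth_matched(pr$a, pr$b, cfg)
  r2 <- run_depth_matched(pr$a, pr$b, cfg)
  expect_identical(r1$sites, r2$sites)
  expect_identical(r1$r_overall, r2$r_overall)
  expect_identical(r1$r_by_depth, r2$r_by_depth)
  # a different seed gives different draws
  r3 <- run_depth_matched(pr$a, pr$b,
                          downsample_config(n_replicates = 5L, seed = 100L))
  expect_false(identical(r1$r_overall, r3$r_overall))
})

test_that("downsampling is unbiased: mean resampled level ~ original", {
  pr <- shared_pair(300, seed = 4)
  cfg <- downsample_config(n_replicates = 400L, seed = 8L)
  run <- run_depth_matched(pr$a, pr$b, cfg)
  shared <- merge(pr$a$calls, pr$b$calls, by = c("chrom", "pos"),
                  suffixes = c("_a", "_b"))
  m <- merge(run$sites, shared, by = c("chrom", "pos"))
  # hypergeometric mean preserves the level; averaged over sites and
  # replicates the paired difference concentrates near zero
  expect_lt(abs(mean(m$mean_level_a - m$level_a)), 0.15)
  expect_lt(abs(mean(m$mean_level_b - m$level_b)), 0.15)
  # identical platforms: expected paired level difference is zero even
  # though independent draws keep every replicate r below 1
  run_aa <- run_depth_matched(pr$a, pr$a,
                              downsample_config(n_replicates = 200L,
                                                seed = 5L))
  expect_lt(abs(mean(run_aa$sites$mean_level_a -
                       run_aa$sites$mean_level_b)), 0.2)
})

test_that("sites already at the matched depth keep their counts", {
  a <- callset(data.frame(chrom = "chr1", pos = 1:50, n_meth = 5,
                          n_unmeth = 5))
  b <- callset(data.frame(chrom = "chr1", pos = 1:50, n_meth = 20,
                          n_unmeth = 10))
  run <- run_depth_matched(a, b, downsample_config(n_replicates = 3L,
                                                   seed = 1L))
  # matched depth is 10 = platform A's own depth -> A levels unchanged
  expect_true(all(run$sites$mean_level_a == 50))
})

test_that("r_by_depth_level summarizes replicate r distributions", {
  pr <- shared_pair(600, seed = 6)
  run <- run_depth_matched(pr$a, pr$b,
                           downsample_config(n_replicates = 50L, seed = 2L))
  tab <- r_by_depth_level(run, min_sites = 20L)
  expect_true(all(tab$r_min <= tab$r_q1 & tab$r_q1 <= tab$r_median &
                    tab$r_median <= tab$r_q3 & tab$r_q3 <= tab$r_max))
  # depth levels below the site threshold are excluded
  expect_true(all(tab$n_sites >= 20L))
  # independent uniform levels: median replicate r stays near 0
  set.seed(9)
  n <- 2000
  mk <- function() {
    k <- rbinom(n, 20, runif(n))
    callset(data.frame(chrom = "chr1", pos = 1:n, n_meth = k,
                       n_unmeth = 20 - k), genome_id = "g")
  }
  run0 <- run_depth_matched(mk(), mk(),
                            downsample_config(n_replicates = 40L,
                                              seed = 3L))
  tab0 <- r_by_depth_level(run0, min_sites = 1000L)
  expect_true(all(abs(tab0$r_median) < 0.06))
})

test_that("binomial (with-replacement) mode is available", {
  set.seed(11)
  k <- downsample_site(rep(6L, 5000), rep(4L, 5000), 5L, replace = TRUE)
  expect_lt(abs(mean(k) - 3.0), 0.1)
  # with replacement the draw may exceed observed depth
  expect_silent(downsample_site(3L, 2L, 10L, replace = TRUE))
})
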