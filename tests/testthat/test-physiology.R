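trial_df <- function(ratios, ec_f = 100) {
  data.frame(ec_i = ratios * ec_f, ec_f = rep(ec_f, length(ratios)))
}

test_that("damage index identities hold", {
  # R_t = R_o -> 0
  expect_equal(damage_index(trial_df(0.2), trial_df(0.2))$d_i, 0)
  # R_t = 1 -> 100 regardless of R_o
  for (ro in c(0.05, 0.2, 0.6)) {
    expect_equal(damage_index(trial_df(1), trial_df(ro))$d_i, 100)
  }
  # R_t = 0.6, R_o = 0.2 -> 50
  expect_equal(damage_index(trial_df(0.6), trial_df(0.2))$d_i, 50)
  expect_error(damage_index(trial_df(0.5), trial_df(1)), "fully leaked")
  expect_error(damage_index(data.frame(ec_i = -1, ec_f = 2),
                            trial_df(0.2)), "positive")
})

test_that("damage index is ratio-scale invariant and monotone in R_t", {
  set.seed(30)
  for (i in 1:20) {
    fr <- data.frame(ec_i = runif(3, 10, 50), ec_f = runif(3, 60, 120))
    ct <- data.frame(ec_i = runif(3, 5, 20), ec_f = runif(3, 60, 120))
    base <- damage_index(fr, ct)$d_i
    k <- runif(1, 0.1, 10)
    scaled <- damage_index(fr * k, ct * k)
    expect_equal(scaled$d_i, base, tolerance = 1e-12)
  }
  ro <- 0.15
  d <- vapply(seq(0.2, 1, by = 0.1), function(rt) {
    damage_index(trial_df(rt), trial_df(ro))$d_i
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("noise-free EL simulation round-trips exactly", {
  truth <- data.frame(genotype = rep(c("a", "b"), each = 3),
                      species = rep(c("A", "B"), each = 3),
                      temperature = rep(c(-10, -20, -30), 2),
                      true_di = c(5, 40, 90, 0, 55.5, 100))
  tab <- simulate_el_table(truth, el_noise_sd = 0, seed = 31)
  di <- damage_index_table(tab)
  merged <- merge(truth, di, by = c("genotype", "temperature"))
  expect_equal(merged$d_i, merged$true_di, tolerance = 1e-9)
  expect_error(simulate_el_table(transform(truth, true_di = 150)),
               "\\[0, 100\\]")
})

test_that("noisy EL recovery is unbiased", {
  truth <- data.frame(genotype = "g", species = "S", temperature = -20,
                      true_di = 60)
  set.seed(32)
  rec <- replicate(100, {
    tab <- simulate_el_table(truth, el_noise_sd = 1)
    damage_index_table(tab)$d_i
  })
  expect_lt(abs(mean(rec) - 60), 2 * sd(rec) / sqrt(100))
})

test_that("winterkill bands follow the 1-5 field scale", {
  expect_equal(winterkill_rating(0, FALSE), 1L)
  expect_equal(winterkill_rating(4.9, TRUE), 1L)
  expect_equal(winterkill_rating(5, FALSE), 2L)
  expect_equal(winterkill_rating(30, FALSE), 3L)
  expect_equal(winterkill_rating(60, TRUE), 4L)
  expect_equal(winterkill_rating(95, FALSE), 5L)
  expect_equal(winterkill_rating(95, TRUE), 4L)
  expect_equal(winterkill_rating(100, FALSE), 5L)
  expect_error(winterkill_rating(101, FALSE))
  # non-decreasing in damage for a fixed resprout flag
  for (rs in c(TRUE, FALSE)) {
    r <- winterkill_rating(seq(0, 100, by = 0.5), rs)
    expect_true(all(diff(r) >= 0))
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(sample(4:10, 1)); y <- rnorm(sample(4:10, 1), mean = 1)
    res <- anova_lsd(c(x, y), rep(c("a", "b"), c(length(x), length(y))))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("equal group means give F = 0 and one shared letter", {
  v <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_lsd(v, g)
  expect_equal(res$f, 0)
  expect_false(res$protected)
  expect_true(all(res$means$letters == res$means$letters[1]))
})

test_that("clearly separated groups get distinct letters", {
  set.seed(34)
  v <- c(rnorm(5, 0, 0.1), rnorm(5, 5, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("lo", "mid", "hi"), each = 5)
  res <- anova_lsd(v, g)
  expect_true(res$protected)
  expect_equal(length(unique(res$means$letters)), 3)
  expect_true(is.finite(res$lsd) && res$lsd > 0)
})

test_that("protection keeps the null letter-split rate near alpha", {
  set.seed(35)
  reps <- 1000
  splits <- replicate(reps, {
    v <- rnorm(12)
    g <- rep(c("a", "b", "c"), each = 4)
    res <- anova_lsd(v, g)
    length(unique(res$means$letters)) > 1
  })
  expect_lte(mean(splits), 0.06)
})

test_that("group_summary matches direct mean/SE arithmetic", {
  rec <- data.frame(species = rep(c("A", "B"), c(3, 1)),
                    temperature = -10,
                    value = c(2, 4, 6, 9))
  out <- group_summary(rec)
  a <- out[out$species == "A", ]
  expect_equal(a$mean, 4)
  expect_equal(a$se, sd(c(2, 4, 6)) / sqrt(3))
  b <- out[out$species == "B", ]
  expect_true(is.na(b$se)) # single record
  same <- group_summary(data.frame(species = "A", temperature = -10,
                                   value = c(3, 3, 3)))
  expect_equal(same$se, 0)
})
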