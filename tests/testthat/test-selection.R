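# The six feature-evaluation methods.

make_planted <- function(seed = 1, n = 400) {
  generate_tabular_dataset(tabular_sim_config(n_samples = n, seed = seed))
}

test_that("mutual information ranks a label copy first and noise near zero", {
  set.seed(31)
  n <- 2000
  y <- factor(rep(c("a", "b", "c", "d"), length.out = n))
  X <- cbind(copy = as.numeric(y) + 0.001 * rnorm(n),
             noise1 = runif(n), noise2 = rnorm(n))
  r <- rank_mutual_information(X, y, selection_config("MI", seed = 2))
  expect_equal(r$ranking[1], "copy")
  expect_lt(r$scores["noise1"], 0.05)
  expect_lt(r$scores["noise2"], 0.05)
  expect_true(all(r$scores >= 0))
  # constant feature scores zero, no error
  Xc <- cbind(X, flat = rep(1, n))
  rc <- rank_mutual_information(Xc, y, selection_config("MI", seed = 2))
  expect_equal(unname(rc$scores["flat"]), 0)
})

test_that("mutual information is stable under monotone feature transforms", {
  tab <- make_planted(seed = 3, n = 600)
  r1 <- rank_mutual_information(tab$X, tab$y, selection_config("MI", seed = 4))
  Xt <- tab$X
  Xt[, "inf1"] <- exp(Xt[, "inf1"] / 4)
  Xt[, "inf3"] <- Xt[, "inf3"]^3
  r2 <- rank_mutual_information(Xt, tab$y, selection_config("MI", seed = 4))
  expect_lt(abs(r1$scores["inf1"] - r2$scores["inf1"]), 0.1)
  expect_lt(abs(r1$scores["inf3"] - r2$scores["inf3"]), 0.1)
})

test_that("univariate F matches the hand-computed two-group ANOVA", {
  y <- factor(rep(c("a", "b"), each = 3))
  X <- cbind(toy = c(1, 2, 3, 7, 8, 9))
  r <- rank_univariate(X, y)
  expect_equal(unname(r$scores["toy"]), 54)
  # cross-check against the stock ANOVA fit
  expect_equal(unname(r$scores["toy"]),
               unname(summary(stats::aov(X[, 1] ~ y))[[1]]$`F value`[1]))
})

test_that("univariate ranking separates signal from identical distributions", {
  set.seed(37)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(A = c(rnorm(n / 2), rnorm(n / 2) + 10), B = rnorm(n))
  r <- rank_univariate(X, y)
  expect_equal(r$ranking[1], "A")
  # permuting labels destroys the ranking signal
  set.seed(38)
  yp <- sample(y)
  rp <- rank_univariate(X, yp)
  expect_lt(rp$scores["A"], r$scores["A"] / 100)
})

test_that("zero within-class variance gets an infinite sentinel, ranked first", {
  y <- factor(rep(c("a", "b"), each = 4))
  X <- cbind(perfect = rep(c(0, 1), each = 4), other = rnorm(8))
  expect_message(r <- rank_univariate(X, y), "zero within-class")
  expect_equal(r$ranking[1], "perfect")
  expect_true(is.infinite(r$scores["perfect"]))
})

test_that("RFE returns all features when nothing must be eliminated", {
  tab <- make_planted(seed = 5, n = 200)
  cfg <- selection_config("RFE", n_select = ncol(tab$X))
  r <- select_rfe(tab$X, tab$y, cfg)
  expect_setequal(r$selected, colnames(tab$X))
  expect_length(r$trace$elimination_order, 0)
})

test_that("RFE recovers a planted informative pair among noise", {
  set.seed(41)
  n <- 400
  y <- factor(rep(c("a", "b", "c"), length.out = n))
  cls <- as.numeric(y)
  X <- cbind(sig1 = 3 * (cls %% 2) + rnorm(n) * 0.3,
             sig2 = 3 * (cls >= 2) + rnorm(n) * 0.3,
             matrix(rnorm(n * 8), n, 8,
                    dimnames = list(NULL, paste0("ns", 1:8))))
  r <- select_rfe(X, y, selection_config("RFE", n_select = 2))
  expect_setequal(r$selected, c("sig1", "sig2"))
  # elimination trace is consistent: eliminated + selected partition the set
  expect_setequal(c(r$trace$elimination_order, r$selected), colnames(X))
  # rfe_step as a fraction also reaches the requested size
  r2 <- select_rfe(X, y, selection_config("RFE", n_select = 2,
                                          rfe_step = 0.3))
  expect_length(r2$selected, 2)
})

test_that("extra-trees importances are normalized, deterministic and focused", {
  set.seed(43)
  n <- 1000
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(s1 = ifelse(y == "a", 0, 4) + rnorm(n) * 0.5,
             s2 = ifelse(y == "a", 2, -2) + rnorm(n) * 0.5,
             matrix(rnorm(n * 8), n, 8,
                    dimnames = list(NULL, paste0("ns", 1:8))))
  cfg <- selection_config("FI", seed = 9)
  r1 <- rank_feature_importance(X, y, cfg)
  r2 <- rank_feature_importance(X, y, cfg)
  expect_equal(sum(r1$scores), 1, tolerance = 1e-9)
  expect_identical(r1$ranking, r2$ranking)
  noise_share <- sum(r1$scores[paste0("ns", 1:8)])
  expect_lt(noise_share, 0.30)
})

test_that("mRMR picks the most relevant feature first and defers duplicates", {
  tab <- make_planted(seed = 7, n = 300)
  ust <- rank_univariate(tab$X, tab$y)
  r1 <- select_mrmr(tab$X, tab$y, selection_config("MRMR", n_select = 1))
  expect_equal(r1$selected, ust$ranking[1])
  # exact duplicate of the top feature is never chosen while others remain
  Xd <- cbind(tab$X, dupe = tab$X[, ust$ranking[1]])
  rd <- select_mrmr(Xd, tab$y, selection_config("MRMR", n_select = 10))
  expect_false("dupe" %in% rd$selected)
})

test_that("mRMR greedy trace equals the brute-force criterion oracle", {
  for (seed in c(11, 12, 13)) {
    tab <- generate_tabular_dataset(tabular_sim_config(
      n_samples = 150, n_informative = 3, n_redundant = 3, n_noise = 4,
      seed = seed))
    got <- select_mrmr(tab$X, tab$y,
                       selection_config("MRMR", n_select = 6))$selected
    expect_identical(got, oracle_mrmr(tab$X, tab$y, 6), label = paste(seed))
  }
})

test_that("backward elimination keeps a perfectly separating feature", {
  set.seed(47)
  n <- 100
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(strong = ifelse(y == "a", 0, 1) + rnorm(n) * 0.01,
             weak = rnorm(n))
  r <- select_backward_elimination(X, y)
  expect_true("strong" %in% r$selected)
})

test_that("backward elimination's final fit clears alpha on pure noise", {
  survivors <- integer(20)
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 500
    y <- factor(rep(c("a", "b"), each = n / 2))
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    r <- select_backward_elimination(X, y)
    survivors[s] <- length(r$selected)
    if (length(r$selected) > 0)
      expect_true(all(r$trace$final_p[r$selected] < 0.05))
    # removal trace strictly shrinks the set
    expect_equal(nrow(r$trace$removals) + length(r$selected), 10)
  }
  expect_lte(median(survivors), 1)
})

test_that("backward elimination removal order matches the refit oracle", {
  for (seed in c(21, 22)) {
    tab <- generate_tabular_dataset(tabular_sim_config(
      n_samples = 120, n_informative = 2, n_redundant = 1, n_noise = 3,
      seed = seed))
    r <- select_backward_elimination(tab$X, tab$y)
    active <- colnames(tab$X)
    for (k in seq_len(nrow(r$trace$removals))) {
      nxt <- oracle_be_next_removal(tab$X, tab$y, active, 0.05)
      expect_identical(r$trace$removals$feature[k], nxt,
                       label = paste("seed", seed, "step", k))
      active <- setdiff(active, nxt)
    }
    expect_null(oracle_be_next_removal(tab$X, tab$y, active, 0.05))
  }
})

test_that("backward elimination drops aliased duplicates first", {
  set.seed(53)
  n <- 80
  y <- factor(rep(c("a", "b"), each = n / 2))
  base <- ifelse(y == "a", 0, 1) + rnorm(n) * 0.1
  X <- cbind(f1 = base, f2 = rnorm(n), f3 = base)  # f3 duplicates f1
  expect_message(r <- select_backward_elimination(X, y), "aliased")
  expect_equal(r$trace$removals$feature[1], "f3")
})

test_that("take_n_best returns nested deterministic prefixes", {
  tab <- make_planted(seed = 9, n = 200)
  r <- rank_univariate(tab$X, tab$y)
  expect_length(take_n_best(r, 0), 0)
  expect_setequal(take_n_best(r, ncol(tab$X)), colnames(tab$X))
  expect_true(all(take_n_best(r, 5) %in% take_n_best(r, 10)))
  expect_error(take_n_best(r, ncol(tab$X) + 1), "between 0")
})

test_that("membership table maps selected ids onto features x channels", {
  empty <- membership_table(character(0), 8)
  expect_equal(dim(empty), c(37, 8))
  expect_false(any(empty))
  ssc_all <- membership_table(paste0("ch", 1:8, "_SSC"), 8)
  expect_true(all(ssc_all["SSC", ]))
  expect_equal(sum(ssc_all), 8)
  mixed <- membership_table(c("ch1_WAMP", "ch3_ZC", "ch3_WL"), 8)
  expect_equal(sum(mixed), 3)
  expect_equal(unname(attr(mixed, "col_sums")["ch3"]), 2)
  expect_error(membership_table("ch1-WAMP"), "malformed")
  expect_error(membership_table("ch9_ZC", 8), "out of range")
  expect_error(membership_table("ch1_BOGUS", 8), "unknown feature")
})

test_that("selectors concentrate on planted structure (smoke, 3 seeds)", {
  for (s in 1:3) {
    tab <- generate_tabular_dataset(tabular_sim_config(seed = 2000 + s))
    good <- c(tab$ground_truth$informative, tab$ground_truth$redundant)
    expect_gte(sum(take_n_best(rank_univariate(
      tab$X, tab$y, selection_config("UST", seed = s)), 5) %in% good), 4)
    expect_gte(sum(take_n_best(rank_mutual_information(
      tab$X, tab$y, selection_config("MI", seed = s)), 5) %in% good), 4)
  }
})
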