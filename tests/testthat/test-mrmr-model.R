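# Feature selection, classifier interface, AUC and prediction MI.

test_that("MRMR picks the label-defining feature first and shuns duplicates", {
  set.seed(71)
  n <- 200
  y <- rep(c("MW", "nonMW"), each = n / 2)
  noise <- matrix(rnorm(n * 20), n)
  x_label <- as.numeric(y == "MW")
  x <- cbind(x_label, noise)
  expect_equal(mrmr_select(x, y, 1), 1L)
  # duplicated informative feature is penalized below an independent one
  inf1 <- x_label + rnorm(n, sd = 0.3)
  inf2 <- inf1                        # exact copy: maximal redundancy
  inf3 <- x_label + rnorm(n, sd = 0.3)  # independently noisy
  xx <- cbind(inf1, inf2, inf3, matrix(rnorm(n * 5), n))
  sel <- mrmr_select(xx, y, 3)
  expect_true(sel[1] %in% c(1, 2))
  expect_equal(sel[2], 3L)            # independent informative before the copy
  expect_error(mrmr_select(xx, y, 100), "exceeds")
})

test_that("MRMR agrees with an exhaustive greedy oracle", {
  # independent oracle: evaluate every candidate at every greedy step
  oracle_mrmr <- function(x, y, K, bins = 8) {
    disc <- lapply(seq_len(ncol(x)), function(j) {
      br <- unique(quantile(x[, j], seq(0, 1, length.out = bins + 1), names = FALSE))
      if (length(br) < 2) rep(1L, nrow(x)) else
        as.integer(cut(x[, j], br, include.lowest = TRUE))
    })
    mi <- function(a, b) {
      tt <- table(a, b); p <- tt / sum(tt)
      pa <- rowSums(p); pb <- colSums(p); i <- p > 0
      sum(p[i] * log(p[i] / outer(pa, pb)[i]))
    }
    yf <- as.integer(factor(y))
    rel <- sapply(disc, mi, b = yf)
    sel <- integer(0)
    for (s in seq_len(K)) {
      best <- -Inf; pick <- NA
      for (j in setdiff(seq_len(ncol(x)), sel)) {
        red <- if (length(sel)) mean(sapply(sel, function(i2) mi(disc[[j]], disc[[i2]]))) else 0
        sc <- rel[j] - red
        if (sc > best) { best <- sc; pick <- j }
      }
      sel <- c(sel, pick)
    }
    sel
  }
  set.seed(72)
  for (rep in 1:3) {
    n <- 120
    y <- sample(c("MW", "nonMW"), n, TRUE)
    x <- cbind(as.numeric(y == "MW") + rnorm(n), matrix(rnorm(n * 5), n))
    expect_equal(mrmr_select(x, y, 3), oracle_mrmr(x, y, 3))
  }
})

test_that("AUC is rank-based with midranks and matches the ROC oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c("MW", "MW", "nonMW", "nonMW")), 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c("MW", "MW", "nonMW", "nonMW")), 0)
  set.seed(73)
  for (i in 1:10) {
    sc <- round(runif(60), 2)  # rounding forces ties -> midrank handling
    la <- sample(c("MW", "nonMW"), 60, TRUE)
    expect_equal(auc(sc, la), oracle_auc_trapezoid(sc, la), tolerance = 1e-12)
  }
  expect_error(auc(1:3, c("MW", "MW", "MW")), "both classes")
  # independent library cross-check
  set.seed(78)
  sc2 <- runif(50); la2 <- sample(c("MW", "nonMW"), 50, TRUE)
  expect_equal(auc(sc2, la2),
               as.numeric(suppressMessages(
                 pROC::auc(pROC::roc(la2, sc2, levels = c("nonMW", "MW"),
                                     direction = "<")))),
               tolerance = 1e-12)
  # label flip symmetry
  sc <- runif(40); la <- sample(c("MW", "nonMW"), 40, TRUE)
  flipped <- ifelse(la == "MW", "nonMW", "MW")
  expect_equal(auc(sc, la), 1 - auc(sc, flipped), tolerance = 1e-12)
})

test_that("random forest separates separable data and is seed-deterministic", {
  set.seed(74)
  n <- 60
  y <- rep(c("MW", "nonMW"), each = n / 2)
  x <- cbind(f1 = as.numeric(y == "MW") * 4 + rnorm(n, sd = 0.1),
             f2 = rnorm(n))
  xt <- cbind(f1 = c(4, 4, 0, 0) + rnorm(4, sd = 0.1), f2 = rnorm(4))
  out <- fit_predict_rf(x, y, xt, seed = 5)
  expect_equal(auc(out$scores, c("MW", "MW", "nonMW", "nonMW")), 1)
  out2 <- fit_predict_rf(x, y, xt, seed = 5)
  expect_identical(out$scores, out2$scores)
  expect_error(fit_predict_rf(x, rep("MW", n), xt), "both classes")
})

test_that("label-shuffled training yields chance AUC", {
  set.seed(75)
  aucs <- replicate(20, {
    n <- 80
    x <- matrix(rnorm(n * 10), n)
    colnames(x) <- paste0("f", 1:10)
    y <- sample(rep(c("MW", "nonMW"), each = n / 2))
    xt <- matrix(rnorm(40 * 10), 40); colnames(xt) <- colnames(x)
    yt <- sample(rep(c("MW", "nonMW"), each = 20))
    auc(fit_predict_rf(x, y, xt, num_trees = 200,
                       seed = sample.int(1e6, 1))$scores, yt)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("channel importance grouping finds a planted channel", {
  set.seed(76)
  n <- 150
  y <- rep(c("MW", "nonMW"), each = n / 2)
  desc <- expand.grid(scale_or_band = paste0("s", 1:3),
                      channel = c("FP1", "CZ", "O1"),
                      family = "MPE", stringsAsFactors = FALSE)
  x <- matrix(rnorm(n * nrow(desc)), n)
  sig_cols <- which(desc$channel == "CZ")
  x[, sig_cols] <- x[, sig_cols] + 2 * as.numeric(y == "MW")
  colnames(x) <- paste0("c", seq_len(ncol(x)))
  fit <- fit_predict_rf(x, y, x[1:2, ], seed = 3)
  ci <- channel_importance(fit$importance, desc)
  expect_equal(names(which.max(ci)), "CZ")
  expect_error(channel_importance(1:5, desc), "match")
  # null features -> importances spread roughly evenly over channels
  ratios <- replicate(20, {
    xr <- matrix(rnorm(n * nrow(desc)), n); colnames(xr) <- colnames(x)
    f <- fit_predict_rf(xr, y, xr[1:2, ], num_trees = 200,
                        seed = sample.int(1e6, 1))
    cir <- channel_importance(f$importance, desc)
    max(cir) / min(cir)
  })
  expect_lt(mean(ratios), 3)
})

test_that("prediction MI: self-information, independence, symmetry", {
  set.seed(77)
  a <- sample(c("MW", "nonMW"), 1e4, TRUE, prob = c(0.3, 0.7))
  h <- -(0.3 * log2(0.3) + 0.7 * log2(0.7))
  expect_equal(prediction_mutual_information(a, a), h, tolerance = 0.02)
  b <- sample(c("MW", "nonMW"), 1e4, TRUE)
  expect_lt(prediction_mutual_information(a, b), 0.01)
  expect_equal(prediction_mutual_information(a, b),
               prediction_mutual_information(b, a))
  expect_gte(prediction_mutual_information(a, b), 0)
  expect_error(prediction_mutual_information(a, b[1:10]), "mismatch")
})
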