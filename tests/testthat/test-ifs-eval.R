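# Nearest-neighbour prediction, jackknife evaluation, metrics, IFS and ROC.

test_that("nearest-neighbour prediction and tie-breaking", {
  X <- rbind(c(0, 0), c(1, 1), c(4, 4))
  y <- c("negative", "positive", "negative")
  expect_equal(nna_predict(X, y, c(1, 1)), "positive")
  # equidistant neighbours -> lowest training-row index wins
  expect_equal(nna_predict(rbind(c(0, 0), c(2, 0)),
                           c("negative", "positive"), c(1, 0)),
               "negative")
  expect_error(nna_predict(X[0, , drop = FALSE], character(), c(0, 0)),
               "empty")

  withr::with_seed(14, {
    Xt <- matrix(rnorm(10 * 3), 10, 3)
    yt <- rep(c("positive", "negative"), 5)
    q <- matrix(rnorm(6 * 3), 6, 3)
    brute <- apply(q, 1, function(v) {
      yt[which.min(apply(Xt, 1, function(r) sqrt(sum((r - v)^2))))]
    })
    expect_equal(nna_predict(Xt, yt, q), brute)
  })
})

test_that("jackknife evaluation counts match an explicit loop", {
  # separable: identical twins per class
  X <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9))
  y <- c("positive", "positive", "negative", "negative")
  cc <- jackknife_evaluate(X, y)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))

  withr::with_seed(31, {
    for (trial in 1:3) {
      n <- 12
      Xr <- matrix(rnorm(n * 4), n, 4)
      yr <- rep(c("positive", "negative"), length.out = n)
      got <- jackknife_evaluate(Xr, yr)
      want <- oracle_jackknife_nna(Xr, yr)
      expect_equal(unlist(got[names(want)]), want)
      # conservation: N predictions, class margins fixed
      expect_equal(got$TP + got$FN, sum(yr == "positive"))
      expect_equal(got$TN + got$FP, sum(yr == "negative"))
    }
  })

  # the generic-classifier path agrees with the fast path
  Xg <- matrix(rnorm(16 * 3), 16, 3)
  yg <- rep(c("positive", "negative"), 8)
  slow <- jackknife_evaluate(Xg, yg,
                             classifier = function(tx, ty, q)
                               nna_predict(tx, ty, q))
  expect_equal(jackknife_evaluate(Xg, yg), slow)

  expect_error(jackknife_evaluate(X, rep("positive", 4)), "both classes")
})

test_that("grouped jackknife holds out whole groups", {
  # two groups; each sample's nearest other-sample is its group twin, so
  # leave-one-sample-out is perfect but leave-one-group-out must cross
  X <- rbind(c(0, 0), c(0.1, 0), c(5, 5), c(5.1, 5))
  y <- c("positive", "positive", "negative", "negative")
  g <- c("a", "a", "b", "b")
  plain <- jackknife_evaluate(X, y)
  grouped <- jackknife_evaluate(X, y, groups = g)
  expect_equal(metrics(plain)$Ac, 1)
  expect_equal(metrics(grouped)$Ac, 0)  # forced to the other class's group
})

test_that("metrics implement the four measures with the zero-factor rule", {
  perfect <- confusion_counts(TP = 5, FP = 0, TN = 7, FN = 0)
  m <- metrics(perfect)
  expect_equal(unlist(m), c(Sn = 1, Sp = 1, Ac = 1, MCC = 1))

  # all predicted positive on a balanced set: MCC 0 by the zero-factor rule
  all_pos <- confusion_counts(TP = 10, FP = 10, TN = 0, FN = 0)
  expect_equal(metrics(all_pos)$MCC, 0)

  # direct formula evaluation
  cc <- confusion_counts(TP = 99, FP = 114, TN = 435, FN = 84)
  m2 <- metrics(cc)
  expect_equal(m2$Sn, 99 / (99 + 84))
  expect_equal(m2$Sp, 435 / (435 + 114))
  expect_equal(m2$Ac, (99 + 435) / (99 + 114 + 435 + 84))
  expect_equal(m2$MCC,
               (99 * 435 - 114 * 84) /
                 sqrt((99 + 114) * (99 + 84) * (435 + 114) * (435 + 84)))

  # MCC invariant under simultaneous class/prediction swap
  swapped <- confusion_counts(TP = 435, FP = 84, TN = 99, FN = 114)
  expect_equal(metrics(swapped)$MCC, m2$MCC)

  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "no evaluated")
})

test_that("the IFS curve agrees with manual truncation and finds optima", {
  withr::with_seed(52, {
    n <- 30
    y <- rep(c("positive", "negative"), length.out = n)
    X <- matrix(rnorm(n * 8), n, 8)
    X[, 3] <- X[, 3] + 2 * (y == "positive")
    ranked <- mrmr_rank(discretize(X), y)
    curve <- run_ifs(X, y, ranked)
    expect_equal(nrow(curve), 8L)
    expect_equal(curve$k, 1:8)

    # bit-for-bit agreement with a manual evaluation at each k
    for (k in c(1, 3, 8)) {
      sel <- ranked$feature_index[1:k]
      manual <- metrics(jackknife_evaluate(X[, sel, drop = FALSE], y))
      expect_equal(unlist(curve[k, c("Sn", "Sp", "Ac", "MCC")]),
                   unlist(manual))
    }

    opt <- find_optimum(curve)
    expect_equal(opt$k, curve$k[which.max(curve$MCC)])  # naive scan
  })

  # plateau tie -> smallest k; strictly increasing -> k = N
  plateau <- structure(tibble::tibble(k = 1:4, Sn = 1, Sp = 1, Ac = 1,
                                      MCC = c(0.1, 0.5, 0.5, 0.2)),
                       class = c("ifs_curve", class(tibble::tibble())))
  expect_equal(find_optimum(plateau)$k, 2L)
  increasing <- structure(tibble::tibble(k = 1:3, Sn = 1, Sp = 1, Ac = 1,
                                         MCC = c(0.1, 0.2, 0.3)),
                          class = c("ifs_curve", class(tibble::tibble())))
  expect_equal(find_optimum(increasing)$k, 3L)
})

test_that("IFS keeps signal features and accuracy approaches 1 on margins", {
  withr::with_seed(61, {
    n <- 40
    y <- rep(c("positive", "negative"), length.out = n)
    X <- matrix(rnorm(n * 10, sd = 0.3), n, 10)
    X[, 1:3] <- X[, 1:3] + 3 * (y == "positive")  # only 1..3 carry signal
    ranked <- mrmr_rank(discretize(X), y)
    curve <- run_ifs(X, y, ranked)
    expect_true(all(diff(curve$MCC[1:3]) >= -1e-9))  # non-degrading to k=3
    expect_lte(find_optimum(curve)$k, 9)
    expect_equal(curve$Ac[3], 1)                     # separable with margin
  })
})

test_that("ROC/AUC agree with pair counting and an external reference", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("positive", "positive",
                                        "negative", "negative")), 1)
  withr::with_seed(71, {
    y <- rep(c("positive", "negative"), each = 500)
    s <- rnorm(1000)
    expect_lt(abs(roc_auc(s, y) - 0.5), 0.06)
  })

  # 8 hand-listed pairs incl. a tie, against the pair-counting oracle
  scores <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4, 0.3, 0.1)
  y8 <- c("positive", "positive", "negative", "positive",
          "negative", "positive", "negative", "negative")
  expect_equal(roc_auc(scores, y8), oracle_auc(scores, y8))

  # cross-check the implementation against pROC on random instances
  withr::with_seed(72, {
    for (i in 1:5) {
      yy <- sample(c("positive", "negative"), 40, replace = TRUE,
                   prob = c(0.4, 0.6))
      if (length(unique(yy)) < 2) next
      ss <- rnorm(40) + (yy == "positive")
      ref <- suppressMessages(as.numeric(pROC::auc(
        pROC::roc(yy, ss, levels = c("negative", "positive"),
                  direction = "<"))))
      expect_equal(roc_auc(ss, yy), ref, tolerance = 1e-12)
    }
  })

  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")

  pts <- roc_points(scores, y8)
  expect_equal(pts$FPR[1], 0)
  expect_equal(pts$TPR[nrow(pts)], 1)
  expect_true(all(diff(pts$FPR) >= 0) && all(diff(pts$TPR) >= 0))
})

test_that("jackknife NNA decision scores separate planted classes", {
  withr::with_seed(81, {
    n <- 30
    y <- rep(c("positive", "negative"), length.out = n)
    X <- matrix(rnorm(n * 4, sd = 0.3), n, 4) + 3 * (y == "positive")
    s <- nna_scores(X, y)
    expect_equal(roc_auc(s, y), 1)
    expect_true(all(s[y == "positive"] > 0))
  })
})
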