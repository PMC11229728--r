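# Logistic tissue models: prediction arithmetic, ROC with operating
# point, stepwise selection behaviour, univariate-consistency pruning and
# cross-validation.

mkModel <- function(A = 0, B = numeric(0), C = numeric(0)) {
  terms <- character(0)
  if (length(B)) terms <- c(terms, names(B))
  if (length(C)) terms <- c(terms, paste0(names(C), "_sq"))
  new("LogisticTissueModel", modelType = "cancer_vs_benign", zone = "PZ",
      intercept = A, linCoef = B, quadCoef = C,
      includedTerms = terms, fitMetadata = list())
}

test_that("predict evaluates the quadratic log-odds exactly", {
  # t = 0 -> 0.5
  m0 <- mkModel(A = 0)
  expect_equal(predict(m0, data.frame(t2w = 1)), 0.5, tolerance = 1e-15)
  # A = 1, B1 = 2, x1 = 1 -> 1 / (1 + e^-3)
  m1 <- mkModel(A = 1, B = c(t2w = 2))
  expect_equal(predict(m1, data.frame(t2w = 1)), 1 / (1 + exp(-3)),
               tolerance = 1e-15)
  # quadratic symmetry: A = 0, C1 = 1 gives the same value at +/- x
  m2 <- mkModel(A = 0, C = c(adc = 1))
  expect_equal(predict(m2, data.frame(adc = -2)),
               predict(m2, data.frame(adc = 2)), tolerance = 1e-15)
  # missing parameter is an error, not an imputation
  expect_error(predict(m1, data.frame(adc = 1)), "missing parameter")
  expect_error(predict(m1, data.frame(t2w = NA_real_)), "NA")
})

test_that("ROC matches the brute-force concordance count and finds the
           balanced operating point", {
  scores <- c(0.1, 0.35, 0.4, 0.8)
  labels <- c(0, 1, 0, 1)
  # independent oracle: pairwise concordance over all pos/neg pairs
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  pairs <- expand.grid(p = pos, n = neg)
  aucOracle <- mean(ifelse(pairs$p > pairs$n, 1, ifelse(pairs$p == pairs$n,
                                                        0.5, 0)))
  roc <- rocWithOperatingPoint(scores, labels)
  expect_equal(roc@auc, aucOracle, tolerance = 1e-12)
  expect_equal(roc@auc, 0.75, tolerance = 1e-12)
  # perfectly separated: AUC 1 and sens = spec = 1 at the operating point
  roc2 <- rocWithOperatingPoint(c(1, 2, 3, 10, 11, 12),
                                c(0, 0, 0, 1, 1, 1))
  expect_equal(roc2@auc, 1)
  expect_equal(unname(roc2@operatingPoint["sensitivity"]), 1)
  expect_equal(unname(roc2@operatingPoint["specificity"]), 1)
  expect_error(rocWithOperatingPoint(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC agrees with pROC on random scores", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      sc <- rnorm(60)
      lb <- rbinom(60, 1, 0.4)
      if (length(unique(lb)) < 2) next
      ours <- rocWithOperatingPoint(sc, lb)@auc
      theirs <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                               direction = "<")))
      expect_equal(ours, theirs, tolerance = 1e-9)
    }
  })
})

test_that("ROC on label-independent scores is near 1/2", {
  withr::with_seed(11, {
    sc <- rnorm(4000)
    lb <- rbinom(4000, 1, 0.5)
  })
  auc <- rocWithOperatingPoint(sc, lb)@auc
  # 3 SE of the null AUC for n ~ 2000/2000
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / 12 * (1 / 2000 + 1 / 2000)))
})

test_that("stepwise selection keeps a separating parameter and admits
           noise terms at roughly the nominal rate", {
  keptSep <- logical(30)
  noiseFrac <- numeric(30)
  for (s in 1:30) {
    tab <- syntheticRoiTable(n = 200, sep = c(t2w = 0, adc = 3, fa = 0,
                                              pe = 0, es = 0, wo = 0),
                             seed = 100 + s)
    m <- suppressWarnings(stepwiseFit(tab, "cancer_vs_benign", "PZ"))
    keptSep[s] <- any(grepl("^adc", modelTerms(m)))
    noise <- setdiff(modelTerms(m), c("adc", "adc_sq"))
    noiseFrac[s] <- length(noise) / 10   # 10 pure-noise candidate terms
  }
  expect_true(all(keptSep))
  # each noise term should be retained at about the entry threshold rate
  expect_lt(mean(noiseFrac), 0.30)
  expect_gt(mean(noiseFrac), 0.02)
})

test_that("stepwise preconditions and degenerate inputs error cleanly", {
  tiny <- syntheticRoiTable(n = 4)
  expect_error(suppressWarnings(stepwiseFit(tiny, "cancer_vs_benign", "PZ")),
               ">= 10 rows")
})

test_that("perfect separation falls back to a regularized fit with warning", {
  tab <- syntheticRoiTable(n = 60, seed = 5)
  tab$adc <- ifelse(tab$tissue_class == "benign", 0, 10)  # exact separation
  expect_warning(m <- stepwiseFit(tab, "cancer_vs_benign", "PZ"),
                 "separation")
  expect_true(isTRUE(m@fitMetadata$separated))
  p <- predict(m, tab)
  expect_true(all(p[tab$tissue_class != "benign"] > 0.5))
  expect_true(all(p[tab$tissue_class == "benign"] < 0.5))
})

test_that("inconsistent factors are pruned to a sign-consistent fixed point", {
  # two collinear predictors: the weaker one picks up a flipped sign in the
  # joint fit but has a positive univariate mean difference
  withr::with_seed(21, {
    n <- 300
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(2 * z))
    tab <- data.frame(case_id = "c", zone = "PZ",
                      tissue_class = ifelse(y == 1, "PCa_low", "benign"),
                      t2w = z + rnorm(n, 0, 0.1),
                      adc = z + rnorm(n, 0, 0.12),
                      fa = rnorm(n), pe = rnorm(n), es = rnorm(n),
                      wo = rnorm(n))
  })
  m <- suppressWarnings(stepwiseFit(tab, "cancer_vs_benign", "PZ"))
  pruned <- suppressWarnings(pruneInconsistent(m, tab))
  df <- ProCaMap:::modelFrame(tab, "cancer_vs_benign", "PZ")
  for (p in names(pruned@linCoef)) {
    uni <- sign(mean(df[[p]][df$.y == 1]) - mean(df[[p]][df$.y == 0]))
    expect_equal(sign(pruned@linCoef[[p]]), uni)
  }
  # idempotence: a second application changes nothing
  again <- suppressWarnings(pruneInconsistent(pruned, tab))
  expect_identical(modelTerms(again), modelTerms(pruned))
  expect_equal(again@linCoef, pruned@linCoef)
  # a consistent model passes through unchanged
  tabC <- syntheticRoiTable(n = 200, sep = c(t2w = 0, adc = 2.5, fa = 0,
                                             pe = 0, es = 0, wo = 0),
                            seed = 8)
  mC <- suppressWarnings(stepwiseFit(tabC, "cancer_vs_benign", "PZ"))
  expect_identical(modelTerms(suppressWarnings(pruneInconsistent(mC, tabC))),
                   modelTerms(mC))
})

test_that("cross-validation recovers a known Bayes AUC and guards tiny
           minority classes", {
  # one informative axis with separation delta in units of its SD:
  # Bayes AUC = pnorm(delta / sqrt(2)); oracle by closed form, checked
  # against large-sample Monte Carlo
  delta <- 2
  bayes <- pnorm(delta / sqrt(2))
  withr::with_seed(31, {
    mc <- mean(rnorm(1e5, delta) > rnorm(1e5))  # Monte-Carlo check
  })
  expect_equal(bayes, mc, tolerance = 0.01)
  tab <- syntheticRoiTable(n = 400, sep = c(t2w = 0, adc = delta, fa = 0,
                                            pe = 0, es = 0, wo = 0),
                           seed = 9)
  cv <- suppressWarnings(crossValidate(tab, "cancer_vs_benign", "PZ",
                                       k = 4, seed = 2))
  expect_true(cv$cv)
  halfWidth <- max(diff(cv$ci95) / 2, 0.03)
  expect_lt(abs(cv$aucMean - bayes), 3 * halfWidth)
  # guard: minority class smaller than k skips CV and flags it
  tabSmall <- syntheticRoiTable(n = 24, seed = 10)
  cvG <- suppressWarnings(crossValidate(tabSmall, "cancer_vs_benign", "PZ",
                                        k = 20, seed = 1))
  expect_false(cvG$cv)
  expect_true(is.na(cvG$ci95[1]))
})

test_that("deterministic refits: same table gives identical models", {
  tab <- syntheticRoiTable(n = 150, sep = c(t2w = 1, adc = 2, fa = 0,
                                            pe = 0, es = 1, wo = 0),
                           seed = 3)
  m1 <- suppressWarnings(stepwiseFit(tab, "cancer_vs_benign", "PZ"))
  m2 <- suppressWarnings(stepwiseFit(tab, "cancer_vs_benign", "PZ"))
  expect_identical(modelTerms(m1), modelTerms(m2))
  expect_equal(m1@linCoef, m2@linCoef, tolerance = 1e-12)
})
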