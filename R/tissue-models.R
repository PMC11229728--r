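# Zone-specific logistic tissue models fitted from the ROI table with a
# mixed stepwise algorithm (likelihood-ratio entry/removal at p <= 0.15),
# a univariate-consistency check that removes sign-inconsistent factors,
# and 4-fold cross-validated AUC assessment.

ALL_TERMS <- c(MRI_PARAMS, paste0(MRI_PARAMS, "_sq"))

termParam <- function(term) sub("_sq$", "", term)
isQuadTerm <- function(term) grepl("_sq$", term)

# Build the (y, X) training frame for one model type and zone.
# Positive-class conventions: cancer (vs benign), high grade (vs low),
# AFMS (vs cancer). AFMS rows are shared across zones: the phantom's AFMS
# is a single midline structure.
modelFrame <- function(table, modelType, zone) {
  stopifnot(modelType %in% MODEL_TYPES, zone %in% ZONES)
  inZone <- table$zone == zone
  if (modelType == "cancer_vs_benign") {
    sel <- inZone & table$tissue_class %in% c("benign", "PCa_low", "PCa_high")
    y <- as.integer(table$tissue_class[sel] != "benign")
  } else if (modelType == "high_vs_low") {
    sel <- inZone & table$tissue_class %in% c("PCa_low", "PCa_high")
    y <- as.integer(table$tissue_class[sel] == "PCa_high")
  } else {  # afms_vs_cancer
    sel <- (table$tissue_class == "AFMS") |
      (inZone & table$tissue_class %in% c("PCa_low", "PCa_high"))
    y <- as.integer(table$tissue_class[sel] == "AFMS")
  }
  df <- table[sel, MRI_PARAMS, drop = FALSE]
  for (p in MRI_PARAMS) df[[paste0(p, "_sq")]] <- df[[p]]^2
  df$.y <- y
  rownames(df) <- NULL
  df
}

fitGlm <- function(df, terms) {
  fm <- if (length(terms)) {
    stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  } else {
    stats::as.formula(".y ~ 1")
  }
  suppressWarnings(stats::glm(fm, family = stats::binomial(), data = df,
                              control = list(maxit = 50)))
}

lrtPvalue <- function(devReduced, devFull) {
  stats::pchisq(max(devReduced - devFull, 0), df = 1, lower.tail = FALSE)
}

separated <- function(fit) {
  co <- stats::coef(fit)
  # perfect separation: infinite/huge coefficients, non-convergence, or a
  # numerically perfect fit (deviance collapses to zero)
  any(!is.finite(co)) || !fit$converged || fit$deviance < 1e-6 ||
    any(stats::fitted(fit) > 1 - 1e-10) && any(stats::fitted(fit) < 1e-10) &&
      fit$deviance < 1e-3
}

# ML refit on the final term set, with an L2-regularized fallback when the
# classes are perfectly separated.
finalFit <- function(df, terms) {
  fit <- fitGlm(df, terms)
  sep <- length(terms) > 0 && separated(fit)
  if (sep) {
    warning("perfect separation detected; falling back to L2-regularized fit")
    X <- as.matrix(df[, terms, drop = FALSE])
    # glmnet needs >= 2 columns
    X2 <- if (ncol(X) == 1) cbind(X, .dummy = 0) else X
    gf <- glmnet::glmnet(X2, df$.y, family = "binomial", alpha = 0,
                         lambda = 1e-2, standardize = TRUE)
    co <- as.numeric(stats::coef(gf))
    names(co) <- c("(Intercept)", colnames(X2))
    co <- co[c("(Intercept)", terms)]
  } else {
    co <- stats::coef(fit)
  }
  list(coef = co, separated = sep)
}

#' Fit a logistic tissue model with mixed stepwise term selection
#'
#' Candidate terms are the six MRI parameters and their squares. The mixed
#' stepwise search repeatedly adds the candidate with the smallest
#' likelihood-ratio p-value when it is at or below the threshold, then
#' removes any included term whose p-value rises above the threshold, until
#' the term set is stable; the final coefficients are the maximum-likelihood
#' fit on that set (ridge-regularized under perfect separation).
#'
#' @param table ROI table with columns case_id, zone, tissue_class and the
#'   six parameter means
#' @param modelType one of `"cancer_vs_benign"`, `"high_vs_low"`,
#'   `"afms_vs_cancer"`
#' @param zone `"PZ"` or `"TZ"`
#' @param pEnterExit significance threshold for entry and removal
#'   (default 0.15)
#' @return a [LogisticTissueModel-class]
#' @export
stepwiseFit <- function(table, modelType, zone, pEnterExit = 0.15) {
  df <- modelFrame(table, modelType, zone)
  n1 <- sum(df$.y == 1); n0 <- sum(df$.y == 0)
  if (n1 < 10 || n0 < 10)
    stop(sprintf("need >= 10 rows per class (have %d positive, %d negative)",
                 n1, n0))
  terms <- character()
  trace <- character()
  seen <- character()
  repeat {
    key <- paste(sort(terms), collapse = "|")
    if (key %in% seen) break  # cycle guard
    seen <- c(seen, key)
    changed <- FALSE
    devCur <- fitGlm(df, terms)$deviance

    # forward: best candidate by LRT p-value
    cand <- setdiff(ALL_TERMS, terms)
    if (length(cand)) {
      pv <- vapply(cand, function(tm)
        lrtPvalue(devCur, fitGlm(df, c(terms, tm))$deviance), numeric(1))
      if (min(pv) <= pEnterExit) {
        add <- cand[which.min(pv)]
        terms <- c(terms, add)
        trace <- c(trace, paste0("+", add))
        devCur <- fitGlm(df, terms)$deviance
        changed <- TRUE
      }
    }
    # backward: drop any term whose p-value exceeds the threshold
    if (length(terms)) {
      pv <- vapply(terms, function(tm)
        lrtPvalue(fitGlm(df, setdiff(terms, tm))$deviance, devCur),
        numeric(1))
      if (max(pv) > pEnterExit) {
        drop <- terms[which.max(pv)]
        terms <- setdiff(terms, drop)
        trace <- c(trace, paste0("-", drop))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ff <- finalFit(df, terms)
  buildModel(modelType, zone, terms, ff$coef,
             list(n = nrow(df), nPositive = n1, nNegative = n0,
                  positiveClass = switch(modelType,
                                         cancer_vs_benign = "cancer",
                                         high_vs_low = "high_grade",
                                         afms_vs_cancer = "AFMS"),
                  trace = trace, separated = ff$separated,
                  pEnterExit = pEnterExit))
}

buildModel <- function(modelType, zone, terms, coefs, metadata) {
  lin <- terms[!isQuadTerm(terms)]
  quad <- termParam(terms[isQuadTerm(terms)])
  linCoef <- if (length(lin)) stats::setNames(coefs[lin], lin) else
    stats::setNames(numeric(0), character(0))
  quadCoef <- if (length(quad))
    stats::setNames(coefs[paste0(quad, "_sq")], quad) else
      stats::setNames(numeric(0), character(0))
  new("LogisticTissueModel", modelType = modelType, zone = zone,
      intercept = unname(coefs["(Intercept)"]), linCoef = linCoef,
      quadCoef = quadCoef, includedTerms = terms, fitMetadata = metadata)
}

#' Remove factors inconsistent with the univariate class means
#'
#' For each included linear term the sign of its coefficient is compared
#' with the sign of the difference of class means (positive minus negative
#' class); mismatched factors are removed from consideration together with
#' their quadratic partner and the model refitted, iterating to a fixed
#' point. Quadratic-only terms have no univariate-mean analogue and are
#' left untouched.
#'
#' @param model a fitted [LogisticTissueModel-class]
#' @param table the ROI table the model was fitted on
#' @return the (possibly) pruned and refitted model
#' @export
pruneInconsistent <- function(model, table) {
  df <- modelFrame(table, model@modelType, model@zone)
  terms <- model@includedTerms
  banned <- character()
  repeat {
    lin <- terms[!isQuadTerm(terms)]
    if (!length(lin)) break
    uniSign <- vapply(lin, function(p)
      sign(mean(df[[p]][df$.y == 1]) - mean(df[[p]][df$.y == 0])),
      numeric(1))
    fitSign <- sign(model@linCoef[lin])
    bad <- lin[uniSign != 0 & fitSign != 0 & uniSign != fitSign]
    if (!length(bad)) break
    banned <- c(banned, bad, paste0(bad, "_sq"))
    terms <- setdiff(terms, c(bad, paste0(bad, "_sq")))
    ff <- finalFit(df, terms)
    meta <- model@fitMetadata
    meta$pruned <- union(meta$pruned, bad)
    meta$separated <- ff$separated
    model <- buildModel(model@modelType, model@zone, terms, ff$coef, meta)
  }
  model
}

#' Predict tissue probability from a logistic tissue model
#'
#' Evaluates P = 1 / (1 + exp(-t)) with
#' t = A + sum(B_i x_i) + sum(C_j x_j^2) over the model's included terms.
#'
#' @param object a [LogisticTissueModel-class]
#' @param newdata matrix or data.frame with named columns covering every
#'   parameter the model uses; missing values are an error (no imputation)
#' @return numeric vector of probabilities in (0, 1)
#' @export
setMethod("predict", "LogisticTissueModel", function(object, newdata) {
  newdata <- as.data.frame(newdata)
  need <- union(names(object@linCoef), names(object@quadCoef))
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  t <- rep(object@intercept, nrow(newdata))
  for (p in names(object@linCoef)) {
    x <- newdata[[p]]
    if (anyNA(x)) stop("NA values in parameter ", p)
    t <- t + object@linCoef[[p]] * x
  }
  for (p in names(object@quadCoef)) {
    x <- newdata[[p]]
    if (anyNA(x)) stop("NA values in parameter ", p)
    t <- t + object@quadCoef[[p]] * x^2
  }
  stats::plogis(t)
})

#' ROC curve with the equal-sensitivity/specificity operating point
#'
#' Sweeps all score thresholds (calls `score >= threshold` positive),
#' computes the trapezoidal AUC, and reports the operating point that
#' maximizes the Youden index sens - (1 - spec), tie-broken toward the
#' threshold where sensitivity and specificity are closest to equal.
#'
#' @param scores numeric scores
#' @param labels binary labels (0/1 or logical)
#' @return a [RocResult-class]
#' @export
rocWithOperatingPoint <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("both classes must be present")
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1) / P,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0) / N,
                 numeric(1))
  fpr <- 1 - spec
  # anchors: everything called positive / nothing called positive
  ox <- c(1, fpr, 0); oy <- c(1, sens, 0)
  ord <- order(ox, oy)
  auc <- sum(diff(ox[ord]) * (utils::head(oy[ord], -1) +
                                utils::tail(oy[ord], -1)) / 2)
  youden <- sens - (1 - spec)
  best <- which(youden == max(youden))
  pick <- best[which.min(abs(sens[best] - spec[best]))]
  new("RocResult", thresholds = thr, sensitivity = sens,
      specificity = spec, auc = auc,
      operatingPoint = c(threshold = thr[pick], sensitivity = sens[pick],
                         specificity = spec[pick]))
}

#' Stratified k-fold cross-validated AUC of a tissue model
#'
#' Rows are assigned to folds stratified by class with a fixed seed; each
#' fold's model is fitted with the stepwise search plus consistency pruning
#' on the remaining folds and scored on the held-out rows. Reports the mean
#' held-out AUC and its t-based 95% confidence interval. When the minority
#' class is too small to populate every fold the cross-validation is
#' skipped and the model is fitted on the full table (guard mirrored from
#' the AFMS-model situation), with `cv = FALSE` in the result.
#'
#' @param table ROI table
#' @param modelType,zone as in [stepwiseFit()]
#' @param k number of folds (default 4)
#' @param seed fold-assignment seed
#' @param pEnterExit stepwise threshold
#' @return list: `aucMean`, `ci95` (length 2), `aucFolds`, `cv` flag,
#'   `model` (fitted on the full table)
#' @export
crossValidate <- function(table, modelType, zone, k = 4, seed = 1,
                          pEnterExit = 0.15) {
  stopifnot(k >= 2)
  fullModel <- pruneInconsistent(
    stepwiseFit(table, modelType, zone, pEnterExit), table)
  df <- modelFrame(table, modelType, zone)
  minClass <- min(sum(df$.y == 1), sum(df$.y == 0))
  if (minClass < k) {
    scores <- predict(fullModel, df)
    auc <- rocWithOperatingPoint(scores, df$.y)@auc
    return(list(aucMean = auc, ci95 = c(NA_real_, NA_real_),
                aucFolds = auc, cv = FALSE, model = fullModel))
  }
  # subset the original table rows matching the model frame, so the fold
  # fits can rebuild their own frames
  keep <- modelFrameRows(table, modelType, zone)
  sub <- table[keep, , drop = FALSE]
  folds <- withSeed(seed, {
    f <- integer(nrow(sub))
    for (cls in unique(df$.y)) {
      idx <- which(df$.y == cls)
      f[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  aucs <- vapply(seq_len(k), function(fold) {
    train <- sub[folds != fold, , drop = FALSE]
    test <- df[folds == fold, , drop = FALSE]
    m <- tryCatch(
      pruneInconsistent(stepwiseFit(train, modelType, zone, pEnterExit),
                        train),
      error = function(e) fullModel)
    rocWithOperatingPoint(predict(m, test), test$.y)@auc
  }, numeric(1))
  mu <- mean(aucs)
  se <- stats::sd(aucs) / sqrt(k)
  ci <- if (is.na(se) || se == 0) c(mu, mu) else
    mu + c(-1, 1) * stats::qt(0.975, k - 1) * se
  list(aucMean = mu, ci95 = ci, aucFolds = aucs, cv = TRUE,
       model = fullModel)
}

# row indices of `table` that enter the model frame (same selection logic)
modelFrameRows <- function(table, modelType, zone) {
  inZone <- table$zone == zone
  if (modelType == "cancer_vs_benign") {
    which(inZone & table$tissue_class %in% c("benign", "PCa_low", "PCa_high"))
  } else if (modelType == "high_vs_low") {
    which(inZone & table$tissue_class %in% c("PCa_low", "PCa_high"))
  } else {
    which((table$tissue_class == "AFMS") |
            (inZone & table$tissue_class %in% c("PCa_low", "PCa_high")))
  }
}

#' Fit the full per-zone model set from an ROI table
#'
#' Fits all three model types for both zones with stepwise selection,
#' consistency pruning and cross-validation (the AFMS models skip
#' cross-validation automatically when AFMS rows are too few to divide
#' into folds).
#'
#' @param table pooled ROI table
#' @param k folds for cross-validation
#' @param seed fold seed
#' @return nested list `models[[zone]][[modelType]]` of
#'   [LogisticTissueModel-class], with a `cvResults` attribute of the
#'   cross-validation summaries
#' @export
fitCohortModels <- function(table, k = 4, seed = 1) {
  models <- list()
  cvRes <- list()
  for (zone in ZONES) {
    models[[zone]] <- list()
    for (mt in MODEL_TYPES) {
      cv <- tryCatch(crossValidate(table, mt, zone, k = k, seed = seed),
                     error = function(e) e)
      if (inherits(cv, "error")) {
        # too few rows in this zone: fall back to a zone-pooled fit
        pooled <- table
        pooled$zone <- zone
        cv <- crossValidate(pooled, mt, zone, k = k, seed = seed)
        cv$model@fitMetadata$pooledZones <- TRUE
        cv$pooledZones <- TRUE
      }
      models[[zone]][[mt]] <- cv$model
      cvRes[[paste(zone, mt, sep = ".")]] <-
        cv[intersect(c("aucMean", "ci95", "aucFolds", "cv", "pooledZones"),
                     names(cv))]
    }
  }
  attr(models, "cvResults") <- cvRes
  models
}
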