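# Shared fixtures. The heavy phantom-study objects are built lazily once
# per test run and reused across test files.

.fixtures <- new.env(parent = emptyenv())

# a small, fast phantom case with fixed lesions
smallCase <- function(seed = 2, ...) {
  cfg <- phantomConfig(
    gridShape = c(64L, 64L, 16L), voxelSpacing = c(1, 1, 3),
    lesionSpecs = data.frame(zone = c("PZ", "TZ"),
                             grade = c("high", "low"),
                             volume_cc = c(0.8, 0.4)),
    rngSeed = seed, ...)
  generateCase(cfg)
}

# full-size single case (the default 96 x 96 x 24 grid)
fullCase <- function(seed = 5, ...) {
  generateCase(phantomConfig(rngSeed = seed, ...))
}

# the shared end-to-end study used by the acceptance tests (40 cases)
studyFixture <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- suppressWarnings(runPhantomStudy(nCases = 40,
                                                        seed = 20))
  }
  .fixtures$study
}

# build a noiseless (point-mass) configuration: every tissue distribution
# collapses to its mean, no bias field, no heterogeneity
noiselessConfig <- function(seed = 3, lesionSpecs = data.frame(
                              zone = c("PZ", "TZ"), grade = c("high", "low"),
                              volume_cc = c(1.0, 0.5))) {
  zeroCov <- function(p) {
    p$cov <- matrix(0, 6, 6)
    p
  }
  phantomConfig(
    tissueParams = lapply(defaultTissueParams(), zeroCov),
    backgroundParams = lapply(defaultBackgroundParams(), zeroCov),
    lesionSpecs = lesionSpecs,
    coilBias = c(amplitude = 0, decay = 30),
    caseJitter = 0, spatialFrac = 0, rngSeed = seed)
}

# synthetic ROI table with controllable class separation
syntheticRoiTable <- function(n = 200, sep = c(t2w = 0, adc = 0, fa = 0,
                                               pe = 0, es = 0, wo = 0),
                              seed = 1, zone = "PZ",
                              classes = c("benign", "PCa_low")) {
  withr::with_seed(seed, {
    cls <- rep(classes, length.out = n)
    pos <- cls != classes[1]
    tab <- data.frame(case_id = "syn", zone = zone, tissue_class = cls)
    base <- c(t2w = 2, adc = 1.3, fa = 0.2, pe = 150, es = 10, wo = 1)
    sds <- c(t2w = 0.5, adc = 0.2, fa = 0.05, pe = 30, es = 3, wo = 0.4)
    for (p in names(base)) {
      tab[[p]] <- stats::rnorm(n, base[p], sds[p]) +
        ifelse(pos, sep[p] * sds[p], 0)
    }
    tab
  })
}
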