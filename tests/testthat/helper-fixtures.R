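# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

tiny_spec <- function(grid = 48L, f = 0, seed = 1L) {
  PhantomSpec(gridShape = grid, cardiacUptakeFraction = f, seed = seed)
}

rand_image <- function(nr = 32L, nc = 32L, seed = 1L, scale = 100) {
  set.seed(seed)
  PlanarImage(matrix(runif(nr * nc, 0, scale), nr, nc))
}

rect_mask <- function(nr, nc, rows, cols, structure = "lv") {
  m <- matrix(0, nr, nc)
  m[rows, cols] <- 1
  LabelMask(m, structure)
}

# sort-based quantile oracle (linear interpolation between order statistics,
# the type-7 definition), independent of stats::quantile
quantile_oracle <- function(x, p) {
  s <- sort(as.numeric(x))
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# all-pairs Mann-Whitney AUC oracle (ties counted 1/2)
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# mock segmentation model: arbitrary per-patch logit function
mock_seg_model <- function(logitFn, structure = "whole_heart") {
  m <- list(kind = "mock_seg", logitFn = logitFn, structure = structure,
            patchHw = c(16L, 16L))
  class(m) <- "scintModel"
  m
}

# mock classifier exposing probFn for predictProba/occlusion
mock_prob_model <- function(probFn) {
  m <- list(kind = "mock_cls", probFn = probFn,
            provenance = list(fold = NA, crop = NA, view = NA))
  class(m) <- "scintModel"
  m
}

# mock model for GradCAM whose class-0 score is the mean of the input over a
# rectangular region: one activation channel A = x * indicator(region),
# dense weights (1, -1) on that channel
mock_region_model <- function(rows, cols) {
  m <- list(kind = "mock_cls",
            convForward = function(px) {
              a <- matrix(0, nrow(px), ncol(px))
              a[rows, cols] <- px[rows, cols]
              array(a, c(dim(px), 1L))
            },
            denseW = rbind(1, -1))
  class(m) <- "scintModel"
  m
}

# quick separable classification set: class 1 carries a bright central blob
blob_samples <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- matrix(runif(64 * 64, 0, 0.3), 64)
    lab <- as.integer(i %% 2 == 0)
    if (lab == 1) m[28:36, 28:36] <- m[28:36, 28:36] + 0.7
    list(image = PlanarImage(pmin(m, 1)), label = lab)
  })
}

# cached small cohorts (built once per test run)
.fixture_env <- new.env()

# whole-heart segmenter trained on uptake-augmented grade-0 phantoms
# (cached; used by robustness-flavoured tests)
aug_segmenter_fixture <- function() {
  if (is.null(.fixture_env$aug_seg)) {
    coh <- cohort_fixture("segtrain", 10, c(1, 0, 0, 0), seed = 11,
                          grid = 48L)
    scheme <- UptakeLevelScheme(minFraction = 0.5, maxFraction = 1.5,
                                step = 0.5, nAugmentedPerCase = 3L)
    tr <- list()
    for (cs in coh[1:7]) {
      augs <- expandCase(caseImages(cs)$anterior, caseMasks(cs)$lv, scheme,
                         seed = 23L)
      for (a in augs) {
        tr[[length(tr) + 1L]] <- list(image = a@image,
                                      mask = caseMasks(cs)$whole_heart)
      }
    }
    va <- segmentationPairs(coh[8:10], "whole_heart", views = "anterior")
    cfg <- SegTrainConfig(patchHw = c(48L, 48L), epochs = 6L, seed = 4L)
    .fixture_env$aug_seg <- trainSegmenter(tr, va, cfg)
  }
  .fixture_env$aug_seg
}

cohort_fixture <- function(name, n, props, seed, grid = 48L, ...) {
  key <- paste0(name)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generateCohort(
      n, props, PhantomSpec(gridShape = grid), seed = seed, ...)
  }
  .fixture_env[[key]]
}
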