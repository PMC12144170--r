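test_that("threshold tables reject overlaps, gaps and partial coverage", {
  expect_error(thresholdTable(c(-Inf, 0, 50), c(0, 100, Inf),
                              c("a", "b", "c")), "overlap")
  expect_error(thresholdTable(c(-Inf, 10), c(0, Inf), c("a", "b")),
               "gap")
  expect_error(thresholdTable(c(0, 10), c(10, 20), c("a", "b")),
               "full")
  expect_error(thresholdTable(c(-Inf, 5), c(5, 4), c("a", "b")),
               "empty interval")
})

test_that("noise-free segmentation reproduces generator ground truth voxelwise", {
  spec <- smallSpec(
    noise_sd = 0,
    plate = list(length = 16, width = 6, thickness = 2, angle_deg = 0),
    screws = list(list(axial_position = 10, axis = c(1, 0, 0),
                       radius = 1.5, length = 14)))
  cv <- generateConstruct(spec)
  seg <- thresholdSegment(cv$volume, defaultThresholdTable())
  expect_identical(labelArray(seg), labelArray(cv$labels))
})

test_that("single-interval and boundary-value conventions hold", {
  vol <- new("VoxelVolume", dims = c(2L, 2L, 2L),
             spacing = c(1, 1, 1), origin = c(0, 0, 0),
             values = array(-1000, dim = c(2, 2, 2)))
  seg <- thresholdSegment(vol, defaultThresholdTable())
  expect_identical(unique(labelLegend(seg)[as.character(labelArray(seg))]),
                   "background")

  ## a value exactly at a shared endpoint belongs to the upper interval
  tab <- thresholdTable(c(-Inf, 100), c(100, Inf), c("low", "high"))
  vol2 <- new("VoxelVolume", dims = c(1L, 1L, 1L), spacing = c(1, 1, 1),
              origin = c(0, 0, 0), values = array(100, dim = c(1, 1, 1)))
  seg2 <- thresholdSegment(vol2, tab)
  expect_identical(unname(labelLegend(seg2)[as.character(labelArray(seg2))]),
                   "high")
})

test_that("segmentation is idempotent on interval-midpoint volumes", {
  tab <- defaultThresholdTable()
  mids <- ifelse(is.finite(tab$lower) & is.finite(tab$upper),
                 (tab$lower + tab$upper) / 2,
                 ifelse(is.finite(tab$upper), tab$upper - 1,
                        tab$lower + 1))
  set.seed(3)
  vals <- array(sample(rep(mids, length.out = 27)), dim = c(3, 3, 3))
  vol <- new("VoxelVolume", dims = c(3L, 3L, 3L), spacing = c(1, 1, 1),
             origin = c(0, 0, 0), values = vals)
  seg1 <- thresholdSegment(vol, tab)
  ## rebuild a piecewise-constant volume from the assigned labels
  lv <- stats::setNames(mids, tab$region)
  regions <- labelLegend(seg1)[as.character(labelArray(seg1))]
  vol2 <- new("VoxelVolume", dims = c(3L, 3L, 3L), spacing = c(1, 1, 1),
              origin = c(0, 0, 0),
              values = array(lv[regions], dim = c(3, 3, 3)))
  seg2 <- thresholdSegment(vol2, tab)
  expect_identical(labelArray(seg1), labelArray(seg2))
})

test_that("misclassification under Gaussian noise respects the normal-tail bound", {
  tab <- defaultThresholdTable()
  gv <- defaultTissueGreyvalues()
  ## distance from each region's greyvalue to its nearest threshold
  delta <- vapply(names(gv), function(rg) {
    row <- tab[tab$region == rg, ]
    min(gv[[rg]] - row$lower, row$upper - gv[[rg]])
  }, numeric(1))
  for (sd in c(40, 80, 120)) {
    cv <- generateConstruct(smallSpec(noise_sd = sd, seed = 11))
    seg <- thresholdSegment(cv$volume, tab)
    wrong <- sum(labelArray(seg) != labelArray(cv$labels))
    truth <- labelLegend(cv$labels)[as.character(labelArray(cv$labels))]
    counts <- table(truth)
    bound <- sum(counts * 2 * stats::pnorm(-delta[names(counts)] / sd))
    ## allow binomial fluctuation above the expected-count bound
    expect_lte(wrong, bound + 5 * sqrt(bound) + 1)
  }
})

test_that("largest-component cleanup removes speckle but is off by default", {
  lab <- array(0L, dim = c(7, 3, 3))
  lab[1:3, , ] <- 1L      # main component
  lab[7, 2, 2] <- 1L      # isolated speckle
  lm <- asLabelMap(lab, legend = c("0" = "background", "1" = "cortical"))
  cleaned <- largestComponentFilter(lm)
  expect_identical(sum(labelArray(cleaned) == 1L), 27L)
  expect_identical(labelArray(cleaned)[7, 2, 2], 0L)
})

test_that("external label maps are accepted directly", {
  lm <- asLabelMap(array(c(0L, 1L), dim = c(2, 1, 1)),
                   legend = c("0" = "background", "1" = "cortical"),
                   spacing = c(2, 2, 2))
  expect_s4_class(lm, "LabelMap")
  expect_identical(voxelSpacing(lm), c(2, 2, 2))
})
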