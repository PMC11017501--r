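test_that("infarct volumetry follows the serial-section area formula", {
  h <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  expect_equal(infarctPercent(SectionMaskSet(list(none), list(h))), 0)
  expect_equal(infarctPercent(SectionMaskSet(list(h), list(h))), 100)

  # three sections with infarct/hemisphere areas (2,3,5) / (20,30,50)
  mk <- function(n, total = 100) {
    m <- matrix(FALSE, 10, 10)
    m[seq_len(n)] <- TRUE
    m
  }
  masks <- SectionMaskSet(infarct = list(mk(2), mk(3), mk(5)),
                          hemisphere = list(mk(20), mk(30), mk(50)))
  expect_identical(infarctPercent(masks), 10)

  # scale invariance under uniform pixel-size rescaling
  masks2 <- masks
  masks2@pixelSizeMm <- masks@pixelSizeMm * 3.7
  expect_equal(infarctPercent(masks2), infarctPercent(masks))
})

test_that("degenerate section masks are rejected", {
  h <- matrix(TRUE, 4, 4)
  none <- matrix(FALSE, 4, 4)
  expect_error(infarctPercent(SectionMaskSet(list(none), list(none))),
               "zero")
  expect_error(SectionMaskSet(list(h), list(none)), "outside")
  expect_error(SectionMaskSet(list(), list()), "at least one")
})
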