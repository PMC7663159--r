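# bonding-pattern classification, distance traces, pyramidalization,
# turnstile dihedral

# a hand-built modified-pair neighbourhood; any named site can be moved
pair_frame <- function(hg1 = c(-0.25, 1.7, 0), hg2 = c(-0.25, -1.7, 0),
                       ...) {
  labels <- c("T7-O4", "T7-O2", "T7-N3", "eA20-N7", "eA20-N6",
              "T19-N3", "A6-N1", "Hg1", "Hg2")
  elements <- c("O", "O", "N", "N", "N", "N", "N", "Hg", "Hg")
  pos <- rbind(c(-2.4, 1.7, 0), c(-2.4, -1.7, 0), c(-2.9, 0, 0),
               c(1.9, 1.7, 0), c(1.9, -1.7, 0),
               c(-2.9, 0, 3.38), c(3.0, 0.6, 3.38),
               hg1, hg2)
  ov <- list(...)
  for (nm in names(ov)) pos[match(nm, labels), ] <- ov[[nm]]
  list(pos = pos, smap = parse_site_labels(labels, elements))
}

# an NN-state frame: the carbonyl edge rotated away, Hg1 bridging
# eA-N7 / T-N3 at 2.15 A each, T-O4 beyond the cutoff
nn_frame <- function() {
  pair_frame(hg1 = c(-0.84, -0.62, 0), `eA20-N7` = c(-0.5, 1.5, 0))
}

test_that("NO / NN / DISSOCIATED classification follows the distance rules", {
  f <- pair_frame()
  expect_identical(classify_pattern(f$pos, f$smap)$label, "NO")

  # Hg1 bridging T-N3 / eA-N7 with T-O4 out of reach -> NN
  f2 <- nn_frame()
  hg1 <- f2$pos[8, ]
  expect_equal(sqrt(sum((hg1 - f2$pos[3, ])^2)), 2.15, tolerance = 0.01)
  expect_gt(sqrt(sum((hg1 - f2$pos[1, ])^2)), 2.6)
  expect_identical(classify_pattern(f2$pos, f2$smap)$label, "NN")

  # both Hg far from every base site -> DISSOCIATED
  f3 <- pair_frame(hg1 = c(0, 8, 0), hg2 = c(0, -8, 0))
  expect_identical(classify_pattern(f3$pos, f3$smap)$label, "DISSOCIATED")

  # missing required sites are reported by name
  bad <- f$smap[f$smap$label != "T7-O4", ]
  expect_error(classify_pattern(f$pos[f$smap$label != "T7-O4", ],
                                parse_site_labels(bad$label, bad$element)),
               "T7-O4")
})

test_that("cross-thymine and adenine-eA bridges are recognized", {
  # Hg2 bridges T7-N3 and T19-N3 (different residues)
  t7n3 <- c(-2.9, 0, 0); t19n3 <- c(-2.9, 0, 3.38)
  mid <- (t7n3 + t19n3) / 2
  f <- pair_frame(hg1 = c(-0.25, 1.7, 0), hg2 = mid)
  cl <- classify_pattern(f$pos, f$smap)
  expect_identical(cl$label, "CROSS_TT")

  # Hg1 bridges A6-N1 and eA20-N6
  a6 <- c(3.0, 0.6, 3.38); ean6 <- c(1.9, -1.7, 0)
  mid2 <- (a6 + ean6) / 2
  # bring the two sites close enough for a 2.2 A bridge
  f2 <- pair_frame(hg1 = mid2)
  d1 <- sqrt(sum((mid2 - a6)^2)); d2 <- sqrt(sum((mid2 - ean6)^2))
  if (d1 <= 2.6 && d2 <= 2.6) {
    expect_identical(classify_pattern(f2$pos, f2$smap)$label, "A_EA")
  } else {
    # geometry spans > cutoff: move the reference sites instead
    f3 <- pair_frame(hg1 = c(2.0, -0.5, 1.5))
    f3$pos[7, ] <- c(2.0, -0.5, 3.6)   # A6-N1 above Hg1
    f3$pos[5, ] <- c(2.0, -0.5, -0.6)  # eA20-N6 below
    expect_identical(classify_pattern(f3$pos, f3$smap)$label, "A_EA")
  }
})

test_that("classification is invariant under rigid-body motion and frame order", {
  f <- pair_frame()
  l0 <- classify_pattern(f$pos, f$smap)$label
  moved <- rigid_motion(f$pos)
  expect_identical(classify_pattern(moved, f$smap)$label, l0)
})

test_that("pattern time series counts transitions with debouncing", {
  f_no <- pair_frame()
  f_nn <- nn_frame()
  # constant trajectory
  pt0 <- pattern_timeseries(rep(list(f_no$pos), 20), f_no$smap)
  expect_identical(unique(pt0$filtered), "NO")
  expect_equal(pt0$transitions, 0L)
  # alternate every 50 frames over 500 frames -> 9 transitions
  frames <- list()
  for (b in 1:10) {
    blk <- if (b %% 2) f_no$pos else f_nn$pos
    frames <- c(frames, rep(list(blk), 50))
  }
  pt <- pattern_timeseries(frames, f_no$smap)
  expect_equal(pt$transitions, length(frames) / 50 - 1)
  expect_setequal(pt$residence$label, c("NO", "NN"))
  # single-frame flicker is debounced away
  flick <- rep(list(f_no$pos), 21); flick[[11]] <- f_nn$pos
  ptf <- pattern_timeseries(flick, f_no$smap, debounce = 3)
  expect_equal(ptf$transitions, 0L)
})

test_that("distance traces report per-frame values and medians", {
  f <- pair_frame()
  tr <- pair_distance_trace(f$pos, f$smap, "Hg1", "T7-O4")
  expect_equal(tr$median, 2.15, tolerance = 1e-9)
  two <- list(rbind(c(0, 0, 0), c(2, 0, 0)), rbind(c(0, 0, 0), c(3, 0, 0)))
  smap2 <- parse_site_labels(c("a", "b"), c("N", "O"))
  tr2 <- pair_distance_trace(two, smap2, "a", "b")
  expect_equal(tr2$median, 2.5)
  expect_equal(tr2$min, 2); expect_equal(tr2$max, 3)
  expect_error(pair_distance_trace(two, smap2, "a", "zz"), "zz")
})

test_that("pyramidalization: planar 0, tetrahedral 54.7, rigid-motion invariant", {
  # planar NH2 + ring carbon
  smap <- parse_site_labels(c("N", "H1", "H2", "C"),
                            c("N", "H", "H", "C"))
  planar <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.5, 0.87, 0),
                  c(-0.5, -0.87, 0))
  expect_equal(pyramidalization(planar, smap, "N", c("H1", "H2", "C")), 0,
               tolerance = 1e-9)
  tet <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / 1
  expect_equal(pyramidalization(tet, smap, "N", c("H1", "H2", "C")),
               54.7356, tolerance = 0.1)
  moved <- rigid_motion(tet)
  expect_equal(pyramidalization(moved, smap, "N", c("H1", "H2", "C")),
               pyramidalization(tet, smap, "N", c("H1", "H2", "C")),
               tolerance = 1e-9)
  # collinear plane atoms are flagged
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  expect_warning(
    expect_true(is.na(pyramidalization(col, smap, "N",
                                       c("H1", "H2", "C")))),
    "collinear")
})

test_that("turnstile dihedral tracks a rotation and unwraps branch cuts", {
  smap <- parse_site_labels(c("N1", "C6", "N6", "Hg1"),
                            c("N", "C", "N", "Hg"))
  base <- rbind(c(-1, 1, 0), c(0, 0, 0), c(1.4, 0, 0), c(2, 0, 1))
  # static
  st <- turnstile_dihedral(rep(list(base), 5), smap, "N1", "C6", "N6",
                           "Hg1")
  expect_equal(st$total_rotation, 0)
  # rotate the Hg about the C6-N6 (x) axis by 180 deg over 100 frames
  frames <- lapply(seq(0, pi, length.out = 101), function(a) {
    p <- base
    p[4, ] <- c(2, sin(a) * 1, cos(a) * 1)
    p
  })
  td <- turnstile_dihedral(frames, smap, "N1", "C6", "N6", "Hg1")
  expect_equal(abs(td$total_rotation), 180, tolerance = 1)
  # full revolution: unwrapped series crosses +/-180 without 360 jumps
  frames2 <- lapply(seq(0, 2 * pi, length.out = 181), function(a) {
    p <- base
    p[4, ] <- c(2, sin(a + 2), cos(a + 2))
    p
  })
  td2 <- turnstile_dihedral(frames2, smap, "N1", "C6", "N6", "Hg1")
  expect_lt(max(abs(diff(td2$unwrapped))), 30)
  expect_equal(abs(td2$total_rotation), 360, tolerance = 1)
})

test_that("unwrap carries NA frames through", {
  th <- c(170, NA, -175, -160)
  un <- unwrap_angles(th)
  expect_true(is.na(un[2]))
  expect_equal(un[3], 185)
})
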