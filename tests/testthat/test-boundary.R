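test_that("quadrant perimeter reproduces the closed-form corner cases", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(quadrantPerimeter(m), pi, tolerance = 1e-12)

  m2 <- matrix(FALSE, 6, 6); m2[3:4, 3:4] <- TRUE
  expect_equal(quadrantPerimeter(m2), 4 + pi, tolerance = 1e-12)

  bar <- matrix(FALSE, 5, 14); bar[3, 2:13] <- TRUE # 1 x 12 bar
  expect_equal(quadrantPerimeter(bar), 2 * 11 + pi, tolerance = 1e-12)

  expect_error(quadrantPerimeter(matrix(FALSE, 4, 4)), "empty")
  multi <- matrix(FALSE, 9, 9); multi[2, 2] <- TRUE; multi[7:8, 6:7] <- TRUE
  expect_warning(p <- quadrantPerimeter(multi), "largest")
  expect_equal(p, 4 + pi, tolerance = 1e-12)
})

test_that("disk perimeters converge to pi * d, error decreasing in radius", {
  errs <- vapply(c(50, 100, 200), function(R) {
    abs(quadrantPerimeter(rasterDisk(R)) - 2 * pi * R) / (2 * pi * R)
  }, numeric(1))
  expect_true(all(errs <= 0.015))
  expect_true(all(diff(errs) < 0))
})

test_that("quadrant perimeter never exceeds the crack perimeter", {
  set.seed(42)
  shapes <- list(rasterDisk(17), rasterDisk(4))
  for (i in 1:4) {
    m <- matrix(FALSE, 40, 40)
    r0 <- sample(5:20, 1); c0 <- sample(5:20, 1)
    m[r0:(r0 + sample(3:12, 1)), c0:(c0 + sample(3:12, 1))] <- TRUE
    m[sample(10:30, 1) + 0:3, sample(10:30, 1) + 0:5] <- TRUE
    shapes <- c(shapes, list(largestComponent(m)))
  }
  for (m in shapes)
    expect_lte(quadrantPerimeter(m), crackPerimeter(m) + 1e-9)
})

test_that("traceBoundary walks the crack lattice as a closed unit chain", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  ch <- traceBoundary(m)
  expect_true(ch@closed)
  v <- ch@vertices
  expect_identical(v[1, ], v[nrow(v), ])
  expect_equal(nrow(v), 5L)
  expect_true(all(rowSums(abs(diff(v))) == 1))
  # vertices are the corners of pixel (1, 1) in 0-based coordinates
  expect_setequal(paste(v[-5, 1], v[-5, 2]), c("1 1", "1 2", "2 2", "2 1"))
})

test_that("margin length measures taut open chains with the corner rule", {
  cal1 <- calibrate(1, 1) # 1 mm per px
  straight <- boundaryChain(cbind(0, 0:100))
  expect_equal(marginLength(straight, calibrate(10, 1)), 10, tolerance = 1e-12)

  corner <- boundaryChain(rbind(c(0, 0), c(0, 1), c(1, 1)))
  expect_equal(marginLength(corner, cal1), 1 + pi / 4, tolerance = 1e-12)

  # additive over concatenation at a straight joint
  a <- boundaryChain(cbind(0, 0:40))
  b <- boundaryChain(cbind(0, 40:100))
  whole <- boundaryChain(cbind(0, 0:100))
  expect_equal(marginLength(a, cal1) + marginLength(b, cal1),
               marginLength(whole, cal1), tolerance = 1e-12)

  closed <- boundaryChain(rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0, 0)),
                          closed = TRUE)
  expect_error(marginLength(closed, cal1), "open chain")
})

test_that("margin length tracks the analytic arc of a digitized half-circle", {
  R <- 60
  disk <- rasterDisk(R)
  chain <- traceBoundary(disk)
  v <- chain@vertices[-nrow(chain@vertices), ]
  ctr <- (ncol(disk)) / 2
  left <- which(v[, 2] == min(v[, 2]))[1]
  right <- which(v[, 2] == max(v[, 2]))[1]
  i <- min(left, right); j <- max(left, right)
  half <- boundaryChain(v[i:j, ])
  expect_equal(marginLength(half, calibrate(1, 1)), pi * R, tolerance = 0.02 * pi * R)
})
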