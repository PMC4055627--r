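test_that("exact circles are recovered by the arc fitter", {
  th <- seq(0.2, 2.1, length.out = 12)
  pts <- cbind(3 + 10 * cos(th), -2 + 10 * sin(th))
  fit <- fitCircularArc(pts)
  expect_false(fit$isStraight)
  expect_equal(fit$center, c(3, -2), tolerance = 1e-8)
  expect_equal(fit$radius, 10, tolerance = 1e-8)
  expect_lt(fit$fitRMS, 1e-8)
})

test_that("degenerate chains are straight", {
  pts <- cbind(seq(0, 4, by = 1), seq(0, 8, by = 2))
  expect_true(fitCircularArc(pts)$isStraight)
  expect_true(fitCircularArc(pts[1:2, ])$isStraight)
  expect_error(fitCircularArc(pts[1, , drop = FALSE]), "at least 2")
})

test_that("noisy quarter-circle radius matches a nonlinear LS oracle", {
  set.seed(42)
  th <- seq(0, pi / 2, length.out = 9)
  pts <- cbind(50 * cos(th) + rnorm(9, 0, 0.2), 50 * sin(th) + rnorm(9, 0, 0.2))
  fit <- fitCircularArc(pts)
  expect_lt(abs(fit$radius - 50) / 50, 0.02)
  ## independent geometric least-squares oracle via general optimizer
  obj <- function(p) sum((sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) - p[3])^2)
  o <- optim(c(0, 0, 45), obj, method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(fit$radius, o$par[3], tolerance = 1e-3)
  expect_equal(fit$center, o$par[1:2], tolerance = 1e-2)
})

test_that("arc fit is invariant under rigid motions", {
  set.seed(7)
  th <- sort(runif(10, 0, 1.5))
  pts <- cbind(4 * cos(th), 4 * sin(th)) + matrix(rnorm(20, 0, 0.01), 10)
  f0 <- fitCircularArc(pts)
  phi <- 0.83; R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  shift <- c(12.5, -3.25)
  f1 <- fitCircularArc(sweep(pts %*% t(R), 2, -shift))
  expect_equal(f1$radius, f0$radius, tolerance = 1e-8)
  expect_equal(f1$center, drop(R %*% f0$center) + shift, tolerance = 1e-8)
})

test_that("limiting tangents are perpendicular to the radius and point away", {
  ## unit circle, junction at (1, 0), edge running counter-clockwise
  th <- seq(0, pi / 2, length.out = 8)
  chain <- cbind(cos(th), sin(th))
  arc <- fitCircularArc(chain)
  expect_equal(limitingTangent(arc, chain, 1L), c(0, 1), tolerance = 1e-7)
  ## straight edge: normalized chord
  ch2 <- rbind(c(0, 0), c(3, 4))
  expect_equal(limitingTangent(list(isStraight = TRUE), ch2, 1L), c(0.6, 0.8))
  expect_equal(limitingTangent(list(isStraight = TRUE), ch2, 2L), c(-0.6, -0.8))
  ## random arcs: tangent orthogonal to (foot - center), unit length
  set.seed(5)
  for (k in 1:20) {
    c0 <- rnorm(2); r <- runif(1, 1, 5)
    a0 <- runif(1, 0, 2 * pi); a1 <- a0 + runif(1, 0.3, 2)
    ch <- cbind(c0[1] + r * cos(seq(a0, a1, length.out = 7)),
                c0[2] + r * sin(seq(a0, a1, length.out = 7)))
    arc <- fitCircularArc(ch)
    for (end in 1:2) {
      t <- limitingTangent(arc, ch, end)
      J <- if (end == 1) ch[1, ] else ch[7, ]
      foot <- arc$center + arc$radius * (J - arc$center) /
        sqrt(sum((J - arc$center)^2))
      expect_lt(abs(sum(t * (foot - arc$center))), 1e-9)
      expect_equal(sum(t^2), 1, tolerance = 1e-9)
    }
  }
})

test_that("angle-method variants behave as defined", {
  ## two-node chain: all methods agree
  ch <- rbind(c(0, 0), c(2, 1))
  arc <- fitCircularArc(ch)
  t <- lapply(c("polyarc", "closest_segment", "minimal_polygon"),
              function(m) angleVariantTangent(ch, arc, m, 1L))
  expect_equal(t[[1]], t[[2]])
  expect_equal(t[[2]], t[[3]])
  ## semicircle: polyarc and chord tangents differ by 90 degrees
  th <- seq(0, pi, length.out = 17)
  semi <- cbind(cos(th), sin(th))
  arcS <- fitCircularArc(semi)
  tp <- angleVariantTangent(semi, arcS, "polyarc", 1L)
  tm <- angleVariantTangent(semi, arcS, "minimal_polygon", 1L)
  expect_lt(abs(sum(tp * tm)), 1e-6)
  ## closest segment equals the normalized first segment
  set.seed(3)
  ch5 <- cbind(cumsum(runif(5)), cumsum(rnorm(5)))
  d <- ch5[2, ] - ch5[1, ]
  expect_equal(angleVariantTangent(ch5, fitCircularArc(ch5),
                                   "closest_segment", 1L),
               d / sqrt(sum(d^2)))
})

test_that("signed curvature follows the convexity convention", {
  ## straight edge
  expect_equal(signedCurvature(list(isStraight = TRUE), rbind(c(0, 0), c(1, 0))), 0)
  ## radius-4 arc with center on the left of the chain: positive 1/4
  th <- seq(-0.5, 0.5, length.out = 9)
  ## chain runs upward along x = 4cos(th) (center at origin, on the left)
  ch <- cbind(4 * cos(th), 4 * sin(th))  # direction of travel: +y, center left
  arc <- fitCircularArc(ch)
  expect_equal(signedCurvature(arc, ch), 0.25, tolerance = 1e-9)
  ## swapping the stored orientation (sides swap) flips the sign
  expect_equal(signedCurvature(arc, ch[rev(seq_len(nrow(ch))), ]), -0.25,
               tolerance = 1e-9)
})

test_that("edge geometry table is complete and flags 2-node chains", {
  m <- smallTissue()$mesh
  geom <- edgeGeometry(m)
  expect_equal(nrow(geom), nEdges(m))
  expect_true(all(is.finite(geom$theta1) & is.finite(geom$theta2)))
  expect_true(all(geom$curvature[geom$isStraight] == 0))
  expect_true(all(!geom$curvatureUsable[geom$nIntermediate == 0L]))
  expect_true(all(geom$chord > 0))
})

test_that("simulator ground truth satisfies the Laplace relation", {
  tis <- smallTissue()
  m <- tis$mesh; truth <- tis$truth
  geom <- edgeGeometry(m)
  ed <- meshEdges(m)
  gi <- match(ed$id, geom$edge)
  use <- !ed$stub & geom$curvatureUsable[gi] &
    as.character(ed$cellLeft) %in% names(truth@pressures) &
    as.character(ed$cellRight) %in% names(truth@pressures)
  q <- truth@tensions[as.character(ed$id)] * geom$curvature[gi]
  dp <- truth@pressures[as.character(ed$cellLeft)] -
    truth@pressures[as.character(ed$cellRight)]
  relRMS <- sqrt(mean((q - dp)[use]^2)) / sqrt(mean(dp[use]^2))
  expect_lt(relRMS, 0.02)
})

test_that("tangent-angle error ranks polyarc < closest segment < chord", {
  ## on annealed tissue, compare each method's junction angles against the
  ## polyarc residual norm of ground truth: methods that approximate the
  ## limiting angle more coarsely violate junction equilibrium more
  tis <- smallTissue()
  m <- tis$mesh; truth <- tis$truth
  res <- vapply(c("polyarc", "closest_segment", "minimal_polygon"),
                function(method) {
    geom <- edgeGeometry(m, method)
    sys <- assembleTensionSystem(m, geom)
    g <- truth@tensions[as.character(sys@cols)]
    r <- sys@G %*% (g / mean(g))
    sqrt(mean(r^2))
  }, numeric(1))
  expect_lt(res[["polyarc"]], res[["closest_segment"]])
  expect_lt(res[["closest_segment"]], res[["minimal_polygon"]])
})
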