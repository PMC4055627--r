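test_that("patch generation is deterministic and Euler-consistent", {
  m1 <- generatePatch(24, seed = 5)
  m2 <- generatePatch(24, seed = 5)
  expect_identical(meshNodes(m1), meshNodes(m2))
  expect_identical(meshChains(m1), meshChains(m2))
  ## planar-graph bounds: E <= 3V - 6 on the junction graph, and each cell
  ## has at least 3 edges
  mBig <- generatePatch(150, seed = 2)
  V <- nJunctions(mBig); E <- nEdges(mBig)
  expect_lte(E, 3 * V - 6)
  expect_true(all(vapply(meshCellEdges(mBig), length, integer(1)) >= 2L))
  ## minimal case: three cells give at least one interior junction
  m3 <- generatePatch(3, seed = 1)
  expect_gte(nJunctions(m3), 1L)
})

test_that("interface tensions follow the type-pair table", {
  m <- generatePatch(20, seed = 3)
  tr <- assignTypesAndTensions(m, seed = 4)
  ed <- meshEdges(m)
  types <- tr@cellTypes
  for (i in seq_len(nrow(ed))) {
    a <- ed$cellLeft[i]; b <- ed$cellRight[i]
    ta <- if (a == 0) NA else types[[as.character(a)]]
    tb <- if (b == 0) NA else types[[as.character(b)]]
    if (is.na(ta)) ta <- tb
    if (is.na(tb)) tb <- ta
    want <- defaultTensionTable[[paste0(min(ta, tb), max(ta, tb))]]
    expect_equal(unname(tr@tensions[[as.character(ed$id[i])]]), want)
  }
  ## two adjacent type-1 cells -> tension 5; forced uniform type 2 -> all 10
  trU <- assignTypesAndTensions(m, types = setNames(
    rep(2L, nCells(m)), as.character(meshCells(m)$id[!meshCells(m)$medium])))
  expect_true(all(trU@tensions == 10))
  ## heterotypic 1|3 interface maps to 7
  expect_equal(unname(defaultTensionTable[["13"]]), 7)
})

test_that("a single uniform-tension cell anneals to a circle", {
  th <- 2 * pi * (0:19) / 20
  sq <- cbind(cos(th) * (1 + 0.2 * cos(3 * th)), sin(th) * (1 + 0.2 * sin(2 * th)))
  nodes <- data.frame(id = 1:20, x = sq[, 1], y = sq[, 2])
  ## four edges of five segments each around the single cell
  chains <- list(`1` = c(1:6), `2` = c(6:11), `3` = c(11:16), `4` = c(16:20, 1))
  edges <- data.frame(id = 1:4, cellLeft = 1L, cellRight = 0L)
  cells <- data.frame(id = c(1L, 0L), partial = c(FALSE, TRUE),
                      medium = c(FALSE, TRUE))
  m <- buildMesh(nodes, edges, cells, chains,
                 list(`1` = 1:4, `0` = 1:4))
  tr <- new("TissueTruth",
            tensions = setNames(rep(2, 4), as.character(1:4)),
            pressures = numeric(0),
            cellTypes = setNames(1L, "1"))
  ann <- annealMesh(m, tr, areaStiffness = 50, pinBoundary = FALSE,
                    rounds = 2, contractTol = 0)
  xy <- cbind(meshNodes(ann$mesh)$x, meshNodes(ann$mesh)$y)
  ctr <- colMeans(xy)
  r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  expect_lt(sd(r) / mean(r), 0.005)
  ## emergent pressure balances the Laplace relation p = gamma / r
  expect_equal(unname(ann$truth@pressures[["1"]]), 2 / mean(r),
               tolerance = 0.02)
})

test_that("three identical cells meet at 120-degree angles", {
  pts <- rbind(c(0, 1), c(-sqrt(3) / 2, -0.5), c(sqrt(3) / 2, -0.5)) * 0.8 + 0.87
  m <- generatePatch(3, seed = 1, points = pts)
  tr <- assignTypesAndTensions(m, types = setNames(rep(1L, 3),
                                                   as.character(1:3)))
  ann <- annealMesh(m, tr, areaStiffness = 60, pinBoundary = FALSE,
                    rounds = 2)
  mm <- ann$mesh
  ## find the interior triple junction (all three incident edges interior)
  jn <- meshJunctions(mm)
  geom <- edgeGeometry(mm)
  for (j in jn$id[jn$order == 3]) {
    eids <- mm@junctionEdges[[as.character(j)]]
    gi <- match(eids, geom$edge)
    interior <- all(meshEdges(mm)$cellLeft[match(eids, meshEdges(mm)$id)] != 0 &
                    meshEdges(mm)$cellRight[match(eids, meshEdges(mm)$id)] != 0)
    if (!interior) next
    th <- ifelse(geom$j1[gi] == j, geom$theta1[gi], geom$theta2[gi])
    th <- sort((th * 180 / pi) %% 360)
    gaps <- diff(c(th, th[1] + 360))
    expect_true(all(abs(gaps - 120) < 0.5))
  }
})

test_that("annealed patches reach junction-level force equilibrium", {
  tis <- smallTissue()
  expect_lt(tis$maxForce, 1e-3 * mean(tis$truth@tensions))
  ## assembling the balance with analytic tangents and true tensions gives
  ## small normalized residuals at every retained junction
  sys <- assembleTensionSystem(tis$mesh, edgeGeometry(tis$mesh))
  g <- tis$truth@tensions[as.character(sys@cols)]
  r <- sys@G %*% (g / mean(g))
  res <- sqrt(r[seq(1, nrow(sys@G), 2)]^2 + r[seq(2, nrow(sys@G), 2)]^2)
  expect_lt(stats::median(res), 1e-2)
})

test_that("region extraction is closed and frayed", {
  tis <- smallTissue()
  m <- tis$mesh
  ed <- meshEdges(m)
  ## every kept edge's side cells are present in the sub-mesh cell table
  expect_true(all(c(ed$cellLeft, ed$cellRight) %in% meshCells(m)$id))
  ## stubs exist (frayed boundary) and are excluded from pressure tallies
  expect_gt(sum(ed$stub), 0L)
  tc <- tallyCounts(m)
  expect_equal(tc@nPressureEqns,
               sum(!ed$stub & vapply(meshChains(m), length,
                                     integer(1))[as.character(ed$id)] >= 3L))
  ## truth restricted to kept edges and cells
  expect_setequal(names(tis$truth@tensions), as.character(ed$id))
  expect_true(all(names(tis$truth@pressures) %in%
                    as.character(meshCells(m)$id)))
})

test_that("full-window extraction keeps every complete cell", {
  tis <- smallTissue()
  patch <- tis$patch
  bb <- attr(patch, "bbox")
  reg <- extractRegion(patch, tis$patchTruth,
                       window = bb + c(-1, 1, -1, 1))
  expect_equal(sum(!meshCells(reg$mesh)$partial & !meshCells(reg$mesh)$medium),
               sum(!meshCells(patch)$partial & !meshCells(patch)$medium))
  expect_error(extractRegion(patch, tis$patchTruth,
                             window = c(-5, -4, -5, -4)), "empty")
})

test_that("noise injection reproduces the specified RMS magnitudes", {
  geom <- data.frame(edge = 1:5000, theta1 = 0, theta2 = 1,
                     curvature = 2, isStraight = FALSE)
  g <- injectNoise(geom, 5, seed = 8)
  dth <- c(g$theta1 - geom$theta1, g$theta2 - geom$theta2) * 180 / pi
  expect_lt(abs(sqrt(mean(dth^2)) - 5), 0.15)
  rel <- g$curvature / geom$curvature - 1
  expect_lt(abs(sqrt(mean(rel^2)) - 0.05), 0.0015)
  ## level 0 is the identity; same seed reproduces
  expect_identical(injectNoise(geom, 0, seed = 1), geom)
  expect_identical(injectNoise(geom, 5, seed = 8), g)
})

test_that("error metrics follow their worked arithmetic", {
  truth <- new("TissueTruth",
               tensions = c(`1` = 1, `2` = 1),
               pressures = c(`1` = 0.5, `2` = -0.5),
               cellTypes = setNames(c(1L, 1L), c("1", "2")))
  m0 <- errorMetrics(c(`1` = 1, `2` = 1), c(`1` = 0.5, `2` = -0.5), truth)
  expect_equal(m0$tensionErrorPct, 0)
  expect_equal(m0$pressureErrorPct, 0)
  m1 <- errorMetrics(c(`1` = 1.1, `2` = 0.9), NULL, truth)
  expect_equal(m1$tensionErrorPct, 10, tolerance = 1e-9)
  m2 <- errorMetrics(c(`1` = 1, `2` = 1), c(`1` = 0.6, `2` = -0.6), truth)
  expect_equal(m2$pressureErrorPct, 20, tolerance = 1e-9)
  ## invariance to uniform tension scale and pressure offset of the truth
  truth2 <- truth
  truth2@tensions <- truth@tensions * 7
  truth2@pressures <- truth@pressures * 7 + 3
  m3 <- errorMetrics(c(`1` = 1, `2` = 1), c(`1` = 0.5, `2` = -0.5), truth2)
  expect_equal(m3$tensionErrorPct, 0, tolerance = 1e-9)
  expect_equal(m3$pressureErrorPct, 0, tolerance = 1e-9)
})

test_that("the validation report is deterministic and complete", {
  tis <- smallTissue()
  rep1 <- runValidation(tissue = tis, methods = c("polyarc", "minimal_polygon"),
                        noiseLevels = c(0, 2), nRuns = 2L, seed = 5)
  rep2 <- runValidation(tissue = tis, methods = c("polyarc", "minimal_polygon"),
                        noiseLevels = c(0, 2), nRuns = 2L, seed = 5)
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), 4L)
  expect_true(all(c("method", "noise", "tensionMean", "tensionSD",
                    "pressureMean", "pressureSD", "nRuns") %in% names(rep1)))
  ## chord angles are worse than polyarc angles at no noise
  expect_lt(rep1$tensionMean[rep1$method == "polyarc" & rep1$noise == 0],
            rep1$tensionMean[rep1$method == "minimal_polygon" & rep1$noise == 0])
})
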