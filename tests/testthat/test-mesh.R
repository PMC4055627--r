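test_that("junctions are derived from edge-end incidence", {
  m <- starMesh(3)
  expect_equal(nJunctions(m), 1L)
  expect_equal(meshJunctions(m)$order, 3L)
  expect_true(all(meshEdges(m)$stub))

  ## four cells around one shared node: a single order-4 (quad) junction
  m4 <- starMesh(4)
  expect_equal(nJunctions(m4), 1L)
  expect_equal(meshJunctions(m4)$order, 4L)
})

test_that("invalid meshes are rejected with informative errors", {
  nodes <- data.frame(id = 1:2, x = c(0, 1), y = c(0, 0))
  edges <- data.frame(id = 1L, cellLeft = 1L, cellRight = 2L)
  cells <- data.frame(id = 1:2, partial = TRUE, medium = FALSE)
  ## chain references a missing node id
  expect_error(
    buildMesh(nodes, edges, cells, list(`1` = c(1L, 99L)),
              list(`1` = 1L, `2` = 1L)),
    "missing node")
  ## a single isolated edge has no junction endpoint at all
  expect_error(
    buildMesh(nodes, edges, cells, list(`1` = c(1L, 2L)),
              list(`1` = 1L, `2` = 1L)),
    "dangling")
})

test_that("a complete cell with a broken loop fails validation", {
  tis <- smallTissue()
  m <- tis$mesh
  cc <- meshCells(m)$id[!meshCells(m)$partial & !meshCells(m)$medium][1]
  ce <- meshCellEdges(m)
  ce[[as.character(cc)]] <- ce[[as.character(cc)]][-2]
  expect_error(
    buildMesh(meshNodes(m), meshEdges(m)[, c("id", "cellLeft", "cellRight")],
              meshCells(m), meshChains(m), ce),
    "loop|border")
})

test_that("excess-edge tally counts attachments beyond three per junction", {
  ## 4 quad junctions and one 6-edge rosette, composed as disjoint stars:
  ## excess = 1 + 1 + 1 + 1 + 3 = 7
  parts <- list(starMesh(6, idOffset = 0L))
  for (k in 1:4)
    parts[[k + 1]] <- starMesh(4, center = c(5 * k, 0), idOffset = 100L * k)
  nodes <- do.call(rbind, lapply(parts, meshNodes))
  edges <- do.call(rbind, lapply(parts, function(m)
    meshEdges(m)[, c("id", "cellLeft", "cellRight")]))
  cells <- do.call(rbind, lapply(parts, meshCells))
  chains <- do.call(c, lapply(parts, meshChains))
  cellEdges <- do.call(c, lapply(parts, meshCellEdges))
  m <- buildMesh(nodes, edges, cells, chains, cellEdges)
  tc <- tallyCounts(m)
  expect_equal(tc@nExcessEdges, 7L)
  expect_equal(tc@nJunctions, 5L)
  ## five disjoint stars are five tension components
  expect_length(tensionComponents(m), 5L)
})

test_that("tally counts match the worked single-junction case", {
  m <- starMesh(3)
  tc <- tallyCounts(m)
  expect_equal(tc@nTensionEqns, 2L)
  expect_equal(tc@nTensions, 3L)
  expect_equal(tc@nStubs, 3L)
  ## no exclusions: nothing removed
  expect_equal(tc@nJunctionsRemoved, 0L)
  expect_equal(tc@nRemovedEdges, 0L)
})

test_that("tallies respect exclusions and pressure-usability rules", {
  tis <- smallTissue()
  m <- tis$mesh
  ed <- meshEdges(m)
  tc0 <- tallyCounts(m)
  expect_equal(tc0@nTensionEqns, 2L * nJunctions(m))
  expect_equal(tc0@nPressures,
               sum(!meshCells(m)$partial & !meshCells(m)$medium) +
                 sum(meshCells(m)$partial))
  ## pressure equations: non-stub edges with at least one intermediate node
  nInter <- vapply(meshChains(m), length, integer(1)) - 2L
  expect_equal(tc0@nPressureEqns,
               sum(!ed$stub & nInter[as.character(ed$id)] >= 1L))
  ## excluding one interior edge removes both its endpoint junctions
  interior <- ed$id[!ed$stub][1]
  tc1 <- tallyCounts(m, excludedEdges = interior)
  expect_equal(tc1@nJunctionsRemoved, 2L)
  expect_equal(tc1@nTensionEqns, 2L * (nJunctions(m) - 2L))
  expect_equal(tc1@nRemovedEdges, 1L)
  expect_error(tallyCounts(m, excludedEdges = 99999L), "not present")
})

test_that("assembled system sizes agree with tallies on random meshes", {
  for (seed in 1:8) {
    m <- randomSmallMesh(seed)
    geom <- edgeGeometry(m)
    tc <- tallyCounts(m)
    sys <- assembleTensionSystem(m, geom)
    expect_equal(nrow(sys@G), tc@nTensionEqns)
    expect_lte(ncol(sys@G), tc@nTensions)
    ## overdetermination implication: eqns >= tensions => rows >= cols
    if (tc@nTensionEqns >= tc@nTensions)
      expect_gte(nrow(sys@G), ncol(sys@G))
  }
})

test_that("tension components agree with a breadth-first oracle", {
  for (seed in 1:20) {
    m <- randomSmallMesh(seed)
    ed <- meshEdges(m)
    excl <- ed$id[seq_len(nrow(ed)) %% 4 == 0]
    got <- canonComponents(tensionComponents(m, excl))
    remJ <- unique(c(ed$j1[ed$id %in% excl], ed$j2[ed$id %in% excl]))
    retained <- setdiff(meshJunctions(m)$id, remJ[!is.na(remJ)])
    link <- ed[!(ed$id %in% excl) & !is.na(ed$j1) & !is.na(ed$j2) &
                 ed$j1 %in% retained & ed$j2 %in% retained, ]
    want <- canonComponents(bfsComponents(retained,
                                          as.matrix(link[, c("j1", "j2")])))
    expect_identical(got, want)
    ## a true partition of the retained junctions
    expect_setequal(unlist(got), retained)
    expect_equal(anyDuplicated(unlist(got)), 0L)
  }
})

test_that("pressure components agree with a union-find oracle", {
  unionFind <- function(vertices, pairs) {
    parent <- setNames(vertices, as.character(vertices))
    find <- function(v) {
      while (parent[[as.character(v)]] != v) v <- parent[[as.character(v)]]
      v
    }
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[[as.character(ra)]] <- rb
    }
    split(vertices, vapply(vertices, find, numeric(1)))
  }
  for (seed in 1:10) {
    m <- randomSmallMesh(seed)
    ed <- meshEdges(m)
    usable <- ed$id[seq_len(nrow(ed)) %% 3 != 0]
    got <- canonComponents(pressureComponents(m, usable))
    pairs <- as.matrix(ed[ed$id %in% usable, c("cellLeft", "cellRight")])
    want <- canonComponents(unionFind(meshCells(m)$id, pairs))
    expect_identical(got, want)
  }
})

test_that("interior edge sidedness is consistent around cell loops", {
  m <- smallTissue()$mesh
  ed <- meshEdges(m)
  cl <- meshCells(m)
  for (cid in cl$id[!cl$partial & !cl$medium]) {
    eids <- meshCellEdges(m)[[as.character(cid)]]
    prevEnd <- NULL
    for (e in eids) {
      i <- match(e, ed$id)
      ch <- meshChains(m)[[as.character(e)]]
      expect_true(ed$cellLeft[i] == cid || ed$cellRight[i] == cid)
      if (ed$cellLeft[i] != cid) ch <- rev(ch)
      if (!is.null(prevEnd)) expect_equal(ch[1], prevEnd)
      prevEnd <- ch[length(ch)]
    }
  }
})
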