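## Label-image reading and mesh extraction.
##
## Conventions: pixel (r, c) of an nr x nc label matrix occupies the unit
## square with corners (c-1, nr-r) to (c, nr-r+1) in mathematical (y-up)
## coordinates, i.e. boundaries run along the inter-pixel corner lattice.
## Regions are 4-connected; boundary chains are traced on the corner lattice
## (8-connected staircases).  Junctions are corners where at least three
## labels meet in the surrounding 2x2 pixel block.  Pixels outside the image
## frame are a sentinel (not medium): boundaries along the frame are not
## membranes, and cells touching the frame are partial.

.OUTSIDE <- -1L

## corner (i, j), i in 0..nr, j in 0..nc -> single integer key
.cornerKey <- function(i, j, nc) i * (nc + 1L) + j

.cornerXY <- function(key, nr, nc) {
  i <- key %/% (nc + 1L); j <- key %% (nc + 1L)
  cbind(x = j, y = nr - i)
}

## labels of the 4 pixels around corner (i, j); OUTSIDE beyond the frame
.cornerLabels <- function(lab, i, j) {
  nr <- nrow(lab); nc <- ncol(lab)
  px <- function(r, c) if (r >= 1L && r <= nr && c >= 1L && c <= nc)
    lab[r, c] else .OUTSIDE
  c(nw = px(i, j), ne = px(i, j + 1L), sw = px(i + 1L, j), se = px(i + 1L, j + 1L))
}

## Trace the outer contour of mask (logical matrix) on the corner lattice,
## keeping the region on the right in image coordinates (so that after the
## y-flip the region lies on the left).  Returns the closed corner sequence
## as (i, j) rows, first corner not repeated.
.traceContour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inR <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  start <- which(mask)[1L]
  r0 <- (start - 1L) %% nr + 1L; c0 <- (start - 1L) %/% nr + 1L
  ## topmost pixel in its column scan: ensure no region pixel above
  while (r0 > 1L && mask[r0 - 1L, c0]) r0 <- r0 - 1L
  i <- r0 - 1L; j <- c0 - 1L
  dir <- "E"
  path <- matrix(NA_integer_, 8L * sum(mask) + 8L, 2L)
  k <- 0L
  starti <- i; startj <- j; startdir <- dir
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    ## advance one corner in direction dir
    if (dir == "E") j <- j + 1L
    else if (dir == "W") j <- j - 1L
    else if (dir == "S") i <- i + 1L
    else i <- i - 1L
    ## choose the next direction at the new corner: with travel direction d,
    ## the pixel right-ahead must stay in R; if both ahead pixels are in R
    ## turn left, if right-ahead leaves R turn right
    if (dir == "E") { ra <- inR(i + 1L, j + 1L); la <- inR(i, j + 1L) }
    else if (dir == "S") { ra <- inR(i + 1L, j); la <- inR(i + 1L, j + 1L) }
    else if (dir == "W") { ra <- inR(i, j); la <- inR(i + 1L, j) }
    else { ra <- inR(i, j + 1L); la <- inR(i, j) }
    dir <- if (ra && !la) dir
    else if (ra && la) switch(dir, E = "N", N = "W", W = "S", S = "E")
    else switch(dir, E = "S", S = "W", W = "N", N = "E")
    if (i == starti && j == startj && dir == startdir) break
    if (k > nrow(path) - 2L) stop("contour tracing did not close")
  }
  path[seq_len(k), , drop = FALSE]
}

#' Build a CellMesh from an integer label matrix
#'
#' Extracts inter-label boundaries as ordered corner chains on the
#' inter-pixel lattice (regions 4-connected, chains 8-connected), detects
#' junctions where three or more labels meet within a 2x2 pixel block,
#' splits each region contour into edges at those junctions, and assembles a
#' \code{\linkS4class{CellMesh}}.  Label 0 denotes the medium; pixels beyond
#' the image frame are neither medium nor cells, so boundaries along the
#' frame are not edges and cells cut by the frame become partial with stub
#' edges where their boundaries meet the frame.
#'
#' @param lab integer label matrix (rows = image rows, top to bottom).
#' @param lengthScale physical units per pixel.
#' @param outsideLabels labels to treat like the out-of-frame sentinel:
#'   their pixels belong to no cell and boundaries against them are not
#'   membranes (used for unmatched rim fragments in re-digitization).
#' @param smoothPasses passes of endpoint-preserving 1-2-1 smoothing applied
#'   to each boundary chain, taming the one-pixel staircase before arc
#'   fitting; 0 keeps raw corner chains.
#' @return a \code{\linkS4class{CellMesh}} in y-up pixel coordinates.
#' @export
meshFromLabels <- function(lab, lengthScale = 1, outsideLabels = integer(),
                           smoothPasses = 16L) {
  if (!is.matrix(lab)) stop("label image must be a matrix")
  if (any(lab != round(lab)) || any(lab < 0))
    stop("label image must contain non-negative integers")
  storage.mode(lab) <- "integer"
  if (length(outsideLabels))
    lab[lab %in% as.integer(outsideLabels)] <- .OUTSIDE
  labs <- sort(unique(as.vector(lab)))
  labs <- labs[labs != .OUTSIDE]
  if (length(labs) < 2L) stop("label image contains a single label")
  nr <- nrow(lab); nc <- ncol(lab)

  ## mark break corners: >= 3 distinct in-frame labels in the 2x2 block, or
  ## membrane-degree >= 3 (checkerboard), or a membrane meeting the frame
  Lp <- matrix(.OUTSIDE, nr + 2L, nc + 2L)
  Lp[2:(nr + 1L), 2:(nc + 1L)] <- lab
  NW <- Lp[1:(nr + 1L), 1:(nc + 1L)]; NE <- Lp[1:(nr + 1L), 2:(nc + 2L)]
  SW <- Lp[2:(nr + 2L), 1:(nc + 1L)]; SE <- Lp[2:(nr + 2L), 2:(nc + 2L)]
  memb <- function(a, b) a != b & a != .OUTSIDE & b != .OUTSIDE
  segN <- memb(NW, NE); segSo <- memb(SW, SE)
  segW <- memb(NW, SW); segEa <- memb(NE, SE)
  deg <- segN + segSo + segW + segEa
  ## count distinct in-frame labels among the 4 pixels
  nlab <- (NW != .OUTSIDE) + ((NE != .OUTSIDE) & NE != NW) +
    ((SW != .OUTSIDE) & SW != NW & SW != NE) +
    ((SE != .OUTSIDE) & SE != NW & SE != NE & SE != SW)
  touchesOut <- NW == .OUTSIDE | NE == .OUTSIDE | SW == .OUTSIDE | SE == .OUTSIDE
  isBreak <- (nlab >= 3L) | (deg >= 3L) | (deg >= 1L & touchesOut)

  edgeEnv <- new.env(hash = TRUE)
  edgeList <- list()
  cellEdges <- list()
  cellPartial <- list()
  warned <- FALSE

  addChain <- function(ik, jk, leftLab) {
    ## ik, jk: corner indices of one membrane chain, in leftLab's traversal
    keys <- .cornerKey(ik, jk, nc)
    k1 <- paste(keys, collapse = ",")
    k2 <- paste(rev(keys), collapse = ",")
    hit <- edgeEnv[[k1]]
    if (is.null(hit)) hit <- edgeEnv[[k2]]
    if (is.null(hit)) {
      ## the label on the other side: inspect the first segment
      di <- ik[2L] - ik[1L]; dj <- jk[2L] - jk[1L]
      labsHere <- .cornerLabels(lab, min(ik[1L], ik[2L]), min(jk[1L], jk[2L]))
      other <- if (dj != 0L) {
        ## horizontal segment: flanked by ne (above) and se (below)
        if (labsHere[["ne"]] == leftLab) labsHere[["se"]] else labsHere[["ne"]]
      } else {
        ## vertical segment: flanked by sw (left in image) and se (right)
        if (labsHere[["sw"]] == leftLab) labsHere[["se"]] else labsHere[["sw"]]
      }
      id <- length(edgeList) + 1L
      edgeList[[id]] <<- list(id = id, keys = keys, left = leftLab,
                              right = as.integer(other))
      edgeEnv[[k1]] <- id
      id
    } else hit
  }

  for (L in labs) {
    if (L == 0L) next  # medium edges are discovered from the cell side
    mask <- lab == L
    comp <- EBImage::bwlabel(mask)
    ncomp <- max(comp)
    if (ncomp > 1L && !warned) {
      warning("label(s) with multiple connected regions; extra regions kept ",
              "as separate partial cells")
      warned <- TRUE
    }
    for (ci in seq_len(ncomp)) {
      cid <- if (ci == 1L) L else max(labs) + length(cellEdges) + 1L
      path <- .traceContour(comp == ci)
      np <- nrow(path)
      ## classify each step: membrane (other side in-frame) or not
      nxt <- c(2:np, 1L)
      i1 <- path[, 1L]; j1 <- path[, 2L]
      i2 <- path[nxt, 1L]; j2 <- path[nxt, 2L]
      isMemb <- logical(np)
      for (s in seq_len(np)) {
        lb <- .cornerLabels(lab, min(i1[s], i2[s]), min(j1[s], j2[s]))
        other <- if (j1[s] != j2[s]) {
          if (lb[["ne"]] == L) lb[["se"]] else lb[["ne"]]
        } else {
          if (lb[["sw"]] == L) lb[["se"]] else lb[["sw"]]
        }
        isMemb[s] <- other != .OUTSIDE
      }
      partial <- any(!isMemb)
      ## break the cyclic step sequence into chains: cut before any step
      ## whose start corner is a break corner, and at membrane gaps
      cutHere <- isBreak[cbind(i1 + 1L, j1 + 1L)] | !isMemb |
        !isMemb[c(np, seq_len(np - 1L))]
      if (!any(cutHere)) {
        ## closed loop without junctions: split into two halves
        cutHere[c(1L, floor(np / 2) + 1L)] <- TRUE
      }
      starts <- which(cutHere)
      ordSteps <- c(starts[1L]:np, if (starts[1L] > 1L) 1:(starts[1L] - 1L))
      eids <- integer(0)
      run <- integer(0)
      flushRun <- function(run) {
        if (length(run) < 1L) return(invisible(NULL))
        ## the contour walk keeps the region on the right in y-up
        ## coordinates; reverse so the owning cell lies on the left
        ii <- rev(c(i1[run], i2[run[length(run)]]))
        jj <- rev(c(j1[run], j2[run[length(run)]]))
        eid <- addChain(ii, jj, L)
        eids <<- c(eids, eid)
        invisible(NULL)
      }
      for (s in ordSteps) {
        if (cutHere[s] && length(run)) { flushRun(run); run <- integer(0) }
        if (isMemb[s]) run <- c(run, s)
        else if (length(run)) { flushRun(run); run <- integer(0) }
      }
      flushRun(run)
      cellEdges[[as.character(cid)]] <- rev(eids)
      cellPartial[[as.character(cid)]] <- partial
    }
  }

  ## medium cell
  mediumPresent <- 0L %in% labs
  if (mediumPresent) {
    medEdges <- vapply(edgeList, function(e)
      e$left == 0L || e$right == 0L, logical(1))
    cellEdges[[as.character(MEDIUM)]] <- vapply(edgeList[medEdges], `[[`,
                                                integer(1), "id")
    cellPartial[[as.character(MEDIUM)]] <- TRUE
  }

  ## drop chains with no junction at either end (cut twice by the frame):
  ## they can contribute no junction equation and no reliable pressure row
  endCount <- table(unlist(lapply(edgeList, function(e)
    e$keys[c(1L, length(e$keys))])))
  floating <- vapply(edgeList, function(e) {
    k <- e$keys
    endCount[[as.character(k[1L])]] < 2L &&
      endCount[[as.character(k[length(k)])]] < 2L
  }, logical(1))
  if (any(floating)) {
    warning(sum(floating), " boundary chain(s) truncated at both ends dropped")
    dropIds <- vapply(edgeList[floating], `[[`, integer(1), "id")
    edgeList <- edgeList[!floating]
    cellEdges <- lapply(cellEdges, function(v) setdiff(v, dropIds))
  }
  if (!length(edgeList)) stop("no usable cell-cell boundaries in image")

  cids <- as.integer(names(cellEdges))
  cells <- data.frame(id = cids,
                      partial = unlist(cellPartial[as.character(cids)]),
                      medium = cids == MEDIUM & mediumPresent)
  ## edges bordering a cell id that never got its own traced contour (only
  ## possible for enclosed holes) -> mark enclosing cell partial
  edgeDf <- data.frame(
    id = vapply(edgeList, `[[`, integer(1), "id"),
    cellLeft = vapply(edgeList, function(e) as.integer(e$left), integer(1)),
    cellRight = vapply(edgeList, function(e) as.integer(e$right), integer(1)))

  ## nodes: all corners used by chains
  allKeys <- unique(unlist(lapply(edgeList, `[[`, "keys")))
  nodeId <- setNames(seq_along(allKeys), as.character(allKeys))
  xy <- .cornerXY(allKeys, nr, nc)
  nodes <- data.frame(id = seq_along(allKeys), x = xy[, 1L], y = xy[, 2L])
  chains <- setNames(lapply(edgeList, function(e)
    unname(nodeId[as.character(e$keys)])), as.character(edgeDf$id))

  ## smooth the pixel-staircase chains (endpoints fixed): interior corners
  ## belong to exactly one chain, so this never tears the topology
  if (smoothPasses > 0L) {
    for (id in names(chains)) {
      ch <- chains[[id]]
      m <- length(ch)
      if (m < 4L) next
      ix <- match(ch, nodes$id)
      cx <- nodes$x[ix]; cy <- nodes$y[ix]
      for (p in seq_len(smoothPasses)) {
        i <- 2:(m - 1L)
        cx[i] <- 0.25 * cx[i - 1L] + 0.5 * cx[i] + 0.25 * cx[i + 1L]
        cy[i] <- 0.25 * cy[i - 1L] + 0.5 * cy[i] + 0.25 * cy[i + 1L]
      }
      nodes$x[ix] <- cx; nodes$y[ix] <- cy
    }
  }

  ## a cell whose boundary includes hole edges cannot form a single loop;
  ## flag it partial (documented limitation for island topologies)
  for (k in seq_len(nrow(cells))) {
    cid <- cells$id[k]
    if (cells$partial[k] || cells$medium[k]) next
    eids <- cellEdges[[as.character(cid)]]
    claimed <- edgeDf$id[edgeDf$cellLeft == cid | edgeDf$cellRight == cid]
    if (!setequal(eids, claimed)) {
      cells$partial[k] <- TRUE
      cellEdges[[as.character(cid)]] <- claimed
      warning(sprintf("cell %d encloses another region; marked partial", cid))
    }
  }

  buildMesh(nodes, edgeDf, cells, chains, cellEdges, lengthScale)
}

#' Read a labeled segmentation image into a CellMesh
#'
#' Accepts an integer-labeled 16-bit TIFF or PNG, one label per cell, 0 =
#' medium/background.  The image row axis is flipped so the mesh lives in
#' mathematical (y-up) coordinates.
#'
#' @param path image file path (.tif/.tiff/.png).
#' @param lengthScale physical units per pixel.
#' @return a \code{\linkS4class{CellMesh}}.
#' @export
readLabelImage <- function(path, lengthScale = 1) {
  ext <- tolower(tools::file_ext(path))
  lab <- if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    round(m * 65535)
  } else stop("unsupported image format: ", ext)
  storage.mode(lab) <- "integer"
  meshFromLabels(lab, lengthScale)
}

#' Write a label matrix as a 16-bit TIFF
#'
#' @param lab integer label matrix (values 0..65535).
#' @param path output path.
#' @export
writeLabelImage <- function(lab, path) {
  if (max(lab) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
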