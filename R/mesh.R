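# Voxel hexahedral mesh construction.

# largest 6-connected component of a logical 3D array; returns logical
# array of the same shape
.largestComponent <- function(mask) {
  d <- dim(mask)
  nvox <- prod(d)
  comp <- integer(nvox)        # 0 = unvisited / not in mask
  compID <- 0L
  idxAll <- which(mask)
  if (!length(idxAll)) return(mask)
  remaining <- logical(nvox); remaining[idxAll] <- TRUE
  sizes <- integer(0)
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  ind <- arrayInd(idxAll, d)
  iArr <- integer(nvox); jArr <- integer(nvox); kArr <- integer(nvox)
  iArr[idxAll] <- ind[, 1]; jArr[idxAll] <- ind[, 2]; kArr[idxAll] <- ind[, 3]
  while (any(remaining)) {
    seedIdx <- which.max(remaining)
    compID <- compID + 1L
    frontier <- seedIdx
    remaining[seedIdx] <- FALSE
    comp[seedIdx] <- compID
    size <- 1L
    while (length(frontier)) {
      nb <- c(
        frontier[iArr[frontier] > 1] - sx,
        frontier[iArr[frontier] < d[1]] + sx,
        frontier[jArr[frontier] > 1] - sy,
        frontier[jArr[frontier] < d[2]] + sy,
        frontier[kArr[frontier] > 1] - sz,
        frontier[kArr[frontier] < d[3]] + sz)
      nb <- unique(nb[remaining[nb]])
      if (length(nb)) {
        remaining[nb] <- FALSE
        comp[nb] <- compID
        size <- size + length(nb)
      }
      frontier <- nb
    }
    sizes[compID] <- size
  }
  best <- which.max(sizes)
  array(comp == best, dim = d)
}

# mesh a logical voxel mask: one hex element per TRUE voxel, shared nodes
.meshFromMask <- function(mask, density, spacing, origin = c(0, 0, 0)) {
  d <- dim(mask)
  vox <- which(mask)
  if (!length(vox)) stop("mesh construction: no voxels above threshold",
                         call. = FALSE)
  ijk <- arrayInd(vox, d)
  nnx <- d[1] + 1L; nny <- d[2] + 1L
  nid <- function(i, j, k) i + nnx * ((j - 1L) + nny * (k - 1L))
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  elems <- cbind(
    nid(i,      j,      k),      nid(i + 1L, j,      k),
    nid(i + 1L, j + 1L, k),      nid(i,      j + 1L, k),
    nid(i,      j,      k + 1L), nid(i + 1L, j,      k + 1L),
    nid(i + 1L, j + 1L, k + 1L), nid(i,      j + 1L, k + 1L))
  used <- sort(unique(as.vector(elems)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  elems <- matrix(remap[elems], ncol = 8L)
  kk <- (used - 1L) %/% (nnx * nny)
  jj <- ((used - 1L) %% (nnx * nny)) %/% nnx
  ii <- (used - 1L) %% nnx
  nodes <- cbind(origin[1] + ii * spacing[1],
                 origin[2] + jj * spacing[2],
                 origin[3] + kk * spacing[3])
  list(nodes = nodes, elements = elems, density = density[vox])
}

#' Build a hexahedral mesh from a calibrated volume
#'
#' Creates one 8-node hexahedral element per voxel whose calibrated
#' density exceeds the bone threshold, keeps the largest face-connected
#' component, and assigns the boundary node sets: the distal cut plane
#' (fully constrained) and the femoral-head loading cap (an angular
#' window of the head surface facing the incoming load). The prescribed
#' displacement direction is set by the loading configuration: `NLS`
#' tilts the downward stance load by `stanceAngleDeg` in the coronal
#' plane; `NLF` is an oblique posterolateral fall load at
#' `fallAngleDeg` from vertical. Volumes without head landmarks (plain
#' blocks) are meshed with the top face as the loaded set and the bottom
#' face constrained.
#'
#' @param volume Calibrated [QCTVolume-class] (mg/cc).
#' @param boneThreshold mg/cc; voxels above it become elements.
#' @param configuration "NLS", "NLF" or "custom".
#' @param loadDirection Optional unit vector overriding the
#'   configuration default.
#' @param stanceAngleDeg,fallAngleDeg,fallAzimuthDeg Loading-direction
#'   angles, degrees.
#' @param capAngleDeg Angular half-width of the loaded head cap.
#' @return A [HexMesh-class]; element densities are in g/cm^3.
#' @export
buildMesh <- function(volume, boneThreshold = 200,
                      configuration = c("NLS", "NLF", "custom"),
                      loadDirection = NULL,
                      stanceAngleDeg = 20, fallAngleDeg = 60,
                      fallAzimuthDeg = 135, capAngleDeg = 55) {
  stopifnot(is(volume, "QCTVolume"))
  configuration <- match.arg(configuration)
  if (!volume@calibrated)
    stop("buildMesh requires a calibrated volume", call. = FALSE)
  if (boneThreshold < 0) stop("boneThreshold must be >= 0", call. = FALSE)

  mask <- volume@grid > boneThreshold
  bm <- volume@landmarks$boneMask
  if (!is.null(bm)) {            # restrict to anatomy, drop phantom rods
    keep <- array(FALSE, dim(volume@grid)); keep[bm] <- TRUE
    mask <- mask & keep
  }
  if (!any(mask)) stop("mesh construction: no voxels above threshold",
                       call. = FALSE)
  mask <- .largestComponent(mask)
  origin <- volume@landmarks$origin
  if (is.null(origin)) origin <- c(0, 0, 0)
  m <- .meshFromMask(mask, volume@grid / 1000, volume@spacing, origin)

  if (is.null(loadDirection)) {
    loadDirection <- switch(configuration,
      NLS = {
        th <- stanceAngleDeg * pi / 180
        c(-sin(th), 0, -cos(th))
      },
      NLF = {
        th <- fallAngleDeg * pi / 180; ph <- fallAzimuthDeg * pi / 180
        c(sin(th) * cos(ph), sin(th) * sin(ph), -cos(th))
      },
      custom = c(0, 0, -1))
  }
  loadDirection <- unitVec(loadDirection)

  zmin <- min(m$nodes[, 3])
  distal <- which(m$nodes[, 3] < zmin + 1e-6)

  lm <- volume@landmarks
  if (!is.null(lm$headCenter)) {
    rel <- sweep(m$nodes, 2, lm$headCenter)
    rr <- sqrt(rowSums(rel^2))
    along <- -(rel %*% loadDirection)          # projection toward the load
    head <- which(rr <= lm$headRadius + max(volume@spacing) &
                  along >= rr * cos(capAngleDeg * pi / 180) & rr > 1e-9)
  } else {
    zmax <- max(m$nodes[, 3])
    head <- which(m$nodes[, 3] > zmax - 1e-6)
  }
  head <- setdiff(head, distal)
  if (!length(head) || !length(distal))
    stop("mesh construction: empty head or distal node set", call. = FALSE)

  new("HexMesh", nodes = m$nodes, elements = m$elements,
      elementDensity = m$density,
      nodeSets = list(headSurface = as.integer(head),
                      distalFace = as.integer(distal)),
      loadDirection = as.numeric(loadDirection),
      spacing = volume@spacing)
}

#' Build a rectangular block mesh directly
#'
#' A uniform-density block of `dims` voxels, loaded on the top z face and
#' constrained on the bottom face. Used for solver validation against
#' closed-form bar solutions and patch tests.
#'
#' @param dims Integer length-3: voxels per axis.
#' @param spacing mm per axis.
#' @param density g/cm^3 (scalar or one per element).
#' @param loadDirection Unit vector (default axial compression).
#' @return A [HexMesh-class].
#' @export
#' @examples
#' blockMesh(c(1, 1, 1), spacing = c(1, 1, 1), density = 0.5)
blockMesh <- function(dims, spacing = c(1, 1, 1), density = 1,
                      loadDirection = c(0, 0, -1)) {
  mask <- array(TRUE, dim = dims)
  dens <- array(rep_len(density, prod(dims)), dim = dims)
  m <- .meshFromMask(mask, dens, spacing)
  zmax <- max(m$nodes[, 3]); zmin <- min(m$nodes[, 3])
  new("HexMesh", nodes = m$nodes, elements = m$elements,
      elementDensity = m$density,
      nodeSets = list(
        headSurface = as.integer(which(m$nodes[, 3] > zmax - 1e-9)),
        distalFace = as.integer(which(m$nodes[, 3] < zmin + 1e-9))),
      loadDirection = unitVec(loadDirection), spacing = spacing)
}
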