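## Static linear elasticity on labeled tetrahedral meshes. Distal
## Dirichlet constraints, proximal total forces split equally over their
## node set, direct sparse Cholesky below a size threshold and
## Jacobi-preconditioned conjugate gradients above it. Units: mm-N-MPa.

#' Define a static load case
#'
#' @param name identifier for the load case.
#' @param dirichlet a constraint or list of constraints; each is a list
#'   with \code{set} (node set name), optional \code{value} (prescribed
#'   displacement: numeric(3), or an n x 3 matrix with one row per set
#'   node; default all-zero) and optional \code{axes} (constrained axes,
#'   default 1:3).
#' @param neumann list of loads; each a list with \code{set} (node set
#'   name) and \code{force} (total force vector in N, split equally over
#'   the set's nodes). An optional \code{weights} entry (one nonnegative
#'   value per set node) splits the total force proportionally instead,
#'   e.g. tributary face areas from
#'   \code{\link{faceTributaryWeights}} for a consistent uniform
#'   traction.
#' @return a list of class \code{LoadCase}.
#' @examples
#' loadCase("walking_peak",
#'          dirichlet = list(set = "DISTAL_FIX"),
#'          neumann = list(list(set = "PROXIMAL_LOAD",
#'                              force = c(150, 0, -1500))))
#' @export
loadCase <- function(name, dirichlet, neumann = list()) {
  if (!is.null(dirichlet$set)) dirichlet <- list(dirichlet)
  if (!length(dirichlet))
    stop("a load case needs at least one Dirichlet constraint set",
         call. = FALSE)
  dirichlet <- lapply(dirichlet, function(d) {
    stopifnot(is.character(d$set))
    if (is.null(d$axes)) d$axes <- 1:3
    if (is.null(d$value)) d$value <- c(0, 0, 0)
    d
  })
  for (nm in neumann) {
    if (is.null(nm$set) || is.null(nm$force) ||
        any(!is.finite(nm$force)) || length(nm$force) != 3L)
      stop("each Neumann load needs a node set and a finite force ",
           "vector of length 3", call. = FALSE)
  }
  structure(list(name = name, dirichlet = dirichlet, neumann = neumann),
            class = "LoadCase")
}

## expand load case -> (constrained dof indices, prescribed values, rhs)
.applyLoadCase <- function(mesh, load) {
  nn <- nrow(mesh@nodes)
  ndof <- 3L * nn
  for (d in load$dirichlet)
    if (is.null(mesh@nodeSets[[d$set]]))
      stop("Dirichlet node set '", d$set, "' not found in mesh",
           call. = FALSE)
  for (nm in load$neumann)
    if (is.null(mesh@nodeSets[[nm$set]]))
      stop("Neumann node set '", nm$set, "' not found in mesh",
           call. = FALSE)

  cdof <- integer(0)
  cval <- numeric(0)
  for (d in load$dirichlet) {
    set <- mesh@nodeSets[[d$set]]
    val <- d$value
    if (is.matrix(val)) {
      if (nrow(val) != length(set) || ncol(val) != 3L)
        stop("per-node Dirichlet values must be a |set| x 3 matrix",
             call. = FALSE)
    } else {
      val <- matrix(rep(as.numeric(val), each = length(set)),
                    ncol = 3L)
    }
    for (ax in d$axes) {
      cdof <- c(cdof, 3L * (set - 1L) + ax)
      cval <- c(cval, val[, ax])
    }
  }
  ## later prescriptions win on duplicate dofs
  keep <- !duplicated(cdof, fromLast = TRUE)
  cdof <- cdof[keep]; cval <- cval[keep]
  ord <- order(cdof)
  cdof <- cdof[ord]; cval <- cval[ord]

  f <- numeric(ndof)
  for (nm in load$neumann) {
    set <- mesh@nodeSets[[nm$set]]
    w <- if (is.null(nm$weights)) rep(1, length(set)) else nm$weights
    if (length(w) != length(set) || any(w < 0) || sum(w) == 0)
      stop("Neumann weights must be nonnegative, one per set node",
           call. = FALSE)
    w <- w / sum(w)
    for (ax in 1:3)
      f[3L * (set - 1L) + ax] <- f[3L * (set - 1L) + ax] +
        nm$force[ax] * w
  }
  list(cdof = cdof, cval = cval, f = f)
}

## number of rigid-body modes not restrained by the constrained dofs
.unconstrainedModes <- function(nodes, cdof) {
  if (!length(cdof)) return(6L)
  nn <- nrow(nodes)
  node <- (cdof - 1L) %/% 3L + 1L
  axis <- (cdof - 1L) %% 3L + 1L
  ## rigid modes: 3 translations + 3 rotations about the origin
  R <- matrix(0, length(cdof), 6L)
  xyz <- nodes[node, , drop = FALSE]
  for (k in 1:3) R[axis == k, k] <- 1
  rot <- list(cbind(0, -xyz[, 3], xyz[, 2]),
              cbind(xyz[, 3], 0, -xyz[, 1]),
              cbind(-xyz[, 2], xyz[, 1], 0))
  for (k in 1:3) R[, 3L + k] <- rot[[k]][cbind(seq_along(cdof), axis)]
  6L - qr(R)$rank
}

#' Assemble and solve a static linear-elastic problem
#'
#' Minimizes the linear-elastic energy subject to the load case's
#' Dirichlet constraints; each Neumann total force is split equally
#' across its node set. Strain and stress tensors are recovered per
#' element (constant for order-1 elements, integration-point average for
#' order-2) and reactions are reported on all constrained nodes.
#'
#' @param mesh a \linkS4class{TetMesh} with the load case's node sets.
#' @param materials a \linkS4class{MaterialTable} covering all elements.
#' @param load a \code{\link{loadCase}}.
#' @param method \code{"auto"} (direct sparse Cholesky up to
#'   \code{direct_limit} free dofs, incomplete-Cholesky preconditioned
#'   conjugate gradients above), \code{"direct"} or \code{"cg"}.
#' @param cg_tol relative residual tolerance of the CG solver.
#' @param direct_limit free-dof threshold for the automatic switch; the
#'   default keeps the direct factorization comfortably inside a few GB
#'   of memory on voxel meshes.
#' @return an \linkS4class{FESolution}.
#' @export
assembleAndSolve <- function(mesh, materials, load,
                             method = c("auto", "direct", "cg"),
                             cg_tol = 1e-10, direct_limit = 120000) {
  method <- match.arg(method)
  m <- nrow(mesh@elements)
  if (length(materials@E) != m)
    stop("material table covers ", length(materials@E),
         " elements, mesh has ", m, call. = FALSE)
  vols <- tetVolumes(mesh)
  if (any(vols <= 0))
    stop("non-positive-definite element (inverted geometry) at element ",
         which(vols <= 0)[1], call. = FALSE)

  bc <- .applyLoadCase(mesh, load)
  nmodes <- .unconstrainedModes(mesh@nodes, bc$cdof)
  if (nmodes > 0L)
    stop("singular system: ", nmodes,
         " unconstrained rigid-body mode(s); add Dirichlet constraints",
         call. = FALSE)

  E <- materials@E
  nu <- materials@nu
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))

  tri <- .assembleTriplets(mesh@nodes, mesh@elements, lambda, mu)
  ndof <- 3L * nrow(mesh@nodes)
  K <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(ndof, ndof), symmetric = TRUE)
  rm(tri)

  free <- setdiff(seq_len(ndof), bc$cdof)
  u <- numeric(ndof)
  u[bc$cdof] <- bc$cval
  rhs <- bc$f[free]
  if (any(bc$cval != 0))
    rhs <- rhs - as.numeric(K[free, bc$cdof, drop = FALSE] %*% bc$cval)

  Kff <- K[free, free]
  ## keep lower-triangle symmetric storage (the PCG kernel requires it)
  Kff <- methods::as(Matrix::forceSymmetric(Kff, uplo = "L"),
                     "CsparseMatrix")
  use_direct <- method == "direct" ||
    (method == "auto" && length(free) <= direct_limit)
  if (use_direct) {
    ch <- tryCatch(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE),
                   error = function(e)
                     stop("singular or non-positive-definite stiffness ",
                          "system: ", conditionMessage(e), call. = FALSE))
    u[free] <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  } else {
    res <- .icpcgSolve(Kff, rhs, tol = cg_tol, maxit = 50000L)
    if (res$relres > cg_tol)
      warning("PCG stopped at relative residual ", signif(res$relres, 3))
    u[free] <- res$x
  }

  r <- as.numeric(K %*% u) - bc$f
  cnodes <- sort(unique((bc$cdof - 1L) %/% 3L + 1L))
  reactions <- matrix(r[rep(3L * (cnodes - 1L), each = 3L) + 1:3],
                      ncol = 3L, byrow = TRUE)
  rownames(reactions) <- cnodes
  colnames(reactions) <- c("Fx", "Fy", "Fz")

  U <- matrix(u, ncol = 3L, byrow = TRUE)
  colnames(U) <- c("ux", "uy", "uz")
  eps <- .elementStrains(mesh@nodes, mesh@elements, U)
  colnames(eps) <- c("xx", "yy", "zz", "xy", "yz", "zx")
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  sig <- 2 * mu * eps
  sig[, 1:3] <- sig[, 1:3] + lambda * tr
  colnames(sig) <- colnames(eps)

  new("FESolution", displacements = U, strain = eps, stress = sig,
      reactions = reactions,
      loadCase = unclass(load))
}

#' Global equilibrium residual of a solution
#'
#' Ratio of |sum of reactions + sum of applied forces| to the applied
#' load magnitude (or to the reaction magnitude for load-free cases).
#'
#' @param solution an \linkS4class{FESolution}.
#' @param mesh the mesh the solution was computed on.
#' @return a dimensionless residual.
#' @export
equilibriumResidual <- function(solution, mesh) {
  applied <- c(0, 0, 0)
  for (nm in solution@loadCase$neumann) applied <- applied + nm$force
  total <- colSums(solution@reactions) + applied
  denom <- max(sqrt(sum(applied^2)),
               sum(sqrt(rowSums(solution@reactions^2))), 1e-300)
  sqrt(sum(total^2)) / denom
}

#' Tributary face weights of a node set on a coordinate plane
#'
#' For a node set lying on a plane of constant coordinate (e.g. the end
#' cross-section of a bar), accumulates one third of the area of every
#' boundary triangle whose vertices all belong to the set. Splitting a
#' total force with these weights reproduces the consistent load vector
#' of a uniform traction on linear tetrahedra, which makes closed-form
#' constant-stress states exactly representable.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param set node set name.
#' @return numeric weights (mm^2), one per set node, in set order.
#' @export
faceTributaryWeights <- function(mesh, set) {
  nodes <- mesh@nodeSets[[set]]
  if (is.null(nodes)) stop("node set '", set, "' not found", call. = FALSE)
  inset <- logical(nrow(mesh@nodes))
  inset[nodes] <- TRUE
  el <- mesh@elements
  corner_faces <- list(c(1L, 2L, 3L), c(1L, 2L, 4L),
                       c(1L, 3L, 4L), c(2L, 3L, 4L))
  ## mid-edge nodes of each face in C3D10 ordering
  mid_faces <- list(c(5L, 6L, 7L), c(5L, 9L, 8L),
                    c(7L, 8L, 10L), c(6L, 10L, 9L))
  faces <- do.call(rbind, lapply(corner_faces, function(fc)
    el[, fc, drop = FALSE]))
  keep <- inset[faces[, 1]] & inset[faces[, 2]] & inset[faces[, 3]]
  if (mesh@order == 2L) {
    mids <- do.call(rbind, lapply(mid_faces, function(fm)
      el[, fm, drop = FALSE]))
    keep <- keep & inset[mids[, 1]] & inset[mids[, 2]] & inset[mids[, 3]]
  }
  faces <- faces[keep, , drop = FALSE]
  if (!nrow(faces))
    stop("node set '", set, "' spans no element faces", call. = FALSE)
  nd <- mesh@nodes
  a <- nd[faces[, 2], , drop = FALSE] - nd[faces[, 1], , drop = FALSE]
  b <- nd[faces[, 3], , drop = FALSE] - nd[faces[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))
  ## consistent uniform-traction loads: area/3 per face corner (TET4) or
  ## per face mid-edge node with zero on corners (TET10)
  recv <- if (mesh@order == 2L) mids[keep, , drop = FALSE] else faces
  w <- numeric(nrow(mesh@nodes))
  for (k in 1:3) {
    acc <- tapply(area / 3, recv[, k], sum)
    idx <- as.integer(names(acc))
    w[idx] <- w[idx] + as.numeric(acc)
  }
  w[nodes]
}
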