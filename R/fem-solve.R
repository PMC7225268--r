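# Linear isotropic elasticity on first-order (P1) tetrahedra.
#
# Internally everything is SI: node coordinates are converted from um to
# meters at assembly, prescribed displacements from um to meters at the
# boundary; strains are dimensionless. Voigt ordering is
# (exx, eyy, ezz, gxy, gyz, gzx) with engineering shear strains.

UM <- 1e-6

iso_elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# shape-function gradients and volume of one tet (coords in meters, 4 x 3)
tet_gradients <- function(X) {
  A <- cbind(1, X)
  vol <- abs(det(A)) / 6
  if (vol <= .Machine$double.eps * max(abs(X))^3)
    return(list(grads = NULL, volume = 0))
  C <- solve(A)                 # rows: coefficients; grad_i = C[2:4, i]
  list(grads = C[2:4, , drop = FALSE], volume = vol)
}

tet_B <- function(grads) {
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    bx <- grads[1, i]; by <- grads[2, i]; bz <- grads[3, i]
    c0 <- 3 * (i - 1)
    B[1, c0 + 1] <- bx
    B[2, c0 + 2] <- by
    B[3, c0 + 3] <- bz
    B[4, c0 + 1] <- by; B[4, c0 + 2] <- bx
    B[5, c0 + 2] <- bz; B[5, c0 + 3] <- by
    B[6, c0 + 1] <- bz; B[6, c0 + 3] <- bx
  }
  B
}

#' Assemble the global stiffness matrix
#'
#' Standard isotropic linear-elastic stiffness over P1 tetrahedra; the
#' unconstrained matrix is symmetric positive semidefinite with the six
#' rigid-body modes in its null space.
#'
#' @param mesh a `tet_mesh` (coordinates in um).
#' @param materials named list with one `list(young_modulus, poisson_ratio)`
#'   per region name appearing in `mesh$region`.
#' @return A list: `K` (sparse dgCMatrix, 3n x 3n, SI units), `n_dof`.
#' @export
assemble_elasticity <- function(mesh, materials) {
  m <- nrow(mesh$elems)
  D_by_region <- lapply(materials, function(mat)
    iso_elastic_D(mat$young_modulus, mat$poisson_ratio))
  ii <- integer(m * 144); jj <- integer(m * 144); xx <- numeric(m * 144)
  pos <- 0L
  for (e in seq_len(m)) {
    X <- mesh$nodes[mesh$elems[e, ], , drop = FALSE] * UM
    g <- tet_gradients(X)
    if (g$volume <= 0)
      abort(sprintf("degenerate element %d", e), class = "imetk_assembly_error")
    B <- tet_B(g$grads)
    D <- D_by_region[[mesh$region[e]]]
    if (is.null(D))
      stop_invalid(paste("no material for region", mesh$region[e]))
    ke <- g$volume * crossprod(B, D %*% B)
    dofs <- as.vector(t(outer(mesh$elems[e, ], 1:3,
                              function(n, d) 3 * (n - 1) + d)))
    idx <- pos + seq_len(144)
    ii[idx] <- rep(dofs, times = 12)
    jj[idx] <- rep(dofs, each = 12)
    xx[idx] <- as.vector(ke)
    pos <- pos + 144L
  }
  n_dof <- 3 * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_dof, n_dof))
  K <- (K + Matrix::t(K)) / 2   # enforce exact symmetry
  list(K = K, n_dof = n_dof)
}

#' Apply Dirichlet boundary conditions
#'
#' Default probe-model conditions: the bottom and side outer tissue surfaces
#' are pinned in all directions, and the probe-top nodes are prescribed
#' `u_x = displacement` with `u_y = u_z = 0` (a skull-tethered headcap
#' cannot move vertically relative to the skull; set `pin_lateral = FALSE`
#' for an x-only prescription). A custom constraint table overrides the
#' defaults entirely.
#'
#' @param system output of [assemble_elasticity()].
#' @param mesh the `tet_mesh`.
#' @param displacement prescribed +X displacement at the probe top, um.
#' @param pin_lateral also pin `u_y`, `u_z` at the probe top.
#' @param constraints optional tibble (`node`, `dof` in 1:3, `value` in um)
#'   replacing the default sets.
#' @return A `fem_system` list with the stiffness, constrained dof indices
#'   and values (SI).
#' @export
apply_boundary_conditions <- function(system, mesh, displacement = 20,
                                      pin_lateral = TRUE, constraints = NULL) {
  if (is.null(constraints)) {
    if (length(mesh$probe_top) == 0)
      abort("empty probe_top boundary set", class = "imetk_configuration_error")
    fixed <- tibble(node = rep(mesh$fixed_outer, each = 3),
                    dof = rep(1:3, length(mesh$fixed_outer)), value = 0)
    top_dofs <- if (pin_lateral) 1:3 else 1L
    top <- tibble(node = rep(mesh$probe_top, each = length(top_dofs)),
                  dof = rep(top_dofs, length(mesh$probe_top)),
                  value = rep(c(displacement, 0, 0)[top_dofs],
                              length(mesh$probe_top)))
    constraints <- bind_rows(fixed, top)
  }
  constraints <- distinct(constraints, .data$node, .data$dof,
                          .keep_all = TRUE)
  cidx <- 3 * (constraints$node - 1) + constraints$dof
  structure(list(K = system$K, n_dof = system$n_dof,
                 constrained = cidx, values = constraints$value * UM),
            class = "fem_system")
}

#' Solve the constrained elastic system
#'
#' Eliminates constrained dofs and solves the reduced symmetric positive
#' definite system with a sparse Cholesky factorization, then verifies the
#' relative residual.
#'
#' @param fem a `fem_system` from [apply_boundary_conditions()].
#' @param tol maximum acceptable relative residual.
#' @return n x 3 matrix of nodal displacements in meters.
#' @export
solve_displacements <- function(fem, tol = 1e-8) {
  u <- numeric(fem$n_dof)
  u[fem$constrained] <- fem$values
  free <- setdiff(seq_len(fem$n_dof), fem$constrained)
  Kff <- fem$K[free, free, drop = FALSE]
  rhs <- -fem$K[free, fem$constrained, drop = FALSE] %*% fem$values
  uf <- tryCatch(Matrix::solve(Kff, rhs),
                 error = function(e) abort(
                   paste("solver failed:", conditionMessage(e)),
                   class = "imetk_solver_error"))
  u[free] <- as.numeric(uf)
  res <- as.numeric(Kff %*% u[free] - rhs)
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)
  if (!is.finite(rel) || rel > tol)
    abort(sprintf("relative residual %.2e exceeds %.1e", rel, tol),
          class = "imetk_solver_error")
  matrix(u, ncol = 3, byrow = TRUE)
}

#' Element-constant small-strain tensors
#'
#' Computes the symmetric small-strain tensor
#' `eps = (grad u + grad u^T) / 2`, constant on each P1 tetrahedron.
#'
#' @param mesh the `tet_mesh`.
#' @param u n x 3 nodal displacement matrix (meters).
#' @return m x 6 matrix in Voigt order `(exx, eyy, ezz, gxy, gyz, gzx)` with
#'   engineering shear strains.
#' @export
compute_element_strains <- function(mesh, u) {
  m <- nrow(mesh$elems)
  eps <- matrix(0, m, 6,
                dimnames = list(NULL, c("exx", "eyy", "ezz", "gxy", "gyz", "gzx")))
  for (e in seq_len(m)) {
    nn <- mesh$elems[e, ]
    g <- tet_gradients(mesh$nodes[nn, , drop = FALSE] * UM)
    ue <- as.vector(t(u[nn, , drop = FALSE]))
    eps[e, ] <- as.numeric(tet_B(g$grads) %*% ue)
  }
  eps
}

#' Principal strains of Voigt strain rows
#'
#' @param eps m x 6 Voigt strain matrix (engineering shears).
#' @return m x 3 matrix of principal strains sorted `e1 >= e2 >= e3`.
#' @export
principal_strains <- function(eps) {
  if (is.null(dim(eps))) eps <- matrix(eps, nrow = 1)
  out <- matrix(0, nrow(eps), 3, dimnames = list(NULL, c("e1", "e2", "e3")))
  for (i in seq_len(nrow(eps))) {
    t3 <- matrix(c(eps[i, 1], eps[i, 4] / 2, eps[i, 6] / 2,
                   eps[i, 4] / 2, eps[i, 2], eps[i, 5] / 2,
                   eps[i, 6] / 2, eps[i, 5] / 2, eps[i, 3]), 3, 3)
    out[i, ] <- sort(eigen(t3, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  out
}

#' von Mises equivalent strain
#'
#' `eps_e = 1/(1+nu) * sqrt(0.5 * ((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2))`,
#' where `nu` is the Poisson's ratio of the brain tissue and `e1 >= e2 >= e3`
#' are the principal strains. A hydrostatic state gives 0; a uniaxial-stress
#' state `(e, -nu*e, -nu*e)` gives exactly `e` for any `nu`.
#'
#' @param e1,e2,e3 principal strains (vectors).
#' @param nu Poisson's ratio of the tissue, in `[0, 0.5)`.
#' @return Non-negative equivalent strain, same length as the inputs.
#' @export
von_mises_strain <- function(e1, e2, e3, nu) {
  if (length(nu) != 1 || nu < 0 || nu >= 0.5)
    stop_invalid("`nu` must be a single value in [0, 0.5)")
  sqrt(0.5 * ((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2)) / (1 + nu)
}
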