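#' Build a concentric three-shell spherical head model
#'
#' Analytic stand-in for a boundary-element head model: three concentric
#' shells (brain, skull, scalp) with piecewise-constant conductivities.
#' Default radii 80/85/92 mm and conductivities 0.33/0.0042/0.33 S/m follow
#' the common scalp:skull conductivity ratio of about 80:1.
#'
#' @param radii Strictly increasing shell outer radii in mm
#'   (brain, skull, scalp).
#' @param conductivities Positive conductivities in S/m, one per shell.
#' @param center Sphere center in MNI mm (RAS).
#' @return A list of class `head_model`.
#' @export
build_head_model <- function(radii = c(80, 85, 92),
                             conductivities = c(0.33, 0.0042, 0.33),
                             center = c(0, -15, 5)) {
  if (length(radii) != length(conductivities))
    stop("geometry error: need one conductivity per shell")
  if (length(radii) < 1L) stop("geometry error: at least one shell required")
  if (any(diff(radii) <= 0))
    stop("geometry error: shell radii must be strictly increasing")
  if (any(radii <= 0)) stop("geometry error: radii must be positive")
  if (any(conductivities <= 0))
    stop("geometry error: conductivities must be positive")
  stopifnot(length(center) == 3L)
  structure(list(radii = as.numeric(radii),
                 conductivities = as.numeric(conductivities),
                 center = as.numeric(center)),
            class = "head_model")
}

# Dimensionless per-degree surface gain t_n for a dipole inside the innermost
# shell of a concentric multishell sphere. Solves, for each spherical-harmonic
# degree n, the radial two-point problem with potential continuity and radial
# current continuity at each interface and zero radial current at the scalp.
# In the homogeneous limit t_n = (2n + 1)/n.
#
# Conditioning: within shell k the radial solutions are expressed in the
# normalized basis (x/rho_k)^n and (rho_k/x)^(n+1), and the dipole source term
# is scaled to unit amplitude at the innermost interface; both keep every
# matrix entry O(n) so the per-degree solve stays well conditioned up to high
# degree. The source scaling is undone explicitly afterwards.
.shell_gains <- function(head, n_max) {
  rho <- head$radii / head$radii[length(head$radii)]
  sig <- head$conductivities
  L <- length(rho)
  tn <- numeric(n_max)
  for (n in seq_len(n_max)) {
    if (L == 1L) {
      tn[n] <- (2 * n + 1) / n
      next
    }
    # unknowns: a_1, then (a_k, b_k) for k = 2..L, in shell-normalized bases
    p <- 2L * L - 1L
    A <- matrix(0, p, p)
    rhs <- numeric(p)
    idx_a <- function(k) if (k == 1L) 1L else 2L * (k - 1L)
    idx_b <- function(k) 2L * (k - 1L) + 1L
    phi <- function(k, x) (x / rho[k])^n
    dphi <- function(k, x) (n / x) * (x / rho[k])^n
    psi <- function(k, x) (rho[k] / x)^(n + 1)
    dpsi <- function(k, x) -((n + 1) / x) * (rho[k] / x)^(n + 1)
    # source, scaled to value 1 at the first interface: (rho_1/x)^(n+1)
    src <- function(x) (rho[1] / x)^(n + 1)
    dsrc <- function(x) -((n + 1) / x) * (rho[1] / x)^(n + 1)
    row <- 0L
    for (k in seq_len(L - 1L)) {
      x <- rho[k]
      # potential continuity
      row <- row + 1L
      A[row, idx_a(k)] <- phi(k, x)
      if (k > 1L) A[row, idx_b(k)] <- psi(k, x)
      A[row, idx_a(k + 1L)] <- -phi(k + 1L, x)
      A[row, idx_b(k + 1L)] <- -psi(k + 1L, x)
      if (k == 1L) rhs[row] <- -src(x)
      # radial current continuity
      row <- row + 1L
      A[row, idx_a(k)] <- sig[k] * dphi(k, x)
      if (k > 1L) A[row, idx_b(k)] <- sig[k] * dpsi(k, x)
      A[row, idx_a(k + 1L)] <- -sig[k + 1L] * dphi(k + 1L, x)
      A[row, idx_b(k + 1L)] <- -sig[k + 1L] * dpsi(k + 1L, x)
      if (k == 1L) rhs[row] <- -sig[1L] * dsrc(x)
    }
    # insulating outer boundary: v_L'(1) = 0
    row <- row + 1L
    A[row, idx_a(L)] <- dphi(L, 1)
    A[row, idx_b(L)] <- dpsi(L, 1)
    coef <- solve(A, rhs)
    v1 <- coef[idx_a(L)] * phi(L, 1) + coef[idx_b(L)] * psi(L, 1)
    # undo the unit-source scaling: actual source coefficient is rho_1^-(n+1)
    tn[n] <- v1 * rho[1]^(-(n + 1))
  }
  tn
}

# Surface potentials for dipoles in a multishell sphere.
#
# dipole_pos: nd x 3 positions (mm, absolute MNI), moments: nd x 3 (nA.m),
# elec: ne x 3 electrode positions (projected onto the scalp sphere).
# Returns ne x nd matrix of potentials in microvolts.
.sphere_potential <- function(head, elec, dipole_pos, moments, tn) {
  center <- head$center
  rL <- head$radii[length(head$radii)]
  sig1 <- head$conductivities[1]
  E <- sweep(as.matrix(elec), 2, center, "-")
  Ehat <- E / sqrt(rowSums(E^2))
  ne <- nrow(Ehat)
  D <- sweep(matrix(dipole_pos, ncol = 3), 2, center, "-")
  nd <- nrow(D)
  M <- matrix(moments, ncol = 3)
  f <- sqrt(rowSums(D^2))
  if (any(f >= head$radii[1]))
    stop("geometry error: dipole outside the innermost shell")
  U <- D / ifelse(f > 1e-9, f, 1)
  U[f <= 1e-9, ] <- 0          # central dipole: radial direction undefined
  fhat <- f / rL

  X <- Ehat %*% t(U)           # cos(gamma), ne x nd
  n_max <- length(tn)
  # accumulate S0 = sum t_n fhat^(n-1) n P_n(x); S1 = same with P_n'(x)
  S0 <- matrix(0, ne, nd)
  S1 <- matrix(0, ne, nd)
  P_prev <- matrix(1, ne, nd)  # P_0
  P_cur <- X                   # P_1
  dP_prev <- matrix(0, ne, nd)
  dP_cur <- matrix(1, ne, nd)  # P_1'
  w <- rep(1, nd)              # fhat^(n-1), with 0^0 = 1
  for (n in seq_len(n_max)) {
    wn <- matrix(w, ne, nd, byrow = TRUE)
    S0 <- S0 + tn[n] * n * P_cur * wn
    S1 <- S1 + tn[n] * dP_cur * wn
    # Bonnet recurrences for P_{n+1}, P_{n+1}'
    P_next <- ((2 * n + 1) * X * P_cur - n * P_prev) / (n + 1)
    dP_next <- X * dP_cur + (n + 1) * P_cur
    P_prev <- P_cur; P_cur <- P_next
    dP_prev <- dP_cur; dP_cur <- dP_next
    w <- w * fhat
  }
  # V = pref * [ (m.u) S0 + (m.ehat - (m.u) x) S1 ]
  m_u <- rowSums(M * U)                 # nd
  ME <- Ehat %*% t(M)                   # ne x nd, m.ehat
  MU <- matrix(m_u, ne, nd, byrow = TRUE)
  # prefactor: radii in mm -> meters; moment nA.m -> A.m; volts -> microvolts
  pref <- 1 / (4 * pi * sig1 * (rL * 1e-3)^2) * 1e-9 * 1e6
  pref * (MU * S0 + (ME - MU * X) * S1)
}

#' Compute an analytic spherical-head lead field on a volumetric grid
#'
#' Evaluates the surface potential of unit dipoles along the x, y and z axes
#' at every voxel of a regular grid inside the brain shell, using the series
#' solution for a dipole in a concentric multishell sphere. Electrode
#' positions are radially projected onto the scalp shell. Lead-field rows are
#' average-referenced by default so they match common-average-referenced data.
#'
#' Units: microvolts of scalp potential per nA.m of dipole moment.
#'
#' @param head A `head_model` from [build_head_model()].
#' @param channel_positions Electrode matrix (channels x 3, MNI mm) or a
#'   montage from [ten_ten_montage()].
#' @param grid_spacing Grid spacing in mm (default 10; 5 approaches the
#'   voxel counts of dense whole-brain scans at much higher cost).
#' @param n_terms Series truncation degree (default 80).
#' @param reference `"average"` (default) or `"none"` (monopolar potentials,
#'   used when simulating data against a physical reference electrode).
#' @param margin Dipoles closer than `margin` mm to the brain-shell boundary
#'   are excluded (series accuracy degrades at the interface).
#' @return A list of class `leadfield`: `K` (array channels x 3 x n_voxels),
#'   `grid` (n_voxels x 3 MNI mm), `spacing`, `n_excluded`, `reference`.
#' @export
compute_leadfield <- function(head, channel_positions, grid_spacing = 10,
                              n_terms = 80, reference = c("average", "none"),
                              margin = 2) {
  reference <- match.arg(reference)
  stopifnot(inherits(head, "head_model"), grid_spacing > 0)
  if (is.data.frame(channel_positions))
    channel_positions <- montage_positions(channel_positions)
  elec <- as.matrix(channel_positions)
  stopifnot(ncol(elec) == 3L)

  r1 <- head$radii[1]
  ax <- lapply(head$center, function(c0) {
    k <- floor(r1 / grid_spacing)
    c0 + seq(-k, k) * grid_spacing
  })
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  d <- sqrt(rowSums(sweep(grid, 2, head$center, "-")^2))
  inside <- d <= (r1 - margin)
  n_excluded <- sum(!inside)
  grid <- grid[inside, , drop = FALSE]
  if (nrow(grid) == 0L) stop("geometry error: no grid voxels inside the brain shell")

  tn <- .shell_gains(head, n_terms)
  nv <- nrow(grid)
  nch <- nrow(elec)
  K <- array(NA_real_, dim = c(nch, 3, nv),
             dimnames = list(rownames(elec), c("x", "y", "z"), NULL))
  eye <- diag(3)
  for (d3 in 1:3) {
    V <- .sphere_potential(head, elec, grid,
                           matrix(eye[d3, ], nv, 3, byrow = TRUE), tn)
    K[, d3, ] <- V
  }
  if (reference == "average") {
    mu <- apply(K, c(2, 3), mean)
    K <- sweep(K, c(2, 3), mu, "-")
  }
  structure(list(K = K, grid = grid, spacing = grid_spacing,
                 n_excluded = n_excluded, reference = reference,
                 head = head, n_terms = n_terms),
            class = "leadfield")
}

#' Lead field of arbitrary dipoles (forward projection for simulation)
#'
#' @param head A `head_model`.
#' @param channel_positions Electrode matrix or montage.
#' @param dipole_pos Dipole positions (n x 3, MNI mm).
#' @param moments Dipole moment vectors (n x 3, nA.m).
#' @param reference_position Optional position of a physical reference
#'   electrode; when given, its potential is subtracted from every channel
#'   (referential recording), otherwise monopolar potentials are returned.
#' @param n_terms Series truncation degree.
#' @return Matrix channels x n of potentials in microvolts.
#' @export
forward_dipoles <- function(head, channel_positions, dipole_pos, moments,
                            reference_position = NULL, n_terms = 80) {
  if (is.data.frame(channel_positions)) {
    if (is.null(reference_position))
      reference_position <- attr(channel_positions, "reference")
    channel_positions <- montage_positions(channel_positions)
  }
  tn <- .shell_gains(head, n_terms)
  elec <- as.matrix(channel_positions)
  if (!is.null(reference_position))
    elec <- rbind(elec, matrix(reference_position, 1, 3))
  V <- .sphere_potential(head, elec, dipole_pos, moments, tn)
  if (!is.null(reference_position)) {
    nch <- nrow(elec) - 1L
    V <- V[seq_len(nch), , drop = FALSE] -
      matrix(V[nch + 1L, ], nch, ncol(V), byrow = TRUE)
  }
  V
}
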