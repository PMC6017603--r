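# Independent oracles used to cross-check the implementation.

# Brute-force rigid-superposition RMSD by Euler-angle (z-y-z) grid
# search: coarse pass over all of SO(3), then local refinement to a
# final angular resolution of `fine_deg`.  Translation is handled in
# closed form by centroid matching; only the rotation is searched, so
# this shares no code with the Kabsch path.
grid_search_rmsd <- function(a, b, coarse_deg = 3, fine_deg = 0.5) {
  a_c <- sweep(a, 2, colMeans(a))
  b_c <- sweep(b, 2, colMeans(b))
  th <- crossprod(b_c, a_c)   # t(H) with H = t(a_c) %*% b_c
  c0 <- sum(a_c^2) + sum(b_c^2)
  n <- nrow(a)
  # score(R) = sum(R * t(H)); RMSD^2 = (c0 - 2 score)/n
  best_over_grid <- function(alpha, beta, gamma) {
    ca <- cos(alpha); sa <- sin(alpha)
    best <- c(score = -Inf, a = 0, b = 0, g = 0)
    cb <- cos(beta); sb <- sin(beta)
    cg <- cos(gamma); sg <- sin(gamma)
    for (ia in seq_along(alpha)) {
      # entries of Rz(a)Ry(b)Rz(g), vectorised over the beta x gamma grid
      m11 <- outer(ca[ia] * cb, cg) - sa[ia] * outer(rep(1, length(beta)), sg)
      m12 <- -outer(ca[ia] * cb, sg) - sa[ia] * outer(rep(1, length(beta)), cg)
      m13 <- ca[ia] * sb %o% rep(1, length(gamma))
      m21 <- outer(sa[ia] * cb, cg) + ca[ia] * outer(rep(1, length(beta)), sg)
      m22 <- -outer(sa[ia] * cb, sg) + ca[ia] * outer(rep(1, length(beta)), cg)
      m23 <- sa[ia] * sb %o% rep(1, length(gamma))
      m31 <- -sb %o% cg
      m32 <- sb %o% sg
      m33 <- cb %o% rep(1, length(gamma))
      sc <- m11 * th[1, 1] + m12 * th[1, 2] + m13 * th[1, 3] +
        m21 * th[2, 1] + m22 * th[2, 2] + m23 * th[2, 3] +
        m31 * th[3, 1] + m32 * th[3, 2] + m33 * th[3, 3]
      i <- arrayInd(which.max(sc), dim(sc))
      if (sc[i] > best["score"]) {
        best <- c(score = sc[i], a = alpha[ia], b = beta[i[1]],
                  g = gamma[i[2]])
      }
    }
    best
  }
  d2r <- pi / 180
  coarse <- best_over_grid(seq(0, 360 - coarse_deg, by = coarse_deg) * d2r,
                           seq(0, 180, by = coarse_deg) * d2r,
                           seq(0, 360 - coarse_deg, by = coarse_deg) * d2r)
  span <- coarse_deg * d2r
  step <- fine_deg * d2r
  fine <- best_over_grid(seq(coarse["a"] - span, coarse["a"] + span, by = step),
                         seq(coarse["b"] - span, coarse["b"] + span, by = step),
                         seq(coarse["g"] - span, coarse["g"] + span, by = step))
  sqrt(max(0, (c0 - 2 * fine[["score"]]) / n))
}

# Analytic solvent-accessible area of one of two equal spheres of
# expanded radius R whose centres are d apart: the buried spherical cap
# has height h = R - d/2, so A = 4 pi R^2 - 2 pi R h.
two_sphere_cap_area <- function(R, d) {
  if (d >= 2 * R) return(4 * pi * R^2)
  h <- R - d / 2
  4 * pi * R^2 - 2 * pi * R * h
}

# Exhaustive H-bond detection by plain nested enumeration, mirroring the
# published geometric criteria but sharing no code with the package.
brute_force_hbonds <- function(frame, pose_xyz, lig_elements,
                               dist_max = 3.5) {
  hits <- list()
  for (ip in seq_len(nrow(frame$xyz))) {
    if (!frame$topology$element[ip] %in% c("N", "O", "S")) next
    for (il in seq_len(nrow(pose_xyz))) {
      if (!lig_elements[il] %in% c("N", "O", "S")) next
      d <- sqrt(sum((frame$xyz[ip, ] - pose_xyz[il, ])^2))
      if (d <= dist_max) {
        hits[[length(hits) + 1L]] <- c(ip = ip, il = il, d = d)
      }
    }
  }
  hits
}
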