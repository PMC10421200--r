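# Shared fixtures built in code.

kT300 <- nanosorb::kB_kJmol() * 300

# minimal two-atom bonded system (Zn-S-like labels, neutral, no LJ)
toy_dimer <- function(r = 2.0, kb = 100, r0 = 2.0) {
  st <- nanostructure(c("A", "B"),
                      rbind(c(0, 0, 0), c(0, 0, r)),
                      box = c(50, 50, 50), charge = c(0, 0),
                      bonds = matrix(c(1L, 2L), 1, 2))
  ff <- forcefield(
    species = data.frame(name = c("A", "B"), q = 0, sigma = 3, epsilon = 0,
                         mass = c(30, 30)),
    bonds = data.frame(a = "A", b = "B", kb = kb, r0 = r0),
    angles = data.frame(end = character(0), apex = character(0),
                        k = numeric(0), theta0 = numeric(0)),
    cutoff = 1.0, coulomb = "off")
  list(structure = st, ff = ff)
}

# charged pair with no bond (for Coulomb closed forms)
charged_pair <- function(r = 10, q = c(2, -2), coulomb = "plain",
                         cutoff = 5) {
  st <- nanostructure(c("P", "Q"),
                      rbind(c(0, 0, 0), c(0, 0, r)),
                      box = c(200, 200, 200), charge = q)
  ff <- forcefield(
    species = data.frame(name = c("P", "Q"), q = q, sigma = 3, epsilon = 0,
                         mass = c(30, 30)),
    bonds = data.frame(a = character(0), b = character(0),
                       kb = numeric(0), r0 = numeric(0)),
    angles = data.frame(end = character(0), apex = character(0),
                        k = numeric(0), theta0 = numeric(0)),
    cutoff = cutoff, coulomb = coulomb)
  list(structure = st, ff = ff)
}

# independent dense-grid least-squares oracle for quadratic fits:
# solves the normal equations for c0 + c1 u + c2 u^2 explicitly, with the
# abscissa centred for conditioning
quad_fit_oracle <- function(f, lo, hi, n = 512) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  u <- x - mean(x)
  X <- cbind(1, u, u^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(k = 2 * beta[3], x0 = mean(x) - beta[2] / (2 * beta[3]))
}

# ideal square-well PMF on a grid (sharp edges aligned with grid points);
# closed = TRUE puts the well value on the hi endpoint too (constant layer)
square_well_pmf <- function(depth = 5, lo = 0.3, hi = 0.6, smax = 1.2,
                            ds = 0.005, temperature = 300, closed = FALSE) {
  s <- seq(lo, smax, by = ds)
  inwell <- if (closed) s <= hi + 1e-12 else s < hi
  W <- ifelse(inwell, -depth, 0)
  pmf_curve(s, W, temperature = temperature)
}
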