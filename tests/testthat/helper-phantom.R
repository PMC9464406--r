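# Shared fixtures, built in code. Phantom construction + measurement is a
# second or two each, so the default phantom and its measurement are cached
# per test run.

.fixtures <- new.env(parent = emptyenv())

defaultPhantom <- function() {
  if (is.null(.fixtures$ph))
    .fixtures$ph <- buildPhantom(phantomSpec(mesh_resolution = "coarse"))
  .fixtures$ph
}

defaultMeasurement <- function() {
  if (is.null(.fixtures$meas)) {
    ph <- defaultPhantom()
    .fixtures$meas <- measureFemur(ph$mesh, ph$landmarks)
  }
  .fixtures$meas
}

# exact points on a sphere (deterministic area-uniform sampling)
spherePoints <- function(n, center, radius, cap_cos = -1) {
  i <- seq_len(n)
  z <- 1 - (1 - cap_cos) * (i - 0.5) / n  # cos(theta) uniform in [cap_cos, 1]
  phi <- i * pi * (3 - sqrt(5))           # golden-angle spiral
  s <- sqrt(1 - z^2)
  sweep(radius * cbind(s * cos(phi), s * sin(phi), z), 2, center, `+`)
}

# brute-force geometric sphere fit (independent oracle: quasi-Newton on the
# summed squared geometric residuals, not Gauss-Newton)
fitSphereOracle <- function(points) {
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(points, 2, p[1:3])^2))
    sum((d - p[4])^2)
  }
  ctr <- colMeans(points)
  r0 <- mean(sqrt(rowSums(sweep(points, 2, ctr)^2)))
  fit <- stats::optim(c(ctr, r0), obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 2000))
  list(center = fit$par[1:3], radius = fit$par[4])
}

# brute-force least squares via explicit pseudoinverse
olsOracle <- function(y, X) {
  Xd <- cbind(1, X)
  b <- solve(t(Xd) %*% Xd) %*% t(Xd) %*% y
  e <- y - Xd %*% b
  s2 <- sum(e^2) / (length(y) - ncol(Xd))
  se <- sqrt(diag(s2 * solve(t(Xd) %*% Xd)))
  ybar <- mean(y)
  r2 <- 1 - sum(e^2) / sum((y - ybar)^2)
  list(coef = as.numeric(b), se = as.numeric(se), r2 = r2,
       f = (r2 / (ncol(Xd) - 1)) / ((1 - r2) / (length(y) - ncol(Xd))))
}
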