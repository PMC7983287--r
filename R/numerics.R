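# Low-level numerics shared by the vorticity, lambda2 and preprocessing code.
# Central differences in the interior, one-sided at grid edges; these are
# exact for fields linear in the differentiated coordinate, which is what the
# analytic-phantom oracles rely on.

# derivative of a 3-D array along `axis` with uniform spacing h
diff_axis <- function(a, axis, h) {
  stopifnot(length(dim(a)) == 3, axis %in% 1:3)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  out <- ap
  if (n == 1) {
    out[] <- 0
  } else {
    out[1, , ] <- (ap[2, , ] - ap[1, , ]) / h
    out[n, , ] <- (ap[n, , ] - ap[n - 1, , ]) / h
    if (n > 2) {
      out[2:(n - 1), , ] <- (ap[3:n, , ] - ap[1:(n - 2), , ]) / (2 * h)
    }
  }
  aperm(out, order(perm))
}

# velocity-gradient tensor of one frame: list J[[i]][[j]] = d v_i / d x_j
# frame: array (nx, ny, nz, 3) in m/s; spacing_mm converted to metres here
velocity_gradient <- function(frame, spacing_mm) {
  h_m <- spacing_mm / 1000
  lapply(1:3, function(i)
    lapply(1:3, function(j) diff_axis(frame[, , , i], j, h_m[j])))
}

# curl components from a gradient-tensor list
curl_from_gradient <- function(J) {
  list(J[[3]][[2]] - J[[2]][[3]],   # dw/dy - dv/dz
       J[[1]][[3]] - J[[3]][[1]],   # du/dz - dw/dx
       J[[2]][[1]] - J[[1]][[2]])   # dv/dx - du/dy
}

# Middle eigenvalue of the symmetric 3x3 matrices S^2 + W^2, vectorised over
# voxels. Inputs are the 6 independent entries (arrays of equal shape).
# Uses the trigonometric closed form for symmetric 3x3 eigenvalues.
sym3_middle_eigenvalue <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  # determinant of (A - qI) / p, guarded where p ~ 0 (A already ~ q I)
  safe_p <- ifelse(p > 0, p, 1)
  b11 <- (a11 - q) / safe_p; b22 <- (a22 - q) / safe_p
  b33 <- (a33 - q) / safe_p
  b12 <- a12 / safe_p; b13 <- a13 / safe_p; b23 <- a23 / safe_p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  eig1 <- q + 2 * p * cos(phi)                 # largest
  eig3 <- q + 2 * p * cos(phi + 2 * pi / 3)    # smallest
  mid <- 3 * q - eig1 - eig3
  ifelse(p2 > 0, mid, q)
}
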