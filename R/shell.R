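#' Real spherical harmonics
#'
#' Evaluates the real, orthonormal spherical harmonic \eqn{Y_{lm}} at unit
#' directions, via the standard associated-Legendre recursion (with the
#' Condon-Shortley phase folded into the normalisation).
#'
#' @param l degree (>= 0).
#' @param m order, `-l <= m <= l` (negative orders are the sine terms).
#' @param dirs n x 3 matrix of directions (need not be normalised).
#' @return numeric vector of Y_lm values.
#' @export
real_sph_harm <- function(l, m, dirs) {
  dirs <- rbind(dirs)
  if (l < 0 || abs(m) > l) stop("need l >= 0 and |m| <= l")
  r <- sqrt(rowSums(dirs^2))
  ct <- dirs[, 3] / r
  phi <- atan2(dirs[, 2], dirs[, 1])
  am <- abs(m)
  # associated Legendre P_l^m(ct), Condon-Shortley included
  pmm <- rep(1, length(ct))
  if (am > 0) {
    somx2 <- sqrt(pmax(0, 1 - ct^2))
    fact <- 1
    for (i in seq_len(am)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == am) {
    plm <- pmm
  } else {
    pmmp1 <- ct * (2 * am + 1) * pmm
    if (l == am + 1) {
      plm <- pmmp1
    } else {
      for (ll in (am + 2):l) {
        pll <- (ct * (2 * ll - 1) * pmmp1 - (ll + am - 1) * pmm) / (ll - am)
        pmm <- pmmp1
        pmmp1 <- pll
      }
      plm <- pmmp1
    }
  }
  norm <- sqrt((2 * l + 1) / (4 * pi) *
                 exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  if (m == 0) return(norm * plm)
  if (m > 0) sqrt(2) * norm * plm * cos(m * phi)
  else sqrt(2) * norm * plm * sin(am * phi)
}

#' Closed-form Laplace solution in a spherical shell
#'
#' The analytic oracle for the forward solver: in the shell
#' \eqn{R_1 \le r \le R_2} the harmonic function
#' \eqn{\Phi = (A r^l + B r^{-(l+1)}) Y_{lm}(\theta,\phi)} satisfies
#' Dirichlet data \eqn{\Phi = Y_{lm}} on the inner sphere and an insulated
#' (zero radial derivative) outer sphere, with `A`, `B` solving the 2 x 2
#' system stated by those two boundary conditions.
#'
#' @param l,m spherical harmonic degree and order.
#' @param R1 inner radius (mm), source surface.
#' @param R2 outer radius (mm), insulated torso, `R2 > R1 > 0`.
#' @return an object of class `shell_harmonic` with fields `l`, `m`, `R1`,
#'   `R2`, `A`, `B`.
#' @export
shell_solution <- function(l, m, R1, R2) {
  if (!(R1 > 0 && R2 > R1)) stop("need 0 < R1 < R2")
  M <- rbind(c(R1^l, R1^(-(l + 1))),
             c(l * R2^(l - 1), -(l + 1) * R2^(-(l + 2))))
  ab <- solve(M, c(1, 0))
  structure(list(l = l, m = m, R1 = R1, R2 = R2, A = ab[1], B = ab[2]),
            class = "shell_harmonic")
}

#' Evaluate a shell harmonic solution at points
#'
#' @param sol a [shell_solution()].
#' @param points n x 3 matrix of points (mm), radii ideally within
#'   `[R1, R2]`.
#' @return potentials at `points`.
#' @export
eval_shell <- function(sol, points) {
  points <- rbind(points)
  r <- sqrt(rowSums(points^2))
  radial <- sol$A * r^sol$l + sol$B * r^(-(sol$l + 1))
  radial * real_sph_harm(sol$l, sol$m, points)
}
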