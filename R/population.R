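#' Build the neuron population
#'
#' Places excitatory neurons with a small uniform jitter on a rectangular
#' grid and inhibitory neurons evenly on an interstitial sub-lattice between
#' them (when the inhibitory count tiles the grid; otherwise they are placed
#' uniformly at random between grid points, with a message). Membership in
#' the lesion projection zone (LPZ) is decided by the neuron's nominal
#' lattice position falling inside the closed configured rectangle, so the
#' LPZ is identical across jitter realizations; the jittered positions are
#' what the distance kernel sees.
#'
#' @param cfg an [msp_config()].
#' @return an object of class \code{msp_population}: a list with \code{n},
#'   \code{n_ex}, \code{n_in}, \code{pos} (n x 2 matrix, um), \code{nominal}
#'   (unjittered positions), \code{is_excitatory}, \code{in_lpz}. Excitatory
#'   neurons come first (indices \code{1..n_ex}).
#' @examples
#' pop <- build_population(msp_config("mini"))
#' sum(pop$in_lpz & pop$is_excitatory)  # 16 on the mini grid
#' @export
build_population <- function(cfg) {
  nw <- cfg$network
  nx <- nw$grid_nx; ny <- nw$grid_ny; sp <- nw$spacing
  n_ex <- nx * ny
  n_in <- nw$n_in

  ex_nom <- cbind(
    x = rep((seq_len(nx) - 1) * sp, times = ny),
    y = rep((seq_len(ny) - 1) * sp, each = nx)
  )

  in_nom <- interstitial_lattice(nx, ny, sp, n_in)
  if (is.null(in_nom)) {
    message("inhibitory count does not tile the grid; ",
            "placing inhibitory neurons uniformly at random")
    in_nom <- cbind(
      x = stats::runif(n_in, 0, (nx - 1) * sp),
      y = stats::runif(n_in, 0, (ny - 1) * sp)
    )
  }

  nominal <- rbind(ex_nom, in_nom)
  n <- n_ex + n_in
  pos <- nominal + matrix(stats::runif(2 * n, -nw$jitter * sp, nw$jitter * sp),
                          ncol = 2)
  pos <- pmax(pos, 0)
  colnames(pos) <- c("x", "y")

  r <- cfg$schedule$lpz_rect
  in_lpz <- nominal[, 1] >= r[1] & nominal[, 1] <= r[3] &
            nominal[, 2] >= r[2] & nominal[, 2] <= r[4]

  structure(list(
    n = n, n_ex = n_ex, n_in = n_in,
    pos = pos, nominal = nominal,
    is_excitatory = rep(c(TRUE, FALSE), c(n_ex, n_in)),
    in_lpz = unname(in_lpz)
  ), class = "msp_population")
}

# Even interstitial sub-lattice for the inhibitory neurons, or NULL when
# n_in does not factor as (nx/sx) * (ny/sy) with a common integer stride.
interstitial_lattice <- function(nx, ny, sp, n_in) {
  if (n_in == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  frac <- sqrt(n_in / (nx * ny))
  ix <- nx * frac
  iy <- ny * frac
  if (abs(ix - round(ix)) > 1e-9 || abs(iy - round(iy)) > 1e-9) return(NULL)
  ix <- as.integer(round(ix)); iy <- as.integer(round(iy))
  if (ix * iy != n_in) return(NULL)
  step_x <- nx / ix * sp
  step_y <- ny / iy * sp
  cbind(
    x = rep(step_x / 2 + (seq_len(ix) - 1) * step_x, times = iy),
    y = rep(step_y / 2 + (seq_len(iy) - 1) * step_y, each = ix)
  )
}

#' @export
print.msp_population <- function(x, ...) {
  cat(sprintf("<msp_population> %d neurons (%d excitatory, %d inhibitory), %d in LPZ\n",
              x$n, x$n_ex, x$n_in, sum(x$in_lpz)))
  invisible(x)
}
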