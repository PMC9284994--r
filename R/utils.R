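#' Wrap angles into (-pi, pi]
#'
#' Principal-value wrapping used throughout: phase images, phase differences
#' and the Goldstein unwrapper all share this convention.
#'
#' @param x numeric vector/array of angles in radians.
#' @return object of the same shape with every value wrapped into (-pi, pi].
#' @examples
#' wrap_phase(4)        # 4 - 2*pi
#' wrap_phase(c(-3, 3)) # unchanged
#' @export
wrap_phase <- function(x) {
  out <- atan2(sin(x), cos(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

# wrapped difference a - b via the complex-ratio angle, elementwise
wrap_diff <- function(a, b) wrap_phase(a - b)

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

# extract frame f of a 4-D array without dropping singleton spatial dims
arr_frame <- function(a, f) {
  out <- a[, , , f, drop = FALSE]
  dim(out) <- dim(a)[1:3]
  out
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# shift a matrix by (di, dj), replicating the edge (zero-flux boundary)
shift_edge <- function(m, di = 0L, dj = 0L) {
  n <- nrow(m); p <- ncol(m)
  i <- pmin(pmax(seq_len(n) + di, 1L), n)
  j <- pmin(pmax(seq_len(p) + dj, 1L), p)
  m[i, j, drop = FALSE]
}
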