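#' Goldstein branch-cut phase unwrapping
#'
#' Two-dimensional phase unwrapping by the branch-cut method: phase residues
#' are detected on every 2x2 pixel loop (the wrapped loop integral is a
#' nonzero multiple of 2*pi), opposite-sign residues are connected by branch
#' cuts (greedy nearest-neighbour pairing, ties broken in row-major order;
#' unbalanced or isolated residues are cut to the nearest image border), and
#' the phase is then integrated by flood fill along paths that do not cross
#' the cuts. The output is unique up to a single global 2*pi*k offset per
#' connected region; pixels that cannot be reached without crossing a cut
#' (cut pixels themselves, and regions isolated by cuts) are flagged.
#'
#' @param psi 2-D numeric matrix of wrapped phase, radians.
#' @return list of class `goldstein_unwrap` with elements `unwrapped` (numeric
#'   matrix), `flagged` (logical matrix, `TRUE` where the value crossed or sat
#'   on a cut), `n_residues` (integer), and `cuts` (logical matrix of branch-cut
#'   pixels).
#' @references Goldstein, Zebker & Werner (1988), Radio Science 23(4):713-720.
#' @export
goldstein_unwrap <- function(psi) {
  abort_if(!is.matrix(psi) || !is.numeric(psi), "psi must be a numeric matrix")
  n <- nrow(psi); m <- ncol(psi)
  abort_if(n < 2L || m < 2L, "psi must be at least 2 x 2")

  res <- phase_residues(psi)
  if (nrow(res) == 0L) {
    # residue-free field: simple path integration is exact
    u <- integrate_residue_free(psi)
    return(structure(list(unwrapped = u,
                          flagged = matrix(FALSE, n, m),
                          n_residues = 0L,
                          cuts = matrix(FALSE, n, m)),
                     class = "goldstein_unwrap"))
  }

  cuts <- place_branch_cuts(res, n, m)
  filled <- flood_integrate(psi, cuts)
  structure(list(unwrapped = filled$unwrapped, flagged = filled$flagged,
                 n_residues = nrow(res), cuts = cuts),
            class = "goldstein_unwrap")
}

#' @export
print.goldstein_unwrap <- function(x, ...) {
  cat(sprintf("<goldstein_unwrap: %d x %d, %d residues, %d flagged pixels>\n",
              nrow(x$unwrapped), ncol(x$unwrapped), x$n_residues, sum(x$flagged)))
  invisible(x)
}

# residues on 2x2 loops; returns tibble (i, j, charge) with loop corner (i, j)
phase_residues <- function(psi) {
  n <- nrow(psi); m <- ncol(psi)
  a <- psi[-n, -m]; b <- psi[-n, -1]; cc <- psi[-1, -1]; d <- psi[-1, -m]
  s <- wrap_phase(b - a) + wrap_phase(cc - b) + wrap_phase(d - cc) + wrap_phase(a - d)
  q <- round(s / (2 * pi))
  idx <- which(q != 0, arr.ind = TRUE)
  tibble::tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                 charge = as.integer(q[idx]))
}

# mark branch-cut pixels for a set of residues (greedy dipole pairing)
place_branch_cuts <- function(res, n, m) {
  cuts <- matrix(FALSE, n, m)
  paired <- rep(FALSE, nrow(res))
  ord <- order(res$i, res$j)    # row-major scan order
  for (k in ord) {
    if (paired[k]) next
    opp <- which(!paired & res$charge == -res$charge[k])
    d_border <- min(res$i[k] - 1L, n - res$i[k], res$j[k] - 1L, m - res$j[k]) + 1L
    if (length(opp) > 0L) {
      dd <- abs(res$i[opp] - res$i[k]) + abs(res$j[opp] - res$j[k])
      best <- opp[order(dd, res$i[opp], res$j[opp])][1]
      if (min(dd) <= d_border) {
        cuts <- mark_line(cuts, res$i[k], res$j[k], res$i[best], res$j[best])
        paired[c(k, best)] <- TRUE
        next
      }
    }
    cuts <- mark_border_cut(cuts, res$i[k], res$j[k])
    paired[k] <- TRUE
  }
  cuts
}

# Bresenham rasterisation between two pixels, marking every visited pixel
mark_line <- function(cuts, i1, j1, i2, j2) {
  di <- abs(i2 - i1); dj <- abs(j2 - j1)
  si <- sign(i2 - i1); sj <- sign(j2 - j1)
  err <- di - dj
  i <- i1; j <- j1
  repeat {
    cuts[i, j] <- TRUE
    if (i == i2 && j == j2) break
    e2 <- 2 * err
    if (e2 > -dj) { err <- err - dj; i <- i + si }
    if (e2 < di)  { err <- err + di; j <- j + sj }
  }
  cuts
}

mark_border_cut <- function(cuts, i, j) {
  n <- nrow(cuts); m <- ncol(cuts)
  d <- c(top = i - 1L, bottom = n - i, left = j - 1L, right = m - j)
  side <- names(d)[which.min(d)]
  switch(side,
         top    = { cuts[1:i, j] <- TRUE },
         bottom = { cuts[i:n, j] <- TRUE },
         left   = { cuts[i, 1:j] <- TRUE },
         right  = { cuts[i, j:m] <- TRUE })
  cuts
}

# residue-free exact integration: first column, then along rows
integrate_residue_free <- function(psi) {
  n <- nrow(psi); m <- ncol(psi)
  u1 <- psi[1, 1] + c(0, cumsum(wrap_phase(diff(psi[, 1]))))
  if (m == 1L) return(matrix(u1, n, 1))
  drow <- wrap_phase(psi[, -1, drop = FALSE] - psi[, -m, drop = FALSE])
  u <- matrix(0, n, m)
  u[, 1] <- u1
  for (j in 2:m) u[, j] <- u[, j - 1] + drow[, j - 1]
  u
}

# BFS integration over non-cut pixels; later components and cut pixels flagged
flood_integrate <- function(psi, cuts) {
  n <- nrow(psi); m <- ncol(psi)
  u <- matrix(NA_real_, n, m)
  flagged <- matrix(TRUE, n, m)
  visited <- cuts                        # cut pixels are barriers
  off_i <- c(-1L, 1L, 0L, 0L)
  off_j <- c(0L, 0L, -1L, 1L)
  first_component <- TRUE
  for (seed in which(!visited)) {
    if (visited[seed]) next
    queue <- integer(n * m)
    queue[1] <- seed
    head <- 1L; tail <- 1L
    visited[seed] <- TRUE
    u[seed] <- psi[seed]
    while (head <= tail) {
      p <- queue[head]; head <- head + 1L
      pi_ <- (p - 1L) %% n + 1L
      pj <- (p - 1L) %/% n + 1L
      for (k in 1:4) {
        qi <- pi_ + off_i[k]; qj <- pj + off_j[k]
        if (qi < 1L || qi > n || qj < 1L || qj > m) next
        q <- (qj - 1L) * n + qi
        if (visited[q]) next
        visited[q] <- TRUE
        u[q] <- u[p] + wrap_phase(psi[q] - psi[p])
        tail <- tail + 1L
        queue[tail] <- q
      }
    }
    if (first_component) {
      flagged[!is.na(u) & flagged] <- FALSE   # main region is trustworthy
      first_component <- FALSE
    }
    # secondary regions keep their values but stay flagged
  }
  # unwrap cut pixels from any already-unwrapped 4-neighbour (repeat to closure)
  todo <- which(cuts & is.na(u))
  while (length(todo) > 0L) {
    progress <- FALSE
    for (p in todo) {
      pi_ <- (p - 1L) %% n + 1L
      pj <- (p - 1L) %/% n + 1L
      for (k in 1:4) {
        qi <- pi_ + off_i[k]; qj <- pj + off_j[k]
        if (qi < 1L || qi > n || qj < 1L || qj > m) next
        q <- (qj - 1L) * n + qi
        if (!is.na(u[q])) {
          u[p] <- u[q] + wrap_phase(psi[p] - psi[q])
          progress <- TRUE
          break
        }
      }
    }
    todo <- which(cuts & is.na(u))
    if (!progress) break                 # fully isolated cut cluster
  }
  u[is.na(u)] <- psi[is.na(u)]           # pathological leftovers: raw phase, flagged
  list(unwrapped = u, flagged = flagged)
}
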