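#' Neighbour pairs within a cutoff under periodic boundaries
#'
#' Finds all unordered pairs of points closer than `cutoff` by 3-D
#' minimum-image distance in an orthorhombic box.  The default engine is
#' a cell list (cell edge >= cutoff); `method = "brute"` is the
#' all-pairs reference the cell list must agree with exactly.
#'
#' @param x n x 3 coordinate matrix (nm).
#' @param box length-3 box vector (nm).
#' @param cutoff nm; must not exceed `min(box)/2` (minimum image).
#' @param method `"cell"` or `"brute"`.
#' @return 2-column integer matrix of pairs with `i < j`, ordered by
#'   (i, j).
#' @export
neighbor_pairs <- function(x, box, cutoff, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), ncol(x) == 3, cutoff > 0)
  if (cutoff > min(box) / 2)
    stop("cutoff exceeds min(box)/2: minimum image invalid")
  if (method == "brute" || nrow(x) < 32) {
    return(brute_pairs(x, box, cutoff))
  }
  cell_pairs(x, box, cutoff)
}

brute_pairs <- function(x, box, cutoff) {
  n <- nrow(x)
  if (n < 2) return(matrix(integer(0), 0, 2))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- x[pr[, 2], , drop = FALSE] - x[pr[, 1], , drop = FALSE]
  bm <- matrix(box, nrow(d), 3, byrow = TRUE)
  d <- d - round(d / bm) * bm
  hit <- rowSums(d * d) <= cutoff^2
  out <- cbind(pr[hit, 1], pr[hit, 2])
  dimnames(out) <- NULL
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

cell_pairs <- function(x, box, cutoff) {
  xw <- wrap_coords(x, box)
  nc <- pmax(1L, floor(box / cutoff))      # cells per axis, edge >= cutoff
  ci <- pmin(floor(sweep(xw, 2, box / nc, "/")), matrix(nc - 1, nrow(xw), 3,
                                                        byrow = TRUE))
  key <- ci[, 1] + nc[1] * (ci[, 2] + nc[2] * ci[, 3])
  ord <- order(key)
  cells <- split(ord, key[ord])
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- list(); k <- 0
  cell_xyz <- function(key) {
    key <- as.integer(key)
    c(key %% nc[1], (key %/% nc[1]) %% nc[2], key %/% (nc[1] * nc[2]))
  }
  for (ckey in names(cells)) {
    a <- cells[[ckey]]
    cc <- cell_xyz(ckey)
    for (r in seq_len(nrow(offsets))) {
      nb <- (cc + offsets[r, ]) %% nc
      nkey <- as.character(nb[1] + nc[1] * (nb[2] + nc[2] * nb[3]))
      b <- cells[[nkey]]
      if (is.null(b)) next
      if (nkey < ckey) next                 # visit each cell pair once
      if (nkey == ckey) {
        if (!all(offsets[r, ] == 0)) {
          # periodic wrap folded a neighbour offset onto the same cell
          # (happens when an axis has < 3 cells); handled by self pass
          next
        }
        if (length(a) < 2) next
        cand_i <- rep(a, times = length(a))
        cand_j <- rep(a, each = length(a))
        keep <- cand_i < cand_j
        cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
      } else {
        cand_i <- rep(a, times = length(b))
        cand_j <- rep(b, each = length(a))
      }
      if (!length(cand_i)) next
      d <- xw[cand_j, , drop = FALSE] - xw[cand_i, , drop = FALSE]
      bm <- matrix(box, nrow(d), 3, byrow = TRUE)
      d <- d - round(d / bm) * bm
      hit <- rowSums(d * d) <= cutoff^2
      if (any(hit)) {
        k <- k + 1
        ii <- cand_i[hit]; jj <- cand_j[hit]
        sw <- ii > jj
        out[[k]] <- cbind(ifelse(sw, jj, ii), ifelse(sw, ii, jj))
      }
    }
  }
  if (!k) return(matrix(integer(0), 0, 2))
  m <- unique(do.call(rbind, out))
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
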