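# Rigid translation of a 3D volume by a (possibly sub-voxel) shift, with
# trilinear interpolation. out(x) = vol(x - shift); content moves by +shift.
# Voxels whose source lies outside the grid take `fill`.
translate_volume <- function(vol, shift, fill = 0) {
  d <- dim(vol)
  stopifnot(length(d) == 3L, length(shift) == 3L)
  if (all(shift == 0)) return(vol)
  if (all(shift == round(shift))) {
    out <- array(fill, d)
    s <- as.integer(round(shift))
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a]) - s[a]
      i[i >= 1 & i <= d[a]]
    })
    dst <- lapply(1:3, function(a) {
      i <- seq_len(d[a])
      i[i - s[a] >= 1 & i - s[a] <= d[a]]
    })
    if (all(lengths(src) > 0))
      out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
    return(out)
  }
  # trilinear: pad by one fill voxel on each side, clamp invalid corners to pad
  pad <- array(fill, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  lows <- frs <- idx0 <- vector("list", 3)
  for (a in 1:3) {
    x <- seq_len(d[a]) - shift[a]
    l <- floor(x)
    lows[[a]] <- as.integer(l)
    frs[[a]] <- x - l
  }
  corner_index <- function(a, c) {
    i <- lows[[a]] + c
    ifelse(i >= 1 & i <= d[a], i + 1L, 1L)  # 1 = pad cell (fill)
  }
  out <- array(0, d)
  for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
    w1 <- if (c1 == 0) 1 - frs[[1]] else frs[[1]]
    w2 <- if (c2 == 0) 1 - frs[[2]] else frs[[2]]
    w3 <- if (c3 == 0) 1 - frs[[3]] else frs[[3]]
    w <- outer(outer(w1, w2), w3)
    out <- out + w * pad[corner_index(1, c1), corner_index(2, c2), corner_index(3, c3)]
  }
  out
}

# Validity of each voxel after back-projection by `shift`: TRUE where the
# source position lies fully inside the grid (no extrapolated support).
translate_valid <- function(d, shift) {
  ok <- vector("list", 3)
  for (a in 1:3) {
    x <- seq_len(d[a]) - shift[a]
    ok[[a]] <- x >= 1 & x <= d[a]
  }
  outer(outer(ok[[1]], ok[[2]]), ok[[3]])
}
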