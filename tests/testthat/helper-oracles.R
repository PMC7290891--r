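# Independent oracles, deliberately naive: used to cross-check the package's
# vectorized/graph-based implementations.

# 26-connected component labelling by breadth-first flood fill
flood_fill_label_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nxt <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo) > 0) {
    seed <- todo[1]
    nxt <- nxt + 1L
    queue <- seed
    lab[seed] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
    todo <- which(mask & lab == 0L)
  }
  lab
}

# are two labelings the same partition of the foreground?
same_partition <- function(lab1, lab2) {
  f1 <- which(lab1 > 0); f2 <- which(lab2 > 0)
  if (!identical(f1, f2)) return(FALSE)
  key <- paste(lab1[f1], lab2[f2])
  length(unique(key)) == length(unique(lab1[f1])) &&
    length(unique(key)) == length(unique(lab2[f2]))
}

# brute-force stats over voxels whose centres fall inside a sphere
sphere_voxel_stats <- function(arr, voxel_size_mm, center_mm, radius_mm) {
  d <- dim(arr)
  vals <- c()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- (c(i, j, k) - 0.5) * voxel_size_mm
    if (sum((p - center_mm)^2) <= radius_mm^2) vals <- c(vals, arr[i, j, k])
  }
  list(n = length(vals), mean = mean(vals), sd = stats::sd(vals))
}
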