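# Independent brute-force oracles used to cross-check the implementation.

# 8-connected component labeling by explicit stack-based flood fill
flood_fill_label <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    k <- k + 1L
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; c <- p[2]
      if (r < 1 || r > nr || c < 1 || c > nc) next
      if (!mask[r, c] || lab[r, c] > 0L) next
      lab[r, c] <- k
      for (dr in -1:1) for (dc in -1:1)
        if (dr || dc) stack[[length(stack) + 1L]] <- c(r + dr, c + dc)
    }
  }
  lab
}

# maximum achievable TP over all one-to-one assignments, by recursion over
# predictions (feasible for <= 5 instances)
brute_force_tp <- function(iou_matrix, threshold) {
  np <- nrow(iou_matrix); ng <- ncol(iou_matrix)
  best <- 0L
  rec <- function(i, used, tp) {
    if (tp + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, tp); return() }
    rec(i + 1L, used, tp)                          # prediction unassigned
    for (j in seq_len(ng)) if (!used[j] && iou_matrix[i, j] > threshold) {
      used[j] <- TRUE
      rec(i + 1L, used, tp + 1L)
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, ng), 0L)
  best
}

# axis-aligned square instance helper
box_instance <- function(x, y, side = 2, label = "crown", confidence = 1) {
  instance_polygon(cbind(c(x, x + side, x + side, x),
                         c(y, y, y + side, y + side)), label, confidence)
}

noise_free_params <- function(...) {
  p <- orchard_params(...)
  p$reflectance$noise_sd <- 0
  p
}
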