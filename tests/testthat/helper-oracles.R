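# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (flood fill, exhaustive
# enumeration) and never call the implementation paths they check.

# queue-based flood fill, the reference for label_components()
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (o in offs) {
        r2 <- r + o[1]; c2 <- c + o[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- r2 + (c2 - 1L) * nr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# exhaustive sign-flip enumeration for the paired (signed-rank) two-sided p
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# exhaustive group-assignment enumeration for the unpaired (rank-sum)
# two-sided p
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)])
  combs <- utils::combn(length(ranks), n1)
  ws <- apply(combs, 2, function(i) sum(ranks[i]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# per-pixel tally by explicit loop, the reference for class_counts()
oracle_counts <- function(green, red, green_thr = 100, red_thr = 100) {
  v <- n <- b <- 0L
  for (i in seq_along(green)) {
    if (red[i] > red_thr) n <- n + 1L
    else if (green[i] > green_thr && red[i] < red_thr) v <- v + 1L
    else b <- b + 1L
  }
  c(viable = v, nonviable = n, background = b)
}

# build a stack whose classification is exactly a given label matrix/list
# (1 = viable, 2 = non-viable, 0 = background)
stack_from_labels <- function(labels, pixel_size_um = 1, z_step_um = 0.71,
                              nonviable_red = 150, field_id = "helper") {
  if (is.matrix(labels)) labels <- list(labels)
  green <- lapply(labels, function(l) {
    g <- matrix(0, nrow(l), ncol(l)); g[l == 1L] <- 150; g
  })
  red <- lapply(labels, function(l) {
    r <- matrix(0, nrow(l), ncol(l)); r[l == 2L] <- nonviable_red; r
  })
  z_stack(green, red, z_step_um = z_step_um, pixel_size_um = pixel_size_um,
          field_id = field_id)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
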