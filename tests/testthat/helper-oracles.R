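# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

## flood-fill connected components by breadth-first search over an explicit
## neighbor enumeration; returns labels in the package's canonical order
## (decreasing size, ties by lowest linear index)
bfs_components <- function(member, connectivity) {
  dims <- dim(member)
  idx <- which(member)
  sub <- arrayInd(idx, dims)
  lab <- integer(length(member))
  comp <- 0L
  for (start in idx) {
    if (lab[start] > 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cs <- arrayInd(cur, dims)[1, ]
      d <- abs(sweep(sub, 2, cs))
      md <- pmax(d[, 1], d[, 2], d[, 3])
      s <- d[, 1] + d[, 2] + d[, 3]
      is_nb <- switch(as.character(connectivity),
                      "6"  = md <= 1 & s == 1,
                      "18" = md <= 1 & s >= 1 & s <= 2,
                      "26" = md <= 1 & s >= 1)
      new <- idx[is_nb & lab[idx] == 0L]
      lab[new] <- comp
      queue <- c(queue, new)
    }
  }
  ## canonical relabeling
  if (comp > 0L) {
    size <- tabulate(lab[idx], comp)
    first <- vapply(seq_len(comp), function(c) min(idx[lab[idx] == c]), 1L)
    new <- integer(comp)
    new[order(-size, first)] <- seq_len(comp)
    lab[idx] <- new[lab[idx]]
  }
  array(lab, dims)
}

## nearest-rank percentile retention by explicit sort-and-count
sort_and_count_threshold <- function(values, idx, percent, direction) {
  v <- values[idx]
  if (direction == "highest") v <- -v
  k <- ceiling(percent / 100 * length(idx))
  sort(idx[order(v, idx)][seq_len(k)])
}

## textbook Pearson correlation
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

## random mask on a small grid
random_mask <- function(grid, p = 0.25) {
  brain_mask(grid, array(stats::runif(prod(grid$shape)) < p, grid$shape))
}

grid_iso <- function(n, mm = 1) {
  volume_grid(rep(n, 3), diag(c(mm, mm, mm, 1)))
}
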