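## constructed fixtures shared across tests

## thick plus sign: two crossing bars through the centre
plus_mask <- function(n = 21L, bar = 3L) {
  m <- matrix(FALSE, n, n)
  mid <- (n + 1L) %/% 2L
  half <- (bar - 1L) %/% 2L
  m[(mid - half):(mid + half), 2:(n - 1)] <- TRUE
  m[2:(n - 1), (mid - half):(mid + half)] <- TRUE
  m
}

## straight horizontal bar
bar_mask <- function(nr = 20L, nc = 30L, width = 5L) {
  m <- matrix(FALSE, nr, nc)
  mid <- nr %/% 2L
  half <- (width - 1L) %/% 2L
  m[(mid - half):(mid + half), 5:(nc - 4)] <- TRUE
  m
}

## unit-width horizontal line with a short perpendicular spur at its middle
line_with_spur <- function(n = 31L, spur_len = 2L) {
  m <- matrix(FALSE, n, n)
  mid <- (n + 1L) %/% 2L
  m[mid, 3:(n - 2)] <- TRUE
  m[(mid - spur_len):(mid - 1L), mid] <- TRUE
  m
}

## two half-plane cells split by a vertical line after column `split`
two_cell_mask <- function(nr = 40L, nc = 40L, split = 20L) {
  m <- matrix(2L, nr, nc)
  m[, seq_len(split)] <- 1L
  m
}

## disc of cell 1 inside cell 2
disc_mask <- function(n = 81L, radius = 25) {
  mid <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - mid)^2, (seq_len(n) - mid)^2, `+`))
  m <- matrix(2L, n, n)
  m[d <= radius] <- 1L
  m
}

## three cells meeting at a single tricellular point
three_cell_mask <- function(n = 60L) {
  m <- matrix(0L, n, n)
  mid <- n %/% 2L
  m[seq_len(mid), seq_len(mid)] <- 1L
  m[seq_len(mid), (mid + 1L):n] <- 2L
  m[(mid + 1L):n, ] <- 3L
  m
}

## polylines for two crossing straight filaments
crossing_polylines <- function(n = 51L) {
  list(rbind(c(5, 5), c(n - 4, n - 4)),
       rbind(c(n - 4, 5), c(5, n - 4)))
}

expect_same_multiset <- function(a, b) {
  expect_equal(sort(a), sort(b))
}
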