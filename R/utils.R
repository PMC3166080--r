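# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible substream seed from a master seed and a string key
#'
#' Stochastic stages (one per plate/well/site) draw from independent
#' substreams derived by a stable polynomial hash of the master seed and a
#' textual key, so results do not depend on generation order.
#'
#' @param seed Master integer seed.
#' @param ... Character or numeric key components (e.g. plate, well, site).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(key)
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps the hash in exact double range
  for (ch in codes) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# Shift a matrix by (di, dj), padding with `fill`. di > 0 moves content down.
shift_mat <- function(m, di, dj, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_i <- seq_len(nr) - di
  src_j <- seq_len(nc) - dj
  ok_i <- src_i >= 1 & src_i <= nr
  ok_j <- src_j >= 1 & src_j <= nc
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

# 8-connected labelling of a logical matrix.
# EBImage::bwlabel is 4-connected, which splits diagonal skeleton paths,
# so thin-structure labelling goes through igraph components instead.
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  pos <- seq_along(idx)
  lookup <- integer(nr * nc)
  lookup[idx] <- pos
  i0 <- ((idx - 1L) %% nr) + 1L
  j0 <- ((idx - 1L) %/% nr) + 1L
  ea <- integer(0); eb <- integer(0)
  # half the 8-neighbourhood avoids double visits
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    ni <- i0 + d[1L]; nj <- j0 + d[2L]
    ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
    nidx <- (nj[ok] - 1L) * nr + ni[ok]
    hit <- lookup[nidx] > 0L
    ea <- c(ea, pos[ok][hit]); eb <- c(eb, lookup[nidx][hit])
  }
  g <- igraph::make_graph(rbind(ea, eb), n = length(pos), directed = FALSE)
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}
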