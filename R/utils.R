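# internal numeric helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn .data
NULL

# row-wise log-sum-exp of a matrix; rows that are all -Inf return -Inf
logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2L:ncol(m)) mx <- pmax(mx, m[, j])
  out <- mx + log(rowSums(exp(m - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

fwhm_factor <- function() 2 * sqrt(2 * log(2))

# 8-connected component labels of a logical matrix; labels are 1..k in order
# of each component's first pixel (column-major), 0 for background
label_components_8 <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(lab)
  pos <- arrayInd(fg, c(nr, nc))
  idx_of <- integer(nr * nc)
  idx_of[fg] <- seq_along(fg)
  edges <- list()
  # forward half of the 8-neighbourhood is enough for an undirected graph
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1L]; dc <- offs[[k]][2L]
    r2 <- pos[, 1L] + dr
    c2 <- pos[, 2L] + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- idx_of[nb] > 0L
    if (!any(hit)) next
    edges[[k]] <- cbind(which(ok)[hit], idx_of[nb[hit]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel so component ids follow first occurrence in column-major order
  first <- match(unique(memb), memb)
  remap <- integer(max(memb))
  remap[memb[sort(first)]] <- seq_along(first)
  lab[fg] <- remap[memb]
  lab
}

# closed-form eigendecomposition of a 2x2 symmetric matrix, used as an
# independent oracle in tests and kept separate from propose_split()
eigen2_closed_form <- function(s) {
  a <- s[1, 1]; b <- s[1, 2]; d <- s[2, 2]
  tr <- a + d
  disc <- sqrt(((a - d) / 2)^2 + b^2)
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (abs(b) < .Machine$double.eps * max(1, abs(tr))) {
    v1 <- if (a >= d) c(1, 0) else c(0, 1)
  } else {
    v1 <- c(l1 - d, b)
    v1 <- v1 / sqrt(sum(v1^2))
  }
  if (v1[1] < 0 || (v1[1] == 0 && v1[2] < 0)) v1 <- -v1
  list(values = c(l1, l2), vector1 = v1)
}
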