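# Independent oracles used to freeze expected values.

# Unpenalised fractional-response logistic MLE via Newton-Raphson.
newton_fractional_logit <- function(X, y, iter = 200) {
  Z <- cbind(1, X)
  b <- numeric(ncol(Z))
  for (i in seq_len(iter)) {
    mu <- plogis(drop(Z %*% b))
    W <- mu * (1 - mu)
    step <- solve(crossprod(Z, Z * W), crossprod(Z, y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  b
}

# Connected components of suprathreshold voxels via igraph, independent of
# the package's flood fill.
igraph_components <- function(voxels, dims, connectivity = 18) {
  if (!length(voxels)) return(list())
  coords <- arrayInd(voxels, dims)
  n <- length(voxels)
  edges <- c()
  for (i in seq_len(n - 1)) {
    d <- abs(sweep(coords[(i + 1):n, , drop = FALSE], 2, coords[i, ]))
    mx <- apply(d, 1, max)
    sm <- rowSums(d)
    adj <- switch(as.character(connectivity),
                  "6" = sm == 1, "18" = mx == 1 & sm <= 2, "26" = mx == 1)
    for (j in which(adj)) edges <- c(edges, i, i + j)
  }
  g <- igraph::make_graph(edges = as.numeric(edges), n = n,
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  split(voxels, comp)
}

# One-sample t by the textbook formula.
hand_t <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
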