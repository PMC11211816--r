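# Exhaustive-scan oracle for edge supports: plain loops over all
# edges/vertices of the supporting graph, written independently of the
# indexed implementation in the package.

oracle_support_one <- function(g, i, gj, max_ext = 200L) {
  kind <- g$edges$kind[i]; u <- g$edges$from[i]; v <- g$edges$to[i]
  ej <- gj$edges
  if (kind == "junction") {
    d <- g$vs$end[u]; a <- g$vs$start[v]
    for (k in seq_len(nrow(ej)))
      if (ej$kind[k] == "junction" &&
          gj$vs$end[ej$from[k]] == d && gj$vs$start[ej$to[k]] == a)
        return(ej$weight[k])
    return(0)
  }
  if (kind == "adjacent") {
    b <- g$vs$end[u]
    for (k in which(ej$kind == "adjacent"))
      if (gj$vs$end[ej$from[k]] == b) return(ej$weight[k])
    for (k in seq_len(nrow(gj$vs)))
      if (gj$vs$start[k] < b && gj$vs$end[k] > b) return(gj$vs$weight[k])
    return(0)
  }
  if (kind == "source") {
    p <- g$vs$end[v]
    v2 <- NA_integer_
    for (k in seq_len(nrow(gj$vs)))
      if (gj$vs$start[k] < p && p <= gj$vs$end[k]) v2 <- k
    if (is.na(v2)) return(0)
    for (k in which(ej$kind == "source"))
      if (ej$to[k] == v2) return(ej$weight[k])
    for (k in which(ej$kind == "adjacent")) {
      if (ej$to[k] == v2) {
        u2 <- ej$from[k]
        if (p - gj$vs$end[u2] <= max_ext)
          for (m in which(ej$kind == "source"))
            if (ej$to[m] == u2) return(ej$weight[m])
      }
    }
    return(0)
  }
  ## sink (ending edge)
  p <- g$vs$start[u]
  v2 <- NA_integer_
  for (k in seq_len(nrow(gj$vs)))
    if (gj$vs$start[k] <= p && p < gj$vs$end[k]) v2 <- k
  if (is.na(v2)) return(0)
  for (k in which(ej$kind == "sink"))
    if (ej$from[k] == v2) return(ej$weight[k])
  for (k in which(ej$kind == "adjacent")) {
    if (ej$from[k] == v2) {
      w2 <- ej$to[k]
      if (gj$vs$start[w2] - p <= max_ext)
        for (m in which(ej$kind == "sink"))
          if (ej$from[m] == w2) return(ej$weight[m])
    }
  }
  0
}

oracle_supports <- function(g, members, max_ext = 200L) {
  m <- matrix(0, nrow = nrow(g$edges), ncol = length(members))
  for (i in seq_len(nrow(g$edges)))
    for (j in seq_along(members))
      m[i, j] <- oracle_support_one(g, i, members[[j]], max_ext)
  m
}
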