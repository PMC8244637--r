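# Independent geometric and statistical oracles used across tests.

# Exact point-to-triangle distance via plane projection + edge clamping
# (formulation independent of the package's C++ region-based routine).
ref_point_triangle_dist <- function(p, A, B, C) {
  e1 <- B - A
  e2 <- C - A
  w <- p - A
  G <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
  uv <- tryCatch(solve(G, c(sum(w * e1), sum(w * e2))), error = function(e) c(-1, -1))
  if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
    q <- A + uv[1] * e1 + uv[2] * e2
    return(sqrt(sum((p - q)^2)))
  }
  seg <- function(P0, P1) {
    d <- P1 - P0
    t <- sum((p - P0) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (P0 + t * d))^2))
  }
  min(seg(A, B), seg(B, C), seg(C, A))
}

ref_point_mesh_dist <- function(p, vertices, triangles) {
  min(vapply(seq_len(nrow(triangles)), function(t) {
    ref_point_triangle_dist(p, vertices[triangles[t, 1], ],
                            vertices[triangles[t, 2], ],
                            vertices[triangles[t, 3], ])
  }, 0))
}

# Brute-force signature weight: explicit double loop over points and axes.
ref_signature_weight <- function(P, mu, sigma) {
  acc <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      acc <- acc + ((P[i, j] - mu[i, j]) / sigma[i, j])^2
    }
  }
  sqrt(acc)
}

# reflect-and-relabel of a per-vertex field on a template
ref_reflect_field <- function(field, mi) {
  out <- field[mi, , drop = FALSE]
  out[, 1] <- -out[, 1]
  out
}

# small cached template so unit tests do not rebuild meshes repeatedly
template_cache <- new.env(parent = emptyenv())
cached_template <- function(M = 600) {
  key <- paste0("M", M)
  if (is.null(template_cache[[key]])) template_cache[[key]] <- make_template(M)
  template_cache[[key]]
}

# tiny landmark set helper on an arbitrary scheme
toy_landmarks <- function(names, coords) {
  landmark_set(structure(coords, dimnames = list(names, NULL)), scheme = NULL)
}
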