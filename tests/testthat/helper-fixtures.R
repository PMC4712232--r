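# Shared fixtures, memoized so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

tiny_params <- function(seed = 1L) {
  anatomy_params(target_edge = c(torso = 40, heart = 12, lung = 40,
                                 liver = 38, spleen = 22),
                 jitter = 0.2, seed = seed)
}

tiny_vc <- function() memo_fixture("tiny_vc", function() {
  make_synthetic_anatomy(tiny_params())
})

default_vc <- function() memo_fixture("default_vc", function() {
  make_synthetic_anatomy(anatomy_params())
})

scaled_sphere <- function(k, radius, label = "sphere") {
  s <- icosphere(k, label = label)
  s$vertices <- s$vertices * radius
  s
}

# independent generalized winding number (pure R; test oracle)
winding_inside <- function(s, p) {
  a <- sweep(s$vertices[s$triangles[, 1], , drop = FALSE], 2, p)
  b <- sweep(s$vertices[s$triangles[, 2], , drop = FALSE], 2, p)
  c3 <- sweep(s$vertices[s$triangles[, 3], , drop = FALSE], 2, p)
  la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c3^2))
  num <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
         a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
         a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * c3) * lb +
         rowSums(b * c3) * la
  w <- sum(2 * atan2(num, den)) / (4 * pi)
  abs(w) > 0.5
}

# independent ray/triangle oracle: plane intersection + barycentric test
raytri_oracle <- function(o, d, v1, v2, v3) {
  n <- c((v2 - v1)[2] * (v3 - v1)[3] - (v2 - v1)[3] * (v3 - v1)[2],
         (v2 - v1)[3] * (v3 - v1)[1] - (v2 - v1)[1] * (v3 - v1)[3],
         (v2 - v1)[1] * (v3 - v1)[2] - (v2 - v1)[2] * (v3 - v1)[1])
  dn <- sum(n * d)
  if (abs(dn) < 1e-12) return(list(hit = FALSE, t = NA_real_))
  t <- sum(n * (v1 - o)) / dn
  p <- o + t * d
  # solve p - v1 = u (v2 - v1) + v (v3 - v1) by least squares (exact in-plane)
  M <- cbind(v2 - v1, v3 - v1)
  uv <- solve(crossprod(M), crossprod(M, p - v1))
  hit <- t > 1e-9 && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1
  list(hit = hit, t = if (hit) t else NA_real_, u = uv[1], v = uv[2])
}
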